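test_that("sites are located with strand-aware CDS coordinates", {
  g <- toy_genome(1000L)
  ft <- suppressWarnings(features_table(
    name = c("plus", "minus", "minus_i1", "tr1"),
    kind = c("CDS", "CDS", "intron", "tRNA"),
    strand = c("+", "-", "-", "+"),
    exon_starts = list(c(101L, 301L), c(501L, 641L), 581L, 801L),
    exon_ends = list(c(200L, 400L), c(580L, 700L), 640L, 872L),
    parent = c(NA, NA, "minus", NA), genome = g))

  # '+' CDS, exon 2: spliced position continues past exon 1
  loc <- locate_site(310L, ft)
  expect_equal(loc$location_class, "CDS")
  expect_equal(loc$cds_position, 110L)
  expect_equal(loc$codon_position, 2L)

  # '-' CDS counts from its own start codon (the rightmost base)
  loc2 <- locate_site(700L, ft)
  expect_equal(loc2$gene, "minus")
  expect_equal(loc2$cds_position, 1L)
  loc3 <- locate_site(501L, ft)
  expect_equal(loc3$cds_position, 140L)

  # intron label carries the CDS position of the preceding exon base:
  # for this '-' gene the exon upstream in transcript order is [641,700]
  loci <- locate_site(600L, ft)
  expect_equal(loci$location_class, "intron")
  expect_equal(loci$gene, "minusi60")

  expect_equal(locate_site(820L, ft)$location_class, "tRNA")
  expect_equal(locate_site(950L, ft)$location_class, "UTR_or_intergenic")
})

test_that("efficiency fractions render at the printed precision", {
  expect_equal(compute_efficiency(6L, 118L), 6 / 118)
  expect_equal(render_percent(6, 118), "5.1%")
  expect_equal(render_percent(16, 267), "6.0%")
  expect_equal(render_percent(5, 75), "6.7%")
  expect_equal(render_percent(41, 267, digits = 0), "15%")
  expect_equal(render_percent(0, 100), "0.0%")
  expect_error(compute_efficiency(1L, 0L))
})

test_that("codon effects cover start/stop creation and removal", {
  # ACG codon 1 + C2U at position 2 -> ATG, start created
  ce <- codon_effect(2L, "C2U", paste0("ACG", "AAA", "TAA"))
  expect_equal(ce$edited_codon, "ATG")
  expect_true("start_created" %in% ce$codon_effect)

  # TCA + C2U at codon position 2 -> TTA, Ser to Leu missense
  ce2 <- codon_effect(5L, "C2U", paste0("ATG", "TCA", "TAA"))
  expect_equal(ce2$ref_aa, "S")
  expect_equal(ce2$edited_aa, "L")
  expect_equal(ce2$codon_effect, "missense")

  # internal TAA + U2C at codon position 1 -> CAA (Gln), stop removed
  ce3 <- codon_effect(4L, "U2C", paste0("ATG", "TAA", "AAA", "TAA"))
  expect_equal(ce3$edited_codon, "CAA")
  expect_equal(ce3$codon_effect, "stop_removed")

  # CGA + C2U at codon position 1 -> TGA, stop created
  ce4 <- codon_effect(4L, "C2U", paste0("ATG", "CGA", "TAA"))
  expect_equal(ce4$edited_codon, "TGA")
  expect_equal(ce4$codon_effect, "stop_created")

  # a C2U edit needs a C at the position
  expect_error(codon_effect(1L, "C2U", "ATGTAA"), "requires C")
  expect_error(codon_effect(99L, "C2U", "ATGTAA"), "beyond CDS length")
})

test_that("functional effect compares residue identity across species", {
  aln <- protein_alignment("g", c(foc = "MSK", a = "MLK", b = "MLK",
                                  c = "MLK"), "foc")
  # edited aa matches 3/3 others, ref 0/3: conservative
  expect_equal(functional_effect("S", "L", 4L, aln), "conservative")
  # tie (1/3 vs 1/3) is not an improvement
  aln2 <- protein_alignment("g", c(foc = "MSK", a = "MLK", b = "MSK",
                                   c = "MAK"), "foc")
  expect_equal(functional_effect("S", "L", 4L, aln2), "non_conservative")
  # premature stop truncates the protein: non-conservative
  expect_equal(functional_effect("S", "*", 4L, aln), "non_conservative")
  # unchanged amino acid is silent regardless of the alignment
  expect_equal(functional_effect("S", "S", 4L, aln2), "silent")
  # coordinates past the focal row signal an alignment mismatch
  aln3 <- protein_alignment("g", c(foc = "M-K", a = "MLK"), "foc")
  expect_error(functional_effect("S", "L", 10L, aln3), "beyond focal row")
})

test_that("summary table reproduces the printed percentage style", {
  mk_sites <- function(n_c2u, n_u2c, codon_pos = integer(0)) {
    n <- n_c2u + n_u2c
    data.frame(position = seq_len(n),
               edit_type = c(rep("C2U", n_c2u), rep("U2C", n_u2c)),
               location_class = "CDS", gene = "g",
               codon_position = rep_len(c(codon_pos, NA), n),
               codon_effect = NA_character_,
               functional_effect = NA_character_,
               efficiency = 0.5, stringsAsFactors = FALSE)
  }
  s <- mk_sites(297L, 3L)
  s$codon_position <- c(rep(1L, 26), rep(2L, 163), rep(3L, 43),
                        rep(NA, 68))
  s$location_class <- c(rep("CDS", 232), rep("UTR_or_intergenic", 68))
  tab <- summarize_edit_sites(s)
  gp <- function(row) tab$pct[tab$row == row]
  expect_equal(gp("C-to-U"), "99.0%")
  expect_equal(gp("U-to-C"), "1.0%")
  expect_equal(gp("Coding"), "77.3%")
  expect_equal(gp("2nd"), "54.3%")
  # edit-type percentages partition the total
  expect_equal(tab$count[tab$row == "C-to-U"] +
                 tab$count[tab$row == "U-to-C"],
               tab$count[tab$row == "Total"])
  # 17 of 27 second-position sites render as 63.0%
  expect_equal(render_percent(17, 27), "63.0%")
  # empty site list: counts 0, percentages dashed
  tab0 <- summarize_edit_sites(s[0, ])
  expect_true(all(tab0$count == 0L))
  expect_true(all(tab0$pct == "—"))
})

test_that("efficiency by effect reports mean, n and 2xSE per class", {
  sites <- data.frame(
    functional_effect = c("conservative", "conservative", "silent",
                          "non_conservative"),
    efficiency = c(1.0, 1.0, 0.4, 0.1), stringsAsFactors = FALSE)
  eff <- efficiency_by_effect(sites)
  cons <- eff[eff$class == "conservative", ]
  expect_equal(cons$mean_efficiency, 1.0)
  expect_equal(cons$se, 0)
  # single-site class: SE undefined
  expect_true(is.na(eff$se[eff$class == "silent"]))
  # empty class omitted
  expect_false("missing" %in% eff$class)
  expect_equal(nrow(eff), 3L)
})
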