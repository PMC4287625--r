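# a read carrying `alt` at genomic `pos`, placed so the mismatch sits
# at the given distance from the read start (untrimmed)
read_with_dist <- function(genome, pos, alt, dist, id, width = 75L) {
  idx <- dist + 1L
  start <- pos - idx + 1L
  tmpl <- substr(genome$sequence, start, start + width - 1L)
  substr(tmpl, idx, idx) <- alt
  make_read(id, start, sprintf("%dM", width), tmpl)
}

one_call <- function(pos, ref, alt) {
  data.frame(position = pos, ref = ref, alt = alt, category = paste0(ref, ":", alt),
             edit_type = "NONEDIT", strand = "*", depth = NA_integer_,
             support = NA_integer_, frequency = NA_real_, trims = "0",
             stringsAsFactors = FALSE)
}

test_that("heteroplasmy rule flags polymorphic DNA and respects bounds", {
  g <- toy_genome(300L)
  pos <- 150L
  ref <- genome_base(g, pos)
  alt <- setdiff(c("A","C","G","T"), ref)[1]
  call <- one_call(pos, ref, alt)
  t <- filter_thresholds()

  dna <- function(n_ref, n_alt) {
    build_pileup(bind_reads(
      reads_with_base_at(g, pos, ref, n_ref, prefix = "d"),
      reads_with_base_at(g, pos, alt, n_alt, prefix = "a")), g)
  }
  # 16/80 alt (20%): heteroplasmy
  fl <- detect_heteroplasmy(call, dna(64L, 16L), t)
  expect_equal(fl$category, "HETEROPLASMY")
  # clean DNA: no flag
  expect_null(detect_heteroplasmy(call, dna(80L, 0L), t))
  # 78/80 alt (97.5%): beyond the heteroplasmy band (reference error)
  expect_null(detect_heteroplasmy(call, dna(2L, 78L), t))
  # insufficient DNA coverage: undetermined, with a note
  und <- detect_heteroplasmy(call, dna(1L, 1L), t)
  expect_equal(nrow(und), 0L)
  expect_match(attr(und, "note"), "insufficient DNA coverage")
})

test_that("end-bias rule requires every supporting read near an end", {
  g <- toy_genome(300L)
  pos <- 150L
  ref <- genome_base(g, pos)
  alt <- setdiff(c("A","C","G","T"), ref)[1]
  call <- one_call(pos, ref, alt)
  t <- filter_thresholds()

  mk <- function(dists) {
    build_pileup(do.call(bind_reads, c(
      lapply(seq_along(dists), function(i)
        read_with_dist(g, pos, alt, dists[i], sprintf("e%d", i))),
      list(reads_with_base_at(g, pos, ref, 10L, prefix = "c")))), g)
  }
  expect_equal(detect_end_bias(call, mk(c(0L, 2L, 3L, 5L, 6L)), t)$category,
               "END_BIAS")
  # one supporting read far from the end defeats the flag
  expect_null(detect_end_bias(call, mk(c(0L, 2L, 3L, 5L, 30L)), t))
  # degenerate single-read case at the 6 bp boundary (inclusive)
  expect_equal(detect_end_bias(call, mk(6L), t)$category, "END_BIAS")
  # missing metadata is an error
  clean <- build_pileup(reads_with_base_at(g, pos, ref, 5L), g)
  expect_error(detect_end_bias(call, clean, t), "no end-distance")
})

test_that("junction rule flags mismapped spliced reads but not intron edits", {
  set.seed(33)
  g <- toy_genome(400L, seed = 33)
  ft <- features_table(
    name = c("gA", "gA_i1"), kind = c("CDS", "intron"),
    strand = c("+", "+"),
    exon_starts = list(c(101L, 181L), 131L),
    exon_ends = list(c(130L, 210L), 180L),
    parent = c(NA, "gA"), genome = g)
  t <- filter_thresholds()
  # find intron offsets where exon2 differs from the intron
  d_mm <- which(vapply(1:8, function(d)
    genome_base(g, 180L + d) != genome_base(g, 130L + d), TRUE))
  expect_true(length(d_mm) >= 1L)
  d1 <- d_mm[1]
  p <- 130L + d1
  alt <- genome_base(g, 180L + d1)

  # three spliced reads mismapped contiguously across the boundary:
  # 16 exon bases then 8 bases of exon2 content over the intron
  mmread <- function(id) {
    bases <- paste0(substr(g$sequence, 115L, 130L),
                    substr(g$sequence, 181L, 188L))
    make_read(id, 115L, "24M", bases)
  }
  reads <- bind_reads(mmread("j1"), mmread("j2"), mmread("j3"))
  pl <- build_pileup(reads, g)
  call <- one_call(p, genome_base(g, p), alt)
  fl <- detect_junction_artifact(call, ft, g, reads, pl, t)
  expect_equal(fl$category, "JUNCTION")
  # every mismapped intron offset is flagged
  for (d in d_mm) {
    cd <- one_call(130L + d, genome_base(g, 130L + d),
                   genome_base(g, 180L + d))
    expect_equal(detect_junction_artifact(cd, ft, g, reads, pl, t)$category,
                 "JUNCTION")
  }

  # a genuine intron edit: supporting reads lie inside the intron and
  # never cross the boundary, so spliced re-interpretation explains
  # nothing
  ep <- 150L
  eref <- genome_base(g, ep)
  ealt <- setdiff(c("A","C","G","T"), eref)[1]
  ereads <- reads_with_base_at(g, ep, ealt, 4L, prefix = "ed")
  epl <- build_pileup(ereads, g)
  ecall <- one_call(ep, eref, ealt)
  expect_null(detect_junction_artifact(ecall, ft, g, ereads, epl, t))

  # far from any boundary: never a junction artifact
  far <- one_call(350L, genome_base(g, 350L), "A")
  expect_null(detect_junction_artifact(far, ft, g, reads, pl, t))
})

test_that("reference-error rule requires DNA consensus plus RNA agreement", {
  g <- toy_genome(300L)
  pos <- 150L
  ref <- genome_base(g, pos)
  alt <- setdiff(c("A","C","G","T"), ref)[1]
  call <- one_call(pos, ref, alt)
  t <- filter_thresholds()
  dna <- function(n_ref, n_alt) {
    build_pileup(bind_reads(
      reads_with_base_at(g, pos, ref, n_ref, prefix = "d"),
      reads_with_base_at(g, pos, alt, n_alt, prefix = "a")), g)
  }
  rna_alt <- build_pileup(reads_with_base_at(g, pos, alt, 10L), g)

  # DNA 49/50 alt and RNA majority alt: genome error with correction
  res <- detect_reference_error(call, dna(1L, 49L), rna_alt, t)
  expect_equal(res$flag$category, "REF_ERROR")
  expect_equal(res$correction,
               data.frame(position = pos, old_base = ref, new_base = alt,
                          stringsAsFactors = FALSE))
  # balanced DNA: a true edit candidate, not a reference error
  expect_null(detect_reference_error(call, dna(25L, 25L), rna_alt, t))
  # 60% DNA consensus: below the 0.9 bar, left to heteroplasmy logic
  expect_null(detect_reference_error(call, dna(20L, 30L), rna_alt, t))
})

test_that("filter_calls partitions calls and never rescues flagged ones", {
  calls <- rbind(one_call(10L, "C", "T"), one_call(20L, "A", "C"),
                 one_call(30L, "G", "A"))
  flags <- data.frame(position = c(20L, 20L), alt = c("C", "C"),
                      category = c("END_BIAS", "HETEROPLASMY"),
                      evidence = "", stringsAsFactors = FALSE)
  fc <- filter_calls(calls, list(flags = flags,
                                 corrections = data.frame()))
  expect_equal(fc$curated$position, c(10L, 30L))
  expect_equal(fc$rejected$position, 20L)
  expect_equal(fc$rejected$categories, "END_BIAS,HETEROPLASMY")

  # no flags anywhere: identity
  none <- filter_calls(calls, list(flags = flags[0, ],
                                   corrections = data.frame()))
  expect_equal(none$curated, calls)
  expect_equal(nrow(none$rejected), 0L)
})
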