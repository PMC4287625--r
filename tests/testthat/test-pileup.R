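test_that("pileup columns follow the CIGAR and trim treatment", {
  g <- toy_genome(500L)
  r <- make_read("a", 10L, "75M", substr(g$sequence, 10, 84))

  p0 <- build_pileup(r, g, trim = 0L)
  expect_equal(sum(p0$depth), 75L)
  expect_equal(which(p0$depth == 1L), 10:84)

  # trim 6: the first and last 6 read bases contribute nowhere
  p6 <- build_pileup(r, g, trim = 6L)
  expect_equal(which(p6$depth == 1L), 16:78)
  expect_equal(sum(p6$depth), 63L)

  # spliced read: no depth under the N gap
  rs <- make_read("b", 10L, "30M100N45M", substr(g$sequence, 10, 84))
  ps <- build_pileup(rs, g, trim = 0L)
  expect_equal(which(ps$depth == 1L), c(10:39, 140:184))

  # trim must stay below half the read length
  expect_error(build_pileup(r, g, trim = 38L), "half the read length")
})

test_that("pileup agrees with a naive per-read CIGAR walk oracle", {
  set.seed(101)
  g <- toy_genome(200L)
  # random reads over ops M/I/D/N/S
  rand_read <- function(id) {
    start <- sample(1:60, 1)
    ops <- c("M")
    lens <- c(sample(10:15, 1))
    for (k in 1:sample(1:2, 1)) {
      op <- sample(c("M", "I", "D", "N", "S"), 1)
      ops <- c(ops, op, "M")
      lens <- c(lens, sample(2:6, 1), sample(5:10, 1))
    }
    nread <- sum(lens[ops %in% c("M", "I", "S")])
    bases <- paste(sample(c("A", "C", "G", "T"), nread, replace = TRUE),
                   collapse = "")
    make_read(id, start, paste0(lens, ops, collapse = ""), bases)
  }
  reads <- do.call(bind_reads, lapply(sprintf("r%02d", 1:15), rand_read))
  p <- build_pileup(reads, g, trim = 0L)

  # independent oracle: re-walk every CIGAR character by character
  counts <- matrix(0L, g$length, 4, dimnames = list(NULL, c("A","C","G","T")))
  for (i in seq_len(nrow(reads))) {
    toks <- regmatches(reads$cigar[i],
                       gregexpr("[0-9]+[A-Z]", reads$cigar[i]))[[1]]
    gp <- reads$start[i]; rp <- 1L
    for (t in toks) {
      op <- substr(t, nchar(t), nchar(t))
      len <- as.integer(substr(t, 1, nchar(t) - 1L))
      if (op == "M") {
        for (k in seq_len(len)) {
          b <- substr(reads$bases[i], rp, rp)
          if (gp <= g$length) counts[gp, b] <- counts[gp, b] + 1L
          gp <- gp + 1L; rp <- rp + 1L
        }
      } else if (op %in% c("I", "S")) rp <- rp + len
      else gp <- gp + len
    }
  }
  expect_equal(unname(p$counts), unname(counts))
})

test_that("mismatch support records untrimmed end distances", {
  g <- toy_genome(500L)
  seqs <- substr(g$sequence, 10, 84)
  substr(seqs, 3, 3) <- setdiff(c("A","C","G","T"),
                                genome_base(g, 12L))[1]
  r <- make_read("a", 10L, "75M", seqs)
  p <- build_pileup(r, g, trim = 0L)
  sup <- p$support[p$support$position == 12L]
  expect_equal(nrow(sup), 1L)
  expect_equal(sup$dist, 2L)   # third base from the read start
})

test_that("mismatch typing follows category and feature strand", {
  ck <- function(ref, alt, strand) classify_mismatch(ref, alt, strand)
  expect_equal(ck("C", "T", "+")[c("category", "edit_type", "inferred_strand")],
               list(category = "C:T", edit_type = "C2U", inferred_strand = "+"))
  expect_equal(ck("G", "A", "-")$edit_type, "C2U")
  expect_equal(ck("T", "C", "+")$edit_type, "U2C")
  expect_equal(ck("A", "G", "-")$edit_type, "U2C")
  expect_equal(ck("A", "C", "+")$edit_type, "NONEDIT")
  # editing-shaped category on the wrong strand is not editing
  expect_equal(ck("C", "T", "-")$edit_type, "NONEDIT")
  # unknown strand infers the strand from the category
  expect_equal(ck("G", "A", "*")[c("edit_type", "inferred_strand")],
               list(edit_type = "C2U", inferred_strand = "-"))
  expect_error(ck("C", "C", "+"), "equals")
})

test_that("union across trims keeps any-treatment calls with trim-0 counts", {
  g <- toy_genome(300L)
  # 20 reads matching the reference, 3 carrying an alt at position 150,
  # one of them only near a read end so trims disagree
  alt <- setdiff(c("A","C","G","T"), genome_base(g, 150L))[1]
  clean <- reads_with_base_at(g, 150L, genome_base(g, 150L), 20L,
                              prefix = "c")
  mm <- reads_with_base_at(g, 150L, alt, 3L, prefix = "m")
  reads <- bind_reads(clean, mm)
  cw <- call_with_trims(reads, g)
  expect_equal(cw$calls$position, 150L)
  expect_equal(cw$calls$alt, alt)
  expect_equal(cw$calls$depth, 23L)   # reported from trim 0
  expect_equal(cw$calls$support, 3L)

  # empty input maps union to empty output
  u <- union_across_trims(list(`0` = cw$calls[0, ]), cw$pileup0)
  expect_equal(nrow(u), 0L)
})
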