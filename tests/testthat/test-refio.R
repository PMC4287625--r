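test_that("genome FASTA round-trips and validation catches bad input", {
  g <- toy_genome(1000L)
  fa <- withr::local_tempfile(fileext = ".fa")
  write_genome(g, fa)
  g2 <- load_genome(fa)
  expect_identical(g2$sequence, g$sequence)
  expect_identical(g2$length, 1000L)

  # non-ACGT character with its position
  bad <- g$sequence
  substr(bad, 7, 7) <- "N"
  writeLines(c(">x", bad), fa)
  expect_error(load_genome(fa), "position 7")

  # multi-record file
  writeLines(c(">a", "ACGT", ">b", "ACGT"), fa)
  expect_error(load_genome(fa), "expected 1 sequence, found 2")
})

test_that("annotation TSV round-trips with exon structure intact", {
  g <- toy_genome(1000L)
  ft <- features_table(
    name = c("geneA", "geneA_i1"), kind = c("CDS", "intron"),
    strand = c("+", "+"),
    exon_starts = list(c(101L, 301L), 203L),
    exon_ends = list(c(202L, 399L), 300L),
    parent = c(NA, "geneA"), genome = g)
  expect_equal(sum(ft$exon_ends[[1]] - ft$exon_starts[[1]] + 1L), 201L)
  expect_equal(ft$parent[2], "geneA")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotation(ft, path)
  ft2 <- load_annotation(path, g)
  expect_equal(ft2$name, ft$name)
  expect_equal(ft2$exon_starts[[1]], ft$exon_starts[[1]])
  expect_equal(ft2$exon_ends[[2]], ft$exon_ends[[2]])

  # exon beyond genome end
  expect_error(
    features_table("g", "CDS", "+", list(1500L), list(2000L), genome = g),
    "outside genome")
  # CDS length not divisible by 3: kept, with a warning
  expect_warning(
    features_table("g", "CDS", "+", list(1L), list(100L), genome = g),
    "not a multiple of 3")
})

test_that("GFF3 annotation is accepted", {
  skip_if_not_installed("rtracklayer")
  g <- toy_genome(1000L)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "toy\t.\tCDS\t101\t202\t.\t+\t0\tID=geneA.1;Name=geneA",
    "toy\t.\tCDS\t301\t399\t.\t+\t0\tID=geneA.2;Name=geneA",
    "toy\t.\tintron\t203\t300\t.\t+\t.\tID=geneA.i1;Parent=geneA"),
    gff)
  ft <- load_annotation(gff, g)
  cds <- ft[ft$kind == "CDS", ]
  expect_equal(cds$exon_starts[[1]], c(101L, 301L))
  expect_equal(ft$parent[ft$kind == "intron"], "geneA")
})

test_that("SAM reading validates records and counts skips", {
  g <- toy_genome(500L)
  sam <- withr::local_tempfile(fileext = ".sam")
  q75 <- strrep("I", 75)
  b75 <- substr(g$sequence, 10, 84)
  writeLines(c(
    "@HD\tVN:1.6",
    sprintf("@SQ\tSN:toy\tLN:%d", g$length),
    sprintf("r1\t0\ttoy\t10\t60\t75M\t*\t0\t0\t%s\t%s", b75, q75),
    sprintf("r2\t0\ttoy\t10\t60\t30M100N45M\t*\t0\t0\t%s\t%s", b75, q75),
    sprintf("r3\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t%s", b75, q75)),
    sam)
  reads <- load_alignments(sam, "RNA", g)
  expect_equal(nrow(reads), 2L)
  expect_equal(attr(reads, "skipped")[["unmapped"]], 1L)
  # 75M at pos 10 spans [10, 84]
  w <- editscan:::walk_cigar(reads$start[1], reads$cigar[1])
  expect_equal(range(w$pos), c(10L, 84L))
  # spliced read: two blocks separated by 100 bp
  w2 <- editscan:::walk_cigar(reads$start[2], reads$cigar[2])
  expect_equal(w2$pos, c(10:39, 140:184))

  # unsupported CIGAR op
  writeLines(c(
    sprintf("@SQ\tSN:toy\tLN:%d", g$length),
    sprintf("r1\t0\ttoy\t10\t60\t70M5H\t*\t0\t0\t%s\t%s",
            substr(b75, 1, 70), strrep("I", 70))), sam)
  expect_error(load_alignments(sam, "RNA", g), "unsupported CIGAR op 'H'")

  # reference-name mismatch
  writeLines(c(
    sprintf("@SQ\tSN:toy\tLN:%d", g$length),
    sprintf("r1\t0\tother\t10\t60\t75M\t*\t0\t0\t%s\t%s", b75, q75)), sam)
  expect_error(load_alignments(sam, "RNA", g), "expected 'toy'")

  # spliced DNA reads are rejected
  writeLines(c(
    sprintf("@SQ\tSN:toy\tLN:%d", g$length),
    sprintf("r1\t0\ttoy\t10\t60\t30M100N45M\t*\t0\t0\t%s\t%s", b75, q75)),
    sam)
  expect_error(load_alignments(sam, "DNA", g), "spliced")
})

test_that("SAM writing round-trips reads", {
  g <- toy_genome(500L)
  reads <- bind_reads(
    make_read("a", 10L, "75M", substr(g$sequence, 10, 84)),
    make_read("b", 50L, "30M100N45M", substr(g$sequence, 50, 124),
              is_reverse = TRUE))
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(reads, g, sam)
  back <- load_alignments(sam, "RNA", g)
  expect_equal(back$read_id, reads$read_id)
  expect_equal(back$cigar, reads$cigar)
  expect_equal(back$bases, reads$bases)
  expect_equal(back$is_reverse, reads$is_reverse)
})

test_that("reference corrections validate, compose and are idempotent", {
  g <- toy_genome(100L)
  expect_identical(apply_corrections(g, NULL)$sequence, g$sequence)

  old50 <- genome_base(g, 50L)
  new50 <- setdiff(c("A", "C", "G", "T"), old50)[1]
  corr <- data.frame(position = 50L, old_base = old50, new_base = new50)
  g2 <- apply_corrections(g, corr)
  expect_identical(genome_base(g2, 50L), new50)
  expect_identical(substr(g2$sequence, 1, 49), substr(g$sequence, 1, 49))
  expect_identical(substr(g2$sequence, 51, 100), substr(g$sequence, 51, 100))

  # stale old_base errors
  expect_error(apply_corrections(g2, corr), "stale correction")

  # batch equals one-at-a-time
  old70 <- genome_base(g, 70L)
  new70 <- setdiff(c("A", "C", "G", "T"), old70)[1]
  corr2 <- data.frame(position = c(50L, 70L),
                      old_base = c(old50, old70),
                      new_base = c(new50, new70))
  batch <- apply_corrections(g, corr2)
  seq_wise <- apply_corrections(apply_corrections(g, corr2[1, ]),
                                corr2[2, ])
  expect_identical(batch$sequence, seq_wise$sequence)
})

test_that("protein alignments load and map CDS positions to columns", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">spA", "MKL-V", ">spB", "MKLQV", ">spC", "M-LQV"), fa)
  aln <- load_protein_alignment(fa, focal_species = "spA", gene = "g1")
  expect_equal(aln$gene, "g1")
  # spA has 4 residues -> CDS length 15 with stop
  map <- build_homology_map(aln, c(spA = 15L, spB = 18L, spC = 15L))
  # identity-for-ungapped: spA codon 4 sits in column 5
  expect_equal(editscan:::map_cds_position(map, "spA", 10L)$column, 5L)
  expect_equal(editscan:::map_cds_position(map, "spA", 10L)$offset, 1L)
  # spB codon 4 sits in column 4 (spA's gap column)
  expect_equal(editscan:::map_cds_position(map, "spB", 11L)$column, 4L)
  # declared CDS length inconsistent with the row
  expect_error(build_homology_map(aln, c(spA = 18L, spB = 18L, spC = 15L)),
               "spA")
})
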