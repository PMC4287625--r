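# Shared fixtures: everything is built in code at test time.

# deterministic toy genome
toy_genome <- function(len = 200L, seed = 7L) {
  set.seed(seed)
  ref_genome("toy", paste(sample(c("A", "C", "G", "T"), len,
                                 replace = TRUE), collapse = ""))
}

# one-row aligned_reads constructor
make_read <- function(read_id, start, cigar, bases, source = "RNA",
                      is_reverse = FALSE) {
  out <- data.frame(read_id = read_id, source = source, start = start,
                    cigar = cigar, bases = bases,
                    is_reverse = is_reverse, stringsAsFactors = FALSE)
  class(out) <- c("aligned_reads", "data.frame")
  out
}

bind_reads <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  class(out) <- c("aligned_reads", "data.frame")
  out
}

# n identical-position reads carrying `base` at genomic position pos,
# embedded mid-read in a reference-matching 31-mer
reads_with_base_at <- function(genome, pos, base, n, offset = 15L,
                               prefix = "r") {
  start <- pos - offset
  width <- 31L
  tmpl <- substr(genome$sequence, start, start + width - 1L)
  seqs <- rep(tmpl, n)
  substr(seqs, offset + 1L, offset + 1L) <- base
  out <- data.frame(read_id = if (n) sprintf("%s%03d", prefix, seq_len(n))
                    else character(0),
                    source = rep("RNA", n),
                    start = rep(start, n),
                    cigar = rep(sprintf("%dM", width), n), bases = seqs,
                    is_reverse = rep(FALSE, n), stringsAsFactors = FALSE)
  class(out) <- c("aligned_reads", "data.frame")
  out
}

# small simulated dataset shared by several test files (cached)
.small_sim_cache <- new.env(parent = emptyenv())

small_sim_config <- function(seed = 11L, n_edit_sites = 12L,
                             n_heteroplasmy = 2L, n_ref_errors = 1L,
                             n_end_bias = 2L, ...) {
  g <- default_sim_genes()
  g <- g[g$name %in% c("psbA", "rpoB", "clpP", "trnV"), ]
  sim_config(seed = seed, genome_length = 7000L, genes = g,
             rna_mean_depth = 50, dna_mean_depth = 30,
             n_edit_sites = n_edit_sites,
             n_heteroplasmy = n_heteroplasmy,
             n_ref_errors = n_ref_errors, n_end_bias = n_end_bias, ...)
}

small_sim <- function() {
  if (is.null(.small_sim_cache$sim)) {
    .small_sim_cache$sim <- simulate_dataset(small_sim_config())
  }
  .small_sim_cache$sim
}

# single-gene exon-only config for efficiency/calibration tests
flat_sim_config <- function(seed, rna_mean_depth = 110,
                            n_edit_sites = 10L, ...) {
  g <- default_sim_genes()
  g <- g[g$name == "psbA", ]
  sim_config(seed = seed, genome_length = 2500L, genes = g,
             rna_mean_depth = rna_mean_depth, dna_mean_depth = 0,
             n_edit_sites = n_edit_sites, n_heteroplasmy = 0L,
             n_ref_errors = 0L, n_end_bias = 0L,
             precursor_fraction = 0, ...)
}

# mirror transform: reverse-complement the genome, reads and features;
# written independently of the package internals so it can serve as a
# strand-symmetry oracle
mirror_genome <- function(genome) {
  ref_genome(genome$seq_id, revcomp(genome$sequence),
             circular = genome$circular)
}

mirror_cigar <- function(cigar) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[A-Z]", cigar))[[1]]
  paste(rev(toks), collapse = "")
}

mirror_reads <- function(reads, L) {
  ends <- vapply(seq_len(nrow(reads)), function(i) {
    toks <- regmatches(reads$cigar[i],
                       gregexpr("[0-9]+[A-Z]", reads$cigar[i]))[[1]]
    op <- substr(toks, nchar(toks), nchar(toks))
    len <- as.integer(substr(toks, 1, nchar(toks) - 1L))
    reads$start[i] + sum(len[op %in% c("M", "D", "N")]) - 1L
  }, 1L)
  out <- reads
  out$start <- L + 1L - ends
  out$cigar <- vapply(reads$cigar, mirror_cigar, "")
  out$bases <- revcomp(reads$bases)
  out$is_reverse <- !reads$is_reverse
  class(out) <- c("aligned_reads", "data.frame")
  out
}

mirror_features <- function(features, L) {
  out <- features
  for (i in seq_len(nrow(features))) {
    s <- features$exon_starts[[i]]; e <- features$exon_ends[[i]]
    out$exon_starts[[i]] <- rev(L + 1L - e)
    out$exon_ends[[i]] <- rev(L + 1L - s)
  }
  out$strand <- ifelse(features$strand == "+", "-", "+")
  out
}
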