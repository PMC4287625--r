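#' @import data.table
NULL

# one row per M-aligned base of every read:
# position, idx (1-based index in the stored read string), read row,
# base, read length, distance to the nearer untrimmed read end
expand_alignments <- function(reads) {
  n <- nrow(reads)
  if (n == 0L) {
    return(data.table::data.table(position = integer(0), idx = integer(0),
                                  row = integer(0), base = character(0),
                                  read_len = integer(0), dist = integer(0)))
  }
  walks <- vector("list", n)
  for (i in seq_len(n)) {
    w <- walk_cigar(reads$start[i], reads$cigar[i])
    walks[[i]] <- data.table::data.table(position = w$pos, idx = w$idx,
                                         row = i)
  }
  dt <- data.table::rbindlist(walks)
  dt[, base := substring(reads$bases[row], idx, idx)]
  dt[, read_len := nchar(reads$bases)[row]]
  dt[, dist := pmin(idx - 1L, read_len - idx)]
  dt
}

#' Build a per-position pileup from aligned RNA or DNA reads
#'
#' Counts the read base aligned over every reference position. With
#' `trim > 0`, the first and last `trim` bases of every read (in stored
#' read coordinates; trimming is symmetric so physical and stored
#' orientation agree) contribute to no column. Deleted and
#' intron-skipped reference positions get no base from that read;
#' inserted bases contribute nowhere. End distances of mismatch
#' supporting reads are always measured on the untrimmed read.
#'
#' @param reads an `aligned_reads` data.frame.
#' @param genome the `ref_genome` (supplies reference bases).
#' @param trim bases masked at each read end (0, 6, 12 in the default
#'   treatments). Must be less than half the shortest read.
#' @return object of class `pileup`: per-position base-count matrix,
#'   depths, and a `support` table of every non-reference base with
#'   its supporting read and end distance.
#' @export
build_pileup <- function(reads, genome, trim = 0L) {
  exp <- expand_alignments(reads)
  pileup_from_expansion(exp, reads, genome, trim)
}

pileup_from_expansion <- function(exp, reads, genome, trim = 0L) {
  trim <- as.integer(trim)
  stopifnot(trim >= 0L)
  if (nrow(exp) && trim > 0L) {
    if (2L * trim >= min(exp$read_len)) {
      stop(sprintf("trim %d is at least half the read length %d",
                   trim, min(exp$read_len)))
    }
    keep <- exp$idx > trim & exp$idx <= exp$read_len - trim
    exp <- exp[keep]
  }
  L <- genome$length
  counts <- matrix(0L, nrow = L, ncol = 4L,
                   dimnames = list(NULL, DNA_BASES))
  if (nrow(exp)) {
    tab <- exp[base %chin% DNA_BASES,
               .N, by = .(position, base)]
    counts[cbind(tab$position, match(tab$base, DNA_BASES))] <- tab$N
  }
  depth <- as.integer(rowSums(counts))
  refv <- substring(genome$sequence, seq_len(L), seq_len(L))
  if (nrow(exp)) {
    sup <- exp[base %chin% DNA_BASES & base != refv[position],
               .(position, base, read_id = reads$read_id[row],
                 dist)]
  } else {
    sup <- data.table::data.table(position = integer(0), base = character(0),
                                  read_id = character(0), dist = integer(0))
  }
  structure(list(seq_id = genome$seq_id, length = L, trim = trim,
                 ref = refv, counts = counts, depth = depth,
                 support = sup),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> %s: %d bp, trim %d, %d covered positions, %d mismatch-supporting bases\n",
              x$seq_id, x$length, x$trim, sum(x$depth > 0), nrow(x$support)))
  invisible(x)
}

# counts for one position as a named vector
pileup_counts_at <- function(pileup, position) {
  stats::setNames(pileup$counts[position, ], DNA_BASES)
}

# end distances of the reads supporting (position, alt)
support_distances <- function(pileup, pos, alt_base) {
  s <- pileup$support[position == pos & base == alt_base]
  stats::setNames(s$dist, s$read_id)
}
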