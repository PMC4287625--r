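SUPPORTED_CIGAR_OPS <- c("M", "I", "D", "N", "S")

# parse "30M100N45M" -> list(op = c("M","N","M"), len = c(30,100,45))
parse_cigar <- function(cigar) {
  m <- gregexpr("[0-9]+[A-Z=]", cigar)[[1]]
  if (m[1] == -1L) stop(sprintf("malformed CIGAR '%s'", cigar))
  toks <- regmatches(cigar, gregexpr("[0-9]+[A-Z=]", cigar))[[1]]
  op <- substr(toks, nchar(toks), nchar(toks))
  len <- as.integer(substr(toks, 1L, nchar(toks) - 1L))
  if (sum(nchar(toks)) != nchar(cigar)) {
    stop(sprintf("malformed CIGAR '%s'", cigar))
  }
  bad <- setdiff(op, SUPPORTED_CIGAR_OPS)
  if (length(bad)) {
    stop(sprintf("unsupported CIGAR op '%s' in '%s'", bad[1], cigar))
  }
  list(op = op, len = len)
}

# genomic position and read index of every M-aligned base
walk_cigar <- function(start, cigar) {
  cg <- parse_cigar(cigar)
  pos <- integer(0); idx <- integer(0)
  g <- start; r <- 1L
  for (k in seq_along(cg$op)) {
    l <- cg$len[k]
    switch(cg$op[k],
      M = { pos <- c(pos, g:(g + l - 1L)); idx <- c(idx, r:(r + l - 1L))
            g <- g + l; r <- r + l },
      I = { r <- r + l },
      S = { r <- r + l },
      D = { g <- g + l },
      N = { g <- g + l })
  }
  list(pos = pos, idx = idx, end = g - 1L)
}

reference_span <- function(start, cigar) {
  cg <- parse_cigar(cigar)
  start + sum(cg$len[cg$op %in% c("M", "D", "N")]) - 1L
}

#' Read aligned reads from a SAM file
#'
#' Unmapped, secondary and supplementary records are skipped and
#' counted (see the `skipped` attribute of the result). CIGAR strings
#' are restricted to M/I/D/N/S; any other op is an error. Spliced (N)
#' alignments are only accepted for RNA reads. Reads whose reference
#' span extends past the genome end are rejected: origin-wrapping
#' alignments on the circular plastid genome are not supported.
#'
#' @param path SAM file (text).
#' @param source "RNA" or "DNA".
#' @param genome optional `ref_genome`; if given, the reference name of
#'   every record (and of the @SQ header) must match `genome$seq_id`
#'   and spans are validated.
#' @return a data.frame of class `aligned_reads` with columns
#'   `read_id`, `source`, `start`, `cigar`, `bases`, `is_reverse`.
#' @export
load_alignments <- function(path, source = c("RNA", "DNA"), genome = NULL) {
  source <- match.arg(source)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (!is.null(genome)) {
    sq <- hdr[startsWith(hdr, "@SQ")]
    if (length(sq) &&
        !any(grepl(paste0("SN:", genome$seq_id, "(\t|$)"), sq))) {
      stop(sprintf("SAM header names no reference '%s'", genome$seq_id))
    }
  }
  skipped <- c(unmapped = 0L, secondary = 0L, supplementary = 0L)
  if (length(body) == 0L) {
    out <- data.frame(read_id = character(0), source = character(0),
                      start = integer(0), cigar = character(0),
                      bases = character(0), is_reverse = logical(0))
    attr(out, "skipped") <- skipped
    class(out) <- c("aligned_reads", "data.frame")
    return(out)
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2]), 1L)
  keep <- rep(TRUE, length(f))
  unm <- bitwAnd(flag, 4L) > 0L
  sec <- bitwAnd(flag, 256L) > 0L
  sup <- bitwAnd(flag, 2048L) > 0L
  skipped <- c(unmapped = sum(unm), secondary = sum(sec & !unm),
               supplementary = sum(sup & !unm & !sec))
  keep <- !(unm | sec | sup)
  f <- f[keep]; flag <- flag[keep]
  rname <- vapply(f, `[`, "", 3L)
  if (!is.null(genome) && any(rname != genome$seq_id)) {
    i <- which(rname != genome$seq_id)[1]
    stop(sprintf("read %s aligned to reference '%s', expected '%s'",
                 f[[i]][1], rname[i], genome$seq_id))
  }
  out <- data.frame(
    read_id = vapply(f, `[`, "", 1L),
    source = source,
    start = vapply(f, function(x) as.integer(x[4]), 1L),
    cigar = vapply(f, `[`, "", 6L),
    bases = toupper(vapply(f, `[`, "", 10L)),
    is_reverse = bitwAnd(flag, 16L) > 0L,
    stringsAsFactors = FALSE)
  validate_reads(out, source, genome)
  attr(out, "skipped") <- skipped
  class(out) <- c("aligned_reads", "data.frame")
  out
}

validate_reads <- function(reads, source, genome = NULL) {
  for (i in seq_len(nrow(reads))) {
    cg <- parse_cigar(reads$cigar[i])
    if (source == "DNA" && "N" %in% cg$op) {
      stop(sprintf("read %s: spliced (N) alignment in DNA source",
                   reads$read_id[i]))
    }
    consumed <- sum(cg$len[cg$op %in% c("M", "I", "S")])
    if (consumed != nchar(reads$bases[i])) {
      stop(sprintf("read %s: CIGAR consumes %d bases, sequence has %d",
                   reads$read_id[i], consumed, nchar(reads$bases[i])))
    }
    if (!is.null(genome)) {
      end <- reference_span(reads$start[i], reads$cigar[i])
      if (reads$start[i] < 1L || end > genome$length) {
        stop(sprintf(
          "read %s spans [%d, %d] outside genome [1, %d] (origin-wrapping alignments unsupported)",
          reads$read_id[i], reads$start[i], end, genome$length))
      }
    }
  }
  invisible(reads)
}

#' Write reads as SAM
#'
#' Emits a minimal valid single-reference SAM file with constant "I"
#' base qualities.
#'
#' @param reads an `aligned_reads` data.frame.
#' @param genome the `ref_genome` the reads are aligned to.
#' @param path output path.
#' @export
write_sam <- function(reads, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", genome$seq_id, genome$length)),
             con)
  if (nrow(reads)) {
    flag <- ifelse(reads$is_reverse, 16L, 0L)
    qual <- vapply(nchar(reads$bases),
                   function(n) strrep("I", n), "")
    writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                       reads$read_id, flag, genome$seq_id, reads$start,
                       reads$cigar, reads$bases, qual), con)
  }
  invisible(path)
}
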