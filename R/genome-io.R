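#' Reference genome container
#'
#' A plastid reference genome: a single sequence over A/C/G/T with an
#' identifier and a circularity flag. Coordinates are 1-based and
#' closed everywhere in this package.
#'
#' @param seq_id sequence identifier.
#' @param sequence DNA string (A/C/G/T only; ambiguity codes rejected).
#' @param circular logical; plastid genomes are circular, but reads
#'   wrapping the origin are not supported and are rejected on load.
#' @return an object of class `ref_genome` with fields `seq_id`,
#'   `sequence`, `length`, `circular`.
#' @export
ref_genome <- function(seq_id, sequence, circular = TRUE) {
  sequence <- toupper(sequence)
  bad <- regexpr("[^ACGT]", sequence)
  if (bad > 0) {
    stop(sprintf("non-ACGT character '%s' at position %d",
                 substr(sequence, bad, bad), bad))
  }
  structure(list(seq_id = as.character(seq_id), sequence = sequence,
                 length = nchar(sequence), circular = isTRUE(circular)),
            class = "ref_genome")
}

#' @export
print.ref_genome <- function(x, ...) {
  cat(sprintf("<ref_genome> %s: %d bp%s\n", x$seq_id, x$length,
              if (x$circular) " (circular)" else ""))
  invisible(x)
}

#' Extract genome bases at positions
#'
#' @param genome a `ref_genome`.
#' @param positions integer vector of 1-based positions.
#' @return character vector of single bases.
#' @export
genome_base <- function(genome, positions) {
  stopifnot(all(positions >= 1L), all(positions <= genome$length))
  substring(genome$sequence, positions, positions)
}

#' Read a reference genome from FASTA
#'
#' The file must contain exactly one record; the sequence must be pure
#' A/C/G/T.
#'
#' @param path path to a FASTA file.
#' @param circular logical, stored on the returned object.
#' @return a [ref_genome()].
#' @export
load_genome <- function(path, circular = TRUE) {
  stopifnot(file.exists(path))
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1L) {
    stop(sprintf("expected 1 sequence, found %d", length(set)))
  }
  id <- strsplit(names(set)[1], "\\s+")[[1]][1]
  ref_genome(id, as.character(set[[1]]), circular = circular)
}

#' Write a reference genome to FASTA
#'
#' @param genome a `ref_genome`.
#' @param path output path.
#' @export
write_genome <- function(genome, path) {
  set <- Biostrings::DNAStringSet(genome$sequence)
  names(set) <- genome$seq_id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Apply reference-sequence corrections
#'
#' Each correction is checked against the current genome: its
#' `old_base` must match, otherwise the correction list is stale and an
#' error is raised. Applying corrections one at a time equals applying
#' them as a batch.
#'
#' @param genome a `ref_genome`.
#' @param corrections data.frame with columns `position`, `old_base`,
#'   `new_base` (may have zero rows).
#' @return a new `ref_genome` differing exactly at the corrected
#'   positions.
#' @export
apply_corrections <- function(genome, corrections) {
  if (is.null(corrections) || nrow(corrections) == 0L) return(genome)
  seq <- genome$sequence
  for (i in seq_len(nrow(corrections))) {
    p <- corrections$position[i]
    if (p < 1L || p > genome$length) {
      stop(sprintf("correction position %d outside genome [1, %d]",
                   p, genome$length))
    }
    have <- substr(seq, p, p)
    if (have != corrections$old_base[i]) {
      stop(sprintf(
        "stale correction at position %d: expected old base %s, genome has %s",
        p, corrections$old_base[i], have))
    }
    substr(seq, p, p) <- corrections$new_base[i]
  }
  out <- genome
  out$sequence <- seq
  out
}
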