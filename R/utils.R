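DNA_BASES <- c("A", "C", "G", "T")

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over plain character vectors.
#'
#' @param x character vector of DNA strings (A/C/G/T only).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @rdname revcomp
#' @export
complement_base <- function(x) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[x])
}

#' Translate a codon with the standard genetic code
#'
#' Stop codons are returned as `"*"`. The standard code is used
#' throughout: plastid genes follow it, and start-codon creation is
#' detected structurally (codon 1 becoming ATG) rather than by
#' translating ACG as methionine.
#'
#' @param codon character vector of 3-base codons.
#' @return character vector of single amino-acid letters.
#' @export
translate_codon <- function(codon) {
  stopifnot(all(nchar(codon) == 3L))
  unname(Biostrings::GENETIC_CODE[codon])
}

# round half away from zero, the convention used for percentage rendering
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Render a fraction as a percentage string
#'
#' Rounds half away from zero so e.g. 6/118 renders as "5.1%" and
#' 17/27 as "63.0%".
#'
#' @param support,depth integer counts, or `x` a fraction directly.
#' @param digits decimal places (default 1).
#' @return character string ending in "%".
#' @export
render_percent <- function(support, depth, digits = 1) {
  render_percent_value(support / depth, digits = digits)
}

#' @rdname render_percent
#' @param x a fraction in [0, 1].
#' @export
render_percent_value <- function(x, digits = 1) {
  paste0(formatC(round_half_up(100 * x, digits), format = "f",
                 digits = digits), "%")
}

# split "12,34" -> integer vector
.split_ints <- function(x) {
  if (is.na(x) || x == "") return(integer(0))
  as.integer(strsplit(x, ",", fixed = TRUE)[[1]])
}

.collapse_ints <- function(x) paste(x, collapse = ",")
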