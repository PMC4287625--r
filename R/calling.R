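#' Mismatch calling thresholds
#'
#' The calling rule retains a (position, alt base) pair when read depth
#' is at least `min_depth` and the number of supporting reads is at
#' least the greater of `ceil(min_frequency * depth)` and
#' `min_support_reads`. The frequency comparison is inclusive ("at
#' least 5 percent"); the ceiling means a fractional read count never
#' satisfies the rule.
#'
#' @param min_depth minimum read depth (default 3).
#' @param min_frequency minimum mismatch frequency (default 0.05).
#' @param min_support_reads minimum supporting reads (default 3).
#' @param trim_lengths read-end trim treatments (default 0, 6, 12 bp).
#' @return object of class `call_thresholds`.
#' @export
call_thresholds <- function(min_depth = 3L, min_frequency = 0.05,
                            min_support_reads = 3L,
                            trim_lengths = c(0L, 6L, 12L)) {
  stopifnot(min_depth >= 1L, min_frequency > 0, min_frequency <= 1,
            min_support_reads >= 1L, all(trim_lengths >= 0L))
  structure(list(min_depth = as.integer(min_depth),
                 min_frequency = min_frequency,
                 min_support_reads = as.integer(min_support_reads),
                 trim_lengths = as.integer(trim_lengths)),
            class = "call_thresholds")
}

#' Does a (depth, support) pair pass the calling rule?
#'
#' Vectorised over `depth` and `support`. A small epsilon inside the
#' ceiling keeps products like 0.05 * 60 at their exact value 3 despite
#' binary floating point.
#'
#' @param depth,support integer vectors.
#' @param thresholds a [call_thresholds()].
#' @return logical vector.
#' @export
passes_call_rule <- function(depth, support, thresholds = call_thresholds()) {
  need <- pmax(ceiling(thresholds$min_frequency * depth - 1e-9),
               thresholds$min_support_reads)
  depth >= thresholds$min_depth & support >= need & support > 0L
}

EDIT_CATEGORIES <- c("C:T", "G:A", "T:C", "A:G")

#' Type a DNA:RNA mismatch
#'
#' The twelve ordered ref:alt pairs are interpreted through the strand
#' of the containing feature: C:T on a "+" feature (or G:A on "-") is
#' C-to-U editing; T:C on "+" (or A:G on "-") is U-to-C; the eight
#' remaining categories cannot be produced by editing and are NONEDIT
#' regardless of strand, as are C:T/G:A/T:C/A:G seen on the wrong
#' strand. With unknown strand ("*") the editing-consistent categories
#' are given their editing interpretation and the implied strand.
#'
#' @param ref_base,alt_base single bases, must differ.
#' @param feature_strand "+", "-" or "*" (unknown).
#' @return list with `category` ("C:T" style), `edit_type`
#'   (C2U/U2C/NONEDIT) and `inferred_strand`.
#' @export
classify_mismatch <- function(ref_base, alt_base, feature_strand = "*") {
  if (ref_base == alt_base) stop("ref_base equals alt_base")
  category <- paste0(ref_base, ":", alt_base)
  infer <- switch(category,
                  "C:T" = list("C2U", "+"), "G:A" = list("C2U", "-"),
                  "T:C" = list("U2C", "+"), "A:G" = list("U2C", "-"),
                  NULL)
  if (is.null(infer)) {
    return(list(category = category, edit_type = "NONEDIT",
                inferred_strand = "*"))
  }
  if (feature_strand == "*") {
    return(list(category = category, edit_type = infer[[1]],
                inferred_strand = infer[[2]]))
  }
  if (feature_strand == infer[[2]]) {
    list(category = category, edit_type = infer[[1]],
         inferred_strand = feature_strand)
  } else {
    # an editing-shaped category on the wrong strand is not editing
    list(category = category, edit_type = "NONEDIT",
         inferred_strand = feature_strand)
  }
}

.empty_calls <- function() {
  data.frame(position = integer(0), ref = character(0),
             alt = character(0), category = character(0),
             edit_type = character(0), strand = character(0),
             depth = integer(0), support = integer(0),
             frequency = numeric(0), trims = character(0),
             stringsAsFactors = FALSE)
}

#' Call candidate mismatch sites from a pileup
#'
#' Applies the depth/frequency/support rule independently to every alt
#' base at every position; two passing alts at one position yield two
#' calls. Strand is taken from the containing feature (priority CDS >
#' tRNA > rRNA > intron), unknown outside features. Insertions and
#' deletions are never candidates.
#'
#' @param pileup a [build_pileup()] result.
#' @param thresholds a [call_thresholds()].
#' @param features an `edit_features` table (may be NULL: all strands
#'   unknown).
#' @return data.frame of calls with columns position, ref, alt,
#'   category, edit_type, strand, depth, support, frequency, trims.
#' @export
call_mismatches <- function(pileup, thresholds = call_thresholds(),
                            features = NULL) {
  out <- list()
  depth <- pileup$depth
  for (b in DNA_BASES) {
    cnt <- pileup$counts[, b]
    hit <- which(pileup$ref != b &
                   passes_call_rule(depth, cnt, thresholds))
    if (length(hit)) {
      out[[b]] <- data.frame(position = hit, ref = pileup$ref[hit],
                             alt = b, depth = depth[hit],
                             support = cnt[hit],
                             stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(.empty_calls())
  calls <- do.call(rbind, out)
  calls <- calls[order(calls$position, calls$alt), , drop = FALSE]
  strand <- if (is.null(features)) rep("*", nrow(calls)) else
    feature_strand_at(calls$position, features)
  cls <- Map(classify_mismatch, calls$ref, calls$alt, strand)
  calls$category <- vapply(cls, `[[`, "", "category")
  calls$edit_type <- vapply(cls, `[[`, "", "edit_type")
  calls$strand <- vapply(cls, `[[`, "", "inferred_strand")
  calls$frequency <- calls$support / calls$depth
  calls$trims <- as.character(pileup$trim)
  rownames(calls) <- NULL
  calls[, names(.empty_calls())]
}

#' Union candidate calls across trim treatments
#'
#' A (position, alt) pair is retained if it passed in any treatment;
#' `trims` records which treatments passed. Reported depth, support and
#' frequency come from the untrimmed (trim-0) pileup, which uses the
#' maximal data. Inconsistent reference bases across treatments signal
#' a pileup bug and raise an error.
#'
#' @param calls_by_trim named list, trim -> call data.frame.
#' @param pileup0 the trim-0 pileup used for reported counts.
#' @param features optional `edit_features` for strand lookup.
#' @return a call data.frame keyed on (position, alt).
#' @export
union_across_trims <- function(calls_by_trim, pileup0, features = NULL) {
  all <- do.call(rbind, Map(function(cl, tr) {
    if (nrow(cl)) cl$trims <- as.character(tr)
    cl
  }, calls_by_trim, names(calls_by_trim)))
  if (is.null(all) || nrow(all) == 0L) return(.empty_calls())
  key <- paste(all$position, all$alt)
  refs <- tapply(all$ref, key, function(r) length(unique(r)))
  if (any(refs > 1L)) {
    stop("inconsistent reference base across trim treatments at position ",
         all$position[match(names(refs)[refs > 1L][1], key)])
  }
  uk <- !duplicated(key)
  calls <- all[uk, , drop = FALSE]
  calls$trims <- vapply(key[uk], function(k) {
    paste(sort(as.integer(all$trims[key == k])), collapse = ",")
  }, "")
  # reported counts from trim 0
  calls$depth <- pileup0$depth[calls$position]
  calls$support <- pileup0$counts[cbind(calls$position,
                                        match(calls$alt, DNA_BASES))]
  calls$frequency <- calls$support / calls$depth
  calls <- calls[order(calls$position, calls$alt), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Call mismatches under all trim treatments and union them
#'
#' Convenience driver: builds one pileup per trim length, calls each,
#' and unions the results.
#'
#' @inheritParams call_mismatches
#' @param reads an `aligned_reads` data.frame (RNA).
#' @param genome a `ref_genome`.
#' @return list with `calls` (unioned), `pileups` (named by trim).
#' @export
call_with_trims <- function(reads, genome, thresholds = call_thresholds(),
                            features = NULL) {
  exp <- expand_alignments(reads)
  pileups <- lapply(thresholds$trim_lengths, function(tr) {
    pileup_from_expansion(exp, reads, genome, tr)
  })
  names(pileups) <- as.character(thresholds$trim_lengths)
  by_trim <- lapply(pileups, call_mismatches, thresholds = thresholds,
                    features = features)
  p0 <- pileups[["0"]]
  if (is.null(p0)) p0 <- pileup_from_expansion(exp, reads, genome, 0L)
  calls <- union_across_trims(by_trim, p0, features)
  list(calls = calls, pileups = pileups, pileup0 = p0)
}

#' Sweep calling thresholds over a grid
#'
#' Counts called mismatches per category for every combination of trim
#' length, minimum frequency and minimum depth, the layout of the
#' parameter-sweep bar charts.
#'
#' @param reads,genome,features as in [call_with_trims()].
#' @param trims,min_frequencies,min_depths grid axes.
#' @param min_support_reads held fixed (default 3).
#' @return long data.frame (trim, min_frequency, min_depth, category,
#'   n), zero rows counted too.
#' @export
sweep_thresholds <- function(reads, genome, features = NULL,
                             trims = c(0L, 6L, 12L),
                             min_frequencies = c(0.05, 0.10, 0.20),
                             min_depths = c(3L, 5L, 10L),
                             min_support_reads = 3L) {
  stopifnot(length(trims) > 0, length(min_frequencies) > 0,
            length(min_depths) > 0)
  cats <- c(EDIT_CATEGORIES,
            sort(setdiff(apply(expand.grid(DNA_BASES, DNA_BASES), 1,
                               paste, collapse = ":"),
                         c(EDIT_CATEGORIES, paste0(DNA_BASES, ":", DNA_BASES)))))
  exp <- expand_alignments(reads)
  rows <- list()
  for (tr in trims) {
    pl <- pileup_from_expansion(exp, reads, genome, tr)
    for (fq in min_frequencies) {
      for (dp in min_depths) {
        th <- call_thresholds(min_depth = dp, min_frequency = fq,
                              min_support_reads = min_support_reads,
                              trim_lengths = tr)
        calls <- call_mismatches(pl, th, features)
        n <- table(factor(calls$category, levels = cats))
        rows[[length(rows) + 1L]] <- data.frame(
          trim = tr, min_frequency = fq, min_depth = dp,
          category = cats, n = as.integer(n), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
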