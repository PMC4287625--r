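#' Artifact-filter thresholds
#'
#' The four false-positive classes (heteroplasmy, read-end hexamer
#' bias, exon/intron junction mismapping, reference-genome error) were
#' originally separated by visual inspection of mapped reads; here each
#' is an explicit rule. The 6 bp end window is inclusive and measured
#' on the untrimmed read; the remaining cutoffs mirror the RNA calling
#' thresholds where a numeric choice was needed and are all
#' configurable.
#'
#' @param end_window mismatches supported only within this many bp of
#'   every supporting read's end are end-bias artifacts (default 6).
#' @param het_min_fraction,het_min_reads minimum DNA alt fraction and
#'   alt read count to call a DNA position heteroplasmic (defaults
#'   0.05, 3).
#' @param ref_error_min_fraction DNA consensus fraction above which a
#'   non-reference consensus marks a reference error (default 0.9);
#'   must exceed `het_min_fraction`.
#' @param junction_window distance from an exon/intron boundary within
#'   which junction mismapping is considered (default: read length).
#' @param dna_min_depth minimum DNA depth for the DNA-based detectors
#'   (default 3).
#' @return object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(end_window = 6L, het_min_fraction = 0.05,
                              het_min_reads = 3L,
                              ref_error_min_fraction = 0.9,
                              junction_window = 75L, dna_min_depth = 3L) {
  stopifnot(end_window > 0L, het_min_fraction > 0, het_min_reads > 0L,
            ref_error_min_fraction > 0, junction_window > 0L,
            dna_min_depth > 0L,
            het_min_fraction < ref_error_min_fraction)
  structure(list(end_window = as.integer(end_window),
                 het_min_fraction = het_min_fraction,
                 het_min_reads = as.integer(het_min_reads),
                 ref_error_min_fraction = ref_error_min_fraction,
                 junction_window = as.integer(junction_window),
                 dna_min_depth = as.integer(dna_min_depth)),
            class = "filter_thresholds")
}

.flag <- function(position, alt, category, evidence) {
  data.frame(position = position, alt = alt, category = category,
             evidence = evidence, stringsAsFactors = FALSE)
}

#' Detect heteroplasmy behind a mismatch call
#'
#' Flags the call when the DNA read pool itself is polymorphic at the
#' position: DNA depth adequate, DNA alt fraction at least
#' `het_min_fraction` with at least `het_min_reads` alt reads, but
#' below `ref_error_min_fraction` (above which the position is a
#' reference error, not heteroplasmy). With insufficient DNA coverage
#' no flag is returned and the evidence note says so.
#'
#' @param call one-row call data.frame.
#' @param dna_pileup DNA [build_pileup()] (trim 0).
#' @param t a [filter_thresholds()].
#' @return one-row flag data.frame; NULL when the position is clear; a
#'   zero-row frame with a "note" attribute when DNA depth is too low
#'   to decide.
#' @export
detect_heteroplasmy <- function(call, dna_pileup, t = filter_thresholds()) {
  cnt <- pileup_counts_at(dna_pileup, call$position)
  depth <- sum(cnt)
  if (depth < t$dna_min_depth) {
    out <- .flag(integer(0), character(0), character(0), character(0))
    attr(out, "note") <- sprintf(
      "position %d: insufficient DNA coverage (%d < %d), heteroplasmy undetermined",
      call$position, depth, t$dna_min_depth)
    return(out)
  }
  altn <- cnt[[call$alt]]
  frac <- altn / depth
  if (frac >= t$het_min_fraction && altn >= t$het_min_reads &&
      frac < t$ref_error_min_fraction) {
    return(.flag(call$position, call$alt, "HETEROPLASMY",
                 sprintf("DNA %d/%d alt reads (%.1f%%)", altn, depth,
                         100 * frac)))
  }
  NULL
}

#' Detect read-end (hexamer mispriming) bias
#'
#' Flags the call when every supporting read carries the mismatch
#' within `end_window` bp (inclusive) of one of its untrimmed ends, the
#' signature of imperfect random-hexamer binding during cDNA synthesis.
#'
#' @param call one-row call data.frame.
#' @param rna_pileup the trim-0 RNA pileup whose `support` table holds
#'   per-read end distances.
#' @inheritParams detect_heteroplasmy
#' @return one-row flag data.frame or NULL.
#' @export
detect_end_bias <- function(call, rna_pileup, t = filter_thresholds()) {
  d <- support_distances(rna_pileup, call$position, call$alt)
  if (length(d) == 0L) {
    stop(sprintf("position %d alt %s: no end-distance metadata in pileup",
                 call$position, call$alt))
  }
  if (all(d <= t$end_window)) {
    return(.flag(call$position, call$alt, "END_BIAS",
                 sprintf("%d supporting reads, all within %d bp of a read end (max distance %d)",
                         length(d), t$end_window, max(d))))
  }
  NULL
}

# boundaries of every intron feature: rows (intron_start, intron_end)
.intron_bounds <- function(features) {
  ix <- which(features$kind == "intron")
  if (!length(ix)) return(NULL)
  data.frame(start = vapply(ix, function(i) features$exon_starts[[i]][1], 1L),
             end = vapply(ix, function(i)
               features$exon_ends[[i]][length(features$exon_ends[[i]])], 1L),
             name = features$name[ix])
}

# read base aligned at a genomic position, NA if the position is not
# M-covered by the read; also whether that M block covers `must_cover`
.read_base_at <- function(read, pos) {
  w <- walk_cigar(read$start, read$cigar)
  k <- match(pos, w$pos)
  if (is.na(k)) return(NA_character_)
  substring(read$bases, w$idx[k], w$idx[k])
}

.read_covers <- function(read, pos) {
  w <- walk_cigar(read$start, read$cigar)
  pos %in% w$pos
}

#' Detect exon/intron junction mismapping
#'
#' A spliced transcript read aligned contiguously across an exon/intron
#' boundary of the unspliced genome places spliced (next-exon) bases
#' onto intron positions. The call is flagged when it lies in an intron
#' within `junction_window` of a boundary and, for every supporting
#' read: the read aligns contiguously across that boundary; relocating
#' the read segment past the boundary to the far side of the intron
#' (re-interpreting the alignment as spliced) removes the mismatch at
#' the call position; and the relocation strictly reduces the
#' segment's total mismatch count. The segment-level condition keeps
#' genuine intron edits near junctions from being flagged when the
#' relocated base matches by coincidence.
#'
#' @param call one-row call data.frame.
#' @param features `edit_features` including intron features.
#' @param genome the (current) `ref_genome`.
#' @param reads the RNA `aligned_reads` table (for supporting-read
#'   lookup).
#' @param rna_pileup trim-0 RNA pileup (supporting read ids).
#' @inheritParams detect_heteroplasmy
#' @return one-row flag data.frame or NULL.
#' @export
detect_junction_artifact <- function(call, features, genome, reads,
                                     rna_pileup, t = filter_thresholds()) {
  ib <- .intron_bounds(features)
  if (is.null(ib)) return(NULL)
  p <- call$position
  inside <- which(p >= ib$start & p <= ib$end)
  if (!length(inside)) return(NULL)
  sup <- rna_pileup$support[position == p & base == call$alt]
  if (nrow(sup) == 0L) return(NULL)
  sup_reads <- reads[match(sup$read_id, reads$read_id), , drop = FALSE]
  for (j in inside) {
    is <- ib$start[j]; ie <- ib$end[j]
    # left boundary (exon | intron at `is`): relocate to ie + offset
    if (p - is < t$junction_window) {
      if (.junction_explains_all(sup_reads, p, boundary = "left",
                                 is = is, ie = ie, genome = genome)) {
        return(.flag(p, call$alt, "JUNCTION",
                     sprintf("intron %s [%d,%d]: spliced re-interpretation across left junction removes mismatch in all %d supporting reads",
                             ib$name[j], is, ie, nrow(sup_reads))))
      }
    }
    # right boundary (intron | exon at `ie`): relocate to is - offset
    if (ie - p < t$junction_window) {
      if (.junction_explains_all(sup_reads, p, boundary = "right",
                                 is = is, ie = ie, genome = genome)) {
        return(.flag(p, call$alt, "JUNCTION",
                     sprintf("intron %s [%d,%d]: spliced re-interpretation across right junction removes mismatch in all %d supporting reads",
                             ib$name[j], is, ie, nrow(sup_reads))))
      }
    }
  }
  NULL
}

# does spliced re-interpretation across one boundary explain the
# mismatch at p for EVERY supporting read?
.junction_explains_all <- function(sup_reads, p, boundary, is, ie, genome) {
  if (nrow(sup_reads) == 0L) return(FALSE)
  for (i in seq_len(nrow(sup_reads))) {
    rd <- sup_reads[i, ]
    w <- walk_cigar(rd$start, rd$cigar)
    if (boundary == "left") {
      # read must contiguously cover the last exon base and the intron
      if (!(is - 1L) %in% w$pos || !is %in% w$pos) return(FALSE)
      seg <- which(w$pos >= is & w$pos <= ie)        # bases past boundary
      reloc <- ie + 1L + (w$pos[seg] - is)
    } else {
      if (!(ie + 1L) %in% w$pos || !ie %in% w$pos) return(FALSE)
      seg <- which(w$pos <= ie & w$pos >= is)
      reloc <- is - 1L - (ie - w$pos[seg])
    }
    if (!length(seg) || !p %in% w$pos[seg]) return(FALSE)
    if (any(reloc < 1L | reloc > genome$length)) return(FALSE)
    segbase <- substring(rd$bases, w$idx[seg], w$idx[seg])
    orig_mm <- sum(segbase != genome_base(genome, w$pos[seg]))
    reloc_mm <- sum(segbase != genome_base(genome, reloc))
    k <- match(p, w$pos[seg])
    if (segbase[k] != genome_base(genome, reloc[k])) return(FALSE)
    if (reloc_mm >= orig_mm) return(FALSE)
  }
  TRUE
}

#' Detect a reference-genome error
#'
#' When both the DNA and the RNA read pools disagree with the published
#' reference at a position -- the DNA consensus reaches
#' `ref_error_min_fraction` for a non-reference base and the RNA
#' majority base agrees with it -- the published sequence is wrong.
#' Returns the flag together with the correction to apply.
#'
#' @param call one-row call data.frame.
#' @param dna_pileup,rna_pileup trim-0 pileups.
#' @inheritParams detect_heteroplasmy
#' @return list(flag, correction) or NULL; correction is a one-row
#'   data.frame (position, old_base, new_base).
#' @export
detect_reference_error <- function(call, dna_pileup, rna_pileup,
                                   t = filter_thresholds()) {
  cnt <- pileup_counts_at(dna_pileup, call$position)
  depth <- sum(cnt)
  if (depth < t$dna_min_depth) return(NULL)
  cons <- DNA_BASES[which.max(cnt)]
  frac <- max(cnt) / depth
  if (cons == call$ref || frac < t$ref_error_min_fraction) return(NULL)
  rcnt <- pileup_counts_at(rna_pileup, call$position)
  if (sum(rcnt) == 0L) return(NULL)
  rna_major <- DNA_BASES[which.max(rcnt)]
  if (rna_major != cons) return(NULL)
  list(flag = .flag(call$position, call$alt, "REF_ERROR",
                    sprintf("DNA consensus %s %d/%d (%.1f%%), RNA majority %s, reference %s",
                            cons, max(cnt), depth, 100 * frac, rna_major,
                            call$ref)),
       correction = data.frame(position = call$position,
                               old_base = call$ref, new_base = cons,
                               stringsAsFactors = FALSE))
}

#' Run all four artifact detectors over a call set
#'
#' Detectors are independent and order-free; a call may collect several
#' flags. Calls at positions with no DNA coverage cannot be cleared of
#' heteroplasmy; they are kept but annotated in the notes.
#'
#' @param calls call data.frame.
#' @param rna_pileup trim-0 RNA pileup.
#' @param dna_pileup trim-0 DNA pileup, or NULL (DNA-based detectors
#'   disabled with a warning).
#' @param reads RNA `aligned_reads`.
#' @param features,genome annotation and current reference.
#' @param t a [filter_thresholds()].
#' @return list with `flags` (data.frame), `corrections`, `notes`
#'   (character).
#' @export
classify_artifacts <- function(calls, rna_pileup, dna_pileup, reads,
                               features, genome, t = filter_thresholds()) {
  flags <- list(); corr <- list(); notes <- character(0)
  if (is.null(dna_pileup)) {
    warning("no DNA pileup: heteroplasmy and reference-error detection disabled")
  }
  for (i in seq_len(nrow(calls))) {
    call <- calls[i, ]
    if (!is.null(dna_pileup)) {
      h <- detect_heteroplasmy(call, dna_pileup, t)
      if (!is.null(h)) {
        if (nrow(h)) flags[[length(flags) + 1L]] <- h
        else notes <- c(notes, attr(h, "note"))
      }
      r <- detect_reference_error(call, dna_pileup, rna_pileup, t)
      if (!is.null(r)) {
        flags[[length(flags) + 1L]] <- r$flag
        corr[[length(corr) + 1L]] <- r$correction
      }
    }
    e <- detect_end_bias(call, rna_pileup, t)
    if (!is.null(e)) flags[[length(flags) + 1L]] <- e
    j <- detect_junction_artifact(call, features, genome, reads,
                                  rna_pileup, t)
    if (!is.null(j)) flags[[length(flags) + 1L]] <- j
  }
  flags <- if (length(flags)) do.call(rbind, flags) else
    .flag(integer(0), character(0), character(0), character(0))
  corrections <- if (length(corr)) unique(do.call(rbind, corr)) else
    data.frame(position = integer(0), old_base = character(0),
               new_base = character(0))
  list(flags = flags, corrections = corrections, notes = notes)
}

#' Partition calls into curated and rejected sets
#'
#' A call with any artifact flag is rejected (never rescued); its
#' rejected record lists all flag categories. Reference-error
#' corrections are returned for genome correction and a second calling
#' pass.
#'
#' @param calls call data.frame.
#' @param artifact result of [classify_artifacts()] (or a compatible
#'   list with `flags` and `corrections`).
#' @return list(curated, rejected, corrections, notes); `rejected` has
#'   the call columns plus `categories` (comma-joined).
#' @export
filter_calls <- function(calls, artifact) {
  flags <- artifact$flags
  key <- paste(calls$position, calls$alt)
  fkey <- paste(flags$position, flags$alt)
  flagged <- key %in% fkey
  curated <- calls[!flagged, , drop = FALSE]
  rejected <- calls[flagged, , drop = FALSE]
  rejected$categories <- vapply(key[flagged], function(k) {
    paste(sort(unique(flags$category[fkey == k])), collapse = ",")
  }, "")
  rownames(curated) <- rownames(rejected) <- NULL
  list(curated = curated, rejected = rejected,
       corrections = artifact$corrections,
       notes = artifact$notes %||% character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
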