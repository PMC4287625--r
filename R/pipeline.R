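#' Windowed transcriptome coverage map
#'
#' Mean per-position read depth in tiling windows (default 10 bp
#' window and step). The final partial window is averaged over its
#' actual width. With step equal to window, window sums conserve the
#' total aligned base count.
#'
#' @param reads an `aligned_reads` data.frame.
#' @param genome a `ref_genome`.
#' @param window,step window and step size in bp.
#' @return data.frame (start, width, mean_depth).
#' @export
coverage_map <- function(reads, genome, window = 10L, step = 10L) {
  stopifnot(window >= 1L, step >= 1L)
  L <- genome$length
  depth <- integer(L)
  exp <- expand_alignments(reads)
  if (nrow(exp)) {
    tab <- exp[, .N, by = position]
    depth[tab$position] <- tab$N
  }
  starts <- seq.int(1L, L, by = step)
  ends <- pmin(starts + window - 1L, L)
  cs <- cumsum(as.numeric(depth))
  sums <- cs[ends] - c(0, cs)[starts]
  data.frame(start = starts, width = ends - starts + 1L,
             mean_depth = sums / (ends - starts + 1L))
}

#' Run the full edit-site detection pipeline
#'
#' Sequences the whole analysis: per-trim calling and union; artifact
#' classification; filtering; a single reference-correction pass
#' (re-call and re-filter against the corrected genome when reference
#' errors were found); annotation of the curated sites; summary
#' tables; and a coverage map. Without DNA reads the
#' heteroplasmy and reference-error detectors are disabled with a
#' warning and the rest completes.
#'
#' @param genome published `ref_genome` (will be corrected if
#'   reference errors are detected).
#' @param features `edit_features` annotation.
#' @param rna_reads,dna_reads `aligned_reads` tables (`dna_reads` may
#'   be NULL).
#' @param alignments optional named list of [protein_alignment()]s for
#'   functional-effect scoring.
#' @param thresholds a [call_thresholds()].
#' @param filter_t a [filter_thresholds()].
#' @param coverage_window window/step for the coverage map.
#' @return list of class `editscan_run`: corrected genome, curated and
#'   rejected calls, corrections, annotated `sites`, `summary` table,
#'   `efficiency_by_effect`, coverage map, trim-0 pileups, and a
#'   structured `log` (one line per retained/rejected call).
#' @export
run_pipeline <- function(genome, features, rna_reads, dna_reads = NULL,
                         alignments = NULL,
                         thresholds = call_thresholds(),
                         filter_t = filter_thresholds(),
                         coverage_window = 10L) {
  pass <- function(gen) {
    cw <- call_with_trims(rna_reads, gen, thresholds, features)
    dna_pileup <- if (!is.null(dna_reads)) {
      build_pileup(dna_reads, gen, trim = 0L)
    } else NULL
    art <- classify_artifacts(cw$calls, cw$pileup0, dna_pileup,
                              rna_reads, features, gen, filter_t)
    fc <- filter_calls(cw$calls, art)
    list(cw = cw, dna_pileup = dna_pileup, fc = fc)
  }
  p1 <- pass(genome)
  corrections <- p1$fc$corrections
  if (nrow(corrections)) {
    # a single correction pass: fix the genome once, re-call,
    # re-filter; later corrections are not iterated
    genome <- apply_corrections(genome, corrections)
    p2 <- pass(genome)
    final <- p2
  } else {
    final <- p1
  }
  curated <- final$fc$curated
  rejected <- final$fc$rejected
  if (nrow(corrections)) {
    # reference-error mismatches disappear after correction; keep
    # their first-pass rejection records in the report
    rr <- p1$fc$rejected
    rr <- rr[grepl("REF_ERROR", rr$categories), , drop = FALSE]
    new <- !paste(rr$position, rr$alt) %in%
      paste(rejected$position, rejected$alt)
    rejected <- rbind(rejected, rr[new, , drop = FALSE])
    rejected <- rejected[order(rejected$position, rejected$alt), ,
                         drop = FALSE]
    rownames(rejected) <- NULL
  }
  sites <- annotate_sites(curated, genome, features, alignments)
  eff <- efficiency_by_effect(sites)
  log <- c(
    sprintf("retained\tpos=%d\talt=%s\t%s\tdepth=%d\tsupport=%d\tfreq=%.4f\ttrims=%s",
            curated$position, curated$alt, curated$edit_type,
            curated$depth, curated$support, curated$frequency,
            curated$trims),
    sprintf("rejected\tpos=%d\talt=%s\t%s\tdepth=%d\tsupport=%d\tfreq=%.4f\tcategories=%s",
            rejected$position, rejected$alt, rejected$edit_type,
            rejected$depth, rejected$support, rejected$frequency,
            rejected$categories),
    final$fc$notes)
  structure(list(
    genome = genome, corrections = corrections,
    curated = curated, rejected = rejected, sites = sites,
    summary = summarize_edit_sites(sites),
    efficiency_by_effect = eff,
    coverage = coverage_map(rna_reads, genome,
                            window = coverage_window,
                            step = coverage_window),
    rna_pileup0 = final$cw$pileup0, dna_pileup = final$dna_pileup,
    log = log), class = "editscan_run")
}

#' @export
print.editscan_run <- function(x, ...) {
  cat(sprintf("<editscan_run> %d curated calls (%d edit sites), %d rejected, %d reference corrections\n",
              nrow(x$curated), nrow(x$sites), nrow(x$rejected),
              nrow(x$corrections)))
  invisible(x)
}

#' Run the pipeline end to end on input files
#'
#' File-based wrapper around [run_pipeline()] for scripted use.
#'
#' @param genome_path single-record FASTA.
#' @param annotation_path annotation (TSV dialect or GFF3).
#' @param rna_sam,dna_sam SAM files (`dna_sam` optional).
#' @param ... passed to [run_pipeline()].
#' @return an `editscan_run`.
#' @export
run_pipeline_files <- function(genome_path, annotation_path, rna_sam,
                               dna_sam = NULL, ...) {
  genome <- load_genome(genome_path)
  features <- load_annotation(annotation_path, genome)
  rna <- load_alignments(rna_sam, "RNA", genome)
  dna <- if (!is.null(dna_sam)) load_alignments(dna_sam, "DNA", genome)
  run_pipeline(genome, features, rna, dna, ...)
}
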