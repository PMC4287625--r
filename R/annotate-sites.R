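#' Locate a genomic position within the annotation
#'
#' Overlapping features resolve with priority CDS > tRNA > rRNA >
#' intron; positions in no feature are UTR_or_intergenic (the package
#' does not distinguish UTRs from intergenic spacers by a distance
#' rule). For CDS hits, `cds_position` counts along the spliced,
#' strand-oriented CDS from the gene's own start codon. Intron hits are
#' labelled gene + "i" + CDS position of the last exonic base before
#' the intron (clpPi71 style).
#'
#' @param position 1-based genome coordinate.
#' @param features an `edit_features` table.
#' @return list(location_class, gene, label, cds_position,
#'   codon_position); CDS fields NA outside coding sequence.
#' @export
locate_site <- function(position, features) {
  pri <- c(CDS = 1L, tRNA = 2L, rRNA = 3L, intron = 4L)
  hit <- NULL; best <- 5L
  for (i in seq_len(nrow(features))) {
    s <- features$exon_starts[[i]]; e <- features$exon_ends[[i]]
    if (any(position >= s & position <= e)) {
      p <- pri[[features$kind[i]]]
      if (p < best) { best <- p; hit <- i }
    }
  }
  if (is.null(hit)) {
    return(list(location_class = "UTR_or_intergenic", gene = NA_character_,
                label = NA_character_, cds_position = NA_integer_,
                codon_position = NA_integer_))
  }
  kind <- features$kind[hit]
  if (kind == "CDS") {
    map <- cds_genomic_map(features, features$name[hit])
    cp <- match(position, map)
    return(list(location_class = "CDS", gene = features$name[hit],
                label = features$name[hit], cds_position = cp,
                codon_position = (cp - 1L) %% 3L + 1L))
  }
  if (kind == "intron") {
    parent <- features$parent[hit]
    lab <- features$name[hit]
    if (!is.na(parent) && parent %in% features$name) {
      # CDS position of the last exon base preceding the intron,
      # in transcript orientation
      map <- cds_genomic_map(features, parent)
      istart <- features$exon_starts[[hit]][1]
      iend <- features$exon_ends[[hit]][length(features$exon_ends[[hit]])]
      strand <- features$strand[match(parent, features$name)]
      prev <- if (strand == "-") {
        map[map > iend]      # transcript-upstream exon bases
      } else {
        map[map < istart]
      }
      if (length(prev)) {
        cp_prev <- if (strand == "-") match(min(prev), map) else
          match(max(prev), map)
        lab <- sprintf("%si%d", parent, cp_prev)
      }
    }
    return(list(location_class = "intron", gene = lab,
                label = lab, cds_position = NA_integer_,
                codon_position = NA_integer_))
  }
  list(location_class = kind, gene = features$name[hit],
       label = features$name[hit], cds_position = NA_integer_,
       codon_position = NA_integer_)
}

#' Editing efficiency of a site
#'
#' The fraction of transcript reads carrying the edited base.
#'
#' @param support edited-read count.
#' @param depth total reads at the site (must be positive).
#' @return `support / depth`.
#' @seealso [render_percent()] for the one-decimal percentage
#'   rendering.
#' @export
compute_efficiency <- function(support, depth) {
  stopifnot(depth > 0, support >= 0, support <= depth)
  support / depth
}

#' Codon-level consequence of an edit
#'
#' Reconstructs the reference and edited codon on the spliced,
#' strand-oriented CDS, translates both with the standard code, and
#' classifies: silent, missense, start_created (codon 1 becomes ATG
#' from a non-ATG), stop_created (a sense codon becomes TAA/TAG/TGA),
#' stop_removed (a stop codon becomes sense, the hallmark of U-to-C
#' editing). ACG-to-ATG start creation is detected structurally, not by
#' translating ACG as methionine.
#'
#' @param cds_position 1-based position in the spliced CDS.
#' @param edit_type "C2U" or "U2C".
#' @param cds_sequence the spliced strand-oriented CDS string.
#' @return list(ref_codon, edited_codon, ref_aa, edited_aa,
#'   codon_effect) with `codon_effect` a character vector (possibly
#'   several labels).
#' @export
codon_effect <- function(cds_position, edit_type, cds_sequence) {
  L <- nchar(cds_sequence)
  if (cds_position < 1L || cds_position > L) {
    stop(sprintf("cds_position %d beyond CDS length %d", cds_position, L))
  }
  codon_i <- ceiling(cds_position / 3)
  off <- (cds_position - 1L) %% 3L + 1L
  ref_codon <- substr(cds_sequence, 3L * codon_i - 2L, 3L * codon_i)
  base <- substr(ref_codon, off, off)
  new <- switch(edit_type, C2U = "T", U2C = "C",
                stop(sprintf("edit_type %s has no codon effect", edit_type)))
  expect <- switch(edit_type, C2U = "C", U2C = "T")
  if (base != expect) {
    stop(sprintf("CDS position %d has %s, but a %s edit requires %s",
                 cds_position, base, edit_type, expect))
  }
  edited_codon <- ref_codon
  substr(edited_codon, off, off) <- new
  ref_aa <- translate_codon(ref_codon)
  edited_aa <- translate_codon(edited_codon)
  eff <- character(0)
  if (ref_aa == edited_aa) {
    eff <- "silent"
  } else if (ref_aa != "*" && edited_aa == "*") {
    eff <- "stop_created"
  } else if (ref_aa == "*" && edited_aa != "*") {
    eff <- "stop_removed"
  } else {
    eff <- "missense"
  }
  if (codon_i == 1L && edited_codon == "ATG" && ref_codon != "ATG") {
    eff <- c(eff, "start_created")
  }
  list(ref_codon = ref_codon, edited_codon = edited_codon,
       ref_aa = ref_aa, edited_aa = edited_aa, codon_effect = eff)
}

#' Functional effect of a coding edit against a protein alignment
#'
#' Silent if the amino acid is unchanged. Otherwise the edited and
#' reference residues are compared with the other species' residues at
#' the homologous alignment column: conservative when the edited
#' residue matches strictly more species than the reference residue;
#' non-conservative otherwise (a tie is not an improvement). Edits that
#' truncate the protein (stop created) are non-conservative.
#'
#' @param ref_aa,edited_aa single letters ("*" for stop).
#' @param cds_position position in the focal spliced CDS.
#' @param aln a [protein_alignment()].
#' @param map optional precomputed [build_homology_map()]; when NULL
#'   only the focal row is mapped (other rows are compared at the same
#'   column).
#' @return "conservative", "non_conservative" or "silent".
#' @export
functional_effect <- function(ref_aa, edited_aa, cds_position, aln,
                              map = NULL) {
  if (ref_aa == edited_aa) return("silent")
  if (edited_aa == "*") return("non_conservative")
  codon_i <- ceiling(cds_position / 3)
  cc <- .row_columns(aln$rows[[aln$focal_species]])
  if (codon_i > length(cc)) {
    stop(sprintf("codon %d beyond focal row of %s", codon_i, aln$gene))
  }
  col <- cc[codon_i]
  others <- setdiff(names(aln$rows), aln$focal_species)
  res <- vapply(others, function(sp) substr(aln$rows[[sp]], col, col), "")
  focal_res <- substr(aln$rows[[aln$focal_species]], col, col)
  if (focal_res == "-") {
    stop(sprintf("focal column %d of %s is a gap: alignment/coordinate mismatch",
                 col, aln$gene))
  }
  res <- res[res != "-"]
  if (sum(res == edited_aa) > sum(res == ref_aa)) "conservative"
  else "non_conservative"
}

#' Annotate curated calls as edit sites
#'
#' Keeps the editing-consistent calls (C2U/U2C), locates each in the
#' annotation, reconstructs codon consequences for coding sites,
#' records efficiency = support/depth, and scores the functional
#' effect where a protein alignment for the gene is available.
#'
#' @param curated curated call data.frame.
#' @param genome the (corrected) `ref_genome`.
#' @param features `edit_features`.
#' @param alignments optional named list of [protein_alignment()]s
#'   keyed by gene.
#' @return data.frame of edit sites (one row per site).
#' @export
annotate_sites <- function(curated, genome, features, alignments = NULL) {
  keep <- curated$edit_type %in% c("C2U", "U2C")
  calls <- curated[keep, , drop = FALSE]
  n <- nrow(calls)
  out <- data.frame(
    position = calls$position, edit_type = calls$edit_type,
    strand = calls$strand, location_class = NA_character_,
    gene = NA_character_, cds_position = NA_integer_,
    codon_position = NA_integer_, ref_codon = NA_character_,
    edited_codon = NA_character_, ref_aa = NA_character_,
    edited_aa = NA_character_, codon_effect = NA_character_,
    functional_effect = NA_character_,
    efficiency = ifelse(calls$depth > 0, calls$support / calls$depth, NA),
    support = calls$support, depth = calls$depth,
    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  cds_cache <- list()
  for (i in seq_len(n)) {
    loc <- locate_site(calls$position[i], features)
    out$location_class[i] <- loc$location_class
    out$gene[i] <- loc$label
    if (loc$location_class == "CDS") {
      out$cds_position[i] <- loc$cds_position
      out$codon_position[i] <- loc$codon_position
      g <- loc$gene
      if (is.null(cds_cache[[g]])) {
        cds_cache[[g]] <- spliced_sequence(genome, features, g)
      }
      ce <- codon_effect(loc$cds_position, calls$edit_type[i],
                         cds_cache[[g]])
      out$ref_codon[i] <- ce$ref_codon
      out$edited_codon[i] <- ce$edited_codon
      out$ref_aa[i] <- ce$ref_aa
      out$edited_aa[i] <- ce$edited_aa
      out$codon_effect[i] <- paste(ce$codon_effect, collapse = ",")
      if (!is.null(alignments) && g %in% names(alignments)) {
        out$functional_effect[i] <- functional_effect(
          ce$ref_aa, ce$edited_aa, loc$cds_position, alignments[[g]])
      }
    }
  }
  out
}

#' Edit-site summary table
#'
#' Counts and one-decimal percentages (of the total) for the standard
#' row taxonomy: total, C-to-U, U-to-C, coding, codon positions 1/2/3,
#' start created, stop created, stop removed, non-coding, intron, tRNA,
#' rRNA, UTR/intergenic. Percentages round half away from zero; with
#' no sites they render as an em dash.
#'
#' @param sites an [annotate_sites()] data.frame.
#' @return data.frame with columns `row`, `count`, `pct`.
#' @export
summarize_edit_sites <- function(sites) {
  total <- nrow(sites)
  has <- function(x, lab) !is.na(x) & grepl(lab, x, fixed = TRUE)
  counts <- c(
    Total = total,
    `C-to-U` = sum(sites$edit_type == "C2U"),
    `U-to-C` = sum(sites$edit_type == "U2C"),
    Coding = sum(sites$location_class == "CDS"),
    `1st` = sum(!is.na(sites$codon_position) & sites$codon_position == 1L),
    `2nd` = sum(!is.na(sites$codon_position) & sites$codon_position == 2L),
    `3rd` = sum(!is.na(sites$codon_position) & sites$codon_position == 3L),
    `start created` = sum(has(sites$codon_effect, "start_created")),
    `stop created` = sum(has(sites$codon_effect, "stop_created")),
    `stop removed` = sum(has(sites$codon_effect, "stop_removed")),
    `Non-coding` = sum(sites$location_class != "CDS"),
    intron = sum(sites$location_class == "intron"),
    tRNA = sum(sites$location_class == "tRNA"),
    rRNA = sum(sites$location_class == "rRNA"),
    UTR = sum(sites$location_class == "UTR_or_intergenic"))
  pct <- if (total == 0L) rep("—", length(counts)) else
    vapply(counts, function(k) render_percent(k, total), "")
  data.frame(row = names(counts), count = as.integer(counts), pct = pct,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Editing efficiency by functional-effect class
#'
#' Mean efficiency, site count and standard error (sd/sqrt(n)) per
#' class, plus 2 x SE (the error-bar convention). Classes with no
#' sites are omitted; a single-site class has undefined SE, reported
#' as NA.
#'
#' @param sites an [annotate_sites()] data.frame with
#'   `functional_effect` assigned.
#' @return data.frame (class, n, mean_efficiency, se, two_se).
#' @export
efficiency_by_effect <- function(sites) {
  cls <- c("conservative", "silent", "non_conservative")
  rows <- lapply(cls, function(cl) {
    e <- sites$efficiency[!is.na(sites$functional_effect) &
                            sites$functional_effect == cl]
    if (!length(e)) return(NULL)
    se <- if (length(e) > 1L) stats::sd(e) / sqrt(length(e)) else NA_real_
    data.frame(class = cl, n = length(e), mean_efficiency = mean(e),
               se = se, two_se = 2 * se, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(class = character(0), n = integer(0),
                      mean_efficiency = numeric(0), se = numeric(0),
                      two_se = numeric(0))
  }
  out
}
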