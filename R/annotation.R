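#' Build an annotation feature table
#'
#' Features are genes (CDS, tRNA, rRNA) and introns, each with one or
#' more 1-based closed exon intervals on the genome. Intron features
#' carry the parent gene's name in `parent`. Exons must be
#' non-overlapping and sorted by genomic coordinate; a CDS whose
#' concatenated exon length is not a multiple of 3 is kept with a
#' warning.
#'
#' @param name,kind,strand,parent character vectors (kind in
#'   CDS/tRNA/rRNA/intron; strand "+" or "-").
#' @param exon_starts,exon_ends lists of integer vectors (parallel).
#' @param genome optional `ref_genome` used to validate coordinates.
#' @return a data.frame of class `edit_features`.
#' @export
features_table <- function(name, kind, strand, exon_starts, exon_ends,
                           parent = NA_character_, genome = NULL) {
  kind <- match.arg(kind, c("CDS", "tRNA", "rRNA", "intron"),
                    several.ok = TRUE)
  n <- length(name)
  ft <- data.frame(name = name, kind = kind, strand = strand,
                   parent = rep_len(parent, n),
                   stringsAsFactors = FALSE)
  ft$exon_starts <- I(lapply(exon_starts, as.integer))
  ft$exon_ends <- I(lapply(exon_ends, as.integer))
  validate_features(ft, genome)
}

validate_features <- function(ft, genome = NULL) {
  for (i in seq_len(nrow(ft))) {
    s <- ft$exon_starts[[i]]; e <- ft$exon_ends[[i]]
    if (length(s) != length(e) || any(e < s)) {
      stop(sprintf("feature %s: malformed exon intervals", ft$name[i]))
    }
    if (is.unsorted(s, strictly = TRUE) && length(s) > 1L) {
      stop(sprintf("feature %s: exons not sorted by coordinate", ft$name[i]))
    }
    if (length(s) > 1L && any(s[-1] <= e[-length(e)])) {
      stop(sprintf("feature %s: overlapping exons", ft$name[i]))
    }
    if (!is.null(genome) && (any(s < 1L) || any(e > genome$length))) {
      stop(sprintf("feature %s: exon outside genome [1, %d]",
                   ft$name[i], genome$length))
    }
    if (ft$kind[i] == "CDS" && sum(e - s + 1L) %% 3L != 0L) {
      warning(sprintf("CDS %s: length %d not a multiple of 3",
                      ft$name[i], sum(e - s + 1L)))
    }
  }
  ft <- ft[order(vapply(ft$exon_starts, min, 1L)), , drop = FALSE]
  rownames(ft) <- NULL
  class(ft) <- c("edit_features", "data.frame")
  ft
}

#' Read gene annotation (TSV dialect or GFF3)
#'
#' The native dialect is a 6-column tab-separated file with a header
#' `name kind strand exon_starts exon_ends parent`, exon coordinates as
#' comma-separated 1-based closed intervals. Files ending in
#' `.gff`/`.gff3` are read through rtracklayer; feature types
#' CDS/tRNA/rRNA/intron are used, with multi-exon CDS grouped by their
#' `Name` (or ID) attribute and introns attached via `Parent`.
#'
#' @param path annotation file.
#' @param genome a `ref_genome` for coordinate validation.
#' @return an `edit_features` data.frame sorted by start.
#' @export
load_annotation <- function(path, genome = NULL) {
  stopifnot(file.exists(path))
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    return(.load_annotation_gff3(path, genome))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("name", "kind", "strand", "exon_starts", "exon_ends", "parent")
  if (!all(need %in% names(tab))) {
    stop("annotation TSV must have columns: ", paste(need, collapse = ", "))
  }
  features_table(tab$name, tab$kind, tab$strand,
                 lapply(tab$exon_starts, .split_ints),
                 lapply(tab$exon_ends, .split_ints),
                 parent = ifelse(tab$parent == "" | is.na(tab$parent),
                                 NA_character_, tab$parent),
                 genome = genome)
}

.load_annotation_gff3 <- function(path, genome) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GFF3 requires the rtracklayer package; ",
         "use the TSV annotation dialect otherwise")
  }
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  df <- df[df$type %in% c("CDS", "tRNA", "rRNA", "intron"), , drop = FALSE]
  nm <- if ("Name" %in% names(df)) as.character(df$Name) else NA
  id <- if ("ID" %in% names(df)) as.character(df$ID) else NA
  df$feat_name <- ifelse(!is.na(nm) & nm != "", nm, id)
  par <- if ("Parent" %in% names(df)) {
    vapply(df$Parent, function(p) if (length(p)) as.character(p)[1]
           else NA_character_, "")
  } else rep(NA_character_, nrow(df))
  key <- paste(df$feat_name, df$type)
  groups <- split(seq_len(nrow(df)), key)
  rows <- lapply(groups, function(ix) {
    o <- ix[order(df$start[ix])]
    list(name = df$feat_name[o[1]], kind = as.character(df$type[o[1]]),
         strand = as.character(df$strand[o[1]]),
         starts = df$start[o], ends = df$end[o], parent = par[o[1]])
  })
  features_table(vapply(rows, `[[`, "", "name"),
                 vapply(rows, `[[`, "", "kind"),
                 vapply(rows, `[[`, "", "strand"),
                 lapply(rows, `[[`, "starts"),
                 lapply(rows, `[[`, "ends"),
                 parent = vapply(rows, `[[`, "", "parent"),
                 genome = genome)
}

#' Write annotation in the TSV dialect
#'
#' @param features an `edit_features` table.
#' @param path output path.
#' @export
write_annotation <- function(features, path) {
  out <- data.frame(
    name = features$name, kind = features$kind, strand = features$strand,
    exon_starts = vapply(features$exon_starts, .collapse_ints, ""),
    exon_ends = vapply(features$exon_ends, .collapse_ints, ""),
    parent = ifelse(is.na(features$parent), "", features$parent))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# exon intervals of a feature in transcript (translation) order:
# for "-" strand genes the rightmost exon comes first
transcript_exons <- function(features, name) {
  i <- match(name, features$name)
  if (is.na(i)) stop(sprintf("no feature named %s", name))
  s <- features$exon_starts[[i]]; e <- features$exon_ends[[i]]
  if (features$strand[i] == "-") {
    o <- order(s, decreasing = TRUE)
  } else {
    o <- order(s)
  }
  list(starts = s[o], ends = e[o], strand = features$strand[i])
}

# genomic positions of the spliced CDS in translation order
cds_genomic_map <- function(features, name) {
  ex <- transcript_exons(features, name)
  unlist(lapply(seq_along(ex$starts), function(k) {
    if (ex$strand == "-") seq(ex$ends[k], ex$starts[k]) else
      seq(ex$starts[k], ex$ends[k])
  }))
}

# spliced, strand-oriented sequence of a feature
spliced_sequence <- function(genome, features, name) {
  map <- cds_genomic_map(features, name)
  b <- genome_base(genome, map)
  if (transcript_exons(features, name)$strand == "-") {
    b <- complement_base(b)
  }
  paste(b, collapse = "")
}

# strand of the containing transcribed feature for each position,
# with overlap priority CDS > tRNA > rRNA > intron; "*" when in none.
feature_strand_at <- function(positions, features) {
  out <- rep("*", length(positions))
  pri <- c(CDS = 1L, tRNA = 2L, rRNA = 3L, intron = 4L)
  best <- rep(5L, length(positions))
  for (i in seq_len(nrow(features))) {
    s <- features$exon_starts[[i]]; e <- features$exon_ends[[i]]
    p <- pri[[features$kind[i]]]
    hit <- rep(FALSE, length(positions))
    for (k in seq_along(s)) {
      hit <- hit | (positions >= s[k] & positions <= e[k])
    }
    upd <- hit & p < best
    out[upd] <- features$strand[i]
    best[upd] <- p
  }
  out
}

#' Intergenic gaps of an annotation
#'
#' The complement of all feature spans, as a data.frame of 1-based
#' closed intervals.
#'
#' @param features an `edit_features` table.
#' @param genome a `ref_genome`.
#' @return data.frame with columns `start`, `end`.
#' @export
intergenic_gaps <- function(features, genome) {
  cov <- rep(FALSE, genome$length)
  for (i in seq_len(nrow(features))) {
    s <- features$exon_starts[[i]]; e <- features$exon_ends[[i]]
    for (k in seq_along(s)) cov[s[k]:e[k]] <- TRUE
  }
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[!r$values], end = ends[!r$values])
}
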