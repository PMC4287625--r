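#' Per-gene protein multiple alignment
#'
#' Holds the aligned amino-acid rows (gaps as "-") of one gene across
#' species, with one species marked focal. All rows must have equal
#' length.
#'
#' @param gene gene name.
#' @param rows named character vector, species -> aligned AA string.
#' @param focal_species name of the focal species (must be a row).
#' @return object of class `protein_alignment`.
#' @export
protein_alignment <- function(gene, rows, focal_species) {
  rows <- toupper(unlist(rows))
  if (length(unique(nchar(rows))) != 1L) {
    stop(sprintf("alignment %s: rows have unequal lengths", gene))
  }
  if (!focal_species %in% names(rows)) {
    stop(sprintf("alignment %s: focal species '%s' not among rows",
                 gene, focal_species))
  }
  structure(list(gene = gene, rows = rows,
                 focal_species = focal_species),
            class = "protein_alignment")
}

#' Read an aligned-FASTA protein alignment
#'
#' Sequence names are taken as species names.
#'
#' @param path aligned FASTA with "-" gaps.
#' @param gene gene name (defaults to the file name without extension).
#' @param focal_species focal species name.
#' @return a [protein_alignment()].
#' @export
load_protein_alignment <- function(path, focal_species,
                                   gene = tools::file_path_sans_ext(basename(path))) {
  set <- Biostrings::readAAStringSet(path)
  rows <- as.character(set)
  names(rows) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  protein_alignment(gene, rows, focal_species)
}

# alignment column of each ungapped residue of one row
.row_columns <- function(row) {
  ch <- strsplit(row, "")[[1]]
  which(ch != "-")
}

#' Map CDS nucleotide positions to alignment columns
#'
#' Position p of a species' spliced CDS maps to the alignment column of
#' amino acid ceiling(p/3) in that species' row, with codon offset
#' ((p-1) mod 3)+1. Each species' ungapped row length times 3 must
#' equal its CDS length minus the stop codon.
#'
#' @param aln a [protein_alignment()].
#' @param cds_lengths named integer vector, species -> CDS length in nt
#'   (including the stop codon).
#' @return object of class `homology_map` with per-species
#'   codon-to-column index vectors.
#' @export
build_homology_map <- function(aln, cds_lengths) {
  cols <- list()
  for (sp in names(cds_lengths)) {
    if (!sp %in% names(aln$rows)) {
      stop(sprintf("species %s absent from alignment of %s", sp, aln$gene))
    }
    cc <- .row_columns(aln$rows[[sp]])
    if (length(cc) * 3L != cds_lengths[[sp]] - 3L) {
      stop(sprintf(
        "gene %s, species %s: %d aligned residues imply CDS length %d, annotation says %d",
        aln$gene, sp, length(cc), length(cc) * 3L + 3L, cds_lengths[[sp]]))
    }
    cols[[sp]] <- cc
  }
  structure(list(gene = aln$gene, columns = cols), class = "homology_map")
}

# (column, offset) of a CDS nucleotide position for one species;
# NA column if the codon index exceeds the mapped row
map_cds_position <- function(map, species, cds_position) {
  codon <- ceiling(cds_position / 3)
  offset <- (cds_position - 1L) %% 3L + 1L
  cc <- map$columns[[species]]
  col <- if (codon <= length(cc)) cc[codon] else NA_integer_
  list(column = col, offset = offset)
}
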