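#' Shared homologous edit sites across species
#'
#' Two coding edit sites in different species are homologous when they
#' fall in the same gene, the same alignment column, the same codon
#' offset, and share the edit type (a C-to-U and a U-to-C at one column
#' are different events). Non-coding sites must be excluded by the
#' caller. Returns the region counts of the n-set Venn diagram over
#' homologous site classes.
#'
#' @param site_sets named list, species -> edit-site data.frame with at
#'   least `gene`, `cds_position`, `edit_type` (CDS sites only).
#' @param maps named list of [build_homology_map()]s keyed by gene.
#' @return data.frame (region, count), region a "&"-joined sorted
#'   species set; attribute `classes` holds the per-class membership
#'   table.
#' @export
shared_edit_sites <- function(site_sets, maps) {
  stopifnot(length(site_sets) >= 1L, !is.null(names(site_sets)))
  memb <- list()
  for (sp in names(site_sets)) {
    ss <- site_sets[[sp]]
    if (is.null(ss) || nrow(ss) == 0L) next
    if (any(is.na(ss$cds_position))) {
      stop(sprintf("species %s: non-coding sites must be excluded", sp))
    }
    for (i in seq_len(nrow(ss))) {
      g <- ss$gene[i]
      m <- maps[[g]]
      if (is.null(m) || !sp %in% names(m$columns)) {
        warning(sprintf(
          "species %s has no alignment mapping for gene %s; site counted as unique",
          sp, g))
        key <- sprintf("%s|unmapped|%s|%d|%s", g, sp, ss$cds_position[i],
                       ss$edit_type[i])
      } else {
        mc <- map_cds_position(m, sp, ss$cds_position[i])
        if (is.na(mc$column)) {
          key <- sprintf("%s|unmapped|%s|%d|%s", g, sp,
                         ss$cds_position[i], ss$edit_type[i])
        } else {
          key <- sprintf("%s|%d|%d|%s", g, mc$column, mc$offset,
                         ss$edit_type[i])
        }
      }
      memb[[key]] <- union(memb[[key]], sp)
    }
  }
  if (!length(memb)) {
    out <- data.frame(region = character(0), count = integer(0))
    attr(out, "classes") <- memb
    return(out)
  }
  region <- vapply(memb, function(s) paste(sort(s), collapse = "&"), "")
  tab <- table(region)
  out <- data.frame(region = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-nchar(out$region), out$region), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "classes") <- memb
  out
}
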