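#' Default gene complement of the simulated plastid genome
#'
#' Six features spanning both strands: four single- or two-exon
#' protein genes, one further CDS, and a tRNA, with group-II-style
#' introns in two of the genes. Lengths are in the range of real
#' plastid genes, scaled to a 20 kb miniature genome.
#'
#' @return data.frame consumed by [sim_config()].
#' @export
default_sim_genes <- function() {
  g <- data.frame(name = c("psbA", "rpoB", "clpP", "ndhB", "petD", "trnV"),
                  kind = c("CDS", "CDS", "CDS", "CDS", "CDS", "tRNA"),
                  strand = c("+", "-", "+", "-", "+", "+"),
                  stringsAsFactors = FALSE)
  g$exon_lens <- I(list(900L, 1200L, c(396L, 204L), c(360L, 363L), 480L, 72L))
  g$intron_lens <- I(list(integer(0), integer(0), 450L, 500L,
                          integer(0), integer(0)))
  g
}

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: a small
#' circular plastid-like genome with sense- and antisense-strand
#' protein genes, a tRNA, introns and intergenic spacers; C-to-U and
#' U-to-C edit sites with per-site efficiencies spanning 5-100 percent;
#' 75 bp reads with elevated error in the terminal 6 bp; heteroplasmic
#' positions in the DNA pool; deliberate reference-sequence errors; and
#' spliced reads mismapped contiguously across exon/intron junctions.
#'
#' @param seed RNG seed; identical seed gives byte-identical output.
#' @param genome_length genome size in bp (default 20000).
#' @param read_length read length in bp (default 75, single-end).
#' @param rna_mean_depth mean RNA read depth over transcribed
#'   positions (default 60).
#' @param dna_mean_depth mean DNA read depth genome-wide (default 40).
#' @param base_error_rate per-base substitution error (default 0.001).
#' @param end_error_rate per-base error within the terminal 6 bp of a
#'   read (default 0.02), the random-hexamer mispriming signature.
#' @param n_edit_sites number of injected edit sites (default 40,
#'   efficiencies evenly spanning 0.05-1.0, shuffled over sites).
#' @param n_heteroplasmy,n_ref_errors,n_end_bias counts of injected
#'   artifact positions per class (defaults 4, 3, 4).
#' @param heteroplasmy_fractions recycled over heteroplasmic sites
#'   (defaults 0.2-0.5; must stay below 0.9 to remain distinct from
#'   reference errors).
#' @param splice_mismap_fraction fraction of long-anchor spliced reads
#'   nevertheless emitted as contiguous alignments (default 0.05).
#' @param mismap_anchor junction overhangs at or below this many bp
#'   are always emitted contiguously: an aligner cannot split a read
#'   on an anchor this short (default 8).
#' @param precursor_fraction fraction of RNA reads drawn from
#'   unspliced precursor transcripts (default 0.3), which is what
#'   gives introns RNA coverage.
#' @param utr_flank transcribed flank beyond gene bounds in bp
#'   (default 100), so UTR/intergenic edits are simulable.
#' @param genes gene table as in [default_sim_genes()].
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 42L, genome_length = 20000L,
                       read_length = 75L, rna_mean_depth = 60,
                       dna_mean_depth = 40, base_error_rate = 0.001,
                       end_error_rate = 0.02, n_edit_sites = 40L,
                       n_heteroplasmy = 4L, n_ref_errors = 3L,
                       n_end_bias = 4L,
                       heteroplasmy_fractions = c(0.2, 0.3, 0.4, 0.5),
                       splice_mismap_fraction = 0.05,
                       mismap_anchor = 8L, precursor_fraction = 0.3,
                       utr_flank = 100L, genes = default_sim_genes()) {
  stopifnot(genome_length >= 2000L, read_length >= 30L,
            base_error_rate >= 0, base_error_rate <= 1,
            end_error_rate >= 0, end_error_rate <= 1,
            splice_mismap_fraction >= 0, splice_mismap_fraction <= 1,
            precursor_fraction >= 0, precursor_fraction <= 1,
            all(heteroplasmy_fractions > 0),
            all(heteroplasmy_fractions < 0.9))
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length),
                 read_length = as.integer(read_length),
                 rna_mean_depth = rna_mean_depth,
                 dna_mean_depth = dna_mean_depth,
                 base_error_rate = base_error_rate,
                 end_error_rate = end_error_rate,
                 n_edit_sites = as.integer(n_edit_sites),
                 n_heteroplasmy = as.integer(n_heteroplasmy),
                 n_ref_errors = as.integer(n_ref_errors),
                 n_end_bias = as.integer(n_end_bias),
                 heteroplasmy_fractions = heteroplasmy_fractions,
                 splice_mismap_fraction = splice_mismap_fraction,
                 mismap_anchor = as.integer(mismap_anchor),
                 precursor_fraction = precursor_fraction,
                 utr_flank = as.integer(utr_flank),
                 genes = genes),
            class = "sim_config")
}

# random CDS: ATG + sense codons + TAA, total length `len` (incl stop)
.random_cds <- function(len) {
  stopifnot(len %% 3L == 0L, len >= 9L)
  codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1,
                  paste, collapse = "")
  sense <- setdiff(codons, STOP_CODONS)
  paste0("ATG",
         paste(sample(sense, len / 3L - 2L, replace = TRUE),
               collapse = ""),
         "TAA")
}

# lay out genes along the genome; returns features + per-gene genomic
# structure, and writes coding sequence into the genome string
.sim_layout <- function(seq, config) {
  genes <- config$genes
  cursor <- 801L
  spacer <- 600L
  fn <- character(0); fk <- character(0); fs <- character(0)
  fp <- character(0); fes <- list(); fee <- list()
  for (i in seq_len(nrow(genes))) {
    exl <- genes$exon_lens[[i]]
    inl <- genes$intron_lens[[i]]
    strand <- genes$strand[i]
    # genomic-order segment lengths (transcript order reversed on "-")
    exg <- if (strand == "-") rev(exl) else exl
    ing <- if (strand == "-") rev(inl) else inl
    seg_len <- integer(0); seg_is_exon <- logical(0)
    for (k in seq_along(exg)) {
      seg_len <- c(seg_len, exg[k]); seg_is_exon <- c(seg_is_exon, TRUE)
      if (k <= length(ing)) {
        seg_len <- c(seg_len, ing[k]); seg_is_exon <- c(seg_is_exon, FALSE)
      }
    }
    ends <- cursor + cumsum(seg_len) - 1L
    starts <- ends - seg_len + 1L
    ex_s <- starts[seg_is_exon]; ex_e <- ends[seg_is_exon]
    in_s <- starts[!seg_is_exon]; in_e <- ends[!seg_is_exon]
    fn <- c(fn, genes$name[i]); fk <- c(fk, genes$kind[i])
    fs <- c(fs, strand); fp <- c(fp, NA_character_)
    fes <- c(fes, list(ex_s)); fee <- c(fee, list(ex_e))
    for (k in seq_along(in_s)) {
      fn <- c(fn, sprintf("%s_intron%d", genes$name[i], k))
      fk <- c(fk, "intron"); fs <- c(fs, strand)
      fp <- c(fp, genes$name[i])
      fes <- c(fes, list(in_s[k])); fee <- c(fee, list(in_e[k]))
    }
    # write the gene sequence into the genome
    if (genes$kind[i] == "CDS") {
      cds <- .random_cds(sum(exl))
      # chunk by transcript-order exon lengths
      offs <- cumsum(c(0L, exl))
      tx_s <- if (strand == "-") rev(ex_s) else ex_s
      tx_e <- if (strand == "-") rev(ex_e) else ex_e
      for (k in seq_along(exl)) {
        chunk <- substr(cds, offs[k] + 1L, offs[k + 1L])
        if (strand == "-") chunk <- revcomp(chunk)
        substr(seq, tx_s[k], tx_e[k]) <- chunk
      }
    }
    cursor <- max(ends) + spacer
  }
  if (cursor - spacer > config$genome_length) {
    stop("genes do not fit in genome_length")
  }
  ft <- features_table(fn, fk, fs, fes, fee, parent = fp)
  list(seq = seq, features = ft)
}

# transcript maps of one gene: genomic position of every transcript
# base, 5'->3', for the mature (spliced) and precursor isoforms
.gene_maps <- function(features, name, config) {
  i <- match(name, features$name)
  s <- features$exon_starts[[i]]; e <- features$exon_ends[[i]]
  strand <- features$strand[i]
  gs <- min(s); ge <- max(e)
  fl <- config$utr_flank
  lo <- max(1L, gs - fl); hi <- min(config$genome_length, ge + fl)
  pre <- seq(lo, hi)
  exonic <- unlist(lapply(seq_along(s), function(k) seq(s[k], e[k])))
  mat <- c(seq(lo, gs - 1L), exonic, seq(ge + 1L, hi))
  if (strand == "-") { pre <- rev(pre); mat <- rev(mat) }
  list(pre = pre, mat = mat, strand = strand)
}

# transcript-strand bases along a map
.map_bases <- function(seq, map, strand) {
  b <- substring(seq, map, map)
  if (strand == "-") complement_base(b) else b
}

.pick_spaced <- function(cands, n, used, minsep = 3L) {
  picked <- integer(0)
  cands <- sample(cands)
  for (p in cands) {
    if (length(picked) >= n) break
    if (!length(used) || min(abs(used - p)) >= minsep) {
      picked <- c(picked, p); used <- c(used, p)
    }
  }
  if (length(picked) < n) {
    stop(sprintf("could not place %d sites with spacing %d", n, minsep))
  }
  list(picked = picked, used = used)
}

# CIGAR for strictly ascending genomic positions (gaps become N)
.cigar_from_positions <- function(pos) {
  d <- diff(pos)
  stopifnot(all(d >= 1L))
  br <- which(d > 1L)
  mlens <- diff(c(0L, br, length(pos)))
  nlens <- d[br] - 1L
  parts <- sprintf("%dM", mlens[1])
  for (k in seq_along(nlens)) {
    parts <- paste0(parts, sprintf("%dN%dM", nlens[k], mlens[k + 1L]))
  }
  parts
}

#' Generate a complete synthetic dataset
#'
#' Builds the true genome, gene annotation, a published genome
#' carrying the injected reference errors, edited RNA reads (mature
#' spliced plus unspliced precursor pools, with junction mismapping),
#' DNA reads with heteroplasmic positions, and the ground-truth
#' tables. All randomness derives from `config$seed`; the same config
#' yields byte-identical output. Random sequencing errors are
#' suppressed at injected-artifact positions so every artifact has a
#' single cause.
#'
#' @param config a [sim_config()].
#' @return list with elements `genome` (published reference, the
#'   pipeline input), `true_genome`, `features`, `rna_reads`,
#'   `dna_reads`, `truth` (list: `edits`, `artifacts`), `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  set.seed(config$seed)
  L <- config$genome_length
  rl <- config$read_length
  seq_true <- paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
  lay <- .sim_layout(seq_true, config)
  seq_true <- lay$seq
  ft <- lay$features
  genes <- config$genes
  base_at <- function(p) substring(seq_true, p, p)
  tx_base <- function(p, strand) {
    b <- base_at(p)
    if (strand == "-") complement_base(b) else b
  }
  maps <- lapply(genes$name, function(g) .gene_maps(ft, g, config))
  names(maps) <- genes$name

  # ---- junction truth: intron positions a contiguously mismapped
  # spliced read would mismatch ----
  ib <- .intron_bounds(ft)
  jrows <- list()
  if (!is.null(ib)) {
    for (j in seq_len(nrow(ib))) {
      is <- ib$start[j]; ie <- ib$end[j]
      for (d in seq_len(rl - 1L)) {
        pl <- is + d - 1L
        if (pl <= ie && ie + d <= L && base_at(ie + d) != base_at(pl)) {
          jrows[[length(jrows) + 1L]] <- data.frame(
            position = pl, alt = base_at(ie + d), category = "JUNCTION",
            param = sprintf("left_boundary=%d", is))
        }
        pr <- ie - d + 1L
        if (pr >= is && is - d >= 1L && base_at(is - d) != base_at(pr)) {
          jrows[[length(jrows) + 1L]] <- data.frame(
            position = pr, alt = base_at(is - d), category = "JUNCTION",
            param = sprintf("right_boundary=%d", ie))
        }
      }
    }
  }
  junction_truth <- if (length(jrows)) do.call(rbind, jrows) else
    data.frame(position = integer(0), alt = character(0),
               category = character(0), param = character(0))

  # positions too close to a junction for clean single-cause artifacts
  near_junction <- integer(0)
  if (!is.null(ib)) {
    for (j in seq_len(nrow(ib))) {
      w <- config$mismap_anchor + 2L
      near_junction <- c(near_junction,
                         (ib$start[j] - w):(ib$start[j] + w),
                         (ib$end[j] - w):(ib$end[j] + w))
    }
  }

  # ---- candidate pools ----
  cds_genes <- genes$name[genes$kind == "CDS"]
  cds_pos_pool <- list()   # gene -> genomic positions of interior CDS bases
  for (g in cds_genes) {
    map <- cds_genomic_map(ft, g)
    interior <- map[4:(length(map) - 3L)]
    cds_pos_pool[[g]] <- setdiff(interior, near_junction)
  }
  all_cds_pos <- unlist(cds_pos_pool, use.names = FALSE)
  strand_of_gene <- stats::setNames(genes$strand, genes$name)

  used <- c(junction_truth$position, near_junction)

  # ---- edit sites ----
  n_utr <- min(4L, config$n_edit_sites)
  n_intron <- if (!is.null(ib) && config$n_edit_sites > 10L) 2L else 0L
  n_trna <- if ("tRNA" %in% genes$kind && config$n_edit_sites > 6L) 1L else 0L
  n_cds <- config$n_edit_sites - n_utr - n_intron - n_trna
  stopifnot(n_cds >= 0L)
  n_u2c <- if (n_cds >= 8L) 4L else 0L

  erow <- list()
  add_edit <- function(pos, type, strand, gene, kind) {
    erow[[length(erow) + 1L]] <<- data.frame(
      position = pos, edit_type = type, strand = strand, gene = gene,
      feature_kind = kind, stringsAsFactors = FALSE)
  }
  # CDS edits: C on the coding strand for C2U, T for U2C
  gene_of_cds_pos <- rep(names(cds_pos_pool),
                         vapply(cds_pos_pool, length, 1L))
  tx_b <- mapply(function(p, g) tx_base(p, strand_of_gene[[g]]),
                 all_cds_pos, gene_of_cds_pos)
  pool_c <- all_cds_pos[tx_b == "C"]; gene_c <- gene_of_cds_pos[tx_b == "C"]
  pool_t <- all_cds_pos[tx_b == "T"]; gene_t <- gene_of_cds_pos[tx_b == "T"]
  pk <- .pick_spaced(pool_c, n_cds - n_u2c, used); used <- pk$used
  for (p in pk$picked) {
    g <- gene_c[match(p, pool_c)]
    add_edit(p, "C2U", strand_of_gene[[g]], g, "CDS")
  }
  if (n_u2c > 0L) {
    pk <- .pick_spaced(pool_t, n_u2c, used); used <- pk$used
    for (p in pk$picked) {
      g <- gene_t[match(p, pool_t)]
      add_edit(p, "U2C", strand_of_gene[[g]], g, "CDS")
    }
  }
  # intron edits (covered only by precursor reads)
  if (n_intron > 0L) {
    ipool <- integer(0); igene <- character(0)
    intr <- which(ft$kind == "intron")
    for (i in intr) {
      s <- ft$exon_starts[[i]][1]; e <- ft$exon_ends[[i]][1]
      cand <- setdiff(seq(s, e), near_junction)
      st <- ft$strand[i]
      cand <- cand[vapply(cand, function(p) tx_base(p, st) == "C", TRUE)]
      ipool <- c(ipool, cand); igene <- c(igene, rep(ft$parent[i], length(cand)))
    }
    pk <- .pick_spaced(ipool, n_intron, used); used <- pk$used
    for (p in pk$picked) {
      g <- igene[match(p, ipool)]
      add_edit(p, "C2U", strand_of_gene[[g]], g, "intron")
    }
  }
  # tRNA edit
  if (n_trna > 0L) {
    ti <- which(ft$kind == "tRNA")[1]
    s <- ft$exon_starts[[ti]][1]; e <- ft$exon_ends[[ti]][1]
    st <- ft$strand[ti]
    cand <- seq(s, e)
    cand <- cand[vapply(cand, function(p) tx_base(p, st) == "C", TRUE)]
    pk <- .pick_spaced(cand, n_trna, used); used <- pk$used
    add_edit(pk$picked, "C2U", st, ft$name[ti], "tRNA")
  }
  # UTR edits, in the transcribed flanks
  if (n_utr > 0L) {
    upool <- integer(0); ugene <- character(0)
    for (g in genes$name) {
      m <- maps[[g]]
      i <- match(g, ft$name)
      span <- c(min(ft$exon_starts[[i]]), max(ft$exon_ends[[i]]))
      fl <- setdiff(m$pre[m$pre < span[1] | m$pre > span[2]], near_junction)
      st <- m$strand
      fl <- fl[vapply(fl, function(p) tx_base(p, st) == "C", TRUE)]
      upool <- c(upool, fl); ugene <- c(ugene, rep(g, length(fl)))
    }
    pk <- .pick_spaced(upool, n_utr, used); used <- pk$used
    for (p in pk$picked) {
      g <- ugene[match(p, upool)]
      add_edit(p, "C2U", strand_of_gene[[g]], g, "UTR")
    }
  }
  edits <- if (length(erow)) do.call(rbind, erow) else
    data.frame(position = integer(0), edit_type = character(0),
               strand = character(0), gene = character(0),
               feature_kind = character(0))
  edits$efficiency <- if (nrow(edits)) {
    sample(seq(0.05, 1, length.out = nrow(edits)))
  } else numeric(0)

  # ---- heteroplasmy / reference-error / end-bias truth ----
  other_base <- function(b) sample(setdiff(DNA_BASES, b), 1L)
  arow <- list()
  if (config$n_heteroplasmy > 0L) {
    pk <- .pick_spaced(all_cds_pos, config$n_heteroplasmy, used)
    used <- pk$used
    fr <- rep_len(config$heteroplasmy_fractions, config$n_heteroplasmy)
    for (k in seq_along(pk$picked)) {
      p <- pk$picked[k]
      arow[[length(arow) + 1L]] <- data.frame(
        position = p, alt = other_base(base_at(p)),
        category = "HETEROPLASMY", param = sprintf("fraction=%g", fr[k]))
    }
  }
  if (config$n_ref_errors > 0L) {
    pk <- .pick_spaced(all_cds_pos, config$n_ref_errors, used)
    used <- pk$used
    for (p in pk$picked) {
      arow[[length(arow) + 1L]] <- data.frame(
        position = p, alt = base_at(p), category = "REF_ERROR",
        param = sprintf("published=%s", other_base(base_at(p))))
    }
  }
  if (config$n_end_bias > 0L) {
    pk <- .pick_spaced(all_cds_pos, config$n_end_bias, used)
    used <- pk$used
    for (p in pk$picked) {
      arow[[length(arow) + 1L]] <- data.frame(
        position = p, alt = other_base(base_at(p)),
        category = "END_BIAS", param = "")
    }
  }
  injected <- if (length(arow)) do.call(rbind, arow) else
    junction_truth[0, ]
  artifacts <- rbind(injected, junction_truth)
  rownames(artifacts) <- NULL

  het <- artifacts[artifacts$category == "HETEROPLASMY", , drop = FALSE]
  het$fraction <- as.numeric(sub("fraction=", "", het$param))
  referr <- artifacts[artifacts$category == "REF_ERROR", , drop = FALSE]
  referr$published <- sub("published=", "", referr$param)
  endb <- artifacts[artifacts$category == "END_BIAS", , drop = FALSE]

  # published genome: true genome with the reference errors injected
  seq_pub <- seq_true
  for (k in seq_len(nrow(referr))) {
    substr(seq_pub, referr$position[k], referr$position[k]) <-
      referr$published[k]
  }

  # random errors never hit injected-artifact positions
  err_excluded <- unique(artifacts$position)

  # ---- RNA reads ----
  rna <- .sim_rna_reads(seq_true, ft, maps, edits, het, endb,
                        err_excluded, config)
  # ---- DNA reads ----
  dna <- .sim_dna_reads(seq_true, het, err_excluded, config)

  genome_pub <- ref_genome("sim_plastid", seq_pub)
  truth <- list(edits = edits[order(edits$position), ],
                artifacts = artifacts[order(artifacts$position), ])
  rownames(truth$edits) <- rownames(truth$artifacts) <- NULL
  list(genome = genome_pub,
       true_genome = ref_genome("sim_plastid", seq_true),
       features = ft, rna_reads = rna, dna_reads = dna,
       truth = truth, config = config)
}

.sim_rna_reads <- function(seq_true, ft, maps, edits, het, endb,
                           err_excluded, config) {
  rl <- config$read_length
  rows <- list()
  for (g in names(maps)) {
    m <- maps[[g]]
    strand <- m$strand
    dir <- if (strand == "-") -1L else 1L
    for (iso in c("mat", "pre")) {
      map <- m[[iso]]
      Lt <- length(map)
      if (Lt < rl) next
      frac <- if (iso == "pre") config$precursor_fraction else
        1 - config$precursor_fraction
      n <- round(frac * config$rna_mean_depth * Lt / rl)
      if (n <= 0L) next
      tb_all <- .map_bases(seq_true, map, strand)
      # transcript indices of events on this isoform
      e_idx <- match(edits$position, map)
      h_idx <- match(het$position, map)
      b_idx <- match(endb$position, map)
      jumps <- which(abs(diff(map)) != 1L)    # junction after this index
      err_ok <- !(map %in% err_excluded)
      starts <- sample.int(Lt - rl + 1L, n, replace = TRUE)
      for (r in seq_len(n)) {
        s <- starts[r]; e <- s + rl - 1L
        tb <- tb_all[s:e]
        # per-read edits at per-site efficiency
        ei <- which(!is.na(e_idx) & e_idx >= s & e_idx <= e)
        for (k in ei) {
          if (stats::runif(1) < edits$efficiency[k]) {
            tb[e_idx[k] - s + 1L] <-
              if (edits$edit_type[k] == "C2U") "T" else "C"
          }
        }
        # heteroplasmy is transcribed too
        hi <- which(!is.na(h_idx) & h_idx >= s & h_idx <= e)
        for (k in hi) {
          if (stats::runif(1) < het$fraction[k]) {
            a <- het$alt[k]
            tb[h_idx[k] - s + 1L] <-
              if (strand == "-") complement_base(a) else a
          }
        }
        # placement: spliced, or contiguous when mismapped
        cross <- jumps[jumps >= s & jumps < e]
        mismap <- FALSE
        if (length(cross) == 1L) {
          left <- cross - s + 1L; right <- rl - left
          mismap <- min(left, right) <= config$mismap_anchor ||
            stats::runif(1) < config$splice_mismap_fraction
          if (mismap) {
            pos <- if (left >= right) map[s] + dir * (0:(rl - 1L)) else
              map[e] - dir * ((rl - 1L):0)
          } else {
            pos <- map[s:e]
          }
        } else if (length(cross) > 1L) {
          pos <- map[s:e]
        } else {
          pos <- map[s:e]
        }
        # sequencing errors (never at injected-artifact positions)
        idx <- seq_len(rl)
        dist <- pmin(idx - 1L, rl - idx)
        rate <- ifelse(dist <= 5L, config$end_error_rate,
                       config$base_error_rate)
        hit <- which(stats::runif(rl) < rate & !(pos %in% err_excluded))
        for (k in hit) {
          tb[k] <- sample(setdiff(DNA_BASES, tb[k]), 1L)
        }
        # deliberate end-biased mismatches at injected positions
        bi <- which(!is.na(b_idx))
        for (k in bi) {
          j <- match(endb$position[k], pos)
          if (!is.na(j) && min(j - 1L, rl - j) <= 6L) {
            a <- endb$alt[k]
            tb[j] <- if (strand == "-") complement_base(a) else a
          }
        }
        if (strand == "-") {
          bases <- revcomp(paste(tb, collapse = ""))
          gpos <- rev(pos)
        } else {
          bases <- paste(tb, collapse = "")
          gpos <- pos
        }
        rows[[length(rows) + 1L]] <- list(
          read_id = sprintf("%s_%s_%05d", g, iso, r),
          start = gpos[1], cigar = .cigar_from_positions(gpos),
          bases = bases, is_reverse = strand == "-")
      }
    }
  }
  out <- data.frame(
    read_id = vapply(rows, `[[`, "", "read_id"),
    source = "RNA",
    start = vapply(rows, `[[`, 1L, "start"),
    cigar = vapply(rows, `[[`, "", "cigar"),
    bases = vapply(rows, `[[`, "", "bases"),
    is_reverse = vapply(rows, `[[`, TRUE, "is_reverse"),
    stringsAsFactors = FALSE)
  class(out) <- c("aligned_reads", "data.frame")
  out
}

.sim_dna_reads <- function(seq_true, het, err_excluded, config) {
  rl <- config$read_length
  L <- config$genome_length
  n <- round(config$dna_mean_depth * L / rl)
  if (n == 0L) {
    out <- data.frame(read_id = character(0), source = character(0),
                      start = integer(0), cigar = character(0),
                      bases = character(0), is_reverse = logical(0))
    class(out) <- c("aligned_reads", "data.frame")
    return(out)
  }
  starts <- sample.int(L - rl + 1L, n, replace = TRUE)
  bases <- substring(seq_true, starts, starts + rl - 1L)
  # heteroplasmic alternates at their fractions
  for (k in seq_len(nrow(het))) {
    p <- het$position[k]
    cov <- which(starts <= p & starts + rl - 1L >= p)
    flip <- cov[stats::runif(length(cov)) < het$fraction[k]]
    for (i in flip) {
      substr(bases[i], p - starts[i] + 1L, p - starts[i] + 1L) <- het$alt[k]
    }
  }
  # uniform sequencing errors, never at injected-artifact positions
  err <- which(matrix(stats::runif(n * rl), n, rl) < config$base_error_rate,
               arr.ind = TRUE)
  for (r in seq_len(nrow(err))) {
    i <- err[r, 1L]; j <- err[r, 2L]
    p <- starts[i] + j - 1L
    if (p %in% err_excluded) next
    cur <- substr(bases[i], j, j)
    substr(bases[i], j, j) <- sample(setdiff(DNA_BASES, cur), 1L)
  }
  out <- data.frame(
    read_id = sprintf("dna_%06d", seq_len(n)),
    source = "DNA", start = starts, cigar = sprintf("%dM", rl),
    bases = bases,
    is_reverse = rep(c(FALSE, TRUE), length.out = n),
    stringsAsFactors = FALSE)
  class(out) <- c("aligned_reads", "data.frame")
  out
}

#' Write a simulated dataset to disk
#'
#' Emits the published and true genomes (FASTA), the annotation (TSV
#' dialect), both read sets (SAM) and the truth tables (TSV).
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome(sim$genome, file.path(dir, "genome.fa"))
  write_genome(sim$true_genome, file.path(dir, "true_genome.fa"))
  write_annotation(sim$features, file.path(dir, "annotation.tsv"))
  write_sam(sim$rna_reads, sim$genome, file.path(dir, "rna.sam"))
  write_sam(sim$dna_reads, sim$genome, file.path(dir, "dna.sam"))
  utils::write.table(sim$truth$edits, file.path(dir, "truth_edits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$artifacts,
                     file.path(dir, "truth_artifacts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Compare pipeline output against simulation truth
#'
#' Scores recovery of injected edit sites (by position and edit type)
#' and the disposition of injected artifacts: an artifact position
#' that was called must end up rejected with its true category; an
#' artifact too weakly supported to be called at all is reported as
#' `not_called`, never as curated.
#'
#' @param curated,rejected curated and rejected call data.frames from
#'   [filter_calls()] (rejected carries `categories`).
#' @param truth the `truth` element of [simulate_dataset()].
#' @param depth0 optional per-position trim-0 RNA depth vector, used
#'   to report depth at missed edit sites.
#' @return list(edits, artifacts, summary): per-site and per-artifact
#'   tables plus scalar counts.
#' @export
truth_compare <- function(curated, rejected, truth, depth0 = NULL) {
  te <- truth$edits
  hit <- match(te$position, curated$position)
  te$recovered <- !is.na(hit) &
    curated$edit_type[hit] == te$edit_type
  te$est_efficiency <- ifelse(is.na(hit), NA,
                              curated$frequency[hit])
  te$depth <- if (!is.null(depth0)) depth0[te$position] else
    ifelse(is.na(hit), NA_integer_, curated$depth[hit])
  te$efficiency_error <- te$est_efficiency - te$efficiency

  ta <- truth$artifacts
  rkey <- match(ta$position, rejected$position)
  ckey <- match(ta$position, curated$position)
  ta$disposition <- ifelse(
    !is.na(rkey),
    ifelse(mapply(function(k, cat) {
      !is.na(k) && cat %in% strsplit(rejected$categories[k], ",")[[1]]
    }, rkey, ta$category), "rejected_correct", "rejected_other"),
    ifelse(!is.na(ckey), "curated", "not_called"))

  summary <- list(
    n_true_edits = nrow(te),
    n_edits_recovered = sum(te$recovered),
    n_artifacts = nrow(ta),
    n_artifacts_called = sum(ta$disposition != "not_called"),
    n_artifacts_rejected_correct = sum(ta$disposition == "rejected_correct"),
    n_artifacts_curated = sum(ta$disposition == "curated"),
    mean_signed_efficiency_error =
      mean(te$efficiency_error[te$recovered], na.rm = TRUE))
  list(edits = te, artifacts = ta, summary = summary)
}
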