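#' Per-genotype mean shapes at one marker
#'
#' Coordinate-wise mean of the line phenotypes within each genotype class,
#' returned as outlines with their scalar shape descriptors. Classes below
#' the minimum size are omitted with a warning.
#'
#' @param phenotypes `shape_pheno` or list of aligned outlines.
#' @param genotypes genotype call per line (NA dropped).
#' @param min_group_size minimum lines per class.
#' @return List with `shapes` (named list of [outline]s, one per genotype)
#'   and `traits` (data frame: genotype, n, length, width, area,
#'   broadest_position).
#' @export
genotype_mean_shapes <- function(phenotypes, genotypes, min_group_size = 5L) {
  ph <- as_shape_pheno(phenotypes)
  if (length(genotypes) != length(ph$lines))
    stop("`genotypes` must have one call per line")
  use <- !is.na(genotypes)
  g <- factor(genotypes[use])
  cnt <- table(g)
  keep <- names(cnt)[cnt >= min_group_size]
  if (length(keep) < nlevels(g))
    warning("omitting genotype classes below the minimum group size")
  if (length(keep) == 0L) stop("no genotype class meets the minimum size")
  shapes <- list()
  traits <- NULL
  for (lvl in keep) {
    sel <- use & genotypes == lvl
    m <- cbind(colMeans(ph$X[sel, , drop = FALSE]),
               colMeans(ph$Y[sel, , drop = FALSE]))
    o <- outline(m, id = lvl)
    td <- trait_descriptors(o)
    shapes[[lvl]] <- o
    traits <- rbind(traits,
                    data.frame(genotype = lvl, n = sum(sel),
                               length = td$length, width = td$width,
                               area = td$area,
                               broadest_position = td$broadest_position))
  }
  list(shapes = shapes, traits = traits)
}

#' Classify a QTL's shape-difference pattern
#'
#' Assigns one of the four QTL expression classes from the genotype mean
#' contours: `LENGTH` (long-narrow vs short-broad: both relative length
#' range and relative width range exceed `tau_rel`), `BASE` (equal axis,
#' width change concentrated in the basal third), `TIP` (equal axis,
#' divergence concentrated in the apical third), `WIDTH` (equal axis,
#' width change spread along the blade), else `NONE`. Regional divergence
#' is the mean pairwise landmark distance between genotype means within
#' each axial third (base/middle/tip) of the pooled mean shape.
#'
#' @param mean_shapes result of [genotype_mean_shapes()], or a named list
#'   of genotype mean [outline]s.
#' @param tau_rel relative-range threshold for "the descriptor moved".
#' @param tau_ratio regional dominance ratio for TIP/BASE calls.
#' @param marker optional marker id carried into the result.
#' @return Object of class `qtl_pattern`: list with `marker`, `class`
#'   (one of LENGTH/WIDTH/TIP/BASE/NONE), `dL`, `dW`, `d_base`, `d_mid`,
#'   `d_tip`.
#' @export
classify_pattern <- function(mean_shapes, tau_rel = 0.045, tau_ratio = 3.0,
                             marker = NA_character_) {
  shapes <- if (!is.null(mean_shapes$shapes)) mean_shapes$shapes else mean_shapes
  if (length(shapes) < 2L) stop("need at least two genotype mean shapes")
  pts <- lapply(shapes, as_outline_points)
  k <- unique(vapply(pts, nrow, 1L))
  if (length(k) != 1L) stop("genotype means must share a landmark count")
  td <- lapply(pts, trait_descriptors)
  lens <- vapply(td, `[[`, 1, "length")
  wids <- vapply(td, `[[`, 1, "width")
  dL <- (max(lens) - min(lens)) / mean(lens)
  dW <- (max(wids) - min(wids)) / mean(wids)
  # axial thirds of the pooled mean shape
  pooled <- Reduce(`+`, pts) / length(pts)
  ctr <- colMeans(pooled)
  p <- sweep(pooled, 2L, ctr)
  ev <- eigen(stats::cov(p), symmetric = TRUE)
  axis <- ev$vectors[, 1L]
  s <- as.numeric(p %*% axis)
  if (s[1L] > 0) { axis <- -axis; s <- -s }
  cuts <- min(s) + (max(s) - min(s)) * c(1, 2) / 3
  region <- ifelse(s < cuts[1L], "base", ifelse(s < cuts[2L], "mid", "tip"))
  # mean pairwise distance between genotype means, landmark-wise
  pairs <- utils::combn(length(pts), 2L)
  dist_lm <- rowMeans(apply(pairs, 2L, function(ij)
    sqrt(rowSums((pts[[ij[1L]]] - pts[[ij[2L]]])^2))))
  d_base <- mean(dist_lm[region == "base"])
  d_mid <- mean(dist_lm[region == "mid"])
  d_tip <- mean(dist_lm[region == "tip"])
  cls <- if (dL > tau_rel && dW > tau_rel) "LENGTH"
  else if (dL <= tau_rel && dW > tau_rel && d_base > 0 &&
           d_base >= tau_ratio * d_tip) "BASE"
  else if (dL <= tau_rel && d_tip > 0 && d_tip >= tau_ratio * d_base) "TIP"
  else if (dL <= tau_rel && dW > tau_rel) "WIDTH"
  else "NONE"
  structure(list(marker = marker, class = cls, dL = dL, dW = dW,
                 d_base = d_base, d_mid = d_mid, d_tip = d_tip),
            class = "qtl_pattern")
}

#' @export
print.qtl_pattern <- function(x, ...) {
  cat(sprintf("<qtl_pattern> %s: %s (dL %.3f, dW %.3f, d_base %.4f, d_mid %.4f, d_tip %.4f)\n",
              x$marker, x$class, x$dL, x$dW, x$d_base, x$d_mid, x$d_tip))
  invisible(x)
}

#' Percent difference between two genotypic means
#'
#' `100 |a - b| / min(a, b)`, the convention used in genotype effect tables
#' where the smaller mean is the baseline; reported to two decimals.
#' Vectorized.
#'
#' @param a,b positive means.
#' @return Percentage difference(s), rounded to 2 decimals.
#' @examples
#' percent_difference(1.823, 1.598)  # 14.08
#' @export
percent_difference <- function(a, b) {
  if (any(!is.finite(a)) || any(!is.finite(b)) || any(a <= 0) || any(b <= 0))
    stop("means must be positive")
  round(100 * abs(a - b) / pmin(a, b), 2)
}

#' Genotype effect table across two demes
#'
#' For each marker and each genotype class present in both demes, computes
#' per-deme mean area, width and length of the line shapes and the
#' cross-deme percent difference of each. Markers significant in exactly
#' one deme are flagged deme-specific. Genotype classes absent (or under
#' the size rule) in one deme yield missing cells, never imputed.
#'
#' @param phen_a,phen_b `shape_pheno` objects for the two demes (e.g. high
#'   and low altitude).
#' @param geno genotype dose matrix (markers x lines) covering both demes'
#'   lines by column name.
#' @param markers character vector of marker ids (rows of `geno`) to
#'   tabulate; defaults to all.
#' @param sig_a,sig_b optional named logical vectors of per-deme
#'   significance (from the scans) used for the deme-specific flag.
#' @param deme_names labels for the two demes in the output.
#' @param min_group_size minimum lines per genotype class and deme.
#' @return Data frame: marker, genotype, per-deme mean area/width/length,
#'   diff_area, diff_width, diff_length (percent), deme_specific.
#' @export
effect_table <- function(phen_a, phen_b, geno, markers = NULL,
                         sig_a = NULL, sig_b = NULL,
                         deme_names = c("high", "low"),
                         min_group_size = 5L) {
  geno <- as.matrix(geno)
  if (is.null(markers)) markers <- rownames(geno) %||% seq_len(nrow(geno))
  ga <- geno[, phen_a$lines, drop = FALSE]
  gb <- geno[, phen_b$lines, drop = FALSE]
  rows <- NULL
  for (mk in markers) {
    ta <- tryCatch(
      suppressWarnings(genotype_mean_shapes(phen_a, ga[mk, ], min_group_size))$traits,
      error = function(e) NULL)
    tb <- tryCatch(
      suppressWarnings(genotype_mean_shapes(phen_b, gb[mk, ], min_group_size))$traits,
      error = function(e) NULL)
    gts <- union(ta$genotype, tb$genotype)
    if (length(gts) == 0L) next
    spec <- if (!is.null(sig_a) && !is.null(sig_b))
      xor(isTRUE(sig_a[[mk]]), isTRUE(sig_b[[mk]])) else NA
    for (gt in gts) {
      ra <- ta[ta$genotype == gt, ]
      rb <- tb[tb$genotype == gt, ]
      va <- if (nrow(ra) == 1L) ra else
        data.frame(area = NA_real_, width = NA_real_, length = NA_real_)
      vb <- if (nrow(rb) == 1L) rb else
        data.frame(area = NA_real_, width = NA_real_, length = NA_real_)
      both <- nrow(ra) == 1L && nrow(rb) == 1L
      rows <- rbind(rows, data.frame(
        marker = mk, genotype = gt,
        area_a = va$area, width_a = va$width, length_a = va$length,
        area_b = vb$area, width_b = vb$width, length_b = vb$length,
        diff_area = if (both) percent_difference(va$area, vb$area) else NA_real_,
        diff_width = if (both) percent_difference(va$width, vb$width) else NA_real_,
        diff_length = if (both) percent_difference(va$length, vb$length) else NA_real_,
        deme_specific = spec))
    }
  }
  if (is.null(rows)) stop("no marker produced a genotype effect row")
  names(rows) <- sub("_a$", paste0("_", deme_names[1L]), names(rows))
  names(rows) <- sub("_b$", paste0("_", deme_names[2L]), names(rows))
  rows
}

#' Bundled worked-example table of genotypic effect means
#'
#' Published per-genotype mean leaf area and width for 23 annotated SNPs in
#' a high- and a low-altitude poplar population, with the printed percent
#' Difference columns. Used by examples and tests to exercise
#' [percent_difference()] against an independent published computation.
#'
#' @return Data frame with columns chrom, pos, gene, genotype,
#'   area_high, width_high, area_low, width_low, diff_area, diff_width.
#' @export
genotype_effect_means <- function() {
  path <- system.file("extdata", "genotype_effect_means.tsv",
                      package = "leafscan", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
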