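#' AR(1) multivariate normal log-density
#'
#' Log-density of a residual vector under a zero-mean Gaussian with
#' first-order autoregressive covariance `Sigma[i, j] = sigma2 * rho^|i-j|`,
#' evaluated in O(K) with the closed-form determinant
#' `K log(sigma2) + (K - 1) log(1 - rho^2)` and the tridiagonal inverse
#' quadratic form.
#'
#' @param e numeric residual vector (length K >= 2).
#' @param sigma2 innovationless marginal variance (> 0).
#' @param rho lag-1 autocorrelation, |rho| < 1.
#' @return Scalar log-density.
#' @examples
#' ar1_loglik(c(0, 0), 1, 0)   # -log(2*pi)
#' @export
ar1_loglik <- function(e, sigma2, rho) {
  k <- length(e)
  if (k < 2L) stop("residual vector must have length >= 2")
  if (!is.finite(sigma2) || sigma2 <= 0) stop("`sigma2` must be > 0")
  if (!is.finite(rho) || abs(rho) >= 1) stop("`rho` must satisfy |rho| < 1")
  ldet <- k * log(sigma2) + (k - 1) * log(1 - rho^2)
  inner <- if (k > 2L) sum(e[2:(k - 1L)]^2) else 0
  q <- (e[1L]^2 + e[k]^2 + (1 + rho^2) * inner -
          2 * rho * sum(e[-k] * e[-1L])) / (sigma2 * (1 - rho^2))
  -k / 2 * log(2 * pi) - ldet / 2 - q / 2
}

# ---- internal fast likelihood core ----------------------------------------
#
# Phenotypes are carried as two n x K matrices (X: x-coordinates, Y:
# y-coordinates). The elliptic Fourier mean curve is fitted by least squares
# on the uniform (landmark-index) Fourier basis, whose hat matrix depends
# only on K and the order and is precomputed once; this is what makes
# thousand-replicate permutation thresholds tractable.

ef_hat_matrix <- function(k, order) {
  b <- fourier_basis(seq_len(k) - 1L, k, order)
  b %*% solve(crossprod(b), t(b))
}

# Profile ML of one AR(1) block from pooled residual scalars.
# Returns list(ll, sigma2, rho).
.ar1_profile <- function(e_mat, n, k) {
  s_end <- sum(e_mat[, 1L]^2) + sum(e_mat[, k]^2)
  s_in <- sum(e_mat^2) - s_end
  s_01 <- sum(e_mat[, -k] * e_mat[, -1L])
  nk <- n * k
  obj <- function(rho) {
    q <- (s_end + (1 + rho^2) * s_in - 2 * rho * s_01) / (1 - rho^2)
    sigma2 <- q / nk
    if (sigma2 <= 0) return(Inf)
    nk / 2 * log(sigma2) + n * (k - 1) / 2 * log(1 - rho^2)
  }
  opt <- stats::optimize(obj, c(-0.99, 0.99), tol = 1e-7)
  rho <- opt$minimum
  q <- (s_end + (1 + rho^2) * s_in - 2 * rho * s_01) / (1 - rho^2)
  sigma2 <- q / nk
  if (!is.finite(sigma2) || sigma2 < 1e-25)
    stop("degenerate data: residuals are identically zero")
  ll <- -nk / 2 * log(2 * pi) - nk / 2 * log(sigma2) -
    n * (k - 1) / 2 * log(1 - rho^2) - nk / 2
  list(ll = ll, sigma2 = sigma2, rho = rho)
}

# Fit group-specific EF mean curves with a shared AR(1) covariance.
# gidx: integer group index 1..J per line. Returns ll and components.
.fit_ll <- function(X, Y, H, gidx, J, details = FALSE) {
  n <- nrow(X); k <- ncol(X)
  cnt <- tabulate(gidx, J)
  Mx <- rowsum(X, gidx, reorder = TRUE) / cnt
  My <- rowsum(Y, gidx, reorder = TRUE) / cnt
  Fx <- Mx %*% H
  Fy <- My %*% H
  Ex <- X - Fx[gidx, , drop = FALSE]
  Ey <- Y - Fy[gidx, , drop = FALSE]
  bx <- .ar1_profile(Ex, n, k)
  by <- .ar1_profile(Ey, n, k)
  if (!details) return(bx$ll + by$ll)
  list(ll = bx$ll + by$ll,
       cov = list(sigma2_x = bx$sigma2, rho_x = bx$rho,
                  sigma2_y = by$sigma2, rho_y = by$rho),
       fitted_x = Fx, fitted_y = Fy, mean_x = Mx, mean_y = My,
       counts = cnt)
}

# LR statistic for one grouping; X, Y already restricted to usable lines.
.lr_core <- function(X, Y, H, gidx, J, ll0 = NULL) {
  ll1 <- .fit_ll(X, Y, H, gidx, J)
  if (is.null(ll0)) ll0 <- .fit_ll(X, Y, H, rep.int(1L, nrow(X)), 1L)
  max(0, 2 * (ll1 - ll0))
}

# ---- phenotype container ---------------------------------------------------

#' Assemble shape phenotypes for association scanning
#'
#' Stacks per-line average shapes (aligned outlines) into the coordinate
#' matrices used by the likelihood machinery, together with line ids and
#' deme labels.
#'
#' @param avg_shapes list of aligned per-line average [outline]s (equal K);
#'   names or `line_id` fields give line ids.
#' @param deme optional named character vector (or vector aligned with
#'   `avg_shapes`) of deme labels per line.
#' @return Object of class `shape_pheno`: list with `X`, `Y` (n x K
#'   matrices), `z` (n x 2K, x block then y block), `lines`, `deme`, `K`.
#' @export
shape_phenotypes <- function(avg_shapes, deme = NULL) {
  if (inherits(avg_shapes, "aligned_shapes")) avg_shapes <- avg_shapes$shapes
  n <- length(avg_shapes)
  if (n == 0L) stop("no shapes supplied")
  ids <- vapply(seq_len(n), function(i) {
    s <- avg_shapes[[i]]
    if (inherits(s, "outline") && !is.na(s$line_id)) s$line_id
    else names(avg_shapes)[i] %||% as.character(i)
  }, "")
  pts <- lapply(avg_shapes, as_outline_points)
  k <- unique(vapply(pts, nrow, 1L))
  if (length(k) != 1L) stop("shapes must share a landmark count")
  X <- t(vapply(pts, function(p) p[, 1L], numeric(k)))
  Y <- t(vapply(pts, function(p) p[, 2L], numeric(k)))
  rownames(X) <- rownames(Y) <- ids
  if (!is.null(deme)) {
    if (!is.null(names(deme))) deme <- unname(deme[ids])
    stopifnot(length(deme) == n)
  }
  structure(list(X = X, Y = Y, z = cbind(X, Y), lines = ids,
                 deme = deme, K = k),
            class = "shape_pheno")
}

#' @export
print.shape_pheno <- function(x, ...) {
  cat(sprintf("<shape_pheno> %d lines x %d landmarks\n", length(x$lines), x$K))
  invisible(x)
}

as_shape_pheno <- function(phenotypes) {
  if (inherits(phenotypes, "shape_pheno")) return(phenotypes)
  if (is.list(phenotypes)) return(shape_phenotypes(phenotypes))
  stop("`phenotypes` must be a `shape_pheno` or a list of aligned outlines")
}

# ---- public model fits -----------------------------------------------------

#' Fit group-specific elliptic Fourier mean shapes with AR(1) covariance
#'
#' Fits one elliptic Fourier mean curve per group (least squares of the
#' group's coordinate-wise mean on the truncated Fourier basis) and a
#' single AR(1) covariance per coordinate block shared across groups,
#' estimated by profile maximum likelihood over the pooled residuals. Mean
#' and covariance fits are iterated until the log-likelihood stabilizes
#' (the least-squares mean does not depend on the covariance, so this
#' converges immediately; the loop guards future generalized fits).
#'
#' @param phenotypes a `shape_pheno` (see [shape_phenotypes()]) or list of
#'   aligned outlines.
#' @param grouping vector of group labels per line (NA lines dropped).
#' @param ef_order elliptic Fourier order of the mean curves.
#' @param min_group_size groups below this size are dropped with a warning.
#' @param tol,max_iter iteration control on the log-likelihood.
#' @return List: `means` (per-group `efd` descriptors of the mean curves),
#'   `cov` (`sigma2_x`, `rho_x`, `sigma2_y`, `rho_y`), `loglik`, `groups`,
#'   `counts`, `converged`.
#' @export
fit_group_model <- function(phenotypes, grouping, ef_order = 4L,
                            min_group_size = 5L, tol = 1e-6, max_iter = 50L) {
  ph <- as_shape_pheno(phenotypes)
  if (length(grouping) != length(ph$lines))
    stop("`grouping` must have one label per line")
  use <- !is.na(grouping)
  g <- factor(grouping[use])
  keep_lvl <- levels(g)[table(g) >= min_group_size]
  if (length(keep_lvl) < length(levels(g)))
    warning("dropping groups below the minimum group size")
  use[use] <- g %in% keep_lvl
  g <- factor(grouping[use])
  if (nlevels(g) < 1L) stop("no group meets the minimum group size")
  X <- ph$X[use, , drop = FALSE]; Y <- ph$Y[use, , drop = FALSE]
  H <- ef_hat_matrix(ph$K, ef_order)
  gidx <- as.integer(g)
  ll_prev <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    fit <- .fit_ll(X, Y, H, gidx, nlevels(g), details = TRUE)
    if (abs(fit$ll - ll_prev) < tol) { converged <- TRUE; break }
    ll_prev <- fit$ll
  }
  if (!converged) warning("group model did not converge; returning last iterate")
  b <- fourier_basis(seq_len(ph$K) - 1L, ph$K, ef_order)
  bh <- solve(crossprod(b), t(b))
  means <- lapply(seq_len(nlevels(g)), function(j) {
    cx <- bh %*% fit$mean_x[j, ]
    cy <- bh %*% fit$mean_y[j, ]
    co <- cbind(a = cx[2L * seq_len(ef_order)],
                b = cx[2L * seq_len(ef_order) + 1L],
                c = cy[2L * seq_len(ef_order)],
                d = cy[2L * seq_len(ef_order) + 1L])
    structure(list(order = ef_order, dc = c(A0 = cx[1L], C0 = cy[1L]),
                   coeffs = co, period = ph$K,
                   t = seq_len(ph$K) - 1L, param = "uniform"),
              class = "efd")
  })
  names(means) <- levels(g)
  list(means = means, cov = fit$cov, loglik = fit$ll,
       groups = levels(g), counts = fit$counts, converged = converged)
}

# Resolve usable lines and group index for one marker's genotype calls.
.marker_grouping <- function(geno, min_group_size) {
  use <- which(!is.na(geno))
  if (length(use) == 0L) return(NULL)
  g <- factor(geno[use])
  keep <- levels(g)[tabulate(g) >= min_group_size]
  if (length(keep) < 2L) return(NULL)
  use <- use[g %in% keep]
  g <- factor(geno[use])
  list(use = use, gidx = as.integer(g), J = nlevels(g), labels = levels(g))
}

#' Likelihood-ratio test of shape difference at one SNP
#'
#' Contrasts the null model (one elliptic Fourier mean shape for all lines)
#' against genotype-specific mean shapes, with AR(1) landmark covariance
#' re-estimated under each hypothesis (shared across genotype groups).
#' `LR = 2 (lnL1 - lnL0)`, clamped at zero.
#'
#' @param phenotypes `shape_pheno` or list of aligned outlines.
#' @param genotypes genotype call per line (any labels; NA = missing,
#'   dropped for this marker).
#' @param ef_order elliptic Fourier order.
#' @param min_group_size genotype classes below this size are dropped.
#' @return LR statistic (scalar); `NA` with attribute `"reason"` when fewer
#'   than two genotype classes meet the size rule.
#' @export
lr_test <- function(phenotypes, genotypes, ef_order = 4L, min_group_size = 5L) {
  ph <- as_shape_pheno(phenotypes)
  if (length(genotypes) != length(ph$lines))
    stop("`genotypes` must have one call per line")
  grp <- .marker_grouping(genotypes, min_group_size)
  if (is.null(grp))
    return(structure(NA_real_, reason = "fewer than two genotype classes meet the group-size rule"))
  H <- ef_hat_matrix(ph$K, ef_order)
  .lr_core(ph$X[grp$use, , drop = FALSE], ph$Y[grp$use, , drop = FALSE],
           H, grp$gidx, grp$J)
}

#' Genome-wide likelihood-ratio scan
#'
#' Applies [lr_test()] to every marker of a genotype matrix and returns a
#' Manhattan-ready table. Markers failing the group-size rule are recorded
#' as skipped, not errored.
#'
#' @param phenotypes `shape_pheno` or list of aligned outlines.
#' @param geno genotype matrix, markers in rows, lines in columns, entries
#'   0/1/2 (alt-allele dose) or NA; column names must match phenotype line
#'   ids (order is reconciled by name when present).
#' @param markers optional data frame of marker metadata (`marker`,
#'   `chrom`, `pos`, `seg_type`, ...), row-aligned with `geno`.
#' @param ef_order elliptic Fourier order.
#' @param min_group_size minimum lines per genotype class.
#' @return Data frame of class `scan_result`: marker, chrom, pos, seg_type,
#'   J, n_used, LR, skipped, reason; sorted into (chrom, pos) order when
#'   positions are available.
#' @export
genome_scan <- function(phenotypes, geno, markers = NULL, ef_order = 4L,
                        min_group_size = 5L) {
  ph <- as_shape_pheno(phenotypes)
  geno <- as.matrix(geno)
  if (!is.null(colnames(geno)) && !is.null(ph$lines) &&
      all(ph$lines %in% colnames(geno)))
    geno <- geno[, ph$lines, drop = FALSE]
  if (ncol(geno) != length(ph$lines))
    stop("genotype matrix columns do not match phenotype lines")
  m <- nrow(geno)
  if (m == 0L) stop("no markers supplied")
  if (is.null(markers)) {
    markers <- data.frame(marker = rownames(geno) %||% paste0("M", seq_len(m)),
                          chrom = NA_character_, pos = NA_integer_)
  }
  seg <- if ("seg_type" %in% names(markers)) markers$seg_type else
    apply(geno, 1L, function(g) classify_segregation(table(factor(g, levels = 0:2))))
  H <- ef_hat_matrix(ph$K, ef_order)
  lr <- rep(NA_real_, m); J <- integer(m); nuse <- integer(m)
  reason <- rep(NA_character_, m)
  ll0_all <- NULL  # cache the no-missing null fit, shared by all complete markers
  for (i in seq_len(m)) {
    grp <- .marker_grouping(geno[i, ], min_group_size)
    if (is.null(grp)) { reason[i] <- "group-size rule"; next }
    if (length(grp$use) == length(ph$lines)) {
      if (is.null(ll0_all))
        ll0_all <- .fit_ll(ph$X, ph$Y, H, rep.int(1L, nrow(ph$X)), 1L)
      lr[i] <- .lr_core(ph$X, ph$Y, H, grp$gidx, grp$J, ll0 = ll0_all)
    } else {
      lr[i] <- .lr_core(ph$X[grp$use, , drop = FALSE],
                        ph$Y[grp$use, , drop = FALSE], H, grp$gidx, grp$J)
    }
    J[i] <- grp$J; nuse[i] <- length(grp$use)
  }
  if (all(is.na(lr))) stop("no usable markers: every marker failed the group-size rule")
  out <- data.frame(marker = markers$marker, chrom = markers$chrom,
                    pos = markers$pos, seg_type = seg, J = J, n_used = nuse,
                    LR = lr, skipped = is.na(lr), reason = reason,
                    stringsAsFactors = FALSE)
  if (!all(is.na(out$pos))) out <- out[order(out$chrom, out$pos), ]
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Permutation threshold for genome-wide significance
#'
#' Shuffles line phenotypes against genotype rows (one shared shuffle per
#' permutation), records the maximum LR over all markers of the requested
#' segregation type, and returns the empirical `1 - alpha` quantile
#' (type-7 interpolation) of the permuted maxima. Deterministic given
#' `seed`.
#'
#' @param phenotypes `shape_pheno` or list of aligned outlines.
#' @param geno genotype matrix (markers x lines, doses 0/1/2 or NA).
#' @param seg_type `"testcross"`, `"intercross"`, or `NULL` for all
#'   markers; with a marker metadata frame supplied, its `seg_type` column
#'   is used, otherwise types are classified from genotype counts.
#' @param markers optional marker metadata frame.
#' @param n_perm number of permutations (the study-scale default is 1000).
#' @param alpha genome-wide type-I error rate.
#' @param seed RNG seed.
#' @param ef_order,min_group_size as in [lr_test()].
#' @return Threshold (scalar) with the permuted maxima attached as
#'   attribute `"maxima"`.
#' @export
permutation_threshold <- function(phenotypes, geno, seg_type = NULL,
                                  markers = NULL, n_perm = 1000L,
                                  alpha = 0.05, seed = NULL,
                                  ef_order = 4L, min_group_size = 5L) {
  if (!is.numeric(n_perm) || n_perm < 1) stop("`n_perm` must be >= 1")
  n_perm <- as.integer(n_perm)
  ph <- as_shape_pheno(phenotypes)
  geno <- as.matrix(geno)
  if (!is.null(colnames(geno)) && all(ph$lines %in% colnames(geno)))
    geno <- geno[, ph$lines, drop = FALSE]
  if (!is.null(seg_type)) {
    seg <- if (!is.null(markers) && "seg_type" %in% names(markers))
      markers$seg_type
    else apply(geno, 1L, function(g)
      classify_segregation(table(factor(g, levels = 0:2))))
    geno <- geno[seg == seg_type, , drop = FALSE]
    if (nrow(geno) == 0L)
      stop(sprintf("no markers of segregation type '%s'", seg_type))
  }
  groupings <- lapply(seq_len(nrow(geno)), function(i)
    .marker_grouping(geno[i, ], min_group_size))
  groupings <- Filter(Negate(is.null), groupings)
  if (length(groupings) == 0L) stop("no usable markers for permutation")
  H <- ef_hat_matrix(ph$K, ef_order)
  n <- nrow(ph$X)
  complete <- vapply(groupings, function(g) length(g$use) == n, TRUE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  maxima <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    ord <- sample.int(n)
    Xp <- ph$X[ord, , drop = FALSE]
    Yp <- ph$Y[ord, , drop = FALSE]
    ll0_all <- if (any(complete))
      .fit_ll(Xp, Yp, H, rep.int(1L, n), 1L) else NULL
    best <- 0
    for (gi in seq_along(groupings)) {
      g <- groupings[[gi]]
      lr <- if (complete[gi])
        .lr_core(Xp, Yp, H, g$gidx, g$J, ll0 = ll0_all)
      else
        .lr_core(Xp[g$use, , drop = FALSE], Yp[g$use, , drop = FALSE],
                 H, g$gidx, g$J)
      if (lr > best) best <- lr
    }
    maxima[p] <- best
  }
  structure(unname(stats::quantile(maxima, 1 - alpha, type = 7)),
            maxima = maxima)
}

#' Per-SNP heritability of a scalar shape trait
#'
#' Between-genotype variance ratio `h2 = 1 - SS_within / SS_total` of a
#' trait across genotype classes at one marker, in `[0, 1]`. Cumulative
#' heritability over a marker set is the sum of per-marker values; linked
#' or correlated markers overlap, so that sum can exceed the joint
#' variance explained (collinearity caveat).
#'
#' @param trait numeric trait value per line.
#' @param genotypes genotype call per line (NA dropped).
#' @return Fraction in `[0, 1]`; 0 with a warning for a constant trait.
#' @export
snp_heritability <- function(trait, genotypes) {
  ok <- !is.na(trait) & !is.na(genotypes)
  trait <- trait[ok]; genotypes <- genotypes[ok]
  g <- factor(genotypes)
  if (nlevels(g) < 2L) stop("need at least two genotype classes")
  sst <- sum((trait - mean(trait))^2)
  if (sst < 1e-300) {
    warning("constant trait: heritability undefined, returning 0")
    return(0)
  }
  ssw <- sum(unlist(tapply(trait, g, function(z) (z - mean(z))^2)))
  min(1, max(0, 1 - ssw / sst))
}
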