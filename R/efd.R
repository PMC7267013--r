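#' Elliptic Fourier decomposition of a closed contour
#'
#' Computes the classical closed-contour elliptic Fourier coefficients of a
#' landmark polygon. The default parameterization is chord length (the
#' polygon's arc length, with the total perimeter as the period); the
#' `"uniform"` alternative assigns every segment the same parameter
#' increment, which is the parameterization in which a contour sampled at
#' equal increments of its generating parameter (e.g. an ellipse sampled at
#' equal angles of its circular parameter) is represented exactly by its
#' generating harmonics.
#'
#' @param x an [outline] or K x 2 matrix (closed; the first point is not
#'   repeated).
#' @param order number of harmonics N (>= 1); needs at least 2N + 1
#'   landmarks.
#' @param param `"chord"` (arc-length, default) or `"uniform"`.
#' @return Object of class `efd`: list with `order`, `dc` = (A0, C0),
#'   `coeffs` (N x 4 matrix, columns a, b, c, d), `period`, `t` (landmark
#'   parameter values, starting at 0) and `param`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 361)[-361]
#' ell <- cbind(2 * cos(th), sin(th))
#' d <- efd_decompose(ell, 4, param = "uniform")
#' round(d$coeffs[1, ], 6)  # a1 = 2, d1 = 1
#' @export
efd_decompose <- function(x, order, param = c("chord", "uniform")) {
  param <- match.arg(param)
  pts <- as_outline_points(x)
  k <- nrow(pts)
  if (!is.numeric(order) || length(order) != 1L || order < 1)
    stop("`order` must be a single integer >= 1")
  order <- as.integer(order)
  if (k < 2L * order + 1L)
    stop(sprintf("need at least %d landmarks for an order-%d decomposition",
                 2L * order + 1L, order))
  d <- rbind(pts[-1L, , drop = FALSE], pts[1L, , drop = FALSE]) - pts
  dt <- if (param == "chord") sqrt(rowSums(d^2)) else rep(1, k)
  if (any(dt < 1e-14)) stop("outline has coincident consecutive points")
  t <- c(0, cumsum(dt))
  T <- t[k + 1L]
  phi <- 2 * pi * t / T
  coeffs <- matrix(0, order, 4L,
                   dimnames = list(NULL, c("a", "b", "c", "d")))
  dxdt <- d[, 1L] / dt
  dydt <- d[, 2L] / dt
  for (n in seq_len(order)) {
    dcos <- diff(cos(n * phi))
    dsin <- diff(sin(n * phi))
    fac <- T / (2 * n^2 * pi^2)
    coeffs[n, ] <- fac * c(sum(dxdt * dcos), sum(dxdt * dsin),
                           sum(dydt * dcos), sum(dydt * dsin))
  }
  # DC terms (Kuhl & Giardina), relative to the start point
  t1 <- t[-(k + 1L)]
  xi0 <- c(0, cumsum(d[, 1L]))[seq_len(k)] - dxdt * t1
  a0 <- sum(dxdt / 2 * (t[-1L]^2 - t1^2) + xi0 * (t[-1L] - t1)) / T + pts[1L, 1L]
  de0 <- c(0, cumsum(d[, 2L]))[seq_len(k)] - dydt * t1
  c0 <- sum(dydt / 2 * (t[-1L]^2 - t1^2) + de0 * (t[-1L] - t1)) / T + pts[1L, 2L]
  structure(
    list(order = order, dc = c(A0 = a0, C0 = c0), coeffs = coeffs,
         period = T, t = t[seq_len(k)], param = param),
    class = "efd")
}

#' @export
print.efd <- function(x, ...) {
  cat(sprintf("<efd> order %d (%s parameterization), period %.4g\n",
              x$order, x$param, x$period))
  print(round(x$coeffs, 6))
  invisible(x)
}

# Evaluate the truncated series at arbitrary parameter values.
efd_evaluate <- function(desc, tvals, order = desc$order) {
  order <- min(order, desc$order)
  phi <- 2 * pi * tvals / desc$period
  xs <- rep(desc$dc[[1L]], length(tvals))
  ys <- rep(desc$dc[[2L]], length(tvals))
  for (n in seq_len(order)) {
    cn <- cos(n * phi); sn <- sin(n * phi)
    xs <- xs + desc$coeffs[n, 1L] * cn + desc$coeffs[n, 2L] * sn
    ys <- ys + desc$coeffs[n, 3L] * cn + desc$coeffs[n, 4L] * sn
  }
  cbind(xs, ys)
}

#' Reconstruct a contour from elliptic Fourier coefficients
#'
#' Evaluates the truncated series at `k` equally spaced parameter values
#' over one period.
#'
#' @param desc an `efd` object from [efd_decompose()].
#' @param k number of points (>= 3).
#' @return An [outline] of the reconstructed contour.
#' @export
efd_reconstruct <- function(desc, k) {
  if (!inherits(desc, "efd")) stop("`desc` must be an `efd` object")
  if (!is.numeric(k) || length(k) != 1L || k < 3)
    stop("`k` must be a single integer >= 3")
  k <- as.integer(k)
  tvals <- seq(0, desc$period, length.out = k + 1L)[-(k + 1L)]
  pts <- efd_evaluate(desc, tvals)
  if (stats::sd(pts[, 1L]) < 1e-14 && stats::sd(pts[, 2L]) < 1e-14) {
    # all-zero harmonics: a degenerate ring at the DC point
    return(structure(
      list(points = pts, closed = TRUE, id = NA_character_,
           line_id = NA_character_, position = NA_character_,
           block = NA_character_),
      class = "outline"))
  }
  outline(pts)
}

# Discrete least-squares Fourier fit of one coordinate sequence on the
# truncated basis at given parameter values; returns fitted values.
fourier_basis <- function(tvals, period, order) {
  phi <- 2 * pi * tvals / period
  b <- matrix(1, length(tvals), 2L * order + 1L)
  for (n in seq_len(order)) {
    b[, 2L * n] <- cos(n * phi)
    b[, 2L * n + 1L] <- sin(n * phi)
  }
  b
}

#' Cumulative shape variance explained per harmonic order
#'
#' For each order N = 1..`max_order`, fits the truncated Fourier basis to
#' each shape's coordinates by least squares and reports the mean over
#' shapes of the reconstruction R-squared, 1 - SSE(N)/SST, where SSE is the
#' summed squared landmark distance between the shape and its order-N
#' reconstruction and SST the summed squared landmark distance from the
#' shape centroid. Nested least squares makes the profile nondecreasing.
#'
#' @param shapes list of aligned [outline]s (or matrices).
#' @param max_order largest harmonic order to profile.
#' @param param parameterization passed to the fit (see [efd_decompose()]).
#' @param method `"residual"` (reconstruction R-squared, default) or
#'   `"power"` (cumulative normalized Fourier power).
#' @return Numeric vector of length `max_order` of cumulative fractions in
#'   `[0, 1]`.
#' @export
variance_explained_profile <- function(shapes, max_order,
                                       param = c("chord", "uniform"),
                                       method = c("residual", "power")) {
  param <- match.arg(param)
  method <- match.arg(method)
  if (inherits(shapes, "aligned_shapes")) shapes <- shapes$shapes
  if (max_order < 1) stop("`max_order` must be >= 1")
  max_order <- as.integer(max_order)
  if (method == "power") {
    pw <- matrix(0, length(shapes), max_order)
    for (i in seq_along(shapes)) {
      d <- efd_decompose(shapes[[i]], max_order, param = param)
      pw[i, ] <- rowSums(d$coeffs^2) / 2
    }
    cum <- apply(pw, 1L, function(z) cumsum(z) / sum(z))
    return(rowMeans(matrix(cum, nrow = max_order)))
  }
  frac <- matrix(NA_real_, length(shapes), max_order)
  for (i in seq_along(shapes)) {
    pts <- as_outline_points(shapes[[i]])
    k <- nrow(pts)
    if (k < 2L * max_order + 1L)
      stop("too few landmarks for the requested maximum order")
    d <- rbind(pts[-1L, , drop = FALSE], pts[1L, , drop = FALSE]) - pts
    dt <- if (param == "chord") sqrt(rowSums(d^2)) else rep(1, k)
    tvals <- c(0, cumsum(dt))[seq_len(k)]
    period <- sum(dt)
    ctr <- colMeans(pts)
    sst <- sum(sweep(pts, 2L, ctr)^2)
    bfull <- fourier_basis(tvals, period, max_order)
    for (nn in seq_len(max_order)) {
      b <- bfull[, seq_len(2L * nn + 1L), drop = FALSE]
      fit <- stats::lm.fit(b, pts)
      frac[i, nn] <- 1 - sum(fit$residuals^2) / sst
    }
  }
  colMeans(frac)
}

#' Select the harmonic order from a variance-explained profile
#'
#' Returns the smallest order whose cumulative explained fraction exceeds
#' the threshold; if no order does, returns `max_order` with a warning.
#'
#' @param shapes either a list of aligned shapes (profiled via
#'   [variance_explained_profile()]) or a numeric cumulative profile
#'   (fractions, or percentages if any value exceeds 1.5).
#' @param max_order maximum order considered (defaults to the profile
#'   length when a profile is given).
#' @param threshold fraction in (0, 1); default 0.95.
#' @param ... passed to [variance_explained_profile()] when `shapes` is a
#'   shape list.
#' @return Selected order (integer) with the profile attached as attribute
#'   `"profile"`.
#' @examples
#' select_order(c(53.7, 91.3, 94.9, 97.2, 98.4, 98.8))  # 4
#' @export
select_order <- function(shapes, max_order = NULL, threshold = 0.95, ...) {
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must be in (0, 1)")
  if (is.numeric(shapes)) {
    profile <- shapes
    if (any(profile > 1.5)) profile <- profile / 100
    if (is.null(max_order)) max_order <- length(profile)
  } else {
    if (is.null(max_order)) max_order <- 6L
    profile <- variance_explained_profile(shapes, max_order, ...)
  }
  hit <- which(profile > threshold)
  if (length(hit) == 0L) {
    warning(sprintf(
      "no order up to %d exceeds the %.0f%% threshold; returning the maximum",
      max_order, 100 * threshold))
    sel <- as.integer(max_order)
  } else sel <- as.integer(min(hit))
  structure(sel, profile = profile)
}

#' Write elliptic Fourier coefficients to CSV
#'
#' One row per (line, harmonic): columns `line_id`, `order_n`, `a`, `b`,
#' `c`, `d`, plus the DC terms as `order_n = 0` with (A0, C0) stored in
#' the `a` and `c` columns.
#'
#' @param descs named list of `efd` objects (names are line ids).
#' @param path output CSV path.
#' @return Invisibly, the path.
#' @export
write_efd_csv <- function(descs, path) {
  rows <- lapply(names(descs), function(id) {
    d <- descs[[id]]
    rbind(data.frame(line_id = id, order_n = 0L, a = d$dc[[1L]], b = 0,
                     c = d$dc[[2L]], d = 0),
          data.frame(line_id = id, order_n = seq_len(d$order),
                     a = d$coeffs[, "a"], b = d$coeffs[, "b"],
                     c = d$coeffs[, "c"], d = d$coeffs[, "d"]))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
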