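#' Resample a closed outline at equal-angle landmarks
#'
#' Casts `k` rays from the outline's area centroid at equal angular
#' increments, traversed clockwise, and places one landmark where each ray
#' crosses the linearly interpolated margin. Landmark 0 lies on the ray
#' through the outline's first point, which is treated as the blade base
#' (petiole junction), so landmark indices are anatomically comparable
#' across leaves.
#'
#' The outline must be star-shaped about its centroid: every ray has to
#' cross the margin exactly once. Leaves without deep lobing satisfy this.
#'
#' @param x an [outline] (or bare K x 2 coordinate matrix).
#' @param k number of landmarks (>= 3).
#' @return An [outline] with `k` landmarks, metadata preserved.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 1001)[-1001]
#' circ <- outline(cbind(cos(th), sin(th)))
#' lm70 <- resample_contour(circ, 70)
#' range(sqrt(rowSums(lm70$points^2)))  # all radii 1
#' @export
resample_contour <- function(x, k) {
  pts <- as_outline_points(if (inherits(x, "outline")) x else outline(x))
  if (!is.numeric(k) || length(k) != 1L || k < 3)
    stop("`k` must be a single integer >= 3")
  k <- as.integer(k)
  ctr <- polygon_centroid(pts)
  p <- sweep(pts, 2L, ctr)                      # margin relative to centroid
  q <- rbind(p[-1L, , drop = FALSE], p[1L, , drop = FALSE])
  u <- q - p                                    # segment vectors
  theta0 <- atan2(p[1L, 2L], p[1L, 1L])
  # clockwise traversal = decreasing polar angle
  angles <- theta0 - 2 * pi * (seq_len(k) - 1L) / k
  cosj <- cos(angles); sinj <- sin(angles)
  # ray x segment intersection, all pairs at once:
  # t = cross(p, d) / cross(d, u), s = cross(p, u) / cross(d, u)
  den <- outer(cosj, u[, 2L]) - outer(sinj, u[, 1L])       # k x n
  tt <- (outer(sinj, p[, 1L]) - outer(cosj, p[, 2L])) / den
  cs <- p[, 1L] * u[, 2L] - p[, 2L] * u[, 1L]
  ss <- rep(cs, each = k) / den
  hit <- abs(den) > 1e-14 & tt >= -1e-9 & tt < 1 + 1e-9 & ss > 1e-12
  nhit <- rowSums(hit)
  out <- matrix(NA_real_, k, 2L)
  ones <- which(nhit == 1L)
  if (length(ones)) {
    idx <- max.col(hit[ones, , drop = FALSE], ties.method = "first")
    tt1 <- tt[cbind(ones, idx)]
    out[ones, ] <- sweep(p[idx, , drop = FALSE] + tt1 * u[idx, , drop = FALSE],
                         2L, ctr, "+")
  }
  for (j in which(nhit != 1L)) {
    h <- which(hit[j, ])
    if (length(h) > 1L) {
      # rays grazing a vertex can register on both adjacent segments:
      # collapse hits whose intersection points coincide
      ipts <- p[h, , drop = FALSE] + tt[j, h] * u[h, , drop = FALSE]
      keep <- !duplicated(round(ipts, 8L))
      h <- h[keep]
    }
    if (length(h) != 1L)
      stop(sprintf(
        "outline is not star-shaped about its centroid: ray at %.1f degrees crosses the margin %d times",
        (angles[j] * 180 / pi) %% 360, length(h)))
    out[j, ] <- ctr + p[h, ] + tt[j, h] * u[h, ]
  }
  with_points(if (inherits(x, "outline")) x else outline(pts), out)
}

#' Generalized Procrustes alignment of landmark shapes
#'
#' Removes translation (centroid to origin), scale (centroid size to 1) and
#' rotation (orthogonal, no reflection) from a set of landmark
#' configurations with equal landmark count, iterating rotations against the
#' running consensus until the consensus stabilizes. Reflections are never
#' applied: leaves carry chirality from imaging and mirror forms must not be
#' merged.
#'
#' @param shapes list of [outline]s (or K x 2 matrices) with identical
#'   landmark counts.
#' @param tol consensus convergence tolerance (RMS coordinate change).
#' @param max_iter maximum consensus iterations.
#' @return An object of class `aligned_shapes`: list with `shapes` (aligned
#'   outlines), `reference` (consensus = arithmetic mean of the aligned
#'   shapes), `transforms` (per shape: centre, scale, rotation angle),
#'   `iterations`, `converged`.
#' @export
procrustes_align <- function(shapes, tol = 1e-8, max_iter = 100L) {
  if (inherits(shapes, "outline") || is.matrix(shapes)) shapes <- list(shapes)
  if (length(shapes) < 1L) stop("need at least one shape")
  pts <- lapply(shapes, as_outline_points)
  kk <- vapply(pts, nrow, 1L)
  if (length(unique(kk)) != 1L)
    stop("all shapes must have the same landmark count")
  n <- length(pts)
  ctrs <- lapply(pts, colMeans)
  sizes <- numeric(n)
  norm <- vector("list", n)
  for (i in seq_len(n)) {
    p <- sweep(pts[[i]], 2L, ctrs[[i]])
    cs <- sqrt(mean(rowSums(p^2)))
    if (cs < 1e-12)
      stop("degenerate shape: all landmarks identical (zero centroid size)")
    sizes[i] <- cs
    norm[[i]] <- p / cs
  }
  rot <- numeric(n)
  aligned <- norm
  ref <- norm[[1L]]
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n)) {
      s <- norm[[i]]
      a <- sum(s * ref)                          # sum x x' + y y'
      b <- sum(s[, 1L] * ref[, 2L] - s[, 2L] * ref[, 1L])
      phi <- atan2(b, a)
      rot[i] <- phi
      cphi <- cos(phi); sphi <- sin(phi)
      aligned[[i]] <- cbind(s[, 1L] * cphi - s[, 2L] * sphi,
                            s[, 1L] * sphi + s[, 2L] * cphi)
    }
    newref <- Reduce(`+`, aligned) / n
    delta <- sqrt(mean((newref - ref)^2))
    ref <- newref
    if (delta < tol) { converged <- TRUE; break }
  }
  out_shapes <- vector("list", n)
  for (i in seq_len(n)) {
    out_shapes[[i]] <- if (inherits(shapes[[i]], "outline")) {
      s <- shapes[[i]]; s$points <- aligned[[i]]; s
    } else outline(aligned[[i]])
  }
  structure(
    list(shapes = out_shapes, reference = ref,
         transforms = lapply(seq_len(n), function(i)
           list(centre = ctrs[[i]], scale = sizes[i], angle = rot[i])),
         iterations = iter, converged = converged),
    class = "aligned_shapes")
}

#' @export
print.aligned_shapes <- function(x, ...) {
  cat(sprintf("<aligned_shapes> %d shapes, %d landmarks, %d iterations (%s)\n",
              length(x$shapes), nrow(x$reference), x$iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

# Apply a stored alignment transform (centre/scale/rotation) to raw points.
apply_alignment <- function(pts, tr) {
  p <- sweep(pts, 2L, tr$centre) / tr$scale
  cphi <- cos(tr$angle); sphi <- sin(tr$angle)
  cbind(p[, 1L] * cphi - p[, 2L] * sphi,
        p[, 1L] * sphi + p[, 2L] * cphi)
}

#' Arithmetic average shape of aligned outlines
#'
#' Landmark-wise arithmetic mean over leaves of one clonal line, used to
#' average out heterophylly (crown position) and block effects before
#' association testing.
#'
#' @param shapes list of aligned [outline]s with equal landmark count.
#' @param line_id optional line identifier for the result (defaults to the
#'   first shape's).
#' @return An [outline] holding the mean configuration.
#' @export
average_shape <- function(shapes, line_id = NULL) {
  if (inherits(shapes, "aligned_shapes")) shapes <- shapes$shapes
  if (length(shapes) == 0L) stop("cannot average an empty list of shapes")
  pts <- lapply(shapes, as_outline_points)
  kk <- vapply(pts, nrow, 1L)
  if (length(unique(kk)) != 1L)
    stop("all shapes must have the same landmark count")
  m <- Reduce(`+`, pts) / length(pts)
  first <- shapes[[1L]]
  lid <- line_id %||%
    (if (inherits(first, "outline")) first$line_id else NA_character_)
  outline(m, id = paste0("avg_", lid), line_id = lid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select the landmark count by AIC over elliptic Fourier reconstruction
#'
#' For each candidate landmark count `k`, every shape is resampled at `k`
#' equal-angle landmarks, the set is Procrustes-aligned, an elliptic Fourier
#' model of the given order is fitted per shape, and the reconstruction is
#' scored against the true margin on a fixed 360-point equal-angle grid so
#' that scores are comparable across `k`. A Gaussian log-likelihood with a
#' pooled residual variance gives AIC = 2p - 2 lnL with
#' p = (4 `ef_order` + 2) coefficients per shape; the candidate with the
#' lowest AIC wins, ties broken toward the smaller count.
#'
#' @param shapes list of [outline]s (raw margins, dense enough to resample
#'   at every candidate and at 360 points).
#' @param candidates integer vector (>= 2 values) of landmark counts.
#' @param ef_order elliptic Fourier order used in the fit.
#' @return The selected landmark count (integer). The AIC table is attached
#'   as attribute `"aic"`.
#' @export
select_landmark_count <- function(shapes, candidates, ef_order = 4L) {
  if (length(candidates) < 2L) stop("need at least two candidate counts")
  candidates <- sort(as.integer(candidates))
  if (any(candidates < 2L * ef_order + 1L))
    stop(sprintf("candidate landmark counts must be >= %d for an order-%d elliptic Fourier fit",
                 2L * ef_order + 1L, ef_order))
  grid_k <- 360L
  n <- length(shapes)
  p_total <- (4L * ef_order + 2L) * n
  sse <- numeric(length(candidates))
  for (ci in seq_along(candidates)) {
    k <- candidates[ci]
    res <- lapply(shapes, resample_contour, k = k)
    al <- procrustes_align(res)
    total <- 0
    for (i in seq_len(n)) {
      # true margin on the fixed grid, carried into this shape's aligned frame
      ref <- resample_contour(shapes[[i]], grid_k)
      refp <- apply_alignment(as_outline_points(ref), al$transforms[[i]])
      desc <- efd_decompose(al$shapes[[i]], order = ef_order)
      rec <- efd_reconstruct(desc, 4L * grid_k)
      recp <- as_outline_points(resample_contour(rec, grid_k))
      total <- total + sum((refp - recp)^2)
    }
    sse[ci] <- total
  }
  m <- n * grid_k * 2L
  sigma2 <- pmax(sse / m, 1e-20)  # variance floor keeps noise-free fits comparable
  lnl <- -m / 2 * (log(2 * pi * sigma2) + 1)
  aic <- 2 * p_total - 2 * lnl
  eligible <- which(aic <= min(aic) + 1e-6)
  sel <- candidates[min(eligible)]
  structure(sel, aic = data.frame(k = candidates, sse = sse, aic = aic))
}

#' Scalar shape descriptors of a leaf outline
#'
#' Computes leaf length (extent along the base--tip axis), width (maximum
#' extent perpendicular to it), area (shoelace polygon area) and the
#' broadest-region position (axial coordinate of the maximum-width chord as
#' a fraction of length from the blade base). The base--tip axis is the
#' principal axis of the landmarks, oriented so the blade-base landmark
#' (the outline's first point) sits at the lower end.
#'
#' @param x an [outline] or K x 2 matrix; closed, non-self-intersecting.
#' @param check_simple if `TRUE`, run a segment-intersection check and error
#'   on self-intersecting margins (O(K^2), off by default).
#' @param n_grid number of axial stations used to locate the widest chord.
#' @return Named list: `length`, `width`, `area`, `broadest_position`.
#' @examples
#' rect <- outline(cbind(c(-.5, -.5, .5, .5), c(-1, 1, 1, -1)))
#' trait_descriptors(rect)[c("length", "width", "area")]
#' @export
trait_descriptors <- function(x, check_simple = FALSE, n_grid = 201L) {
  pts <- as_outline_points(x)
  if (check_simple && !is_simple_polygon(pts))
    stop("outline is self-intersecting; shape descriptors are undefined")
  area <- abs(polygon_signed_area(pts))
  ctr <- colMeans(pts)
  p <- sweep(pts, 2L, ctr)
  ev <- eigen(stats::cov(p), symmetric = TRUE)
  axis <- ev$vectors[, 1L]
  s <- p %*% axis
  if (s[1L] > 0) { axis <- -axis; s <- -s }    # base landmark at the low end
  w <- p %*% c(-axis[2L], axis[1L])
  len <- max(s) - min(s)
  wid <- max(w) - min(w)
  # widest chord: scan axial stations, intersect with the margin
  svals <- as.numeric(s); wvals <- as.numeric(w)
  sn <- c(svals[-1L], svals[1L]); wn <- c(wvals[-1L], wvals[1L])
  grid <- seq(min(svals) + 1e-9 * len, max(svals) - 1e-9 * len,
              length.out = n_grid)
  widths <- vapply(grid, function(sg) {
    cr <- (svals - sg) * (sn - sg) <= 0 & abs(sn - svals) > 0
    if (sum(cr) < 2L) return(0)
    tt <- (sg - svals[cr]) / (sn[cr] - svals[cr])
    wc <- wvals[cr] + tt * (wn[cr] - wvals[cr])
    max(wc) - min(wc)
  }, 1)
  s_star <- grid[which.max(widths)]
  list(length = len, width = wid, area = area,
       broadest_position = min(1, max(0, (s_star - min(svals)) / len)))
}

# Brute-force simple-polygon check (non-adjacent segment intersection).
is_simple_polygon <- function(pts) {
  n <- nrow(pts)
  a <- pts; b <- rbind(pts[-1L, , drop = FALSE], pts[1L, , drop = FALSE])
  seg_int <- function(p1, p2, p3, p4) {
    d1 <- p2 - p1; d2 <- p4 - p3
    den <- d1[1L] * d2[2L] - d1[2L] * d2[1L]
    if (abs(den) < 1e-14) return(FALSE)
    t <- ((p3[1L] - p1[1L]) * d2[2L] - (p3[2L] - p1[2L]) * d2[1L]) / den
    u <- ((p3[1L] - p1[1L]) * d1[2L] - (p3[2L] - p1[2L]) * d1[1L]) / den
    t > 1e-10 && t < 1 - 1e-10 && u > 1e-10 && u < 1 - 1e-10
  }
  for (i in seq_len(n - 2L)) {
    for (j in seq((i + 2L), n)) {
      if (i == 1L && j == n) next
      if (seg_int(a[i, ], b[i, ], a[j, ], b[j, ])) return(FALSE)
    }
  }
  TRUE
}

#' Trace a leaf outline from a binary silhouette image
#'
#' Extracts the boundary of the largest connected white region of a binary
#' (or grayscale, thresholded at 0.5) image, white = leaf, black =
#' background. Holes are ignored. Requires the `EBImage` package.
#'
#' @param img an `EBImage` Image, a numeric matrix in `[0, 1]`, or a path to
#'   a PNG file.
#' @param ... passed on to [outline()].
#' @return An [outline] tracing the silhouette margin.
#' @export
outline_from_image <- function(img, ...) {
  if (!requireNamespace("EBImage", quietly = TRUE))
    stop("outline_from_image() requires the EBImage package")
  if (is.character(img)) img <- EBImage::readImage(img)
  m <- EBImage::imageData(img)
  if (length(dim(m)) > 2L) m <- m[, , 1L]
  bw <- EBImage::bwlabel(m > 0.5)
  if (max(bw) == 0) stop("no foreground (white) region found in image")
  sizes <- tabulate(bw[bw > 0])
  keep <- which.max(sizes)
  oc <- EBImage::ocontour(EBImage::Image(bw == keep))[[1L]]
  outline(oc, ...)
}
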