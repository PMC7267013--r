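#' Construct a leaf outline
#'
#' An `outline` is a closed, ordered sequence of 2-D boundary points tracing a
#' leaf margin, together with the metadata used downstream (clonal line,
#' crown position, nursery block). Traversal direction is normalized to
#' clockwise on construction so that landmark indices are comparable across
#' leaves; the first point is kept first and is treated as the blade-base
#' (petiole junction) point.
#'
#' @param points numeric matrix with 2 columns (x, y) or a data frame with
#'   columns `x` and `y`; at least 3 points, consecutive duplicates dropped.
#' @param id leaf identifier.
#' @param line_id clonal-line identifier.
#' @param position crown-section label (e.g. "upper", "middle", "lower").
#' @param block nursery block label.
#' @param closed logical; the last point connects back to the first
#'   (always `TRUE` for leaf margins).
#' @return An object of class `outline`: a list with elements `points`
#'   (K x 2 matrix), `closed`, `id`, `line_id`, `position`, `block`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 101)[-101]
#' circ <- outline(cbind(cos(th), sin(th)), id = "leaf1")
#' nrow(circ$points)
#' @export
outline <- function(points, id = NA_character_, line_id = NA_character_,
                    position = NA_character_, block = NA_character_,
                    closed = TRUE) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y")])
  points <- unname(as.matrix(points))
  if (!is.numeric(points) || ncol(points) != 2L)
    stop("`points` must be a numeric matrix with two columns (x, y)")
  if (anyNA(points) || any(!is.finite(points)))
    stop("outline points must be finite")
  # drop consecutive duplicates (incl. a repeated closing point)
  n <- nrow(points)
  if (n > 1L) {
    dup <- c(FALSE, rowSums(abs(diff(points))) == 0)
    points <- points[!dup, , drop = FALSE]
    if (nrow(points) > 1L &&
        all(points[1L, ] == points[nrow(points), ]))
      points <- points[-nrow(points), , drop = FALSE]
  }
  if (nrow(points) < 3L) stop("an outline needs at least 3 distinct points")
  if (polygon_signed_area(points) > 0) {
    # counter-clockwise: reverse, keeping the first (base) point first
    points <- points[c(1L, nrow(points):2L), , drop = FALSE]
  }
  structure(
    list(points = points, closed = isTRUE(closed), id = id, line_id = line_id,
         position = position, block = block),
    class = "outline")
}

#' @export
print.outline <- function(x, ...) {
  cat(sprintf("<outline> %s: %d points (line %s, position %s, block %s)\n",
              x$id, nrow(x$points), x$line_id, x$position, x$block))
  invisible(x)
}

# Accept either an outline or a bare K x 2 matrix.
as_outline_points <- function(x) {
  if (inherits(x, "outline")) x$points
  else if (is.matrix(x) && ncol(x) == 2L) x
  else stop("expected an `outline` or a two-column coordinate matrix")
}

# Replace coordinates, keeping metadata.
with_points <- function(o, pts) {
  if (inherits(o, "outline")) { o$points <- pts; o }
  else outline(pts)
}

# Signed area via the shoelace formula; positive for counter-clockwise
# traversal in standard (y-up) orientation.
polygon_signed_area <- function(pts) {
  x <- pts[, 1L]; y <- pts[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

# Area centroid of a simple polygon (falls back to the vertex mean for
# degenerate, near-zero-area rings).
polygon_centroid <- function(pts) {
  x <- pts[, 1L]; y <- pts[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(pts))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# Root-mean-square distance of landmarks from their (vertex-mean) centroid.
centroid_size <- function(pts) {
  ctr <- colMeans(pts)
  sqrt(mean((pts[, 1L] - ctr[1L])^2 + (pts[, 2L] - ctr[2L])^2))
}
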