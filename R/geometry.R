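#' Construct a validated planar polygon
#'
#' Polygons are the breast-border primitive: an ordered vertex list in image
#' pixel coordinates (x rightward, y downward), implicitly closed. Validation
#' enforces the invariants every downstream measurement relies on: at least 3
#' vertices, finite coordinates, distinct consecutive vertices, simplicity
#' (no self-intersection) and strictly positive enclosed area.
#'
#' @param vertices numeric matrix with two columns (x, y) or an object
#'   coercible to one; rows are vertices in drawing order. The closing edge
#'   from the last vertex back to the first is implicit.
#' @return a numeric matrix of class `bsi_polygon` with columns `x`, `y`.
#' @examples
#' sq <- polygon_new(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' polygon_area(sq)
#' @export
polygon_new <- function(vertices) {
  v <- as.matrix(vertices)
  if (!is.numeric(v) || ncol(v) != 2L)
    stop_invalid_geometry("polygon vertices must be an n x 2 numeric matrix")
  if (nrow(v) < 3L)
    stop_invalid_geometry("polygon needs at least 3 vertices, got ", nrow(v))
  if (!all(is.finite(v)))
    stop_invalid_geometry("polygon vertices contain non-finite coordinates")
  nxt <- c(2:nrow(v), 1L)
  if (any(v[, 1] == v[nxt, 1] & v[, 2] == v[nxt, 2]))
    stop_invalid_geometry("polygon has identical consecutive vertices")
  if (!is_simple_polygon(v))
    stop_invalid_geometry("polygon is self-intersecting")
  if (shoelace_area(v) <= 0)
    stop_invalid_geometry("polygon is degenerate (zero enclosed area)")
  dimnames(v) <- list(NULL, c("x", "y"))
  class(v) <- c("bsi_polygon", "matrix", "array")
  v
}

as_polygon <- function(x) {
  if (inherits(x, "bsi_polygon")) x else polygon_new(x)
}

stop_invalid_geometry <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("bsi_geometry_error", "error")))
}

# Unsigned shoelace area; winding-independent.
shoelace_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  nxt <- c(2:nrow(v), 1L)
  abs(sum(x * y[nxt] - x[nxt] * y)) / 2
}

# Simplicity: no two non-adjacent edges intersect or touch.
# O(n^2) vectorised orientation tests; adequate up to ~10^3 vertices.
is_simple_polygon <- function(v) {
  n <- nrow(v)
  nxt <- c(2:n, 1L)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  adjacent <- (j - i == 1L) | (i == 1L & j == n)
  i <- i[!adjacent]; j <- j[!adjacent]
  if (!length(i)) return(TRUE)
  ax <- v[i, 1]; ay <- v[i, 2]; bx <- v[nxt[i], 1]; by <- v[nxt[i], 2]
  cx <- v[j, 1]; cy <- v[j, 2]; dx <- v[nxt[j], 1]; dy <- v[nxt[j], 2]
  d1 <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  d2 <- (bx - ax) * (dy - ay) - (by - ay) * (dx - ax)
  d3 <- (dx - cx) * (ay - cy) - (dy - cy) * (ax - cx)
  d4 <- (dx - cx) * (by - cy) - (dy - cy) * (bx - cx)
  proper <- (d1 * d2 < 0) & (d3 * d4 < 0)
  if (any(proper)) return(FALSE)
  # touching / collinear-overlap: an endpoint lies on the other segment
  on_seg <- function(px, py, qx, qy, rx, ry, d) {
    d == 0 &
      rx >= pmin(px, qx) & rx <= pmax(px, qx) &
      ry >= pmin(py, qy) & ry <= pmax(py, qy)
  }
  touch <- on_seg(ax, ay, bx, by, cx, cy, d1) |
    on_seg(ax, ay, bx, by, dx, dy, d2) |
    on_seg(cx, cy, dx, dy, ax, ay, d3) |
    on_seg(cx, cy, dx, dy, bx, by, d4)
  !any(touch)
}

#' Polygon area (shoelace)
#'
#' Absolute enclosed area in squared pixels, independent of winding direction.
#'
#' @param p a polygon ([polygon_new()]) or an n x 2 vertex matrix.
#' @return area in squared pixels.
#' @export
polygon_area <- function(p) {
  shoelace_area(as_polygon(p))
}

#' Polygon perimeter
#'
#' Sum of Euclidean edge lengths including the implicit closing edge, in
#' pixels. This is the "circumference" measurement of a traced breast border.
#'
#' @inheritParams polygon_area
#' @return perimeter in pixels.
#' @export
polygon_perimeter <- function(p) {
  v <- as_polygon(p)
  nxt <- c(2:nrow(v), 1L)
  sum(sqrt((v[nxt, 1] - v[, 1])^2 + (v[nxt, 2] - v[, 2])^2))
}

#' Strict point-in-polygon test
#'
#' Even-odd (ray crossing) containment. Points exactly on the boundary are
#' reported as not interior: a nipple landmark on its border would make radial
#' ratio factors degenerate, so the annotation invariants require strict
#' interiority.
#'
#' @param pt numeric length-2 vector `c(x, y)` in pixels.
#' @inheritParams polygon_area
#' @return `TRUE` iff `pt` is strictly inside `p`.
#' @export
point_in_polygon <- function(pt, p) {
  v <- as_polygon(p)
  x <- pt[1]; y <- pt[2]
  n <- nrow(v)
  nxt <- c(2:n, 1L)
  ax <- v[, 1]; ay <- v[, 2]; bx <- v[nxt, 1]; by <- v[nxt, 2]
  # boundary check: collinear with an edge and inside its bounding box
  cr <- (bx - ax) * (y - ay) - (by - ay) * (x - ax)
  on <- cr == 0 &
    x >= pmin(ax, bx) & x <= pmax(ax, bx) &
    y >= pmin(ay, by) & y <= pmax(ay, by)
  if (any(on)) return(FALSE)
  crosses <- ((ay > y) != (by > y)) &
    (x < (bx - ax) * (y - ay) / (by - ay) + ax)
  sum(crosses) %% 2L == 1L
}

#' Radial distance profile from an interior point to a polygon boundary
#'
#' Casts `n` rays from `center` at equal angular steps, starting at 12 o'clock
#' (straight up on the displayed image) and advancing in the requested
#' rotational direction as seen on screen. Each distance is measured to the
#' nearest intersection of the ray with the polygon boundary. With the default
#' `n = 24` this is the 24-cut nipple-to-border profile whose left/right
#' per-cut ratios enter the radial symmetry factor.
#'
#' @param center interior point `c(x, y)`; typically a nipple landmark.
#' @param border the breast-border polygon.
#' @param n number of cuts (rays), default 24; must be >= 3.
#' @param orientation `"cw"` (clockwise on screen) or `"ccw"`. Mirrored
#'   breasts are profiled with opposite orientations so that cut i on one side
#'   faces cut i on the other.
#' @return an object of class `radial_profile`: list with `distances` (pixels),
#'   `angles` (degrees from 12 o'clock, in cast order) and `orientation`.
#' @export
radial_profile <- function(center, border, n = 24L, orientation = c("cw", "ccw")) {
  orientation <- match.arg(orientation)
  v <- as_polygon(border)
  if (n < 3L) stop("n must be at least 3")
  if (!point_in_polygon(center, v))
    stop_invalid_geometry("center must lie strictly inside the border polygon")
  theta <- (seq_len(n) - 1L) * 2 * pi / n
  sgn <- if (orientation == "cw") 1 else -1
  # image space is y-down: "up" is (0, -1); clockwise on screen advances
  # towards +x first.
  dirx <- sgn * sin(theta)
  diry <- -cos(theta)
  m <- nrow(v)
  nxt <- c(2:m, 1L)
  ax <- v[, 1]; ay <- v[, 2]
  ex <- v[nxt, 1] - ax; ey <- v[nxt, 2] - ay
  rx <- ax - center[1]; ry <- ay - center[2]
  # ray i: center + t * d_i ; edge j: a_j + s * e_j ; solve per (i, j)
  denom <- outer(dirx, ey) - outer(diry, ex)            # cross(d_i, e_j)
  tnum <- outer(rep(1, n), rx * ey - ry * ex)           # cross(a-c, e_j)
  snum <- outer(diry, rx) - outer(dirx, ry)             # cross(a-c, d_i)
  tt <- tnum / denom
  ss <- snum / denom
  # small slack on the edge parameter so a ray passing exactly through a
  # vertex (shared by two edges) cannot slip between both intervals
  hit <- is.finite(tt) & is.finite(ss) & tt > 1e-12 & ss >= -1e-9 & ss < 1
  tt[!hit] <- Inf
  d <- apply(tt, 1L, min)
  stopifnot(all(is.finite(d)))  # impossible for a strictly interior center
  structure(list(distances = d,
                 angles = theta * 180 / pi,
                 orientation = orientation),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("Radial profile: %d cuts (%s from 12 o'clock)\n",
              length(x$distances),
              if (x$orientation == "cw") "clockwise" else "counter-clockwise"))
  cat(sprintf("  distances [px]: min %.2f, median %.2f, max %.2f\n",
              min(x$distances), stats::median(x$distances), max(x$distances)))
  invisible(x)
}
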