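#' Construct a breast landmark annotation
#'
#' Bundles the full landmark set clicked on one frontal torso photograph:
#' the jugulum (suprasternal notch), the two nipple centres and the two
#' manually traced breast borders. "Left" and "right" are viewer-relative,
#' i.e. sides of the displayed image, matching how an annotator works on
#' screen. Coordinates are pixels, x rightward, y downward.
#'
#' Validation enforces that each nipple lies strictly inside its own border
#' and that the two borders share no vertex. A jugulum that does not lie above
#' both nipples (smaller y) is anatomically suspect and raises a warning, not
#' an error.
#'
#' @param jugulum,nipple_left,nipple_right numeric `c(x, y)` landmarks in
#'   pixels.
#' @param border_left,border_right breast-border polygons ([polygon_new()] or
#'   n x 2 vertex matrices).
#' @param image_id free-text label identifying the source image.
#' @param validate set `FALSE` to skip invariant checks (internal use on
#'   annotations derived from already-validated ones by exact transforms).
#' @return an object of class `breast_annotation`.
#' @export
breast_annotation <- function(jugulum, nipple_left, nipple_right,
                              border_left, border_right,
                              image_id = "", validate = TRUE) {
  pt_ok <- function(p, what) {
    if (!is.numeric(p) || length(p) != 2L || !all(is.finite(p)))
      stop_field_error(what, "must be a finite numeric c(x, y) pair")
    as.numeric(p)
  }
  jugulum <- pt_ok(jugulum, "jugulum")
  nipple_left <- pt_ok(nipple_left, "nipple_left")
  nipple_right <- pt_ok(nipple_right, "nipple_right")
  if (validate) {
    border_left <- tryCatch(as_polygon(border_left),
                            bsi_geometry_error = function(e)
                              stop_field_error("border_left", conditionMessage(e)))
    border_right <- tryCatch(as_polygon(border_right),
                             bsi_geometry_error = function(e)
                               stop_field_error("border_right", conditionMessage(e)))
    if (!point_in_polygon(nipple_left, border_left))
      stop_field_error("nipple_left", "must lie strictly inside border_left")
    if (!point_in_polygon(nipple_right, border_right))
      stop_field_error("nipple_right", "must lie strictly inside border_right")
    key <- function(v) paste(v[, 1], v[, 2])
    if (any(key(border_left) %in% key(border_right)))
      stop_field_error("border_right", "shares vertices with border_left")
    if (jugulum[2] >= min(nipple_left[2], nipple_right[2]))
      warning("jugulum does not lie above both nipples (y-down convention)")
  } else {
    border_left <- unclass_polygon(border_left)
    border_right <- unclass_polygon(border_right)
  }
  structure(list(jugulum = jugulum,
                 nipple_left = nipple_left,
                 nipple_right = nipple_right,
                 border_left = border_left,
                 border_right = border_right,
                 image_id = as.character(image_id)),
            class = "breast_annotation")
}

unclass_polygon <- function(x) {
  v <- as.matrix(x)
  dimnames(v) <- list(NULL, c("x", "y"))
  class(v) <- c("bsi_polygon", "matrix", "array")
  v
}

stop_field_error <- function(field, ...) {
  stop(errorCondition(paste0(field, ": ", ...),
                      field = field,
                      class = c("bsi_field_error", "error")))
}

#' @export
print.breast_annotation <- function(x, ...) {
  cat("Breast annotation", if (nzchar(x$image_id)) sprintf("[%s]", x$image_id),
      "\n")
  cat(sprintf("  jugulum       (%.1f, %.1f)\n", x$jugulum[1], x$jugulum[2]))
  cat(sprintf("  nipple left   (%.1f, %.1f)   right (%.1f, %.1f)\n",
              x$nipple_left[1], x$nipple_left[2],
              x$nipple_right[1], x$nipple_right[2]))
  cat(sprintf("  border left   %d vertices, area %.0f px^2\n",
              nrow(x$border_left), polygon_area(x$border_left)))
  cat(sprintf("  border right  %d vertices, area %.0f px^2\n",
              nrow(x$border_right), polygon_area(x$border_right)))
  invisible(x)
}

#' Plot a breast annotation
#'
#' Draws both borders, the nipple and jugulum landmarks and, optionally, the
#' radial cuts, in image coordinates (y axis increasing downwards, as on
#' screen).
#'
#' @param x a `breast_annotation`.
#' @param rays draw the radial cuts from each nipple to its border.
#' @param n_cuts number of radial cuts when `rays = TRUE`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.breast_annotation <- function(x, rays = FALSE, n_cuts = 24L, ...) {
  all_xy <- rbind(x$border_left, x$border_right, x$jugulum,
                  x$nipple_left, x$nipple_right)
  graphics::plot(NA, xlim = range(all_xy[, 1]), ylim = rev(range(all_xy[, 2])),
                 xlab = "x [px]", ylab = "y [px]", asp = 1, ...)
  for (side in c("border_left", "border_right")) {
    v <- x[[side]]
    graphics::polygon(v[, 1], v[, 2], border = "steelblue4")
  }
  if (rays) {
    for (side in c("left", "right")) {
      np <- x[[paste0("nipple_", side)]]
      pr <- radial_profile(np, x[[paste0("border_", side)]], n = n_cuts,
                           orientation = if (side == "left") "cw" else "ccw")
      th <- pr$angles * pi / 180
      sgn <- if (side == "left") 1 else -1
      graphics::segments(np[1], np[2],
                         np[1] + pr$distances * sgn * sin(th),
                         np[2] - pr$distances * cos(th),
                         col = "grey70")
    }
  }
  graphics::points(rbind(x$nipple_left, x$nipple_right), pch = 19, col = "firebrick")
  graphics::points(x$jugulum[1], x$jugulum[2], pch = 17, col = "darkgreen")
  invisible(x)
}
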