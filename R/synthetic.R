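#' Parameters of a synthetic breast contour pair
#'
#' Describes one breast contour as a star-shaped radial function around its
#' centre — an ellipse with an optional inferior "droop" elongation — plus the
#' landmark layout of the torso. [make_symmetric_pair()] discretises the
#' contour and mirrors it about the torso midline, so the defaults here define
#' a realistic, exactly symmetric annotation on a nominal ~1000 px wide
#' frontal photograph.
#'
#' @param semi_axis_horizontal,semi_axis_vertical ellipse semi-axes in pixels.
#' @param droop dimensionless inferior elongation coefficient (>= 0): the
#'   radius in a direction with downward component s is multiplied by
#'   `1 + droop * max(0, s)`, elongating the lower pole.
#' @param nipple_offset `c(dx, dy)` of the nipple from the contour centre, in
#'   pixels; must leave the nipple strictly inside the contour.
#' @param torso_midline_x x coordinate of the mirror axis, in pixels.
#' @param jugulum jugulum landmark `c(x, y)`; for an exactly symmetric pair
#'   its x must equal `torso_midline_x` (the default places it there).
#' @param center_left centre of the left-breast contour; default is placed
#'   laterally and below the jugulum from the other parameters.
#' @param n_vertices vertices used to discretise one contour (>= 36).
#' @param irregularity amplitude (fraction of radius) of smooth low-order
#'   radial perturbations that make the contour less perfectly elliptic;
#'   0 disables. Values well below 1 keep the contour star-shaped.
#' @param seed integer seed for the irregularity harmonics; ignored when
#'   `irregularity = 0`.
#' @return an object of class `shape_params`.
#' @export
shape_params <- function(semi_axis_horizontal = 120,
                         semi_axis_vertical = 100,
                         droop = 0.15,
                         nipple_offset = c(0, 10),
                         torso_midline_x = 500,
                         jugulum = c(torso_midline_x, 150),
                         center_left = c(torso_midline_x - 1.6 * semi_axis_horizontal,
                                         jugulum[2] + 2.6 * semi_axis_vertical),
                         n_vertices = 96L,
                         irregularity = 0,
                         seed = 1L) {
  if (semi_axis_horizontal <= 0 || semi_axis_vertical <= 0)
    stop("semi-axes must be positive")
  if (droop < 0) stop("droop must be non-negative")
  if (n_vertices < 36L) stop("n_vertices must be at least 36")
  if (irregularity < 0 || irregularity >= 0.5)
    stop("irregularity must lie in [0, 0.5)")
  structure(list(semi_axis_horizontal = semi_axis_horizontal,
                 semi_axis_vertical = semi_axis_vertical,
                 droop = droop,
                 nipple_offset = as.numeric(nipple_offset),
                 torso_midline_x = torso_midline_x,
                 jugulum = as.numeric(jugulum),
                 center_left = as.numeric(center_left),
                 n_vertices = as.integer(n_vertices),
                 irregularity = irregularity,
                 seed = as.integer(seed)),
            class = "shape_params")
}

# radial contour of one breast: direction angles measured clockwise from
# 12 o'clock (image up); returns an n x 2 vertex matrix around `center`.
contour_vertices <- function(p, center) {
  th <- (seq_len(p$n_vertices) - 1L) * 2 * pi / p$n_vertices
  ux <- sin(th); uy <- -cos(th)            # y-down image space
  a <- p$semi_axis_horizontal; b <- p$semi_axis_vertical
  r <- a * b / sqrt((b * ux)^2 + (a * uy)^2)
  r <- r * (1 + p$droop * pmax(0, uy))     # uy > 0 points inferiorly
  if (p$irregularity > 0) {
    set.seed(p$seed)
    amp <- p$irregularity * stats::runif(3, 0.3, 1)
    ph <- stats::runif(3, 0, 2 * pi)
    r <- r * (1 + amp[1] * sin(2 * th + ph[1]) / 3 +
                amp[2] * sin(3 * th + ph[2]) / 3 +
                amp[3] * sin(4 * th + ph[3]) / 3)
  }
  cbind(center[1] + r * ux, center[2] + r * uy)
}

#' Generate an exactly mirror-symmetric synthetic annotation
#'
#' Builds the left breast contour and nipple from [shape_params()], then
#' reflects every coordinate about the vertical line `x = torso_midline_x` to
#' produce the right side. The result passes all annotation invariants and
#' scores a symmetry index of 0 (up to floating-point noise), which makes it
#' the baseline onto which [apply_asymmetry()] grafts controlled defects.
#'
#' @param p a [shape_params()].
#' @param image_id label for the generated annotation.
#' @return a [breast_annotation()].
#' @export
make_symmetric_pair <- function(p = shape_params(), image_id = "synthetic") {
  stopifnot(inherits(p, "shape_params"))
  vl <- contour_vertices(p, p$center_left)
  nl <- p$center_left + p$nipple_offset
  if (max(vl[, 1]) >= p$torso_midline_x)
    stop("left contour crosses the torso midline; move center_left laterally")
  mirror_x <- function(x) 2 * p$torso_midline_x - x
  vr <- cbind(mirror_x(vl[, 1]), vl[, 2])
  nr <- c(mirror_x(nl[1]), nl[2])
  ann <- breast_annotation(jugulum = p$jugulum,
                           nipple_left = nl, nipple_right = nr,
                           border_left = vl, border_right = vr,
                           image_id = image_id)
  ann
}

#' Unilateral asymmetry specification
#'
#' The controlled defects grafted onto one side of a symmetric annotation:
#' a nipple displacement, an isotropic rescaling of the border about the
#' nipple (area multiplies by the square of the factor), and a vertical shift
#' of the whole side.
#'
#' @param side which breast is perturbed, `"right"` or `"left"`
#'   (viewer-relative).
#' @param nipple_shift `c(dx, dy)` pixels applied to that side's nipple.
#' @param area_scale positive factor scaling that side's border about its
#'   nipple.
#' @param vertical_shift pixels added to the y of every point on that side
#'   (border and nipple).
#' @return an object of class `asymmetry_spec`.
#' @export
asymmetry_spec <- function(side = c("right", "left"),
                           nipple_shift = c(0, 0),
                           area_scale = 1,
                           vertical_shift = 0) {
  side <- match.arg(side)
  if (area_scale <= 0) stop("area_scale must be positive")
  structure(list(side = side, nipple_shift = as.numeric(nipple_shift),
                 area_scale = area_scale, vertical_shift = vertical_shift),
            class = "asymmetry_spec")
}

#' Apply a unilateral perturbation to an annotation
#'
#' Returns a new annotation with the requested side perturbed; the other side
#' and the jugulum are returned untouched. The perturbed nipple must remain
#' strictly inside its (possibly rescaled) border.
#'
#' @param ann a [breast_annotation()].
#' @param spec an [asymmetry_spec()].
#' @return a [breast_annotation()].
#' @export
apply_asymmetry <- function(ann, spec) {
  stopifnot(inherits(ann, "breast_annotation"), inherits(spec, "asymmetry_spec"))
  nip_f <- paste0("nipple_", spec$side)
  bor_f <- paste0("border_", spec$side)
  nip <- ann[[nip_f]] + c(0, spec$vertical_shift) + spec$nipple_shift
  bor <- unclass(ann[[bor_f]])
  bor[, 2] <- bor[, 2] + spec$vertical_shift
  if (spec$area_scale != 1) {
    bor <- cbind(nip[1] + spec$area_scale * (bor[, 1] - nip[1]),
                 nip[2] + spec$area_scale * (bor[, 2] - nip[2]))
  }
  out <- ann
  out[[nip_f]] <- nip
  out[[bor_f]] <- unclass_polygon(bor)
  if (!point_in_polygon(nip, out[[bor_f]]))
    stop("perturbation moved ", nip_f, " outside its border")
  withCallingHandlers(
    breast_annotation(out$jugulum, out$nipple_left, out$nipple_right,
                      out$border_left, out$border_right,
                      image_id = out$image_id),
    warning = function(w) invokeRestart("muffleWarning"))
}

# smooth displacement field along a closed contour: per-vertex marginal
# N(0, sd^2) per coordinate, built from low-order Fourier harmonics so a
# rater's error displaces whole stretches of the border coherently.
smooth_contour_jitter <- function(nv, sd) {
  if (sd == 0) return(matrix(0, nv, 2))
  hmax <- 3L
  t <- (seq_len(nv) - 1L) / nv
  one <- function() {
    co <- stats::rnorm(2 * hmax + 1, sd = sd / sqrt(2 * hmax + 1) * sqrt(2))
    # constant term has unit basis, harmonics have amplitude sqrt(2)-scaled
    d <- co[1] / sqrt(2)
    for (h in seq_len(hmax))
      d <- d + co[2 * h] * cos(2 * pi * h * t) + co[2 * h + 1] * sin(2 * pi * h * t)
    d
  }
  cbind(one(), one())
}

#' Simulate an annotation panel of imperfect raters
#'
#' Emulates k investigators independently annotating the same photograph:
#' each rater's copy displaces every landmark and border vertex by isotropic
#' Gaussian error with marginal standard deviation `jitter_sd` pixels. Border
#' displacements are spatially smooth along the contour (a rater misplaces
#' whole stretches of the traced border, not individual pixels), which keeps
#' the perturbed borders simple; landmark points are jittered independently.
#' A draw that violates the annotation invariants (e.g. a nipple pushed onto
#' its border) is resampled a bounded number of times.
#'
#' @param ann the true [breast_annotation()].
#' @param k number of raters (>= 2).
#' @param jitter_sd per-coordinate error standard deviation in pixels.
#' @param seed integer seed; the panel is reproducible bit-for-bit.
#' @param max_retries resampling attempts per rater before giving up.
#' @return list of `k` [breast_annotation()] objects.
#' @export
simulate_rater_panel <- function(ann, k, jitter_sd, seed = 1L,
                                 max_retries = 25L) {
  stopifnot(inherits(ann, "breast_annotation"))
  if (k < 2L) stop("k must be at least 2")
  if (jitter_sd < 0) stop("jitter_sd must be non-negative")
  set.seed(seed)
  jitter_once <- function(rater) {
    jit_pt <- function(p) p + stats::rnorm(2, sd = jitter_sd)
    jit_border <- function(v) unclass(v) + smooth_contour_jitter(nrow(v), jitter_sd)
    withCallingHandlers(
      breast_annotation(jit_pt(ann$jugulum),
                        jit_pt(ann$nipple_left), jit_pt(ann$nipple_right),
                        jit_border(ann$border_left), jit_border(ann$border_right),
                        image_id = sprintf("%s/rater%02d", ann$image_id, rater)),
      warning = function(w) invokeRestart("muffleWarning"))
  }
  lapply(seq_len(k), function(rater) {
    for (try in seq_len(max_retries)) {
      out <- tryCatch(jitter_once(rater), error = function(e) NULL)
      if (!is.null(out)) return(out)
    }
    stop("could not draw a valid annotation for rater ", rater,
         " after ", max_retries, " attempts (jitter_sd too large?)")
  })
}
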