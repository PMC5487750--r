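# shared fixture builders and independent geometry oracles

# regular n-gon approximating a circle
regular_ngon <- function(n, radius = 1, center = c(0, 0)) {
  th <- (seq_len(n) - 1) * 2 * pi / n
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

# random star-shaped polygon: random radii at jittered equispaced angles
# (angular gaps stay below pi, which guarantees simplicity)
random_star_polygon <- function(n, radius = 100, wobble = 0.35,
                                center = c(0, 0)) {
  th <- (seq_len(n) - 1 + stats::runif(n, 0.05, 0.95)) * 2 * pi / n
  r <- radius * (1 + stats::runif(n, -wobble, wobble))
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# vectorised even-odd containment for many points (Monte-Carlo oracle);
# independent of the package's point_in_polygon
pip_crossing_many <- function(px, py, v) {
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]; xj <- v[j, 1]; yj <- v[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# winding-number oracle via summed signed angles (off-boundary points only)
pip_winding <- function(pt, v) {
  dx <- v[, 1] - pt[1]; dy <- v[, 2] - pt[2]
  a <- atan2(dy, dx)
  d <- diff(c(a, a[1]))
  d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
  abs(sum(d)) > pi  # winding number != 0
}

# Monte-Carlo polygon area estimate on the bounding box
mc_area <- function(v, n_samples = 1e6) {
  bb <- apply(v, 2, range)
  px <- stats::runif(n_samples, bb[1, 1], bb[2, 1])
  py <- stats::runif(n_samples, bb[1, 2], bb[2, 2])
  mean(pip_crossing_many(px, py, v)) * diff(bb[, 1]) * diff(bb[, 2])
}

# random valid shape parameters for property tests
random_shape_params <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  shape_params(semi_axis_horizontal = stats::runif(1, 70, 160),
               semi_axis_vertical = stats::runif(1, 60, 140),
               droop = stats::runif(1, 0, 0.4),
               nipple_offset = c(stats::runif(1, -15, 15),
                                 stats::runif(1, -10, 25)),
               n_vertices = sample(36:120, 1),
               irregularity = stats::runif(1, 0, 0.25),
               seed = sample.int(1e6, 1))
}

# a small panel study: n subjects with graded asymmetry, k jittered raters
# each; returns the n x k matrix of BSI scores
simulate_bsi_matrix <- function(n_subjects = 10, k = 5, jitter_sd = 2,
                                seed = 1) {
  set.seed(seed)
  shifts <- seq(0, 45, length.out = n_subjects)
  scales <- seq(1, 1.35, length.out = n_subjects)
  scores <- matrix(NA_real_, n_subjects, k)
  for (i in seq_len(n_subjects)) {
    truth <- make_symmetric_pair(shape_params(n_vertices = 60))
    truth <- apply_asymmetry(truth, asymmetry_spec(
      side = "right", nipple_shift = c(0, shifts[i]), area_scale = scales[i]))
    panel <- simulate_rater_panel(truth, k = k, jitter_sd = jitter_sd,
                                  seed = seed * 1000L + i)
    scores[i, ] <- vapply(panel, function(a) bsi_score(a)$bsi, numeric(1))
  }
  rating_matrix(scores)
}

# hand-built non-trivial annotation used in io round-trip tests
fixture_annotation <- function() {
  breast_annotation(
    jugulum = c(200, 50),
    nipple_left = c(120.5, 180.25),
    nipple_right = c(280.5, 184),
    border_left = cbind(c(120, 160, 170, 150, 120, 85, 70, 80),
                        c(120, 140, 185, 230, 245, 230, 185, 140)),
    border_right = cbind(c(280, 320, 335, 325, 280, 245, 230, 240),
                         c(122, 142, 187, 232, 246, 232, 187, 142)),
    image_id = "fixture-01")
}
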