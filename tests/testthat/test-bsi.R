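test_that("ratio factor implements shorter/longer with the zero conventions", {
  expect_equal(ratio_factor(5, 5), 1)
  expect_equal(ratio_factor(3, 4), 0.75)
  expect_equal(ratio_factor(4, 3), 0.75)     # symmetric in arguments
  expect_equal(ratio_factor(0, 7), 0)
  expect_equal(ratio_factor(0, 0), 1)        # both null: perfectly symmetric
  expect_error(ratio_factor(-1, 2))
})

test_that("annotation invariants are enforced", {
  ann <- fixture_annotation()
  expect_s3_class(ann, "breast_annotation")
  # nipple outside its border
  expect_error(
    breast_annotation(c(200, 50), c(400, 400), ann$nipple_right,
                      ann$border_left, ann$border_right),
    class = "bsi_field_error")
  # shared vertices between the borders
  expect_error(
    breast_annotation(ann$jugulum, ann$nipple_left, ann$nipple_right,
                      ann$border_left, ann$border_left),
    class = "bsi_field_error")
  # jugulum below a nipple warns but does not error
  expect_warning(
    breast_annotation(c(200, 300), ann$nipple_left, ann$nipple_right,
                      ann$border_left, ann$border_right),
    "jugulum")
})

test_that("factors are exact on a mirror annotation and its perturbations", {
  base <- make_symmetric_pair(shape_params(irregularity = 0.15, seed = 9))
  f0 <- compute_factors(base)
  expect_equal(unclass(f0), c(direct = 1, horizontal = 1, vertical = 1,
                              radial = 1, area = 1, circumference = 1),
               tolerance = 1e-12)

  # uniform scaling of the right border about the right nipple
  scaled <- apply_asymmetry(base, asymmetry_spec("right", area_scale = 1.1))
  fs <- compute_factors(scaled)
  expect_equal(fs[["area"]], 1 / 1.1^2, tolerance = 1e-9)
  expect_equal(fs[["circumference"]], 1 / 1.1, tolerance = 1e-9)
  expect_equal(fs[["radial"]], 1 / 1.1, tolerance = 1e-9)
  expect_equal(fs[["direct"]], 1)
  expect_equal(fs[["horizontal"]], 1)
  expect_equal(fs[["vertical"]], 1)

  # nipple moved 10 px down with a vertical offset of 40 px on the other side
  p <- shape_params(nipple_offset = c(0, 0))
  v <- (p$center_left[2]) - p$jugulum[2]    # left vertical offset
  shifted <- apply_asymmetry(make_symmetric_pair(p),
                             asymmetry_spec("right", nipple_shift = c(0, 10)))
  ff <- compute_factors(shifted)
  expect_equal(ff[["vertical"]], v / (v + 10), tolerance = 1e-9)
  # fixture chosen so v = 40 gives the hand value 0.8
  p40 <- shape_params(nipple_offset = c(0, 0),
                      jugulum = c(500, 150),
                      center_left = c(300, 190),
                      semi_axis_horizontal = 120, semi_axis_vertical = 100)
  sh40 <- apply_asymmetry(
    suppressWarnings(make_symmetric_pair(p40)),
    asymmetry_spec("right", nipple_shift = c(0, 10)))
  expect_equal(compute_factors(sh40)[["vertical"]], 40 / 50, tolerance = 1e-9)
})

test_that("questionnaire pooling reproduces the published overall means", {
  m <- pooled_means(default_questionnaire())
  expect_equal(round(m[["mamilla_position"]], 2), 1.41)
  expect_equal(round(m[["circumference"]], 2), 2.24)
  expect_equal(m[["mamilla_position"]], (10 * 1.333 + 8 * 1.5) / 18)
})

test_that("weight derivation normalises 5 - pooled mean with the mamilla split", {
  w <- derive_weights()
  expect_s3_class(w, "bsi_weights")
  expect_equal(sum(w$w), 1, tolerance = 1e-15)
  grp_mam <- sum(w$w[c("direct", "horizontal", "vertical", "radial")])
  # frozen hand-normalisation of r = 5 - m over the three groups
  expect_equal(grp_mam, 0.389555, tolerance = 1e-6)
  expect_equal(w$w[["area"]], 0.311246, tolerance = 1e-6)
  expect_equal(w$w[["circumference"]], 0.299199, tolerance = 1e-6)
  expect_equal(w$w[["direct"]], 0.0973887, tolerance = 1e-6)
  # all four mamilla sub-weights equal
  expect_equal(length(unique(w$w[c("direct", "horizontal", "vertical", "radial")])), 1L)
  # nipple group dominates both area and circumference
  expect_gt(grp_mam, w$w[["area"]])
  expect_gt(grp_mam, w$w[["circumference"]])
})

test_that("weight constructor enforces normalisation and sign", {
  expect_error(bsi_weights(0.3, 0.3, 0.3, 0.3, 0.3, 0.3), "sum to 1")
  expect_error(bsi_weights(-0.1, 0.3, 0.2, 0.2, 0.2, 0.2), "non-negative")
})

test_that("bsi combines weighted asymmetries onto the 0-15 scale", {
  f1 <- c(direct = 1, horizontal = 1, vertical = 1, radial = 1,
          area = 1, circumference = 1)
  expect_equal(compute_bsi(f1)$bsi, 0)
  f0 <- f1 * 0
  r0 <- compute_bsi(f0)
  expect_equal(r0$bsi, 15)                   # weights sum to 1: exact saturation
  expect_equal(r0$harris, 4L)
  # frozen arithmetic oracle for a scaled-border case
  fs <- c(direct = 1, horizontal = 1, vertical = 1, radial = 1,
          area = 1 / 1.21, circumference = 1 / 1.1)
  rs <- compute_bsi(fs)
  expect_equal(rs$bsi, 1.2182677435, tolerance = 1e-9)
  expect_equal(rs$bsi_mammilla, 0)
  expect_equal(rs$bsi, rs$bsi_mammilla + rs$bsi_area)
})

test_that("harris banding reproduces the published half-unit table", {
  expect_identical(harris_band(2.5), 1L)
  expect_identical(harris_band(6.5), 2L)
  expect_identical(harris_band(10), 3L)
  expect_identical(harris_band(10.5), 4L)
  expect_identical(harris_band(0), 1L)
  grid <- seq(0, 15, by = 0.5)
  want <- ifelse(grid <= 2.5, 1L, ifelse(grid <= 6.5, 2L,
                                         ifelse(grid <= 10, 3L, 4L)))
  expect_identical(harris_band(grid), want)
  # off-grid values round to the nearest half unit, ties away from zero
  expect_identical(harris_band(2.6), 1L)
  expect_identical(harris_band(2.75), 2L)
  expect_identical(harris_band(10.24), 3L)
  expect_identical(harris_band(10.25), 4L)
  expect_error(harris_band(15.2))
  expect_error(harris_band(-0.1))
})

test_that("mirror annotations score zero and swapping sides is invariant", {
  set.seed(202)
  for (rep in 1:40) {
    ann <- make_symmetric_pair(random_shape_params())
    expect_lt(bsi_score(ann)$bsi, 1e-9)
  }
  # left/right swap via reflection of a perturbed annotation
  base <- make_symmetric_pair(shape_params())
  pert <- apply_asymmetry(base, asymmetry_spec(
    "right", nipple_shift = c(4, 12), area_scale = 1.15))
  mirror <- function(ann, mx) {
    fx <- function(p) c(2 * mx - p[1], p[2])
    fv <- function(v) cbind(2 * mx - v[, 1], v[, 2])
    breast_annotation(fx(ann$jugulum), fx(ann$nipple_right), fx(ann$nipple_left),
                      fv(ann$border_right), fv(ann$border_left),
                      image_id = ann$image_id)
  }
  swapped <- mirror(pert, 500)
  expect_equal(bsi_score(swapped)$bsi, bsi_score(pert)$bsi, tolerance = 1e-9)
})

test_that("bsi is invariant under translation and uniform scaling", {
  base <- apply_asymmetry(make_symmetric_pair(shape_params()),
                          asymmetry_spec("left", nipple_shift = c(-6, 9),
                                         area_scale = 0.9))
  ref <- bsi_score(base)
  transform <- function(ann, s, dx, dy) {
    f <- function(p) s * p + c(dx, dy)
    fv <- function(v) cbind(s * v[, 1] + dx, s * v[, 2] + dy)
    suppressWarnings(breast_annotation(
      f(ann$jugulum), f(ann$nipple_left), f(ann$nipple_right),
      fv(ann$border_left), fv(ann$border_right)))
  }
  for (case in list(c(1, 250, -80), c(3.7, 0, 0), c(0.25, 40, 1000))) {
    got <- bsi_score(transform(base, case[1], case[2], case[3]))
    expect_equal(got$bsi, ref$bsi, tolerance = 1e-9)
    expect_equal(unclass(got$factors), unclass(ref$factors), tolerance = 1e-9)
  }
})

test_that("bsi stays in range and increases with the size of a defect", {
  set.seed(77)
  for (rep in 1:200) {
    f <- stats::runif(6)
    names(f) <- c("direct", "horizontal", "vertical", "radial",
                  "area", "circumference")
    r <- stats::runif(6)
    w <- bsi_weights(r[1] / sum(r), r[2] / sum(r), r[3] / sum(r),
                     r[4] / sum(r), r[5] / sum(r),
                     1 - sum(r[1:5]) / sum(r))
    b <- compute_bsi(f, w)
    expect_gte(b$bsi, 0)
    expect_lte(b$bsi, 15)
    expect_equal(b$bsi, b$bsi_mammilla + b$bsi_area)
  }
  # monotone dose-response along two defect rays
  base <- make_symmetric_pair(shape_params())
  shift_scores <- vapply(seq(0, 40, by = 5), function(h)
    bsi_score(apply_asymmetry(base, asymmetry_spec(
      "right", nipple_shift = c(0, h))))$bsi, numeric(1))
  expect_true(all(diff(shift_scores) >= -1e-12))
  scale_scores <- vapply(seq(1, 1.4, by = 0.05), function(s)
    bsi_score(apply_asymmetry(base, asymmetry_spec(
      "right", area_scale = s)))$bsi, numeric(1))
  expect_true(all(diff(scale_scores) >= -1e-12))
})
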