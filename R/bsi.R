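#' Bilateral ratio factor
#'
#' The elementary symmetry comparison: the shorter of a bilateral measurement
#' pair divided by the longer, giving a value in `[0, 1]` where 1 means the
#' two sides agree exactly. When both measurements are identically zero the
#' pair is perfectly symmetric and the factor is 1 by convention; when exactly
#' one side is zero the factor is 0 (maximal asymmetry).
#'
#' @param a,b non-negative lengths or areas (vectorised).
#' @return ratio in `[0, 1]`.
#' @examples
#' ratio_factor(3, 4)   # 0.75
#' @export
ratio_factor <- function(a, b) {
  if (any(a < 0) || any(b < 0)) stop("ratio_factor inputs must be non-negative")
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  ifelse(hi == 0, 1, lo / hi)
}

#' Compute the six bilateral symmetry factors
#'
#' Measures each component on both sides of an annotation and reduces each
#' pair to a [ratio_factor()]:
#' \describe{
#'   \item{f_direct}{straight jugulum-to-nipple distances.}
#'   \item{f_horizontal}{horizontal nipple offsets `|x_nipple - x_jugulum|`.}
#'   \item{f_vertical}{vertical nipple offsets `|y_nipple - y_jugulum|`.}
#'   \item{f_area}{enclosed border areas.}
#'   \item{f_circumference}{border perimeters.}
#'   \item{f_radial}{arithmetic mean of the per-cut ratios of the two
#'     nipple-to-border radial profiles. The left profile is cast clockwise
#'     and the right counter-clockwise so that cut i on one side faces cut i
#'     anatomically on the other (mirror correspondence).}
#' }
#'
#' @param ann a [breast_annotation()].
#' @param n_cuts number of radial cuts; default 24.
#' @return an object of class `symmetry_factors`: named numeric vector of the
#'   six factors, each in `(0, 1]`.
#' @export
compute_factors <- function(ann, n_cuts = 24L) {
  stopifnot(inherits(ann, "breast_annotation"))
  dl <- ann$nipple_left - ann$jugulum
  dr <- ann$nipple_right - ann$jugulum
  prof_l <- radial_profile(ann$nipple_left, ann$border_left,
                           n = n_cuts, orientation = "cw")
  prof_r <- radial_profile(ann$nipple_right, ann$border_right,
                           n = n_cuts, orientation = "ccw")
  f <- c(
    direct = ratio_factor(sqrt(sum(dl^2)), sqrt(sum(dr^2))),
    horizontal = ratio_factor(abs(dl[1]), abs(dr[1])),
    vertical = ratio_factor(abs(dl[2]), abs(dr[2])),
    radial = mean(ratio_factor(prof_l$distances, prof_r$distances)),
    area = ratio_factor(polygon_area(ann$border_left),
                        polygon_area(ann$border_right)),
    circumference = ratio_factor(polygon_perimeter(ann$border_left),
                                 polygon_perimeter(ann$border_right)))
  structure(f, class = "symmetry_factors")
}

#' @export
print.symmetry_factors <- function(x, ...) {
  cat("Symmetry factors (1 = perfect bilateral agreement):\n")
  print(round(unclass(x), 4), ...)
  invisible(x)
}

#' Combine symmetry factors into the 0-15 symmetry index
#'
#' Each factor f is turned into an asymmetry `d = 1 - f`; the weighted
#' asymmetries of the four nipple-position components form the mammilla
#' sub-score and those of area and circumference the area sub-score, each
#' scaled by the 15-point maximum. Their sum is the total index: 0 for
#' perfect bilateral symmetry, 15 for the poorest. The total is also banded
#' onto the four-level Harris cosmesis scale ([harris_band()]).
#'
#' @param factors a `symmetry_factors` vector ([compute_factors()]) or a named
#'   numeric vector with entries `direct`, `horizontal`, `vertical`, `radial`,
#'   `area`, `circumference`, each in `[0, 1]`.
#' @param weights a [bsi_weights()]; defaults to the questionnaire-derived
#'   configuration.
#' @return an object of class `bsi_result` with components `bsi_mammilla`,
#'   `bsi_area`, `bsi`, `harris`, `factors` and `weights`.
#' @export
compute_bsi <- function(factors, weights = derive_weights()) {
  stopifnot(inherits(weights, "bsi_weights"))
  f <- unclass(factors)
  need <- names(weights$w)
  if (!all(need %in% names(f)))
    stop("factors must be named with: ", paste(need, collapse = ", "))
  f <- f[need]
  if (any(f < 0 | f > 1)) stop("factors must lie in [0, 1]")
  d <- 1 - f
  mam <- c("direct", "horizontal", "vertical", "radial")
  are <- c("area", "circumference")
  bsi_mam <- weights$scale_max * sum(weights$w[mam] * d[mam])
  bsi_are <- weights$scale_max * sum(weights$w[are] * d[are])
  bsi <- bsi_mam + bsi_are
  structure(list(bsi_mammilla = bsi_mam,
                 bsi_area = bsi_are,
                 bsi = bsi,
                 harris = harris_band(bsi, scale_max = weights$scale_max),
                 factors = structure(f, class = "symmetry_factors"),
                 weights = weights),
            class = "bsi_result")
}

#' Map a symmetry index value onto the Harris cosmesis groups
#'
#' The published banding enumerates half-unit index values: group 1
#' (excellent) covers 1-2.5, group 2 (good) 3-6.5, group 3 (fair) 7-10 and
#' group 4 (poor) 10.5-15. Scores are therefore first rounded to the nearest
#' 0.5 (ties away from zero) and then looked up; rounded values below 1 fall
#' in group 1.
#'
#' @param bsi symmetry index value(s) in `[0, scale_max]`.
#' @param scale_max upper end of the index scale; default 15.
#' @return integer Harris group(s) in `1:4`.
#' @examples
#' harris_band(c(0, 2.5, 6.5, 10, 10.5))
#' @export
harris_band <- function(bsi, scale_max = 15) {
  if (any(!is.finite(bsi)) || any(bsi < 0 | bsi > scale_max))
    stop("bsi must lie in [0, ", scale_max, "]")
  r <- floor(2 * bsi + 0.5) / 2  # nearest 0.5, ties away from zero
  as.integer(cut(r, breaks = c(-Inf, 2.5, 6.5, 10, Inf), labels = FALSE))
}

#' Score an annotation: the one-call front end
#'
#' Convenience wrapper running [compute_factors()] then [compute_bsi()].
#'
#' @inheritParams compute_factors
#' @inheritParams compute_bsi
#' @return a `bsi_result`; see [compute_bsi()].
#' @examples
#' ann <- make_symmetric_pair(shape_params())
#' bsi_score(ann)   # exactly symmetric: index 0, Harris group 1
#' @export
bsi_score <- function(ann, weights = derive_weights(), n_cuts = 24L) {
  compute_bsi(compute_factors(ann, n_cuts = n_cuts), weights = weights)
}

harris_labels <- c("excellent", "good", "fair", "poor")

#' @export
print.bsi_result <- function(x, digits = 3, ...) {
  cat(sprintf("BSI %s  (mammilla %s + area %s)  Harris group %d (%s)\n",
              format(round(x$bsi, digits)),
              format(round(x$bsi_mammilla, digits)),
              format(round(x$bsi_area, digits)),
              x$harris, harris_labels[x$harris]))
  invisible(x)
}

#' @export
summary.bsi_result <- function(object, ...) {
  cat("Breast Symmetry Index (0 = perfect symmetry, ",
      object$weights$scale_max, " = poorest)\n\n", sep = "")
  print(object)
  cat("\n")
  print(object$factors)
  cat("\n")
  print(object$weights)
  invisible(object)
}

#' Coerce a result to a one-row data frame
#'
#' @param x a `bsi_result`.
#' @param ... unused.
#' @export
as.data.frame.bsi_result <- function(x, ...) {
  f <- unclass(x$factors)
  data.frame(f_direct = f[["direct"]], f_horizontal = f[["horizontal"]],
             f_vertical = f[["vertical"]], f_radial = f[["radial"]],
             f_area = f[["area"]], f_circumference = f[["circumference"]],
             bsi_mammilla = x$bsi_mammilla, bsi_area = x$bsi_area,
             bsi = x$bsi, harris = x$harris)
}
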