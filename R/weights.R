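#' Questionnaire importance summary
#'
#' Panel means of the perceived importance of breast-appearance aspects,
#' scored 1 (very important) to 4 (not important), split into an expert
#' (breast surgeons) and a non-expert (medical students) panel. These summary
#' statistics drive the default component weighting of the symmetry index.
#'
#' @param expert_mean,nonexpert_mean named numeric vectors with entries
#'   `circumference`, `area`, `mamilla_position`, `scars`; per-panel mean
#'   importance scores in `[1, 4]`.
#' @param n_expert,n_nonexpert panel sizes.
#' @return an object of class `questionnaire_summary`.
#' @seealso [default_questionnaire()] for the published panel values,
#'   [derive_weights()] for the weighting scheme.
#' @export
questionnaire_summary <- function(expert_mean, nonexpert_mean,
                                  n_expert, n_nonexpert) {
  items <- c("circumference", "area", "mamilla_position", "scars")
  chk <- function(m, what) {
    if (!all(items %in% names(m)))
      stop(what, " must be named with: ", paste(items, collapse = ", "))
    m <- m[items]
    if (any(m < 1 | m > 4)) stop(what, " values must lie in [1, 4]")
    m
  }
  if (n_expert <= 0 || n_nonexpert <= 0) stop("panel sizes must be positive")
  structure(list(expert_mean = chk(expert_mean, "expert_mean"),
                 nonexpert_mean = chk(nonexpert_mean, "nonexpert_mean"),
                 n_expert = as.integer(n_expert),
                 n_nonexpert = as.integer(n_nonexpert)),
            class = "questionnaire_summary")
}

#' Published questionnaire panel summary
#'
#' The importance ratings of the original expert (n = 10) and non-expert
#' (n = 8) panels; the source of the default weight configuration.
#'
#' @return a [questionnaire_summary()].
#' @export
default_questionnaire <- function() {
  questionnaire_summary(
    expert_mean = c(circumference = 2.333, area = 2.333,
                    mamilla_position = 1.333, scars = 2.444),
    nonexpert_mean = c(circumference = 2.125, area = 1.875,
                       mamilla_position = 1.5, scars = 1.875),
    n_expert = 10, n_nonexpert = 8)
}

#' Pooled questionnaire item means
#'
#' Size-weighted pooling of the expert and non-expert panel means per item.
#'
#' @param q a [questionnaire_summary()].
#' @return named numeric vector of pooled means, one per item.
#' @export
pooled_means <- function(q) {
  stopifnot(inherits(q, "questionnaire_summary"))
  m <- (q$n_expert * q$expert_mean + q$n_nonexpert * q$nonexpert_mean) /
    (q$n_expert + q$n_nonexpert)
  if (any(m < 1 | m > 4)) stop("pooled means fall outside the [1, 4] scale")
  m
}

#' Weight configuration for the symmetry index
#'
#' Normalised non-negative weights for the six symmetry components, plus the
#' scale maximum (default 15, giving the 0-15 score range). Weights must sum
#' to one; the four nipple-position weights (direct, horizontal, vertical,
#' radial) form the mammilla sub-score and the area + circumference weights
#' the area sub-score.
#'
#' @param w_direct,w_horizontal,w_vertical,w_radial,w_area,w_circumference
#'   non-negative component weights summing to 1.
#' @param scale_max score attained at total asymmetry; default 15.
#' @return an object of class `bsi_weights`.
#' @export
bsi_weights <- function(w_direct, w_horizontal, w_vertical, w_radial,
                        w_area, w_circumference, scale_max = 15) {
  w <- c(direct = w_direct, horizontal = w_horizontal, vertical = w_vertical,
         radial = w_radial, area = w_area, circumference = w_circumference)
  if (any(w < 0)) stop("weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-12)
    stop("weights must sum to 1 (got ", format(sum(w), digits = 15), ")")
  if (scale_max <= 0) stop("scale_max must be positive")
  structure(list(w = w, scale_max = scale_max), class = "bsi_weights")
}

#' Derive component weights from questionnaire importance scores
#'
#' Converts panel importance means into the default weight configuration:
#' the expert and non-expert means are pooled by panel size; each BSI-relevant
#' item (mamilla position, area, circumference; scars is rated but never part
#' of the index) gets a raw weight `5 - pooled mean`, inverting the 1-4
#' importance scale; the three raw weights are normalised to sum 1; and the
#' mamilla group weight is split equally over its four components (direct,
#' horizontal, vertical, radial), for which the questionnaire offers no finer
#' breakdown. With the published panel values this reproduces the intended
#' ordering: the nipple-position group outweighs both area and circumference.
#'
#' @param q a [questionnaire_summary()]; defaults to the published panels.
#' @param scale_max passed through to [bsi_weights()].
#' @return a [bsi_weights()] object.
#' @export
derive_weights <- function(q = default_questionnaire(), scale_max = 15) {
  m <- pooled_means(q)[c("mamilla_position", "area", "circumference")]
  r <- 5 - m
  g <- r / sum(r)
  bsi_weights(w_direct = g[["mamilla_position"]] / 4,
              w_horizontal = g[["mamilla_position"]] / 4,
              w_vertical = g[["mamilla_position"]] / 4,
              w_radial = g[["mamilla_position"]] / 4,
              w_area = g[["area"]],
              w_circumference = g[["circumference"]],
              scale_max = scale_max)
}

#' @export
print.bsi_weights <- function(x, ...) {
  cat("BSI weight configuration (scale maximum", x$scale_max, ")\n")
  grp <- sum(x$w[c("direct", "horizontal", "vertical", "radial")])
  cat(sprintf("  mammilla group %.4f  (each of direct/horizontal/vertical/radial %.4f)\n",
              grp, x$w[["direct"]]))
  cat(sprintf("  area           %.4f\n", x$w[["area"]]))
  cat(sprintf("  circumference  %.4f\n", x$w[["circumference"]]))
  invisible(x)
}

#' Read / write a weight configuration file
#'
#' Plain `key: value` text (YAML subset) with keys `w_direct`, `w_horizontal`,
#' `w_vertical`, `w_radial`, `w_area`, `w_circumference` and optional
#' `scale_max`. Lets users override the questionnaire-derived defaults.
#'
#' @param path file path.
#' @return `read_weights()` a [bsi_weights()]; `write_weights()` the path,
#'   invisibly.
#' @export
read_weights <- function(path) {
  if (!file.exists(path)) stop("weight config file not found: ", path)
  y <- yaml::read_yaml(path)
  need <- c("w_direct", "w_horizontal", "w_vertical", "w_radial",
            "w_area", "w_circumference")
  miss <- setdiff(need, names(y))
  if (length(miss))
    stop("weight config ", path, " is missing: ", paste(miss, collapse = ", "))
  bsi_weights(y$w_direct, y$w_horizontal, y$w_vertical, y$w_radial,
              y$w_area, y$w_circumference,
              scale_max = if (is.null(y$scale_max)) 15 else y$scale_max)
}

#' @rdname read_weights
#' @param w a [bsi_weights()] object.
#' @export
write_weights <- function(w, path) {
  stopifnot(inherits(w, "bsi_weights"))
  y <- as.list(w$w)
  names(y) <- paste0("w_", names(y))
  y$scale_max <- w$scale_max
  yaml::write_yaml(y, path, precision = 17L)
  invisible(path)
}
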