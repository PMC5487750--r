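#' Rating matrix for agreement analysis
#'
#' A complete n-subjects x k-raters grid of scores (no missing cells), the
#' input to the intraclass correlation. Rows are subjects, columns raters.
#'
#' @param scores numeric matrix or data frame, subjects x raters.
#' @param subject_ids,rater_ids optional labels; taken from dimnames when
#'   absent.
#' @return a numeric matrix of class `rating_matrix`.
#' @export
rating_matrix <- function(scores, subject_ids = NULL, rater_ids = NULL) {
  m <- as.matrix(scores)
  storage.mode(m) <- "double"
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("rating matrix needs at least 2 subjects and 2 raters")
  if (any(!is.finite(m)))
    stop("rating matrix has missing or non-finite cells; complete designs only")
  rownames(m) <- if (!is.null(subject_ids)) subject_ids else
    if (!is.null(rownames(m))) rownames(m) else paste0("S", seq_len(nrow(m)))
  colnames(m) <- if (!is.null(rater_ids)) rater_ids else
    if (!is.null(colnames(m))) colnames(m) else paste0("R", seq_len(ncol(m)))
  class(m) <- c("rating_matrix", "matrix", "array")
  m
}

#' Two-way absolute-agreement intraclass correlation
#'
#' Inter-rater reliability of a complete rating grid under the two-way model
#' with absolute agreement, i.e. systematic rater offsets count as
#' disagreement. Mean squares for subjects (MSR), raters (MSC) and error
#' (MSE) come from the two-way ANOVA decomposition without replication, and
#' the coefficient follows the McGraw-Wong definitions:
#' \deqn{ICC(A,1) = \frac{MSR - MSE}{MSR + (k-1)MSE + \frac{k}{n}(MSC - MSE)}}
#' \deqn{ICC(A,k) = \frac{MSR - MSE}{MSR + (MSC - MSE)/n}}
#' Average measures, `form = "average"`, rate the reliability of the k-rater
#' mean score and are the default. Confidence bounds use the F-distribution
#' method for the single-measures form, carried to average measures by the
#' Spearman-Brown step-up.
#'
#' The coefficient is undefined when the between-subject variance is zero
#' (all subjects truly identical); this is reported as `NA` with an
#' explanatory note, never silently as 0.
#'
#' @param m a [rating_matrix()] or plain subjects x raters matrix.
#' @param form `"average"` for ICC(A,k) or `"single"` for ICC(A,1).
#' @param conf_level confidence level for the interval; default 0.95.
#' @return an object of class `bsi_icc`: list with `icc`, `form`, `lower`,
#'   `upper`, `conf_level`, `n`, `k`, the three mean squares, and `note`
#'   (non-`NULL` when the coefficient is undefined).
#' @export
icc_agreement <- function(m, form = c("average", "single"), conf_level = 0.95) {
  form <- match.arg(form)
  if (!inherits(m, "rating_matrix")) m <- rating_matrix(m)
  n <- nrow(m); k <- ncol(m)
  g <- mean(m)
  rm_ <- rowMeans(m); cm_ <- colMeans(m)
  msr <- k * sum((rm_ - g)^2) / (n - 1)
  msc <- n * sum((cm_ - g)^2) / (k - 1)
  mse <- sum((m - outer(rm_, rep(1, k)) - outer(rep(1, n), cm_) + g)^2) /
    ((n - 1) * (k - 1))
  out <- list(icc = NA_real_, form = form, lower = NA_real_, upper = NA_real_,
              conf_level = conf_level, n = n, k = k,
              msr = msr, msc = msc, mse = mse, note = NULL)
  scale2 <- mean((m - g)^2)
  if (msr <= .Machine$double.eps * max(1, scale2)) {
    out$note <- "zero between-subject variance: ICC undefined"
    class(out) <- "bsi_icc"
    return(out)
  }
  a1 <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  ak <- (msr - mse) / (msr + (msc - mse) / n)
  # F-method interval for ICC(A,1) (two-way, absolute agreement)
  alpha <- 1 - conf_level
  a <- (k * a1) / (n * (1 - a1))
  b <- 1 + (k * a1 * (n - 1)) / (n * (1 - a1))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f1 <- stats::qf(1 - alpha / 2, n - 1, v)
  f2 <- stats::qf(1 - alpha / 2, v, n - 1)
  lo1 <- n * (msr - f1 * mse) /
    (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
  up1 <- n * (f2 * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f2 * msr)
  sb <- function(r) k * r / (1 + (k - 1) * r)  # Spearman-Brown step-up
  if (form == "single") {
    out$icc <- a1; out$lower <- lo1; out$upper <- up1
  } else {
    out$icc <- ak; out$lower <- sb(lo1); out$upper <- sb(up1)
  }
  class(out) <- "bsi_icc"
  out
}

#' @export
print.bsi_icc <- function(x, ...) {
  lab <- if (x$form == "average") sprintf("ICC(A,%d)", x$k) else "ICC(A,1)"
  cat(sprintf("Two-way absolute-agreement ICC, %s measures (n = %d subjects, k = %d raters)\n",
              x$form, x$n, x$k))
  if (!is.null(x$note)) {
    cat("  ", x$note, "\n", sep = "")
  } else {
    cat(sprintf("  %s = %.4f  [%g%% CI %.4f, %.4f]\n", lab, x$icc,
                100 * x$conf_level, x$lower, x$upper))
  }
  invisible(x)
}

#' Pearson correlation with test
#'
#' Product-moment correlation between two score sequences (e.g. subjective
#' Harris ratings against the objective index), with the t-based two-sided
#' p-value, confidence interval and coefficient of determination. Thin,
#' explicit wrapper over [stats::cor.test()] that refuses degenerate input
#' rather than returning `NA` quietly.
#'
#' @param x,y equal-length numeric vectors (length >= 3), each with nonzero
#'   variance.
#' @param conf_level confidence level; default 0.95.
#' @return list of class `bsi_pearson` with `r`, `r_squared`, `p_value`,
#'   `lower`, `upper`, `n`.
#' @export
pearson_r <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: an input sequence is constant")
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = conf_level)
  structure(list(r = unname(ct$estimate),
                 r_squared = unname(ct$estimate)^2,
                 p_value = ct$p.value,
                 lower = ct$conf.int[1], upper = ct$conf.int[2],
                 conf_level = conf_level,
                 n = length(x)),
            class = "bsi_pearson")
}

#' @export
print.bsi_pearson <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f (r^2 = %.4f), n = %d, p = %.3g  [%g%% CI %.4f, %.4f]\n",
              x$r, x$r_squared, x$n, x$p_value,
              100 * x$conf_level, x$lower, x$upper))
  invisible(x)
}
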