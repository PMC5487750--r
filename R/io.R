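ANNOTATION_SCHEMA_VERSION <- "1.0"

stop_parse_error <- function(path, ...) {
  stop(errorCondition(paste0(path, ": ", ...),
                      class = c("bsi_parse_error", "error")))
}

#' Read a breast annotation file
#'
#' Annotation files are JSON with an explicit `schema_version`: landmark
#' coordinates as `[x, y]` pairs and each border as an array of `[x, y]`
#' pairs, all floating-point pixels, 0-based, y increasing downwards.
#' Example:
#' ```json
#' {
#'   "schema_version": "1.0",
#'   "image_id": "case-001",
#'   "jugulum": [500.0, 150.0],
#'   "nipple_left": [308.0, 420.0],
#'   "nipple_right": [692.0, 420.0],
#'   "border_left": [[308.0, 310.0], ...],
#'   "border_right": [[692.0, 310.0], ...]
#' }
#' ```
#' Optional fields `image_path`, `rater_id` and `timestamp` are preserved as
#' attributes. Structural problems raise a parse error naming the offending
#' field; geometric violations (e.g. a nipple outside its border) raise the
#' annotation's own validation errors.
#'
#' @param path file to read.
#' @return a [breast_annotation()].
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop_parse_error(path, "file not found")
  j <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                error = function(e)
                  stop_parse_error(path, "not valid JSON: ", conditionMessage(e)))
  if (!is.list(j)) stop_parse_error(path, "top level must be a JSON object")
  need <- c("schema_version", "image_id", "jugulum", "nipple_left",
            "nipple_right", "border_left", "border_right")
  miss <- setdiff(need, names(j))
  if (length(miss))
    stop_parse_error(path, "missing field(s): ", paste(miss, collapse = ", "))
  if (!identical(as.character(j$schema_version), ANNOTATION_SCHEMA_VERSION))
    stop_parse_error(path, "schema_version: unsupported version '",
                     j$schema_version, "' (expected ", ANNOTATION_SCHEMA_VERSION, ")")
  get_pt <- function(field) {
    p <- unlist(j[[field]])
    if (!is.numeric(p) || length(p) != 2L || anyNA(p))
      stop_parse_error(path, field, ": must be a numeric [x, y] pair")
    p
  }
  get_border <- function(field) {
    b <- j[[field]]
    if (!is.list(b) || length(b) < 3L)
      stop_parse_error(path, field, ": must be an array of at least 3 [x, y] pairs")
    bad <- !vapply(b, function(q) is.numeric(unlist(q)) &&
                     length(unlist(q)) == 2L && !anyNA(unlist(q)), logical(1))
    if (any(bad))
      stop_parse_error(path, field, ": entry ", which(bad)[1],
                       " is not a numeric [x, y] pair")
    do.call(rbind, lapply(b, unlist))
  }
  ann <- breast_annotation(jugulum = get_pt("jugulum"),
                           nipple_left = get_pt("nipple_left"),
                           nipple_right = get_pt("nipple_right"),
                           border_left = get_border("border_left"),
                           border_right = get_border("border_right"),
                           image_id = as.character(j$image_id))
  for (opt in c("image_path", "rater_id", "timestamp"))
    if (!is.null(j[[opt]])) attr(ann, opt) <- as.character(j[[opt]])
  ann
}

#' Write a breast annotation file
#'
#' Inverse of [read_annotation()]; coordinates are serialised at full double
#' precision so a write/read round trip reproduces the annotation exactly.
#'
#' @param ann a [breast_annotation()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "breast_annotation"))
  as_pairs <- function(v) lapply(seq_len(nrow(v)), function(i) unname(v[i, ]))
  j <- list(schema_version = ANNOTATION_SCHEMA_VERSION,
            image_id = ann$image_id,
            jugulum = unname(ann$jugulum),
            nipple_left = unname(ann$nipple_left),
            nipple_right = unname(ann$nipple_right),
            border_left = as_pairs(ann$border_left),
            border_right = as_pairs(ann$border_right))
  for (opt in c("image_path", "rater_id", "timestamp"))
    if (!is.null(attr(ann, opt))) j[[opt]] <- attr(ann, opt)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a rating matrix from CSV
#'
#' Subjects as rows, raters as columns; a header row of rater ids and an
#' optional first column of subject ids (used when non-numeric).
#'
#' @param path CSV file.
#' @return a [rating_matrix()].
#' @export
read_rating_matrix <- function(path) {
  if (!file.exists(path)) stop_parse_error(path, "file not found")
  d <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
  if (ncol(d) >= 2L && !is.numeric(d[[1]])) {
    ids <- as.character(d[[1]])
    d <- d[-1]
  } else ids <- NULL
  if (!all(vapply(d, is.numeric, logical(1))))
    stop_parse_error(path, "non-numeric score cells")
  rating_matrix(as.matrix(d), subject_ids = ids, rater_ids = names(d))
}

#' Score a batch of annotations into a report table
#'
#' Runs [bsi_score()] over files or in-memory annotations and collects one
#' row per annotation: image id, the six symmetry factors, the two sub-scores,
#' the total index and the Harris group.
#'
#' @param x character vector of annotation file paths, a single
#'   [breast_annotation()], or a list of them.
#' @param weights a [bsi_weights()]; default questionnaire-derived.
#' @param n_cuts radial cuts per breast; default 24.
#' @param keep_going if `TRUE`, per-annotation failures are reported as
#'   messages and skipped instead of aborting the batch.
#' @return a `data.frame` of class `bsi_report` (attribute `weights` carries
#'   the configuration used). With `keep_going`, failed inputs are recorded in
#'   attribute `failures`.
#' @export
score_annotations <- function(x, weights = derive_weights(), n_cuts = 24L,
                              keep_going = FALSE) {
  if (inherits(x, "breast_annotation")) x <- list(x)
  rows <- list(); failures <- character()
  for (i in seq_along(x)) {
    item <- x[[i]]
    lab <- if (is.character(item)) item else
      if (nzchar(item$image_id)) item$image_id else sprintf("annotation %d", i)
    res <- tryCatch({
      ann <- if (is.character(item)) read_annotation(item) else item
      cbind(data.frame(image_id = ann$image_id),
            as.data.frame(bsi_score(ann, weights = weights, n_cuts = n_cuts)))
    }, error = function(e) {
      if (!keep_going) stop(e)
      message("skipping ", lab, ": ", conditionMessage(e))
      failures <<- c(failures, lab)
      NULL
    })
    rows[[i]] <- res
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no annotation could be scored")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "weights") <- weights
  attr(out, "failures") <- failures
  class(out) <- c("bsi_report", "data.frame")
  out
}

#' Write a score report as CSV
#'
#' Deterministic column order; the weight configuration used is embedded as
#' `#`-prefixed provenance comment lines above the header, so a report is
#' self-describing and two runs on the same inputs are byte-identical.
#'
#' @param report a `bsi_report` from [score_annotations()].
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "bsi_report"))
  w <- attr(report, "weights")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("# breastsym score report",
               sprintf("# scale_max: %.15g", w$scale_max),
               sprintf("# %s", paste(sprintf("w_%s: %.15g", names(w$w), w$w),
                                     collapse = "  "))), con)
  utils::write.csv(as.data.frame(report), con, row.names = FALSE)
  invisible(path)
}
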