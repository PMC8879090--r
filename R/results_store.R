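#' @title Prediction and ground-truth storage
#' @description Readers, writers and validators for the canonical data model:
#'   per-image, per-model top-5 prediction records and a binary ground-truth
#'   table, persisted as CSV, JSONL (one record object per line) or an SQLite
#'   store with tables `predictions`, `truth` and `models`.
#' @name results_store
NULL

SYNSET_PATTERN <- "^n[0-9]{8}$"
PREDICTION_COLS <- c("image_id", "model_id", "rank", "synset_id", "confidence")
TRUTH_COLS <- c("image_id", "is_positive")

#' Validate a table of top-5 prediction records
#'
#' Checks the schema and the record invariants: ranks are integers in 1..5,
#' at most five records (with distinct ranks) per `(image_id, model_id)`
#' group, synset ids match the WordNet pattern `n` + 8 digits, confidences
#' lie in `[0,1]` and are non-increasing with rank within a group. Malformed
#' input raises a classed validation error; nothing is silently dropped.
#'
#' @param records data.frame-like with columns `image_id`, `model_id`,
#'   `rank`, `synset_id`, `confidence`.
#' @return the validated records as a `data.table` (invisibly usable
#'   downstream), with `rank` coerced to integer.
#' @export
validate_predictions <- function(records) {
  dt <- as.data.table(records)
  missing_cols <- setdiff(PREDICTION_COLS, names(dt))
  if (length(missing_cols)) {
    ct_validation_error("prediction schema error: missing column(s) %s",
                        paste(missing_cols, collapse = ", "))
  }
  dt <- dt[, PREDICTION_COLS, with = FALSE]
  if (nrow(dt) == 0L) return(dt[, rank := as.integer(rank)][])
  if (anyNA(dt)) ct_validation_error("prediction records contain NA values")
  rk <- dt$rank
  if (!is.numeric(rk) || any(rk != as.integer(rk))) {
    ct_validation_error("rank must be integer-valued")
  }
  dt[, rank := as.integer(rank)]
  bad <- dt$rank < 1L | dt$rank > 5L
  if (any(bad)) {
    ct_validation_error("rank outside 1..5 in %d row(s), e.g. image %s rank %d",
                        sum(bad), dt$image_id[which(bad)[1L]],
                        dt$rank[which(bad)[1L]])
  }
  if (any(!grepl(SYNSET_PATTERN, dt$synset_id))) {
    off <- dt$synset_id[!grepl(SYNSET_PATTERN, dt$synset_id)][1L]
    ct_validation_error("malformed synset id '%s' (expected 'n' + 8 digits)", off)
  }
  if (any(dt$confidence < 0 | dt$confidence > 1)) {
    ct_validation_error("confidence outside [0,1]")
  }
  dup <- dt[, .N, by = .(image_id, model_id, rank)][N > 1L]
  if (nrow(dup)) {
    ct_validation_error("duplicate (image, model, rank): %s/%s rank %d",
                        dup$image_id[1L], dup$model_id[1L], dup$rank[1L])
  }
  # confidence ordering is authoritative by rank; allow ties, reject inversions
  setorder(dt, image_id, model_id, rank)
  inv <- dt[, any(diff(confidence) > 1e-12), by = .(image_id, model_id)]
  if (any(inv$V1)) {
    g <- inv[which(V1)[1L]]
    ct_validation_error("confidence increases with rank for image %s, model %s",
                        g$image_id, g$model_id)
  }
  dt[]
}

#' Validate a ground-truth table
#'
#' @param truth data.frame-like with columns `image_id`, `is_positive` and
#'   optionally `camera_id`, `timestamp`.
#' @return validated `data.table` with logical `is_positive`.
#' @export
validate_truth <- function(truth) {
  dt <- as.data.table(truth)
  missing_cols <- setdiff(TRUTH_COLS, names(dt))
  if (length(missing_cols)) {
    ct_validation_error("truth schema error: missing column(s) %s",
                        paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(dt$image_id)) {
    ct_validation_error("duplicate image_id in truth: %s",
                        dt$image_id[anyDuplicated(dt$image_id)])
  }
  if (is.numeric(dt$is_positive) || is.integer(dt$is_positive)) {
    if (!all(dt$is_positive %in% c(0, 1))) {
      ct_validation_error("is_positive must be boolean (0/1)")
    }
    dt[, is_positive := as.logical(is_positive)]
  }
  if (!is.logical(dt$is_positive) || anyNA(dt$is_positive)) {
    ct_validation_error("is_positive must be a non-missing boolean")
  }
  dt[]
}

#' Check that every predicted image has a truth row
#'
#' @param records validated prediction records
#' @param truth validated truth table
#' @return invisibly TRUE; raises a validation error listing offending image
#'   ids otherwise.
#' @export
check_truth_coverage <- function(records, truth) {
  orphan <- setdiff(unique(records$image_id), truth$image_id)
  if (length(orphan)) {
    shown <- paste(head(orphan, 5L), collapse = ", ")
    ct_validation_error(
      "%d predicted image(s) missing from truth (e.g. %s)",
      length(orphan), shown)
  }
  invisible(TRUE)
}

infer_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("csv", "jsonl", "sqlite")))
  switch(tolower(tools::file_ext(path)),
         csv = "csv", jsonl = "jsonl", ndjson = "jsonl",
         sqlite = "sqlite", db = "sqlite", sqlite3 = "sqlite",
         ct_error("cannot infer format from extension of '%s'", path))
}

#' Read top-5 prediction records
#'
#' @param path file path (CSV, JSONL or SQLite database).
#' @param format one of `"csv"`, `"jsonl"`, `"sqlite"`; inferred from the
#'   file extension when `NULL`.
#' @return validated `data.table` of prediction records.
#' @export
read_predictions <- function(path, format = NULL) {
  format <- infer_format(path, format)
  if (!file.exists(path)) ct_error("no such file: %s", path)
  raw <- switch(format,
    csv = fread(path, colClasses = list(character = c("image_id", "model_id",
                                                      "synset_id"))),
    jsonl = read_jsonl(path),
    sqlite = sqlite_read_table(path, "predictions"))
  validate_predictions(raw)
}

#' Write top-5 prediction records
#'
#' The written file (or SQLite `predictions` table) re-reads to an identical
#' multiset of records: ids and ranks byte-for-byte, confidences to full
#' double precision. An empty record set writes a valid file carrying only
#' the schema.
#'
#' @param records prediction records (validated before writing).
#' @param path destination path.
#' @inheritParams read_predictions
#' @return invisibly `path`.
#' @export
write_predictions <- function(records, path, format = NULL) {
  format <- infer_format(path, format)
  dt <- validate_predictions(records)
  switch(format,
    csv = fwrite(dt, path),
    jsonl = write_jsonl(dt, path),
    sqlite = sqlite_write_table(path, "predictions", dt))
  invisible(path)
}

#' Read a ground-truth table
#' @inheritParams read_predictions
#' @return validated `data.table`.
#' @export
read_truth <- function(path, format = NULL) {
  format <- infer_format(path, format)
  if (!file.exists(path)) ct_error("no such file: %s", path)
  raw <- switch(format,
    csv = fread(path, colClasses = list(character = "image_id")),
    jsonl = read_jsonl(path),
    sqlite = sqlite_read_table(path, "truth"))
  validate_truth(raw)
}

#' Write a ground-truth table
#' @param truth truth table (validated before writing).
#' @inheritParams write_predictions
#' @return invisibly `path`.
#' @export
write_truth <- function(truth, path, format = NULL) {
  format <- infer_format(path, format)
  dt <- validate_truth(truth)
  out <- copy(dt)
  if (format %in% c("csv", "sqlite")) out[, is_positive := as.integer(is_positive)]
  switch(format,
    csv = fwrite(out, path),
    jsonl = write_jsonl(dt, path),
    sqlite = sqlite_write_table(path, "truth", out))
  invisible(path)
}

read_jsonl <- function(path) {
  as.data.table(jsonlite::stream_in(file(path), verbose = FALSE))
}

write_jsonl <- function(dt, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  jsonlite::stream_out(as.data.frame(dt), con, verbose = FALSE, digits = NA)
}

#' Load the bundled catalog of the 36 evaluated classifier models
#'
#' One row per pre-trained ImageNet model: abbreviation (`model_id`), full
#' name, default input size in pixels, published top-1/top-5 ImageNet
#' accuracy (top-5 unavailable for the MobileNet v3 family), the library the
#' weights originate from, parameter count and FLOP count (millions) of the
#' frozen graph, and measured inference rate in images per second.
#'
#' @return `data.table` with 36 rows, keyed by `model_id`.
#' @export
load_model_catalog <- function() {
  path <- system.file("extdata", "model_catalog.csv", package = "camtrapeval",
                      mustWork = TRUE)
  cat <- fread(path)
  if (nrow(cat) != 36L || anyDuplicated(cat$model_id)) {
    ct_error("model catalog fixture is corrupted")
  }
  stopifnot(all(cat$input_size_px %in% c(224L, 227L, 299L, 331L)))
  setkey(cat, model_id)[]
}

#' Load the bundled per-model lynx confusion counts
#'
#' The reference evaluation of all 36 models on the 293,604-image
#' camera-trap dataset (1630 positives): TP/TN/FP/FN per model.
#'
#' @return `data.table` with columns `model_id`, `tp`, `tn`, `fp`, `fn`.
#' @export
lynx_confusion_counts <- function() {
  path <- system.file("extdata", "confusion_lynx.csv", package = "camtrapeval",
                      mustWork = TRUE)
  cc <- fread(path)
  cc[, c("tp", "tn", "fp", "fn") := lapply(.SD, as.numeric),
     .SDcols = c("tp", "tn", "fp", "fn")]
  cc[]
}

#' Published per-model metric values for the reference evaluation
#' @return `data.table`, one row per model, 12 metric columns as printed in
#'   the source tables (5 or 6 decimals).
#' @export
reported_metric_values <- function() {
  fread(system.file("extdata", "reported_metrics.csv",
                    package = "camtrapeval", mustWork = TRUE))
}

#' Published ensemble confusion counts and metrics (Multi-5/4/3)
#' @return `data.table` with one row per ensemble.
#' @export
reported_ensemble_values <- function() {
  en <- fread(system.file("extdata", "reported_ensembles.csv",
                          package = "camtrapeval", mustWork = TRUE))
  en[, c("tp", "tn", "fp", "fn") := lapply(.SD, as.numeric),
     .SDcols = c("tp", "tn", "fp", "fn")]
  en[]
}
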