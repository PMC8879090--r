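#' Target synsets for Eurasian lynx detection
#'
#' ImageNet's 1000 classes contain no "lynx-only" label. Two classes cover
#' the animal: `n02127052` (*lynx, catamount*) and `n02125311` (*cougar,
#' puma, catamount, ...*), whose label strings overlap in the homonym
#' "catamount". Matching is therefore done on synset ids, and the
#' appearance of either id anywhere in a model's top-5 counts as a lynx
#' detection.
#'
#' @return character vector of the two synset ids.
#' @export
lynx_synsets <- function() c("n02127052", "n02125311")

#' Map one top-5 output to a binary detection
#'
#' `TRUE` iff any entry of `top5_synsets` is in `targets`; rank and
#' confidence are ignored (top-5 membership alone decides).
#'
#' @param top5_synsets ordered character vector of 1 to 5 synset ids.
#' @param targets set of target synset ids.
#' @return logical scalar.
#' @export
#' @examples
#' detect_one(c("n02127052", "n02123045", "n02110341"))  # TRUE, rank 1 hit
detect_one <- function(top5_synsets, targets = lynx_synsets()) {
  if (length(top5_synsets) == 0L) {
    ct_validation_error("model produced no top-5 output for this image")
  }
  if (length(top5_synsets) > 5L) {
    ct_validation_error("more than 5 entries in a top-5 list")
  }
  any(top5_synsets %in% targets)
}

#' Build the image-by-model binary detection matrix
#'
#' Scans every `(image_id, model_id)` group of top-5 records and records
#' whether any target synset appears. Every predicted image must have a
#' truth row; groups may hold fewer than five ranks (some deployments emit
#' fewer).
#'
#' @param records prediction records (validated).
#' @param truth truth table (validated).
#' @param targets target synset ids.
#' @return a `detection_matrix`: list with `image_id` (n), `model_id` (m),
#'   logical `detected` matrix (n x m) and logical `truth` (n).
#' @export
build_detection_matrix <- function(records, truth, targets = lynx_synsets()) {
  records <- validate_predictions(records)
  truth <- validate_truth(truth)
  check_truth_coverage(records, truth)
  if (nrow(records) == 0L) ct_validation_error("no prediction records")
  hits <- records[, .(detected = any(synset_id %in% targets)),
                  by = .(image_id, model_id)]
  models <- sort(unique(hits$model_id))
  images <- truth$image_id
  wide <- dcast(hits, image_id ~ model_id, value.var = "detected")
  wide <- wide[data.table(image_id = images), on = "image_id"]
  det <- as.matrix(wide[, models, with = FALSE])
  # images with truth but no predictions count as "not detected"
  det[is.na(det)] <- FALSE
  dimnames(det) <- list(images, models)
  new_detection_matrix(images, models, det, truth$is_positive)
}

new_detection_matrix <- function(image_id, model_id, detected, truth) {
  stopifnot(is.matrix(detected), nrow(detected) == length(image_id),
            ncol(detected) == length(model_id),
            length(truth) == length(image_id))
  structure(list(image_id = as.character(image_id),
                 model_id = as.character(model_id),
                 detected = detected, truth = as.logical(truth)),
            class = "detection_matrix")
}

#' @export
print.detection_matrix <- function(x, ...) {
  cat(sprintf("<detection_matrix> %d images x %d models, %d positives (%.2f%%)\n",
              length(x$image_id), length(x$model_id), sum(x$truth),
              100 * mean(x$truth)))
  invisible(x)
}

#' @export
dim.detection_matrix <- function(x) dim(x$detected)

#' Export a detection matrix as wide CSV
#'
#' Columns: `image_id`, `truth` (0/1), then one 0/1 column per model.
#'
#' @param x a `detection_matrix`.
#' @param path destination CSV path.
#' @return invisibly `path`.
#' @export
write_detection_matrix <- function(x, path) {
  stopifnot(inherits(x, "detection_matrix"))
  dt <- data.table(image_id = x$image_id, truth = as.integer(x$truth))
  for (m in x$model_id) dt[[m]] <- as.integer(x$detected[, m])
  fwrite(dt, path)
  invisible(path)
}

#' Read a detection matrix written by [write_detection_matrix()]
#' @param path CSV path.
#' @return a `detection_matrix`.
#' @export
read_detection_matrix <- function(path) {
  dt <- fread(path, colClasses = list(character = "image_id"))
  if (!all(c("image_id", "truth") %in% names(dt))) {
    ct_validation_error("detection matrix file must have image_id and truth columns")
  }
  models <- setdiff(names(dt), c("image_id", "truth"))
  det <- as.matrix(dt[, models, with = FALSE]) > 0
  dimnames(det) <- list(dt$image_id, models)
  new_detection_matrix(dt$image_id, models, det, dt$truth > 0)
}
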