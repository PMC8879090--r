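#' @title Gaussian-copula synthetic top-5 prediction generator
#' @description Stands in for real CNN inference output so the whole
#'   pipeline is testable offline: rare positives, heterogeneous per-model
#'   sensitivity/specificity and positively correlated detections across
#'   models viewing the same image.
#' @name synthetic_data
NULL

#' Default distractor synsets
#'
#' Thirty ImageNet classes a camera-trap classifier plausibly confuses
#' with wildlife scenes (other felids, canids, bears, ungulates, small
#' mammals), all disjoint from the lynx target set.
#'
#' @return character vector of 30 synset ids.
#' @export
default_distractors <- function() c(
  "n02123045", "n02123159", "n02124075", "n02128385", "n02128925",
  "n02129165", "n02129604", "n02130308", "n02114367", "n02114548",
  "n02117135", "n02119022", "n02120505", "n02132136", "n02133161",
  "n02134084", "n02137549", "n02325366", "n02326432", "n02342885",
  "n02346627", "n02356798", "n02361337", "n02396427", "n02403003",
  "n02408429", "n02410509", "n02412070", "n02415577", "n02417914")

#' Default per-model detector profiles
#'
#' The 36 (model_id, TPR, TNR) triples of the reference evaluation,
#' derived at full precision from the bundled confusion counts.
#'
#' @return `data.table` with columns `model_id`, `tpr`, `tnr`.
#' @export
default_model_profiles <- function() {
  cc <- lynx_confusion_counts()
  cc[, .(model_id, tpr = tp / (tp + fn), tnr = tn / (tn + fp))]
}

#' Build and validate a synthetic-data configuration
#'
#' The defaults restate the reference study's conditions: 293,604 images,
#' prevalence 1630/293,604 (~0.55%), the 36 reference model profiles and
#' inter-model latent correlation 0.5.
#'
#' @param n_images number of images (> 0).
#' @param prevalence positive fraction, in (0,1).
#' @param model_profiles data.frame with columns `model_id`, `tpr`, `tnr`
#'   (rates in (0,1), unique ids).
#' @param correlation latent Gaussian correlation rho in \[0,1).
#' @param seed integer RNG seed.
#' @param target_synsets synsets emitted on detection.
#' @param distractor_pool >= 20 synsets, disjoint from targets.
#' @param fixed_positive_count if non-NULL, exactly this many positives are
#'   drawn (uniformly placed) instead of per-image Bernoulli(prevalence).
#' @return a `synthetic_config` object.
#' @export
synthetic_config <- function(n_images = 293604L,
                             prevalence = 1630 / 293604,
                             model_profiles = default_model_profiles(),
                             correlation = 0.5,
                             seed = 1L,
                             target_synsets = lynx_synsets(),
                             distractor_pool = default_distractors(),
                             fixed_positive_count = NULL) {
  n_images <- as.integer(n_images)
  if (is.na(n_images) || n_images < 1L) ct_validation_error("n_images must be > 0")
  if (!(prevalence > 0 && prevalence < 1)) {
    ct_validation_error("prevalence must be in (0,1)")
  }
  if (!(correlation >= 0 && correlation < 1)) {
    ct_validation_error("correlation must be in [0,1)")
  }
  mp <- as.data.table(model_profiles)
  if (nrow(mp) == 0L || !all(c("model_id", "tpr", "tnr") %in% names(mp))) {
    ct_validation_error("model_profiles needs non-empty model_id/tpr/tnr")
  }
  if (anyDuplicated(mp$model_id)) {
    ct_validation_error("duplicate model ids in profiles")
  }
  # endpoints allowed so degenerate (perfect / blind) detectors are testable
  if (!all(mp$tpr >= 0 & mp$tpr <= 1 & mp$tnr >= 0 & mp$tnr <= 1)) {
    ct_validation_error("tpr and tnr must be in [0,1]; use rates, not counts")
  }
  if (length(distractor_pool) < 20L) {
    ct_validation_error("distractor_pool must hold at least 20 synsets")
  }
  if (length(intersect(target_synsets, distractor_pool))) {
    ct_validation_error("distractor_pool overlaps target_synsets")
  }
  if (prevalence * n_images < 1) {
    warning("prevalence * n_images < 1: positives unlikely", call. = FALSE)
  }
  structure(list(n_images = n_images, prevalence = prevalence,
                 model_profiles = mp, correlation = correlation,
                 seed = as.integer(seed),
                 target_synsets = as.character(target_synsets),
                 distractor_pool = as.character(distractor_pool),
                 fixed_positive_count = fixed_positive_count),
            class = "synthetic_config")
}

#' Read a synthetic configuration from a JSON file
#' @param path JSON file with any subset of the [synthetic_config()] fields;
#'   `model_profiles` as an array of objects.
#' @return a `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  args <- list()
  for (f in c("n_images", "prevalence", "correlation", "seed",
              "target_synsets", "distractor_pool", "fixed_positive_count")) {
    if (!is.null(cfg[[f]])) args[[f]] <- cfg[[f]]
  }
  if (!is.null(cfg$model_profiles)) {
    args$model_profiles <- as.data.table(cfg$model_profiles)
  }
  do.call(synthetic_config, args)
}

#' Simulate correlated top-5 prediction records
#'
#' Truth labels are Bernoulli(prevalence) per image (or a fixed positive
#' count). Detection uses a Gaussian copula: one latent standard-normal
#' difficulty `z_i` per image; model `m` detects image `i` iff
#' \deqn{\rho z_i + \sqrt{1-\rho^2}\,\epsilon_{im} \le \Phi^{-1}(p_m)}
#' with `p_m = tpr_m` on positives and `1 - tnr_m` on negatives, so the
#' marginal per-model rates are exact for every rho while detections are
#' positively correlated across models. A detected cell places one
#' uniformly chosen target synset at a uniformly chosen rank and fills the
#' rest with distinct distractors; confidences are uniform draws sorted
#' decreasing by rank (the analysis only uses top-5 membership).
#'
#' @param config a [synthetic_config()].
#' @param records build the full per-rank record table (`TRUE`, the
#'   contract output). `FALSE` skips it and returns only the detection
#'   matrix, for large calibration runs.
#' @return list with `predictions` (`data.table` of records, or `NULL`),
#'   `truth` (`data.table`) and `detections` (a `detection_matrix`).
#'   Fully reproducible from `config$seed`.
#' @export
simulate_predictions <- function(config, records = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_images
  mp <- config$model_profiles
  m <- nrow(mp)
  image_id <- sprintf("img%07d", seq_len(n))

  is_positive <- if (!is.null(config$fixed_positive_count)) {
    k <- as.integer(config$fixed_positive_count)
    if (k > n) ct_validation_error("fixed_positive_count exceeds n_images")
    pos <- logical(n); pos[sample.int(n, k)] <- TRUE; pos
  } else {
    runif(n) < config$prevalence
  }
  truth <- data.table(image_id = image_id, is_positive = is_positive)

  rho <- config$correlation
  z <- rnorm(n)
  det <- matrix(FALSE, n, m, dimnames = list(image_id, mp$model_id))
  for (j in seq_len(m)) {
    p <- ifelse(is_positive, mp$tpr[j], 1 - mp$tnr[j])
    lat <- rho * z + sqrt(1 - rho^2) * rnorm(n)
    det[, j] <- lat <= qnorm(p)
  }
  dm <- new_detection_matrix(image_id, mp$model_id, det, is_positive)

  preds <- NULL
  if (records) preds <- build_records(config, det)
  list(predictions = preds, truth = truth, detections = dm)
}

# expand the boolean detection matrix into 5 ranked records per cell
build_records <- function(config, det) {
  n <- nrow(det); m <- ncol(det)
  pool <- config$distractor_pool
  targets <- config$target_synsets
  ncell <- n * m
  # 5 distinct distractors per cell; cells that detect overwrite one rank
  dr_idx <- vapply(seq_len(ncell),
                   function(i) sample.int(length(pool), 5L), integer(5L))
  syn <- matrix(pool[dr_idx], nrow = 5L)
  hit <- as.vector(det)
  nhit <- sum(hit)
  if (nhit > 0L) {
    tgt <- targets[sample.int(length(targets), nhit, replace = TRUE)]
    rk <- sample.int(5L, nhit, replace = TRUE)
    syn[cbind(rk, which(hit))] <- tgt
  }
  conf <- matrix(runif(5L * ncell), nrow = 5L)
  conf <- apply(conf, 2L, sort, decreasing = TRUE)
  data.table(
    image_id = rep(rep(rownames(det), m), each = 5L),
    model_id = rep(colnames(det), each = 5L * n),
    rank = rep(1:5, ncell),
    synset_id = as.vector(syn),
    confidence = as.vector(conf))
}
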