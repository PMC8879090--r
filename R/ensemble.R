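#' @title Threshold-voting ensembles of detector models
#' @description Member selection by Cohen's kappa and evaluation of
#'   "Multi-k" ensembles that declare a detection when at least `t` member
#'   models agree.
#' @name ensemble
NULL

#' Member-selection rule
#'
#' Two distinct criteria, applied in order after ranking models by
#' descending kappa: a hard cutoff (keep models with kappa >= `kappa_cutoff`),
#' an optional truncation before the first adjacent relative kappa drop
#' exceeding `drop_fraction`, and finally truncation to `max_members`.
#'
#' @param kappa_cutoff minimum kappa, in (0,1); default 0.2 ("fair
#'   agreement" boundary).
#' @param max_members maximum ensemble size (>= 1).
#' @param drop_fraction optional relative drop threshold in (0,1); e.g.
#'   0.25 truncates before a >25% kappa fall between adjacent ranks.
#' @return a `selection_rule` object.
#' @export
selection_rule <- function(kappa_cutoff = 0.2, max_members = 5L,
                           drop_fraction = NULL) {
  if (!(kappa_cutoff > 0 && kappa_cutoff < 1)) {
    ct_validation_error("kappa_cutoff must be in (0,1)")
  }
  if (max_members < 1L) ct_validation_error("max_members must be >= 1")
  if (!is.null(drop_fraction) &&
      !(drop_fraction > 0 && drop_fraction < 1)) {
    ct_validation_error("drop_fraction must be in (0,1)")
  }
  structure(list(kappa_cutoff = kappa_cutoff,
                 max_members = as.integer(max_members),
                 drop_fraction = drop_fraction),
            class = "selection_rule")
}

#' Select ensemble members from a metric table
#'
#' @param table metric table with `model_id` and `kappa` columns.
#' @param rule a [selection_rule()].
#' @return character vector of model ids, descending kappa.
#' @export
select_members <- function(table, rule = selection_rule()) {
  dt <- as.data.table(table)
  if (!all(c("model_id", "kappa") %in% names(dt))) {
    ct_validation_error("table must have model_id and kappa columns")
  }
  if (anyNA(dt$kappa)) ct_validation_error("kappa undefined for some models")
  pass <- dt[kappa >= rule$kappa_cutoff]
  if (nrow(pass) == 0L) {
    ct_validation_error("no model reaches the kappa cutoff %.3f",
                        rule$kappa_cutoff)
  }
  ord <- order(-pass$kappa, -(pass$mcc %||% pass$kappa), pass$model_id)
  members <- pass$model_id[ord]
  kappas <- pass$kappa[ord]
  if (!is.null(rule$drop_fraction) && length(members) > 1L) {
    drops <- -diff(kappas) / head(kappas, -1L)
    cut <- which(drops > rule$drop_fraction)
    if (length(cut)) members <- head(members, cut[1L])
  }
  head(members, rule$max_members)
}

#' Ensemble specification
#'
#' @param members ordered model ids (unique).
#' @param threshold minimum number of agreeing members for a detection,
#'   in 1..length(members). The default 3 reproduces the reference
#'   "three or more models" rule for 3-5 member ensembles.
#' @return an `ensemble_spec` object.
#' @export
ensemble_spec <- function(members, threshold = 3L) {
  members <- as.character(members)
  if (anyDuplicated(members)) ct_validation_error("duplicate ensemble members")
  if (length(members) == 0L) ct_validation_error("empty member list")
  threshold <- as.integer(threshold)
  if (threshold < 1L || threshold > length(members)) {
    ct_validation_error("threshold %d out of range 1..%d", threshold,
                        length(members))
  }
  structure(list(members = members, threshold = threshold),
            class = "ensemble_spec")
}

#' @export
print.ensemble_spec <- function(x, ...) {
  cat(sprintf("<ensemble_spec> Multi-%d (t=%d): %s\n", length(x$members),
              x$threshold, paste(x$members, collapse = ", ")))
  invisible(x)
}

#' Per-image voting detections of an ensemble
#'
#' An image is detected iff at least `spec$threshold` member models detect
#' it. `t = 1` is the union (OR) of member columns, `t = |members|` the
#' intersection (AND).
#'
#' @param x a `detection_matrix` containing all member columns.
#' @param spec an [ensemble_spec()].
#' @return logical vector, one element per image.
#' @export
ensemble_detections <- function(x, spec) {
  stopifnot(inherits(x, "detection_matrix"), inherits(spec, "ensemble_spec"))
  absent <- setdiff(spec$members, x$model_id)
  if (length(absent)) {
    ct_validation_error("member(s) absent from detection matrix: %s",
                        paste(absent, collapse = ", "))
  }
  votes <- rowSums(x$detected[, spec$members, drop = FALSE])
  unname(votes >= spec$threshold)
}

#' Evaluate a voting ensemble
#'
#' @inheritParams ensemble_detections
#' @param dp_scale see [compute_metrics()].
#' @return list with `counts` (`confusion_counts`) and `metrics`
#'   (`metric_vector`).
#' @export
evaluate_ensemble <- function(x, spec, dp_scale = DP_SCALE_REFERENCE) {
  d <- ensemble_detections(x, spec)
  t <- x$truth
  counts <- confusion_counts_from(tp = sum(d & t), tn = sum(!d & !t),
                                  fp = sum(d & !t), fn = sum(!d & t))
  list(counts = counts, metrics = compute_metrics(counts, dp_scale = dp_scale))
}

#' Brute-force search over voting thresholds
#'
#' Evaluates every threshold `t` in `1..length(members)` and reports the
#' argmax by `objective` (default kappa, the same metric used for member
#' selection). Ties go to the higher MCC, then to the smallest `t`.
#'
#' @param x a `detection_matrix`.
#' @param members model ids forming the ensemble.
#' @param objective metric name to maximize.
#' @param dp_scale see [compute_metrics()].
#' @return list with `table` (one row per threshold: `t`, counts, metrics)
#'   and `best_t`.
#' @export
threshold_search <- function(x, members, objective = "kappa",
                             dp_scale = DP_SCALE_REFERENCE) {
  if (!objective %in% METRIC_NAMES) {
    ct_validation_error("unknown objective '%s'", objective)
  }
  rows <- lapply(seq_along(members), function(t) {
    ev <- evaluate_ensemble(x, ensemble_spec(members, t), dp_scale = dp_scale)
    data.table(t = t, as.data.table(as.list(unclass(ev$counts))),
               as.data.table(as.list(unclass(ev$metrics))))
  })
  tab <- rbindlist(rows)
  ord <- order(-tab[[objective]], -tab[["mcc"]], tab[["t"]])
  list(table = tab, best_t = tab$t[ord[1L]])
}

#' Relative improvement of an ensemble over a standalone model
#'
#' Expressed as a percentage of the ensemble value:
#' \eqn{100 (e - s)/e}. This is the convention under which the reference
#' comparisons (23% F1, 23.5% kappa, 22.5% MCC) are stated.
#'
#' @param ensemble_value metric value of the ensemble (non-zero).
#' @param standalone_value metric value of the standalone model.
#' @return percent improvement (positive when the ensemble is better).
#' @export
relative_improvement <- function(ensemble_value, standalone_value) {
  if (any(ensemble_value == 0)) ct_validation_error("ensemble value is zero")
  (ensemble_value - standalone_value) / ensemble_value * 100
}
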