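#' @title Confusion-matrix metric suite
#' @description The twelve derived evaluation parameters used throughout the
#'   package: TPR, TNR, PPV, ACC, ERR, BAC, GM, YI, DP, F1, MCC and Cohen's
#'   kappa, computed from TP/TN/FP/FN in full double precision.
#' @name metrics
NULL

METRIC_NAMES <- c("tpr", "tnr", "ppv", "acc", "err", "bac",
                  "gm", "yi", "dp", "f1", "mcc", "kappa")

# the reference analysis computed discriminant power with pi rounded to
# 3.14; sqrt(3)/3.14 reproduces its printed DP values to <5e-7, the exact
# constant sqrt(3)/pi differs from them by a relative 5.07e-4
DP_SCALE_REFERENCE <- sqrt(3) / 3.14

#' Construct confusion counts
#'
#' @param tp,tn,fp,fn non-negative counts of images.
#' @return a `confusion_counts` object (named numeric vector).
#' @export
confusion_counts_from <- function(tp, tn, fp, fn) {
  v <- c(tp = as.numeric(tp), tn = as.numeric(tn),
         fp = as.numeric(fp), fn = as.numeric(fn))
  if (anyNA(v) || any(v < 0) || any(v != round(v))) {
    ct_validation_error("confusion counts must be non-negative integers")
  }
  if (sum(v) <= 0) ct_validation_error("empty dataset (all counts zero)")
  structure(v, class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%.0f TN=%.0f FP=%.0f FN=%.0f (n=%.0f, %.0f positives)\n",
              x[["tp"]], x[["tn"]], x[["fp"]], x[["fn"]],
              sum(x), x[["tp"]] + x[["fn"]]))
  invisible(x)
}

#' Tally the confusion matrix of one model against ground truth
#'
#' @param x a `detection_matrix`.
#' @param model_id one of `x$model_id`.
#' @return a `confusion_counts` object.
#' @export
confusion_counts <- function(x, model_id) {
  stopifnot(inherits(x, "detection_matrix"))
  if (!model_id %in% x$model_id) {
    ct_validation_error("unknown model id '%s'", model_id)
  }
  d <- x$detected[, model_id]
  t <- x$truth
  confusion_counts_from(tp = sum(d & t), tn = sum(!d & !t),
                        fp = sum(d & !t), fn = sum(!d & t))
}

#' Compute the twelve derived evaluation parameters
#'
#' Definitions (all from TP/TN/FP/FN):
#' \deqn{TPR = TP/(TP+FN), \quad TNR = TN/(TN+FP), \quad PPV = TP/(TP+FP)}
#' \deqn{ACC = (TP+TN)/n, \quad ERR = 1-ACC, \quad BAC = (TPR+TNR)/2}
#' \deqn{GM = \sqrt{TPR \cdot TNR}, \quad YI = TPR+TNR-1}
#' \deqn{DP = s\,[\log_{10}(TPR/(1-TPR)) + \log_{10}(TNR/(1-TNR))]}
#' \deqn{F1 = 2\,PPV\,TPR/(PPV+TPR)}
#' \deqn{MCC = (TP\,TN - FP\,FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#' \deqn{\kappa = 2(TP\,TN - FP\,FN)/[(TP+FP)(FP+TN) + (TP+FN)(FN+TN)]}
#'
#' Kappa uses the closed count form, algebraically identical to the usual
#' \eqn{(p_o - p_e)/(1 - p_e)} but free of intermediate rounding. A zero
#' denominator (e.g. `TP+FP = 0` for PPV, or TPR/TNR at 0 or 1 for DP)
#' flags the affected field as `NA` with a warning; it never silently
#' becomes 0 and never aborts the computation.
#'
#' @param counts a `confusion_counts` object (or anything
#'   [confusion_counts_from()] accepts as a named vector/list).
#' @param dp_scale multiplier of the base-10 logit sum in discriminant
#'   power. The default `sqrt(3)/3.14` matches the reference analysis,
#'   which rounded \eqn{\pi}; pass `sqrt(3)/pi` for the exact textbook
#'   constant (relative difference 5e-4).
#' @return named numeric vector of the 12 metrics, class `metric_vector`.
#' @export
compute_metrics <- function(counts, dp_scale = DP_SCALE_REFERENCE) {
  if (!inherits(counts, "confusion_counts")) {
    counts <- confusion_counts_from(counts[["tp"]], counts[["tn"]],
                                    counts[["fp"]], counts[["fn"]])
  }
  tp <- counts[["tp"]]; tn <- counts[["tn"]]
  fp <- counts[["fp"]]; fn <- counts[["fn"]]
  n <- tp + tn + fp + fn
  undefined <- character()
  safe_div <- function(num, den, what) {
    if (den == 0) { undefined <<- c(undefined, what); return(NA_real_) }
    num / den
  }
  tpr <- safe_div(tp, tp + fn, "tpr")
  tnr <- safe_div(tn, tn + fp, "tnr")
  ppv <- safe_div(tp, tp + fp, "ppv")
  acc <- (tp + tn) / n
  err <- 1 - acc
  bac <- (tpr + tnr) / 2
  gm <- sqrt(tpr * tnr)
  yi <- tpr + tnr - 1
  dp <- if (is.na(tpr) || is.na(tnr) || tpr %in% c(0, 1) || tnr %in% c(0, 1)) {
    undefined <- c(undefined, "dp")
    NA_real_
  } else {
    dp_scale * (log10(tpr / (1 - tpr)) + log10(tnr / (1 - tnr)))
  }
  f1 <- if (is.na(ppv) || is.na(tpr) || ppv + tpr == 0) {
    undefined <- c(undefined, "f1"); NA_real_
  } else 2 * ppv * tpr / (ppv + tpr)
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- safe_div(tp * tn - fp * fn, mcc_den, "mcc")
  kap_den <- (tp + fp) * (fp + tn) + (tp + fn) * (fn + tn)
  kappa <- safe_div(2 * (tp * tn - fp * fn), kap_den, "kappa")
  if (length(undefined)) {
    warning(sprintf("undefined metric(s) flagged NA: %s",
                    paste(unique(undefined), collapse = ", ")),
            call. = FALSE)
  }
  structure(setNames(c(tpr, tnr, ppv, acc, err, bac, gm, yi, dp, f1, mcc,
                       kappa), METRIC_NAMES),
            class = "metric_vector")
}

#' @export
print.metric_vector <- function(x, digits = 5, ...) {
  print(round(unclass(x), digits))
  invisible(x)
}

#' Per-model confusion counts and metric table
#'
#' One row per model with the four basic counts and all twelve derived
#' metrics. Accepts either a `detection_matrix` or a data.frame of
#' pre-tallied counts (columns `model_id`, `tp`, `tn`, `fp`, `fn`), e.g.
#' [lynx_confusion_counts()].
#'
#' @param x detection matrix or counts table.
#' @param dp_scale see [compute_metrics()].
#' @return `data.table`, columns `model_id`, `tp`, `tn`, `fp`, `fn`, then
#'   the 12 metrics, in full precision.
#' @export
metric_table <- function(x, dp_scale = DP_SCALE_REFERENCE) {
  counts <- if (inherits(x, "detection_matrix")) {
    if (length(x$model_id) == 0L) ct_validation_error("empty detection matrix")
    rbindlist(lapply(x$model_id, function(m) {
      cc <- confusion_counts(x, m)
      data.table(model_id = m, tp = cc[["tp"]], tn = cc[["tn"]],
                 fp = cc[["fp"]], fn = cc[["fn"]])
    }))
  } else {
    dt <- as.data.table(x)
    need <- c("model_id", "tp", "tn", "fp", "fn")
    if (!all(need %in% names(dt))) {
      ct_validation_error("counts table must have columns %s",
                          paste(need, collapse = ", "))
    }
    if (nrow(dt) == 0L) ct_validation_error("empty counts table")
    dt[, need, with = FALSE]
  }
  mets <- rbindlist(lapply(seq_len(nrow(counts)), function(i) {
    v <- compute_metrics(counts[i], dp_scale = dp_scale)
    as.data.table(as.list(unclass(v)))
  }))
  cbind(counts, mets)
}

#' Round a metric table the way the reference reports do
#'
#' 5 decimals for rate-like metrics (TPR..BAC, F1, MCC, kappa), 6 decimals
#' for GM, YI and DP. Stored values stay full precision; this is display
#' formatting only.
#'
#' @param table output of [metric_table()].
#' @return a rounded copy.
#' @export
round_metric_table <- function(table) {
  out <- copy(as.data.table(table))
  five <- intersect(c("tpr", "tnr", "ppv", "acc", "err", "bac",
                      "f1", "mcc", "kappa"), names(out))
  six <- intersect(c("gm", "yi", "dp"), names(out))
  out[, (five) := lapply(.SD, round, 5L), .SDcols = five]
  out[, (six) := lapply(.SD, round, 6L), .SDcols = six]
  out[]
}

#' Top-k and bottom-k models by a metric
#'
#' Ordering is by the metric, ties broken by MCC, then lexicographic
#' model id, so reports are deterministic. The top list is in descending
#' order of the metric; the bottom list starts at the worst model.
#'
#' @param table a metric table.
#' @param metric_name one of the 12 metric column names.
#' @param k list length (0 gives empty lists).
#' @return list with character vectors `top` and `bottom`.
#' @export
rank_models <- function(table, metric_name, k = 5L) {
  dt <- as.data.table(table)
  if (!metric_name %in% names(dt)) {
    ct_validation_error("unknown metric '%s'", metric_name)
  }
  if (k > nrow(dt)) {
    ct_validation_error("k = %d exceeds the %d available models", k, nrow(dt))
  }
  ord <- order(-dt[[metric_name]], -dt[["mcc"]], dt[["model_id"]])
  ranked <- dt$model_id[ord]
  list(top = head(ranked, k), bottom = rev(tail(ranked, k)))
}
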