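test_that("confusion counts partition tiny hand cases", {
  dm <- new_dm <- structure(list(
    image_id = paste0("i", 1:4), model_id = "M",
    detected = matrix(c(TRUE, FALSE, TRUE, FALSE), ncol = 1,
                      dimnames = list(paste0("i", 1:4), "M")),
    truth = c(TRUE, TRUE, FALSE, FALSE)), class = "detection_matrix")
  cc <- confusion_counts(dm, "M")
  expect_equal(unclass(cc), c(tp = 1, tn = 1, fp = 1, fn = 1))
  expect_error(confusion_counts(dm, "nope"),
               class = "camtrapeval_validation_error")
})

test_that("all-negative detector on the reference dataset shape", {
  dm <- structure(list(
    image_id = as.character(1:10), model_id = "M",
    detected = matrix(FALSE, 10, 1, dimnames = list(as.character(1:10), "M")),
    truth = rep(c(TRUE, FALSE), c(3, 7))), class = "detection_matrix")
  cc <- confusion_counts(dm, "M")
  expect_equal(unclass(cc), c(tp = 0, tn = 7, fp = 0, fn = 3))
  # and directly on the published shape
  cc2 <- confusion_counts_from(0, 291974, 0, 1630)
  expect_equal(sum(cc2), 293604)
})

test_that("counts from a simulation equal a brute-force per-image tally", {
  sim <- small_sim(n = 900, seed = 41)
  dm <- sim$detections
  for (m in dm$model_id) {
    cc <- confusion_counts(dm, m)
    tally <- c(tp = 0, tn = 0, fp = 0, fn = 0)
    for (i in seq_along(dm$image_id)) {
      d <- dm$detected[i, m]; t <- dm$truth[i]
      k <- if (d && t) "tp" else if (!d && !t) "tn" else if (d) "fp" else "fn"
      tally[k] <- tally[k] + 1
    }
    expect_equal(unclass(cc), tally)
  }
})

test_that("chance-level symmetric counts zero out the skill metrics", {
  m <- suppressWarnings(compute_metrics(confusion_counts_from(50, 50, 50, 50)))
  expect_equal(m[["tpr"]], 0.5)
  expect_equal(m[["tnr"]], 0.5)
  expect_equal(m[["bac"]], 0.5)
  expect_equal(m[["gm"]], 0.5)
  expect_equal(m[["yi"]], 0)
  expect_equal(m[["mcc"]], 0)
  expect_equal(m[["kappa"]], 0)
  expect_equal(m[["dp"]], 0)
})

test_that("1000 random count vectors agree with the dual-formula oracle to 1e-12", {
  set.seed(1234)
  for (rep in 1:1000) {
    cts <- random_counts()
    got <- compute_metrics(confusion_counts_from(cts$tp, cts$tn, cts$fp, cts$fn))
    want <- oracle_metrics(cts$tp, cts$tn, cts$fp, cts$fn)
    expect_lt(max(abs(unclass(got) - want)), 1e-12)
  }
})

test_that("undefined metrics are flagged NA with a warning, never 0", {
  # tp + fp = 0: ppv (and f1) undefined, everything else finite
  expect_warning(m <- compute_metrics(confusion_counts_from(0, 90, 0, 10)),
                 "undefined")
  expect_true(is.na(m[["ppv"]]))
  expect_true(is.na(m[["dp"]]))   # tpr = 0
  expect_true(is.na(m[["mcc"]])) # zero row sum
  expect_equal(m[["tnr"]], 1)
  expect_equal(m[["acc"]], 0.9)
})

test_that("metric_table composes with compute_metrics row by row", {
  sim <- small_sim(n = 300, seed = 43)
  tab <- suppressWarnings(metric_table(sim$detections))
  expect_equal(nrow(tab), 3L)
  for (i in seq_len(nrow(tab))) {
    v <- suppressWarnings(
      compute_metrics(confusion_counts_from(tab$tp[i], tab$tn[i],
                                            tab$fp[i], tab$fn[i])))
    expect_equal(unlist(tab[i, names(v), with = FALSE]), unclass(v))
  }
  single <- metric_table(data.frame(model_id = "M", tp = 5, tn = 80,
                                    fp = 10, fn = 5))
  expect_equal(nrow(single), 1L)
  expect_error(metric_table(data.frame(model_id = character(), tp = numeric(),
                                       tn = numeric(), fp = numeric(),
                                       fn = numeric())),
               class = "camtrapeval_validation_error")
})

test_that("reference fixture rows partition the dataset", {
  cc <- lynx_confusion_counts()
  expect_equal(nrow(cc), 36L)
  expect_true(all(cc[, tp + tn + fp + fn] == 293604))
  expect_true(all(cc[, tp + fn] == 1630))
})

test_that("identity chain and AM-GM hold on every reference row", {
  tab <- metric_table(lynx_confusion_counts())
  expect_equal(tab$err, 1 - tab$acc, tolerance = 1e-12)
  expect_equal(tab$yi, 2 * tab$bac - 1, tolerance = 1e-12)
  expect_equal(tab$gm^2, tab$tpr * tab$tnr, tolerance = 1e-12)
  expect_true(all(tab$gm <= tab$bac + 1e-12))
})

test_that("DP needs base-10 logits; the natural-log variant misses the tables", {
  tab <- metric_table(lynx_confusion_counts())
  rep <- reported_metric_values()
  data.table::setkey(tab, model_id)
  rep <- rep[order(model_id)]; tab <- tab[order(model_id)]
  expect_lt(max(abs(tab$dp - rep$dp)), 5e-6)
  dp_natural <- (sqrt(3) / 3.14) *
    (log(tab$tpr / (1 - tab$tpr)) + log(tab$tnr / (1 - tab$tnr)))
  expect_gt(min(abs(dp_natural - rep$dp)), 0.1)
})

test_that("mcc and kappa agree on balanced counts, diverge on imbalanced", {
  bal <- compute_metrics(confusion_counts_from(500, 505, 50, 51))
  expect_equal(bal[["mcc"]], bal[["kappa"]], tolerance = 1e-4)
  # the most imbalanced reference rows show a visible gap
  rep <- reported_metric_values()
  expect_gt(rep[model_id == "Xcp_v1", abs(mcc - kappa)], 0.03)
  expect_gt(rep[model_id == "Inc_v3", abs(mcc - kappa)], 0.02)
})

test_that("rank_models reproduces the published orderings", {
  tab <- metric_table(lynx_confusion_counts())
  expect_identical(rank_models(tab, "kappa", 5)$top,
                   c("Inc_Res_v2", "Pns_lrg", "Inc_v4", "Ns_lrg", "Inc_v3"))
  expect_identical(rank_models(tab, "acc", 1)$top, "Inc_v1")
  k0 <- rank_models(tab, "f1", 0)
  expect_length(k0$top, 0)
  expect_length(k0$bottom, 0)
  expect_error(rank_models(tab, "f1", 37),
               class = "camtrapeval_validation_error")
  expect_error(rank_models(tab, "nope", 3),
               class = "camtrapeval_validation_error")
})

test_that("round_metric_table mimics the published display precision", {
  tab <- metric_table(lynx_confusion_counts())
  r <- round_metric_table(tab)
  expect_equal(r[model_id == "Inc_Res_v2", tpr], 0.47055)
  expect_equal(r[model_id == "Inc_Res_v2", gm], 0.684137)
})
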