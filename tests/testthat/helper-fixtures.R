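# shared builders for tiny in-code fixtures

toy_profiles <- function(ids = c("A", "B", "C"),
                         tpr = c(0.8, 0.6, 0.4),
                         tnr = c(0.95, 0.90, 0.99)) {
  data.frame(model_id = ids, tpr = tpr, tnr = tnr)
}

toy_records <- function() {
  # 2 images x 2 models, hand-written: img1 has the lynx, img2 does not;
  # model M1 detects img1 (rank 2 target) and img2 (false positive);
  # model M2 detects neither
  data.frame(
    image_id = rep(c("img1", "img2"), each = 10),
    model_id = rep(rep(c("M1", "M2"), each = 5), 2),
    rank = rep(1:5, 4),
    synset_id = c(
      "n02123045", "n02127052", "n02128385", "n02129165", "n02114367",  # img1 M1
      "n02123045", "n02123159", "n02128385", "n02129165", "n02114367",  # img1 M2
      "n02125311", "n02123159", "n02124075", "n02132136", "n02134084",  # img2 M1
      "n02403003", "n02410509", "n02412070", "n02415577", "n02417914"), # img2 M2
    confidence = rep(c(0.5, 0.2, 0.1, 0.05, 0.01), 4))
}

toy_truth <- function() {
  data.frame(image_id = c("img1", "img2"), is_positive = c(TRUE, FALSE))
}

small_sim <- function(n = 400, rho = 0.3, seed = 7, ...) {
  simulate_predictions(synthetic_config(
    n_images = n, prevalence = 0.25, model_profiles = toy_profiles(),
    correlation = rho, seed = seed, ...))
}

# independently coded metric oracle: naive transliteration of the defining
# formulas, kappa via the observed/expected-agreement form
oracle_metrics <- function(tp, tn, fp, fn, dp_scale = sqrt(3) / 3.14) {
  n <- tp + tn + fp + fn
  tpr <- tp / (tp + fn); tnr <- tn / (tn + fp); ppv <- tp / (tp + fp)
  acc <- (tp + tn) / n
  po <- acc
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  c(tpr = tpr, tnr = tnr, ppv = ppv, acc = acc, err = 1 - acc,
    bac = (tpr + tnr) / 2, gm = sqrt(tpr * tnr), yi = tpr + tnr - 1,
    dp = dp_scale * log10((tpr / (1 - tpr)) * (tnr / (1 - tnr))),
    f1 = 2 * tp / (2 * tp + fp + fn),
    mcc = (tp * tn - fp * fn) /
      sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)),
    kappa = (po - pe) / (1 - pe))
}

random_counts <- function(max_n = 500) {
  stats::setNames(as.list(1 + stats::rbinom(4, max_n, runif(4, 0.05, 0.9))),
                  c("tp", "tn", "fp", "fn"))
}
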