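test_that("confusion reports match the published rounding convention", {
  # DB1-style counts
  r1 <- evaluation_report(TP = 8, TN = 69, FP = 1, FN = 8)
  expect_equal(petrad:::percent(r1$sensitivity), 50)
  expect_equal(petrad:::percent(r1$specificity), 99)  # 68.57... -> 98.57 -> 99
  # DB2-style counts
  r2 <- evaluation_report(TP = 3, TN = 19, FP = 1, FN = 6)
  expect_equal(petrad:::percent(r2$sensitivity), 33)
  expect_equal(petrad:::percent(r2$specificity), 95)

  r3 <- confusion(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(r3$sensitivity, 1)
  expect_equal(r3$specificity, 1)
  expect_equal(r3$gmean, 1)
  expect_error(confusion(c(1, 0), c(1, 0, 1)), "length")
})

test_that("confusion invariants hold on fuzzed prediction/truth pairs", {
  set.seed(3)
  for (i in 1:300) {
    n <- sample(2:40, 1)
    pred <- sample(0:1, n, replace = TRUE)
    truth <- sample(0:1, n, replace = TRUE)
    r <- confusion(pred, truth)
    expect_equal(r$TP + r$FN, sum(truth == 1))
    expect_equal(r$TN + r$FP, sum(truth == 0))
    if (r$TP + r$FN > 0) expect_equal(r$sensitivity, r$TP / (r$TP + r$FN))
    if (r$TN + r$FP > 0) expect_equal(r$specificity, r$TN / (r$TN + r$FP))
    if (!is.na(r$gmean)) {
      expect_equal(r$gmean, sqrt(r$sensitivity * r$specificity))
    }
  }
})

test_that("the unified rule is OR and dominates its components", {
  expect_identical(unified_predict(c(0, 1, 0, 1), c(0, 0, 1, 1)),
                   c(0L, 1L, 1L, 1L))
  set.seed(5)
  for (i in 1:50) {
    n <- 30
    truth <- sample(0:1, n, replace = TRUE, prob = c(0.7, 0.3))
    if (length(unique(truth)) < 2) next
    vis <- sample(0:1, n, replace = TRUE)
    rad <- sample(0:1, n, replace = TRUE)
    u <- confusion(unified_predict(vis, rad), truth)
    rv <- confusion(vis, truth)
    rr <- confusion(rad, truth)
    expect_gte(u$sensitivity, max(rv$sensitivity, rr$sensitivity))
    expect_lte(u$specificity, min(rv$specificity, rr$specificity))
  }
})

test_that("the univariate classifier applies a strict positive-low cut", {
  expect_identical(univariate_classifier(0.20, 0.2755, "positive-low"), 1L)
  expect_identical(univariate_classifier(0.30, 0.2755, "positive-low"), 0L)
  expect_identical(univariate_classifier(0.2755, 0.2755, "positive-low"), 0L)
  expect_identical(univariate_classifier(0.30, 0.2755, "positive-high"), 1L)
})

test_that("the scanner robustness test is calibrated and powered", {
  set.seed(7)
  p_null <- vapply(1:400, function(i) {
    ch <- as_cohort(data.frame(patient_id = sprintf("p%02d", 1:30),
                               ln_histology = rep(c(1L, 0L), c(5, 25)),
                               visual_detection = 0L,
                               scanner_id = rep(c("a", "b", "c"), each = 10),
                               F1 = rnorm(30)))
    scanner_robustness(ch, "F1")
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(p_null, "punif"))$p.value, 0.01)

  shifted <- as_cohort(data.frame(patient_id = sprintf("p%02d", 1:30),
                                  ln_histology = rep(c(1L, 0L), c(5, 25)),
                                  visual_detection = 0L,
                                  scanner_id = rep(c("a", "b"), each = 15),
                                  F1 = c(rnorm(15), rnorm(15) + 5)))
  expect_lt(scanner_robustness(shifted, "F1"), 0.001)

  single <- shifted
  single$scanner_id <- "a"
  expect_error(scanner_robustness(single, "F1"), "2 scanner groups")
})

test_that("evaluate_pipeline wires each mode to the right predictions", {
  ch <- mk_toy_cohort(n = 40, n_pos = 12, sep = c(GLSZM_ZP = -3), seed = 8)
  ch$visual_detection <- as.integer(ch$ln_histology == 1 &
                                      seq_len(40) %% 2 == 0)
  rv <- evaluate_pipeline(ch, "visual")
  expect_equal(rv$TP + rv$FN, 12)
  ru <- evaluate_pipeline(ch, "univariate", feature_name = "GLSZM_ZP")
  expect_gte(ru$sensitivity, 0.8)  # strongly separated synthetic feature
  run <- evaluate_pipeline(ch, "unified-univariate",
                           feature_name = "GLSZM_ZP")
  expect_gte(run$sensitivity, max(rv$sensitivity, ru$sensitivity))
  expect_lte(run$specificity, min(rv$specificity, ru$specificity))
  expect_error(evaluate_pipeline(ch, "multivariate"), "requires a trained")

  # multivariate mode round-trips a trained ensemble
  ch2 <- mk_toy_cohort(n = 30, n_pos = 10, sep = c(F1 = 5, F2 = 5), seed = 10)
  ens <- train_final_ensemble(ch2, model_spec(c("F1", "F2"), 2), n_runs = 5,
                              seed = 1, max_epochs = 150)
  rm_ <- evaluate_pipeline(ch2, "multivariate", ensemble = ens)
  expect_gte(rm_$gmean, 0.9)
})

test_that("visual mode recovers the generator operating point", {
  cfg <- cohort_config(n_patients = 80, n_positive = 40,
                       params_positive = tumour_param_dist(
                         radius_mm = c(6, 6, 6), noise_frac = 0,
                         psf_fwhm_mm = 0, lobulation = 0),
                       params_negative = tumour_param_dist(
                         radius_mm = c(6, 6, 6), noise_frac = 0,
                         psf_fwhm_mm = 0, lobulation = 0),
                       visual_sensitivity = 0.5, visual_specificity = 0.99,
                       seed = 31)
  ch <- generate_cohort(cfg, extract = FALSE)
  r <- evaluate_pipeline(ch, "visual")
  expect_lt(abs(r$sensitivity - 0.5), 0.25)   # 40 Bernoulli draws
  expect_gte(r$specificity, 0.9)
})
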