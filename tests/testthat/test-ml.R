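# Synthetic training generator, preprocessing rules, regression harness,
# sensitivity metric.

test_that("synthetic training data is reproducible with planted truth", {
  a <- generate_synthetic_training(200, seed = 5)
  b <- generate_synthetic_training(200, seed = 5)
  expect_identical(a, b)
  c <- generate_synthetic_training(200, seed = 6)
  expect_false(identical(a$systolic_bp, c$systolic_bp))
  expect_error(generate_synthetic_training(5), "n must be")
  tr <- attr(a, "truth")
  expect_equal(length(tr$coef_sys), length(feature_names()))
})

test_that("noise-free linear data refits to the planted coefficients", {
  feats <- c("x10WidthTime", "pulseRiseTime", "peakAmplitude")
  cf <- c(x10WidthTime = 30, pulseRiseTime = -12, peakAmplitude = 4)
  d <- generate_synthetic_training(400, seed = 11, features = feats,
                                   coef_sys = cf, coef_dia = cf / 2,
                                   noise_sd = 0)
  fit <- lm(systolic_bp ~ x10WidthTime + pulseRiseTime + peakAmplitude,
            data = d)
  expect_equal(unname(coef(fit)[-1]), unname(cf), tolerance = 1e-6)
  expect_equal(unname(coef(fit)[1]), 120, tolerance = 1e-6)
})

test_that("refit residual sd recovers the planted noise level", {
  feats <- c("x10WidthTime", "pulseRiseTime")
  d <- generate_synthetic_training(1e4, seed = 21, features = feats,
                                   coef_sys = c(x10WidthTime = 20,
                                                pulseRiseTime = 10),
                                   noise_sd = 5)
  fit <- lm(systolic_bp ~ x10WidthTime + pulseRiseTime, data = d)
  expect_equal(sd(residuals(fit)), 5, tolerance = 0.04)  # 5 +- 0.2
})

test_that("preprocessing: planted violations filtered, then rescaled", {
  feats <- c("f1", "f2")
  set.seed(31)
  n <- 100
  d <- data.frame(f1 = rnorm(n, 0, 1), f2 = rnorm(n, 0, 1),
                  systolic_bp = rnorm(n, 120, 3),
                  diastolic_bp = rnorm(n, 80, 2),
                  window_sys_range = runif(n, 0, 10),
                  window_dia_range = runif(n, 0, 5))
  # plant 3 range violations and 2 gross feature outliers (~5 sd)
  d$window_sys_range[c(4, 50)] <- 25
  d$window_dia_range[17] <- 15
  d$f1[70] <- 5 * sd(d$f1[-70])
  d$f2[81] <- -5 * sd(d$f2[-81])
  out <- preprocess_training(d)
  expect_equal(nrow(out), 95)
  info <- attr(out, "preprocess")
  expect_equal(info$n_range_discarded, 3)
  expect_equal(info$n_outliers_removed, 2)
  # features rescaled to [0, 1]
  expect_equal(range(out$f1), c(0, 1))
  expect_equal(range(out$f2), c(0, 1))
  # blood pressures untouched (up to the removed rows)
  expect_true(all(out$systolic_bp %in% d$systolic_bp))
})

test_that("preprocessing is idempotent", {
  d <- generate_synthetic_training(300, seed = 41)
  once <- preprocess_training(d)
  twice <- preprocess_training(once)
  attr(once, "preprocess") <- NULL
  attr(twice, "preprocess") <- NULL
  expect_equal(twice, once, tolerance = 1e-12)
})

test_that("all-identical samples survive with a degenerate-rescale warning", {
  d <- data.frame(f1 = rep(0.3, 20), systolic_bp = rep(120, 20),
                  diastolic_bp = rep(80, 20),
                  window_sys_range = rep(1, 20),
                  window_dia_range = rep(1, 20))
  expect_warning(out <- preprocess_training(d), "constant")
  expect_equal(nrow(out), 20)
  expect_true(all(out$f1 == 0))
})

test_that("evaluate_split: perfect and constant predictors, closed forms", {
  d <- generate_synthetic_training(400, seed = 51, noise_sd = 0)
  oracle <- bp_model("custom",
                     fit = function(x, y) lm.fit(cbind(1, x), y),
                     predict = function(fit, x)
                       as.numeric(cbind(1, x) %*% fit$coefficients))
  ev <- evaluate_split(oracle, d, seed = 3)
  expect_lt(max(abs(ev$mean_error)), 1e-8)
  expect_lt(max(ev$sd_error), 1e-8)
  # constant predictor: error sd equals the BP sd of the test split
  const <- bp_model("custom",
                    fit = function(x, y) mean(y),
                    predict = function(fit, x) rep(fit, nrow(x)))
  ev2 <- evaluate_split(const, d, seed = 3)
  set.seed(3)
  idx <- sample.int(400)
  test_i <- idx[-seq_len(max(10, round(0.7 * 400)))]
  expect_equal(unname(ev2$sd_error["systolic"]),
               sd(d$systolic_bp[test_i]), tolerance = 1e-12)
  expect_error(evaluate_split(oracle, d[1:5, ], folds = 10), "folds")
})

test_that("sensitivity: zero for constant models, pass-through for identity", {
  cohort <- generate_synthetic_training(100, seed = 61)
  const <- bp_model("custom",
                    fit = function(x, y) mean(y),
                    predict = function(fit, x) rep(fit, nrow(x)))
  fitted_const <- bp_fit(const, cohort)
  rep_const <- sensitivity_analysis(fitted_const, cohort)
  expect_equal(rep_const$sd_systolic, 0)
  expect_equal(rep_const$sd_diastolic, 0)
  # identity on one feature: prediction sd equals that feature's
  # (population) sd in the cohort
  ident <- bp_model("custom",
                    fit = function(x, y) NULL,
                    predict = function(fit, x) x[, "x10WidthTime"])
  fitted_id <- bp_fit(ident, cohort)
  rep_id <- sensitivity_analysis(fitted_id, cohort)
  v <- cohort$x10WidthTime
  expect_equal(rep_id$sd_systolic, sqrt(mean((v - mean(v))^2)),
               tolerance = 1e-12)
  expect_error(sensitivity_analysis(bp_model("linear"), cohort),
               "not been fitted")
  expect_error(sensitivity_analysis(fitted_id, cohort[1, , drop = FALSE]),
               "two rows")
})

test_that("sensitivity is invariant to row order and cohort duplication", {
  cohort <- generate_synthetic_training(80, seed = 71)
  m <- bp_fit(bp_model("linear"), cohort)
  base <- sensitivity_analysis(m, cohort)
  shuf <- sensitivity_analysis(m, cohort[sample.int(80), ])
  expect_equal(shuf$sd_systolic, base$sd_systolic, tolerance = 1e-12)
  dup <- sensitivity_analysis(m, rbind(cohort, cohort))
  expect_equal(dup$sd_systolic, base$sd_systolic, tolerance = 1e-12)
})

test_that("linear sensitivity responds monotonically to planted effects", {
  feats <- c("x10WidthTime", "pulseRiseTime")
  sds <- vapply(c(5, 20, 60), function(beta) {
    d <- generate_synthetic_training(500, seed = 81, features = feats,
                                     coef_sys = c(x10WidthTime = beta,
                                                  pulseRiseTime = 0),
                                     noise_sd = 1)
    m <- bp_fit(bp_model("linear"), d)
    sensitivity_analysis(m, d)$sd_systolic
  }, numeric(1))
  expect_true(all(diff(sds) > 0))
})

test_that("the packaged svm, trees and nn backends honor the contract", {
  d <- generate_synthetic_training(150, seed = 91)
  cohort <- generate_synthetic_training(60, seed = 92)
  for (type in c("svm", "trees", "nn")) {
    opts <- if (type == "nn") list(size = 5, maxit = 50) else list()
    m <- do.call(bp_model, c(list(type = type), opts))
    fit <- bp_fit(m, d)
    pr <- predict(fit, cohort)
    expect_equal(dim(pr), c(60, 2))
    expect_true(all(is.finite(pr)))
    rep <- sensitivity_analysis(fit, cohort)
    expect_gte(rep$sd_systolic, 0)
  }
})
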