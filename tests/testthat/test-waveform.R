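# Gaussian templates, fitting, record synthesis and noise injection.

test_that("gaussian_sum matches an independently evaluated closed form", {
  gp <- ppg_pulse_template(23)
  t <- seq(0, 0.8, by = 0.001)
  # independent evaluation: per-component columns summed the other way
  comp <- sapply(1:3, function(i) gp$a[i] * exp(-((t - gp$b[i]) / gp$c[i])^2))
  expect_equal(gaussian_sum(gp, t), rowSums(comp), tolerance = 1e-12)
  # trivial identities
  zero <- gaussian_params(c(0, 0), c(0.1, 0.2), c(0.1, 0.1))
  expect_true(all(gaussian_sum(zero, t) == 0))
  single <- gaussian_params(1.3, 0.35, 0.07)
  expect_equal(gaussian_sum(single, 0.35), 1.3)
  expect_error(gaussian_params(1, 0.1, -0.1), "width")
  expect_error(gaussian_params(-1, 0.1, 0.1), "amplitude")
})

test_that("median relative error: identities, scaling, outlier robustness", {
  y <- gaussian_sum(ppg_pulse_template(55), seq(0, 0.8, length.out = 100))
  expect_equal(median_relative_error(y, y), 0)
  expect_equal(median_relative_error(1.05 * y, y), 5, tolerance = 1e-9)
  # a single corrupted sample leaves the median untouched
  y2 <- y
  y2[37] <- 10 * y[37]
  expect_equal(median_relative_error(y2, y), 0)
  expect_error(median_relative_error(y, numeric(100)), "zero")
  expect_error(median_relative_error(y[1:10], y), "length")
})

test_that("template refit recovers the generating parameters", {
  gp <- ppg_pulse_template(34.4)
  t <- seq(0, 0.8, length.out = 96)
  y <- gaussian_sum(gp, t)
  fit <- fit_ppg_template(y, t, n_gaussians = 3, seed = 4)
  expect_lt(fit$median_relative_error, 0.5)
  # parameters recovered up to component permutation, 5% per parameter
  ref <- cbind(gp$a, gp$b, gp$c)
  est <- cbind(fit$params$a, fit$params$b, fit$params$c)
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  ok <- vapply(perms, function(p)
    all(abs(est[p, ] - ref) / abs(ref) < 0.05), logical(1))
  expect_true(any(ok))
})

test_that("a single-Gaussian template is fitted exactly by a 3-Gaussian model", {
  t <- seq(0, 0.8, length.out = 80)
  y <- 0.9 * exp(-((t - 0.3) / 0.1)^2)
  fit <- fit_ppg_template(y, t, n_gaussians = 3, seed = 2)
  expect_lt(fit$median_relative_error, 0.1)
})

test_that("fit error is non-increasing in the number of Gaussians", {
  gp <- ppg_pulse_template(44.8)
  t <- seq(0, 0.8, length.out = 96)
  y <- gaussian_sum(gp, t)
  errs <- vapply(1:3, function(k)
    fit_ppg_template(y, t, n_gaussians = k, seed = 7)$median_relative_error,
    numeric(1))
  expect_true(all(diff(errs) <= 1e-6))
  expect_error(fit_ppg_template(rep(1, 50)), "constant")
  expect_error(fit_ppg_template(y[1:10]), "20 samples")
})

test_that("fit object implements the modelling-method surface", {
  t <- seq(0, 0.8, length.out = 96)
  y <- gaussian_sum(ppg_pulse_template(23), t)
  fit <- fit_ppg_template(y, t, seed = 1)
  expect_named(coef(fit), c("a1", "a2", "a3", "b1", "b2", "b3",
                            "c1", "c2", "c3"))
  expect_equal(fitted(fit), predict(fit), tolerance = 1e-12)
  expect_equal(residuals(fit), y - fitted(fit))
  expect_output(print(fit), "Gaussians")
})

test_that("synthesis: sample count, beat count, scaling contract", {
  gp <- ppg_pulse_template(23)
  rec <- synthesize_ppg(gp, hr = 75, fs = 120, duration = 30,
                        ac = 2.5, dc = 1.0)
  expect_equal(length(rec$samples), 3600)
  expect_equal(min(rec$samples), 1.0)
  expect_equal(max(rec$samples) - min(rec$samples), 2.5)
  # 30 s at 75 bpm: 37 complete beats plus half a beat
  expect_equal(30 * 75 / 60, 37.5)
  # exact periodicity of the tiled signal (96 samples per beat)
  per <- round(120 * 60 / 75)
  expect_equal(rec$samples[seq_len(3600 - per)],
               rec$samples[seq_len(3600 - per) + per], tolerance = 1e-9)
  expect_error(synthesize_ppg(gp, hr = 0), "positive")
  expect_error(synthesize_ppg(gp, fs = -1), "positive")
})

test_that("hr retiling rescales the template time axis, preserving shape", {
  gp <- ppg_pulse_template(55)
  r60 <- synthesize_ppg(gp, hr = 60, fs = 200, duration = 10, ac = 1, dc = 0)
  r75 <- synthesize_ppg(gp, hr = 75, fs = 200, duration = 10, ac = 1, dc = 0)
  # one beat of each, compared on the normalized phase axis
  b60 <- r60$samples[1:200]          # 1.0 s period
  b75 <- r75$samples[1:160]          # 0.8 s period
  phase <- seq(0, 1 - 1e-9, length.out = 400)
  f60 <- approx(seq(0, 1, length.out = 201)[1:200], b60, xout = phase)$y
  f75 <- approx(seq(0, 1, length.out = 161)[1:160], b75, xout = phase)$y
  expect_lt(max(abs(f60 - f75), na.rm = TRUE), 0.02)
})

test_that("noise injection: identity, closed-form RMS, metadata", {
  gp <- ppg_pulse_template(23)
  rec <- synthesize_ppg(gp, ac = 3, dc = 10)
  silent <- suppressWarnings(
    add_ppg_noise(rec, noise_spec(fraction = c(0, 0, 0))))
  expect_equal(silent$samples, rec$samples)
  # single 20 Hz tone at full AC amplitude, phase pi/2:
  # RMS of the added noise is ac/sqrt(2)
  noisy <- suppressWarnings(
    add_ppg_noise(rec, noise_spec(frequency = 20, fraction = 1,
                                  phase = pi / 2)))
  rms <- sqrt(mean((noisy$samples - rec$samples)^2))
  expect_equal(rms, 3 / sqrt(2), tolerance = 0.01)
  # default spec records itself in the metadata and warns at Nyquist
  expect_warning(n2 <- add_ppg_noise(rec), "Nyquist")
  expect_equal(n2$meta$noise$frequency, c(20, 40, 60))
  expect_equal(n2$meta$noise$fraction, c(0.38, 0.59, 0.59))
  bare <- ppg_record(rec$samples, 120)
  expect_error(add_ppg_noise(bare), "AC")
})

test_that("synthesis is deterministic and self-consistent", {
  gp <- ppg_pulse_template(44.8)
  rec <- synthesize_ppg(gp, hr = 75, fs = 120, duration = 30, ac = 1, dc = 2)
  tpl <- synthesize_ppg(gp, hr = 75, fs = 120, duration = 30, ac = 1, dc = 2)
  expect_identical(rec$samples, tpl$samples)
  expect_equal(median_relative_error(rec$samples, tpl$samples), 0)
})
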