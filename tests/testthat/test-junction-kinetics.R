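# FRAP normalization/fitting and ablation recoil fitting.

test_that("normalization pins the closed-form endpoints of the recovery", {
  tr <- generate_frap_trace(0.8, 0.01, noise_sd = 0)
  nt <- normalize_frap(tr)
  post <- which(nt$time_s >= 0)
  expect_equal(nt$i_n[post[1]], 0)                 # I = I_min
  # a trace pinned at I_max normalizes to 1
  tr2 <- tr
  tr2$roi_intensity[tr2$time_s >= 0] <- attr(tr, "truth")$i_max
  # keep a distinct post-bleach minimum so I_max > I_min
  tr2$roi_intensity[which(tr2$time_s >= 0)[1]] <- attr(tr, "truth")$i_min
  nt2 <- normalize_frap(tr2)
  expect_equal(tail(nt2$i_n, 1), 1)
})

test_that("reference-based correction removes acquisition bleaching exactly", {
  # raw = true signal x decay; correction must recover a constant normalized
  # trace to within 1e-6
  tr <- generate_frap_trace(0.8, 0.01, noise_sd = 0, ref_bleach_rate = 5e-4)
  nt <- normalize_frap(tr)
  ideal <- generate_frap_trace(0.8, 0.01, noise_sd = 0, ref_bleach_rate = 0)
  ni <- normalize_frap(ideal)
  expect_lt(max(abs(nt$i_n - ni$i_n), na.rm = TRUE), 1e-6)
  bad <- tr
  bad$ref_1 <- -bad$ref_1
  expect_error(normalize_frap(bad), "reference")
})

test_that("degenerate and malformed FRAP traces error cleanly", {
  tr <- generate_frap_trace(0.8, 0.01, noise_sd = 0)
  flat <- tr
  flat$roi_intensity <- rep(attr(tr, "truth")$i_max, nrow(flat))
  expect_error(normalize_frap(flat), "degenerate")
  norefs <- tr[, c("time_s", "roi_intensity")]
  expect_error(normalize_frap(norefs), "reference")
})

test_that("noiseless recovery fits return the generating parameters to 6 decimals", {
  f <- fit_frap(generate_frap_trace(0.8, 0.01, noise_sd = 0))
  expect_equal(f$mobile_fraction, 0.8, tolerance = 1e-7)
  expect_equal(f$k, 0.01, tolerance = 1e-6)
  expect_equal(f$half_time_s, 69.31472, tolerance = 1e-4)
  expect_equal(f$recovery_rate, 0.8 * 0.01, tolerance = 1e-7)
})

test_that("half-time and recovery-rate identities hold for every fit", {
  set.seed(13)
  for (i in 1:10) {
    A <- runif(1, 0.4, 1); k <- 10^runif(1, -3, -1.5)
    f <- fit_frap(generate_frap_trace(A, k, noise_sd = runif(1, 0, 2)))
    expect_lt(abs(f$half_time_s * f$k - log(2)), 1e-12)
    # recovery rate equals the numerical slope of the fitted curve at t = 0
    h <- 1e-6
    slope0 <- f$mobile_fraction * (1 - exp(-f$k * h)) / h
    expect_lt(abs(f$recovery_rate - slope0), 1e-6)
  }
  # k = ln 2 gives a half time of exactly 1 s
  f1 <- fit_frap(generate_frap_trace(0.9, log(2), dt_s = 0.5, noise_sd = 0))
  expect_equal(f1$half_time_s, 1, tolerance = 1e-6)
})

test_that("parameter recovery over noisy ensembles is unbiased within 2%", {
  # noise applied to the normalized trace: this bounds the fitter itself
  # (the Cramer-Rao floor for k at this design is ~7%)
  set.seed(1)
  t <- seq(0, 39 * 20, 20)
  fits <- t(replicate(50, {
    tr <- structure(
      data.frame(time_s = t,
                 i_n = 0.8 * (1 - exp(-0.01 * t)) + rnorm(length(t), 0, 0.05)),
      class = c("frap_trace", "data.frame"))
    f <- fit_frap(tr)
    c(f$mobile_fraction, f$k)
  }))
  expect_lt(abs(mean(fits[, 1]) - 0.8) / 0.8, 0.02)
  expect_lt(abs(mean(fits[, 2]) - 0.01) / 0.01, 0.02)
  expect_lt(sqrt(mean((fits[, 1] - 0.8)^2)) / 0.8, 0.08)
  expect_lt(sqrt(mean((fits[, 2] - 0.01)^2)) / 0.01, 0.08)
})

test_that("elastic recoil fits recover amplitude, timescale, and initial speed", {
  f <- fit_recoil(generate_recoil_trace(2, 1, 10, "elastic", noise_sd = 0))
  expect_equal(f$lf_um, 1, tolerance = 1e-6)
  expect_equal(f$T_s, 10, tolerance = 1e-6)
  expect_equal(f$initial_speed_um_s, 0.1, tolerance = 1e-6)
  expect_equal(f$amplitude_um, f$lf_um)
  expect_true(f$fit_ok)
  # normalized recoil at t = 0 is exactly zero by construction
  tr <- generate_recoil_trace(2, 1, 10, "elastic", noise_sd = 0)
  expect_equal((tr$vertex_distance_um[1] - 2) / 2, 0)
  # the fitted curve never exceeds the amplitude
  expect_true(all(f$lf_um * (1 - exp(-tr$time_s / f$T_s)) <= f$lf_um))
})

test_that("viscoelastic (resorbing) recoils are flagged unfittable", {
  rv <- generate_recoil_trace(2, 1, 10, "viscoelastic", noise_sd = 0)
  f <- fit_recoil(rv)
  expect_false(f$fit_ok)
  expect_true(is.na(f$amplitude_um))
  # sanity: the trace really resorbs by more than half its peak
  r <- (rv$vertex_distance_um - 2) / 2
  expect_lt(tail(r, 1), 0.5 * max(r))
})

test_that("a flat trace yields a degenerate zero-amplitude fit", {
  flat <- data.frame(time_s = seq(0, 58, 2), vertex_distance_um = rep(2, 30))
  f <- fit_recoil(flat, l0_um = 2)
  expect_equal(f$amplitude_um, 0)
  expect_true(f$degenerate)
  expect_false(f$fit_ok)
  expect_error(fit_recoil(flat[, ], l0_um = NULL), "l0")
})

test_that("junction intensity fold changes mirror the LOF/GOF conventions", {
  set.seed(2)
  control <- rnorm(300, 100, 10)
  expect_equal(junction_intensity_fold_change(control, control)$fold_change,
               1, tolerance = 1e-12)
  up <- junction_intensity_fold_change(1.5 * control, control)
  expect_equal(up$fold_change, 1.5, tolerance = 1e-12)   # ~50% increase (LOF)
  down <- junction_intensity_fold_change(0.75 * control, control)
  expect_equal(down$fold_change, 0.75, tolerance = 1e-12) # ~25% decrease (GOF)
  expect_error(junction_intensity_fold_change(1:2, control), "3 junctions")
  expect_error(junction_intensity_fold_change(control, control - mean(control)),
               "positive")
})
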