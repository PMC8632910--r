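# Rotation/area measurement, logistic fits, pulses, totals, correlation, and
# the two-sample tests.

make_pair_movie <- function(angle2_deg) {
  # R2 and R5 squares rotating about the image center; furrow horizontal
  place <- function(theta_deg) {
    m <- matrix(0L, 70, 70)
    th <- theta_deg * pi / 180
    c2 <- c(35, 35) + 20 * c(-cos(th), -sin(th))  # (x, y), y down
    c5 <- c(35, 35) + 20 * c(cos(th), sin(th))
    put <- function(m, ctr, lab) {
      m[round(ctr[2]) + (-2:2), round(ctr[1]) + (-2:2)] <- lab
      m
    }
    put(put(m, c2, 3L), c5, 6L)
  }
  frames <- list(place(0), place(angle2_deg))
  tracks <- data.frame(frame = rep(0:1, each = 2), label = rep(c(3, 6), 2),
                       cell_id = rep(c(3, 6), 2), parent_id = NA_integer_)
  tissue_movie(frames, tracks, 0.1, 10)
}

pair_annotation <- function() {
  ommatidium_annotation(
    roles = setNames(c("R1", "R2", "R3", "R4", "R5", "R6", "R7", "R8"),
                     as.character(c(2, 3, 4, 5, 6, 7, 8, 1))),
    furrow_axis_deg = 0, r7_frame = 0, chirality = "counterclockwise")
}

test_that("a rigid 30-degree turn between frames measures as delta R = 30", {
  rot <- measure_rotation(make_pair_movie(30), pair_annotation())
  expect_equal(diff(rot$R_deg), 30, tolerance = 0.05)
  still <- measure_rotation(make_pair_movie(0), pair_annotation())
  expect_equal(diff(still$R_deg), 0)
})

test_that("frames with an untracked photoreceptor become gaps, not guesses", {
  mov <- make_pair_movie(30)
  mov$tracks <- mov$tracks[!(mov$tracks$frame == 1 & mov$tracks$cell_id == 6), ]
  rot <- measure_rotation(mov, pair_annotation())
  expect_true(is.na(rot$R_deg[2]))
  expect_false(is.na(rot$R_deg[1]))
})

test_that("noiseless wild-type movie rotation matches its schedule within 1 degree", {
  g <- small_movie(quiet_preset(), n_frames = 12, seed = 3)
  rot <- measure_rotation(g$movie, g$annotation)
  expect_lt(max(abs(rot$R_deg - g$truth$rotation_deg)), 1)
})

test_that("eight unit-square photoreceptors sum to 8 um^2; scaling by half quarters the area", {
  m1 <- matrix(0L, 80, 80)
  m2 <- matrix(0L, 80, 80)
  for (k in 1:8) {
    r0 <- 10 * ((k - 1) %/% 4) + 20; c0 <- 15 * ((k - 1) %% 4) + 10
    m1[r0 + (1:10), c0 + (1:10)] <- k          # 10x10 px = 1 um^2
    m2[r0 + (1:5), c0 + (1:5)] <- k            # linear x0.5 -> area x0.25
  }
  tracks <- data.frame(frame = rep(0:1, each = 8), label = rep(1:8, 2),
                       cell_id = rep(1:8, 2), parent_id = NA_integer_)
  mov <- tissue_movie(list(m1, m2), tracks, 0.1, 10)
  ann <- pair_annotation()
  ar <- measure_area(mov, ann)
  expect_equal(ar$area_um2[1], 8, tolerance = 0.02)
  expect_equal(ar$area_um2[2] / ar$area_um2[1], 0.25, tolerance = 0.02)
})

test_that("noiseless wild-type movie area matches the schedule within 2%", {
  g <- small_movie(quiet_preset(), n_frames = 12, seed = 3)
  ar <- measure_area(g$movie, g$annotation)
  expect_lt(max(abs(ar$area_um2 - g$truth$area_measured_um2) /
                  g$truth$area_measured_um2), 0.02)
})

test_that("alignment shifts t = 0 to R7 recruitment", {
  s <- simulate_rotation_series(noise_sd = 0)
  ann <- pair_annotation(); ann$r7_frame <- 5
  al <- align_at_r7(s, ann)
  expect_equal(al$time_min[al$frame == 5], 0)
  expect_equal(al$time_min[1], -50)
  # aligning two identical series gives identical output
  expect_equal(align_at_r7(s, ann), al)
})

test_that("the constriction-curve estimator recovers a withheld r7 frame", {
  g <- small_movie(quiet_preset(), n_frames = 26, seed = 4)
  blind <- g$annotation
  blind$r7_frame <- NA; blind$r16_frame <- NA
  ar <- measure_area(g$movie, blind)
  al <- align_at_r7(ar)
  expect_lte(abs(attr(al, "r7_frame") - g$truth$r7_frame), 2)
  # monotone-increasing area cannot be aligned
  up <- ar; up$area_um2 <- seq_along(up$area_um2)
  expect_error(align_at_r7(up), "alignment")
})

test_that("noiseless logistic fits recover parameters to 4 significant figures", {
  s <- simulate_rotation_series(noise_sd = 0)
  f <- fit_logistic(s)
  expect_equal(f$amplitude, 90, tolerance = 1e-4)
  expect_equal(f$tau, 60 * 90 / (4 * 11), tolerance = 1e-4)
  expect_equal(f$t0, 250, tolerance = 1e-4)
  expect_equal(f$rate, 11, tolerance = 1e-4)   # deg/h

  sa <- simulate_area_series(noise_sd = 0)
  fa <- fit_logistic(sa)
  expect_equal(fa$amplitude, 12, tolerance = 1e-4)
  expect_equal(fa$baseline, 20, tolerance = 1e-4)
  expect_equal(fa$tau, 72, tolerance = 1e-4)
  expect_equal(fa$rate, 2.5, tolerance = 1e-4)  # um^2/h
  expect_equal(fa$plateau, 8, tolerance = 1e-4)
})

test_that("constant series cannot be fitted (no inflection)", {
  flat <- data.frame(frame = 0:19, time_min = (0:19) * 10, R_deg = rep(5, 20))
  expect_error(fit_logistic(flat, "rotation"), "constant")
  short <- simulate_rotation_series(n_frames = 5, noise_sd = 0)
  expect_error(fit_logistic(short), "8")
})

test_that("noisy ensemble rates stay within 5% of truth", {
  set.seed(11)
  omega <- replicate(11, fit_logistic(simulate_rotation_series(noise_sd = 2))$rate)
  expect_equal(mean(omega), 11, tolerance = 0.05)
  cc <- replicate(11, fit_logistic(simulate_area_series(noise_sd = 0.5))$rate)
  expect_equal(mean(cc), 2.5, tolerance = 0.05)
})

test_that("rate segmentation finds one pulse for monotone rotation and alternates on a sawtooth", {
  s <- new_series <- data.frame(frame = 0:19, time_min = (0:19) * 10,
                                R_deg = seq(0, 57, 3))
  class(s) <- c("rotation_series", "data.frame")
  seg <- rotation_rate(s)
  expect_equal(nrow(seg$segmentation), 1)
  expect_equal(seg$segmentation$class, "pulse")

  saw <- data.frame(frame = 0:23, time_min = (0:23) * 10,
                    R_deg = rep(c(0, 5, 10, 5), 6))
  class(saw) <- c("rotation_series", "data.frame")
  seg2 <- rotation_rate(saw, window = 1)
  cls <- seg2$segmentation$class
  expect_true(all(cls[-1] != cls[-length(cls)]))  # alternation
  expect_gte(sum(cls == "pulse"), 5)
  expect_error(rotation_rate(saw, window = 30), "window")
})

test_that("pulse counts track the modulation period on noiseless schedules", {
  for (P in c(80, 100)) {
    p <- genotype_preset("wild_type", pulse_period_min = P)
    s <- simulate_rotation_series(noise_sd = 0, pulses = TRUE, preset = p)
    seg <- rotation_rate(s)
    n_pulse <- sum(seg$segmentation$class == "pulse")
    expect_lte(abs(n_pulse - 500 / P), 1)
  }
})

test_that("constriction/expansion totals obey their conservation identity", {
  expect_equal(unname(constriction_expansion_totals(c(20, 8))), c(12, 0))
  expect_equal(unname(constriction_expansion_totals(c(20, 18, 19, 8))),
               c(13, 1))
  set.seed(8)
  for (i in 1:20) {
    a <- cumsum(rnorm(30)) + 50
    tot <- constriction_expansion_totals(a)
    expect_equal(tot[["constriction_total"]] - tot[["expansion_total"]],
                 a[1] - a[length(a)])
  }
})

test_that("unstabilized (gof) pulses expand more than wild type", {
  tot <- function(name) {
    s <- simulate_area_series(preset = genotype_preset(name), pulses = TRUE,
                              noise_sd = 0, seed = 7)
    constriction_expansion_totals(s)[["expansion_total"]]
  }
  expect_gt(tot("gof"), tot("wild_type"))
  expect_gt(tot("wild_type"), tot("lof"))
})

test_that("cross-correlation peaks at zero lag for y = x and shifts equivariantly", {
  set.seed(3)
  x <- rnorm(60)
  cc <- cross_correlation(x, x, 8)
  expect_equal(attr(cc, "peak_lag"), 0)
  expect_equal(attr(cc, "peak_correlation"), 1)
  y <- c(rep(0, 3), x)[1:60]
  expect_equal(attr(cross_correlation(x, y, 8), "peak_lag"), 3)
  expect_error(cross_correlation(x, rep(1, 60), 8), "zero-variance")
  expect_error(cross_correlation(x[1:5], x[1:5], 2), "10")
})

test_that("KS statistic equals the brute-force ECDF sweep; degenerate cases hit bounds", {
  expect_equal(ks_statistic(1:5, 1:5)$D, 0)
  expect_equal(ks_statistic(c(0, 0, 0), c(1, 1, 1))$D, 1)
  set.seed(9)
  for (i in 1:25) {
    a <- rnorm(sample(5:40, 1)); b <- rnorm(sample(5:40, 1), sd = 2)
    expect_equal(ks_statistic(a, b)$D, ks_bruteforce(a, b))
  }
  expect_error(ks_statistic(numeric(0), 1:3), "n >= 2")
})

test_that("t test matches the pooled-variance hand formula", {
  a <- c(2, 4, 9); b <- c(1, 3, 5, 7)
  res <- t_test(a, b)
  sp2 <- (2 * var(a) + 3 * var(b)) / 5
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 4))
  expect_equal(res$t, t_hand)
  welch <- t_test(a, b, welch = TRUE)
  expect_false(isTRUE(all.equal(res$p, welch$p)))  # Welch df differs
})
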