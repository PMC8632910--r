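# FRAP trace generation, normalization, and single-exponential recovery fits.
#
# Normalization: I_N(t) = (I(t) - I_min) / (I_max - I_min), with I_max the
# mean pre-bleach intensity and I_min the intensity immediately after
# bleaching, after correcting the ROI by the coefficient of acquisition
# bleaching measured on unbleached reference junctions. The recovery model is
# I_N(t) = A (1 - exp(-k t)) with mobile fraction A and rate k; the recovery
# rate is A * k (the slope at t = 0) and the half recovery time is
# T_1/2 = ln(2) / k.

#' Generate a synthetic FRAP trace with known kinetics
#'
#' Emits `n_prebleach` pre-bleach frames (t < 0) at `i_max`, then a recovery
#' following `i_min + (i_max - i_min) * A (1 - exp(-k t))` from the bleach at
#' t = 0, sampled every `dt_s` seconds. The whole acquisition (ROI and
#' `n_ref` reference junctions) is multiplied by an exponential acquisition-
#' bleaching decay of rate `ref_bleach_rate`, so the reference-based
#' correction in [normalize_frap()] can be exercised against ground truth.
#'
#' @param mobile_fraction Mobile fraction A, in (0, 1].
#' @param k Recovery rate constant, 1/s (> 0).
#' @param i_max,i_min Pre-bleach and immediately-post-bleach intensities
#'   (`i_max > i_min`).
#' @param noise_sd Gaussian intensity noise SD.
#' @param n_points Number of post-bleach points.
#' @param dt_s Sampling interval, seconds (default 20).
#' @param seed Integer seed, or `NULL`.
#' @param n_prebleach Pre-bleach frames (default 5).
#' @param n_ref Number of reference junction traces.
#' @param ref_bleach_rate Acquisition bleaching rate, 1/s (0 disables).
#' @return A `frap_trace` data frame: `time_s`, `roi_intensity`,
#'   `ref_1` ... columns; attribute `truth` records the generating
#'   parameters.
#' @export
generate_frap_trace <- function(mobile_fraction, k, i_max = 100, i_min = 20,
                                noise_sd = 0, n_points = 40, dt_s = 20,
                                seed = NULL, n_prebleach = 5, n_ref = 2,
                                ref_bleach_rate = 0) {
  if (mobile_fraction <= 0 || mobile_fraction > 1) {
    stop("mobile_fraction must be in (0, 1]")
  }
  if (k <= 0) stop("k must be positive")
  if (i_max <= i_min) stop("parameter error: i_max must exceed i_min")
  if (!is.null(seed)) set.seed(seed)
  t <- c(-(n_prebleach:1), 0:(n_points - 1)) * dt_s
  post <- t >= 0
  ideal <- ifelse(post,
                  i_min + (i_max - i_min) * mobile_fraction *
                    (1 - exp(-k * pmax(t, 0))),
                  i_max)
  decay <- exp(-ref_bleach_rate * (t - t[1]))
  roi <- ideal * decay + rnorm(length(t), 0, noise_sd)
  refs <- vapply(seq_len(n_ref), function(j) {
    i_max * decay + rnorm(length(t), 0, noise_sd)
  }, numeric(length(t)))
  colnames(refs) <- paste0("ref_", seq_len(n_ref))
  out <- data.frame(time_s = t, roi_intensity = roi)
  out <- cbind(out, refs)
  structure(out, class = c("frap_trace", "data.frame"),
            truth = list(mobile_fraction = mobile_fraction, k = k,
                         i_max = i_max, i_min = i_min,
                         ref_bleach_rate = ref_bleach_rate))
}

#' Normalize a FRAP trace
#'
#' Corrects the ROI intensity for acquisition bleaching by the coefficient
#' `c(t) = mean_ref(t_first) / mean_ref(t)` (mean over all supplied
#' reference junctions), then applies
#' `I_N(t) = (I(t) - I_min) / (I_max - I_min)` with `I_max` the mean of the
#' corrected pre-bleach frames (t < 0) and `I_min` the corrected intensity
#' at the first post-bleach frame.
#'
#' @param trace A `frap_trace` (columns `time_s`, `roi_intensity`, and at
#'   least one `ref_*` column).
#' @return The trace with an `i_n` column filled for t >= 0 and attributes
#'   `i_max`, `i_min`.
#' @export
normalize_frap <- function(trace) {
  refs <- as.matrix(trace[, grep("^ref_", names(trace)), drop = FALSE])
  if (!ncol(refs)) stop("at least one reference trace is required")
  mref <- rowMeans(refs)
  if (any(mref <= 0)) stop("correction error: non-positive reference intensity")
  corr <- trace$roi_intensity * (mref[1] / mref)
  pre <- trace$time_s < 0
  if (!any(pre)) stop("no pre-bleach frames (t < 0) found")
  i_max <- mean(corr[pre])
  first_post <- which(trace$time_s >= 0)[1]
  i_min <- corr[first_post]
  if (abs(i_max - i_min) < 1e-12) stop("degenerate trace: I_max equals I_min")
  out <- trace
  out$corrected <- corr
  out$i_n <- ifelse(trace$time_s >= 0, (corr - i_min) / (i_max - i_min),
                    NA_real_)
  attr(out, "i_max") <- i_max
  attr(out, "i_min") <- i_min
  out
}

#' Fit the single-exponential FRAP recovery model
#'
#' Least-squares fit of `I_N(t) = A (1 - exp(-k t))` to the normalized
#' post-bleach trace (Levenberg-Marquardt). Initialization: A from the last
#' normalized value, k from a log-linear regression of `A - I_N`. Mobile
#' fractions slightly above 1 (<= 1.2) are tolerated to absorb normalization
#' noise, with a warning.
#'
#' @param trace A `frap_trace`; [normalize_frap()] is applied first when the
#'   `i_n` column is missing.
#' @return Object of class `frap_fit`: `mobile_fraction`, `k`,
#'   `recovery_rate` (= A k, the fitted slope at t = 0), `half_time_s`
#'   (= ln 2 / k), `rms_residual`, `n`.
#' @export
fit_frap <- function(trace) {
  if (!"i_n" %in% names(trace)) trace <- normalize_frap(trace)
  post <- trace$time_s >= 0 & is.finite(trace$i_n)
  t <- trace$time_s[post]
  y <- trace$i_n[post]
  if (length(t) < 6) stop("need at least 6 post-bleach points")
  a0 <- max(tail(y, 3))
  a0 <- min(max(a0, 0.05), 1.2)
  pos <- which(a0 + 0.05 - y > 1e-9 & t > 0)
  k0 <- if (length(pos) >= 2) {
    sl <- coef(lm(log(a0 + 0.05 - y[pos]) ~ t[pos]))[2]
    max(-sl, 1e-5)
  } else 1 / max(t)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * (1 - exp(-k * t)), data = data.frame(t = t, y = y),
      start = list(A = a0, k = unname(k0)),
      lower = c(1e-6, 1e-8), upper = c(1.2, 100),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e) stop("fit_frap() did not converge: ",
                             conditionMessage(e)))
  p <- coef(fit)
  A <- unname(p["A"]); k <- unname(p["k"])
  if (A > 1) warning("mobile fraction > 1 (", signif(A, 3),
                     "); normalization noise?")
  if (k >= 100 - 1e-6 || k <= 2e-8) {
    stop("fit error: rate constant at bound")
  }
  res <- y - predict(fit)
  structure(list(mobile_fraction = A, k = k, recovery_rate = A * k,
                 half_time_s = log(2) / k,
                 rms_residual = sqrt(mean(res^2)), n = length(t)),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat("<frap_fit>\n")
  cat(sprintf("  mobile fraction %.4g, k %.4g /s\n", x$mobile_fraction, x$k))
  cat(sprintf("  recovery rate %.4g /s, T1/2 %.4g s (n = %d, rms %.3g)\n",
              x$recovery_rate, x$half_time_s, x$n, x$rms_residual))
  invisible(x)
}

#' Junction intensity fold change relative to a control group
#'
#' Divides each test-junction intensity by the control-group mean and
#' reports the mean and SD of the ratios, the convention for comparing
#' steady-state junctional E-cadherin levels between a perturbed clone and
#' its neighboring control tissue.
#'
#' @param test_intensities,control_intensities Numeric vectors (>= 3
#'   junctions each).
#' @return Named list `fold_change`, `sd`, `n`.
#' @export
junction_intensity_fold_change <- function(test_intensities,
                                           control_intensities) {
  if (length(test_intensities) < 3 || length(control_intensities) < 3) {
    stop("need at least 3 junctions per group")
  }
  m <- mean(control_intensities)
  if (m <= 0) stop("control mean must be positive")
  ratios <- test_intensities / m
  list(fold_change = mean(ratios), sd = sd(ratios), n = length(ratios))
}
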