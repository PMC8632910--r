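# Laser-ablation recoil traces and exponential recoil fits.
#
# After ablation the distance l(t) between the two vertices of the severed
# junction is tracked; the normalized recoil is (l(t) - l0)/l0. For elastic
# tissue the rise L = l_f (1 - exp(-t/T)) is fitted; the initial recoil
# speed is l_f / T and the recoil amplitude is l_f. Viscoelastic tissue
# (rise followed by resorption of the opened gap) is flagged as unfittable
# rather than forced through the exponential.

#' Generate a synthetic ablation recoil trace
#'
#' Elastic mode: `l(t) = l0 + l_f (1 - exp(-t/T))`. Viscoelastic mode: the
#' same rise multiplied by a decaying envelope `exp(-t/envelope_tau_s)`, so
#' the vertex distance peaks and then returns toward `l0`, emulating
#' junction reformation and shrinkage.
#'
#' @param l0_um Pre-ablation junction length, um (> 0).
#' @param lf_um Recoil amplitude l_f, um.
#' @param T_s Recoil timescale, seconds (> 0).
#' @param mode `"elastic"` or `"viscoelastic"`.
#' @param noise_sd Gaussian noise SD on the distance, um.
#' @param n_points Number of samples.
#' @param dt_s Sampling interval, seconds (default 2).
#' @param seed Integer seed, or `NULL`.
#' @param envelope_tau_s Resorption timescale of the viscoelastic envelope.
#' @return A `recoil_trace` data frame (`time_s`, `vertex_distance_um`) with
#'   attributes `l0_um`, `mode`, `truth`.
#' @export
generate_recoil_trace <- function(l0_um, lf_um, T_s,
                                  mode = c("elastic", "viscoelastic"),
                                  noise_sd = 0, n_points = 60, dt_s = 2,
                                  seed = NULL, envelope_tau_s = 5 * T_s) {
  mode <- match.arg(mode)
  if (l0_um <= 0) stop("l0_um must be positive")
  if (T_s <= 0) stop("parameter error: T_s must be positive")
  if (!is.null(seed)) set.seed(seed)
  t <- (seq_len(n_points) - 1) * dt_s
  rise <- lf_um * (1 - exp(-t / T_s))
  l <- if (mode == "elastic") l0_um + rise else
    l0_um + rise * exp(-t / envelope_tau_s)
  l <- l + rnorm(n_points, 0, noise_sd)
  structure(data.frame(time_s = t, vertex_distance_um = l),
            class = c("recoil_trace", "data.frame"),
            l0_um = l0_um, mode = mode,
            truth = list(lf_um = lf_um, T_s = T_s,
                         envelope_tau_s = envelope_tau_s))
}

#' Fit the exponential recoil model to an ablation trace
#'
#' Computes the normalized recoil `(l(t) - l0)/l0` and fits
#' `L(t) = l_f (1 - exp(-t/T))` to the vertex-distance increase by
#' Levenberg-Marquardt least squares. Before fitting, the trace is screened
#' for the viscoelastic signature: if the (median-smoothed) recoil peaks and
#' then drops by more than `resorption_frac` (default 20%) of the peak, the
#' exponential model is rejected (`fit_ok = FALSE`) and the parameters are
#' returned as `NA`. A flat trace yields a degenerate fit with amplitude 0,
#' also flagged.
#'
#' @param trace A `recoil_trace`, or any data frame with `time_s` and
#'   `vertex_distance_um`.
#' @param l0_um Pre-ablation junction length; defaults to the trace
#'   attribute.
#' @param resorption_frac Peak-to-end drop (fraction of peak) above which
#'   the exponential is rejected.
#' @return Object of class `recoil_fit`: `lf_um`, `T_s`, `initial_speed_um_s`
#'   (= l_f/T), `amplitude_um` (= l_f), `fit_ok`, `degenerate`,
#'   `rms_residual`.
#' @export
fit_recoil <- function(trace, l0_um = NULL, resorption_frac = 0.2) {
  l0 <- l0_um %||% attr(trace, "l0_um")
  if (is.null(l0)) stop("pre-ablation length l0_um is missing")
  t <- trace$time_s
  l <- trace$vertex_distance_um
  if (length(t) < 5) stop("need at least 5 points")
  r <- (l - l0) / l0
  sm <- if (length(r) >= 7) stats::runmed(r, 5) else r
  peak_i <- which.max(sm)
  peak <- sm[peak_i]
  rng <- diff(range(l))
  degenerate <- rng < max(1e-9, 1e-6 * l0)
  if (degenerate) {
    return(structure(list(lf_um = 0, T_s = NA_real_,
                          initial_speed_um_s = NA_real_, amplitude_um = 0,
                          fit_ok = FALSE, degenerate = TRUE,
                          rms_residual = 0), class = "recoil_fit"))
  }
  resorbed <- peak > 0 && peak_i < length(sm) &&
    (peak - sm[length(sm)]) > resorption_frac * peak
  if (resorbed) {
    return(structure(list(lf_um = NA_real_, T_s = NA_real_,
                          initial_speed_um_s = NA_real_,
                          amplitude_um = NA_real_, fit_ok = FALSE,
                          degenerate = FALSE, rms_residual = NA_real_),
                     class = "recoil_fit"))
  }
  dl <- l - l0
  fit <- tryCatch(
    minpack.lm::nlsLM(
      dl ~ lf * (1 - exp(-t / Tc)), data = data.frame(t = t, dl = dl),
      start = list(lf = max(dl), Tc = max(t[2], max(t) / 10)),
      lower = c(0, 1e-6), upper = c(10 * max(abs(dl)) + 1e-6, 100 * max(t)),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e) stop("fit_recoil() did not converge: ",
                             conditionMessage(e)))
  p <- coef(fit)
  lf <- unname(p["lf"]); Tc <- unname(p["Tc"])
  res <- dl - predict(fit)
  structure(list(lf_um = lf, T_s = Tc, initial_speed_um_s = lf / Tc,
                 amplitude_um = lf, fit_ok = TRUE, degenerate = FALSE,
                 rms_residual = sqrt(mean(res^2))),
            class = "recoil_fit")
}

#' @export
print.recoil_fit <- function(x, ...) {
  cat("<recoil_fit>\n")
  if (!x$fit_ok) {
    cat(if (x$degenerate) "  degenerate (flat) trace; amplitude 0\n" else
      "  exponential rejected: viscoelastic (resorbing) recoil profile\n")
    return(invisible(x))
  }
  cat(sprintf("  amplitude l_f %.4g um, T %.4g s, initial speed %.4g um/s\n",
              x$amplitude_um, x$T_s, x$initial_speed_um_s))
  invisible(x)
}
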