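# Three-parameter logistic fits for rotation and apical-area trajectories.
#
# The sigmoid family is fixed as the logistic because the rate conventions
# rate = 60 * amplitude / (4 * tau) (deg/h or um^2/h) equal the logistic's
# maximum slope amplitude/(4 tau) rescaled from minutes to hours; no other
# common sigmoid has that identity.

#' Fit a three-parameter logistic to a rotation or area trajectory
#'
#' Rotation series are fitted as R(t) = amplitude / (1 + exp(-(t - t0)/tau));
#' area series as A(t) = A0 - A1 / (1 + exp(-(t - t0)/tau)) (four parameters,
#' including the baseline A0). Fitting is Levenberg-Marquardt least squares
#' with data-driven initialization (range for the amplitude, mid-crossing for
#' t0, span/8 for tau) and box bounds: tau in (0, 4 x span], amplitude in
#' [0, 2 x data range].
#'
#' @param series A `rotation_series` or `area_series` (or any data frame with
#'   a `time_min` column and a value column named `R_deg` or `area_um2`).
#' @param kind `"rotation"` or `"area"`; inferred from the class/columns when
#'   missing.
#' @param nominal_amplitude Amplitude used for the conventional rate
#'   `rate_nominal = 60 * nominal_amplitude / (4 * tau)`; defaults to the
#'   full 90-degree turn for rotation and to the fitted amplitude for area.
#' @return An object of class `logistic_fit` with fields `kind`, `amplitude`,
#'   `baseline` (0 for rotation), `t0`, `tau`, `rate`
#'   (= 60 x amplitude / (4 tau)), `rate_nominal`, `plateau` (area fits:
#'   baseline - amplitude), `rms_residual`, `tau_at_bound`, `n`.
#' @export
fit_logistic <- function(series, kind = NULL,
                         nominal_amplitude = NULL) {
  kind <- kind %||% infer_series_kind(series)
  kind <- match.arg(kind, c("rotation", "area"))
  t <- series$time_min
  y <- if (kind == "rotation") series$R_deg else series$area_um2
  keep <- is.finite(t) & is.finite(y)
  t <- t[keep]; y <- y[keep]
  if (length(t) < 8) {
    stop("fit_logistic() needs at least 8 finite time points")
  }
  rng <- diff(range(y))
  if (rng < 1e-8 || sd(y) < 1e-8) {
    stop("fit_logistic(): series is constant; no inflection to fit")
  }
  span <- diff(range(t))
  mid <- min(y) + rng / 2
  t0_init <- t[which.min(abs(y - mid))]
  tau_init <- span / 8
  df <- data.frame(t = t, y = y)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14, ptol = 1e-14)

  if (kind == "rotation") {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A / (1 + exp(-(t - b) / tau)), data = df,
        start = list(A = max(y), b = t0_init, tau = tau_init),
        lower = c(0, min(t) - 2 * span, 1e-6),
        upper = c(2 * rng + 2 * abs(min(y)), max(t) + 2 * span, 4 * span),
        control = ctrl),
      error = function(e) stop("fit_logistic() did not converge: ",
                               conditionMessage(e)))
    p <- coef(fit)
    amplitude <- unname(p["A"]); baseline <- 0
  } else {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a0 - a1 / (1 + exp(-(t - b) / tau)), data = df,
        start = list(a0 = max(y), a1 = rng, b = t0_init, tau = tau_init),
        lower = c(0, 0, min(t) - 2 * span, 1e-6),
        upper = c(2 * max(y), 2 * rng, max(t) + 2 * span, 4 * span),
        control = ctrl),
      error = function(e) stop("fit_logistic() did not converge: ",
                               conditionMessage(e)))
    p <- coef(fit)
    amplitude <- unname(p["a1"]); baseline <- unname(p["a0"])
  }
  tau <- unname(p["tau"]); t0 <- unname(p["b"])
  tau_at_bound <- tau >= 4 * span - 1e-6 || tau <= 2e-6
  if (tau_at_bound) {
    warning("fit_logistic(): tau is at its bound; fit may be degenerate")
  }
  nominal <- nominal_amplitude %||% if (kind == "rotation") 90 else amplitude
  res <- y - predict(fit)
  structure(list(
    kind = kind,
    amplitude = amplitude,
    baseline = baseline,
    t0 = t0,
    tau = tau,
    rate = 60 * amplitude / (4 * tau),
    rate_nominal = 60 * nominal / (4 * tau),
    plateau = if (kind == "area") baseline - amplitude else NA_real_,
    rms_residual = sqrt(mean(res^2)),
    tau_at_bound = tau_at_bound,
    n = length(t)
  ), class = "logistic_fit")
}

infer_series_kind <- function(series) {
  if (inherits(series, "rotation_series") || "R_deg" %in% names(series)) {
    "rotation"
  } else if (inherits(series, "area_series") || "area_um2" %in% names(series)) {
    "area"
  } else {
    stop("cannot infer series kind; pass kind = 'rotation' or 'area'")
  }
}

#' @export
print.logistic_fit <- function(x, ...) {
  unit <- if (x$kind == "rotation") c("deg", "deg/h") else c("um^2", "um^2/h")
  cat(sprintf("<logistic_fit: %s>\n", x$kind))
  cat(sprintf("  amplitude %.4g %s, t0 %.4g min, tau %.4g min\n",
              x$amplitude, unit[1], x$t0, x$tau))
  if (x$kind == "area") {
    cat(sprintf("  baseline %.4g um^2, plateau %.4g um^2\n",
                x$baseline, x$plateau))
  }
  cat(sprintf("  rate %.4g %s (nominal %.4g), rms residual %.3g, n = %d\n",
              x$rate, unit[2], x$rate_nominal, x$rms_residual, x$n))
  invisible(x)
}
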