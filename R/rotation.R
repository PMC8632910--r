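# Rotation and apical-area measurement, temporal alignment, rate/pulse
# segmentation, cross-correlation, and the two small distribution tests.

#' Measure cluster rotation from a tracked movie
#'
#' Per frame, the signed angle (degrees) between the R2 -> R5 centroid line
#' and the morphogenetic-furrow axis, unwrapped across frames (no +-180 deg
#' jumps) and signed so rotation along the annotated chirality is positive.
#' Frames in which R2 or R5 is untracked are recorded as gaps (`NA`); no
#' interpolation is performed.
#'
#' @param movie A [tissue_movie()].
#' @param annotation An [ommatidium_annotation()] naming R2 and R5.
#' @return A `rotation_series` data frame (`frame`, `time_min`, `R_deg`,
#'   `normalized` = R/90).
#' @export
measure_rotation <- function(movie, annotation) {
  r2 <- role_cell(annotation, "R2")
  r5 <- role_cell(annotation, "R5")
  if (is.na(r2) || is.na(r5)) stop("annotation must assign R2 and R5")
  nf <- n_frames(movie)
  ang <- rep(NA_real_, nf)
  for (f in seq_len(nf) - 1L) {
    p2 <- cell_centroid_at(movie, f, r2)
    p5 <- cell_centroid_at(movie, f, r5)
    if (anyNA(c(p2, p5))) next
    # y-down image coordinates; angle of the directed R2 -> R5 line
    ang[f + 1L] <- atan2(p5[2] - p2[2], p5[1] - p2[1]) * 180 / pi
  }
  sgn <- if (annotation$chirality == "clockwise") -1 else 1
  rel <- sgn * (ang - annotation$furrow_axis_deg)
  rel <- unwrap_degrees(rel)
  new_rotation_series((seq_len(nf) - 1L) * movie$frame_interval_min, rel,
                      frame = seq_len(nf) - 1L,
                      frame_interval_min = movie$frame_interval_min)
}

# remove 360-degree wraps between consecutive finite observations
unwrap_degrees <- function(a) {
  ok <- which(is.finite(a))
  if (length(ok) < 2) return(a)
  for (k in seq_along(ok)[-1]) {
    i <- ok[k - 1]; j <- ok[k]
    d <- a[j] - a[i]
    a[j] <- a[j] - 360 * round(d / 360)
  }
  a
}

#' Measure combined apical area of the photoreceptor cluster
#'
#' Sums the polygon areas of the recruited R cells per frame. Before R1/R6
#' (resp. R7) recruitment, only the cells recruited so far contribute, as
#' given by the annotation's `r16_frame` / `r7_frame`. Frames with a missing
#' recruited R cell are recorded as gaps.
#'
#' @inheritParams measure_rotation
#' @return An `area_series` data frame (`frame`, `time_min`, `area_um2`,
#'   `constriction` = 1 - A/A0 with A0 the first finite area).
#' @export
measure_area <- function(movie, annotation) {
  rroles <- paste0("R", 1:8)
  ids <- vapply(rroles, function(r) role_cell(annotation, r), integer(1))
  nf <- n_frames(movie)
  area <- rep(NA_real_, nf)
  for (f in seq_len(nf) - 1L) {
    recruited <- rroles
    if (!is.na(annotation$r16_frame) && f < annotation$r16_frame) {
      recruited <- setdiff(recruited, c("R1", "R6", "R7"))
    } else if (!is.na(annotation$r7_frame) && f < annotation$r7_frame) {
      recruited <- setdiff(recruited, "R7")
    }
    geom <- build_cell_graph(movie, f)
    a <- 0; ok <- TRUE
    for (r in recruited) {
      row <- geom$cells[geom$cells$cell_id == ids[[r]], ]
      if (!nrow(row)) { ok <- FALSE; break }
      a <- a + row$area_um2
    }
    if (ok) area[f + 1L] <- a
  }
  new_area_series((seq_len(nf) - 1L) * movie$frame_interval_min, area,
                  frame = seq_len(nf) - 1L,
                  frame_interval_min = movie$frame_interval_min)
}

#' Align a series so t = 0 at R7 recruitment
#'
#' If the annotation's `r7_frame` is known, time is shifted so that frame is
#' t = 0. Otherwise the recruitment frame is estimated from the constriction
#' curve as the first frame whose area falls below `frac` (default 0.85) of
#' the mean over the first three frames -- the same stand-in used for
#' clusters whose R7 joined before acquisition.
#'
#' @param series A `rotation_series` or `area_series`.
#' @param annotation Optional [ommatidium_annotation()] with `r7_frame`.
#' @param area_series Area series used for estimation when `r7_frame` is
#'   unknown (an `area_series` passed as `series` is used directly).
#' @param frac Fraction of the initial area that marks recruitment.
#' @return The series with `time_min` shifted (attribute `r7_frame` records
#'   the frame used).
#' @export
align_at_r7 <- function(series, annotation = NULL, area_series = NULL,
                        frac = 0.85) {
  r7 <- if (!is.null(annotation) && !is.na(annotation$r7_frame)) {
    annotation$r7_frame
  } else {
    ref <- area_series %||% series
    if (!("area_um2" %in% names(ref))) {
      stop("r7_frame unknown and no area series available for estimation")
    }
    estimate_r7_frame(ref, frac)
  }
  shift <- series$time_min[match(r7, series$frame)]
  if (is.na(shift)) stop("r7 frame not present in series")
  out <- series
  out$time_min <- out$time_min - shift
  attr(out, "r7_frame") <- r7
  out
}

estimate_r7_frame <- function(area_series, frac = 0.85) {
  a <- area_series$area_um2
  base <- mean(head(a[is.finite(a)], 3))
  idx <- which(is.finite(a) & a < frac * base)
  idx <- idx[idx > 3]  # recruitment cannot precede the baseline window
  if (!length(idx)) {
    stop("alignment error: area never falls below ", frac,
         " of its initial level")
  }
  area_series$frame[idx[1]]
}

#' Rotation rate and pulse segmentation
#'
#' Computes dR/dt by centered finite differences (one-sided at the ends),
#' smooths it with a centered moving average (default window 3 frames), and
#' partitions the series into maximal runs of positive smoothed rate
#' ("pulse") alternating with non-positive runs ("anti").
#'
#' @param series A `rotation_series`.
#' @param window Moving-average window in frames (odd; default 3).
#' @return List with `rate` (data frame `frame`, `time_min`,
#'   `dRdt_deg_min`, `smoothed`) and `segmentation` (data frame
#'   `start_frame`, `end_frame`, `class`), class `pulse_segmentation`.
#' @export
rotation_rate <- function(series, window = 3) {
  n <- nrow(series)
  if (n < 3) stop("need at least 3 points")
  if (window >= n) stop("window must be shorter than the series")
  t <- series$time_min
  y <- series$R_deg %||% series[[3]]
  d <- rep(NA_real_, n)
  d[1] <- (y[2] - y[1]) / (t[2] - t[1])
  d[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  sm <- moving_average(d, window)
  cls <- ifelse(sm > 0, "pulse", "anti")
  runs <- rle(cls)
  ends <- cumsum(runs$lengths)
  starts <- c(1, head(ends, -1) + 1)
  seg <- data.frame(start_frame = series$frame[starts],
                    end_frame = series$frame[ends],
                    class = runs$values)
  structure(list(
    rate = data.frame(frame = series$frame, time_min = t,
                      dRdt_deg_min = d, smoothed = sm),
    segmentation = seg), class = "pulse_segmentation")
}

moving_average <- function(x, window) {
  if (window <= 1) return(x)
  half <- window %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Total constriction and expansion of an area series
#'
#' Sums |dA| over frame pairs with decreasing area (constriction) and dA over
#' frame pairs with increasing area (expansion). The two totals satisfy
#' `constriction - expansion = A_first - A_last` exactly.
#'
#' @param series An `area_series` (or numeric vector of areas).
#' @return Named numeric vector `c(constriction_total, expansion_total)`,
#'   um^2.
#' @export
constriction_expansion_totals <- function(series) {
  a <- if (is.numeric(series)) series else series$area_um2
  a <- a[is.finite(a)]
  if (length(a) < 2) stop("need at least 2 points")
  d <- diff(a)
  c(constriction_total = sum(-d[d < 0]), expansion_total = sum(d[d > 0]))
}

#' Normalized cross-correlation between two series at integer lags
#'
#' Both series are z-scored; the correlation at lag `l` is the Pearson
#' correlation between `x[t]` and `y[t + l]` over the overlapping window.
#' Positive peak lag means `y` lags behind `x`.
#'
#' @param x,y Equal-length numeric vectors or series data frames (the value
#'   column is the third column).
#' @param max_lag Maximum |lag| in frames.
#' @return Data frame (`lag`, `correlation`) with attributes `peak_lag` and
#'   `peak_correlation`.
#' @export
cross_correlation <- function(x, y, max_lag = 10) {
  vx <- if (is.numeric(x)) x else x[[3]]
  vy <- if (is.numeric(y)) y else y[[3]]
  if (length(vx) != length(vy)) stop("series must have equal length")
  n <- length(vx)
  if (n < 10) stop("need at least 10 overlapping points")
  if (sd(vx) < 1e-12 || sd(vy) < 1e-12) {
    stop("undefined correlation: zero-variance series")
  }
  vx <- (vx - mean(vx)) / sd(vx)
  vy <- (vy - mean(vy)) / sd(vy)
  lags <- seq(-max_lag, max_lag)
  r <- vapply(lags, function(l) {
    if (l >= 0) {
      xs <- vx[seq_len(n - l)]; ys <- vy[seq_len(n - l) + l]
    } else {
      xs <- vx[seq_len(n + l) - l]; ys <- vy[seq_len(n + l)]
    }
    if (length(xs) < 3 || sd(xs) < 1e-12 || sd(ys) < 1e-12) return(NA_real_)
    cor(xs, ys)
  }, numeric(1))
  out <- data.frame(lag = lags, correlation = r)
  peak <- which.max(r)
  attr(out, "peak_lag") <- lags[peak]
  attr(out, "peak_correlation") <- r[peak]
  out
}

#' Two-sample distribution tests
#'
#' Thin wrappers over [stats::ks.test()] (two-sided, asymptotic p) and
#' [stats::t.test()] (two-tailed; Student by default, Welch optional), the
#' conventions used for comparing per-ommatidium angle and shape
#' distributions between genotypes.
#'
#' @param sample1,sample2 Numeric samples (n >= 2 each).
#' @return `ks_statistic()`: named list `D`, `p`. `t_test()`: named list
#'   `t`, `p`.
#' @export
ks_statistic <- function(sample1, sample2) {
  if (length(sample1) < 2 || length(sample2) < 2) {
    stop("both samples need n >= 2")
  }
  res <- suppressWarnings(ks.test(sample1, sample2, exact = FALSE))
  list(D = unname(res$statistic), p = res$p.value)
}

#' @rdname ks_statistic
#' @param welch Use the Welch unequal-variance variant.
#' @export
t_test <- function(sample1, sample2, welch = FALSE) {
  if (length(sample1) < 2 || length(sample2) < 2) {
    stop("both samples need n >= 2")
  }
  res <- t.test(sample1, sample2, var.equal = !welch)
  list(t = unname(res$statistic), p = res$p.value)
}
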