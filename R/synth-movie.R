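# Synthetic tracked-tissue movies with known ground truth.
#
# The phantom is kinematic: an 8-cell photoreceptor cluster occupies a disk
# whose total area follows the preset's constriction schedule A*(t) and whose
# internal sector boundaries rotate rigidly by the rotation schedule R*(t)
# (logistic plus pulsatile modulation); interommatidial cells are the Voronoi
# cells of seed points on a jittered hexagonal lattice performing seeded
# random walks. Every frame is rendered to an integer label image, so the
# whole measurement pipeline (tracking table included) can be exercised
# against the generating schedules.

#' Generate a synthetic tracked tissue movie with ground truth
#'
#' @param preset A [genotype_preset()].
#' @param n_frames Number of frames (>= 3), spaced `frame_interval_min` apart.
#' @param seed Integer RNG seed (fixed; identical inputs give bit-identical
#'   movies).
#' @param field_um Side of the square field, microns.
#' @param pixel_size_um Rasterization pixel size, microns/px (small enough
#'   that geometric error is well below measurement tolerances).
#' @param frame_interval_min Frame spacing, minutes (default 10).
#' @param ic_spacing_um Hexagonal lattice spacing of interommatidial seeds.
#' @param noise Apply the preset's Gaussian angle/area noise to the rendered
#'   schedules (`TRUE`) or render the noiseless schedules (`FALSE`).
#'
#' @return List with elements `movie` (a [tissue_movie()]), `annotation`
#'   (an [ommatidium_annotation()]; `first_level_ics` frozen at the
#'   R7-recruitment frame), and `truth`: list with the realized per-frame
#'   `rotation_deg` and cluster-disk `area_um2` schedules, the
#'   recruitment-adjusted `area_measured_um2` expected from [measure_area()],
#'   `ic_positions` (array n_ic x 2 x n_frames of seed trajectories, um),
#'   `r7_frame`, `r16_frame`, and the `preset`.
#'
#' @details Cell ids: 1 = R8 (central disk), 2..8 = R1..R7 (annulus sectors),
#'   9+ = interommatidial cells. R7-recruitment is defined on the
#'   constriction curve itself (first frame with A*(t) below 0.85 of its
#'   initial three-frame mean; R1/R6 at the 0.95 crossing), matching how
#'   recruitment is estimated from data when unobserved.
#' @export
generate_tissue_movie <- function(preset = genotype_preset("wild_type"),
                                  n_frames = 31, seed = 1,
                                  field_um = 16, pixel_size_um = 0.05,
                                  frame_interval_min = 10,
                                  ic_spacing_um = 1.9, noise = FALSE) {
  if (n_frames < 3) stop("n_frames must be >= 3")
  if (pixel_size_um <= 0) stop("pixel size must be positive")
  if (frame_interval_min <= 0) stop("frame interval must be positive")
  validate_preset(preset)
  set.seed(seed)

  t <- (seq_len(n_frames) - 1) * frame_interval_min
  rot <- rotation_schedule(t, preset$rotation_amplitude_deg,
                           preset$rotation_t0_min, preset$rotation_tau_min,
                           preset$pulse_amplitude, preset$pulse_period_min)
  area <- area_schedule(t, preset$area_baseline_um2, preset$area_amplitude_um2,
                        preset$area_t0_min, preset$area_tau_min,
                        preset$area_pulse_amplitude, preset$pulse_period_min)
  if (noise) {
    rot <- rot + rnorm(n_frames, 0, preset$noise_sd_deg)
    area <- pmax(area + rnorm(n_frames, 0, preset$noise_sd_um2),
                 0.2 * preset$area_baseline_um2)
  }

  r_max <- sqrt(max(area) / pi)
  if (2 * (r_max + ic_spacing_um) > field_um) {
    stop("geometry error: cluster does not fit in the field")
  }
  center <- c(field_um, field_um) / 2

  # recruitment defined on the noiseless constriction curve
  sched <- area_schedule(t, preset$area_baseline_um2, preset$area_amplitude_um2,
                         preset$area_t0_min, preset$area_tau_min, 0,
                         preset$pulse_period_min)
  base0 <- mean(sched[1:3])
  first_below <- function(frac) {
    i <- which(sched < frac * base0)
    if (length(i)) i[1] - 1L else 0L
  }
  r7_frame <- first_below(0.85)
  r16_frame <- min(first_below(0.95), r7_frame)

  # interommatidial seeds: jittered hex lattice outside the cluster footprint
  ic0 <- hex_lattice(field_um, ic_spacing_um)
  keep <- sqrt(rowSums((ic0 - matrix(center, nrow(ic0), 2, byrow = TRUE))^2)) >
    r_max + 0.6 * ic_spacing_um
  ic0 <- ic0[keep, , drop = FALSE]
  ic0 <- ic0 + matrix(runif(length(ic0), -0.2, 0.2) * ic_spacing_um,
                      nrow(ic0), 2)
  n_ic <- nrow(ic0)
  ic_pos <- array(0, c(n_ic, 2, n_frames))
  ic_pos[, , 1] <- ic0
  if (n_frames > 1) {
    for (f in 2:n_frames) {
      step <- matrix(rnorm(2 * n_ic, 0, preset$ic_motility_um_per_frame),
                     n_ic, 2)
      p <- ic_pos[, , f - 1] + step
      # keep seeds out of the cluster footprint and inside the field
      d <- sqrt(rowSums((p - matrix(center, n_ic, 2, byrow = TRUE))^2))
      lim <- r_max + 0.3 * ic_spacing_um
      too_close <- d < lim
      if (any(too_close)) {
        scl <- lim / d[too_close]
        p[too_close, ] <- matrix(center, sum(too_close), 2, byrow = TRUE) +
          (p[too_close, , drop = FALSE] -
             matrix(center, sum(too_close), 2, byrow = TRUE)) * scl
      }
      p <- pmin(pmax(p, 0.1), field_um - 0.1)
      ic_pos[, , f] <- p
    }
  }

  chir_sign <- if (preset$chirality == "clockwise") -1 else 1
  furrow <- 0
  sector_w <- 360 / 7

  npx <- round(field_um / pixel_size_um)
  xs <- (matrix(seq_len(npx), npx, npx, byrow = TRUE) - 0.5) * pixel_size_um
  ys <- (matrix(seq_len(npx), npx, npx) - 0.5) * pixel_size_um
  dx <- xs - center[1]; dy <- ys - center[2]
  r_px <- sqrt(dx^2 + dy^2)
  ang_px <- atan2(dy, dx) * 180 / pi

  frames <- vector("list", n_frames)
  tracks <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    r_cl <- sqrt(area[f] / pi)
    # sector mid-angle bookkeeping: the directed R2 -> R5 centroid line must
    # sit at furrow + chirality * R(t)
    base <- furrow - 90 - 2.5 * sector_w + chir_sign * rot[f]
    lab <- matrix(0L, npx, npx)
    inside <- r_px <= r_cl
    lab[inside & r_px <= 0.4 * r_cl] <- 1L  # R8
    ring <- inside & r_px > 0.4 * r_cl
    sector <- 1L + as.integer(floor(((ang_px - (base - sector_w / 2)) %% 360) /
                                      sector_w))
    sector[sector > 7L] <- 7L
    lab[ring] <- 1L + sector[ring]          # R1..R7 -> ids 2..8
    out <- !inside
    nearest <- nearest_seed(xs, ys, ic_pos[, , f])
    lab[out] <- 8L + nearest[out]           # ICs -> ids 9+
    frames[[f]] <- lab
    ids <- sort(setdiff(unique(as.vector(lab)), 0L))
    tracks[[f]] <- data.frame(frame = f - 1L, label = ids, cell_id = ids,
                              parent_id = NA_integer_)
  }
  movie <- tissue_movie(frames, do.call(rbind, tracks), pixel_size_um,
                        frame_interval_min)

  # roles and first-level ICs (frozen at r7_frame)
  ic_ids <- sort(setdiff(unique(unlist(lapply(frames, function(m)
    unique(as.vector(m))))), 0:8))
  roles <- stats::setNames(c("R8", paste0("R", 1:7),
                             rep("IC", length(ic_ids))),
                           c(1:8, ic_ids))
  adj <- label_adjacency(frames[[r7_frame + 1L]])
  touches_r <- adj[adj[, 1] %in% 1:8 | adj[, 2] %in% 1:8, , drop = FALSE]
  first_level <- sort(setdiff(unique(as.vector(touches_r)), 1:8))
  annotation <- ommatidium_annotation(
    roles = roles, furrow_axis_deg = furrow, r7_frame = r7_frame,
    chirality = preset$chirality, first_level_ics = first_level,
    r16_frame = r16_frame)

  sector_frac <- (1 - 0.4^2) / 7
  frac <- ifelse(seq_len(n_frames) - 1L < r16_frame, 1 - 3 * sector_frac,
                 ifelse(seq_len(n_frames) - 1L < r7_frame,
                        1 - sector_frac, 1))
  truth <- list(rotation_deg = rot, area_um2 = area,
                area_measured_um2 = area * frac,
                ic_positions = ic_pos, r7_frame = r7_frame,
                r16_frame = r16_frame, preset = preset)
  list(movie = movie, annotation = annotation, truth = truth)
}

hex_lattice <- function(field_um, spacing) {
  dy <- spacing * sqrt(3) / 2
  rows <- seq(0.4 * spacing, field_um, by = dy)
  pts <- lapply(seq_along(rows), function(i) {
    off <- if (i %% 2 == 0) spacing / 2 else 0
    x <- seq(0.4 * spacing + off, field_um, by = spacing)
    cbind(x, rows[i])
  })
  do.call(rbind, pts)
}

# index of nearest seed for every pixel (running minimum over seeds)
nearest_seed <- function(xs, ys, seeds) {
  best <- matrix(Inf, nrow(xs), ncol(xs))
  idx <- matrix(1L, nrow(xs), ncol(xs))
  for (i in seq_len(nrow(seeds))) {
    d <- (xs - seeds[i, 1])^2 + (ys - seeds[i, 2])^2
    w <- d < best
    best[w] <- d[w]
    idx[w] <- i
  }
  idx
}
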