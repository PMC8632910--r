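# Genotype presets for the synthetic tissue generator.
#
# Wild-type kinetic defaults are pinned by the study's printed headline
# numbers and the logistic rate identity rate = 60 * amplitude / (4 * tau):
#   * rotation: amplitude 90 deg at angular velocity 11 deg/h
#     -> tau_R = 60 * 90 / (4 * 11) = 122.727 min
#   * area: constriction of ~60% from A0 to a plateau of ~8 um^2
#     -> A0 = 20 um^2, A1 = 12 um^2; constriction rate 2.5 um^2/h
#     -> tau_A = 60 * 12 / (4 * 2.5) = 72 min
# Low-fluidity (LOF) and high-fluidity (GOF) presets are qualitative
# transformations of wild type (x0.3 / x2.5 motility and exchange; altered
# pulse stabilization); no numeric rates are published for them.

#' Genotype preset for the synthetic tissue generator
#'
#' Bundles the kinematic schedule parameters that define one simulated
#' genotype: the logistic rotation and apical-constriction schedules of the
#' photoreceptor cluster, pulse modulation, interommatidial-cell (IC)
#' motility, and per-bin event schedules (division, delamination, neighbor
#' exchange).
#'
#' @param name One of `"wild_type"`, `"lof"` (low fluidity), `"gof"`
#'   (high fluidity), or `"custom"`.
#' @param ... Named overrides of individual preset fields.
#'
#' @return An object of class `genotype_preset`: a list with fields
#'   `rotation_amplitude_deg`, `rotation_tau_min`, `rotation_t0_min`,
#'   `area_baseline_um2`, `area_amplitude_um2`, `area_tau_min`,
#'   `pulse_period_min`, `pulse_amplitude`, `area_pulse_amplitude`,
#'   `exchange_rate_start`, `exchange_rate_end`, `division_schedule`,
#'   `delamination_schedule` (per-ommatidium counts per 90-min bin),
#'   `ic_motility_um_per_frame`, `noise_sd_deg`, `noise_sd_um2`, `chirality`.
#'
#' @details Fluidity ordering is built in: `lof < wild_type < gof` in both
#'   `ic_motility_um_per_frame` and the exchange schedule, mirroring the
#'   caging-to-fluid phenotypic series.
#'
#' @examples
#' wt <- genotype_preset("wild_type")
#' 60 * wt$rotation_amplitude_deg / (4 * wt$rotation_tau_min) # ~11 deg/h
#' @export
genotype_preset <- function(name = c("wild_type", "lof", "gof", "custom"), ...) {
  name <- match.arg(name)
  base <- list(
    name = name,
    rotation_amplitude_deg = 90,
    rotation_tau_min = 60 * 90 / (4 * 11), # 122.727 min -> 11 deg/h
    rotation_t0_min = 250,
    area_baseline_um2 = 20,
    area_amplitude_um2 = 12,
    area_tau_min = 60 * 12 / (4 * 2.5),    # 72 min -> 2.5 um^2/h
    area_t0_min = 250,
    pulse_period_min = 40,
    pulse_amplitude = 0.08,
    area_pulse_amplitude = 0.08,
    exchange_rate_start = 7,
    exchange_rate_end = 4,
    division_schedule = c(3, 2, 1, 0, 0, 0),
    delamination_schedule = c(1, 1, 1, 1, 1, 1),
    ic_motility_um_per_frame = 0.20,
    noise_sd_deg = 2,
    noise_sd_um2 = 0.5,
    chirality = "counterclockwise"
  )
  mods <- switch(name,
    wild_type = list(),
    lof = list(
      # under-rotation, steadier constriction (stabilized pulses), caged ICs
      rotation_amplitude_deg = 50,
      pulse_amplitude = 0.05,
      area_pulse_amplitude = 0.03,
      exchange_rate_start = 7 * 0.3,
      exchange_rate_end = 4 * 0.3,
      division_schedule = c(2, 1, 0, 0, 0, 0),
      delamination_schedule = c(0, 1, 0, 1, 0, 0),
      ic_motility_um_per_frame = 0.20 * 0.3
    ),
    gof = list(
      # variable over-rotation, unstabilized pulses, fluid ICs
      rotation_amplitude_deg = 100,
      pulse_amplitude = 0.12,
      area_pulse_amplitude = 0.18,
      exchange_rate_start = 7 * 2.5,
      exchange_rate_end = 4 * 2.5,
      division_schedule = c(3, 2, 1, 0, 0, 0),
      delamination_schedule = c(2, 2, 1, 1, 1, 1),
      ic_motility_um_per_frame = 0.20 * 2.5
    ),
    custom = list()
  )
  preset <- utils::modifyList(base, mods)
  preset <- utils::modifyList(preset, list(...))
  validate_preset(preset)
  structure(preset, class = "genotype_preset")
}

validate_preset <- function(p) {
  stopifnot(
    p$rotation_tau_min > 0, p$area_tau_min > 0,
    p$area_baseline_um2 > p$area_amplitude_um2,
    p$area_amplitude_um2 > 0,
    p$exchange_rate_start >= 0, p$exchange_rate_end >= 0,
    all(p$division_schedule >= 0), all(p$delamination_schedule >= 0),
    p$ic_motility_um_per_frame >= 0,
    p$noise_sd_deg >= 0, p$noise_sd_um2 >= 0,
    p$pulse_period_min > 0, p$pulse_amplitude >= 0,
    p$chirality %in% c("clockwise", "counterclockwise")
  )
  invisible(p)
}

#' @export
print.genotype_preset <- function(x, ...) {
  cat("<genotype_preset>", x$name, "\n")
  cat(sprintf("  rotation: %g deg, tau %.1f min (rate %.2f deg/h)\n",
              x$rotation_amplitude_deg, x$rotation_tau_min,
              60 * x$rotation_amplitude_deg / (4 * x$rotation_tau_min)))
  cat(sprintf("  area: A0 %g um^2, A1 %g um^2, tau %.1f min (rate %.2f um^2/h)\n",
              x$area_baseline_um2, x$area_amplitude_um2, x$area_tau_min,
              60 * x$area_amplitude_um2 / (4 * x$area_tau_min)))
  cat(sprintf("  exchange %g -> %g /ommatidium/frame-pair; IC motility %.3f um/frame\n",
              x$exchange_rate_start, x$exchange_rate_end,
              x$ic_motility_um_per_frame))
  invisible(x)
}
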