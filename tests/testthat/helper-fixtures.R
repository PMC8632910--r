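# Shared fixtures: all built in code at test time.

# preset without measurement noise (round-trip comparisons)
quiet_preset <- function(name = "wild_type", ...) {
  genotype_preset(name, noise_sd_deg = 0, noise_sd_um2 = 0, ...)
}

# fully static phantom: no rotation, no constriction, no pulses, no motility
static_preset <- function(...) {
  genotype_preset("custom", noise_sd_deg = 0, noise_sd_um2 = 0,
                  pulse_amplitude = 0, area_pulse_amplitude = 0,
                  rotation_amplitude_deg = 1e-6, area_amplitude_um2 = 1e-6,
                  ic_motility_um_per_frame = 0, ...)
}

# coarse-but-accurate movie settings used throughout the suite
small_movie <- function(preset, n_frames = 12, seed = 3, field_um = 14,
                        pixel_size_um = 0.1) {
  generate_tissue_movie(preset, n_frames = n_frames, seed = seed,
                        field_um = field_um, pixel_size_um = pixel_size_um)
}

# single-frame movie from an integer label matrix
frame_movie <- function(m, pixel_size_um = 0.1) {
  labs <- sort(setdiff(unique(as.vector(m)), 0L))
  tissue_movie(list(m),
               data.frame(frame = 0L, label = labs, cell_id = labs,
                          parent_id = NA_integer_),
               pixel_size_um, 10)
}

# rasterized Voronoi tessellation of given seeds as a one-frame movie
voronoi_movie <- function(seeds, field_um, pixel_size_um = 0.05) {
  npx <- round(field_um / pixel_size_um)
  xs <- (matrix(seq_len(npx), npx, npx, byrow = TRUE) - 0.5) * pixel_size_um
  ys <- (matrix(seq_len(npx), npx, npx) - 0.5) * pixel_size_um
  lab <- ommatidyn:::nearest_seed(xs, ys, seeds)
  frame_movie(matrix(as.integer(lab), npx, npx), pixel_size_um)
}

# hexagonal lattice movie; optionally with one planted T1 (a seed pair pulled
# apart about its midpoint until the shared Voronoi edge flips)
hex_movie <- function(t1 = FALSE, field_um = 12, spacing = 1.6,
                      pixel_size_um = 0.05) {
  seeds <- ommatidyn:::hex_lattice(field_um, spacing)
  if (t1) {
    ctr <- matrix(field_um / 2, nrow(seeds), 2)
    i <- which.min(rowSums((seeds - ctr)^2))
    d2 <- rowSums((seeds - matrix(seeds[i, ], nrow(seeds), 2, byrow = TRUE))^2)
    j <- order(d2)[2]
    mid <- (seeds[i, ] + seeds[j, ]) / 2
    seeds[i, ] <- mid + (seeds[i, ] - mid) * 2.15
    seeds[j, ] <- mid + (seeds[j, ] - mid) * 2.15
  }
  voronoi_movie(seeds, field_um, pixel_size_um)
}

# brute-force two-sample KS statistic: sup over the pooled sample
ks_bruteforce <- function(a, b) {
  pool <- c(a, b)
  max(vapply(pool, function(v) abs(mean(a <= v) - mean(b <= v)), numeric(1)))
}

# random simple (star-shaped) polygon around the origin
random_polygon <- function(n_vertices = 8) {
  th <- sort(runif(n_vertices, 0, 2 * pi))
  r <- runif(n_vertices, 0.3, 2)
  cbind(r * cos(th), r * sin(th))
}
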