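# Event detection, binned statistics, neighbor-exchange counting, and
# motility fields, validated against planted ground truth.

test_that("detectors recover planted events exactly (precision = recall = 1)", {
  led <- generate_event_ledger(genotype_preset("wild_type"), n_frames = 34,
                               n_ommatidia = 2, seed = 42)
  div <- detect_divisions(led)
  tru <- led$truth$divisions
  expect_equal(div[order(div$parent), c("frame", "parent")],
               tru[order(tru$parent), c("frame", "parent")],
               ignore_attr = TRUE)
  del <- detect_delaminations(led)
  trd <- led$truth$delaminations
  expect_equal(del[order(del$cell_id), c("frame", "cell_id")],
               trd[order(trd$cell_id), c("frame", "cell_id")],
               ignore_attr = TRUE)
})

test_that("an event-free schedule yields empty ledgers from every detector", {
  quiet <- genotype_preset("wild_type",
                           division_schedule = rep(0, 6),
                           delamination_schedule = rep(0, 6),
                           exchange_rate_start = 0, exchange_rate_end = 0)
  led <- generate_event_ledger(quiet, n_frames = 20, seed = 1)
  expect_equal(nrow(detect_divisions(led)), 0)
  expect_equal(nrow(detect_delaminations(led)), 0)
  ex <- count_neighbor_exchange(led)
  expect_true(all(ex$n == 0))
})

test_that("tracks that simply end at the movie boundary are censored", {
  led <- generate_event_ledger(genotype_preset("wild_type"), n_frames = 20,
                               seed = 3)
  del <- detect_delaminations(led)
  last_frames <- tapply(led$tracks$frame, led$tracks$cell_id, max)
  survivors <- as.integer(names(last_frames)[last_frames == 19])
  expect_length(intersect(del$cell_id, survivors), 0)
})

test_that("binned event statistics match hand-computed mean and SEM", {
  ev1 <- data.frame(frame = c(2, 4, 7), ommatidium = 1)
  b1 <- count_events_binned(ev1, n_ommatidia = 1, n_frames = 10)
  expect_equal(b1$mean[1], 3)
  expect_equal(b1$sem[1], 0)        # n = 1 convention
  expect_true(attr(b1, "sem_degenerate"))

  ev2 <- data.frame(frame = c(2, 4, 1, 3, 5, 7), ommatidium = rep(1:2, c(2, 4)))
  b2 <- count_events_binned(ev2, n_ommatidia = 2, n_frames = 10)
  expect_equal(b2$mean[1], 3)
  expect_equal(b2$sem[1], 1)        # sd(c(2,4))/sqrt(2)
  expect_warning(
    count_events_binned(data.frame(frame = 99, ommatidium = 1),
                        n_ommatidia = 1, n_frames = 10), "dropped")
})

test_that("division counts per bin equal the planted schedule and then cease", {
  wt <- genotype_preset("wild_type")
  led <- generate_event_ledger(wt, n_frames = 34, n_ommatidia = 3, seed = 42)
  div <- detect_divisions(led)
  b <- count_events_binned(div, n_ommatidia = 3, n_frames = 34,
                           first_level = led$first_level)
  sched <- wt$division_schedule[seq_len(nrow(b))]
  expect_equal(b$mean, sched)
  # divisions cease after the scheduled cessation bin (~250 min)
  expect_true(all(b$mean[b$bin_start_min >= 270] == 0))
})

test_that("neighbor-exchange counts recover the planted schedule exactly", {
  led <- generate_event_ledger(genotype_preset("wild_type"), n_frames = 34,
                               n_ommatidia = 2, seed = 42)
  ex <- count_neighbor_exchange(led)
  tru <- led$truth$exchange_counts
  m <- merge(ex[, c("frame_pair", "ommatidium", "n")], tru,
             by = c("frame_pair", "ommatidium"))
  expect_true(all(m$n.x == m$n.y))
  expect_equal(mean(ex$n[ex$frame_pair == 0]), 7)
  expect_equal(mean(ex$n[ex$frame_pair == max(ex$frame_pair)]), 4)
})

test_that("a single planted swap scores exactly its two first-level cells", {
  one <- genotype_preset("wild_type",
                         division_schedule = rep(0, 6),
                         delamination_schedule = rep(0, 6),
                         exchange_rate_start = 2, exchange_rate_end = 2)
  led <- generate_event_ledger(one, n_frames = 3, seed = 1)
  ex <- count_neighbor_exchange(led)
  expect_equal(ex$n, c(2, 2))
  planted <- led$truth$exchanges
  scored <- ex$cells[[1]]
  expect_setequal(scored, planted$cell_id[planted$frame_pair == 0])
  expect_equal(ex$fraction[1], 2 / 12)
})

test_that("divisions and delaminations alone never score as exchanges", {
  pure <- genotype_preset("wild_type",
                          exchange_rate_start = 0, exchange_rate_end = 0)
  led <- generate_event_ledger(pure, n_frames = 30, seed = 6)
  expect_gt(nrow(led$truth$divisions) + nrow(led$truth$delaminations), 0)
  ex <- count_neighbor_exchange(led)
  expect_true(all(ex$n == 0))
})

test_that("IC trajectories co-move with the cluster and vanish for static phantoms", {
  g <- small_movie(static_preset(), n_frames = 6, seed = 2)
  tr <- ic_trajectories(g$movie, g$annotation, window_min = 50)
  nets <- vapply(tr, function(d) {
    sqrt((tail(d$x_um, 1) - d$x_um[1])^2 + (tail(d$y_um, 1) - d$y_um[1])^2)
  }, numeric(1))
  expect_lt(max(nets), 0.1)
  expect_warning(ic_trajectories(g$movie, g$annotation, window_min = 1e4),
                 "truncated")
})

test_that("displacement fields average vectors per grid cell and conserve the mean", {
  # two synthetic trajectories with opposite unit displacements through the
  # same grid cell average to zero
  mk <- function(dx) {
    structure(data.frame(frame = 0:1, time_min = c(0, 10),
                         x_um = c(0.1, 0.1 + dx), y_um = c(0.1, 0.1)),
              class = "data.frame")
  }
  tr <- structure(list(a = mk(0.5), b = mk(-0.5)),
                  class = "ic_trajectories", window_min = 10)
  df <- displacement_field(tr, grid_um = 1.25)
  cell0 <- df$grid[df$grid$gx_um == 0.625 & df$grid$gy_um == 0.625, ]
  expect_equal(cell0$dx_um[1], 0)
  expect_equal(unname(df$mean_displacement), c(0.5, 0.5))

  # occupancy-weighted grid mean equals the incidence-pooled trajectory mean
  g <- small_movie(quiet_preset(), n_frames = 8, seed = 5)
  trj <- ic_trajectories(g$movie, g$annotation, window_min = 70)
  fld <- displacement_field(trj)
  wmean <- colSums(fld$grid[, c("dx_um", "dy_um")] * fld$grid$occupancy) /
    sum(fld$grid$occupancy)
  # pooled mean over (grid cell, IC) incidences, computed independently
  inc <- do.call(rbind, lapply(seq_along(trj), function(i) {
    d <- trj[[i]]
    cells <- unique(paste(floor(d$x_um / 1.25), floor(d$y_um / 1.25)))
    data.frame(dx = tail(d$x_um, 1) - d$x_um[1],
               dy = tail(d$y_um, 1) - d$y_um[1], n = length(cells))
  }))
  expect_equal(unname(wmean[1]), sum(inc$dx * inc$n) / sum(inc$n))
  expect_equal(unname(wmean[2]), sum(inc$dy * inc$n) / sum(inc$n))
})

test_that("mean IC displacement is strictly ordered lof < wild type < gof", {
  md <- function(name) {
    g <- small_movie(quiet_preset(name), n_frames = 16, seed = 7)
    trj <- ic_trajectories(g$movie, g$annotation, window_min = 120)
    mean(displacement_field(trj)$mean_displacement)
  }
  m_lof <- md("lof"); m_wt <- md("wild_type"); m_gof <- md("gof")
  expect_lt(m_lof, m_wt)
  expect_lt(m_wt, m_gof)
})
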