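test_that("movie write/read round trip is lossless", {
  g <- small_movie(quiet_preset(), n_frames = 4, seed = 5, field_um = 12)
  path <- tempfile()
  write_movie(g$movie, path)
  back <- read_movie(path)
  expect_identical(lapply(g$movie$frames, unname),
                   lapply(back$frames, unname))
  expect_equal(g$movie$tracks, back$tracks)
  expect_equal(back$pixel_size_um, g$movie$pixel_size_um)
  expect_equal(back$frame_interval_min, g$movie$frame_interval_min)
})

test_that("annotation JSON and YAML round trips preserve all fields", {
  g <- small_movie(quiet_preset(), n_frames = 4, seed = 5, field_um = 12)
  for (ext in c(".json", ".yaml")) {
    path <- tempfile(fileext = ext)
    write_annotation(g$annotation, path)
    back <- read_annotation(path)
    expect_equal(back$roles, g$annotation$roles)
    expect_equal(back$first_level_ics, g$annotation$first_level_ics)
    expect_equal(back$r7_frame, g$annotation$r7_frame)
    expect_equal(back$chirality, g$annotation$chirality)
  }
})

test_that("tracking-table inconsistencies are rejected", {
  m <- matrix(0L, 10, 10); m[3:6, 3:6] <- 1L
  # CSV references a label absent from the image
  expect_error(
    tissue_movie(list(m), data.frame(frame = 0, label = c(1, 99),
                                     cell_id = 1:2, parent_id = NA), 0.1),
    "consistency")
  # duplicate (frame, label) rows
  expect_error(
    tissue_movie(list(m), data.frame(frame = c(0, 0), label = c(1, 1),
                                     cell_id = 1:2, parent_id = NA), 0.1),
    "duplicate")
  expect_error(
    tissue_movie(list(m), data.frame(frame = 0, label = 1, cell_id = 1,
                                     parent_id = NA), -0.1),
    "pixel_size")
})

test_that("a hand-written 2-frame, 3-cell movie yields a 6-row track table", {
  m1 <- matrix(0L, 12, 12)
  m1[2:5, 2:5] <- 1L; m1[2:5, 7:10] <- 2L; m1[7:10, 2:5] <- 3L
  m2 <- m1
  tracks <- data.frame(frame = rep(0:1, each = 3), label = rep(1:3, 2),
                       cell_id = rep(1:3, 2), parent_id = NA_integer_)
  mov <- tissue_movie(list(m1, m2), tracks, 0.1)
  expect_equal(nrow(mov$tracks), 6)
})

test_that("a single square cell measures its true area and perimeter", {
  m <- matrix(0L, 40, 40); m[11:30, 11:30] <- 1L   # 20x20 px at 0.1 um/px
  g <- build_cell_graph(frame_movie(m), 0)
  expect_equal(g$cells$area_um2, 4.0, tolerance = 0.05)
  expect_equal(g$cells$perimeter_um, 8.0, tolerance = 0.05)
  expect_false(g$cells$border)
})

test_that("two abutting squares are mutually adjacent, and only they", {
  m <- matrix(0L, 40, 60)
  m[11:30, 11:30] <- 1L; m[11:30, 31:50] <- 2L
  g <- build_cell_graph(frame_movie(m), 0)
  expect_equal(nrow(g$adjacency), 1)
  expect_equal(sort(as.vector(g$adjacency)), c(1, 2))
  expect_equal(g$cells$n_sides, c(1, 1))
})

test_that("corner-touching cells are not neighbors (4-connectivity)", {
  m <- matrix(0L, 20, 20)
  m[2:9, 2:9] <- 1L; m[10:18, 10:18] <- 2L   # touch only at one corner
  g <- build_cell_graph(frame_movie(m), 0)
  expect_equal(nrow(g$adjacency), 0)
})

test_that("empty frames warn and return empty geometry", {
  m <- matrix(0L, 10, 10); m[3:6, 3:6] <- 1L
  mov <- tissue_movie(list(m, matrix(0L, 10, 10)),
                      data.frame(frame = 0, label = 1, cell_id = 1,
                                 parent_id = NA), 0.1)
  expect_warning(g <- build_cell_graph(mov, 1), "empty")
  expect_equal(nrow(g$cells), 0)
  expect_error(build_cell_graph(mov, 5), "frame")
})

test_that("label-image areas match pixel-count oracles on a Voronoi fixture", {
  set.seed(21)
  W <- 12
  seeds <- cbind(runif(16, 0, W), runif(16, 0, W))
  mov <- voronoi_movie(seeds, W, pixel_size_um = 0.05)
  g <- build_cell_graph(mov, 0)
  m <- mov$frames[[1]]
  for (i in seq_len(16)) {
    row <- g$cells[g$cells$cell_id == i, ]
    if (row$border) next
    pix_area <- sum(m == i) * 0.05^2
    expect_equal(row$area_um2, pix_area, tolerance = 0.03)
  }
})

test_that("kinetic trace CSV round trips preserve the data", {
  tr <- generate_frap_trace(0.8, 0.01, noise_sd = 1, seed = 2)
  path <- tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read_trace(path, "frap")
  expect_equal(back$roi_intensity, tr$roi_intensity)
  rc <- generate_recoil_trace(2, 1, 10, noise_sd = 0.02, seed = 2)
  path2 <- tempfile(fileext = ".csv")
  write_trace(rc, path2)
  back2 <- read_trace(path2, "recoil", l0_um = 2)
  expect_equal(back2$vertex_distance_um, rc$vertex_distance_um)
  expect_error(read_trace(path2, "recoil"), "l0_um")
})
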