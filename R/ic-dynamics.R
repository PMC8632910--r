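# Interommatidial-cell event scoring and motility fields.

# --- tracked cell tables -----------------------------------------------------
# The detectors run on a "tracked cell table": one row per (frame, cell) with
# columns frame, cell_id, parent_id, area_um2, ommatidium, plus a per-frame
# adjacency lookup. Event ledgers carry this table directly; tissue movies
# are reduced to it via build_cell_graph().

tracked_table <- function(x, ...) UseMethod("tracked_table")

#' @export
tracked_table.event_ledger <- function(x, ...) {
  list(tracks = x$tracks,
       adjacency = lapply(x$graphs, `[[`, "edges"),
       n_frames = x$n_frames,
       frame_interval_min = x$frame_interval_min)
}

#' @export
tracked_table.tissue_movie <- function(x, ...) {
  geoms <- lapply(seq_len(n_frames(x)) - 1L, function(f)
    build_cell_graph(x, f))
  tracks <- do.call(rbind, lapply(geoms, function(g) {
    data.frame(frame = g$frame, cell_id = g$cells$cell_id,
               parent_id = NA_integer_, area_um2 = g$cells$area_um2,
               ommatidium = 1L)
  }))
  lineage <- movie_lineage(x)
  tracks$parent_id <- unname(lineage[as.character(tracks$cell_id)])
  list(tracks = tracks,
       adjacency = lapply(geoms, `[[`, "adjacency"),
       n_frames = n_frames(x),
       frame_interval_min = x$frame_interval_min)
}

check_lineage <- function(tracks) {
  par <- tracks[!duplicated(tracks$cell_id), c("cell_id", "parent_id")]
  pmap <- stats::setNames(par$parent_id, par$cell_id)
  for (id in par$cell_id) {
    seen <- character(0); cur <- as.character(id)
    while (!is.na(pmap[cur] %||% NA)) {
      if (cur %in% seen) stop("format error: lineage cycle at cell ", cur)
      seen <- c(seen, cur)
      cur <- as.character(pmap[cur])
      if (!cur %in% names(pmap)) break
    }
  }
  invisible(pmap)
}

# map every cell id to its founder ancestor
root_map <- function(tracks) {
  pmap <- check_lineage(tracks)
  roots <- stats::setNames(names(pmap), names(pmap))
  for (id in names(pmap)) {
    cur <- id
    while (!is.na(pmap[cur] %||% NA) && as.character(pmap[cur]) %in% names(pmap)) {
      cur <- as.character(pmap[cur])
    }
    roots[id] <- cur
  }
  stats::setNames(as.integer(roots), names(roots))
}

#' Detect cell divisions / delaminations from tracked lineage
#'
#' `detect_divisions()` scores a division where a track's lineage splits into
#' exactly two daughters that first appear on the frame after the parent's
#' last, whose combined first-frame area is within [0.6, 1.4] of the parent's
#' last area, and which are mutually adjacent (sharing the parent's
#' footprint). `detect_delaminations()` scores a track that ends before the
#' last frame with no daughters, whose area decreased monotonically over its
#' final three frames and collapsed below `collapse_frac` (default 25%) of
#' the track's running median area. Tracks still alive at the last frame are
#' censored, not scored.
#'
#' @param x An `event_ledger` or [tissue_movie()] (lineage from its tracking
#'   table).
#' @param collapse_frac Area-collapse threshold relative to the running
#'   median.
#' @return Data frame of event records (`frame`, cells involved,
#'   `ommatidium`).
#' @export
detect_divisions <- function(x) {
  tt <- tracked_table(x)
  tr <- tt$tracks
  check_lineage(tr)
  out <- list()
  kids <- split(tr$cell_id[!duplicated(tr$cell_id) & !is.na(tr$parent_id)],
                tr$parent_id[!duplicated(tr$cell_id) & !is.na(tr$parent_id)])
  for (p in names(kids)) {
    ds <- unique(kids[[p]])
    if (length(ds) != 2) next
    p_rows <- tr[tr$cell_id == as.integer(p), ]
    if (!nrow(p_rows)) next
    p_last <- max(p_rows$frame)
    d_first <- vapply(ds, function(d) min(tr$frame[tr$cell_id == d]),
                      numeric(1))
    if (!all(d_first == p_last + 1)) next
    a_d <- sum(vapply(ds, function(d)
      tr$area_um2[tr$cell_id == d & tr$frame == p_last + 1][1], numeric(1)))
    a_p <- p_rows$area_um2[p_rows$frame == p_last][1]
    if (is.na(a_d) || is.na(a_p) || a_d < 0.6 * a_p || a_d > 1.4 * a_p) next
    adj <- tt$adjacency[[p_last + 2L]]
    touching <- any((adj[, 1] == ds[1] & adj[, 2] == ds[2]) |
                      (adj[, 1] == ds[2] & adj[, 2] == ds[1]))
    if (!touching) next
    out[[length(out) + 1L]] <- data.frame(
      frame = p_last + 1L, parent = as.integer(p),
      daughter1 = ds[1], daughter2 = ds[2],
      ommatidium = p_rows$ommatidium[1])
  }
  if (!length(out)) {
    return(data.frame(frame = integer(0), parent = integer(0),
                      daughter1 = integer(0), daughter2 = integer(0),
                      ommatidium = integer(0)))
  }
  out <- do.call(rbind, out)
  out[order(out$frame, out$parent), , drop = FALSE]
}

#' @rdname detect_divisions
#' @export
detect_delaminations <- function(x, collapse_frac = 0.25) {
  tt <- tracked_table(x)
  tr <- tt$tracks
  has_kids <- unique(tr$parent_id[!is.na(tr$parent_id)])
  out <- list()
  for (id in unique(tr$cell_id)) {
    rows <- tr[tr$cell_id == id, ]
    rows <- rows[order(rows$frame), ]
    last <- max(rows$frame)
    if (last >= tt$n_frames - 1L) next      # censored at the movie end
    if (id %in% has_kids) next              # divided, not delaminated
    if (nrow(rows) < 4) next
    tail3 <- tail(rows$area_um2, 3)
    if (any(diff(tail3) >= 0)) next
    if (tail(rows$area_um2, 1) >= collapse_frac * median(rows$area_um2)) next
    out[[length(out) + 1L]] <- data.frame(
      frame = last + 1L, cell_id = id, ommatidium = rows$ommatidium[1])
  }
  if (!length(out)) {
    return(data.frame(frame = integer(0), cell_id = integer(0),
                      ommatidium = integer(0)))
  }
  out <- do.call(rbind, out)
  out[order(out$frame, out$cell_id), , drop = FALSE]
}

#' Bin event records into 90-minute summaries across ommatidia
#'
#' Computes, per time bin, the mean and standard error of the per-ommatidium
#' event count. An ommatidium with no events in a bin contributes 0. With a
#' single ommatidium the SEM is reported as 0 and flagged.
#'
#' @param events Event data frame with columns `frame` and `ommatidium`
#'   (as returned by the detectors), with aligned times.
#' @param n_ommatidia Number of ommatidia observed (denominators).
#' @param frame_interval_min Minutes per frame.
#' @param bin_min Bin width, minutes (default 90).
#' @param n_frames Total frames observed; events beyond the span are dropped
#'   with a warning.
#' @param first_level Optional list (per ommatidium) of first-level cell ids;
#'   events on other cells are excluded.
#' @return Object of class `binned_event_stats`: data frame `bin_start_min`,
#'   `bin_end_min`, `mean`, `sem`, `n_ommatidia`; attribute `sem_degenerate`
#'   when n = 1.
#' @export
count_events_binned <- function(events, n_ommatidia, frame_interval_min = 10,
                                bin_min = 90, n_frames = NULL,
                                first_level = NULL) {
  if (!is.null(first_level)) {
    cell_col <- if ("parent" %in% names(events)) "parent" else "cell_id"
    keep <- mapply(function(cell, om) cell %in% first_level[[om]],
                   events[[cell_col]], events$ommatidium)
    events <- events[as.logical(keep), , drop = FALSE]
  }
  t_ev <- events$frame * frame_interval_min
  span <- if (is.null(n_frames)) max(c(t_ev, bin_min)) else
    (n_frames - 1L) * frame_interval_min
  drop <- t_ev > span
  if (any(drop)) {
    warning(sum(drop), " event(s) outside the series span dropped")
    events <- events[!drop, , drop = FALSE]
    t_ev <- t_ev[!drop]
  }
  edges <- seq(0, ceiling(span / bin_min) * bin_min, by = bin_min)
  nb <- length(edges) - 1L
  counts <- matrix(0, nb, n_ommatidia)
  if (nrow(events)) {
    b <- pmin(findInterval(t_ev, edges, rightmost.closed = TRUE), nb)
    for (i in seq_along(b)) {
      counts[b[i], events$ommatidium[i]] <- counts[b[i], events$ommatidium[i]] + 1
    }
  }
  m <- rowMeans(counts)
  sem <- if (n_ommatidia > 1) apply(counts, 1, sd) / sqrt(n_ommatidia) else
    rep(0, nb)
  out <- data.frame(bin_start_min = edges[-length(edges)],
                    bin_end_min = edges[-1], mean = m, sem = sem,
                    n_ommatidia = n_ommatidia)
  structure(out, class = c("binned_event_stats", "data.frame"),
            sem_degenerate = n_ommatidia == 1)
}

#' Count first-level interommatidial neighbor exchanges per frame pair
#'
#' A first-level IC scores an exchange between frames t and t+1 when its
#' neighbor-id set changes after (i) remapping daughter cells to their
#' founder ancestor, so divisions do not score, and (ii) removing ids absent
#' from either frame, so delaminations and divisions of neighbors do not
#' score. N(t) counts scoring ICs; the fraction divides by the first-level
#' ICs alive in both frames.
#'
#' @param x An `event_ledger` (or anything with a `tracked_table()` method
#'   plus per-frame adjacency).
#' @param first_level List per ommatidium of frozen first-level cell ids;
#'   defaults to the ledger's own sets.
#' @return Data frame `frame_pair` (0-based index of t), `ommatidium`, `n`,
#'   `fraction`, plus columns `cells` (list of scoring ids).
#' @export
count_neighbor_exchange <- function(x, first_level = NULL) {
  tt <- tracked_table(x)
  first_level <- first_level %||% x$first_level
  if (is.null(first_level)) stop("first-level IC sets are required")
  tr <- tt$tracks
  roots <- root_map(tr)
  known <- unique(tr$cell_id)
  out <- list()
  for (f in seq_len(tt$n_frames - 1L) - 1L) {
    e0 <- tt$adjacency[[f + 1L]]
    e1 <- tt$adjacency[[f + 2L]]
    bad <- setdiff(unique(c(e0, e1)), known)
    if (length(bad)) {
      stop("consistency error: untracked id(s) in graph: ",
           paste(bad, collapse = ","))
    }
    ids0 <- unique(tr$cell_id[tr$frame == f])
    ids1 <- unique(tr$cell_id[tr$frame == f + 1L])
    roots0 <- unique(unname(roots[as.character(ids0)]))
    roots1 <- unique(unname(roots[as.character(ids1)]))
    shared <- intersect(roots0, roots1)
    for (om in seq_along(first_level)) {
      fl <- first_level[[om]]
      live <- intersect(fl, shared)
      scored <- integer(0)
      for (cell in live) {
        n0 <- neighbor_roots(e0, cell, roots, shared)
        n1 <- neighbor_roots(e1, cell, roots, shared)
        if (!setequal(n0, n1)) scored <- c(scored, cell)
      }
      out[[length(out) + 1L]] <- data.frame(
        frame_pair = f, ommatidium = om, n = length(scored),
        fraction = if (length(live)) length(scored) / length(live) else NA,
        cells = I(list(scored)))
    }
  }
  do.call(rbind, out)
}

# remapped neighbor set of `cell` (a founder id): neighbors of the cell and
# all its descendants, mapped to founder ids, restricted to `universe`
neighbor_roots <- function(edges, cell, roots, universe) {
  members <- as.integer(names(roots)[roots == cell])
  nb <- unique(c(edges[edges[, 1] %in% members, 2],
                 edges[edges[, 2] %in% members, 1]))
  nb <- unique(unname(roots[as.character(nb)]))
  setdiff(intersect(nb, universe), cell)
}

#' Interommatidial-cell trajectories relative to the cluster
#'
#' Tracks IC centroids from R7 recruitment to `window_min` minutes after it,
#' expressed relative to the instantaneous cluster centroid (the pre-cluster
#' sits at the origin).
#'
#' @param movie A [tissue_movie()].
#' @param annotation An [ommatidium_annotation()].
#' @param window_min Analysis window after R7 recruitment, minutes
#'   (default 120); truncated with a warning if the movie is shorter.
#' @param cells IC cell ids to track; defaults to all annotated ICs.
#' @return Object of class `ic_trajectories`: list of data frames (`frame`,
#'   `time_min`, `x_um`, `y_um`) named by cell id, with attribute
#'   `window_min`.
#' @export
ic_trajectories <- function(movie, annotation, window_min = 120,
                            cells = NULL) {
  r7 <- annotation$r7_frame
  if (is.na(r7)) stop("r7_frame required (align or annotate first)")
  dt <- movie$frame_interval_min
  f_end <- r7 + window_min / dt
  if (f_end > n_frames(movie) - 1L) {
    warning("window exceeds movie span; truncated")
    f_end <- n_frames(movie) - 1L
  }
  frames <- seq(r7, floor(f_end))
  rids <- vapply(paste0("R", 1:8), function(r) role_cell(annotation, r),
                 integer(1))
  rids <- rids[!is.na(rids)]
  cells <- cells %||%
    as.integer(names(annotation$roles)[annotation$roles %in% c("IC", "cone")])
  cl_cent <- vapply(frames, function(f) cluster_centroid(movie, f, rids),
                    numeric(2))
  out <- lapply(cells, function(id) {
    pos <- vapply(frames, function(f) cell_centroid_at(movie, f, id),
                  numeric(2))
    data.frame(frame = frames, time_min = (frames - r7) * dt,
               x_um = pos[1, ] - cl_cent[1, ],
               y_um = pos[2, ] - cl_cent[2, ])
  })
  names(out) <- cells
  out <- out[vapply(out, function(d) !anyNA(d$x_um), logical(1))]
  structure(out, class = "ic_trajectories", window_min = window_min,
            frame_interval_min = dt)
}

cluster_centroid <- function(movie, frame, rids) {
  cents <- vapply(rids, function(id) cell_centroid_at(movie, frame, id),
                  numeric(2))
  rowMeans(cents, na.rm = TRUE)
}

#' Grid-averaged displacement field of IC trajectories
#'
#' Divides the plane around the cluster (origin) into square grid cells
#' (default 1.25 um) and assigns each grid cell the average net displacement
#' vector of the ICs whose trajectories pass through it. Speed is the
#' displacement magnitude over the elapsed window, interpolated bilinearly
#' onto a `fine_factor`-times finer grid for mapping; unoccupied cells are
#' excluded from the interpolation support.
#'
#' @param trajectories An [ic_trajectories()] result.
#' @param grid_um Grid spacing, microns (default 1.25).
#' @param fine_factor Refinement factor of the interpolated speed grid.
#' @return Object of class `displacement_field`: list with `grid` (data
#'   frame `gx_um`, `gy_um`, `dx_um`, `dy_um`, `speed_um_min`, `occupancy`),
#'   `fine` (interpolated speed grid), `mean_displacement` (named vector of
#'   per-cell net displacement magnitudes, um), `grid_um`.
#' @export
displacement_field <- function(trajectories, grid_um = 1.25,
                               fine_factor = 4) {
  if (!length(trajectories)) stop("need at least one trajectory")
  stopifnot(grid_um > 0)
  elapsed <- vapply(trajectories, function(d) diff(range(d$time_min)),
                    numeric(1))
  net <- t(vapply(trajectories, function(d) {
    c(tail(d$x_um, 1) - d$x_um[1], tail(d$y_um, 1) - d$y_um[1])
  }, numeric(2)))
  mean_disp <- sqrt(rowSums(net^2))
  names(mean_disp) <- names(trajectories)

  acc <- new.env(parent = emptyenv())
  for (i in seq_along(trajectories)) {
    d <- trajectories[[i]]
    gx <- floor(d$x_um / grid_um); gy <- floor(d$y_um / grid_um)
    for (key in unique(paste(gx, gy))) {
      prev <- acc[[key]] %||% list(v = c(0, 0), n = 0L, t = 0)
      acc[[key]] <- list(v = prev$v + net[i, ], n = prev$n + 1L,
                         t = prev$t + elapsed[i])
    }
  }
  keys <- ls(acc)
  cells <- do.call(rbind, lapply(keys, function(k) {
    g <- as.numeric(strsplit(k, " ")[[1]])
    e <- acc[[k]]
    v <- e$v / e$n
    data.frame(gx_um = (g[1] + 0.5) * grid_um, gy_um = (g[2] + 0.5) * grid_um,
               dx_um = v[1], dy_um = v[2],
               speed_um_min = sqrt(sum(v^2)) / (e$t / e$n),
               occupancy = e$n)
  }))
  fine <- interpolate_speed(cells, grid_um, fine_factor)
  structure(list(grid = cells, fine = fine, mean_displacement = mean_disp,
                 grid_um = grid_um),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("<displacement_field> %d occupied cells (%.3g um grid), %d ICs\n",
              nrow(x$grid), x$grid_um, length(x$mean_displacement)))
  cat(sprintf("  mean |displacement| %.3g um\n", mean(x$mean_displacement)))
  invisible(x)
}

# bilinear interpolation of speed onto a finer grid, support = occupied cells
interpolate_speed <- function(cells, grid_um, fine_factor) {
  if (nrow(cells) < 3) return(cells[, c("gx_um", "gy_um", "speed_um_min")])
  h <- grid_um / fine_factor
  fx <- seq(min(cells$gx_um), max(cells$gx_um), by = h)
  fy <- seq(min(cells$gy_um), max(cells$gy_um), by = h)
  key <- paste(round(cells$gx_um / grid_um - 0.5),
               round(cells$gy_um / grid_um - 0.5))
  val <- stats::setNames(cells$speed_um_min, key)
  out <- expand.grid(gx_um = fx, gy_um = fy)
  sp <- mapply(function(x, y) {
    cx <- x / grid_um - 0.5; cy <- y / grid_um - 0.5
    x0 <- floor(cx); y0 <- floor(cy)
    wsum <- 0; vsum <- 0
    for (ix in c(x0, x0 + 1)) for (iy in c(y0, y0 + 1)) {
      v <- val[paste(ix, iy)]
      if (is.na(v)) next
      w <- (1 - abs(cx - ix)) * (1 - abs(cy - iy))
      if (w <= 0) next
      wsum <- wsum + w; vsum <- vsum + w * v
    }
    if (wsum > 0) vsum / wsum else NA_real_
  }, out$gx_um, out$gy_um)
  out$speed_um_min <- as.numeric(sp)
  out[!is.na(out$speed_um_min), , drop = FALSE]
}
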