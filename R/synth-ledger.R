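# Graph-level synthetic event ledgers: sequences of per-frame cell adjacency
# graphs with planted divisions, delaminations and neighbor exchanges whose
# ground truth is returned alongside, for exercising the event detectors.

#' Generate a synthetic cell-graph event ledger with ground truth
#'
#' Builds, per ommatidium, a fixed template graph (8 photoreceptors, a ring
#' of 12 first-level interommatidial cells, a ring of 18 second-level cells)
#' and evolves it over `n_frames` frames. Planted events:
#' \itemize{
#'   \item divisions: a first-level node is replaced by two mutually adjacent
#'     daughters inheriting its current neighbors, each with half its area;
#'     per-ommatidium counts per 90-min bin follow the preset's
#'     `division_schedule`.
#'   \item delaminations: a first-level node shrinks monotonically over its
#'     last three frames to 15% of its typical area, then disappears; counts
#'     follow `delamination_schedule`.
#'   \item neighbor exchanges: per frame pair, ring edges between consecutive
#'     first-level cells are toggled (a symmetric swap scoring both cells)
#'     plus, where the target is odd, an edge toggle between a first-level
#'     and a second-level cell (scoring one). The per-pair target declines
#'     linearly from `exchange_rate_start` to `exchange_rate_end` and is
#'     realized exactly, capped by the 12 first-level cells available.
#' }
#' Divisions and delaminations are wired so that, after lineage remapping and
#' removal of ids absent from either frame, they change no surviving cell's
#' neighbor set: only planted exchanges score.
#'
#' @param preset A [genotype_preset()].
#' @param n_frames Number of frames (>= 2).
#' @param n_ommatidia Number of independent ommatidium graphs.
#' @param seed Integer RNG seed.
#' @param frame_interval_min Frame spacing, minutes.
#' @return Object of class `event_ledger`: list with `graphs` (per frame:
#'   `nodes` data frame `cell_id`, `ommatidium`, `level` in {R, F, S},
#'   `area_um2`; `edges` two-column cell_id matrix), `tracks` (data frame
#'   `frame`, `cell_id`, `parent_id`, `area_um2`, `ommatidium`),
#'   `first_level` (list per ommatidium of frozen first-level ids),
#'   `frame_interval_min`, `n_frames`, and `truth` (planted `divisions`,
#'   `delaminations`, `exchanges` data frames plus `exchange_counts` per
#'   frame pair and ommatidium).
#' @export
generate_event_ledger <- function(preset = genotype_preset("wild_type"),
                                  n_frames = 34, n_ommatidia = 1, seed = 1,
                                  frame_interval_min = 10) {
  if (n_frames < 2) stop("n_frames must be >= 2")
  validate_preset(preset)
  set.seed(seed)

  oms <- lapply(seq_len(n_ommatidia), function(om) {
    build_om_ledger(preset, n_frames, om, (om - 1L) * 1000L,
                    frame_interval_min)
  })
  graphs <- lapply(seq_len(n_frames), function(f) {
    list(nodes = do.call(rbind, lapply(oms, function(o) o$graphs[[f]]$nodes)),
         edges = do.call(rbind, lapply(oms, function(o) o$graphs[[f]]$edges)))
  })
  cat_df <- function(field) do.call(rbind, lapply(oms, `[[`, field))
  structure(list(
    graphs = graphs,
    tracks = cat_df("tracks"),
    first_level = lapply(oms, `[[`, "first_level"),
    frame_interval_min = frame_interval_min,
    n_frames = n_frames,
    truth = list(
      divisions = cat_df("divisions"),
      delaminations = cat_df("delaminations"),
      exchanges = cat_df("exchanges"),
      exchange_counts = cat_df("exchange_counts"))),
    class = "event_ledger")
}

#' @export
print.event_ledger <- function(x, ...) {
  cat(sprintf("<event_ledger> %d frames, %d ommatidia\n", x$n_frames,
              length(x$first_level)))
  cat(sprintf("  planted: %d divisions, %d delaminations, %d exchange scores\n",
              nrow(x$truth$divisions), nrow(x$truth$delaminations),
              nrow(x$truth$exchanges)))
  invisible(x)
}

# one ommatidium; ids offset so ommatidia never collide
build_om_ledger <- function(preset, n_frames, om, off, frame_interval_min) {
  ids_R <- off + 1:8          # 1 = R8 hub, 2..8 = R1..R7 ring
  ids_F <- off + 9:20         # first-level ICs (frozen set)
  ids_S <- off + 21:38        # second-level ICs
  all_ids <- c(ids_R, ids_F, ids_S)
  area0 <- stats::setNames(
    c(rep(preset$area_baseline_um2 / 8, 8), rep(3, 30)), all_ids)
  lv <- stats::setNames(c(rep("R", 8), rep("F", 12), rep("S", 18)), all_ids)

  ring <- function(ids) cbind(ids, c(ids[-1], ids[1]))
  template <- norm_edges(rbind(
    cbind(ids_R[1], ids_R[2:8]),              # R8 hub
    ring(ids_R[2:8]),                         # photoreceptor ring
    ring(ids_F),                              # first-level ring
    do.call(rbind, lapply(1:12, function(j) { # F-R attachments
      r <- 1 + ((j - 1) * 7) %/% 12
      cbind(ids_F[j], ids_R[1 + c(r, r %% 7 + 1)])
    })),
    ring(ids_S),                              # second-level ring
    do.call(rbind, lapply(1:18, function(k) { # S-F attachments
      fidx <- 1 + ((k - 1) * 12) %/% 18
      cbind(ids_S[k], ids_F[c(fidx, fidx %% 12 + 1)])
    }))))

  alive_from <- stats::setNames(rep(0L, length(all_ids)), all_ids)
  alive_to <- stats::setNames(rep(n_frames - 1L, length(all_ids)), all_ids)
  parent <- stats::setNames(rep(NA_integer_, length(all_ids)), all_ids)
  areas <- matrix(rep(unname(area0), n_frames), length(all_ids), n_frames,
                  dimnames = list(all_ids, NULL))
  lv <- c(lv)

  n_pairs <- n_frames - 1L
  times <- (seq_len(n_frames) - 1L) * frame_interval_min
  bin_of <- floor(times / 90) + 1L

  # planted division / delamination frames (event frame = frame at which the
  # change first becomes visible); room left for the shrink run-in and for
  # observing the disappearance before the movie ends
  pick_event_frames <- function(schedule) {
    fr <- integer(0)
    for (b in seq_along(schedule)) {
      cand <- which(bin_of == b) - 1L
      cand <- cand[cand >= 4L & cand <= n_frames - 2L]
      k <- schedule[b]
      if (k < 1 || !length(cand)) next
      fr <- c(fr, if (k > length(cand)) sample(rep(cand, length.out = k)) else
        sample(cand, k))
    }
    sort(fr)
  }
  div_frames <- pick_event_frames(preset$division_schedule)
  del_frames <- pick_event_frames(preset$delamination_schedule)
  if (length(div_frames) + length(del_frames) > length(ids_F)) {
    stop("generation error: more division/delamination events than available cells")
  }

  pool <- ids_F
  divisions <- list(); delaminations <- list()
  next_id <- off + 500L
  for (f in div_frames) {
    p <- pool[1]; pool <- pool[-1]
    d1 <- next_id; d2 <- next_id + 1L; next_id <- next_id + 2L
    alive_to[as.character(p)] <- f - 1L
    for (d in c(d1, d2)) {
      alive_from[as.character(d)] <- f
      alive_to[as.character(d)] <- n_frames - 1L
      parent[as.character(d)] <- p
      lv[as.character(d)] <- "F"
      areas <- rbind(areas, matrix(areas[as.character(p), 1] / 2, 1, n_frames,
                                   dimnames = list(d, NULL)))
    }
    divisions[[length(divisions) + 1L]] <-
      data.frame(frame = f, parent = p, daughter1 = d1, daughter2 = d2,
                 ommatidium = om)
  }
  for (f in del_frames) {
    p <- pool[1]; pool <- pool[-1]
    key <- as.character(p)
    alive_to[key] <- f - 1L
    a <- areas[key, 1]
    areas[key, f - 2L] <- 0.80 * a   # frame f-3
    areas[key, f - 1L] <- 0.45 * a   # frame f-2
    areas[key, f]      <- 0.15 * a   # frame f-1, last visible
    delaminations[[length(delaminations) + 1L]] <-
      data.frame(frame = f, cell_id = p, ommatidium = om)
  }

  # exchange planting: linear decline, exact per frame pair. Exchanges are
  # planted on the live representative of each frozen first-level root: the
  # cell itself or, after it divides, its first daughter (the detector scores
  # the root either way, via lineage remapping). Delaminated roots drop out.
  sched <- round(seq(preset$exchange_rate_start, preset$exchange_rate_end,
                     length.out = n_pairs))
  ring_next <- stats::setNames(c(ids_F[-1], ids_F[1]), ids_F)
  s_partner <- stats::setNames(ids_S[1L + ((seq_len(12) - 1L) * 18L) %/% 12L],
                               ids_F)
  div_frame_of <- stats::setNames(rep(NA_integer_, 12), ids_F)
  members_of <- stats::setNames(as.list(ids_F), ids_F)
  if (length(divisions)) {
    for (d in divisions) {
      div_frame_of[as.character(d$parent)] <- d$frame
      members_of[[as.character(d$parent)]] <- c(d$daughter1, d$daughter2)
    }
  }
  del_frame_of <- stats::setNames(rep(NA_integer_, 12), ids_F)
  if (length(delaminations)) {
    for (d in delaminations) del_frame_of[as.character(d$cell_id)] <- d$frame
  }
  # cells embodying a frozen root at frame f (the root itself, or both
  # daughters once it has divided); second-level partners embody themselves
  embody <- function(id, f) {
    key <- as.character(id)
    if (!id %in% ids_F) return(id)
    fd <- div_frame_of[key]
    if (!is.na(fd) && f >= fd) members_of[[key]] else id
  }
  toggles <- vector("list", n_pairs)
  exchanges <- list(); exch_counts <- integer(n_pairs)
  for (j in seq_len(n_pairs)) {
    eligible <- ids_F[vapply(ids_F, function(root) {
      fd <- div_frame_of[as.character(root)]
      fr <- del_frame_of[as.character(root)]
      (is.na(fd) || j != fd) && (is.na(fr) || j <= fr - 1L)
    }, logical(1))]
    if (length(eligible) > 1) {  # rotate so toggles spread around the ring
      r <- (j - 1L) %% length(eligible)
      if (r > 0L) {
        eligible <- c(eligible[(r + 1L):length(eligible)], eligible[1:r])
      }
    }
    target <- min(sched[j], length(eligible))
    tg <- list(); scored <- integer(0)
    remaining <- eligible
    while (length(scored) + 1L < target) {
      pair_found <- FALSE
      for (a in remaining) {
        b <- ring_next[as.character(a)]
        if (!is.na(b) && b %in% remaining) { pair_found <- TRUE; break }
      }
      if (!pair_found) break
      tg[[length(tg) + 1L]] <- c(a, b)
      scored <- c(scored, a, b)
      remaining <- setdiff(remaining, c(a, b))
    }
    if (length(scored) < target) {
      for (a in utils::head(remaining, target - length(scored))) {
        tg[[length(tg) + 1L]] <- c(a, s_partner[as.character(a)])
        scored <- c(scored, a)
      }
    }
    toggles[[j]] <- if (length(tg)) do.call(rbind, tg) else
      matrix(integer(0), ncol = 2)
    exch_counts[j] <- length(scored)
    if (length(scored)) {
      exchanges[[length(exchanges) + 1L]] <-
        data.frame(frame_pair = j - 1L, cell_id = scored, ommatidium = om)
    }
  }

  # materialize per-frame graphs from the evolving edge set
  edge_state <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(template))) {
    assign(edge_key(template[i, 1], template[i, 2]), TRUE, envir = edge_state)
  }
  div_by_frame <- split(seq_along(div_frames), div_frames)
  graphs <- vector("list", n_frames)
  tracks <- vector("list", n_frames)
  for (f in seq_len(n_frames) - 1L) {
    if (f > 0L) {
      for (i in seq_len(nrow(toggles[[f]]))) {
        for (ma in embody(toggles[[f]][i, 1], f)) {
          for (mb in embody(toggles[[f]][i, 2], f)) {
            key <- edge_key(ma, mb)
            cur <- if (exists(key, envir = edge_state))
              get(key, envir = edge_state) else FALSE
            assign(key, !cur, envir = edge_state)
          }
        }
      }
    }
    ids <- as.integer(names(alive_from))[alive_from <= f & alive_to >= f]
    # wire daughters born this frame to the parent's current neighbors
    for (di in div_by_frame[[as.character(f)]] %||% integer(0)) {
      d <- divisions[[di]]
      live_edges <- current_edges(edge_state)
      nbrs <- intersect(edges_of(live_edges, d$parent), ids)
      for (nb in c(nbrs, d$daughter2)) {
        assign(edge_key(d$daughter1, nb), TRUE, envir = edge_state)
      }
      for (nb in nbrs) {
        assign(edge_key(d$daughter2, nb), TRUE, envir = edge_state)
      }
    }
    em <- current_edges(edge_state)
    em <- em[em[, 1] %in% ids & em[, 2] %in% ids, , drop = FALSE]
    nodes <- data.frame(cell_id = ids, ommatidium = om,
                        level = unname(lv[as.character(ids)]),
                        area_um2 = unname(areas[as.character(ids), f + 1L]))
    graphs[[f + 1L]] <- list(nodes = nodes, edges = em)
    tracks[[f + 1L]] <- data.frame(
      frame = f, cell_id = ids,
      parent_id = unname(parent[as.character(ids)]),
      area_um2 = nodes$area_um2, ommatidium = om)
  }

  empty <- function(...) {
    cols <- list(...)
    as.data.frame(stats::setNames(rep(list(integer(0)), length(cols)), cols))
  }
  list(graphs = graphs, tracks = do.call(rbind, tracks),
       first_level = ids_F,
       divisions = if (length(divisions)) do.call(rbind, divisions) else
         empty("frame", "parent", "daughter1", "daughter2", "ommatidium"),
       delaminations = if (length(delaminations))
         do.call(rbind, delaminations) else
           empty("frame", "cell_id", "ommatidium"),
       exchanges = if (length(exchanges)) do.call(rbind, exchanges) else
         empty("frame_pair", "cell_id", "ommatidium"),
       exchange_counts = data.frame(frame_pair = seq_len(n_pairs) - 1L,
                                    ommatidium = om, n = exch_counts))
}

edge_key <- function(a, b) paste(min(a, b), max(a, b), sep = "_")

current_edges <- function(edge_state) {
  keys <- ls(edge_state)
  on <- keys[vapply(keys, get, logical(1), envir = edge_state)]
  if (!length(on)) return(matrix(integer(0), ncol = 2))
  do.call(rbind, lapply(strsplit(on, "_"), as.integer))
}

norm_edges <- function(e) {
  if (!nrow(e)) return(matrix(integer(0), ncol = 2))
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e[e[, 1] != e[, 2], , drop = FALSE])
}

edges_of <- function(edges, id) {
  unique(c(edges[edges[, 1] == id, 2], edges[edges[, 2] == id, 1]))
}
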