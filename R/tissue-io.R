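# Containers and file I/O for tracked, segmented tissue movies.
#
# A movie is a list of integer label matrices (rows = y, columns = x,
# background 0), a tracking table mapping (frame, label) to a persistent
# cell_id with optional parent_id lineage, and physical metadata. Frames are
# 0-based throughout; image coordinates are x-right / y-down; centroids and
# polygons are reported in microns.

#' Construct a tracked tissue movie
#'
#' @param frames List of integer label matrices (background 0, labels > 0).
#' @param tracks Data frame with columns `frame`, `label`, `cell_id`,
#'   `parent_id` (NA for founder cells). One row per labeled region.
#' @param pixel_size_um Pixel edge length, microns.
#' @param frame_interval_min Time between frames, minutes.
#' @return An object of class `tissue_movie`.
#' @export
tissue_movie <- function(frames, tracks, pixel_size_um, frame_interval_min = 10) {
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  if (frame_interval_min <= 0) stop("frame_interval_min must be positive")
  stopifnot(is.list(frames), length(frames) >= 1)
  tracks <- as.data.frame(tracks)
  need <- c("frame", "label", "cell_id", "parent_id")
  if (!all(need %in% names(tracks))) {
    stop("tracks must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tracks[, c("frame", "label")])) {
    stop("duplicate (frame, label) rows in tracking table")
  }
  if (anyDuplicated(tracks[, c("frame", "cell_id")])) {
    stop("a cell_id occupies more than one region in a frame")
  }
  # every tracked label must exist in its frame
  for (f in unique(tracks$frame)) {
    present <- setdiff(unique(as.vector(frames[[f + 1L]])), 0L)
    missing <- setdiff(tracks$label[tracks$frame == f], present)
    if (length(missing)) {
      stop(sprintf("consistency error: label(s) %s in tracking table absent from frame %d",
                   paste(missing, collapse = ","), f))
    }
  }
  structure(list(frames = frames, tracks = tracks,
                 pixel_size_um = pixel_size_um,
                 frame_interval_min = frame_interval_min),
            class = "tissue_movie")
}

#' @export
print.tissue_movie <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<tissue_movie> %d frames of %dx%d px (%.3g um/px, %g min/frame)\n",
              length(x$frames), d[1], d[2], x$pixel_size_um,
              x$frame_interval_min))
  cat(sprintf("  %d tracked regions, %d cells\n", nrow(x$tracks),
              length(unique(x$tracks$cell_id))))
  invisible(x)
}

n_frames <- function(movie) length(movie$frames)

# lineage as named vector: cell_id -> parent_id (NA for founders)
movie_lineage <- function(movie) {
  tr <- movie$tracks[!duplicated(movie$tracks$cell_id), ]
  stats::setNames(tr$parent_id, tr$cell_id)
}

# label of a cell in a frame, NA if absent
cell_label_at <- function(movie, frame, cell_id) {
  tr <- movie$tracks
  hit <- tr$frame == frame & tr$cell_id == cell_id
  if (!any(hit)) return(NA_integer_)
  tr$label[hit][1]
}

# centroid (um) of a cell in a frame from pixel positions, NA if absent
cell_centroid_at <- function(movie, frame, cell_id) {
  lab <- cell_label_at(movie, frame, cell_id)
  if (is.na(lab)) return(c(NA_real_, NA_real_))
  m <- movie$frames[[frame + 1L]]
  idx <- which(m == lab)
  if (!length(idx)) return(c(NA_real_, NA_real_))
  nr <- nrow(m)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  c(mean(cols) - 0.5, mean(rows) - 0.5) * movie$pixel_size_um
}

#' Construct an ommatidium annotation
#'
#' Records which tracked cells play which role in one ommatidium, the
#' orientation of the morphogenetic furrow in image coordinates, the frame at
#' which R7 is recruited (the temporal alignment landmark), the rotation
#' chirality, and the set of first-level interommatidial neighbors frozen at
#' the R7-recruitment frame.
#'
#' @param roles Named character vector mapping cell_id (names) to one of
#'   `"R1"`..`"R8"`, `"cone"`, `"IC"`.
#' @param furrow_axis_deg Orientation of the furrow line, degrees, in image
#'   coordinates (x-right, y-down).
#' @param r7_frame 0-based frame of R7 recruitment, or `NA` if unknown.
#' @param chirality `"clockwise"` or `"counterclockwise"`.
#' @param first_level_ics Integer cell_ids of first-level IC neighbors
#'   (cone cells included), frozen at `r7_frame`.
#' @param r16_frame Optional 0-based frame at which R1/R6 join the cluster.
#' @return Object of class `ommatidium_annotation`.
#' @export
ommatidium_annotation <- function(roles, furrow_axis_deg = 0, r7_frame = NA,
                                  chirality = c("counterclockwise", "clockwise"),
                                  first_level_ics = integer(0),
                                  r16_frame = NA) {
  chirality <- match.arg(chirality)
  rcells <- names(roles)[roles %in% paste0("R", 1:8)]
  counts <- table(roles[roles %in% paste0("R", 1:8)])
  if (any(counts != 1)) stop("each R1-R8 role must be assigned exactly once")
  if (length(intersect(as.integer(rcells), as.integer(first_level_ics)))) {
    stop("first_level_ics must be disjoint from the R cells")
  }
  structure(list(roles = roles, furrow_axis_deg = furrow_axis_deg,
                 r7_frame = r7_frame, r16_frame = r16_frame,
                 chirality = chirality,
                 first_level_ics = as.integer(first_level_ics)),
            class = "ommatidium_annotation")
}

role_cell <- function(annotation, role) {
  id <- names(annotation$roles)[annotation$roles == role]
  if (!length(id)) return(NA_integer_)
  as.integer(id[1])
}

#' Write / read a tracked tissue movie
#'
#' The on-disk layout is a multi-page TIFF of 16-bit label images (background
#' 0), a tracking CSV (`frame,label,cell_id,parent_id`), and a JSON metadata
#' file carrying pixel size and frame interval. The round trip is lossless
#' for label values below 65536.
#'
#' @param movie A [tissue_movie()].
#' @param path Base path; `<path>.tif`, `<path>_tracks.csv` and
#'   `<path>_meta.json` are written next to each other.
#' @return `write_movie()` returns `path` invisibly; `read_movie()` returns a
#'   [tissue_movie()].
#' @export
write_movie <- function(movie, path) {
  pages <- lapply(movie$frames, function(m) {
    if (max(m) > 65535L) stop("label value exceeds uint16 range")
    m / 65535
  })
  tiff::writeTIFF(pages, paste0(path, ".tif"), bits.per.sample = 16L)
  write.csv(movie$tracks, paste0(path, "_tracks.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(pixel_size_um = movie$pixel_size_um,
         frame_interval_min = movie$frame_interval_min),
    paste0(path, "_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  pages <- tiff::readTIFF(paste0(path, ".tif"), all = TRUE)
  frames <- lapply(pages, function(m) {
    storage <- round(m * 65535)
    mode(storage) <- "integer"
    storage
  })
  tracks <- read.csv(paste0(path, "_tracks.csv"))
  for (col in c("frame", "label", "cell_id", "parent_id")) {
    tracks[[col]] <- as.integer(tracks[[col]])
  }
  meta <- jsonlite::read_json(paste0(path, "_meta.json"), simplifyVector = TRUE)
  tissue_movie(frames, tracks, meta$pixel_size_um, meta$frame_interval_min)
}

#' Write / read an ommatidium annotation (JSON or YAML)
#'
#' @param annotation An [ommatidium_annotation()].
#' @param path File path; format chosen by extension (`.json`, `.yml`/`.yaml`).
#' @export
write_annotation <- function(annotation, path) {
  payload <- list(
    roles = as.list(annotation$roles),
    furrow_axis_deg = annotation$furrow_axis_deg,
    r7_frame = if (is.na(annotation$r7_frame)) "unknown" else annotation$r7_frame,
    r16_frame = if (is.na(annotation$r16_frame)) "unknown" else annotation$r16_frame,
    chirality = annotation$chirality,
    first_level_ics = annotation$first_level_ics)
  if (grepl("\\.(yml|yaml)$", path)) {
    yaml::write_yaml(payload, path)
  } else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  payload <- if (grepl("\\.(yml|yaml)$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  parse_frame <- function(x) {
    if (is.null(x) || identical(x, "unknown")) NA else as.integer(x)
  }
  ommatidium_annotation(
    roles = unlist(payload$roles),
    furrow_axis_deg = payload$furrow_axis_deg,
    r7_frame = parse_frame(payload$r7_frame),
    chirality = payload$chirality,
    first_level_ics = as.integer(unlist(payload$first_level_ics)),
    r16_frame = parse_frame(payload$r16_frame))
}

#' Write / read kinetic traces as CSV
#'
#' Column units are documented in the header names (`time_s`,
#' `roi_intensity`, `ref_*` for FRAP; `time_s`, `vertex_distance_um` for
#' recoil).
#'
#' @param trace A `frap_trace` or `recoil_trace` data frame.
#' @param path CSV path.
#' @export
write_trace <- function(trace, path) {
  df <- as.data.frame(trace)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @param type `"frap"` or `"recoil"`.
#' @param l0_um Pre-ablation junction length for recoil traces (required when
#'   reading a recoil trace).
#' @export
read_trace <- function(path, type = c("frap", "recoil"), l0_um = NULL) {
  type <- match.arg(type)
  df <- read.csv(path)
  if (type == "frap") {
    stopifnot(all(c("time_s", "roi_intensity") %in% names(df)))
    class(df) <- c("frap_trace", "data.frame")
  } else {
    stopifnot(all(c("time_s", "vertex_distance_um") %in% names(df)))
    if (is.null(l0_um)) stop("l0_um is required for recoil traces")
    attr(df, "l0_um") <- l0_um
    class(df) <- c("recoil_trace", "data.frame")
  }
  df
}
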