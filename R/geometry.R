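# Cell-shape and jamming metrics.
#
# The shape index p0 = L / sqrt(A) (perimeter over root area) is the
# standard dimensionless readout of epithelial fluidity: the isoperimetric
# bound gives p0 >= 2 sqrt(pi) ~ 3.545 for any cell, regular polygons sit at
# sqrt(4 n tan(pi/n)), and a jamming transition has been proposed at the
# regular-pentagon value 3.81, below which a confluent tissue behaves as a
# solid. The classification here is always reported as a comparison against
# that literature threshold, never hard-coded into pass/fail logic.

#' Cell shape index
#'
#' `p0 = L / sqrt(A)` for perimeter `L` and area `A`; dimensionless and
#' invariant under uniform scaling.
#'
#' @param L Perimeter (um). @param A Area (um^2). Both must be positive;
#'   vectors recycle.
#' @return Numeric shape index.
#' @examples
#' shape_index(4, 1)                         # unit square: 4
#' p <- regular_polygon(5)                   # regular pentagon: 3.81,
#' shape_index(polygon_perimeter(p), polygon_area(p)) # the jamming threshold
#' @export
shape_index <- function(L, A) {
  if (any(!is.finite(L)) || any(!is.finite(A)) || any(L <= 0) || any(A <= 0)) {
    stop("domain error: L and A must be positive")
  }
  L / sqrt(A)
}

#' Jamming threshold shape index
#'
#' The regular-pentagon shape index `sqrt(20 tan(pi/5))` = 3.812...,
#' the proposed solid-fluid transition point for confluent tissue.
#' @return Numeric scalar.
#' @export
jamming_threshold <- function() sqrt(20 * tan(pi / 5))

#' First- and second-level interommatidial neighbors of a cluster
#'
#' First-level cells are those adjacent to any photoreceptor (R1-R8) in the
#' given frame geometry (cone cells included); second-level cells are those
#' adjacent to a first-level cell, excluding the cluster and the first level
#' itself.
#'
#' @param geometry A [build_cell_graph()] result at the R7-recruitment frame.
#' @param annotation An [ommatidium_annotation()].
#' @return List with integer vectors `first` and `second`.
#' @export
neighbor_levels <- function(geometry, annotation) {
  rids <- vapply(paste0("R", 1:8), function(r) role_cell(annotation, r),
                 integer(1))
  rids <- rids[!is.na(rids)]
  adj <- geometry$adjacency
  nb_of <- function(ids) {
    sel <- adj[, 1] %in% ids | adj[, 2] %in% ids
    setdiff(unique(as.vector(adj[sel, , drop = FALSE])), ids)
  }
  first <- sort(setdiff(nb_of(rids), rids))
  second <- sort(setdiff(nb_of(first), c(rids, first)))
  list(first = first, second = second)
}

#' Shape-index statistics over the interommatidial field
#'
#' Mean and standard deviation of the shape index over the union of the
#' first- and second-level IC neighbors of the cluster (levels selectable),
#' excluding border-touching cells. Both moments together are the standard
#' per-ommatidium fluidity readout: higher and more variable p0 indicates a
#' more fluid field.
#'
#' @param geometry A [build_cell_graph()] result at the R7-recruitment frame.
#' @param annotation An [ommatidium_annotation()].
#' @param levels Which neighbor levels to pool (subset of `c(1, 2)`).
#' @param exclude_cones Drop cells annotated as cone cells.
#' @return Named list `mean`, `sd`, `n`, `cells`, `above_threshold`
#'   (comparison of the mean against [jamming_threshold()]).
#' @export
field_shape_stats <- function(geometry, annotation, levels = c(1, 2),
                              exclude_cones = FALSE) {
  lv <- neighbor_levels(geometry, annotation)
  pool <- c(if (1 %in% levels) lv$first, if (2 %in% levels) lv$second)
  if (exclude_cones) {
    cones <- as.integer(names(annotation$roles)[annotation$roles == "cone"])
    pool <- setdiff(pool, cones)
  }
  cells <- geometry$cells
  cells <- cells[cells$cell_id %in% pool & !cells$border, , drop = FALSE]
  if (nrow(cells) < 3) {
    stop("insufficient data: fewer than 3 eligible cells")
  }
  p0 <- shape_index(cells$perimeter_um, cells$area_um2)
  list(mean = mean(p0), sd = sd(p0), n = length(p0),
       cells = cells$cell_id, above_threshold = mean(p0) > jamming_threshold())
}

#' Polygon-class (side-number) distribution
#'
#' Histogram of neighbor counts over interior cells, classes 3 ... 9+ with
#' fractions normalized to 1. Altered polygon distributions (fewer hexagons,
#' more pentagons) accompany reduced junctional remodeling.
#'
#' @param geometry A [build_cell_graph()] result.
#' @param cells Cell ids to tally; defaults to all interior (non-border)
#'   cells.
#' @return Data frame `class` ("3".."8", "9+"), `count`, `fraction`.
#' @export
polygon_class_distribution <- function(geometry, cells = NULL) {
  tab <- geometry$cells
  tab <- tab[!tab$border, , drop = FALSE]
  if (!is.null(cells)) tab <- tab[tab$cell_id %in% cells, , drop = FALSE]
  if (!nrow(tab)) stop("no interior cells to tally")
  n <- pmax(tab$n_sides, 3)
  cls <- ifelse(n >= 9, "9+", as.character(n))
  levels <- c(as.character(3:8), "9+")
  counts <- vapply(levels, function(l) sum(cls == l), numeric(1))
  data.frame(class = levels, count = as.integer(counts),
             fraction = counts / sum(counts), row.names = NULL)
}
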