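#' Friction surface
#'
#' A raster of traversal cost in minutes per metre for one travel mode.
#'
#' @param layer raster_grid of minutes/metre (values > 0 or NA).
#' @param mode "walk" or "drive".
#' @return object of class `friction_surface`.
#' @export
friction_surface <- function(layer, mode = c("walk", "drive")) {
  mode <- match.arg(mode)
  stopifnot(inherits(layer, "raster_grid"))
  if (any(layer$values <= 0, na.rm = TRUE))
    stop("friction values must be > 0 (or nodata)")
  structure(list(layer = layer, mode = mode), class = "friction_surface")
}

#' Filter a facility table by size class
#'
#' The production analysis restricts to "medium and large" facilities; the
#' size threshold is an input, not a constant.
#'
#' @param facilities data.frame with a `size_class` column.
#' @param keep character vector of size classes to retain.
#' @return filtered data.frame.
#' @export
filter_facilities <- function(facilities, keep = c("medium", "large")) {
  stopifnot("size_class" %in% names(facilities))
  out <- facilities[facilities$size_class %in% keep, , drop = FALSE]
  if (nrow(out) == 0) stop("no facilities left after size filter")
  out
}

#' Least-cost travel time to the nearest facility
#'
#' Multi-source least-cost distance over the friction raster with
#' 8-connectivity: the cost of a step between adjacent cells is the mean of
#' the two cells' friction (minutes/metre) times the step length
#' (`cell_size`, or `cell_size * sqrt(2)` diagonally). Exact Dijkstra via
#' the igraph shortest-path machinery; no heuristic.
#'
#' @param friction [friction_surface()].
#' @param facilities data.frame with `x`, `y` columns (metres).
#' @return object of class `travel_time_layer`: list with `layer`
#'   (raster_grid of minutes, 0 at facility cells, NA where friction is
#'   nodata) and `mode`.
#' @export
travel_time <- function(friction, facilities) {
  stopifnot(inherits(friction, "friction_surface"))
  g <- friction$layer
  nr <- nrow(g$values); nc <- ncol(g$values); cs <- g$cell_size
  fr <- g$values
  if (nrow(facilities) < 1) stop("need at least one facility")
  rc <- locate_cells(g, facilities$x, facilities$y)
  fac_idx <- unique((rc$row - 1L) * nc + rc$col)  # row-major vertex ids
  ok <- !is.na(fr[cbind(rc$row, rc$col)])
  if (!any(ok)) stop("all facilities fall on nodata cells")
  fac_idx <- unique((rc$row[ok] - 1L) * nc + rc$col[ok])

  # build 8-connected lattice edges once (vectorized over offsets)
  vid <- function(r, c) (r - 1L) * nc + c
  edges <- list(); wts <- list(); k <- 0
  offsets <- rbind(c(0, 1, 1), c(1, 0, 1), c(1, 1, sqrt(2)), c(1, -1, sqrt(2)))
  rows <- matrix(rep(seq_len(nr), nc), nr, nc)
  colsm <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  for (o in seq_len(nrow(offsets))) {
    dr <- offsets[o, 1]; dc <- offsets[o, 2]; len <- offsets[o, 3] * cs
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0) seq_len(nc - dc) else seq.int(1 - dc, nc)
    from_r <- rep(r1, times = length(c1)); from_c <- rep(c1, each = length(r1))
    to_r <- from_r + dr; to_c <- from_c + dc
    w <- (fr[cbind(from_r, from_c)] + fr[cbind(to_r, to_c)]) / 2 * len
    keep <- !is.na(w)
    k <- k + 1
    edges[[k]] <- rbind(vid(from_r, from_c)[keep], vid(to_r, to_c)[keep])
    wts[[k]] <- w[keep]
  }
  el <- do.call(cbind, edges)
  graph <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  graph <- igraph::add_edges(graph, as.vector(el))
  d <- igraph::distances(graph, v = fac_idx, weights = unlist(wts),
                         algorithm = "dijkstra")
  tmin <- apply(d, 2, min)
  out <- matrix(tmin, nr, nc, byrow = TRUE)
  out[is.na(fr)] <- NA
  structure(list(layer = raster_grid(out, cell_size = cs, xll = g$xll,
                                     yll = g$yll, crs = g$crs),
                 mode = friction$mode),
            class = "travel_time_layer")
}
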