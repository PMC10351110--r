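#' Zonal aggregation of raster layers
#'
#' Population-weighted mean plus cell min/max of every layer within every
#' zone, and the zone population total. Zones with no valid cells are
#' returned flagged (`empty = TRUE`) rather than dropped.
#'
#' @param layers raster_stack (or single raster_grid).
#' @param zones raster_grid of integer zone labels.
#' @param population raster_grid, or NULL for unweighted means.
#' @return data.frame: `zone`, `population`, `empty`, and per layer
#'   `<name>_mean`, `<name>_min`, `<name>_max`.
#' @export
zonal_aggregate <- function(layers, zones, population = NULL) {
  if (inherits(layers, "raster_grid"))
    layers <- raster_stack(list(layer = layers))
  ref <- layers[[1]]
  stopifnot(same_geometry(ref, zones))
  if (!is.null(population)) stopifnot(same_geometry(ref, population))
  zl <- zones$values
  zs <- sort(unique(zl[!is.na(zl)]))
  rows <- lapply(zs, function(z) {
    inz <- !is.na(zl) & zl == z
    pw <- if (is.null(population)) rep(1, sum(inz)) else population$values[inz]
    out <- list(zone = z,
                population = if (is.null(population)) sum(inz) else sum(pw, na.rm = TRUE))
    any_valid <- FALSE
    for (nm in names(layers)) {
      v <- layers[[nm]]$values[inz]
      ok <- !is.na(v) & !is.na(pw)
      if (any(ok)) {
        any_valid <- TRUE
        out[[paste0(nm, "_mean")]] <- sum(v[ok] * pw[ok]) / sum(pw[ok])
        out[[paste0(nm, "_min")]] <- min(v[ok])
        out[[paste0(nm, "_max")]] <- max(v[ok])
      } else {
        out[[paste0(nm, "_mean")]] <- NA_real_
        out[[paste0(nm, "_min")]] <- NA_real_
        out[[paste0(nm, "_max")]] <- NA_real_
      }
    }
    out$empty <- !any_valid
    as.data.frame(out)
  })
  out <- do.call(rbind, rows)
  out[, c("zone", "population", "empty",
          setdiff(names(out), c("zone", "population", "empty")))]
}

#' Range summary across an aggregation level
#'
#' @param values numeric vector of per-zone values at one aggregation level
#'   (e.g. state means of an index).
#' @return list with `min`, `max`, `width` (= max - min).
#' @export
range_summary <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 1) stop("range_summary needs at least one value")
  list(min = min(values), max = max(values), width = max(values) - min(values))
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Mean Cumulative Score across the 3Cs
#'
#' The MCS summarizes heterogeneity within a region at one aggregation
#' level: given the three per-index range widths (max - min), the
#' cumulative score is their sum and the MCS is the nearest integer of the
#' mean (rounding halves away from zero).
#'
#' @param widths numeric vector of exactly three non-negative widths
#'   (confidence, complacency, convenience — order irrelevant).
#' @return list of class `mcs_result`: `widths`, `cumulative_score`, `mcs`.
#' @export
mean_cumulative_score <- function(widths) {
  if (length(widths) != 3) stop("exactly three index widths required")
  if (any(widths < 0)) stop("negative width")
  cumulative <- sum(widths)
  structure(list(widths = widths, cumulative_score = cumulative,
                 mcs = round_half_away(cumulative / 3)),
            class = "mcs_result")
}

#' @export
print.mcs_result <- function(x, ...) {
  cat(sprintf("<mcs_result: widths %s, cumulative %g, MCS %g>\n",
              paste(x$widths, collapse = "/"), x$cumulative_score, x$mcs))
  invisible(x)
}

#' Prevalent hesitancy determinant per grid cell
#'
#' The determinant whose (orientation-corrected) score is highest per cell:
#' confidence and convenience are inverted (100 - score) so that for all
#' three layers a higher value means a stronger barrier, then the cellwise
#' argmax is taken. Ties are broken by the `priority` order (first named
#' wins). Nodata in any input propagates.
#'
#' @param confidence,complacency,convenience aligned 0-100 raster_grid (or
#'   predicted_layer) objects.
#' @param priority tie-break order, strongest first.
#' @return list: `layer` (raster_grid of integer codes), `labels` (code ->
#'   determinant name).
#' @export
prevalent_determinant <- function(confidence, complacency, convenience,
                                  priority = c("convenience", "complacency",
                                               "confidence")) {
  as_grid <- function(x) if (inherits(x, "predicted_layer")) x$layer else x
  g1 <- as_grid(confidence); g2 <- as_grid(complacency); g3 <- as_grid(convenience)
  stopifnot(same_geometry(g1, g2), same_geometry(g1, g3))
  stopifnot(setequal(priority, c("confidence", "complacency", "convenience")))
  transformed <- list(confidence = 100 - g1$values,
                      complacency = g2$values,
                      convenience = 100 - g3$values)
  # evaluate in priority order so that on ties the earlier name wins
  best_val <- transformed[[priority[1]]]
  best_cat <- matrix(priority[1], nrow(best_val), ncol(best_val))
  for (nm in priority[-1]) {
    beat <- !is.na(transformed[[nm]]) & !is.na(best_val) &
      transformed[[nm]] > best_val
    best_val[beat] <- transformed[[nm]][beat]
    best_cat[beat] <- nm
  }
  nodata <- is.na(transformed[[1]]) | is.na(transformed[[2]]) |
    is.na(transformed[[3]])
  labels <- c(confidence = 1, complacency = 2, convenience = 3)
  code <- matrix(labels[best_cat], nrow(best_val), ncol(best_val))
  code[nodata] <- NA
  list(layer = raster_grid(code, cell_size = g1$cell_size, xll = g1$xll,
                           yll = g1$yll, crs = g1$crs),
       labels = c("1" = "confidence", "2" = "complacency",
                  "3" = "convenience"))
}

#' People-count layer aggregation
#'
#' Combines a proportion layer (e.g. the low-confidence tercile share) with
#' the population raster: per zone, the count is the sum over cells of
#' share x population; the national total equals the sum over zones.
#'
#' @param share_layer raster_grid (or predicted_layer) with values in [0,1].
#' @param population raster_grid of persons per cell.
#' @param zones raster_grid of integer zone labels.
#' @return data.frame: `zone`, `count`.
#' @export
population_count <- function(share_layer, population, zones) {
  g <- if (inherits(share_layer, "predicted_layer")) share_layer$layer
       else share_layer
  stopifnot(same_geometry(g, population), same_geometry(g, zones))
  v <- g$values
  if (any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE))
    stop("share layer has values outside [0,1]; renormalize terciles first")
  zl <- zones$values
  zs <- sort(unique(zl[!is.na(zl)]))
  counts <- vapply(zs, function(z) {
    inz <- !is.na(zl) & zl == z
    sum(v[inz] * population$values[inz], na.rm = TRUE)
  }, numeric(1))
  data.frame(zone = zs, count = counts)
}

#' Multi-criteria zone targeting
#'
#' Returns the zones satisfying ALL criteria, each criterion a triple
#' (column, comparator, threshold) evaluated against a zone-stats table —
#' e.g. isolate LGAs with at least 50% speakers of a language that also
#' have majority low-confidence proportions. With no criteria, all zones
#' are returned. Output is ordered by zone id.
#'
#' @param zone_stats data.frame with a `zone` column (e.g.
#'   [zonal_aggregate()] output).
#' @param criteria list of lists: `list(column=, op=, threshold=)` with op
#'   one of ">=", ">", "<=", "<", "==".
#' @return vector of zone ids.
#' @export
select_zones <- function(zone_stats, criteria = list()) {
  stopifnot("zone" %in% names(zone_stats))
  keep <- rep(TRUE, nrow(zone_stats))
  for (cr in criteria) {
    if (!cr$column %in% names(zone_stats))
      stop("unknown layer/column in criteria: ", cr$column)
    x <- zone_stats[[cr$column]]
    keep <- keep & switch(cr$op,
      ">=" = x >= cr$threshold, ">" = x > cr$threshold,
      "<=" = x <= cr$threshold, "<" = x < cr$threshold,
      "==" = x == cr$threshold,
      stop("unknown comparator: ", cr$op))
  }
  keep[is.na(keep)] <- FALSE
  sort(zone_stats$zone[keep])
}
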