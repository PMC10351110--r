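#' Write zone polygons to GeoJSON
#'
#' Each LGA becomes one rectangular Polygon feature (zones are rectangles
#' in the synthetic world; for a general label raster the bounding box of
#' the label is written) with properties `lga_id` and `state_id`.
#' Coordinates are in the local metre frame; the CRS tag is carried in the
#' top-level `crs_note` member as pass-through metadata.
#'
#' @param lga_zones raster_grid of LGA labels.
#' @param state_zones raster_grid of state labels (majority state per LGA).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_zones_geojson <- function(lga_zones, state_zones, path) {
  stopifnot(same_geometry(lga_zones, state_zones))
  zl <- lga_zones$values; cs <- lga_zones$cell_size
  nr <- nrow(zl)
  feats <- lapply(sort(unique(zl[!is.na(zl)])), function(z) {
    idx <- which(zl == z, arr.ind = TRUE)
    # cell rows count from north; convert to metre extents
    x0 <- lga_zones$xll + (min(idx[, 2]) - 1) * cs
    x1 <- lga_zones$xll + max(idx[, 2]) * cs
    y0 <- lga_zones$yll + (nr - max(idx[, 1])) * cs
    y1 <- lga_zones$yll + (nr - min(idx[, 1]) + 1) * cs
    st <- state_zones$values[idx]
    st <- as.numeric(names(sort(table(st), decreasing = TRUE))[1])
    list(type = "Feature",
         properties = list(lga_id = z, state_id = st),
         geometry = list(type = "Polygon",
                         coordinates = list(list(
                           c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1),
                           c(x0, y0)))))
  })
  gj <- list(type = "FeatureCollection",
             crs_note = lga_zones$crs,
             features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# even-odd (ray casting) point-in-polygon; ring is a 2-column matrix
point_in_ring <- function(px, py, ring) {
  n <- nrow(ring) - 1
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Rasterize zone polygons from GeoJSON onto a template grid
#'
#' Cell membership by the containing-cell-centre rule (a cell belongs to
#' the polygon that contains its centre; even-odd test), which matches the
#' rectangular half-open cell convention used throughout.
#'
#' @param path GeoJSON FeatureCollection with Polygon features carrying an
#'   id property.
#' @param template raster_grid defining the target geometry.
#' @param id_property property naming the zone id (default "lga_id").
#' @return raster_grid of zone labels (NA outside all polygons).
#' @export
read_zones_geojson <- function(path, template, id_property = "lga_id") {
  if (!file.exists(path)) stop("no such file: ", path)
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a FeatureCollection: ", path)
  cc <- cell_centres(template)
  lab <- rep(NA_real_, nrow(cc))
  for (f in gj$features) {
    if (f$geometry$type != "Polygon") stop("only Polygon features supported")
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    id <- f$properties[[id_property]]
    if (is.null(id)) stop("feature without property '", id_property, "'")
    hit <- point_in_ring(cc$x, cc$y, ring)
    lab[hit] <- as.numeric(id)
  }
  raster_grid(matrix(lab, nrow(template$values), ncol(template$values),
                     byrow = TRUE),
              cell_size = template$cell_size, xll = template$xll,
              yll = template$yll, crs = template$crs)
}

#' Read a survey CSV with schema validation
#'
#' @param path CSV path.
#' @param required character vector of required columns.
#' @return data.frame.
#' @export
read_survey_csv <- function(path,
                            required = c("respondent_id", "cluster_id",
                                         "state_id", "lga_id", "x", "y",
                                         "weight")) {
  if (!file.exists(path)) stop("no such survey file: ", path)
  df <- as.data.frame(data.table::fread(path))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("survey file ", path, " missing required column(s): ",
         paste(missing, collapse = ", "))
  df
}
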