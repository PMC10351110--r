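#' Raster grid and raster stack containers
#'
#' `raster_grid()` wraps a numeric matrix in a minimal north-up, row-major
#' raster: row 1 is the northernmost row, cells are square with side
#' `cell_size` metres, and the grid origin (`xll`, `yll`) is the lower-left
#' corner in a local projected frame. Cells are half-open intervals
#' `[x, x + cell_size)` so point-to-cell lookup is deterministic on edges.
#' `NA` entries are nodata.
#'
#' @param values numeric matrix (row 1 = north).
#' @param cell_size cell side length in metres.
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @param crs free-text CRS tag carried as pass-through metadata.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, cell_size = 1000, xll = 0, yll = 0,
                        crs = "local-metric") {
  stopifnot(is.matrix(values), is.numeric(cell_size), cell_size > 0)
  storage.mode(values) <- "double"
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         xll = as.numeric(xll), yll = as.numeric(yll), crs = crs),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid %d x %d, cell %g m, origin (%g, %g)>\n",
              nrow(x$values), ncol(x$values), x$cell_size, x$xll, x$yll))
  rng <- suppressWarnings(range(x$values, na.rm = TRUE))
  cat(sprintf("  values: [%.4g, %.4g], %d nodata cells\n",
              rng[1], rng[2], sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' Test that two rasters share one geometry
#' @param a,b raster_grid objects.
#' @return TRUE/FALSE.
#' @export
same_geometry <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$cell_size, a$xll, a$yll),
                     c(b$cell_size, b$xll, b$yll)))
}

#' Raster stack: named list of aligned raster_grid layers
#' @param layers named list of `raster_grid` objects sharing one geometry.
#' @return An object of class `raster_stack`.
#' @export
raster_stack <- function(layers) {
  stopifnot(is.list(layers), length(layers) >= 1,
            !is.null(names(layers)), all(nzchar(names(layers))))
  for (l in layers) stopifnot(inherits(l, "raster_grid"))
  ref <- layers[[1]]
  for (l in layers[-1]) {
    if (!same_geometry(ref, l)) stop("raster_stack layers are not aligned")
  }
  structure(list(layers = layers), class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("<raster_stack of %d layers: %s>\n", length(x$layers),
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' @export
names.raster_stack <- function(x) names(x$layers)

#' @export
`[[.raster_stack` <- function(x, i) x$layers[[i]]

#' Cell-centre coordinates for every cell of a raster
#'
#' @param grid raster_grid.
#' @return data.frame with `row`, `col`, `x`, `y` (one row per cell,
#'   row-major order, matching `as.vector(t(values))` ... cells are listed
#'   by row then column).
#' @export
cell_centres <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values); cs <- grid$cell_size
  rows <- rep(seq_len(nr), each = nc)
  cols <- rep(seq_len(nc), times = nr)
  data.frame(
    row = rows, col = cols,
    x = grid$xll + (cols - 0.5) * cs,
    y = grid$yll + (nr - rows + 0.5) * cs
  )
}

#' Locate the cell containing each point (half-open cell convention)
#'
#' @param grid raster_grid.
#' @param x,y point coordinates (metres, same frame as the grid).
#' @return data.frame with `row`, `col` (1-based; row 1 = north).
#' @export
locate_cells <- function(grid, x, y) {
  stopifnot(length(x) == length(y))
  nr <- nrow(grid$values); nc <- ncol(grid$values); cs <- grid$cell_size
  col <- floor((x - grid$xll) / cs) + 1
  row_from_s <- floor((y - grid$yll) / cs) + 1
  row <- nr - row_from_s + 1
  bad <- which(col < 1 | col > nc | row < 1 | row > nr | !is.finite(x) | !is.finite(y))
  if (length(bad)) {
    stop("points outside raster bounds: ids ", paste(bad, collapse = ", "))
  }
  data.frame(row = row, col = col)
}

#' Extract raster values at point locations
#'
#' Pure cell-value lookup at the containing cell (no smoothing). Points on a
#' cell edge belong to the cell whose half-open interval contains them.
#'
#' @param layer raster_grid.
#' @param x,y point coordinates.
#' @return numeric vector of cell values (NA where the cell is nodata).
#' @export
extract_at_points <- function(layer, x, y) {
  rc <- locate_cells(layer, x, y)
  layer$values[cbind(rc$row, rc$col)]
}

#' Write a raster to an ESRI ASCII grid (.asc)
#'
#' Plain-text interchange format; values are written with 17 significant
#' digits so doubles round-trip exactly. Nodata is encoded as -9999 unless
#' that value occurs in the data, in which case a safe sentinel is chosen.
#'
#' @param grid raster_grid.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  v <- grid$values
  nodata <- -9999
  while (any(v == nodata, na.rm = TRUE)) nodata <- nodata * 10 - 1
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.17g", grid$xll),
    sprintf("yllcorner %.17g", grid$yll),
    sprintf("cellsize %.17g", grid$cell_size),
    sprintf("NODATA_value %.17g", nodata)
  ), con)
  writeLines(apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")), con)
  invisible(path)
}

#' Read an ESRI ASCII grid (.asc)
#'
#' @param path file path.
#' @param crs CRS tag to attach.
#' @return raster_grid.
#' @export
read_ascii_grid <- function(path, crs = "local-metric") {
  if (!file.exists(path)) stop("no such raster file: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("malformed ASCII grid header in ", path, " (line ", i, ")")
  }
  body <- lines[i:length(lines)]
  vals <- as.numeric(unlist(strsplit(trimws(body[nzchar(trimws(body))]), "\\s+")))
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) {
    stop("ASCII grid ", path, ": expected ", nr * nc, " values, got ", length(vals))
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  raster_grid(m,
              cell_size = hdr$cellsize,
              xll = if (is.null(hdr$xllcorner)) 0 else hdr$xllcorner,
              yll = if (is.null(hdr$yllcorner)) 0 else hdr$yllcorner,
              crs = crs)
}

#' Convert a raster stack to a covariate matrix (one row per cell)
#'
#' Rows are in row-major cell order (the order of [cell_centres()]).
#'
#' @param stack raster_stack.
#' @return numeric matrix, one column per layer.
#' @export
stack_to_matrix <- function(stack) {
  cols <- lapply(stack$layers, function(l) as.vector(t(l$values)))
  m <- do.call(cbind, cols)
  colnames(m) <- names(stack$layers)
  m
}
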