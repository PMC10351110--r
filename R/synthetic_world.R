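#' Configuration of the synthetic country
#'
#' The generator emulates the data environment of the Nigeria application at
#' desk scale: a 60 x 60 grid of 1 km^2 cells, 6 states subdivided into 4
#' LGAs each, 120 survey clusters of 41 respondents (4,920 respondents,
#' mirroring the ~4,922 of the source survey), and 12 smooth spatial
#' covariates standing in for the "approximately 130" satellite-derived
#' layers of the production system.
#'
#' @param grid_width,grid_height grid dimensions in cells.
#' @param cell_size cell side in metres (default 1000 = 1 km^2 cells).
#' @param n_states number of first-level admin zones.
#' @param lgas_per_state second-level zones nested per state.
#' @param n_clusters number of survey clusters (cells).
#' @param respondents_per_cluster respondents drawn per cluster.
#' @param n_covariates number of synthetic covariate layers (>= 3).
#' @param covariate_smoothness Gaussian correlation length, in cells.
#' @param effect_matrix `n_covariates x 4` loadings of the covariates on the
#'   latent constructs (columns `confidence`, `complacency`, `accessibility`,
#'   `time_financial`). Default: [default_effect_matrix()].
#' @param noise_sd sd of the smooth spatial noise added to each latent field,
#'   on the latent (logit) scale.
#' @param n_facilities number of health facilities to place.
#' @param seed integer seed; the same seed yields a bit-identical world.
#' @return list of class `world_config`.
#' @export
world_config <- function(grid_width = 60, grid_height = 60, cell_size = 1000,
                         n_states = 6, lgas_per_state = 4,
                         n_clusters = 120, respondents_per_cluster = 41,
                         n_covariates = 12, covariate_smoothness = 6,
                         effect_matrix = default_effect_matrix(n_covariates),
                         noise_sd = 0.4, n_facilities = 30, seed = 1L) {
  cfg <- list(grid_width = as.integer(grid_width),
              grid_height = as.integer(grid_height),
              cell_size = cell_size, n_states = as.integer(n_states),
              lgas_per_state = as.integer(lgas_per_state),
              n_clusters = as.integer(n_clusters),
              respondents_per_cluster = as.integer(respondents_per_cluster),
              n_covariates = as.integer(n_covariates),
              covariate_smoothness = covariate_smoothness,
              effect_matrix = effect_matrix, noise_sd = noise_sd,
              n_facilities = as.integer(n_facilities), seed = as.integer(seed))
  counts <- c(cfg$grid_width, cfg$grid_height, cfg$n_states,
              cfg$lgas_per_state, cfg$n_clusters, cfg$respondents_per_cluster,
              cfg$n_covariates, cfg$n_facilities)
  if (any(counts <= 0)) stop("all counts in world_config must be > 0")
  if (cfg$n_covariates < 3) stop("need at least 3 covariates")
  if (cfg$n_states * cfg$lgas_per_state > cfg$grid_width * cfg$grid_height)
    stop("more zones than grid cells")
  if (cfg$n_clusters > cfg$grid_width * cfg$grid_height)
    stop("more clusters than grid cells")
  stopifnot(is.matrix(effect_matrix),
            nrow(effect_matrix) == cfg$n_covariates,
            ncol(effect_matrix) == 4)
  colnames(cfg$effect_matrix) <- c("confidence", "complacency",
                                   "accessibility", "time_financial")
  class(cfg) <- "world_config"
  cfg
}

#' Default covariate loadings for the four latent constructs
#'
#' Each construct loads on three covariates (one shared "urbanicity" driver,
#' two construct-specific), so every construct has recoverable signal while
#' the constructs stay distinguishable.
#'
#' @param n_covariates number of covariate layers (>= 3).
#' @return `n_covariates x 4` numeric matrix.
#' @export
default_effect_matrix <- function(n_covariates = 12) {
  em <- matrix(0, nrow = n_covariates, ncol = 4,
               dimnames = list(NULL, c("confidence", "complacency",
                                       "accessibility", "time_financial")))
  em[1, ] <- c(0.5, 0.4, 0.7, 0.3)  # urbanicity drives all four constructs
  pick <- function(k) (k %% n_covariates) + 1
  em[pick(2), 1] <- 0.8; em[pick(3), 1] <- -0.5
  em[pick(4), 2] <- 0.8; em[pick(5), 2] <- -0.5
  em[pick(6), 3] <- 0.6
  em[pick(7), 4] <- 0.8; em[pick(8), 4] <- -0.5
  em
}

# smooth Gaussian random field: white noise convolved with a separable
# Gaussian kernel (reflected edges), standardized to mean 0 / sd 1
gaussian_field <- function(nr, nc, smoothness) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (smoothness <= 0) return(standardize_field(z))
  half <- max(1L, ceiling(3 * smoothness))
  k <- stats::dnorm(seq(-half, half), sd = smoothness)
  k <- k / sum(k)
  conv1 <- function(m) {  # convolve columns of m with k, reflect padding
    n <- nrow(m)
    pad <- rbind(m[rev(seq_len(min(half, n))), , drop = FALSE],
                 m,
                 m[rev(seq.int(max(1L, n - half + 1L), n)), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    off <- nrow(pad) - n - min(half, n)  # rows of bottom pad
    top <- min(half, n)
    for (j in seq_along(k)) {
      idx <- seq_len(n) + top + (j - 1L) - half
      idx[idx < 1L] <- 1L; idx[idx > nrow(pad)] <- nrow(pad)
      out <- out + k[j] * pad[idx, , drop = FALSE]
    }
    out
  }
  z <- conv1(z)
  z <- t(conv1(t(z)))
  standardize_field(z)
}

standardize_field <- function(m) {
  s <- stats::sd(as.vector(m))
  if (!is.finite(s) || s == 0) return(m - mean(m))
  (m - mean(m)) / s
}

# rectangular partition of an nr x nc grid into n contiguous blocks,
# returned as an integer label matrix (labels 1..n, row-major block order)
partition_zones <- function(nr, nc, n) {
  a <- floor(sqrt(n))
  while (n %% a != 0) a <- a - 1
  b <- n / a  # a block-rows x b block-cols, a <= b
  if (nr > nc) { tmp <- a; a <- b; b <- tmp }  # taller grid: more block-rows
  row_breaks <- floor(seq(0, nr, length.out = a + 1))
  col_breaks <- floor(seq(0, nc, length.out = b + 1))
  lab <- matrix(0L, nr, nc)
  z <- 0L
  for (i in seq_len(a)) for (j in seq_len(b)) {
    z <- z + 1L
    lab[(row_breaks[i] + 1):row_breaks[i + 1],
        (col_breaks[j] + 1):col_breaks[j + 1]] <- z
  }
  lab
}

# definition of the attitudinal survey items (Table-2-style inputs):
# construct, type (binary / ordered3), intercept a, discrimination b, and
# sign s: +1 if agreement indicates a HIGHER value of the construct's index
item_definitions <- function() {
  d <- function(item, construct, type, a, b, s)
    data.frame(item = item, construct = construct, type = type,
               a = a, b = b, s = s, stringsAsFactors = FALSE)
  rbind(
    d("vac_not_safe",            "confidence", "ordered3", 0.2, 1.6, -1),
    d("vac_not_effective",       "confidence", "ordered3", 0.1, 1.6, -1),
    d("vac_no_new_strains",      "confidence", "binary",  -0.3, 1.3, -1),
    d("trusted_not_vaccinated",  "confidence", "binary",  -0.5, 1.2, -1),
    d("no_risk_friends_family",  "complacency", "ordered3", 0.2, 1.6,  1),
    d("healthy_no_worry",        "complacency", "ordered3", 0.4, 1.5,  1),
    d("covid_not_spreading",     "complacency", "binary",   0.0, 1.3,  1),
    d("covid_not_real",          "complacency", "binary",  -0.9, 1.2,  1),
    d("had_covid_no_fear",       "complacency", "binary",  -0.6, 1.1,  1),
    d("dont_know_where",         "time_financial", "binary", -0.2, 1.5, -1),
    d("no_time",                 "time_financial", "binary", -0.4, 1.4, -1),
    d("financial_cost",          "time_financial", "binary",  0.3, 1.5, -1),
    d("scooter_owner",           "accessibility", "binary", -0.8, 1.0,  1)
  )
}

# P(yes) for binary items / P(level) for ordered3, given construct latent L
ordered3_thresholds <- c(-0.9, 0.9)

item_agree_prob <- function(def, latent) {
  eta <- def$a + def$s * def$b * latent
  if (def$type == "binary") stats::plogis(eta)
  else stats::plogis(eta - ordered3_thresholds[2])  # P("agree")
}

draw_item <- function(def, latent) {
  n <- length(latent)
  eta <- def$a + def$s * def$b * latent
  if (def$type == "binary") {
    ifelse(stats::runif(n) < stats::plogis(eta), "yes", "no")
  } else {
    u <- eta + stats::rlogis(n)
    as.character(cut(u, c(-Inf, ordered3_thresholds, Inf),
                     labels = c("disagree", "neutral", "agree")))
  }
}

#' Generate a synthetic country with known ground truth
#'
#' Builds smooth covariate fields, latent 3Cs propensity surfaces that are
#' linear in the covariates plus spatial noise, friction and population
#' rasters, health facilities placed preferentially in high-urbanicity
#' cells, nested state/LGA zones, least-cost travel-time layers, and a
#' cluster survey whose categorical responses are drawn from logistic models
#' of the cell-level latents — so interpolation has a recoverable signal and
#' every stage can be checked against the stored truth surfaces.
#'
#' @param config [world_config()].
#' @return list of class `synthetic_world` with elements `covariates`,
#'   `state_zones`, `lga_zones`, `friction_walk`, `friction_drive`,
#'   `travel_walk`, `travel_drive`, `facilities`, `population`, `latents`,
#'   `truth_indices`, `survey`, `item_defs`, `config`.
#' @export
generate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  if (all(config$effect_matrix == 0))
    warning("effect_matrix is all zeros: latent surfaces carry no covariate signal")
  withr::with_seed(config$seed, generate_world_impl(config))
}

generate_world_impl <- function(cfg) {
  nr <- cfg$grid_height; nc <- cfg$grid_width; cs <- cfg$cell_size
  ncell <- nr * nc
  grid0 <- function(m) raster_grid(m, cell_size = cs)

  # covariates: first two have interpretable roles
  cov_names <- c("urbanicity", "terrain",
                 sprintf("cov%02d", seq_len(cfg$n_covariates))[-(1:2)])
  covs <- lapply(seq_len(cfg$n_covariates), function(i)
    gaussian_field(nr, nc, cfg$covariate_smoothness))
  names(covs) <- cov_names
  covariates <- raster_stack(lapply(covs, grid0))
  X <- do.call(cbind, lapply(covs, as.vector))  # column-major cellwise

  # latent construct fields (index direction: higher = more of the construct)
  latents <- list()
  for (k in colnames(cfg$effect_matrix)) {
    f <- matrix(X %*% cfg$effect_matrix[, k], nr, nc)
    if (cfg$noise_sd > 0)
      f <- f + cfg$noise_sd * gaussian_field(nr, nc, cfg$covariate_smoothness)
    latents[[k]] <- standardize_field(f)
  }

  # population: log-linear in urbanicity, ~250 persons per cell on average
  pop <- exp(1.2 * covs$urbanicity + 0.3 * gaussian_field(nr, nc, cfg$covariate_smoothness))
  pop <- pop / mean(pop) * 250
  population <- grid0(pop)

  # friction (minutes per metre): walking ~12 min/km, driving ~1 min/km at
  # baseline, cheaper where accessibility latent is high, dearer on terrain
  fw <- 0.012 * exp(-0.35 * latents$accessibility + 0.20 * covs$terrain)
  fd <- 0.001 * exp(-0.50 * latents$accessibility + 0.30 * covs$terrain)
  friction_walk <- grid0(fw); friction_drive <- grid0(fd)

  # facilities: placement probability increasing in urbanicity
  pfac <- exp(1.5 * covs$urbanicity)
  fac_cells <- sample.int(ncell, cfg$n_facilities, prob = as.vector(pfac))
  fac_row <- ((fac_cells - 1) %% nr) + 1   # column-major index -> row/col
  fac_col <- ((fac_cells - 1) %/% nr) + 1
  size_class <- sample(c("small", "medium", "large"), cfg$n_facilities,
                       replace = TRUE, prob = c(0.35, 0.45, 0.20))
  if (!any(size_class %in% c("medium", "large"))) size_class[1] <- "medium"
  facilities <- data.frame(
    facility_id = sprintf("fac%03d", seq_len(cfg$n_facilities)),
    x = (fac_col - 0.5) * cs, y = (nr - fac_row + 0.5) * cs,
    size_class = size_class, stringsAsFactors = FALSE)

  # zones
  state_lab <- partition_zones(nr, nc, cfg$n_states)
  lga_lab <- matrix(0L, nr, nc)
  for (s in seq_len(cfg$n_states)) {
    idx <- which(state_lab == s, arr.ind = TRUE)
    sub <- partition_zones(max(idx[, 1]) - min(idx[, 1]) + 1,
                           max(idx[, 2]) - min(idx[, 2]) + 1,
                           cfg$lgas_per_state)
    lga_lab[min(idx[, 1]):max(idx[, 1]), min(idx[, 2]):max(idx[, 2])] <-
      (s - 1L) * cfg$lgas_per_state + sub
  }
  state_zones <- grid0(state_lab + 0); lga_zones <- grid0(lga_lab + 0)

  # least-cost travel times to medium/large facilities
  fac_ml <- facilities[facilities$size_class %in% c("medium", "large"), ]
  travel_walk <- travel_time(friction_surface(friction_walk, "walk"), fac_ml)
  travel_drive <- travel_time(friction_surface(friction_drive, "drive"), fac_ml)

  # measured accessibility surface: good access = short (log) travel times;
  # blended with the latent so scooter ownership stays informative
  acc_meas <- -0.5 * (standardize_field(log1p(travel_walk$layer$values)) +
                      standardize_field(log1p(travel_drive$layer$values)))
  latents$accessibility <- standardize_field(
    0.7 * acc_meas + 0.3 * latents$accessibility)

  minmax100 <- function(m) {
    rng <- range(m)
    if (diff(rng) == 0) return(m * 0 + 50)
    (m - rng[1]) / diff(rng) * 100
  }
  truth <- list(
    confidence     = minmax100(latents$confidence),
    complacency    = minmax100(latents$complacency),
    accessibility  = minmax100(latents$accessibility),
    time_financial = minmax100(latents$time_financial))
  truth$convenience <- minmax100(
    standardize_field(latents$accessibility + latents$time_financial))
  truth_indices <- raster_stack(lapply(truth, grid0))
  latent_stack <- raster_stack(lapply(latents, grid0))

  # survey: clusters sampled by population; coordinates are cell centres
  cl_cells <- sample.int(ncell, cfg$n_clusters, prob = as.vector(pop))
  cl_row <- ((cl_cells - 1) %% nr) + 1
  cl_col <- ((cl_cells - 1) %/% nr) + 1
  m <- cfg$respondents_per_cluster
  n <- cfg$n_clusters * m
  ri <- rep(seq_len(cfg$n_clusters), each = m)
  row_i <- cl_row[ri]; col_i <- cl_col[ri]
  cell_i <- cbind(row_i, col_i)

  urb <- covs$urbanicity[cell_i]
  survey <- data.frame(
    respondent_id = sprintf("r%05d", seq_len(n)),
    cluster_id = sprintf("c%03d", ri),
    state_id = state_lab[cell_i],
    lga_id = lga_lab[cell_i],
    x = (col_i - 0.5) * cs, y = (nr - row_i + 0.5) * cs,
    weight = 1,
    urbanicity = ifelse(urb > 0.95, "urban", "rural"),
    gender = sample(c("female", "male"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  survey$asset_owner <- ifelse(
    stats::runif(n) < stats::plogis(0.2 + 0.8 * urb + 0.5 * covs[[3]][cell_i]),
    "yes", "no")
  survey$radio_owner <- ifelse(
    stats::runif(n) < stats::plogis(0.8 + 0.4 * covs[[min(4, cfg$n_covariates)]][cell_i]),
    "yes", "no")
  survey$age_group <- sample(c("18-24", "25-34", "35-44", "45+"), n,
                             replace = TRUE, prob = c(0.28, 0.30, 0.22, 0.20))

  defs <- item_definitions()
  for (i in seq_len(nrow(defs))) {
    def <- defs[i, ]
    L <- latent_stack[[def$construct]]$values[cell_i]
    survey[[def$item]] <- draw_item(def, L)
  }
  survey$walk_time <- travel_walk$layer$values[cell_i]
  survey$drive_time <- travel_drive$layer$values[cell_i]

  structure(list(
    config = cfg, covariates = covariates, state_zones = state_zones,
    lga_zones = lga_zones, friction_walk = friction_walk,
    friction_drive = friction_drive, travel_walk = travel_walk,
    travel_drive = travel_drive, facilities = facilities,
    population = population, latents = latent_stack,
    truth_indices = truth_indices, survey = survey, item_defs = defs),
    class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world %dx%d cells, %d states / %d LGAs, %d respondents in %d clusters>\n",
              nrow(x$population$values), ncol(x$population$values),
              x$config$n_states, x$config$n_states * x$config$lgas_per_state,
              nrow(x$survey), x$config$n_clusters))
  invisible(x)
}

#' Generator probability of agreement for one item at survey members' cells
#'
#' Exposes the generating model's own P("yes"/"agree") so tests can compare
#' weighted survey shares with the latent probabilities they were drawn from.
#'
#' @param world synthetic_world.
#' @param item item column name.
#' @return numeric vector, one probability per survey row.
#' @export
item_probability <- function(world, item) {
  def <- world$item_defs[world$item_defs$item == item, ]
  if (nrow(def) != 1) stop("unknown item: ", item)
  rc <- locate_cells(world$latents[[def$construct]],
                     world$survey$x, world$survey$y)
  L <- world$latents[[def$construct]]$values[cbind(rc$row, rc$col)]
  item_agree_prob(def, L)
}

#' Write a synthetic world to disk
#'
#' Emits one ESRI ASCII grid per raster layer, the survey and facility CSVs,
#' LGA zone polygons as GeoJSON, and a JSON manifest recording the seed,
#' config and every file written. Round-trips losslessly through
#' [read_world()].
#'
#' @param world synthetic_world.
#' @param directory output directory (created if needed).
#' @return manifest list, invisibly.
#' @export
write_world <- function(world, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  files <- character(0)
  put <- function(grid, name) {
    f <- file.path(directory, paste0(name, ".asc"))
    write_ascii_grid(grid, f)
    files <<- c(files, basename(f))
  }
  for (nm in names(world$covariates))
    put(world$covariates[[nm]], paste0("covariate_", nm))
  put(world$state_zones, "state_zones"); put(world$lga_zones, "lga_zones")
  put(world$friction_walk, "friction_walk"); put(world$friction_drive, "friction_drive")
  put(world$travel_walk$layer, "travel_walk"); put(world$travel_drive$layer, "travel_drive")
  put(world$population, "population")
  for (nm in names(world$truth_indices))
    put(world$truth_indices[[nm]], paste0("truth_", nm))
  data.table::fwrite(world$survey, file.path(directory, "survey.csv"))
  data.table::fwrite(world$facilities, file.path(directory, "facilities.csv"))
  files <- c(files, "survey.csv", "facilities.csv")
  write_zones_geojson(world$lga_zones, world$state_zones,
                      file.path(directory, "zones.geojson"))
  files <- c(files, "zones.geojson")
  cfg <- unclass(world$config)
  cfg$effect_matrix <- unclass(cfg$effect_matrix)
  manifest <- list(seed = world$config$seed,
                   config = cfg,
                   covariate_names = names(world$covariates),
                   truth_names = names(world$truth_indices),
                   files = c(files, "manifest.json"))
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a world directory written by [write_world()]
#'
#' @param directory directory containing a `manifest.json`.
#' @return list with `covariates`, `state_zones`, `lga_zones`, friction,
#'   travel, `population`, `truth_indices`, `survey`, `facilities`,
#'   `manifest`.
#' @export
read_world <- function(directory) {
  mf <- file.path(directory, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", directory)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  rg <- function(name) read_ascii_grid(file.path(directory, paste0(name, ".asc")))
  covs <- lapply(manifest$covariate_names, function(nm) rg(paste0("covariate_", nm)))
  names(covs) <- manifest$covariate_names
  truth <- lapply(manifest$truth_names, function(nm) rg(paste0("truth_", nm)))
  names(truth) <- manifest$truth_names
  list(
    covariates = raster_stack(covs),
    state_zones = rg("state_zones"), lga_zones = rg("lga_zones"),
    friction_walk = rg("friction_walk"), friction_drive = rg("friction_drive"),
    travel_walk = rg("travel_walk"), travel_drive = rg("travel_drive"),
    population = rg("population"),
    truth_indices = raster_stack(truth),
    survey = as.data.frame(data.table::fread(file.path(directory, "survey.csv"))),
    facilities = as.data.frame(data.table::fread(file.path(directory, "facilities.csv"))),
    manifest = manifest)
}
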