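#' Weighted zone means of a survey variable with bootstrap CIs
#'
#' Means are weighted; 95% confidence intervals come from a seeded
#' cluster-level bootstrap (clusters resampled with replacement within each
#' zone), respecting the survey's cluster design. Zones with a single
#' cluster get an undefined CI (flagged); zones with no respondents are
#' flagged, not fatal.
#'
#' @param survey data.frame with `cluster_id` and the zone column.
#' @param weights respondent weights.
#' @param values per-respondent numeric values of the variable.
#' @param zone per-respondent zone labels (e.g. `survey$state_id`).
#' @param n_boot bootstrap replicates (default 500).
#' @param seed integer seed.
#' @return data.frame: `zone`, `survey_mean`, `ci_low`, `ci_high`,
#'   `n_clusters`, `ci_defined`.
#' @export
survey_zone_mean_ci <- function(survey, weights, values, zone,
                                n_boot = 500, seed = 1) {
  stopifnot(length(weights) == nrow(survey), length(values) == nrow(survey),
            length(zone) == nrow(survey))
  zones <- sort(unique(zone))
  withr::with_seed(seed, {
    rows <- lapply(zones, function(z) {
      in_z <- zone == z & !is.na(values)
      if (!any(in_z))
        return(data.frame(zone = z, survey_mean = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, n_clusters = 0L,
                          ci_defined = FALSE))
      w <- weights[in_z]; v <- values[in_z]; cl <- survey$cluster_id[in_z]
      m <- sum(w * v) / sum(w)
      ucl <- unique(cl)
      if (length(ucl) < 2)
        return(data.frame(zone = z, survey_mean = m, ci_low = NA_real_,
                          ci_high = NA_real_, n_clusters = length(ucl),
                          ci_defined = FALSE))
      idx_by_cl <- split(seq_along(v), cl)
      boots <- vapply(seq_len(n_boot), function(b) {
        take <- sample(ucl, length(ucl), replace = TRUE)
        ii <- unlist(idx_by_cl[as.character(take)], use.names = FALSE)
        sum(w[ii] * v[ii]) / sum(w[ii])
      }, numeric(1))
      q <- stats::quantile(boots, c(0.025, 0.975), names = FALSE, type = 7)
      data.frame(zone = z, survey_mean = m,
                 ci_low = min(q[1], m), ci_high = max(q[2], m),
                 n_clusters = length(ucl), ci_defined = TRUE)
    })
  })
  do.call(rbind, rows)
}

#' Validate a predicted layer against survey zone means
#'
#' Implements the two-step robustness check: the absolute difference
#' between the survey mean and the (population-weighted) raster mean is
#' computed at the survey's level of representativeness, and significance
#' is read off the survey confidence intervals — a zone passes when the
#' raster mean lies inside the survey CI. Failing zones are listed so
#' downstream outputs can carry caution flags.
#'
#' @param layer predicted_layer or raster_grid.
#' @param population raster_grid of population per cell (or NULL for
#'   unweighted raster means).
#' @param zones raster_grid of integer zone labels.
#' @param survey_stats output of [survey_zone_mean_ci()].
#' @return list of class `validation_report`: `table` (per-zone rows with
#'   `raster_mean`, `abs_diff`, `within_ci`), `passed`, `failing_zones`.
#' @export
validate_layer <- function(layer, population, zones, survey_stats) {
  g <- if (inherits(layer, "predicted_layer")) layer$layer else layer
  stopifnot(same_geometry(g, zones))
  if (!is.null(population)) stopifnot(same_geometry(g, population))
  zl <- zones$values
  tab <- survey_stats
  tab$raster_mean <- NA_real_
  for (i in seq_len(nrow(tab))) {
    z <- tab$zone[i]
    cells <- !is.na(zl) & zl == z & !is.na(g$values)
    if (!any(cells)) stop("zone absent from raster: ", z)
    wts <- if (is.null(population)) rep(1, sum(cells))
           else population$values[cells]
    tab$raster_mean[i] <- sum(g$values[cells] * wts) / sum(wts)
  }
  tab$abs_diff <- abs(tab$survey_mean - tab$raster_mean)
  tab$within_ci <- ifelse(tab$ci_defined,
                          tab$raster_mean >= tab$ci_low &
                            tab$raster_mean <= tab$ci_high, NA)
  judged <- tab$within_ci[!is.na(tab$within_ci)]
  failing <- tab$zone[!is.na(tab$within_ci) & !tab$within_ci]
  structure(list(table = tab,
                 passed = length(judged) > 0 && all(judged),
                 failing_zones = failing),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report: %s; %d/%d zones within survey CI>\n",
              if (x$passed) "PASS" else "CAUTION",
              sum(x$table$within_ci, na.rm = TRUE),
              sum(!is.na(x$table$within_ci))))
  if (length(x$failing_zones))
    cat("  failing zones:", paste(x$failing_zones, collapse = ", "), "\n")
  invisible(x)
}
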