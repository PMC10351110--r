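#' Marginal target specification for raking
#'
#' @param variable categorical survey column name.
#' @param targets named numeric vector: category -> population proportion.
#'   Must be non-negative and sum to 1 (tolerance 1e-9).
#' @return object of class `margin_spec`.
#' @export
margin_spec <- function(variable, targets) {
  stopifnot(is.character(variable), length(variable) == 1,
            is.numeric(targets), !is.null(names(targets)))
  if (any(targets < 0)) stop("margin targets must be >= 0")
  if (abs(sum(targets) - 1) > 1e-9)
    stop("margin targets for '", variable, "' must sum to 1 (got ",
         format(sum(targets)), ")")
  structure(list(variable = variable, targets = targets),
            class = "margin_spec")
}

#' Read margin specs from a YAML file
#'
#' Format: a mapping of variable name to a {category: proportion} mapping.
#'
#' @param path YAML file.
#' @return list of [margin_spec()].
#' @export
read_margins_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(names(raw), function(v)
    margin_spec(v, unlist(raw[[v]])))
}

#' Rake survey weights by Iterative Proportional Fitting
#'
#' Classical raking: multiplicative weight updates cycling over the margins
#' in their listed order until every weighted category share matches its
#' target within `tol`. Weights are returned normalized to sum to the survey
#' size so downstream 0-100 index normalization is weight-scale-free.
#'
#' @param survey data.frame.
#' @param margins list of [margin_spec()].
#' @param tol convergence tolerance on margin shares (default 1e-6).
#' @param max_iter maximum full cycles (default 100).
#' @param base_weights optional starting weights (default all 1).
#' @param cap optional upper bound on the ratio of final to initial weight
#'   (weight trimming); default `Inf` = off.
#' @return list of class `weight_result`: `weights`, `iterations`,
#'   `max_margin_error`, `converged`.
#' @export
ipf_rake <- function(survey, margins, tol = 1e-6, max_iter = 100,
                     base_weights = NULL, cap = Inf) {
  stopifnot(is.data.frame(survey), length(margins) >= 1)
  n <- nrow(survey)
  if (n == 0) stop("empty survey")
  for (m in margins) {
    stopifnot(inherits(m, "margin_spec"))
    v <- m$variable
    if (!v %in% names(survey)) stop("margin variable not in survey: ", v)
    x <- survey[[v]]
    if (anyNA(x)) stop("margin variable has missing values: ", v)
    have <- unique(as.character(x))
    extra <- setdiff(have, names(m$targets))
    if (length(extra))
      stop("survey categories of '", v, "' missing from targets: ",
           paste(extra, collapse = ", "))
    zero <- setdiff(names(m$targets)[m$targets > 0], have)
    if (length(zero))
      stop("structural zero: category '", zero[1], "' of '", v,
           "' has a positive target but no respondents")
  }
  w0 <- if (is.null(base_weights)) rep(1, n) else as.numeric(base_weights)
  stopifnot(length(w0) == n, all(w0 > 0))
  w <- w0 / sum(w0) * n

  margin_error <- function(w) {
    max(vapply(margins, function(m) {
      sh <- tapply(w, as.character(survey[[m$variable]]), sum) / sum(w)
      max(abs(sh - m$targets[names(sh)]))
    }, numeric(1)))
  }

  iterations <- 0L
  err <- margin_error(w)
  while (err > tol && iterations < max_iter) {
    iterations <- iterations + 1L
    for (m in margins) {
      x <- as.character(survey[[m$variable]])
      sh <- tapply(w, x, sum) / sum(w)
      fac <- m$targets[names(sh)] / sh
      w <- w * fac[x]
      w <- w / sum(w) * n
    }
    if (is.finite(cap)) {
      w <- pmin(w, cap * w0 / sum(w0) * n)
      w <- w / sum(w) * n
    }
    err <- margin_error(w)
  }
  if (iterations == 0L) iterations <- 1L  # fixed point detected on entry
  structure(list(weights = as.numeric(w), iterations = iterations,
                 max_margin_error = err, converged = err <= tol),
            class = "weight_result")
}

#' @export
print.weight_result <- function(x, ...) {
  cat(sprintf("<weight_result: %s in %d iteration(s), max margin error %.2e>\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$max_margin_error))
  invisible(x)
}

#' Weighted category shares of a survey variable
#'
#' @param survey data.frame.
#' @param variable categorical column name.
#' @param weights per-respondent weights (default: `survey$weight`, else 1).
#' @return named numeric vector of proportions summing to 1.
#' @export
weighted_share <- function(survey, variable, weights = NULL) {
  if (nrow(survey) == 0) stop("empty survey")
  if (!variable %in% names(survey)) stop("no such variable: ", variable)
  if (is.null(weights))
    weights <- if ("weight" %in% names(survey)) survey$weight else rep(1, nrow(survey))
  stopifnot(length(weights) == nrow(survey))
  s <- tapply(weights, as.character(survey[[variable]]), sum)
  out <- as.numeric(s) / sum(weights)
  names(out) <- names(s)
  out
}

#' Weighted mean helper
#' @param x numeric vector.
#' @param w weights.
#' @return scalar weighted mean (NAs in x dropped pairwise).
#' @export
weighted_mean2 <- function(x, w) {
  ok <- !is.na(x)
  sum(x[ok] * w[ok]) / sum(w[ok])
}

#' Weighted quantile (lower / left-continuous convention)
#'
#' Sort-and-accumulate: the p-quantile is the smallest value whose
#' cumulative weight reaches p of the total. Ties resolve to the lower
#' value, matching the binning rule used for continuous index inputs.
#'
#' @param x numeric vector.
#' @param w positive weights.
#' @param probs probabilities in [0,1].
#' @return numeric vector of quantiles.
#' @export
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w >= 0), all(probs >= 0 & probs <= 1))
  o <- order(x)
  xs <- x[o]; cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(p) xs[which(cw >= p - 1e-12)[1]], numeric(1))
}
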