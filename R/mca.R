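#' Index specification
#'
#' Names the categorical survey inputs of one index, the anchor input that
#' fixes the sign of the index, and the binning rule for any continuous
#' inputs (continuous index inputs are transformed to categorical before the
#' correspondence analysis).
#'
#' @param name one of "confidence", "complacency", "accessibility",
#'   "time_financial" (free names are accepted for custom indices).
#' @param inputs character vector (>= 2) of survey column names.
#' @param anchor_input one of `inputs`; its numeric coding fixes the sign.
#' @param anchor_direction +1 or -1: required sign of the weighted
#'   correlation between the anchor's numeric coding and the final index
#'   (e.g. -1 for "vaccines may not be safe" on the confidence index:
#'   agreement must lower confidence).
#' @param continuous_inputs named list: input name -> number of
#'   weighted-quantile bins (default 3) for inputs that arrive continuous.
#' @return object of class `index_spec`.
#' @export
index_spec <- function(name, inputs, anchor_input,
                       anchor_direction = -1, continuous_inputs = list()) {
  stopifnot(length(inputs) >= 2, anchor_input %in% inputs,
            anchor_direction %in% c(-1, 1))
  stopifnot(all(names(continuous_inputs) %in% inputs))
  structure(list(name = name, inputs = inputs, anchor_input = anchor_input,
                 anchor_direction = anchor_direction,
                 continuous_inputs = continuous_inputs),
            class = "index_spec")
}

#' Read index specs from a YAML file
#'
#' Format per index: `inputs` (list), `anchor_input`, `anchor_direction`,
#' optional `continuous_inputs` mapping input -> n_bins.
#'
#' @param path YAML file.
#' @return named list of [index_spec()].
#' @export
read_index_specs_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    r <- raw[[nm]]
    index_spec(nm, unlist(r$inputs), r$anchor_input,
               if (is.null(r$anchor_direction)) -1 else r$anchor_direction,
               if (is.null(r$continuous_inputs)) list() else r$continuous_inputs)
  })
  names(out) <- names(raw)
  out
}

#' The default Table-2-style index specifications for the synthetic survey
#' @return named list of four [index_spec()] objects.
#' @export
default_index_specs <- function() {
  list(
    confidence = index_spec(
      "confidence",
      c("vac_not_safe", "vac_not_effective", "vac_no_new_strains",
        "trusted_not_vaccinated"),
      anchor_input = "vac_not_safe", anchor_direction = -1),
    complacency = index_spec(
      "complacency",
      c("no_risk_friends_family", "healthy_no_worry", "covid_not_spreading",
        "covid_not_real", "had_covid_no_fear"),
      anchor_input = "no_risk_friends_family", anchor_direction = 1),
    accessibility = index_spec(
      "accessibility",
      c("walk_time", "drive_time", "scooter_owner"),
      anchor_input = "walk_time", anchor_direction = -1,
      continuous_inputs = list(walk_time = 3, drive_time = 3)),
    time_financial = index_spec(
      "time_financial",
      c("dont_know_where", "no_time", "financial_cost"),
      anchor_input = "financial_cost", anchor_direction = -1)
  )
}

#' Bin a continuous variable into weighted-quantile categories
#'
#' Interior cutpoints are weighted quantiles at i/n_bins; intervals are
#' closed on the right so ties at a cutpoint resolve to the lower bin. If
#' there are fewer distinct cutpoints than requested the number of bins is
#' reduced with a warning.
#'
#' @param values finite numeric vector.
#' @param weights positive weights (default equal).
#' @param n_bins requested number of bins (>= 2).
#' @return ordered factor with levels `bin1 < bin2 < ...`; the numeric
#'   cutpoints are attached as attribute `breaks`.
#' @export
bin_continuous <- function(values, weights = NULL, n_bins = 3) {
  stopifnot(n_bins >= 2)
  if (any(!is.finite(values))) stop("bin_continuous requires finite values")
  if (is.null(weights)) weights <- rep(1, length(values))
  qs <- weighted_quantile(values, weights, seq_len(n_bins - 1) / n_bins)
  breaks <- unique(qs)
  breaks <- breaks[breaks < max(values)]  # a break at the max would empty the top bin
  if (length(breaks) < n_bins - 1)
    warning(sprintf("reducing bins from %d to %d (too few distinct values)",
                    n_bins, length(breaks) + 1))
  cuts <- c(-Inf, breaks, Inf)
  f <- cut(values, cuts, labels = sprintf("bin%d", seq_len(length(breaks) + 1)),
           right = TRUE, ordered_result = TRUE)
  attr(f, "breaks") <- breaks
  f
}

# numeric coding of a categorical input: ordered agreement scale or yes/no
# get rank 0..k-1; ordered factors use level order; numerics pass through
input_numeric <- function(x) {
  if (is.numeric(x)) return(x)
  lv <- if (is.factor(x)) levels(x) else sort(unique(as.character(x)))
  known <- list(c("no", "yes"), c("disagree", "neutral", "agree"),
                c("disagree", "agree"))
  for (k in known) if (setequal(lv, k)) lv <- k
  if (is.ordered(x)) lv <- levels(x)
  match(as.character(x), lv) - 1
}

# weighted Pearson correlation
wcor <- function(x, y, w) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]; w <- w[ok] / sum(w[ok])
  mx <- sum(w * x); my <- sum(w * y)
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx == 0 || vy == 0) return(NA_real_)
  sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}

# materialize the categorical input table for an index spec: continuous
# inputs are binned (fit: new breaks; scoring: stored breaks)
prepare_inputs <- function(survey, spec, weights, breaks = NULL) {
  out <- list(); used_breaks <- list()
  for (v in spec$inputs) {
    if (!v %in% names(survey)) stop("index input not in survey: ", v)
    x <- survey[[v]]
    if (v %in% names(spec$continuous_inputs)) {
      if (is.null(breaks)) {
        f <- bin_continuous(x, weights, spec$continuous_inputs[[v]])
        used_breaks[[v]] <- attr(f, "breaks")
      } else {
        cuts <- c(-Inf, breaks[[v]], Inf)
        f <- cut(x, cuts, labels = sprintf("bin%d", seq_len(length(breaks[[v]]) + 1)),
                 right = TRUE, ordered_result = TRUE)
      }
      out[[v]] <- f
    } else {
      out[[v]] <- x
    }
  }
  list(data = as.data.frame(out, stringsAsFactors = FALSE),
       breaks = used_breaks)
}

#' Fit an MCA index model
#'
#' Correspondence analysis of the complete disjunctive (indicator) matrix
#' with row weights: dimension-1 category standard coordinates define the
#' index, a respondent's raw score is the mean of the coordinates of their
#' response categories (the standard row principal coordinate), and the sign
#' is flipped if needed so the anchor input correlates with the index in the
#' stated direction. Rows with a missing response to any input are dropped
#' from the fit (listwise per index). Explained variance is reported both
#' raw and Benzecri-corrected.
#'
#' @param survey data.frame.
#' @param spec [index_spec()].
#' @param weights row weights (default `survey$weight`, else 1).
#' @return object of class `mca_model`: category coordinates (dimension 1,
#'   signed), eigenvalues, raw and corrected dimension-1 inertia shares,
#'   sign, normalization bounds, weighted tercile cutpoints on the 0-100
#'   scale, stored bin breaks for continuous inputs, and the spec.
#' @export
fit_mca <- function(survey, spec, weights = NULL) {
  stopifnot(inherits(spec, "index_spec"))
  if (is.null(weights))
    weights <- if ("weight" %in% names(survey)) survey$weight else rep(1, nrow(survey))
  stopifnot(length(weights) == nrow(survey), all(weights >= 0))
  prep <- prepare_inputs(survey, spec, weights)
  dat <- prep$data
  keep <- stats::complete.cases(dat) & weights > 0
  dat <- dat[keep, , drop = FALSE]
  w <- weights[keep]
  n <- nrow(dat)
  if (n < 2) stop("fit_mca needs at least 2 respondents with complete inputs")
  for (v in names(dat)) {
    if (length(unique(as.character(dat[[v]]))) < 2)
      stop("constant input column: ", v)
  }

  Q <- ncol(dat)
  Zcols <- lapply(names(dat), function(v) {
    f <- factor(dat[[v]])
    m <- stats::model.matrix(~ f - 1)
    colnames(m) <- paste0(v, "=", levels(f))
    m
  })
  Z <- do.call(cbind, Zcols)
  r <- w / sum(w)
  cm <- as.vector(crossprod(Z, r)) / Q        # column masses
  S <- Z * (r / Q)                            # P matrix
  S <- sweep(S - outer(r, cm), 1, sqrt(r), "/")
  S <- sweep(S, 2, sqrt(cm), "/")
  sv <- svd(S)
  eig <- sv$d^2
  nontriv <- eig > 1e-12
  eig <- eig[nontriv]
  total_inertia <- sum(eig)
  raw_share <- if (total_inertia > 0) eig[1] / total_inertia else NA_real_
  adj <- ifelse(eig > 1 / Q, ((Q / (Q - 1)) * (eig - 1 / Q))^2, 0)
  corrected_share <- if (sum(adj) > 0) adj[1] / sum(adj) else NA_real_

  B1 <- sv$v[, which(nontriv)[1]] / sqrt(cm)  # dim-1 column standard coords
  names(B1) <- colnames(Z)
  # transition formula: mean of standard column coords over the Q responses
  # IS the row principal coordinate (D_r^-1 P B = D_r^-1/2 U D)
  score_raw <- as.vector(Z %*% B1) / Q

  anchor <- input_numeric(dat[[spec$anchor_input]])
  a_cor <- wcor(anchor, score_raw, w)
  sgn <- if (!is.na(a_cor) && sign(a_cor) != 0 &&
             sign(a_cor) != spec$anchor_direction) -1 else 1
  B1 <- B1 * sgn
  score_raw <- score_raw * sgn

  norm_min <- min(score_raw); norm_max <- max(score_raw)
  if (norm_min == norm_max)
    stop("degenerate index: all respondents share one raw score")
  s100 <- (score_raw - norm_min) / (norm_max - norm_min) * 100
  cut13 <- weighted_quantile(s100, w, c(1 / 3, 2 / 3))
  if (cut13[1] >= cut13[2]) {
    warning("tercile cutpoints coincide; collapsing to 2 levels")
    cut13 <- unique(cut13)
  }

  structure(list(
    name = spec$name, spec = spec, q = Q,
    category_coords = B1,
    sing_value = sv$d[which(nontriv)[1]],
    eigenvalues = eig, inertia_share_raw = raw_share,
    inertia_share_corrected = corrected_share,
    sign = sgn, norm_min = norm_min, norm_max = norm_max,
    tercile_cutpoints = cut13, breaks = prep$breaks,
    categories = colnames(Z)),
    class = "mca_model")
}

#' @export
print.mca_model <- function(x, ...) {
  cat(sprintf("<mca_model '%s': %d inputs, dim-1 inertia raw %.3f / corrected %.3f>\n",
              x$name, x$q, x$inertia_share_raw, x$inertia_share_corrected))
  invisible(x)
}

#' Score respondents with a fitted MCA index model
#'
#' Raw score = mean of the (signed) category coordinates of the respondent's
#' responses; 0-100 score by min-max with the model's stored bounds (new
#' scores outside the fitted range are clipped with a warning); tercile by
#' the model's weighted cutpoints, closed on the left (a score strictly
#' greater than a cutpoint enters the upper class).
#'
#' @param survey data.frame with the model's input columns.
#' @param model [fit_mca()] result.
#' @param weights carried through to the result (default `survey$weight`).
#' @return object of class `index_scores`: `name`, `score_raw`,
#'   `score_0_100`, `tercile` (factor low/mid/high), `weights`, `ids`.
#' @export
score_index <- function(survey, model, weights = NULL) {
  stopifnot(inherits(model, "mca_model"))
  if (is.null(weights))
    weights <- if ("weight" %in% names(survey)) survey$weight else rep(1, nrow(survey))
  prep <- prepare_inputs(survey, model$spec, weights, breaks = model$breaks)
  dat <- prep$data
  if (anyNA(dat)) stop("score_index: missing responses; drop or impute first")
  coords <- model$category_coords
  sc <- numeric(nrow(dat))
  for (v in names(dat)) {
    key <- paste0(v, "=", as.character(dat[[v]]))
    unseen <- setdiff(unique(key), names(coords))
    if (length(unseen))
      stop("unseen categories for index '", model$name, "': ",
           paste(unseen, collapse = ", "))
    sc <- sc + coords[key]
  }
  raw <- as.numeric(sc) / model$q
  s100 <- (raw - model$norm_min) / (model$norm_max - model$norm_min) * 100
  n_clip <- sum(s100 < -1e-9 | s100 > 100 + 1e-9)
  if (n_clip > 0)
    warning(n_clip, " score(s) outside fitted range clipped to [0,100]")
  s100 <- pmin(pmax(s100, 0), 100)
  tercile <- classify_terciles(s100, model$tercile_cutpoints)
  ids <- if ("respondent_id" %in% names(survey)) survey$respondent_id
         else as.character(seq_len(nrow(survey)))
  structure(list(name = model$name, score_raw = raw, score_0_100 = s100,
                 tercile = tercile, weights = weights, ids = ids),
            class = "index_scores")
}

classify_terciles <- function(s, cutpoints) {
  if (length(cutpoints) == 2) {
    factor(ifelse(s <= cutpoints[1], "low",
           ifelse(s <= cutpoints[2], "mid", "high")),
           levels = c("low", "mid", "high"))
  } else {
    factor(ifelse(s <= cutpoints[1], "low", "high"),
           levels = c("low", "mid", "high"))
  }
}

#' @export
print.index_scores <- function(x, ...) {
  cat(sprintf("<index_scores '%s': n=%d, weighted mean %.1f>\n",
              x$name, length(x$score_0_100),
              weighted_mean2(x$score_0_100, x$weights)))
  invisible(x)
}

#' Composite convenience index
#'
#' The convenience index is the sum of the accessibility and the
#' time-and-financial-burden sub-indices: per respondent the two 0-100
#' sub-scores are added, the sum is re-normalized to 0-100 over the weighted
#' sample, and terciles are recomputed on the composite.
#'
#' @param accessibility,time_financial [score_index()] results on the same
#'   respondents (matched by id).
#' @param weights optional weights (default: accessibility's).
#' @return `index_scores` named "convenience".
#' @export
composite_convenience <- function(accessibility, time_financial, weights = NULL) {
  stopifnot(inherits(accessibility, "index_scores"),
            inherits(time_financial, "index_scores"))
  if (!identical(accessibility$ids, time_financial$ids))
    stop("sub-indices cover different respondent sets")
  if (is.null(weights)) weights <- accessibility$weights
  raw <- accessibility$score_0_100 + time_financial$score_0_100
  rng <- range(raw)
  if (diff(rng) == 0) {
    warning("composite convenience is constant; terciles degenerate")
    s100 <- rep(50, length(raw))
    tercile <- factor(rep("mid", length(raw)), levels = c("low", "mid", "high"))
  } else {
    s100 <- (raw - rng[1]) / diff(rng) * 100
    cut13 <- weighted_quantile(s100, weights, c(1 / 3, 2 / 3))
    if (cut13[1] >= cut13[2]) {
      warning("composite convenience tercile cutpoints coincide; 2 levels")
      cut13 <- unique(cut13)
    }
    tercile <- classify_terciles(s100, cut13)
  }
  structure(list(name = "convenience", score_raw = raw, score_0_100 = s100,
                 tercile = tercile, weights = weights,
                 ids = accessibility$ids),
            class = "index_scores")
}

#' Pairwise input-index correlations (driver report)
#'
#' Weighted Pearson correlation between each input (numeric coding:
#' category rank for ordered items, 0/1 for yes/no, raw values for
#' continuous inputs) and the 0-100 index score, with a 95% significance
#' flag from a design-effect-naive t approximation.
#'
#' @param survey data.frame.
#' @param scores [score_index()] result.
#' @param spec the index's [index_spec()].
#' @param weights weights (default: scores' weights).
#' @return data.frame with `input`, `r`, `significant_at_95`.
#' @export
driver_correlations <- function(survey, scores, spec, weights = NULL) {
  if (is.null(weights)) weights <- scores$weights
  n <- length(scores$score_0_100)
  rows <- lapply(spec$inputs, function(v) {
    x <- input_numeric(survey[[v]])
    r <- wcor(x, scores$score_0_100, weights)
    sig <- NA
    if (!is.na(r)) {
      tstat <- r * sqrt((n - 2) / max(1 - r^2, 1e-12))
      sig <- abs(tstat) > stats::qt(0.975, df = n - 2)
    }
    data.frame(input = v, r = r, significant_at_95 = sig,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-abs(out$r)), , drop = FALSE]
}

#' MCA model diagnostics
#'
#' Reports raw and Benzecri-corrected dimension-1 explained-variance shares
#' and flags models whose corrected share falls below `threshold` (default
#' 0.74, the weakest primary dimension observed in the source application;
#' all attitudinal indices there exceeded 0.90).
#'
#' @param model `mca_model`.
#' @param threshold minimum acceptable corrected dimension-1 share.
#' @return list with `name`, `inertia_share_raw`, `inertia_share_corrected`,
#'   `threshold`, `flagged`.
#' @export
mca_diagnostics <- function(model, threshold = 0.74) {
  stopifnot(inherits(model, "mca_model"))
  list(name = model$name,
       inertia_share_raw = model$inertia_share_raw,
       inertia_share_corrected = model$inertia_share_corrected,
       threshold = threshold,
       flagged = is.na(model$inertia_share_corrected) ||
         model$inertia_share_corrected < threshold)
}
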