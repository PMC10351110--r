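#' Default learner registry for spatial interpolation
#'
#' Each learner is a list with `id`, `fit(X, y, seed)` and
#' `predict(fit, X)`; `X` always carries the cluster/cell coordinates as
#' columns `x` and `y` plus the selected covariates. The pool is
#' configurable: pass any registry of the same shape to [select_model()].
#' Shipped learners: elastic net (`enet`), thin-plate spatial GAM (`gam`),
#' k-nearest-neighbour on coordinates (`knn`), and ordinary least squares
#' (`ols`).
#'
#' @return named list of learner definitions.
#' @export
default_learner_pool <- function() {
  list(
    enet = list(
      id = "enet",
      fit = function(X, y, seed) {
        if (ncol(X) < 2) return(list(kind = "mean", mu = mean(y)))
        foldid <- rep_len(1:5, nrow(X))[order(order(y))]  # deterministic
        # explicit lambda path down to ~0 so a noiseless linear signal can
        # be fitted essentially unpenalized (glmnet's default path stops
        # early once deviance saturates)
        lmax <- glmnet::glmnet(X, y, alpha = 0.5, nlambda = 3)$lambda[1]
        lam <- exp(seq(log(lmax), log(lmax * 1e-8), length.out = 120))
        cv <- glmnet::cv.glmnet(X, y, alpha = 0.5, foldid = foldid,
                                standardize = TRUE, lambda = lam)
        list(kind = "enet", cv = cv)
      },
      predict = function(fit, X) {
        if (fit$kind == "mean") return(rep(fit$mu, nrow(X)))
        as.numeric(stats::predict(fit$cv, newx = X, s = "lambda.min"))
      }),
    gam = list(
      id = "gam",
      fit = function(X, y, seed) {
        df <- as.data.frame(X)
        kk <- max(5, min(25, floor(nrow(df) / 3)))
        covs <- setdiff(colnames(X), c("x", "y"))
        form <- stats::as.formula(paste(
          "y ~ s(x, y, k = kk)",
          if (length(covs)) paste("+", paste(covs, collapse = " + ")) else ""))
        df$y <- y
        env <- environment(form); env$kk <- kk
        m <- suppressWarnings(mgcv::gam(form, data = df, method = "REML"))
        list(kind = "gam", m = m)
      },
      predict = function(fit, X) {
        as.numeric(mgcv::predict.gam(fit$m, newdata = as.data.frame(X)))
      }),
    knn = list(
      id = "knn",
      fit = function(X, y, seed)
        list(kind = "knn", xy = X[, c("x", "y"), drop = FALSE], y = y,
             k = min(5, nrow(X) - 1)),
      predict = function(fit, X) {
        FNN::knn.reg(train = fit$xy, test = X[, c("x", "y"), drop = FALSE],
                     y = fit$y, k = fit$k)$pred
      }),
    ols = list(
      id = "ols",
      fit = function(X, y, seed) {
        df <- as.data.frame(X); df$y <- y
        list(kind = "ols", m = stats::lm(y ~ ., data = df))
      },
      predict = function(fit, X)
        as.numeric(suppressWarnings(
          stats::predict(fit$m, newdata = as.data.frame(X)))))
  )
}

#' An intercept-only learner (useful as a baseline in custom pools)
#' @return single-learner registry entry.
#' @export
intercept_learner <- function() {
  list(intercept = list(
    id = "intercept",
    fit = function(X, y, seed) list(kind = "mean", mu = mean(y)),
    predict = function(fit, X) rep(fit$mu, nrow(X))))
}

#' Build the cluster-level modelling frame
#'
#' Aggregates a per-respondent target to weighted cluster means (index
#' scores should be passed already rescaled to [0,1], i.e. score/100) and
#' samples the covariate stack at the cluster centroids. If `target` is a
#' factor, one frame per level is returned (weighted level shares, which
#' sum to 1 within each cluster).
#'
#' @param survey data.frame with `cluster_id`, `x`, `y`.
#' @param weights respondent weights.
#' @param target numeric vector (one value per respondent) or factor.
#' @param covariates raster_stack.
#' @return data.frame of class `cluster_frame` (or a named list of them for
#'   factor targets): `cluster_id`, `x`, `y`, `n`, `target`, one column per
#'   covariate layer.
#' @export
build_cluster_frame <- function(survey, weights, target, covariates) {
  stopifnot(all(c("cluster_id", "x", "y") %in% names(survey)),
            length(weights) == nrow(survey))
  if (is.factor(target) || is.character(target)) {
    f <- factor(target)
    out <- lapply(levels(f), function(lv)
      build_cluster_frame(survey, weights, as.numeric(f == lv), covariates))
    names(out) <- levels(f)
    return(out)
  }
  stopifnot(length(target) == nrow(survey))
  if (anyNA(target)) stop("missing target values; filter respondents first")
  dt <- data.table::data.table(cluster_id = survey$cluster_id,
                               x = survey$x, y = survey$y,
                               w = weights, t = target)
  ag <- dt[, .(x = x[1], y = y[1], n = .N, target = sum(w * t) / sum(w)),
           by = cluster_id]
  ag <- ag[order(cluster_id)]
  cm <- vapply(names(covariates), function(nm)
    extract_at_points(covariates[[nm]], ag$x, ag$y), numeric(nrow(ag)))
  if (anyNA(cm)) stop("cluster centroid falls on nodata covariate cells")
  out <- cbind(as.data.frame(ag), as.data.frame(cm))
  class(out) <- c("cluster_frame", class(out))
  out
}

covariate_names <- function(frame)
  setdiff(names(frame), c("cluster_id", "x", "y", "n", "target"))

make_folds <- function(n, k, seed) {
  withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
}

cv_eval <- function(frame, covs, learner, k_folds, folds, seed) {
  X <- as.matrix(frame[, c("x", "y", covs), drop = FALSE])
  y <- frame$target
  pred <- rep(NA_real_, length(y))
  fold_rmse <- numeric(k_folds)
  for (f in seq_len(k_folds)) {
    tr <- folds != f
    fit <- tryCatch(learner$fit(X[tr, , drop = FALSE], y[tr], seed),
                    error = function(e) e)
    if (inherits(fit, "error"))
      return(list(ok = FALSE, reason = conditionMessage(fit)))
    p <- tryCatch(learner$predict(fit, X[!tr, , drop = FALSE]),
                  error = function(e) e)
    if (inherits(p, "error"))
      return(list(ok = FALSE, reason = conditionMessage(p)))
    pred[!tr] <- p
    fold_rmse[f] <- sqrt(mean((p - y[!tr])^2))
  }
  list(ok = TRUE, cv_rmse = sqrt(mean((pred - y)^2)),
       se = stats::sd(fold_rmse) / sqrt(k_folds), pred = pred)
}

# forward selection on CV RMSE over correlation-ranked covariates,
# 1-SE stopping; OLS is used as the (cheap, deterministic) selection learner
select_covariates <- function(frame, k_folds, folds, seed, max_covs = 10) {
  covs <- covariate_names(frame)
  if (length(covs) == 0) return(character(0))
  r <- vapply(covs, function(v) abs(wcor(frame[[v]], frame$target, frame$n)),
              numeric(1))
  r[is.na(r)] <- 0
  ranked <- covs[order(-r)]
  ranked <- ranked[seq_len(min(length(ranked), max_covs))]
  sel_learner <- default_learner_pool()$ols
  rmse_path <- numeric(length(ranked) + 1)
  se_path <- numeric(length(ranked) + 1)
  ev0 <- cv_eval(frame, character(0), sel_learner, k_folds, folds, seed)
  rmse_path[1] <- ev0$cv_rmse; se_path[1] <- ev0$se
  for (i in seq_along(ranked)) {
    ev <- cv_eval(frame, ranked[seq_len(i)], sel_learner, k_folds, folds, seed)
    if (!ev$ok) { rmse_path[i + 1] <- Inf; se_path[i + 1] <- Inf; next }
    rmse_path[i + 1] <- ev$cv_rmse; se_path[i + 1] <- ev$se
  }
  best <- which.min(rmse_path)
  thresh <- rmse_path[best] + se_path[best]
  size <- which(rmse_path <= thresh)[1] - 1  # smallest model within 1 SE
  ranked[seq_len(size)]
}

#' Cross-validated learner selection for one interpolation target
#'
#' Covariates are chosen by correlation-ranked forward selection with 1-SE
#' stopping; every learner in the pool is then scored by k-fold
#' cross-validation (folds are whole clusters: the frame has one row per
#' cluster, so no cluster is ever split across folds). The learner with the
#' lowest CV RMSE wins; all learners within one standard error of the best
#' are averaged as an ensemble. Learners that fail on any fold are
#' disqualified with a logged reason.
#'
#' @param frame [build_cluster_frame()] output.
#' @param learner_pool registry (default [default_learner_pool()]).
#' @param k_folds number of CV folds (default 5).
#' @param seed integer; fixes fold assignment and any stochastic learner.
#' @param max_covs cap on the number of covariates entering selection.
#' @return object of class `interp_model`: `learners` (ensemble member
#'   ids), `best_learner`, `covariates`, `cv_rmse`, `cv_se`, `fits`
#'   (members trained on all clusters), `seed`, `k_folds`, `scores` (per
#'   learner), `log` (disqualifications), `stage`.
#' @export
select_model <- function(frame, learner_pool = default_learner_pool(),
                         k_folds = 5, seed = 1, max_covs = 10) {
  stopifnot(nrow(frame) >= 2 * k_folds)
  folds <- make_folds(nrow(frame), k_folds, seed)
  sel_covs <- select_covariates(frame, k_folds, folds, seed, max_covs)
  all_covs <- covariate_names(frame)
  # canonical (frame) column order: equal covariate SETS must give
  # bit-identical fits regardless of the order selection found them in
  sel_covs <- sel_covs[order(match(sel_covs, all_covs))]
  # candidate models: every learner on the selected subset AND (null check
  # built in) on the full covariate set; the final model therefore never
  # loses to the all-covariate null of any pool learner
  cov_sets <- list(selected = sel_covs)
  if (!setequal(sel_covs, all_covs)) cov_sets$full <- all_covs
  cand <- list(); log <- character(0)
  for (id in names(learner_pool)) {
    for (sn in names(cov_sets)) {
      ev <- cv_eval(frame, cov_sets[[sn]], learner_pool[[id]],
                    k_folds, folds, seed)
      if (!ev$ok) {
        log <- c(log, sprintf("learner '%s' (%s covariates) disqualified: %s",
                              id, sn, ev$reason))
        next
      }
      cand[[paste(id, sn, sep = "/")]] <-
        list(learner = id, set = sn, covs = cov_sets[[sn]],
             cv_rmse = ev$cv_rmse, se = ev$se)
    }
  }
  if (length(cand) == 0) stop("all learners failed: ",
                              paste(log, collapse = "; "))
  rmses <- vapply(cand, `[[`, numeric(1), "cv_rmse")
  best_i <- which.min(rmses)  # ties: first in pool order
  best <- cand[[best_i]]
  # ensemble: candidates within one SE of the best, at most one per learner
  # (each learner's better covariate set)
  ok <- rmses <= best$cv_rmse + best$se
  members <- list()
  for (id in unique(vapply(cand[ok], `[[`, character(1), "learner"))) {
    sub <- cand[ok][vapply(cand[ok], `[[`, character(1), "learner") == id]
    members[[id]] <- sub[[which.min(vapply(sub, `[[`, numeric(1), "cv_rmse"))]]
  }
  fits <- lapply(members, function(m) {
    X <- as.matrix(frame[, c("x", "y", m$covs), drop = FALSE])
    learner_pool[[m$learner]]$fit(X, frame$target, seed)
  })
  member_covs <- lapply(members, `[[`, "covs")
  scores_tab <- cbind(cv_rmse = rmses,
                      se = vapply(cand, `[[`, numeric(1), "se"))
  structure(list(learners = names(members), best_learner = best$learner,
                 covariates = best$covs,
                 member_covariates = member_covs,
                 cv_rmse = best$cv_rmse, cv_se = best$se,
                 fits = fits, pool = learner_pool[names(members)],
                 seed = seed, k_folds = k_folds, folds = folds,
                 scores = scores_tab, log = log, stage = 1L),
            class = "interp_model")
}

#' @export
print.interp_model <- function(x, ...) {
  cat(sprintf("<interp_model: %s on %d covariate(s), CV RMSE %.4f%s>\n",
              paste(x$learners, collapse = "+"), length(x$covariates),
              x$cv_rmse,
              if (length(x$log)) paste0("; ", length(x$log), " learner(s) disqualified") else ""))
  invisible(x)
}

#' Null-model check: selected model vs all-covariate null
#'
#' The null model is the winning learner family refitted on ALL covariates
#' (no selection), cross-validated with the identical fold assignment. The
#' check passes when the final model's CV RMSE does not exceed the null's,
#' confirming that covariate selection did not hurt. Failure is a reported
#' state, not an exception.
#'
#' @param frame the cluster frame the model was selected on.
#' @param final [select_model()] result.
#' @param learner_pool registry containing the final model's best learner.
#' @return list with `null_rmse`, `final_rmse`, `passed`.
#' @export
null_model_check <- function(frame, final,
                             learner_pool = default_learner_pool()) {
  all_covs <- covariate_names(frame)
  ev <- cv_eval(frame, all_covs, learner_pool[[final$best_learner]],
                final$k_folds, final$folds, final$seed)
  if (!ev$ok) return(list(null_rmse = NA_real_, final_rmse = final$cv_rmse,
                          passed = NA))
  list(null_rmse = ev$cv_rmse, final_rmse = final$cv_rmse,
       passed = final$cv_rmse <= ev$cv_rmse)
}

#' Predict an interpolation model over the full grid
#'
#' Cellwise ensemble prediction (simple mean over ensemble members),
#' clipped to `bounds`; cells where any covariate is nodata are nodata.
#'
#' @param model [select_model()] result.
#' @param covariates raster_stack holding at least the model's covariates.
#' @param bounds length-2 clip interval (default c(0, 1)); use NULL for no
#'   clipping.
#' @param target_name label carried on the output.
#' @return object of class `predicted_layer`: `layer` (raster_grid),
#'   `target`, `bounds`, `n_clipped`.
#' @export
predict_grid <- function(model, covariates, bounds = c(0, 1),
                         target_name = "target") {
  need <- unique(unlist(model$member_covariates))
  missing_cov <- setdiff(need, names(covariates))
  if (length(missing_cov))
    stop("covariate bands missing from stack: ",
         paste(missing_cov, collapse = ", "))
  ref <- covariates[[1]]
  cc <- cell_centres(ref)
  M <- cbind(x = cc$x, y = cc$y)
  if (length(need)) {
    cm <- stack_to_matrix(raster_stack(
      lapply(stats::setNames(need, need), function(nm) covariates[[nm]])))
    M <- cbind(M, cm)
  }
  ok <- stats::complete.cases(M)
  pred <- rep(NA_real_, nrow(M))
  if (any(ok)) {
    ps <- vapply(model$learners, function(id) {
      Xm <- M[ok, c("x", "y", model$member_covariates[[id]]), drop = FALSE]
      model$pool[[id]]$predict(model$fits[[id]], Xm)
    }, numeric(sum(ok)))
    pred[ok] <- if (is.matrix(ps)) rowMeans(ps) else mean(ps)
  }
  n_clipped <- 0L
  if (!is.null(bounds)) {
    n_clipped <- sum(pred < bounds[1] | pred > bounds[2], na.rm = TRUE)
    pred <- pmin(pmax(pred, bounds[1]), bounds[2])
  }
  vals <- matrix(pred, nrow(ref$values), ncol(ref$values), byrow = TRUE)
  structure(list(layer = raster_grid(vals, cell_size = ref$cell_size,
                                     xll = ref$xll, yll = ref$yll,
                                     crs = ref$crs),
                 target = target_name, bounds = bounds,
                 n_clipped = n_clipped),
            class = "predicted_layer")
}

#' Two-stage interpolation for attitudinal targets
#'
#' Stage 1 interpolates demographic/socioeconomic targets from the base
#' covariates; the predicted stage-1 layers are then appended to the
#' covariate stack (as `s1_<name>`) before stage-2 (attitudinal) targets
#' are interpolated, so opinion layers can borrow strength from the
#' demographic surfaces associated with them.
#'
#' @param survey data.frame with `cluster_id`, `x`, `y`.
#' @param weights respondent weights.
#' @param stage1_targets named list of per-respondent numeric vectors on
#'   [0,1] (may be empty: the pipeline then reduces to single-stage).
#' @param stage2_targets named list of per-respondent numeric vectors.
#' @param covariates base raster_stack.
#' @param learner_pool,k_folds,seed,max_covs passed to [select_model()].
#' @param bounds clip bounds for predictions.
#' @return list with `stage1` and `stage2`, each a named list of
#'   `list(model, layer, null)`; plus `covariates_extended`.
#' @export
two_stage_interpolate <- function(survey, weights, stage1_targets,
                                  stage2_targets, covariates,
                                  learner_pool = default_learner_pool(),
                                  k_folds = 5, seed = 1, max_covs = 10,
                                  bounds = c(0, 1)) {
  overlap <- intersect(names(stage1_targets), names(stage2_targets))
  if (length(overlap))
    stop("targets cannot appear in both stages: ",
         paste(overlap, collapse = ", "))
  run_one <- function(tv, stack, stage, nm, seed_off) {
    frame <- build_cluster_frame(survey, weights, tv, stack)
    model <- select_model(frame, learner_pool, k_folds,
                          seed = seed + seed_off, max_covs = max_covs)
    model$stage <- stage
    layer <- predict_grid(model, stack, bounds = bounds, target_name = nm)
    null <- null_model_check(frame, model, learner_pool)
    list(model = model, layer = layer, null = null)
  }
  s1 <- list()
  for (i in seq_along(stage1_targets)) {
    nm <- names(stage1_targets)[i]
    s1[[nm]] <- run_one(stage1_targets[[i]], covariates, 1L, nm, i)
  }
  stack2 <- covariates
  if (length(s1)) {
    layers <- c(covariates$layers,
                stats::setNames(lapply(s1, function(r) r$layer$layer),
                                paste0("s1_", names(s1))))
    stack2 <- raster_stack(layers)
  }
  s2 <- list()
  for (i in seq_along(stage2_targets)) {
    nm <- names(stage2_targets)[i]
    s2[[nm]] <- run_one(stage2_targets[[i]], stack2, 2L, nm, 1000 + i)
  }
  list(stage1 = s1, stage2 = s2, covariates_extended = stack2)
}

#' Renormalize three tercile share layers to sum to one per cell
#'
#' Cellwise: clip each share to [0,1], then divide by the sum. Cells whose
#' clipped shares sum to zero get equal thirds and are counted in
#' `n_flagged`.
#'
#' @param low,mid,high predicted_layer (or raster_grid) share layers.
#' @return list with `low`, `mid`, `high` (raster_grid) and `n_flagged`.
#' @export
renormalize_terciles <- function(low, mid, high) {
  as_grid <- function(x) if (inherits(x, "predicted_layer")) x$layer else x
  gl <- as_grid(low); gm <- as_grid(mid); gh <- as_grid(high)
  stopifnot(same_geometry(gl, gm), same_geometry(gl, gh))
  a <- pmin(pmax(gl$values, 0), 1)
  b <- pmin(pmax(gm$values, 0), 1)
  c_ <- pmin(pmax(gh$values, 0), 1)
  s <- a + b + c_
  zero <- !is.na(s) & s == 0
  n_flagged <- sum(zero)
  a[zero] <- 1; b[zero] <- 1; c_[zero] <- 1; s[zero] <- 3
  mk <- function(v) raster_grid(v / s, cell_size = gl$cell_size,
                                xll = gl$xll, yll = gl$yll, crs = gl$crs)
  list(low = mk(a), mid = mk(b), high = mk(c_), n_flagged = n_flagged)
}
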