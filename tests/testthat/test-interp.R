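make_frame_world <- function(seed = 1) {
  cached(paste0("frame_world_", seed), function()
    generate_world(tiny_config(seed = seed)))
}

test_that("cluster frame aggregates weighted means and samples covariates", {
  w <- make_frame_world()
  s <- w$survey
  wts <- rep(1, nrow(s))
  tgt <- as.numeric(s$covid_not_real == "yes")
  fr <- build_cluster_frame(s, wts, tgt, w$covariates)
  expect_equal(nrow(fr), w$config$n_clusters)
  # hand-computed weighted mean on one cluster with custom weights
  cid <- fr$cluster_id[1]
  in_c <- s$cluster_id == cid
  wts2 <- wts; wts2[in_c][1:3] <- c(2, 1, 1)
  fr2 <- build_cluster_frame(s, wts2, tgt, w$covariates)
  want <- sum(wts2[in_c] * tgt[in_c]) / sum(wts2[in_c])
  expect_equal(fr2$target[fr2$cluster_id == cid], want, tolerance = 1e-12)
  # identical respondents give the individual value
  expect_true(all(fr$target >= 0 & fr$target <= 1))
  # covariates sampled at the centroid cell
  expect_equal(fr$urbanicity,
               extract_at_points(w$covariates[["urbanicity"]], fr$x, fr$y))
  # factor target -> per-level share frames summing to 1
  frs <- build_cluster_frame(s, wts, factor(s$age_group), w$covariates)
  tot <- Reduce(`+`, lapply(frs, function(f) f$target))
  expect_equal(tot, rep(1, nrow(fr)), tolerance = 1e-12)
})

test_that("planted linear signal is recovered by the penalized learner", {
  w <- make_frame_world()
  fr <- build_cluster_frame(w$survey, rep(1, nrow(w$survey)),
                            rep(0.5, nrow(w$survey)), w$covariates)
  fr$target <- fr$cov03  # noiseless single-covariate signal
  pool <- c(intercept_learner(), default_learner_pool()["enet"])
  m <- select_model(fr, pool, k_folds = 5, seed = 2)
  expect_true("enet" %in% m$learners)
  expect_false(identical(m$best_learner, "intercept"))
  expect_lt(m$cv_rmse, 0.01)
  expect_true("cov03" %in% m$covariates)
})

test_that("pure-noise target: nothing materially beats the intercept", {
  w <- make_frame_world()
  base <- build_cluster_frame(w$survey, rep(1, nrow(w$survey)),
                              rep(0.5, nrow(w$survey)), w$covariates)
  ratios <- vapply(1:6, function(sd) {
    fr <- base
    fr$target <- withr::with_seed(300 + sd, rnorm(nrow(fr), 0.5, 0.1))
    pool <- c(intercept_learner(), default_learner_pool()[c("enet", "knn")])
    m <- select_model(fr, pool, k_folds = 5, seed = sd)
    m$cv_rmse / sd(fr$target)
  }, numeric(1))
  # scaled down from the 20-seed design: CV RMSE stays near the target SD
  expect_gt(mean(ratios), 0.9)
})

test_that("tied learners break by pool order; fold assignment is seeded", {
  w <- make_frame_world()
  fr <- build_cluster_frame(w$survey, rep(1, nrow(w$survey)),
                            as.numeric(w$survey$gender == "female"),
                            w$covariates)
  pool <- c(intercept_learner(), intercept_learner())
  names(pool) <- c("first", "second")
  pool$first$id <- "first"; pool$second$id <- "second"
  m <- select_model(fr, pool, seed = 5)
  expect_equal(m$best_learner, "first")
  expect_identical(make_folds(40, 5, 9), make_folds(40, 5, 9))
  expect_false(identical(make_folds(40, 5, 9), make_folds(40, 5, 10)))
  # determinism: same seed, same model and raster
  m2 <- select_model(fr, default_learner_pool()["enet"], seed = 5)
  m3 <- select_model(fr, default_learner_pool()["enet"], seed = 5)
  expect_identical(m2$folds, m3$folds)
  expect_identical(m2$covariates, m3$covariates)
  p2 <- predict_grid(m2, w$covariates)
  p3 <- predict_grid(m3, w$covariates)
  expect_identical(p2$layer$values, p3$layer$values)
})

test_that("null model check: equality case and intercept closed form", {
  w <- make_frame_world()
  fr <- build_cluster_frame(w$survey, rep(1, nrow(w$survey)),
                            as.numeric(w$survey$asset_owner == "yes"),
                            w$covariates)
  pool <- default_learner_pool()["enet"]
  m <- select_model(fr, pool, seed = 3)
  nc <- null_model_check(fr, m, pool)
  expect_true(isTRUE(nc$passed))          # guaranteed by construction
  expect_lte(m$cv_rmse, nc$null_rmse + 1e-12)
  if (setequal(m$covariates, hesitmap:::covariate_names(fr)))
    expect_equal(nc$null_rmse, m$cv_rmse, tolerance = 1e-12)
  # intercept-only pool: null rmse equals held-out RMSE around fold means
  ipool <- intercept_learner()
  mi <- select_model(fr, ipool, seed = 3)
  nci <- null_model_check(fr, mi, ipool)
  y <- fr$target; folds <- mi$folds
  pred <- numeric(length(y))
  for (f in 1:5) pred[folds == f] <- mean(y[folds != f])
  expect_equal(nci$null_rmse, sqrt(mean((pred - y)^2)), tolerance = 1e-12)
})

test_that("grid prediction: constants, in-sample consistency, clipping, nodata", {
  w <- make_frame_world()
  fr <- build_cluster_frame(w$survey, rep(1, nrow(w$survey)),
                            as.numeric(w$survey$radio_owner == "yes"),
                            w$covariates)
  ipool <- intercept_learner()
  mi <- select_model(fr, ipool, seed = 1)
  pl <- predict_grid(mi, w$covariates, bounds = c(0, 1))
  expect_equal(length(unique(as.vector(pl$layer$values))), 1)
  expect_equal(pl$layer$values[1, 1], mean(fr$target), tolerance = 1e-12)
  # deterministic learner: predictions at centroids equal fitted values
  pool <- default_learner_pool()["ols"]
  mo <- select_model(fr, pool, seed = 1)
  pl2 <- predict_grid(mo, w$covariates, bounds = NULL)
  at_cl <- extract_at_points(pl2$layer, fr$x, fr$y)
  X <- as.matrix(fr[, c("x", "y", mo$member_covariates$ols), drop = FALSE])
  fitted_vals <- mo$pool$ols$predict(mo$fits$ols, X)
  expect_equal(at_cl, fitted_vals, tolerance = 1e-9)
  # clipping is applied and counted
  mi$fits[[1]]$mu <- 1.07
  pl3 <- predict_grid(mi, w$covariates, bounds = c(0, 1))
  expect_equal(max(pl3$layer$values), 1)
  expect_equal(pl3$n_clipped, length(pl3$layer$values))
  # nodata covariate cells propagate
  cov_na <- w$covariates
  cov_na$layers$urbanicity$values[3, 3] <- NA
  mo2 <- select_model(fr, default_learner_pool()["enet"], seed = 1)
  if ("urbanicity" %in% unlist(mo2$member_covariates)) {
    pl4 <- predict_grid(mo2, cov_na)
    expect_true(is.na(pl4$layer$values[3, 3]))
  }
  expect_error(predict_grid(mo, raster_stack(w$covariates$layers["terrain"])),
               "missing from stack")
})

test_that("two-stage interpolation exploits a planted dependency", {
  pool <- default_learner_pool()[c("enet", "knn")]
  wins <- 0; used <- 0; nrep <- 6  # scaled down from the 20-seed design
  for (sd in seq_len(nrep)) {
    w <- generate_world(tiny_config(seed = sd))
    s <- w$survey; wts <- rep(1, nrow(s))
    demo <- as.numeric(s$asset_owner == "yes")
    att <- withr::with_seed(500 + sd,
                            pmin(pmax(0.8 * demo + 0.2 * runif(nrow(s)), 0), 1))
    ts <- two_stage_interpolate(s, wts, list(demo = demo), list(att = att),
                                w$covariates, learner_pool = pool, seed = sd)
    ss <- two_stage_interpolate(s, wts, list(), list(att = att),
                                w$covariates, learner_pool = pool, seed = sd)
    wins <- wins + (ts$stage2$att$model$cv_rmse < ss$stage2$att$model$cv_rmse)
    used <- used +
      any(grepl("^s1_", unlist(ts$stage2$att$model$member_covariates)))
  }
  expect_gte(wins, ceiling(0.7 * nrep))
  expect_gte(used, ceiling(0.7 * nrep))
})

test_that("empty stage-1 list reduces to the single-stage pipeline", {
  w <- make_frame_world()
  s <- w$survey; wts <- rep(1, nrow(s))
  tgt <- as.numeric(s$covid_not_real == "yes")
  pool <- default_learner_pool()["enet"]
  ts <- two_stage_interpolate(s, wts, list(), list(t1 = tgt), w$covariates,
                              learner_pool = pool, seed = 4)
  fr <- build_cluster_frame(s, wts, tgt, w$covariates)
  m <- select_model(fr, pool, seed = 4 + 1001)
  expect_identical(ts$stage2$t1$model$covariates, m$covariates)
  expect_equal(ts$stage2$t1$model$cv_rmse, m$cv_rmse, tolerance = 1e-12)
  expect_identical(names(ts$covariates_extended), names(w$covariates))
  expect_error(
    two_stage_interpolate(s, wts, list(a = tgt), list(a = tgt), w$covariates,
                          learner_pool = pool),
    "both stages")
})

test_that("tercile renormalization conserves mass and flags zero cells", {
  mk <- function(m) raster_grid(m, cell_size = 10)
  lo <- mk(matrix(0.2, 2, 2)); mi <- mk(matrix(0.3, 2, 2))
  hi <- mk(matrix(0.5, 2, 2))
  rn <- renormalize_terciles(lo, mi, hi)
  expect_equal(rn$low$values, matrix(0.2, 2, 2), tolerance = 1e-12)
  rn2 <- renormalize_terciles(mk(matrix(0.5, 2, 2)), mk(matrix(0.5, 2, 2)),
                              mk(matrix(0.5, 2, 2)))
  expect_equal(rn2$mid$values[1, 1], 1 / 3, tolerance = 1e-15)
  withr::with_seed(8, {
    a <- mk(matrix(runif(9, -0.1, 1.2), 3, 3))
    b <- mk(matrix(runif(9), 3, 3)); c_ <- mk(matrix(runif(9), 3, 3))
  })
  a$values[2, 2] <- 0; b$values[2, 2] <- 0; c_$values[2, 2] <- -0.3
  rn3 <- renormalize_terciles(a, b, c_)
  s <- rn3$low$values + rn3$mid$values + rn3$high$values
  expect_true(all(abs(s - 1) < 1e-12))
  expect_equal(rn3$n_flagged, 1)
  expect_equal(rn3$low$values[2, 2], 1 / 3)
})
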