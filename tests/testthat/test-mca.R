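test_that("perfectly correlated binary inputs put all corrected inertia on dim 1", {
  df <- data.frame(a = rep(c("yes", "no"), each = 6),
                   b = rep(c("hi", "lo"), each = 6))
  m <- fit_mca(df, index_spec("toy", c("a", "b"), "a", 1))
  expect_equal(m$inertia_share_corrected, 1.0, tolerance = 1e-12)
})

test_that("row scores match the eigendecomposition oracle on a 6x2 toy", {
  df <- data.frame(a = c("y", "y", "n", "n", "y", "n"),
                   b = c("p", "q", "q", "q", "p", "p"))
  w <- c(1, 2, 1, 1, 3, 1)
  m <- fit_mca(df, index_spec("toy", c("a", "b"), "a", 1), weights = w)
  got <- score_index(df, m, weights = w)$score_raw
  want <- mca_row_scores_oracle(df, w)
  err <- min(max(abs(got - want)), max(abs(got + want)))
  expect_lt(err, 1e-8)
})

test_that("row scores match the oracle across random small tables", {
  for (seed in 1:8) {
    n <- withr::with_seed(seed, sample(8:40, 1))
    q <- withr::with_seed(seed + 100, sample(2:4, 1))
    df <- rand_cat_table(n, q, seed)
    ok <- vapply(df, function(col) length(unique(col)) >= 2, logical(1))
    if (!all(ok)) next
    w <- withr::with_seed(seed + 200, runif(n, 0.5, 2))
    m <- tryCatch(fit_mca(df, index_spec("t", names(df), names(df)[1], 1),
                          weights = w),
                  error = function(e) NULL)
    if (is.null(m)) next
    got <- score_index(df, m, weights = w)$score_raw
    want <- mca_row_scores_oracle(df, w)
    err <- min(max(abs(got - want)), max(abs(got + want)))
    expect_lt(err, 1e-8)
  }
})

test_that("weighted centering and normalization endpoints hold", {
  w <- tiny_world()
  wts <- withr::with_seed(31, runif(nrow(w$survey), 0.5, 2))
  m <- fit_mca(w$survey, default_index_specs()$confidence, wts)
  sc <- score_index(w$survey, m, wts)
  expect_lt(abs(weighted_mean2(sc$score_raw, wts)), 1e-9)
  expect_equal(min(sc$score_0_100), 0, tolerance = 1e-9)
  expect_equal(max(sc$score_0_100), 100, tolerance = 1e-9)
})

test_that("anchor direction is enforced and drivers are all negative", {
  w <- default_world()
  spec <- default_index_specs()$confidence
  wts <- rep(1, nrow(w$survey))
  m <- fit_mca(w$survey, spec, wts)
  sc <- score_index(w$survey, m, wts)
  dr <- driver_correlations(w$survey, sc, spec, wts)
  # concern inputs all correlate negatively with confidence (Table-3-style
  # sign pattern) and significantly so at this n
  expect_true(all(dr$r < 0))
  expect_true(all(dr$significant_at_95))
  expect_lt(dr$r[dr$input == "vac_not_safe"], -0.5)
})

test_that("most-concern response pattern scores at the low extreme", {
  w <- tiny_world()
  spec <- default_index_specs()$confidence
  m <- fit_mca(w$survey, spec, rep(1, nrow(w$survey)))
  # pick the lowest-coordinate category of every input: no observed pattern
  # can score below it, so after clipping it sits exactly at 0
  worst <- lapply(spec$inputs, function(v) {
    cc <- m$category_coords[grep(paste0("^", v, "="), names(m$category_coords))]
    sub("^[^=]+=", "", names(cc)[which.min(cc)])
  })
  names(worst) <- spec$inputs
  s <- suppressWarnings(score_index(as.data.frame(worst), m, 1))
  expect_equal(s$score_0_100, 0, tolerance = 1e-9)
})

test_that("tercile assignment equals the weighted-quantile oracle", {
  w <- tiny_world()
  wts <- withr::with_seed(32, runif(nrow(w$survey), 0.5, 2))
  m <- fit_mca(w$survey, default_index_specs()$complacency, wts)
  sc <- score_index(w$survey, m, wts)
  # brute-force oracle: sort by score, accumulate weights (same boundary
  # tolerance as the documented cutpoint rule)
  o <- order(sc$score_0_100)
  cw <- cumsum(wts[o]) / sum(wts)
  c1 <- sc$score_0_100[o][which(cw >= 1 / 3 - 1e-12)[1]]
  c2 <- sc$score_0_100[o][which(cw >= 2 / 3 - 1e-12)[1]]
  want <- ifelse(sc$score_0_100 <= c1, "low",
                 ifelse(sc$score_0_100 <= c2, "mid", "high"))
  expect_equal(as.character(sc$tercile), want)
  # equal weights: tercile shares each 1/3 within 1/n
  m2 <- fit_mca(w$survey, default_index_specs()$complacency,
                rep(1, nrow(w$survey)))
  sc2 <- score_index(w$survey, m2, rep(1, nrow(w$survey)))
  shares <- table(sc2$tercile) / length(sc2$tercile)
  expect_true(all(abs(shares - 1 / 3) <= 0.05 + 1 / nrow(w$survey)))
})

test_that("0-100 scores are invariant to positive affine transforms", {
  w <- tiny_world()
  m <- fit_mca(w$survey, default_index_specs()$time_financial,
               rep(1, nrow(w$survey)))
  sc <- score_index(w$survey, m, rep(1, nrow(w$survey)))
  m2 <- m
  m2$category_coords <- 3 * m$category_coords + 7
  m2$norm_min <- 3 * m$norm_min + 7
  m2$norm_max <- 3 * m$norm_max + 7
  sc2 <- score_index(w$survey, m2, rep(1, nrow(w$survey)))
  expect_equal(sc2$score_0_100, sc$score_0_100, tolerance = 1e-9)
})

test_that("error paths: constant column, single respondent, unseen category", {
  df <- data.frame(a = rep("x", 6), b = rep(c("p", "q"), 3))
  expect_error(fit_mca(df, index_spec("t", c("a", "b"), "a", 1)),
               "constant input column: a")
  df1 <- data.frame(a = "x", b = "p")
  expect_error(fit_mca(df1, index_spec("t", c("a", "b"), "a", 1)),
               "at least 2")
  df2 <- data.frame(a = c("y", "n", "y", "n"), b = c("p", "q", "q", "p"))
  m <- fit_mca(df2, index_spec("t", c("a", "b"), "a", 1))
  new <- data.frame(a = "maybe", b = "p")
  expect_error(score_index(new, m), "unseen categor")
})

test_that("bin_continuous produces weighted-quantile bins", {
  b <- bin_continuous(1:9, n_bins = 3)
  expect_equal(as.vector(table(b)), c(3, 3, 3))
  expect_warning(b1 <- bin_continuous(rep(5, 10), n_bins = 3), "reducing bins")
  expect_equal(length(levels(droplevels(b1))), 1)
  # skewed data vs brute-force sort-and-accumulate oracle
  withr::with_seed(5, {
    x <- rexp(200); wts <- runif(200, 0.2, 3)
  })
  b2 <- bin_continuous(x, wts, 4)
  o <- order(x); cw <- cumsum(wts[o]) / sum(wts)
  brk <- vapply(c(.25, .5, .75), function(p) x[o][which(cw >= p)[1]],
                numeric(1))
  want <- cut(x, c(-Inf, brk, Inf), labels = paste0("bin", 1:4), right = TRUE)
  expect_equal(as.character(b2), as.character(want))
  # ties resolve to the lower bin
  b3 <- bin_continuous(c(1, 1, 1, 2, 3, 3), n_bins = 3)
  expect_equal(as.character(b3)[1:3], rep("bin1", 3))
})

test_that("composite convenience: idempotence, cancellation, arithmetic", {
  w <- tiny_world()
  wts <- rep(1, nrow(w$survey))
  specs <- default_index_specs()
  acc <- score_index(w$survey, fit_mca(w$survey, specs$accessibility, wts), wts)
  tf <- score_index(w$survey, fit_mca(w$survey, specs$time_financial, wts), wts)
  # idempotence: composite of an index with itself is the index
  cc <- composite_convenience(acc, acc, wts)
  expect_equal(cc$score_0_100, acc$score_0_100, tolerance = 1e-9)
  # arithmetic oracle
  cv <- composite_convenience(acc, tf, wts)
  s <- acc$score_0_100 + tf$score_0_100
  want <- (s - min(s)) / (max(s) - min(s)) * 100
  expect_equal(cv$score_0_100, want, tolerance = 1e-9)
  expect_equal(cv$name, "convenience")
  # perfect anti-correlation collapses the composite
  anti <- acc
  anti$score_0_100 <- 100 - acc$score_0_100
  expect_warning(cst <- composite_convenience(acc, anti, wts), "constant")
  expect_true(all(cst$score_0_100 == 50))
  # mismatched respondents rejected
  acc2 <- acc
  acc2$ids <- rev(acc2$ids)
  expect_error(composite_convenience(acc2, tf, wts), "different respondent")
})

test_that("driver correlations: identity, null behaviour, zero variance", {
  n <- 500
  withr::with_seed(9, x <- rnorm(n))
  sv <- data.frame(a = x, b = rnorm(n))
  sc <- structure(list(score_0_100 = x, weights = rep(1, n)),
                  class = "index_scores")
  spec <- index_spec("t", c("a", "b"), "a", 1,
                     continuous_inputs = list())
  dr <- driver_correlations(sv, sc, spec)
  expect_equal(dr$r[dr$input == "a"], 1, tolerance = 1e-12)
  # independent input: small, non-significant r in >= 90% of seeded reps
  nrep <- 100; good <- 0
  for (i in seq_len(nrep)) {
    withr::with_seed(1000 + i, {
      idx <- rnorm(5000); inp <- rbinom(5000, 1, 0.5)
    })
    svi <- data.frame(a = inp, b = inp)
    sci <- structure(list(score_0_100 = idx, weights = rep(1, 5000)),
                     class = "index_scores")
    d <- driver_correlations(svi, sci, index_spec("t", c("a", "b"), "a", 1))
    r <- d$r[d$input == "a"]
    if (abs(r) < 0.05 && !d$significant_at_95[d$input == "a"]) good <- good + 1
  }
  expect_gte(good, 90)
  # zero-variance input reported as missing
  svz <- data.frame(a = x, b = rep(1, n))
  drz <- driver_correlations(svz, sc, index_spec("t", c("a", "b"), "a", 1))
  expect_true(is.na(drz$r[drz$input == "b"]))
})

test_that("mca diagnostics flag weak primary dimensions", {
  df <- data.frame(a = rep(c("y", "n"), each = 10),
                   b = rep(c("p", "q"), each = 10))
  m <- fit_mca(df, index_spec("t", c("a", "b"), "a", 1))
  d <- mca_diagnostics(m)
  expect_equal(d$inertia_share_corrected, 1.0, tolerance = 1e-12)
  expect_false(d$flagged)
  expect_lte(sum(m$eigenvalues) - sum(m$eigenvalues), 1e-12)
  expect_lte(m$inertia_share_raw, 1)
  # independent inputs: corrected share well below 0.9 at large n
  withr::with_seed(3, {
    dfi <- data.frame(a = sample(c("y", "n"), 2000, TRUE),
                      b = sample(c("p", "q"), 2000, TRUE),
                      c = sample(c("u", "v"), 2000, TRUE))
  })
  mi <- fit_mca(dfi, index_spec("t", c("a", "b", "c"), "a", 1))
  di <- mca_diagnostics(mi)
  expect_lt(di$inertia_share_corrected, 0.9)
  expect_true(di$flagged)
})
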