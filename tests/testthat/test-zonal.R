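test_that("zonal aggregation: uniform layers, arithmetic oracle, conservation", {
  zl <- raster_grid(matrix(c(1, 1, 2, 2), 2, 2), cell_size = 10)
  uni <- raster_grid(matrix(7, 2, 2), cell_size = 10)
  zs <- zonal_aggregate(uni, zl)
  expect_equal(zs$layer_mean, c(7, 7))
  expect_equal(zs$layer_min, c(7, 7))
  expect_equal(zs$layer_max, c(7, 7))
  # two-cell zone, values (10, 30), population (1, 3) -> mean 25
  vals <- raster_grid(matrix(c(10, 30, 0, 0), 2, 2), cell_size = 10)
  pop <- raster_grid(matrix(c(1, 3, 1, 1), 2, 2), cell_size = 10)
  zs2 <- zonal_aggregate(vals, zl, pop)
  expect_equal(zs2$layer_mean[1], 25)
  # national mean equals the population-weighted mean of zone means
  w <- tiny_world()
  t1 <- w$truth_indices[["confidence"]]
  st <- zonal_aggregate(t1, w$state_zones, w$population)
  nat <- sum(t1$values * w$population$values) / sum(w$population$values)
  expect_equal(sum(st$layer_mean * st$population) / sum(st$population), nat,
               tolerance = 1e-9)
  expect_true(all(st$layer_min <= st$layer_mean & st$layer_mean <= st$layer_max))
})

test_that("range summaries and the Table-4-style width arithmetic", {
  rs <- range_summary(c(48, 55, 61, 69))
  expect_equal(rs$width, 21)
  expect_equal(range_summary(42)$width, 0)
  expect_error(range_summary(numeric(0)), "at least one")
})

test_that("mean cumulative score reproduces the four published rows", {
  # Katsina LGA / hyperlocal; Bayelsa LGA / hyperlocal (per-index widths)
  k_lga <- mean_cumulative_score(c(38, 20, 33))
  expect_equal(k_lga$cumulative_score, 91)
  expect_equal(k_lga$mcs, 30)
  k_hyp <- mean_cumulative_score(c(53, 47, 66))
  expect_equal(k_hyp$cumulative_score, 166)
  expect_equal(k_hyp$mcs, 55)
  b_lga <- mean_cumulative_score(c(12, 7, 12))
  expect_equal(b_lga$cumulative_score, 31)
  expect_equal(b_lga$mcs, 10)
  b_hyp <- mean_cumulative_score(c(34, 26, 53))
  expect_equal(b_hyp$cumulative_score, 113)
  expect_equal(b_hyp$mcs, 38)
  expect_equal(mean_cumulative_score(c(0, 0, 0))$mcs, 0)
  expect_error(mean_cumulative_score(c(-1, 2, 3)), "negative")
  expect_error(mean_cumulative_score(c(1, 2)), "three")
})

test_that("prevalent determinant: arithmetic, ties, brute-force oracle", {
  mk <- function(v) raster_grid(matrix(v, 1, 1), cell_size = 10)
  pd <- prevalent_determinant(mk(40), mk(50), mk(20))
  expect_equal(unname(pd$labels[as.character(pd$layer$values[1, 1])]),
               "convenience")  # transformed (60, 50, 80)
  # three-way tie at 50 -> priority order applies (convenience first)
  pd2 <- prevalent_determinant(mk(50), mk(50), mk(50))
  expect_equal(unname(pd2$labels[as.character(pd2$layer$values[1, 1])]),
               "convenience")
  pd3 <- prevalent_determinant(mk(50), mk(50), mk(50),
                               priority = c("complacency", "convenience",
                                            "confidence"))
  expect_equal(unname(pd3$labels[as.character(pd3$layer$values[1, 1])]),
               "complacency")
  # brute-force per-cell oracle on random 20x20 layers
  withr::with_seed(12, {
    conf <- matrix(runif(400, 0, 100), 20, 20)
    comp <- matrix(runif(400, 0, 100), 20, 20)
    conv <- matrix(runif(400, 0, 100), 20, 20)
  })
  conf[3, 3] <- NA
  g <- function(m) raster_grid(m, cell_size = 10)
  pd4 <- prevalent_determinant(g(conf), g(comp), g(conv))
  prio <- c("convenience", "complacency", "confidence")
  for (r in 1:20) for (c in 1:20) {
    if (is.na(conf[r, c])) { expect_true(is.na(pd4$layer$values[r, c])); next }
    tr <- c(confidence = 100 - conf[r, c], complacency = comp[r, c],
            convenience = 100 - conv[r, c])
    want <- prio[which.max(tr[prio])]
    expect_equal(unname(pd4$labels[as.character(pd4$layer$values[r, c])]),
                 want)
  }
  # invariance to a common constant on the transformed scale
  pd5 <- prevalent_determinant(g(conf - 5), g(comp + 5), g(conv - 5))
  expect_equal(pd5$layer$values, pd4$layer$values)
})

test_that("population counts: closed forms and the per-cell loop oracle", {
  zl <- raster_grid(matrix(c(1, 1, 2, 2), 2, 2), cell_size = 10)
  pop <- raster_grid(matrix(c(400, 600, 250, 750), 2, 2), cell_size = 10)
  half <- raster_grid(matrix(0.5, 2, 2), cell_size = 10)
  pc <- population_count(half, pop, zl)
  expect_equal(pc$count, c(500, 500))
  ones <- raster_grid(matrix(1, 2, 2), cell_size = 10)
  expect_equal(population_count(ones, pop, zl)$count, c(1000, 1000))
  withr::with_seed(2, sh <- matrix(runif(4), 2, 2))
  pcr <- population_count(raster_grid(sh, cell_size = 10), pop, zl)
  want <- c(sum(sh[, 1] * pop$values[, 1]), sum(sh[, 2] * pop$values[, 2]))
  expect_equal(pcr$count, want, tolerance = 1e-12)
  bad <- raster_grid(matrix(1.4, 2, 2), cell_size = 10)
  expect_error(population_count(bad, pop, zl), "outside")
})

test_that("multi-criteria targeting matches hand enumeration", {
  zs <- data.frame(zone = 1:5,
                   hausa = c(0.6, 0.4, 0.8, 0.55, 0.3),
                   low_conf = c(0.7, 0.8, 0.45, 0.52, 0.9))
  expect_equal(select_zones(zs), 1:5)
  expect_equal(select_zones(zs, list(list(column = "hausa", op = ">=",
                                          threshold = 2))), numeric(0))
  got <- select_zones(zs, list(list(column = "hausa", op = ">=", threshold = 0.5),
                               list(column = "low_conf", op = ">", threshold = 0.5)))
  expect_equal(got, c(1, 4))
  expect_error(select_zones(zs, list(list(column = "igbo", op = ">=",
                                          threshold = 0.5))),
               "unknown layer")
  expect_error(select_zones(zs, list(list(column = "hausa", op = "~",
                                          threshold = 0.5))),
               "unknown comparator")
})

test_that("aggregation shrinks ranges: hyperlocal >= LGA >= state widths", {
  w <- tiny_world()
  for (nm in c("confidence", "complacency", "convenience")) {
    layer <- w$truth_indices[[nm]]
    st <- zonal_aggregate(layer, w$state_zones, w$population)
    lg <- zonal_aggregate(layer, w$lga_zones, w$population)
    w_state <- range_summary(st$layer_mean)$width
    w_lga <- range_summary(lg$layer_mean)$width
    w_hyp <- range_summary(as.vector(layer$values))$width
    expect_lte(w_state, w_lga + 1e-9)
    expect_lte(w_lga, w_hyp + 1e-9)
  }
})
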