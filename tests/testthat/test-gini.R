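# Lorenz curve and trapezoid Gini coefficient.

test_that("lorenz curve matches hand constructions and its invariants", {
  # all resource in the second of two equal-measure regions
  lc <- lorenz_curve(allocation(m = c(1, 1), e = c(0, 1)))
  expect_equal(lc$x, c(0, 0.5, 1))
  expect_equal(lc$y, c(0, 0, 1))

  # proportional allocation lies on the diagonal
  lc <- lorenz_curve(allocation(m = c(1, 2, 3), e = c(2, 4, 6)))
  expect_equal(lc$y, lc$x)

  # entry order is irrelevant (construction sorts by density)
  set.seed(7)
  al <- random_allocation(12)
  shuffled <- allocation(m = rev(al$m), e = rev(al$e), zone = rev(al$zone),
                         region_id = rev(al$region_id))
  expect_equal(lorenz_curve(shuffled), lorenz_curve(al))

  # structural invariants on random instances
  for (i in 1:20) {
    al <- random_allocation(sample(2:40, 1))
    lc <- lorenz_curve(al)
    expect_equal(lc$x[1], 0)
    expect_equal(lc$y[1], 0)
    expect_equal(lc$x[nrow(lc)], 1, tolerance = 1e-12)
    expect_equal(lc$y[nrow(lc)], 1, tolerance = 1e-12)
    expect_true(all(diff(lc$x) > 0))
    expect_true(all(diff(lc$y) >= 0))
    expect_true(all(lc$y <= lc$x + 1e-12))  # convexity below diagonal
  }

  expect_error(lorenz_curve(allocation(m = c(1, 1), e = c(0, 0))),
               class = "equipanel_error_degenerate")
})

test_that("trapezoid Gini matches hand values and the mean-difference oracle", {
  expect_equal(gini_index(c(0.5, 0.5), c(0, 1)), 0.5)
  expect_equal(gini_index(c(0.25, 0.25, 0.5), c(0.1, 0.2, 0.7)), 0.225)
  expect_equal(gini_index(c(0.25, 0.25, 0.5), c(0.1, 0.2, 0.7)),
               gini_mean_difference(c(0.25, 0.25, 0.5), c(0.1, 0.2, 0.7)),
               tolerance = 1e-12)
  # proportional allocation
  expect_equal(gini_index(c(1, 2, 3), c(10, 20, 30)), 0, tolerance = 1e-12)

  set.seed(11)
  for (i in 1:200) {
    n <- sample(2:50, 1)
    m <- exp(rnorm(n)); e <- exp(rnorm(n))
    expect_equal(gini_index(m, e), gini_mean_difference(m, e),
                 tolerance = 1e-10)
  }
})

test_that("Gini is scale- and permutation-invariant and respects transfers", {
  set.seed(23)
  for (i in 1:25) {
    n <- sample(3:30, 1)
    m <- exp(rnorm(n)); e <- exp(rnorm(n))
    g <- gini_index(m, e)
    expect_equal(gini_index(3.7 * m, e), g, tolerance = 1e-12)
    expect_equal(gini_index(m, 0.002 * e), g, tolerance = 1e-12)
    p <- sample(n)
    expect_equal(gini_index(m[p], e[p]), g, tolerance = 1e-12)

    # progressive transfer: move resource from the densest to the least
    # dense region, small enough not to cross ranks
    d <- e / m
    hi <- which.max(d); lo <- which.min(d)
    eps <- 0.05 * (d[hi] - d[lo]) * min(m[hi], m[lo])
    e2 <- e; e2[hi] <- e2[hi] - eps; e2[lo] <- e2[lo] + eps
    expect_lte(gini_index(m, e2), g + 1e-12)
  }
})

test_that("fairness bands are left-closed and reject out-of-range G", {
  expect_equal(classify_gini(0.169), "optimal")
  expect_equal(classify_gini(0.55), "alert")
  expect_equal(classify_gini(c(0, 0.3, 0.4, 0.5, 0.6, 0.999)),
               c("optimal", "normal", "gap", "alert", "danger", "danger"))
  expect_error(classify_gini(1), class = "equipanel_error_domain")
  expect_error(classify_gini(-0.1), class = "equipanel_error_domain")
})

test_that("gini_series is year-ordered, constant for a frozen panel", {
  df <- small_panel_df(2003:2007)
  # same cross-section every year
  for (col in resource_columns()) {
    df[[col]] <- rep(df[[col]][df$year == 2003], times = 5)
  }
  gs <- gini_series(as_resource_panel(df), "cmhi", "bed", "population")
  expect_equal(nrow(gs), 5)
  expect_equal(gs$year, 2003:2007)
  expect_equal(length(unique(gs$gini)), 1)

  pan <- generate_panel(generator_config(), seed = 3)
  gs <- gini_series(pan, "th", "personnel", "geography")
  expect_equal(nrow(gs), 18)
  expect_true(all(gs$band == classify_gini(gs$gini)))
})

test_that("rising within-zone dispersion raises expected Gini over seeds", {
  first_last <- vapply(1:40, function(s) {
    pan <- generate_panel(generator_config(inequality_drift = 0.02),
                          seed = 7000 + s)
    g <- gini_series(pan, "cmhi", "bed", "population")$gini
    c(g[1], g[length(g)])
  }, numeric(2))
  expect_gt(mean(first_last[2, ]), mean(first_last[1, ]))
})
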