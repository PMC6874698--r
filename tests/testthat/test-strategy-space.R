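test_that("grid construction enforces the invariants", {
  g <- strategy_grid(101)
  expect_equal(sum(g$weights), 1)           # volume of [0, 1]
  expect_true(all(g$weights > 0))
  expect_error(strategy_grid(2), "at least 3")
  expect_error(strategy_grid(c(0, 0.5, 0.5)), "strictly increasing")
  expect_error(strategy_grid(c(0, 0.5, 1), weights = c(1, -1, 1)),
               "positive")
})

test_that("measures of sets are quadratures and are additive", {
  g <- strategy_grid(101)
  f <- density_field(g, times = c(0, 1),
                     values = matrix(1, 101, 2), bound = 1 + 1e-9)
  full <- subset_indicator(g, rep(TRUE, 101))
  half <- subset_indicator(g, function(v) v <= 0.5)
  expect_equal(measure_of_set(f, full, 0), 1)
  # proportionality up to the boundary half-cell of the node mask
  expect_lt(abs(measure_of_set(f, half, 0.5) - 0.5),
            max(diff(g$nodes)))
  expect_equal(measure_of_set(f, subset_indicator(g, rep(FALSE, 101)), 0), 0)
  expect_error(measure_of_set(f, full, 2), "outside")
  # countable additivity over a disjoint cover of the grid
  set.seed(1)
  vals <- matrix(runif(101 * 2), 101, 2)
  f2 <- density_field(g, c(0, 1), vals)
  masks <- split(seq_len(101), rep(1:5, length.out = 101))
  parts <- vapply(masks, function(ix) {
    m <- rep(FALSE, 101); m[ix] <- TRUE
    measure_of_set(f2, subset_indicator(g, m), 0.3)
  }, numeric(1))
  expect_equal(sum(parts), measure_of_set(f2, full, 0.3),
               tolerance = 1e-12)
  # complement decomposition
  expect_equal(measure_of_set(f2, half, 1) +
                 measure_of_set(f2, complement(half), 1),
               measure_of_set(f2, full, 1), tolerance = 1e-12)
})

test_that("the declared measure bound is enforced", {
  g <- strategy_grid(11)
  expect_error(density_field(g, 0:1, matrix(3, 11, 2), bound = 1),
               "bound")
  expect_silent(density_field(g, 0:1, matrix(3, 11, 2), bound = 3.1))
})

test_that("neighbourhoods contain their centre and respect the metric", {
  g <- strategy_grid(101)
  nb <- neighbourhood(g, 0.5, 0.02)
  expect_equal(g$nodes[as.logical(nb)],
               c(0.48, 0.49, 0.50, 0.51, 0.52), tolerance = 1e-12)
  expect_equal(sum(neighbourhood(g, 0.5, 1)), 101)     # full grid
  nb0 <- neighbourhood(g, 0, 0.02)                     # boundary point
  expect_equal(g$nodes[as.logical(nb0)], c(0, 0.01, 0.02),
               tolerance = 1e-12)
  expect_warning(neighbourhood(g, 0.5, 0.001), "single node")
})

test_that("the generalised density transform is a pointwise power", {
  g <- strategy_grid(c(0, 0.5, 1))
  rho <- density_field(g, 0:1, matrix(c(1, 4, 9, 1, 4, 9), 3, 2))
  eta <- transform_density(rho, 2)        # square root
  expect_equal(eta$values[, 1], c(1, 2, 3))
  expect_equal(transform_density(rho, 1)$values, rho$values)  # identity
  expect_error(transform_density(rho, c(1, 0, 1)), "positive")
  # monotone: rho1 >= rho2 pointwise => eta1 >= eta2 pointwise
  set.seed(2)
  for (i in 1:5) {
    a <- matrix(runif(6, 0, 4), 3, 2)
    b <- a * matrix(runif(6, 0, 1), 3, 2)
    R <- runif(3, 0.5, 3)
    ea <- transform_density(density_field(g, 0:1, a), R)
    eb <- transform_density(density_field(g, 0:1, b), R)
    expect_true(all(ea$values >= eb$values - 1e-14))
  }
  # eta vanishes exactly where rho vanishes
  z <- transform_density(density_field(g, 0:1, matrix(c(0, 1, 2), 3, 2)),
                         function(v) 1 + v)
  expect_identical(z$values[1, ], c(0, 0))
})

test_that("fields round-trip through CSV", {
  g <- strategy_grid(seq(0, 1, by = 0.25))
  f <- density_field(g, c(0, 2, 5), matrix(seq_len(15) / 10, 5, 3))
  path <- tempfile(fileext = ".csv")
  write_field_csv(f, path)
  f2 <- read_field_csv(path)
  expect_equal(f2$values, f$values)
  expect_equal(f2$times, f$times)
  expect_equal(f2$grid$nodes, g$nodes)
  unlink(path)
})
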