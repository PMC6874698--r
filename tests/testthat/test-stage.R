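test_that("the stage matrix follows the life-history mapping exactly", {
  expect_equal(ref_stage_matrix(),
               matrix(c(-1.1, 1, 2, -0.2), 2, 2))
  # all rates zero: zero matrix
  m0 <- stage_model(2, b = c(0, 0), a = c(0, 0), p = 0)
  expect_equal(build_stage_matrix(m0), matrix(0, 2, 2))
  # n = 3 with only b3 > 0: first row (-p1 - a1, 0, b3)
  m3 <- stage_model(3, b = c(0, 0, 1.5), a = c(0.2, 0.1, 0.3),
                    p = c(0.7, 0.4))
  L3 <- build_stage_matrix(m3)
  expect_equal(L3[1, ], c(-0.9, 0, 1.5))
  expect_equal(L3[2, ], c(0.7, -0.5, 0))
  expect_equal(L3[3, ], c(0, 0.4, -0.3))
  expect_error(stage_model(1, b = 0, a = 0.1, p = numeric(0)),
               "at least 2")
  expect_error(stage_model(2, b = c(1, 2), a = c(0, 0), p = 1),
               "b\\[1\\]")
})

test_that("dominant eigenvalues match closed-form oracles", {
  sr <- dominant_eigenvalue(diag(c(3, 1)))
  expect_equal(sr$lambda1, 3)
  expect_equal(sr$vector1, c(1, 0))
  # quadratic-formula oracle for the reference matrix
  sr2 <- dominant_eigenvalue(ref_stage_matrix())
  expect_equal(sr2$lambda1, ref_lambda1, tolerance = 1e-12)
  expect_equal(sum(sr2$vector1), 1)
  expect_true(all(sr2$vector1 >= 0))
  # spectral shift: L + cI shifts lambda1 by exactly c
  L <- ref_stage_matrix()
  expect_equal(dominant_eigenvalue(L + 0.37 * diag(2))$lambda1,
               sr2$lambda1 + 0.37, tolerance = 1e-12)
  # complex dominant pair is flagged
  rot <- matrix(c(0, -1, 1, 0), 2, 2)
  expect_warning(dominant_eigenvalue(rot), "complex")
})

test_that("the analytic stage fitness is lambda1 / R with its scalings", {
  g <- strategy_grid(21)
  base <- stage_model(2, b = function(v) c(0, 2 + v), a = c(0.1, 0.2),
                      p = 1, R = 1, grid = g)
  land <- stage_fitness(base)
  # J increases with fecundity: argmax at v = 1 and monotone landscape
  expect_equal(attr(land, "argmax"), 1)
  expect_true(all(diff(land$J) > 0))
  # oracle at v = 0 is the reference eigenvalue
  expect_equal(land$J[1], ref_lambda1, tolerance = 1e-12)
  # doubling R halves J everywhere
  double_R <- stage_model(2, b = function(v) c(0, 2 + v),
                          a = c(0.1, 0.2), p = 1, R = 2, grid = g)
  expect_equal(stage_fitness(double_R)$J, land$J / 2, tolerance = 1e-12)
  # equal lambda1, smaller R => larger J
  m_v <- stage_model(2, b = c(0, 2), a = c(0.1, 0.2), p = 1, R = 1)
  m_w <- stage_model(2, b = c(0, 2), a = c(0.1, 0.2), p = 1, R = 2)
  expect_gt(stage_fitness(m_v), stage_fitness(m_w))
})

test_that("frequencies of the nonlinear system equal the normalised linear flow", {
  L <- ref_stage_matrix()
  expect_lt(frequency_solution_check(L, c(0.5, 0.5), 20), 1e-6)
  # diagonal matrix: closed-form exponentials
  expect_lt(frequency_solution_check(diag(c(0.4, -0.3)), c(0.7, 0.3), 15),
            1e-9)
  # eigenvector initial condition: constant frequencies
  e1 <- dominant_eigenvalue(L)$vector1
  tr <- simulate_frequencies(L, e1, 30)
  expect_true(all(abs(tr$xi1 - e1[1]) < 1e-7))
  expect_true(all(abs(tr$F - ref_lambda1) < 1e-7))
})

test_that("long-run F converges to the dominant eigenvalue", {
  L <- ref_stage_matrix()
  tr <- simulate_frequencies(L, c(0.5, 0.5), 60)
  expect_equal(long_term_F(tr, c(30, 60)), ref_lambda1, tolerance = 1e-6)
  # diagonal with a pure state: F constant at the corresponding rate
  trd <- simulate_frequencies(diag(c(3, 1)), c(1, 0), 10)
  expect_true(all(abs(trd$F - 3) < 1e-9))
  # F is the component sum of L xi when the frequencies sum to 1
  xi <- as.matrix(tr[, c("xi1", "xi2")])
  Fsum <- apply(xi, 1, function(x) sum(L %*% x))
  expect_true(all(abs(Fsum - tr$F) < 1e-10))
})

test_that("the nonlinear stage system matches the spectral predictions", {
  # no limitation: per-capita growth of Z converges to lambda1
  m <- stage_model(2, b = c(0, 2), a = c(0.1, 0.2), p = 1, R = 1,
                   limitation = function(z) 0)
  tr <- simulate_stage_system(m, z0 = c(1, 0), horizon = 40,
                              times = seq(0, 40, length.out = 81))
  Z <- tr$Z[1, ]
  slope <- (log(Z[81]) - log(Z[41])) / 20
  expect_equal(slope, ref_lambda1, tolerance = 1e-6)
  # zero initial state stays zero
  tr0 <- simulate_stage_system(m, z0 = c(0, 0), horizon = 10)
  expect_true(all(tr0$Z == 0))
  # two strategies: the one with larger J excludes the other
  g <- strategy_grid(c(0, 0.5, 1))
  m2 <- stage_model(2, b = function(v) c(0, 2 + v), a = c(0.1, 0.2),
                    p = 1, R = 1, grid = g)
  tr2 <- simulate_stage_system(m2, z0 = function(v) c(0.1, 0.1),
                               horizon = 300,
                               times = seq(0, 300, length.out = 151))
  eta_ratio <- tr2$eta$values[1, 151] / tr2$eta$values[3, 151]
  expect_lt(eta_ratio, 1e-3)
  # analytic argmax equals the surviving strategy
  expect_equal(attr(stage_fitness(m2), "argmax"), 1)
})

test_that("stage fitness is independent of initial conditions", {
  g <- strategy_grid(11)
  m <- random_stage_model(11, grid = g, separate_fitness = TRUE)
  land1 <- stage_fitness(m)
  land2 <- stage_fitness(m)
  expect_identical(land1$J, land2$J)   # no initial data consumed
  set.seed(5)
  winners <- vapply(1:5, function(i) {
    z0 <- matrix(runif(11 * m$n, 0.05, 1), 11, m$n)
    tr <- simulate_stage_system(m, z0 = z0, horizon = 400,
                                times = seq(0, 400, length.out = 101))
    land <- fitness_landscape(tr$eta, window = c(200, 400))
    attr(land, "argmax")[1]
  }, numeric(1))
  expect_equal(winners, rep(attr(land1, "argmax"), 5))
})
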