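test_that("the characteristic matrix assembles the delayed coefficients", {
  dm <- delay_model(1, tau = 1, q = 1, r = 0)
  expect_equal(Re(char_matrix(dm, 0)), matrix(1, 1, 1))          # e^0
  expect_equal(Re(char_matrix(dm, log(2))), matrix(0.5, 1, 1))   # e^{-ln 2}
  # m = 0: constant in lambda, equal to r
  L <- ref_stage_matrix()
  dm0 <- delay_model(2, tau = numeric(0), q = array(0, c(2, 2, 0)), r = L)
  expect_equal(Re(char_matrix(dm0, 0)), L)
  expect_equal(Re(char_matrix(dm0, 5 + 2i)), L)
  expect_error(delay_model(1, tau = -1, q = 1, r = 0), "positive")
})

test_that("rightmost roots match bisection and eigensolver oracles", {
  # scalar lambda = e^{-lambda}: the omega constant
  dm <- delay_model(1, tau = 1, q = 1, r = 0)
  rs <- rightmost_root(dm)
  expect_equal(Re(attr(rs, "rightmost")), scalar_delay_root(1, 1),
               tolerance = 1e-10)
  expect_true(all(rs$residual < 1e-10))
  # tau -> 0 collapses to the ODE rate
  dm2 <- delay_model(1, tau = 1e-12, q = 2, r = 0)
  expect_equal(Re(attr(rightmost_root(dm2), "rightmost")), 2,
               tolerance = 1e-9)
  # m = 0 agrees with the matrix eigensolver
  L <- ref_stage_matrix()
  dm0 <- delay_model(2, tau = numeric(0), q = array(0, c(2, 2, 0)), r = L)
  expect_equal(Re(attr(rightmost_root(dm0), "rightmost")), ref_lambda1,
               tolerance = 1e-10)
})

test_that("complex roots come in conjugate pairs and validate by substitution", {
  # negative feedback with delay: rightmost pair is complex
  dm <- delay_model(1, tau = 1, q = -2, r = 0)
  rs <- rightmost_root(dm, floor = -1)
  expect_true(all(rs$residual < 1e-10))
  ims <- sort(rs$im[abs(rs$im) > 1e-8])
  expect_equal(ims, -rev(ims))      # conjugate symmetry
  for (i in seq_len(nrow(rs))) {
    val <- validate_root(dm, complex(real = rs$re[i],
                                     imaginary = rs$im[i]))
    expect_lt(val$residual, 1e-8)
  }
})

test_that("delay fitness scales and orders like the rightmost root", {
  # larger q gives the larger real root (bisection oracle)
  g3 <- strategy_grid(c(0, 0.5, 1))
  dm <- delay_model(1, tau = 1, q = function(v) array(1 + v, c(1, 1, 1)),
                    r = 0, grid = g3)
  land <- delay_fitness(dm)
  expect_equal(land$J, vapply(c(1, 1.5, 2), scalar_delay_root, numeric(1),
                              tau = 1), tolerance = 1e-9)
  expect_equal(attr(land, "argmax"), 1)
  # R scaled by 2 halves J
  dm_R <- delay_model(1, tau = 1, q = function(v) array(1 + v, c(1, 1, 1)),
                      r = 0, R = 2, grid = g3)
  expect_equal(delay_fitness(dm_R)$J, land$J / 2, tolerance = 1e-12)
  # m = 0 embedding of a stage model reproduces stage_fitness
  g <- strategy_grid(11)
  sm <- random_stage_model(7, grid = g)
  dm0 <- delay_model(sm$n, tau = numeric(0),
                     q = array(0, c(sm$n, sm$n, 0)),
                     r = function(v) build_stage_matrix(sm, v),
                     R = function(v) if (is.function(sm$R)) sm$R(v)
                       else sm$R,
                     grid = g)
  expect_equal(delay_fitness(dm0)$J, stage_fitness(sm)$J,
               tolerance = 1e-6)
})

test_that("delay simulation matches its linear and delay-free limits", {
  # all q = 0: pure ODE z' = rz, matches the exponential
  dm <- delay_model(1, tau = 1, q = array(0, c(1, 1, 1)), r = 0.3,
                    history = 2)
  tr <- simulate_dde(dm, 10, times = seq(0, 10, length.out = 21))
  expect_equal(tr$Z[1, ], 2 * exp(0.3 * tr$times), tolerance = 1e-7)
  # linear scalar DDE: log slope equals the rightmost root
  dm1 <- delay_model(1, tau = 1, q = 1, r = 0, history = 1)
  tr1 <- simulate_dde(dm1, 60, times = seq(0, 60, length.out = 121))
  slope <- (log(tr1$Z[1, 121]) - log(tr1$Z[1, 61])) / 30
  expect_equal(slope, scalar_delay_root(1, 1), tolerance = 1e-6)
  # zero history: identically zero (strong inheritance)
  dm0 <- delay_model(1, tau = 1, q = 1, r = 0, history = 0)
  tr0 <- simulate_dde(dm0, 10)
  expect_true(all(tr0$Z == 0))
})

test_that("the exponential change of variables linearises the limited system", {
  # no limitation: the transform is the identity
  dm_id <- delay_model(1, tau = 1, q = 1, r = 0,
                       f = function(z) 0, history = 1)
  expect_lt(change_of_variables_check(dm_id, 30), 1e-8)
  # logistic limitation, single strategy
  dm <- delay_model(1, tau = 1, q = 1, r = 0, R = 1,
                    f = total_density_limitation(), history = 1)
  expect_lt(change_of_variables_check(dm, 50), 1e-5)
  # two-strategy competition: the identity holds per strategy
  g3 <- strategy_grid(c(0, 0.5, 1))
  dm2 <- delay_model(1, tau = 0.8,
                     q = function(v) array(0.8 + 0.4 * v, c(1, 1, 1)),
                     r = -0.1, R = 1, grid = g3,
                     f = total_density_limitation(g3), history = 1)
  expect_lt(change_of_variables_check(dm2, 50), 1e-5)
})

test_that("the age-structured reduction produces the printed coefficients", {
  dm <- foerster_to_delay(tau = 1, a = c(0.1, 0.2), b = c(0, 2))
  qa <- dm$shape_q(dm$q(NULL))
  expect_equal(qa[2, 2, 1], 2 * exp(-0.1), tolerance = 1e-12)
  expect_equal(qa[1, 2, 1], -2 * exp(-0.1), tolerance = 1e-12)
  ra <- dm$shape_r(dm$r(NULL))
  expect_equal(diag(ra), c(-0.1, -0.2))
  expect_true(all(ra[2, 1] == 0))     # only row 1 carries births
  # zero mortality: survival factors are 1, q entries are +/- b_j
  dm0 <- foerster_to_delay(tau = c(1, 2), a = c(0, 0, 0), b = c(0, 1, 3))
  qa0 <- dm0$shape_q(dm0$q(NULL))
  expect_equal(qa0[2, , 1], c(0, 1, 3))
  expect_equal(qa0[1, , 1], c(0, -1, -3))
  expect_equal(qa0[3, , 2], c(0, 1, 3))
  expect_error(foerster_to_delay(tau = c(2, 1), a = rep(0, 3),
                                 b = c(0, 1, 1)), "increasing")
  expect_error(foerster_to_delay(tau = 1, a = c(0, 0), b = c(1, 1)),
               "b\\[1\\]")
  # the reduction is dynamically consistent: simulated growth of the
  # linear system matches its rightmost characteristic root
  rr <- Re(attr(rightmost_root(dm), "rightmost"))
  tr <- simulate_dde(dm, 80, times = seq(0, 80, length.out = 161))
  Z <- tr$Z[1, ]
  expect_equal((log(Z[161]) - log(Z[81])) / 40, rr, tolerance = 1e-4)
})
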