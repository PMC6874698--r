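test_that("time-average fitness recovers exact exponential rates", {
  g <- strategy_grid(11)
  tt <- seq(0, 10, by = 0.5)
  f <- density_field(g, tt, outer(rep(1, 11), exp(0.7 * tt)))
  est <- time_average_fitness(f, 0.3, window = c(0, 10))
  expect_equal(est$J1, 0.7, tolerance = 1e-12)
  expect_true(est$converged)
  # constant field: flat landscape at zero
  fc <- density_field(g, tt, matrix(1, 11, length(tt)))
  land <- fitness_landscape(fc, window = c(0, 10))
  expect_equal(land$J1, rep(0, 11))
  expect_equal(attr(land, "argmax"), g$nodes)   # polymorphic maximum
  # zero density in the window is an error, not a number
  fz <- density_field(g, tt, matrix(0, 11, length(tt)))
  expect_error(time_average_fitness(fz, 0.5), "undefined|zero")
})

test_that("trade-off run: ranking, fitness and transversality agree", {
  run <- linear_tradeoff_run()
  # the strategy with the larger k/r ranks above the smaller
  rp <- rank_pair(run$eta, 1, 0)
  expect_equal(rp$verdict, "v_better")
  # anti-symmetry: swapping the pair flips the verdict
  rp_rev <- rank_pair(run$eta, 0, 1)
  expect_equal(rp_rev$verdict, "w_better")
  # a strategy compared with itself is incomparable (ratio = 1)
  expect_equal(rank_pair(run$eta, 0.5, 0.5)$verdict, "incomparable")
  # landscape argmax sits at the argmax of k/r and its J1 is ~0
  land <- fitness_landscape(run$eta, window = c(250, 500))
  expect_equal(attr(land, "argmax"), 1)
  expect_lt(abs(land$J1[land$v == 1]), 1e-2)
  # J1 at the bottom of the landscape: k(0)/r(0) - k(1)/r(1) = -1
  j0 <- time_average_fitness(run$eta, 0, window = c(250, 500))
  expect_equal(j0$J1, -1, tolerance = 1e-2)
})

test_that("fitness preserves the ranking order on simulated models", {
  run <- linear_tradeoff_run()
  land <- fitness_landscape(run$eta, window = c(250, 500))
  set.seed(4)
  pairs <- replicate(8, sort(sample(run$grid$nodes, 2)), simplify = FALSE)
  for (p in pairs) {
    jv <- land$J1[land$v == p[2]]; jw <- land$J1[land$v == p[1]]
    rp <- rank_pair(run$eta, p[2], p[1])
    if (is.na(jv) || is.na(jw)) next
    if (jv > jw + 0.05) expect_equal(rp$verdict, "v_better")
    if (rp$verdict == "v_better") expect_gt(jv, jw)
  }
})

test_that("rank_pair demands positive initial measure in both neighbourhoods", {
  g <- strategy_grid(11)
  vals <- matrix(1, 11, 3); vals[1:3, ] <- 0
  f <- density_field(g, c(0, 1, 2), vals)
  expect_error(suppressWarnings(rank_pair(f, 1, 0.1, radius = 0.05)),
               "positive initial density")
})

test_that("whole-population extinction is flagged, not ranked", {
  g <- strategy_grid(11)
  tt <- 0:10
  f <- density_field(g, tt, outer(rep(1e-3, 11), exp(-2 * tt)))
  A <- subset_indicator(g, function(v) v < 0.5)
  expect_error(detect_selection(f, A, tolerance = 1e-3), "extinction")
  expect_error(detect_selection(f, subset_indicator(g, rep(FALSE, 11))),
               "non-empty")
})

test_that("verdict sets are checked for order-axiom violations", {
  expect_true(ranking_consistency_check(list())$consistent)
  run <- two_strategy_run()
  # consistent three-strategy chain from an actual simulation
  g <- strategy_grid(c(0, 0.5, 1))
  m <- nonlocal_logistic_model(g, k = c(1.0, 1.25, 1.5), r = 1,
                               rho0 = 0.5, coupling = "total")
  fld <- simulate_nonlocal_logistic(m, 300)
  eta <- generalised_density(fld, m)
  reps <- list(
    suppressWarnings(rank_pair(eta, 1, 0.5, radius = 0.1)),
    suppressWarnings(rank_pair(eta, 0.5, 0, radius = 0.1)),
    suppressWarnings(rank_pair(eta, 1, 0, radius = 0.1)))
  expect_equal(vapply(reps, `[[`, "", "verdict"),
               rep("v_better", 3))
  chk <- ranking_consistency_check(reps)
  expect_true(chk$consistent)
  # corrupt the closing verdict: transitivity violation must be reported
  bad <- reps
  bad[[3]]$verdict <- "w_better"     # claim 0 beats 1
  chk_bad <- ranking_consistency_check(bad)
  expect_false(chk_bad$consistent)
  expect_true(length(chk_bad$violations) > 0)
  # symmetric pair is impossible and must be reported
  sym <- list(reps[[1]], reps[[1]])
  sym[[2]]$pair <- c(v = 0.5, w = 1)
  sym[[2]]$verdict <- "v_better"
  expect_false(ranking_consistency_check(sym)$consistent)
})
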