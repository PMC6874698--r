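# Shared fixtures, built in code at test time.

# Trade-off logistic run (k = 1 + v, r = 1) on a modest grid; used by the
# ranking and fitness tests.  Cached per test file.
linear_tradeoff_run <- local({
  cache <- NULL
  function(horizon = 500, n_nodes = 101) {
    if (!is.null(cache)) return(cache)
    g <- strategy_grid(n_nodes)
    fam <- tradeoff_family("linear", g)
    m <- nonlocal_logistic_model(g, k = fam$k, r = fam$r, rho0 = 1,
                                 coupling = "total")
    fld <- simulate_nonlocal_logistic(m, horizon,
                                      times = seq(0, horizon,
                                                  length.out = 201))
    cache <<- list(grid = g, model = m, rho = fld,
                   eta = generalised_density(fld, m))
    cache
  }
})

# Two-strategy competition embedded in a 3-node grid (middle node empty).
two_strategy_run <- function(k_v = 1.5, k_w = 1.0, horizon = 200) {
  g <- strategy_grid(c(0, 0.5, 1))
  m <- nonlocal_logistic_model(g, k = c(k_w, k_w, k_v), r = 1,
                               rho0 = c(0.5, 0, 0.5), coupling = "total")
  fld <- simulate_nonlocal_logistic(m, horizon)
  list(grid = g, model = m, rho = fld, eta = generalised_density(fld, m))
}

# Reference 2-stage matrix with a closed-form dominant eigenvalue.
ref_stage_matrix <- function() {
  m <- stage_model(2, b = c(0, 2), a = c(0.1, 0.2), p = 1)
  build_stage_matrix(m)
}

# Quadratic-formula oracle for the reference matrix: eigenvalues of
# [[-1.1, 2], [1, -0.2]] solve x^2 + 1.3 x - 1.78 = 0.
ref_lambda1 <- (-1.3 + sqrt(1.3^2 + 4 * 1.78)) / 2

# Bisection oracle for the real root of lambda = q * exp(-lambda * tau).
scalar_delay_root <- function(q, tau, lo = -5, hi = 50) {
  uniroot(function(x) x - q * exp(-x * tau), c(lo, hi), tol = 1e-14)$root
}
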