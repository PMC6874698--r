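#' Right-hand side of the cyclic three-strategy replicator system
#'
#' For frequencies \eqn{\mu = (\mu_1, \mu_2, \mu_3)} on the simplex the
#' dynamics are \deqn{d\mu_i/dt = \mu_i \mu_{i+1} -
#' \mu_i(\mu_1\mu_2 + \mu_2\mu_3 + \mu_3\mu_1),} with the cyclic
#' convention \eqn{\mu_4 \equiv \mu_1}.  The components of the derivative
#' sum to zero, so the simplex is invariant, and any face (a coordinate
#' equal to zero) is invariant too: strategies absent at the start never
#' appear (strong inheritance).
#'
#' @param mu numeric 3-vector of nonnegative frequencies summing to 1.
#' @return numeric 3-vector of time derivatives.
#' @examples
#' replicator_rhs(c(1, 1, 1) / 3)   # interior equilibrium
#' replicator_rhs(c(0.5, 0.5, 0))
#' @export
replicator_rhs <- function(mu) {
  mu <- check_simplex(mu)
  Q <- mu[1] * mu[2] + mu[2] * mu[3] + mu[3] * mu[1]
  nxt <- c(mu[2], mu[3], mu[1])
  mu * nxt - mu * Q
}

check_simplex <- function(mu, tol = 1e-9) {
  mu <- as.numeric(mu)
  if (length(mu) != 3L) stop("replicator state must have 3 components")
  if (any(mu < -tol)) stop("replicator frequencies must be nonnegative")
  if (abs(sum(mu) - 1) > 1e-6)
    stop("replicator frequencies must sum to 1")
  pmax(mu, 0)
}

#' Simulate the three-strategy replicator system
#'
#' Integrates [replicator_rhs()] with an adaptive stiff-capable solver.
#' The trajectory is renormalised onto the simplex only through the
#' conservation of the dynamics themselves; the total is monitored and a
#' drift beyond tolerance raises an error.
#'
#' @param mu0 initial frequencies (3-vector on the simplex).
#' @param horizon final time.
#' @param times optional output times (default 400 points to `horizon`).
#' @param rtol,atol solver tolerances.
#' @return a data.frame with columns `t`, `mu1`, `mu2`, `mu3` of class
#'   `replicator_trajectory`.
#' @examples
#' tr <- simulate_replicator(c(0.2, 0.3, 0.5), horizon = 100)
#' tail(tr, 1)
#' @export
simulate_replicator <- function(mu0, horizon, times = NULL,
                                rtol = 1e-10, atol = 1e-12) {
  mu0 <- check_simplex(mu0)
  if (is.null(times)) times <- seq(0, horizon, length.out = 401)
  rhs <- function(t, y, p) list(replicator_rhs_raw(y))
  sol <- deSolve::ode(y = mu0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("replicator solver failed; last valid time ",
         max(sol[, 1], na.rm = TRUE))
  out <- as.data.frame(sol)
  names(out) <- c("t", "mu1", "mu2", "mu3")
  tot <- rowSums(out[, 2:4])
  if (any(abs(tot - 1) > 1e-6))
    stop("simplex total drifted beyond tolerance")
  class(out) <- c("replicator_trajectory", "data.frame")
  out
}

# rhs without simplex checks, for the inner solver loop (faces must be
# exactly invariant: mu_i = 0 gives dmu_i = 0 identically).
replicator_rhs_raw <- function(mu) {
  Q <- mu[1] * mu[2] + mu[2] * mu[3] + mu[3] * mu[1]
  mu * c(mu[2], mu[3], mu[1]) - mu * Q
}

#' Simulate the reduced two-strategy face system
#'
#' On the face where strategy 1 is absent, the competition between the
#' remaining two strategies reduces to the planar system
#' \deqn{d\mu_2/dt = \mu_2^2\,\mu_3, \qquad d\mu_3/dt = -\mu_2^2\,\mu_3,}
#' which conserves \eqn{\mu_2 + \mu_3} and drives \eqn{\mu_2 \to 1}
#' exponentially: strategy 2 ranks above strategy 3 on this face.
#'
#' @param mu0 initial `c(mu2, mu3)`, nonnegative, summing to 1.
#' @param horizon final time.
#' @param times optional output times.
#' @param rtol,atol solver tolerances.
#' @return data.frame with columns `t`, `mu2`, `mu3`.
#' @export
simulate_replicator_face <- function(mu0, horizon, times = NULL,
                                     rtol = 1e-8, atol = 1e-12) {
  mu0 <- as.numeric(mu0)
  stopifnot(length(mu0) == 2L, all(mu0 >= 0), abs(sum(mu0) - 1) < 1e-6)
  if (is.null(times)) times <- seq(0, horizon, length.out = 401)
  rhs <- function(t, y, p) {
    flow <- y[1]^2 * y[2]
    list(c(flow, -flow))
  }
  sol <- deSolve::ode(y = mu0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  out <- as.data.frame(sol)
  names(out) <- c("t", "mu2", "mu3")
  out
}

#' Map a replicator trajectory onto a three-node density field
#'
#' Embeds the three strategies at given nodes of a strategy grid so that
#' ranking and fitness machinery built for density fields applies to the
#' replicator example.  Frequencies are used directly as measure
#' densities (weights are taken uniform so node mass equals frequency).
#'
#' @param traj a `replicator_trajectory`.
#' @param nodes positions of the three strategies (default 0, 0.5, 1).
#' @return a [density_field()] on a 3-node grid with unit weights.
#' @export
replicator_field <- function(traj, nodes = c(0, 0.5, 1)) {
  stopifnot(inherits(traj, "replicator_trajectory"), length(nodes) == 3L)
  g <- strategy_grid(nodes, weights = rep(1, 3))
  density_field(g, traj$t, t(as.matrix(traj[, c("mu1", "mu2", "mu3")])),
                bound = 1 + 1e-9)
}
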