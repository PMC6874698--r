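#' Stage-structured life-history model
#'
#' Population of `n` developmental stages with densities
#' \eqn{z_i(v, t)} per strategy \eqn{v}.  Newborns (stage 1) are produced
#' by stages \eqn{i \ge 2} at rates \eqn{b_i(v)}; individuals age from
#' stage \eqn{i} to \eqn{i + 1} at rates \eqn{p_i(v)}, die naturally at
#' rates \eqn{a_i(v)}, and suffer extra mortality \eqn{R(v)\,y(t)} from a
#' shared limitation factor \eqn{y(t)} (by default the total density over
#' all strategies and stages).  In matrix form \eqn{z' = L(v) z -
#' R(v) y(t) z}, and the analytic fitness of the generalised density
#' \eqn{\eta = (\sum_i z_i)^{1/R(v)}} is \eqn{\lambda_1(v) / R(v)}, the
#' dominant eigenvalue of \eqn{L(v)} scaled by the limitation
#' sensitivity — independent of initial conditions.
#'
#' @param n number of stages (at least 2).
#' @param b reproduction rates: length-`n` numeric (entry 1 must be 0) or
#'   `function(v)` returning such a vector.
#' @param a natural mortality rates: length-`n` numeric or `function(v)`.
#' @param p stage-transition rates: length-`n-1` numeric or
#'   `function(v)`.
#' @param R positive limitation sensitivity: scalar or `function(v)`.
#' @param grid optional [strategy_grid()] when the model lives on a
#'   strategy space; coefficients are then evaluated per node.
#' @param limitation `function(z_total)` mapping the vector of per-node
#'   total densities to the scalar limitation factor `y`; default the
#'   quadrature of the total density over the grid (or the plain total
#'   for a single strategy).
#' @return an object of class `stage_model`.
#' @export
stage_model <- function(n, b, a, p, R = 1, grid = NULL, limitation = NULL) {
  n <- as.integer(n)
  if (n < 2L) stop("a stage model needs at least 2 stages")
  get <- function(coef, len, nm, v = NULL) {
    x <- if (is.function(coef)) coef(v) else coef
    x <- as.numeric(x)
    if (length(x) == 1L && len > 1L && nm == "R") x <- rep(x, len)
    if (length(x) != len) stop(nm, " must have length ", len)
    x
  }
  check <- function(v = NULL) {
    bb <- get(b, n, "b", v); aa <- get(a, n, "a", v)
    pp <- get(p, n - 1L, "p", v)
    RR <- if (is.function(R)) R(v) else R
    if (any(bb < 0) || any(aa < 0) || any(pp < 0))
      stop("rates b, a, p must be nonnegative")
    if (bb[1] != 0) stop("stage 1 (newborns) cannot reproduce: b[1] must be 0")
    if (RR <= 0) stop("R must be positive")
    list(b = bb, a = aa, p = pp, R = RR)
  }
  if (is.null(grid)) check() else for (v in grid$nodes) check(v)
  structure(list(n = n, b = b, a = a, p = p, R = R, grid = grid,
                 limitation = limitation),
            class = "stage_model")
}

stage_coefs <- function(model, v = NULL) {
  g <- function(coef, len) {
    x <- if (is.function(coef)) coef(v) else coef
    as.numeric(x)
  }
  list(b = g(model$b), a = g(model$a), p = g(model$p),
       R = if (is.function(model$R)) model$R(v) else model$R)
}

#' Build the stage matrix L(v)
#'
#' Entries: `L[1,1] = -p1 - a1`, first row `L[1,i] = b_i` for
#' `i >= 2`, subdiagonal `L[i,i-1] = p_{i-1}`, diagonal
#' `L[i,i] = -p_i - a_i` with the convention `p_n = 0`; all other
#' entries zero.  The result is a Metzler matrix (nonnegative off the
#' diagonal), so its dominant eigenvalue is real with a nonnegative
#' eigenvector whenever the matrix is irreducible.
#'
#' @param model a [stage_model()].
#' @param v strategy point (needed when coefficients are functions).
#' @return an `n x n` numeric matrix.
#' @examples
#' m <- stage_model(2, b = c(0, 2), a = c(0.1, 0.2), p = 1)
#' build_stage_matrix(m)   # [[-1.1, 2], [1, -0.2]]
#' @export
build_stage_matrix <- function(model, v = NULL) {
  stopifnot(inherits(model, "stage_model"))
  cf <- stage_coefs(model, v)
  n <- model$n
  L <- matrix(0, n, n)
  p_full <- c(cf$p, 0)  # p_n = 0
  L[1, 1] <- -p_full[1] - cf$a[1]
  if (n >= 2) L[1, 2:n] <- cf$b[2:n]
  for (i in 2:n) {
    L[i, i - 1] <- cf$p[i - 1]
    L[i, i] <- -p_full[i] - cf$a[i]
  }
  L
}

#' Dominant eigenvalue and Perron vector of a stage matrix
#'
#' Eigenvalues sorted by descending real part.  The dominant eigenvector
#' is rescaled to unit component sum, the convention under which the
#' equilibrium of the frequency dynamics is the eigenvector itself and
#' the asymptotic per-capita growth rate equals the eigenvalue.  For
#' other (possibly complex) eigenvectors unit component sum can be
#' meaningless; those are normalised by their maximum-modulus component.
#'
#' @param M square numeric matrix (a stage matrix, or any matrix).
#' @return an object of class `spectral_result`: list with
#'   `values` (sorted eigenvalues), `lambda1` (largest real part, as a
#'   real number when the dominant eigenvalue is real),
#'   `vector1` (dominant eigenvector, unit component sum),
#'   `dominant_complex` and `dominant_repeated` flags.
#' @export
dominant_eigenvalue <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("matrix must be square")
  e <- eigen(M)
  ord <- order(-Re(e$values), -abs(Im(e$values)))
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  lam1 <- vals[1]
  complex_dom <- abs(Im(lam1)) > 1e-10 * max(1, abs(lam1))
  repeated <- length(vals) > 1 &&
    abs(vals[1] - vals[2]) < 1e-10 * max(1, abs(vals[1]))
  if (complex_dom)
    warning("dominant eigenvalue is complex; asymptotics are oscillatory")
  if (repeated)
    warning("dominant eigenvalue is (numerically) repeated")
  v1 <- vecs[, 1]
  s <- sum(v1)
  v1 <- if (abs(s) > 1e-12 * max(abs(v1))) v1 / s
  else v1 / v1[which.max(abs(v1))]
  if (max(abs(Im(v1))) < 1e-10) v1 <- Re(v1)
  structure(list(values = vals,
                 lambda1 = if (complex_dom) lam1 else Re(lam1),
                 vector1 = v1,
                 dominant_complex = complex_dom,
                 dominant_repeated = repeated),
            class = "spectral_result")
}

#' Analytic fitness landscape of a stage model
#'
#' \eqn{J(v) = \lambda_1(v) / R(v)}: the dominant eigenvalue of the
#' stage matrix scaled by the limitation sensitivity.  Does not depend on
#' initial conditions.  Models whose dominant eigenvalue is complex
#' (outside the realness assumption of the underlying theory) use the
#' real part and are flagged.
#'
#' @param model a [stage_model()] with a grid (or without, for a single
#'   strategy).
#' @return for a gridded model, an object of class `analytic_landscape`:
#'   data.frame with columns `v`, `lambda1`, `R`, `J` and attribute
#'   `argmax`; for a single strategy, the scalar `J`.
#' @export
stage_fitness <- function(model) {
  stopifnot(inherits(model, "stage_model"))
  one <- function(v) {
    sr <- suppressWarnings(dominant_eigenvalue(build_stage_matrix(model, v)))
    cf <- stage_coefs(model, v)
    c(lambda1 = Re(sr$lambda1[1]), R = cf$R,
      complex = as.numeric(sr$dominant_complex))
  }
  if (is.null(model$grid)) {
    x <- one(NULL)
    return(unname(x["lambda1"] / x["R"]))
  }
  rows <- t(vapply(model$grid$nodes, one, numeric(3)))
  out <- data.frame(v = model$grid$nodes, lambda1 = rows[, "lambda1"],
                    R = rows[, "R"], J = rows[, "lambda1"] / rows[, "R"],
                    complex_dominant = rows[, "complex"] > 0)
  attr(out, "argmax") <- out$v[out$J >= max(out$J) - 1e-12]
  class(out) <- c("analytic_landscape", "data.frame")
  out
}

#' Simulate the nonlinear stage-structured system
#'
#' Integrates \eqn{z' = L(v) z - R(v) y(t) z} per strategy node, where
#' the limitation factor \eqn{y(t)} couples all nodes (by default the
#' quadrature over strategies of the total per-node density).  Strong
#' inheritance holds exactly: a node starting at zero stays at zero.
#'
#' @param model a [stage_model()].
#' @param z0 initial stage densities: for a gridded model an
#'   `n_nodes x n` matrix (or a length-`n` vector recycled over nodes,
#'   or `function(v)`); for a single strategy a length-`n` vector.
#' @param horizon final time.
#' @param times optional output times.
#' @param rtol,atol solver tolerances.
#' @param bound abort when the limitation factor exceeds this value
#'   (blow-up detection).
#' @return an object of class `stage_trajectory`: list with `times`,
#'   `z` (array nodes x stages x times), `total` ([density_field()] of
#'   \eqn{Z = \sum_i z_i}), `eta` ([density_field()] of
#'   \eqn{Z^{1/R(v)}}), `y` (limitation trace) and the model.
#' @export
simulate_stage_system <- function(model, z0, horizon, times = NULL,
                                  rtol = 1e-8, atol = 1e-12,
                                  bound = 1e8) {
  stopifnot(inherits(model, "stage_model"))
  if (is.null(times)) times <- seq(0, horizon, length.out = 201)
  single <- is.null(model$grid)
  nodes <- if (single) NA_real_ else model$grid$nodes
  nn <- length(nodes)
  n <- model$n
  Ls <- lapply(seq_len(nn), function(i)
    build_stage_matrix(model, if (single) NULL else nodes[i]))
  Rs <- vapply(seq_len(nn), function(i)
    stage_coefs(model, if (single) NULL else nodes[i])$R, numeric(1))
  w <- if (single) 1 else model$grid$weights
  lim <- model$limitation
  if (is.null(lim)) lim <- function(z_total) sum(w * z_total)
  if (is.function(z0)) z0 <- t(vapply(nodes, z0, numeric(n)))
  z0 <- if (is.matrix(z0)) z0 else matrix(z0, nn, n, byrow = TRUE)
  if (any(z0 < 0)) stop("initial stage densities must be nonnegative")
  rhs <- function(t, y, p) {
    z <- matrix(y, nn, n)
    ztot <- rowSums(z)
    yfac <- lim(ztot)
    if (!is.finite(yfac) || yfac > bound)
      stop("limitation factor exceeded the bound: density blow-up at t = ", t)
    dz <- vapply(seq_len(nn), function(i)
      as.numeric(Ls[[i]] %*% z[i, ]) - Rs[i] * yfac * z[i, ],
      numeric(n))
    list(as.vector(t(dz)))
  }
  sol <- deSolve::ode(y = as.vector(z0), times = times, func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) stop("stage-system solver failed")
  nt <- length(times)
  zarr <- array(t(unname(as.matrix(as.data.frame(sol)[, -1]))),
                dim = c(nn, n, nt))
  zarr[zarr < 0 & zarr > -1e-12] <- 0
  Z <- apply(zarr, c(1, 3), sum)
  ytrace <- vapply(seq_len(nt), function(j) lim(Z[, j]), numeric(1))
  total <- if (single) NULL else density_field(model$grid, times, Z)
  eta <- if (single) NULL else transform_density(total, function(v)
    stage_coefs(model, v)$R)
  structure(list(times = times, z = zarr, total = total, eta = eta,
                 y = data.frame(t = times, y = ytrace),
                 Z = Z, model = model),
            class = "stage_trajectory")
}

#' Simulate the frequency dynamics of a stage matrix
#'
#' Nonlinear frequency system \eqn{\xi' = L\xi - \xi F(t)} with
#' \eqn{F(t) = \sum_{ij} q_{ij}\xi_j} (the component sum of
#' \eqn{L\xi} when \eqn{\sum_i \xi_i = 1}, which keeps the simplex
#' invariant exactly).
#'
#' @param L square stage matrix.
#' @param xi0 initial frequencies (positive, summing to 1; renormalised).
#' @param horizon final time.
#' @param times optional output times.
#' @param rtol,atol solver tolerances.
#' @return data.frame with `t`, frequency columns `xi1..xin` and `F`.
#' @export
simulate_frequencies <- function(L, xi0, horizon, times = NULL,
                                 rtol = 1e-10, atol = 1e-12) {
  L <- as.matrix(L)
  n <- nrow(L)
  xi0 <- as.numeric(xi0) / sum(xi0)
  if (is.null(times)) times <- seq(0, horizon, length.out = 201)
  colsum <- colSums(L)
  rhs <- function(t, xi, p) {
    Fv <- sum(colsum * xi)
    list(as.numeric(L %*% xi) - xi * Fv)
  }
  sol <- deSolve::ode(y = xi0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  out <- as.data.frame(sol)
  names(out) <- c("t", paste0("xi", seq_len(n)))
  out$F <- as.numeric(as.matrix(out[, 1 + seq_len(n)]) %*% colsum)
  out
}

#' Check the frequency/linear-solution identity
#'
#' The nonlinear frequency system and the linear system
#' \eqn{\zeta' = L\zeta} started from matched initial data satisfy
#' \eqn{\xi_i(t) = \zeta_i(t) / \sum_j \zeta_j(t)} identically.  This
#' verifies that identity numerically and returns the maximal deviation
#' over the trajectory.
#'
#' @param L square stage matrix.
#' @param xi0 initial frequencies (positive vector; normalised).
#' @param horizon final time.
#' @param times optional output times.
#' @return maximal absolute deviation
#'   \eqn{\max_t \max_i |\xi_i - \zeta_i/\sum\zeta|}.
#' @export
frequency_solution_check <- function(L, xi0, horizon, times = NULL) {
  L <- as.matrix(L)
  n <- nrow(L)
  xi0 <- as.numeric(xi0) / sum(xi0)
  if (is.null(times)) times <- seq(0, horizon, length.out = 201)
  xi <- simulate_frequencies(L, xi0, horizon, times)
  lin_rhs <- function(t, z, p) list(as.numeric(L %*% z))
  zeta <- deSolve::ode(y = xi0, times = times, func = lin_rhs,
                       parms = NULL, method = "lsoda",
                       rtol = 1e-10, atol = 1e-14)
  zeta <- unname(as.matrix(as.data.frame(zeta)[, -1]))
  S <- rowSums(zeta)
  if (any(abs(S) < 1e-300))
    stop("component sum of the linear solution crossed zero")
  dev <- abs(as.matrix(xi[, 1 + seq_len(n)]) - zeta / S)
  max(dev)
}

#' Long-term average of the generalised reproduction coefficient F
#'
#' Averages \eqn{F(t) = \sum_{ij} q_{ij}\xi_j(t)} over a trailing
#' window of a frequency trajectory.  As the window end grows this
#' converges to the dominant eigenvalue \eqn{\lambda_1} of the stage
#' matrix.
#'
#' @param traj a data.frame from [simulate_frequencies()] (with columns
#'   `t` and `F`).
#' @param window numeric `c(T0, T)`; default the second half of the
#'   trajectory.
#' @return the window average of `F` (time-weighted trapezoid).
#' @export
long_term_F <- function(traj, window = NULL) {
  stopifnot(is.data.frame(traj), all(c("t", "F") %in% names(traj)))
  tt <- traj$t
  if (is.null(window)) window <- c(tt[1] + (max(tt) - tt[1]) / 2, max(tt))
  sel <- tt >= window[1] - 1e-12 & tt <= window[2] + 1e-12
  if (sum(sel) < 2) stop("window contains fewer than two stored times")
  t_s <- tt[sel]; F_s <- traj$F[sel]
  sum(diff(t_s) * (F_s[-length(F_s)] + F_s[-1]) / 2) / (max(t_s) - min(t_s))
}
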