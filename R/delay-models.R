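#' Generic delay model for self-replicating systems
#'
#' A system of `n` variables \eqn{z_l(v, t)} per strategy, with `m`
#' discrete delays:
#' \deqn{z_l' = \sum_{j,i} q_{lji}(v)\, z_j(t - \tau_i)\,
#'   e^{-R(v)\int_{t-\tau_i}^{t} f\,dt}
#'   + \sum_j r_{lj}(v)\, z_j(t) - R(v)\, z_l\, f(z, t).}
#' The delayed replenishment terms carry a survival factor over the
#' limitation experienced since the delayed time.  The analytic fitness
#' is \eqn{J(v) = \max_i \Re\lambda_i(v) / R(v)} with \eqn{\lambda_i}
#' the roots of the transcendental characteristic equation
#' \eqn{\det(H(\lambda) - \lambda E) = 0},
#' \eqn{h_{lj}(\lambda) = \sum_i q_{lji} e^{-\lambda\tau_i} + r_{lj}}.
#'
#' @param n number of variables (at least 1).
#' @param tau positive delays (length `m`; may be empty for a pure ODE).
#' @param q coefficient tensor: numeric array `n x n x m` (or a matrix
#'   for `m = 1`, or scalar for `n = m = 1`), or `function(v)` returning
#'   such an array.
#' @param r instantaneous coefficient matrix `n x n` (scalar allowed for
#'   `n = 1`), or `function(v)`.
#' @param R positive limitation sensitivity: scalar or `function(v)`.
#' @param grid optional [strategy_grid()] for models over a strategy
#'   space.
#' @param f limitation functional `function(z_total)` mapping per-node
#'   total densities to the scalar limitation, or `NULL` for the linear
#'   (unlimited) model.  See [total_density_limitation()].
#' @param history initial history on `[-max(tau), 0]`: a length-`n`
#'   constant vector, an `n_nodes x n` matrix, or
#'   `function(t, v)` returning a length-`n` vector.  Default constant 1.
#' @return an object of class `delay_model`.
#' @export
delay_model <- function(n, tau, q, r, R = 1, grid = NULL, f = NULL,
                        history = 1) {
  n <- as.integer(n)
  if (n < 1L) stop("delay model needs at least one variable")
  tau <- as.numeric(tau)
  m <- length(tau)
  if (any(tau <= 0)) stop("all delays tau must be positive")
  shape_q <- function(x) {
    x <- if (is.array(x) && length(dim(x)) == 3L) x
    else array(as.numeric(x), dim = c(n, n, m))
    if (!all(dim(x) == c(n, n, m))) stop("q must be an n x n x m array")
    x
  }
  shape_r <- function(x) {
    x <- as.matrix(x)
    if (length(x) == 1L && n == 1L) x <- matrix(as.numeric(x), 1, 1)
    if (!all(dim(x) == c(n, n))) stop("r must be an n x n matrix")
    x
  }
  if (!is.function(q)) q <- local({ qa <- shape_q(q); function(v) qa })
  else { qa_check <- shape_q(q(if (is.null(grid)) NULL else grid$nodes[1])) }
  if (!is.function(r)) r <- local({ ra <- shape_r(r); function(v) ra })
  Rfun <- if (is.function(R)) R else local({ R0 <- as.numeric(R)
    function(v) R0 })
  if (Rfun(if (is.null(grid)) NULL else grid$nodes[1]) <= 0)
    stop("R must be positive")
  hist_fun <- if (is.function(history)) history
  else local({
    h0 <- as.numeric(history)
    if (length(h0) == 1L) h0 <- rep(h0, n)
    if (length(h0) != n) stop("constant history must have length n")
    function(t, v) h0
  })
  structure(list(n = n, m = m, tau = tau, q = q, r = r, R = Rfun,
                 grid = grid, f = f, history = hist_fun,
                 shape_q = shape_q, shape_r = shape_r),
            class = "delay_model")
}

#' Quadrature-of-total-density limitation functional
#'
#' The default density-dependent limitation: the quadrature over the
#' strategy grid of the per-node total density (or the plain total for a
#' single strategy).
#'
#' @param grid a [strategy_grid()], or `NULL` for a single strategy.
#' @return a `function(z_total)` suitable for [delay_model()]'s `f`.
#' @export
total_density_limitation <- function(grid = NULL) {
  w <- if (is.null(grid)) 1 else grid$weights
  function(z_total) sum(w * z_total)
}

#' Characteristic matrix of a delay model
#'
#' \eqn{H(\lambda)_{lj} = \sum_i q_{lji} e^{-\lambda\tau_i} + r_{lj}};
#' entire in \eqn{\lambda}, constant when `m = 0`.
#'
#' @param model a [delay_model()].
#' @param lambda complex (or real) eigenvalue candidate.
#' @param v strategy point (for gridded models).
#' @return `n x n` complex matrix.
#' @export
char_matrix <- function(model, lambda, v = NULL) {
  stopifnot(inherits(model, "delay_model"))
  qa <- model$shape_q(model$q(v))
  H <- model$shape_r(model$r(v)) * (1 + 0i)
  if (model$m > 0)
    for (i in seq_len(model$m))
      H <- H + qa[, , i] * exp(-lambda * model$tau[i])
  H
}

# Complex determinant by Gaussian elimination with partial pivoting.
cdet <- function(M) {
  n <- nrow(M)
  det <- 1 + 0i
  for (k in seq_len(n)) {
    p <- which.max(Mod(M[k:n, k])) + k - 1L
    if (Mod(M[p, k]) == 0) return(0 + 0i)
    if (p != k) { M[c(k, p), ] <- M[c(p, k), ]; det <- -det }
    det <- det * M[k, k]
    if (k < n) {
      rows <- (k + 1):n
      M[rows, ] <- M[rows, ] - outer(M[rows, k] / M[k, k], M[k, ])
    }
  }
  det
}

# det(H(lambda) - lambda I) and, optionally, the Newton step
# -det/det' using Jacobi's formula det'/det = tr(M^{-1} M').
char_det <- function(model, lambda, v = NULL) {
  H <- char_matrix(model, lambda, v)
  cdet(H - diag(lambda, model$n))
}

char_newton_step <- function(model, lambda, v = NULL) {
  qa <- model$shape_q(model$q(v))
  H <- char_matrix(model, lambda, v)
  M <- H - diag(lambda, model$n)
  dH <- diag(-1 + 0i, model$n)
  if (model$m > 0)
    for (i in seq_len(model$m))
      dH <- dH - model$tau[i] * qa[, , i] * exp(-lambda * model$tau[i])
  tr <- sum(diag(solve(M, dH)))
  -1 / tr          # Newton increment for det(M(lambda)) = 0
}

# Upper bound on the real part of any characteristic root:
# if Re(lambda) >= 0 then |lambda| <= max row sum of |q| + |r|.
root_upper_bound <- function(model, v = NULL) {
  qa <- model$shape_q(model$q(v))
  ra <- model$shape_r(model$r(v))
  qsum <- if (model$m > 0) apply(abs(qa), 1, sum) else rep(0, model$n)
  max(qsum + rowSums(abs(ra)))
}

#' Roots of the characteristic equation with largest real parts
#'
#' Enumerates the roots of \eqn{\det(H(\lambda) - \lambda E) = 0} with
#' real part above a floor.  Real roots are bracketed by a sign scan of
#' the (real-valued on the real axis) determinant and refined by Newton
#' iteration; complex roots are located by argument-principle counting
#' on rectangles in the upper half plane (conjugates are added by
#' symmetry) with Newton polishing from grid seeds.  A mismatch between
#' the argument-principle count and the roots actually found raises an
#' error rather than returning a silently wrong answer.  For `m = 0` the
#' equation is an ordinary eigenproblem and is solved directly.
#'
#' @param model a [delay_model()].
#' @param v strategy point (for gridded models).
#' @param floor report roots with real part above this value; default
#'   the upper bound minus 10.
#' @param resid_tol residual contract: every reported root must satisfy
#'   \eqn{|\det(H(\lambda) - \lambda E)| <} `resid_tol`.
#' @return an object of class `root_set`: data.frame with columns `re`,
#'   `im`, `residual`, sorted by descending real part; the first row is
#'   the rightmost root (attribute `rightmost`, complex scalar).
#' @examples
#' m <- delay_model(1, tau = 1, q = 1, r = 0)
#' rightmost_root(m)   # the omega constant 0.567143...
#' @export
rightmost_root <- function(model, v = NULL, floor = NULL,
                           resid_tol = 1e-10) {
  stopifnot(inherits(model, "delay_model"))
  B <- root_upper_bound(model, v)
  if (is.null(floor)) floor <- B - 10
  if (model$m == 0L) {
    ev <- eigen(model$shape_r(model$r(v)), only.values = TRUE)$values
    ev <- ev[Re(ev) >= floor]
    ev <- ev[order(-Re(ev), -abs(Im(ev)))]
    resid <- vapply(ev, function(l) Mod(char_det(model, l, v)), numeric(1))
    out <- data.frame(re = Re(ev), im = Im(ev), residual = resid)
    attr(out, "rightmost") <- ev[1]
    class(out) <- c("root_set", "data.frame")
    return(out)
  }
  roots <- complex(0)
  # --- real-axis scan ---------------------------------------------------
  xs <- seq(floor, B + 0.5, length.out = 4001L)
  fx <- vapply(xs, function(x) Re(char_det(model, x + 0i, v)), numeric(1))
  sgn <- sign(fx)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in idx) {
    root <- tryCatch(stats::uniroot(function(x)
      Re(char_det(model, x + 0i, v)), c(xs[i], xs[i + 1]),
      tol = 1e-13)$root, error = function(e) NULL)
    if (!is.null(root)) roots <- c(roots, polish_root(model, root + 0i, v))
  }
  # near-real pairs and touching zeros: polish from local minima of |det|
  af <- abs(fx)
  loc_min <- which(af[-c(1, length(af))] < af[-(1:2)] &
                   af[-c(1, length(af))] < af[-c(length(af) - 1, length(af))]) + 1L
  loc_min <- loc_min[af[loc_min] < 1e-4 * max(1, stats::median(af))]
  for (i in loc_min) {
    r <- polish_root(model, xs[i] + 1e-3i, v)
    if (Mod(char_det(model, r, v)) < 1e-10)
      roots <- c(roots, r, Conj(r))
  }
  # --- complex roots via argument principle -----------------------------
  # Complex enumeration covers real parts within 0.5 of the rightmost
  # real root (or down to the floor when no real root exists); this is
  # always enough to certify the rightmost root overall.
  bestreal <- if (length(roots)) max(Re(roots)) else -Inf
  x_lo <- if (is.finite(bestreal)) max(floor, bestreal - 0.5) else floor
  qa <- model$shape_q(model$q(v))
  ra <- model$shape_r(model$r(v))
  qrow <- apply(abs(qa), 1, function(x)
    sum(x * rep(exp(-x_lo * model$tau), each = model$n)))
  ymax <- min(max(qrow + rowSums(abs(ra))) + 1, 1e3)
  cplx <- rectangle_roots(model, v, x_lo, B + 0.5, 0.05, ymax)
  roots <- c(roots, cplx, Conj(cplx))
  roots <- dedupe_roots(roots)
  roots <- roots[Re(roots) >= floor - 1e-9]
  if (length(roots) == 0L)
    stop("no characteristic root found above the floor ", floor)
  resid <- vapply(roots, function(l) Mod(char_det(model, l, v)), numeric(1))
  keep <- resid < resid_tol
  if (!all(keep))
    warning(sum(!keep), " candidate root(s) failed the residual contract ",
            "and were dropped")
  roots <- roots[keep]; resid <- resid[keep]
  ord <- order(-Re(roots), -abs(Im(roots)))
  roots <- roots[ord]; resid <- resid[ord]
  out <- data.frame(re = Re(roots), im = Im(roots), residual = resid)
  attr(out, "rightmost") <- roots[1]
  class(out) <- c("root_set", "data.frame")
  out
}

polish_root <- function(model, lambda, v, maxit = 60L) {
  for (k in seq_len(maxit)) {
    step <- tryCatch(char_newton_step(model, lambda, v),
                     error = function(e) NA_complex_)
    if (!is.finite(Re(step))) break
    lambda <- lambda + step
    if (Mod(step) < 1e-14 * max(1, Mod(lambda))) break
  }
  if (abs(Im(lambda)) < 1e-10) lambda <- Re(lambda) + 0i
  lambda
}

dedupe_roots <- function(roots, tol = 1e-7) {
  if (length(roots) <= 1L) return(roots)
  out <- roots[1]
  for (r in roots[-1])
    if (all(Mod(out - r) > tol)) out <- c(out, r)
  out
}

# Argument-principle root count on the boundary of a rectangle in the
# upper half plane, with Newton polishing from interior seeds; recursive
# bisection until each box holds at most one root.
rectangle_roots <- function(model, v, x0, x1, y0, y1, depth = 0L) {
  count <- winding_count(model, v, x0, x1, y0, y1)
  if (is.na(count)) {       # contour too close to a root: nudge the box
    return(rectangle_roots(model, v, x0 - 1e-4, x1 + 1e-4,
                           y0 * 0.97, y1 + 1e-3, depth))
  }
  if (count == 0L) return(complex(0))
  if (count == 1L || depth >= 8L) {
    gx <- x0 + (x1 - x0) * c(0.5, 0.25, 0.75, 0.1, 0.9)
    gy <- y0 + (y1 - y0) * c(0.5, 0.2, 0.8, 0.35, 0.65)
    seeds <- as.vector(outer(gx, gy, function(a, b)
      complex(real = a, imaginary = b)))
    found <- complex(0)
    for (s in seeds) {
      r <- polish_root(model, s, v)
      if (Re(r) >= x0 - 1e-8 && Re(r) <= x1 + 1e-8 &&
          Im(r) >= y0 - 1e-8 && Im(r) <= y1 + 1e-8 &&
          Mod(char_det(model, r, v)) < 1e-10)
        found <- c(found, r)
      if (length(dedupe_roots(found)) >= count) break
    }
    found <- dedupe_roots(found)
    if (length(found) < count)
      stop("argument principle counts ", count, " root(s) in [",
           signif(x0, 4), ",", signif(x1, 4), "]x[", signif(y0, 4), ",",
           signif(y1, 4), "]i but only ", length(found),
           " could be located")
    return(found)
  }
  xm <- (x0 + x1) / 2
  c(rectangle_roots(model, v, x0, xm, y0, y1, depth + 1L),
    rectangle_roots(model, v, xm, x1, y0, y1, depth + 1L))
}

# Winding number of det(H(lambda) - lambda I) along the rectangle
# boundary, by phase tracking with adaptive refinement.  NA when the
# phase step cannot be resolved (likely a root on the contour).
winding_count <- function(model, v, x0, x1, y0, y1) {
  corners <- c(complex(real = x0, imaginary = y0),
               complex(real = x1, imaginary = y0),
               complex(real = x1, imaginary = y1),
               complex(real = x0, imaginary = y1),
               complex(real = x0, imaginary = y0))
  total <- 0
  for (s in 1:4) {
    d <- phase_change(model, v, corners[s], corners[s + 1])
    if (is.na(d)) return(NA_integer_)
    total <- total + d
  }
  round(total / (2 * pi))
}

phase_change <- function(model, v, za, zb, depth = 0L) {
  fa <- char_det(model, za, v); fb <- char_det(model, zb, v)
  if (Mod(fa) < 1e-300 || Mod(fb) < 1e-300) return(NA_real_)
  d <- Arg(fb / fa)
  if (abs(d) < pi / 2 && depth > 2L) return(d)
  if (depth >= 24L) return(NA_real_)
  zm <- (za + zb) / 2
  d1 <- phase_change(model, v, za, zm, depth + 1L)
  if (is.na(d1)) return(NA_real_)
  d2 <- phase_change(model, v, zm, zb, depth + 1L)
  if (is.na(d2)) return(NA_real_)
  d1 + d2
}

#' Validate a characteristic root by substitution
#'
#' A root \eqn{\lambda} of the characteristic equation admits a
#' nontrivial vector \eqn{e} with \eqn{(H(\lambda) - \lambda E)e = 0};
#' the exponential solution \eqn{e\,e^{\lambda t}} then satisfies the
#' linear delay system identically.  This computes the best such vector
#' (the singular vector of the smallest singular value, normalised to
#' unit length) and the residual \eqn{\|(H(\lambda) - \lambda E)e\|},
#' which bounds the defect of the seeded exponential solution at
#' \eqn{t = 0}.
#'
#' @param model a [delay_model()].
#' @param lambda the root to validate (complex or real).
#' @param v strategy point (for gridded models).
#' @return list with `e` (unit eigenvector) and `residual`.
#' @export
validate_root <- function(model, lambda, v = NULL) {
  M <- char_matrix(model, lambda, v) - diag(lambda, model$n)
  if (model$n == 1L) {
    return(list(e = 1 + 0i, residual = Mod(M[1, 1])))
  }
  sv <- svd(M)
  e <- sv$v[, model$n]
  list(e = e, residual = sqrt(sum(Mod(M %*% e)^2)))
}

#' Analytic fitness landscape of a delay model
#'
#' \eqn{J(v) = \max_i \Re\lambda_i(v) / R(v)}: the rightmost
#' characteristic root scaled by the limitation sensitivity.  Consumes
#' no initial data — the landscape is independent of initial conditions.
#' A root-finder failure at a node leaves that node `NA` (with a
#' warning) and the run continues.
#'
#' @param model a [delay_model()] with a grid (or without, for a single
#'   strategy).
#' @return for gridded models an `analytic_landscape` data.frame with
#'   columns `v`, `lambda1`, `R`, `J` and attribute `argmax`; otherwise
#'   the scalar `J`.
#' @export
delay_fitness <- function(model) {
  stopifnot(inherits(model, "delay_model"))
  one <- function(v) {
    rs <- tryCatch(rightmost_root(model, v), error = function(e) {
      warning("root finding failed at v = ", v, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(rs)) return(c(lambda1 = NA_real_, R = model$R(v)))
    c(lambda1 = Re(attr(rs, "rightmost")), R = model$R(v))
  }
  if (is.null(model$grid)) {
    x <- one(NULL)
    return(unname(x["lambda1"] / x["R"]))
  }
  rows <- t(vapply(model$grid$nodes, one, numeric(2)))
  out <- data.frame(v = model$grid$nodes, lambda1 = rows[, "lambda1"],
                    R = rows[, "R"], J = rows[, "lambda1"] / rows[, "R"])
  ok <- !is.na(out$J)
  attr(out, "argmax") <- out$v[ok & out$J >= max(out$J[ok]) - 1e-12]
  class(out) <- c("analytic_landscape", "data.frame")
  out
}

#' Simulate a delay model
#'
#' Integrates the delay system with deSolve's delay machinery (stored
#' dense history; effectively the method of steps with adaptive
#' stepping).  The running integral \eqn{\Phi(t) = \int_0^t f\,dt} is
#' carried as an auxiliary state so the delayed survival factor uses
#' stored values \eqn{\Phi(t) - \Phi(t - \tau_i)}; \eqn{\Phi} is
#' extended by 0 backwards of \eqn{t = 0}.
#'
#' @param model a [delay_model()].
#' @param horizon final time.
#' @param times optional output times.
#' @param rtol,atol solver tolerances.
#' @return an object of class `delay_trajectory`: list with `times`,
#'   `z` (array nodes x variables x times), `total` and `eta`
#'   ([density_field()]s over the grid, `NULL` for a single strategy),
#'   `Z` (matrix nodes x times of totals), `Phi` (data.frame `t`,
#'   `Phi`) and the model.
#' @export
simulate_dde <- function(model, horizon, times = NULL,
                         rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(model, "delay_model"))
  if (is.null(times)) times <- seq(0, horizon, length.out = 201)
  single <- is.null(model$grid)
  nodes <- if (single) list(NULL) else as.list(model$grid$nodes)
  nn <- length(nodes)
  n <- model$n
  qs <- lapply(nodes, function(v) model$shape_q(model$q(v)))
  rs <- lapply(nodes, function(v) model$shape_r(model$r(v)))
  Rv <- vapply(nodes, function(v) model$R(v), numeric(1))
  f <- model$f
  hist0 <- function(t) {                       # nn x n
    h <- vapply(nodes, function(v) model$history(t, v), numeric(n))
    t(matrix(h, nrow = n))
  }
  z0 <- hist0(0)
  if (any(z0 < 0)) stop("history must be nonnegative at t = 0")
  y0 <- c(as.vector(z0), 0)                    # state: z's then Phi
  nz <- nn * n
  t0 <- times[1]
  derivs <- function(t, y, p) {
    z <- matrix(y[seq_len(nz)], nn, n)
    ztot <- rowSums(z)
    fnow <- if (is.null(f)) 0 else f(ztot)
    Phi <- y[nz + 1]
    dz <- matrix(0, nn, n)
    for (d in seq_len(model$m)) {
      tl <- t - model$tau[d]
      if (tl <= t0 + 1e-14) {
        zl <- hist0(tl)
        Phil <- 0
      } else {
        lag <- deSolve::lagvalue(tl)
        zl <- matrix(lag[seq_len(nz)], nn, n)
        Phil <- lag[nz + 1]
      }
      surv <- exp(-Rv * (Phi - Phil))          # per node
      for (i in seq_len(nn))
        dz[i, ] <- dz[i, ] + as.numeric(qs[[i]][, , d] %*% zl[i, ]) * surv[i]
    }
    for (i in seq_len(nn))
      dz[i, ] <- dz[i, ] + as.numeric(rs[[i]] %*% z[i, ]) -
        Rv[i] * fnow * z[i, ]
    list(c(as.vector(dz), fnow))
  }
  sol <- if (model$m > 0)
    deSolve::dede(y = y0, times = times, func = derivs, parms = NULL,
                  rtol = rtol, atol = atol,
                  control = list(mxhist = 1e5))
  else
    deSolve::ode(y = y0, times = times, func = derivs, parms = NULL,
                 method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) stop("delay solver failed")
  m <- t(unname(as.matrix(as.data.frame(sol)[, -1])))
  nt <- length(times)
  zarr <- array(m[seq_len(nz), , drop = FALSE], dim = c(nn, n, nt))
  Phit <- m[nz + 1, ]
  Z <- apply(zarr, c(1, 3), sum)
  Z <- matrix(Z, nn, nt)
  total <- eta <- NULL
  if (!single) {
    total <- density_field(model$grid, times, pmax(Z, 0))
    eta <- transform_density(total, function(v) model$R(v))
  }
  structure(list(times = times, z = zarr, total = total, eta = eta,
                 Z = Z, Phi = data.frame(t = times, Phi = Phit),
                 model = model),
            class = "delay_trajectory")
}

#' Verify the exponential change of variables for delay models
#'
#' The substitution \eqn{\zeta(t) = z(t)\, e^{R\int_0^t f\,dt}}
#' transforms the limited (nonlinear) delay system into the linear
#' system \eqn{\zeta' = \sum q\,\zeta(t - \tau) + r\,\zeta}.  This
#' simulates both from the same history and returns the maximal
#' relative deviation between \eqn{z\,e^{R\Phi}} and \eqn{\zeta}
#' (computed in log space when the exponential factor is large).
#'
#' @param model a [delay_model()] with a non-`NULL` limitation `f`.
#' @param horizon final time.
#' @param times optional output times.
#' @return maximal relative deviation over times, variables and nodes.
#' @export
change_of_variables_check <- function(model, horizon, times = NULL) {
  stopifnot(inherits(model, "delay_model"))
  if (is.null(model$f)) stop("model has no limitation functional f")
  nl <- simulate_dde(model, horizon, times)
  lin_model <- model
  lin_model$f <- NULL
  lin <- simulate_dde(lin_model, horizon, times)
  Rv <- vapply(if (is.null(model$grid)) list(NULL)
               else as.list(model$grid$nodes),
               function(v) model$R(v), numeric(1))
  nt <- length(nl$times)
  dev <- 0
  for (j in seq_len(nt)) {
    fac <- Rv * nl$Phi$Phi[j]
    zexp_log <- log(pmax(nl$z[, , j, drop = FALSE], 1e-300)) +
      array(fac, dim = dim(nl$z[, , j, drop = FALSE]))
    zeta <- lin$z[, , j, drop = FALSE]
    rel <- abs(exp(zexp_log - log(pmax(abs(zeta), 1e-300))) - 1)
    rel[zeta == 0 & nl$z[, , j, drop = FALSE] == 0] <- 0
    dev <- max(dev, rel)
  }
  dev
}

#' Reduce a von Foerster age-structured population to a delay model
#'
#' An age-structured population with piecewise-constant mortality
#' `a_i` and fecundity `b_i` on age classes delimited by thresholds
#' `tau_1 < ... < tau_{n-1}` (stage 1 = pre-reproductive ages below
#' `tau_1`, the minimum reproductive age) reduces, by integrating the
#' transport equation along characteristics, to a delay system for the
#' stage totals \eqn{S_i(t)} with delays equal to the age thresholds.
#' Stage `l`'s inflow of maturing individuals is delayed by
#' `tau_{l-1}` and discounted by the cumulative survival
#' \eqn{\exp(-\sum_{k<l} a_k(\tau_k - \tau_{k-1}))}; its outflow is
#' delayed by `tau_l` with survival through stage `l` (the last stage
#' has no outflow).  Stage 1's inflow (newborns) is undelayed and is
#' carried by the instantaneous matrix `r` (first row `b_j`), whose
#' diagonal holds `-a_l`.
#'
#' @param tau increasing positive age thresholds, length `n - 1`.
#' @param a natural mortality per stage, length `n` (or `function(v)`).
#' @param b fecundity per stage, length `n` with `b[1] = 0` (or
#'   `function(v)`).
#' @param R positive limitation sensitivity (scalar or `function(v)`).
#' @param grid optional [strategy_grid()].
#' @param f limitation functional (see [delay_model()]).
#' @param history history for the resulting delay model.
#' @return a [delay_model()] with `m = n - 1` delays.
#' @examples
#' dm <- foerster_to_delay(tau = 1, a = c(0.1, 0.2), b = c(0, 2))
#' dm$shape_q(dm$q(NULL))[2, 2, 1]   # 2 * exp(-0.1)
#' @export
foerster_to_delay <- function(tau, a, b, R = 1, grid = NULL, f = NULL,
                              history = 1) {
  tau <- as.numeric(tau)
  if (any(diff(tau) <= 0) || any(tau <= 0))
    stop("age thresholds tau must be positive and strictly increasing")
  n <- length(tau) + 1L
  build <- function(av, bv) {
    av <- as.numeric(av); bv <- as.numeric(bv)
    if (length(av) != n || length(bv) != n)
      stop("a and b must have length ", n)
    if (bv[1] != 0) stop("stage 1 is pre-reproductive: b[1] must be 0")
    dt <- diff(c(0, tau))
    surv <- exp(-cumsum(av[seq_len(n - 1)] * dt))  # surv[l] through stage l
    qa <- array(0, dim = c(n, n, n - 1L))
    for (l in 2:n)                       # maturation inflow, delay tau_{l-1}
      qa[l, , l - 1L] <- bv * surv[l - 1L]
    if (n >= 2) for (l in seq_len(n - 1L))  # outflow, delay tau_l
      qa[l, , l] <- -bv * surv[l]
    ra <- diag(-av, n)
    ra[1, ] <- ra[1, ] + bv              # undelayed newborn inflow
    list(q = qa, r = ra)
  }
  if (is.function(a) || is.function(b)) {
    qfun <- function(v) build(if (is.function(a)) a(v) else a,
                              if (is.function(b)) b(v) else b)$q
    rfun <- function(v) build(if (is.function(a)) a(v) else a,
                              if (is.function(b)) b(v) else b)$r
    delay_model(n, tau, qfun, rfun, R, grid, f, history)
  } else {
    qr <- build(a, b)
    delay_model(n, tau, qr$q, qr$r, R, grid, f, history)
  }
}
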