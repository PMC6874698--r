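#' Discretised strategy space
#'
#' A `strategy_grid` represents a compact one-dimensional strategy space
#' (by default the unit interval) by an ordered set of nodes together with
#' positive quadrature weights.  Measures of strategy sets are computed as
#' quadratures of a density over node masks, so the weights must sum to the
#' volume of the space.
#'
#' @param nodes strictly increasing numeric vector of strategy points
#'   (at least 3), or a single integer giving the number of uniformly
#'   spaced nodes on `interval`.
#' @param interval numeric length-2 vector, the strategy interval; only
#'   used when `nodes` is a count.
#' @param weights optional positive quadrature weights; by default
#'   trapezoidal weights on the supplied nodes.
#' @param metric distance function on strategy points; defaults to the
#'   absolute difference.
#' @return an object of class `strategy_grid` with components `nodes`,
#'   `weights` and `metric`.
#' @examples
#' g <- strategy_grid(101)
#' sum(g$weights)  # volume of [0,1]
#' @export
strategy_grid <- function(nodes = 101L, interval = c(0, 1), weights = NULL,
                          metric = function(x, y) abs(x - y)) {
  if (length(nodes) == 1L) {
    n <- as.integer(nodes)
    if (n < 3L) stop("a strategy grid needs at least 3 nodes")
    nodes <- seq(interval[1], interval[2], length.out = n)
  }
  nodes <- as.numeric(nodes)
  if (length(nodes) < 3L) stop("a strategy grid needs at least 3 nodes")
  if (any(diff(nodes) <= 0)) stop("grid nodes must be strictly increasing")
  if (is.null(weights)) weights <- trapezoid_weights(nodes)
  weights <- as.numeric(weights)
  if (length(weights) != length(nodes)) stop("one weight per node required")
  if (any(weights <= 0)) stop("quadrature weights must be positive")
  structure(list(nodes = nodes, weights = weights, metric = metric),
            class = "strategy_grid")
}

# Composite trapezoid weights; exact for piecewise-linear densities and
# additive over contiguous node masks.
trapezoid_weights <- function(nodes) {
  n <- length(nodes)
  h <- diff(nodes)
  w <- numeric(n)
  w[1] <- h[1] / 2
  w[n] <- h[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (h[-1] + h[-(n - 1)]) / 2
  w
}

#' @export
print.strategy_grid <- function(x, ...) {
  cat(sprintf("strategy_grid: %d nodes on [%g, %g], volume %g\n",
              length(x$nodes), min(x$nodes), max(x$nodes), sum(x$weights)))
  invisible(x)
}

#' Time-indexed density on a strategy grid
#'
#' A `density_field` stores a nonnegative measure density \eqn{\eta(v, t)}
#' sampled at the grid nodes and at an increasing set of time points.  The
#' measure of a strategy set at a given time is the quadrature of the
#' density over the set (see [measure_of_set()]).  An optional `bound`
#' declares the uniform bound on the total measure.
#'
#' @param grid a [strategy_grid()].
#' @param times increasing numeric vector of time points.
#' @param values numeric matrix, nodes in rows and times in columns,
#'   with nonnegative entries.
#' @param bound optional positive bound on the total measure at any time;
#'   validated against the stored values when supplied.
#' @return an object of class `density_field`.
#' @export
density_field <- function(grid, times, values, bound = NULL) {
  stopifnot(inherits(grid, "strategy_grid"))
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  values <- as.matrix(values)
  if (nrow(values) != length(grid$nodes) || ncol(values) != length(times))
    stop("values must be a nodes x times matrix")
  if (any(values < 0)) {
    if (min(values) > -1e-12) values[values < 0] <- 0
    else stop("density values must be nonnegative")
  }
  if (!is.null(bound)) {
    tot <- as.numeric(crossprod(grid$weights, values))
    if (any(tot > bound * (1 + 1e-9)))
      stop("total measure exceeds the declared bound")
  }
  structure(list(grid = grid, times = times, values = values, bound = bound),
            class = "density_field")
}

#' @export
print.density_field <- function(x, ...) {
  cat(sprintf("density_field: %d nodes x %d times, t in [%g, %g]\n",
              nrow(x$values), ncol(x$values), min(x$times), max(x$times)))
  invisible(x)
}

# Linear interpolation of the field columns at time t, clipped at zero.
field_at_time <- function(field, t) {
  tt <- field$times
  if (t < tt[1] - 1e-12 || t > tt[length(tt)] + 1e-12)
    stop("time ", t, " outside the field's time range")
  t <- min(max(t, tt[1]), tt[length(tt)])
  i <- findInterval(t, tt, all.inside = TRUE)
  t0 <- tt[i]; t1 <- tt[i + 1]
  a <- if (t1 > t0) (t - t0) / (t1 - t0) else 0
  eta <- (1 - a) * field$values[, i] + a * field$values[, i + 1]
  pmax(eta, 0)
}

#' Indicator mask for a strategy subset
#'
#' Subsets of the discretised strategy space are represented as logical
#' masks over the grid nodes (the finite sigma-algebra of the
#' discretisation).  The full grid and every complement are representable.
#'
#' @param grid a [strategy_grid()].
#' @param mask logical vector over nodes, or a predicate `function(v)`.
#' @return an object of class `subset_indicator` (a logical vector with the
#'   grid attached).
#' @examples
#' g <- strategy_grid(11)
#' A <- subset_indicator(g, function(v) v <= 0.5)
#' @export
subset_indicator <- function(grid, mask) {
  stopifnot(inherits(grid, "strategy_grid"))
  if (is.function(mask)) mask <- vapply(grid$nodes, mask, logical(1))
  mask <- as.logical(mask)
  if (length(mask) != length(grid$nodes))
    stop("mask length must equal the number of grid nodes")
  structure(mask, grid = grid, class = "subset_indicator")
}

#' Complement of a subset indicator
#' @param A a [subset_indicator()].
#' @return the complementary `subset_indicator`.
#' @export
complement <- function(A) {
  subset_indicator(attr(A, "grid"), !as.logical(A))
}

#' Measure of a strategy set at a time point
#'
#' Computes \eqn{\mu(t)(A) = \int_A \eta(v, t)\,dv} by quadrature of the
#' density over the masked nodes.  Countably additive over disjoint masks
#' up to floating tolerance; linear interpolation in time between stored
#' columns.
#'
#' @param field a [density_field()].
#' @param A a [subset_indicator()] on the same grid (or a logical vector).
#' @param t time point inside the field's time range.
#' @return nonnegative scalar measure; 0 for an empty mask.
#' @export
measure_of_set <- function(field, A, t) {
  stopifnot(inherits(field, "density_field"))
  mask <- as.logical(A)
  if (length(mask) != length(field$grid$nodes))
    stop("mask does not match the field's grid")
  if (!any(mask)) return(0)
  eta <- field_at_time(field, t)
  sum(field$grid$weights[mask] * eta[mask])
}

#' Neighbourhood of a strategy point
#'
#' Returns the mask of all nodes within `radius` of `v` under the grid
#' metric.  Always contains the node closest to `v`; if the radius is
#' below the local grid spacing a warning is raised and the mask is the
#' single node.
#'
#' @param grid a [strategy_grid()].
#' @param v strategy point (should be on, or near, a grid node).
#' @param radius positive radius.
#' @return a [subset_indicator()].
#' @export
neighbourhood <- function(grid, v, radius) {
  stopifnot(inherits(grid, "strategy_grid"), radius > 0)
  d <- vapply(grid$nodes, function(x) grid$metric(x, v), numeric(1))
  mask <- d <= radius + 1e-12
  mask[which.min(d)] <- TRUE
  if (sum(mask) == 1L)
    warning("radius below grid spacing; neighbourhood is a single node")
  subset_indicator(grid, mask)
}

#' Generalised density transform
#'
#' Transforms a population density \eqn{\rho(v, t)} into the generalised
#' measure density \eqn{\eta(v, t) = \rho(v, t)^{1/R(v)}} used to
#' characterise the presence of a strategy.  `R` must be positive
#' everywhere; \eqn{\eta} vanishes exactly where \eqn{\rho} vanishes, so
#' the transform preserves extinction and is pointwise monotone.
#'
#' @param rho a [density_field()] of population densities.
#' @param R positive exponent scale: a scalar, a vector over nodes, or a
#'   `function(v)`.
#' @return a [density_field()] holding \eqn{\eta}.
#' @export
transform_density <- function(rho, R) {
  stopifnot(inherits(rho, "density_field"))
  Rv <- eval_coef(R, rho$grid$nodes)
  if (any(Rv <= 0)) stop("R(v) must be positive at every node")
  eta <- rho$values^(1 / Rv)
  density_field(rho$grid, rho$times, eta)
}

# Evaluate a coefficient given as scalar, per-node vector, or function(v).
eval_coef <- function(coef, nodes) {
  if (is.function(coef)) {
    out <- vapply(nodes, coef, numeric(1))
  } else if (length(coef) == 1L) {
    out <- rep(as.numeric(coef), length(nodes))
  } else {
    out <- as.numeric(coef)
    if (length(out) != length(nodes))
      stop("coefficient vector length does not match the grid")
  }
  out
}

#' Write a density field to CSV
#'
#' Long format with columns `t`, `v`, `eta`.
#' @param field a [density_field()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, path) {
  df <- data.frame(
    t = rep(field$times, each = length(field$grid$nodes)),
    v = rep(field$grid$nodes, times = length(field$times)),
    eta = as.vector(field$values))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a density field from CSV
#'
#' Inverse of [write_field_csv()]; the grid is rebuilt with trapezoidal
#' weights on the stored nodes.
#' @param path CSV file with columns `t`, `v`, `eta`.
#' @return a [density_field()].
#' @export
read_field_csv <- function(path) {
  df <- utils::read.csv(path)
  nodes <- sort(unique(df$v))
  times <- sort(unique(df$t))
  vals <- matrix(NA_real_, length(nodes), length(times))
  vals[cbind(match(df$v, nodes), match(df$t, times))] <- df$eta
  density_field(strategy_grid(nodes), times, vals)
}
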