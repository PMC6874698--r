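#' Selection detection for a strategy set
#'
#' A set `A` is selected when the measure of its complement tends to zero
#' at large times while the measure of `A` itself does not.  At finite
#' horizon this is operationalised as: at the final stored time the
#' complement's measure is below `tolerance` while the measure of `A` is
#' above it.  Whole-population extinction (total measure below
#' `tolerance`) is excluded and raises an error.
#'
#' @param field a [density_field()] spanning a long horizon.
#' @param A a [subset_indicator()] (non-empty).
#' @param tolerance vanishing threshold on measures.
#' @return a list with `selected` (logical) and `trace`, a data.frame of
#'   `t`, `measure_A`, `measure_complement`.
#' @export
detect_selection <- function(field, A, tolerance = 1e-3) {
  stopifnot(inherits(field, "density_field"))
  if (!any(as.logical(A))) stop("A must be non-empty")
  Ac <- !as.logical(A)
  mA <- vapply(field$times, function(t) measure_of_set(field, A, t),
               numeric(1))
  mC <- vapply(field$times, function(t) measure_of_set(field, Ac, t),
               numeric(1))
  n <- length(field$times)
  if (mA[n] + mC[n] < tolerance)
    stop("whole-population extinction: total measure below tolerance")
  list(selected = mC[n] < tolerance && mA[n] > tolerance,
       trace = data.frame(t = field$times, measure_A = mA,
                          measure_complement = mC))
}

# Log-density matrix over the full grid (-Inf at zero nodes), preferring
# an exact log representation stored by the simulators.
log_eta_matrix <- function(field) {
  Lmat <- attr(field, "log_values")
  if (!is.null(Lmat)) {
    pos <- attr(field, "positive_nodes")
    out <- matrix(-Inf, nrow(field$values), ncol(field$values))
    out[pos, ] <- Lmat
    out
  } else {
    suppressWarnings(log(field$values))
  }
}

#' Pairwise ranking of two strategies from a density trajectory
#'
#' Strategy `v` ranks above `w` when the ratio of densities
#' \eqn{\eta(w', t)/\eta(v', t)} tends to zero uniformly over
#' neighbourhoods of the two points.  At finite horizon the supremum of
#' the ratio over all node pairs in the two neighbourhoods is tracked in
#' time; the verdict is `v_better` when the final supremum is below
#' `tolerance` *and* the supremum decreases monotonically across the last
#' three dyadic time windows (a limit that fails to settle — e.g. a
#' periodic succession — yields `incomparable`, never a number).
#' The two directed ratios are both computed, which makes the verdict
#' anti-symmetric by construction.
#'
#' @param field a [density_field()] (ideally with a `"log_values"`
#'   attribute from the simulators, so vanishing ratios stay computable).
#' @param v,w strategy points to compare.
#' @param radius neighbourhood radius; default twice the local grid
#'   spacing.
#' @param tolerance ratio-vanishing threshold.
#' @return an object of class `ranking_report`: list with `pair`,
#'   `verdict` (`"v_better"`, `"w_better"` or `"incomparable"`),
#'   `sup_ratio_trace` (data.frame `t`, `ratio_wv`, `ratio_vw`),
#'   `radius`, `tolerance` and `initial_measures`.
#' @export
rank_pair <- function(field, v, w, radius = NULL, tolerance = 1e-4) {
  stopifnot(inherits(field, "density_field"))
  g <- field$grid
  if (is.null(radius)) radius <- 2 * max(diff(g$nodes)) + 1e-12
  Ov <- suppressWarnings(neighbourhood(g, v, radius))
  Ow <- suppressWarnings(neighbourhood(g, w, radius))
  L <- log_eta_matrix(field)
  iv <- which(as.logical(Ov) & is.finite(L[, 1]))
  iw <- which(as.logical(Ow) & is.finite(L[, 1]))
  if (length(iv) == 0L || length(iw) == 0L)
    stop("every neighbourhood of a compared strategy must carry ",
         "positive initial density")
  # directed sup ratios over node pairs, in log space
  log_swv <- apply(L[iw, , drop = FALSE], 2, max) -
    apply(L[iv, , drop = FALSE], 2, min)   # sup eta(w')/eta(v')
  log_svw <- apply(L[iv, , drop = FALSE], 2, max) -
    apply(L[iw, , drop = FALSE], 2, min)
  vanishes <- function(log_s) {
    n <- length(log_s)
    if (!is.finite(log_s[n]) || exp(log_s[n]) >= tolerance) return(FALSE)
    dyadic_decreasing(field$times, log_s)
  }
  verdict <- if (vanishes(log_swv)) "v_better"
  else if (vanishes(log_svw)) "w_better"
  else "incomparable"
  structure(list(
    pair = c(v = v, w = w), verdict = verdict,
    sup_ratio_trace = data.frame(t = field$times,
                                 ratio_wv = exp(log_swv),
                                 ratio_vw = exp(log_svw)),
    radius = radius, tolerance = tolerance,
    initial_measures = c(O_v = measure_of_set(field, Ov, field$times[1]),
                         O_w = measure_of_set(field, Ow, field$times[1]))),
    class = "ranking_report")
}

# Monotone-trend test: mean of the statistic over the last three dyadic
# windows (T/8..T/4, T/4..T/2, T/2..T) must be strictly decreasing.
dyadic_decreasing <- function(times, stat) {
  T1 <- times[length(times)]; T0 <- times[1]
  span <- T1 - T0
  edges <- T0 + span * c(1 / 8, 1 / 4, 1 / 2, 1)
  means <- vapply(1:3, function(i) {
    sel <- times > edges[i] - 1e-12 & times <= edges[i + 1] + 1e-12
    if (!any(sel)) return(NA_real_)
    mean(stat[sel])
  }, numeric(1))
  if (anyNA(means)) return(FALSE)
  all(diff(means) < 0)
}

#' @export
print.ranking_report <- function(x, ...) {
  cat(sprintf("ranking_report: v = %g vs w = %g -> %s (radius %.3g, tol %g)\n",
              x$pair["v"], x$pair["w"], x$verdict, x$radius, x$tolerance))
  invisible(x)
}

#' Empirical fitness as a long-term time average
#'
#' The empirical evolutionary fitness of a strategy is the long-term time
#' average of its per-capita growth rate of the generalised density,
#' which for a window \eqn{[T_0, T]} equals
#' \eqn{(\ln\eta(v, T) - \ln\eta(v, T_0)) / (T - T_0)}.  The estimate is
#' flagged as non-converged when the averages over the two half-windows
#' differ by more than `drift_tol`.
#'
#' @param field a [density_field()].
#' @param v strategy point (snapped to the nearest node).
#' @param window numeric `c(T0, T)`; default the second half of the
#'   stored time range.
#' @param drift_tol half-window drift tolerance for the convergence flag.
#' @return an object of class `fitness_estimate`: list with `v`, `J1`,
#'   `window`, `converged`.
#' @examples
#' g <- strategy_grid(11)
#' f <- density_field(g, 0:10, outer(rep(1, 11), exp(0.3 * (0:10))))
#' time_average_fitness(f, 0.5)$J1  # 0.3
#' @export
time_average_fitness <- function(field, v, window = NULL,
                                 drift_tol = 1e-2) {
  stopifnot(inherits(field, "density_field"))
  i <- which.min(abs(field$grid$nodes - v))
  L <- log_eta_matrix(field)[i, ]
  tt <- field$times
  if (is.null(window)) window <- c(tt[1] + (tt[length(tt)] - tt[1]) / 2,
                                   tt[length(tt)])
  i0 <- which.min(abs(tt - window[1]))
  i1 <- which.min(abs(tt - window[2]))
  if (i1 <= i0) stop("window must span at least two stored times")
  if (!all(is.finite(L[i0:i1])))
    stop("density is zero inside the window: fitness undefined at v = ", v)
  J1 <- (L[i1] - L[i0]) / (tt[i1] - tt[i0])
  im <- i0 + which.min(abs(tt[i0:i1] - (tt[i0] + tt[i1]) / 2)) - 1L
  Ja <- (L[im] - L[i0]) / (tt[im] - tt[i0])
  Jb <- (L[i1] - L[im]) / (tt[i1] - tt[im])
  structure(list(v = field$grid$nodes[i], J1 = J1,
                 window = c(tt[i0], tt[i1]),
                 converged = abs(Ja - Jb) <= drift_tol),
            class = "fitness_estimate")
}

#' @export
print.fitness_estimate <- function(x, ...) {
  cat(sprintf("fitness_estimate: v = %g, J1 = %.6g over [%g, %g]%s\n",
              x$v, x$J1, x$window[1], x$window[2],
              if (x$converged) "" else "  (NOT converged)"))
  invisible(x)
}

#' Empirical fitness landscape over the grid
#'
#' Applies [time_average_fitness()] at every node with positive density
#' on the window and reports the per-node estimates together with the
#' argmax set (ties within `tie_tol` of the maximum are all reported:
#' a polymorphic maximum is a set, not a point).  Nodes whose estimate
#' has not converged are flagged, never silently dropped.
#'
#' @inheritParams time_average_fitness
#' @param tie_tol tie tolerance for the argmax set.
#' @return an object of class `fitness_landscape`: data.frame with
#'   columns `v`, `J1`, `converged`; attributes `argmax` (vector of
#'   nodes) and `window`.
#' @export
fitness_landscape <- function(field, window = NULL, drift_tol = 1e-2,
                              tie_tol = 1e-9) {
  stopifnot(inherits(field, "density_field"))
  nodes <- field$grid$nodes
  est <- lapply(nodes, function(v) {
    tryCatch(time_average_fitness(field, v, window, drift_tol),
             error = function(e) NULL)
  })
  J1 <- vapply(est, function(e) if (is.null(e)) NA_real_ else e$J1,
               numeric(1))
  conv <- vapply(est, function(e) if (is.null(e)) NA else e$converged,
                 logical(1))
  out <- data.frame(v = nodes, J1 = J1, converged = conv)
  # argmax over converged estimates only: a non-converged window average
  # is not a fitness value (falls back to all finite estimates when
  # nothing converged, so the non-convergence is still visible)
  use <- !is.na(J1) & !is.na(conv) & conv
  if (!any(use)) use <- !is.na(J1)
  mx <- max(J1[use])
  attr(out, "argmax") <- nodes[use & J1 >= mx - tie_tol]
  attr(out, "window") <- if (is.null(est[[which(!is.na(J1))[1]]])) window
  else est[[which(!is.na(J1))[1]]]$window
  class(out) <- c("fitness_landscape", "data.frame")
  out
}

#' Consistency check on a set of ranking reports
#'
#' The ranking relation is a partial order: it must be anti-symmetric
#' (never `v` above `w` and `w` above `v`) and transitive (`v` above `w`
#' and `w` above `u` force `v` above `u` whenever the pair `(v, u)` was
#' compared and found comparable).
#'
#' @param reports list of [rank_pair()] reports sharing radius and
#'   tolerance.
#' @return a list with `consistent` (logical) and `violations`
#'   (character vector describing each violation).
#' @export
ranking_consistency_check <- function(reports) {
  if (length(reports) == 0L)
    return(list(consistent = TRUE, violations = character(0)))
  edges <- do.call(rbind, lapply(reports, function(r) {
    stopifnot(inherits(r, "ranking_report"))
    if (r$verdict == "v_better")
      data.frame(from = r$pair[["v"]], to = r$pair[["w"]])
    else if (r$verdict == "w_better")
      data.frame(from = r$pair[["w"]], to = r$pair[["v"]])
    else NULL
  }))
  compared <- unique(do.call(rbind, lapply(reports, function(r)
    data.frame(a = min(r$pair), b = max(r$pair)))))
  viol <- character(0)
  if (!is.null(edges) && nrow(edges) > 0) {
    key <- paste(edges$from, edges$to)
    if (any(paste(edges$to, edges$from) %in% key))
      viol <- c(viol, "symmetric pair: some v and w each rank above the other")
    # transitivity over length-2 chains with the closing pair compared
    for (i in seq_len(nrow(edges))) for (j in seq_len(nrow(edges))) {
      if (edges$to[i] == edges$from[j]) {
        a <- edges$from[i]; c <- edges$to[j]
        if (a == c) next
        pair_seen <- any(compared$a == min(a, c) & compared$b == max(a, c))
        closed <- any(edges$from == a & edges$to == c)
        if (pair_seen && !closed)
          viol <- c(viol, sprintf(
            "transitivity violated: %g > %g > %g but the compared pair (%g, %g) does not close the chain",
            a, edges$to[i], c, a, c))
      }
    }
  }
  list(consistent = length(viol) == 0L, violations = unique(viol))
}
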