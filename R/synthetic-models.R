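#' Random, well-posed stage model
#'
#' Draws a stage-structured model whose coefficients are smooth positive
#' low-order polynomials of the strategy, suitable as a test fixture.
#' Transition rates `p_i` are kept strictly positive and at least one
#' fecundity `b_i` strictly positive, which makes the stage matrix
#' irreducible so the dominant eigenvalue is simple and real at every
#' node.  The same seed always yields the same model.
#'
#' @param seed integer seed.
#' @param n number of stages (default 2 or 3, drawn from the seed).
#' @param grid a [strategy_grid()] (default 21 nodes on `[0, 1]`).
#' @param separate_fitness logical; when `TRUE` the model is redrawn
#'   until the fitness landscape has a unique argmax with a margin of at
#'   least 0.05 over the rest of the grid.
#' @return a [stage_model()] with an attached `"recipe"` attribute.
#' @export
random_stage_model <- function(seed, n = NULL, grid = strategy_grid(21),
                               separate_fitness = FALSE) {
  draw <- function(s) {
    set.seed(s)
    nn <- if (is.null(n)) sample(2:3, 1) else as.integer(n)
    # positive low-order polynomial coefficient: c0 + c1 v + c2 v^2
    poly <- function(lo, hi) {
      c0 <- stats::runif(1, lo, hi)
      c1 <- stats::runif(1, -c0 / 2, hi / 2)
      c2 <- stats::runif(1, -c0 / 4, hi / 4)
      function(v) c0 + c1 * v + c2 * v^2
    }
    bf <- lapply(seq_len(nn), function(i)
      if (i == 1) function(v) 0 else poly(0.5, 3))
    af <- lapply(seq_len(nn), function(i) poly(0.05, 0.5))
    pf <- lapply(seq_len(max(nn - 1, 1)), function(i) poly(0.3, 1.5))
    Rf <- poly(0.5, 2)
    stage_model(
      n = nn,
      b = function(v) vapply(bf, function(f) f(v), numeric(1)),
      a = function(v) vapply(af, function(f) f(v), numeric(1)),
      p = function(v) vapply(pf[seq_len(nn - 1)], function(f) f(v),
                             numeric(1)),
      R = function(v) Rf(v),
      grid = grid)
  }
  model <- draw(seed)
  if (separate_fitness) {
    tries <- 0L
    repeat {
      land <- stage_fitness(model)
      srt <- sort(land$J, decreasing = TRUE)
      if (length(attr(land, "argmax")) == 1L &&
          srt[1] - srt[2] >= 1e-4 &&
          srt[1] - min(land$J) >= 0.05) break
      tries <- tries + 1L
      if (tries > 100L)
        stop("could not draw a fitness-separated stage model in 100 tries")
      model <- draw(seed + 7919L * tries)
    }
  }
  attr(model, "recipe") <- list(kind = "stage", seed = seed, n = model$n)
  model
}

#' Random, well-posed delay model
#'
#' Draws a delay model with nonnegative delayed coefficients `q`,
#' a diagonally dominant negative instantaneous matrix `r`, and delays
#' in `[0.1, 2]`.  The rightmost characteristic root is certified below
#' `cap` using the row-sum upper bound (redrawing up to 100 times, then
#' failing explicitly).  Deterministic in the seed.
#'
#' @param seed integer seed.
#' @param n number of variables.
#' @param m number of delays.
#' @param cap upper bound required on the rightmost root; `Inf` to
#'   disable.
#' @param grid optional [strategy_grid()]; coefficients then vary
#'   smoothly (linearly) with the strategy.
#' @param f,history passed to [delay_model()].
#' @return a [delay_model()] with an attached `"recipe"` attribute.
#' @export
random_delay_model <- function(seed, n = 1L, m = 1L, cap = Inf,
                               grid = NULL, f = NULL, history = 1) {
  n <- as.integer(n); m <- as.integer(m)
  stopifnot(n >= 1L, m >= 1L)
  for (try in 0:100) {
    set.seed(seed + 104729L * try)
    tau <- stats::runif(m, 0.1, 2)
    q0 <- array(stats::runif(n * n * m, 0, 1.5), dim = c(n, n, m))
    q1 <- array(stats::runif(n * n * m, -0.3, 0.8), dim = c(n, n, m))
    r_off <- matrix(stats::runif(n * n, 0, 0.3), n, n)
    diag(r_off) <- 0
    dgn <- -stats::runif(n, 0.5, 1.5) - rowSums(r_off)
    r0 <- r_off + diag(dgn, n)
    qfun <- if (is.null(grid)) q0 else local({
      qa <- q0; qb <- q1
      function(v) qa + qb * v
    })
    model <- delay_model(n, tau, qfun, r0, R = 1, grid = grid,
                         f = f, history = history)
    ok <- TRUE
    if (is.finite(cap)) {
      # screen with the cheap row-sum bound, then certify with the
      # actual rightmost root at the grid extremes
      vs <- if (is.null(grid)) list(NULL) else as.list(range(grid$nodes))
      for (v in vs) {
        rr <- tryCatch(Re(attr(rightmost_root(model, v), "rightmost")),
                       error = function(e) Inf)
        if (rr >= cap) { ok <- FALSE; break }
      }
    }
    if (ok) {
      attr(model, "recipe") <- list(kind = "delay", seed = seed,
                                    n = n, m = m, cap = cap)
      return(model)
    }
  }
  stop("could not draw a delay model under the cap in 100 tries")
}

#' Named reproduction/competition trade-off families
#'
#' Coefficient families `k(v)` (reproduction) and `r(v)` (competition
#' weight) for nonlocal logistic runs, with the analytic argmax of the
#' fitness `k/r` documented in the result.
#'
#' Families: `"linear"` (`k = 1 + v`, `r = 1`; argmax 1),
#' `"linear-quadratic"` (`k = 1 + v`, `r = 1 + v^2/2`; argmax
#' `sqrt(3) - 1`), `"constant"` (`k = r = 1`; flat — every strategy is a
#' maximiser).
#'
#' @param name family name.
#' @param grid a [strategy_grid()].
#' @return list with functions `k`, `r`, the analytic `argmax` (of
#'   `k/r` on the continuum; `NULL` when flat), and the grid argmax
#'   `argmax_grid` (all tying nodes).
#' @export
tradeoff_family <- function(name, grid = strategy_grid(101)) {
  fams <- list(
    "linear" = list(k = function(v) 1 + v, r = function(v) 1,
                    argmax = 1),
    "linear-quadratic" = list(k = function(v) 1 + v,
                              r = function(v) 1 + v^2 / 2,
                              argmax = sqrt(3) - 1),
    "constant" = list(k = function(v) 1, r = function(v) 1,
                      argmax = NULL))
  if (!name %in% names(fams))
    stop("unknown family '", name, "'; available: ",
         paste(names(fams), collapse = ", "))
  fam <- fams[[name]]
  ratio <- fam$k(grid$nodes) / fam$r(grid$nodes)
  fam$argmax_grid <- grid$nodes[ratio >= max(ratio) - 1e-12]
  fam$grid <- grid
  fam
}
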