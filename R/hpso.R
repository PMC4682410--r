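# Self-organizing hierarchical particle swarm optimization (HPSO) with
# time-varying acceleration coefficients.
#
# The velocity update has no inertia term: each component is rebuilt
# from the cognitive and social attractions alone,
#   v = c1 * rand() * (p - x) + c2 * Rand() * (pg - x),
# with c1 ramped down (2.5 -> 0.5) and c2 ramped up (0.5 -> 2.5) over
# the run. When a velocity component collapses to exactly zero (which
# happens whenever x = p = pg), it is re-energized to a random sign
# times a small, linearly decaying fraction of v_max -- the
# self-organizing rule that keeps the inertia-free swarm searching.

#' HPSO configuration
#'
#' @param n_particles swarm size (>= 2).
#' @param max_iter maximum iterations (MAXITR of the c1/c2 ramps).
#' @param c1i,c1f initial/final cognitive acceleration (default 2.5 -> 0.5).
#' @param c2i,c2f initial/final social acceleration (default 0.5 -> 2.5).
#' @param bounds 2 x d matrix; row 1 lower, row 2 upper box bounds.
#' @param v_max per-dimension velocity cap; `NULL` means half the box
#'   width.
#' @param reinit_fraction_init,reinit_fraction_final fraction of `v_max`
#'   used to re-energize zero velocity components, decayed linearly over
#'   the run.
#' @param seed RNG seed used by [hpso_optimize()] (`NULL` = leave the
#'   RNG state alone).
#' @param tol early-stop tolerance on global-best improvement; `NULL`
#'   means `1e-8 * initial best objective`.
#' @param patience iterations without `tol` improvement before stopping.
#' @return an `hpso_config` list.
#' @export
hpso_config <- function(n_particles = 40L, max_iter = 1000L,
                        c1i = 2.5, c1f = 0.5, c2i = 0.5, c2f = 2.5,
                        bounds, v_max = NULL,
                        reinit_fraction_init = 0.1,
                        reinit_fraction_final = 0.01,
                        seed = NULL, tol = NULL, patience = 50L) {
  bounds <- as.matrix(bounds)
  if (nrow(bounds) != 2L || any(bounds[1L, ] > bounds[2L, ]))
    stop("bounds must be a 2 x d matrix with lower <= upper", call. = FALSE)
  stopifnot(n_particles >= 2L, max_iter >= 1L)
  if (is.null(v_max)) v_max <- (bounds[2L, ] - bounds[1L, ]) / 2
  structure(list(n_particles = as.integer(n_particles),
                 max_iter = as.integer(max_iter),
                 c1i = c1i, c1f = c1f, c2i = c2i, c2f = c2f,
                 bounds = bounds, v_max = rep_len(v_max, ncol(bounds)),
                 reinit_fraction_init = reinit_fraction_init,
                 reinit_fraction_final = reinit_fraction_final,
                 seed = seed, tol = tol, patience = as.integer(patience)),
            class = "hpso_config")
}

#' Time-varying acceleration coefficients
#'
#' Linear ramps `c1 = (c1f - c1i) * iter / MAXITR + c1i` and the
#' analogous `c2`.
#'
#' @param iter current iteration, `0 <= iter <= max_iter`.
#' @param cfg an [hpso_config()].
#' @return named vector `c(c1 = , c2 = )`.
#' @export
acceleration_coefficients <- function(iter, cfg) {
  if (iter < 0 || iter > cfg$max_iter)
    stop("iter must lie in [0, max_iter]", call. = FALSE)
  frac <- iter / cfg$max_iter
  c(c1 = (cfg$c1f - cfg$c1i) * frac + cfg$c1i,
    c2 = (cfg$c2f - cfg$c2i) * frac + cfg$c2i)
}

# Evaluate the objective for all particle rows; accepts objectives that
# are either matrix-vectorized (n x d -> n) or scalar (d -> 1).
# Non-finite values become +Inf so a wild particle never poisons the
# swarm bookkeeping.
eval_objective <- function(objective, X) {
  f <- tryCatch(objective(X), error = function(e) NULL)
  if (!(is.numeric(f) && length(f) == nrow(X)))
    f <- apply(X, 1L, function(row) {
      v <- tryCatch(objective(row), error = function(e) Inf)
      if (length(v) != 1L) Inf else as.numeric(v)
    })
  f[!is.finite(f)] <- Inf
  f
}

hpso_init <- function(objective, cfg) {
  d <- ncol(cfg$bounds)
  n <- cfg$n_particles
  lo <- matrix(cfg$bounds[1L, ], n, d, byrow = TRUE)
  hi <- matrix(cfg$bounds[2L, ], n, d, byrow = TRUE)
  X <- lo + matrix(runif(n * d), n, d) * (hi - lo)
  V <- matrix(runif(n * d, -1, 1), n, d) *
    matrix(cfg$v_max, n, d, byrow = TRUE)
  f <- eval_objective(objective, X)
  g <- which.min(f)
  structure(list(X = X, V = V, P = X, f_P = f,
                 P_g = X[g, ], f_g = f[g], iter = 0L),
            class = "swarm_state")
}

#' One HPSO iteration
#'
#' Recomputes every velocity component from fresh uniform draws (no
#' inertia), re-energizes exactly-zero components, clamps velocities to
#' `v_max` and positions to the bounds (zeroing the offending velocity
#' component), evaluates the objective at the new positions and updates
#' the personal and global bests.
#'
#' @param state swarm state from `hpso_init()` or a previous step.
#' @param objective function mapping a parameter vector (or an `n x d`
#'   matrix of row vectors) to objective value(s); minimized.
#' @param cfg an [hpso_config()].
#' @return the updated swarm state.
#' @export
hpso_step <- function(state, objective, cfg) {
  n <- cfg$n_particles
  d <- ncol(cfg$bounds)
  cc <- acceleration_coefficients(min(state$iter, cfg$max_iter), cfg)
  R1 <- matrix(runif(n * d), n, d)
  R2 <- matrix(runif(n * d), n, d)
  Pg <- matrix(state$P_g, n, d, byrow = TRUE)
  V <- cc[["c1"]] * R1 * (state$P - state$X) +
       cc[["c2"]] * R2 * (Pg - state$X)
  vmax <- matrix(cfg$v_max, n, d, byrow = TRUE)
  # self-organizing re-initialization of collapsed velocity components
  frac <- cfg$reinit_fraction_init +
    (cfg$reinit_fraction_final - cfg$reinit_fraction_init) *
    min(state$iter / cfg$max_iter, 1)
  zero <- V == 0
  if (any(zero)) {
    sgn <- sign(runif(sum(zero)) - 0.5)
    sgn[sgn == 0] <- 1
    V[zero] <- sgn * frac * vmax[zero]
  }
  V <- pmin(pmax(V, -vmax), vmax)
  X <- state$X + V
  lo <- matrix(cfg$bounds[1L, ], n, d, byrow = TRUE)
  hi <- matrix(cfg$bounds[2L, ], n, d, byrow = TRUE)
  out <- X < lo | X > hi
  X <- pmin(pmax(X, lo), hi)
  V[out] <- 0
  f <- eval_objective(objective, X)
  better <- f < state$f_P
  state$P[better, ] <- X[better, ]
  state$f_P[better] <- f[better]
  g <- which.min(state$f_P)
  if (state$f_P[g] < state$f_g) {
    state$f_g <- state$f_P[g]
    state$P_g <- state$P[g, ]
  }
  state$X <- X
  state$V <- V
  state$iter <- state$iter + 1L
  state
}

#' Minimize an objective with HPSO
#'
#' Runs [hpso_step()] until `max_iter` iterations or until the global
#' best has improved by less than `tol` for `patience` consecutive
#' iterations.
#'
#' @inheritParams hpso_step
#' @return list with `theta` (best position), `value` (best objective),
#'   `iterations`, and the final `state`.
#' @export
hpso_optimize <- function(objective, cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  state <- hpso_init(objective, cfg)
  tol <- if (is.null(cfg$tol)) 1e-8 * abs(state$f_g) else cfg$tol
  stall <- 0L
  f_prev <- state$f_g
  while (state$iter < cfg$max_iter) {
    state <- hpso_step(state, objective, cfg)
    stall <- if (f_prev - state$f_g < tol) stall + 1L else 0L
    f_prev <- state$f_g
    if (stall >= cfg$patience) break
  }
  theta <- state$P_g
  names(theta) <- colnames(cfg$bounds)
  list(theta = theta, value = state$f_g, iterations = state$iter,
       state = state)
}

#' Sum-of-squares fitting objective
#'
#' `F(theta) = sum_m (V(m, theta) - S(m))^2` for a model curve evaluated
#' on observed points.
#'
#' @param points list or data frame with numeric `m` (or `mz`) and
#'   `intensity` components.
#' @param model function mapping m/z values to fitted intensities.
#' @return the sum of squared residuals (>= 0).
#' @export
objective_sse <- function(points, model) {
  m <- if (!is.null(points$m)) points$m else points$mz
  y <- points$intensity
  if (length(m) < 1L || length(m) != length(y))
    stop("points must hold matching non-empty m and intensity", call. = FALSE)
  sum((model(m) - y)^2)
}
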