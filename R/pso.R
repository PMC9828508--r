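#' Particle swarm optimizer settings
#'
#' Defaults follow the swarm parameterization used for hyperparameter
#' training: inertia weight 0.729, cognitive and social rates 1.490, search
#' bounds \[0, 3\], and a relative-difference stall criterion (threshold 1e-7
#' over 20 consecutive iterations). Swarm size and the iteration cap are not
#' part of that parameterization; defaults are `max(4 * ndim, 50)` particles
#' (resolved at [pso_optimize] time when `n_particles = NULL`) and 1000
#' iterations.
#'
#' @param omega inertia weight.
#' @param phi_p cognitive learning rate.
#' @param phi_g social learning rate.
#' @param theta_min,theta_max box bounds of the search space.
#' @param sigma_thresh relative-difference convergence threshold.
#' @param n_stall consecutive stalled iterations required for convergence.
#' @param n_particles swarm size (`NULL` = `max(4 * ndim, 50)`).
#' @param max_iter iteration cap.
#' @param seed integer seed for the optimizer's private RNG stream.
#' @return A list of class `pso_control`.
#' @export
pso_control <- function(omega = 0.729, phi_p = 1.490, phi_g = 1.490,
                        theta_min = 0.0, theta_max = 3.0,
                        sigma_thresh = 1e-7, n_stall = 20L,
                        n_particles = NULL, max_iter = 1000L, seed = 1L) {
  structure(list(omega = omega, phi_p = phi_p, phi_g = phi_g,
                 theta_min = theta_min, theta_max = theta_max,
                 sigma_thresh = sigma_thresh, n_stall = as.integer(n_stall),
                 n_particles = if (!is.null(n_particles)) as.integer(n_particles),
                 max_iter = as.integer(max_iter), seed = as.integer(seed)),
            class = "pso_control")
}

# Run expr with a private RNG stream, restoring the caller's stream after.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Velocity update of the swarm
#'
#' `v <- omega*v + phi_p*r1*(p - x) + phi_g*r2*(g - x)` with `r1`, `r2` drawn
#' uniformly on \[0, 1\] per particle and per dimension.
#'
#' @param state list with matrices `x` (positions), `v` (velocities), `p`
#'   (per-particle best positions) and vector `g` (global best), particles in
#'   rows.
#' @param config a [pso_control].
#' @return The new velocity matrix.
#' @export
pso_update_velocity <- function(state, config) {
  np <- nrow(state$x); nd <- ncol(state$x)
  r1 <- matrix(stats::runif(np * nd), np, nd)
  r2 <- matrix(stats::runif(np * nd), np, nd)
  config$omega * state$v +
    config$phi_p * r1 * (state$p - state$x) +
    config$phi_g * r2 * (sweep(-state$x, 2L, state$g, `+`))
}

#' One swarm cycle
#'
#' Updates velocities, advances positions (clamped to the box with the
#' velocity zeroed on clamped dimensions), evaluates the objective once per
#' particle, and updates per-particle and global bests once per cycle. A
#' particle whose objective evaluation fails (e.g. an ill-conditioned model)
#' scores -Inf for the cycle and the swarm continues.
#'
#' @param state swarm state list (`x`, `v`, `p`, `p_val`, `g`, `g_val`).
#' @param config a [pso_control].
#' @param objective function(theta) -> scalar to maximize.
#' @return Updated state.
#' @export
pso_step <- function(state, config, objective) {
  state$v <- pso_update_velocity(state, config)
  state$x <- state$x + state$v
  lo <- state$x < config$theta_min
  hi <- state$x > config$theta_max
  state$x[lo] <- config$theta_min
  state$x[hi] <- config$theta_max
  state$v[lo | hi] <- 0
  vals <- apply(state$x, 1L, function(th)
    tryCatch(objective(th), error = function(e) -Inf))
  better <- vals > state$p_val
  state$p[better, ] <- state$x[better, , drop = FALSE]
  state$p_val[better] <- vals[better]
  ib <- which.max(state$p_val)
  if (state$p_val[ib] > state$g_val) {
    state$g <- state$p[ib, ]
    state$g_val <- state$p_val[ib]
  }
  state
}

#' Relative-difference stall convergence test
#'
#' Converged when `|g(t+1) - g(t)| / |g(t)| < sigma_thresh` held for the last
#' `n_stall` consecutive steps of the global-best history (absolute
#' difference is used where `g(t) = 0`).
#'
#' @param best_history numeric vector of per-iteration global best values.
#' @param config a [pso_control].
#' @return TRUE iff converged.
#' @export
pso_converged <- function(best_history, config) {
  n <- length(best_history)
  if (n < config$n_stall + 1L) return(FALSE)
  g0 <- best_history[(n - config$n_stall):(n - 1L)]
  g1 <- best_history[(n - config$n_stall + 1L):n]
  denom <- abs(g0)
  rd <- ifelse(denom > 0, abs(g1 - g0) / denom, abs(g1 - g0))
  all(rd < config$sigma_thresh)
}

#' Maximize an objective by particle swarm optimization
#'
#' Positions and velocities are initialized uniformly on
#' \[theta_min, theta_max\] per dimension; the swarm iterates [pso_step]
#' until the stall criterion [pso_converged] fires or `max_iter` is reached.
#' The optimizer draws from a private RNG stream seeded by `config$seed`, so
#' results are reproducible and the caller's RNG is untouched.
#'
#' @param objective function(theta) -> scalar to maximize (e.g. the marginal
#'   log-likelihood of a GP).
#' @param ndim dimensionality of the search space.
#' @param config a [pso_control].
#' @return List with `theta` (best position), `value` (best objective),
#'   `converged`, `iterations`, and `history` (global best trace).
#' @export
pso_optimize <- function(objective, ndim, config = pso_control()) {
  stopifnot(ndim >= 1L)
  np <- if (is.null(config$n_particles)) max(4L * ndim, 50L) else config$n_particles
  with_local_seed(config$seed, {
    x <- matrix(stats::runif(np * ndim, config$theta_min, config$theta_max),
                np, ndim)
    v <- matrix(stats::runif(np * ndim, config$theta_min, config$theta_max),
                np, ndim)
    vals <- apply(x, 1L, function(th)
      tryCatch(objective(th), error = function(e) -Inf))
    state <- list(x = x, v = v, p = x, p_val = vals,
                  g = x[which.max(vals), ], g_val = max(vals))
    history <- state$g_val
    it <- 0L
    while (it < config$max_iter) {
      it <- it + 1L
      state <- pso_step(state, config, objective)
      history <- c(history, state$g_val)
      if (pso_converged(history, config)) break
    }
    list(theta = state$g, value = state$g_val,
         converged = pso_converged(history, config),
         iterations = it, history = history)
  })
}
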