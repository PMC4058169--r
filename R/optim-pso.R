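#' Particle swarm optimization
#'
#' Standard global-best PSO over a box: each particle's velocity is updated as
#' \deqn{v \leftarrow w v + c_1 r_1 (p_{best} - x) + c_2 r_2 (g_{best} - x)}
#' with fresh `r1, r2 ~ U(0,1)` per particle and dimension, then `x <- x + v`.
#' Velocities are clamped to 20% of each dimension's range and positions to
#' the bounds. The inertia weight decays linearly from `inertia[1]` to
#' `inertia[2]` over the run (pass a single value for fixed inertia). The
#' acceleration defaults `c1 = 1.5`, `c2 = 1.7` are the reference settings of
#' the tuning experiments; personal and global bests are elitist, so the
#' best-fitness trace is non-decreasing.
#'
#' @param objective function of an encoded position vector, maximized.
#' @param bounds 2 x d matrix `rbind(lower, upper)` (see [space_bounds()]).
#' @param pop swarm size (default 20).
#' @param iters number of generations (default 100).
#' @param c1,c2 cognitive and social acceleration coefficients.
#' @param inertia length-2 vector (linear decay) or scalar (fixed).
#' @param seed integer seed; identical seeds give identical runs.
#' @param init list to warm-start the swarm: `positions` (pop x d),
#'   `fitness`, and optionally `gbest_pos`/`gbest_fit` (used by the
#'   CS-then-PSO hybrid); `NULL` for a random swarm.
#' @param trace_offset generation number offset for the trace rows.
#' @return An `optim_run`: list with `best` (`position`, `fitness`), `trace`
#'   (one row per generation), and `evals` (objective evaluation count,
#'   `pop * iters` plus `pop` for a cold-start initialization).
#' @export
optimize_pso <- function(objective, bounds, pop = 20L, iters = 100L,
                         c1 = 1.5, c2 = 1.7, inertia = c(0.9, 0.4),
                         seed = 1L, init = NULL, trace_offset = 0L) {
  bounds <- validate_bounds(bounds)
  objective <- counted_objective(objective)
  with_seed(seed, {
    state <- pso_init(objective, bounds, pop, c1, c2, inertia[1], init)
    w_seq <- if (length(inertia) == 2) {
      seq(inertia[1], inertia[2], length.out = max(iters, 2))
    } else rep(inertia, iters)
    trace <- vector("list", iters)
    for (g in seq_len(iters)) {
      state$w <- w_seq[g]
      state <- pso_step(state, objective, bounds)
      trace[[g]] <- new_trace_row(g + trace_offset, state$gbest_fit,
                                  mean(state$fitness),
                                  stats::setNames(state$gbest_pos, colnames(bounds)))
    }
    optim_result(stats::setNames(state$gbest_pos, colnames(bounds)),
                 state$gbest_fit, do.call(rbind, trace),
                 counted_total(objective), list(state = state))
  })
}

# Build the initial swarm state; warm start skips re-evaluation when fitness
# values are supplied.
pso_init <- function(objective, bounds, pop, c1, c2, w, init = NULL) {
  d <- ncol(bounds)
  if (is.null(init)) {
    positions <- random_positions(pop, bounds)
    fitness <- apply(positions, 1, objective)
  } else {
    positions <- clamp_rows(init$positions, bounds)
    stopifnot(nrow(positions) == pop)
    fitness <- if (!is.null(init$fitness)) init$fitness
               else apply(positions, 1, objective)
  }
  gi <- which.max(fitness)
  gbest_pos <- positions[gi, ]; gbest_fit <- fitness[gi]
  if (!is.null(init$gbest_fit) && init$gbest_fit > gbest_fit) {
    gbest_pos <- init$gbest_pos; gbest_fit <- init$gbest_fit
  }
  list(positions = positions, velocities = matrix(0, pop, d),
       fitness = fitness, pbest_pos = positions, pbest_fit = fitness,
       gbest_pos = gbest_pos, gbest_fit = gbest_fit,
       c1 = c1, c2 = c2, w = w,
       vmax = 0.2 * (bounds[2, ] - bounds[1, ]))
}

#' One particle swarm generation
#'
#' Applies the velocity/position update to every particle, clamps to the box,
#' evaluates, and refreshes personal and global bests (ties keep the
#' incumbent). Exposed mainly for testing; [optimize_pso()] drives it.
#'
#' @param state swarm state list as built by [optimize_pso()].
#' @param objective function of a position vector, maximized.
#' @param bounds 2 x d bounds matrix.
#' @return the updated state.
#' @export
pso_step <- function(state, objective, bounds) {
  bounds <- validate_bounds(bounds)
  pop <- nrow(state$positions); d <- ncol(state$positions)
  r1 <- matrix(runif(pop * d), pop, d)
  r2 <- matrix(runif(pop * d), pop, d)
  gb <- matrix(state$gbest_pos, pop, d, byrow = TRUE)
  v <- state$w * state$velocities +
    state$c1 * r1 * (state$pbest_pos - state$positions) +
    state$c2 * r2 * (gb - state$positions)
  vmax <- matrix(state$vmax, pop, d, byrow = TRUE)
  v <- pmin(pmax(v, -vmax), vmax)
  x <- clamp_rows(state$positions + v, bounds)
  fit <- apply(x, 1, objective)

  improved <- fit > state$pbest_fit
  state$pbest_pos[improved, ] <- x[improved, , drop = FALSE]
  state$pbest_fit[improved] <- fit[improved]
  bi <- which.max(state$pbest_fit)
  if (state$pbest_fit[bi] > state$gbest_fit) {
    state$gbest_fit <- state$pbest_fit[bi]
    state$gbest_pos <- state$pbest_pos[bi, ]
  }
  state$positions <- x
  state$velocities <- v
  state$fitness <- fit
  state
}
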