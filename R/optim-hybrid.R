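#' Two-stage cuckoo-search-then-PSO hybrid
#'
#' The tuner behind CS-PSO-SVM. Stage 1 runs cuckoo search for
#' `round(cs_fraction * total_iters)` generations to find good initial
#' hyperparameters; stage 2 seeds a particle swarm from the cuckoo stage and
#' refines for the remaining generations. With the default
#' `transfer = "population"` the swarm starts at the final nest positions
#' (their fitness values are reused, not re-evaluated); with
#' `transfer = "best"` one particle starts at the cuckoo best and the rest
#' are random. In both modes the swarm's global best is initialized to the
#' cuckoo best with zero initial velocities, so the concatenated best-fitness
#' trace is non-decreasing and the final best can never be worse than the
#' cuckoo stage's.
#'
#' @inheritParams optimize_pso
#' @param total_iters total generations across both stages (default 100).
#' @param cs_fraction fraction of `total_iters` spent in the cuckoo stage,
#'   in (0, 1); default 0.5.
#' @param pa cuckoo abandonment probability.
#' @param lambda,alpha_frac Lévy parameters, see [optimize_cuckoo()].
#' @param transfer `"population"` (default) or `"best"`: what the cuckoo
#'   stage hands to the swarm.
#' @return An `optim_run` with `best`, the concatenated `trace`
#'   (`total_iters` rows, generations numbered 1..`total_iters`), `evals`,
#'   and `stages` (the two stage results).
#' @export
optimize_hybrid <- function(objective, bounds, pop = 20L, total_iters = 100L,
                            cs_fraction = 0.5, pa = 0.25, c1 = 1.5, c2 = 1.7,
                            inertia = c(0.9, 0.4), lambda = 1.5,
                            alpha_frac = 0.01, seed = 1L,
                            transfer = c("population", "best")) {
  transfer <- match.arg(transfer)
  stopifnot(cs_fraction > 0, cs_fraction < 1)
  bounds <- validate_bounds(bounds)
  cs_iters <- max(1L, round(cs_fraction * total_iters))
  pso_iters <- total_iters - cs_iters
  stopifnot(pso_iters >= 1)

  cs <- optimize_cuckoo(objective, bounds, pop = pop, iters = cs_iters,
                        pa = pa, lambda = lambda, alpha_frac = alpha_frac,
                        seed = seed)
  init <- if (transfer == "population") {
    list(positions = cs$nests$positions, fitness = cs$nests$fitness,
         gbest_pos = cs$best$position, gbest_fit = cs$best$fitness)
  } else {
    pos <- with_seed(seed + 1L, random_positions(pop, bounds))
    pos[1, ] <- cs$best$position
    list(positions = pos, fitness = NULL,
         gbest_pos = cs$best$position, gbest_fit = cs$best$fitness)
  }
  ps <- optimize_pso(objective, bounds, pop = pop, iters = pso_iters,
                     c1 = c1, c2 = c2, inertia = inertia, seed = seed + 1L,
                     init = init, trace_offset = cs_iters)
  optim_result(ps$best$position, ps$best$fitness,
               rbind(cs$trace, ps$trace), cs$evals + ps$evals,
               list(stages = list(cs = cs, pso = ps)))
}
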