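## Genetic algorithm for selecting parameter sets with desired response
## characteristics (e.g. PhoPQ-like overshooting induction).

#' Fitness criteria for parameter selection
#'
#' Fold-change thresholds for the three selection criteria:
#' \code{f1} — activated over resting \eqn{[RRP_2]};
#' \code{f2} — activated over resting total RR;
#' \code{f3} — peak \eqn{[RRP_2]} over its activated steady state
#' (overshoot). Each contributes a saturating score
#' \eqn{\min(\mathrm{fold}_i/\mathrm{threshold}_i, 1)} and the fitness is
#' their product, so a set meeting all thresholds has fitness 1.
#'
#' @param f1,f2,f3 fold thresholds (> 1); default 2-fold each.
#' @return a \code{tcs_fitness_criteria} object.
#' @export
fitnessCriteria <- function(f1 = 2, f2 = 2, f3 = 2) {
  if (any(c(f1, f2, f3) <= 1)) stop("fold thresholds must be > 1")
  structure(list(f1 = f1, f2 = f2, f3 = f3),
            class = "tcs_fitness_criteria")
}

#' Selection fitness of a parameter set
#'
#' Product of the three saturating fold scores (see
#' \code{\link{fitnessCriteria}}), evaluated between the resting
#' (\code{k_ph_rest}) and activated (\code{k_ph_act}) conditions; the
#' overshoot fold uses the peak of the activation trajectory. Sets that are
#' unsolvable (or infeasible, when \code{require_feasible = TRUE}) score 0.
#'
#' @inheritParams solveSteadyState
#' @param criteria a \code{tcs_fitness_criteria}.
#' @param k_ph_rest,k_ph_act resting/activating signal.
#' @param require_feasible additionally require the full
#'   \code{\link{feasibilityFilter}} to pass (default FALSE: only
#'   solvability is required, which keeps the evaluation cheap inside the
#'   evolutionary loop).
#' @return numeric fitness in [0, 1].
#' @export
gaFitness <- function(params, criteria = fitnessCriteria(),
                      k_ph_rest = 10, k_ph_act = 0.1,
                      require_feasible = FALSE) {
  if (require_feasible) {
    feas <- feasibilityFilter(params)
    if (feas$verdict != "feasible") return(0)
  }
  wt <- makeTopology("wild_type")
  rest <- solveSteadyState(params, wt, k_ph = k_ph_rest)
  if (!rest$converged) return(0)
  act <- solveSteadyState(params, wt, k_ph = k_ph_act, guess = rest$state)
  if (!act$converged) return(0)
  traj <- .activationTrajectory(params, wt, k_ph_rest, k_ph_act, act$state,
                                state0 = rest$state)
  if (!isTRUE(attr(traj, "converged"))) return(0)
  rrp2_rest <- unname(rest$state["RRP2"]); rrp2_act <- unname(act$state["RRP2"])
  if (rrp2_rest <= 0 || rrp2_act <= 0) return(0)
  fold1 <- rrp2_act / rrp2_rest
  fold2 <- .observableTarget(act$state, "RR_tot") /
    .observableTarget(rest$state, "RR_tot")
  fold3 <- max(traj[, "RRP2"]) / rrp2_act
  score <- function(fold, thr) min(fold / thr, 1)
  score(fold1, criteria$f1) * score(fold2, criteria$f2) *
    score(fold3, criteria$f3)
}

## multiplicative log-normal perturbation of the kinetic constants
.perturb <- function(params, sigma) {
  vals <- unlist(params[.TCS_KINETIC_PARAMS])
  vals <- as.list(vals * exp(stats::rnorm(length(vals), 0, sigma)))
  do.call(setParams, c(list(params), vals))
}

#' Evolve parameter sets by a genetic algorithm
#'
#' Simple evolutionary search: each generation multiplicatively perturbs the
#' kinetic constants of selected parents (log-normal, scale \code{sigma}),
#' evaluates the fitness of the population, and keeps the top fraction as
#' parents for the next generation with elitism (the best individuals carried
#' over unchanged, so best-so-far fitness never decreases). If an entire
#' generation scores 0, the population is re-seeded from the original seeds
#' with a widened perturbation.
#'
#' @param seed_population non-empty list of \code{tcs_params} seeds.
#' @param generations number of generations (0 returns the best seed).
#' @param fitness function mapping a \code{tcs_params} to a numeric fitness;
#'   default wraps \code{\link{gaFitness}}.
#' @param pop_size population size per generation (default 50).
#' @param sigma log-normal perturbation scale (natural-log units,
#'   default 0.2).
#' @param top_frac fraction of the population kept as parents (default 0.2).
#' @param elite number of elite individuals copied unchanged (default 1).
#' @return list with \code{best} (a \code{tcs_params}),
#'   \code{best_fitness}, and \code{history} (data.frame of per-generation
#'   best and mean fitness).
#' @export
gaEvolve <- function(seed_population, generations = 20,
                     fitness = function(p) gaFitness(p),
                     pop_size = 50, sigma = 0.2, top_frac = 0.2, elite = 1) {
  if (!length(seed_population)) stop("seed population must be non-empty")
  if (inherits(seed_population, "tcs_params"))
    seed_population <- list(seed_population)
  evalPop <- function(pop) vapply(pop, fitness, numeric(1))
  pop <- seed_population
  fit <- evalPop(pop)
  ord <- order(fit, decreasing = TRUE)
  best <- pop[[ord[1]]]; best_fit <- fit[ord[1]]
  history <- data.frame(generation = 0L, best_fitness = best_fit,
                        mean_fitness = mean(fit))
  n_parents <- max(1L, ceiling(pop_size * top_frac))
  for (gen in seq_len(generations)) {
    parents <- pop[ord[seq_len(min(n_parents, length(pop)))]]
    nextpop <- pop[ord[seq_len(min(elite, length(pop)))]]
    while (length(nextpop) < pop_size) {
      parent <- parents[[sample.int(length(parents), 1)]]
      child <- try(.perturb(parent, sigma), silent = TRUE)
      if (!inherits(child, "try-error"))
        nextpop[[length(nextpop) + 1L]] <- child
    }
    pop <- nextpop
    fit <- evalPop(pop)
    if (all(fit == 0)) {
      ## degenerate generation: restart from the seeds, explore wider
      pop <- lapply(seq_len(pop_size), function(i)
        .perturb(seed_population[[((i - 1) %% length(seed_population)) + 1]],
                 2 * sigma))
      fit <- evalPop(pop)
    }
    ord <- order(fit, decreasing = TRUE)
    if (fit[ord[1]] > best_fit) {
      best <- pop[[ord[1]]]; best_fit <- fit[ord[1]]
    }
    history <- rbind(history,
                     data.frame(generation = gen, best_fitness = best_fit,
                                mean_fitness = mean(fit)))
  }
  list(best = best, best_fitness = best_fit, history = history)
}
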