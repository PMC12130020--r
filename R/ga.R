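#' Genetic-algorithm outer loop
#'
#' Population-based search over bounded parameter vectors: uniform
#' initialization within the bounds, tournament selection (size
#' `tournament_k`), uniform crossover (per-gene rate `cx_rate`), per-gene
#' Gaussian mutation (standard deviation `mut_sigma_frac` of the bound
#' width, rate `mut_rate`), clipping to bounds and elitism of one.  The best
#' fitness trace is therefore non-decreasing.  Deterministic per seed.  A
#' fitness callable that throws is scored at `worst_fitness` and the run
#' continues.
#'
#' @param bounds Named list of `c(low, high)` per free parameter.
#' @param fitness Function taking a named numeric vector and returning a
#'   numeric scalar or a `fitness_report` (its `global` is used).  Higher is
#'   better.
#' @param pop_size Population size, >= 2.
#' @param generations Number of generations.
#' @param seed Integer seed.
#' @param tournament_k,cx_rate,mut_sigma_frac,mut_rate GA operator settings.
#' @param worst_fitness Score assigned to failing individuals.
#' @return A `ga_run`: `best` (named vector), `best_fitness`, `population`,
#'   `fitness_values`, `history` (data frame generation/best/median), `seed`.
#' @export
run_ga <- function(bounds, fitness, pop_size = 100, generations = 100,
                   seed = 1, tournament_k = 3, cx_rate = 0.5,
                   mut_sigma_frac = 0.1, mut_rate = 0.2,
                   worst_fitness = -1e12) {
  stopifnot(pop_size >= 2, generations >= 1)
  set.seed(seed)
  nm <- names(bounds)
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  width <- hi - lo
  eval1 <- function(x) {
    v <- tryCatch(fitness(stats::setNames(x, nm)), error = function(e) worst_fitness)
    if (inherits(v, "fitness_report")) v <- v$global
    v <- suppressWarnings(as.numeric(v)[1])
    if (!is.finite(v)) worst_fitness else v
  }
  pop <- vapply(seq_along(nm), function(j) stats::runif(pop_size, lo[j], hi[j]),
                numeric(pop_size))
  pop <- matrix(pop, nrow = pop_size, dimnames = list(NULL, nm))
  fit <- apply(pop, 1, eval1)
  hist <- data.frame(generation = integer(), best = numeric(), median = numeric())
  for (gen in seq_len(generations)) {
    hist <- rbind(hist, data.frame(generation = gen, best = max(fit),
                                   median = stats::median(fit)))
    if (gen == generations) break
    newpop <- matrix(0, pop_size, length(nm), dimnames = list(NULL, nm))
    # elitism of 1: the incumbent best survives unchanged
    best_i <- which.max(fit)
    newpop[1, ] <- pop[best_i, ]
    for (k in 2:pop_size) {
      pick <- function() {
        cand <- sample.int(pop_size, tournament_k, replace = TRUE)
        cand[which.max(fit[cand])]
      }
      p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
      sw <- stats::runif(length(nm)) < cx_rate
      child <- ifelse(sw, p2, p1)
      mu <- stats::runif(length(nm)) < mut_rate
      child[mu] <- child[mu] + stats::rnorm(sum(mu), 0, mut_sigma_frac * width[mu])
      newpop[k, ] <- pmin(pmax(child, lo), hi)
    }
    newfit <- c(fit[best_i], apply(newpop[-1, , drop = FALSE], 1, eval1))
    pop <- newpop; fit <- newfit
  }
  best_i <- which.max(fit)
  structure(list(best = pop[best_i, ], best_fitness = fit[best_i],
                 population = pop, fitness_values = fit, history = hist,
                 seed = seed),
            class = "ga_run")
}

#' @export
print.ga_run <- function(x, ...) {
  cat(sprintf("ga_run: %d generations, best fitness %.6g (seed %d)\n",
              nrow(x$history), x$best_fitness, x$seed))
  invisible(x)
}

#' Convergence statistics over repeated GA trials
#'
#' @param trials List of `ga_run` objects (same number of generations).
#' @return Data frame per generation: `median`, `q1`, `q3`, `min`, `max` of
#'   the best-fitness traces across trials.
#' @export
convergence_stats <- function(trials) {
  stopifnot(length(trials) >= 1)
  traces <- vapply(trials, function(tr) tr$history$best,
                   numeric(nrow(trials[[1]]$history)))
  traces <- matrix(traces, nrow = nrow(trials[[1]]$history))
  data.frame(
    generation = trials[[1]]$history$generation,
    median = apply(traces, 1, stats::median),
    q1 = apply(traces, 1, stats::quantile, 0.25),
    q3 = apply(traces, 1, stats::quantile, 0.75),
    min = apply(traces, 1, min),
    max = apply(traces, 1, max)
  )
}

#' Fitness closure for fitting Ca-AdEx genomes with the GA
#'
#' Builds a fitness callable over a chosen subset of free genome parameters:
#' the remaining parameters are pinned to `base`, and each candidate is
#' scored with [ca_adex_fitness()] against a pre-computed AdEx reference
#' (so the reference is not re-simulated per individual).
#'
#' @param base A complete genome supplying the pinned parameters.
#' @param free Character vector of parameter names the GA may vary.
#' @param Is_grid,Id_grid,stim_duration,h Passed to [ca_adex_fitness()].
#' @return A function mapping a named vector over `free` to a
#'   `fitness_report`.
#' @export
genome_fitness_fn <- function(base, free, Is_grid = seq(0, 600, by = 150),
                              Id_grid = seq(0, 900, by = 150),
                              stim_duration = 1000, h = 0.1) {
  reference <- make_adex_reference(base, Is_grid, stim_duration, h)
  pulse_spec <- pulse_task_spec(genome = base)
  function(x) {
    g <- base
    g[free] <- x[free]
    ca_adex_fitness(g, reference = reference, Is_grid = Is_grid,
                    Id_grid = Id_grid, stim_duration = stim_duration, h = h,
                    pulse_spec = pulse_spec)
  }
}
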