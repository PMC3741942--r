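# Differential evolution, rand/1/bin: difference-vector mutation,
# binomial crossover with a forced mutant component, and greedy
# per-individual selection. Written as a generic bounded real-vector
# minimizer; the polar-section segmenter supplies its own repair hook.

#' Differential evolution configuration
#'
#' @param np population size, at least 4 (three mutually distinct donor
#'   indices different from the target must exist).
#' @param generations number of generations `G` (default 10).
#' @param f differentiation (scaling) factor in (0, 2] (default 0.1).
#' @param cr crossover rate in \[0, 1\] (default 0.8).
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#' @param stability_window early-stop patience: stop when the best
#'   fitness has not improved for this many consecutive generations;
#'   0 disables early stopping (default).
#' @param pure_crossover if `TRUE`, drop the forced mutant component in
#'   the binomial crossover so a trial can equal its target exactly.
#' @return an object of class `de_config`.
#' @export
de_config <- function(np = 15L, generations = 10L, f = 0.1, cr = 0.8,
                      seed = NULL, stability_window = 0L,
                      pure_crossover = FALSE) {
  np <- as.integer(np)
  generations <- as.integer(generations)
  if (is.na(np) || np < 4L)
    stop("np must be an integer >= 4", call. = FALSE)
  if (is.na(generations) || generations < 1L)
    stop("generations must be a positive integer", call. = FALSE)
  if (!is.numeric(f) || f <= 0 || f > 2)
    stop("f must lie in (0, 2]", call. = FALSE)
  if (!is.numeric(cr) || cr < 0 || cr > 1)
    stop("cr must lie in [0, 1]", call. = FALSE)
  if (stability_window < 0)
    stop("stability_window must be nonnegative", call. = FALSE)
  structure(list(np = np, generations = generations, f = f, cr = cr,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 stability_window = as.integer(stability_window),
                 pure_crossover = isTRUE(pure_crossover)),
            class = "de_config")
}

#' DE mutation (rand/1)
#'
#' Builds the mutant vector `V = X_r1 + F (X_r2 - X_r3)` with `r1, r2,
#' r3` drawn uniformly without replacement from the population indices
#' excluding the target `i`. Consumes one `sample()` draw from the
#' current RNG stream.
#'
#' @param pop numeric matrix, one individual per row.
#' @param i target row index.
#' @param f differentiation factor.
#' @return mutant vector.
#' @export
de_mutate <- function(pop, i, f) {
  np <- nrow(pop)
  if (np < 4L) stop("population must have at least 4 individuals",
                    call. = FALSE)
  r <- sample(setdiff(seq_len(np), i), 3L)
  pop[r[1L], ] + f * (pop[r[2L], ] - pop[r[3L], ])
}

#' DE binomial crossover
#'
#' Componentwise, the trial takes the mutant value when a uniform draw
#' is at most `cr`, otherwise the target value. One component chosen
#' uniformly at random is always taken from the mutant so the trial
#' differs from the target whenever the mutant does; `pure = TRUE`
#' disables that convention. Consumes `d` uniforms plus (unless pure)
#' one index draw.
#'
#' @param target,mutant numeric vectors of equal length.
#' @param cr crossover rate.
#' @param pure drop the forced mutant component.
#' @return trial vector.
#' @export
de_crossover <- function(target, mutant, cr, pure = FALSE) {
  d <- length(target)
  if (length(mutant) != d)
    stop("target and mutant must have equal length", call. = FALSE)
  take <- stats::runif(d) <= cr
  if (!pure) {
    j_rand <- if (d == 1L) 1L else sample.int(d, 1L)
    take[j_rand] <- TRUE
  }
  ifelse(take, mutant, target)
}

#' DE greedy selection
#'
#' Returns the trial vector iff its fitness is strictly lower than the
#' target's; ties retain the target. Non-finite fitnesses are treated
#' as `+Inf` and never selected.
#'
#' @param target,trial numeric vectors.
#' @param f_target,f_trial their fitness values.
#' @return list with `x` (the surviving vector) and `fitness`.
#' @export
de_select <- function(target, trial, f_target, f_trial) {
  if (!is.finite(f_trial)) f_trial <- Inf
  if (!is.finite(f_target)) f_target <- Inf
  if (f_trial < f_target) list(x = trial, fitness = f_trial)
  else list(x = target, fitness = f_target)
}

#' Run differential evolution
#'
#' Minimizes `fn` over a box by rand/1/bin DE. Each generation mutates,
#' crosses over, repairs and greedily selects every individual in index
#' order. The `repair` hook is applied to every trial vector before
#' evaluation (the restriction step used by the sectional segmenter);
#' the default projects onto the box bounds.
#'
#' @param fn fitness function taking a numeric vector, returning a
#'   scalar (minimized).
#' @param lower,upper numeric vectors of finite box bounds.
#' @param config a [de_config()].
#' @param init optional numeric matrix (`np` rows) of initial
#'   individuals inside the bounds; `NULL` draws uniformly in the box.
#' @param repair function mapping a trial vector into the feasible set.
#' @return list with `best` (vector), `best_fitness`, `trace` (data
#'   frame `generation,best,mean`; generation 0 is the initial
#'   population), `fitness_history` (matrix, one row per generation
#'   including generation 0, one column per individual), `population`,
#'   `fitnesses`, and `generations_run`.
#' @export
run_de <- function(fn, lower, upper, config = de_config(), init = NULL,
                   repair = NULL) {
  d <- length(lower)
  if (d < 1L || length(upper) != d)
    stop("lower and upper must be equal-length, nonempty", call. = FALSE)
  if (!all(is.finite(lower)) || !all(is.finite(upper)) ||
      any(lower > upper))
    stop("bounds must be finite with lower <= upper", call. = FALSE)
  np <- config$np
  if (is.null(repair))
    repair <- function(v) pmin(pmax(v, lower), upper)
  if (!is.null(config$seed)) {
    old_seed <- get_rng_state()
    on.exit(restore_rng_state(old_seed), add = TRUE)
    set.seed(config$seed)
  }
  if (is.null(init)) {
    pop <- matrix(stats::runif(np * d, rep(lower, each = np),
                               rep(upper, each = np)), np, d)
  } else {
    pop <- as.matrix(init)
    if (nrow(pop) != np || ncol(pop) != d)
      stop("init must be an np x d matrix", call. = FALSE)
  }
  fit <- apply(pop, 1L, function(v) {
    val <- fn(v)
    if (is.finite(val)) val else Inf
  })

  g_total <- config$generations
  hist <- matrix(NA_real_, g_total + 1L, np)
  hist[1L, ] <- fit
  best_trace <- numeric(g_total + 1L)
  mean_trace <- numeric(g_total + 1L)
  best_trace[1L] <- min(fit)
  mean_trace[1L] <- mean(fit)
  stale <- 0L
  gens_run <- 0L

  for (g in seq_len(g_total)) {
    for (i in seq_len(np)) {
      v <- de_mutate(pop, i, config$f)
      u <- de_crossover(pop[i, ], v, config$cr,
                        pure = config$pure_crossover)
      u <- repair(u)
      fu <- fn(u)
      sel <- de_select(pop[i, ], u, fit[i], fu)
      pop[i, ] <- sel$x
      fit[i] <- sel$fitness
    }
    gens_run <- g
    hist[g + 1L, ] <- fit
    best_trace[g + 1L] <- min(fit)
    mean_trace[g + 1L] <- mean(fit)
    if (config$stability_window > 0L) {
      if (best_trace[g + 1L] >= best_trace[g]) stale <- stale + 1L
      else stale <- 0L
      if (stale >= config$stability_window) break
    }
  }
  keep <- seq_len(gens_run + 1L)
  ib <- which.min(fit)
  list(best = pop[ib, ], best_fitness = fit[ib],
       trace = data.frame(generation = keep - 1L,
                          best = best_trace[keep],
                          mean = mean_trace[keep]),
       fitness_history = hist[keep, , drop = FALSE],
       population = pop, fitnesses = fit, generations_run = gens_run)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
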