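#' Search settings for the stochastic pose/shape optimizer
#'
#' Defaults follow a standard real-coded, Holland-style genetic algorithm:
#' tournament selection, blend crossover, per-gene Gaussian mutation and
#' elitism. The seed makes every search reproducible.
#'
#' @param pop_size population size.
#' @param generations number of generations.
#' @param tournament tournament size for selection.
#' @param crossover_rate probability a pair of parents is recombined.
#' @param mutation_rate per-gene mutation probability.
#' @param mutation_sd_frac mutation standard deviation as a fraction of the
#'   bound width of each gene.
#' @param elitism number of best individuals copied unchanged.
#' @param seed integer RNG seed (`NULL` uses the current RNG state).
#' @param polish run a derivative-free Nelder-Mead descent from the GA
#'   optimum (off by default).
#' @param polish_maxit iteration budget of the polish step.
#' @param pose_bounds length-6 half-widths `(mm, mm, mm, deg, deg, deg)` of
#'   the pose search box centered on the initial pose (used by the
#'   registration wrappers).
#' @param coeff_bound_sd shape-coefficient bounds in units of mode SD.
#' @return A list of class `search_settings`.
#' @export
search_settings <- function(pop_size = 60, generations = 40, tournament = 3,
                            crossover_rate = 0.9, mutation_rate = 0.1,
                            mutation_sd_frac = 0.05, elitism = 2,
                            seed = NULL, polish = FALSE, polish_maxit = 80,
                            pose_bounds = c(3, 3, 3, 3, 3, 3),
                            coeff_bound_sd = 3) {
  structure(list(pop_size = pop_size, generations = generations,
                 tournament = tournament, crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 mutation_sd_frac = mutation_sd_frac, elitism = elitism,
                 seed = seed, polish = polish, polish_maxit = polish_maxit,
                 pose_bounds = pose_bounds, coeff_bound_sd = coeff_bound_sd),
            class = "search_settings")
}

#' Bounded genetic-algorithm minimization
#'
#' Real-coded GA with tournament selection, blend crossover, Gaussian
#' mutation and elitism; deterministic for a fixed `settings$seed`. Returns
#' the best-ever individual, which by elitism is never worse than the best
#' of the initial population.
#'
#' @param cost function mapping a length-d numeric vector to a scalar cost
#'   (evaluable everywhere inside the bounds; non-finite values are treated
#'   as a large penalty).
#' @param lower,upper finite length-d bounds.
#' @param settings a [search_settings()] object.
#' @param init optional matrix (or vector) of individuals seeded into the
#'   initial population.
#' @return List with `par`, `value`, `trace` (best cost per generation) and
#'   `population` (final population matrix, costs in attribute `costs`).
#' @export
ga_optimize <- function(cost, lower, upper, settings = search_settings(),
                        init = NULL) {
  stopifnot(length(lower) == length(upper), all(is.finite(lower)),
            all(is.finite(upper)), all(upper >= lower))
  d <- length(lower)
  if (!is.null(settings$seed)) set.seed(settings$seed)
  np <- settings$pop_size
  width <- upper - lower
  evalc <- function(v) {
    x <- tryCatch(cost(v), error = function(e) Inf)
    if (!is.finite(x)) 1e10 else x
  }
  pop <- matrix(runif(np * d), np, d)
  pop <- sweep(sweep(pop, 2, width, "*"), 2, lower, "+")
  if (!is.null(init)) {
    init <- matrix(init, ncol = d)
    ni <- min(nrow(init), np)
    pop[seq_len(ni), ] <- pmin(pmax(init[seq_len(ni), , drop = FALSE],
                                    matrix(lower, ni, d, byrow = TRUE)),
                               matrix(upper, ni, d, byrow = TRUE))
  }
  costs <- apply(pop, 1, evalc)
  best_i <- which.min(costs)
  best <- list(par = pop[best_i, ], value = costs[best_i])
  trace <- numeric(settings$generations)
  select <- function() {
    cand <- sample.int(np, settings$tournament, replace = TRUE)
    cand[which.min(costs[cand])]
  }
  for (g in seq_len(settings$generations)) {
    ord <- order(costs)
    newpop <- matrix(0, np, d)
    ne <- min(settings$elitism, np)
    newpop[seq_len(ne), ] <- pop[ord[seq_len(ne)], , drop = FALSE]
    i <- ne
    while (i < np) {
      p1 <- pop[select(), ]; p2 <- pop[select(), ]
      if (runif(1) < settings$crossover_rate) {
        u <- runif(d, -0.25, 1.25)   # blend (BLX-style) crossover
        c1 <- p1 + u * (p2 - p1)
        c2 <- p2 + u * (p1 - p2)
      } else {
        c1 <- p1; c2 <- p2
      }
      for (ch in list(c1, c2)) {
        if (i >= np) break
        mut <- runif(d) < settings$mutation_rate
        if (any(mut))
          ch[mut] <- ch[mut] + rnorm(sum(mut), 0,
                                     settings$mutation_sd_frac * width[mut])
        i <- i + 1
        newpop[i, ] <- pmin(pmax(ch, lower), upper)
      }
    }
    pop <- newpop
    costs <- apply(pop, 1, evalc)
    gi <- which.min(costs)
    if (costs[gi] < best$value)
      best <- list(par = pop[gi, ], value = costs[gi])
    trace[g] <- best$value
  }
  if (isTRUE(settings$polish)) {
    pol <- stats::optim(best$par, function(v) {
      if (any(v < lower) || any(v > upper)) return(1e10)
      evalc(v)
    }, method = "Nelder-Mead",
    control = list(maxit = settings$polish_maxit))
    if (pol$value < best$value)
      best <- list(par = pmin(pmax(pol$par, lower), upper),
                   value = pol$value)
  }
  attr(pop, "costs") <- costs
  list(par = best$par, value = best$value, trace = trace, population = pop)
}
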