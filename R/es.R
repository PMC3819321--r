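#' Mutation and recombination operators of the Evolution Strategy
#'
#' `es_mutate()` multiplies each factor by `2^u` with `u` uniform on
#' `(-delta, delta)` -- mutation is multiplicative in log2 space, respecting
#' the geometry of scaling factors -- and re-canonicalizes the child to
#' product 1. `es_recombine()` performs per-coordinate uniform crossover
#' between two parents, followed by the same canonicalization. Both draw
#' from R's current random stream; wrap in [withr::with_seed()] for
#' reproducibility.
#'
#' @param y,a,b Positive numeric factor vectors (same length for `a`, `b`).
#' @param delta Mutation magnitude in log2 units (default 0.02).
#' @return A positive numeric vector with product 1.
#' @export
es_mutate <- function(y, delta = 0.02) {
  if (delta <= 0) abort("`delta` must be positive.")
  child <- y * 2^runif(length(y), -delta, delta)
  child / exp(mean(log(child)))
}

#' @rdname es_mutate
#' @export
es_recombine <- function(a, b) {
  if (length(a) != length(b)) abort("parents must have the same dimension.")
  pick <- runif(length(a)) < 0.5
  child <- ifelse(pick, a, b)
  child / exp(mean(log(child)))
}

#' Evolution Strategy normalization
#'
#' Stochastic search over product-1 scaling-factor vectors that directly
#' maximizes the number of uniform genes (the fitness of a candidate vector
#' is the uniform-gene count of the scaled matrix). The population starts
#' from `init_size` random vectors (`2^r`, `r` uniform on `[-0.5, 0.5)`)
#' plus the identity -- or from user-supplied previous solutions -- and is
#' grown, sorted, and trimmed in rounds. Each round adds four offspring
#' classes: (a) 5 mutants of the current best, (b) 5 mutants of parents
#' drawn from ranks 2-10, (c) 5 mutants of parents drawn from the remaining
#' ranks, (d) 5 uniform-crossover recombinants of two distinct random
#' individuals. Parents and offspring are then sorted together by
#' decreasing fitness (ties kept in insertion order) and truncated to
#' `population_cap`. The search stops after `convergence_rounds` rounds
#' without improvement of the best fitness, after `max_rounds` rounds, or
#' when `time_budget` seconds have elapsed. Elitist truncation makes the
#' best fitness non-decreasing; fitness is invariant to a global rescaling
#' of the factor vector, which justifies the product-1 canonicalization.
#'
#' @param data An expression tibble.
#' @param cov_cutoff CoV cutoff defining uniform genes (default 0.25).
#' @param delta Mutation magnitude in log2 units (default 0.02).
#' @param population_cap Population size after truncation (default 200).
#' @param init_size Number of random initial individuals (default 10).
#' @param convergence_rounds Improvement-free rounds before stopping
#'   (default 100).
#' @param max_rounds Hard cap on rounds (default `Inf`).
#' @param time_budget Optional wall-clock budget in seconds.
#' @param seed Integer seed; the whole trajectory is reproducible under it.
#' @param init_factors Optional list of factor tibbles (or named numeric
#'   vectors) used as the initial population instead of random vectors; the
#'   identity individual is always added, so the trajectory starts at the
#'   unnormalized fitness.
#' @return A `tx_norm` result. `details$trajectory` is a tibble
#'   (`round`, `best_fitness`), `details$fitness` the final best fitness.
#' @export
normalize_es <- function(data, cov_cutoff = 0.25, delta = 0.02,
                         population_cap = 200L, init_size = 10L,
                         convergence_rounds = 100L, max_rounds = Inf,
                         time_budget = NULL, seed = 1L, init_factors = NULL) {
  data <- check_expression(data)
  m <- expr_matrix(data)
  samples <- colnames(m)
  n <- length(samples)
  fitness <- uniform_counter(m, cov_cutoff)
  t0 <- Sys.time()

  run <- function() {
    canon <- function(y) y / exp(mean(log(y)))
    if (is.null(init_factors)) {
      pop <- lapply(seq_len(init_size), function(i) canon(2^runif(n, -0.5, 0.5)))
    } else {
      pop <- lapply(init_factors, function(f) canon(unname(factor_vector(f, data))))
    }
    pop <- c(pop, list(rep(1, n)))
    fit <- vapply(pop, fitness, double(1L))
    id <- seq_along(pop)
    next_id <- length(pop) + 1L
    ord <- order(-fit, id)
    pop <- pop[ord]; fit <- fit[ord]; id <- id[ord]

    trajectory <- integer()
    stale <- 0L
    round <- 0L
    repeat {
      round <- round + 1L
      npop <- length(pop)
      parents <- list()
      # (a) mutants of the best
      parents <- c(parents, rep(list(pop[[1L]]), 5L))
      # (b) mutants of parents ranked 2..10
      mid <- if (npop >= 2L) 2L:min(10L, npop) else 1L
      parents <- c(parents, pop[sample_ranks(mid, 5L)])
      # (c) mutants of the remaining individuals
      rest <- if (npop >= 11L) 11L:npop else seq_len(npop)
      parents <- c(parents, pop[sample_ranks(rest, 5L)])
      children <- lapply(parents, es_mutate, delta = delta)
      # (d) recombinants of two distinct random individuals
      for (i in seq_len(5L)) {
        pair <- if (npop >= 2L) sample(npop, 2L) else c(1L, 1L)
        children <- c(children, list(es_recombine(pop[[pair[1L]]], pop[[pair[2L]]])))
      }
      cfit <- vapply(children, fitness, double(1L))
      cid <- seq.int(next_id, length.out = length(children))
      next_id <- next_id + length(children)

      pop <- c(pop, children); fit <- c(fit, cfit); id <- c(id, cid)
      ord <- order(-fit, id)
      keep <- head(ord, population_cap)
      pop <- pop[keep]; fit <- fit[keep]; id <- id[keep]

      best_now <- fit[1L]
      improved <- length(trajectory) && best_now > max(trajectory)
      if (!length(trajectory)) improved <- TRUE
      stale <- if (improved) 0L else stale + 1L
      trajectory <- c(trajectory, best_now)
      if (stale >= convergence_rounds) break
      if (round >= max_rounds) break
      if (!is.null(time_budget) &&
          as.double(difftime(Sys.time(), t0, units = "secs")) > time_budget) break
    }
    list(best = pop[[1L]], fitness = fit[1L], trajectory = trajectory,
         rounds = round)
  }
  res <- withr::with_seed(seed, run())

  factors <- scaling_factors(setNames(res$best, samples), adjusted = TRUE)
  new_tx_norm(
    "es", apply_factors(data, factors), factors,
    details = list(
      fitness = res$fitness, rounds = res$rounds,
      trajectory = tibble(round = seq_along(res$trajectory),
                          best_fitness = res$trajectory),
      cov_cutoff = cov_cutoff, delta = delta, seed = seed
    )
  )
}

# sample k ranks (with replacement) from an index vector; handles length 1
sample_ranks <- function(idx, k) {
  if (length(idx) == 1L) return(rep(idx, k))
  idx[sample.int(length(idx), k, replace = TRUE)]
}
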