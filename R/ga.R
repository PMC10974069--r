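#' Genetic-algorithm configuration for wavelength selection
#'
#' Defaults follow the tuned values used throughout: population 40, crossover
#' probability 0.5, per-gene mutation probability 0.01, 100 generations, and
#' 10 independent repeats whose best result (by fitness) is kept.
#'
#' @param population_size number of chromosomes per generation (>= 2).
#' @param crossover_prob probability that a mated pair undergoes uniform
#'   crossover.
#' @param mutation_prob per-gene bit-flip probability.
#' @param n_generations fixed generation budget (no early stopping).
#' @param n_repeats independent GA restarts aggregated by [select_bands()].
#' @param init_inclusion_prob per-gene Bernoulli inclusion probability for the
#'   initial population (~10% of channels, matching the scale of selected
#'   band counts).
#' @param min_bands smallest admissible number of selected channels.
#' @param elitism number of best chromosomes carried forward unchanged.
#' @param seed integer seed; the whole selection is a pure function of
#'   (X, y, config).
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population_size = 40, crossover_prob = 0.5,
                      mutation_prob = 0.01, n_generations = 100,
                      n_repeats = 10, init_inclusion_prob = 0.10,
                      min_bands = 2, elitism = 1, seed = 1L) {
  stopifnot(population_size >= 2,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            init_inclusion_prob >= 0, init_inclusion_prob <= 1,
            n_generations >= 1, n_repeats >= 1, min_bands >= 1, elitism >= 0)
  structure(
    list(population_size = as.integer(population_size),
         crossover_prob = crossover_prob, mutation_prob = mutation_prob,
         n_generations = as.integer(n_generations),
         n_repeats = as.integer(n_repeats),
         init_inclusion_prob = init_inclusion_prob,
         min_bands = as.integer(min_bands), elitism = as.integer(elitism),
         seed = as.integer(seed)),
    class = "ga_config"
  )
}

#' GA fitness: cross-validated RMSE of PLSR on a channel subset
#'
#' Runs [cross_validate()] on the column subset selected by `mask` and returns
#' the RMSEcv at its optimal component count. Lower is fitter. Masks with
#' fewer than `min_bands` channels receive `Inf`.
#'
#' @param mask logical vector over channels.
#' @param X,y data.
#' @param folds CV fold labels (default leave-one-out).
#' @param max_ncomp passed to [cross_validate()] (capped at the subset width).
#' @param min_bands smallest admissible mask cardinality.
#' @return RMSEcv (response units), or `Inf` for an inadmissible mask.
#' @export
ga_fitness <- function(mask, X, y, folds = NULL, max_ncomp = NULL,
                       min_bands = 2) {
  nb <- sum(mask)
  if (nb < min_bands) return(Inf)
  n <- nrow(X)
  if (is.null(folds)) folds <- cv_folds(n, "loo")
  n_train_min <- n - max(tabulate(folds))
  if (is.null(max_ncomp)) max_ncomp <- min(10L, n - 2L)
  mc <- min(max_ncomp, n_train_min - 1L, nb)
  cv <- cross_validate(X[, mask, drop = FALSE], y, max_ncomp = mc,
                       folds = folds)
  cv$rmse_cv
}

resample_admissible <- function(p, prob, min_bands) {
  repeat {
    m <- stats::runif(p) < prob
    if (sum(m) >= min_bands) return(m)
  }
}

#' Run one genetic-algorithm search for an informative band subset
#'
#' Binary chromosomes over channels; initialization by per-gene
#' Bernoulli(`init_inclusion_prob`) with inadmissible individuals resampled.
#' Each generation: fitness evaluation, tournament selection (size 2),
#' uniform crossover on mated pairs with probability `crossover_prob`,
#' per-gene bit-flip mutation, and elitist carry-forward. Runs exactly
#' `n_generations` generations.
#'
#' @param X,y data (modeling set).
#' @param config a [ga_config()].
#' @param folds CV fold labels used by the fitness (default leave-one-out).
#' @param max_ncomp component-count cap passed to the fitness.
#' @return A list of class `ga_run` with `final_mask`, `final_fitness`,
#'   `best_fitness_per_generation`, `best_mask_per_generation` (logical
#'   matrix, generations by channels).
#' @export
ga_evolve <- function(X, y, config = ga_config(), folds = NULL,
                      max_ncomp = NULL) {
  stopifnot(inherits(config, "ga_config"))
  p <- ncol(X)
  if (p < config$min_bands) stop("fewer channels than min_bands")
  if (is.null(folds)) folds <- cv_folds(nrow(X), "loo")
  set.seed(config$seed)

  npop <- config$population_size
  pop <- t(vapply(seq_len(npop), function(i)
    resample_admissible(p, config$init_inclusion_prob, config$min_bands),
    logical(p)))
  if (is.null(max_ncomp)) max_ncomp <- min(10L, nrow(X) - 2L)
  # batch compiled route; ga_fitness() is the equivalent per-mask R route
  eval_fitness <- function(masks)
    .ga_population_fitness(as.matrix(X), as.numeric(y), masks,
                           as.integer(folds), as.integer(max_ncomp),
                           as.integer(config$min_bands))
  fit <- eval_fitness(pop)

  best_trace <- numeric(config$n_generations)
  best_masks <- matrix(FALSE, config$n_generations, p)

  for (g in seq_len(config$n_generations)) {
    ord <- order(fit)
    elite_idx <- ord[seq_len(min(config$elitism, npop))]
    best_trace[g] <- fit[ord[1L]]
    best_masks[g, ] <- pop[ord[1L], ]

    n_children <- npop - length(elite_idx)
    children <- matrix(FALSE, n_children, p)
    i <- 1L
    while (i <= n_children) {
      # tournament selection, size 2
      pick <- function() {
        c2 <- sample.int(npop, 2L, replace = TRUE)
        c2[which.min(fit[c2])]
      }
      pa <- pop[pick(), ]; pb <- pop[pick(), ]
      if (stats::runif(1) < config$crossover_prob) {
        swap <- stats::runif(p) < 0.5
        tmp <- pa[swap]; pa[swap] <- pb[swap]; pb[swap] <- tmp
      }
      mut <- function(m) xor(m, stats::runif(p) < config$mutation_prob)
      children[i, ] <- mut(pa)
      if (i + 1L <= n_children) children[i + 1L, ] <- mut(pb)
      i <- i + 2L
    }
    child_fit <- if (n_children > 0) eval_fitness(children) else numeric(0)
    pop <- rbind(pop[elite_idx, , drop = FALSE], children)
    fit <- c(fit[elite_idx], child_fit)
  }

  final <- which.min(fit)
  structure(
    list(final_mask = pop[final, ], final_fitness = fit[final],
         best_fitness_per_generation = best_trace,
         best_mask_per_generation = best_masks),
    class = "ga_run"
  )
}

#' Select wavelength bands by repeated GA runs
#'
#' Runs [ga_evolve()] `n_repeats` times with sub-seeds `seed + r - 1` and
#' returns the best final chromosome across repeats (lowest fitness). The
#' per-repeat band counts and per-channel selection frequencies are retained
#' for reporting.
#'
#' @inheritParams ga_evolve
#' @return A list of class `ga_selection` with `mask` (logical over channels),
#'   `fitness` (its RMSEcv), `repeat_fitness`, `repeat_band_counts`,
#'   `selection_frequency` (per-channel fraction of repeats selecting the
#'   channel), and `best_repeat`.
#' @export
select_bands <- function(X, y, config = ga_config(), folds = NULL,
                         max_ncomp = NULL) {
  stopifnot(inherits(config, "ga_config"))
  runs <- lapply(seq_len(config$n_repeats), function(r) {
    cfg_r <- config
    cfg_r$seed <- config$seed + r - 1L
    ga_evolve(X, y, cfg_r, folds = folds, max_ncomp = max_ncomp)
  })
  fits <- vapply(runs, `[[`, numeric(1), "final_fitness")
  masks <- do.call(rbind, lapply(runs, `[[`, "final_mask"))
  best <- which.min(fits)
  structure(
    list(mask = runs[[best]]$final_mask,
         fitness = fits[best],
         repeat_fitness = fits,
         repeat_band_counts = as.integer(rowSums(masks)),
         selection_frequency = colMeans(masks),
         best_repeat = best,
         runs = runs),
    class = "ga_selection"
  )
}

#' @export
print.ga_selection <- function(x, ...) {
  cat(sprintf(
    "<ga_selection> %d/%d channels selected, RMSEcv = %.4g (best of %d repeats)\n",
    sum(x$mask), length(x$mask), x$fitness, length(x$repeat_fitness)))
  invisible(x)
}
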