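#' Genetic-algorithm configuration for feature-subset search
#'
#' @param population individuals per generation (>= 2).
#' @param generations number of generations.
#' @param crossover_rate probability of uniform crossover per offspring.
#' @param mutation_rate per-bit flip probability; default 1/k features.
#' @param elitism number of elite individuals carried over (the raced elite).
#' @param seed RNG seed.
#' @return a `ga_config` list.
#' @export
ga_config <- function(population = 32, generations = 20, crossover_rate = 0.8,
                      mutation_rate = NULL, elitism = 1, seed = 1) {
  stopifnot(population >= 2, generations >= 0,
            crossover_rate >= 0, crossover_rate <= 1)
  structure(as.list(environment()), class = "ga_config")
}

mask_key <- function(mask) paste(as.integer(mask), collapse = "")

# Memoised per-protein MCC evaluator for feature masks: fold i = the i-th
# protein (in a fixed seeded shuffle shared by every candidate, so races
# compare on common folds).
make_fold_evaluator <- function(instances, learner, feature_names,
                                fold_order, target_positive_fraction = NULL,
                                seed = 1) {
  cache <- new.env(parent = emptyenv())
  n_trainings <- 0L
  eval_fold <- function(mask, fold) {
    key <- mask_key(mask)
    hit <- cache[[key]]
    if (!is.null(hit) && !is.na(hit[fold])) return(hit[fold])
    if (is.null(hit)) hit <- rep(NA_real_, length(fold_order))
    p <- fold_order[fold]
    feats <- feature_names[mask]
    test <- instances[instances$protein_id == p, , drop = FALSE]
    train <- instances[instances$protein_id != p, , drop = FALSE]
    if (!is.null(target_positive_fraction)) {
      train <- undersample(train, target_positive_fraction,
                           seed = seed * 10000L + fold)
    }
    model <- learner$fit(train[, c("label", feats)], features = feats)
    n_trainings <<- n_trainings + 1L
    pred <- learner$margin(model, test[, feats, drop = FALSE]) >= 0
    hit[fold] <- classification_stats(confusion_counts(test$label, pred))$mcc
    cache[[key]] <- hit
    hit[fold]
  }
  list(eval_fold = eval_fold, trainings = function() n_trainings)
}

repair_mask <- function(mask) {
  if (!any(mask)) mask[sample(length(mask), 1)] <- TRUE
  mask
}

breed <- function(parents, cfg, k) {
  mut <- cfg$mutation_rate %||% (1 / k)
  a <- parents[[sample(length(parents), 1)]]
  b <- parents[[sample(length(parents), 1)]]
  child <- if (runif(1) < cfg$crossover_rate) {
    pick <- runif(k) < 0.5
    ifelse(pick, a, b)
  } else a
  flip <- runif(k) < mut
  repair_mask(xor(child, flip))
}

#' Genetic feature-subset search with elite racing
#'
#' Evolves feature masks by uniform crossover and per-bit mutation; each
#' generation's individuals are raced (see [race()]) against the best
#' subset found so far on the shared leave-one-protein-out folds, so
#' clearly inferior subsets are abandoned after a few folds. Fitness is
#' the mean per-protein MCC.
#'
#' @param instances instance tibble with per-protein grouping.
#' @param learner learner adapter.
#' @param feature_names features over which to search; defaults to all.
#' @param cfg a [ga_config()].
#' @param delta racing confidence parameter (0 = full evaluation).
#' @param target_positive_fraction optional training-fold under-sampling.
#' @param initial_population optional list of starting masks (logical
#'   vectors over `feature_names`); random when `NULL`. Supplying every
#'   non-empty mask with `generations = 0` and `delta = 0` turns the search
#'   into exhaustive enumeration.
#' @return a `radt_ga` list: `best_mask` (named logical), `best_features`,
#'   `best_score`, `history` (per-generation elite fitness), `summary`
#'   racing summaries, `n_trainings`.
#' @export
ga_search <- function(instances, learner = adtree_learner(),
                      feature_names = NULL, cfg = ga_config(), delta = 0.05,
                      target_positive_fraction = NULL,
                      initial_population = NULL) {
  feature_names <- feature_names %||% instance_features(instances)
  k <- length(feature_names)
  if (k < 2) abort("feature search needs >= 2 features")
  proteins <- unique(instances$protein_id)
  if (length(proteins) < 2) abort("feature search needs >= 2 proteins")
  with_seed(cfg$seed, {
    fold_order <- sample(proteins)
    N <- length(fold_order)
    ev <- make_fold_evaluator(instances, learner, feature_names, fold_order,
                              target_positive_fraction, seed = cfg$seed)
    population <- initial_population %||%
      purrr::map(seq_len(cfg$population), ~ repair_mask(runif(k) < 0.5))
    # seed the elite with the first individual, fully evaluated via race
    elite <- population[[1]]
    r0 <- race(population[-1], elite, ev$eval_fold, N, delta = delta)
    elite <- r0$elite
    elite_mean <- r0$elite_mean
    history <- tibble::tibble(generation = 0L, elite_mean = elite_mean,
                              elite_mask = mask_key(elite))
    summaries <- list(r0$summary)
    for (g in seq_len(cfg$generations)) {
      parent_pool <- c(list(elite), population)
      offspring <- purrr::map(seq_len(cfg$population),
                              ~ breed(parent_pool, cfg, k))
      rg <- race(offspring, elite, ev$eval_fold, N, delta = delta)
      elite <- rg$elite
      elite_mean <- rg$elite_mean
      population <- offspring
      history <- dplyr::bind_rows(history,
        tibble::tibble(generation = g, elite_mean = elite_mean,
                       elite_mask = mask_key(elite)))
      summaries[[g + 1]] <- rg$summary
    }
    structure(
      list(best_mask = setNames(elite, feature_names),
           best_features = feature_names[elite],
           best_score = elite_mean,
           history = history,
           summaries = summaries,
           n_trainings = ev$trainings()),
      class = "radt_ga"
    )
  })
}

#' @export
print.radt_ga <- function(x, ...) {
  cat(sprintf("<radt_ga> best subset {%s}, mean MCC %.3f (%d model fits)\n",
              paste(x$best_features, collapse = ", "), x$best_score,
              x$n_trainings))
  invisible(x)
}

#' Per-feature selection tally over repeated runs
#'
#' Repeats the genetic search under different seeds (and optionally
#' different learners) and counts how often each feature appears in the
#' final subset - the "how consistently is this feature selected" view of
#' a feature-selection experiment.
#'
#' @param instances instance tibble.
#' @param learners list of learner adapters.
#' @param runs seeded runs per learner.
#' @param cfg base [ga_config()]; the per-run seed is derived from it.
#' @param ... passed to [ga_search()].
#' @return tibble: feature, count, n_runs, plus one logical column per
#'   run/learner combination.
#' @export
ga_feature_tally <- function(instances, learners = list(adtree_learner()),
                             runs = 5, cfg = ga_config(), ...) {
  feature_names <- instance_features(instances)
  cols <- list()
  for (li in seq_along(learners)) {
    for (r in seq_len(runs)) {
      cfg_r <- cfg
      cfg_r$seed <- cfg$seed + 1000L * li + r
      res <- ga_search(instances, learners[[li]], feature_names,
                       cfg = cfg_r, ...)
      cols[[sprintf("%s_run%d", learners[[li]]$name, r)]] <- res$best_mask
    }
  }
  sel <- do.call(cbind, cols)
  tibble::tibble(feature = feature_names,
                 count = unname(rowSums(sel)),
                 n_runs = ncol(sel)) |>
    dplyr::bind_cols(tibble::as_tibble(sel)) |>
    dplyr::arrange(dplyr::desc(.data$count))
}
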