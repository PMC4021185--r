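#' Leave-one-protein-out cross-validation
#'
#' Each fold holds out every residue instance of one protein, trains the
#' learner on the remainder (optionally under-sampled to a target class
#' balance - the held-out test residues are never resampled), and scores
#' the held-out protein. The summary score is the mean MCC over proteins.
#'
#' @param instances instance tibble (see [build_instances()] or
#'   [make_planted_instances()]).
#' @param learner a learner adapter (default [adtree_learner()]).
#' @param features feature columns to use; defaults to all.
#' @param target_positive_fraction if non-`NULL`, under-sample each
#'   training fold to this positive fraction.
#' @param seed seed for the per-fold under-sampling.
#' @return a `radt_lopo` tibble: one row per protein with confusion counts
#'   and metrics; mean MCC in `attr(, "mean_mcc")` and via [glance()].
#' @export
lopo_cv <- function(instances, learner = adtree_learner(), features = NULL,
                    target_positive_fraction = NULL, seed = 1) {
  proteins <- unique(instances$protein_id)
  if (length(proteins) < 2) abort("leave-one-protein-out needs >= 2 proteins")
  features <- features %||% instance_features(instances)
  rows <- purrr::imap(proteins, function(p, fold) {
    test <- instances[instances$protein_id == p, , drop = FALSE]
    train <- instances[instances$protein_id != p, , drop = FALSE]
    if (nrow(test) == 0) {
      warn(sprintf("protein %s has no instances; skipped", p))
      return(NULL)
    }
    if (!is.null(target_positive_fraction)) {
      train <- undersample(train, target_positive_fraction,
                           seed = seed * 10000L + fold)
    }
    model <- learner$fit(train[, c("label", features)], features = features)
    pred <- learner$margin(model, test[, features, drop = FALSE]) >= 0
    cc <- confusion_counts(test$label, pred)
    dplyr::bind_cols(tibble::tibble(protein_id = p, n = nrow(test)), cc,
                     classification_stats(cc))
  })
  out <- purrr::list_rbind(purrr::compact(rows))
  attr(out, "mean_mcc") <- mean(out$mcc)
  attr(out, "learner") <- learner$name
  class(out) <- c("radt_lopo", class(out))
  out
}

#' @export
glance.radt_lopo <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x), learner = attr(x, "learner"),
    mean_mcc = attr(x, "mean_mcc"),
    mean_tpr = mean(x$tpr), mean_tnr = mean(x$tnr),
    mean_prc = mean(x$prc), mean_f1 = mean(x$f1)
  )
}

#' Class-distribution sweep
#'
#' Re-runs leave-one-protein-out cross-validation with the training folds
#' under-sampled to each target positive fraction, recording the mean true
#' positive and true negative rates. The crossing fraction - where the two
#' rates meet, giving a balanced prediction - is linearly interpolated from
#' the sign change of TPr - TNr (argmin of |TPr - TNr| when the sweep does
#' not bracket a crossing).
#'
#' @param instances instance tibble.
#' @param fractions positive fractions to sweep (default 0.30 to 0.70).
#' @param learner learner adapter.
#' @param features feature columns; defaults to all.
#' @param seed under-sampling seed.
#' @return a `radt_sweep` tibble (fraction, tpr, tnr, mcc) with the
#'   crossing fraction in `attr(, "crossing")`.
#' @export
distribution_sweep <- function(instances, fractions = seq(0.30, 0.70, by = 0.10),
                               learner = adtree_learner(), features = NULL,
                               seed = 1) {
  stopifnot(all(fractions > 0 & fractions < 1))
  rows <- purrr::imap(fractions, function(f, i) {
    cv <- lopo_cv(instances, learner, features,
                  target_positive_fraction = f, seed = seed + i)
    tibble::tibble(fraction = f, tpr = mean(cv$tpr), tnr = mean(cv$tnr),
                   mcc = attr(cv, "mean_mcc"))
  })
  out <- purrr::list_rbind(rows)
  attr(out, "crossing") <- sweep_crossing(out$fraction, out$tpr, out$tnr)
  class(out) <- c("radt_sweep", class(out))
  out
}

sweep_crossing <- function(fraction, tpr, tnr) {
  d <- tpr - tnr
  s <- which(diff(sign(d)) != 0)
  if (length(s) > 0) {
    i <- s[1]
    # linear interpolation of the sign change
    fraction[i] + (0 - d[i]) * (fraction[i + 1] - fraction[i]) / (d[i + 1] - d[i])
  } else {
    fraction[which.min(abs(d))]
  }
}

#' Iterative removal of the worst-scoring proteins
#'
#' At each step, runs leave-one-protein-out cross-validation, removes the
#' protein with the lowest MCC (ties broken by lexicographically smallest
#' id), and records the mean MCC of the remaining proteins. Optionally
#' tracks the per-step MCCs of a fixed subset of proteins for as long as
#' they remain in the set.
#'
#' @param instances instance tibble.
#' @param learner learner adapter.
#' @param steps number of removal steps (default: until 2 proteins remain).
#' @param tracked character vector of protein ids to track.
#' @param features feature columns; defaults to all.
#' @param target_positive_fraction optional training-fold under-sampling.
#' @param seed under-sampling seed.
#' @return a `radt_removal` tibble: step, removed, mean_mcc_after,
#'   n_remaining; tracked per-step scores in `attr(, "tracked")`.
#' @export
iterative_removal <- function(instances, learner = adtree_learner(),
                              steps = NULL, tracked = NULL, features = NULL,
                              target_positive_fraction = NULL, seed = 1) {
  proteins <- unique(instances$protein_id)
  if (length(proteins) < 3) abort("iterative removal needs >= 3 proteins")
  steps <- steps %||% (length(proteins) - 2L)
  steps <- min(steps, length(proteins) - 2L)
  current <- instances
  trace <- vector("list", steps)
  tracked_rows <- list()
  for (k in seq_len(steps)) {
    cv <- lopo_cv(current, learner, features,
                  target_positive_fraction = target_positive_fraction,
                  seed = seed + k)
    worst <- cv$protein_id[order(cv$mcc, cv$protein_id)][1]
    remain <- cv[cv$protein_id != worst, , drop = FALSE]
    trace[[k]] <- tibble::tibble(step = k, removed = worst,
                                 mean_mcc_after = mean(remain$mcc),
                                 n_remaining = nrow(remain))
    if (!is.null(tracked)) {
      still <- cv[cv$protein_id %in% tracked, c("protein_id", "mcc")]
      if (nrow(still) > 0) {
        still$step <- k
        tracked_rows[[k]] <- still
      }
    }
    current <- current[current$protein_id != worst, , drop = FALSE]
  }
  out <- purrr::list_rbind(trace)
  attr(out, "tracked") <- purrr::list_rbind(tracked_rows)
  class(out) <- c("radt_removal", class(out))
  out
}
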