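# Hoeffding racing for model selection over a finite, known set of
# cross-validation folds. The classic race eliminates a candidate when its
# optimistic bound x_bar + epsilon cannot beat the leader; with the fold
# count N known, the bound is tightened to a weighted average of the
# evaluated empirical mean and the optimistic value of the unevaluated
# remainder: (n/N) x_bar + ((N-n)/N)(x_bar + epsilon). At n = N the bound
# collapses to the empirical mean.

hoeffding_epsilon <- function(n, delta, range = 2) {
  if (delta <= 0) return(Inf)
  range * sqrt(log(2 / delta) / (2 * n))
}

#' Finite-population Hoeffding confidence bounds
#'
#' @param mean empirical mean over the evaluated folds.
#' @param n folds evaluated so far (>= 1).
#' @param N total folds available.
#' @param delta confidence parameter; `delta = 0` gives infinite bounds
#'   (racing degenerates to full evaluation).
#' @param range score range (2 for MCC on \[-1, 1\]).
#' @return the upper bound; `hoeffding_lower_bound` mirrors it downward.
#' @examples
#' hoeffding_upper_bound(0.5, n = 10, N = 20, delta = 2 * exp(-4)) # 0.6
#' @export
hoeffding_upper_bound <- function(mean, n, N, delta = 0.05, range = 2) {
  stopifnot(N >= 1, n <= N)
  if (n < 1) abort("no folds evaluated: bound undefined")
  eps <- hoeffding_epsilon(n, delta, range)
  if (n == N) return(mean)
  (n / N) * mean + ((N - n) / N) * (mean + eps)
}

#' @rdname hoeffding_upper_bound
#' @export
hoeffding_lower_bound <- function(mean, n, N, delta = 0.05, range = 2) {
  stopifnot(N >= 1, n <= N)
  if (n < 1) abort("no folds evaluated: bound undefined")
  eps <- hoeffding_epsilon(n, delta, range)
  if (n == N) return(mean)
  (n / N) * mean + ((N - n) / N) * (mean - eps)
}

#' Race candidates against an elite
#'
#' Folds are evaluated in a fixed shared order (paired racing: every
#' candidate sees the same folds), in batches. A candidate is eliminated
#' as soon as its upper confidence bound falls below the elite's lower
#' bound. Any candidate that survives full evaluation with a higher mean
#' than the elite becomes the new elite.
#'
#' @param candidates list of candidate identifiers (anything
#'   `eval_fold` understands, e.g. logical feature masks).
#' @param elite the current elite candidate; fully evaluated up front.
#' @param eval_fold function(candidate, fold_index) -> score in
#'   \[-range/2, range/2\].
#' @param N total number of folds.
#' @param delta confidence parameter (0 disables elimination).
#' @param range score range (2 for MCC).
#' @param batch folds evaluated between elimination checks.
#' @return list: `elite`, `elite_mean`, `summary` tibble (candidate index,
#'   folds evaluated, mean, eliminated), `n_evaluations` (total fold
#'   evaluations including the elite's).
#' @export
race <- function(candidates, elite, eval_fold, N, delta = 0.05, range = 2,
                 batch = 1L) {
  if (length(candidates) == 0) abort("no candidates to race")
  elite_scores <- vapply(seq_len(N), function(i) eval_fold(elite, i), numeric(1))
  elite_mean <- mean(elite_scores)
  n_eval <- N

  scores <- vector("list", length(candidates))
  alive <- rep(TRUE, length(candidates))
  n_done <- integer(length(candidates))
  fold <- 0L
  while (fold < N && any(alive)) {
    todo <- seq.int(fold + 1L, min(N, fold + batch))
    fold <- max(todo)
    for (ci in which(alive)) {
      scores[[ci]] <- c(scores[[ci]],
                        vapply(todo, function(i) eval_fold(candidates[[ci]], i),
                               numeric(1)))
      n_done[ci] <- fold
      n_eval <- n_eval + length(todo)
    }
    if (fold < N) {
      elite_lower <- hoeffding_lower_bound(mean(elite_scores[seq_len(fold)]),
                                           fold, N, delta, range)
      for (ci in which(alive)) {
        ub <- hoeffding_upper_bound(mean(scores[[ci]]), fold, N, delta, range)
        if (ub < elite_lower) alive[ci] <- FALSE
      }
    }
  }

  means <- vapply(scores, function(s) if (length(s)) mean(s) else NA_real_,
                  numeric(1))
  finished <- alive & n_done == N
  best <- if (any(finished)) which(finished)[which.max(means[finished])] else NA
  new_elite <- elite
  new_mean <- elite_mean
  if (!is.na(best) && means[best] > elite_mean) {
    new_elite <- candidates[[best]]
    new_mean <- means[best]
  }
  list(
    elite = new_elite,
    elite_mean = new_mean,
    summary = tibble::tibble(candidate = seq_along(candidates),
                             n_evaluated = n_done, mean = means,
                             eliminated = !alive),
    n_evaluations = n_eval
  )
}
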