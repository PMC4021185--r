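#' Build labelled training instances from features and labels
#'
#' Inner join of per-residue interface labels and feature rows on the
#' residue key; rows with a missing value in any selected feature are
#' dropped and counted (`attr(, "n_dropped")`).
#'
#' @param features feature tibble from [compute_features()] (one or several
#'   proteins bound together).
#' @param labelings an `interface_labeling` or list of them.
#' @param feature_subset character vector of feature columns to keep;
#'   defaults to every available feature column.
#' @return instance tibble: protein_id, chain_id, seq_num, insertion_code,
#'   label, selected feature columns.
#' @export
build_instances <- function(features, labelings,
                            feature_subset = NULL) {
  if (inherits(labelings, "interface_labeling")) labelings <- list(labelings)
  labels <- purrr::map(labelings, function(l) {
    tibble::tibble(protein_id = l$monomer_id,
                   l$labels[, c("chain_id", "seq_num", "insertion_code")],
                   label = l$labels$label)
  }) |> purrr::list_rbind()
  feature_subset <- feature_subset %||%
    intersect(FEATURE_COLUMNS, names(features))
  missing_cols <- setdiff(feature_subset, names(features))
  if (length(missing_cols) > 0) {
    abort(paste("unknown feature columns:", paste(missing_cols, collapse = ", ")))
  }
  joined <- dplyr::inner_join(
    labels, features,
    by = c("protein_id", "chain_id", "seq_num", "insertion_code")
  )
  if (nrow(joined) == 0) abort("labels and features share no residues")
  keep_cols <- c("protein_id", "chain_id", "seq_num", "insertion_code",
                 "label", feature_subset)
  joined <- joined[, keep_cols]
  complete <- stats::complete.cases(joined[, feature_subset, drop = FALSE])
  out <- joined[complete, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!complete)
  out
}

instance_features <- function(instances) {
  setdiff(names(instances),
          c("protein_id", "chain_id", "seq_num", "insertion_code", "label"))
}

#' Random under-sampling to a target class balance
#'
#' Removes instances of the over-represented class (relative to the target
#' positive fraction) at random, without replacement, until the achieved
#' positive fraction is within one instance of the target. The minority
#' class is never touched and no instances are synthesised. Deterministic
#' under a fixed seed.
#'
#' @param instances instance tibble with a logical `label` column.
#' @param target_positive_fraction desired fraction of positive instances.
#' @param seed RNG seed.
#' @return the under-sampled subset (row order preserved).
#' @export
undersample <- function(instances, target_positive_fraction = 0.5, seed = 1) {
  stopifnot(target_positive_fraction > 0, target_positive_fraction < 1)
  pos <- which(instances$label)
  neg <- which(!instances$label)
  if (length(pos) == 0 || length(neg) == 0) {
    abort("undersample requires both classes present")
  }
  f <- target_positive_fraction
  cur <- length(pos) / nrow(instances)
  keep <- with_seed(seed, {
    if (cur < f) {
      n_neg <- round(length(pos) * (1 - f) / f)
      sort(c(pos, sample(neg, min(n_neg, length(neg)))))
    } else if (cur > f) {
      n_pos <- round(length(neg) * f / (1 - f))
      sort(c(sample(pos, min(n_pos, length(pos))), neg))
    } else {
      sort(c(pos, neg))
    }
  })
  instances[keep, , drop = FALSE]
}
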