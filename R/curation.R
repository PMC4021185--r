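#' Monomer quality-filter configuration
#'
#' Thresholds used to restrict the training universe to high-quality,
#' regular-sized unbound protein structures: resolution at most 3.5 A, at
#' most 5 chains, chain lengths within 100-800 standard residues with a
#' between-chain standard deviation of at most 5, at most 1000 CONECT
#' records and 100 SSBOND records, B-factors present on all atoms, no
#' nucleotide residues, no antibody complexes. Deduplication drops any
#' monomer sharing more than 70% sequence identity with one already kept.
#'
#' @param max_resolution,max_chains,min_chain_len,max_chain_len,max_chain_len_sd,max_connections,max_disulphides
#'   numeric thresholds (see above for defaults).
#' @param require_bfactors,forbid_nucleotides,forbid_antibody logical switches.
#' @param dedup_identity strict identity threshold in (0, 1) above which two
#'   monomers are duplicates.
#' @return a `filter_config` list.
#' @export
filter_config <- function(max_resolution = 3.5,
                          max_chains = 5L,
                          min_chain_len = 100L,
                          max_chain_len = 800L,
                          max_chain_len_sd = 5,
                          max_connections = 1000L,
                          max_disulphides = 100L,
                          require_bfactors = TRUE,
                          forbid_nucleotides = TRUE,
                          forbid_antibody = TRUE,
                          dedup_identity = 0.70) {
  stopifnot(max_resolution > 0, max_chains > 0, min_chain_len > 0,
            max_chain_len >= min_chain_len, max_chain_len_sd > 0,
            max_connections > 0, max_disulphides > 0,
            dedup_identity > 0, dedup_identity < 1)
  structure(as.list(environment()), class = "filter_config")
}

#' Apply the monomer curation filters to a structure
#'
#' All rules are evaluated (no short-circuiting) so `failed_rules` is a
#' complete report. Chain lengths count standard amino acids only. A missing
#' resolution fails the resolution rule.
#'
#' @param s a `radt_structure` (must be a monomer: one COMPND entry).
#' @param cfg a [filter_config()].
#' @return a `filter_verdict`: list with `accepted`, `failed_rules` and a
#'   named `measured` list of the per-rule measured values.
#' @export
apply_curation_filters <- function(s, cfg = filter_config()) {
  if (!is_monomer(s)) {
    abort("curation filters apply to monomers (exactly one COMPND entry)")
  }
  seqs <- chain_sequences(s)
  lens <- nchar(seqs)
  measured <- list(
    resolution = if (is.na(s$resolution)) "missing" else s$resolution,
    n_chains = length(lens),
    min_chain_len = min(lens),
    max_chain_len = max(lens),
    chain_len_sd = if (length(lens) > 1) sd(lens) else 0,
    connections = s$conect_count,
    disulphides = s$ssbond_count,
    all_atoms_have_bfactor = s$all_atoms_have_bfactor,
    has_nucleotides = s$has_nucleotides,
    is_antibody = s$is_antibody_complex
  )
  failed <- character()
  fail <- function(rule, bad) if (bad) failed <<- c(failed, rule)
  fail("resolution", is.na(s$resolution) || s$resolution > cfg$max_resolution)
  fail("n_chains", measured$n_chains > cfg$max_chains)
  fail("min_chain_len", measured$min_chain_len < cfg$min_chain_len)
  fail("max_chain_len", measured$max_chain_len > cfg$max_chain_len)
  fail("chain_len_sd", measured$chain_len_sd > cfg$max_chain_len_sd)
  fail("connections", measured$connections > cfg$max_connections)
  fail("disulphides", measured$disulphides > cfg$max_disulphides)
  fail("bfactors", cfg$require_bfactors && !s$all_atoms_have_bfactor)
  fail("nucleotides", cfg$forbid_nucleotides && s$has_nucleotides)
  fail("antibody", cfg$forbid_antibody && s$is_antibody_complex)
  structure(list(accepted = length(failed) == 0,
                 failed_rules = failed,
                 measured = measured),
            class = "filter_verdict")
}

#' @export
print.filter_verdict <- function(x, ...) {
  cat(sprintf("<filter_verdict> %s%s\n",
              if (x$accepted) "accepted" else "rejected: ",
              paste(x$failed_rules, collapse = ", ")))
  invisible(x)
}

#' Curate a set of monomers into a manifest
#'
#' @param structures named list of `radt_structure` monomers.
#' @param cfg a [filter_config()].
#' @return tibble manifest: pdb_id, accepted, failed_rules (comma-joined),
#'   representative_chain (for accepted entries), sequence.
#' @export
curate_structures <- function(structures, cfg = filter_config()) {
  purrr::imap(structures, function(s, id) {
    v <- apply_curation_filters(s, cfg)
    rep_chain <- if (v$accepted) select_representative_chain(s) else NA_character_
    tibble::tibble(
      pdb_id = if (nzchar(id)) id else s$pdb_id,
      accepted = v$accepted,
      failed_rules = paste(v$failed_rules, collapse = ","),
      representative_chain = rep_chain,
      sequence = if (v$accepted) unname(chain_sequences(s)[rep_chain]) else NA_character_
    )
  }) |> purrr::list_rbind()
}

#' Greedy sequence-identity deduplication
#'
#' A single pass in input order: a monomer is dropped iff its identity with
#' any already-kept monomer strictly exceeds `threshold`; identity exactly at
#' the threshold keeps both. Output order preserves input order.
#'
#' @param monomers data frame with columns `id` and `sequence` (a curation
#'   manifest works after renaming `pdb_id`).
#' @param threshold strict identity threshold (default 0.70).
#' @return the kept subset of `monomers`, as a tibble.
#' @export
deduplicate <- function(monomers, threshold = 0.70) {
  stopifnot(!anyDuplicated(monomers$id))
  kept <- logical(nrow(monomers))
  for (i in seq_len(nrow(monomers))) {
    dup <- FALSE
    for (j in which(kept)) {
      if (pairwise_identity(monomers$sequence[i], monomers$sequence[j]) > threshold) {
        dup <- TRUE
        break
      }
    }
    kept[i] <- !dup
  }
  tibble::as_tibble(monomers[kept, , drop = FALSE])
}
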