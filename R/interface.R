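# Residue keys of the standard residues of one chain, in file order.
chain_residue_keys <- function(s, chain) {
  res <- structure_residues(s, chain = chain)
  res <- res[res$is_standard_aa, , drop = FALSE]
  res[, c("chain_id", "seq_num", "insertion_code", "res_name")]
}

atom_xyz <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

cross_dist2 <- function(A, B) {
  # squared Euclidean cross-distances, n_A x n_B (clamped: cancellation can
  # produce tiny negative values)
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  pmax(d2, 0)
}

#' Match a monomer to the chains of a complex
#'
#' The monomer's representative chain is globally aligned to every chain of
#' the complex; chains reaching at least `min_identity` sequence identity
#' (inclusive) yield a match carrying the residue-level map of identical
#' aligned positions.
#'
#' @param monomer a monomer `radt_structure`.
#' @param complex a complex `radt_structure` (>= 2 COMPND entries).
#' @param monomer_chain chain id; defaults to [select_representative_chain()].
#' @param min_identity inclusive identity threshold (default 0.80).
#' @return tibble of matches: monomer_id, monomer_chain, complex_id,
#'   complex_chain, identity, residue_map (list of position-pair tibbles);
#'   zero rows when nothing matches.
#' @export
match_monomer_to_complex <- function(monomer, complex,
                                     monomer_chain = NULL,
                                     min_identity = 0.80) {
  if (!is_complex(complex)) {
    abort("matching target must be a complex (more than one COMPND entry)")
  }
  monomer_chain <- monomer_chain %||% select_representative_chain(monomer)
  mono_seq <- chain_sequences(monomer)[[monomer_chain]]
  cplx_seqs <- chain_sequences(complex)
  rows <- purrr::imap(cplx_seqs, function(seq_b, ch) {
    if (!nzchar(seq_b)) return(NULL)
    ident <- pairwise_identity(mono_seq, seq_b)
    if (ident < min_identity) return(NULL)
    tibble::tibble(
      monomer_id = monomer$pdb_id, monomer_chain = monomer_chain,
      complex_id = complex$pdb_id, complex_chain = ch,
      identity = ident,
      residue_map = list(align_residue_map(mono_seq, seq_b))
    )
  })
  out <- purrr::list_rbind(purrr::compact(rows))
  if (nrow(out) == 0) {
    out <- tibble::tibble(monomer_id = character(), monomer_chain = character(),
                          complex_id = character(), complex_chain = character(),
                          identity = numeric(), residue_map = list())
  }
  out
}

# COMPND entity id of each chain in a complex.
chain_entity <- function(s) {
  ent <- integer()
  for (i in seq_len(nrow(s$compnd))) {
    for (ch in s$compnd$chains[[i]]) ent[ch] <- s$compnd$mol_id[i]
  }
  ent
}

#' Label interface residues of a matched monomer chain
#'
#' A complex residue is interacting iff any of its atoms lies within
#' `cutoff` (default 4.5 A, inclusive) of any atom of any chain belonging to
#' a different COMPND entity. Labels are transferred to the monomer through
#' the match's residue map. The labelling is rejected when fewer than
#' `min_mapped` of the monomer chain's residues could be mapped, or when the
#' complex has no inter-entity atom contact at all.
#'
#' @param match one row of [match_monomer_to_complex()] output.
#' @param complex the complex `radt_structure`.
#' @param monomer the monomer `radt_structure`.
#' @param cutoff contact distance in Angstroms (default 4.5).
#' @param min_mapped minimum mapped-residue fraction (default 0.90).
#' @return an `interface_labeling`: list with `monomer_id`, `chain_id`,
#'   `labels` (tibble: residue key, res_name, label, sources) and
#'   `mapped_residue_fraction`.
#' @export
label_interface <- function(match, complex, monomer,
                            cutoff = 4.5, min_mapped = 0.90) {
  if (nrow(match) != 1) abort("label_interface expects a single match row")
  ent <- chain_entity(complex)
  my_chain <- match$complex_chain
  my_ent <- ent[[my_chain]]
  partner_chains <- names(ent)[ent != my_ent]
  if (length(partner_chains) == 0) {
    abort("matched chain has no partner-entity chains in the complex")
  }

  # global inter-entity contact check over all entity pairs
  if (!any_interentity_contact(complex, ent, cutoff)) {
    abort(sprintf(
      "unacceptable interface: no inter-entity atom pair within %.2f A in %s",
      cutoff, complex$pdb_id))
  }

  my_atoms <- complex$atoms[complex$atoms$chain_id == my_chain &
                              complex$atoms$res_name %in% c(AA3, names(MODIFIED_AA)), ]
  partner_atoms <- complex$atoms[complex$atoms$chain_id %in% partner_chains, ]
  d2 <- cross_dist2(atom_xyz(my_atoms), atom_xyz(partner_atoms))
  atom_contact <- matrixStats_rowMins(d2) <= cutoff^2 + 1e-9

  keys_cplx <- chain_residue_keys(complex, my_chain)
  res_id <- paste(my_atoms$seq_num, my_atoms$insertion_code)
  contact_res <- unique(res_id[atom_contact])
  cplx_interacting <- paste(keys_cplx$seq_num, keys_cplx$insertion_code) %in% contact_res

  keys_mono <- chain_residue_keys(monomer, match$monomer_chain)
  map <- match$residue_map[[1]]
  mapped_fraction <- nrow(map) / nrow(keys_mono)
  if (mapped_fraction < min_mapped) {
    abort(sprintf(
      "unacceptable interface site: only %.1f%% of monomer residues mapped (< %.0f%%)",
      100 * mapped_fraction, 100 * min_mapped))
  }

  label <- rep(FALSE, nrow(keys_mono))
  label[map$pos_a] <- cplx_interacting[map$pos_b]
  sources <- vector("list", nrow(keys_mono))
  src <- list(tibble::tibble(complex_id = match$complex_id,
                             partner_chain = paste(partner_chains, collapse = ",")))
  sources[label] <- src
  labels <- dplyr::bind_cols(keys_mono,
                             tibble::tibble(label = label, sources = sources))
  structure(list(monomer_id = match$monomer_id,
                 chain_id = match$monomer_chain,
                 labels = labels,
                 mapped_residue_fraction = mapped_fraction),
            class = "interface_labeling")
}

matrixStats_rowMins <- function(m) {
  # row minima without an extra dependency
  do.call(pmin, c(as.data.frame(m), list(na.rm = TRUE)))
}

any_interentity_contact <- function(complex, ent, cutoff) {
  chains <- names(ent)
  for (i in seq_along(chains)) {
    for (j in seq_along(chains)) {
      if (j <= i || ent[[chains[i]]] == ent[[chains[j]]]) next
      A <- atom_xyz(complex$atoms[complex$atoms$chain_id == chains[i], ])
      B <- atom_xyz(complex$atoms[complex$atoms$chain_id == chains[j], ])
      if (nrow(A) == 0 || nrow(B) == 0) next
      if (min(cross_dist2(A, B)) <= cutoff^2 + 1e-9) return(TRUE)
    }
  }
  FALSE
}

#' Combine labellings of one monomer against several complexes
#'
#' The final label is the OR of the per-complex labels; sources accumulate.
#' Order-independent and idempotent.
#'
#' @param labelings list of `interface_labeling` for the same monomer chain.
#' @return a single merged `interface_labeling`.
#' @export
combine_labelings <- function(labelings) {
  stopifnot(length(labelings) >= 1)
  out <- labelings[[1]]
  if (length(labelings) == 1) return(out)
  for (l in labelings[-1]) {
    stopifnot(identical(l$chain_id, out$chain_id),
              nrow(l$labels) == nrow(out$labels))
    newly <- l$labels$label
    out$labels$sources <- purrr::map2(out$labels$sources, l$labels$sources,
                                      function(a, b) {
                                        x <- dplyr::bind_rows(a, b)
                                        if (nrow(x) == 0) NULL else dplyr::distinct(x)
                                      })
    out$labels$label <- out$labels$label | newly
    out$mapped_residue_fraction <- max(out$mapped_residue_fraction,
                                       l$mapped_residue_fraction)
  }
  out
}

#' @export
print.interface_labeling <- function(x, ...) {
  cat(sprintf("<interface_labeling> %s chain %s: %d/%d interacting (%.0f%% mapped)\n",
              x$monomer_id, x$chain_id, sum(x$labels$label), nrow(x$labels),
              100 * x$mapped_residue_fraction))
  invisible(x)
}

#' Cluster interface residues into spatial sites
#'
#' Single-linkage clustering of the interacting residues: two residues are
#' linked iff any inter-atomic distance is at most `link_cutoff`.
#'
#' @param labeling an `interface_labeling`.
#' @param s the monomer `radt_structure` the labels refer to.
#' @param link_cutoff linkage distance in Angstroms (default 6.0).
#' @return tibble: residue key columns plus `site_id`; zero rows when no
#'   residue is interacting.
#' @export
interface_sites <- function(labeling, s, link_cutoff = 6.0) {
  keys <- labeling$labels[labeling$labels$label, , drop = FALSE]
  if (nrow(keys) == 0) {
    return(tibble::tibble(chain_id = character(), seq_num = integer(),
                          insertion_code = character(), res_name = character(),
                          site_id = integer()))
  }
  if (nrow(keys) == 1) {
    keys$site_id <- 1L
    return(keys[, c("chain_id", "seq_num", "insertion_code", "res_name", "site_id")])
  }
  dmin <- min_residue_distances(s, keys)
  cl <- cutree(hclust(as.dist(dmin), method = "single"), h = link_cutoff)
  keys$site_id <- as.integer(cl)
  keys[, c("chain_id", "seq_num", "insertion_code", "res_name", "site_id")]
}

# k x k matrix of minimum inter-atomic distances between the given residues
min_residue_distances <- function(s, keys) {
  k <- nrow(keys)
  a <- s$atoms[s$atoms$chain_id %in% unique(keys$chain_id), ]
  rid <- paste(a$chain_id, a$seq_num, a$insertion_code)
  want <- paste(keys$chain_id, keys$seq_num, keys$insertion_code)
  a <- a[rid %in% want, ]
  rid <- rid[rid %in% want]
  idx <- match(rid, want)
  d <- sqrt(cross_dist2(atom_xyz(a), atom_xyz(a)))
  out <- matrix(Inf, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      out[i, j] <- min(d[idx == i, idx == j, drop = FALSE])
    }
  }
  out
}

#' Interface-site rate and NI-subset membership
#'
#' The rate is the number of interface sites per 100 residues of the chain;
#' a protein belongs to the NI-k subset iff its rate is at least k (NI1: at
#' least one site per 100 residues; NI2: at least two).
#'
#' @param labeling an `interface_labeling`.
#' @param sites output of [interface_sites()].
#' @return one-row tibble: n_sites, chain_length, rate, ni1, ni2.
#' @export
ni_rate <- function(labeling, sites) {
  n_sites <- if (nrow(sites) == 0) 0L else length(unique(sites$site_id))
  len <- nrow(labeling$labels)
  rate <- 100 * n_sites / len
  tibble::tibble(monomer_id = labeling$monomer_id, n_sites = n_sites,
                 chain_length = len, rate = rate,
                 ni1 = rate >= 1, ni2 = rate >= 2)
}
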