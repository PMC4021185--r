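#' Per-residue view of a structure
#'
#' @param s a `radt_structure`.
#' @param chain optional chain id to restrict to.
#' @return tibble with one row per residue: chain_id, seq_num,
#'   insertion_code, res_name, is_standard_aa, n_atoms, mean B-factor and
#'   centroid coordinates.
#' @export
structure_residues <- function(s, chain = NULL) {
  a <- s$atoms
  if (!is.null(chain)) a <- a[a$chain_id %in% chain, , drop = FALSE]
  a |>
    dplyr::group_by(.data$chain_id, .data$seq_num, .data$insertion_code,
                    .data$res_name) |>
    dplyr::summarise(
      n_atoms = dplyr::n(),
      b_mean = mean(.data$b_factor),
      cx = mean(.data$x), cy = mean(.data$y), cz = mean(.data$z),
      first_serial = min(.data$serial),
      .groups = "drop"
    ) |>
    dplyr::mutate(is_standard_aa = .data$res_name %in% AA3) |>
    dplyr::arrange(.data$first_serial) |>
    dplyr::select(-"first_serial")
}

#' Chain one-letter sequences
#'
#' Sequences are built from standard amino acids only; modified residues
#' kept for geometry (e.g. MSE) are excluded.
#'
#' @param s a `radt_structure`.
#' @return named character vector, one sequence per chain (file order).
#' @export
chain_sequences <- function(s) {
  res <- structure_residues(s)
  res <- res[res$is_standard_aa, , drop = FALSE]
  split_idx <- split(seq_len(nrow(res)), res$chain_id)
  # preserve file order of chains
  chain_order <- unique(structure_residues(s)$chain_id)
  out <- vapply(chain_order, function(ch) {
    i <- split_idx[[ch]]
    if (is.null(i)) "" else paste(AA1[res$res_name[i]], collapse = "")
  }, character(1))
  out
}

#' @export
n_chains <- function(s) length(unique(s$atoms$chain_id))

#' Monomer / complex classification
#'
#' A structure is a monomer iff it has exactly one COMPND molecule entry,
#' a complex iff it has more than one.
#'
#' @param s a `radt_structure`.
#' @return logical scalar.
#' @export
is_monomer <- function(s) nrow(s$compnd) == 1L

#' @rdname is_monomer
#' @export
is_complex <- function(s) nrow(s$compnd) > 1L

#' Select the representative chain of a monomer
#'
#' The longest chain (by standard-residue count); ties are broken by the
#' lowest sum of B-factors, remaining ties by file order.
#'
#' @param s a monomer `radt_structure`.
#' @return chain id (character scalar).
#' @export
select_representative_chain <- function(s) {
  res <- structure_residues(s)
  res <- res[res$is_standard_aa, , drop = FALSE]
  chain_order <- unique(structure_residues(s)$chain_id)
  stats_tbl <- res |>
    dplyr::group_by(.data$chain_id) |>
    dplyr::summarise(len = dplyr::n(),
                     b_sum = sum(.data$b_mean * .data$n_atoms),
                     .groups = "drop")
  stats_tbl$file_order <- match(stats_tbl$chain_id, chain_order)
  stats_tbl <- stats_tbl[order(-stats_tbl$len, stats_tbl$b_sum,
                               stats_tbl$file_order), , drop = FALSE]
  stats_tbl$chain_id[1]
}

#' Expand BIOMT biological-assembly transforms
#'
#' Applies each stored BIOMT transform to its target chains, appending the
#' generated chains under fresh chain ids (lower-case letters, then digits).
#' The identity transform therefore yields a coordinate-identical copy of
#' each targeted chain.
#'
#' @param s a `radt_structure` with at least one BIOMT transform.
#' @return a new `radt_structure` with the expanded chain set.
#' @export
expand_biomt <- function(s) {
  if (length(s$biomt) == 0) {
    abort("structure has no BIOMT transforms to expand")
  }
  fresh_ids <- setdiff(c(letters, as.character(0:9)),
                       unique(s$atoms$chain_id))
  out <- s
  new_blocks <- list()
  k <- 0L
  serial_next <- max(s$atoms$serial) + 1L
  for (tr in s$biomt) {
    det <- det(tr$R)
    if (abs(abs(det) - 1) > 1e-6) {
      abort(sprintf("BIOMT transform %d has non-orthonormal rotation (|det| = %g)",
                    tr$id, abs(det)))
    }
    targets <- tr$chains
    if (length(targets) == 0) targets <- unique(s$atoms$chain_id)
    for (ch in targets) {
      a <- s$atoms[s$atoms$chain_id == ch, , drop = FALSE]
      if (nrow(a) == 0) next
      k <- k + 1L
      if (k > length(fresh_ids)) abort("ran out of fresh chain ids in expand_biomt")
      xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(tr$R)
      a$x <- xyz[, 1] + tr$t[1]
      a$y <- xyz[, 2] + tr$t[2]
      a$z <- xyz[, 3] + tr$t[3]
      a$chain_id <- fresh_ids[k]
      a$serial <- seq.int(serial_next, length.out = nrow(a))
      serial_next <- serial_next + nrow(a)
      new_blocks[[k]] <- a
    }
  }
  out$atoms <- dplyr::bind_rows(c(list(s$atoms), new_blocks))
  out$biomt <- list()
  out
}

#' Write a structure back to PDB format
#'
#' Emits COMPND, REMARK 2 resolution, and fixed-column ATOM/HETATM records
#' (coordinates at 3 decimals), with TER records between chains.
#'
#' @param s a `radt_structure`.
#' @param path optional file path; if `NULL` the text is returned invisibly.
#' @return the PDB text, invisibly.
#' @export
write_pdb <- function(s, path = NULL) {
  lines <- character()
  for (i in seq_len(nrow(s$compnd))) {
    lines <- c(lines,
      sprintf("COMPND %3s MOL_ID: %d;", if (i == 1) "" else as.character(i), s$compnd$mol_id[i]))
    if (!is.na(s$compnd$molecule[i])) {
      lines <- c(lines, sprintf("COMPND %3d MOLECULE: %s;", i + 1L, s$compnd$molecule[i]))
    }
    if (length(s$compnd$chains[[i]]) > 0) {
      lines <- c(lines, sprintf("COMPND %3d CHAIN: %s;", i + 2L,
                                paste(s$compnd$chains[[i]], collapse = ", ")))
    }
  }
  if (!is.na(s$resolution)) {
    lines <- c(lines, sprintf("REMARK   2 RESOLUTION. %7.2f ANGSTROMS.", s$resolution))
  }
  a <- s$atoms
  fmt_name <- function(nm, el) {
    # short element names start in column 14 per the PDB convention
    ifelse(nchar(nm) >= 4 | nchar(el) == 2, substr(formatC(nm, width = -4), 1, 4),
           formatC(paste0(" ", nm), width = -4))
  }
  prev_chain <- ""
  for (i in seq_len(nrow(a))) {
    if (prev_chain != "" && a$chain_id[i] != prev_chain) lines <- c(lines, "TER")
    prev_chain <- a$chain_id[i]
    lines <- c(lines, sprintf(
      "%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      if (a$het[i]) "HETATM" else "ATOM",
      a$serial[i] %% 100000L,
      fmt_name(a$name[i], a$element[i]),
      a$alt_loc[i],
      a$res_name[i],
      a$chain_id[i],
      a$seq_num[i],
      a$insertion_code[i],
      a$x[i], a$y[i], a$z[i],
      a$occupancy[i],
      if (is.na(a$b_factor[i])) 0 else a$b_factor[i],
      a$element[i]
    ))
  }
  lines <- c(lines, "TER", "END")
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) writeLines(text, path, sep = "")
  invisible(text)
}

#' One-line chain/residue/record census of a structure
#'
#' @param s a `radt_structure`.
#' @return tibble with one row per chain plus record counts.
#' @export
structure_summary <- function(s) {
  res <- structure_residues(s)
  res |>
    dplyr::group_by(chain_id = .data$chain_id) |>
    dplyr::summarise(n_residues = dplyr::n(),
                     n_standard = sum(.data$is_standard_aa),
                     n_atoms = sum(.data$n_atoms), .groups = "drop") |>
    dplyr::mutate(pdb_id = s$pdb_id,
                  monomer = is_monomer(s),
                  resolution = s$resolution,
                  ssbond = s$ssbond_count,
                  conect = s$conect_count,
                  n_biomt = length(s$biomt), .before = 1)
}
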