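FEATURE_COLUMNS <- c("relSESA", "protrusion", "roughness", "density",
                     "curvature", "hydrophobicity", "propensity", "esolv",
                     "bfactor", "bfactor_norm", "epot",
                     "scorecons", "rate4site", "disorder")

#' Compute the per-residue feature table of a structure
#'
#' Assembles the geometric surface features (relative accessible area,
#' protrusion, roughness, density, curvature), the physicochemical features
#' (hydrophobicity, propensity, solvation energy, raw and normalised
#' B-factors, screened electrostatic potential) and placeholders for the
#' injected evolutionary features (scorecons, rate4site, disorder). Features
#' are computed for every standard residue, buried or exposed. Missing
#' values are explicit `NA`s; see [feature_mask()].
#'
#' @param s a `radt_structure`.
#' @param chain optional chain id to restrict the table to.
#' @param cfg a [feature_config()].
#' @param propensity optional propensity scale from [propensity_scale()].
#' @param external optional external feature table (path or data frame),
#'   see [load_external_features()].
#' @return a feature tibble keyed by (protein_id, chain_id, seq_num,
#'   insertion_code) with one row per standard residue.
#' @export
compute_features <- function(s, chain = NULL, cfg = feature_config(),
                             propensity = NULL, external = NULL) {
  if (!is.null(chain)) {
    s$atoms <- s$atoms[s$atoms$chain_id %in% chain, , drop = FALSE]
  }
  areas <- accessible_surface_area(s, cfg)
  res_area <- areas$residues
  geo <- neighbourhood_features(s, areas, cfg)
  cx <- protrusion(s, cfg)
  phys <- physicochemical_features(s, areas, cfg, propensity = propensity)

  key <- c("chain_id", "seq_num", "insertion_code", "res_name")
  out <- structure_residues(s)[, key]
  out <- out[out$res_name %in% AA3, , drop = FALSE]
  out$protein_id <- s$pdb_id
  out <- out[, c("protein_id", key)]
  join <- function(x, y) dplyr::left_join(x, y, by = key)
  out <- join(out, dplyr::rename(res_area, residue_area = "area")[,
                                 c(key, "residue_area")])
  out$relSESA <- relative_sesa(out$residue_area, out$res_name, cfg)
  out$residue_area <- NULL
  out <- join(out, cx)
  out <- join(out, geo)
  out <- join(out, phys)
  out$scorecons <- NA_real_
  out$rate4site <- NA_real_
  out$disorder <- NA_real_
  if (!is.null(external)) out <- load_external_features(external, out)
  tibble::as_tibble(out)
}

#' Missing-value mask of a feature table
#'
#' @param features a feature tibble from [compute_features()].
#' @return logical tibble (TRUE = masked/missing) over the feature columns,
#'   with the residue key columns retained.
#' @export
feature_mask <- function(features) {
  cols <- intersect(FEATURE_COLUMNS, names(features))
  dplyr::bind_cols(
    features[, intersect(c("protein_id", "chain_id", "seq_num", "insertion_code"),
                         names(features))],
    purrr::map_dfc(features[cols], is.na)
  )
}

#' Join externally computed evolutionary features
#'
#' Conservation (scorecons), evolutionary rate shift (rate4site) and
#' disorder have no internal approximation; they are injected from a TSV
#' with columns pdb_id, chain, seq_num, icode, scorecons, rate4site,
#' disorder. Residues absent from the file stay masked (`NA`).
#'
#' @param table_path path to the TSV, or a data frame already read.
#' @param features feature tibble to join onto.
#' @return the feature tibble with the external columns filled in.
#' @export
load_external_features <- function(table_path, features) {
  ext <- if (is.data.frame(table_path)) {
    table_path
  } else {
    utils::read.delim(table_path, sep = "\t", stringsAsFactors = FALSE,
                      colClasses = c(pdb_id = "character", chain = "character",
                                     icode = "character"))
  }
  required <- c("pdb_id", "chain", "seq_num", "icode",
                "scorecons", "rate4site", "disorder")
  missing_cols <- setdiff(required, names(ext))
  if (length(missing_cols) > 0) {
    abort(paste("external feature table lacks columns:",
                paste(missing_cols, collapse = ", ")))
  }
  ext$icode[is.na(ext$icode)] <- ""
  key <- paste(ext$pdb_id, ext$chain, ext$seq_num, ext$icode)
  if (anyDuplicated(key)) {
    abort(sprintf("duplicate residue key in external feature table: %s",
                  key[duplicated(key)][1]))
  }
  for (col in c("scorecons", "rate4site", "disorder")) {
    v <- ext[[col]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v) & v != "")
      if (length(bad) > 0) {
        abort(sprintf("non-numeric %s value at external table row %d: '%s'",
                      col, bad[1], v[bad[1]]))
      }
      ext[[col]] <- conv
    }
  }
  fkey <- paste(features$protein_id, features$chain_id, features$seq_num,
                features$insertion_code)
  idx <- match(fkey, key)
  for (col in c("scorecons", "rate4site", "disorder")) {
    features[[col]] <- ext[[col]][idx]
  }
  features
}

#' Point-biserial correlation of each feature with the interface label
#'
#' @param features feature tibble (or any tibble with feature columns).
#' @param label logical label vector aligned with the rows.
#' @return tibble: feature, r, p (two-tailed), n.
#' @export
feature_label_correlations <- function(features, label) {
  cols <- intersect(FEATURE_COLUMNS, names(features))
  purrr::map(cols, function(col) {
    v <- features[[col]]
    ok <- !is.na(v)
    if (sum(ok) < 3 || sd(v[ok]) == 0) return(NULL)
    ct <- pearson_feature_correlation(v[ok], label[ok])
    tibble::tibble(feature = col, r = ct$r, p = ct$p, n = sum(ok))
  }) |> purrr::list_rbind()
}
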