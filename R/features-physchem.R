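# Residue physicochemical features: hydrophobicity (Fauchere-Pliska pi
# scale), interface propensity (log-odds from training labels), solvation
# energy (atomic solvation parameters x accessible area), normalised
# B-factors, and a screened-Coulomb electrostatic potential.

# Fauchere & Pliska (1983) octanol-water side-chain transfer free energies.
FAUCHERE_PLISKA <- c(
  ALA = 0.31, ARG = -1.01, ASN = -0.60, ASP = -0.77, CYS = 1.54,
  GLN = -0.22, GLU = -0.64, GLY = 0.00, HIS = 0.13, ILE = 1.80,
  LEU = 1.70, LYS = -0.99, MET = 1.23, PHE = 1.79, PRO = 0.72,
  SER = -0.04, THR = 0.26, TRP = 2.25, TYR = 0.96, VAL = 1.22
)

# Eisenberg & McLachlan (1986) atomic solvation parameters, kcal/(mol A^2).
SOLVATION_PARAMS <- c(C = 0.016, N = -0.006, O = -0.006,
                      `O-` = -0.024, `N+` = -0.050, S = 0.021, SE = 0.021,
                      H = 0, P = 0.016)

# Integer side-chain charges for the screened Coulomb term.
RESIDUE_CHARGE <- c(LYS = 1, ARG = 1, ASP = -1, GLU = -1, HIS = 0.5)

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

solvation_class <- function(atoms) {
  cls <- atoms$element
  side <- !(atoms$name %in% BACKBONE_ATOMS)
  cls[side & cls == "O" & atoms$res_name %in% c("ASP", "GLU")] <- "O-"
  cls[side & cls == "N" & atoms$res_name %in% c("LYS", "ARG")] <- "N+"
  cls
}

side_chain_centroids <- function(s) {
  a <- s$atoms
  a$side <- !(a$name %in% BACKBONE_ATOMS)
  a |>
    dplyr::group_by(.data$chain_id, .data$seq_num, .data$insertion_code,
                    .data$res_name) |>
    dplyr::summarise(
      cx = if (any(.data$side)) mean(.data$x[.data$side]) else mean(.data$x),
      cy = if (any(.data$side)) mean(.data$y[.data$side]) else mean(.data$y),
      cz = if (any(.data$side)) mean(.data$z[.data$side]) else mean(.data$z),
      .groups = "drop"
    )
}

#' Screened-Coulomb electrostatic potential per residue
#'
#' Debye-Hueckel form: the potential at residue i's side-chain centroid is
#' the sum over charged residues j != i of q_j / (epsilon r_ij) *
#' exp(-r_ij / lambda_D), with unit charges on LYS/ARG (+1), ASP/GLU (-1)
#' and +0.5 on HIS. Model units (unit charge / (relative dielectric x A)).
#'
#' @param s a `radt_structure`.
#' @param cfg a [feature_config()].
#' @return per-residue tibble with an `epot` column.
#' @export
electrostatic_potential <- function(s, cfg = feature_config()) {
  cen <- side_chain_centroids(s)
  q <- RESIDUE_CHARGE[cen$res_name]
  q[is.na(q)] <- 0
  xyz <- as.matrix(cen[, c("cx", "cy", "cz")])
  charged <- which(q != 0)
  epot <- numeric(nrow(cen))
  if (length(charged) > 0) {
    d <- sqrt(cross_dist2(xyz, xyz[charged, , drop = FALSE]))
    contrib <- sweep(exp(-d / cfg$debye_length) /
                       (cfg$epsilon_dielectric * pmax(d, 1e-6)),
                     2, q[charged], "*")
    # exclude each residue's own charge
    for (k in seq_along(charged)) contrib[charged[k], k] <- 0
    epot <- rowSums(contrib)
  }
  tibble::tibble(cen[, c("chain_id", "seq_num", "insertion_code", "res_name")],
                 epot = epot)
}

#' Interface propensity scale from training labels
#'
#' Log-odds of a residue type's frequency among interface residues versus
#' all residues, with add-one smoothing.
#'
#' @param res_name 3-letter residue names of the training residues.
#' @param label logical interface labels aligned with `res_name`.
#' @return named numeric vector over the 20 standard residues.
#' @export
propensity_scale <- function(res_name, label) {
  stopifnot(length(res_name) == length(label))
  tab_all <- table(factor(res_name, levels = AA3))
  tab_int <- table(factor(res_name[label], levels = AA3))
  f_int <- (as.numeric(tab_int) + 1) / (sum(tab_int) + length(AA3))
  f_all <- (as.numeric(tab_all) + 1) / (sum(tab_all) + length(AA3))
  setNames(log(f_int / f_all), AA3)
}

#' Physicochemical residue features
#'
#' @param s a `radt_structure`.
#' @param areas output of [accessible_surface_area()] for `s`.
#' @param cfg a [feature_config()].
#' @param propensity optional named propensity scale (see
#'   [propensity_scale()]); `NA` column when absent.
#' @return per-residue tibble: hydrophobicity, propensity, esolv
#'   (kcal/mol), bfactor (raw residue mean), bfactor_norm (per-structure
#'   z-score; 0 when the structure has uniform B-factors), epot.
#' @export
physicochemical_features <- function(s, areas = accessible_surface_area(s, cfg),
                                     cfg = feature_config(),
                                     propensity = NULL) {
  res <- structure_residues(s)
  a <- areas$atoms
  a$solv <- SOLVATION_PARAMS[solvation_class(a)]
  esolv <- a |>
    dplyr::group_by(.data$chain_id, .data$seq_num, .data$insertion_code) |>
    dplyr::summarise(esolv = sum(.data$solv * .data$area), .groups = "drop")

  out <- res[, c("chain_id", "seq_num", "insertion_code", "res_name")]
  out$hydrophobicity <- unname(FAUCHERE_PLISKA[res$res_name])
  out$propensity <- if (is.null(propensity)) NA_real_ else unname(propensity[res$res_name])
  out <- dplyr::left_join(out, esolv,
                          by = c("chain_id", "seq_num", "insertion_code"))
  out$bfactor <- res$b_mean
  b_sd <- sd(res$b_mean)
  out$bfactor_norm <- if (is.na(b_sd) || b_sd == 0) 0 else
    (res$b_mean - mean(res$b_mean)) / b_sd
  ep <- electrostatic_potential(s, cfg)
  out$epot <- ep$epot[match(paste(out$chain_id, out$seq_num, out$insertion_code),
                            paste(ep$chain_id, ep$seq_num, ep$insertion_code))]
  out
}
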