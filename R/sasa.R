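# Sphere-sampling accessible surface area (Shrake-Rupley style): each
# atom's sphere at r_vdw + probe is sampled with a deterministic Fibonacci
# point set; points inside any neighbouring atom's probe-extended sphere
# are occluded. The per-residue area is the sum over the residue's atoms.

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, SE = 1.90,
               P = 1.80, H = 1.20)

vdw_radius <- function(element, atom_label = element) {
  r <- VDW_RADII[element]
  if (anyNA(r)) {
    bad <- which(is.na(r))[1]
    abort(sprintf("unknown element '%s' for atom %s: no van der Waals radius",
                  element[bad], atom_label[bad]))
  }
  unname(r)
}

#' Feature computation configuration
#'
#' @param probe_radius solvent probe radius in Angstroms (water, 1.4).
#' @param sasa_points sphere sample points per atom (more = smoother area).
#' @param cx_sphere_radius,cx_atom_volume,cx_cap protrusion (CX) parameters:
#'   counting-sphere radius (A), mean atom volume (A^3), value cap.
#' @param neighbour_min,neighbour_max,neighbour_cutoff residue-local
#'   neighbourhood: nearest residues by centroid within the cutoff (A),
#'   clipped to the min-max range (typically two to six neighbours).
#' @param epsilon_dielectric,debye_length screened-Coulomb electrostatics:
#'   relative dielectric and Debye screening length (A).
#' @return a `feature_config` list.
#' @export
feature_config <- function(probe_radius = 1.4, sasa_points = 960,
                           cx_sphere_radius = 10, cx_atom_volume = 20.1,
                           cx_cap = 100,
                           neighbour_min = 2L, neighbour_max = 6L,
                           neighbour_cutoff = 8,
                           epsilon_dielectric = 80, debye_length = 8) {
  stopifnot(probe_radius > 0, sasa_points > 10,
            neighbour_min <= neighbour_max, neighbour_cutoff > 0,
            cx_sphere_radius > 0, cx_atom_volume > 0)
  structure(as.list(environment()), class = "feature_config")
}

#' Accessible surface area by sphere sampling
#'
#' @param s a `radt_structure` (or an atoms tibble).
#' @param cfg a [feature_config()].
#' @return list with `atoms` (the atoms tibble plus `radius` and `area`
#'   columns, area in A^2) and `residues` (per-residue summed areas).
#' @examples
#' # an isolated carbon atom has area 4*pi*(1.7 + 1.4)^2 ~ 120.76 A^2
#' @export
accessible_surface_area <- function(s, cfg = feature_config()) {
  atoms <- if (inherits(s, "radt_structure")) s$atoms else s
  xyz <- atom_xyz(atoms)
  radii <- vdw_radius(atoms$element,
                      paste0(atoms$name, "/", atoms$res_name, atoms$seq_num)) +
    cfg$probe_radius
  pts <- fibonacci_sphere(cfg$sasa_points)
  n <- nrow(xyz)
  area <- numeric(n)
  d2all <- cross_dist2(xyz, xyz)
  for (i in seq_len(n)) {
    nb <- which(d2all[i, ] < (radii[i] + radii)^2 & seq_len(n) != i)
    sp <- pts * radii[i]
    sp <- sweep(sp, 2, xyz[i, ], "+")
    free <- rep(TRUE, nrow(sp))
    for (j in nb) {
      if (!any(free)) break
      dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
        (sp[, 3] - xyz[j, 3])^2
      free <- free & dj2 > radii[j]^2
    }
    area[i] <- 4 * pi * radii[i]^2 * mean(free)
  }
  atoms$radius <- radii
  atoms$area <- area
  residues <- atoms |>
    dplyr::group_by(.data$chain_id, .data$seq_num, .data$insertion_code,
                    .data$res_name) |>
    dplyr::summarise(area = sum(.data$area), n_atoms = dplyr::n(),
                     .groups = "drop")
  list(atoms = atoms, residues = residues)
}

# ---- reference maximum areas (extended Gly-X-Gly tripeptides) ----------

SIDE_CHAIN_ELEMENTS <- list(
  ALA = "C",
  ARG = c("C", "C", "C", "N", "C", "N", "N"),
  ASN = c("C", "C", "O", "N"),
  ASP = c("C", "C", "O", "O"),
  CYS = c("C", "S"),
  GLN = c("C", "C", "C", "O", "N"),
  GLU = c("C", "C", "C", "O", "O"),
  GLY = character(),
  HIS = c("C", "C", "N", "C", "C", "N"),
  ILE = c("C", "C", "C", "C"),
  LEU = c("C", "C", "C", "C"),
  LYS = c("C", "C", "C", "C", "N"),
  MET = c("C", "C", "S", "C"),
  PHE = c("C", "C", "C", "C", "C", "C", "C"),
  PRO = c("C", "C", "C"),
  SER = c("C", "O"),
  THR = c("C", "O", "C"),
  TRP = c("C", "C", "C", "C", "N", "C", "C", "C", "C", "C"),
  TYR = c("C", "C", "C", "C", "C", "C", "C", "O"),
  VAL = c("C", "C", "C")
)

# Idealised extended tripeptide Gly-X-Gly: backbone N/CA/C/O zig-zag along
# x, side chain of the middle residue grown perpendicular in z. Coarse
# geometry: the reference is self-consistent with the same SASA engine.
build_gxg <- function(res_name) {
  stopifnot(res_name %in% AA3)
  bb <- function(seq_num, res, x0) {
    tibble::tibble(
      name = c("N", "CA", "C", "O"),
      element = c("N", "C", "C", "O"),
      res_name = res, seq_num = seq_num,
      x = x0 + c(-1.2, 0, 1.2, 1.6),
      y = c(0.5, 0, 0.5, 1.6),
      z = 0
    )
  }
  sc_el <- SIDE_CHAIN_ELEMENTS[[res_name]]
  sc <- if (length(sc_el) > 0) {
    k <- seq_along(sc_el)
    tibble::tibble(
      name = paste0("S", k), element = sc_el,
      res_name = res_name, seq_num = 2L,
      x = 3.8 + 0.4 * (k %% 2), y = -0.6 * (k %% 3 - 1), z = 1.5 * k
    )
  } else NULL
  a <- dplyr::bind_rows(bb(1L, "GLY", 0), bb(2L, res_name, 3.8), sc,
                        bb(3L, "GLY", 7.6))
  a$serial <- seq_len(nrow(a))
  a$chain_id <- "A"
  a$insertion_code <- ""
  a$alt_loc <- ""
  a$occupancy <- 1
  a$b_factor <- 0
  a$het <- FALSE
  a
}

ref_area_cache <- new.env(parent = emptyenv())

#' Reference maximum residue areas
#'
#' Computed once per configuration by running the same sphere-sampling
#' engine on idealised extended Gly-X-Gly tripeptides and taking the middle
#' residue's area; used as the denominator of the relative accessible area.
#'
#' @param cfg a [feature_config()].
#' @return named numeric vector over the 20 standard residues (A^2).
#' @export
reference_max_areas <- function(cfg = feature_config()) {
  key <- sprintf("p%.3f_n%d", cfg$probe_radius, cfg$sasa_points)
  if (!is.null(ref_area_cache[[key]])) return(ref_area_cache[[key]])
  out <- vapply(AA3, function(rn) {
    sa <- accessible_surface_area(build_gxg(rn), cfg)
    sa$residues$area[sa$residues$seq_num == 2]
  }, numeric(1))
  ref_area_cache[[key]] <- out
  out
}

#' Relative accessible surface area
#'
#' @param residue_area numeric vector of residue areas (A^2).
#' @param res_name matching 3-letter residue names.
#' @param cfg a [feature_config()].
#' @return relSESA fraction (0 for fully buried; may exceed 1 for extended
#'   conformations).
#' @export
relative_sesa <- function(residue_area, res_name, cfg = feature_config()) {
  ref <- reference_max_areas(cfg)
  if (!all(res_name %in% names(ref))) {
    abort(sprintf("no reference area for residue '%s'",
                  setdiff(res_name, names(ref))[1]))
  }
  unname(residue_area / ref[res_name])
}
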