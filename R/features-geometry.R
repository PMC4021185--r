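# Residue-local geometric features: protrusion (CX), roughness, surface
# density and curvature, each computed over a small neighbourhood of
# nearest residues (typically two to six) and assigned to the nodal
# residue.

#' Protrusion index (CX)
#'
#' For each atom, the number of atoms inside a fixed-radius sphere defines
#' the occupied volume `V_int = count x atom_volume`; the protrusion index
#' is the empty-to-occupied ratio `(V_sphere - V_int) / V_int`, capped, and
#' averaged over each residue's atoms. Protruding atoms see mostly empty
#' space (high CX), buried atoms approach 0.
#'
#' @param s a `radt_structure`.
#' @param cfg a [feature_config()].
#' @return per-residue tibble with a `protrusion` column.
#' @export
protrusion <- function(s, cfg = feature_config()) {
  atoms <- s$atoms
  xyz <- atom_xyz(atoms)
  d2 <- cross_dist2(xyz, xyz)
  counts <- rowSums(d2 <= cfg$cx_sphere_radius^2 + 1e-9) # includes self
  v_sphere <- 4 / 3 * pi * cfg$cx_sphere_radius^3
  v_int <- counts * cfg$cx_atom_volume
  cx <- pmin((v_sphere - v_int) / v_int, cfg$cx_cap)
  cx <- pmax(cx, 0)
  atoms$cx <- cx
  atoms |>
    dplyr::group_by(.data$chain_id, .data$seq_num, .data$insertion_code,
                    .data$res_name) |>
    dplyr::summarise(protrusion = mean(.data$cx), .groups = "drop")
}

# Least-squares sphere fit (algebraic): returns centre, radius; NULL when
# the system is rank-deficient (coplanar/collinear points = flat patch).
fit_sphere <- function(P) {
  if (nrow(P) < 4) return(NULL)
  A <- cbind(2 * P, 1)
  b <- rowSums(P^2)
  fit <- lm.fit(A, b)
  if (fit$rank < 4) return(NULL)
  cf <- fit$coefficients
  centre <- cf[1:3]
  r2 <- cf[4] + sum(centre^2)
  if (!is.finite(r2) || r2 <= 0) return(NULL)
  list(centre = centre, radius = sqrt(r2))
}

# Neighbour sets: nearest residues by centroid distance within the cutoff,
# clipped to [min, max]; residues with too few neighbours are masked.
residue_neighbours <- function(centroids, cfg) {
  n <- nrow(centroids)
  d <- sqrt(cross_dist2(centroids, centroids))
  lapply(seq_len(n), function(i) {
    cand <- setdiff(order(d[i, ]), i)
    cand <- cand[d[i, cand] <= cfg$neighbour_cutoff]
    if (length(cand) < cfg$neighbour_min) return(NULL)
    cand[seq_len(min(length(cand), cfg$neighbour_max))]
  })
}

#' Neighbourhood surface features: roughness, density, curvature
#'
#' Roughness is the summed atomic accessible area of the neighbourhood
#' divided by the area of the smooth reference patch: the disc footprint of
#' the neighbourhood centroids projected onto their best-fit plane,
#' inflated by the mean probe-extended atom radius. A smooth patch is near
#' 1; spikes raise the true area but not the footprint, so roughness
#' increases. Density is the neighbourhood atom count per unit of
#' neighbourhood accessible area (atoms per A^2). Curvature is the signed
#' inverse radius of the sphere fitted to the neighbourhood centroids
#' (1/A; positive = convex outward, sign taken by comparing the fitted
#' centre with the protein centroid), 0 for flat patches.
#'
#' @param s a `radt_structure`.
#' @param areas output of [accessible_surface_area()] for the same structure.
#' @param cfg a [feature_config()].
#' @return per-residue tibble with `roughness`, `density`, `curvature`
#'   (NA where the residue has fewer than `neighbour_min` neighbours).
#' @export
neighbourhood_features <- function(s, areas = accessible_surface_area(s, cfg),
                                   cfg = feature_config()) {
  res <- structure_residues(s)
  centroids <- as.matrix(res[, c("cx", "cy", "cz")])
  protein_centroid <- colMeans(centroids)
  nbrs <- residue_neighbours(centroids, cfg)
  rid_atoms <- paste(areas$atoms$chain_id, areas$atoms$seq_num,
                     areas$atoms$insertion_code)
  rid_res <- paste(res$chain_id, res$seq_num, res$insertion_code)
  mean_atom_radius <- mean(areas$atoms$radius)

  out <- res[, c("chain_id", "seq_num", "insertion_code", "res_name")]
  out$roughness <- NA_real_
  out$density <- NA_real_
  out$curvature <- NA_real_
  for (i in seq_len(nrow(res))) {
    nb <- nbrs[[i]]
    if (is.null(nb)) next
    patch <- c(i, nb)
    in_patch <- rid_atoms %in% rid_res[patch]
    patch_area <- sum(areas$atoms$area[in_patch])
    n_atoms <- sum(in_patch)
    P <- centroids[patch, , drop = FALSE]
    sph <- fit_sphere(P)
    if (is.null(sph)) {
      out$curvature[i] <- 0 # flat or degenerate patch
    } else {
      convex <- sqrt(sum((sph$centre - protein_centroid)^2)) <=
        sqrt(sum((colMeans(P) - protein_centroid)^2))
      out$curvature[i] <- (if (convex) 1 else -1) / sph$radius
    }
    # smooth reference: disc footprint on the best-fit plane of the patch
    pc <- colMeans(P)
    Pc <- sweep(P, 2, pc)
    normal <- eigen(crossprod(Pc), symmetric = TRUE)$vectors[, 3]
    proj <- Pc - outer(as.vector(Pc %*% normal), normal)
    r_max <- sqrt(max(rowSums(proj^2)))
    smooth_area <- pi * (r_max + mean_atom_radius)^2
    out$roughness[i] <- if (smooth_area > 0) patch_area / smooth_area else NA_real_
    out$density[i] <- if (patch_area > 0) n_atoms / patch_area else NA_real_
  }
  out
}
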