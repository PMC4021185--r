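single_atom <- function(element = "C") {
  tibble::tibble(serial = 1L, name = "CA", alt_loc = "", res_name = "ALA",
                 chain_id = "A", seq_num = 1L, insertion_code = "",
                 x = 0, y = 0, z = 0, occupancy = 1, b_factor = 20,
                 element = element, het = FALSE)
}

test_that("sphere-sampling area matches closed forms and a dense oracle", {
  cfg <- feature_config()
  # isolated atom: full sphere at r_vdw + probe
  sa <- accessible_surface_area(single_atom(), cfg)
  expect_equal(sa$atoms$area, 4 * pi * 3.1^2, tolerance = 0.02)

  # atom enclosed by a dense shell: area ~ 0
  shell <- radt:::fibonacci_sphere(30) * 3
  atoms <- dplyr::bind_rows(
    single_atom(),
    purrr::map(seq_len(nrow(shell)), function(i) {
      a <- single_atom()
      a$serial <- i + 1L
      a$seq_num <- i + 1L
      a[, c("x", "y", "z")] <- as.list(shell[i, ])
      a
    }))
  sa2 <- accessible_surface_area(atoms, cfg)
  expect_lt(sa2$atoms$area[1], 1)

  # two-atom fixture vs a dense-sampling (1e5 points) oracle within 2%
  two <- dplyr::bind_rows(single_atom(), single_atom())
  two$serial <- 1:2; two$seq_num <- 1:2; two$x <- c(0, 2.5)
  got <- accessible_surface_area(two, cfg)$atoms$area
  dense <- accessible_surface_area(two, feature_config(sasa_points = 1e5))$atoms$area
  expect_equal(got, dense, tolerance = 0.02)

  # per-residue areas sum the per-atom areas
  s <- make_synth_structure(synth_structure_config(n_residues = 10))
  sa3 <- accessible_surface_area(s, cfg)
  expect_equal(sum(sa3$residues$area), sum(sa3$atoms$area))

  bad <- single_atom("XX")
  expect_error(accessible_surface_area(bad, cfg), "unknown element")
})

test_that("relative area is 1 on the reference conformation and 0 when buried", {
  cfg <- feature_config(sasa_points = 240)
  ref <- reference_max_areas(cfg)
  expect_length(ref, 20)
  expect_true(all(ref > 0))
  # the Gly-X-Gly reference itself scores 1 by construction
  gxg <- radt:::build_gxg("LEU")
  sa <- accessible_surface_area(gxg, cfg)
  mid <- sa$residues[sa$residues$seq_num == 2, ]
  expect_equal(relative_sesa(mid$area, "LEU", cfg), 1.0, tolerance = 1e-12)
  expect_equal(relative_sesa(0, "TRP", cfg), 0)
  expect_error(relative_sesa(10, "XYZ", cfg), "no reference area")
})

test_that("protrusion follows the empty-to-occupied volume definition", {
  cfg <- feature_config()
  # isolated atom: CX = (V_sphere - v)/v ~ 207, capped at 100
  p1 <- protrusion(list(atoms = single_atom()) |> structure(class = "radt_structure"),
                   cfg)
  expect_equal(p1$protrusion, 100)
  v <- 4 / 3 * pi * 10^3
  expect_equal(pmin((v - 20.1) / 20.1, 100), 100) # uncapped value is ~207

  # equality with a brute-force neighbour count on a fixture
  s <- make_synth_structure(synth_structure_config(n_residues = 30, geometry = "helix"))
  got <- protrusion(s, cfg)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")])
  oracle <- vapply(seq_len(nrow(xyz)), function(i) {
    cnt <- 0
    for (j in seq_len(nrow(xyz))) {
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= 10) cnt <- cnt + 1
    }
    vi <- cnt * cfg$cx_atom_volume
    min(max((v - vi) / vi, 0), 100)
  }, numeric(1))
  expect_equal(got$protrusion, oracle, tolerance = 1e-12)

  # an atom at the centre of a dense ball tends to zero
  ball <- expand.grid(x = seq(-9, 9, 3), y = seq(-9, 9, 3), z = seq(-9, 9, 3))
  atoms <- purrr::map(seq_len(nrow(ball)), function(i) {
    a <- single_atom()
    a$serial <- i; a$seq_num <- i
    a[, c("x", "y", "z")] <- as.list(unlist(ball[i, ]))
    a
  }) |> purrr::list_rbind()
  pc <- protrusion(structure(list(atoms = atoms), class = "radt_structure"), cfg)
  centre <- which(ball$x == 0 & ball$y == 0 & ball$z == 0)
  expect_lt(pc$protrusion[centre], 1)
})

test_that("curvature recovers analytic limits: sphere 1/R, plane 0", {
  cfg <- feature_config(sasa_points = 120)
  sph <- make_synth_structure(synth_structure_config(
    n_residues = 80, geometry = "sphere_shell", radius = 15, jitter = 0))
  nf <- neighbourhood_features(sph, cfg = cfg)
  ok <- !is.na(nf$curvature)
  expect_gt(mean(ok), 0.9)
  expect_equal(nf$curvature[ok], rep(1 / 15, sum(ok)), tolerance = 0.05)

  flat <- make_synth_structure(synth_structure_config(
    n_residues = 49, geometry = "plane", jitter = 0))
  nf2 <- neighbourhood_features(flat, cfg = cfg)
  expect_true(all(abs(nf2$curvature[!is.na(nf2$curvature)]) < 0.01))
})

test_that("roughness increases when spike atoms are added to a smooth patch", {
  cfg <- feature_config(sasa_points = 240)
  sph <- make_synth_structure(synth_structure_config(
    n_residues = 60, geometry = "sphere_shell", radius = 12, jitter = 0))
  base <- neighbourhood_features(sph, cfg = cfg)
  # add a spike atom 3 A above every third residue: extra exposed area in
  # the same footprint
  spiky <- sph
  idx <- which(spiky$atoms$seq_num %% 3 == 0)
  extra <- spiky$atoms[idx, ]
  xyz <- as.matrix(extra[, c("x", "y", "z")])
  r <- sqrt(rowSums(xyz^2))
  extra[, c("x", "y", "z")] <- as.data.frame(xyz * (r + 3) / r)
  extra$serial <- max(spiky$atoms$serial) + seq_len(nrow(extra))
  extra$name <- "CB"
  spiky$atoms <- dplyr::bind_rows(spiky$atoms, extra)
  rough <- neighbourhood_features(spiky, cfg = cfg)
  ok <- !is.na(base$roughness) & !is.na(rough$roughness)
  expect_gt(mean(rough$roughness[ok]), mean(base$roughness[ok]))
  expect_true(all(base$roughness[!is.na(base$roughness)] > 0))
})

test_that("residues with too few neighbours are masked, not silently filled", {
  cfg <- feature_config()
  # three residues, far apart: nobody has 2 neighbours within 8 A
  s <- parse_structure(simple_chain_pdb(3, spacing = 20))
  nf <- neighbourhood_features(s, cfg = cfg)
  expect_true(all(is.na(nf$roughness)))
  expect_true(all(is.na(nf$curvature)))
})

test_that("physicochemical features match closed forms", {
  # uniform B-factors normalise to zero
  s <- parse_structure(simple_chain_pdb(5, b = rep(15, 5)))
  ph <- physicochemical_features(s, cfg = feature_config(sasa_points = 120))
  expect_equal(ph$bfactor_norm, rep(0, 5))
  expect_equal(ph$bfactor, rep(15, 5))
  expect_equal(ph$hydrophobicity,
               unname(radt:::FAUCHERE_PLISKA[c("ALA", "GLY", "SER", "ALA", "GLY")]))

  # a single charged residue with no partner charge has zero potential
  one_lys <- parse_structure(build_pdb(pdb_atom_line(1, "CA", "LYS", "A", 1, 0, 0, 0)))
  expect_equal(electrostatic_potential(one_lys)$epot, 0)

  # two unit charges 10 A apart, eps = 80, lambda = 8 A
  two_lys <- parse_structure(build_pdb(c(
    pdb_atom_line(1, "CA", "LYS", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "LYS", "A", 2, 10, 0, 0))))
  ep <- electrostatic_potential(two_lys)
  expect_equal(ep$epot, rep(exp(-10 / 8) / (80 * 10), 2), tolerance = 1e-9)
  # opposite charges flip the sign
  mixed <- parse_structure(build_pdb(c(
    pdb_atom_line(1, "CA", "LYS", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "GLU", "A", 2, 10, 0, 0))))
  epm <- electrostatic_potential(mixed)
  expect_lt(epm$epot[1], 0)
  expect_gt(epm$epot[2], 0)
})

test_that("propensity scale is log-odds of interface enrichment", {
  res <- rep(c("TRP", "ALA"), c(50, 50))
  lab <- c(rep(TRUE, 40), rep(FALSE, 10), rep(TRUE, 10), rep(FALSE, 40))
  ps <- propensity_scale(res, lab)
  expect_gt(ps[["TRP"]], 0) # enriched at interfaces
  expect_lt(ps[["ALA"]], 0)
  expect_equal(ps[["TRP"]], log((41 / 70) / (51 / 120)))
})

test_that("features are invariant under rigid-body motion", {
  cfg <- feature_config(sasa_points = 240)
  s <- make_synth_structure(synth_structure_config(n_residues = 25, geometry = "helix",
                                                   seed = 11))
  theta <- 0.7
  R <- matrix(c(cos(theta), -sin(theta), 0, sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
  s2 <- s
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% R
  s2$atoms$x <- xyz[, 1] + 13.7
  s2$atoms$y <- xyz[, 2] - 4.2
  s2$atoms$z <- xyz[, 3] + 1.1
  f1 <- compute_features(s, cfg = cfg)
  f2 <- compute_features(s2, cfg = cfg)
  for (col in c("protrusion", "hydrophobicity", "epot", "bfactor_norm")) {
    expect_equal(f2[[col]], f1[[col]], tolerance = 1e-6, info = col)
  }
  expect_equal(f2$relSESA, f1$relSESA, tolerance = 0.05)
  expect_equal(f2$esolv, f1$esolv, tolerance = 0.05)
})

test_that("feature computation is pure and correlates as expected", {
  cfg <- feature_config(sasa_points = 120)
  # two-shell structure: outer residues exposed, inner residues buried
  outer <- radt:::fibonacci_sphere(40) * 12
  inner <- radt:::fibonacci_sphere(25) * 5
  xyz <- rbind(outer, inner)
  atoms <- purrr::map(seq_len(nrow(xyz)), function(i) {
    a <- single_atom()
    a$serial <- i; a$seq_num <- i
    a$res_name <- rep_len(radt:::AA3, nrow(xyz))[i]
    a[, c("x", "y", "z")] <- as.list(xyz[i, ])
    a
  }) |> purrr::list_rbind()
  s <- structure(list(pdb_id = "SHELL", atoms = atoms,
                      compnd = tibble::tibble(mol_id = 1L, molecule = NA,
                                              chains = list("A")),
                      resolution = 2, ssbond_count = 0L, conect_count = 0L,
                      biomt = list(), has_nucleotides = FALSE,
                      all_atoms_have_bfactor = TRUE,
                      is_antibody_complex = FALSE),
                 class = "radt_structure")
  f1 <- compute_features(s, cfg = cfg)
  f2 <- compute_features(s, cfg = cfg)
  expect_identical(f1, f2) # purity
  # exposure-driven features agree: protrusion vs relSESA strongly positive
  expect_gt(cor(f1$protrusion, f1$relSESA), 0.5)
})

test_that("external feature injection joins, masks and validates", {
  s <- make_synth_structure(synth_structure_config(n_residues = 10), pdb_id = "SYN1")
  f <- compute_features(s, cfg = feature_config(sasa_points = 120))
  ext <- tibble::tibble(pdb_id = "SYN1", chain = "A", seq_num = 1:10,
                        icode = "", scorecons = runif(10),
                        rate4site = rnorm(10), disorder = runif(10))
  full <- load_external_features(ext, f)
  expect_false(anyNA(full$scorecons))

  part <- load_external_features(ext[-(2:4), ], f)
  expect_equal(sum(is.na(part$scorecons)), 3)
  mask <- feature_mask(part)
  expect_equal(sum(mask$scorecons), 3)

  shuf <- load_external_features(ext[sample(10), ], f)
  expect_equal(shuf$scorecons, full$scorecons)

  expect_error(load_external_features(ext[c(1, 1:10), ], f), "duplicate")
  bad <- ext
  bad$rate4site <- as.character(bad$rate4site)
  bad$rate4site[5] <- "not-a-number"
  expect_error(load_external_features(bad, f), "row 5")
})
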