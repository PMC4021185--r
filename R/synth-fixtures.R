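# Deterministic, download-free fixtures: coarse CA-only structures with
# known contact geometry, and planted-signal instance tables with known
# informative features.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Synthetic structure configuration
#'
#' @param n_residues residues per chain.
#' @param geometry one of "extended", "helix", "sphere_shell", "plane".
#' @param n_chains number of chains (entities) in a complex fixture.
#' @param gap inter-chain gap in Angstroms for complex fixtures (> 6 so
#'   non-patch residues are unambiguously non-contacting).
#' @param patch_size number of contiguous contact residues planted at 3.8 A.
#' @param radius sphere radius for the "sphere_shell" geometry.
#' @param jitter coordinate jitter amplitude (A); small enough to keep the
#'   4.5 A contact rule unambiguous (no pair lands in \[4.4, 6.0\] A).
#' @param seed RNG seed (B-factors and jitter).
#' @return a `synth_structure_config` list.
#' @export
synth_structure_config <- function(n_residues = 50, geometry = "extended",
                                   n_chains = 1, gap = 12, patch_size = 5,
                                   radius = 15, jitter = 0.05, seed = 1) {
  geometry <- match.arg(geometry, c("extended", "helix", "sphere_shell", "plane"))
  stopifnot(gap > 6, patch_size <= n_residues, jitter >= 0)
  structure(as.list(environment()), class = "synth_structure_config")
}

backbone_coords <- function(cfg) {
  n <- cfg$n_residues
  switch(cfg$geometry,
    extended = cbind(5 * (seq_len(n) - 1), 0, 0),
    helix = cbind(1.5 * seq_len(n),
                  2.3 * cos(seq_len(n) * 100 * pi / 180),
                  2.3 * sin(seq_len(n) * 100 * pi / 180)),
    sphere_shell = fibonacci_sphere(n) * cfg$radius,
    plane = {
      k <- ceiling(sqrt(n))
      g <- expand.grid(x = 5 * seq_len(k), y = 5 * seq_len(k))[seq_len(n), ]
      cbind(g$x, g$y, 0)
    }
  )
}

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

atom_line <- function(serial, name, res_name, chain, seq_num, x, y, z, b,
                      element = substr(name, 1, 1)) {
  sprintf("ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, res_name, chain, seq_num, x, y, z, 1.00, b, element)
}

#' Emit a synthetic single-chain structure as PDB text
#'
#' CA-only residues placed on the configured geometry, with seeded jitter
#' and B-factors; residue names cycle through the 20 standard amino acids.
#'
#' @param cfg a [synth_structure_config()].
#' @return PDB-format text (character scalar). Deterministic under seed.
#' @export
synth_structure_pdb <- function(cfg = synth_structure_config()) {
  with_seed(cfg$seed, {
    xyz <- backbone_coords(cfg)
    xyz <- xyz + matrix(runif(length(xyz), -cfg$jitter, cfg$jitter), ncol = 3)
    b <- round(runif(nrow(xyz), 10, 50), 2)
    res_names <- rep_len(AA3, nrow(xyz))
    lines <- c(
      "COMPND     MOL_ID: 1;",
      "COMPND   2 MOLECULE: SYNTHETIC PROTEIN;",
      "COMPND   3 CHAIN: A;",
      "REMARK   2 RESOLUTION.    2.00 ANGSTROMS.",
      vapply(seq_len(nrow(xyz)), function(i) {
        atom_line(i, "CA", res_names[i], "A", i,
                  xyz[i, 1], xyz[i, 2], xyz[i, 3], b[i], element = "C")
      }, character(1)),
      "TER", "END"
    )
    paste0(paste(lines, collapse = "\n"), "\n")
  })
}

#' @rdname synth_structure_pdb
#' @param pdb_id identifier for the parsed structure.
#' @return `make_synth_structure()` returns the parsed `radt_structure`.
#' @export
make_synth_structure <- function(cfg = synth_structure_config(), pdb_id = "SYN1") {
  parse_structure(synth_structure_pdb(cfg), pdb_id = pdb_id)
}

#' Build a toy monomer/complex pair with a known contact patch
#'
#' Two CA-only chains laid out in parallel: chain A at y = 0, chain B at
#' y = `gap`, except over a contiguous patch where B's residues sit at
#' 3.8 A from their A counterparts. By construction no atom pair falls in
#' the ambiguous band between 4.4 and 6.0 A, so the 4.5 A contact rule
#' recovers exactly the planted patch. The complex file carries two COMPND
#' entities; the monomer file is chain A alone.
#'
#' @param cfg a [synth_structure_config()]; `patch_size` residues starting
#'   at the centre of the chain form the patch (`patch_size = 0` plants no
#'   contact at all).
#' @return list with `monomer` and `complex` (`radt_structure`s), `truth`
#'   (tibble of chain A residue keys with the ground-truth `label`), and
#'   `monomer_pdb` / `complex_pdb` text.
#' @export
make_toy_complex <- function(cfg = synth_structure_config()) {
  n <- cfg$n_residues
  patch <- if (cfg$patch_size > 0) {
    start <- max(1L, (n - cfg$patch_size) %/% 2L)
    seq.int(start, length.out = cfg$patch_size)
  } else integer()
  with_seed(cfg$seed, {
    xa <- 5 * (seq_len(n) - 1)
    jit <- function(k) runif(k, -cfg$jitter, cfg$jitter)
    ya <- jit(n); za <- jit(n)
    yb <- rep(cfg$gap, n); yb[patch] <- 3.8
    yb <- yb + jit(n); zb <- jit(n)
    ba <- round(runif(n, 10, 50), 2)
    bb <- round(runif(n, 10, 50), 2)
    res_names <- rep_len(AA3, n)
    a_lines <- vapply(seq_len(n), function(i) {
      atom_line(i, "CA", res_names[i], "A", i, xa[i], ya[i], za[i], ba[i], "C")
    }, character(1))
    b_lines <- vapply(seq_len(n), function(i) {
      atom_line(n + i, "CA", res_names[i], "B", i, xa[i], yb[i], zb[i], bb[i], "C")
    }, character(1))
    mono_txt <- paste0(paste(c(
      "COMPND     MOL_ID: 1;",
      "COMPND   2 MOLECULE: SYNTHETIC MONOMER;",
      "COMPND   3 CHAIN: A;",
      "REMARK   2 RESOLUTION.    2.00 ANGSTROMS.",
      a_lines, "TER", "END"), collapse = "\n"), "\n")
    cplx_txt <- paste0(paste(c(
      "COMPND     MOL_ID: 1;",
      "COMPND   2 MOLECULE: SYNTHETIC ENTITY ONE;",
      "COMPND   3 CHAIN: A;",
      "COMPND   4 MOL_ID: 2;",
      "COMPND   5 MOLECULE: SYNTHETIC ENTITY TWO;",
      "COMPND   6 CHAIN: B;",
      "REMARK   2 RESOLUTION.    2.00 ANGSTROMS.",
      a_lines, "TER", b_lines, "TER", "END"), collapse = "\n"), "\n")
    monomer <- parse_structure(mono_txt, pdb_id = "SYNM")
    complex <- parse_structure(cplx_txt, pdb_id = "SYNC")
    truth <- chain_residue_keys(monomer, "A")
    truth$label <- seq_len(n) %in% patch
    list(monomer = monomer, complex = complex, truth = truth,
         monomer_pdb = mono_txt, complex_pdb = cplx_txt)
  })
}

#' Planted-signal instance generator configuration
#'
#' Defaults emulate the better-labelled training conditions: 12 proteins of
#' 40 residues each, 26% of residues interacting (the observed rate in a
#' one-interface-per-100-residues subset), two informative features whose
#' class-conditional means are separated by 2 SD, and six pure-noise
#' features.
#'
#' @param n_proteins,residues_per_protein dataset dimensions.
#' @param n_informative,n_noise feature counts.
#' @param effect_size class separation of informative features, in SD units.
#' @param positive_fraction fraction of interacting residues per protein.
#' @param seed RNG seed.
#' @return a `planted_signal_config` list.
#' @export
planted_signal_config <- function(n_proteins = 12, residues_per_protein = 40,
                                  n_informative = 2, n_noise = 6,
                                  effect_size = 2, positive_fraction = 0.26,
                                  seed = 1) {
  stopifnot(effect_size >= 0, positive_fraction > 0, positive_fraction < 1,
            n_informative >= 1)
  structure(as.list(environment()), class = "planted_signal_config")
}

#' Generate a planted-signal instance table
#'
#' Informative features are drawn from class-conditional normal
#' distributions N(0, 1) for non-interacting and N(effect_size, 1) for
#' interacting residues; noise features are N(0, 1) regardless of class.
#' The per-protein positive count is exact: round(residues x fraction).
#'
#' @param cfg a [planted_signal_config()].
#' @return tibble: protein_id, chain_id, seq_num, insertion_code, label
#'   (logical), and feature columns `inf1..infK`, `noise1..noiseM`, with the
#'   informative feature names in `attr(, "informative")`.
#' @export
make_planted_instances <- function(cfg = planted_signal_config()) {
  inf_names <- paste0("inf", seq_len(cfg$n_informative))
  noise_names <- if (cfg$n_noise > 0) paste0("noise", seq_len(cfg$n_noise)) else character()
  with_seed(cfg$seed, {
    rows <- purrr::map(seq_len(cfg$n_proteins), function(p) {
      n <- cfg$residues_per_protein
      npos <- round(n * cfg$positive_fraction)
      label <- sample(rep(c(TRUE, FALSE), c(npos, n - npos)))
      feats <- c(
        setNames(purrr::map(inf_names, ~ rnorm(n, mean = cfg$effect_size * label)),
                 inf_names),
        setNames(purrr::map(noise_names, ~ rnorm(n)), noise_names)
      )
      tibble::tibble(protein_id = sprintf("P%02d", p), chain_id = "A",
                     seq_num = seq_len(n), insertion_code = "",
                     label = label, !!!feats)
    })
    out <- purrr::list_rbind(rows)
    attr(out, "informative") <- inf_names
    out
  })
}
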