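# two-entity complex with controlled inter-chain distance d between the
# CA atoms of residue 1 of each chain; other residues far apart.
two_entity_pdb <- function(d, n = 3) {
  a <- vapply(seq_len(n), function(i) {
    pdb_atom_line(i, "CA", "ALA", "A", i, 5 * (i - 1), 0, 0)
  }, character(1))
  b <- vapply(seq_len(n), function(i) {
    pdb_atom_line(n + i, "CA", "ALA", "B", i, 5 * (i - 1),
                  ifelse(i == 1, d, 50), 0)
  }, character(1))
  parse_structure(build_pdb(c(a, b), chains_by_mol = list("A", "B")),
                  pdb_id = "CPLX")
}

mono_pdb <- function(n = 3) {
  a <- vapply(seq_len(n), function(i) {
    pdb_atom_line(i, "CA", "ALA", "A", i, 5 * (i - 1), 0, 0)
  }, character(1))
  parse_structure(build_pdb(a), pdb_id = "MONO")
}

test_that("monomer-complex matching applies the inclusive 80% identity rule", {
  toy <- make_toy_complex(synth_structure_config(n_residues = 100, patch_size = 5))
  m <- match_monomer_to_complex(toy$monomer, toy$complex)
  expect_equal(nrow(m), 2) # both chains identical to the monomer here
  expect_equal(m$identity, c(1, 1))

  # mutate chain B: 21 mismatches -> 0.79, no match; 20 -> 0.80, match
  mutate_chain <- function(cplx, chain, k) {
    idx <- which(cplx$atoms$chain_id == chain & cplx$atoms$seq_num <= k)
    cplx$atoms$res_name[idx] <- ifelse(cplx$atoms$res_name[idx] == "TRP",
                                       "GLY", "TRP")
    cplx
  }
  c79 <- mutate_chain(mutate_chain(toy$complex, "B", 21), "A", 21)
  m79 <- match_monomer_to_complex(toy$monomer, c79)
  expect_equal(nrow(m79), 0)
  c80 <- mutate_chain(mutate_chain(toy$complex, "B", 20), "A", 20)
  m80 <- match_monomer_to_complex(toy$monomer, c80)
  expect_equal(nrow(m80), 2)
  expect_equal(m80$identity, c(0.80, 0.80))
})

test_that("the 4.5 A atom-pair rule is inclusive and zero contact rejects", {
  mono <- mono_pdb()
  # exactly 4.50 A: both owning residues interact
  c450 <- two_entity_pdb(4.5)
  m <- match_monomer_to_complex(mono, c450)
  m <- m[m$complex_chain == "A", ]
  lab <- label_interface(m, c450, mono)
  expect_identical(lab$labels$label, c(TRUE, FALSE, FALSE))

  # 4.51 A and no other contact anywhere: rejection
  c451 <- two_entity_pdb(4.51)
  m2 <- match_monomer_to_complex(mono, c451)
  expect_error(label_interface(m2[m2$complex_chain == "A", ], c451, mono),
               "no inter-entity atom pair")
})

test_that("labelling equals the all-pairs atom distance oracle on toys", {
  for (seed in 1:3) {
    toy <- make_toy_complex(synth_structure_config(
      n_residues = 20, patch_size = 4, seed = seed))
    m <- match_monomer_to_complex(toy$monomer, toy$complex)
    m <- m[m$complex_chain == "A", ]
    lab <- label_interface(m, toy$complex, toy$monomer)
    oracle <- oracle_contact_residues(toy$complex, "A", "B", 4.5)
    got <- paste(lab$labels$seq_num[lab$labels$label],
                 lab$labels$insertion_code[lab$labels$label])
    expect_setequal(got, oracle)
    expect_identical(lab$labels$label, toy$truth$label)
  }
})

test_that("raising the cutoff never removes an interacting label", {
  toy <- make_toy_complex(synth_structure_config(n_residues = 25, patch_size = 5))
  m <- match_monomer_to_complex(toy$monomer, toy$complex)
  m <- m[m$complex_chain == "A", ]
  lab1 <- label_interface(m, toy$complex, toy$monomer, cutoff = 4.5)
  lab2 <- label_interface(m, toy$complex, toy$monomer, cutoff = 7.0)
  expect_true(all(lab2$labels$label[lab1$labels$label]))
})

test_that("low mapped-residue coverage rejects the labelling", {
  toy <- make_toy_complex(synth_structure_config(n_residues = 20, patch_size = 4))
  cplx <- toy$complex
  # drop 3 of chain A's 20 residues from the complex: 85% coverage
  drop <- cplx$atoms$chain_id == "A" & cplx$atoms$seq_num %in% 1:3
  cplx$atoms <- cplx$atoms[!drop, ]
  m <- match_monomer_to_complex(toy$monomer, cplx)
  m <- m[m$complex_chain == "A", ]
  expect_error(label_interface(m, cplx, toy$monomer), "85.0%")
})

test_that("interface sites are single-linkage clusters matching a graph oracle", {
  toy <- make_toy_complex(synth_structure_config(n_residues = 20, patch_size = 0))
  truth_lab <- structure(list(monomer_id = "SYNM", chain_id = "A",
                              labels = dplyr::mutate(toy$truth, sources = list(NULL)),
                              mapped_residue_fraction = 1),
                         class = "interface_labeling")
  expect_equal(nrow(interface_sites(truth_lab, toy$monomer)), 0)

  # two interacting residues 30 A apart: two sites
  lab2 <- truth_lab
  lab2$labels$label[c(1, 7)] <- TRUE # x = 0 and x = 30
  s2 <- interface_sites(lab2, toy$monomer)
  expect_equal(length(unique(s2$site_id)), 2)

  # planted two-patch fixture vs brute-force connected components
  lab3 <- truth_lab
  lab3$labels$label[c(2, 3, 4, 11, 12, 18)] <- TRUE
  s3 <- interface_sites(lab3, toy$monomer, link_cutoff = 6)
  keys <- lab3$labels[lab3$labels$label, ]
  oracle <- oracle_site_components(toy$monomer, keys, 6)
  # same partition (site ids up to relabelling)
  expect_equal(length(unique(s3$site_id)), length(unique(oracle)))
  expect_true(all(tapply(oracle, s3$site_id, function(v) length(unique(v))) == 1))
})

test_that("interface-site rates define NI membership", {
  mk_lab <- function(len) {
    structure(list(monomer_id = "X", chain_id = "A",
                   labels = tibble::tibble(chain_id = "A", seq_num = seq_len(len),
                                           insertion_code = "", res_name = "ALA",
                                           label = FALSE, sources = list(NULL)),
                   mapped_residue_fraction = 1),
              class = "interface_labeling")
  }
  sites_of <- function(k) tibble::tibble(site_id = rep(seq_len(k), each = 2))
  r <- ni_rate(mk_lab(150), sites_of(2))
  expect_equal(r$rate, 100 * 2 / 150, tolerance = 1e-12)
  expect_true(r$ni1); expect_false(r$ni2)
  r0 <- ni_rate(mk_lab(100), sites_of(0)[0, ])
  expect_equal(r0$rate, 0); expect_false(r0$ni1)
  r3 <- ni_rate(mk_lab(100), sites_of(3))
  expect_equal(r3$rate, 3); expect_true(r3$ni1 && r3$ni2)
})

test_that("labels from several complexes combine as an order-independent OR", {
  toy <- make_toy_complex(synth_structure_config(n_residues = 20, patch_size = 3, seed = 5))
  m <- match_monomer_to_complex(toy$monomer, toy$complex)
  labA <- label_interface(m[m$complex_chain == "A", ], toy$complex, toy$monomer)
  # a second complex with the patch elsewhere: shift contact to residues 2-4
  toy2 <- make_toy_complex(synth_structure_config(n_residues = 20, patch_size = 3, seed = 6))
  toy2$complex$atoms$y[toy2$complex$atoms$chain_id == "B"] <- 50
  sel <- toy2$complex$atoms$chain_id == "B" & toy2$complex$atoms$seq_num %in% 2:4
  toy2$complex$atoms$y[sel] <- 3.8
  m2 <- match_monomer_to_complex(toy$monomer, toy2$complex)
  labB <- label_interface(m2[m2$complex_chain == "A", ], toy2$complex, toy$monomer)

  ab <- combine_labelings(list(labA, labB))
  ba <- combine_labelings(list(labB, labA))
  expect_identical(ab$labels$label, labA$labels$label | labB$labels$label)
  expect_identical(ab$labels$label, ba$labels$label)
  # idempotent
  aa <- combine_labelings(list(labA, labA))
  expect_identical(aa$labels$label, labA$labels$label)
})
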