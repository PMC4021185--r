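# Build small custom PDB fixtures in code.

pdb_atom_line <- function(serial, name, res_name, chain, seq_num, x, y, z,
                          b = 20, occ = 1, alt = " ", icode = " ",
                          element = substr(name, 1, 1), record = "ATOM  ",
                          b_text = NULL) {
  b_field <- if (is.null(b_text)) sprintf("%6.2f", b) else sprintf("%6s", b_text)
  sprintf("%-6s%5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%s          %2s",
          record, serial, name, alt, res_name, chain, seq_num, icode,
          x, y, z, occ, b_field, element)
}

pdb_compnd <- function(chains_by_mol) {
  lines <- character()
  k <- 1L
  for (i in seq_along(chains_by_mol)) {
    lines <- c(lines,
               sprintf("COMPND %3s MOL_ID: %d;", if (k == 1) "" else as.character(k), i),
               sprintf("COMPND %3d CHAIN: %s;", k + 1L,
                       paste(chains_by_mol[[i]], collapse = ", ")))
    k <- k + 2L
  }
  lines
}

build_pdb <- function(atom_lines, chains_by_mol = list("A"),
                      resolution = 2.0, extra = character()) {
  paste0(paste(c(
    pdb_compnd(chains_by_mol),
    if (!is.na(resolution))
      sprintf("REMARK   2 RESOLUTION. %7.2f ANGSTROMS.", resolution),
    extra,
    atom_lines,
    "END"), collapse = "\n"), "\n")
}

# a minimal k-residue single-chain structure along the x axis
simple_chain_pdb <- function(k = 3, res_names = rep_len(c("ALA", "GLY", "SER"), k),
                             chain = "A", spacing = 5, b = seq(10, by = 1, length.out = k),
                             y = 0) {
  lines <- vapply(seq_len(k), function(i) {
    pdb_atom_line(i, "CA", res_names[i], chain, i, spacing * (i - 1), y, 0,
                  b = b[i], element = "C")
  }, character(1))
  build_pdb(lines)
}
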