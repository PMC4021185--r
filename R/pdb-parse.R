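#' Parse a PDB-format structure
#'
#' Reads the fixed-column PDB records needed by the curation and labelling
#' pipeline: `ATOM`/`HETATM` coordinates with occupancies and B-factors,
#' `COMPND` molecule entries (the monomer/complex distinction), `REMARK 2`
#' resolution, `SSBOND` and `CONECT` record counts, and `REMARK 350` `BIOMT`
#' biological-assembly transforms. Only the first NMR model is kept.
#' Alternate locations are resolved to the highest-occupancy conformer
#' (ties broken by alternate-location character order). Hetero residues are
#' dropped except modified standard residues (e.g. selenomethionine), which
#' are retained for geometry but excluded from chain sequences.
#'
#' @param pdb_text character scalar (possibly multi-line) or character vector
#'   of lines with the PDB file content.
#' @param pdb_id optional identifier; defaults to the `HEADER` id or "XXXX".
#' @return An object of class `radt_structure`: a list with
#'   `pdb_id`, `atoms` (tibble: serial, name, alt_loc, res_name, chain_id,
#'   seq_num, insertion_code, x, y, z, occupancy, b_factor, element, het),
#'   `compnd` (tibble: mol_id, molecule, chains), `resolution` (Angstroms or
#'   `NA`), `ssbond_count`, `conect_count`, `biomt` (list of transforms),
#'   `has_nucleotides`, `all_atoms_have_bfactor`, `is_antibody_complex`.
#' @examples
#' s <- parse_structure(synth_structure_pdb(synth_structure_config(n_residues = 3)))
#' n_chains(s)
#' @export
parse_structure <- function(pdb_text, pdb_id = NULL) {
  lines <- if (length(pdb_text) == 1L && grepl("\n", pdb_text, fixed = TRUE)) {
    strsplit(pdb_text, "\n", fixed = TRUE)[[1]]
  } else {
    pdb_text
  }
  rec <- substr(lines, 1, 6)

  # first model only
  endmdl <- which(trimws(rec) == "ENDMDL")
  if (length(endmdl) > 0) {
    lines <- lines[seq_len(endmdl[1] - 1L)]
    rec <- rec[seq_len(endmdl[1] - 1L)]
  }

  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(is_atom)) {
    abort("no ATOM records found: not a parseable PDB structure")
  }

  atoms <- parse_atom_lines(lines[is_atom], which(is_atom))
  compnd <- parse_compnd(lines[rec == "COMPND"])
  if (nrow(compnd) == 0) {
    # headerless files: one implicit molecule spanning all chains
    compnd <- tibble::tibble(
      mol_id = 1L, molecule = NA_character_,
      chains = list(unique(atoms$chain_id))
    )
  }

  has_nucleotides <- any(atoms$res_name %in% NUCLEOTIDES)

  standard <- atoms$res_name %in% AA3
  modified <- atoms$res_name %in% names(MODIFIED_AA)
  keep <- standard | (modified & atoms$het)
  atoms <- atoms[standard | modified, , drop = FALSE][
    keep[standard | modified], , drop = FALSE]

  atoms <- resolve_altlocs(atoms)

  header <- lines[rec %in% c("HEADER", "TITLE ", "COMPND")]
  structure(
    list(
      pdb_id = pdb_id %||% parse_header_id(lines[rec == "HEADER"]),
      atoms = atoms,
      compnd = compnd,
      resolution = parse_resolution(lines[rec == "REMARK"]),
      ssbond_count = sum(rec == "SSBOND"),
      conect_count = sum(rec == "CONECT"),
      biomt = parse_biomt(lines[rec == "REMARK"]),
      has_nucleotides = has_nucleotides,
      all_atoms_have_bfactor = !anyNA(atoms$b_factor),
      is_antibody_complex = detect_antibody(header)
    ),
    class = "radt_structure"
  )
}

#' Read a PDB file from disk
#'
#' @param path path to a PDB-format file.
#' @inheritParams parse_structure
#' @return A [parse_structure()] `radt_structure`.
#' @export
read_pdb <- function(path, pdb_id = NULL) {
  if (is.null(pdb_id)) {
    pdb_id <- toupper(sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE))
  }
  parse_structure(readLines(path, warn = FALSE), pdb_id = pdb_id)
}

parse_atom_lines <- function(x, line_numbers) {
  pad <- function(s) formatC(s, width = 80, flag = "-")
  x <- pad(x)
  num <- function(field, from, to, required = TRUE) {
    raw <- trimws(substr(x, from, to))
    v <- suppressWarnings(as.numeric(raw))
    bad <- is.na(v) & raw != ""
    if (any(bad)) {
      abort(sprintf("malformed %s field at line %d: '%s'",
                    field, line_numbers[which(bad)[1]],
                    trimws(x[which(bad)[1]])))
    }
    if (required && any(raw == "")) {
      abort(sprintf("missing %s field at line %d",
                    field, line_numbers[which(raw == "")[1]]))
    }
    v
  }
  element <- trimws(substr(x, 77, 78))
  name <- trimws(substr(x, 13, 16))
  # infer element from the atom name when column 77-78 is blank
  element <- ifelse(element == "", gsub("[^A-Za-z].*$", "", sub("^[0-9]*", "", name)), element)
  element <- toupper(substr(element, 1, 2))
  element <- ifelse(element %in% c("SE", "CL", "BR", "ZN", "FE", "MG", "MN"),
                    element, substr(element, 1, 1))
  occ <- num("occupancy", 55, 60, required = FALSE)
  is_het <- substr(x, 1, 6) == "HETATM"
  tibble::tibble(
    serial = as.integer(num("serial", 7, 11)),
    name = name,
    alt_loc = substr(x, 17, 17),
    res_name = trimws(substr(x, 18, 20)),
    chain_id = substr(x, 22, 22),
    seq_num = as.integer(num("residue number", 23, 26)),
    insertion_code = trimws(substr(x, 27, 27)),
    x = num("x coordinate", 31, 38),
    y = num("y coordinate", 39, 46),
    z = num("z coordinate", 47, 54),
    occupancy = ifelse(is.na(occ), 1, occ),
    b_factor = num("B-factor", 61, 66, required = FALSE),
    element = element,
    het = is_het
  )
}

resolve_altlocs <- function(atoms) {
  atoms$alt_loc <- trimws(atoms$alt_loc)
  if (all(atoms$alt_loc == "")) return(atoms)
  atoms |>
    dplyr::group_by(.data$chain_id, .data$seq_num, .data$insertion_code, .data$name) |>
    dplyr::arrange(dplyr::desc(.data$occupancy), .data$alt_loc, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$serial)
}

parse_compnd <- function(x) {
  if (length(x) == 0) {
    return(tibble::tibble(mol_id = integer(), molecule = character(),
                          chains = list()))
  }
  content <- trimws(substr(x, 11, 80))
  tokens <- strsplit(sub(";\\s*$", "", content), ":\\s*")
  mol_ids <- integer()
  molecules <- character()
  chains <- list()
  cur <- 0L
  for (tk in tokens) {
    if (length(tk) < 2) next
    key <- toupper(trimws(tk[1]))
    val <- trimws(paste(tk[-1], collapse = ":"))
    if (key == "MOL_ID") {
      cur <- cur + 1L
      mol_ids[cur] <- suppressWarnings(as.integer(val))
      molecules[cur] <- NA_character_
      chains[[cur]] <- character()
    } else if (cur > 0 && key == "MOLECULE") {
      molecules[cur] <- val
    } else if (cur > 0 && key == "CHAIN") {
      chains[[cur]] <- trimws(strsplit(val, ",")[[1]])
    }
  }
  tibble::tibble(mol_id = mol_ids, molecule = molecules, chains = chains)
}

parse_resolution <- function(remarks) {
  r2 <- remarks[trimws(substr(remarks, 8, 10)) == "2"]
  hit <- grep("RESOLUTION\\.", r2, value = TRUE)
  if (length(hit) == 0) return(NA_real_)
  m <- regmatches(hit[1], regexpr("[0-9]+\\.?[0-9]*(?=\\s*ANGSTROM)", hit[1], perl = TRUE))
  if (length(m) == 0) return(NA_real_)
  as.numeric(m)
}

parse_biomt <- function(remarks) {
  r350 <- remarks[trimws(substr(remarks, 8, 10)) == "350"]
  if (length(r350) == 0) return(list())
  out <- list()
  chains <- character()
  rows <- list()
  flush_chain <- function(line) {
    m <- sub(".*CHAINS:\\s*", "", line)
    trimws(strsplit(m, ",")[[1]])
  }
  for (ln in r350) {
    body <- substr(ln, 12, nchar(ln))
    if (grepl("APPLY THE FOLLOWING TO CHAINS:", body)) {
      chains <- flush_chain(body)
    } else if (grepl("^\\s*BIOMT[123]", body)) {
      f <- strsplit(trimws(body), "\\s+")[[1]]
      row_i <- as.integer(substr(f[1], 6, 6))
      tid <- as.integer(f[2])
      vals <- as.numeric(f[3:6])
      key <- as.character(tid)
      if (is.null(rows[[key]])) {
        rows[[key]] <- list(id = tid, chains = chains,
                            R = matrix(NA_real_, 3, 3), t = rep(NA_real_, 3))
      }
      rows[[key]]$R[row_i, ] <- vals[1:3]
      rows[[key]]$t[row_i] <- vals[4]
      # chains stanza precedes its BIOMT rows; remember current chain scope
      rows[[key]]$chains <- chains
    }
  }
  unname(rows)
}

parse_header_id <- function(header) {
  if (length(header) == 0) return("XXXX")
  id <- trimws(substr(header[1], 63, 66))
  if (id == "") "XXXX" else id
}

detect_antibody <- function(header_lines) {
  any(grepl("\\b(antibody|immunoglobulin|fab|fv)\\b",
            header_lines, ignore.case = TRUE))
}

#' @export
print.radt_structure <- function(x, ...) {
  cat(sprintf("<radt_structure> %s: %d chain(s), %d residue(s), %d atom(s)\n",
              x$pdb_id, n_chains(x), nrow(structure_residues(x)), nrow(x$atoms)))
  cat(sprintf("  %s | resolution %s A | SSBOND %d | CONECT %d | BIOMT %d\n",
              if (is_monomer(x)) "monomer" else "complex",
              ifelse(is.na(x$resolution), "NA", format(x$resolution)),
              x$ssbond_count, x$conect_count, length(x$biomt)))
  invisible(x)
}
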