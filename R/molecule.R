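#' Molecular data model and structure input
#'
#' A `coformr_molecule` is a light container: an atom table (element, 3D
#' coordinates in Angstrom, Gasteiger partial charge in elementary-charge
#' units, Bondi van der Waals radius, polarity flag for N/O/S, formal charge,
#' aromaticity), a bond table (1-based atom indices, bond order, aromatic
#' flag), a name and a canonical SMILES. Explicit hydrogens are always
#' present, and inputs must be a single covalent unit: salts and other
#' multi-fragment records are rejected.
#'
#' @name molecule
NULL

new_molecule <- function(rec) {
  a <- rec$atoms
  element <- unlist(a$element)
  fc <- as.integer(unlist(a$formal_charge))
  q <- as.numeric(unlist(a$partial_charge))
  # charge models conserve the total formal charge; remove serialisation
  # round-off so neutral molecules have an exactly origin-free dipole
  q <- q - (sum(q) - sum(fc)) / length(q)
  atoms <- tibble::tibble(
    element = element,
    x = NA_real_, y = NA_real_, z = NA_real_,
    formal_charge = fc,
    partial_charge = q,
    vdw_radius = vdw_radius_of(element),
    is_polar = element %in% POLAR_ELEMENTS,
    aromatic = as.logical(unlist(a$aromatic)),
    in_ring = as.logical(unlist(a$in_ring))
  )
  b <- rec$bonds
  bonds <- tibble::tibble(
    i = as.integer(unlist(b$i)),
    j = as.integer(unlist(b$j)),
    order = as.numeric(unlist(b$order)),
    aromatic = as.logical(unlist(b$aromatic))
  )
  stopifnot(all(bonds$i >= 1), all(bonds$j <= nrow(atoms)))
  coords <- conformer_matrix(rec$conformers[[1]])
  atoms$x <- coords[, 1]; atoms$y <- coords[, 2]; atoms$z <- coords[, 3]
  structure(
    list(name = rec$name, smiles = rec$smiles, atoms = atoms, bonds = bonds),
    class = "coformr_molecule"
  )
}

conformer_matrix <- function(conf) {
  m <- do.call(rbind, lapply(conf, function(p) as.numeric(unlist(p))))
  colnames(m) <- c("x", "y", "z")
  m
}

#' @export
print.coformr_molecule <- function(x, ...) {
  heavy <- sum(x$atoms$element != "H")
  cat("<coformr_molecule> ", x$name, "\n", sep = "")
  cat("  ", x$smiles, "\n", sep = "")
  cat("  ", nrow(x$atoms), " atoms (", heavy, " heavy), ",
      nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

#' Read small-molecule structures
#'
#' Parses a SMILES file (one record per line, optional whitespace-separated
#' name) or an SDF (V2000/V3000), adds explicit hydrogens, assigns Gasteiger
#' partial charges, and produces one 3D geometry per molecule (ETKDG
#' embedding with the given seed when the input has no 3D coordinates).
#'
#' @param path Path to the structure file.
#' @param format `"smiles"` or `"sdf"`. Defaults from the file extension.
#' @param seed Integer seed for 3D embedding (deterministic).
#' @return A named list of `coformr_molecule` objects.
#' @export
read_structures <- function(path, format = c("smiles", "sdf"), seed = 1L) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (missing(format)) {
    format <- if (grepl("\\.sdf$|\\.mol$", path, ignore.case = TRUE)) "sdf" else "smiles"
  }
  format <- match.arg(format)
  records <- if (format == "smiles") smiles_records(path) else sdf_records(path)
  if (length(records) == 0) abort(paste0("No records found in ", path))
  build_molecules(records, seed = seed)
}

#' Build a molecule from a SMILES string
#'
#' @param smiles SMILES string.
#' @param name Molecule name.
#' @param seed Integer seed for the 3D embedding.
#' @return A `coformr_molecule`.
#' @export
#' @examples
#' \dontrun{
#' mol_from_smiles("CC(=O)O", "acetic_acid")
#' }
mol_from_smiles <- function(smiles, name = "unnamed", seed = 1L) {
  build_molecules(list(list(name = name, smiles = smiles)), seed = seed)[[1]]
}

build_molecules <- function(records, seed = 1L) {
  res <- run_prep(records, n_confs = 1, seed = seed)
  bad <- which(map_lgl(res, ~ !is.null(.x$error)))
  if (length(bad) > 0) {
    msgs <- map_chr(bad, function(k) {
      paste0("record ", k, " (", res[[k]]$name, "): ", res[[k]]$error)
    })
    abort(paste0("Structure input failed:\n  ",
                 paste(msgs, collapse = "\n  ")))
  }
  mols <- map(res, new_molecule)
  names(mols) <- map_chr(mols, "name")
  mols
}

smiles_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  imap(lines, function(line, k) {
    parts <- strsplit(line, "[ \t]+")[[1]]
    list(name = if (length(parts) > 1) paste(parts[-1], collapse = " ")
         else paste0("mol_", k),
         smiles = parts[[1]])
  })
}

sdf_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  idx <- cumsum(c(1, head(grepl("^\\$\\$\\$\\$", lines), -1)))
  blocks <- split(lines, idx)
  blocks <- keep(blocks, function(b) {
    any(nzchar(trimws(b)) & !grepl("^\\$\\$\\$\\$", b))
  })
  imap(unname(blocks), function(b, k) {
    b <- b[!grepl("^\\$\\$\\$\\$", b)]
    nm <- trimws(b[[1]])
    list(name = if (nzchar(nm)) nm else paste0("mol_", k),
         molblock = paste(c(b, ""), collapse = "\n"))
  })
}

# ---- small accessors used throughout ----------------------------------------

n_atoms <- function(mol) nrow(mol$atoms)

mol_coords <- function(mol) {
  as.matrix(mol$atoms[, c("x", "y", "z")])
}

set_mol_coords <- function(mol, coords) {
  mol$atoms$x <- coords[, 1]
  mol$atoms$y <- coords[, 2]
  mol$atoms$z <- coords[, 3]
  mol
}

heavy_idx <- function(mol) which(mol$atoms$element != "H")

mol_graph <- function(mol) {
  igraph::graph_from_edgelist(as.matrix(mol$bonds[, c("i", "j")]),
                              directed = FALSE)
}

# Neighbour atom indices of atom k.
bonded_to <- function(mol, k) {
  b <- mol$bonds
  c(b$j[b$i == k], b$i[b$j == k])
}

#' Molecular formula (Hill order)
#'
#' @param mol A `coformr_molecule`.
#' @return Formula string, e.g. `"C10H7N3S"`.
#' @export
mol_formula <- function(mol) {
  counts <- table(mol$atoms$element)
  els <- names(counts)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(map_chr(ord, function(e) {
    paste0(e, if (counts[[e]] > 1) counts[[e]] else "")
  }), collapse = "")
}

#' Net formal charge of a molecule
#' @param mol A `coformr_molecule`.
#' @return Integer net charge.
#' @export
net_charge <- function(mol) sum(mol$atoms$formal_charge)
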