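#' Generate a conformer ensemble
#'
#' Embeds up to `n` distinct 3D conformations of a molecule (seeded ETKDG
#' distance-geometry embedding followed by MMFF94 minimisation), pruned by
#' heavy-atom RMSD so near-duplicate geometries collapse to one. The result
#' is bit-reproducible for a fixed (molecule, n, seed) triple. Screening an
#' API as an ensemble rather than a single geometry keeps coformers that are
#' complementary to several accessible shapes of the molecule.
#'
#' @param mol A `coformr_molecule`.
#' @param n Requested number of conformers (>= 1). Fewer may be returned for
#'   rigid molecules; that raises a warning, not an error.
#' @param seed Integer seed.
#' @param prune_rms Heavy-atom RMSD deduplication threshold in Angstrom.
#' @return A `conformer_ensemble`: the molecule, a list of coordinate
#'   matrices (one row per atom, Angstrom), relative MMFF energies
#'   (kcal/mol, minimum at 0), and a `validation` slot filled by
#'   [validate_geometry()].
#' @export
generate_conformers <- function(mol, n, seed = 1L, prune_rms = 0.5) {
  stopifnot(inherits(mol, "coformr_molecule"))
  if (n < 1) abort("n must be >= 1")
  res <- run_prep(list(list(name = mol$name, smiles = mol$smiles)),
                  n_confs = n, seed = seed, prune_rms = prune_rms)[[1]]
  if (!is.null(res$error)) {
    abort(paste0("Conformer generation failed for ", mol$name, ": ", res$error))
  }
  coords <- map(res$conformers, conformer_matrix)
  if (length(coords) < n) {
    warn(paste0(mol$name, ": only ", length(coords), " of ", n,
                " requested conformers are distinct at the ",
                prune_rms, " Angstrom RMSD threshold."))
  }
  # the prep step may renumber atoms when re-parsing from SMILES; rebuild the
  # molecule record so atom tables and coordinates always correspond
  mol_out <- new_molecule(res)
  mol_out$name <- mol$name
  structure(
    list(molecule = mol_out, coords = coords,
         energies = as.numeric(unlist(res$energies)),
         validation = NULL),
    class = "conformer_ensemble"
  )
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat("<conformer_ensemble> ", x$molecule$name, ": ", length(x$coords),
      " conformer(s)\n", sep = "")
  if (!is.null(x$validation)) {
    cat("  geometry check: ",
        sum(map_lgl(x$validation, "pass")), " of ", length(x$validation),
        " pass\n", sep = "")
  }
  invisible(x)
}

#' Number of conformers in an ensemble
#' @param ensemble A `conformer_ensemble`.
#' @return Integer count.
#' @export
n_conformers <- function(ensemble) length(ensemble$coords)

# ---- geometry validation -----------------------------------------------------

#' Default geometry reference ranges
#'
#' A static table of allowed windows (roughly mean plus or minus four
#' standard deviations of typical organic-crystal geometry) per bond-length
#' and valence-angle class, used to check that generated conformations are
#' realistically possible. Bond classes are written
#' `bond.<el><sym><el>` with elements sorted and `-`/`=`/`#`/`:` for
#' single/double/triple/aromatic order; angle classes are
#' `angle.<element><degree>` for the central atom. Torsions are matched by
#' the catch-all class `torsion.any`. Users can replace the table with their
#' own CSV (`feature_class,min,max`) for stricter, library-derived windows.
#'
#' @param path Optional CSV with columns `feature_class`, `min`, `max`.
#' @return A tibble with those three columns.
#' @export
geometry_reference_ranges <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "geometry_ranges.csv", package = "coformr")
  }
  tab <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  stopifnot(all(c("feature_class", "min", "max") %in% names(tab)))
  tab
}

bond_class <- function(el_i, el_j, order, aromatic) {
  # triple bonds use '%' (not '#', which CSV readers treat as a comment)
  sym <- ifelse(aromatic, ":",
                ifelse(order >= 3, "%", ifelse(order >= 2, "=", "-")))
  a <- pmin(el_i, el_j)
  b <- pmax(el_i, el_j)
  paste0("bond.", a, sym, b)
}

#' Validate ensemble geometry against reference ranges
#'
#' Measures every bond length, valence angle and proper torsion of each
#' conformer and compares it to the allowed window of its feature class.
#' Features whose class has no entry in the range table are reported as
#' `uncovered` rather than silently passing. A conformer passes when it has
#' no outliers.
#'
#' @param ensemble A `conformer_ensemble`.
#' @param ranges Reference-range tibble; see [geometry_reference_ranges()].
#' @return The ensemble with `validation` filled: one `geometry_check` per
#'   conformer, each holding `bond_length_outliers`, `angle_outliers`,
#'   `torsion_outliers`, `uncovered`, the full `features` table and a `pass`
#'   flag.
#' @export
validate_geometry <- function(ensemble, ranges = geometry_reference_ranges()) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  mol <- ensemble$molecule
  ensemble$validation <- map(ensemble$coords, function(coords) {
    check_conformer_geometry(mol, coords, ranges)
  })
  ensemble
}

check_conformer_geometry <- function(mol, coords, ranges) {
  feats <- dplyr::bind_rows(
    measure_bonds(mol, coords),
    measure_angles(mol, coords),
    measure_torsions(mol, coords)
  )
  m <- match(feats$feature_class, ranges$feature_class)
  feats$min <- ranges$min[m]
  feats$max <- ranges$max[m]
  feats$status <- dplyr::case_when(
    is.na(m) ~ "uncovered",
    feats$observed < feats$min | feats$observed > feats$max ~ "outlier",
    TRUE ~ "ok"
  )
  out <- function(kind) {
    dplyr::filter(feats, .data$status == "outlier", .data$kind == !!kind)
  }
  structure(
    list(bond_length_outliers = out("bond"),
         angle_outliers = out("angle"),
         torsion_outliers = out("torsion"),
         uncovered = dplyr::filter(feats, .data$status == "uncovered"),
         features = feats,
         pass = !any(feats$status == "outlier")),
    class = "geometry_check"
  )
}

#' @export
print.geometry_check <- function(x, ...) {
  cat("<geometry_check> ", if (x$pass) "PASS" else "FAIL",
      " (", nrow(x$features), " features, ",
      sum(x$features$status == "outlier"), " outliers, ",
      nrow(x$uncovered), " uncovered)\n", sep = "")
  invisible(x)
}

measure_bonds <- function(mol, coords) {
  b <- mol$bonds
  if (nrow(b) == 0) return(tibble::tibble())
  el <- mol$atoms$element
  d <- sqrt(rowSums((coords[b$i, , drop = FALSE] -
                     coords[b$j, , drop = FALSE])^2))
  tibble::tibble(
    kind = "bond",
    feature_id = paste0(el[b$i], b$i, "-", el[b$j], b$j),
    feature_class = bond_class(el[b$i], el[b$j], b$order, b$aromatic),
    observed = d
  )
}

measure_angles <- function(mol, coords) {
  el <- mol$atoms$element
  rows <- list()
  for (k in seq_len(n_atoms(mol))) {
    nb <- sort(bonded_to(mol, k))
    if (length(nb) < 2) next
    pairs <- utils::combn(nb, 2)
    for (p in seq_len(ncol(pairs))) {
      a <- pairs[1, p]; c <- pairs[2, p]
      ang <- vec_angle(coords[a, ] - coords[k, ], coords[c, ] - coords[k, ])
      rows[[length(rows) + 1]] <- tibble::tibble(
        kind = "angle",
        feature_id = paste0(el[a], a, "-", el[k], k, "-", el[c], c),
        feature_class = paste0("angle.", el[k], length(nb)),
        observed = ang
      )
    }
  }
  dplyr::bind_rows(rows)
}

measure_torsions <- function(mol, coords) {
  el <- mol$atoms$element
  b <- mol$bonds
  rows <- list()
  for (r in seq_len(nrow(b))) {
    j <- b$i[r]; k <- b$j[r]
    nj <- setdiff(bonded_to(mol, j), k)
    nk <- setdiff(bonded_to(mol, k), j)
    if (length(nj) == 0 || length(nk) == 0) next
    # one representative torsion per central bond keeps reports readable
    a <- min(nj); d <- min(nk)
    rows[[length(rows) + 1]] <- tibble::tibble(
      kind = "torsion",
      feature_id = paste0(el[a], a, "-", el[j], j, "-", el[k], k, "-", el[d], d),
      feature_class = "torsion.any",
      observed = dihedral_angle(coords[a, ], coords[j, ], coords[k, ], coords[d, ])
    )
  }
  dplyr::bind_rows(rows)
}

# ---- geometry primitives -----------------------------------------------------

vec_angle <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Best-fit (Kabsch) RMSD between two conformations of the same atom list.
rmsd_aligned <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  s <- svd(t(Bc) %*% Ac)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((Ac - Bc %*% R)^2)))
}
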