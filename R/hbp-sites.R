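#' Hydrogen-bond site taxonomy and geometric observation extraction
#'
#' Donor sites are D--H pairs on N, O or S; acceptor sites are N, O or S
#' atoms carrying a lone pair. Each site gets a functional-group category
#' from a fixed, closed taxonomy; the categories, together with a
#' competition function, steric density and aromaticity flags, are the
#' descriptors of the logistic propensity model.
#'
#' @name hbp_sites
NULL

DONOR_CATEGORIES <- c("carboxylic_OH", "hydroxyl_OH", "amide_NH",
                      "aromatic_NH", "amine_NH", "thiol_SH")
ACCEPTOR_CATEGORIES <- c("carbonyl_O", "hydroxyl_O", "ether_O", "oxide_O",
                         "aromatic_N", "amine_N", "thioether_S")

# distance prefilter for observation extraction; comfortably above any
# vdW(D) + vdW(A) + 0.1 in the Bondi table
HB_PREFILTER <- 5.0
HB_VDW_SLACK <- 0.1
HB_MIN_ANGLE <- 120

#' Enumerate hydrogen-bond donor and acceptor sites
#'
#' Every N--H, O--H or S--H yields one donor site per hydrogen; every N, O
#' or S with an available lone pair yields an acceptor site. Categories are
#' assigned by substructure rules with documented precedence (most specific
#' wins): carboxylic acid OH before generic hydroxyl; amide NH before
#' aromatic NH before generic amine NH. Amide nitrogens, pyrrole-type
#' aromatic NH nitrogens and positively charged nitrogens are not acceptors.
#'
#' @param mol A `coformr_molecule`.
#' @return A tibble ordered by heavy-atom index: `molecule`, `kind`
#'   (donor/acceptor), `atom` (heavy atom index), `h_atom` (hydrogen index,
#'   `NA` for acceptors), `element`, `category`, `aromatic_attached`,
#'   `steric_density`.
#' @export
enumerate_sites <- function(mol) {
  stopifnot(inherits(mol, "coformr_molecule"))
  a <- mol$atoms
  g <- mol_graph(mol)
  rows <- list()
  for (k in seq_len(nrow(a))) {
    if (!a$element[k] %in% POLAR_ELEMENTS) next
    nb <- sort(bonded_to(mol, k))
    h_nb <- nb[a$element[nb] == "H"]
    heavy_nb <- nb[a$element[nb] != "H"]
    arom_att <- a$aromatic[k] || any(a$aromatic[heavy_nb])
    # donors: one site per attached hydrogen
    for (h in h_nb) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        molecule = mol$name, kind = "donor", atom = k, h_atom = h,
        element = a$element[k],
        category = donor_category(mol, k),
        aromatic_attached = arom_att
      )
    }
    acc <- acceptor_category(mol, k, h_nb, heavy_nb)
    if (!is.na(acc)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        molecule = mol$name, kind = "acceptor", atom = k, h_atom = NA_integer_,
        element = a$element[k],
        category = acc,
        aromatic_attached = arom_att
      )
    }
  }
  sites <- dplyr::bind_rows(rows)
  if (nrow(sites) == 0) {
    sites <- tibble::tibble(molecule = character(), kind = character(),
                            atom = integer(), h_atom = integer(),
                            element = character(), category = character(),
                            aromatic_attached = logical())
  }
  sites <- dplyr::arrange(sites, .data$atom, .data$h_atom)
  sites$steric_density <- map_dbl(sites$atom, function(k) {
    steric_density(mol, k, graph = g)
  })
  sites
}

# is atom k's neighbour set containing a carbonyl-like carbon (C with a
# double-bonded O/S)?
attached_to_carbonyl_c <- function(mol, k) {
  a <- mol$atoms; b <- mol$bonds
  for (c_idx in bonded_to(mol, k)) {
    if (a$element[c_idx] != "C") next
    dbl <- b[(b$i == c_idx | b$j == c_idx) & b$order >= 2 & !b$aromatic, ]
    if (nrow(dbl) == 0) next
    other <- ifelse(dbl$i == c_idx, dbl$j, dbl$i)
    if (any(a$element[other] %in% c("O", "S"))) return(TRUE)
  }
  FALSE
}

donor_category <- function(mol, k) {
  a <- mol$atoms
  el <- a$element[k]
  if (el == "O") {
    if (attached_to_carbonyl_c(mol, k)) return("carboxylic_OH")
    return("hydroxyl_OH")
  }
  if (el == "N") {
    if (attached_to_carbonyl_c(mol, k)) return("amide_NH")
    if (a$aromatic[k]) return("aromatic_NH")
    return("amine_NH")
  }
  if (el == "S") return("thiol_SH")
  abort(paste0("no donor category for element ", el))
}

acceptor_category <- function(mol, k, h_nb, heavy_nb) {
  a <- mol$atoms; b <- mol$bonds
  el <- a$element[k]
  dbl <- b[(b$i == k | b$j == k) & b$order >= 2 & !b$aromatic, ]
  if (el == "O") {
    if (nrow(dbl) > 0) {
      other <- ifelse(dbl$i[1] == k, dbl$j[1], dbl$i[1])
      return(if (a$element[other] == "C") "carbonyl_O" else "oxide_O")
    }
    if (length(h_nb) > 0) return("hydroxyl_O")
    return("ether_O")
  }
  if (el == "N") {
    if (a$formal_charge[k] > 0) return(NA_character_)        # no lone pair
    if (a$aromatic[k] && length(h_nb) > 0) return(NA_character_)  # pyrrole-type
    if (attached_to_carbonyl_c(mol, k)) return(NA_character_)     # amide N
    if (a$aromatic[k]) return("aromatic_N")
    if (length(bonded_to(mol, k)) <= 3) return("amine_N")
    return(NA_character_)
  }
  if (el == "S") {
    if (length(heavy_nb) == 2 && length(h_nb) == 0 && nrow(dbl) == 0) {
      return("thioether_S")
    }
    return(NA_character_)
  }
  NA_character_
}

#' Steric density of a site atom
#'
#' The number of heavy atoms within 3.5 Angstrom of the site atom in a
#' reference conformer, excluding atoms two or fewer bonds away, divided
#' by 10. Measures how buried a donor/acceptor is.
#'
#' @param mol A `coformr_molecule` with coordinates.
#' @param k Atom index.
#' @param shell Shell radius in Angstrom.
#' @param graph Optional precomputed molecular graph.
#' @return Dimensionless density (>= 0).
#' @export
steric_density <- function(mol, k, shell = 3.5, graph = NULL) {
  g <- graph %||% mol_graph(mol)
  coords <- mol_coords(mol)
  d_space <- sqrt(rowSums(sweep(coords, 2, coords[k, ])^2))
  d_graph <- as.numeric(igraph::distances(g, v = k))
  heavy <- mol$atoms$element != "H"
  sum(heavy & d_space <= shell & d_graph > 2) / 10
}

#' Geometric hydrogen-bond test
#'
#' A donor--acceptor contact counts as a hydrogen bond when the D--A
#' distance is at most vdW(D) + vdW(A) + 0.1 Angstrom and the D--H...A angle
#' at the hydrogen exceeds 120 degrees.
#'
#' @param donor List with `element`, `xyz` (donor heavy atom) and `h_xyz`
#'   (its hydrogen).
#' @param acceptor List with `element` and `xyz`.
#' @param radii Van der Waals radius table ([bondi_radii()]).
#' @return Logical.
#' @export
#' @examples
#' detect_hbond(
#'   donor = list(element = "O", xyz = c(0, 0, 0), h_xyz = c(0.96, 0, 0)),
#'   acceptor = list(element = "N", xyz = c(2.9, 0, 0)))
detect_hbond <- function(donor, acceptor, radii = bondi_radii()) {
  if (is.null(donor$h_xyz) || anyNA(donor$h_xyz)) {
    abort("donor hydrogen coordinates are required for the angle criterion")
  }
  rd <- radii$vdw_radius[match(donor$element, radii$element)]
  ra <- radii$vdw_radius[match(acceptor$element, radii$element)]
  if (anyNA(c(rd, ra))) abort("element missing from the radius table")
  d_da <- sqrt(sum((donor$xyz - acceptor$xyz)^2))
  if (d_da > rd + ra + HB_VDW_SLACK) return(FALSE)
  ang <- vec_angle(donor$xyz - donor$h_xyz, acceptor$xyz - donor$h_xyz)
  ang > HB_MIN_ANGLE
}

#' Extract hydrogen-bond observations from a molecular cluster
#'
#' Enumerates every intermolecular (donor site, acceptor site) pair within a
#' 5 Angstrom donor--acceptor prefilter and labels it formed/not-formed by
#' the geometric criterion. A donor hydrogen reaching k acceptors
#' (bifurcation) contributes k formed observations. Pair features
#' (competition, steric densities, categories, aromaticity) are computed
#' against the full cluster site system, so the result feeds directly into
#' [fit_hbp()].
#'
#' @param cluster A list of `coformr_molecule`s positioned in a common
#'   coordinate frame (at least two molecules).
#' @param prefilter Donor--acceptor distance prefilter (Angstrom).
#' @return An observation tibble: donor/acceptor molecule names and atom
#'   indices, `distance`, `angle`, the model feature columns
#'   (`donor_category`, `acceptor_category`, `donor_steric`,
#'   `acceptor_steric`, `competition`, `donor_aromatic`,
#'   `acceptor_aromatic`) and `formed` (0/1).
#' @export
extract_observations <- function(cluster, prefilter = HB_PREFILTER) {
  if (length(cluster) < 2) abort("a cluster needs at least two molecules")
  sites <- map(cluster, enumerate_sites)
  all_sites <- dplyr::bind_rows(sites)
  comp <- competition_value(all_sites)
  rows <- list()
  for (a in seq_along(cluster)) {
    don <- dplyr::filter(sites[[a]], .data$kind == "donor")
    if (nrow(don) == 0) next
    ca <- mol_coords(cluster[[a]])
    for (b in seq_along(cluster)) {
      if (a == b) next
      acc <- dplyr::filter(sites[[b]], .data$kind == "acceptor")
      if (nrow(acc) == 0) next
      cb <- mol_coords(cluster[[b]])
      for (di in seq_len(nrow(don))) {
        for (ai in seq_len(nrow(acc))) {
          dxyz <- ca[don$atom[di], ]; axyz <- cb[acc$atom[ai], ]
          d_da <- sqrt(sum((dxyz - axyz)^2))
          if (d_da > prefilter) next
          hxyz <- ca[don$h_atom[di], ]
          formed <- detect_hbond(
            donor = list(element = don$element[di], xyz = dxyz, h_xyz = hxyz),
            acceptor = list(element = acc$element[ai], xyz = axyz))
          ang <- vec_angle(dxyz - hxyz, axyz - hxyz)
          rows[[length(rows) + 1]] <- tibble::tibble(
            donor_molecule = don$molecule[di], donor_atom = don$atom[di],
            donor_h = don$h_atom[di],
            acceptor_molecule = acc$molecule[ai], acceptor_atom = acc$atom[ai],
            distance = d_da, angle = ang,
            donor_category = don$category[di],
            acceptor_category = acc$category[ai],
            donor_steric = don$steric_density[di],
            acceptor_steric = acc$steric_density[ai],
            competition = comp,
            donor_aromatic = as.integer(don$aromatic_attached[di]),
            acceptor_aromatic = as.integer(acc$aromatic_attached[ai]),
            formed = as.integer(formed)
          )
        }
      }
    }
  }
  if (length(rows) == 0) return(empty_observations())
  dplyr::bind_rows(rows)
}

empty_observations <- function() {
  tibble::tibble(
    donor_molecule = character(), donor_atom = integer(), donor_h = integer(),
    acceptor_molecule = character(), acceptor_atom = integer(),
    distance = numeric(), angle = numeric(),
    donor_category = character(), acceptor_category = character(),
    donor_steric = numeric(), acceptor_steric = numeric(),
    competition = numeric(), donor_aromatic = integer(),
    acceptor_aromatic = integer(), formed = integer()
  )
}

# competition = acceptors / (donor hydrogens + acceptors) over a site system
competition_value <- function(sites) {
  n_acc <- sum(sites$kind == "acceptor")
  n_don <- sum(sites$kind == "donor")
  if (n_acc + n_don == 0) return(0)
  n_acc / (n_don + n_acc)
}

#' Expand an observation row into the model feature vector
#'
#' Fixed feature order: competition, donor/acceptor steric densities,
#' one-hot donor category, one-hot acceptor category, donor/acceptor
#' aromaticity. The taxonomy is closed: unknown categories are an error.
#'
#' @param obs A tibble of observations (rows with the schema written by
#'   [extract_observations()] / [generate_observations()]).
#' @return A numeric design matrix, one row per observation, with
#'   [hbp_feature_names()] columns.
#' @export
featurize <- function(obs) {
  bad_d <- setdiff(unique(obs$donor_category), DONOR_CATEGORIES)
  bad_a <- setdiff(unique(obs$acceptor_category), ACCEPTOR_CATEGORIES)
  if (length(bad_d) || length(bad_a)) {
    abort(paste0("unknown site category: ",
                 paste(c(bad_d, bad_a), collapse = ", "),
                 " (the taxonomy is closed)"))
  }
  n <- nrow(obs)
  X <- matrix(0, n, length(hbp_feature_names()),
              dimnames = list(NULL, hbp_feature_names()))
  X[, "competition"] <- obs$competition
  X[, "donor_steric"] <- obs$donor_steric
  X[, "acceptor_steric"] <- obs$acceptor_steric
  for (cat in DONOR_CATEGORIES) {
    X[, paste0("donor_cat_", cat)] <- as.numeric(obs$donor_category == cat)
  }
  for (cat in ACCEPTOR_CATEGORIES) {
    X[, paste0("acceptor_cat_", cat)] <- as.numeric(obs$acceptor_category == cat)
  }
  X[, "donor_aromatic"] <- as.numeric(obs$donor_aromatic)
  X[, "acceptor_aromatic"] <- as.numeric(obs$acceptor_aromatic)
  X
}

#' Canonical feature names of the propensity model
#' @return Character vector.
#' @export
hbp_feature_names <- function() {
  c("competition", "donor_steric", "acceptor_steric",
    paste0("donor_cat_", DONOR_CATEGORIES),
    paste0("acceptor_cat_", ACCEPTOR_CATEGORIES),
    "donor_aromatic", "acceptor_aromatic")
}

#' Read / write observation CSVs
#'
#' The observation schema is `donor_category`, `acceptor_category`,
#' `donor_steric`, `acceptor_steric`, `competition`, `donor_aromatic`,
#' `acceptor_aromatic`, `formed` (0/1); extra columns are carried along.
#'
#' @param path CSV path.
#' @return A validated observation tibble.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  obs <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  required <- c("donor_category", "acceptor_category", "donor_steric",
                "acceptor_steric", "competition", "donor_aromatic",
                "acceptor_aromatic", "formed")
  missing <- setdiff(required, names(obs))
  if (length(missing)) {
    abort(paste0("observation CSV is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!all(obs$formed %in% c(0, 1))) abort("column 'formed' must be 0/1")
  obs
}

#' @rdname read_observations
#' @param obs Observation tibble.
#' @param header Optional comment lines (seed provenance etc.) written before
#'   the data.
#' @export
write_observations <- function(obs, path, header = NULL) {
  lines <- character()
  if (!is.null(header)) lines <- paste0("# ", header)
  body <- sub("\n$", "", readr::format_csv(obs))
  writeLines(c(lines, strsplit(body, "\n", fixed = TRUE)[[1]]), path)
  invisible(path)
}
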