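# Shared fixtures. Molecules read through the structure bridge are cached per
# session so the test suite pays interpreter start-up once per molecule set.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

fixture_coformers <- function() {
  cached("coformers", function() {
    read_structures(system.file("extdata", "coformers.smi", package = "coformr"))
  })
}

fixture_api <- function() {
  cached("api", function() {
    read_structures(system.file("extdata", "pf4_like.smi", package = "coformr"))[[1]]
  })
}

fixture_mol <- function(smiles, name = "m") {
  cached(paste0("smi:", smiles), function() mol_from_smiles(smiles, name))
}

# Build a molecule object directly (no embedding) for geometry-level tests
# where exact coordinates, charges and radii must be controlled.
make_mol <- function(elements, coords, bonds = NULL, charges = NULL,
                     formal = NULL, aromatic = NULL, name = "synthetic") {
  coords <- matrix(coords, ncol = 3, byrow = TRUE)
  n <- length(elements)
  atoms <- tibble::tibble(
    element = elements,
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    formal_charge = as.integer(formal %||% rep(0L, n)),
    partial_charge = charges %||% rep(0, n),
    vdw_radius = coformr::bondi_radii()$vdw_radius[
      match(elements, coformr::bondi_radii()$element)],
    is_polar = elements %in% c("N", "O", "S"),
    aromatic = aromatic %||% rep(FALSE, n),
    in_ring = rep(FALSE, n)
  )
  if (is.null(bonds)) {
    bonds <- tibble::tibble(i = integer(), j = integer(), order = numeric(),
                            aromatic = logical())
  } else {
    bonds <- tibble::as_tibble(bonds)
    if (!"aromatic" %in% names(bonds)) bonds$aromatic <- FALSE
    if (!"order" %in% names(bonds)) bonds$order <- 1
  }
  structure(list(name = name, smiles = NA_character_, atoms = atoms,
                 bonds = bonds),
            class = "coformr_molecule")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A minimal one-row descriptor tibble for screening tests.
desc_row <- function(molecule = "m", dipole = 0, fpv = 0, m_over_l = 0.5,
                     s_over_l = 0.3, S = 5) {
  tibble::tibble(molecule = molecule, vdw_volume = 100, polar_volume = fpv * 100,
                 fpv = fpv, dipole = dipole, S = S, M = m_over_l * 10,
                 L = 10, s_over_l = s_over_l, m_over_l = m_over_l,
                 s_over_m = s_over_l / m_over_l,
                 donor_count = 1L, acceptor_count = 1L)
}

default_cutoffs <- function() {
  cutoff_set(ml_ratio_delta_max = 0.25, sl_ratio_delta_max = 0.25,
             s_axis_delta_max = 2.5)
}

# An hbp_model with chosen coefficients, bypassing fitting.
manual_model <- function(alpha = 0, betas = numeric()) {
  full <- setNames(numeric(length(hbp_feature_names())), hbp_feature_names())
  full[names(betas)] <- betas
  structure(
    list(alpha = alpha, betas = full, feature_names = hbp_feature_names(),
         regularization = 0, hessian = NULL,
         fit_diagnostics = list(log_likelihood = NA_real_, iterations = 0L,
                                converged = TRUE, n_obs = 0L, n_formed = 0L)),
    class = "hbp_model")
}
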