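#' Synthetic data generators
#'
#' Everything the screening funnel consumes can be generated offline with
#' known ground truth: logistic observation datasets with chosen
#' coefficients (stand-in for crystal-contact training data), planted
#' hydrogen-bond cluster geometries for the geometric detector, and toy
#' molecule series with monotone polarity or shape for the complementarity
#' descriptors.
#'
#' @name synthetic_data
NULL

#' Generate logistic hydrogen-bond observations with known coefficients
#'
#' Draws pair features from simple distributions (uniform competition and
#' steric densities, uniform categorical site categories, Bernoulli(1/2)
#' aromaticity flags), then draws `formed ~ Bernoulli(pi)` where
#' `logit(pi) = alpha + X beta`. Deterministic for a fixed seed.
#'
#' @param n Number of observations.
#' @param alpha True intercept.
#' @param betas Named numeric vector over [hbp_feature_names()] (features not
#'   named get coefficient 0).
#' @param seed Integer seed.
#' @param competition_range,steric_range Uniform ranges for the continuous
#'   features.
#' @return An observation tibble in the [read_observations()] schema, with
#'   the generating spec attached as attribute `"spec"`.
#' @export
generate_observations <- function(n, alpha = 0, betas = numeric(), seed = 1L,
                                  competition_range = c(0.2, 0.8),
                                  steric_range = c(0, 1)) {
  if (n < 1) abort("n must be >= 1")
  unknown <- setdiff(names(betas), hbp_feature_names())
  if (length(unknown)) {
    abort(paste0("unknown feature(s) in betas: ", paste(unknown, collapse = ", ")))
  }
  withr_seed(seed, {
    obs <- tibble::tibble(
      donor_category = sample(DONOR_CATEGORIES, n, replace = TRUE),
      acceptor_category = sample(ACCEPTOR_CATEGORIES, n, replace = TRUE),
      donor_steric = runif(n, steric_range[1], steric_range[2]),
      acceptor_steric = runif(n, steric_range[1], steric_range[2]),
      competition = runif(n, competition_range[1], competition_range[2]),
      donor_aromatic = rbinom(n, 1, 0.5),
      acceptor_aromatic = rbinom(n, 1, 0.5)
    )
    beta_full <- setNames(numeric(length(hbp_feature_names())),
                          hbp_feature_names())
    beta_full[names(betas)] <- betas
    pi <- plogis(alpha + drop(featurize(obs) %*% beta_full))
    obs$formed <- rbinom(n, 1, pi)
    attr(obs, "spec") <- list(alpha = alpha, betas = beta_full, n = n,
                              seed = seed)
    obs
  })
}

# run code under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(code)
}

#' Plant a hydrogen-bond cluster with prescribed geometry
#'
#' Builds a donor molecule (methanol, hydroxyl donor) and one acceptor
#' molecule (trimethylamine, lone-pair nitrogen, no donor hydrogens) per
#' requested contact, all sharing the single donor hydrogen — so two or
#' more contacts form a bifurcated donor. Contact `i` is placed at
#' donor--acceptor distance `distances[i]` (Angstrom) and D--H...A angle
#' `angles[i]` (degrees), at evenly spaced azimuths around the O--H axis.
#' Because trimethylamine has no N--H/O--H/S--H, the planted donor--acceptor
#' pairs are the only observation pairs the cluster can produce.
#'
#' @param distances,angles Equal-length numeric vectors, one entry per
#'   planted contact.
#' @param seed Integer seed for the 3D embedding of the component molecules.
#' @return A list of positioned `coformr_molecule`s (donor first), ready for
#'   [extract_observations()].
#' @export
plant_hbond_cluster <- function(distances, angles, seed = 1L) {
  if (length(distances) != length(angles) || length(distances) < 1) {
    abort("distances and angles must be equal-length, non-empty vectors")
  }
  if (any(distances < 2.0)) {
    abort("requested D--A distance below covalent overlap; not physically realisable")
  }
  if (any(angles <= 0 | angles > 180)) abort("angles must lie in (0, 180]")
  donor <- mol_from_smiles("CO", "donor_methanol", seed = seed)
  # orient: hydroxyl O at origin, O-H along +x
  o_idx <- which(donor$atoms$element == "O")
  h_idx <- intersect(bonded_to(donor, o_idx),
                     which(donor$atoms$element == "H"))[1]
  dc <- mol_coords(donor)
  dc <- sweep(dc, 2, dc[o_idx, ])
  R <- rotation_from_to(dc[h_idx, ], c(1, 0, 0))
  dc <- dc %*% t(R)
  donor <- set_mol_coords(donor, dc)
  h_len <- dc[h_idx, 1]
  azimuths <- (seq_along(distances) - 1) * 2 * pi / max(length(distances), 2)
  cluster <- list(donor)
  for (k in seq_along(distances)) {
    d <- distances[k]
    psi <- (180 - angles[k]) * pi / 180     # angle of H->A from the +x axis
    disc <- h_len^2 * cos(psi)^2 - h_len^2 + d^2
    if (disc < 0) {
      abort(sprintf("contact %d (d = %.2f A, angle = %.0f deg) is not realisable", k, d, angles[k]))
    }
    t_ha <- -h_len * cos(psi) + sqrt(disc)
    az <- azimuths[k]
    a_pos <- c(h_len + t_ha * cos(psi),
               t_ha * sin(psi) * cos(az),
               t_ha * sin(psi) * sin(az))
    acc <- mol_from_smiles("CN(C)C", paste0("acceptor_amine_", k), seed = seed)
    n_idx <- which(acc$atoms$element == "N")
    ac <- mol_coords(acc)
    ac <- sweep(ac, 2, ac[n_idx, ])
    # point the amine body away from the donor hydrogen
    outward <- a_pos - c(h_len, 0, 0)
    outward <- outward / sqrt(sum(outward^2))
    body <- colMeans(ac[acc$atoms$element != "H", , drop = FALSE])
    if (sum(body^2) > 1e-9) {
      ac <- ac %*% t(rotation_from_to(body, outward))
    }
    ac <- sweep(ac, 2, a_pos, FUN = "+")
    cluster[[k + 1]] <- set_mol_coords(acc, ac)
  }
  cluster
}

# Rodrigues rotation taking direction u onto direction v.
rotation_from_to <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # pick any axis orthogonal to u
    ax <- if (abs(u[1]) < 0.9) cross3(u, c(1, 0, 0)) else cross3(u, c(0, 1, 0))
    ax <- ax / sqrt(sum(ax^2))
    K <- skew3(ax)
    return(diag(3) + 2 * K %*% K)
  }
  w <- cross3(u, v)
  K <- skew3(w)
  diag(3) + K + K %*% K / (1 + c_)
}

skew3 <- function(w) {
  matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0), 3, byrow = TRUE)
}

#' Toy molecule series with monotone descriptors
#'
#' `polar_series`: six-carbon backbones carrying 0, 1, 2, ... hydroxyl
#' groups, so the fractional polar volume increases strictly along the
#' series. `shape_series`: linear acenes (benzene, naphthalene, anthracene,
#' ...), rigid molecules that elongate ring by ring, so the S/L box ratio
#' decreases strictly without any conformational ambiguity.
#'
#' @param kind `"polar_series"` or `"shape_series"`.
#' @param n Series length (2 to 6).
#' @return A tibble with `name` and `smiles`.
#' @export
toy_library <- function(kind = c("polar_series", "shape_series"), n) {
  kind <- match.arg(kind)
  if (n < 2) abort("a series needs n >= 2")
  if (n > 6) abort("series are defined up to n = 6")
  if (kind == "polar_series") {
    smiles <- map_chr(seq_len(n) - 1, function(k) {
      paste0(strrep("C(O)", k), strrep("C", 6 - k))
    })
    names_ <- paste0("hexane_", seq_len(n) - 1, "ol")
  } else {
    acenes <- c(
      benzene = "c1ccccc1",
      naphthalene = "c1ccc2ccccc2c1",
      anthracene = "c1ccc2cc3ccccc3cc2c1",
      tetracene = "c1ccc2cc3cc4ccccc4cc3cc2c1",
      pentacene = "c1ccc2cc3cc4cc5ccccc5cc4cc3cc2c1",
      hexacene = "c1ccc2cc3cc4cc5cc6ccccc6cc5cc4cc3cc2c1"
    )
    smiles <- unname(acenes[seq_len(n)])
    names_ <- names(acenes)[seq_len(n)]
  }
  tibble::tibble(name = names_, smiles = smiles)
}
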