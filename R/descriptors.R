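#' Molecular complementarity descriptors
#'
#' The complementarity screen compares an API and a candidate coformer on
#' five descriptors: dipole moment, fractional polar volume (FPV), the
#' M/L and S/L ratios of the minimum rectangular box enclosing the van der
#' Waals volume, and the short box axis S itself. Similar polarity (dipole,
#' FPV) and similar shape (box axes) both favour cocrystal formation.
#'
#' @name descriptors
NULL

# 1 e.Angstrom in Debye (1 D = 3.33564e-30 C.m)
EA_TO_DEBYE <- 4.80321

#' Van der Waals volume by voxel integration
#'
#' Computes the volume of the union of atomic van der Waals spheres on a
#' cubic voxel grid, together with the polar part: the volume of voxels
#' whose nearest covering sphere belongs to a polar atom (N, O or S), ties
#' broken toward the lower atom index.
#'
#' @param mol A `coformr_molecule`.
#' @param coords Optional coordinate matrix (defaults to the molecule's own).
#' @param resolution Voxel edge length in Angstrom. Must be finer than the
#'   smallest atomic radius present.
#' @return A list with `total` and `polar` volumes in cubic Angstrom.
#' @export
compute_vdw_volume <- function(mol, coords = NULL, resolution = 0.2) {
  coords <- coords %||% mol_coords(mol)
  radii <- mol$atoms$vdw_radius
  if (resolution <= 0) abort("resolution must be positive")
  if (resolution > min(radii)) {
    abort("resolution is coarser than the smallest van der Waals radius")
  }
  voxel_union_volume(coords, radii, mol$atoms$is_polar, resolution)
}

voxel_union_volume <- function(coords, radii, is_polar, resolution) {
  lo <- apply(coords - radii, 2, min) - resolution
  hi <- apply(coords + radii, 2, max) + resolution
  nx <- ceiling((hi - lo) / resolution)
  gx <- lo[1] + (seq_len(nx[1]) - 0.5) * resolution
  gy <- lo[2] + (seq_len(nx[2]) - 0.5) * resolution
  gz <- lo[3] + (seq_len(nx[3]) - 0.5) * resolution
  nvox <- prod(nx)
  best_d2 <- rep(Inf, nvox)
  best_polar <- rep(FALSE, nvox)
  for (a in seq_len(nrow(coords))) {
    r <- radii[a]; ctr <- coords[a, ]
    ix <- which(abs(gx - ctr[1]) <= r)
    iy <- which(abs(gy - ctr[2]) <= r)
    iz <- which(abs(gz - ctr[3]) <= r)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (gx[ix] - ctr[1])^2
    dy2 <- (gy[iy] - ctr[2])^2
    dz2 <- (gz[iz] - ctr[3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    sub <- which(d2 <= r^2)
    if (!length(sub)) next
    # map subgrid linear indices to full-grid linear indices
    si <- arrayInd(sub, c(length(ix), length(iy), length(iz)))
    lin <- ix[si[, 1]] + (iy[si[, 2]] - 1) * nx[1] +
      (iz[si[, 3]] - 1) * nx[1] * nx[2]
    closer <- d2[sub] < best_d2[lin]   # strict: earlier atom wins ties
    lin <- lin[closer]
    best_d2[lin] <- d2[sub][closer]
    best_polar[lin] <- is_polar[a]
  }
  covered <- is.finite(best_d2)
  v <- resolution^3
  list(total = sum(covered) * v, polar = sum(best_polar[covered]) * v)
}

#' Fractional polar volume
#'
#' The fraction of a molecule's van der Waals volume contributed by polar
#' atoms (N, O, S) — the strongest single correlate of cocrystallisation in
#' large-scale complementarity analyses of known cocrystals.
#'
#' @param total Total van der Waals volume (cubic Angstrom).
#' @param polar Polar part of the volume.
#' @return `polar / total`, in `[0, 1]`.
#' @export
#' @examples
#' compute_fpv(100, 29.4)
compute_fpv <- function(total, polar) {
  if (total <= 0) abort("total volume must be positive")
  if (polar < 0 || polar > total) abort("polar volume must lie in [0, total]")
  polar / total
}

#' Dipole moment from partial charges
#'
#' The magnitude of `sum(q_i * r_i)` over atomic partial charges, converted
#' from e.Angstrom to Debye (1 e.Angstrom = 4.80321 D). For neutral
#' molecules the value is origin-independent; charged species trigger a
#' warning because the dipole then depends on the coordinate origin.
#'
#' @param mol A `coformr_molecule` (Gasteiger charges assigned at read time).
#' @param coords Optional coordinate matrix.
#' @param charges Optional charge vector overriding the molecule's.
#' @return Dipole moment in Debye.
#' @export
compute_dipole <- function(mol, coords = NULL, charges = NULL) {
  coords <- coords %||% mol_coords(mol)
  q <- charges %||% mol$atoms$partial_charge
  if (abs(sum(mol$atoms$formal_charge)) > 0) {
    warn(paste0(mol$name, " carries net charge; dipole moment is origin-dependent."))
  }
  mu <- colSums(coords * q)
  sqrt(sum(mu^2)) * EA_TO_DEBYE
}

# ---- minimum enclosing rectangular box ---------------------------------------

euler_zyz <- function(a, b, g) {
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
  cg <- cos(g); sg <- sin(g)
  rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, byrow = TRUE)
  ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, byrow = TRUE)
  rz2 <- matrix(c(cg, -sg, 0, sg, cg, 0, 0, 0, 1), 3, byrow = TRUE)
  rz1 %*% ry %*% rz2
}

# Box edge lengths for one orientation: project sphere centres on the three
# frame axes (rows of R) and pad by radii.
box_edges_for_rotation <- function(coords, radii, R) {
  P <- coords %*% t(R)                   # n x 3 projections
  apply(P + radii, 2, max) - apply(P - radii, 2, min)
}

# Vectorised box volumes for a batch of orientations given as a list of
# three m x 3 axis matrices (rows of each rotation matrix).
box_volumes_batch <- function(coords, radii, axes1, axes2, axes3) {
  ext <- function(U) {
    P <- coords %*% t(U)                 # n x m
    hi <- Reduce(pmax, asplit(P + radii, 1))
    lo <- Reduce(pmin, asplit(P - radii, 1))
    hi - lo
  }
  ext(axes1) * ext(axes2) * ext(axes3)
}

#' Minimum enclosing rectangular box of the van der Waals volume
#'
#' Finds the rectangular box of (near-)minimal volume enclosing all atomic
#' van der Waals spheres: a coarse search over a rotation grid followed by
#' Nelder--Mead refinement of the Euler angles, with the principal-axis
#' orientation added as a candidate so the result is never worse than the
#' principal-axis-aligned box. Edge lengths are returned sorted
#' `S <= M <= L`; the ratios S/L, M/L, S/M describe molecular shape
#' independently of absolute size.
#'
#' @param mol A `coformr_molecule`.
#' @param coords Optional coordinate matrix.
#' @param coarse_step Coarse rotation-grid spacing in degrees.
#' @param refine Run local refinement after the grid search.
#' @return A `box_axes` object: `S`, `M`, `L` (Angstrom), `rotation`
#'   (orthonormal 3x3, molecule frame to box frame) and `volume`.
#' @export
compute_box_axes <- function(mol, coords = NULL, coarse_step = 10,
                             refine = TRUE) {
  coords <- coords %||% mol_coords(mol)
  if (nrow(coords) < 1) abort("molecule has no atoms")
  radii <- mol$atoms$vdw_radius
  min_box_search(coords, radii, coarse_step = coarse_step, refine = refine)
}

min_box_search <- function(coords, radii, coarse_step = 10, refine = TRUE) {
  ctr <- colMeans(coords)
  X <- sweep(coords, 2, ctr)
  step <- coarse_step * pi / 180
  # covering domain for box orientations: the box frame is invariant under
  # quarter-turns about z (alpha mod 90 degrees); beta/gamma take their full
  # ZYZ ranges so no orientation is missed
  alphas <- seq(0, pi / 2 - 1e-9, by = step)
  betas <- seq(0, pi, by = step)
  gammas <- seq(0, 2 * pi - 1e-9, by = step)
  grid <- expand.grid(a = alphas, b = betas, g = gammas)
  rots <- lapply(seq_len(nrow(grid)),
                 function(k) euler_zyz(grid$a[k], grid$b[k], grid$g[k]))
  ax <- function(row) do.call(rbind, lapply(rots, function(R) R[row, ]))
  vols <- box_volumes_batch(X, radii, ax(1), ax(2), ax(3))
  best <- which.min(vols)
  ang <- c(grid$a[best], grid$b[best], grid$g[best])
  vol_of <- function(p) {
    prod(box_edges_for_rotation(X, radii, euler_zyz(p[1], p[2], p[3])))
  }
  if (refine) {
    # local refinement from several coarse-grid basins: the volume landscape
    # has multiple minima and the best grid point is not always in the
    # global basin
    best_val <- vols[best]
    for (idx in order(vols)[seq_len(min(5, length(vols)))]) {
      start <- c(grid$a[idx], grid$b[idx], grid$g[idx])
      opt <- stats::optim(start, vol_of, method = "Nelder-Mead",
                          control = list(maxit = 400, reltol = 1e-10))
      if (opt$value < best_val) {
        best_val <- opt$value
        ang <- opt$par
      }
    }
  }
  # principal-axis candidate guarantees we never exceed the PCA-aligned box
  pca_rot <- principal_axes(X)
  cand <- list(euler_zyz(ang[1], ang[2], ang[3]), pca_rot)
  cand_vol <- vapply(cand, function(R) {
    prod(box_edges_for_rotation(X, radii, R))
  }, numeric(1))
  R <- cand[[which.min(cand_vol)]]
  edges <- box_edges_for_rotation(X, radii, R)
  ord <- order(edges)
  structure(
    list(S = edges[ord[1]], M = edges[ord[2]], L = edges[ord[3]],
         rotation = R[ord, , drop = FALSE], volume = prod(edges)),
    class = "box_axes"
  )
}

principal_axes <- function(X) {
  if (nrow(X) == 1) return(diag(3))
  e <- eigen(stats::cov(X) + diag(1e-12, 3), symmetric = TRUE)
  V <- e$vectors
  if (det(V) < 0) V[, 3] <- -V[, 3]
  t(V)
}

#' @export
print.box_axes <- function(x, ...) {
  cat(sprintf("<box_axes> S = %.3f, M = %.3f, L = %.3f A (volume %.2f A^3)\n",
              x$S, x$M, x$L, x$volume))
  invisible(x)
}

# ---- descriptor vector -------------------------------------------------------

#' Full complementarity descriptor vector for one conformation
#'
#' @param mol A `coformr_molecule`.
#' @param coords Optional coordinate matrix (one conformer).
#' @param resolution Voxel resolution in Angstrom for volume integration.
#' @param fpv_mode `"volumetric"` (fraction of van der Waals volume from
#'   polar atoms, the default) or `"atom_count"` (fraction of heavy atoms
#'   that are polar).
#' @param coarse_step Rotation-grid spacing for the box search, degrees.
#' @return A one-row tibble: molecule name, `vdw_volume`, `polar_volume`,
#'   `fpv`, `dipole` (Debye), `S`, `M`, `L` (Angstrom), `s_over_l`,
#'   `m_over_l`, `s_over_m`, `donor_count`, `acceptor_count`.
#' @export
descriptor_vector <- function(mol, coords = NULL, resolution = 0.2,
                              fpv_mode = c("volumetric", "atom_count"),
                              coarse_step = 10) {
  fpv_mode <- match.arg(fpv_mode)
  coords <- coords %||% mol_coords(mol)
  vol <- compute_vdw_volume(mol, coords, resolution)
  fpv <- if (fpv_mode == "volumetric") {
    compute_fpv(vol$total, vol$polar)
  } else {
    heavy <- mol$atoms$element != "H"
    mean(mol$atoms$is_polar[heavy])
  }
  box <- compute_box_axes(mol, coords, coarse_step = coarse_step)
  sites <- enumerate_sites(mol)
  tibble::tibble(
    molecule = mol$name,
    vdw_volume = vol$total,
    polar_volume = vol$polar,
    fpv = fpv,
    dipole = compute_dipole(mol, coords),
    S = box$S, M = box$M, L = box$L,
    s_over_l = box$S / box$L,
    m_over_l = box$M / box$L,
    s_over_m = box$S / box$M,
    donor_count = sum(sites$kind == "donor"),
    acceptor_count = sum(sites$kind == "acceptor")
  )
}

#' Descriptor table over molecules or a conformer ensemble
#'
#' @param x A list of `coformr_molecule`s or a `conformer_ensemble`.
#' @param ... Passed to [descriptor_vector()].
#' @return A tibble with one row per (molecule, conformer), with a
#'   `conformer` index column.
#' @export
descriptor_table <- function(x, ...) {
  if (inherits(x, "conformer_ensemble")) {
    rows <- imap(x$coords, function(coords, k) {
      dplyr::mutate(descriptor_vector(x$molecule, coords, ...),
                    conformer = k, .after = "molecule")
    })
    return(dplyr::bind_rows(rows))
  }
  if (inherits(x, "coformr_molecule")) x <- list(x)
  dplyr::bind_rows(map(x, function(m) {
    dplyr::mutate(descriptor_vector(m, ...), conformer = 1L,
                  .after = "molecule")
  }))
}
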