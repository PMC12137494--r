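#' Bondi van der Waals radii
#'
#' Van der Waals radii (Angstrom) from the Bondi compilation, for the
#' elements commonly encountered in drug-like molecules. These radii drive
#' volume/box descriptors and the geometric hydrogen-bond distance criterion
#' (D--A distance at most vdW(D) + vdW(A) + 0.1 Angstrom).
#'
#' @return A tibble with columns `element` and `vdw_radius` (Angstrom).
#' @export
#' @examples
#' bondi_radii()
bondi_radii <- function() {
  tibble::tibble(
    element = c("H", "He", "C", "N", "O", "F", "Ne", "Si", "P", "S", "Cl",
                "Ar", "As", "Se", "Br", "Kr", "Te", "I", "Xe"),
    vdw_radius = c(1.20, 1.40, 1.70, 1.55, 1.52, 1.47, 1.54, 2.10, 1.80,
                   1.80, 1.75, 1.88, 1.85, 1.90, 1.85, 2.02, 2.06, 1.98, 2.16)
  )
}

# Polar elements for fractional-polar-volume purposes: N, O, S.
POLAR_ELEMENTS <- c("N", "O", "S")

vdw_radius_of <- function(element) {
  tab <- bondi_radii()
  idx <- match(element, tab$element)
  if (anyNA(idx)) {
    abort(paste0("No van der Waals radius for element(s): ",
                 paste(unique(element[is.na(idx)]), collapse = ", ")))
  }
  tab$vdw_radius[idx]
}
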