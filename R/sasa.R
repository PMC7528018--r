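#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numeric SASA with a fixed spherical quadrature (golden-spiral points).
#' Hydrogens are ignored; van der Waals radii are a hard-coded Bondi set
#' (see \code{\link{buried_area}} for the consequences on interface areas).
#'
#' @param model an \code{atomic_model}.
#' @param probe_radius solvent probe radius in angstrom (default 1.4).
#' @param n_points quadrature points per atom (default 960).
#' @return Numeric vector of per-atom areas (angstrom^2) for the non-hydrogen
#'   atoms, with the total as attribute \code{"total"}.
#' @export
sasa <- function(model, probe_radius = 1.4, n_points = 960) {
  stopifnot(probe_radius > 0, n_points >= 12)
  a <- model$atoms
  a <- a[toupper(trimws(a$elesy)) != "H", , drop = FALSE]
  if (nrow(a) == 0) stop("model has no heavy atoms")
  per_atom <- cpp_sasa(as.matrix(a[, c("x", "y", "z")]), element_vdw(a$elesy),
                       probe_radius, as.integer(n_points))
  attr(per_atom, "total") <- sum(per_atom)
  per_atom
}

#' Buried interface area between two selections
#'
#' SASA(A alone) + SASA(B alone) - SASA(A and B assembled), computed with all
#' atoms outside the two selections removed. The exact value depends on the
#' radii set and quadrature; agreement with other interface-area tools is
#' expected at the ~10 percent level.
#'
#' @param model an \code{atomic_model} containing both selections in their
#'   assembled pose.
#' @param selA,selB non-overlapping \code{residue_selection}s (or selection
#'   strings accepted by \code{\link{parse_selection}}).
#' @param probe_radius solvent probe radius (angstrom).
#' @param n_points quadrature points per atom.
#' @return Buried area in angstrom^2 (non-negative up to quadrature noise).
#' @export
buried_area <- function(model, selA, selB, probe_radius = 1.4,
                        n_points = 960) {
  if (is.character(selA)) selA <- parse_selection(selA)
  if (is.character(selB)) selB <- parse_selection(selB)
  ia <- selection_index(model, selA)
  ib <- selection_index(model, selB)
  if (!any(ia) || !any(ib)) stop("empty selection")
  if (any(ia & ib)) stop("selections overlap")
  mA <- atomic_model(model$atoms[ia, , drop = FALSE])
  mB <- atomic_model(model$atoms[ib, , drop = FALSE])
  mAB <- atomic_model(model$atoms[ia | ib, , drop = FALSE])
  tot <- function(m) attr(sasa(m, probe_radius, n_points), "total")
  tot(mA) + tot(mB) - tot(mAB)
}
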