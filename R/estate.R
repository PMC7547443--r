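#' Intrinsic atomic values
#'
#' The Kier-Hall intrinsic state of each heavy atom,
#' \eqn{I_i = ((2/N)^2 \delta^v + 1) / \delta}, with \eqn{N} the principal
#' quantum number, \eqn{\delta^v = Z^v - h} the valence electrons in the
#' hydrogen-suppressed skeleton and \eqn{\delta} the sigma-electron
#' (heavy-neighbour) count. Formal charges adjust the valence-electron
#' bookkeeping (\eqn{Z^v} decreases by the positive charge).
#'
#' @param mol a [mol3d()].
#' @return tibble with one row per heavy atom: `atom`, `element`,
#'   `n_quantum`, `delta_v`, `delta`, `i`.
#' @export
intrinsic_values <- function(mol) {
  stopifnot(inherits(mol, "mol3d"))
  a <- mol$atoms[mol$atoms$is_heavy, ]
  if (nrow(a) == 0) abort(sprintf("molecule '%s': no heavy atoms", mol$id))
  el <- element_data()
  m <- match(a$element, el$element)
  n_q <- el$n_quantum[m]
  zv <- el$z_valence[m] - a$charge
  delta_v <- zv - a$n_hydrogens
  delta <- heavy_degree(mol)[as.character(a$index)]
  if (any(delta == 0)) {
    bad <- a$index[delta == 0]
    abort(sprintf(
      "molecule '%s': intrinsic value undefined for isolated heavy atom(s) %s",
      mol$id, paste(bad, collapse = ", ")))
  }
  tibble(
    atom = a$index, element = a$element,
    n_quantum = n_q, delta_v = delta_v, delta = as.numeric(delta),
    i = ((2 / n_q)^2 * delta_v + 1) / delta
  )
}

heavy_degree <- function(mol) {
  heavy <- mol$atoms$index[mol$atoms$is_heavy]
  deg <- setNames(integer(length(heavy)), as.character(heavy))
  b <- mol$bonds
  if (nrow(b) > 0) {
    keep <- b$a1 %in% heavy & b$a2 %in% heavy
    for (v in c(b$a1[keep], b$a2[keep])) {
      key <- as.character(v)
      deg[key] <- deg[key] + 1L
    }
  }
  deg
}

# Pairwise heavy-atom Euclidean distance matrix in Angstrom.
heavy_distance_matrix <- function(mol) {
  a <- mol$atoms[mol$atoms$is_heavy, ]
  d <- as.matrix(dist(cbind(a$x, a$y, a$z)))
  dimnames(d) <- list(a$index, a$index)
  d
}

#' Field perturbation of the intrinsic values
#'
#' Through-space perturbation of atom `i` by every other heavy atom `j`:
#' \eqn{\Delta I_i = \sum_{j \ne i} (I_i - I_j) / r_{ij}^p} with
#' \eqn{r_{ij}} the 3D Euclidean distance in Angstrom and `p = 2` by
#' default. The pairwise contributions are antisymmetric, so
#' \eqn{\sum_i \Delta I_i = 0}. `perturbation_sign = "sum"` replaces the
#' difference by \eqn{(I_i + I_j)} for auditing the alternative printed
#' reading of the formula.
#'
#' @param mol a [mol3d()].
#' @param i intrinsic values in heavy-atom order (defaults to
#'   [intrinsic_values()]).
#' @param perturbation_sign `"difference"` (default) or `"sum"`.
#' @param distance_power exponent on the Euclidean distance (default 2).
#' @return numeric vector of per-heavy-atom perturbations, named by atom
#'   ordinal.
#' @export
estate_perturbation <- function(mol, i = NULL,
                                perturbation_sign = c("difference", "sum"),
                                distance_power = 2) {
  perturbation_sign <- match.arg(perturbation_sign)
  if (is.null(i)) i <- intrinsic_values(mol)$i
  d <- heavy_distance_matrix(mol)
  if (nrow(d) != length(i)) abort("length of 'i' must match heavy atom count")
  if (nrow(d) == 1) return(setNames(0, rownames(d)))
  off <- upper.tri(d) | lower.tri(d)
  if (any(d[off] == 0)) {
    idx <- which(d == 0 & off, arr.ind = TRUE)[1, ]
    abort(sprintf("molecule '%s': coincident heavy atoms %s and %s",
                  mol$id, rownames(d)[idx[1]], colnames(d)[idx[2]]))
  }
  term <- if (perturbation_sign == "difference") outer(i, i, "-") else
    outer(i, i, "+")
  contrib <- term / d^distance_power
  diag(contrib) <- 0
  setNames(rowSums(contrib), rownames(d))
}

#' Electrotopographic state index per heavy atom
#'
#' The topographic E-state of each heavy atom: intrinsic value plus the 3D
#' field perturbation, \eqn{Sstate3D_i = I_i + \Delta I_i}. Hydrogens enter
#' only through the hydrogen counts of their heavy neighbours; distances are
#' taken from the stored coordinates with no cutoff, so the value is
#' invariant under rigid motions of the molecule.
#'
#' @inheritParams estate_perturbation
#' @return tibble with one row per heavy atom: `atom`, `element`,
#'   `n_quantum`, `delta_v`, `delta`, `i`, `di`, `sstate3d`.
#' @export
sstate3d <- function(mol, perturbation_sign = c("difference", "sum"),
                     distance_power = 2) {
  perturbation_sign <- match.arg(perturbation_sign)
  iv <- intrinsic_values(mol)
  di <- estate_perturbation(mol, iv$i, perturbation_sign, distance_power)
  iv$di <- unname(di[as.character(iv$atom)])
  iv$sstate3d <- iv$i + iv$di
  iv
}

#' E-state table for a set of molecules
#'
#' Convenience wrapper running [sstate3d()] over a list of molecules and
#' stacking the results with a `molecule_id` column.
#'
#' @param mols list of [mol3d()] objects.
#' @inheritParams estate_perturbation
#' @return tibble with `molecule_id` plus the [sstate3d()] columns.
#' @export
sstate3d_table <- function(mols, perturbation_sign = c("difference", "sum"),
                           distance_power = 2) {
  perturbation_sign <- match.arg(perturbation_sign)
  purrr::map_dfr(mols, function(m) {
    out <- sstate3d(m, perturbation_sign, distance_power)
    dplyr::bind_cols(tibble(molecule_id = m$id), out)
  })
}
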