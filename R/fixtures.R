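#' Specification for a deterministic 3D test molecule
#'
#' Describes a small synthetic molecule with exact, reproducible
#' coordinates: all-trans chains (tetrahedral zigzag), planar regular
#' rings, tetrahedral branches, or two hexagonal rings joined by a short
#' chain linker (for exercising fragment path closure). The same spec and
#' seed always regenerate byte-identical structures.
#'
#' @param topology one of `"chain"`, `"ring"`, `"branch"`,
#'   `"two_dc_linker"`.
#' @param n_atoms heavy-atom count (for `two_dc_linker`: the linker
#'   length; the rings contribute 12 more atoms).
#' @param elements optional element symbols, recycled over the heavy atoms
#'   (default all carbon).
#' @param bond_length ideal bond length in Angstrom, default 1.54.
#' @param jitter amplitude of deterministic coordinate noise in Angstrom
#'   (default 0, exact geometry).
#' @param seed integer seed used only when `jitter > 0`.
#' @param id molecule label.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(topology = c("chain", "ring", "branch",
                                      "two_dc_linker"),
                         n_atoms = 6, elements = NULL, bond_length = 1.54,
                         jitter = 0, seed = 1L, id = NULL) {
  topology <- match.arg(topology)
  if (topology == "chain" && n_atoms < 1) abort("chain needs >= 1 atom")
  if (topology == "ring" && n_atoms < 3) abort("ring needs >= 3 atoms")
  if (topology == "branch" && (n_atoms < 4 || n_atoms > 5)) {
    abort("branch supports 4 (C3-like) or 5 (C4-like) atoms")
  }
  if (topology == "two_dc_linker" && n_atoms < 1) {
    abort("two_dc_linker needs a linker of >= 1 atom")
  }
  if (is.null(id)) id <- sprintf("%s_%d", topology, n_atoms)
  structure(list(topology = topology, n_atoms = n_atoms,
                 elements = elements, bond_length = bond_length,
                 jitter = jitter, seed = as.integer(seed), id = id),
            class = "fixture_spec")
}

#' Build the molecule described by a fixture spec
#'
#' @param spec a [fixture_spec()].
#' @return a [mol3d()].
#' @export
make_molecule <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  L <- spec$bond_length
  geo <- switch(spec$topology,
    chain = chain_geometry(spec$n_atoms, L),
    ring = ring_geometry(spec$n_atoms, L),
    branch = branch_geometry(spec$n_atoms, L),
    two_dc_linker = linker_geometry(spec$n_atoms, L)
  )
  coords <- geo$coords
  if (spec$jitter > 0) {
    set.seed(spec$seed)
    coords <- coords + matrix(runif(length(coords), -spec$jitter,
                                    spec$jitter), ncol = 3)
  }
  n <- nrow(coords)
  elements <- if (is.null(spec$elements)) rep("C", n) else
    rep(spec$elements, length.out = n)
  atoms <- tibble(index = seq_len(n), element = elements,
                  x = round(coords[, 1], 4), y = round(coords[, 2], 4),
                  z = round(coords[, 3], 4), charge = 0L)
  bonds <- tibble(a1 = geo$bonds[, 1], a2 = geo$bonds[, 2],
                  order = rep(1L, nrow(geo$bonds)))
  mol3d(spec$id, atoms, bonds)
}

chain_geometry <- function(n, L) {
  theta <- 109.471 / 2 * pi / 180
  k <- seq_len(n) - 1
  coords <- cbind(k * L * sin(theta), (k %% 2) * L * cos(theta), 0)
  bonds <- if (n > 1) cbind(seq_len(n - 1), seq(2, n)) else
    matrix(integer(0), ncol = 2)
  list(coords = coords, bonds = bonds)
}

ring_geometry <- function(n, L, center = c(0, 0, 0), phase = 0) {
  r <- L / (2 * sin(pi / n))
  ang <- phase + 2 * pi * (seq_len(n) - 1) / n
  coords <- cbind(center[1] + r * cos(ang), center[2] + r * sin(ang),
                  center[3])
  bonds <- cbind(seq_len(n), c(seq(2, n), 1L))
  list(coords = coords, bonds = bonds)
}

branch_geometry <- function(n, L) {
  dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
    sqrt(3)
  k <- n - 1
  coords <- rbind(c(0, 0, 0), dirs[seq_len(k), , drop = FALSE] * L)
  bonds <- cbind(rep(1L, k), seq(2, n))
  list(coords = coords, bonds = bonds)
}

# Two planar hexagons joined through an all-x chain of `m` linker atoms.
linker_geometry <- function(m, L) {
  ring1 <- ring_geometry(6, L)
  r <- L / (2 * sin(pi / 6))
  # attachment atom of ring 1 sits at (r, 0, 0); linker runs along +x
  link_x <- r + seq_len(m) * L
  link <- cbind(link_x, 0, 0)
  c2 <- link_x[m] + L + r
  ring2 <- ring_geometry(6, L, center = c(c2, 0, 0), phase = pi)
  coords <- rbind(ring1$coords, link, ring2$coords)
  bonds <- rbind(
    ring1$bonds,
    cbind(c(1L, if (m > 1) 6L + seq_len(m - 1)), 6L + seq_len(m)),
    ring2$bonds + 6L + m,
    cbind(6L + m, 6L + m + 1L)
  )
  list(coords = coords, bonds = bonds)
}

#' Packaged published reference tables
#'
#' Returns the published evaluation tables shipped with the package as
#' tibbles: per-atom Sstate3D values for the reference compounds 6k and 6c,
#' the similarity blocks of every dataset compound against the most and
#' least active references (8c, 7j) by method with the TcIC50 column, the
#' activity table, published Mann-Whitney U values, published Pearson
#' correlations, and the published MCPhd screening table.
#'
#' @return named list of tibbles: `estate_6k`, `estate_6c`, `similarity`,
#'   `activity`, `ranktest_u`, `correlations_vs_mcphd`,
#'   `correlations_vs_tcic50`, `screening`.
#' @export
reference_tables <- function() {
  rd <- function(name) {
    readr::read_csv(system.file("extdata", name, package = "mcphd",
                                mustWork = TRUE),
                    comment = "#", show_col_types = FALSE, progress = FALSE)
  }
  list(
    estate_6k = rd("estate_6k.csv"),
    estate_6c = rd("estate_6c.csv"),
    similarity = rd("similarity_8c_7j.csv"),
    activity = rd("activity.csv"),
    ranktest_u = rd("ranktest_u.csv"),
    correlations_vs_mcphd = rd("correlations_vs_mcphd.csv"),
    correlations_vs_tcic50 = rd("correlations_vs_tcic50.csv"),
    screening = rd("screening_mcphd.csv")
  )
}

#' Reproducible random screening toy
#'
#' A symmetric similarity matrix with unit diagonal and random activity
#' labels, for brute-force validation of screening tables.
#'
#' @param n number of molecules (>= 3).
#' @param seed integer seed.
#' @return list with `sim` (matrix, ids `m1..mn`) and `labels` (tibble with
#'   `id`, `active`).
#' @export
make_screening_toy <- function(n, seed = 1L) {
  stopifnot(n >= 3)
  set.seed(seed)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- round(runif(n * (n - 1) / 2), 3)
  m <- m + t(m)
  diag(m) <- 1
  ids <- sprintf("m%d", seq_len(n))
  dimnames(m) <- list(ids, ids)
  labels <- tibble(id = ids,
                   active = as.integer(runif(n) < 0.5))
  list(sim = m, labels = labels)
}
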