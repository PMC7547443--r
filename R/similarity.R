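#' Continuous Tanimoto coefficient of two scalar properties
#'
#' \eqn{t(a,b) = ab / (a^2 + b^2 - ab)}; equals 1 iff `a == b != 0`.
#' Negative property values are legal inputs and may yield a negative
#' coefficient (which simply never passes a positive similarity threshold).
#'
#' @param a,b numeric vectors (recycled).
#' @return numeric vector.
#' @export
continuous_tanimoto <- function(a, b) {
  if (any(a == 0 & b == 0)) {
    abort("continuous Tanimoto undefined for a = b = 0")
  }
  a * b / (a^2 + b^2 - a * b)
}

#' Canberra distance between two scalar distances
#'
#' \eqn{|d_1 - d_2| / (d_1 + d_2)}, with the coincident-centers case
#' \eqn{d_1 = d_2 = 0} defined as 0.
#'
#' @param d1,d2 non-negative numeric vectors (recycled).
#' @return numeric vector in \[0, 1\].
#' @export
canberra_distance <- function(d1, d2) {
  if (any(d1 < 0 | d2 < 0)) abort("Canberra distance needs non-negative inputs")
  s <- d1 + d2
  ifelse(s == 0, 0, abs(d1 - d2) / s)
}

#' Descriptor-center similarity matrix between two reduced graphs
#'
#' Applies the similarity coefficient to every pair of DC property totals.
#'
#' @param rg1,rg2 [reduce_graph()] results.
#' @param coefficient binary similarity function (default
#'   [continuous_tanimoto()]).
#' @return matrix with `rg1` DCs as rows and `rg2` DCs as columns.
#' @export
dc_similarity_matrix <- function(rg1, rg2, coefficient = continuous_tanimoto) {
  v1 <- rg1$dcs$total_sstate3d; v2 <- rg2$dcs$total_sstate3d
  s <- outer(v1, v2, coefficient)
  dimnames(s) <- list(rg1$dcs$label, rg2$dcs$label)
  s
}

#' Select DC pairs above the similarity threshold
#'
#' Keeps every (i, j) with `S[i, j] > u` (strictly greater), sorted by
#' descending similarity, then by row and column index.
#'
#' @param s DC similarity matrix.
#' @param u similarity threshold in (0, 1\].
#' @return tibble with columns `i`, `j`, `s`; zero rows signal dissimilar
#'   molecules.
#' @export
select_dc_pairs <- function(s, u) {
  stopifnot(u >= 0, u <= 1)
  idx <- which(s > u, arr.ind = TRUE)
  out <- tibble(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]),
                s = s[idx])
  dplyr::arrange(out, dplyr::desc(.data$s), .data$i, .data$j)
}

#' Geometrically consistent DC-pair lists
#'
#' For each selected anchor pair (i, j), collects the companion pairs
#' (k, l) whose DC-DC distances agree geometrically: the Canberra distance
#' between `dist1[i, k]` and `dist2[j, l]` is at most `cutoff`. Each anchor
#' is a member of its own list (Canberra 0).
#'
#' @param selected tibble from [select_dc_pairs()].
#' @param rg1,rg2 the reduced graphs.
#' @param cutoff Canberra cutoff (inclusive), default 0.15.
#' @return list of tibbles (one per anchor, in `selected` order), each with
#'   the anchor as attribute `anchor`.
#' @export
build_pair_lists <- function(selected, rg1, rg2, cutoff = 0.15) {
  stopifnot(cutoff > 0)
  d1 <- rg1$dist; d2 <- rg2$dist
  lapply(seq_len(nrow(selected)), function(a) {
    i <- selected$i[a]; j <- selected$j[a]
    keep <- canberra_distance(d1[i, selected$i], d2[j, selected$j]) <= cutoff
    out <- selected[keep, ]
    attr(out, "anchor") <- c(i = i, j = j)
    out
  })
}

# Largest one-to-one sub-assignment of a candidate list, maximising size
# then total similarity; deterministic tie-break by the (i, j) sequence of
# the list order (which is itself deterministic). Exact branch-and-bound;
# candidate lists are tiny (molecules carry a handful of DCs).
best_assignment <- function(cand) {
  cand <- dplyr::arrange(cand, dplyr::desc(.data$s), .data$i, .data$j)
  n <- nrow(cand)
  best <- list(rows = integer(0), size = 0L, ssum = -Inf)
  rec <- function(k, rows, used_i, used_j, ssum) {
    remaining <- n - k + 1L
    if (length(rows) + remaining < best$size) return()
    if (k > n) {
      size <- length(rows)
      if (size > best$size || (size == best$size && ssum > best$ssum + 1e-12)) {
        best <<- list(rows = rows, size = size, ssum = ssum)
      }
      return()
    }
    i <- cand$i[k]; j <- cand$j[k]
    if (!(i %in% used_i) && !(j %in% used_j)) {
      rec(k + 1L, c(rows, k), c(used_i, i), c(used_j, j), ssum + cand$s[k])
    }
    rec(k + 1L, rows, used_i, used_j, ssum)
  }
  rec(1L, integer(0), integer(0), integer(0), 0)
  cand[best$rows, c("i", "j", "s")]
}

#' Best DC correspondence among the candidate lists
#'
#' From each geometric pair list, takes the largest mutually consistent
#' one-to-one set of DC pairs; across lists, picks the largest such set,
#' breaking ties by highest total DC similarity and then by lexicographic
#' pair order, so the result is deterministic.
#'
#' @param candidates list of tibbles from [build_pair_lists()].
#' @return tibble with columns `i`, `j`, `s` (the matched DC pairs).
#' @export
select_best_correspondence <- function(candidates) {
  if (length(candidates) == 0) {
    return(tibble(i = integer(0), j = integer(0), s = numeric(0)))
  }
  assignments <- lapply(candidates, best_assignment)
  pick_best_assignment(assignments)
}

pick_best_assignment <- function(assignments) {
  keys <- vapply(assignments, function(a) {
    paste(sprintf("%03d-%03d", a$i, a$j), collapse = ";")
  }, character(1))
  score <- data.frame(
    size = vapply(assignments, nrow, integer(1)),
    ssum = vapply(assignments, function(a) sum(a$s), numeric(1)),
    key = keys
  )
  ord <- order(-score$size, -score$ssum, score$key)
  assignments[[ord[1]]]
}

#' Extract the matched fragments
#'
#' The fragment of each molecule is the union of the member atoms of its
#' matched DCs plus the atoms on shortest heavy-atom paths connecting the
#' matched DCs pairwise (lexicographically smallest path on ties, for
#' determinism). `c` is the smaller heavy-atom count of the two fragments.
#'
#' @param corr correspondence tibble from [select_best_correspondence()].
#' @param mol1,mol2 the molecules.
#' @param rg1,rg2 their reduced graphs.
#' @return list with `f1_atoms`, `f2_atoms` (sorted atom ordinals) and `c`.
#' @export
extract_fragments <- function(corr, mol1, mol2, rg1, rg2) {
  if (nrow(corr) == 0) {
    return(list(f1_atoms = integer(0), f2_atoms = integer(0), c = 0L))
  }
  f1 <- connect_dc_atoms(mol1, rg1$dcs$members[corr$i])
  f2 <- connect_dc_atoms(mol2, rg2$dcs$members[corr$j])
  list(f1_atoms = f1, f2_atoms = f2,
       c = as.integer(min(length(f1), length(f2))))
}

connect_dc_atoms <- function(mol, member_sets) {
  atoms <- sort(unique(unlist(member_sets)))
  if (length(member_sets) < 2) return(atoms)
  g <- heavy_graph(mol)
  vnames <- igraph::V(g)$name
  for (a in seq_along(member_sets)) {
    for (b in seq_len(a - 1L)) {
      atoms <- union(atoms,
                     shortest_link(g, vnames, member_sets[[a]],
                                   member_sets[[b]]))
    }
  }
  frag <- sort(unique(atoms))
  sub <- igraph::induced_subgraph(g, which(vnames %in% as.character(frag)))
  comp <- igraph::components(sub)
  if (comp$no > 1L) {
    warn(sprintf("molecule '%s': fragment disconnected; keeping largest component",
                 mol$id))
    big <- which.max(comp$csize)
    frag <- sort(as.integer(igraph::V(sub)$name[comp$membership == big]))
  }
  frag
}

# Atoms of the lexicographically smallest shortest path between two member
# sets of a heavy-atom graph.
shortest_link <- function(g, vnames, m1, m2) {
  dmat <- igraph::distances(g, v = which(vnames %in% as.character(m1)),
                            to = which(vnames %in% as.character(m2)))
  if (!any(is.finite(dmat))) return(integer(0))
  dmin <- min(dmat)
  if (dmin <= 1) return(integer(0))     # adjacent or overlapping sets
  hits <- which(dmat == dmin, arr.ind = TRUE)
  from <- as.integer(rownames(dmat)[hits[, 1]])
  to <- as.integer(colnames(dmat)[hits[, 2]])
  ord <- order(pmin(from, to), pmax(from, to))
  a <- from[ord[1]]; b <- to[ord[1]]
  paths <- igraph::all_shortest_paths(
    g, from = which(vnames == as.character(a)),
    to = which(vnames == as.character(b)))$vpaths
  seqs <- lapply(paths, function(p) as.integer(vnames[as.integer(p)]))
  keys <- vapply(seqs, function(s) paste(sprintf("%05d", s), collapse = ","),
                 character(1))
  seqs[[order(keys)[1]]]
}

#' Modified Tanimoto similarity on heavy-atom counts
#'
#' \eqn{Tc = c / (a + b - c)} with `a`, `b` the heavy-atom counts of the two
#' molecules and `c` the smaller heavy-atom count of the matched fragments.
#'
#' @param c matched-fragment heavy-atom count, `0 <= c <= min(a, b)`.
#' @param a,b heavy-atom counts of the molecules.
#' @return numeric in \[0, 1\].
#' @export
tc_mcphd <- function(c, a, b) {
  stopifnot(a >= 1, b >= 1)
  if (any(c < 0) || any(c > pmin(a, b))) {
    abort("fragment size c must satisfy 0 <= c <= min(a, b)")
  }
  c / (a + b - c)
}

#' Maximum-common-property similarity of two molecules
#'
#' The full matching pipeline: per-atom Sstate3D, graph reduction to
#' descriptor centers, DC similarity matrix and threshold selection,
#' Canberra-consistent geometric pair lists, best one-to-one DC
#' correspondence, fragment extraction, and the modified Tanimoto score.
#' When several candidate lists tie on correspondence size, the fragments
#' of each are evaluated and the pair with the highest similarity wins.
#' An empty DC selection yields similarity 0 with an empty fragment.
#'
#' @param mol1,mol2 [mol3d()] objects with 3D coordinates.
#' @param u similarity threshold in (0, 1\], default 0.95 (strictly
#'   greater-than).
#' @param cutoff Canberra geometric cutoff, default 0.15 (inclusive).
#' @param coefficient DC similarity coefficient.
#' @param ring_mode,centroid passed to [reduce_graph()].
#' @param perturbation_sign,distance_power passed to [sstate3d()].
#' @return An `mcphd_sim` object; see [glance.mcphd_sim()] and
#'   [tidy.mcphd_sim()].
#' @export
mcphd_similarity <- function(mol1, mol2, u = 0.95, cutoff = 0.15,
                             coefficient = continuous_tanimoto,
                             ring_mode = "fused_system", centroid = "mass",
                             perturbation_sign = "difference",
                             distance_power = 2) {
  rg1 <- reduce_graph(mol1, sstate3d(mol1, perturbation_sign, distance_power),
                      ring_mode, centroid)
  rg2 <- reduce_graph(mol2, sstate3d(mol2, perturbation_sign, distance_power),
                      ring_mode, centroid)
  mcphd_similarity_rg(mol1, mol2, rg1, rg2, u, cutoff, coefficient)
}

mcphd_similarity_rg <- function(mol1, mol2, rg1, rg2, u = 0.95, cutoff = 0.15,
                                coefficient = continuous_tanimoto) {
  a <- heavy_atom_count(mol1); b <- heavy_atom_count(mol2)
  s <- dc_similarity_matrix(rg1, rg2, coefficient)
  selected <- select_dc_pairs(s, u)
  params <- list(u = u, cutoff = cutoff)
  if (nrow(selected) == 0) {
    return(new_mcphd_sim(mol1$id, mol2$id, 0, integer(0), integer(0), 0L,
                         a, b, selected, params))
  }
  lists <- build_pair_lists(selected, rg1, rg2, cutoff)
  assignments <- lapply(lists, best_assignment)
  sizes <- vapply(assignments, nrow, integer(1))
  top <- assignments[sizes == max(sizes)]
  keys <- vapply(top, function(x)
    paste(sprintf("%03d-%03d", x$i, x$j), collapse = ";"), character(1))
  top <- top[!duplicated(keys)]
  frags <- lapply(top, extract_fragments, mol1 = mol1, mol2 = mol2,
                  rg1 = rg1, rg2 = rg2)
  tcs <- vapply(frags, function(f) tc_mcphd(f$c, a, b), numeric(1))
  ssums <- vapply(top, function(x) sum(x$s), numeric(1))
  keys <- vapply(top, function(x)
    paste(sprintf("%03d-%03d", x$i, x$j), collapse = ";"), character(1))
  pick <- order(-tcs, -ssums, keys)[1]
  corr <- top[[pick]]
  corr$dc1 <- rg1$dcs$label[corr$i]
  corr$dc2 <- rg2$dcs$label[corr$j]
  f <- frags[[pick]]
  new_mcphd_sim(mol1$id, mol2$id, tcs[pick], f$f1_atoms, f$f2_atoms, f$c,
                a, b, corr, params)
}

new_mcphd_sim <- function(id1, id2, tc, f1, f2, c, a, b, pairs, params) {
  structure(list(id1 = id1, id2 = id2, tc_mcphd = tc,
                 f1_atoms = f1, f2_atoms = f2, c = c, a = a, b = b,
                 pairs = pairs, params = params),
            class = "mcphd_sim")
}

#' @export
print.mcphd_sim <- function(x, ...) {
  cat(sprintf("<mcphd_sim> %s vs %s: Tc = %.4f (c = %d, a = %d, b = %d, %d DC pairs)\n",
              x$id1, x$id2, x$tc_mcphd, x$c, x$a, x$b, nrow(x$pairs)))
  invisible(x)
}

#' Tidy the matched DC pairs of a similarity result
#'
#' @param x an `mcphd_sim`.
#' @param ... unused.
#' @return tibble with one row per matched DC pair.
#' @method tidy mcphd_sim
#' @export
tidy.mcphd_sim <- function(x, ...) {
  p <- x$pairs
  tibble(id1 = x$id1, id2 = x$id2,
         dc1 = if ("dc1" %in% names(p)) p$dc1 else character(nrow(p)),
         dc2 = if ("dc2" %in% names(p)) p$dc2 else character(nrow(p)),
         similarity = p$s)
}

#' One-row summary of a similarity result
#'
#' @param x an `mcphd_sim`.
#' @param ... unused.
#' @return one-row tibble with `id1`, `id2`, `tc_mcphd`, fragment sizes and
#'   molecule heavy-atom counts.
#' @method glance mcphd_sim
#' @export
glance.mcphd_sim <- function(x, ...) {
  tibble(id1 = x$id1, id2 = x$id2, tc_mcphd = x$tc_mcphd,
         c = x$c, a = x$a, b = x$b, n_f1 = length(x$f1_atoms),
         n_f2 = length(x$f2_atoms), n_pairs = nrow(x$pairs))
}

#' All-against-all MCPhd similarity matrix
#'
#' Computes each molecule's reduced graph once and scores every unordered
#' pair; the diagonal is 1 by construction.
#'
#' @param mols list of [mol3d()] objects.
#' @inheritParams mcphd_similarity
#' @return symmetric matrix of class `mcphd_matrix`, molecule ids as
#'   dimnames.
#' @export
mcphd_matrix <- function(mols, u = 0.95, cutoff = 0.15,
                         coefficient = continuous_tanimoto,
                         ring_mode = "fused_system", centroid = "mass",
                         perturbation_sign = "difference",
                         distance_power = 2) {
  ids <- unname(vapply(mols, function(m) m$id, character(1)))
  if (anyDuplicated(ids)) abort("duplicate molecule ids")
  rgs <- lapply(mols, function(m)
    reduce_graph(m, sstate3d(m, perturbation_sign, distance_power),
                 ring_mode, centroid))
  n <- length(mols)
  out <- diag(1, n)
  dimnames(out) <- list(ids, ids)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        r <- mcphd_similarity_rg(mols[[i]], mols[[j]], rgs[[i]], rgs[[j]],
                                 u, cutoff, coefficient)
        out[i, j] <- out[j, i] <- r$tc_mcphd
      }
    }
  }
  class(out) <- c("mcphd_matrix", class(out))
  out
}

#' @export
print.mcphd_matrix <- function(x, ...) {
  cat(sprintf("<mcphd_matrix> %d molecules\n", nrow(x)))
  print(unclass(round(x, 2)))
  invisible(x)
}

#' Long form of a similarity matrix
#'
#' @param x an `mcphd_matrix` (or any labelled symmetric matrix).
#' @param ... unused.
#' @return tibble with columns `id1`, `id2`, `similarity` (unordered pairs,
#'   `id1` before `id2` in matrix order, diagonal excluded).
#' @method tidy mcphd_matrix
#' @export
tidy.mcphd_matrix <- function(x, ...) {
  m <- unclass(x)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble(id1 = rownames(m)[idx[, 1]], id2 = colnames(m)[idx[, 2]],
         similarity = m[idx])
}
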