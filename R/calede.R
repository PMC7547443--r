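#' Ring-system descriptor centers
#'
#' Finds ring descriptor centers (kind `Rn`) on the heavy-atom graph. With
#' `ring_mode = "fused_system"` (default) every fused or bridged ring system
#' forms a single DC whose order `n` is the number of distinct ring atoms,
#' so a bicyclo\[2.2.2\]octane core yields `R8`. With `ring_mode = "sssr"`
#' each ring of a smallest-set-of-smallest-rings basis yields its own DC
#' (atoms shared between rings are assigned to the smaller ring first).
#'
#' @param mol a [mol3d()].
#' @param ring_mode `"fused_system"` or `"sssr"`.
#' @return tibble with columns `kind` and `members` (list of atom ordinals);
#'   zero rows for acyclic molecules.
#' @export
detect_ring_centers <- function(mol, ring_mode = c("fused_system", "sssr")) {
  ring_mode <- match.arg(ring_mode)
  g <- heavy_graph(mol)
  if (igraph::ecount(g) == 0) {
    return(tibble(kind = character(0), members = list()))
  }
  ring_edges <- setdiff(seq_len(igraph::ecount(g)), igraph::bridges(g))
  if (length(ring_edges) == 0) {
    return(tibble(kind = character(0), members = list()))
  }
  sg <- igraph::subgraph_from_edges(g, ring_edges, delete.vertices = TRUE)
  if (ring_mode == "fused_system") {
    comp <- igraph::components(sg)
    members <- lapply(seq_len(comp$no), function(k) {
      sort(as.integer(igraph::V(sg)$name[comp$membership == k]))
    })
    return(tibble(kind = sprintf("R%d", lengths(members)), members = members))
  }
  rings <- sssr_rings(sg)
  sizes <- lengths(rings)
  taken <- integer(0)
  members <- lapply(rings, function(m) {
    out <- setdiff(m, taken)
    taken <<- union(taken, m)
    sort(out)
  })
  keep <- lengths(members) > 0
  # kind reflects the ring size even when fused atoms were already claimed
  tibble(kind = sprintf("R%d", sizes[keep]), members = members[keep])
}

# Approximate SSSR: for every ring edge, the shortest cycle through it;
# unique cycles kept smallest-first. Adequate for the simple fused systems
# this package targets.
sssr_rings <- function(sg) {
  rings <- list()
  for (eid in seq_len(igraph::ecount(sg))) {
    ends <- igraph::ends(sg, eid, names = FALSE)
    g2 <- igraph::delete_edges(sg, eid)
    p <- suppressWarnings(
      igraph::shortest_paths(g2, from = ends[1], to = ends[2])$vpath[[1]])
    if (length(p) == 0) next
    cyc <- sort(as.integer(igraph::V(sg)$name[as.integer(p)]))
    key <- paste(cyc, collapse = ",")
    rings[[key]] <- cyc
  }
  rings <- unname(rings)
  rings[order(lengths(rings))]
}

#' Branching-cluster descriptor centers
#'
#' A `C3` (`C4`) DC for every non-ring heavy atom of heavy degree 3 (4),
#' together with its not-yet-assigned non-ring heavy neighbours. Atoms are
#' claimed in ordinal order; first assignment wins.
#'
#' @param mol a [mol3d()].
#' @param assigned integer vector of atom ordinals already claimed by DCs.
#' @return tibble with columns `kind` and `members`.
#' @export
detect_cluster_centers <- function(mol, assigned = integer(0)) {
  deg <- heavy_degree(mol)
  heavy <- as.integer(names(deg))
  nbrs <- heavy_neighbours(mol)
  kinds <- character(0); members <- list()
  for (v in heavy) {
    if (v %in% assigned) next
    d <- deg[[as.character(v)]]
    if (d != 3 && d != 4) next
    grp <- sort(unique(c(v, setdiff(nbrs[[as.character(v)]], assigned))))
    kinds <- c(kinds, sprintf("C%d", d))
    members <- c(members, list(grp))
    assigned <- union(assigned, grp)
  }
  tibble(kind = kinds, members = members)
}

heavy_neighbours <- function(mol) {
  heavy <- mol$atoms$index[mol$atoms$is_heavy]
  out <- setNames(vector("list", length(heavy)), as.character(heavy))
  b <- mol$bonds
  if (nrow(b) > 0) {
    keep <- b$a1 %in% heavy & b$a2 %in% heavy
    for (k in which(keep)) {
      out[[as.character(b$a1[k])]] <- c(out[[as.character(b$a1[k])]], b$a2[k])
      out[[as.character(b$a2[k])]] <- c(out[[as.character(b$a2[k])]], b$a1[k])
    }
  }
  lapply(out, function(x) sort(as.integer(x)))
}

#' Heteroatom and terminal-group descriptor centers
#'
#' `X` DCs collect the remaining heteroatoms: each unassigned non-carbon
#' heavy atom seeds a group that absorbs contiguous unassigned heteroatoms
#' and any unassigned carbon that is multiply bonded to a heteroatom or
#' bonded to at least two heteroatoms (so an ester \eqn{-C(=O)O-} collapses
#' into one X). `M3`/`M2`/`M` DCs then label the remaining terminal carbons
#' carrying 3/2/1 hydrogens.
#'
#' @inheritParams detect_cluster_centers
#' @return tibble with columns `kind` and `members`.
#' @export
detect_hetero_and_terminal_centers <- function(mol, assigned = integer(0)) {
  atoms <- mol$atoms
  deg <- heavy_degree(mol)
  nbrs <- heavy_neighbours(mol)
  hetero <- atoms$index[atoms$is_heavy & !atoms$element %in% c("C", "H")]
  kinds <- character(0); members <- list()

  group_carbon_ok <- function(v) {
    nb <- nbrs[[as.character(v)]]
    het_nb <- nb[atoms$element[nb] != "C"]
    if (length(het_nb) >= 2) return(TRUE)
    b <- mol$bonds
    multi <- b[(b$a1 == v & b$a2 %in% het_nb) |
               (b$a2 == v & b$a1 %in% het_nb), , drop = FALSE]
    any(multi$order %in% c(2L, 3L, 4L))
  }

  for (seed in hetero) {
    if (seed %in% assigned) next
    grp <- integer(0)
    queue <- seed
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (v %in% grp || v %in% assigned) next
      is_c <- atoms$element[v] == "C"
      if (is_c && !group_carbon_ok(v)) next
      grp <- c(grp, v)
      queue <- c(queue, setdiff(nbrs[[as.character(v)]], c(grp, assigned)))
    }
    grp <- sort(grp)
    kinds <- c(kinds, "X")
    members <- c(members, list(grp))
    assigned <- union(assigned, grp)
  }

  terminals <- atoms$index[atoms$is_heavy & atoms$element == "C" &
                           !atoms$index %in% assigned]
  for (v in terminals) {
    if (deg[[as.character(v)]] != 1) next
    h <- atoms$n_hydrogens[v]
    if (!h %in% 1:3) next
    kinds <- c(kinds, c("M", "M2", "M3")[h])
    members <- c(members, list(v))
    assigned <- union(assigned, v)
  }
  tibble(kind = kinds, members = members)
}

#' Reduce a molecule to its descriptor-center graph
#'
#' Runs the full reduction: ring systems, then branching clusters, then
#' heteroatom and terminal groups, with first-assignment-wins precedence
#' (unassigned chain carbons remain linkers outside any DC). Each DC
#' carries the sum of its member atoms' Sstate3D values and a center of
#' mass; the result also holds the DC-DC Euclidean distance matrix.
#'
#' @param mol a [mol3d()].
#' @param estates optional precomputed [sstate3d()] table for `mol`.
#' @param ring_mode passed to [detect_ring_centers()].
#' @param centroid `"mass"` (default, standard atomic masses of the heavy
#'   members) or `"geometric"`.
#' @return A `reduced_graph`: list with `molecule_id`, `dcs` (tibble with
#'   `label`, `kind`, `members`, `total_sstate3d`, `cx`, `cy`, `cz`) and
#'   `dist` (labelled symmetric matrix, Angstrom).
#' @export
reduce_graph <- function(mol, estates = NULL,
                         ring_mode = c("fused_system", "sssr"),
                         centroid = c("mass", "geometric")) {
  ring_mode <- match.arg(ring_mode)
  centroid <- match.arg(centroid)
  if (is.null(estates)) estates <- sstate3d(mol)
  rings <- detect_ring_centers(mol, ring_mode)
  assigned <- unlist(rings$members)
  clusters <- detect_cluster_centers(mol, assigned)
  assigned <- c(assigned, unlist(clusters$members))
  rest <- detect_hetero_and_terminal_centers(mol, assigned)
  dcs <- dplyr::bind_rows(rings, clusters, rest)
  if (nrow(dcs) == 0) {
    abort(sprintf("molecule '%s': reduction produced no descriptor centers",
                  mol$id))
  }
  dcs$label <- sprintf("%s_%d", dcs$kind, seq_len(nrow(dcs)))
  ss <- setNames(estates$sstate3d, estates$atom)
  el <- element_data()
  atoms <- mol$atoms
  com <- t(vapply(dcs$members, function(m) {
    sub <- atoms[match(m, atoms$index), ]
    w <- if (centroid == "mass") el$mass[match(sub$element, el$element)] else
      rep(1, nrow(sub))
    c(sum(w * sub$x), sum(w * sub$y), sum(w * sub$z)) / sum(w)
  }, numeric(3)))
  dcs$total_sstate3d <- vapply(dcs$members, function(m)
    sum(ss[as.character(m)]), numeric(1))
  dcs$cx <- com[, 1]; dcs$cy <- com[, 2]; dcs$cz <- com[, 3]
  dcs <- dcs[, c("label", "kind", "members", "total_sstate3d",
                 "cx", "cy", "cz")]
  d <- as.matrix(dist(com))
  dimnames(d) <- list(dcs$label, dcs$label)
  structure(list(molecule_id = mol$id, dcs = dcs, dist = d),
            class = "reduced_graph")
}

#' @export
print.reduced_graph <- function(x, ...) {
  cat(sprintf("<reduced_graph> %s: %d DCs (%s)\n", x$molecule_id,
              nrow(x$dcs), paste(x$dcs$kind, collapse = ", ")))
  invisible(x)
}

#' @rdname reduce_graph
#' @param x a `reduced_graph`.
#' @param ... unused.
#' @method tidy reduced_graph
#' @export
tidy.reduced_graph <- function(x, ...) {
  d <- x$dcs
  tibble(
    molecule_id = x$molecule_id, label = d$label, kind = d$kind,
    n_members = lengths(d$members),
    members = vapply(d$members, paste, character(1), collapse = ","),
    total_sstate3d = d$total_sstate3d, cx = d$cx, cy = d$cy, cz = d$cz
  )
}
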