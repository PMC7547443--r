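# Independent brute-force oracles, deliberately written as naive loops so
# they share no code path with the implementation they check.

# E-state perturbation by an explicit double loop over ordered pairs.
oracle_perturbation <- function(mol, i_vals, power = 2) {
  a <- mol$atoms[mol$atoms$is_heavy, ]
  n <- nrow(a)
  out <- numeric(n)
  for (p in seq_len(n)) {
    for (q in seq_len(n)) {
      if (p == q) next
      r <- sqrt((a$x[p] - a$x[q])^2 + (a$y[p] - a$y[q])^2 +
                  (a$z[p] - a$z[q])^2)
      out[p] <- out[p] + (i_vals[p] - i_vals[q]) / r^power
    }
  }
  out
}

# All one-to-one sub-assignments of each geometric pair list, fully
# enumerated; scored by size, then total similarity, then the pair-key.
oracle_best_correspondence <- function(selected, rg1, rg2, cutoff = 0.15) {
  d1 <- rg1$dist; d2 <- rg2$dist
  best_of_list <- function(rows) {
    n <- nrow(rows)
    best <- NULL
    for (mask in 0:(2^n - 1)) {
      take <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
      sub <- rows[take, , drop = FALSE]
      if (anyDuplicated(sub$i) || anyDuplicated(sub$j)) next
      key <- paste(sprintf("%03d-%03d", sub$i, sub$j), collapse = ";")
      cand <- list(size = nrow(sub), ssum = sum(sub$s), key = key, rows = sub)
      if (is.null(best) ||
          cand$size > best$size ||
          (cand$size == best$size && cand$ssum > best$ssum + 1e-12) ||
          (cand$size == best$size && abs(cand$ssum - best$ssum) <= 1e-12 &&
             cand$key < best$key)) {
        best <- cand
      }
    }
    best
  }
  winners <- list()
  for (a in seq_len(nrow(selected))) {
    i <- selected$i[a]; j <- selected$j[a]
    keep <- logical(nrow(selected))
    for (b in seq_len(nrow(selected))) {
      k <- selected$i[b]; l <- selected$j[b]
      dd <- d1[i, k] + d2[j, l]
      cb <- if (dd == 0) 0 else abs(d1[i, k] - d2[j, l]) / dd
      keep[b] <- cb <= cutoff
    }
    winners[[a]] <- best_of_list(selected[keep, , drop = FALSE])
  }
  ord <- order(-vapply(winners, `[[`, numeric(1), "size"),
               -vapply(winners, `[[`, numeric(1), "ssum"),
               vapply(winners, `[[`, character(1), "key"))
  winners[[ord[1]]]$rows
}

# Screening counts by direct enumeration of molecule pairs.
oracle_screening <- function(sim, labels, threshold) {
  ids <- rownames(sim)
  act <- stats::setNames(labels$active, labels$id)[ids]
  counts <- c("active-active" = 0, "inactive-inactive" = 0,
              "active-inactive" = 0, "inactive-active" = 0)
  for (p in seq_along(ids)) {
    for (q in seq_along(ids)) {
      if (q <= p) next
      if (sim[p, q] < threshold) next
      cat_name <- if (act[p] == 1 && act[q] == 1) "active-active"
        else if (act[p] == 0 && act[q] == 0) "inactive-inactive"
        else if (act[p] == 1) "active-inactive" else "inactive-active"
      counts[cat_name] <- counts[cat_name] + 1
    }
  }
  counts
}

# Mann-Whitney U by direct pair counting with half-credit for ties.
oracle_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  }
  u
}

# Fake reduced graph with random DC property totals and 3D centers.
random_rg <- function(n_dc, seed, id = sprintf("rg%d", seed)) {
  set.seed(seed)
  com <- matrix(stats::runif(3 * n_dc, -5, 5), ncol = 3)
  dcs <- tibble::tibble(
    label = sprintf("D_%d", seq_len(n_dc)),
    kind = "X",
    members = as.list(seq_len(n_dc)),
    total_sstate3d = stats::runif(n_dc, 0.5, 10),
    cx = com[, 1], cy = com[, 2], cz = com[, 3])
  d <- as.matrix(stats::dist(com))
  dimnames(d) <- list(dcs$label, dcs$label)
  structure(list(molecule_id = id, dcs = dcs, dist = d),
            class = "reduced_graph")
}
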