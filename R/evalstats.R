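#' Potency similarity of two IC50 values
#'
#' Continuous Tanimoto of two half-maximal inhibitory concentrations:
#' \eqn{TcIC50 = ab / (a^2 + b^2 - ab)}. The coefficient is
#' scale-invariant, lies in (0, 1\] for positive potencies, and equals 1
#' iff the potencies are equal; it serves as a pseudo-ground-truth of
#' "activity similarity" when evaluating structural similarity methods.
#'
#' @param a,b positive IC50 values (same unit, conventionally micromolar).
#' @return numeric vector in (0, 1\].
#' @export
tc_ic50 <- function(a, b) {
  if (any(!is.finite(a) | !is.finite(b) | a <= 0 | b <= 0)) {
    abort("IC50 values must be positive")
  }
  continuous_tanimoto(a, b)
}

#' Pearson correlation with domain checks
#'
#' Standard product-moment correlation; errors on short or constant input
#' instead of returning NA.
#'
#' @param x,y equal-length numeric vectors (length >= 3, nonzero variance).
#' @return correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("correlation undefined for zero-variance input")
  }
  stats::cor(x, y)
}

#' Mann-Whitney U test for two similarity vectors
#'
#' U is computed with midranks for ties; the reported statistic follows the
#' min convention, `U = min(U_x, U_y)` with `U_x + U_y = n_x * n_y`. The
#' two-sided p-value uses the normal approximation with tie correction and
#' continuity correction (via [stats::wilcox.test()]); `exact = TRUE`
#' switches to the exact distribution (only available without ties).
#'
#' @param x,y numeric vectors.
#' @param exact logical; exact p-value instead of the asymptotic one.
#' @return one-row tibble with `u`, `u_x`, `u_y`, `p`.
#' @export
mann_whitney_u <- function(x, y, exact = FALSE) {
  if (length(x) == 0 || length(y) == 0) abort("samples must be non-empty")
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE,
                       alternative = "two.sided"))
  u_x <- unname(wt$statistic)
  u_y <- length(x) * length(y) - u_x
  tibble(u = min(u_x, u_y), u_x = u_x, u_y = u_y, p = wt$p.value)
}

#' Screening table at a similarity threshold
#'
#' Counts unordered molecule pairs (diagonal excluded) whose similarity is
#' at or above the threshold, split by activity category. The first label
#' of a mixed pair is the one appearing first in the matrix order, matching
#' the asymmetric active-inactive / inactive-active convention of published
#' screening tables; `correct` pairs share the activity label.
#'
#' @param sim labelled symmetric similarity matrix (e.g. [mcphd_matrix()]).
#' @param labels tibble with columns `id`, `active` (0/1), or a named 0/1
#'   vector covering all matrix ids.
#' @param thresholds numeric vector of similarity thresholds (inclusive).
#' @return tibble of class `screening_table` with columns `threshold`,
#'   `category` (`active-active`, `inactive-inactive`, `active-inactive`,
#'   `inactive-active`, `correct`, `incorrect`, `total`), `pairs`, `pct`.
#' @export
screening_table <- function(sim, labels, thresholds) {
  m <- unclass(sim)
  ids <- rownames(m)
  if (is.null(ids)) abort("similarity matrix must carry molecule ids")
  if (is.data.frame(labels)) labels <- setNames(labels$active, labels$id)
  missing <- setdiff(ids, names(labels))
  if (length(missing) > 0) {
    abort(sprintf("no activity label for: %s", paste(missing, collapse = ", ")))
  }
  act <- as.logical(labels[ids])
  idx <- which(upper.tri(m), arr.ind = TRUE)
  sim_v <- m[idx]
  cat_v <- dplyr::case_when(
    act[idx[, 1]] & act[idx[, 2]] ~ "active-active",
    !act[idx[, 1]] & !act[idx[, 2]] ~ "inactive-inactive",
    act[idx[, 1]] ~ "active-inactive",
    TRUE ~ "inactive-active"
  )
  cats <- c("active-active", "inactive-inactive", "active-inactive",
            "inactive-active")
  out <- purrr::map_dfr(thresholds, function(th) {
    sel <- sim_v >= th
    counts <- vapply(cats, function(ct) sum(sel & cat_v == ct), integer(1))
    total <- sum(counts)
    correct <- counts[1] + counts[2]
    pairs <- c(counts, correct = correct, incorrect = total - correct,
               total = total)
    tibble(threshold = th,
           category = c(cats, "correct", "incorrect", "total"),
           pairs = as.integer(pairs),
           pct = if (total > 0) 100 * pairs / total else rep(0, 7))
  })
  class(out) <- c("screening_table", class(out))
  out
}

#' Compare similarity methods against MCPhd and potency similarity
#'
#' For one reference molecule, takes each method's similarity vector over
#' the dataset and reports its Pearson correlation with the TcIC50 potency
#' similarity and with the MCPhd vector, plus the Mann-Whitney U (min
#' convention) and two-sided asymptotic p against the MCPhd vector.
#'
#' Input is either a tidy tibble with columns `id`, `ic50` and one column
#' per method (one row per dataset molecule, reference row included), or a
#' named list of labelled similarity matrices sharing ids plus an `ic50`
#' table, from which the reference's vectors are pulled.
#'
#' @param sims tidy per-molecule tibble, or named list of similarity
#'   matrices (must include an `mcphd` entry/column).
#' @param reference reference molecule id (needed to compute TcIC50 and,
#'   for matrix input, to select the column).
#' @param ic50 optional activity tibble (`id`, `ic50`) when `sims` is a
#'   list of matrices.
#' @param mcphd_col name of the MCPhd column/entry, default `"mcphd"`.
#' @return tibble with one row per comparator method: `method`,
#'   `r_vs_tcic50`, `r_vs_mcphd`, `u_vs_mcphd`, `p_vs_mcphd`, plus one row
#'   for MCPhd itself (`r_vs_tcic50` only).
#' @export
compare_methods <- function(sims, reference, ic50 = NULL,
                            mcphd_col = "mcphd") {
  if (!is.data.frame(sims)) {
    mats <- sims
    ids <- rownames(mats[[1]])
    for (m in mats) {
      if (!identical(rownames(m), ids)) abort("matrices must share molecule ids")
    }
    if (is.null(ic50)) abort("ic50 table required with matrix input")
    sims <- tibble(id = ids)
    sims <- dplyr::left_join(sims, ic50[, c("id", "ic50")], by = "id")
    for (nm in names(mats)) sims[[nm]] <- mats[[nm]][, reference]
  }
  if (!all(c("id", "ic50", mcphd_col) %in% names(sims))) {
    abort(sprintf("need columns id, ic50 and '%s'", mcphd_col))
  }
  if (!reference %in% sims$id) abort(sprintf("unknown reference '%s'", reference))
  ref_ic50 <- sims$ic50[sims$id == reference]
  tcic <- if ("tcic50" %in% names(sims)) sims$tcic50 else
    tc_ic50(ref_ic50, sims$ic50)
  methods <- setdiff(names(sims), c("id", "ic50", "tcic50"))
  mc <- sims[[mcphd_col]]
  purrr::map_dfr(methods, function(nm) {
    v <- sims[[nm]]
    if (nm == mcphd_col) {
      return(tibble(method = nm, r_vs_tcic50 = pearson_r(v, tcic),
                    r_vs_mcphd = NA_real_, u_vs_mcphd = NA_real_,
                    p_vs_mcphd = NA_real_))
    }
    u <- mann_whitney_u(mc, v)
    tibble(method = nm, r_vs_tcic50 = pearson_r(v, tcic),
           r_vs_mcphd = pearson_r(v, mc),
           u_vs_mcphd = u$u, p_vs_mcphd = u$p)
  })
}
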