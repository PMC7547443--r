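test_that("continuous Tanimoto has the expected fixed points", {
  expect_equal(continuous_tanimoto(2, 2), 1)
  expect_equal(continuous_tanimoto(1, 2), 2 / 3)
  expect_equal(continuous_tanimoto(0, 5), 0)
  expect_error(continuous_tanimoto(0, 0), "undefined")
  # negative property totals are legal and give a coefficient below zero
  expect_lt(continuous_tanimoto(-1, 2), 0)
})

test_that("Canberra distance handles identical and degenerate inputs", {
  expect_equal(canberra_distance(3, 3), 0)
  expect_equal(canberra_distance(1, 3), 0.5)
  expect_equal(canberra_distance(0, 0), 0)
  expect_error(canberra_distance(-1, 1), "non-negative")
})

test_that("DC pair selection is strict and ordered by similarity", {
  s <- matrix(c(0.96, 0.1, 0.2, 0.99), 2, 2, byrow = TRUE)
  sel <- select_dc_pairs(s, 0.95)
  expect_equal(sel$i, c(2L, 1L))
  expect_equal(sel$j, c(2L, 1L))

  expect_equal(nrow(select_dc_pairs(s, 0.999)), 0)
  # vacuous threshold keeps every positive entry
  expect_equal(nrow(select_dc_pairs(s, 0)), 4)
  # strictness: an entry equal to u is not selected
  expect_equal(nrow(select_dc_pairs(matrix(0.95), 0.95)), 0)
})

test_that("self-comparison gives a unit diagonal in the DC matrix", {
  rg <- reduce_graph(make_molecule(fixture_spec("two_dc_linker", 2,
                                                id = "two_rings")))
  s <- dc_similarity_matrix(rg, rg)
  expect_equal(unname(diag(s)), rep(1, nrow(s)))
  rg1 <- random_rg(1, seed = 3)
  rg1$dcs$total_sstate3d <- 1
  rg2 <- random_rg(1, seed = 4)
  rg2$dcs$total_sstate3d <- 2
  expect_equal(unname(dc_similarity_matrix(rg1, rg2)[1, 1]), 2 / 3)
})

test_that("geometric pair lists contain the anchor and respect the cutoff", {
  rg <- reduce_graph(make_molecule(fixture_spec("two_dc_linker", 2,
                                                id = "two_rings")))
  sel <- select_dc_pairs(dc_similarity_matrix(rg, rg), 0.95)
  lists <- build_pair_lists(sel, rg, rg, 0.15)
  expect_length(lists, nrow(sel))
  for (k in seq_along(lists)) {
    anchor <- attr(lists[[k]], "anchor")
    expect_true(any(lists[[k]]$i == anchor["i"] &
                      lists[[k]]$j == anchor["j"]))
  }
  # identical geometry: the diagonal anchors admit every diagonal companion
  diag_list <- lists[[which(sel$i == 1 & sel$j == 1)]]
  expect_true(any(diag_list$i == 2 & diag_list$j == 2))

  single <- sel[1, ]
  one <- build_pair_lists(single, rg, rg, 0.15)
  expect_equal(nrow(one[[1]]), 1)
})

test_that("best correspondence is the exhaustive-enumeration optimum", {
  set.seed(42)
  cases <- expand.grid(n1 = 2:5, n2 = 2:5, rep = 1:3)
  for (r in seq_len(nrow(cases))) {
    rg1 <- random_rg(cases$n1[r], seed = 100 + r)
    rg2 <- random_rg(cases$n2[r], seed = 200 + r, id = "b")
    s <- dc_similarity_matrix(rg1, rg2)
    sel <- select_dc_pairs(s, 0.6)
    if (nrow(sel) == 0) next
    got <- select_best_correspondence(build_pair_lists(sel, rg1, rg2, 0.25))
    want <- oracle_best_correspondence(sel, rg1, rg2, 0.25)
    expect_equal(nrow(got), nrow(want), label = sprintf("case %d size", r))
    expect_equal(sum(got$s), sum(want$s), tolerance = 1e-12,
                 label = sprintf("case %d score", r))
  }
})

test_that("equal-size candidates are resolved by total similarity", {
  cand <- list(
    tibble::tibble(i = c(1L, 2L), j = c(1L, 2L), s = c(0.96, 0.96)),
    tibble::tibble(i = c(3L, 4L), j = c(3L, 4L), s = c(0.99, 0.98))
  )
  best <- select_best_correspondence(cand)
  expect_equal(best$i, c(3L, 4L))
  single <- list(tibble::tibble(i = 1L, j = 2L, s = 0.97))
  expect_equal(select_best_correspondence(single)$j, 2L)
  expect_equal(nrow(select_best_correspondence(list())), 0)
})

test_that("fragments are DC members plus connecting shortest paths", {
  two <- make_molecule(fixture_spec("two_dc_linker", 2, id = "two_rings"))
  rg <- reduce_graph(two)
  # both rings matched: members (12) plus the 2-carbon linker
  corr <- tibble::tibble(i = c(1L, 2L), j = c(1L, 2L), s = 1)
  frag <- extract_fragments(corr, two, two, rg, rg)
  expect_equal(frag$c, 14L)
  expect_setequal(frag$f1_atoms, 1:14)

  # single matched DC: members only, no path closure
  corr1 <- tibble::tibble(i = 1L, j = 1L, s = 1)
  frag1 <- extract_fragments(corr1, two, two, rg, rg)
  expect_equal(sort(frag1$f1_atoms), 1:6)
  expect_equal(frag1$c, 6L)

  empty <- extract_fragments(tibble::tibble(i = integer(0), j = integer(0),
                                            s = numeric(0)),
                             two, two, rg, rg)
  expect_equal(empty$c, 0L)
})

test_that("the modified Tanimoto scores heavy-atom counts correctly", {
  expect_equal(tc_mcphd(23, 36, 37), 0.46)
  expect_equal(tc_mcphd(10, 10, 10), 1)
  expect_equal(tc_mcphd(0, 6, 9), 0)
  expect_error(tc_mcphd(7, 6, 9), "min")
})

test_that("similarity is symmetric, bounded, and 1 for self-comparison", {
  mols <- standard_fixtures()
  for (m in mols) {
    expect_equal(mcphd_similarity(m, m)$tc_mcphd, 1,
                 label = sprintf("self %s", m$id))
  }
  pairs <- utils::combn(length(mols), 2)
  for (k in seq_len(ncol(pairs))) {
    m1 <- mols[[pairs[1, k]]]; m2 <- mols[[pairs[2, k]]]
    ab <- mcphd_similarity(m1, m2)$tc_mcphd
    ba <- mcphd_similarity(m2, m1)$tc_mcphd
    expect_equal(ab, ba, tolerance = 1e-9,
                 label = sprintf("symmetry %s/%s", m1$id, m2$id))
    expect_gte(ab, 0); expect_lte(ab, 1)
  }
})

test_that("raising the threshold never enlarges the matched correspondence", {
  a <- make_molecule(fixture_spec("two_dc_linker", 2, id = "a"))
  b <- make_molecule(fixture_spec("two_dc_linker", 3, id = "b"))
  sizes <- vapply(c(0.5, 0.8, 0.9, 0.95, 0.99, 0.999999),
                  function(u) nrow(mcphd_similarity(a, b, u = u)$pairs),
                  integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("dissimilar molecules yield zero similarity, not an error", {
  ring <- make_molecule(fixture_spec("ring", 6, id = "ring"))
  butane <- make_molecule(fixture_spec("chain", 4, id = "butane"))
  r <- mcphd_similarity(ring, butane)
  expect_equal(r$tc_mcphd, 0)
  expect_equal(r$c, 0L)
  expect_equal(nrow(tidy(r)), 0)
})

test_that("the two-ring pair reproduces its by-construction similarity", {
  # one extra linker atom: fragments are whole molecules, c = 14, a = 14,
  # b = 15 -> 14/15
  a <- make_molecule(fixture_spec("two_dc_linker", 2, id = "a"))
  b <- make_molecule(fixture_spec("two_dc_linker", 3, id = "b"))
  r <- mcphd_similarity(a, b)
  expect_equal(r$tc_mcphd, 14 / 15, tolerance = 1e-12)
  g <- glance(r)
  expect_equal(g$c, 14L)
  expect_equal(g$n_f2, 15L)
})

test_that("the all-against-all matrix is symmetric with unit diagonal", {
  mols <- standard_fixtures()
  m <- mcphd_matrix(mols)
  expect_equal(unname(diag(m)), rep(1, 4))
  expect_equal(unclass(m), t(unclass(m)), tolerance = 1e-9)
  long <- tidy(m)
  expect_equal(nrow(long), 6)
  expect_true(all(long$similarity >= 0 & long$similarity <= 1))
})
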