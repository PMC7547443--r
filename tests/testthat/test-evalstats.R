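test_that("potency similarity behaves like a scale-free Tanimoto", {
  expect_equal(round(tc_ic50(0.05, 2.25), 4), 0.0227)
  expect_equal(tc_ic50(0.7, 0.7), 1)
  # scale invariance: micromolar vs nanomolar makes no difference
  expect_equal(tc_ic50(0.05, 0.06), tc_ic50(50, 60), tolerance = 1e-12)
  expect_equal(tc_ic50(0.05, 0.06), 0.9677, tolerance = 1e-4)
  expect_error(tc_ic50(0, 1), "positive")
  expect_error(tc_ic50(0.5, -2), "positive")
})

test_that("Pearson wrapper validates and computes the product-moment r", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(2, 1, 3)), 0.5)
  expect_error(pearson_r(x, rep(1, 4)), "zero-variance")
  expect_error(pearson_r(1:2, 1:2), "3 observations")
  # affine invariance (sign-preserving)
  set.seed(9)
  a <- runif(20); b <- runif(20)
  expect_equal(pearson_r(a, b), pearson_r(3 * a - 1, 0.5 * b + 7),
               tolerance = 1e-12)
})

test_that("Mann-Whitney U follows the min convention with midranks", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$u, 0)
  x <- c(0.2, 0.4, 0.6, 0.8)
  r2 <- mann_whitney_u(x, x)
  expect_equal(r2$u, length(x)^2 / 2)

  set.seed(11)
  for (k in 1:5) {
    a <- round(runif(12), 1)  # rounding forces ties
    b <- round(runif(9), 1)
    r3 <- mann_whitney_u(a, b)
    expect_equal(r3$u_x + r3$u_y, length(a) * length(b))
    expect_equal(r3$u_x, oracle_u(a, b), label = sprintf("oracle U rep %d", k))
    expect_gte(r3$p, 0); expect_lte(r3$p, 1)
  }
})

test_that("screening tables match brute-force pair enumeration", {
  for (seed in c(7, 19, 31)) {
    toy <- make_screening_toy(8, seed = seed)
    for (th in c(0.3, 0.5, 0.8)) {
      tab <- screening_table(toy$sim, toy$labels, th)
      want <- oracle_screening(toy$sim, toy$labels, th)
      for (ct in names(want)) {
        expect_equal(tab$pairs[tab$category == ct], unname(want[ct]),
                     label = sprintf("seed %d th %.1f %s", seed, th, ct))
      }
      correct <- tab$pairs[tab$category == "correct"]
      total <- tab$pairs[tab$category == "total"]
      expect_equal(correct,
                   sum(want[c("active-active", "inactive-inactive")]))
      expect_equal(total, sum(want))
    }
  }
})

test_that("screening counts are stable under molecule reordering", {
  toy <- make_screening_toy(7, seed = 5)
  perm <- c(4, 1, 7, 3, 6, 2, 5)
  sim_p <- toy$sim[perm, perm]
  tab <- screening_table(toy$sim, toy$labels, 0.5)
  tab_p <- screening_table(sim_p, toy$labels, 0.5)
  for (ct in c("active-active", "inactive-inactive", "correct", "total")) {
    expect_equal(tab_p$pairs[tab_p$category == ct],
                 tab$pairs[tab$category == ct], label = ct)
  }
  # mixed pairs may swap orientation, but their union cannot change
  mixed <- function(t) sum(t$pairs[t$category %in%
                                     c("active-inactive", "inactive-active")])
  expect_equal(mixed(tab_p), mixed(tab))
})

test_that("degenerate screening inputs are handled", {
  toy <- make_screening_toy(5, seed = 2)
  high <- screening_table(toy$sim, toy$labels, 1.01)
  expect_true(all(high$pairs == 0))
  expect_error(screening_table(toy$sim, toy$labels[-1, ], 0.5), "label")
})

test_that("method comparison reports correlations and rank tests per method", {
  toy <- make_screening_toy(10, seed = 13)
  ids <- rownames(toy$sim)
  set.seed(13)
  sims <- tibble::tibble(
    id = ids,
    ic50 = round(runif(10, 0.05, 2.5), 2),
    mcphd = toy$sim[, 1],
    other = pmin(1, toy$sim[, 1] * 0.8 + 0.1),
    clone = toy$sim[, 1]
  )
  rep <- compare_methods(sims, reference = ids[1])
  expect_setequal(rep$method, c("mcphd", "other", "clone"))
  # an identical vector correlates perfectly and shares every rank
  expect_equal(rep$r_vs_mcphd[rep$method == "clone"], 1)
  expect_equal(rep$u_vs_mcphd[rep$method == "clone"], 10 * 10 / 2)
  # the report recomputes what a direct calculation gives
  tc <- tc_ic50(sims$ic50[1], sims$ic50)
  expect_equal(rep$r_vs_tcic50[rep$method == "other"],
               pearson_r(sims$other, tc))
  expect_equal(rep$r_vs_mcphd[rep$method == "other"],
               pearson_r(sims$other, sims$mcphd))
})

test_that("matrix-list input to compare_methods matches tidy input", {
  toy <- make_screening_toy(6, seed = 21)
  ids <- rownames(toy$sim)
  m2 <- toy$sim * 0.9; diag(m2) <- 1
  ic50 <- tibble::tibble(id = ids, ic50 = seq(0.1, 0.6, by = 0.1))
  via_mats <- compare_methods(list(mcphd = toy$sim, alt = m2),
                              reference = ids[2], ic50 = ic50)
  sims <- tibble::tibble(id = ids, ic50 = ic50$ic50,
                         mcphd = toy$sim[, 2], alt = m2[, 2])
  via_tbl <- compare_methods(sims, reference = ids[2])
  expect_equal(via_mats$r_vs_tcic50, via_tbl$r_vs_tcic50)
  expect_equal(via_mats$u_vs_mcphd, via_tbl$u_vs_mcphd)
})
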