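test_that("sample partition is equal-sized, ordered and deterministic", {
  p <- partition_by_mirna(make_named(rnorm(9)), k = 3)
  expect_identical(p$sizes, c(3L, 3L, 3L))
  # lowest three values in stratum 1
  x <- make_named(c(5, 1, 9, 2, 8, 3, 7, 4, 6))
  p2 <- partition_by_mirna(x, k = 3)
  expect_setequal(p2$strata[[1]], names(x)[x <= 3])

  # remainder rule: extras to extreme blocks first (low, high, alternating)
  expect_identical(partition_by_mirna(make_named(rnorm(520)), 3)$sizes,
                   c(174L, 173L, 173L))
  expect_identical(partition_by_mirna(make_named(rnorm(22)), 4)$sizes,
                   c(6L, 5L, 5L, 6L))

  # ties straddling a boundary resolved by sample ID
  v <- make_named(c(1, 1, 1, 1, 1, 1, 2, 2, 2))
  p3 <- partition_by_mirna(v, k = 3)
  expect_identical(sort(p3$strata[[1]]), names(v)[1:3])
  expect_identical(sort(p3$strata[[2]]), names(v)[4:6])

  expect_error(partition_by_mirna(make_named(rnorm(8)), 3), "3\\*k")
})

test_that("t-domain transform: published anchor, antisymmetry, monotonicity", {
  expect_identical(t_transform(0, 100), 0)
  # the r-cutoff/significance anchor of the coexpression network:
  # r = 0.099 at n = 520 has one-sided P = 0.012
  p <- stats::pt(t_transform(0.099, 520), df = 518, lower.tail = FALSE)
  expect_equal(round(p, 3), 0.012)
  expect_equal(t_transform(-0.3, 50), -t_transform(0.3, 50))
  rhos <- seq(-0.95, 0.95, by = 0.05)
  expect_true(all(diff(t_transform(rhos, 30)) > 0))
  # clipping keeps perfect correlation finite
  expect_true(is.finite(t_transform(1, 10)))
  expect_error(t_transform(0.5, 2), "n > 2")
})

test_that("interaction score implements the max-positive minus min-abs rule", {
  expect_equal(interaction_score(c(3, -1, 0.5)),
               list(delta = 2.5, g_opt = 1L))
  expect_equal(interaction_score(c(-1, -2, -0.5)),
               list(delta = 0, g_opt = NA_integer_))
  # all-equal positive: score 0, no optimized group
  expect_equal(interaction_score(c(2, 2, 2)),
               list(delta = 0, g_opt = NA_integer_))
  # single positive that is also smallest in magnitude: score 0
  expect_equal(interaction_score(c(0.5, -2, -3))$delta, 0)
  # monotonicity: raising the positive max raises the score by the same
  expect_equal(interaction_score(c(4, -1, 0.5))$delta,
               interaction_score(c(3, -1, 0.5))$delta + 1)
})

test_that("interaction score is nonnegative and label-permutation invariant", {
  set.seed(1)
  for (i in 1:200) {
    tv <- rnorm(sample(2:6, 1), sd = 3)
    sc <- interaction_score(tv)
    expect_gte(sc$delta, 0)
    expect_equal(interaction_score(sample(tv))$delta, sc$delta)
    if (sc$delta > 0) expect_identical(sc$g_opt, which.max(tv))
    else expect_true(is.na(sc$g_opt))
  }
})

test_that("interaction profile: degenerate, invariance, per-stratum n", {
  set.seed(2)
  mirna <- make_named(rnorm(60))
  part <- partition_by_mirna(mirna, 3)
  x <- make_named(rnorm(60))
  # identical genes: rho clipped to 1, large positive t everywhere
  pr <- interaction_profile(x, x, part)
  expect_true(all(abs(pr$rho - 1) < 1e-12))
  expect_true(all(pr$t > 1e5))
  # reordering samples identically leaves the profile unchanged
  y <- make_named(rnorm(60))
  perm <- sample(names(x))
  pr1 <- interaction_profile(x, y, part)
  pr2 <- interaction_profile(x[perm], y[perm], part)
  expect_equal(pr1$rho, pr2$rho)
  expect_equal(pr1$n, as.numeric(part$sizes))
  # zero variance flags, not scores
  flat <- make_named(rep(1, 60))
  expect_true(interaction_profile(flat, y, part)$filtered)
})

test_that("independent noise rarely crosses the significance threshold", {
  tab <- shared_null_table()
  thr <- delta_threshold(tab, 0.01)
  set.seed(3)
  mirna <- make_named(rnorm(450))
  part <- partition_by_mirna(mirna, 3)
  hits <- 0
  for (i in 1:100) {
    pr <- interaction_profile(make_named(rnorm(450)), make_named(rnorm(450)),
                              part)
    if (interaction_score(pr)$delta > thr) hits <- hits + 1
  }
  expect_lte(hits / 100, 0.05)
})

test_that("planted miRNA-modulated pairs are recovered with the right stratum", {
  tab <- shared_null_table()
  thr <- delta_threshold(tab, 0.01)
  set.seed(4)
  called <- correct_g <- 0
  n_rep <- 150
  for (r in seq_len(n_rep)) {
    mirna <- make_named(rnorm(450))
    part <- partition_by_mirna(mirna, 3)
    x <- make_named(rnorm(450))
    y <- make_named(rnorm(450))
    s <- part$strata[[2]]   # plant in the middle stratum
    y[s] <- 0.6 * x[s] + sqrt(1 - 0.36) * y[s]
    sc <- interaction_score(interaction_profile(x, y, part))
    if (sc$delta > thr) {
      called <- called + 1
      if (identical(sc$g_opt, 2L)) correct_g <- correct_g + 1
    }
  }
  expect_gte(correct_g / n_rep, 0.90)
})

test_that("vectorized scoring agrees with per-triplet profiles", {
  des <- simulation_design(n_samples = 120, n_genes = 8, n_mirnas = 2,
                           seed = 9)
  sim <- simulate_cohort(des)
  tm <- list(MIR001 = rownames(sim$genes)[1:5],
             MIR002 = rownames(sim$genes)[4:8])
  tr <- enumerate_triplets(tm, rownames(sim$genes), rownames(sim$mirnas))
  res <- score_triplets(sim$genes, sim$mirnas, tr, cv_threshold = 0)
  for (r in seq_len(nrow(res))) {
    part <- partition_by_mirna(sim$mirnas[res$mirna[r], ], 3)
    pr <- interaction_profile(sim$genes[res$gene_i[r], ],
                              sim$genes[res$gene_j[r], ], part)
    sc <- interaction_score(pr)
    expect_equal(unlist(res[r, paste0("rho_", 1:3)], use.names = FALSE),
                 pr$rho, tolerance = 1e-12)
    expect_equal(res$delta_i[r], sc$delta, tolerance = 1e-12)
  }
  # missing values: slow path drops samples pairwise within stratum
  genes_na <- sim$genes
  genes_na[1, 3] <- NA
  res_na <- score_triplets(genes_na, sim$mirnas, tr, cv_threshold = 0)
  r1 <- which(res_na$gene_i == "GENE0001")[1]
  part <- partition_by_mirna(sim$mirnas[res_na$mirna[r1], ], 3)
  pr <- interaction_profile(genes_na[res_na$gene_i[r1], ],
                            genes_na[res_na$gene_j[r1], ], part)
  expect_equal(res_na$delta_i[r1], interaction_score(pr)$delta,
               tolerance = 1e-12)
})

test_that("CV filter marks triplets of non-informative genes as unscored", {
  des <- simulation_design(n_samples = 90, n_genes = 4, n_mirnas = 1,
                           seed = 10)
  sim <- simulate_cohort(des)
  sim$genes[2, ] <- 100 + 0.001 * sim$genes[2, ]  # tiny CV everywhere
  tm <- list(MIR001 = rownames(sim$genes))
  tr <- enumerate_triplets(tm, rownames(sim$genes), "MIR001")
  res <- score_triplets(sim$genes, sim$mirnas, tr)
  bad <- res$gene_i == "GENE0002" | res$gene_j == "GENE0002"
  expect_true(all(res$filtered[bad]))
  expect_true(all(is.na(res$delta_i[bad])))
  expect_false(any(res$filtered[!bad]))
})
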