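toy_clinical <- function(time, event, ids = sprintf("P%02d", seq_along(time))) {
  data.frame(sample = ids, time_months = time, event = event,
             stringsAsFactors = FALSE)
}

test_that("log-rank test matches the direct observed-minus-expected oracle", {
  # 6-subject toy: one group dies early, the other late
  cl <- toy_clinical(c(1, 2, 3, 4, 5, 6), rep(1L, 6))
  grp <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  lr <- logrank_test(cl, grp)
  expect_equal(lr$chi2,
               oracle_logrank_chi2(cl$time_months, cl$event, grp),
               tolerance = 1e-10)
  expect_equal(lr$p, stats::pchisq(lr$chi2, 1, lower.tail = FALSE))

  # identical groups: no signal
  cl2 <- toy_clinical(rep(c(3, 7, 11), 2), rep(c(1L, 0L, 1L), 2))
  lr2 <- logrank_test(cl2, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(lr2$chi2, 0, tolerance = 1e-10)
  expect_equal(lr2$p, 1, tolerance = 1e-10)

  # censored mixtures still match the oracle exactly
  set.seed(41)
  for (i in 1:10) {
    n <- 40
    cl3 <- toy_clinical(round(rexp(n, 0.08), 2), rbinom(n, 1, 0.7))
    g3 <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(g3) || all(g3) || sum(cl3$event) == 0) next
    expect_equal(logrank_test(cl3, g3)$chi2,
                 oracle_logrank_chi2(cl3$time_months, cl3$event, g3),
                 tolerance = 1e-10)
  }

  # an all-censored group is handled through the standard machinery
  cl4 <- toy_clinical(c(2, 4, 6, 8, 10, 12), c(1L, 1L, 1L, 0L, 0L, 0L))
  lr4 <- logrank_test(cl4, c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_true(is.finite(lr4$chi2))

  expect_error(logrank_test(cl, rep(TRUE, 6)), "nonempty")
  expect_error(logrank_test(toy_clinical(1:4, rep(0L, 4)),
                            c(TRUE, TRUE, FALSE, FALSE)), "events")
})

test_that("Kaplan-Meier estimate matches the hand product-limit", {
  # no censoring, times 1..10: S steps by 1/10; median at 5
  cl <- toy_clinical(1:10, rep(1L, 10))
  km <- km_estimate(cl)
  expect_equal(km$surv, seq(1, 0, by = -0.1))
  expect_equal(km$median_os, 5)
  expect_equal(km$rate_at(4.5), 0.6)

  # all censored: flat curve, undefined median
  km2 <- km_estimate(toy_clinical(c(3, 8, 12), c(0L, 0L, 0L)))
  expect_true(all(km2$surv == 1))
  expect_true(is.na(km2$median_os))

  # textbook censored fixture vs the direct formula
  cl3 <- toy_clinical(c(6, 6, 6, 7, 10, 13, 16, 22, 23, 6, 9, 10, 11, 17),
                      c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L,
                        0L, 0L, 0L, 0L, 0L))
  km3 <- km_estimate(cl3)
  orc <- oracle_km(cl3$time_months, cl3$event)
  got <- km3$rate_at(orc$time)
  expect_equal(got, orc$surv, tolerance = 1e-10)
})

test_that("average pairwise t-correlation follows its definition", {
  set.seed(42)
  expr <- matrix(rnorm(4 * 50), 4, 50,
                 dimnames = list(paste0("G", 1:4), sprintf("S%02d", 1:50)))
  samples <- sprintf("S%02d", 1:20)
  genes <- paste0("G", 1:3)
  direct <- mean(c(
    t_transform(cor(expr["G1", samples], expr["G2", samples]), 20),
    t_transform(cor(expr["G1", samples], expr["G3", samples]), 20),
    t_transform(cor(expr["G2", samples], expr["G3", samples]), 20)))
  expect_equal(avg_pairwise_tcorr(expr, genes, samples), direct,
               tolerance = 1e-12)

  # identical genes: clipped large positive t
  expr2 <- rbind(expr, G5 = expr["G1", ])
  expect_gt(avg_pairwise_tcorr(expr2, c("G1", "G5"), samples), 1e5)

  # independent genes: small average
  set.seed(43)
  expr3 <- matrix(rnorm(3 * 200), 3, 200,
                  dimnames = list(paste0("G", 1:3), sprintf("S%03d", 1:200)))
  expect_lt(abs(avg_pairwise_tcorr(expr3, paste0("G", 1:3),
                                   colnames(expr3))), 1)

  # zero-variance gene contributes r = 0 pairs
  expr4 <- rbind(expr, FLAT = rep(1, 50))
  expect_message(v <- avg_pairwise_tcorr(expr4, c("G1", "FLAT"), samples),
                 "zero-variance")
  expect_equal(v, 0)
})

planted_cohort <- function(n = 200, n_planted = 30, n_genes = 3,
                           noise = 0.08, seed = 1) {
  set.seed(seed)
  ids <- sprintf("S%03d", seq_len(n))
  planted <- ids[seq_len(n_planted)]
  f <- rnorm(n_planted)
  expr <- matrix(rnorm(n_genes * n), n_genes, n,
                 dimnames = list(paste0("G", seq_len(n_genes)), ids))
  for (g in seq_len(n_genes)) {
    expr[g, planted] <- f + noise * rnorm(n_planted)
  }
  list(expr = expr, planted = planted, ids = ids)
}

test_that("subset search: trace, boundary, and planted-subset recovery", {
  pc <- planted_cohort(seed = 44)
  sr <- optimized_subset_search(pc$expr, paste0("G", 1:3),
                                n_seed_draws = 400, rng_seed = 5)
  expect_true(all(diff(sr$trace) > 0))
  expect_false(anyDuplicated(sr$selected_samples) > 0)
  expect_gte(mean(pc$planted %in% sr$selected_samples), 0.8)

  # frac = 1: the seed is the whole cohort and growth is a no-op
  sr_all <- optimized_subset_search(pc$expr, paste0("G", 1:3), frac = 1,
                                    rng_seed = 6)
  expect_identical(length(sr_all$selected_samples), ncol(pc$expr))
  expect_identical(length(sr_all$trace), 1L)

  # reproducibility
  sr2 <- optimized_subset_search(pc$expr, paste0("G", 1:3),
                                 n_seed_draws = 400, rng_seed = 5)
  expect_identical(sr$selected_samples, sr2$selected_samples)
  expect_equal(sr$avg_t_corr, sr2$avg_t_corr)
})

test_that("repeat summary contrasts survival of selected vs other samples", {
  pc <- planted_cohort(seed = 45)
  mask <- stats::setNames(pc$ids %in% pc$planted, pc$ids)
  cl <- simulate_survival(mask, hazard_ratio = 0.4, seed = 46)
  sm <- repeat_search_summary(pc$expr, paste0("G", 1:3), cl,
                              n_seed_draws = 150, n_repeats = 12,
                              rng_seed = 9)
  expect_identical(nrow(sm$per_repeat), 12L)
  expect_gt(sm$frac_median_in_gt_out, 0.8)
  expect_gt(mean(sm$per_repeat$tcorr_in), mean(sm$per_repeat$tcorr_out,
                                               na.rm = TRUE))
  expect_identical(sm$best_repeat,
                   which.max(sm$per_repeat$tcorr_in))

  # identical per-repeat seeds give identical rows
  sm2 <- repeat_search_summary(pc$expr, paste0("G", 1:3), cl,
                               n_seed_draws = 100, n_repeats = 2,
                               repeat_seeds = c(7L, 7L))
  expect_identical(sm2$per_repeat$median_os_in[1],
                   sm2$per_repeat$median_os_in[2])
  expect_identical(sm2$per_repeat$tcorr_in[1], sm2$per_repeat$tcorr_in[2])
})

test_that("per-triplet survival screen has power on a planted protective stratum", {
  # samples in the optimized stratum of a planted triplet survive longer
  set.seed(47)
  n <- 500
  mirna <- make_named(rnorm(n))
  part <- partition_by_mirna(mirna, 3)
  mask <- stats::setNames(names(mirna) %in% part$strata[[1]], names(mirna))
  hits <- 0
  n_rep <- 60
  for (r in seq_len(n_rep)) {
    cl <- simulate_survival(mask, hazard_ratio = 0.5)
    if (logrank_test(cl, mask)$p < 0.01) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.8)
})
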