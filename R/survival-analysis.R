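#' Two-group log-rank test
#'
#' Compares survival between an "optimized group" of samples and the rest
#' via the standard log-rank chi-square (df = 1).
#'
#' @param clinical data.frame with `sample`, `time_months`, `event`.
#' @param group_mask Logical vector, either named by sample ID or aligned
#'   to the clinical rows; `TRUE` = in-group.
#' @return List with `chi2`, `p`, and `n` (group sizes).
#' @export
logrank_test <- function(clinical, group_mask) {
  validate_clinical(clinical)
  grp <- align_mask(clinical, group_mask)
  if (!any(grp) || all(grp)) stop("both groups must be nonempty")
  if (sum(clinical$event) < 1L) stop("no events observed")
  sd_ <- survival::survdiff(
    survival::Surv(time_months, event) ~ grp,
    data = cbind(clinical, grp = grp))
  chi2 <- unname(sd_$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
       n = c(out_group = sum(!grp), in_group = sum(grp)))
}

align_mask <- function(clinical, group_mask) {
  if (!is.null(names(group_mask))) {
    miss <- setdiff(clinical$sample, names(group_mask))
    if (length(miss)) stop("group_mask missing sample(s): ",
                           paste(utils::head(miss, 5L), collapse = ", "))
    group_mask <- group_mask[clinical$sample]
  }
  stopifnot(length(group_mask) == nrow(clinical), !anyNA(group_mask))
  as.logical(group_mask)
}

#' Kaplan-Meier estimate with median OS and time-point survival rates
#'
#' Product-limit survival curve for one group. The median OS is the
#' earliest time at which survival drops to 0.5 or below (undefined, `NA`,
#' if the curve never does); `rate_at(t)` evaluates the right-continuous
#' step curve, e.g. `rate_at(24)` for the 2-year survival rate.
#'
#' @param clinical data.frame with `sample`, `time_months`, `event`.
#' @return List with `time`, `surv` (step-curve coordinates including the
#'   origin), `median_os`, `rate_at` (function of time), and the
#'   underlying `survfit` object as `fit`.
#' @export
km_estimate <- function(clinical) {
  validate_clinical(clinical)
  if (!nrow(clinical)) stop("clinical table is empty")
  fit <- survival::survfit(survival::Surv(time_months, event) ~ 1,
                           data = clinical)
  tm <- fit$time
  sv <- fit$surv
  drop_times <- tm[sv <= 0.5]
  median_os <- if (length(drop_times)) min(drop_times) else NA_real_
  rate_at <- function(t) {
    vapply(t, function(tt) {
      idx <- which(tm <= tt & fit$n.event > 0)
      if (!length(idx)) 1 else sv[max(idx)]
    }, numeric(1L))
  }
  list(time = c(0, tm), surv = c(1, sv), median_os = median_os,
       rate_at = rate_at, fit = fit)
}

#' Average pairwise t-domain correlation of a gene set
#'
#' Mean over all gene pairs of the t-transformed Pearson correlation
#' computed on the given sample subset (with n = subset size). A
#' zero-variance gene on the subset contributes correlation 0 to its pairs.
#'
#' @param expr Expression matrix (genes x samples).
#' @param genes Character vector of >= 2 gene IDs.
#' @param samples Character vector of >= 3 sample IDs.
#' @return The average pairwise t-domain correlation.
#' @export
avg_pairwise_tcorr <- function(expr, genes, samples) {
  stopifnot(length(genes) >= 2L, length(samples) >= 3L)
  X <- t(expr[genes, samples, drop = FALSE])
  C <- suppressWarnings(stats::cor(X))
  if (any(!is.finite(C[upper.tri(C)]))) {
    message("zero-variance gene on subset: correlation treated as 0")
    C[!is.finite(C)] <- 0
  }
  mean(t_transform(C[upper.tri(C)], nrow(X)))
}

# Average pairwise t-correlation from an n x g sample-by-gene matrix and a
# row index set; used in the tight seed-search loop.
avg_tcorr_idx <- function(X, idx) {
  C <- suppressWarnings(stats::cor(X[idx, , drop = FALSE]))
  C[!is.finite(C)] <- 0
  mean(t_transform(C[upper.tri(C)], length(idx)))
}

#' Seed-then-greedy search for a maximally correlated sample subset
#'
#' Draws `n_seed_draws` random subsets of ceil(frac * n) samples, keeps the
#' one with the largest average pairwise t-domain correlation of the gene
#' set as the seed, then greedily adds the single sample yielding the
#' largest strict increase (ties broken by sample-ID order), stopping when
#' no addition improves the correlation. The per-iteration trace is
#' strictly increasing after the seed entry by construction.
#'
#' @param expr Expression matrix (genes x samples).
#' @param genes Gene set (>= 2 genes).
#' @param frac Seed subset fraction of the cohort (default 0.1).
#' @param n_seed_draws Number of random seed draws (default 50000).
#' @param rng_seed Optional RNG seed for reproducibility.
#' @return Object of class `subset_search`: list with `selected_samples`
#'   (seed samples then additions, in order), `avg_t_corr`, `trace`,
#'   `seed_size` and `seed_used`.
#' @export
optimized_subset_search <- function(expr, genes, frac = 0.1,
                                    n_seed_draws = 50000L, rng_seed = NULL) {
  samp <- sort(colnames(expr))
  n <- length(samp)
  stopifnot(n >= 20L, frac > 0, frac <= 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  X <- t(expr[genes, samp, drop = FALSE])
  g <- length(genes)
  m0 <- ceiling(frac * n)
  if (m0 == n) {
    best_idx <- seq_len(n)
    best_val <- avg_tcorr_idx(X, best_idx)
  } else {
    best_val <- -Inf
    best_idx <- NULL
    for (d in seq_len(n_seed_draws)) {
      idx <- sample.int(n, m0)
      v <- avg_tcorr_idx(X, idx)
      if (v > best_val) { best_val <- v; best_idx <- idx }
    }
  }
  pairs <- utils::combn(g, 2L)
  sel <- sort(best_idx)
  s1 <- colSums(X[sel, , drop = FALSE])
  CP <- crossprod(X[sel, , drop = FALSE])
  cur <- best_val
  trace <- cur
  order_added <- samp[sel]
  repeat {
    cand <- setdiff(seq_len(n), sel)   # ascending = sample-ID order
    if (!length(cand)) break
    m <- length(sel)
    nn <- m + 1L
    Xc <- X[cand, , drop = FALSE]
    tsum <- numeric(length(cand))
    for (p in seq_len(ncol(pairs))) {
      a <- pairs[1L, p]; b <- pairs[2L, p]
      s1a <- s1[a] + Xc[, a]; s1b <- s1[b] + Xc[, b]
      cov_ab <- (CP[a, b] + Xc[, a] * Xc[, b]) - s1a * s1b / nn
      var_a <- (CP[a, a] + Xc[, a]^2) - s1a^2 / nn
      var_b <- (CP[b, b] + Xc[, b]^2) - s1b^2 / nn
      r <- ifelse(var_a > 0 & var_b > 0,
                  cov_ab / sqrt(pmax(var_a, 0) * pmax(var_b, 0)), 0)
      tsum <- tsum + t_transform(r, nn)
    }
    avg <- tsum / ncol(pairs)
    best_c <- which.max(avg)
    if (!(avg[best_c] > cur)) break
    add <- cand[best_c]
    s1 <- s1 + X[add, ]
    CP <- CP + tcrossprod(X[add, ])
    sel <- c(sel, add)
    cur <- avg[best_c]
    trace <- c(trace, cur)
    order_added <- c(order_added, samp[add])
  }
  structure(list(selected_samples = order_added,
                 avg_t_corr = avg_pairwise_tcorr(expr, genes,
                                                 samp[sort(sel)]),
                 trace = trace, seed_size = m0, seed_used = rng_seed),
            class = "subset_search")
}

#' @export
print.subset_search <- function(x, ...) {
  cat("optimized subset:", length(x$selected_samples), "samples (seed",
      x$seed_size, "), avg t-corr", format(x$avg_t_corr, digits = 4),
      "after", length(x$trace) - 1L, "greedy additions\n")
  invisible(x)
}

#' Repeat the optimized-subset search and summarize survival contrasts
#'
#' Runs the seed-then-greedy search `n_repeats` times with distinct RNG
#' seeds, and for each repeat contrasts the selected (in) samples against
#' the rest (out): average pairwise t-correlation, Kaplan-Meier median OS,
#' 2-year survival rate and the log-rank P. Aggregates report a paired
#' t-test on the per-repeat in/out median OS, the fraction of repeats whose
#' in-group 2-year rate exceeds the full cohort's, and the best-correlation
#' repeat.
#'
#' @param expr Expression matrix (genes x samples).
#' @param genes Gene set (>= 2 genes).
#' @param clinical Clinical table covering the samples.
#' @param frac,n_seed_draws Passed to [optimized_subset_search()].
#' @param n_repeats Number of repeats (>= 2; default 1000).
#' @param rng_seed Base seed; repeat r uses `rng_seed + r - 1`.
#' @param repeat_seeds Optional explicit per-repeat seed vector (overrides
#'   `rng_seed`).
#' @return List with `per_repeat` (data.frame), `paired_t_p`,
#'   `frac_2yr_above_cohort`, `frac_median_in_gt_out`, `best_repeat`
#'   (index), and `full_cohort` (median OS and 2-year rate).
#' @export
repeat_search_summary <- function(expr, genes, clinical, frac = 0.1,
                                  n_seed_draws = 1000L, n_repeats = 1000L,
                                  rng_seed = 1L, repeat_seeds = NULL) {
  stopifnot(n_repeats >= 2L)
  validate_clinical(clinical)
  if (is.null(repeat_seeds)) {
    repeat_seeds <- (rng_seed + seq_len(n_repeats) - 1L) %% 2147483647L
  }
  stopifnot(length(repeat_seeds) == n_repeats)
  full_km <- km_estimate(clinical)
  full_rate24 <- full_km$rate_at(24)
  rows <- lapply(seq_len(n_repeats), function(r) {
    sr <- optimized_subset_search(expr, genes, frac = frac,
                                  n_seed_draws = n_seed_draws,
                                  rng_seed = repeat_seeds[r])
    in_s <- sr$selected_samples
    out_s <- setdiff(colnames(expr), in_s)
    mask <- stats::setNames(clinical$sample %in% in_s, clinical$sample)
    km_in <- km_estimate(clinical[clinical$sample %in% in_s, , drop = FALSE])
    km_out <- km_estimate(clinical[clinical$sample %in% out_s, , drop = FALSE])
    lr <- tryCatch(logrank_test(clinical, mask)$p, error = function(e) NA_real_)
    data.frame(repeat_id = r, seed = repeat_seeds[r],
               n_in = length(in_s),
               tcorr_in = sr$avg_t_corr,
               tcorr_out = if (length(out_s) >= 3L)
                 avg_pairwise_tcorr(expr, genes, out_s) else NA_real_,
               median_os_in = km_in$median_os,
               median_os_out = km_out$median_os,
               rate24_in = km_in$rate_at(24),
               rate24_out = km_out$rate_at(24),
               logrank_p = lr)
  })
  per_repeat <- do.call(rbind, rows)
  ok <- stats::complete.cases(per_repeat[, c("median_os_in", "median_os_out")])
  paired_t_p <- if (sum(ok) >= 2L) {
    tryCatch(stats::t.test(per_repeat$median_os_in[ok],
                           per_repeat$median_os_out[ok],
                           paired = TRUE)$p.value,
             error = function(e) NA_real_)
  } else NA_real_
  list(per_repeat = per_repeat,
       paired_t_p = paired_t_p,
       frac_2yr_above_cohort = mean(per_repeat$rate24_in > full_rate24,
                                    na.rm = TRUE),
       frac_median_in_gt_out = mean(per_repeat$median_os_in >
                                      per_repeat$median_os_out, na.rm = TRUE),
       best_repeat = which.max(per_repeat$tcorr_in),
       full_cohort = list(median_os = full_km$median_os,
                          rate24 = full_rate24))
}
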