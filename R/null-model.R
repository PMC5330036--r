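#' Build the empirical null distribution of the interaction score
#'
#' Each draw samples k independent Student-t(df) variates (the null
#' distribution of the per-stratum t-domain correlation under independence)
#' and computes the interaction score; the sorted draws form an empirical
#' lookup table for P-values. The table is keyed by the modal stratum's
#' degrees of freedom (df = stratum size - 2): strata whose sizes differ by
#' one sample have negligibly different t tails relative to Monte-Carlo
#' error, so one table is shared.
#'
#' @param df Degrees of freedom of the per-stratum t distribution (>= 3).
#' @param k Number of strata.
#' @param n_draws Number of simulated scores (default 1e6).
#' @param seed RNG seed; identical (df, k, n_draws, seed) give bit-identical
#'   tables.
#' @param chunk_size Draws per chunk (memory control).
#' @param cache_dir Optional directory: the table is saved to / loaded from
#'   a file keyed by (df, k, n_draws, seed).
#' @return Object of class `null_table` with `sorted_scores`, `df`, `k`,
#'   `n_draws`, `seed` and `p_positive` (empirical P(score > 0)).
#' @export
build_null_table <- function(df, k = 3L, n_draws = 1e6, seed = 1L,
                             chunk_size = 1e6, cache_dir = NULL) {
  stopifnot(df >= 3L, k >= 2L, n_draws >= 1)
  n_draws <- as.integer(round(n_draws))
  cache_file <- NULL
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    cache_file <- file.path(cache_dir, sprintf(
      "null_df%d_k%d_n%d_seed%d.rds", as.integer(df), as.integer(k),
      n_draws, as.integer(seed)))
    if (file.exists(cache_file)) return(readRDS(cache_file))
  }
  set.seed(seed)
  scores <- numeric(n_draws)
  done <- 0L
  while (done < n_draws) {
    m <- min(as.integer(chunk_size), n_draws - done)
    tm <- matrix(stats::rt(m * k, df), m, k)
    scores[(done + 1L):(done + m)] <- delta_from_tmat(tm)
    done <- done + m
  }
  tab <- structure(list(df = as.integer(df), k = as.integer(k),
                        n_draws = n_draws, seed = as.integer(seed),
                        sorted_scores = sort(scores),
                        p_positive = mean(scores > 0)),
                   class = "null_table")
  if (!is.null(cache_file)) saveRDS(tab, cache_file)
  tab
}

#' @export
print.null_table <- function(x, ...) {
  cat("Empirical null of the interaction score: k =", x$k, ", df =", x$df,
      ",", format(x$n_draws, big.mark = ","), "draws (seed", x$seed, ")\n")
  cat("P(score > 0) =", format(x$p_positive, digits = 4),
      "; 0.01 threshold =",
      format(delta_threshold(x, 0.01), digits = 4), "\n")
  invisible(x)
}

#' Empirical P-value of an interaction score
#'
#' P = (number of null draws strictly greater than `delta`) / (table size).
#' When no draw exceeds `delta` the value 1/n_draws is returned as an upper
#' bound, flagged in the `"is_bound"` attribute; [tail_quantile()] serves
#' the regime beyond the table's resolution.
#'
#' @param table A `null_table`.
#' @param delta Nonnegative score(s); vectorized.
#' @return Numeric P-value(s) in (0, 1], with logical attribute
#'   `"is_bound"`.
#' @export
null_pvalue <- function(table, delta) {
  stopifnot(inherits(table, "null_table"))
  if (any(delta < 0, na.rm = TRUE)) stop("delta must be nonnegative")
  n <- table$n_draws
  cnt_le <- findInterval(delta, table$sorted_scores)
  p <- (n - cnt_le) / n
  bound <- !is.na(p) & p == 0
  p[bound] <- 1 / n
  attr(p, "is_bound") <- bound
  p
}

#' Score threshold at a significance level
#'
#' Smallest stored score tau with P(score > tau) <= alpha. Because the null
#' has a point mass at zero, alpha must lie below the positive mass of the
#' table.
#'
#' @param table A `null_table`.
#' @param alpha Significance level.
#' @return The threshold tau.
#' @export
delta_threshold <- function(table, alpha) {
  stopifnot(inherits(table, "null_table"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (alpha >= table$p_positive) {
    stop("alpha = ", alpha, " is not reachable: the null has a point mass ",
         format(1 - table$p_positive, digits = 4),
         " at zero, so P-values cannot exceed ",
         format(table$p_positive, digits = 4))
  }
  n <- table$n_draws
  s <- table$sorted_scores
  m <- ceiling((1 - alpha) * n)
  # step left while the smaller stored value still keeps strict exceedance
  # within alpha (ties collapse the exceedance count)
  while (m > 1L && (n - findInterval(s[m - 1L], s)) / n <= alpha) m <- m - 1L
  s[m]
}

#' Analytic upper-tail probability of the null interaction score
#'
#' Closed-form reduction of P(score > q) for k iid Student-t(df) variates:
#' conditioning on which coordinate attains the maximum (necessarily > q on
#' the event) gives
#' P = k * Int_q^Inf f(t) \[F(t)^(k-1) - (F(t) - F(t-q) + F(q-t))^(k-1)\] dt,
#' evaluated by adaptive quadrature. Serves as the deterministic oracle for
#' the Monte-Carlo table and the importance sampler.
#'
#' @param q Positive score.
#' @param df Degrees of freedom.
#' @param k Number of strata.
#' @return P(score > q).
#' @export
null_tail_prob <- function(q, df, k = 3L) {
  stopifnot(q > 0, k >= 2L)
  f <- function(t) {
    a <- t - q
    Ft <- stats::pt(t, df)
    inner <- Ft - stats::pt(a, df) + stats::pt(-a, df)
    k * stats::dt(t, df) * (Ft^(k - 1L) - pmax(inner, 0)^(k - 1L))
  }
  stats::integrate(f, q, Inf, rel.tol = 1e-10, abs.tol = 0,
                   subdivisions = 500L)$value
}

#' Extreme-tail quantile of the null interaction score
#'
#' Returns the score exceeded with probability `p_raw` under the k-variate
#' Student-t null, for tail probabilities far beyond the reach of a plain
#' Monte-Carlo table (e.g. Bonferroni-level cutoffs around 1e-12). Two
#' routes are provided: tail-conditioned importance sampling on the maximal
#' coordinate (the designated coordinate is drawn from the t distribution
#' conditioned on the (q, Inf) tail, with exact symmetry factor k and
#' reweighting by the tail mass), and direct numeric integration via
#' [null_tail_prob()]. Common random numbers make the sampling route a
#' smooth monotone function of q, solved by root finding.
#'
#' @param df Degrees of freedom.
#' @param k Number of strata.
#' @param p_raw Upper-tail probability, in (0, 0.1).
#' @param method `"importance_sampling"` or `"numeric_integration"`.
#' @param seed RNG seed (sampling route).
#' @param n_samples Importance-sampling draws (default 2e5).
#' @param max_rel_se Abort if the relative standard error of the tail
#'   probability at the returned quantile exceeds this (default 0.1).
#' @return The quantile, with attributes `rel_se` (relative SE of the tail
#'   probability; 0 for the integration route) and `method`.
#' @export
tail_quantile <- function(df, k = 3L, p_raw,
                          method = c("importance_sampling",
                                     "numeric_integration"),
                          seed = 1L, n_samples = 2e5, max_rel_se = 0.1) {
  method <- match.arg(method)
  stopifnot(p_raw > 0, p_raw < 0.1, k >= 2L)
  if (method == "numeric_integration") {
    fn <- function(q) log(null_tail_prob(q, df, k)) - log(p_raw)
    hi <- 2
    while (fn(hi) > 0) hi <- hi * 2
    root <- stats::uniroot(fn, c(1e-6, hi), tol = 1e-9)$root
    return(structure(root, rel_se = 0, method = method))
  }
  set.seed(seed)
  u <- stats::runif(n_samples)
  others <- matrix(stats::rt(n_samples * (k - 1L), df), n_samples, k - 1L)
  oth_max <- do.call(pmax, lapply(seq_len(k - 1L), function(i) others[, i]))
  oth_minabs <- do.call(pmin, lapply(seq_len(k - 1L),
                                     function(i) abs(others[, i])))
  indicator <- function(q) {
    s1 <- stats::pt(q, df, lower.tail = FALSE)
    t1 <- stats::qt(u * s1, df, lower.tail = FALSE)
    list(ind = (t1 > oth_max) & (oth_minabs < t1 - q), s1 = s1)
  }
  phat <- function(q) {
    z <- indicator(q)
    k * z$s1 * mean(z$ind)
  }
  lo <- 1e-3
  while (phat(lo) <= p_raw) lo <- lo / 4
  hi <- stats::qt(p_raw / k, df, lower.tail = FALSE)
  while (phat(hi) > p_raw) hi <- hi * 1.5
  root <- stats::uniroot(function(q) log(max(phat(q), 1e-300)) - log(p_raw),
                         c(lo, hi), tol = 1e-7)$root
  z <- indicator(root)
  mu <- mean(z$ind)
  rel_se <- if (mu > 0) stats::sd(z$ind) / (sqrt(n_samples) * mu) else Inf
  if (rel_se > max_rel_se) {
    stop("tail_quantile did not converge (relative SE ",
         format(rel_se, digits = 3), " > ", max_rel_se,
         "); increase n_samples")
  }
  structure(root, rel_se = rel_se, method = method)
}

#' Bonferroni correction
#'
#' @param p Raw P-value(s) in (0, 1].
#' @param n_tests Number of tests (>= 1); for the triplet screen this is
#'   the number of putative triplets submitted to scoring, before the CV
#'   filter.
#' @return min(1, p * n_tests), vectorized.
#' @export
bonferroni <- function(p, n_tests) {
  stopifnot(n_tests >= 1)
  if (any(p <= 0 | p > 1, na.rm = TRUE)) stop("p must be in (0, 1]")
  pmin(1, p * n_tests)
}
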