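#' Stratum labels for a k-way partition
#'
#' With the default k = 3 the strata are labelled L/M/H (low, medium, high
#' miRNA expression); for other k they are G1..Gk, always ordered low to
#' high.
#' @param k Number of strata.
#' @return Character vector of length `k`.
#' @export
stratum_labels <- function(k) {
  if (k == 3L) c("L", "M", "H") else paste0("G", seq_len(k))
}

# Remainder rule: when n mod k = r > 0, the r extra samples go to the
# extreme blocks first (lowest, then highest, alternating inward).
partition_sizes <- function(n, k) {
  base <- n %/% k
  r <- n %% k
  sizes <- rep.int(base, k)
  if (r > 0L) {
    lo <- 1L; hi <- k; take_low <- TRUE
    recipients <- integer(0)
    while (length(recipients) < r) {
      if (take_low) { recipients <- c(recipients, lo); lo <- lo + 1L }
      else          { recipients <- c(recipients, hi); hi <- hi - 1L }
      take_low <- !take_low
    }
    sizes[recipients] <- sizes[recipients] + 1L
  }
  sizes
}

#' Partition samples into k equally-sized strata by miRNA expression
#'
#' Samples are sorted by ascending miRNA expression (ties broken by sample
#' ID so the split is deterministic) and cut into k contiguous blocks whose
#' sizes differ by at most one; stratum 1 holds the lowest expression.
#' Samples with non-finite miRNA values are excluded from the partition.
#'
#' @param mirna_expr Named numeric vector of miRNA expression over samples.
#' @param k Number of strata (>= 2; default 3, labelled L/M/H).
#' @return Object of class `group_partition`: list with `k`, `assignment`
#'   (named integer vector, stratum index 1..k per analyzed sample),
#'   `sizes`, `labels`, and `strata` (list of sample-ID vectors).
#' @examples
#' x <- stats::setNames(stats::rnorm(9), paste0("S", 1:9))
#' partition_by_mirna(x, k = 3)$sizes
#' @export
partition_by_mirna <- function(mirna_expr, k = 3L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  ids <- names(mirna_expr)
  if (is.null(ids)) ids <- as.character(seq_along(mirna_expr))
  fin <- is.finite(mirna_expr)
  n <- sum(fin)
  if (n < 3L * k) stop("need at least 3*k = ", 3L * k,
                       " samples with finite miRNA values, have ", n)
  v <- mirna_expr[fin]
  id <- ids[fin]
  ord <- order(v, id)
  sizes <- partition_sizes(n, k)
  assignment <- rep.int(seq_len(k), sizes)
  names(assignment) <- id[ord]
  structure(list(k = k,
                 assignment = assignment,
                 sizes = sizes,
                 labels = stratum_labels(k),
                 strata = split(names(assignment), assignment)),
            class = "group_partition")
}

#' @export
print.group_partition <- function(x, ...) {
  cat("k =", x$k, "strata (", paste(x$labels, collapse = "/"),
      "), sizes:", paste(x$sizes, collapse = "/"), "\n")
  invisible(x)
}

#' Coefficient-of-variation filter for non-informative ceRNAs
#'
#' A gene is eliminated when its coefficient of variation (sd/|mean|,
#' computed on the values as provided) falls below `threshold` in at least
#' one stratum. A stratum mean within machine epsilon of zero with positive
#' sd yields CV = +Inf (retained); zero sd yields CV = 0 (eliminated).
#'
#' @param gene_expr Named numeric vector of one gene's expression.
#' @param part A `group_partition`.
#' @param threshold CV threshold (default 0.05, i.e. 5%).
#' @return `TRUE` if the gene should be eliminated.
#' @export
cv_filter <- function(gene_expr, part, threshold = 0.05) {
  stopifnot(inherits(part, "group_partition"))
  cvs <- vapply(part$strata, function(s) {
    coefficient_of_variation(gene_expr[s])
  }, numeric(1L))
  any(cvs < threshold)
}

#' Transform a Pearson correlation to the t-domain
#'
#' Maps a correlation rho observed on n samples to its test statistic
#' t = rho * sqrt((n - 2) / (1 - rho^2)), which makes inter-stratum changes
#' comparable across correlation magnitudes (a change from 0 to 0.2 is not
#' statistically equivalent to one from 0.8 to 1). rho is clipped to
#' +/-(1 - 1e-12) so that t stays finite on degenerate perfect correlations.
#'
#' @param rho Correlation(s) in `[-1, 1]`; vectorized.
#' @param n Sample size(s) (> 2) behind each correlation.
#' @return Numeric t value(s); odd and strictly increasing in rho.
#' @export
t_transform <- function(rho, n) {
  if (any(n <= 2L)) stop("t_transform requires n > 2")
  r <- pmin(pmax(rho, -(1 - 1e-12)), 1 - 1e-12)
  r * sqrt((n - 2) / (1 - r^2))
}

#' Per-stratum correlation profile of a ce-pair
#'
#' Computes the Pearson correlation of the two genes within each miRNA
#' stratum and maps each to the t-domain using that stratum's own sample
#' count. Stratum membership is fixed by the full miRNA vector; samples
#' with a missing value in either gene are dropped pairwise within their
#' stratum only.
#'
#' @param x_i,x_j Named numeric expression vectors of the two genes.
#' @param part A `group_partition`.
#' @return Object of class `interaction_profile`: list with `rho`, `t`,
#'   `n` (per-stratum vectors), or with `filtered = TRUE` and a `reason`
#'   when a stratum is degenerate (fewer than 3 complete pairs or zero
#'   variance).
#' @export
interaction_profile <- function(x_i, x_j, part) {
  stopifnot(inherits(part, "group_partition"))
  k <- part$k
  rho <- t_val <- n_eff <- numeric(k)
  for (g in seq_len(k)) {
    s <- part$strata[[g]]
    xi <- x_i[s]; xj <- x_j[s]
    ok <- is.finite(xi) & is.finite(xj)
    if (sum(ok) < 3L) {
      return(structure(list(filtered = TRUE, reason = "too_few_samples"),
                       class = "interaction_profile"))
    }
    xi <- xi[ok]; xj <- xj[ok]
    if (stats::sd(xi) == 0 || stats::sd(xj) == 0) {
      return(structure(list(filtered = TRUE, reason = "zero_variance"),
                       class = "interaction_profile"))
    }
    rho[g] <- stats::cor(xi, xj)
    n_eff[g] <- sum(ok)
    t_val[g] <- t_transform(rho[g], n_eff[g])
  }
  structure(list(rho = rho, t = t_val, n = n_eff, filtered = FALSE),
            class = "interaction_profile")
}

#' Interaction score of a ce-triplet
#'
#' The interaction score is the largest positive per-stratum t minus the
#' smallest per-stratum |t|, or 0 when no stratum has a positive t. The
#' optimized group G_opt is the stratum attaining the largest positive t
#' (lowest stratum index on ties); it is defined only when the score is
#' strictly positive.
#'
#' @param profile An `interaction_profile`, or a numeric vector of
#'   per-stratum t values.
#' @return List with `delta` (score, >= 0) and `g_opt` (stratum index, or
#'   `NA` when `delta` = 0).
#' @examples
#' interaction_score(c(3, -1, 0.5))  # delta 2.5, g_opt 1
#' @export
interaction_score <- function(profile) {
  t_values <- if (inherits(profile, "interaction_profile")) profile$t else profile
  stopifnot(is.numeric(t_values), length(t_values) >= 2L)
  if (!any(t_values > 0)) return(list(delta = 0, g_opt = NA_integer_))
  delta <- max(t_values) - min(abs(t_values))
  g_opt <- if (delta > 0) which.max(t_values) else NA_integer_
  list(delta = delta, g_opt = g_opt)
}

# Vectorized interaction score over a draws-by-k matrix of t values.
delta_from_tmat <- function(m) {
  cols <- lapply(seq_len(ncol(m)), function(i) m[, i])
  row_max <- do.call(pmax, cols)
  min_abs <- do.call(pmin, lapply(cols, abs))
  ifelse(row_max > 0, row_max - min_abs, 0)
}

#' Score putative ce-triplets against the miRNA-stratified null
#'
#' The main scoring routine: for each bridging miRNA, samples are
#' partitioned once into k strata; every triplet bridged by that miRNA gets
#' per-stratum Pearson correlations, t-domain values, the interaction score
#' and (when a null table is supplied) an empirical P-value with Bonferroni
#' adjustment. Genes whose coefficient of variation drops below
#' `cv_threshold` in any stratum mark their triplets as filtered
#' (unscored).
#'
#' @param gene_expr Gene expression matrix (genes x samples).
#' @param mirna_expr miRNA expression matrix (miRNAs x samples), same
#'   samples.
#' @param triplets data.frame from [enumerate_triplets()].
#' @param k Number of miRNA strata (default 3).
#' @param cv_threshold Per-stratum CV elimination threshold (default 0.05).
#' @param null_table Optional `null_table` for P-values; its `k` must match.
#' @param n_tests Bonferroni denominator; defaults to the number of putative
#'   triplets submitted (before the CV filter).
#' @return data.frame with one row per triplet: identifiers, per-stratum
#'   `rho_*` and `t_*`, `delta_i`, `p_value`, `p_adjusted`, `g_opt` (stratum
#'   label), `filtered`, `filter_reason`.
#' @export
score_triplets <- function(gene_expr, mirna_expr, triplets, k = 3L,
                           cv_threshold = 0.05, null_table = NULL,
                           n_tests = nrow(triplets)) {
  stopifnot(is.matrix(gene_expr), is.matrix(mirna_expr))
  if (!nrow(triplets)) stop("no triplets to score")
  k <- as.integer(k)
  missing_g <- setdiff(unique(c(triplets$gene_i, triplets$gene_j)),
                       rownames(gene_expr))
  if (length(missing_g)) stop("gene(s) absent from gene matrix: ",
                              paste(utils::head(missing_g, 5L), collapse = ", "))
  missing_m <- setdiff(unique(triplets$mirna), rownames(mirna_expr))
  if (length(missing_m)) stop("miRNA(s) absent from miRNA matrix: ",
                              paste(utils::head(missing_m, 5L), collapse = ", "))
  if (!is.null(null_table)) {
    stopifnot(inherits(null_table, "null_table"))
    if (null_table$k != k) stop("null table was built for k = ", null_table$k)
  }
  labels <- stratum_labels(k)
  chunks <- split(seq_len(nrow(triplets)), triplets$mirna)
  out <- vector("list", length(chunks))
  names(out) <- names(chunks)
  for (m in names(chunks)) {
    idx <- chunks[[m]]
    tr <- triplets[idx, , drop = FALSE]
    part <- partition_by_mirna(mirna_expr[m, ], k)
    genes <- unique(c(tr$gene_i, tr$gene_j))
    sub <- gene_expr[genes, names(part$assignment), drop = FALSE]
    res <- if (anyNA(sub)) {
      score_block_slow(sub, tr, part, cv_threshold)
    } else {
      score_block_fast(sub, tr, part, cv_threshold)
    }
    res <- cbind(tr[, c("gene_i", "gene_j", "mirna")], res)
    out[[m]] <- res
  }
  res <- do.call(rbind, out)
  res <- res[order(unlist(chunks, use.names = FALSE)), , drop = FALSE]
  rownames(res) <- NULL
  sc <- delta_gopt_from_tmat(as.matrix(res[, paste0("t_", seq_len(k))]))
  res$delta_i <- ifelse(res$filtered, NA_real_, sc$delta)
  res$g_opt <- ifelse(res$filtered | is.na(sc$g_opt), NA_character_,
                      labels[sc$g_opt])
  if (!is.null(null_table)) {
    p <- rep(NA_real_, nrow(res))
    ok <- !res$filtered
    p[ok] <- null_pvalue(null_table, res$delta_i[ok])
    res$p_value <- p
    res$p_adjusted <- bonferroni(p, n_tests)
  } else {
    res$p_value <- NA_real_
    res$p_adjusted <- NA_real_
  }
  res
}

delta_gopt_from_tmat <- function(tm) {
  tm[is.na(tm)] <- -Inf
  cols <- lapply(seq_len(ncol(tm)), function(i) tm[, i])
  row_max <- do.call(pmax, cols)
  min_abs <- do.call(pmin, lapply(cols, abs))
  delta <- ifelse(row_max > 0, row_max - min_abs, 0)
  g_opt <- max.col(tm, ties.method = "first")
  g_opt[which(!(row_max > 0) | !(delta > 0))] <- NA_integer_
  list(delta = delta, g_opt = g_opt)
}

# Fast path: complete data. Standardizes the gene block per stratum so the
# correlation of a pair is a single inner product.
score_block_fast <- function(sub, tr, part, cv_threshold) {
  k <- part$k
  genes <- rownames(sub)
  i_idx <- match(tr$gene_i, genes)
  j_idx <- match(tr$gene_j, genes)
  nt <- nrow(tr)
  rho <- t_val <- matrix(NA_real_, nt, k)
  elim <- matrix(FALSE, length(genes), k)
  zerovar <- matrix(FALSE, length(genes), k)
  for (g in seq_len(k)) {
    s <- part$strata[[g]]
    X <- sub[, s, drop = FALSE]
    n_g <- length(s)
    mu <- rowMeans(X)
    Xc <- X - mu
    sd_g <- sqrt(rowSums(Xc^2) / (n_g - 1))
    cv <- ifelse(abs(mu) < .Machine$double.eps,
                 ifelse(sd_g > 0, Inf, 0), sd_g / abs(mu))
    elim[, g] <- cv < cv_threshold
    zerovar[, g] <- sd_g == 0
    denom <- sd_g * sqrt(n_g - 1)
    denom[denom == 0] <- NA_real_
    Z <- Xc / denom
    r <- rowSums(Z[i_idx, , drop = FALSE] * Z[j_idx, , drop = FALSE])
    rho[, g] <- r
    t_val[, g] <- t_transform(r, n_g)
  }
  gene_elim <- rowSums(elim) > 0L
  gene_zv <- rowSums(zerovar) > 0L
  zv_trip <- gene_zv[i_idx] | gene_zv[j_idx]
  filt <- gene_elim[i_idx] | gene_elim[j_idx] | zv_trip
  reason <- rep(NA_character_, nt)
  reason[filt] <- "low_cv"
  reason[zv_trip] <- "zero_variance"
  res <- data.frame(rho, t_val)
  names(res) <- c(paste0("rho_", seq_len(k)), paste0("t_", seq_len(k)))
  res$filtered <- filt
  res$filter_reason <- reason
  res
}

# Slow path: per-triplet pairwise-complete handling of missing values.
score_block_slow <- function(sub, tr, part, cv_threshold) {
  k <- part$k
  nt <- nrow(tr)
  rho <- t_val <- matrix(NA_real_, nt, k)
  filt <- logical(nt)
  reason <- rep(NA_character_, nt)
  cv_elim <- vapply(rownames(sub), function(g) {
    cv_filter(sub[g, ], part, cv_threshold)
  }, logical(1L))
  for (r in seq_len(nt)) {
    if (cv_elim[[tr$gene_i[r]]] || cv_elim[[tr$gene_j[r]]]) {
      filt[r] <- TRUE
      reason[r] <- "low_cv"
      next
    }
    pr <- interaction_profile(sub[tr$gene_i[r], ], sub[tr$gene_j[r], ], part)
    if (isTRUE(pr$filtered)) {
      filt[r] <- TRUE
      reason[r] <- pr$reason
    } else {
      rho[r, ] <- pr$rho
      t_val[r, ] <- pr$t
    }
  }
  res <- data.frame(rho, t_val)
  names(res) <- c(paste0("rho_", seq_len(k)), paste0("t_", seq_len(k)))
  res$filtered <- filt
  res$filter_reason <- reason
  res
}

#' Write a triplet results table as TSV
#' @param results data.frame from [score_triplets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
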