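#' Define a synthetic cohort design
#'
#' Describes a sample-paired miRNA/gene expression cohort with the
#' statistical structure the differential-correlation screen assumes:
#' continuous log2-like expression (level-3 array scale, mean 8, sd 2),
#' i.i.d. miRNA abundance, and optionally planted ce-triplets whose gene
#' pair is correlated at `rho_opt` inside one miRNA stratum and `rho_base`
#' elsewhere. Stratum boundaries use the same equal-split partition rule as
#' the detector, so generator and detector agree on the planted stratum.
#'
#' @param n_samples Cohort size (default 450: 150 per stratum at k = 3).
#' @param n_genes,n_mirnas Numbers of genes and miRNAs.
#' @param k Number of miRNA strata (default 3).
#' @param planted Optional data.frame with columns `gene_i`, `gene_j`,
#'   `mirna` (integer indices), `stratum` (index 1..k or label L/M/H),
#'   `rho_opt`, `rho_base`. Planted genes must be distinct across rows.
#' @param expr_mean,expr_sd Expression location/scale (defaults 8 and 2).
#' @param noise_sd Additive measurement noise sd on top of the correlated
#'   signal (default 0, so realized correlations match the design).
#' @param seed RNG seed.
#' @return Object of class `sim_design` (a validated list).
#' @export
simulation_design <- function(n_samples = 450L, n_genes = 60L,
                              n_mirnas = 6L, k = 3L, planted = NULL,
                              expr_mean = 8, expr_sd = 2, noise_sd = 0,
                              seed = 1L) {
  if (!is.null(planted) && nrow(planted)) {
    need <- c("gene_i", "gene_j", "mirna", "stratum", "rho_opt", "rho_base")
    miss <- setdiff(need, names(planted))
    if (length(miss)) stop("planted is missing column(s): ",
                           paste(miss, collapse = ", "))
    planted$stratum <- resolve_stratum(planted$stratum, k)
    stopifnot(all(planted$gene_i >= 1 & planted$gene_i <= n_genes),
              all(planted$gene_j >= 1 & planted$gene_j <= n_genes),
              all(planted$mirna >= 1 & planted$mirna <= n_mirnas),
              all(abs(planted$rho_opt) < 1), all(abs(planted$rho_base) < 1),
              all(planted$gene_i != planted$gene_j))
    pg <- c(planted$gene_i, planted$gene_j)
    if (anyDuplicated(pg)) stop("planted genes must be distinct across rows")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 n_mirnas = as.integer(n_mirnas), k = as.integer(k),
                 planted = planted, expr_mean = expr_mean,
                 expr_sd = expr_sd, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sim_design")
}

resolve_stratum <- function(stratum, k) {
  if (is.character(stratum)) {
    idx <- match(stratum, stratum_labels(k))
    if (anyNA(idx)) stop("unknown stratum label(s): ",
                         paste(stratum[is.na(idx)], collapse = ", "))
    idx
  } else {
    stopifnot(all(stratum >= 1L & stratum <= k))
    as.integer(stratum)
  }
}

#' Simulate a sample-paired miRNA/gene expression cohort
#'
#' miRNA values are drawn i.i.d. normal; non-planted genes are independent
#' noise. For each planted triplet, within every stratum of its bridging
#' miRNA the gene pair is drawn bivariate-normal (Cholesky mixing of
#' independent normals) with the stratum's design correlation (`rho_opt` in
#' the target stratum, `rho_base` elsewhere).
#'
#' @param design A `sim_design`.
#' @return List with `genes` (matrix), `mirnas` (matrix), `truth`
#'   (data.frame of planted triplets with resolved IDs) and `design`.
#' @export
simulate_cohort <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(design$seed)
  n <- design$n_samples
  sample_ids <- sprintf("S%04d", seq_len(n))
  gene_ids <- sprintf("GENE%04d", seq_len(design$n_genes))
  mirna_ids <- sprintf("MIR%03d", seq_len(design$n_mirnas))
  mirnas <- matrix(stats::rnorm(design$n_mirnas * n, design$expr_mean,
                                design$expr_sd),
                   design$n_mirnas, n,
                   dimnames = list(mirna_ids, sample_ids))
  z <- matrix(stats::rnorm(design$n_genes * n), design$n_genes, n,
              dimnames = list(gene_ids, sample_ids))
  truth <- data.frame(gene_i = character(0), gene_j = character(0),
                      mirna = character(0), stratum = character(0),
                      rho_opt = numeric(0), rho_base = numeric(0))
  pl <- design$planted
  if (!is.null(pl) && nrow(pl)) {
    for (r in seq_len(nrow(pl))) {
      m <- mirna_ids[pl$mirna[r]]
      part <- partition_by_mirna(mirnas[m, ], design$k)
      gi <- gene_ids[pl$gene_i[r]]
      gj <- gene_ids[pl$gene_j[r]]
      for (g in seq_len(design$k)) {
        rho <- if (g == pl$stratum[r]) pl$rho_opt[r] else pl$rho_base[r]
        s <- part$strata[[g]]
        z[gj, s] <- rho * z[gi, s] + sqrt(1 - rho^2) * z[gj, s]
      }
    }
    truth <- data.frame(gene_i = gene_ids[pl$gene_i],
                        gene_j = gene_ids[pl$gene_j],
                        mirna = mirna_ids[pl$mirna],
                        stratum = stratum_labels(design$k)[pl$stratum],
                        rho_opt = pl$rho_opt, rho_base = pl$rho_base,
                        stringsAsFactors = FALSE)
  }
  genes <- design$expr_mean + design$expr_sd * z
  if (design$noise_sd > 0) {
    genes <- genes + matrix(stats::rnorm(length(genes), 0, design$noise_sd),
                            nrow(genes), ncol(genes))
  }
  list(genes = genes, mirnas = mirnas, truth = truth, design = design)
}

#' Build a target map for a simulated cohort
#'
#' Gives each miRNA its planted gene pair (so planted triplets are
#' putative) plus `background_per_mirna` deterministic background targets,
#' producing a realistic mixture of null and planted triplets.
#'
#' @param sim Output of [simulate_cohort()].
#' @param background_per_mirna Background targets per miRNA (default 6).
#' @return Named list, miRNA -> character vector of target genes.
#' @export
cohort_target_map <- function(sim, background_per_mirna = 6L) {
  gene_ids <- rownames(sim$genes)
  mirna_ids <- rownames(sim$mirnas)
  planted_genes <- unique(c(sim$truth$gene_i, sim$truth$gene_j))
  pool <- setdiff(gene_ids, planted_genes)
  tm <- lapply(seq_along(mirna_ids), function(i) {
    bg <- pool[(seq_len(background_per_mirna) +
                  (i - 1L) * background_per_mirna - 1L) %% length(pool) + 1L]
    pl <- sim$truth[sim$truth$mirna == mirna_ids[i], ]
    unique(c(pl$gene_i, pl$gene_j, bg))
  })
  stats::setNames(tm, mirna_ids)
}

#' Simulate survival with a group-dependent hazard
#'
#' Exponential survival times with baseline hazard `baseline_hazard`
#' (per month) outside the mask and `baseline_hazard * hazard_ratio`
#' inside, independently censored by an exponential clock of rate
#' `censor_rate` (0 = no censoring). Defaults emulate a glioblastoma-like
#' cohort: baseline median OS 14 months.
#'
#' @param group_mask Named logical vector over samples (`TRUE` = in-group).
#' @param hazard_ratio Hazard ratio of the in-group (> 0; 1 = no effect).
#' @param baseline_hazard Events per month outside the group
#'   (default log(2)/14).
#' @param censor_rate Censoring events per month (default 1/60).
#' @param seed Optional RNG seed.
#' @return Clinical data.frame: `sample`, `time_months`, `event`.
#' @export
simulate_survival <- function(group_mask, hazard_ratio = 1,
                              baseline_hazard = log(2) / 14,
                              censor_rate = 1 / 60, seed = NULL) {
  stopifnot(hazard_ratio > 0, baseline_hazard > 0, censor_rate >= 0,
            !is.null(names(group_mask)))
  if (!is.null(seed)) set.seed(seed)
  n <- length(group_mask)
  rate <- ifelse(group_mask, baseline_hazard * hazard_ratio, baseline_hazard)
  t_event <- stats::rexp(n, rate)
  t_cens <- if (censor_rate > 0) stats::rexp(n, censor_rate) else rep(Inf, n)
  data.frame(sample = names(group_mask),
             time_months = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens),
             stringsAsFactors = FALSE)
}
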