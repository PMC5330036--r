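#' Read a pipeline run configuration from YAML
#'
#' @param path YAML file mirroring the arguments of [run_pipeline()].
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' Run the end-to-end ceRNA inference pipeline
#'
#' Orchestrates enumerate -> CV filter -> score -> P-values -> network,
#' optionally followed by the per-triplet survival screen (log-rank on
#' membership in the optimized stratum of each significant triplet).
#' Writes a results TSV, network exports and a JSON manifest recording
#' seeds and the triplet counts at every stage.
#'
#' @param config Named list (or path to a YAML file) with entries:
#'   `gene_expr`, `mirna_expr`, `target_map` (paths or in-memory objects),
#'   optional `clinical`, and optional `k` (3), `cv_threshold` (0.05),
#'   `n_draws` (1e6), `seed` (1), `p_cutoff` (0.01), `adjusted` (FALSE),
#'   `method` ("ceidca", "smi" or "cmi"), `n_perm` (1000, MI methods),
#'   `n_bins` (8), `out_dir`.
#' @return Invisibly, a list with `results`, `network` and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  cfg <- utils::modifyList(
    list(k = 3L, cv_threshold = 0.05, n_draws = 1e6, seed = 1L,
         p_cutoff = 0.01, adjusted = FALSE, method = "ceidca",
         n_perm = 1000L, n_bins = 8L, out_dir = NULL, clinical = NULL),
    config)
  stage <- function(name) message("[", name, "] ",
                                  format(Sys.time(), "%H:%M:%S"))
  load_mat <- function(x, what) {
    if (is.character(x)) {
      if (!file.exists(x)) stop(what, " file not found: ", x)
      read_expression_matrix(x)
    } else x
  }
  stage("load")
  gene_expr <- load_mat(cfg$gene_expr, "gene_expr")
  mirna_expr <- load_mat(cfg$mirna_expr, "mirna_expr")
  target_map <- if (is.character(cfg$target_map)) {
    read_target_map(cfg$target_map)
  } else cfg$target_map
  clinical <- if (is.character(cfg$clinical)) {
    read_clinical_table(cfg$clinical)
  } else cfg$clinical
  stage("enumerate")
  triplets <- enumerate_triplets(target_map, rownames(gene_expr),
                                 rownames(mirna_expr))
  if (!nrow(triplets)) stop("stage enumerate: no putative triplets")
  stage("score")
  set.seed(cfg$seed)
  if (cfg$method == "ceidca") {
    sizes <- partition_sizes(ncol(gene_expr), cfg$k)
    modal_df <- sort(sizes)[ceiling(cfg$k / 2)] - 2L
    tab <- build_null_table(df = modal_df, k = cfg$k,
                            n_draws = cfg$n_draws, seed = cfg$seed)
    results <- score_triplets(gene_expr, mirna_expr, triplets, k = cfg$k,
                              cv_threshold = cfg$cv_threshold,
                              null_table = tab, n_tests = nrow(triplets))
  } else {
    results <- score_triplets(gene_expr, mirna_expr, triplets, k = cfg$k,
                              cv_threshold = cfg$cv_threshold)
    results <- mi_pvalues(results, gene_expr, mirna_expr, cfg)
  }
  results$method <- cfg$method
  stage("network")
  net <- build_network(results, p_cutoff = cfg$p_cutoff,
                       adjusted = cfg$adjusted)
  survival_screen <- NULL
  if (!is.null(clinical)) {
    stage("survival")
    survival_screen <- screen_triplet_survival(results, mirna_expr,
                                               clinical, cfg)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("ceidca")),
    method = cfg$method, k = cfg$k, seed = cfg$seed,
    n_draws = if (cfg$method == "ceidca") cfg$n_draws else NA,
    p_cutoff = cfg$p_cutoff, adjusted = cfg$adjusted,
    counts = list(
      genes = nrow(gene_expr), mirnas = nrow(mirna_expr),
      samples = ncol(gene_expr),
      putative_triplets = nrow(triplets),
      unique_pairs = attr(triplets, "unique_pairs"),
      scored = sum(!results$filtered),
      filtered = sum(results$filtered),
      significant = net$n_triplets,
      network_nodes = length(net$nodes),
      network_edges = nrow(net$edges)))
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results(results, file.path(cfg$out_dir, "results.tsv"))
    export_network(net, cfg$out_dir)
    if (!is.null(survival_screen)) {
      utils::write.table(survival_screen,
                         file.path(cfg$out_dir, "survival_screen.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(results = results, network = net, manifest = manifest,
                 survival_screen = survival_screen))
}

# Permutation inference for the MI baselines over all unfiltered triplets.
mi_pvalues <- function(results, gene_expr, mirna_expr, cfg) {
  p <- rep(NA_real_, nrow(results))
  delta <- rep(NA_real_, nrow(results))
  for (r in which(!results$filtered)) {
    xi <- gene_expr[results$gene_i[r], ]
    xj <- gene_expr[results$gene_j[r], ]
    mv <- mirna_expr[results$mirna[r], ]
    if (cfg$method == "smi") {
      part <- partition_by_mirna(mv, cfg$k)
      fn <- function(a, b) smi_score(a, b, part, cfg$n_bins)
    } else {
      fn <- function(a, b) cmi_score(a, b, mv, cfg$n_bins)
    }
    pv <- permutation_pvalue(fn, xi, xj, n_perm = cfg$n_perm)
    p[r] <- as.numeric(pv)
    delta[r] <- attr(pv, "observed")
  }
  results$delta_i <- delta
  results$p_value <- p
  results$p_adjusted <- bonferroni(p, nrow(results))
  results
}

# Per-triplet survival screen: log-rank on membership in the triplet's
# optimized stratum of its bridging miRNA.
screen_triplet_survival <- function(results, mirna_expr, clinical, cfg) {
  p <- if (cfg$adjusted) results$p_adjusted else results$p_value
  sig <- which(!is.na(p) & p < cfg$p_cutoff & !is.na(results$g_opt))
  if (!length(sig)) return(NULL)
  labels <- stratum_labels(cfg$k)
  rows <- lapply(sig, function(r) {
    part <- partition_by_mirna(mirna_expr[results$mirna[r], ], cfg$k)
    g <- match(results$g_opt[r], labels)
    in_s <- part$strata[[g]]
    mask <- stats::setNames(clinical$sample %in% in_s, clinical$sample)
    lr <- tryCatch(logrank_test(clinical, mask),
                   error = function(e) list(chi2 = NA_real_, p = NA_real_))
    data.frame(gene_i = results$gene_i[r], gene_j = results$gene_j[r],
               mirna = results$mirna[r], g_opt = results$g_opt[r],
               n_in = sum(mask), logrank_chi2 = lr$chi2, logrank_p = lr$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
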