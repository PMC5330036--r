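#' Merge significant triplets into a ceRNA interaction network
#'
#' Triplets passing the P-value cutoff are collapsed into unordered
#' ce-pair edges; a pair bridged by several miRNAs becomes one edge
#' annotated with all bridging miRNAs and the best (minimal) P-value.
#'
#' @param results data.frame from [score_triplets()].
#' @param p_cutoff Significance cutoff (default 0.01).
#' @param adjusted Use `p_adjusted` instead of `p_value` (default FALSE).
#' @return Object of class `cerna_network`: list with `nodes`, `edges`
#'   (data.frame `gene_i`, `gene_j`, `mirnas`, `n_mirnas`, `best_p`),
#'   `degree` (named integer), `n_triplets` (passing triplets) and
#'   `connectivity` (mean node degree).
#' @export
build_network <- function(results, p_cutoff = 0.01, adjusted = FALSE) {
  p <- if (adjusted) results$p_adjusted else results$p_value
  keep <- !is.na(p) & p < p_cutoff
  sub <- results[keep, , drop = FALSE]
  psub <- p[keep]
  if (!nrow(sub)) {
    return(structure(list(nodes = character(0),
                          edges = data.frame(gene_i = character(0),
                                             gene_j = character(0),
                                             mirnas = character(0),
                                             n_mirnas = integer(0),
                                             best_p = numeric(0)),
                          degree = integer(0), n_triplets = 0L,
                          connectivity = 0),
                     class = "cerna_network"))
  }
  key <- paste(sub$gene_i, sub$gene_j, sep = "\r")
  ord <- order(key)
  sub <- sub[ord, , drop = FALSE]
  psub <- psub[ord]
  key <- key[ord]
  first <- !duplicated(key)
  grp <- cumsum(first)
  edges <- data.frame(
    gene_i = sub$gene_i[first],
    gene_j = sub$gene_j[first],
    mirnas = vapply(split(sub$mirna, grp), function(m)
      paste(sort(unique(m)), collapse = ","), character(1L)),
    n_mirnas = vapply(split(sub$mirna, grp), function(m)
      length(unique(m)), integer(1L)),
    best_p = vapply(split(psub, grp), min, numeric(1L)),
    stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  nodes <- sort(unique(c(edges$gene_i, edges$gene_j)))
  degree <- table(factor(c(edges$gene_i, edges$gene_j), levels = nodes))
  degree <- stats::setNames(as.integer(degree), nodes)
  structure(list(nodes = nodes, edges = edges, degree = degree,
                 n_triplets = nrow(sub),
                 connectivity = 2 * nrow(edges) / length(nodes)),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  cat("ceRNA network:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges,", x$n_triplets, "triplets; connectivity (mean degree) =",
      format(x$connectivity, digits = 4), "\n")
  invisible(x)
}

#' Hub nodes of a degree distribution
#'
#' Hubs are the top `top_frac` of nodes by degree: all nodes whose degree
#' is at least the (1 - top_frac) quantile, so boundary ties are included.
#'
#' @param degree Named integer/numeric vector of node degrees.
#' @param top_frac Fraction defining hubs (default 0.05, i.e. top 5%).
#' @return Character vector of hub node names.
#' @export
hub_nodes <- function(degree, top_frac = 0.05) {
  stopifnot(length(degree) > 0, top_frac > 0, top_frac <= 1)
  q <- stats::quantile(degree, 1 - top_frac, names = FALSE, type = 7)
  names(degree)[degree >= q]
}

#' Degree map of the genome-wide coexpression network
#'
#' Builds the network of gene pairs whose Pearson correlation exceeds
#' `r_cutoff` and returns the per-gene degree. The default cutoff 0.099 is
#' the correlation whose one-sided significance is P = 0.012 at n = 520
#' (see [t_transform()]). Rows are processed in blocks so gene sets of 1e4+
#' never materialize the full correlation matrix.
#'
#' @param expr Expression matrix (genes x samples), >= 3 samples.
#' @param r_cutoff Correlation threshold; edge iff r > r_cutoff.
#' @param block_size Genes per block (default 2000).
#' @return Named integer vector of degrees.
#' @export
build_coexpression_network <- function(expr, r_cutoff = 0.099,
                                       block_size = 2000L) {
  stopifnot(is.matrix(expr), ncol(expr) >= 3L)
  n <- ncol(expr)
  mu <- rowMeans(expr)
  ce <- expr - mu
  sd_r <- sqrt(rowSums(ce^2))
  sd_r[sd_r == 0] <- NA_real_
  Z <- ce / sd_r
  ng <- nrow(expr)
  degree <- integer(ng)
  starts <- seq(1L, ng, by = block_size)
  for (s in starts) {
    e <- min(s + block_size - 1L, ng)
    R <- Z[s:e, , drop = FALSE] %*% t(Z)
    hits <- rowSums(R > r_cutoff, na.rm = TRUE)
    self <- diag(R[, s:e, drop = FALSE])[seq_len(e - s + 1L)]
    degree[s:e] <- as.integer(hits) - as.integer(!is.na(self) & self > r_cutoff)
  }
  stats::setNames(degree, rownames(expr))
}

#' Overrepresentation of ce-triplets at one gene
#'
#' One-sided Fisher's exact test of whether a gene participates in more
#' triplets than its pooled share. Each triplet contributes two gene slots;
#' the observed (count, rest) row is tested against the pooled expectation
#' (round(2T/n_genes), rest), overridable via `expected`.
#'
#' @param gene_triplet_count Number of triplets the gene appears in.
#' @param total_triplets Total number of triplets T.
#' @param n_genes Total number of ceRNAs in the network.
#' @param expected Optional length-2 integer vector overriding the
#'   background row of the 2x2 table.
#' @return One-sided (greater) Fisher P-value.
#' @export
triplet_overrepresentation <- function(gene_triplet_count, total_triplets,
                                       n_genes, expected = NULL) {
  stopifnot(gene_triplet_count >= 0, total_triplets >= gene_triplet_count,
            n_genes >= 2)
  slots <- 2L * total_triplets
  if (slots == 0L) return(1)
  if (is.null(expected)) {
    e1 <- round(slots / n_genes)
    expected <- c(e1, slots - e1)
  }
  tab <- rbind(c(gene_triplet_count, slots - gene_triplet_count), expected)
  unname(stats::fisher.test(tab, alternative = "greater")$p.value)
}

#' Compare interaction-score distributions between cohorts
#'
#' Validation-style comparison (e.g. core triplets rescored in a second
#' cohort vs the background of other putative triplets): Welch two-sample
#' t-test P and the two-sample Kolmogorov-Smirnov statistic and P.
#'
#' @param scores_a,scores_b Nonempty numeric score vectors.
#' @return List with `t_p`, `ks_stat`, `ks_p`.
#' @export
compare_score_distributions <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) > 0, length(scores_b) > 0)
  t_p <- tryCatch(stats::t.test(scores_a, scores_b)$p.value,
                  error = function(e) 1)
  ks <- suppressWarnings(stats::ks.test(scores_a, scores_b))
  list(t_p = t_p, ks_stat = unname(ks$statistic), ks_p = ks$p.value)
}

#' Export a ceRNA network for external tools
#'
#' Writes a Cytoscape SIF file, a GraphML file (edge attributes: bridging
#' miRNAs and best P), an edge-list TSV and a per-node degree report.
#'
#' @param net A `cerna_network`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"cerna"`).
#' @return Character vector of the written paths, invisibly.
#' @export
export_network <- function(net, dir, prefix = "cerna") {
  stopifnot(inherits(net, "cerna_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sif <- file.path(dir, paste0(prefix, ".sif"))
  writeLines(paste(net$edges$gene_i, "cerna", net$edges$gene_j, sep = "\t"),
             sif)
  edge_tsv <- file.path(dir, paste0(prefix, "_edges.tsv"))
  utils::write.table(net$edges, edge_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  deg_tsv <- file.path(dir, paste0(prefix, "_degree.tsv"))
  utils::write.table(data.frame(gene = names(net$degree),
                                degree = as.integer(net$degree)),
                     deg_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  gml <- file.path(dir, paste0(prefix, ".graphml"))
  if (nrow(net$edges)) {
    g <- igraph::graph_from_data_frame(
      net$edges[, c("gene_i", "gene_j", "mirnas", "best_p")],
      directed = FALSE,
      vertices = data.frame(name = net$nodes))
    igraph::write_graph(g, gml, format = "graphml")
  } else {
    writeLines(character(0), gml)
  }
  invisible(c(sif, edge_tsv, deg_tsv, gml))
}
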