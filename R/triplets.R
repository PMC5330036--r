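#' Enumerate putative ceRNA triplets
#'
#' A putative ce-pair is two genes sharing at least one predicted targeting
#' miRNA; a ce-triplet is such a pair plus one shared (bridging) miRNA. For
#' every miRNA present in the data, all unordered pairs of its targets that
#' are present in the gene matrix are emitted, with `gene_i < gene_j`
#' lexicographically. A gene is never paired with itself.
#'
#' @param target_map Named list, miRNA -> character vector of target genes
#'   (as returned by [read_target_map()]).
#' @param genes_present Character vector of genes available in the gene
#'   expression matrix.
#' @param mirnas_present Character vector of miRNAs available in the miRNA
#'   expression matrix.
#' @return data.frame with columns `gene_i`, `gene_j`, `mirna`, sorted by
#'   (mirna, gene_i, gene_j). The number of distinct ce-pairs across all
#'   miRNAs is attached as attribute `"unique_pairs"`.
#' @examples
#' tm <- list(m1 = c("a", "b"), m2 = c("b", "c"))
#' enumerate_triplets(tm, c("a", "b", "c"), c("m1", "m2"))
#' @export
enumerate_triplets <- function(target_map, genes_present, mirnas_present) {
  mirnas <- sort(intersect(names(target_map), mirnas_present))
  parts <- lapply(mirnas, function(m) {
    tg <- sort(unique(intersect(target_map[[m]], genes_present)))
    n <- length(tg)
    if (n < 2L) return(NULL)
    # vectorized unordered pairs of a sorted vector: i < j by construction
    i <- rep.int(seq_len(n - 1L), rev(seq_len(n - 1L)))
    j <- sequence(rev(seq_len(n - 1L))) + i
    data.frame(gene_i = tg[i], gene_j = tg[j], mirna = m,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) {
    out <- data.frame(gene_i = character(0), gene_j = character(0),
                      mirna = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "unique_pairs") <-
    length(unique(paste(out$gene_i, out$gene_j, sep = "\r")))
  out
}

#' Write a triplet table as TSV
#' @param triplets data.frame from [enumerate_triplets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_triplets <- function(triplets, path) {
  utils::write.table(triplets, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
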