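#' Read a feature-by-sample expression matrix
#'
#' Parses a tab-separated expression table with a header row of sample IDs
#' and a first column of feature IDs. Values are continuous expression on
#' whatever scale the file provides (log2-scale level-3 array values are the
#' typical input); the scale is not enforced.
#'
#' @param path Path to a TSV file. First header field names the feature
#'   column, remaining header fields are sample IDs.
#' @param missing_token String marking a missing cell (default `"NA"`).
#'   Matching cells become `NA` in the returned matrix.
#' @return A numeric matrix (features x samples) with feature IDs as row
#'   names and sample IDs as column names, both in file order.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("feature\tS1\tS2", "G1\t1.5\t2.0", "G2\t0.1\tNA"), f)
#' m <- read_expression_matrix(f)
#' dim(m)
#' @export
read_expression_matrix <- function(path, missing_token = "NA") {
  if (!file.exists(path)) stop("expression file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("expression file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  sample_ids <- header[-1L]
  if (length(sample_ids) < 1L) stop("expression file has no sample columns")
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) {
    stop("duplicated sample ID(s) in header: ", paste(unique(dup), collapse = ", "))
  }
  ncol_exp <- length(header)
  body <- fields[-1L]
  widths <- lengths(body)
  bad <- which(widths != ncol_exp)
  if (length(bad)) {
    stop("ragged row at line ", bad[1L] + 1L, ": expected ", ncol_exp,
         " fields, found ", widths[bad[1L]])
  }
  feature_ids <- vapply(body, `[[`, character(1L), 1L)
  dupf <- feature_ids[duplicated(feature_ids)]
  if (length(dupf)) {
    stop("duplicated feature ID(s): ", paste(unique(dupf), collapse = ", "))
  }
  cells <- unlist(lapply(body, `[`, -1L), use.names = FALSE)
  cells[cells == missing_token] <- NA_character_
  values <- suppressWarnings(as.numeric(cells))
  bad_cell <- which(is.na(values) & !is.na(cells))
  if (length(bad_cell)) {
    stop("non-numeric cell not matching missing_token: '",
         cells[bad_cell[1L]], "'")
  }
  mat <- matrix(values, nrow = length(body), ncol = ncol_exp - 1L,
                byrow = TRUE, dimnames = list(feature_ids, sample_ids))
  mat
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]: values are printed with 17
#' significant digits so a read/write round trip is lossless.
#'
#' @param mat Numeric matrix with feature row names and sample column names.
#' @param path Output file path.
#' @param feature_col Name of the first header field (default `"feature"`).
#' @param missing_token String written for `NA` cells (default `"NA"`).
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path, feature_col = "feature",
                                    missing_token = "NA") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  header <- paste(c(feature_col, colnames(mat)), collapse = "\t")
  rows <- vapply(seq_len(nrow(mat)), function(i) {
    v <- mat[i, ]
    cells <- ifelse(is.na(v), missing_token,
                    formatC(v, format = "g", digits = 17))
    paste(c(rownames(mat)[i], cells), collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

# CV with a total rule at degenerate means: a probe flat at zero is
# maximally uninformative (CV 0); a varying probe centred on zero is
# maximally variable (CV +Inf) so it can still be chosen deterministically.
coefficient_of_variation <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(0)
  m <- mean(x)
  s <- stats::sd(x)
  if (abs(m) < .Machine$double.eps) {
    if (s > 0) Inf else 0
  } else {
    s / abs(m)
  }
}

#' Collapse multi-probe features to one row per gene
#'
#' For genes measured by several probes, keeps the probe with the largest
#' coefficient of variation (sd/|mean|) across all samples, computed on the
#' values as provided; ties are broken by the lexicographically smaller
#' probe ID. Probes absent from `probe_to_gene` are dropped with a message.
#'
#' @param mat Expression matrix with probe row names.
#' @param probe_to_gene Named character vector mapping probe ID (name) to
#'   gene symbol (value).
#' @return Expression matrix with one row per gene, rows named by gene.
#' @export
collapse_probes <- function(mat, probe_to_gene) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  probes <- rownames(mat)
  mapped <- probes[probes %in% names(probe_to_gene)]
  n_drop <- length(probes) - length(mapped)
  if (n_drop > 0L) message(n_drop, " unmapped probe(s) dropped")
  if (!length(mapped)) stop("no probe maps to a gene; output would be empty")
  genes <- probe_to_gene[mapped]
  cv <- apply(mat[mapped, , drop = FALSE], 1L, coefficient_of_variation)
  ord <- order(genes, -cv, mapped)   # per gene: highest CV, then lexicographic probe
  keep <- mapped[ord][!duplicated(genes[ord])]
  out <- mat[keep, , drop = FALSE]
  rownames(out) <- probe_to_gene[keep]
  out[order(rownames(out)), , drop = FALSE]
}

#' Read a miRNA-to-target-gene prediction table
#'
#' Expects a two-column TSV (miRNA ID, gene symbol) in the TargetScan-style
#' layout distributed via miRSystem; an optional header row such as
#' `mirna<TAB>gene` is auto-detected and skipped. IDs are taken verbatim.
#'
#' @param path Path to the two-column TSV.
#' @return Named list: one character vector of unique target genes per miRNA.
#' @export
read_target_map <- function(path) {
  if (!file.exists(path)) stop("target map file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("target map file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  f1 <- tolower(trimws(vapply(fields, `[`, character(1L), 1L)[1L]))
  f2 <- if (length(fields[[1L]]) >= 2L) tolower(trimws(fields[[1L]][2L])) else ""
  if (f1 %in% c("mirna", "mir", "mirna_id") &&
      f2 %in% c("gene", "target", "gene_symbol", "target_gene")) {
    fields <- fields[-1L]
  }
  ok <- vapply(fields, function(f) length(f) >= 2L && nzchar(f[1L]) && nzchar(f[2L]),
               logical(1L))
  n_skip <- sum(!ok)
  if (n_skip > 0L) message(n_skip, " malformed target-map row(s) skipped")
  fields <- fields[ok]
  if (!length(fields)) stop("target map has no usable rows: ", path)
  mirna <- vapply(fields, `[`, character(1L), 1L)
  gene <- vapply(fields, `[`, character(1L), 2L)
  lapply(split(gene, mirna), function(g) unique(g))
}

#' Read a clinical table (sample, time, event)
#'
#' @param path TSV with columns `sample`, `time_months`, `event`
#'   (1 = death observed, 0 = censored).
#' @return data.frame with one row per sample.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  cl <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "time_months", "event")
  miss <- setdiff(need, names(cl))
  if (length(miss)) stop("clinical table missing column(s): ",
                         paste(miss, collapse = ", "))
  validate_clinical(cl)
  cl[need]
}

validate_clinical <- function(cl) {
  if (anyDuplicated(cl$sample)) stop("duplicated sample in clinical table")
  if (!all(is.finite(cl$time_months)) || any(cl$time_months < 0)) {
    stop("clinical time_months must be finite and nonnegative")
  }
  if (!all(cl$event %in% c(0L, 1L))) stop("clinical event must be 0 or 1")
  invisible(cl)
}
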