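#' Discretize a continuous vector for plug-in MI estimation
#'
#' Equal-frequency binning assigns contiguous rank blocks whose counts
#' differ by at most one (ties broken by original index, so the assignment
#' is deterministic); equal-width binning cuts the observed range into
#' equally wide intervals. A constant vector maps entirely to bin 1, so
#' conditioning on it is a no-op.
#'
#' @param x Numeric vector.
#' @param n_bins Number of bins (>= 2; default 8).
#' @param strategy `"equal_frequency"` (default) or `"equal_width"`.
#' @return Integer vector of bin indices in 1..n_bins.
#' @export
discretize <- function(x, n_bins = 8L,
                       strategy = c("equal_frequency", "equal_width")) {
  strategy <- match.arg(strategy)
  stopifnot(n_bins >= 2L)
  n <- length(x)
  ux <- unique(x)
  # already-categorical data (<= n_bins distinct values) is taken as is:
  # rank-splitting ties across bins would corrupt the joint table
  if (length(ux) <= n_bins) return(match(x, sort(ux)))
  if (strategy == "equal_frequency") {
    bounds <- round(seq(0, n, length.out = n_bins + 1L))
    bins <- integer(n)
    bins[order(x)] <- rep.int(seq_len(n_bins), diff(bounds))
    bins
  } else {
    brk <- seq(min(x), max(x), length.out = n_bins + 1L)
    brk[1L] <- brk[1L] - 1e-9
    as.integer(cut(x, brk))
  }
}

entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Plug-in mutual information of two continuous vectors
#'
#' Both vectors are discretized and the maximum-likelihood (plug-in) MI of
#' the joint table is returned in bits. Symmetric and nonnegative; a
#' constant input yields 0.
#'
#' @param x,y Numeric vectors of equal length (>= 10).
#' @param n_bins,strategy Passed to [discretize()].
#' @return MI in bits.
#' @export
mutual_information <- function(x, y, n_bins = 8L,
                               strategy = "equal_frequency") {
  stopifnot(length(x) == length(y))
  if (length(x) < 10L) stop("need at least 10 samples for MI estimation")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    message("constant vector: MI = 0")
    return(0)
  }
  bx <- discretize(x, n_bins, strategy)
  by <- discretize(y, n_bins, strategy)
  hx <- entropy_bits(tabulate(bx, n_bins))
  hy <- entropy_bits(tabulate(by, n_bins))
  hxy <- entropy_bits(tabulate(bx + n_bins * (by - 1L), n_bins^2))
  max(hx + hy - hxy, 0)
}

#' Plug-in conditional mutual information CMI(x; y | z)
#'
#' Estimated from the discretized triple as
#' H(x,z) + H(y,z) - H(z) - H(x,y,z), in bits. Conditioning on a constant
#' reduces exactly to [mutual_information()].
#'
#' @param x,y,z Numeric vectors of equal length.
#' @param n_bins,strategy Passed to [discretize()].
#' @return CMI in bits (nonnegative).
#' @export
conditional_mi <- function(x, y, z, n_bins = 8L,
                           strategy = "equal_frequency") {
  stopifnot(length(x) == length(y), length(y) == length(z))
  if (length(x) < 10L) stop("need at least 10 samples for CMI estimation")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    message("constant vector: CMI = 0")
    return(0)
  }
  bx <- discretize(x, n_bins, strategy)
  by <- discretize(y, n_bins, strategy)
  bz <- discretize(z, n_bins, strategy)
  nb <- n_bins
  hz <- entropy_bits(tabulate(bz, nb))
  hxz <- entropy_bits(tabulate(bx + nb * (bz - 1L), nb^2))
  hyz <- entropy_bits(tabulate(by + nb * (bz - 1L), nb^2))
  hxyz <- entropy_bits(tabulate(bx + nb * (by - 1L) + nb^2 * (bz - 1L), nb^3))
  max(hxz + hyz - hz - hxyz, 0)
}

#' Stratified-MI (SMI) interaction score
#'
#' The per-stratum t-domain correlation of the interaction score is
#' replaced by the per-stratum MI of the ce-pair; since MI is nonnegative
#' the score reduces to max(per-stratum MI) - min(per-stratum MI).
#'
#' @param x_i,x_j Named expression vectors of the ce-pair.
#' @param part A `group_partition` over the bridging miRNA.
#' @param n_bins,strategy Passed to [discretize()].
#' @return SMI score (>= 0).
#' @export
smi_score <- function(x_i, x_j, part, n_bins = 8L,
                      strategy = "equal_frequency") {
  stopifnot(inherits(part, "group_partition"))
  mi <- vapply(part$strata, function(s) {
    mutual_information(x_i[s], x_j[s], n_bins, strategy)
  }, numeric(1L))
  max(mi) - min(mi)
}

#' Conditional-MI (CMI) interaction score
#'
#' Tests the improvement of the miRNA-ceRNA dependence given the partner
#' ceRNA: CMI(i; m | j) - MI(i; m). May be negative.
#'
#' @param x_i,x_j Expression vectors of the ce-pair (i is the tested gene,
#'   j the conditioning partner).
#' @param mirna Expression vector of the bridging miRNA.
#' @param n_bins,strategy Passed to [discretize()].
#' @return CMI score.
#' @export
cmi_score <- function(x_i, x_j, mirna, n_bins = 8L,
                      strategy = "equal_frequency") {
  conditional_mi(x_i, mirna, x_j, n_bins, strategy) -
    mutual_information(x_i, mirna, n_bins, strategy)
}

#' Permutation P-value for an MI-based score
#'
#' Permutes the sample labels of gene j only - the minimal scheme that
#' breaks the i-j and j-m coupling while preserving the tested i-m margin -
#' and recomputes the score. The add-one estimator
#' P = (1 + #\{permuted >= observed\}) / (n_perm + 1) avoids zero P-values
#' at finite permutation counts, giving a precision floor of
#' 1/(n_perm + 1).
#'
#' @param score_fn Function of `(x_i, x_j)` returning the score (capture
#'   the miRNA vector / partition and binning options in its closure).
#' @param x_i,x_j Expression vectors; `x_j` is the permuted one.
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param seed Optional RNG seed.
#' @return P-value with attributes `observed` and `n_perm`.
#' @export
permutation_pvalue <- function(score_fn, x_i, x_j, n_perm = 1000L,
                               seed = NULL) {
  stopifnot(n_perm >= 100L)
  if (!is.null(seed)) set.seed(seed)
  obs <- score_fn(x_i, x_j)
  n <- length(x_j)
  ge <- 0L
  for (b in seq_len(n_perm)) {
    xp <- x_j[sample.int(n)]
    names(xp) <- names(x_j)
    if (score_fn(x_i, xp) >= obs) ge <- ge + 1L
  }
  p <- (1 + ge) / (n_perm + 1)
  attr(p, "observed") <- obs
  attr(p, "n_perm") <- n_perm
  p
}
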