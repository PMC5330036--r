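# Independent direct-formula oracles used to cross-check the package's
# implementations. These deliberately avoid the code paths (and the
# packages) the implementations call.

# Log-rank chi-square by direct observed-minus-expected summation over
# distinct event times.
oracle_logrank_chi2 <- function(time, event, grp) {
  stopifnot(length(time) == length(event), length(event) == length(grp))
  ev_times <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (tt in ev_times) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & grp)
    e1 <- n1 * d / n
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o_minus_e)^2 / v
}

# Kaplan-Meier product-limit curve evaluated at the distinct event times.
oracle_km <- function(time, event) {
  ev_times <- sort(unique(time[event == 1]))
  surv <- numeric(length(ev_times))
  s <- 1
  for (i in seq_along(ev_times)) {
    tt <- ev_times[i]
    n <- sum(time >= tt)
    d <- sum(time == tt & event == 1)
    s <- s * (1 - d / n)
    surv[i] <- s
  }
  data.frame(time = ev_times, surv = surv)
}

# Plug-in MI (bits) by direct summation over the cells of a joint count
# matrix.
oracle_mi_from_table <- function(counts) {
  n <- sum(counts)
  p <- counts / n
  px <- rowSums(p)
  py <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
    }
  }
  s
}

# Plug-in CMI (bits) by direct summation over a 3-d joint count array
# (dims: x, y, z).
oracle_cmi_from_array <- function(counts) {
  n <- sum(counts)
  s <- 0
  for (kz in seq_len(dim(counts)[3])) {
    slab <- counts[, , kz]
    pz <- sum(slab) / n
    if (pz > 0) s <- s + pz * oracle_mi_from_table(slab)
  }
  s
}

# One-sided (greater) Fisher's exact P by exhaustive hypergeometric
# enumeration with choose(); table rows (a, b) / (c, d).
oracle_fisher_greater <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- choose(r1, xs) * choose(n - r1, c1 - xs) / choose(n, c1)
  sum(probs[xs >= a])
}

# Analytic zero mass of the null interaction score for k iid symmetric
# continuous variates: P(all nonpositive) + P(the minimum-magnitude
# coordinate is the only positive one) = 2^-k + 2^-k.
oracle_zero_mass <- function(k) 2^(1 - k)

# Named expression vector / matrix builders.
make_named <- function(x, prefix = "S") {
  stats::setNames(x, sprintf("%s%04d", prefix, seq_along(x)))
}

make_expr <- function(values, genes, samples) {
  matrix(values, length(genes), length(samples),
         dimnames = list(genes, samples))
}

# Small shared null table (lazy, built once per test run).
shared_null_table <- local({
  tab <- NULL
  function(df = 148L, k = 3L, n_draws = 2e5, seed = 77L) {
    key <- paste(df, k, n_draws, seed)
    if (is.null(tab) || !identical(attr(tab, "key"), key)) {
      tab <<- build_null_table(df, k, n_draws, seed)
      attr(tab, "key") <<- key
    }
    tab
  }
})
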