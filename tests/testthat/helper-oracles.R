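# Independent oracles used across the suite.  These re-derive expected
# values by brute force / closed form, never by calling the code paths
# they check.

# Upper-tail hypergeometric probability P(X >= k) by direct summation of
# binomial-coefficient ratios over the support.
hyper_tail_oracle <- function(k, K, n, N) {
  j <- max(k, max(0L, n + K - N)):min(n, K)
  if (k > min(n, K)) return(0)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# Naive Benjamini-Hochberg step-up: m * p_(i) / i with a running minimum
# from the largest p downwards, mapped back to input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- m * p[o] / seq_len(m)
  for (i in rev(seq_len(m - 1))) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

# Exact two-sided Mann-Whitney p by exhaustive enumeration of all
# C(na+nb, na) group assignments: the fraction of assignments whose U
# statistic is at least as far from its null mean as the observed one.
mw_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  na <- length(x); nb <- length(y)
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  center <- na * nb / 2
  obs <- abs(u_stat(x, y) - center)
  combos <- utils::combn(na + nb, na)
  us <- apply(combos, 2, function(idx)
    u_stat(pooled[idx], pooled[-idx]))
  mean(abs(us - center) >= obs - 1e-12)
}

# Welch's unpaired t-test recomputed from group summary statistics.
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t_stat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * pt(-abs(t_stat), df)
}

# Naive agglomerative clustering for a handful of items (single /
# complete / average linkage), returning successive merge heights.
naive_linkage_heights <- function(mat, method = "single") {
  d <- as.matrix(dist(mat))
  clusters <- as.list(seq_len(nrow(mat)))
  heights <- numeric(0)
  link <- switch(method, single = min, complete = max,
                 average = mean)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      h <- link(d[clusters[[i]], clusters[[j]], drop = FALSE])
      if (h < best[1]) best <- c(h, j, i)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# A small valid spectral-count table with known group sums.
make_id_records <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    accession = rep(sprintf("P%03d", seq_len(n)), 2),
    description = "x",
    gene = rep(sprintf("G%03d", seq_len(n)), 2),
    group = rep(c("VPG", "CG"), each = n),
    n_peptides = sample(1:6, 2 * n, replace = TRUE),
    min_peptide_score = round(runif(2 * n, 10, 60), 1),
    spectral_count = rpois(2 * n, 8))
}
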