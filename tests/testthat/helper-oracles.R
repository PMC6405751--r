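# Independent oracles, deliberately naive implementations.

# classical tie-free Spearman formula
rho_formula <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# brute-force BH step-up on the sorted vector
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(p[o][i:m] * m / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# exhaustive Floyd-Warshall shortest paths
fw_distances <- function(panel, edges) {
  n <- length(panel)
  d <- matrix(Inf, n, n, dimnames = list(panel, panel))
  diag(d) <- 0
  for (k in seq_len(nrow(edges))) {
    d[edges$taxon_a[k], edges$taxon_b[k]] <- 1
    d[edges$taxon_b[k], edges$taxon_a[k]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

oracle_path_metrics <- function(net) {
  d <- fw_distances(net$panel, net$edges)
  ut <- d[upper.tri(d)]
  geo <- if (any(is.finite(ut))) mean(ut[is.finite(ut)]) else NA_real_
  inv <- 1 / ut
  inv[!is.finite(inv)] <- 0
  list(geodesic = geo, efficiency = mean(inv))
}
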