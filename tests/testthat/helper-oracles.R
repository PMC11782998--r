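# Brute-force oracles, kept independent of the implementation paths
# they check.

# Benjamini-Hochberg step-up by direct definition:
# q_(i) = min_{j >= i} min(1, n p_(j) / j), in the order of sorted p.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) {
    q[i] <- min(1, min(n * ps[i:n] / (i:n)))
  }
  out <- numeric(n)
  out[o] <- q
  out
}

# Upper-tail hypergeometric P(X >= k) by enumerating every n-subset of
# a universe of size N containing K marked items.
hyper_oracle <- function(k, K, N, n) {
  if (k <= 0) return(1)
  items <- seq_len(N)
  marked <- seq_len(K)
  combos <- utils::combn(items, n)
  hits <- apply(combos, 2, function(cc) sum(cc %in% marked) >= k)
  mean(hits)
}

# Exact two-sided rank-sum p by enumerating all assignments of ranks
# to group A (no ties assumed). U statistic as in wilcox.test.
wilcox_oracle <- function(a, b) {
  m <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(length(pooled), m)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

# Gaussian-peak chromatogram constructed directly (no simulator), for
# end-to-end quantitation checks.
gaussian_trace <- function(area, rt = 1.6, sigma = 0.02,
                           times = seq(1.2, 2.0, by = 0.002)) {
  amp <- area / (sigma * sqrt(2 * pi))
  data.frame(time = times, intensity = amp * exp(-(times - rt)^2 / (2 * sigma^2)))
}

# mean silhouette width of a 2-group labelling on a score matrix
silhouette_mean <- function(scores, labels) {
  d <- as.matrix(dist(scores))
  s <- vapply(seq_len(nrow(scores)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(d)) != i])
    b <- mean(d[i, !own])
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
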