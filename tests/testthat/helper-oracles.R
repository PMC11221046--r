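# Naive reference implementations and fixture builders used across tests.
# These stay deliberately loop-based and independent of the package's
# vectorized code paths.

naive_similarity <- function(g, gamma2) {
  m <- nrow(g)
  s <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      s[i, j] <- exp(-sum((g[i, ] - g[j, ])^2) / (2 * gamma2))
    }
  }
  s
}

naive_tom <- function(s) {
  m <- nrow(s)
  a <- matrix(0, m, m)
  k <- numeric(m)
  for (i in seq_len(m)) k[i] <- sum(s[i, -i])
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(m)) {
        if (u != i && u != j) l <- l + s[i, u] * s[u, j]
      }
      a[i, j] <- (l + s[i, j]) / (min(k[i], k[j]) + 1 - s[i, j])
    }
  }
  a
}

brute_conductance <- function(a, labels, cl) {
  m <- nrow(a)
  cut <- 0
  vol <- 0
  for (u in seq_len(m)) {
    if (labels[u] != cl) next
    for (v in seq_len(m)) {
      vol <- vol + a[u, v]
      if (labels[v] != cl) cut <- cut + a[u, v]
    }
  }
  cut / vol
}

# exact hypergeometric tail by explicit binomial-coefficient sums;
# choose() values are exact in doubles for N <= 40
hyper_tail_oracle <- function(x, K, N, n, direction) {
  lo <- max(0L, n + K - N)
  hi <- min(n, K)
  supp <- lo:hi
  pmf <- choose(K, supp) * choose(N - K, n - supp) / choose(N, n)
  if (direction == "over") sum(pmf[supp >= x]) else sum(pmf[supp <= x])
}

# random symmetric similarity matrix with unit diagonal, entries in [0, 1]
random_similarity <- function(m) {
  s <- matrix(runif(m * m), m, m)
  s <- (s + t(s)) / 2
  diag(s) <- 1
  s
}

# weighted planted-partition adjacency: dense blocks, weak between-block
# weights, jittered so the spectrum is not exactly degenerate
planted_adjacency <- function(sizes, within = 0.9, between = 0.01,
                              jitter = 0.02) {
  m <- sum(sizes)
  labels <- rep(seq_along(sizes), sizes)
  a <- matrix(between, m, m) + matrix(runif(m * m, 0, jitter), m, m)
  same <- outer(labels, labels, "==")
  a[same] <- within + runif(sum(same), 0, jitter)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  rownames(a) <- colnames(a) <- sprintf("g%03d", seq_len(m))
  list(adjacency = a, labels = labels)
}

# c disconnected equal-size uniform-weight cliques
clique_adjacency <- function(n_cliques, size = 6L, weight = 1) {
  m <- n_cliques * size
  a <- matrix(0, m, m)
  for (b in seq_len(n_cliques)) {
    idx <- ((b - 1L) * size + 1L):(b * size)
    a[idx, idx] <- weight
  }
  diag(a) <- 0
  rownames(a) <- colnames(a) <- sprintf("g%03d", seq_len(m))
  a
}

# minimal spectrum object for candidate_ks arithmetic tests
fake_spectrum <- function(values) {
  structure(list(values = values, n_computed = length(values)),
            class = "coex_spectrum")
}

# minimal embedding object for clustering/classification tests
fake_embedding <- function(x, k = NULL, ids = sprintf("g%03d", seq_len(nrow(x)))) {
  structure(list(values = x, k = if (is.null(k)) ncol(x) %/% 2L else k,
                 gene_ids = ids),
            class = "coex_embedding")
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
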