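# Independent oracle implementations used by the tests. These deliberately
# avoid the package's code paths: explicit loops and textbook formulas.

# Pearson correlation of two vectors, by the sum formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# full correlation matrix by looping oracle_pearson over row pairs
oracle_cor_matrix <- function(rows) {
  n <- nrow(rows)
  C <- diag(0, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    C[i, j] <- oracle_pearson(rows[i, ], rows[j, ])
  C
}

# z-score a column with the sample-SD convention
oracle_zscore <- function(v) (v - mean(v)) / sqrt(sum((v - mean(v))^2) / (length(v) - 1))

# cosine similarity by explicit dot/norm
oracle_cosine <- function(a, b) sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))

# dense diffusion-map oracle: build the Markov operator P explicitly and
# eigendecompose it directly (nonsymmetric path), then apply the same
# lambda/(1-lambda) scaling contract
oracle_diffusion <- function(W, n_components, alpha = 0.5) {
  d <- rowSums(W)
  W1 <- W / outer(d^alpha, d^alpha)
  P <- W1 / rowSums(W1)
  e <- eigen(P)
  lam <- Re(e$values)
  ord <- order(-lam)
  lam <- lam[ord]
  V <- Re(e$vectors)[, ord, drop = FALSE]
  keep <- 2:(n_components + 1)
  lam <- lam[keep]
  V <- V[, keep, drop = FALSE]
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  emb <- sweep(V, 2, lam / (1 - lam), "*")
  list(embedding = emb, eigenvalues = lam)
}

# align column signs of A to B (both region x component)
sign_align <- function(A, B) {
  s <- sign(colSums(A * B)); s[s == 0] <- 1
  sweep(A, 2, s, "*")
}

# BH step-up adjusted values by direct enumeration of the definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  adj <- p[ord] * m / seq_len(m)
  # monotonicity: q_(i) = min_{j >= i} adj_(j)
  run <- rev(cummin(rev(adj)))
  q[ord] <- pmin(run, 1)
  q
}

# random symmetric connected affinity on n nodes (strictly positive edges
# with probability pe, plus a connecting ring)
random_affinity <- function(n, pe = 0.4) {
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- stats::runif(n * (n - 1) / 2) *
    (stats::runif(n * (n - 1) / 2) < pe)
  A <- A + t(A)
  for (i in seq_len(n)) {             # ring keeps the graph connected
    j <- if (i == n) 1 else i + 1
    A[i, j] <- A[j, i] <- max(A[i, j], 0.5 + stats::runif(1) / 2)
  }
  diag(A) <- 0
  A
}

# reduced-scale spec used by replicate simulations in the tests
test_spec <- function(seed, ...) {
  synthetic_spec(n_regions = 100, n_timepoints = 140, n_controls = 12,
                 n_patients = 12, n_genes = 150, n_signal_genes = 15,
                 seed = seed, ...)
}
TEST_DENSITY <- 0.15
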