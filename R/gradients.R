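#' Row-wise density sparsification of a connectivity matrix
#'
#' For every row, keeps the `ceiling(density * (N - 1))` largest off-diagonal
#' values (by signed value; strong negative correlations are therefore
#' dropped naturally) and zeroes the rest. Ties at the threshold are broken
#' by lower region index, for determinism. The result is generally
#' asymmetric.
#'
#' @param mat Square connectivity matrix (zero diagonal).
#' @param density Fraction of connections to retain per row, in (0, 1).
#'   Default 0.10 (the top 10% of each region's connections).
#' @return Matrix of the same shape with non-retained entries set to 0.
#' @examples
#' m <- fc_matrix(matrix(rnorm(11 * 40), 11, 40))
#' sp <- sparsify_rows(m, 0.10)   # exactly 1 retained entry per row
#' @export
sparsify_rows <- function(mat, density = 0.10) {
  mat <- as.matrix(unclass(mat))
  n <- nrow(mat)
  if (n != ncol(mat)) stop("matrix must be square")
  if (!(density > 0 && density < 1)) stop("density must lie in (0, 1)")
  k <- ceiling(density * (n - 1))
  if (k < 1) stop("invalid parameter: density retains fewer than 1 entry")
  out <- matrix(0, n, n, dimnames = dimnames(mat))
  for (i in seq_len(n)) {
    idx <- setdiff(seq_len(n), i)
    keep <- idx[order(-mat[i, idx], idx)][seq_len(k)]
    out[i, keep] <- mat[i, keep]
  }
  out
}

#' Cosine-similarity affinity between region connectivity profiles
#'
#' Entry (i, j) is the cosine of the angle between rows i and j of the
#' (sparsified) connectivity matrix, clipped below at 0 so the affinity is
#' nonnegative; diagonal zeroed.
#'
#' @param sparse_mat Row-sparsified connectivity matrix (no all-zero rows).
#' @return Symmetric affinity matrix with entries in \[0, 1\], zero diagonal.
#' @export
cosine_affinity <- function(sparse_mat) {
  M <- as.matrix(unclass(sparse_mat))
  nrm <- sqrt(rowSums(M^2))
  if (any(nrm == 0)) {
    bad <- which(nrm == 0)[1]
    nm <- if (!is.null(rownames(M))) rownames(M)[bad] else bad
    stop("region ", nm, " has an all-zero connectivity profile")
  }
  A <- tcrossprod(M) / tcrossprod(nrm)
  A[A < 0] <- 0
  A[A > 1] <- 1
  A <- (A + t(A)) / 2
  diag(A) <- 0
  A
}

# connected components of a nonnegative symmetric adjacency, by BFS
.graph_components <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(A[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

.new_gradient_set <- function(embedding, eigenvalues, variance_fraction,
                              aligned = FALSE, reference_id = NULL) {
  colnames(embedding) <- paste0("g", seq_len(ncol(embedding)))
  structure(list(embedding = embedding, eigenvalues = eigenvalues,
                 variance_fraction = variance_fraction, aligned = aligned,
                 reference_id = reference_id),
            class = "gradient_set")
}

#' @export
print.gradient_set <- function(x, ...) {
  cat("Gradient set:", nrow(x$embedding), "regions x",
      ncol(x$embedding), "components",
      if (isTRUE(x$aligned)) "(aligned)" else "(unaligned)", "\n")
  cat("  variance fractions:",
      paste(sprintf("%.3f", x$variance_fraction), collapse = " "), "\n")
  invisible(x)
}

#' Diffusion map embedding of an affinity matrix
#'
#' Applies the anisotropic normalization `W' = D^-alpha W D^-alpha` (D the
#' degree diagonal), forms the Markov operator `P` by row-normalizing `W'`,
#' and eigen-decomposes it. For numerical stability the decomposition is
#' carried out on the symmetric conjugate `S = D'^{-1/2} W' D'^{-1/2}` and the
#' eigenvectors are back-transformed; the spectrum of `P` is real and lies in
#' (-1, 1] with the trivial constant eigenvector at 1, which is dropped.
#' Gradient k is eigenvector k scaled by `lambda_k / (1 - lambda_k)` when
#' `diffusion_time = 0`, else by `lambda_k^diffusion_time`. The variance
#' fraction of gradient k is `lambda_k / sum(retained lambda)`.
#'
#' @param aff Symmetric nonnegative affinity matrix, zero diagonal,
#'   describing a connected graph.
#' @param n_components Number of nontrivial gradients to retain (>= 2).
#' @param alpha Anisotropic-diffusion exponent in \[0, 1\]; 0.5 discounts the
#'   sampling-density contribution to the operator. Default 0.5.
#' @param diffusion_time Diffusion time t; 0 selects the multiscale
#'   `lambda / (1 - lambda)` scaling.
#' @return A `gradient_set`: region x component embedding, nonincreasing
#'   eigenvalues, per-component variance fractions.
#' @export
diffusion_embed <- function(aff, n_components = 10, alpha = 0.5,
                            diffusion_time = 0) {
  W <- as.matrix(unclass(aff))
  n <- nrow(W)
  if (n != ncol(W) || max(abs(W - t(W))) > 1e-10)
    stop("affinity must be square and symmetric")
  if (any(W < 0)) stop("affinity must be nonnegative")
  if (n_components < 2) stop("n_components must be >= 2")
  comp <- .graph_components(W)
  if (max(comp) > 1)
    stop("affinity graph is disconnected; component sizes: ",
         paste(tabulate(comp), collapse = ", "))
  d <- rowSums(W)
  W1 <- W / outer(d^alpha, d^alpha)
  d1 <- rowSums(W1)
  S <- W1 / outer(sqrt(d1), sqrt(d1))
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lambda <- e$values
  vecs <- e$vectors / sqrt(d1)          # eigenvectors of P
  if (sum(abs(lambda) > 1e-12) < n_components + 1)
    stop("fewer than n_components + 1 nonzero eigenvalues")
  keep <- 2:(n_components + 1)          # drop trivial lambda = 1
  lam <- lambda[keep]
  V <- vecs[, keep, drop = FALSE]
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  # deterministic sign: largest-magnitude element positive
  for (j in seq_len(ncol(V))) {
    m <- which.max(abs(V[, j]))
    if (V[m, j] < 0) V[, j] <- -V[, j]
  }
  scalefac <- if (diffusion_time == 0) lam / (1 - lam) else lam^diffusion_time
  emb <- sweep(V, 2, scalefac, "*")
  rownames(emb) <- rownames(W)
  .new_gradient_set(emb, lam, lam / sum(lam))
}

#' Iterative Procrustes alignment of gradient embeddings
#'
#' Rotates each embedding (orthogonal transform after column centering; no
#' scaling) to the current reference in the least-squares sense, updates the
#' reference to the mean of the aligned embeddings, and repeats until the
#' reference changes by less than `tol` (mean squared change) or `n_iter`
#' iterations. Finally each aligned column's sign is fixed so it correlates
#' positively with the corresponding reference column.
#'
#' @param gradient_sets List of `gradient_set` objects sharing region and
#'   component counts.
#' @param reference A `gradient_set` (typically from [group_template()]).
#' @param n_iter Maximum iterations. Default 10.
#' @param tol Convergence tolerance on the reference update. Default 1e-8.
#' @return List of aligned `gradient_set`s (embeddings centered and rotated);
#'   the final consensus reference is attached as attribute `"reference"`.
#' @export
procrustes_align <- function(gradient_sets, reference, n_iter = 10,
                             tol = 1e-8) {
  stopifnot(length(gradient_sets) >= 1, inherits(reference, "gradient_set"))
  embs <- lapply(gradient_sets, function(g) {
    stopifnot(inherits(g, "gradient_set"))
    g$embedding
  })
  dims <- vapply(embs, dim, integer(2))
  if (any(dims[1, ] != nrow(reference$embedding)) ||
      any(dims[2, ] != ncol(reference$embedding)))
    stop("all embeddings must share the reference's region and component counts")
  center <- function(X) sweep(X, 2, colMeans(X))
  Xc <- lapply(embs, center)
  Rc <- center(reference$embedding)
  aligned <- Xc
  for (it in seq_len(n_iter)) {
    aligned <- lapply(Xc, function(X) {
      sv <- svd(crossprod(X, Rc))
      X %*% (sv$u %*% t(sv$v))
    })
    newR <- Reduce(`+`, aligned) / length(aligned)
    delta <- mean((newR - Rc)^2)
    Rc <- newR
    if (delta < tol) break
  }
  aligned <- lapply(aligned, function(A) {
    s <- sign(colSums(A * Rc))
    s[s == 0] <- 1
    sweep(A, 2, s, "*")
  })
  out <- Map(function(g, A) {
    colnames(A) <- colnames(g$embedding)
    rownames(A) <- rownames(g$embedding)
    g$embedding <- A
    g$aligned <- TRUE
    g$reference_id <- reference$reference_id %||% "group_template"
    g
  }, gradient_sets, aligned)
  ref_out <- reference
  ref_out$embedding <- Rc
  attr(out, "reference") <- ref_out
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Group-level template gradients from a set of connectivity matrices
#'
#' Element-wise mean connectivity over all subjects (both groups, so
#' alignment treats groups symmetrically), then sparsification, cosine
#' affinity, and diffusion map embedding. Used as the Procrustes reference.
#'
#' @param mats Nonempty list of connectivity matrices of equal dimension.
#' @param density,n_components,alpha,diffusion_time Passed to
#'   [sparsify_rows()] and [diffusion_embed()].
#' @return A `gradient_set` with `reference_id = "group_template"`.
#' @export
group_template <- function(mats, density = 0.10, n_components = 10,
                           alpha = 0.5, diffusion_time = 0) {
  if (length(mats) == 0) stop("need at least one connectivity matrix")
  dims <- vapply(mats, dim, integer(2))
  if (length(unique(dims[1, ])) != 1 || length(unique(dims[2, ])) != 1)
    stop("connectivity matrices must share dimensions")
  M <- Reduce(`+`, lapply(mats, function(m) as.matrix(unclass(m)))) /
    length(mats)
  g <- diffusion_embed(cosine_affinity(sparsify_rows(M, density)),
                       n_components = n_components, alpha = alpha,
                       diffusion_time = diffusion_time)
  g$reference_id <- "group_template"
  g
}
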