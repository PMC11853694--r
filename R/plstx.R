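.std_cols <- function(X, what = "gene") {
  s <- apply(X, 2, stats::sd)
  if (any(s == 0 | !is.finite(s))) {
    bad <- which(s == 0 | !is.finite(s))[1]
    nm <- if (!is.null(colnames(X))) colnames(X)[bad] else bad
    stop(what, " column ", nm, " has zero variance")
  }
  Xs <- scale(X)
  attr(Xs, "scaled:center") -> ctr
  attr(Xs, "scaled:scale") -> scl
  attr(Xs, "scaled:center") <- NULL
  attr(Xs, "scaled:scale") <- NULL
  list(X = Xs, center = ctr, scale = scl)
}

# deflation-based single-response PLS on pre-standardized X, y
.pls1_core <- function(Xs, ys, ncomp) {
  n <- nrow(Xs); p <- ncol(Xs)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp); qv <- numeric(ncomp); r2 <- numeric(ncomp)
  ssy <- sum(ys^2)
  Xd <- Xs; yd <- ys
  for (k in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw == 0) stop("rank collapse: X'y vanished at component ", k)
    w <- w / nw
    t <- drop(Xd %*% w)
    tt <- sum(t^2)
    if (tt == 0) stop("rank collapse: degenerate scores at component ", k)
    pl <- drop(crossprod(Xd, t)) / tt
    q <- sum(yd * t) / tt
    Xd <- Xd - tcrossprod(t, pl)
    yd <- yd - q * t
    W[, k] <- w; P[, k] <- pl; Tm[, k] <- t; qv[k] <- q
    r2[k] <- q^2 * tt / ssy
  }
  list(weights = W, x_loadings = P, scores = Tm, y_loadings = qv, r2 = r2)
}

#' Fit a single-response partial least squares model
#'
#' Sequential deflation-based PLS1 relating gene expression (predictors,
#' regions x genes) to a region map such as the group-difference z-map
#' (response). Predictor columns and the response are z-scored internally.
#' Each component's weight vector maximizes the covariance between the
#' X-scores and the current response residual; with a single response the
#' component-1 weight is, in closed form, the dominant eigenvector of
#' `X'y y'X` (i.e. proportional to `X'y`).
#'
#' @param X Numeric region x gene matrix (gene symbols as column names).
#' @param y Numeric region vector, or a z-map data frame from
#'   [zmap_from_t()] (its `z` column is used).
#' @param n_components Number of components. Default 2.
#' @return An object of class `pls_fit` with elements `x_weights` (gene x
#'   component, unit norm), `scores` (region x component), `y_loadings`,
#'   `r2_y` (per-component fraction of response variance explained),
#'   `cum_r2_y`, and the centering/scaling used.
#' @examples
#' X <- matrix(rnorm(40 * 6), 40, 6,
#'             dimnames = list(NULL, paste0("G", 1:6)))
#' y <- X[, 1] + rnorm(40, sd = 0.2)
#' fit <- pls_fit(X, y)
#' fit$cum_r2_y
#' @export
pls_fit <- function(X, y, n_components = 2) {
  X <- as.matrix(X)
  if (is.data.frame(y)) {
    if (!"z" %in% names(y)) stop("data-frame response must have a 'z' column")
    y <- y$z
  }
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("regions of X and y must match")
  if (nrow(X) < n_components + 2)
    stop("need at least n_components + 2 regions")
  if (stats::sd(y) == 0) stop("response has zero variance")
  sx <- .std_cols(X, "gene")
  ys <- as.numeric(scale(y))
  if (qr(sx$X)$rank < n_components)
    stop("rank of X is below n_components")
  core <- .pls1_core(sx$X, ys, n_components)
  genes <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  dimnames(core$weights) <- list(genes, paste0("comp", seq_len(n_components)))
  structure(list(
    n_components = n_components,
    x_weights = core$weights, x_loadings = core$x_loadings,
    scores = core$scores, y_loadings = core$y_loadings,
    r2_y = core$r2, cum_r2_y = cumsum(core$r2),
    genes = genes,
    x_center = sx$center, x_scale = sx$scale,
    y_center = mean(y), y_scale = stats::sd(y),
    y = y, call = match.call()
  ), class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, ...) {
  cat("PLS1 fit:", length(x$genes), "genes,", nrow(x$scores), "regions,",
      x$n_components, "components\n")
  cat("  response variance explained:",
      paste(sprintf("%.1f%%", 100 * x$r2_y), collapse = " + "),
      sprintf("= %.1f%% cumulative\n", 100 * max(x$cum_r2_y)))
  invisible(x)
}

#' @export
summary.pls_fit <- function(object, n_top = 5, ...) {
  print(object)
  for (k in seq_len(object$n_components)) {
    w <- object$x_weights[, k]
    top <- order(-abs(w))[seq_len(min(n_top, length(w)))]
    cat("  component", k, "top genes by |weight|:",
        paste(sprintf("%s (%.3f)", object$genes[top], w[top]),
              collapse = ", "), "\n")
  }
  invisible(object)
}

#' @export
coef.pls_fit <- function(object, ...) {
  # regression coefficients of the standardized response on standardized X
  W <- object$x_weights; P <- object$x_loadings; q <- object$y_loadings
  B <- W %*% solve(crossprod(P, W), q)
  stats::setNames(drop(B), object$genes)
}

#' @export
predict.pls_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  Xs <- sweep(sweep(as.matrix(newdata), 2, object$x_center), 2,
              object$x_scale, "/")
  drop(Xs %*% coef(object)) * object$y_scale + object$y_center
}

#' @export
fitted.pls_fit <- function(object, ...) {
  drop(object$scores %*% object$y_loadings) * object$y_scale +
    object$y_center
}

#' @export
residuals.pls_fit <- function(object, ...) object$y - fitted(object)

#' Correlation between PLS component score maps and the response map
#'
#' @param fit A [pls_fit()] object.
#' @param y Response map (numeric vector or z-map data frame).
#' @return Numeric vector of per-component Pearson r.
#' @export
score_map_correlation <- function(fit, y) {
  stopifnot(inherits(fit, "pls_fit"))
  if (is.data.frame(y)) y <- y$z
  drop(stats::cor(fit$scores, as.numeric(y)))
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt(p * sum_k SSY_k (w_jk / ||w_k||)^2 / sum_k SSY_k)` with
#' `p` the gene count and `SSY_k` the response variance explained by
#' component k. The squared VIPs average to 1 across genes; genes with
#' VIP > `threshold` are selected.
#'
#' @param fit A [pls_fit()] object.
#' @param threshold Selection threshold. Default 1.
#' @return List with `vip` (named numeric) and `selected` (character).
#' @export
vip_scores <- function(fit, threshold = 1) {
  stopifnot(inherits(fit, "pls_fit"))
  r2 <- fit$r2_y
  if (sum(r2) <= 0) stop("no response variance explained by any component")
  W <- fit$x_weights
  Wn <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  p <- nrow(W)
  vip <- sqrt(p * drop(Wn^2 %*% r2) / sum(r2))
  names(vip) <- fit$genes
  list(vip = vip, selected = fit$genes[vip > threshold])
}

# binned semivariogram: mean of 0.5 (y_i - y_j)^2 per distance bin; pair
# indices are pre-sorted by bin so evaluation is a single grouped sum
.variogram_bins <- function(coords, n_bins = 10) {
  D <- as.matrix(stats::dist(coords[, c("x", "y", "z")]))
  ut <- upper.tri(D)
  dvals <- D[ut]
  breaks <- seq(0, max(dvals), length.out = n_bins + 1)
  bin <- cut(dvals, breaks, include.lowest = TRUE, labels = FALSE)
  ij <- which(ut, arr.ind = TRUE)
  ord <- order(bin)
  counts <- tabulate(bin, nbins = n_bins)
  ends <- cumsum(counts)
  list(D = D, i = ij[ord, 1], j = ij[ord, 2], n_bins = n_bins,
       breaks = breaks, counts = counts, ends = ends)
}

.variogram_of <- function(v, vb) {
  sq <- 0.5 * (v[vb$i] - v[vb$j])^2
  cs <- c(0, cumsum(sq)[vb$ends])
  out <- diff(cs) / vb$counts
  out[vb$counts == 0] <- NA_real_
  out
}

#' Spatial-autocorrelation-preserving surrogate maps
#'
#' Each surrogate is a permutation of the source map's values, re-ordered by
#' rank-matching against a smoothed Gaussian random field (exponential
#' kernel over the region coordinates). The field's length scale is chosen
#' from a candidate grid, with one refinement pass, to minimize the relative
#' error between the surrogates' binned semivariogram (10 bins) and the
#' source map's, weighting short-distance bins more heavily (weights
#' proportional to 1/bin) since short-range smoothness is what drives
#' spurious map-to-map association; each surrogate is then re-drawn (up to
#' `max_tries` candidate fields) until its own binned variogram is within
#' `variogram_target` weighted relative error of the source's, keeping the
#' best candidate otherwise. The value multiset of every surrogate equals the
#' source's exactly. For a spatially unstructured source the selected length
#' scale collapses toward zero and the surrogates reduce to plain
#' permutations.
#'
#' @param y Source map (numeric vector or z-map data frame).
#' @param coords Region coordinates (`x`, `y`, `z` columns), same order as y.
#' @param n Number of surrogates (>= 1).
#' @param seed Integer seed.
#' @param n_bins Variogram bins. Default 10.
#' @param variogram_target Per-surrogate mean relative error target. Default
#'   0.10.
#' @param max_tries Candidate fields drawn per surrogate before keeping the
#'   best. Default 40.
#' @return `n` x regions matrix of class `surrogate_ensemble`, with
#'   attributes `length_scale`, `variogram_source`, `variogram_achieved`,
#'   and `variogram_error` (mean relative error over bins).
#' @export
surrogate_maps <- function(y, coords, n, seed = 1L, n_bins = 10,
                           variogram_target = 0.10, max_tries = 40) {
  if (is.data.frame(y)) y <- y$z
  y <- as.numeric(y)
  if (n < 1) stop("n must be >= 1")
  if (nrow(coords) != length(y)) stop("coords must cover all regions")
  vb <- .variogram_bins(coords, n_bins)
  v_src <- .variogram_of(y, vb)
  ok_bins <- which(!is.na(v_src) & v_src > 0)
  # short distances dominate a map's effective smoothness, and smoothness is
  # what drives spurious map-to-map association; weight the match accordingly
  wts <- 1 / seq_along(ok_bins)
  wts <- wts / sum(wts)
  werr <- function(vs) sum(wts * abs(vs[ok_bins] - v_src[ok_bins]) /
                             v_src[ok_bins])
  N <- length(y)
  ys <- sort(y)
  set.seed(as.integer(seed))
  gen <- function(L, m) {
    Z <- L %*% matrix(stats::rnorm(N * m), N, m)
    apply(Z, 2, function(z) ys[rank(z, ties.method = "first")])
  }
  score_ls <- function(ls, m = 15) {
    L <- if (ls <= 0) diag(N) else .sa_chol(coords, ls)
    S <- gen(L, m)
    vs <- rowMeans(apply(S, 2, .variogram_of, vb = vb))
    list(err = werr(vs), L = L)
  }
  dpos <- vb$D[upper.tri(vb$D)]
  grid <- c(0, stats::quantile(dpos, c(0.02, 0.05, 0.1, 0.2, 0.35, 0.6)),
            max(dpos))
  fits <- lapply(grid, score_ls)
  errs <- vapply(fits, `[[`, numeric(1), "err")
  b <- which.min(errs)
  # refine between the best candidate and its neighbours
  refine <- unique(c(
    if (b > 1) sqrt(max(grid[b - 1], 1e-3) * max(grid[b], 1e-3)),
    if (b < length(grid)) sqrt(max(grid[b], 1e-3) * grid[b + 1])))
  for (ls in refine) {
    f <- score_ls(ls)
    if (f$err < errs[b]) { fits[[b]] <- f; errs[b] <- f$err; grid[b] <- ls }
  }
  best <- fits[[which.min(errs)]]
  # per-surrogate iterative re-ordering: redraw the field until the
  # rank-matched permutation's variogram is close enough to the source's
  gen_one <- function() {
    kept <- NULL; kept_err <- Inf
    for (i in seq_len(max_tries)) {
      z <- best$L %*% stats::rnorm(N)
      s <- ys[rank(z, ties.method = "first")]
      e <- werr(.variogram_of(s, vb))
      if (e < kept_err) { kept_err <- e; kept <- s }
      if (e <= variogram_target) break
    }
    kept
  }
  S <- t(vapply(seq_len(n), function(i) gen_one(), numeric(N)))
  v_ach <- colMeans(t(apply(S, 1, .variogram_of, vb = vb)))
  structure(S,
            length_scale = grid[which.min(errs)],
            variogram_source = v_src,
            variogram_achieved = v_ach,
            variogram_error = mean(abs(v_ach[ok_bins] - v_src[ok_bins]) /
                                     v_src[ok_bins]),
            method = "variogram_matched_permutation",
            class = c("surrogate_ensemble", "matrix", "array"))
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat("Surrogate ensemble:", nrow(x), "maps x", ncol(x), "regions",
      sprintf("(length scale %.2f, variogram error %.1f%%)\n",
              attr(x, "length_scale"), 100 * attr(x, "variogram_error")))
  invisible(x)
}

#' Spatial-autocorrelation-corrected permutation test for PLS components
#'
#' Tests whether the cumulative response variance explained by each PLS
#' component exceeds chance, against a null of surrogate response maps that
#' preserve the observed map's values and spatial autocorrelation. P-values
#' use the add-one rule and are never 0.
#'
#' @param X Region x gene expression matrix.
#' @param y Response map (numeric or z-map data frame).
#' @param coords Region coordinates.
#' @param n_components PLS components. Default 2.
#' @param n_perm Number of surrogates. Default 1000.
#' @param seed Integer seed.
#' @return List with `perm_p` (per component), `observed_cum_r2`, and
#'   `null_cum_r2` (n_perm x components).
#' @export
sa_permutation_test <- function(X, y, coords, n_components = 2,
                                n_perm = 1000, seed = 1L) {
  X <- as.matrix(X)
  if (is.data.frame(y)) y <- y$z
  fit <- pls_fit(X, y, n_components)
  obs <- fit$cum_r2_y
  S <- surrogate_maps(y, coords, n_perm, seed = seed)
  Xs <- .std_cols(X)$X
  null_r2 <- t(apply(S, 1, function(yp) {
    cumsum(.pls1_core(Xs, as.numeric(scale(yp)), n_components)$r2)
  }))
  perm_p <- vapply(seq_len(n_components), function(k)
    (1 + sum(null_r2[, k] >= obs[k])) / (n_perm + 1), numeric(1))
  list(perm_p = perm_p, observed_cum_r2 = obs, null_cum_r2 = null_r2)
}

#' Bootstrap-corrected PLS gene weights
#'
#' Regions are resampled with replacement, the PLS refitted, and each
#' replicate's weights sign-aligned to the original fit per component (dot
#' product rule; PLS weights are sign-indeterminate across refits). The
#' corrected weight is the original weight divided by its bootstrap standard
#' error; genes are ranked per component by descending corrected weight.
#' Degenerate resamples (rank collapse or zero-variance columns) are dropped;
#' more than 10% dropped is an error, as is a zero bootstrap SE.
#'
#' @param X Region x gene expression matrix.
#' @param y Response map.
#' @param n_components PLS components. Default 2.
#' @param n_boot Bootstrap replicates. Default 1000.
#' @param seed Integer seed.
#' @param resample Resampling function `function(n)` returning indices; the
#'   default draws `n` indices with replacement. Exposed for testing.
#' @return List with `weights` (original), `se`, `boot_z` (gene x
#'   component), `ranking` (list of gene vectors, descending boot_z per
#'   component), and `n_dropped`.
#' @export
bootstrap_gene_weights <- function(X, y, n_components = 2, n_boot = 1000,
                                   seed = 1L,
                                   resample = function(n)
                                     sample.int(n, replace = TRUE)) {
  X <- as.matrix(X)
  if (is.data.frame(y)) y <- y$z
  y <- as.numeric(y)
  fit <- pls_fit(X, y, n_components)
  W0 <- fit$x_weights
  n <- nrow(X)
  set.seed(as.integer(seed))
  acc <- array(NA_real_, c(nrow(W0), n_components, n_boot))
  dropped <- 0L
  for (b in seq_len(n_boot)) {
    idx <- resample(n)
    Xb <- X[idx, , drop = FALSE]
    yb <- y[idx]
    Wb <- tryCatch({
      if (any(apply(Xb, 2, stats::sd) == 0) || stats::sd(yb) == 0)
        stop("degenerate resample")
      .pls1_core(.std_cols(Xb)$X, as.numeric(scale(yb)),
                 n_components)$weights
    }, error = function(e) NULL)
    if (is.null(Wb)) { dropped <- dropped + 1L; next }
    s <- sign(colSums(Wb * W0)); s[s == 0] <- 1
    acc[, , b] <- sweep(Wb, 2, s, "*")
  }
  if (dropped > 0.10 * n_boot)
    stop("more than 10% of bootstrap resamples were degenerate (",
         dropped, "/", n_boot, ")")
  if (dropped > 0)
    message(dropped, " degenerate bootstrap resample(s) dropped")
  se <- apply(acc, c(1, 2), stats::sd, na.rm = TRUE)
  if (any(se == 0))
    stop("bootstrap SE is zero for at least one gene weight")
  boot_z <- W0 / se
  dimnames(boot_z) <- dimnames(W0)
  ranking <- lapply(seq_len(n_components), function(k)
    fit$genes[order(-boot_z[, k])])
  names(ranking) <- colnames(W0)
  list(weights = W0, se = se, boot_z = boot_z, ranking = ranking,
       n_dropped = dropped)
}
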