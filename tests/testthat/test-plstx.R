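test_that("pls fit matches the closed-form eigen oracle on a fixture", {
  X <- matrix(c(
    0.5, 1.2, -0.3,
    -1.1, 0.4, 0.8,
    0.9, -0.7, 0.2,
    0.1, 0.6, -1.4,
    -0.8, -1.3, 0.5,
    1.3, 0.2, 0.9,
    -0.4, 0.8, -0.6,
    0.2, -1.1, 0.3), nrow = 8, byrow = TRUE,
    dimnames = list(NULL, c("gA", "gB", "gC")))
  y <- c(0.7, -1.2, 0.9, -0.1, -1.0, 1.5, -0.3, 0.1)
  fit <- pls_fit(X, y, n_components = 2)

  # first weight = dominant eigenvector of X'y y'X on the standardized data
  Xs <- scale(X); ys <- as.numeric(scale(y))
  M <- crossprod(Xs, ys) %*% t(crossprod(Xs, ys))
  ev <- eigen(M, symmetric = TRUE)$vectors[, 1]
  ev <- ev * sign(sum(ev * fit$x_weights[, 1]))
  expect_lt(max(abs(fit$x_weights[, 1] - ev)), 1e-8)

  # component-1 r2 equals the squared correlation of scores with y
  expect_equal(fit$r2_y[1], cor(fit$scores[, 1], y)^2, tolerance = 1e-10)
  expect_true(all(diff(fit$cum_r2_y) >= -1e-12))
  expect_lte(max(fit$cum_r2_y), 1 + 1e-9)
})

test_that("pls reaches r2 = 1 on its own gene and 0 on an orthogonal response", {
  set.seed(11)
  x <- rnorm(30)
  fitX <- pls_fit(cbind(g1 = x), x, n_components = 1)
  expect_equal(fitX$r2_y[1], 1.0, tolerance = 1e-10)
  expect_equal(score_map_correlation(fitX, x)[1], 1.0, tolerance = 1e-8)

  X <- matrix(rnorm(30 * 3), 30, 3)
  y0 <- rnorm(30)
  Xs <- scale(X)
  y_orth <- y0 - Xs %*% solve(crossprod(Xs), crossprod(Xs, y0))
  y_orth <- y_orth - mean(y_orth)
  fitO <- pls_fit(X, as.numeric(y_orth), n_components = 2)
  expect_lt(fitO$r2_y[1], 1e-10)
})

test_that("pls model methods are mutually consistent", {
  set.seed(12)
  X <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("g", 1:6)))
  y <- X[, 1] - 0.5 * X[, 3] + rnorm(40, sd = 0.3)
  fit <- pls_fit(X, y, n_components = 2)
  expect_equal(predict(fit, X), fitted(fit), tolerance = 1e-8)
  expect_equal(residuals(fit), y - fitted(fit), tolerance = 1e-10)
  expect_named(coef(fit), paste0("g", 1:6))
  expect_output(print(fit), "PLS1 fit")
  # sign-flipped response flips score-map correlations
  fit2 <- pls_fit(X, -y, n_components = 2)
  expect_equal(score_map_correlation(fit2, -y),
               -score_map_correlation(fit2, y), tolerance = 1e-12)
  expect_error(pls_fit(X[, c(1, 1)], y), "rank")
})

test_that("VIP satisfies the sum rule, the single-gene identity, and the formula", {
  set.seed(13)
  X <- matrix(rnorm(25 * 7), 25, 7, dimnames = list(NULL, paste0("g", 1:7)))
  y <- X %*% rnorm(7) + rnorm(25)
  fit <- pls_fit(X, as.numeric(y), n_components = 2)
  v <- vip_scores(fit)
  expect_equal(sum(v$vip^2), 7, tolerance = 1e-6)

  # a single gene has VIP exactly 1
  xs <- rnorm(15)
  expect_equal(unname(vip_scores(
    pls_fit(cbind(solo = xs), xs + rnorm(15), n_components = 1))$vip), 1)

  x1 <- rnorm(20)
  fit1 <- pls_fit(cbind(only = x1, pad = rnorm(20)), x1, n_components = 2)
  # by-hand evaluation of the VIP formula from the fitted quantities
  W <- fit1$x_weights; r2 <- fit1$r2_y
  hand <- sqrt(2 * (W[, 1]^2 / sum(W[, 1]^2) * r2[1] +
                    W[, 2]^2 / sum(W[, 2]^2) * r2[2]) / sum(r2))
  expect_equal(unname(vip_scores(fit1)$vip), unname(hand), tolerance = 1e-10)
})

test_that("surrogates preserve the value multiset and the variogram", {
  spec <- synthetic_spec(n_regions = 100, seed = 21)
  coords <- region_coords(spec)
  L <- gradientscope:::.sa_chol(coords, spec$sa_length_scale)
  set.seed(33)
  y <- as.numeric(L %*% rnorm(100))
  S <- surrogate_maps(y, coords, n = 1000, seed = 2)
  expect_true(all(apply(S[1:50, ], 1, function(s)
    identical(sort(s), sort(y)))))
  # mean binned variogram of the ensemble within 20% of the source's (the
  # operation's contract); individual bins may deviate more, sanity-bounded
  expect_lt(attr(S, "variogram_error"), 0.20)
  v_src <- attr(S, "variogram_source")
  v_ach <- attr(S, "variogram_achieved")
  ok <- v_src > 0
  expect_lt(max(abs(v_ach[ok] - v_src[ok]) / v_src[ok]), 0.5)
})

test_that("an unstructured map yields surrogates close to plain permutations", {
  spec <- synthetic_spec(n_regions = 80, seed = 22)
  coords <- region_coords(spec)
  set.seed(44)
  y <- rnorm(80)                       # i.i.d.: flat variogram
  S <- surrogate_maps(y, coords, n = 200, seed = 3)
  v <- attr(S, "variogram_achieved")
  expect_lt(diff(range(v)) / mean(v), 0.35)   # flat achieved variogram
  expect_error(surrogate_maps(y, coords, n = 0), "n must be")
})

test_that("sa permutation p-values use the add-one rule and detect planted signal", {
  spec <- synthetic_spec(n_regions = 100, n_genes = 60, n_signal_genes = 10,
                         signal_beta = 3, seed = 23)
  coords <- region_coords(spec)
  map <- latent_axis(spec, "control")
  ex <- simulate_expression(spec, map)
  res <- sa_permutation_test(ex$expression, map, coords, n_perm = 100,
                             seed = 5)
  expect_true(all(res$perm_p > 0 & res$perm_p <= 1))
  expect_lte(res$perm_p[1], 0.02)      # strong planted association
  expect_equal(dim(res$null_cum_r2), c(100L, 2L))
  # invariance to monotone rescaling of y (z-scoring absorbs it)
  res2 <- sa_permutation_test(ex$expression, 10 * map + 3, coords,
                              n_perm = 100, seed = 5)
  expect_equal(res2$perm_p, res$perm_p)
  expect_equal(res2$observed_cum_r2, res$observed_cum_r2, tolerance = 1e-10)
})

test_that("bootstrap weights recover planted genes and handle degeneracy", {
  spec <- synthetic_spec(n_regions = 100, n_genes = 60, n_signal_genes = 10,
                         signal_beta = 2, seed = 24)
  map <- latent_axis(spec, "control")
  ex <- simulate_expression(spec, map)
  bw <- bootstrap_gene_weights(ex$expression, map, n_boot = 300, seed = 6)
  top <- names(sort(abs(bw$boot_z[, 1]), decreasing = TRUE))[1:10]
  expect_gte(mean(top %in% ex$signal_genes), 0.8)
  expect_equal(dim(bw$boot_z), c(60L, 2L))

  # flipping y flips weight signs but not the |boot_z| ranking
  bw2 <- bootstrap_gene_weights(ex$expression, -map, n_boot = 300, seed = 6)
  expect_equal(unname(bw2$weights), unname(-bw$weights), tolerance = 1e-10)
  expect_identical(order(-abs(bw2$boot_z[, 1])), order(-abs(bw$boot_z[, 1])))

  # a constant resampler gives zero bootstrap SE, which is an error
  expect_error(
    bootstrap_gene_weights(ex$expression, map, n_boot = 20, seed = 7,
                           resample = function(n) seq_len(n)),
    "SE is zero")
})
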