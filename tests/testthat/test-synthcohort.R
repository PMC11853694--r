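test_that("partition splits regions into near-equal contiguous blocks", {
  p <- make_partition(synthetic_spec(n_regions = 14, n_networks = 7))
  expect_true(all(table(p$network_label) == 2))

  p400 <- make_partition(synthetic_spec(n_regions = 400, n_networks = 7))
  sizes <- as.integer(table(p400$network_label))
  expect_true(all(sizes %in% c(57L, 58L)))
  expect_identical(sum(sizes), 400L)
  # contiguity: region ids of each network form a run
  for (lab in levels(p400$network_label)) {
    ids <- p400$region_id[p400$network_label == lab]
    expect_identical(ids, seq(min(ids), max(ids)))
  }

  # one region per network violates the >= 2 regions-per-label invariant
  expect_error(make_partition(synthetic_spec(n_regions = 7, n_networks = 7)),
               "fewer than 2 regions")
})

test_that("spec validation rejects out-of-range parameters", {
  expect_error(synthetic_spec(n_networks = 9, n_regions = 8), "exceeds")
  expect_error(synthetic_spec(gradient_compression = 0), "compression")
  expect_error(synthetic_spec(gradient_compression = 1.2), "compression")
  expect_error(synthetic_spec(n_signal_genes = 30, n_genes = 20),
               "n_signal_genes")
  expect_error(synthetic_spec(sa_length_scale = 0), "sa_length_scale")
  expect_error(synthetic_spec(n_timepoints = 1), "counts")
  expect_error(simulate_timeseries_cohort(
    local({s <- synthetic_spec(); s$n_timepoints <- 2L; s})),
    "n_timepoints")
})

test_that("cohort simulation is bit-identical for a fixed spec", {
  spec <- synthetic_spec(n_regions = 21, n_timepoints = 30, n_controls = 3,
                         n_patients = 3, seed = 42)
  a <- simulate_timeseries_cohort(spec)
  b <- simulate_timeseries_cohort(spec)
  expect_identical(a, b)
  ma <- simulate_morphometry_cohort(spec)
  mb <- simulate_morphometry_cohort(spec)
  expect_identical(ma, mb)
  ea <- simulate_expression(spec, a$true_diff_map)
  eb <- simulate_expression(spec, a$true_diff_map)
  expect_identical(ea, eb)
})

test_that("sample correlations converge to the closed-form population law", {
  spec <- synthetic_spec(n_regions = 21, n_timepoints = 5000, n_controls = 2,
                         n_patients = 2, noise_sd = 1e-6, seed = 5)
  coh <- simulate_timeseries_cohort(spec)
  # closed form computed independently of the package internals
  g <- seq(-1, 1, length.out = 21)
  part <- make_partition(spec)
  same <- outer(part$network_label, part$network_label, "==")
  R <- spec$corr_base * exp(-abs(outer(g, g, "-")) / spec$corr_length) +
    spec$corr_network * same
  diag(R) <- 1
  C <- cor(t(coh$series[[1]]))
  expect_lt(max(abs(C - R)), 0.08)    # entrywise, n = 5000 sampling error
})

test_that("patient latent axis is compressed and shifted by construction", {
  spec <- synthetic_spec(n_regions = 70, gradient_compression = 0.6,
                         network_shift = c(limbic = 0.3))
  g_con <- latent_axis(spec, "control")
  g_pat <- latent_axis(spec, "patient")
  expect_equal(diff(range(g_con)) * 0.6,
               diff(range(g_pat - spec$network_shift[
                 as.character(make_partition(spec)$network_label)])))
  part <- make_partition(spec)
  lim <- part$network_label == "limbic"
  expect_equal(g_pat[lim], g_con[lim] * 0.6 + 0.3)
  expect_equal(g_pat[!lim], g_con[!lim] * 0.6)
})

test_that("morphometry is a deterministic latent map in the noise-free limit", {
  spec <- synthetic_spec(n_regions = 21, n_controls = 3, n_patients = 3,
                         noise_sd = 0, seed = 9)
  mor <- simulate_morphometry_cohort(spec)
  # without noise all same-group subjects share the exact feature table
  expect_identical(mor$features[["con001"]], mor$features[["con002"]])
  expect_identical(mor$features[["pat001"]], mor$features[["pat002"]])
  expect_identical(dim(mor$features[[1]]), c(21L, 5L))
})

test_that("strong planted genes rank top by correlation with the true map", {
  spec <- synthetic_spec(n_regions = 60, n_genes = 40, n_signal_genes = 5,
                         signal_beta = 5, noise_sd = 0.1, seed = 3)
  map <- latent_axis(spec, "control")
  ex <- simulate_expression(spec, map)
  cors <- abs(cor(ex$expression, map))
  top <- colnames(ex$expression)[order(-cors)][1:5]
  expect_setequal(top, ex$signal_genes)
  # columns are z-scored across regions
  expect_lt(max(abs(colMeans(ex$expression))), 1e-12)
  expect_lt(max(abs(apply(ex$expression, 2, sd) - 1)), 1e-12)
})

test_that("a lone signal gene tracks the map in the noise-free limit", {
  # smallest admissible gene count with one planted signal gene
  spec <- synthetic_spec(n_regions = 60, n_genes = 2, n_signal_genes = 1,
                         signal_beta = 1, noise_sd = 1e-8, seed = 3)
  map <- latent_axis(spec, "control")
  ex <- simulate_expression(spec, map)
  expect_gt(abs(cor(ex$expression[, ex$signal_genes], map)), 0.999)
})

test_that("null expression genes carry no preferential map association", {
  spec <- synthetic_spec(n_regions = 100, n_genes = 150, n_signal_genes = 15,
                         signal_beta = 0, seed = 8)
  map <- latent_axis(spec, "control")
  ex <- simulate_expression(spec, map)
  cors <- abs(cor(ex$expression, map))
  sig <- colnames(ex$expression) %in% ex$signal_genes
  # with beta = 0 "signal" genes are indistinguishable from the rest
  expect_lt(abs(mean(cors[sig]) - mean(cors[!sig])), 0.15)
})

test_that("gene sets contain the signal pathway and round-trip through GMT", {
  universe <- sprintf("G%04d", 1:60)
  sig <- universe[c(3, 17, 41)]
  one <- make_gene_sets(sig, universe, n_sets = 1, set_size = 10, seed = 1)
  expect_identical(names(one), "signal_pathway")
  expect_true(all(sig %in% one[[1]]))

  sets <- make_gene_sets(sig, universe, n_sets = 50, set_size = 20, seed = 2)
  expect_length(sets, 50)
  expect_true(all(vapply(sets, function(s)
    length(unique(s)) == 20, logical(1))))

  path <- tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_identical(lapply(back, sort), lapply(sets, sort))

  expect_error(make_gene_sets(sig, universe, set_size = 2), "set_size")
})

test_that("region coordinates are finite and monotone in latent distance", {
  spec <- synthetic_spec(n_regions = 50)
  co <- region_coords(spec)
  expect_true(all(is.finite(as.matrix(co[, c("x", "y", "z")]))))
  D <- as.matrix(dist(co[, c("x", "y", "z")]))
  # distance from region 1 increases with latent separation
  expect_true(all(diff(D[1, ]) > 0))
})
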