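#' Canonical seven-network labels
#'
#' Network labels used by the synthetic parcellation, ordered along the
#' unimodal-to-transmodal latent axis (visual at one end, default mode at the
#' other).
#'
#' @format Character vector of length 7.
#' @export
YEO7_LABELS <- c("visual", "sensorimotor", "dorsal_attention",
                 "ventral_attention", "limbic", "frontoparietal",
                 "default_mode")

#' Specification of a synthetic cohort
#'
#' Collects every knob of the synthetic-cohort generator: cohort layout
#' (regions, networks, timepoints, group sizes), the group effect on the
#' latent connectivity axis (compression factor and per-network shifts),
#' the population connectivity law, measurement noise, and the transcriptomic
#' component (gene counts, planted association strength, spatial
#' autocorrelation range). All downstream simulators take a `synthetic_spec`
#' so that a cohort is fully reproducible from the spec alone.
#'
#' @param n_regions Number of cortical regions (parcels). Default 400.
#' @param n_networks Number of networks partitioning the regions. Default 7.
#' @param n_timepoints Number of timepoints per functional series. Default 140
#'   (a 150-volume resting-state run with the first 10 volumes discarded).
#' @param n_controls,n_patients Group sizes. Defaults 74 and 72.
#' @param gradient_compression Factor in (0, 1] multiplying the patient-group
#'   latent axis; 1 means no compression.
#' @param network_shift Named numeric vector of additive offsets applied to
#'   the patient-group latent axis per network label; unnamed networks get 0.
#' @param noise_sd Positive measurement-noise standard deviation, shared by
#'   the time-series, morphometry and expression generators.
#' @param corr_base,corr_network,corr_length Parameters of the population
#'   correlation law `corr(i, j) = corr_base * exp(-|g_i - g_j| / corr_length)
#'   + corr_network * [same network]` on the latent axis g in [-1, 1].
#'   `corr_base + corr_network < 1` keeps the matrix positive definite by
#'   construction; larger values fall back to a nearest-PSD projection.
#' @param n_genes,n_signal_genes Total genes and planted signal genes.
#' @param signal_beta Association strength of signal genes with the true
#'   group-difference map (in units of the standardized map).
#' @param sa_length_scale Spatial-autocorrelation range (exponential kernel)
#'   of the expression noise field, in coordinate units.
#' @param seed Integer seed; expanded into per-component substreams.
#'
#' @return An object of class `synthetic_spec`.
#' @examples
#' spec <- synthetic_spec(n_regions = 70, n_controls = 10, n_patients = 10)
#' spec$n_regions
#' @export
synthetic_spec <- function(n_regions = 400, n_networks = 7,
                           n_timepoints = 140,
                           n_controls = 74, n_patients = 72,
                           gradient_compression = 1,
                           network_shift = NULL,
                           noise_sd = 0.8,
                           corr_base = 0.65, corr_network = 0.05,
                           corr_length = 0.8,
                           n_genes = 200, n_signal_genes = 20,
                           signal_beta = 2,
                           sa_length_scale = 20,
                           seed = 1L) {
  counts <- c(n_regions = n_regions, n_networks = n_networks,
              n_timepoints = n_timepoints, n_controls = n_controls,
              n_patients = n_patients, n_genes = n_genes)
  if (n_signal_genes < 1 || n_signal_genes != round(n_signal_genes))
    stop("n_signal_genes must be an integer >= 1")
  if (any(counts < 2) || any(counts != round(counts)))
    stop("all counts must be integers >= 2; offending: ",
         paste(names(counts)[counts < 2 | counts != round(counts)],
               collapse = ", "))
  if (n_networks > n_regions)
    stop("invalid spec: n_networks (", n_networks,
         ") exceeds n_regions (", n_regions, ")")
  if (!(gradient_compression > 0 && gradient_compression <= 1))
    stop("gradient_compression must lie in (0, 1]")
  if (n_signal_genes > n_genes)
    stop("invalid spec: n_signal_genes > n_genes")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (sa_length_scale <= 0) stop("invalid spec: sa_length_scale must be > 0")
  if (corr_base <= 0 || corr_network < 0 || corr_length <= 0)
    stop("population correlation parameters must be positive")
  labels <- if (n_networks == 7) YEO7_LABELS else
    paste0("network", seq_len(n_networks))
  shift <- stats::setNames(rep(0, n_networks), labels)
  if (!is.null(network_shift)) {
    if (is.null(names(network_shift)) ||
        !all(names(network_shift) %in% labels))
      stop("network_shift must be named with valid network labels")
    shift[names(network_shift)] <- network_shift
  }
  structure(list(
    n_regions = as.integer(n_regions), n_networks = as.integer(n_networks),
    n_timepoints = as.integer(n_timepoints),
    n_controls = as.integer(n_controls), n_patients = as.integer(n_patients),
    gradient_compression = gradient_compression,
    network_shift = shift, noise_sd = noise_sd,
    corr_base = corr_base, corr_network = corr_network,
    corr_length = corr_length,
    n_genes = as.integer(n_genes),
    n_signal_genes = as.integer(n_signal_genes),
    signal_beta = signal_beta, sa_length_scale = sa_length_scale,
    seed = as.integer(seed), labels = labels
  ), class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("Synthetic cohort spec:", x$n_regions, "regions /", x$n_networks,
      "networks,", x$n_controls, "controls vs", x$n_patients, "patients\n")
  cat("  timepoints:", x$n_timepoints, " noise_sd:", x$noise_sd,
      " compression:", x$gradient_compression, "\n")
  cat("  genes:", x$n_genes, "(", x$n_signal_genes, "signal, beta =",
      x$signal_beta, ")  SA length scale:", x$sa_length_scale, "\n")
  invisible(x)
}

# deterministic substream seeds: one global seed, fixed per-component offsets
.substream <- function(spec, component) {
  offsets <- c(timeseries = 11L, morphometry = 23L, expression = 37L,
               genesets = 53L)
  s <- (abs(spec$seed) + offsets[[component]] * 9973L) %% 2147483647L
  as.integer(s)
}

#' Partition regions into contiguous network blocks
#'
#' Assigns regions to networks as contiguous blocks along the latent axis,
#' with block sizes differing by at most one (e.g. 400 regions over 7
#' networks gives block sizes 57 or 58). Every network must receive at least
#' two regions.
#'
#' @param spec A [synthetic_spec()].
#' @return A data frame with columns `region_id` (0-based) and
#'   `network_label` (factor over the spec's labels).
#' @examples
#' p <- make_partition(synthetic_spec(n_regions = 14, n_networks = 7))
#' table(p$network_label)
#' @export
make_partition <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_regions; k <- spec$n_networks
  base <- n %/% k
  if (base < 2)
    stop("invalid spec: partition would give a network fewer than 2 regions")
  sizes <- rep(base, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- base + 1L
  data.frame(
    region_id = 0:(n - 1L),
    network_label = factor(rep(spec$labels, times = sizes),
                           levels = spec$labels)
  )
}

#' Latent unimodal-to-transmodal axis of a spec
#'
#' Regions are placed evenly on \[-1, 1\], ordered with the partition so the
#' visual end sits at -1 and the default-mode end at +1.
#'
#' @param spec A [synthetic_spec()].
#' @param group `"control"` (identity axis) or `"patient"` (axis multiplied by
#'   `gradient_compression` plus the per-network `network_shift`).
#' @return Numeric vector of length `n_regions`.
#' @export
latent_axis <- function(spec, group = c("control", "patient")) {
  group <- match.arg(group)
  g <- seq(-1, 1, length.out = spec$n_regions)
  if (group == "patient") {
    part <- make_partition(spec)
    g <- g * spec$gradient_compression +
      spec$network_shift[as.character(part$network_label)]
  }
  unname(g)
}

#' Region centroid coordinates
#'
#' Places regions on a one-dimensional arc in 3-D (radius 50, arbitrary
#' units) so that Euclidean distance is monotone in latent-axis distance.
#' Used only for spatial-autocorrelation modelling of expression noise and
#' surrogate maps.
#'
#' @param spec A [synthetic_spec()].
#' @return Data frame with columns `region_id`, `x`, `y`, `z`.
#' @export
region_coords <- function(spec) {
  g <- seq(-1, 1, length.out = spec$n_regions)
  theta <- g * (pi / 2)          # arc spans half a circle: chord monotone
  r <- 50
  data.frame(region_id = 0:(spec$n_regions - 1L),
             x = r * cos(theta), y = r * sin(theta), z = 0)
}

# population region-by-region correlation for a latent axis
.population_corr <- function(g, part, spec) {
  same <- outer(part$network_label, part$network_label, "==")
  R <- spec$corr_base * exp(-abs(outer(g, g, "-")) / spec$corr_length) +
    spec$corr_network * same
  diag(R) <- 1
  if (spec$corr_base + spec$corr_network >= 1) R <- nearest_psd_corr(R)
  R
}

#' Project a symmetric matrix to the nearest valid correlation matrix
#'
#' Eigenvalue clipping at a small floor followed by rescaling to unit
#' diagonal. Fallback used when a parameterised population correlation is
#' not positive definite by construction.
#'
#' @param R Symmetric matrix with unit diagonal.
#' @param eps Eigenvalue floor.
#' @return A positive-definite correlation matrix.
#' @export
nearest_psd_corr <- function(R, eps = 1e-8) {
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  R2 <- e$vectors %*% (vals * t(e$vectors))
  stats::cov2cor(R2)
}

#' Simulate a two-group functional time-series cohort
#'
#' Each region carries a latent coordinate on the unimodal-to-transmodal
#' axis; the population region-pair correlation decays exponentially with
#' latent distance, plus a within-network elevation. The patient group's
#' axis is compressed by `gradient_compression` and offset per network by
#' `network_shift`. Subject series are multivariate Gaussian draws from
#' `(R + noise_sd^2 I) / (1 + noise_sd^2)`, so the noise-free limit recovers
#' the population correlation exactly. No temporal autocorrelation is
#' modelled: the downstream gradients depend only on the correlation
#' structure.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `series` (named list of region x timepoint
#'   matrices), `manifest` (data frame: `subject_id`, `group`), `partition`,
#'   `latent` (list `control`, `patient`), and `true_network_diff` (named
#'   per-network control-minus-patient mean latent difference).
#' @examples
#' coh <- simulate_timeseries_cohort(
#'   synthetic_spec(n_regions = 21, n_timepoints = 30,
#'                  n_controls = 3, n_patients = 3))
#' dim(coh$series[[1]])
#' @export
simulate_timeseries_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_timepoints < 3)
    stop("invalid spec: n_timepoints must be >= 3")
  part <- make_partition(spec)
  g_con <- latent_axis(spec, "control")
  g_pat <- latent_axis(spec, "patient")
  mix <- function(R) (R + spec$noise_sd^2 * diag(nrow(R))) /
    (1 + spec$noise_sd^2)
  L_con <- chol(mix(.population_corr(g_con, part, spec)))
  L_pat <- chol(mix(.population_corr(g_pat, part, spec)))
  ids <- c(sprintf("con%03d", seq_len(spec$n_controls)),
           sprintf("pat%03d", seq_len(spec$n_patients)))
  groups <- rep(c("control", "patient"),
                c(spec$n_controls, spec$n_patients))
  set.seed(.substream(spec, "timeseries"))
  series <- vector("list", length(ids))
  names(series) <- ids
  for (s in seq_along(ids)) {
    Z <- matrix(stats::rnorm(spec$n_regions * spec$n_timepoints),
                spec$n_regions, spec$n_timepoints)
    L <- if (groups[s] == "control") L_con else L_pat
    X <- crossprod(L, Z)           # rows = regions, cols = timepoints
    rownames(X) <- part$region_id
    series[[s]] <- X
  }
  diff_map <- g_con - g_pat
  true_net <- tapply(diff_map, part$network_label, mean)
  list(series = series,
       manifest = data.frame(subject_id = ids, group = groups),
       partition = part,
       latent = list(control = g_con, patient = g_pat),
       true_diff_map = diff_map,
       true_network_diff = true_net)
}

# fixed 5 x 2 loadings of the morphometric features (GM volume, cortical
# thickness, surface area, intrinsic curvature, mean curvature) on the two
# latent structural axes
.MORPH_LOADINGS <- matrix(c(
   1.0,  0.3,
   0.8, -0.5,
   0.6,  0.9,
  -0.7,  0.6,
  -0.9, -0.4), nrow = 5, byrow = TRUE,
  dimnames = list(c("gm_volume", "cortical_thickness", "surface_area",
                    "intrinsic_curvature", "mean_curvature"), NULL))

#' Simulate a two-group morphometric cohort
#'
#' Each region carries a two-dimensional latent structural profile (the
#' unimodal-to-transmodal axis and a second smooth axis); five features are
#' generated as fixed loadings on that profile plus Gaussian noise, so
#' regions close on the latent axis have similar feature vectors. A group
#' effect can be planted per network by shifting the patient-group latent
#' coordinate.
#'
#' @param spec A [synthetic_spec()].
#' @param network_shift Optional named vector of patient-group latent shifts
#'   per network; defaults to the spec's `network_shift`.
#' @return List with `features` (named list of region x 5 matrices),
#'   `manifest`, and `partition`.
#' @export
simulate_morphometry_cohort <- function(spec, network_shift = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  part <- make_partition(spec)
  g <- seq(-1, 1, length.out = spec$n_regions)
  shift <- spec$network_shift
  if (!is.null(network_shift)) {
    if (is.null(names(network_shift)) ||
        !all(names(network_shift) %in% spec$labels))
      stop("network_shift must be named with valid network labels")
    shift[] <- 0
    shift[names(network_shift)] <- network_shift
  }
  g_pat <- g * spec$gradient_compression +
    shift[as.character(part$network_label)]
  second <- sin(pi * g)                 # second smooth structural axis
  prof_con <- cbind(g, second)
  prof_pat <- cbind(g_pat, sin(pi * g_pat))
  ids <- c(sprintf("con%03d", seq_len(spec$n_controls)),
           sprintf("pat%03d", seq_len(spec$n_patients)))
  groups <- rep(c("control", "patient"),
                c(spec$n_controls, spec$n_patients))
  set.seed(.substream(spec, "morphometry"))
  feats <- vector("list", length(ids))
  names(feats) <- ids
  for (s in seq_along(ids)) {
    prof <- if (groups[s] == "control") prof_con else prof_pat
    F <- prof %*% t(.MORPH_LOADINGS) +
      spec$noise_sd * matrix(stats::rnorm(spec$n_regions * 5),
                             spec$n_regions, 5)
    dimnames(F) <- list(part$region_id, rownames(.MORPH_LOADINGS))
    feats[[s]] <- F
  }
  list(features = feats,
       manifest = data.frame(subject_id = ids, group = groups),
       partition = part)
}

# lower-triangular factor of the exponential SA kernel over region coords
.sa_chol <- function(coords, length_scale) {
  D <- as.matrix(stats::dist(coords[, c("x", "y", "z")]))
  K <- exp(-D / length_scale)
  t(chol(K + 1e-8 * diag(nrow(K))))
}

#' Simulate spatially autocorrelated gene expression
#'
#' Signal genes follow `signal_beta * standardized(true_diff_map)` plus a
#' spatially autocorrelated Gaussian noise field (exponential kernel over the
#' region coordinates, marginal SD `noise_sd`); non-signal genes are pure SA
#' noise. Columns are z-scored across regions.
#'
#' @param spec A [synthetic_spec()].
#' @param true_diff_map Numeric region vector the signal genes track
#'   (typically `true_diff_map` or the group-difference z-map of a simulated
#'   cohort).
#' @param coords Optional region coordinates; default [region_coords()].
#' @return List with `expression` (region x gene matrix, gene symbols as
#'   column names), `signal_genes` (character), and `coords`.
#' @export
simulate_expression <- function(spec, true_diff_map,
                                coords = region_coords(spec)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (length(true_diff_map) != spec$n_regions)
    stop("true_diff_map must have length n_regions")
  if (spec$sa_length_scale <= 0)
    stop("invalid spec: sa_length_scale must be > 0")
  n <- spec$n_regions
  m <- spec$n_genes
  map <- if (stats::sd(true_diff_map) > 0)
    as.numeric(scale(true_diff_map)) else rep(0, n)
  L <- .sa_chol(coords, spec$sa_length_scale)
  set.seed(.substream(spec, "expression"))
  noise <- L %*% matrix(stats::rnorm(n * m), n, m) * spec$noise_sd
  E <- noise
  sig <- seq_len(spec$n_signal_genes)
  E[, sig] <- E[, sig] + spec$signal_beta * map
  genes <- sprintf("G%04d", seq_len(m))
  # shuffle columns so signal genes are not positionally identifiable
  ord <- sample.int(m)
  E <- E[, ord, drop = FALSE]
  signal_genes <- genes[match(sig, ord)]
  colnames(E) <- genes
  rownames(E) <- 0:(n - 1L)
  E <- scale(E)
  attr(E, "scaled:center") <- NULL
  attr(E, "scaled:scale") <- NULL
  list(expression = E, signal_genes = signal_genes, coords = coords)
}

#' Build synthetic gene sets around a planted signal pathway
#'
#' The first set ("signal_pathway") contains all signal genes, padded with
#' random other genes up to `set_size`; remaining sets are random draws from
#' the universe.
#'
#' @param signal_genes Character vector of signal gene symbols.
#' @param universe All gene symbols.
#' @param n_sets Number of sets.
#' @param set_size Genes per set; must be at least `length(signal_genes)`
#'   and at most `length(universe)`.
#' @param seed Integer seed.
#' @return Named list of character vectors (a gene-set collection).
#' @export
make_gene_sets <- function(signal_genes, universe, n_sets = 50,
                           set_size = 20, seed = 1L) {
  if (!all(signal_genes %in% universe))
    stop("signal genes must be contained in the universe")
  if (set_size > length(universe) || set_size < length(signal_genes))
    stop("invalid spec: set_size must satisfy length(signal_genes) <= ",
         "set_size <= length(universe)")
  if (n_sets < 1) stop("n_sets must be >= 1")
  set.seed(as.integer(seed))
  pad <- sample(setdiff(universe, signal_genes),
                set_size - length(signal_genes))
  sets <- vector("list", n_sets)
  sets[[1]] <- c(signal_genes, pad)
  if (n_sets > 1)
    for (i in 2:n_sets) sets[[i]] <- sample(universe, set_size)
  names(sets) <- c("signal_pathway",
                   if (n_sets > 1) sprintf("random_set_%02d", 2:n_sets))
  sets
}
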