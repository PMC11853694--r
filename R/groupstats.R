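#' Per-subject network-average gradient scores
#'
#' For each subject, network and gradient, the unweighted mean of the
#' gradient values over the network's member regions.
#'
#' @param gradient_sets Named list of aligned `gradient_set`s (names are
#'   subject ids).
#' @param partition Data frame with `region_id` and `network_label` covering
#'   all regions.
#' @param manifest Data frame with `subject_id` and `group`.
#' @param gradients Integer vector of gradient indices to score. Default 1:2.
#' @return Long data frame: `subject_id`, `group`, `network_label`,
#'   `gradient`, `score`.
#' @export
network_scores <- function(gradient_sets, partition, manifest,
                           gradients = 1:2) {
  stopifnot(all(names(gradient_sets) %in% manifest$subject_id))
  labs <- levels(factor(partition$network_label))
  n_regions <- nrow(gradient_sets[[1]]$embedding)
  if (nrow(partition) != n_regions)
    stop("partition must cover all regions")
  rows <- list()
  for (sid in names(gradient_sets)) {
    emb <- gradient_sets[[sid]]$embedding
    if (max(gradients) > ncol(emb)) stop("gradient index out of range")
    grp <- manifest$group[match(sid, manifest$subject_id)]
    for (k in gradients) {
      sc <- tapply(emb[, k], partition$network_label, mean)
      if (anyNA(sc)) stop("label absent from partition: ",
                          paste(names(sc)[is.na(sc)], collapse = ", "))
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = sid, group = grp, network_label = names(sc),
        gradient = k, score = as.numeric(sc))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pooled two-sample Student t-test
#'
#' Pooled-variance t with `df = n1 + n2 - 2`, oriented control minus patient
#' (first argument minus second); two-sided p.
#'
#' @param control_scores,patient_scores Numeric vectors, each of length >= 2.
#' @return List with `t`, `p`, `df`.
#' @examples
#' two_sample_t(c(1, 2, 3), c(4, 5, 6))   # t = -3.674, df = 4
#' @export
two_sample_t <- function(control_scores, patient_scores) {
  x <- control_scores; y <- patient_scores
  if (length(x) < 2 || length(y) < 2) stop("each group needs n >= 2")
  if (!all(is.finite(c(x, y)))) stop("scores must be finite")
  n1 <- length(x); n2 <- length(y)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
  if (sp2 == 0) stop("zero pooled variance")
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values with monotonicity enforcement; `q` lies in
#' \[p, 1\].
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))   # all 0.04
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Cohen's d with pooled standard deviation
#'
#' `d = (mean(control) - mean(patient)) / s_pooled`, with the
#' df-weighted pooled SD.
#'
#' @param control_scores,patient_scores Numeric vectors, each n >= 2.
#' @return Numeric effect size.
#' @examples
#' cohens_d(c(1, 2, 3), c(4, 5, 6))   # -3
#' @export
cohens_d <- function(control_scores, patient_scores) {
  x <- control_scores; y <- patient_scores
  if (length(x) < 2 || length(y) < 2) stop("each group needs n >= 2")
  df <- length(x) + length(y) - 2
  sp <- sqrt(((length(x) - 1) * stats::var(x) +
              (length(y) - 1) * stats::var(y)) / df)
  if (sp == 0) stop("zero pooled SD")
  (mean(x) - mean(y)) / sp
}

#' Analytic power of the two-sided pooled two-sample t-test
#'
#' Noncentrality `delta = |d| * sqrt(n1 * n2 / (n1 + n2))`,
#' `df = n1 + n2 - 2`; power is the probability that |T| exceeds the
#' two-sided critical value under the noncentral t distribution.
#'
#' @param d Cohen's d (standardized mean difference).
#' @param n1,n2 Group sizes (>= 2).
#' @param alpha Two-sided significance level in (0, 1). Default 0.05.
#' @return Power in (0, 1\]; equals `alpha` at `d = 0`.
#' @examples
#' t_test_power(0.695, 72, 74)    # 0.986
#' @export
t_test_power <- function(d, n1, n2, alpha = 0.05) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  ncp <- abs(d) * sqrt(n1 * n2 / (n1 + n2))
  df <- n1 + n2 - 2
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tcrit, df, ncp) + stats::pt(tcrit, df, ncp, lower.tail = FALSE)
}

#' Network-level group comparison with effect sizes and power
#'
#' For every network and gradient in a [network_scores()] table: pooled
#' two-sample t (control minus patient), two-sided p, BH-FDR q (adjusted
#' within each gradient's family of networks), Cohen's d, and analytic power
#' at the observed d.
#'
#' @param scores Data frame from [network_scores()].
#' @param alpha Significance level for the power computation. Default 0.05.
#' @return Data frame: `network_label`, `gradient`, `t`, `p`, `q`, `d`,
#'   `power`.
#' @export
group_compare <- function(scores, alpha = 0.05) {
  need <- c("subject_id", "group", "network_label", "gradient", "score")
  stopifnot(all(need %in% names(scores)))
  out <- list()
  for (k in sort(unique(scores$gradient))) {
    sk <- scores[scores$gradient == k, ]
    labs <- unique(sk$network_label)
    res <- lapply(labs, function(lab) {
      x <- sk$score[sk$network_label == lab & sk$group == "control"]
      y <- sk$score[sk$network_label == lab & sk$group == "patient"]
      tt <- two_sample_t(x, y)
      data.frame(network_label = lab, gradient = k, t = tt$t, p = tt$p,
                 d = cohens_d(x, y),
                 power = t_test_power(cohens_d(x, y), length(x), length(y),
                                      alpha))
    })
    res <- do.call(rbind, res)
    res$q <- bh_fdr(res$p)
    out[[length(out) + 1]] <- res[, c("network_label", "gradient",
                                      "t", "p", "q", "d", "power")]
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Region-wise pooled two-sample t statistics
#'
#' One pooled t (control minus patient) per region on a chosen aligned
#' gradient across subjects.
#'
#' @param gradient_sets Named list of aligned `gradient_set`s.
#' @param manifest Data frame with `subject_id`, `group`.
#' @param gradient Gradient index. Default 1.
#' @return Numeric vector of t values, one per region.
#' @export
regionwise_t <- function(gradient_sets, manifest, gradient = 1) {
  G <- vapply(gradient_sets, function(g) g$embedding[, gradient],
              numeric(nrow(gradient_sets[[1]]$embedding)))
  grp <- manifest$group[match(colnames(G), manifest$subject_id)]
  apply(G, 1, function(v)
    two_sample_t(v[grp == "control"], v[grp == "patient"])$t)
}

#' Z-map from region-wise t values
#'
#' Standardizes the region-wise t statistics across regions (sample-SD
#' convention) to zero mean and unit variance.
#'
#' @param region_t Numeric vector of per-region t values (>= 2 regions,
#'   nonconstant).
#' @return Data frame: `region_id` (0-based), `t`, `z`.
#' @export
zmap_from_t <- function(region_t) {
  if (length(region_t) < 2) stop("need at least 2 regions")
  s <- stats::sd(region_t)
  if (s == 0) stop("t values are constant across regions")
  data.frame(region_id = 0:(length(region_t) - 1L),
             t = region_t,
             z = (region_t - mean(region_t)) / s)
}
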