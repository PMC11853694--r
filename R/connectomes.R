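.as_connectivity <- function(C, kind, subject_id = NULL) {
  C <- (C + t(C)) / 2
  C[C > 1] <- 1; C[C < -1] <- -1
  diag(C) <- 0
  structure(C, kind = kind, subject_id = subject_id,
            class = c("connectivity_matrix", "matrix", "array"))
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(attr(x, "kind"), "connectivity matrix:", nrow(x), "x", ncol(x),
      "regions", if (!is.null(attr(x, "subject_id")))
        paste0("(subject ", attr(x, "subject_id"), ")"), "\n")
  invisible(x)
}

#' Functional connectivity matrix from a region time-series
#'
#' Pairwise Pearson correlation between region time courses. The diagonal is
#' stored as 0 (not 1) so that row-wise density thresholding downstream never
#' selects self-connections.
#'
#' @param series Numeric region x timepoint matrix (>= 3 timepoints).
#' @param subject_id Optional subject identifier carried as an attribute.
#' @return A symmetric `connectivity_matrix` of kind `"FC"` with zero
#'   diagonal and entries in \[-1, 1\].
#' @examples
#' s <- matrix(rnorm(5 * 30), 5, 30)
#' fc <- fc_matrix(s)
#' @export
fc_matrix <- function(series, subject_id = NULL) {
  series <- as.matrix(series)
  if (ncol(series) < 3) stop("need at least 3 timepoints")
  v <- apply(series, 1, stats::var)
  if (any(v == 0 | !is.finite(v))) {
    bad <- which(v == 0 | !is.finite(v))[1]
    nm <- if (!is.null(rownames(series))) rownames(series)[bad] else bad
    stop("region ", nm, " has zero-variance series")
  }
  .as_connectivity(stats::cor(t(series)), "FC", subject_id)
}

#' Morphometric similarity matrix from a region feature table
#'
#' Each feature column is z-scored across regions, then the entry (i, j) is
#' the Pearson correlation of the two regions' z-scored feature vectors
#' (canonically 5 features: gray-matter volume, cortical thickness, surface
#' area, intrinsic and mean curvature).
#'
#' @param features Numeric region x feature matrix (>= 2 regions, >= 2
#'   features, each feature with nonzero variance across regions).
#' @param subject_id Optional subject identifier.
#' @return A symmetric `connectivity_matrix` of kind `"MSN"`.
#' @export
msn_matrix <- function(features, subject_id = NULL) {
  features <- as.matrix(features)
  if (nrow(features) < 2) stop("need at least 2 regions")
  if (ncol(features) < 2) stop("need at least 2 features")
  v <- apply(features, 2, stats::var)
  if (any(v == 0 | !is.finite(v))) {
    bad <- which(v == 0 | !is.finite(v))[1]
    nm <- if (!is.null(colnames(features))) colnames(features)[bad] else bad
    stop("feature ", nm, " is constant across regions")
  }
  Z <- scale(features)
  .as_connectivity(stats::cor(t(Z)), "MSN", subject_id)
}
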