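#' Hypergeometric gene-set over-representation analysis
#'
#' For each gene set, the probability of observing at least the realized
#' overlap between the selected genes and the set under hypergeometric
#' sampling from the universe, followed by BH-FDR correction across the
#' retained sets. Sets that do not intersect the universe are dropped with a
#' message.
#'
#' @param selected Character vector of selected genes (e.g. VIP > 1); must
#'   be nonempty and contained in the universe.
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()] or [make_gene_sets()]).
#' @param universe Character vector of all scored genes (>= 2).
#' @return Data frame sorted by `q` then `p`: `set`, `k` (overlap), `K`
#'   (set size in universe), `n` (selected size), `N` (universe size), `p`
#'   (hypergeometric upper tail, in (0, 1\]), `q` (BH-FDR).
#' @examples
#' sets <- list(A = c("g1", "g2", "g3"), B = c("g4", "g5"))
#' hypergeom_enrich(c("g1", "g2"), sets, paste0("g", 1:10))
#' @export
hypergeom_enrich <- function(selected, gene_sets, universe) {
  universe <- unique(universe)
  if (length(universe) < 2) stop("universe must contain at least 2 genes")
  selected <- unique(selected)
  if (length(selected) == 0) stop("selected gene list is empty")
  if (!all(selected %in% universe))
    stop("selected genes must be contained in the universe")
  if (is.null(names(gene_sets))) stop("gene sets must be named")
  sets <- lapply(gene_sets, function(s) intersect(unique(s), universe))
  empty <- lengths(sets) == 0
  if (any(empty)) {
    message("dropping ", sum(empty), " set(s) not intersecting the universe: ",
            paste(names(sets)[empty], collapse = ", "))
    sets <- sets[!empty]
  }
  if (length(sets) == 0) stop("no gene set intersects the universe")
  N <- length(universe); n <- length(selected)
  res <- data.frame(
    set = names(sets),
    k = vapply(sets, function(s) length(intersect(s, selected)), integer(1)),
    K = lengths(sets), n = n, N = N)
  # P(overlap >= k) = upper tail at k - 1
  res$p <- stats::phyper(res$k - 1, res$K, N - res$K, n, lower.tail = FALSE)
  res$q <- bh_fdr(res$p)
  res <- res[order(res$q, res$p), ]
  rownames(res) <- NULL
  res
}
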