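#' Write a region-indexed matrix as tab-delimited text
#'
#' First column `region_id` (0-based), remaining columns the matrix columns;
#' header row included. The standard on-disk form for series, features,
#' connectivity matrices, expression and gradient tables.
#'
#' @param mat Matrix with one row per region.
#' @param path Output file path.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(region_id = if (!is.null(rownames(mat))) rownames(mat)
                   else 0:(nrow(mat) - 1L),
                   as.data.frame(unclass(mat)), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a region-indexed tab-delimited matrix
#'
#' @param path File written by [write_matrix_tsv()] (or any tab-delimited
#'   file whose first column is `region_id`).
#' @return Numeric matrix with `region_id` as row names.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write gene sets in GMT format
#'
#' One line per set: name, description, then tab-separated gene symbols.
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "synthetic") {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("gene sets must be named")
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file path.
#' @return Named list of character vectors (description field dropped).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop("malformed GMT line(s): ", which(bad)[1])
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  sets
}

#' Write a cohort manifest
#'
#' CSV with columns `subject_id`, `group`, and optional path columns.
#'
#' @param manifest Data frame with at least `subject_id` and `group`.
#' @param path Output CSV path.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(all(c("subject_id", "group") %in% names(manifest)))
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
}

#' Read a cohort manifest
#' @param path CSV path.
#' @return Data frame.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path)
  stopifnot(all(c("subject_id", "group") %in% names(m)))
  if (!all(m$group %in% c("control", "patient")))
    stop("manifest group must be 'control' or 'patient'")
  m
}
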