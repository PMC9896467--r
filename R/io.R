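# Readers and writers for the tab-delimited formats used by the
# gold-standard DTI benchmark networks, plus the package's own outputs.

#' Read a labeled square similarity matrix
#'
#' Parses a whitespace/tab-delimited file with a header row of entity ids
#' and one id-labeled row per entity, the layout of the drug-structure and
#' protein-sequence similarity files shipped with the gold-standard DTI
#' networks. Values must lie in \[0, 1\]; the table must be square with
#' matching row and column ids and no duplicates. The matrix is *not*
#' symmetrized by default (substructure similarity scores can be
#' asymmetric; the source data is preserved as stored).
#'
#' @param path path to the file.
#' @param symmetrize if `TRUE`, replace the matrix M by (M + t(M))/2.
#' @return a numeric matrix with row and column names set to the ids.
#' @seealso [write_similarity_matrix()]
#' @export
read_similarity_matrix <- function(path, symmetrize = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    stopf("similarity file '%s': need a header row and at least one data row", path)
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  header <- fields[[1L]]
  body <- fields[-1L]
  # A corner label in the header (one extra field) is tolerated and dropped.
  if (length(header) == length(body[[1L]])) {
    header <- header[-1L]
  }
  col_ids <- header
  n <- length(col_ids)
  if (length(body) != n) {
    stopf("similarity file '%s': non-square table (%d columns, %d rows)",
          path, n, length(body))
  }
  bad <- which(vapply(body, length, 1L) != n + 1L)
  if (length(bad)) {
    stopf("similarity file '%s': row %d has %d fields, expected %d",
          path, bad[1L], length(body[[bad[1L]]]), n + 1L)
  }
  row_ids <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(col_ids) || anyDuplicated(row_ids)) {
    stopf("similarity file '%s': duplicate ids", path)
  }
  if (!identical(row_ids, col_ids)) {
    stopf("similarity file '%s': row ids do not match column ids", path)
  }
  vals <- suppressWarnings(
    vapply(body, function(f) as.numeric(f[-1L]), numeric(n))
  )
  mat <- t(matrix(vals, nrow = n, dimnames = list(col_ids, row_ids)))
  if (anyNA(mat)) stopf("similarity file '%s': non-numeric values", path)
  if (any(mat < 0) || any(mat > 1)) {
    stopf("similarity file '%s': values outside [0, 1]", path)
  }
  if (symmetrize) mat <- (mat + t(mat)) / 2
  mat
}

#' Write a labeled square matrix in the similarity-file layout
#'
#' @param mat numeric matrix with row and column names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(mat, path) {
  ids <- rownames(mat)
  if (is.null(ids)) stopf("matrix must have row names")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("", ids), collapse = "\t"), con)
  for (i in seq_len(nrow(mat))) {
    writeLines(paste(c(ids[i], sprintf("%.12g", mat[i, ])), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' Read an interaction pair list into a binary matrix
#'
#' Parses a two-column pair list in the gold-standard layout (target id,
#' then drug id, per line) into an n x m binary matrix with drugs as rows.
#' Pairs referencing ids absent from `drug_ids`/`target_ids` raise an error
#' naming the offending lines; duplicated pairs are accepted once with a
#' warning. Ids are matched case-sensitively and verbatim.
#'
#' @param path path to the pair list (may be empty: all-zero matrix).
#' @param drug_ids,target_ids id vectors fixing the matrix layout.
#' @param columns `"target_drug"` (default, gold-standard layout) or
#'   `"drug_target"` for the transposed dialect.
#' @return numeric n x m matrix of 0/1 with dimnames.
#' @export
read_interaction_pairs <- function(path, drug_ids, target_ids,
                                   columns = c("target_drug", "drug_target")) {
  columns <- match.arg(columns)
  n <- length(drug_ids)
  m <- length(target_ids)
  mat <- matrix(0, n, m, dimnames = list(drug_ids, target_ids))
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(mat)
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(vapply(fields, length, 1L) != 2L)
  if (length(bad)) {
    stopf("pair file '%s': line %d does not have two columns", path, lineno[bad[1L]])
  }
  first <- vapply(fields, `[[`, "", 1L)
  second <- vapply(fields, `[[`, "", 2L)
  if (columns == "target_drug") {
    tgt <- first; drg <- second
  } else {
    drg <- first; tgt <- second
  }
  di <- match(drg, drug_ids)
  ti <- match(tgt, target_ids)
  unknown <- is.na(di) | is.na(ti)
  if (any(unknown)) {
    off <- which(unknown)
    stopf("pair file '%s': unknown ids on line(s) %s (e.g. '%s')",
          path, paste(lineno[off], collapse = ", "), lines[off[1L]])
  }
  key <- paste(di, ti)
  if (anyDuplicated(key)) {
    warnf("pair file '%s': %d duplicate pair(s) accepted once",
          path, sum(duplicated(key)))
  }
  mat[cbind(di, ti)] <- 1
  mat
}

#' Write an interaction matrix as a (target, drug) pair list
#'
#' @param interactions binary matrix, drugs in rows, targets in columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interaction_pairs <- function(interactions, path) {
  idx <- which(interactions == 1, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  lines <- paste(colnames(interactions)[idx[, 2L]],
                 rownames(interactions)[idx[, 1L]], sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write ranked interaction predictions
#'
#' Writes a TSV with columns `drug_id`, `target_id`, `score`, sorted by
#' descending score; rows with tied scores keep their input order.
#'
#' @param pairs data frame with columns `drug_id`, `target_id`, `score`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranked_predictions <- function(pairs, path) {
  need <- c("drug_id", "target_id", "score")
  if (!all(need %in% names(pairs))) {
    stopf("pairs must have columns %s", paste(need, collapse = ", "))
  }
  if (!all(is.finite(pairs$score))) stopf("scores must be finite")
  ord <- order(-pairs$score)  # order() is stable: ties keep input order
  out <- pairs[ord, need, drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("drug_id\ttarget_id\tscore", con)
  writeLines(sprintf("%s\t%s\t%.10g", out$drug_id, out$target_id, out$score),
             con)
  invisible(path)
}

#' Read a ranked prediction table written by [write_ranked_predictions()]
#'
#' @param path path to the TSV.
#' @return data frame with columns `drug_id`, `target_id`, `score`.
#' @export
read_ranked_predictions <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "character", "numeric"))
}

#' Write a DTI network to a directory
#'
#' Writes `drug_similarity.tsv`, `target_similarity.tsv` and
#' `interactions.tsv` (pair-list layout) under `dir`, the same formats
#' [read_network()] and the gold-standard parsers consume.
#'
#' @param network a [dti_network()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_network <- function(network, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_similarity_matrix(network$drug_sim, file.path(dir, "drug_similarity.tsv"))
  write_similarity_matrix(network$target_sim, file.path(dir, "target_similarity.tsv"))
  write_interaction_pairs(network$interactions, file.path(dir, "interactions.tsv"))
  invisible(dir)
}

#' Read a DTI network from a directory written by [write_network()]
#'
#' @param dir directory holding the three network files.
#' @param symmetrize passed to [read_similarity_matrix()].
#' @return a [dti_network()].
#' @export
read_network <- function(dir, symmetrize = FALSE) {
  ds <- read_similarity_matrix(file.path(dir, "drug_similarity.tsv"), symmetrize)
  ts <- read_similarity_matrix(file.path(dir, "target_similarity.tsv"), symmetrize)
  y <- read_interaction_pairs(file.path(dir, "interactions.tsv"),
                              rownames(ds), rownames(ts))
  dti_network(rownames(ds), rownames(ts), ds, ts, y)
}

#' Read a methods-by-datasets score table
#'
#' Reads a TSV with method names in the first column and one column per
#' dataset, as consumed by [friedman_test()]. The package ships the AUC
#' and AUPR benchmark tables of the eight literature methods plus the
#' screened-negative spherical-search ELM under
#' `system.file("extdata", c("benchmark_auc.tsv", "benchmark_aupr.tsv"), package = "spherelm")`.
#'
#' @param path path to the TSV.
#' @return numeric matrix, methods in rows.
#' @export
read_score_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                          check.names = FALSE)
  as.matrix(df)
}
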