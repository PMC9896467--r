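#' Drug-target interaction network
#'
#' Container for a bipartite drug-target network: a drug-drug similarity
#' matrix, a target-target similarity matrix, and a binary interaction
#' matrix with drugs as rows and targets as columns. Similarity values must
#' lie in \[0, 1\] with a unit diagonal; the interaction matrix holds 1 for
#' a known (experimentally verified) interaction and 0 for an unlabeled
#' pair. Similarity matrices are not required to be symmetric: chemical
#' substructure scores such as those distributed with the gold-standard
#' benchmark networks can be asymmetric, and they are consumed as stored.
#'
#' @param drug_ids character vector of drug identifiers (e.g. "D00002").
#' @param target_ids character vector of target identifiers (e.g. "hsa:10").
#' @param drug_sim numeric n x n matrix of drug-drug similarities.
#' @param target_sim numeric m x m matrix of target-target similarities.
#' @param interactions numeric or integer n x m matrix of 0/1 interaction
#'   labels (drugs in rows, targets in columns).
#'
#' @return An object of class `dti_network` with fields `drug_ids`,
#'   `target_ids`, `drug_sim`, `target_sim`, `interactions`.
#'
#' @examples
#' net <- dti_network(
#'   drug_ids = c("d1", "d2"), target_ids = c("t1", "t2", "t3"),
#'   drug_sim = diag(2), target_sim = diag(3),
#'   interactions = matrix(c(1, 0, 0, 0, 0, 1), nrow = 2)
#' )
#' net
#' @export
dti_network <- function(drug_ids, target_ids, drug_sim, target_sim,
                        interactions) {
  drug_ids <- as.character(drug_ids)
  target_ids <- as.character(target_ids)
  drug_sim <- as.matrix(drug_sim)
  target_sim <- as.matrix(target_sim)
  interactions <- as.matrix(interactions)
  storage.mode(drug_sim) <- "double"
  storage.mode(target_sim) <- "double"
  storage.mode(interactions) <- "double"

  n <- length(drug_ids)
  m <- length(target_ids)
  if (anyDuplicated(drug_ids)) stopf("duplicate drug ids")
  if (anyDuplicated(target_ids)) stopf("duplicate target ids")
  check_similarity(drug_sim, n, "drug_sim")
  check_similarity(target_sim, m, "target_sim")
  if (!all(dim(interactions) == c(n, m))) {
    stopf("interactions must be %d x %d, got %d x %d",
          n, m, nrow(interactions), ncol(interactions))
  }
  if (!all(interactions %in% c(0, 1))) {
    stopf("interaction entries must be exactly 0 or 1")
  }
  dimnames(drug_sim) <- list(drug_ids, drug_ids)
  dimnames(target_sim) <- list(target_ids, target_ids)
  dimnames(interactions) <- list(drug_ids, target_ids)

  structure(
    list(drug_ids = drug_ids, target_ids = target_ids,
         drug_sim = drug_sim, target_sim = target_sim,
         interactions = interactions),
    class = "dti_network"
  )
}

check_similarity <- function(mat, n, what) {
  if (nrow(mat) != n || ncol(mat) != n) {
    stopf("%s must be %d x %d, got %d x %d", what, n, n, nrow(mat), ncol(mat))
  }
  if (anyNA(mat) || !all(is.finite(mat))) {
    stopf("%s contains missing or non-finite values; missing similarity entries are not allowed", what)
  }
  if (any(mat < 0) || any(mat > 1)) {
    stopf("%s has values outside [0, 1]", what)
  }
  if (n > 0 && any(abs(diag(mat) - 1) > 1e-12)) {
    stopf("%s must have a unit diagonal", what)
  }
  invisible(TRUE)
}

#' @export
print.dti_network <- function(x, ...) {
  n <- length(x$drug_ids)
  m <- length(x$target_ids)
  cat(sprintf("dti_network: %d drugs x %d targets, %d known interactions\n",
              n, m, sum(x$interactions)))
  invisible(x)
}

#' @export
dim.dti_network <- function(x) {
  c(length(x$drug_ids), length(x$target_ids))
}
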