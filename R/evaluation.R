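# Ranking metrics, stratified cross-validation, and the cross-validated
# fitness that couples the ELM to the spherical-search optimizer.

#' Area under the ROC curve
#'
#' Computed through the rank statistic (equivalent to the Wilcoxon
#' Mann-Whitney U): the probability that a random positive scores above a
#' random negative, with tied pairs counting 1/2. Requires both classes.
#'
#' @param labels 0/1 vector.
#' @param scores numeric vector of the same length.
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.numeric(labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stopf("AUC undefined: both classes must be present")
  }
  r <- rank(scores)  # average ranks give the 1/2 tie contribution
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Average precision: the mean, over the positives in score-descending
#' order, of the precision at each positive's rank. Tied scores are
#' ordered negatives-first (the pessimistic convention), so the reported
#' value never benefits from an arbitrary tie order; with all scores tied
#' the precision at the j-th positive is j / (n_neg + j).
#'
#' @param labels 0/1 vector (at least one positive).
#' @param scores numeric vector.
#' @return average precision in \[0, 1\].
#' @export
compute_aupr <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.numeric(labels)
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stopf("AUPR undefined: no positive samples")
  ord <- order(-scores, labels)  # within a tie, negatives (0) first
  lab <- labels[ord]
  prec <- cumsum(lab) / seq_along(lab)
  sum(prec[lab == 1]) / n_pos
}

#' Stratified k-fold assignment
#'
#' Shuffles each class separately and deals its samples round-robin over
#' the k folds, so per-class fold sizes differ by at most one. If the
#' rarer class has fewer than k members the assignment degrades to a
#' plain (non-stratified) random split with a warning.
#'
#' @param n_samples number of samples.
#' @param labels 0/1 vector of length `n_samples` (ignored when
#'   unstratified).
#' @param k number of folds.
#' @param seed integer seed; the same seed reproduces the assignment.
#' @return integer vector of fold ids in 1..k.
#' @export
make_folds <- function(n_samples, labels, k = 10, seed = 1) {
  stopifnot(n_samples >= k)
  labels <- as.numeric(labels)
  stopifnot(length(labels) == n_samples)
  with_seed(seed, {
    folds <- integer(n_samples)
    classes <- unique(labels)
    if (min(table(labels)) < k) {
      warnf("a class has fewer than %d members; using a non-stratified split", k)
      folds <- rep_len(seq_len(k), n_samples)[sample.int(n_samples)]
    } else {
      for (cl in classes) {
        idx <- which(labels == cl)
        idx <- idx[sample.int(length(idx))]
        folds[idx] <- rep_len(seq_len(k), length(idx))
      }
    }
    folds
  })
}

# Decode a flat spherical-search parameter vector into ELM hidden-layer
# weights and biases: first L*d entries row-major as W (L x d), last L as b.
decode_elm_params <- function(par, hidden_nodes, d) {
  L <- as.integer(hidden_nodes)
  if (length(par) != L * (d + 1L)) {
    stopf("parameter vector has length %d, expected L*(d+1) = %d",
          length(par), L * (d + 1L))
  }
  list(W = matrix(par[seq_len(L * d)], nrow = L, byrow = TRUE),
       b = par[L * d + seq_len(L)])
}

#' Cross-validated ELM performance for fixed hidden parameters
#'
#' For each fold, fits the ELM output weights on the training portion
#' (hidden weights/biases held fixed), scores the held-out portion, and
#' records AUC and AUPR. The fitness is the mean over folds of
#' (AUC + AUPR)/2, a bounded score in \[0, 1\]; the literal across-fold
#' sum (k times the mean) is reported alongside.
#'
#' @param features N x d matrix.
#' @param labels 0/1 vector.
#' @param folds fold assignment from [make_folds()].
#' @param W,b ELM hidden weights (L x d) and biases.
#' @param activation hidden activation name.
#' @return list of class `cv_result`: `per_fold` (data frame with
#'   `fold`, `auc`, `aupr`), `auc` and `aupr` (means), `fitness` (mean
#'   form), `fitness_sum` (literal sum form).
#' @export
elm_cv <- function(features, labels, folds, W, b, activation = "sigmoid") {
  features <- as.matrix(features)
  labels <- as.numeric(labels)
  H <- elm_hidden_output(features, W, b, activation)
  ids <- sort(unique(folds))
  auc <- aupr <- numeric(length(ids))
  for (f in seq_along(ids)) {
    test <- folds == ids[f]
    beta <- MASS::ginv(H[!test, , drop = FALSE]) %*% labels[!test]
    sc <- drop(H[test, , drop = FALSE] %*% beta)
    auc[f] <- compute_auc(labels[test], sc)
    aupr[f] <- compute_aupr(labels[test], sc)
  }
  fitness <- mean((auc + aupr) / 2)
  structure(
    list(per_fold = data.frame(fold = ids, auc = auc, aupr = aupr),
         auc = mean(auc), aupr = mean(aupr),
         fitness = fitness, fitness_sum = fitness * length(ids)),
    class = "cv_result"
  )
}

#' Cross-validated fitness of a flat ELM parameter vector
#'
#' Decodes `par` into hidden weights and biases (first `L*d` entries
#' row-major, then `L` biases) and returns the [elm_cv()] fitness - the
#' objective the spherical search maximizes (pass its negation to
#' [ss_optimize()]).
#'
#' @param par numeric vector of length `L*(d+1)`.
#' @param features,labels,folds,activation as in [elm_cv()].
#' @param hidden_nodes number of hidden nodes L.
#' @return scalar fitness in \[0, 1\].
#' @export
cv_fitness <- function(par, features, labels, folds, hidden_nodes,
                       activation = "sigmoid") {
  p <- decode_elm_params(par, hidden_nodes, ncol(features))
  elm_cv(features, labels, folds, p$W, p$b, activation)$fitness
}
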