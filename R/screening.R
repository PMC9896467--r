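# Negative-sample screening: score unlabeled drug-target pairs by
# similarity-weighted interaction profiles and select the lowest-scoring
# pairs as high-confidence negatives.

#' Screening score for one unlabeled drug-target pair
#'
#' For drug k and target j, the score is the average of two
#' similarity-weighted interaction profiles:
#' \deqn{SPC_{jk} = \frac{\sum_{l \ne j} PS_{jl}\, y_{kl}}{\sum_{l \ne j} PS_{jl}}, \qquad
#'       SCP_{kj} = \frac{\sum_{i \ne k} CS_{ki}\, y_{ij}}{\sum_{i \ne k} CS_{ki}},}
#' \deqn{S_{kj} = (SPC_{jk} + SCP_{kj}) / 2,}
#' where PS/CS are the target/drug similarity matrices and y the known
#' interaction labels. A high score means the pair resembles known
#' interactions; pairs with the lowest scores are the best negative
#' candidates. A score side carries no evidence when its similarity
#' denominator is zero or the entity has no known interactions feeding the
#' numerator; such a side contributes 0 and the pair is flagged (see
#' `undefined` in the return value of [score_all()]).
#'
#' @param network a [dti_network()].
#' @param k drug index.
#' @param j target index.
#' @return scalar score in \[0, 1\] with attribute `undefined`.
#' @export
score_pair <- function(network, k, j) {
  y <- network$interactions
  n <- nrow(y)
  m <- ncol(y)
  if (!(is_scalar_number(k) && k >= 1 && k <= n)) stopf("drug index out of range")
  if (!(is_scalar_number(j) && j >= 1 && j <= m)) stopf("target index out of range")
  if (y[k, j] == 1) stopf("pair (%d, %d) is a known positive; screening scores are defined on unlabeled pairs", k, j)
  ps <- network$target_sim[j, -j]
  yk <- y[k, -j]
  den1 <- sum(ps)
  undef1 <- den1 == 0 || sum(yk) == 0
  spc <- if (den1 > 0) sum(ps * yk) / den1 else 0
  cs <- network$drug_sim[k, -k]
  yj <- y[-k, j]
  den2 <- sum(cs)
  undef2 <- den2 == 0 || sum(yj) == 0
  scp <- if (den2 > 0) sum(cs * yj) / den2 else 0
  s <- (spc + scp) / 2
  attr(s, "undefined") <- undef1 || undef2
  s
}

#' Screening scores for all unlabeled pairs
#'
#' Vectorized version of [score_pair()] over the whole network. Entries at
#' known-positive positions are `NA` (they are never scored).
#'
#' @param network a [dti_network()].
#' @return list of class `negative_score_matrix` with n x m matrices
#'   `scores` (S, `NA` at positives), `spc`, `scp` (the two sides), and
#'   logical `undefined` marking pairs where at least one side carried no
#'   evidence (zero similarity mass or no known interactions).
#' @export
score_all <- function(network) {
  y <- network$interactions
  cs <- network$drug_sim
  ps <- network$target_sim
  n <- nrow(y)
  m <- ncol(y)

  # SPC[k, j] = sum_{l != j} PS[j, l] y[k, l] / sum_{l != j} PS[j, l]
  num_spc <- y %*% t(ps) - sweep(y, 2L, diag(ps), `*`)
  den_spc <- rowSums(ps) - diag(ps)            # per target j
  spc <- sweep(num_spc, 2L, ifelse(den_spc > 0, den_spc, 1), `/`)
  spc[, den_spc == 0] <- 0

  # SCP[k, j] = sum_{i != k} CS[k, i] y[i, j] / sum_{i != k} CS[k, i]
  num_scp <- cs %*% y - sweep(y, 1L, diag(cs), `*`)
  den_scp <- rowSums(cs) - diag(cs)            # per drug k
  scp <- sweep(num_scp, 1L, ifelse(den_scp > 0, den_scp, 1), `/`)
  scp[den_scp == 0, ] <- 0

  scores <- (spc + scp) / 2

  # evidence support, with the self pair excluded from both sums
  drug_pos <- rowSums(y)     # known targets of drug k
  target_pos <- colSums(y)   # known drugs of target j
  spc_undef <- outer(drug_pos, rep(1, m)) - y == 0
  spc_undef <- spc_undef | matrix(den_spc == 0, n, m, byrow = TRUE)
  scp_undef <- outer(rep(1, n), target_pos) - y == 0
  scp_undef <- scp_undef | matrix(den_scp == 0, n, m)
  undefined <- spc_undef | scp_undef

  pos <- y == 1
  scores[pos] <- NA_real_
  spc[pos] <- NA_real_
  scp[pos] <- NA_real_
  undefined[pos] <- NA
  dimnames(scores) <- dimnames(y)
  structure(
    list(scores = scores, spc = spc, scp = scp, undefined = undefined),
    class = "negative_score_matrix"
  )
}

#' Build a class-balanced training set of positives and screened negatives
#'
#' Takes every known interaction as a positive and the
#' `ceiling(ratio * n_pos)` lowest-scoring unlabeled pairs as negatives.
#' Ties are broken by row-major pair index (drug-major), so the selection
#' is deterministic; the maximum selected score never exceeds the minimum
#' unselected score.
#'
#' @param network a [dti_network()].
#' @param scores a `negative_score_matrix` from [score_all()] (computed if
#'   missing).
#' @param ratio negatives per positive (default 1: class balance).
#' @return data frame of class `labeled_pair_set` with columns `drug`,
#'   `target` (indices), `drug_id`, `target_id`, `label` (1/0) and
#'   `score` (`NA` for positives).
#' @export
build_balanced_training_set <- function(network, scores = score_all(network),
                                        ratio = 1) {
  stopifnot(ratio > 0)
  y <- network$interactions
  n <- nrow(y)
  m <- ncol(y)
  pos <- which(y == 1)
  n_pos <- length(pos)
  if (n_pos == 0) stopf("network has no known interactions")
  n_neg <- as.integer(ceiling(ratio * n_pos))
  unl <- which(y == 0)
  if (length(unl) < n_neg) {
    stopf("only %d unlabeled pairs available, need %d negatives",
          length(unl), n_neg)
  }
  k_unl <- ((unl - 1L) %% n) + 1L       # drug index (column-major linear)
  j_unl <- ((unl - 1L) %/% n) + 1L
  rowmajor <- (k_unl - 1L) * m + j_unl  # deterministic tie-break
  s_unl <- scores$scores[unl]
  ord <- order(s_unl, rowmajor)
  sel <- ord[seq_len(n_neg)]

  k_pos <- ((pos - 1L) %% n) + 1L
  j_pos <- ((pos - 1L) %/% n) + 1L
  out <- data.frame(
    drug = c(k_pos, k_unl[sel]),
    target = c(j_pos, j_unl[sel]),
    drug_id = network$drug_ids[c(k_pos, k_unl[sel])],
    target_id = network$target_ids[c(j_pos, j_unl[sel])],
    label = rep(c(1, 0), c(n_pos, n_neg)),
    score = c(rep(NA_real_, n_pos), s_unl[sel]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("labeled_pair_set", "data.frame")
  out
}

#' Similarity-profile feature vectors for labeled pairs
#'
#' Each pair (drug k, target j) is represented by the concatenation of
#' target j's similarity profile and drug k's similarity profile,
#' `[target_sim[j, ] , drug_sim[k, ]]`, of length m + n. Labels stay in
#' the pair set; only the feature matrix is returned.
#'
#' @param network a [dti_network()].
#' @param pairs a `labeled_pair_set` (or any data frame with integer
#'   columns `drug` and `target`).
#' @return numeric matrix, one row per pair, m + n columns.
#' @export
build_feature_vectors <- function(network, pairs) {
  stopifnot(all(pairs$drug >= 1), all(pairs$drug <= nrow(network$interactions)),
            all(pairs$target >= 1), all(pairs$target <= ncol(network$interactions)))
  x <- cbind(network$target_sim[pairs$target, , drop = FALSE],
             network$drug_sim[pairs$drug, , drop = FALSE])
  rownames(x) <- NULL
  x
}
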