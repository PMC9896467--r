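# Independent oracles and tiny fixtures, kept deliberately naive (scalar
# loops, exhaustive enumeration) so they share no code path with the
# vectorized implementations they check.

# Screening score by direct double summation over all entities.
brute_screening_score <- function(net, k, j) {
  ps <- net$target_sim
  cs <- net$drug_sim
  y <- net$interactions
  num1 <- den1 <- 0
  for (l in seq_len(ncol(y))) {
    if (l == j) next
    num1 <- num1 + ps[j, l] * y[k, l]
    den1 <- den1 + ps[j, l]
  }
  spc <- if (den1 > 0) num1 / den1 else 0
  num2 <- den2 <- 0
  for (i in seq_len(nrow(y))) {
    if (i == k) next
    num2 <- num2 + cs[k, i] * y[i, j]
    den2 <- den2 + cs[k, i]
  }
  scp <- if (den2 > 0) num2 / den2 else 0
  (spc + scp) / 2
}

# AUC as the exhaustive mean over all (positive, negative) pairs.
pairwise_auc_oracle <- function(labels, scores) {
  p <- scores[labels == 1]
  n <- scores[labels == 0]
  total <- 0
  for (a in p) {
    for (b in n) {
      total <- total + (a > b) + 0.5 * (a == b)
    }
  }
  total / (length(p) * length(n))
}

# Average precision by an explicit walk down the ranked list, ties
# ordered negatives-first (the package's documented pessimistic rule).
rankwalk_aupr_oracle <- function(labels, scores) {
  ord <- order(-scores, labels)
  lab <- labels[ord]
  tp <- 0
  ap <- 0
  for (r in seq_along(lab)) {
    if (lab[r] == 1) {
      tp <- tp + 1
      ap <- ap + tp / r
    }
  }
  ap / sum(labels == 1)
}

# Hidden-layer output by scalar loops.
loop_hidden_oracle <- function(X, W, b, g) {
  H <- matrix(0, nrow(X), nrow(W))
  for (p in seq_len(nrow(X))) {
    for (i in seq_len(nrow(W))) {
      H[p, i] <- g(sum(X[p, ] * W[i, ]) + b[i])
    }
  }
  H
}

# Random valid DTI network (similarities in [0,1], unit diagonal).
random_network <- function(n, m, density = 0.3) {
  ds <- matrix(runif(n * n), n, n)
  ds <- (ds + t(ds)) / 2
  diag(ds) <- 1
  ts <- matrix(runif(m * m), m, m)
  ts <- (ts + t(ts)) / 2
  diag(ts) <- 1
  y <- matrix(rbinom(n * m, 1, density), n, m)
  dti_network(sprintf("d%d", seq_len(n)), sprintf("t%d", seq_len(m)),
              ds, ts, y)
}

# 3-drug x 3-target hand-built network used across screening tests.
tiny_network <- function() {
  ds <- matrix(c(1, 0.8, 0.1,
                 0.8, 1, 0.3,
                 0.1, 0.3, 1), 3, 3, byrow = TRUE)
  ts <- matrix(c(1, 0.6, 0.2,
                 0.6, 1, 0.4,
                 0.2, 0.4, 1), 3, 3, byrow = TRUE)
  y <- matrix(c(1, 0, 0,
                0, 1, 0,
                0, 0, 0), 3, 3, byrow = TRUE)
  dti_network(c("dA", "dB", "dC"), c("tA", "tB", "tC"), ds, ts, y)
}
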