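# Similarity-weighted negative screening.

test_that("pair scores match the brute-force double-summation oracle", {
  net <- tiny_network()
  for (k in 1:3) {
    for (j in 1:3) {
      if (net$interactions[k, j] == 1) next
      expect_lt(abs(as.numeric(score_pair(net, k, j)) -
                      brute_screening_score(net, k, j)), 1e-12)
    }
  }
})

test_that("vectorized scoring agrees with the scalar loop on random networks", {
  set.seed(31)
  for (rep in 1:5) {
    net <- random_network(10, 10)
    s <- score_all(net)
    for (k in 1:10) {
      for (j in 1:10) {
        if (net$interactions[k, j] == 1) {
          expect_true(is.na(s$scores[k, j]))
        } else {
          expect_lt(abs(s$scores[k, j] - as.numeric(score_pair(net, k, j))),
                    1e-12)
          expect_lt(abs(s$scores[k, j] - brute_screening_score(net, k, j)),
                    1e-12)
        }
      }
    }
    ok <- !is.na(s$scores)
    expect_true(all(s$scores[ok] >= 0 & s$scores[ok] <= 1))
  }
})

test_that("empty-support and saturated pairs hit the score bounds", {
  # drug 2 has no known targets and target 2 no known drugs
  ds <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  ts <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  y <- matrix(c(1, 0, 0, 0), 2, 2)
  net <- dti_network(c("d1", "d2"), c("t1", "t2"), ds, ts, y)
  s22 <- score_pair(net, 2, 2)
  expect_equal(as.numeric(s22), 0)
  expect_true(attr(s22, "undefined"))
  expect_true(score_all(net)$undefined[2, 2])

  # for unlabeled pair (d1, t1): the only other target (sim 1) is hit by
  # d1 and the only other drug (sim 1) hits t1 -> both sides saturate
  y_sat <- matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE)
  sat <- dti_network(c("d1", "d2"), c("t1", "t2"),
                     matrix(c(1, 1, 1, 1), 2, 2),
                     matrix(c(1, 1, 1, 1), 2, 2), y_sat)
  s11 <- score_pair(sat, 1, 1)
  expect_equal(as.numeric(s11), 1)
})

test_that("known positives are excluded and errors are raised in range checks", {
  net <- tiny_network()
  expect_error(score_pair(net, 1, 1), "known positive")
  expect_error(score_pair(net, 0, 1), "out of range")
  expect_error(score_pair(net, 1, 9), "out of range")
  s <- score_all(net)
  expect_true(all(is.na(s$scores[net$interactions == 1])))
})

test_that("adding an interaction at a similar target never lowers SPC", {
  set.seed(77)
  for (rep in 1:20) {
    net <- random_network(6, 6)
    unl <- which(net$interactions == 0, arr.ind = TRUE)
    p <- unl[sample(nrow(unl), 1), ]
    k <- p[1]; j <- p[2]
    # flip on some other unlabeled target of drug k
    cand <- setdiff(which(net$interactions[k, ] == 0), j)
    if (!length(cand)) next
    l <- sample(cand, 1)
    before <- score_all(net)$spc[k, j]
    net$interactions[k, l] <- 1
    after <- score_all(net)$spc[k, j]
    expect_gte(after, before - 1e-12)
  }
})

test_that("balanced sets take the lowest-scoring negatives deterministically", {
  set.seed(5)
  net <- random_network(10, 10, density = 0.2)
  s <- score_all(net)
  pairs <- build_balanced_training_set(net, s)
  n_pos <- sum(net$interactions)
  expect_equal(sum(pairs$label == 1), n_pos)
  expect_equal(sum(pairs$label == 0), n_pos)

  neg <- pairs[pairs$label == 0, ]
  sel_idx <- cbind(neg$drug, neg$target)
  unsel <- s$scores
  unsel[sel_idx] <- NA  # positives already NA
  expect_lte(max(neg$score), min(unsel, na.rm = TRUE))

  # full-sort oracle when scores are distinct
  all_unl <- sort(s$scores[!is.na(s$scores)])
  expect_equal(sort(neg$score), all_unl[seq_len(n_pos)])
})

test_that("tied scores fall back to row-major pair order", {
  n <- 4; m <- 3
  ds <- diag(n); ts <- diag(m)
  y <- matrix(0, n, m); y[4, 3] <- 1
  net <- dti_network(sprintf("d%d", 1:n), sprintf("t%d", 1:m), ds, ts, y)
  s <- score_all(net)
  expect_equal(length(unique(s$scores[!is.na(s$scores)])), 1L)  # all tied
  pairs <- build_balanced_training_set(net, s)
  neg <- pairs[pairs$label == 0, ]
  expect_equal(nrow(neg), 1L)
  expect_equal(c(neg$drug, neg$target), c(1L, 1L))  # first in row-major order

  # a 2:1 ratio takes (1,1) then (1,2)
  neg2 <- subset(build_balanced_training_set(net, s, ratio = 2), label == 0)
  expect_equal(neg2$drug, c(1L, 1L))
  expect_equal(neg2$target, c(1L, 2L))
})

test_that("ratio demands are validated against available unlabeled pairs", {
  net <- tiny_network()  # 2 positives, 7 unlabeled
  expect_error(build_balanced_training_set(net, ratio = 4), "unlabeled")
  p <- build_balanced_training_set(net, ratio = 3.5)
  expect_equal(sum(p$label == 0), 7L)
})

test_that("feature vectors concatenate target and drug similarity profiles", {
  net <- random_network(3, 2)
  pairs <- data.frame(drug = c(1L, 3L), target = c(2L, 1L))
  X <- build_feature_vectors(net, pairs)
  expect_equal(dim(X), c(2L, 5L))  # m + n = 2 + 3
  expect_equal(unname(X[1, 1:2]), unname(net$target_sim[2, ]))
  expect_equal(unname(X[1, 3:5]), unname(net$drug_sim[1, ]))
  # drug self-similarity sits at coordinate m + k
  expect_equal(unname(X[1, 2 + 1]), 1)
  expect_equal(unname(X[2, 2 + 3]), 1)
})

test_that("permuting target ids permutes the first m feature coordinates", {
  set.seed(12)
  net <- random_network(4, 5)
  perm <- sample(5)
  net2 <- dti_network(net$drug_ids, net$target_ids[perm],
                      net$drug_sim, net$target_sim[perm, perm],
                      net$interactions[, perm])
  pairs <- data.frame(drug = 2L, target = 3L)
  pairs2 <- data.frame(drug = 2L, target = match(3L, perm))
  x1 <- build_feature_vectors(net, pairs)
  x2 <- build_feature_vectors(net2, pairs2)
  expect_equal(unname(x2[1, seq_len(5)]), unname(x1[1, perm]))
  expect_equal(unname(x2[1, 5 + 1:4]), unname(x1[1, 5 + 1:4]))
})
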