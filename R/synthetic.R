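#' Specification for a synthetic DTI network
#'
#' Defines a block-structured network in which drugs and targets are
#' partitioned into matched clusters: similarity is high inside a cluster
#' and low between clusters, and interactions are planted inside matched
#' drug/target cluster blocks. This reproduces, in idealized form, the
#' structure that makes similarity-based negative screening work on real
#' chemogenomic data: similar drugs tend to share targets, so pairs that
#' are dissimilar to every known interaction are good negative candidates.
#'
#' Defaults mirror the desk-scale benchmark used throughout the test
#' suite: a 40 x 40 network with 4 matched clusters and interaction
#' density 0.3 inside the blocks.
#'
#' @param n_drugs,m_targets entity counts.
#' @param n_clusters number of matched clusters (must not exceed either
#'   entity count).
#' @param within_cluster_sim similarity inside a cluster, in (0, 1].
#' @param between_cluster_sim similarity between clusters, in \[0, 1);
#'   must be below `within_cluster_sim`.
#' @param interaction_density probability of a planted interaction inside
#'   a matched block, in (0, 1).
#' @param label_noise probability that any interaction label is flipped
#'   after planting, in \[0, 0.5).
#' @param jitter half-width of the symmetric uniform jitter added to
#'   off-diagonal similarities (breaks ties in screening sorts; set to 0
#'   for exact tests).
#' @param seed integer seed; the same spec and seed give a bit-identical
#'   network.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_drugs = 40, m_targets = 40, n_clusters = 4,
                           within_cluster_sim = 0.8,
                           between_cluster_sim = 0.2,
                           interaction_density = 0.3, label_noise = 0,
                           jitter = 0.02, seed = 1) {
  stopifnot(n_drugs >= 1, m_targets >= 1, n_clusters >= 1)
  if (n_clusters > n_drugs || n_clusters > m_targets) {
    stopf("n_clusters (%d) exceeds an entity count (%d drugs, %d targets)",
          n_clusters, n_drugs, m_targets)
  }
  if (!(within_cluster_sim > 0 && within_cluster_sim <= 1)) {
    stopf("within_cluster_sim must be in (0, 1]")
  }
  if (!(between_cluster_sim >= 0 && between_cluster_sim < 1)) {
    stopf("between_cluster_sim must be in [0, 1)")
  }
  if (within_cluster_sim <= between_cluster_sim) {
    stopf("within_cluster_sim must exceed between_cluster_sim")
  }
  if (!(interaction_density > 0 && interaction_density < 1)) {
    stopf("interaction_density must be in (0, 1)")
  }
  if (!(label_noise >= 0 && label_noise < 0.5)) {
    stopf("label_noise must be in [0, 0.5)")
  }
  stopifnot(jitter >= 0)
  structure(
    list(n_drugs = as.integer(n_drugs), m_targets = as.integer(m_targets),
         n_clusters = as.integer(n_clusters),
         within_cluster_sim = within_cluster_sim,
         between_cluster_sim = between_cluster_sim,
         interaction_density = interaction_density,
         label_noise = label_noise, jitter = jitter,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# Cluster sizes as equal as possible; the remainder goes to the first
# clusters, so the assignment is deterministic.
cluster_assignment <- function(n, k) {
  sizes <- rep(n %/% k, k)
  r <- n %% k
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  rep.int(seq_len(k), sizes)
}

block_similarity <- function(clusters, within, between, jitter) {
  n <- length(clusters)
  mat <- matrix(between, n, n)
  same <- outer(clusters, clusters, `==`)
  mat[same] <- within
  if (jitter > 0 && n > 1) {
    j <- matrix(stats::runif(n * n, -jitter, jitter), n, n)
    j[lower.tri(j)] <- t(j)[lower.tri(j)]  # symmetric jitter
    mat <- mat + j
    mat <- pmin(pmax(mat, 0), 1)
  }
  diag(mat) <- 1
  mat
}

#' Generate a synthetic DTI network with planted cluster structure
#'
#' Drugs and targets are partitioned into `n_clusters` clusters; drug
#' cluster g is matched to target cluster g. Similarities equal
#' `within_cluster_sim` inside a cluster and `between_cluster_sim`
#' outside, plus an optional symmetric uniform jitter clipped to \[0, 1\],
#' with the diagonal forced to 1. Interactions are planted independently
#' at rate `interaction_density` inside matched blocks only, then every
#' label is flipped with probability `label_noise`.
#'
#' @param spec a [synthetic_spec()].
#' @return a [dti_network()] with attributes `drug_clusters`,
#'   `target_clusters` and `planted` (the pre-noise interaction matrix).
#' @examples
#' net <- generate_network(synthetic_spec(n_drugs = 10, m_targets = 8,
#'                                        n_clusters = 2, seed = 7))
#' sum(net$interactions)
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_drugs
    m <- spec$m_targets
    dc <- cluster_assignment(n, spec$n_clusters)
    tc <- cluster_assignment(m, spec$n_clusters)
    ds <- block_similarity(dc, spec$within_cluster_sim,
                           spec$between_cluster_sim, spec$jitter)
    ts <- block_similarity(tc, spec$within_cluster_sim,
                           spec$between_cluster_sim, spec$jitter)
    matched <- outer(dc, tc, `==`)
    planted <- matrix(0, n, m)
    planted[matched] <- stats::rbinom(sum(matched), 1L,
                                      spec$interaction_density)
    y <- planted
    if (spec$label_noise > 0) {
      flips <- matrix(stats::rbinom(n * m, 1L, spec$label_noise), n, m)
      y <- abs(y - flips)
    }
    net <- dti_network(
      drug_ids = sprintf("D%04d", seq_len(n)),
      target_ids = sprintf("T%04d", seq_len(m)),
      drug_sim = ds, target_sim = ts, interactions = y
    )
    attr(net, "drug_clusters") <- dc
    attr(net, "target_clusters") <- tc
    dimnames(planted) <- dimnames(net$interactions)
    attr(net, "planted") <- planted
    net
  })
}
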