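---
title: "Screened negatives and spherical-search ELM tuning for drug-target interaction prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screened negatives and spherical-search ELM tuning for drug-target interaction prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spherelm)
```

## The model

A drug–target network consists of drug–drug similarities $CS \in
[0,1]^{n \times n}$, target–target similarities $PS \in [0,1]^{m \times
m}$ (unit diagonals, not necessarily symmetric), and binary interaction
labels $Y \in \{0,1\}^{n \times m}$, where $y_{kj} = 1$ marks a verified
interaction and $0$ means *unlabeled* — possibly a true non-interaction,
possibly an undiscovered one. The package predicts interaction scores
for unlabeled pairs in three stages.

### Stage 1: negative screening

Each unlabeled pair $(k, j)$ receives the average of two
similarity-weighted interaction profiles:

$$
SPC_{jk} = \frac{\sum_{l \ne j} PS_{jl}\, y_{kl}}{\sum_{l \ne j} PS_{jl}},
\qquad
SCP_{kj} = \frac{\sum_{i \ne k} CS_{ki}\, y_{ij}}{\sum_{i \ne k} CS_{ki}},
\qquad
S_{kj} = \tfrac{1}{2}(SPC_{jk} + SCP_{kj}).
$$

$SPC$ asks: how similar are drug $k$'s known targets to target $j$?
$SCP$ asks the mirrored question for drugs. Both are bounded in $[0,1]$
and increase monotonically when an interaction is added at a similar
neighbor. Pairs scoring lowest are the ones most dissimilar to the
entire known interaction set; `build_balanced_training_set()` takes all
positives plus the $\lceil \text{ratio} \cdot n_{pos} \rceil$
lowest-scoring unlabeled pairs as negatives (ratio 1 by default, giving
class balance). Ties are broken by row-major pair index so the
selection is deterministic.

Two boundary rules matter. When an entity has zero similarity mass (the
denominator vanishes) or no known interactions feeding the numerator,
that side of the score carries no evidence: it contributes $0$ and the
pair is flagged in the `undefined` mask of `score_all()`. Such pairs
remain eligible as negatives — total dissimilarity from the known
interactome is exactly what the screening rule treats as evidence of
non-interaction. The known set consists of verified interactions only;
no self-training augmentation with predicted pairs is performed.

### Stage 2: the extreme learning machine

Pair $(k, j)$ is encoded as the concatenation of target $j$'s similarity
profile and drug $k$'s similarity profile, a vector of length $m + n$
whose coordinate $m + k$ is the drug's unit self-similarity. The ELM
maps features through a fixed hidden layer $H = g(XW^\top + b)$
($g$ sigmoid by default; `tanh` and `identity` are available) and
solves only the output weights, in closed form, as the minimum-norm
least-squares solution $\beta = H^\dagger T$ via the SVD-based
Moore–Penrose pseudoinverse. No ridge term is used — the plain
pseudoinverse already handles rank deficiency, and regularization is
deliberately out of scope. Targets are plain $\{0,1\}$ scalars; ranking
metrics consume the continuous score $H\beta$ directly, and hard labels
(when requested) threshold at $0.5$.

### Stage 3: spherical-search tuning of the hidden layer

The hidden layer $(W, b)$ is flattened row-major into a vector of
dimension $D = L(d+1)$ and optimized over the box $[-1, 1]^D$ — the
natural weight range for sigmoid activations on $[0,1]$-valued
features. The optimizer is a spherical-search evolutionary method:

* **Trial generation.** For individual $x_i$, a search direction $z_i$
  is built either *towards-rand* ($x_p + x_q - x_r - x_i$, used by the
  better half of the population, which can afford to explore) or
  *towards-best* ($x_{pbest} + x_q - x_r - x_i$ with $x_{pbest}$ drawn
  from the top 11%, pulling weak solutions toward good ones; an odd
  population places its median individual in this half). The trial is
  $y_i = x_i + c_i\, m_i z_i$, where $m_i = A^\top \mathrm{diag}(b_i) A$
  is a random orthogonal projection of rank $r_i$ — so the step
  explores a random $r_i$-dimensional slice of a spherical neighborhood
  around the direction. Coordinates leaving the box are repaired to the
  midpoint between the parent coordinate and the violated bound.
* **Greedy selection.** A trial replaces its parent iff its objective
  is no worse; the best-so-far trace is therefore monotone.
* **Success-history adaptation.** A $2 \times 5$ memory stores recent
  successful control values: projection ranks (as probabilities $r/D$)
  and step sizes. New values are sampled by choosing a memory column
  uniformly, then $r_i \sim \mathrm{Binomial}(D, \cdot)$ clamped to
  $[1, D-1]$ and $c_i \sim \mathrm{Cauchy}(\cdot, 0.1)$, redrawn while
  non-positive and truncated at 1. After each iteration the cursor cell
  is overwritten with improvement-weighted Lehmer means
  $\sum w v^2 / \sum w v$, which never fall below the arithmetic mean
  and so bias the memory toward larger successful values. The memory is
  seeded at rank probability $0.5$ and step $0.7$. If every accepted
  trial tied its parent exactly (zero total improvement), equal weights
  are used so the mean stays defined.
* **Population reduction.** The population interpolates from 100 down
  to 4 over the evaluation budget (linear by default; an exponential
  schedule is available), dropping the worst-ranked individuals
  whenever the target shrinks. Four is the floor because trial
  generation needs four distinct indices.

The fitness is the $k$-fold cross-validated mean of
$(\mathrm{AUC} + \mathrm{AUPR})/2$ (the across-fold *sum*, which is
just $k$ times the mean, is exposed alongside), maximized by minimizing
its negation. Folds are stratified and fixed once per experiment from
the master seed, so the optimizer faces a stationary objective rather
than chasing resampling noise; an ELM parameter vector is evaluated by
re-solving $\beta$ on each training fold with the hidden layer held
fixed.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `ratio` | 1 | screened negatives per positive |
| `hidden_nodes` (L) | 100 (ELM), 20 (pipeline) | hidden-layer width; the pipeline default keeps the search dimension $D = L(d+1)$ desk-scale |
| `activation` | sigmoid | hidden nonlinearity |
| `folds` | 10 | CV folds inside the fitness |
| `nfes_max` | 10,000 (optimizer), 2,000 (pipeline) | objective-evaluation budget |
| `pop_init`, `pop_min` | 100, 4 | population schedule endpoints |
| `pbest_rate` | 0.11 | top fraction eligible as towards-best attractor |
| `memory_size` | 5 | success-history columns |

The optimizer defaults are the published control settings of the
method; the pipeline-level `hidden_nodes = 20` and `nfes_max = 2000`
are this package's desk-scale choices (see *Problem sizes* below).

## Metrics and their tie rules

`compute_auc()` uses the rank statistic (Wilcoxon–Mann–Whitney): tied
positive/negative score pairs contribute $1/2$, and the value is
invariant under strictly monotone transforms of the scores.
`compute_aupr()` is average precision — the mean of the precision at
each positive's rank — rather than trapezoidal interpolation of the PR
curve, which is known to be optimistic. Tied scores are ordered
negatives-first, a pessimistic convention under which the reported
value never benefits from an arbitrary tie order; with all scores tied
the precision at the $j$-th positive is $j/(n_{neg}+j)$, slightly
*below* prevalence. Confusion counts, where needed, threshold scores at
0.5, but ROC/PR always sweep the full score range.

`friedman_test()` ranks methods ascending within each dataset column
(best method = rank $k$, matching the convention in which the
top-performing method carries the highest average rank), averages tied
rank positions, and corrects the chi-square statistic by
$C = 1 - \sum(t^3-t)/\bigl(n(k^3-k)\bigr)$; the statistic is undefined
(and an error) when every column is completely tied. The package ships
the 9-method × 4-dataset AUC and AUPR benchmark tables as fixtures, and
the test suite verifies the statistic and average ranks against their
published values.

## The synthetic generator

`generate_network()` plants the one structural feature the screening
rule relies on: *similar drugs share targets*. Drugs and targets are
split into matched clusters (sizes as equal as possible, remainder to
the first clusters); similarity is `within_cluster_sim` (default 0.8)
inside a cluster and `between_cluster_sim` (default 0.2) outside, the
high/low levels chosen to mimic the clear modular structure of the
benchmark classes while keeping the two levels well separated; a small
symmetric jitter (±0.02) breaks ties so screening sorts are almost
surely unique (set `jitter = 0` for exact tests). Interactions are
planted Bernoulli(`interaction_density`) inside matched blocks only,
then every label flips with probability `label_noise`. The default
40 × 40, 4-cluster, density-0.3, noise-free configuration is the
benchmark used throughout the acceptance tests.

What the generator does *not* emulate: realistic similarity
distributions (SIMCOMP scores are heavily right-skewed), hub drugs and
promiscuous targets, correlated noise, or asymmetric similarities.
Passing tests on synthetic networks therefore demonstrate correctness
of the machinery and recoverability of planted structure — not
performance on real chemogenomic data, which is why full-size
benchmark runs remain a separate, optional exercise.

One property of the screening score deserves emphasis: it scales with
interaction degree. A planted positive whose drug and target each have
only one or two other interactions can score *below* a well-connected
cross-block pair, so "every positive outranks every unlabeled
cross-block pair" is false pointwise even on noise-free networks. What
holds — and what the tests assert — is that positives outscore
cross-block pairs on average, and that the *selected* negative set
(the lowest-scoring slice actually used for training) sits strictly
below every positive and entirely in unmatched blocks. The practical
reading: screening is reliable for choosing negatives, but sparse
"cold-start" entities are exactly where its evidence is weakest.

## Numerical choices

* **Pseudoinverse.** `MASS::ginv` (SVD with the standard relative
  tolerance). Tests verify the Moore–Penrose identity, least-squares
  optimality against random coefficient draws, and minimum-norm
  agreement with a direct SVD solve on rank-deficient fixtures.
* **Orthogonal matrices.** One orthogonal matrix is generated per
  iteration and shared across individuals (per-individual binary masks
  differ); refreshing per individual would multiply the cost without an
  established benefit. Up to dimension 200 the matrix comes from QR
  orthogonalization of a standard-normal matrix. Above that — the ELM
  search sits around $D \approx 1600$ — a dense QR is an $O(D^3)$
  factorization per iteration that would dominate the entire run, so
  the operator is instead a product of two random Householder
  reflections and a random signed permutation: exactly orthogonal,
  $O(D)$ to apply, and every projection law (symmetry, idempotency,
  trace = rank, step confined to the projection subspace) holds
  identically. The test suite checks both constructions.
* **Initialization** draws coordinates from the half-open interval
  $(\text{lower}, \text{upper}]$, implemented as $1 - U[0,1)$ scaled to
  the box.
* **Bound repair** is midpoint reflection toward the violated bound,
  the convention standard in success-history DE variants.
* **Degenerate objectives.** Non-finite objective values are treated as
  $+\infty$ with a warning; an infinite parent replaced by an infinite
  trial records zero improvement.
* **Determinism.** Every stochastic entry point takes a seed and runs
  under a local RNG scope that restores the caller's `.Random.seed`,
  so identical seeds give bit-identical networks, folds, populations
  and traces.

## Problem sizes used by the test suite

The suite runs entirely on synthetic or hand-built fixtures: screening
oracles on 10 × 10 random networks, metric oracles on instances of up
to 25 samples, optimizer benchmarks on the 10-D sphere with the full
10,000-evaluation budget, and the end-to-end pipeline on the 40 × 40
planted-cluster network with a 2,000-evaluation budget and $L = 20$
hidden nodes — sizes chosen so the planted structure is comfortably
recoverable while a complete run stays in the minutes range on a single
core. The paired benchmark (tuned hidden layer versus a single random
draw on identical folds, 20 seeds) is the desk-scale form of the
method's core claim that optimizing the ELM's hidden layer beats
accepting a random one.

## Known limitations

* Screening uses known interactions only; iterative augmentation with
  high-confidence predictions is not implemented (the procedure is
  underdetermined, and PU-learning is a non-goal).
* The screening score's degree dependence (above) makes sparse entities
  its weak spot.
* No archive mechanism is maintained in the optimizer; accepted
  parents are simply replaced.
* Pair-level cross-validation estimates in-network generalization; it
  does not measure cold-start performance for entirely new drugs or
  targets, which would require per-entity splits.
* Similarity values are consumed as stored — no rescaling, no
  symmetrization unless requested, and missing entries are an error
  rather than imputed, since the screening denominators would be
  undefined under missingness.
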