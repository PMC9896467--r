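# Spherical search: a population-based global optimizer whose trial points
# lie on projected spherical neighborhoods of the current solutions. Trial
# steps are c_i * m_i %*% z_i with m_i = A' diag(b_i) A a random orthogonal
# projection of rank rank_i; rank_i and the step size c_i are adapted by a
# success-history memory (weighted Lehmer means of values that produced
# improvements), and the population shrinks from pop_init to pop_min over
# the evaluation budget.

#' Configuration for the spherical-search optimizer
#'
#' Defaults are the published control settings of the method: budget
#' 10,000 evaluations, population 100 shrinking to 4, pbest rate 0.11,
#' success-history memory of 5 columns seeded with rank probability 0.5
#' and step size 0.7.
#'
#' @param dimension problem dimension D.
#' @param lower,upper box bounds, scalars or length-D vectors.
#' @param nfes_max maximum number of objective evaluations.
#' @param pop_init initial population size.
#' @param pop_min final population size (>= 4; trial generation needs four
#'   distinct indices).
#' @param pbest_rate fraction of top solutions eligible as the
#'   towards-best attractor.
#' @param memory_size number of success-history memory columns H.
#' @param init_rank_prob initial value of the rank-probability memory row.
#' @param init_step initial value of the step-size memory row.
#' @param reduction population schedule: `"linear"` (default) or
#'   `"exponential"` interpolation from `pop_init` to `pop_min`.
#' @param seed integer seed; a run is fully reproducible from it.
#' @return object of class `ss_config`.
#' @export
ss_config <- function(dimension, lower = -1, upper = 1, nfes_max = 10000,
                      pop_init = 100, pop_min = 4, pbest_rate = 0.11,
                      memory_size = 5, init_rank_prob = 0.5, init_step = 0.7,
                      reduction = c("linear", "exponential"), seed = 1) {
  reduction <- match.arg(reduction)
  dimension <- as.integer(dimension)
  stopifnot(dimension >= 1, nfes_max >= 1, pop_init >= 4, pop_min >= 4,
            pop_min <= pop_init, memory_size >= 1)
  if (!(pbest_rate > 0 && pbest_rate <= 1)) stopf("pbest_rate must be in (0, 1]")
  lower <- rep_len(as.numeric(lower), dimension)
  upper <- rep_len(as.numeric(upper), dimension)
  if (!all(is.finite(lower)) || !all(is.finite(upper)) || any(lower >= upper)) {
    stopf("bounds must be finite with lower < upper")
  }
  structure(
    list(dimension = dimension, lower = lower, upper = upper,
         nfes_max = as.integer(nfes_max), pop_init = as.integer(pop_init),
         pop_min = as.integer(pop_min), pbest_rate = pbest_rate,
         memory_size = as.integer(memory_size),
         init_rank_prob = init_rank_prob, init_step = init_step,
         reduction = reduction, seed = as.integer(seed)),
    class = "ss_config"
  )
}

ss_safe_eval <- function(objective, x) {
  v <- objective(x)
  if (!is.numeric(v) || length(v) != 1L || is.na(v) || !is.finite(v)) {
    warnf("objective returned a non-finite value; treated as +Inf")
    v <- Inf
  }
  v
}

#' Initialize a spherical-search population
#'
#' Draws every coordinate uniformly from (lower, upper\] and evaluates the
#' objective once per individual. Uses the current RNG state; callers
#' wanting reproducibility seed the RNG (as [ss_optimize()] does from
#' `config$seed`).
#'
#' @param objective function mapping a length-D vector to a scalar
#'   (minimized).
#' @param config an [ss_config()].
#' @return list with `population` (N x D), `fitness`, `memory` (2 x H),
#'   `memory_cursor`, `nfes`.
#' @export
ss_init_population <- function(objective, config) {
  n <- config$pop_init
  d <- config$dimension
  # 1 - runif in [0,1) gives (0,1], matching the open-low interval
  u <- 1 - matrix(stats::runif(n * d), n, d)
  pop <- sweep(sweep(u, 2L, config$upper - config$lower, `*`),
               2L, config$lower, `+`)
  fit <- apply(pop, 1L, function(x) ss_safe_eval(objective, x))
  memory <- rbind(rep(config$init_rank_prob, config$memory_size),
                  rep(config$init_step, config$memory_size))
  list(population = pop, fitness = fit, memory = memory,
       memory_cursor = 1L, nfes = n)
}

#' Random orthogonal projection matrix
#'
#' Builds `m = t(A) %*% diag(b) %*% A` where A is a random orthogonal
#' matrix (QR orthogonalization of a standard-normal matrix) and b a
#' random binary mask with `rank` ones. The result is symmetric,
#' idempotent, and has trace equal to `rank`. Uses the current RNG state.
#'
#' @param D dimension.
#' @param rank projection rank, in 1..D (inside the optimizer the rank is
#'   kept strictly below D so the step is a genuine projection).
#' @return D x D projection matrix.
#' @export
ss_make_projection <- function(D, rank) {
  if (!(rank >= 1 && rank <= D)) stopf("rank must be in 1..%d", D)
  A <- qr.Q(qr(matrix(stats::rnorm(D * D), D, D)))
  mask <- numeric(D)
  mask[sample.int(D, rank)] <- 1
  t(A) %*% (mask * A)
}

# Orthogonal operator used inside the optimizer. For small D a dense
# QR-orthogonalized matrix; for large D a product of two random
# Householder reflections and a random signed permutation, which is
# exactly orthogonal but applies in O(D) instead of O(D^2) (and avoids an
# O(D^3) factorization per iteration).
ss_random_orthogonal <- function(D, dense_limit = 200L) {
  if (D <= dense_limit) {
    A <- qr.Q(qr(matrix(stats::rnorm(D * D), D, D)))
    list(
      apply = function(z) drop(A %*% z),
      apply_t = function(z) drop(crossprod(A, z))
    )
  } else {
    u1 <- stats::rnorm(D); u1 <- u1 / sqrt(sum(u1^2))
    u2 <- stats::rnorm(D); u2 <- u2 / sqrt(sum(u2^2))
    perm <- sample.int(D)
    signs <- sample(c(-1, 1), D, replace = TRUE)
    iperm <- order(perm)
    refl <- function(u, z) z - 2 * u * sum(u * z)
    list(
      # A = P S H2 H1 (P permutation, S signs, H reflections)
      apply = function(z) (signs * refl(u2, refl(u1, z)))[perm],
      apply_t = function(z) refl(u1, refl(u2, signs * z[iperm]))
    )
  }
}

#' Sample per-individual control parameters from the success memory
#'
#' For each of `n` individuals a memory column is chosen uniformly;
#' `rank_i` is drawn from Binomial(D, memory\[1, j\]) and clamped to
#' \[1, D - 1\]; `c_i` is drawn from Cauchy(memory\[2, j\], 0.1),
#' redrawn while non-positive and truncated at 1. Uses the current RNG.
#'
#' @param memory 2 x H success-history matrix.
#' @param n number of individuals.
#' @param D problem dimension.
#' @return list with integer vector `rank` and numeric vector `step`.
#' @export
ss_sample_control <- function(memory, n, D) {
  h <- ncol(memory)
  j <- sample.int(h, n, replace = TRUE)
  rank <- stats::rbinom(n, D, memory[1L, j])
  rank <- pmin(pmax(rank, 1L), max(D - 1L, 1L))
  step <- stats::rcauchy(n, memory[2L, j], 0.1)
  bad <- step <= 0
  while (any(bad)) {
    step[bad] <- stats::rcauchy(sum(bad), memory[2L, j[bad]], 0.1)
    bad <- step <= 0
  }
  list(rank = as.integer(rank), step = pmin(step, 1))
}

#' Assign search directions across the population
#'
#' The better half of the population (by objective value) explores with
#' towards-rand steps; the worse half is pulled by towards-best steps. An
#' odd population puts the median individual in the worse half. Ties are
#' resolved by index order (stable sort), so the split is deterministic.
#'
#' @param fitness numeric vector of objective values (minimization).
#' @return character vector of `"rand"`/`"best"` labels per individual.
#' @export
ss_assign_directions <- function(fitness) {
  n <- length(fitness)
  n_rand <- n %/% 2L
  dirs <- rep("best", n)
  dirs[order(fitness)[seq_len(n_rand)]] <- "rand"
  dirs
}

#' Weighted Lehmer mean
#'
#' `sum(w v^2) / sum(w v)` - the contraharmonic mean used by
#' success-history parameter adaptation; it never falls below the weighted
#' arithmetic mean, biasing the memory toward larger successful values.
#'
#' @param values positive values of successful control parameters.
#' @param weights non-negative weights (normalized improvements).
#' @return scalar.
#' @export
ss_lehmer_mean <- function(values, weights = rep(1, length(values))) {
  if (sum(weights) == 0) weights <- rep(1, length(values))
  sum(weights * values^2) / sum(weights * values)
}

#' Update the success-history memory
#'
#' When an iteration produced successful trials, the cursor column of the
#' memory is overwritten with the weighted Lehmer means of the successful
#' rank values (stored as probabilities rank/D) and step sizes, weighted
#' by the fitness improvements; the cursor then advances cyclically. With
#' no successes the memory is unchanged.
#'
#' @param memory 2 x H matrix.
#' @param cursor current column index.
#' @param s_rank integer vector of successful ranks.
#' @param s_step numeric vector of successful step sizes.
#' @param improvements fitness improvements (parent - trial) per success.
#' @param D problem dimension (converts ranks to probabilities).
#' @return list with updated `memory` and `cursor`.
#' @export
ss_update_memory <- function(memory, cursor, s_rank, s_step, improvements, D) {
  if (length(s_rank) == 0L) {
    return(list(memory = memory, cursor = cursor))
  }
  w <- improvements
  if (sum(w) <= 0) w <- rep(1, length(w)) else w <- w / sum(w)
  memory[1L, cursor] <- ss_lehmer_mean(s_rank / D, w)
  memory[2L, cursor] <- ss_lehmer_mean(s_step, w)
  cursor <- cursor %% ncol(memory) + 1L
  list(memory = memory, cursor = cursor)
}

#' Population-size schedule
#'
#' Interpolates the population size from `pop_init` at zero evaluations to
#' `pop_min` at budget exhaustion, linearly by default or exponentially
#' (`round(pop_init * (pop_min/pop_init)^(nfes/nfes_max))`).
#'
#' @param nfes evaluations used so far.
#' @param config an [ss_config()].
#' @return integer target population size.
#' @export
ss_pop_schedule <- function(nfes, config) {
  frac <- min(nfes / config$nfes_max, 1)
  size <- if (config$reduction == "linear") {
    round(config$pop_init + (config$pop_min - config$pop_init) * frac)
  } else {
    round(config$pop_init * (config$pop_min / config$pop_init)^frac)
  }
  max(as.integer(size), config$pop_min)
}

# One trial vector for individual i. `ord` is the index permutation
# sorting the population best-first; bound violations are repaired to the
# midpoint between the parent coordinate and the violated bound.
ss_trial <- function(pop, ord, i, step, proj_apply, proj_apply_t, mask,
                     direction, config) {
  n <- nrow(pop)
  if (n < 4L) stopf("population too small to draw three distinct partners")
  others <- sample(setdiff(seq_len(n), i), 3L)
  xi <- pop[i, ]
  if (direction == "rand") {
    z <- pop[others[1L], ] + pop[others[2L], ] - pop[others[3L], ] - xi
  } else {
    top <- max(1L, ceiling(config$pbest_rate * n))
    pbest <- ord[sample.int(top, 1L)]
    z <- pop[pbest, ] + pop[others[1L], ] - pop[others[2L], ] - xi
  }
  y <- xi + step * proj_apply_t(mask * proj_apply(z))
  low <- y < config$lower
  if (any(low)) y[low] <- (xi[low] + config$lower[low]) / 2
  high <- y > config$upper
  if (any(high)) y[high] <- (xi[high] + config$upper[high]) / 2
  y
}

#' Run the spherical-search optimizer
#'
#' Minimizes `objective` over the box in `config` with the full loop:
#' control-parameter sampling from the success memory, projected trial
#' steps (towards-rand for the better half of the population,
#' towards-best for the worse half), greedy selection (a trial replaces
#' its parent when its objective is no worse), Lehmer-mean memory update,
#' and population reduction. Fully reproducible from `config$seed`.
#'
#' To maximize a bounded fitness, pass its negation as the objective.
#'
#' @param objective function: length-D numeric vector -> scalar.
#'   Non-finite returns are treated as +Inf with a warning.
#' @param config an [ss_config()].
#' @return list of class `ss_result`: `par` (best solution), `value`
#'   (best objective), `nfes`, `trace` (data frame with one row per
#'   iteration: `iteration`, `nfes`, `pop_size`, `best_value`),
#'   `population`, `fitness`, `memory`.
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- ss_optimize(sphere, ss_config(5, -5, 5, nfes_max = 2000, seed = 1))
#' res$value
#' @export
ss_optimize <- function(objective, config) {
  stopifnot(inherits(config, "ss_config"))
  with_seed(config$seed, ss_optimize_impl(objective, config))
}

ss_optimize_impl <- function(objective, config) {
  d <- config$dimension
  state <- ss_init_population(objective, config)
  pop <- state$population
  fit <- state$fitness
  memory <- state$memory
  cursor <- state$memory_cursor
  nfes <- state$nfes
  best_i <- which.min(fit)
  best_par <- pop[best_i, ]
  best_val <- fit[best_i]
  trace <- list()
  iter <- 0L

  while (nfes < config$nfes_max) {
    iter <- iter + 1L
    n <- nrow(pop)
    ord <- order(fit)
    dirs <- ss_assign_directions(fit)
    ctrl <- ss_sample_control(memory, n, d)
    orth <- ss_random_orthogonal(d)

    n_eval <- min(n, config$nfes_max - nfes)
    s_rank <- integer(0)
    s_step <- numeric(0)
    s_impr <- numeric(0)
    for (i in seq_len(n_eval)) {
      mask <- numeric(d)
      mask[sample.int(d, ctrl$rank[i])] <- 1
      y <- ss_trial(pop, ord, i, ctrl$step[i], orth$apply, orth$apply_t,
                    mask, dirs[i], config)
      fy <- ss_safe_eval(objective, y)
      nfes <- nfes + 1L
      if (fy <= fit[i]) {
        impr <- fit[i] - fy
        if (!is.finite(impr)) impr <- 0  # Inf parent replaced by Inf trial
        s_rank <- c(s_rank, ctrl$rank[i])
        s_step <- c(s_step, ctrl$step[i])
        s_impr <- c(s_impr, impr)
        pop[i, ] <- y
        fit[i] <- fy
        if (fy < best_val) {
          best_val <- fy
          best_par <- y
        }
      }
    }

    upd <- ss_update_memory(memory, cursor, s_rank, s_step, s_impr, d)
    memory <- upd$memory
    cursor <- upd$cursor

    target <- ss_pop_schedule(nfes, config)
    if (target < nrow(pop)) {
      keep <- order(fit)[seq_len(target)]
      pop <- pop[keep, , drop = FALSE]
      fit <- fit[keep]
    }
    trace[[iter]] <- c(iteration = iter, nfes = nfes,
                       pop_size = nrow(pop), best_value = best_val)
  }

  trace <- as.data.frame(do.call(rbind, trace))
  structure(
    list(par = best_par, value = best_val, nfes = nfes, trace = trace,
         population = pop, fitness = fit, memory = memory),
    class = "ss_result"
  )
}

#' @export
print.ss_result <- function(x, ...) {
  cat(sprintf("spherical search: best value %.6g after %d evaluations (final population %d)\n",
              x$value, x$nfes, nrow(x$population)))
  invisible(x)
}
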