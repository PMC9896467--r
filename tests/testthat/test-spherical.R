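# Spherical-search optimizer and its components.

sphere <- function(x) sum(x^2)

test_that("initial populations are uniform in the box and reproducible", {
  cfg <- ss_config(3, lower = c(-2, 0, 1), upper = c(2, 4, 3),
                   pop_init = 50, nfes_max = 100, seed = 4)
  a <- spherelm:::with_seed(4, ss_init_population(sphere, cfg))
  b <- spherelm:::with_seed(4, ss_init_population(sphere, cfg))
  expect_identical(a$population, b$population)
  expect_equal(a$nfes, 50)
  expect_length(a$fitness, 50)
  expect_true(all(sweep(a$population, 2, cfg$lower, `>`)))
  expect_true(all(sweep(a$population, 2, cfg$upper, `<=`)))

  # empirical coordinate mean over many draws within 3 sigma of midpoint
  big <- ss_config(1, lower = 0, upper = 1, pop_init = 10000, nfes_max = 10000)
  draws <- spherelm:::with_seed(1, ss_init_population(function(x) 0, big))
  se <- sqrt(1 / 12 / 10000)
  expect_lt(abs(mean(draws$population) - 0.5), 3 * se)
})

test_that("projection matrices obey the projection laws", {
  set.seed(10)
  for (rep in 1:20) {
    D <- sample(3:20, 1)
    r <- sample(seq_len(D - 1), 1)
    m <- ss_make_projection(D, r)
    expect_lt(max(abs(m - t(m))), 1e-9)          # symmetric
    expect_lt(max(abs(m %*% m - m)), 1e-9)       # idempotent
    expect_lt(abs(sum(diag(m)) - r), 1e-9)       # trace = rank
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(ev > 0.5), r)
    expect_lt(max(abs(ev - round(ev))), 1e-8)    # eigenvalues 0/1
  }
  expect_equal(ss_make_projection(4, 4), diag(4), tolerance = 1e-9)
  expect_error(ss_make_projection(5, 0), "rank")
  expect_error(ss_make_projection(5, 6), "rank")
})

test_that("the large-dimension orthogonal operator is exactly orthogonal", {
  set.seed(11)
  D <- 300  # above the dense QR cutoff
  orth <- spherelm:::ss_random_orthogonal(D)
  z <- rnorm(D)
  expect_lt(abs(sqrt(sum(orth$apply(z)^2)) - sqrt(sum(z^2))), 1e-9)
  expect_lt(max(abs(orth$apply_t(orth$apply(z)) - z)), 1e-9)
  # composed projection still idempotent
  mask <- as.numeric(runif(D) < 0.5)
  proj <- function(v) orth$apply_t(mask * orth$apply(v))
  expect_lt(max(abs(proj(proj(z)) - proj(z))), 1e-9)
})

test_that("control parameters follow the memory distributions", {
  D <- 40
  mem1 <- rbind(rep(1, 5), rep(0.7, 5))
  ctrl <- spherelm:::with_seed(1, ss_sample_control(mem1, 100, D))
  expect_true(all(ctrl$rank == D - 1))  # Binomial(D, 1) = D, clamped

  mem5 <- rbind(rep(0.5, 5), rep(0.7, 5))
  ctrl2 <- spherelm:::with_seed(2, ss_sample_control(mem5, 10000, D))
  se <- sqrt(D * 0.25 / 10000)
  expect_lt(abs(mean(ctrl2$rank) - 20), 3 * se)
  expect_true(all(ctrl2$rank >= 1 & ctrl2$rank <= D - 1))
  expect_true(all(ctrl2$step > 0 & ctrl2$step <= 1))
})

test_that("direction assignment splits the population by fitness", {
  d4 <- ss_assign_directions(c(3, 1, 4, 2))
  expect_equal(sum(d4 == "rand"), 2)
  expect_equal(d4[2], "rand")  # best individual explores
  expect_equal(d4[3], "best")  # worst individual exploits

  d5 <- ss_assign_directions(c(5, 4, 3, 2, 1))
  expect_equal(sum(d5 == "rand"), 2)
  expect_equal(sum(d5 == "best"), 3)  # odd N: median goes to the worse half

  tied <- ss_assign_directions(rep(1, 4))
  expect_equal(tied, c("rand", "rand", "best", "best"))  # index order
})

test_that("the Lehmer mean reproduces hand values and dominates the mean", {
  expect_equal(ss_lehmer_mean(0.4), 0.4)
  expect_equal(ss_lehmer_mean(c(0.2, 0.8)), (0.04 + 0.64) / (0.2 + 0.8))
  set.seed(12)
  for (rep in 1:50) {
    v <- runif(sample(1:8, 1), 0.01, 1)
    w <- runif(length(v))
    expect_gte(ss_lehmer_mean(v, w) + 1e-12,
               sum(w * v) / sum(w))
  }
})

test_that("memory updates overwrite the cursor cell and cycle", {
  mem <- rbind(rep(0.5, 3), rep(0.7, 3))
  # no successes: unchanged
  u0 <- ss_update_memory(mem, 1L, integer(0), numeric(0), numeric(0), 10)
  expect_identical(u0$memory, mem)
  expect_identical(u0$cursor, 1L)
  # single success of value v -> cell equals v
  u1 <- ss_update_memory(mem, 1L, s_rank = 4L, s_step = 0.33,
                         improvements = 0.2, D = 10)
  expect_equal(u1$memory[1, 1], 0.4)
  expect_equal(u1$memory[2, 1], 0.33)
  expect_identical(u1$cursor, 2L)
  # cursor wraps around
  u3 <- ss_update_memory(u1$memory, 3L, 5L, 0.5, 1, 10)
  expect_identical(u3$cursor, 1L)
  # zero improvements fall back to equal weights
  u4 <- ss_update_memory(mem, 1L, c(2L, 8L), c(0.2, 0.8), c(0, 0), 10)
  expect_equal(u4$memory[2, 1], ss_lehmer_mean(c(0.2, 0.8)))
})

test_that("the population schedule interpolates pop_init to pop_min", {
  cfg <- ss_config(5, nfes_max = 10000, pop_init = 100, pop_min = 4)
  expect_equal(ss_pop_schedule(0, cfg), 100L)
  expect_equal(ss_pop_schedule(10000, cfg), 4L)
  sizes <- vapply(seq(0, 10000, by = 250), ss_pop_schedule, integer(1),
                  config = cfg)
  expect_false(is.unsorted(rev(sizes)))
  cfge <- ss_config(5, nfes_max = 10000, pop_init = 100, pop_min = 4,
                    reduction = "exponential")
  expect_equal(ss_pop_schedule(0, cfge), 100L)
  expect_equal(ss_pop_schedule(10000, cfge), 4L)
  expect_lt(ss_pop_schedule(5000, cfge), ss_pop_schedule(5000, cfg))
})

test_that("trial steps stay in the projection subspace and respect bounds", {
  set.seed(13)
  # bounds wide enough that no repair triggers: the raw step stays inside
  cfg <- ss_config(6, lower = -10, upper = 10, pop_init = 8, nfes_max = 100)
  pop <- matrix(runif(8 * 6, -1, 1), 8, 6)
  fit <- apply(pop, 1, sphere)
  ord <- order(fit)
  for (rep in 1:20) {
    r <- sample(1:5, 1)
    m <- ss_make_projection(6, r)
    proj_apply <- function(z) drop(m %*% z)   # pre-projected operator
    id <- function(z) z
    i <- sample(8, 1)
    y <- spherelm:::ss_trial(pop, ord, i, step = 0.6, proj_apply = proj_apply,
                             proj_apply_t = id, mask = rep(1, 6),
                             direction = sample(c("rand", "best"), 1),
                             config = cfg)
    expect_true(all(y >= cfg$lower & y <= cfg$upper))
    step_vec <- y - pop[i, ]
    # the step lies in the projection subspace: m (y - x) = (y - x)
    expect_lt(max(abs(m %*% step_vec - step_vec)), 1e-9)
  }
  # bound repair moves a violating coordinate to the parent/bound midpoint
  tight <- ss_config(6, lower = -1.01, upper = 1.01, pop_init = 8,
                     nfes_max = 100)
  blow <- function(z) z * 100
  yr <- spherelm:::ss_trial(pop, ord, 1, step = 1, proj_apply = blow,
                            proj_apply_t = id, mask = rep(1, 6),
                            direction = "rand", config = tight)
  expect_true(all(yr >= tight$lower & yr <= tight$upper))
  # zero step size or zero direction leaves the parent unchanged
  y0 <- spherelm:::ss_trial(pop, ord, 1, step = 0,
                            proj_apply = function(z) z,
                            proj_apply_t = function(z) z,
                            mask = rep(1, 6), direction = "rand", config = cfg)
  expect_equal(y0, pop[1, ])
})

test_that("greedy selection is monotone and accepts equal-fitness trials", {
  # accept-on-equal is observable through a constant objective: every
  # trial ties its parent, so the population keeps moving while the best
  # value stays the constant
  cfgc <- ss_config(3, nfes_max = 300, pop_init = 10, seed = 2)
  resc <- ss_optimize(function(x) 7, cfgc)
  expect_equal(resc$value, 7)
  expect_true(all(resc$trace$best_value == 7))

  cfg <- ss_config(5, lower = -5, upper = 5, nfes_max = 2000, pop_init = 20,
                   seed = 3)
  res <- ss_optimize(sphere, cfg)
  expect_false(is.unsorted(-res$trace$best_value))  # monotone best-so-far
  expect_true(all(res$population >= -5 & res$population <= 5))
})

test_that("full runs are reproducible and hit the budget exactly", {
  cfg <- ss_config(4, lower = -3, upper = 3, nfes_max = 1500, pop_init = 30,
                   seed = 11)
  a <- ss_optimize(sphere, cfg)
  b <- ss_optimize(sphere, cfg)
  expect_identical(a$trace, b$trace)
  expect_identical(a$par, b$par)
  expect_equal(a$nfes, 1500)
  expect_equal(nrow(a$population), 4)
})

test_that("non-finite objectives are treated as +Inf with a warning", {
  expect_warning(v <- spherelm:::ss_safe_eval(function(x) NaN, 1),
                 "non-finite")
  expect_identical(v, Inf)
  bad <- function(x) if (x[1] > 0) NaN else sum(x^2)
  cfg <- ss_config(2, lower = -1, upper = 1, nfes_max = 60, pop_init = 10,
                   seed = 5)
  res <- suppressWarnings(ss_optimize(bad, cfg))
  expect_true(is.finite(res$value))
  expect_lte(res$par[1], 0)
})

test_that("spherical search beats pure random search on quadratics", {
  quad <- function(x) sum((x - 0.5)^2 * seq_along(x))
  wins <- 0
  for (s in 1:10) {
    cfg <- ss_config(8, lower = -5, upper = 5, nfes_max = 1000,
                     pop_init = 30, seed = s)
    ss_val <- ss_optimize(quad, cfg)$value
    rs_val <- spherelm:::with_seed(s, {
      min(apply(matrix(runif(1000 * 8, -5, 5), 1000, 8), 1, quad))
    })
    wins <- wins + (ss_val < rs_val)
  }
  expect_gte(wins, 9)
})
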