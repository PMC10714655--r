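test_that("fitness matches the hand-computed one-step-ahead form", {
  # two concepts, one transition, zero network: predictions are sigmoid(0.5)
  obs <- fcm_trajectory(rbind(c(0.5, 0.5), c(0.6, 0.7)), c("a", "b"))
  W0 <- fcm_weights(matrix(0, 2, 2), c("a", "b"))
  # E = (|sigma(.5) - .6| + |sigma(.5) - .7|) / 2 = 0.05 exactly
  expect_equal(fcm_fitness(W0, obs), 1 / 6, tolerance = 1e-12)

  # perfect reproduction gives fitness exactly 1
  set.seed(11)
  W <- rand_map(3)
  traj <- rollout_traj(W, steps = 4)
  expect_identical(fcm_fitness(W, traj), 1)
  expect_identical(fcm_in_sample_error(W, traj), 0)
})

test_that("fitness and errors are invariant under concept relabelling", {
  set.seed(3)
  W <- rand_map(4)
  traj <- rollout_traj(W, steps = 3)
  perm <- c(3, 1, 4, 2)
  Wp <- fcm_weights(unclass(W)[perm, perm], rownames(W)[perm])
  tp <- fcm_trajectory(unclass(traj)[, perm])
  expect_equal(fcm_fitness(Wp, tp), fcm_fitness(W, traj), tolerance = 1e-15)
  expect_equal(fcm_in_sample_error(Wp, tp), fcm_in_sample_error(W, traj),
               tolerance = 1e-15)
})

test_that("in-sample error is the free-running deviation from baseline", {
  # single concept, zero weight: rollout gives sigmoid(0.5)
  obs <- fcm_trajectory(matrix(c(0.5, 0.9), 2, 1), "a")
  W0 <- fcm_weights(matrix(0, 1, 1), "a")
  expect_equal(fcm_in_sample_error(W0, obs),
               abs(1 / (1 + exp(-0.5)) - 0.9), tolerance = 1e-12)
  expect_equal(fcm_in_sample_error(W0, obs), 0.2775407, tolerance = 1e-6)
})

test_that("out-of-sample error is zero against itself and stable in k", {
  set.seed(21)
  W <- rand_map(3)
  expect_identical(fcm_out_of_sample_error(W, W, n_steps = 3, k = 5), 0)

  ref <- rand_map(3)
  set.seed(100)
  e1 <- fcm_out_of_sample_error(W, ref, n_steps = 3, k = 1000)
  set.seed(200)
  e2 <- fcm_out_of_sample_error(W, ref, n_steps = 3, k = 1000)
  expect_gte(e1, 0)
  expect_lt(abs(e1 - e2), 0.01)
})

test_that("crossover swaps exactly one cell and conserves values", {
  set.seed(5)
  a <- rand_map(3); b <- rand_map(3)
  for (i in 1:50) {
    cx <- fcm_crossover(a, b, prob = 1)
    d1 <- sum(cx$offspring[[1]] != a)
    d2 <- sum(cx$offspring[[2]] != b)
    expect_lte(d1, 1)
    expect_lte(d2, 1)
    expect_true(cx$modified)
    # the multiset of all 2 n^2 values is conserved across the pair
    expect_equal(sort(c(cx$offspring[[1]], cx$offspring[[2]])),
                 sort(c(unclass(a), unclass(b))), tolerance = 0)
  }
  # no-op branch and identical parents
  cx0 <- fcm_crossover(a, b, prob = 0)
  expect_identical(cx0$offspring[[1]], unclass(a)[, ])
  cxe <- fcm_crossover(a, a, prob = 1)
  expect_equal(cxe$offspring[[1]], unclass(a)[, ], tolerance = 0)
})

test_that("mutation redraws at most one cell, uniformly on [-1, 1]", {
  Z <- matrix(0, 3, 3)
  expect_identical(fcm_mutate(Z, prob = 0)$weights, Z)
  set.seed(9)
  vals <- numeric(1e4)
  for (i in seq_along(vals)) {
    m <- fcm_mutate(Z, prob = 1)
    changed <- which(m$weights != 0)
    expect_lte(length(changed), 1L)
    vals[i] <- if (length(changed)) m$weights[changed] else 0
  }
  ks <- suppressWarnings(stats::ks.test(vals, "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(vals >= -1 & vals <= 1))
})

test_that("tournament selection favours fitness and degenerates to argmax", {
  set.seed(2)
  fit <- c(0.1, 0.9, 0.3, 0.5)
  # full-size tournaments always return the best individual
  sel <- fcm_select(fit, size = 20, tournament_size = length(fit))
  expect_true(all(sel == 2L))
  # identical fitness keeps composition arbitrary but valid
  sel2 <- fcm_select(rep(0.5, 4), size = 10, tournament_size = 3)
  expect_true(all(sel2 %in% 1:4))
  expect_error(fcm_select(numeric(0)), "empty")
})

test_that("learning is reproducible, elitist and respects its budget", {
  set.seed(77)
  W <- rand_map(3, scale = 0.6)
  traj <- rollout_traj(W, steps = 4)
  ctl <- fcm_control(population_size = 30, max_generations = 25, seed = 123)
  fit1 <- fcm_learn(traj, ctl)
  fit2 <- fcm_learn(traj, ctl)
  expect_identical(fit1$weights, fit2$weights)
  expect_identical(fit1$fitness_history, fit2$fitness_history)
  # elitism: best fitness never decreases
  expect_true(all(diff(fit1$fitness_history) >= 0))
  expect_lte(fit1$generations, 25L)
  # every weight of the learned map respects the bounds
  expect_true(all(fit1$weights >= -1 & fit1$weights <= 1))

  # one-generation budget runs exactly one generation
  fit3 <- fcm_learn(traj, fcm_control(population_size = 10,
                                      max_generations = 1, seed = 1))
  expect_identical(fit3$generations, 1L)
})

test_that("the learner recovers small noise-free maps", {
  ok <- 0L
  for (s in 1:5) {
    set.seed(s)
    W <- rand_map(3, scale = 0.5)
    traj <- rollout_traj(W, steps = 4)
    fit <- fcm_learn(traj, fcm_control(population_size = 60,
                                       max_generations = 120,
                                       seed = 1000 + s),
                     reference = W, k_oos = 50)
    if (fit$in_sample_error <= 0.05) ok <- ok + 1L
    expect_gte(fit$out_of_sample_error, 0)
  }
  expect_gte(ok, 4L)
})

test_that("fcm_fit methods expose coefficients, predictions and residuals", {
  set.seed(8)
  W <- rand_map(3)
  traj <- rollout_traj(W, steps = 3)
  fit <- fcm_learn(traj, fcm_control(population_size = 20,
                                     max_generations = 10, seed = 4))
  expect_identical(coef(fit), fit$weights)
  p1 <- predict(fit)
  expect_identical(dim(p1), c(3L, 3L))
  expect_equal(unclass(residuals(fit)),
               unclass(traj)[-1, ] - p1, tolerance = 1e-15,
               ignore_attr = TRUE)
  pr <- predict(fit, type = "rollout")
  expect_identical(dim(pr), c(3L, 3L))
  sim <- simulate(fit)
  expect_s3_class(sim, "fcm_sim")
  expect_output(print(fit), "Fuzzy cognitive map fit")
  expect_output(print(summary(fit)), "nonzero edges")
})
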