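test_that("augmenting adds an inert-inbound intervention node", {
  set.seed(13)
  W <- rand_map(4)
  spec <- fcm_intervention(c(C2 = 0.5, C4 = -0.3), name = "demo")
  Wa <- fcm_augment(W, spec)
  expect_identical(dim(Wa), c(5L, 5L))
  # original block is bit-identical
  expect_identical(Wa[1:4, 1:4], unclass(W)[, ])
  node <- "intervention:demo"
  expect_identical(Wa[node, "C2"], 0.5)
  expect_identical(Wa[node, "C4"], -0.3)
  expect_true(all(Wa[node, c("C1", "C3", node)] == 0))
  # nothing points at the intervention node
  expect_true(all(Wa[, node] == 0))

  empty <- fcm_intervention(numeric(0), name = "empty")
  We <- fcm_augment(W, empty)
  expect_true(all(We[5, ] == 0) && all(We[, 5] == 0))

  expect_error(fcm_augment(W, fcm_intervention(c(zz = 0.5))), "zz")
})

test_that("a published-shape weight vector lands intact in the source row", {
  concepts <- fruit_intake_concepts()
  W <- fcm_weights(matrix(0, 16, 16), concepts)
  basic <- fcm_intervention(
    c(awareness = 0.591, attitude = 0.340, attitude_price = -0.340,
      self_efficacy_1 = 0.500, self_efficacy_2 = 0.058),
    name = "basic")
  Wa <- fcm_augment(W, basic)
  row <- Wa["intervention:basic", ]
  expect_identical(unname(row[c("awareness", "attitude", "attitude_price",
                                "self_efficacy_1", "self_efficacy_2")]),
                   c(0.591, 0.340, -0.340, 0.500, 0.058))
  expect_identical(sum(row != 0), 5L)
})

test_that("an inert intervention changes nothing and runs are deterministic", {
  set.seed(31)
  W <- rand_map(4)
  base <- fcm_state(setNames(runif(4, 0.2, 0.8), rownames(W)))
  spec <- fcm_intervention(numeric(0), name = "null")
  r1 <- fcm_run_scenario(W, base, spec)
  expect_true(r1$converged)
  expect_true(all(abs(r1$percent_change) == 0))
  expect_identical(r1$baseline_equilibrium, r1$intervention_equilibrium)
  r2 <- fcm_run_scenario(W, base, spec)
  expect_identical(r1, r2)

  # single-shot with zero perturbation is also an identity
  ss <- fcm_intervention(c(C1 = 0), name = "null", mode = "single-shot")
  r3 <- fcm_run_scenario(W, base, ss)
  expect_true(all(abs(r3$percent_change) == 0))
})

test_that("the intervention node stays clamped at its activation level", {
  set.seed(41)
  W <- rand_map(3)
  base <- fcm_state(setNames(runif(3, 0.2, 0.8), rownames(W)))
  spec <- fcm_intervention(c(C1 = 0.6), name = "x", activation = 0.8)
  Wa <- fcm_augment(W, spec)
  ctl <- fcm_sim_control(clamped = 4L)
  init <- c(base, 0.8)
  names(init) <- rownames(Wa)
  sim <- fcm_simulate(init, Wa, ctl)
  expect_true(all(sim$states[, 4] == 0.8))
})

test_that("a single positive edge raises its target at equilibrium", {
  set.seed(51)
  for (i in 1:20) {
    W <- rand_map(4)
    base <- fcm_state(setNames(runif(4, 0.2, 0.8), rownames(W)))
    spec <- fcm_intervention(c(C3 = 0.7), name = "up")
    r <- fcm_run_scenario(W, base, spec)
    expect_true(r$converged)
    expect_gt(r$percent_change[["C3"]], 0)
  }
})

test_that("cohort summaries match an independent re-summation", {
  set.seed(61)
  W <- rand_map(4)
  spec <- fcm_intervention(c(C2 = 0.5), name = "s")
  results <- lapply(1:25, function(i) {
    base <- fcm_state(setNames(runif(4, 0.2, 0.8), rownames(W)))
    attr(base, "participant_id") <- paste0("p", i)
    fcm_run_scenario(W, base, spec)
  })
  summ <- fcm_summarize_cohort(results, outcome = "C2")
  # independent tabulation: plain arithmetic over the raw results
  raw <- sapply(results, function(r) r$percent_change)
  expect_equal(summ$table$mean_pct_change, unname(rowMeans(raw)),
               tolerance = 1e-12)
  expect_equal(summ$table$sd_pct_change, unname(apply(raw, 1, sd)),
               tolerance = 1e-12)
  expect_identical(summ$n_converged, 25L)
  expect_identical(nrow(summ$individual), 25L)
  expect_equal(summ$individual$pct_change, unname(raw["C2", ]),
               tolerance = 1e-15)
})

test_that("degenerate cohorts are handled: n = 1 and unconverged runs", {
  set.seed(71)
  W <- rand_map(3)
  base <- fcm_state(setNames(runif(3, 0.2, 0.8), rownames(W)))
  spec <- fcm_intervention(c(C1 = 0.4), name = "s")
  one <- fcm_run_scenario(W, base, spec)
  summ1 <- fcm_summarize_cohort(list(one))
  expect_true(all(summ1$table$sd_pct_change == 0))
  expect_false(summ1$sd_defined)
  expect_equal(summ1$table$mean_pct_change, unname(one$percent_change),
               tolerance = 1e-15)

  # a run flagged unconverged is excluded from the summary
  bad <- one
  bad$converged <- FALSE
  summ2 <- fcm_summarize_cohort(list(one, bad))
  expect_identical(summ2$n_converged, 1L)
  expect_identical(summ2$n_excluded, 1L)
  expect_error(fcm_summarize_cohort(list(bad)), "no converged")
  expect_error(fcm_summarize_cohort(list()), "empty")
})
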