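test_that("endorsement activation returns expert fractions", {
  v <- fcm_vocabulary()
  act <- fcm_activate(c("low", "medium", "medium"), v)
  expect_equal(act[["low"]], 1 / 3, tolerance = 1e-15)
  expect_equal(act[["medium"]], 2 / 3, tolerance = 1e-15)
  expect_equal(sum(act), 1, tolerance = 1e-15)

  expect_equal(fcm_activate("medium", v), c(medium = 1))
  # non-existent counts in the denominator but activates nothing
  act2 <- fcm_activate(c("non-existent", "high", "high"), v)
  expect_identical(names(act2), "high")
  expect_equal(act2[["high"]], 2 / 3, tolerance = 1e-15)

  expect_error(fcm_activate(character(0), v), "at least one")
  expect_error(fcm_activate("enormous", v), "unknown linguistic term")
})

test_that("family-max aggregation is a clipped pointwise maximum", {
  v <- fcm_vocabulary()
  # a single fully activated term reproduces its own membership function
  c1 <- fcm_aggregate(c(medium = 1), v)
  expect_equal(c1, mf_membership(v$mfs$medium, v$grid), tolerance = 1e-15)

  act <- c(low = 1 / 3, medium = 2 / 3)
  agg <- fcm_aggregate(act, v)
  # commutative in its set argument
  expect_identical(agg, fcm_aggregate(rev(act), v))
  # bounded by 1 and dominating each clipped input
  expect_true(all(agg <= 1))
  expect_true(all(agg >= pmin(mf_membership(v$mfs$low, v$grid), 1 / 3)))
  expect_true(all(agg >= pmin(mf_membership(v$mfs$medium, v$grid), 2 / 3)))
})

test_that("the centroid of a symmetric triangle is its peak, exactly", {
  v <- fcm_vocabulary()
  # "medium" is symmetric about 0.5 under the default vocabulary
  expect_equal(fcm_defuzzify(fcm_aggregate(c(medium = 1), v), v$grid), 0.5)
  expect_identical(fcm_elicit_weight(c("medium", "medium", "medium"),
                                     vocab = v), 0.5)
  # a custom symmetric term returns its peak regardless of placement
  v2 <- fcm_vocabulary(peaks = c("very-low" = 0.1, "low" = 0.2,
                                 "medium" = 0.4, "high" = 0.6,
                                 "very-high" = 0.8))
  expect_equal(fcm_elicit_weight("medium", vocab = v2), 0.4,
               tolerance = 1e-12)
})

test_that("grid centroid agrees with a fine-grid oracle on all 3-expert multisets", {
  v <- fcm_vocabulary()
  sets <- term_multisets(fcm_terms(), 3)
  expect_length(sets, 56L)
  got <- vapply(sets, function(terms) {
    fcm_defuzzify(fcm_aggregate(fcm_activate(terms, v), v), v$grid)
  }, numeric(1))
  want <- vapply(sets, oracle_centroid, numeric(1), vocab = v)
  expect_true(all(abs(got - want) < 1e-3))
})

test_that("unanimously stronger ratings elicit strictly larger weights", {
  # single-expert upgrades are not monotone in general (an upgraded term's
  # clipped triangle can be narrower, shifting mass toward the remaining
  # lower terms), but unanimous panels order strictly with the vocabulary
  v <- fcm_vocabulary()
  graded <- setdiff(fcm_terms(), "non-existent")
  cents <- vapply(graded, function(term) {
    fcm_elicit_weight(rep(term, 3), vocab = v)
  }, numeric(1))
  expect_true(all(diff(cents) > 0))
  # each unanimous centroid is the full triangle's centre of mass
  expected <- vapply(v$mfs[graded], function(m) (m$a + m$b + m$c) / 3,
                     numeric(1))
  expect_equal(unname(cents), unname(expected), tolerance = 1e-3)
})

test_that("polarity signs the magnitude and conflicts are an error", {
  v <- fcm_vocabulary()
  expect_identical(fcm_elicit_weight("medium", polarity = -1, vocab = v),
                   -0.5)
  w <- fcm_elicit_weight(c("low", "medium", "medium"), polarity = -1,
                         vocab = v)
  expect_identical(w, -fcm_elicit_weight(c("low", "medium", "medium"),
                                         vocab = v))
  expect_error(
    fcm_elicit_weight(c("low", "high"), polarity = c(1, -1), vocab = v),
    "polarity conflict")
  # non-existent ratings are sign-neutral: no conflict with either side
  expect_silent(
    fcm_elicit_weight(c("non-existent", "high"), polarity = c(-1, 1),
                      vocab = v))
})

test_that("unanimous non-existent ratings elicit weight exactly zero", {
  v <- fcm_vocabulary()
  expect_identical(fcm_elicit_weight(rep("non-existent", 3), vocab = v), 0)
  expect_identical(
    fcm_elicit_weight(rep("non-existent", 2), polarity = -1, vocab = v), 0)
})

test_that("elicited magnitudes stay within the activated supports", {
  v <- fcm_vocabulary()
  for (tt in term_multisets(fcm_terms(), 3)) {
    active <- setdiff(unique(tt), "non-existent")
    if (!length(active)) next
    feet <- range(unlist(lapply(v$mfs[active], function(m) c(m$a, m$c))))
    w <- fcm_elicit_weight(tt, vocab = v)
    expect_gte(w, feet[1])
    expect_lte(w, feet[2])
  }
  # result is independent of expert ordering
  expect_identical(fcm_elicit_weight(c("low", "high", "medium"), vocab = v),
                   fcm_elicit_weight(c("high", "medium", "low"), vocab = v))
})

test_that("a ratings table elicits one signed weight per scenario target", {
  ratings <- read_ratings(system.file("extdata", "example_ratings.csv",
                                      package = "fcmlearn"))
  tab <- fcm_elicit_weights(ratings)
  basic <- tab[tab$scenario == "basic", ]
  # five targets, mirroring a basic nutrition-education scenario
  expect_setequal(basic$target,
                  c("awareness", "attitude", "attitude_price",
                    "self_efficacy_1", "self_efficacy_2"))
  expect_true(all(basic$weight[basic$target != "attitude_price"] > 0))
  expect_lt(basic$weight[basic$target == "attitude_price"], 0)
  expect_true(all(basic$n_experts == 3))
  plus <- tab[tab$scenario == "plus", ]
  expect_true(all(c("availability_home", "visibility_home") %in%
                    plus$target))
})
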