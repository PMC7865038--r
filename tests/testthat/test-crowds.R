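test_that("cumulative means are the running arithmetic means", {
  expect_equal(cumulative_means(c(10, 20, 30)), c(10, 15, 20))
  expect_equal(cumulative_means(7), 7)
  fx <- two_crowds_fixture()
  expect_equal(cumulative_means(fx$crowd_a), c(12, -1, 1 / 3))
  expect_error(cumulative_means(numeric(0)), "empty")
})

test_that("cumulative means agree with naive re-summation", {
  set.seed(42)
  for (r in 1:20) {
    x <- stats::rnorm(sample(1:50, 1), sd = 10^sample(-3:3, 1))
    oracle <- vapply(seq_along(x), function(t) mean(x[seq_len(t)]), 0)
    expect_lt(max(abs(cumulative_means(x) - oracle)), 1e-12 * max(1, max(abs(x))))
  }
})

test_that("inner crowds: one chronological series per participant and set size", {
  trials <- simulate_experiment(simulation_config(63, seed = 17))
  inner <- build_inner_crowds(trials)
  keys <- unique(inner[, c("unit_id", "set_size")])
  expect_equal(nrow(keys), 63 * 6)
  expect_true(all(table(inner$unit_id, inner$set_size) == 10))
  expect_true(all(inner$crowd_type == "inner"))

  # estimates appear in trial order, whatever positions the trials occupied
  scattered <- make_trials("P001", c(3L, 17L, 41L), 50L, c(30L, 40L, 50L))
  series <- build_inner_crowds(scattered)
  expect_equal(series$estimate, c(30, 40, 50))
  expect_equal(series$position, 1:3)
})

test_that("outer crowds have the right size, anchor and shared member order", {
  trials <- simulate_experiment(simulation_config(63, seed = 23))
  outer <- build_outer_crowds(trials, crowd_size = 10, seed = 4)
  crowds <- split(outer, outer$unit_id)
  expect_length(crowds, 63)
  firsts <- first_estimates(trials)
  for (cr in crowds) {
    anchor <- sub("^crowd:", "", cr$unit_id[1])
    # every participant anchors the one crowd named after them
    expect_true(all(cr$member_id[cr$position == 1] == anchor))
    # each set size aggregates crowd_size first estimates
    expect_true(all(table(cr$set_size) == 10))
    # member order is identical across the six set sizes
    orders <- split(cr$member_id[order(cr$set_size, cr$position)],
                    sort(cr$set_size))
    expect_length(unique(orders), 1L)
    # members enter with their chronologically first estimate
    m <- merge(cr, firsts,
               by.x = c("member_id", "set_size"),
               by.y = c("participant_id", "set_size"))
    expect_equal(m$estimate.x, as.numeric(m$estimate.y))
    # no repeated member within the crowd
    expect_equal(anyDuplicated(cr$member_id[cr$set_size == cr$set_size[1]]), 0L)
  }
})

test_that("crowd_size equal to n yields permutations of all participants", {
  trials <- simulate_experiment(simulation_config(6, seed = 2))
  outer <- build_outer_crowds(trials, crowd_size = 6, seed = 3)
  for (cr in split(outer, outer$unit_id)) {
    members <- cr$member_id[cr$set_size == cr$set_size[1]]
    expect_setequal(members, unique(trials$participant_id))
  }
  expect_error(build_outer_crowds(trials, crowd_size = 7, seed = 1), "exceeds")
})

test_that("companion sampling is uniform over the other participants", {
  trials <- simulate_experiment(simulation_config(5, seed = 9))
  # P(specific non-anchor in a given crowd) = 2/4 by the hypergeometric law
  hits <- vapply(1:2000, function(s) {
    outer <- build_outer_crowds(trials, crowd_size = 3, seed = s)
    cr <- outer[outer$unit_id == "crowd:P001" & outer$set_size == 50, ]
    "P002" %in% cr$member_id
  }, logical(1))
  p_hat <- mean(hits)
  expect_lt(abs(p_hat - 0.5), 4 * sqrt(0.25 / 2000))
})

test_that("curve observations square the proportional error of running means", {
  series <- data.frame(unit_id = "u1", crowd_type = "inner", set_size = 50,
                       position = 1:2, estimate = c(40, 60))
  obs <- curve_observations(series)
  expect_equal(obs$msep, c(0.04, 0))

  # optional median aggregation: robust to a wild third estimate
  wild <- data.frame(unit_id = "u1", crowd_type = "inner", set_size = 50,
                     position = 1:3, estimate = c(40, 60, 400))
  med <- curve_observations(wild, statistic = "median")
  expect_equal(cumulative_medians(c(40, 60, 400)), c(40, 50, 60))
  expect_equal(med$msep, c(0.04, 0, 0.04))

  perfect <- data.frame(unit_id = "u1", crowd_type = "inner", set_size = 70,
                        position = 1:10, estimate = rep(70, 10))
  expect_true(all(curve_observations(perfect)$msep == 0))

  # t = 1 is the squared proportional error of the first estimate
  trials <- simulate_experiment(simulation_config(10, seed = 19))
  inner <- build_inner_crowds(trials)
  obs <- curve_observations(inner)
  first <- inner[inner$position == 1, ]
  got <- obs[obs$t == 1, ]
  expect_equal(got$msep,
               squared_proportional_error(first$estimate, first$set_size))
})

test_that("aggregating raw estimates equals aggregating proportional errors", {
  trials <- simulate_experiment(simulation_config(8, seed = 29))
  inner <- build_inner_crowds(trials)
  obs_raw <- curve_observations(inner)
  prop <- inner
  prop$estimate <- proportional_error(inner$estimate, inner$set_size)
  running <- stats::ave(prop$estimate,
                        interaction(prop$unit_id, prop$set_size, drop = TRUE),
                        FUN = cumulative_means)
  expect_equal(obs_raw$msep[order(obs_raw$unit_id, obs_raw$set_size, obs_raw$t)],
               (running[order(prop$unit_id, prop$set_size, prop$position)])^2)
})

test_that("the full-crowd aggregate is invariant to member order", {
  trials <- simulate_experiment(simulation_config(8, seed = 37))
  final_msep <- function(seed) {
    outer <- build_outer_crowds(trials, crowd_size = 8, seed = seed)
    obs <- curve_observations(outer[, 1:5])
    x <- obs[obs$t == 8, ]
    x[order(x$unit_id, x$set_size), "msep"]
  }
  expect_equal(final_msep(1), final_msep(999))
})

test_that("mean aggregation error is non-increasing in t on average", {
  trials <- simulate_experiment(simulation_config(150, set_sizes = 70L,
                                                  seed = 41))
  obs <- curve_observations(build_inner_crowds(trials))
  curve <- tapply(obs$msep, obs$t, mean)
  se <- tapply(obs$msep, obs$t, function(x) stats::sd(x) / sqrt(length(x)))
  steps <- diff(curve)
  expect_true(all(steps <= 3 * se[-1]))
  expect_lt(curve[10], curve[1])
})

test_that("duplicate trial indices are rejected", {
  dup <- make_trials("P001", c(1L, 1L), 50L, c(40L, 45L))
  expect_error(build_inner_crowds(dup), "duplicate")
})
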