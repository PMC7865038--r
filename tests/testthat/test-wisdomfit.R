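test_that("parabolic mean behaves like a/t + b", {
  expect_equal(parabolic_mean(1:10, 0, 0.07), rep(0.07, 10))
  expect_lt(abs(parabolic_mean(1e9, 0.3, 0.045) - 0.045), 1e-8)
  expect_equal(parabolic_mean(1, 0.05, 0.09), 0.14)
  # strictly decreasing whenever a > 0
  vals <- parabolic_mean(1:50, 0.02, 0.01)
  expect_true(all(diff(vals) < 0))
  expect_error(parabolic_mean(0, 0.1, 0.1), "t must be")
  expect_error(parabolic_mean(1, -0.1, 0.1), "nonnegative")
})

test_that("half-normal prior density at zero follows the closed form", {
  expect_equal(prior_density_at_zero(half_normal_prior(0.5)),
               2 / (0.5 * sqrt(2 * pi)))
  expect_equal(round(prior_density_at_zero(half_normal_prior(0.5)), 5), 1.59577)
  expect_equal(round(prior_density_at_zero(half_normal_prior(1.0)), 5), 0.79788)
  expect_equal(dhalfnorm(c(-2, -0.001), half_normal_prior()), c(0, 0))
  expect_error(half_normal_prior(0), "positive")
})

test_that("prior draws give a Savage-Dickey ratio near one", {
  prior <- half_normal_prior(0.5)
  set.seed(314)
  bf <- savage_dickey_bf10(rhalfnorm(5e4, prior), prior)
  expect_gt(as.numeric(bf), 0.85)
  expect_lt(as.numeric(bf), 1.18)
  expect_error(savage_dickey_bf10(rhalfnorm(500, prior), prior), "1000")
})

test_that("posterior mass far from zero caps the Bayes factor finitely", {
  prior <- half_normal_prior(0.5)
  set.seed(9)
  draws <- 3.5 + abs(stats::rnorm(5000, 0, 0.05))  # all beyond 6 prior scales
  bf <- savage_dickey_bf10(draws, prior)
  expect_gte(as.numeric(bf), 3)
  expect_true(is.finite(as.numeric(bf)))
  expect_equal(as.numeric(bf), 1e6)
  expect_equal(attr(bf, "verdict"), "alternative")
})

test_that("the density estimator matches the conjugate truncated-normal oracle", {
  # toy model: y_i ~ N(a, s^2) with known s, prior a ~ half-normal(0, 0.5);
  # the posterior is N(m, v) truncated at 0, so the Savage-Dickey ratio has
  # a closed form to compare the kernel estimator against.
  prior <- half_normal_prior(0.5)
  s <- 0.5; n <- 25; ybar <- 0.12
  v <- 1 / (1 / prior$scale^2 + n / s^2)
  m <- v * n * ybar / s^2
  post0 <- stats::dnorm(0, m, sqrt(v)) / stats::pnorm(m / sqrt(v))
  bf_analytic <- prior_density_at_zero(prior) / post0

  set.seed(2718)
  u <- stats::runif(5e4)
  lo <- stats::pnorm(-m / sqrt(v))
  draws <- m + sqrt(v) * stats::qnorm(lo + u * (1 - lo))
  bf_hat <- savage_dickey_bf10(draws, prior)
  expect_lt(abs(as.numeric(bf_hat) - bf_analytic) / bf_analytic, 0.10)
})

test_that("verdicts follow the 3 / 0.33 evidence thresholds", {
  expect_equal(bf_verdict(c(3, 5, 0.33, 0.1, 1)),
               c("alternative", "alternative", "null", "null", "inconclusive"))
  expect_error(bf_verdict(-1))
})

test_that("the model recovers parameters from parabolic data", {
  obs <- sim_parabolic_obs(0.10, 0.045, n_units = 20, seed = 55)
  fit <- fit_crowd_model(obs, mcmc = mcmc_config(chains = 2,
                                                 draws_per_chain = 1500,
                                                 warmup = 750, seed = 12),
                         retries = 2)
  expect_s3_class(fit, "crowd_fit")
  expect_true(fit$a_ci95[1] <= 0.10 && 0.10 <= fit$a_ci95[2])
  expect_true(fit$b_ci95[1] <= 0.045 && 0.045 <= fit$b_ci95[2])
  expect_true(all(fit$a_draws >= 0) && all(fit$b_draws >= 0))
  gate <- fit$diagnostics[fit$diagnostics$parameter %in% c("a", "b", "sigma"), ]
  expect_true(all(gate$rhat <= fit$mcmc$rhat_threshold))

  # summary is consistent with the stored draws and Bayes factors
  s <- summarize_fit(fit)
  expect_equal(s$mean, c(fit$a_mean, fit$b_mean))
  expect_equal(s$bf10, c(as.numeric(fit$bf10_a), as.numeric(fit$bf10_b)))
  expect_equal(s$parameter, c("a", "b"))
})

test_that("flat observations shrink a towards zero and centre b on the level", {
  level <- 0.05
  obs <- sim_parabolic_obs(0, level, n_units = 15, noise = 0.002, seed = 77)
  fit <- fit_crowd_model(obs, mcmc = mcmc_config(chains = 2,
                                                 draws_per_chain = 1500,
                                                 warmup = 750, seed = 3),
                         retries = 2)
  prior_mean <- half_normal_prior()$scale * sqrt(2 / pi)
  expect_lt(fit$a_mean, prior_mean)
  expect_lt(fit$a_mean, 0.005)
  expect_lt(abs(fit$b_mean - level), 0.005)
  expect_equal(attr(fit$bf10_a, "verdict"), "null")
})

test_that("degenerate and malformed inputs raise the documented errors", {
  obs <- sim_parabolic_obs(0.1, 0.05, n_units = 10, seed = 1)
  one_t <- obs[obs$t == 1, ]
  expect_error(fit_crowd_model(one_t), class = "crowdwise_identifiability_error")

  mixed <- cbind(obs, crowd_type = rep(c("inner", "outer"), length.out = nrow(obs)))
  expect_error(fit_crowd_model(mixed), "one crowd type")

  expect_error(mcmc_config(chains = 1), "2 chains")

  neg <- obs; neg$msep[1] <- -0.01
  expect_error(fit_crowd_model(neg), "nonnegative")
  zero <- obs; zero$msep[1] <- 0
  expect_error(fit_crowd_model(zero, likelihood = "gamma"), "positive")
})

test_that("an unconverged short run raises a diagnostic-bearing error", {
  obs <- sim_parabolic_obs(0.1, 0.045, n_units = 30, seed = 5)
  err <- tryCatch(
    suppressWarnings(
      fit_crowd_model(obs, mcmc = mcmc_config(chains = 2, draws_per_chain = 40,
                                              warmup = 10,
                                              rhat_threshold = 1.0001))),
    crowdwise_convergence_error = function(e) e)
  expect_s3_class(err, "crowdwise_convergence_error")
  expect_true(is.data.frame(err$diagnostics))
  expect_true(all(c("rhat", "n_eff") %in% names(err$diagnostics)))
})

test_that("the gamma likelihood fits strictly positive curves", {
  obs <- sim_parabolic_obs(0.08, 0.05, n_units = 12, noise = 0.004, seed = 13)
  obs$msep <- pmax(obs$msep, 1e-4)
  fit <- fit_crowd_model(obs, mcmc = mcmc_config(chains = 2,
                                                 draws_per_chain = 1200,
                                                 warmup = 600, seed = 21),
                         likelihood = "gamma", retries = 2)
  expect_lt(abs(fit$a_mean - 0.08), 0.03)
  expect_lt(abs(fit$b_mean - 0.05), 0.02)
})

test_that("summaries render posterior mean, sd and Bayes factor verbatim", {
  fake <- structure(list(crowd_type = "inner",
                         a_mean = 0.05, a_sd = 0.01,
                         b_mean = 0.09, b_sd = 0.01,
                         a_ci95 = c(0.03, 0.07), b_ci95 = c(0.07, 0.11),
                         bf10_a = structure(1417.13, verdict = "alternative"),
                         bf10_b = structure(9.83e14, verdict = "alternative")),
                    class = "crowd_fit")
  s <- summarize_fit(fake)
  expect_equal(s$mean[s$parameter == "a"], 0.05)
  expect_equal(s$sd[s$parameter == "a"], 0.01)
  expect_equal(s$bf10[s$parameter == "a"], 1417.13)
  expect_equal(s$verdict, c("alternative", "alternative"))
})
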