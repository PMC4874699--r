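test_that("default sampler settings reproduce the study protocol", {
  s <- sampler_settings()
  expect_equal(s$n_chains, 8L)
  expect_equal(s$n_iter, 100000L)
  expect_equal(s$thin, 10L)
  expect_equal(s$n_adapt, 50000L)
  t <- sampler_settings("test")
  expect_equal(t$n_chains, 4L)
  expect_equal(t$n_iter, 5000L)
  expect_error(sampler_settings("test", n_chains = 1))
})

test_that("generic sampler recovers known distributions", {
  # standard normal target
  d <- sample_posterior(function(x) -x^2 / 2, init = 0,
                        settings = sampler_settings("test", seed = 31),
                        param_names = "z")
  z <- draws_of(d, "z")
  expect_lt(abs(mean(z)), 0.05)
  expect_lt(abs(stats::sd(z) - 1), 0.05)

  # Beta(3, 5) on (0, 1): mean 3/8, support handled by -Inf rejection
  d2 <- sample_posterior(function(x) stats::dbeta(x, 3, 5, log = TRUE),
                         init = 0.5,
                         settings = sampler_settings("test", seed = 32),
                         param_names = "p")
  p <- draws_of(d2, "p")
  expect_lt(abs(mean(p) - 0.375), 0.02)
  expect_true(all(p > 0 & p < 1))
})

test_that("sampling is deterministic given seed and settings", {
  lp <- function(x) -sum(x^2) / 2
  s <- sampler_settings("short", seed = 77)
  d1 <- sample_posterior(lp, c(0, 0), s)
  d2 <- sample_posterior(lp, c(0, 0), s)
  expect_identical(d1$draws, d2$draws)
  d3 <- sample_posterior(lp, c(0, 0), sampler_settings("short", seed = 78))
  expect_false(identical(d1$draws, d3$draws))
})

test_that("state-space fit is deterministic given seed", {
  ds <- simulate_dataset(small_sim_config(), seed = 9)
  f1 <- fit_state_space(ds$state_year, settings = sampler_settings("short", seed = 5))
  f2 <- fit_state_space(ds$state_year, settings = sampler_settings("short", seed = 5))
  expect_identical(f1$draws$draws, f2$draws$draws)
})

test_that("initialization failure errors with a diagnostic after bounded retries", {
  expect_error(
    sample_posterior(function(x) -Inf, init = 0,
                     settings = sampler_settings("short", seed = 1)),
    "initialization failed"
  )
})

test_that("posterior summaries match sorting and moment oracles", {
  chains <- list(matrix(c(1, 2, 3, 4, 5), ncol = 1),
                 matrix(c(5, 4, 3, 2, 1), ncol = 1))
  d <- posterior_draws(chains, "x", sampler_settings("short"), 1)
  s <- summarize_draws(d, "x")
  expect_equal(s$estimate, 3)
  expect_equal(s$std.error, stats::sd(c(1:5, 5:1)))
  # percentile interval equals the brute-force sorted-quantile oracle
  v <- sort(c(1:5, 5:1))
  expect_equal(c(s$conf.low, s$conf.high),
               stats::quantile(v, c(0.025, 0.975), names = FALSE))
  # invariant to chain concatenation order
  d_swap <- posterior_draws(rev(chains), "x", sampler_settings("short"), 1)
  s_swap <- summarize_draws(d_swap, "x")
  expect_equal(s_swap$estimate, s$estimate)
  expect_equal(s_swap$conf.low, s$conf.low)
})

test_that("derived growth summary decomposes r by signal and counts draws", {
  set.seed(8)
  n <- 500
  mk <- function(b0a, b0b, b1) {
    cbind(`beta0[A]` = b0a, `beta0[B]` = b0b, beta1 = b1)
  }
  chains <- list(mk(rnorm(n, 0.16, 0.01), rnorm(n, 0.14, 0.01), rnorm(n, -0.04, 0.01)),
                 mk(rnorm(n, 0.16, 0.01), rnorm(n, 0.14, 0.01), rnorm(n, -0.04, 0.01)))
  d <- posterior_draws(chains, colnames(chains[[1]]), sampler_settings("short"), 1)
  g <- derived_growth_summary(d, check_convergence = FALSE)
  b1 <- draws_of(d, "beta1")
  b0a <- draws_of(d, "beta0[A]")
  # r at D=0 is the beta0 draws; r at D=1 is beta0 + beta1
  expect_equal(g$growth$estimate[g$growth$state == "A" & g$growth$signal_D == 0],
               mean(b0a))
  expect_equal(g$growth$estimate[g$growth$state == "A" & g$growth$signal_D == 1],
               mean(b0a + b1))
  # probabilities equal brute-force draw counting
  expect_equal(g$p_negative, sum(b1 < 0) / length(b1))
  expect_equal(g$prob_ratio, (sum(b1 < 0) / length(b1)) / (sum(b1 > 0) / length(b1)))

  # all-negative draws: ratio reported as ">max"
  neg <- lapply(chains, function(m) { m[, "beta1"] <- -abs(m[, "beta1"]); m })
  dneg <- posterior_draws(neg, colnames(neg[[1]]), sampler_settings("short"), 1)
  gneg <- derived_growth_summary(dneg, check_convergence = FALSE)
  expect_equal(gneg$p_negative, 1)
  expect_identical(gneg$ratio_label, ">max")

  # symmetric draws: ratio near 1
  sym <- lapply(chains, function(m) { m[, "beta1"] <- c(-abs(m[1:(n/2), "beta1"]), abs(m[1:(n/2), "beta1"])); m })
  dsym <- posterior_draws(sym, colnames(sym[[1]]), sampler_settings("short"), 1)
  gsym <- derived_growth_summary(dsym, check_convergence = FALSE)
  expect_equal(gsym$prob_ratio, 1)
})

test_that("derived growth summary refuses unconverged draws", {
  set.seed(2)
  n <- 300
  mk <- function(shift) cbind(`beta0[A]` = rnorm(n, shift), beta1 = rnorm(n))
  chains <- list(mk(0), mk(40)) # wildly diverged beta0 chains
  d <- posterior_draws(chains, c("beta0[A]", "beta1"), sampler_settings("short"), 1)
  expect_error(derived_growth_summary(d), "convergence gate failed")
})

test_that("draws persist to per-chain CSVs and reload identically", {
  ds <- simulate_dataset(small_sim_config(), seed = 3)
  fit <- fit_state_space(ds$state_year, settings = sampler_settings("short", seed = 4))
  dir <- withr::local_tempdir()
  save_draws(fit$draws, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- load_draws(dir)
  expect_equal(back$param_names, fit$draws$param_names)
  expect_equal(back$draws, fit$draws$draws, tolerance = 1e-12)
  expect_equal(back$seed, fit$draws$seed)
})
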