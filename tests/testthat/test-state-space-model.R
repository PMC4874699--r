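test_that("growth rate is linear in the policy signal", {
  # posterior-mean-scale check: 0.16 baseline with -0.04 year-long effect
  expect_equal(growth_rate(0.16, -0.04, 1), 0.12)
  expect_equal(growth_rate(0.7, 0, 0.3), 0.7)
  expect_equal(growth_rate(0.14, -0.04, 0.5), 0.12)
  expect_error(growth_rate(0.1, 0.1, 1.5))
})

test_that("population projection is exponential growth minus scaled removals", {
  expect_equal(project_population(100, 0, 10, 1), 90)
  expect_equal(project_population(100, 0.16, 0, 3), 100 * exp(0.16))
  # gamma > 1: each culled wolf costs more than one wolf
  expect_equal(project_population(100, 0, 10, 1.5), 85)
  # over-culling floors at floor_eps rather than going negative
  expect_equal(project_population(10, 0, 100, 1), 1e-3)
})

test_that("process log-density is lognormal with closed-form value at the median", {
  for (case in list(c(50, 0.1), c(120, 0.05), c(3, 1.2))) {
    nd <- case[1]; s <- case[2]
    expect_equal(process_logdensity(nd, nd, s),
                 -log(nd) - log(s) - 0.5 * log(2 * pi))
  }
  # normalization by quadrature
  total <- stats::integrate(function(x) exp(process_logdensity(x, 80, 0.3)),
                            lower = 1e-8, upper = Inf)$value
  expect_equal(total, 1, tolerance = 1e-6)
  # lognormal scaling property: logdensity(kN, kN, s) + log(k) constant in k
  base <- process_logdensity(40, 40, 0.2)
  for (k in c(0.5, 2, 10)) {
    expect_equal(process_logdensity(k * 40, k * 40, 0.2) + log(k), base)
  }
})

test_that("observation layer has Poisson-Gamma mixture moments", {
  # E[n_obs] = theta * N (law of total expectation), Var = m + sigma^2
  theta <- 0.8; N <- 100; sigma <- 5
  m <- theta * N
  grid <- 0:2000
  mass <- exp(observation_logdensity(grid, N, theta, sigma))
  expect_equal(sum(mass), 1, tolerance = 1e-10)
  expect_equal(sum(grid * mass), m, tolerance = 1e-8)
  expect_equal(sum((grid - m)^2 * mass), m + sigma^2, tolerance = 1e-6)
})

test_that("observation layer converges to the Poisson mass as sigma_obs -> 0", {
  y <- 72; N <- 100; theta <- 0.8
  pois <- stats::dpois(y, theta * N, log = TRUE)
  diffs <- vapply(c(1, 0.1, 0.01),
                  function(s) abs(observation_logdensity(y, N, theta, s) - pois),
                  numeric(1))
  expect_true(all(diff(diffs) < 0))
  expect_lt(diffs[3], 1e-3)
  expect_error(observation_logdensity(5, 10, 0.5, 0), "sigma_obs")
})

test_that("joint log-posterior matches term-by-term brute-force summation", {
  data <- toy_state_year()
  params <- toy_params(data)
  priors <- default_priors()
  expect_equal(joint_logposterior(params, data, priors),
               brute_force_logposterior(params, data, priors),
               tolerance = 1e-10)
  # and across several random parameter points
  set.seed(11)
  for (i in 1:10) {
    p <- params
    p$beta0[] <- stats::rnorm(2, 0.1, 0.1)
    p$beta1 <- stats::rnorm(1, 0, 0.1)
    p$gamma <- stats::runif(1, 0.5, 1.5)
    p$sigma_proc <- stats::runif(1, 0.02, 0.5)
    p$theta_min <- stats::runif(1, 0.4, 1)
    p$theta_max <- stats::runif(1, 1, 3)
    p$sigma_obs_min <- stats::runif(1, 1, 20)
    p$sigma_obs_max <- stats::runif(1, 1, 20)
    p$n_true[] <- p$n_true * exp(stats::rnorm(8, 0, 0.2))
    expect_equal(joint_logposterior(p, data, priors),
                 brute_force_logposterior(p, data, priors),
                 tolerance = 1e-10)
  }
})

test_that("compiled log-posterior equals the R reference", {
  data <- toy_state_year()
  params <- toy_params(data)
  priors <- default_priors()
  model <- wolfpolicy:::ssm_model_list(data, priors, 1e-3)
  set.seed(5)
  for (i in 1:10) {
    p <- params
    p$n_true[] <- p$n_true * exp(stats::rnorm(8, 0, 0.3))
    p$sigma_proc <- stats::runif(1, 0.02, 0.5)
    p$theta_min <- stats::runif(1, 0.4, 1)
    pv <- pack_params(p, model$states, model$years)
    expect_equal(wolfpolicy:::cpp_ssm_logposterior(pv, model),
                 joint_logposterior(p, data, priors), tolerance = 1e-10)
  }
})

test_that("removing one observed count changes the log-posterior by its term", {
  data <- toy_state_year()
  params <- toy_params(data)
  lp_all <- joint_logposterior(params, data)
  drop <- data
  drop$n_obs_min[4] <- NA # state A, year 2004
  term <- observation_logdensity(data$n_obs_min[4],
                                 params$n_true["A", "2004"],
                                 params$theta_min, params$sigma_obs_min)
  expect_equal(joint_logposterior(params, drop), lp_all - term)
})

test_that("with beta1 = 0 the posterior is invariant to the signal covariate", {
  data <- toy_state_year()
  params <- toy_params(data)
  params$beta1 <- 0
  shuffled <- data
  shuffled$D <- c(1, 0.2, 0, 0.7, 0.9, 0, 1, 0.3)
  expect_equal(joint_logposterior(params, data),
               joint_logposterior(params, shuffled))
})

test_that("signal and implementation are separate: D matters even with no culling", {
  data <- toy_state_year()
  data$culled <- 0
  params <- toy_params(data)
  data2 <- data
  data2$D <- 0
  expect_false(isTRUE(all.equal(joint_logposterior(params, data),
                                joint_logposterior(params, data2))))
})

test_that("theta factors act only through their own observation layer", {
  data <- toy_state_year()
  params <- toy_params(data)
  lp <- joint_logposterior(params, data)
  # changing theta_max only shifts the max-count terms (state A has max counts)
  p2 <- params; p2$theta_max <- 1.5
  d_nomax <- data; d_nomax$n_obs_max <- NA
  expect_equal(joint_logposterior(params, d_nomax),
               joint_logposterior(p2, d_nomax))
  expect_false(isTRUE(all.equal(joint_logposterior(p2, data), lp)))
})

test_that("parameters outside prior support give -Inf, not an error", {
  data <- toy_state_year()
  params <- toy_params(data)
  bad <- params; bad$theta_min <- 1.2
  expect_identical(joint_logposterior(bad, data), -Inf)
  bad <- params; bad$sigma_proc <- -0.1
  expect_identical(joint_logposterior(bad, data), -Inf)
  bad <- params; bad$gamma <- -0.5
  expect_identical(joint_logposterior(bad, data), -Inf)
  bad <- params; bad$n_true["A", "2002"] <- -3
  expect_identical(joint_logposterior(bad, data), -Inf)
  # strictly inside support: finite
  expect_true(is.finite(joint_logposterior(params, data)))
})
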