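test_that("linear and logistic predictors have their closed forms", {
  expect_equal(pack_size_model(4, 0.002, 500), 5)
  expect_equal(pack_size_model(4, 0, c(10, 1000)), c(4, 4))
  expect_equal(reproduction_prob(0, 0, 123), 0.5)
  expect_equal(reproduction_prob(log(3), 0, 7), 0.75)
  # monotone in N with the sign of e1
  N <- seq(0, 1000, by = 100)
  expect_true(all(diff(reproduction_prob(0, 0.01, N)) > 0))
  expect_true(all(diff(reproduction_prob(0, -0.01, N)) < 0))
  expect_error(area_logdensity(100, 0, 1, 50, -1))
})

test_that("predictors are invariant under centring with intercept shift", {
  N <- c(100, 300, 700)
  nbar <- mean(N)
  expect_equal(pack_size_model(4 + 0.002 * nbar, 0.002, N - nbar),
               pack_size_model(4, 0.002, N))
  expect_equal(reproduction_prob(1 + 0.003 * nbar, 0.003, N - nbar),
               reproduction_prob(1, 0.003, N))
})

test_that("exact flat-prior area coefficients match the regression oracle", {
  set.seed(21)
  N <- stats::setNames(seq(100, 800, length.out = 10), 2001:2010)
  area <- tibble::tibble(
    wolf_year = 2001:2010,
    area_km2 = 500 + 15 * unname(N) + stats::rnorm(10, 0, 200)
  )
  exact <- area_fit_exact(area, N)
  oracle <- stats::lm(area_km2 ~ n, data = data.frame(area_km2 = area$area_km2,
                                                      n = unname(N)))
  expect_equal(exact$d0, unname(stats::coef(oracle)[1]), tolerance = 1e-8)
  expect_equal(exact$d1, unname(stats::coef(oracle)[2]), tolerance = 1e-8)
  expect_equal(exact$sigma, summary(oracle)$sigma, tolerance = 1e-8)
})

test_that("area fit recovers a simulated slope", {
  set.seed(4)
  yrs <- 2000:2011
  N <- stats::setNames(75 * exp(0.15 * (seq_along(yrs) - 1)), yrs)
  area <- tibble::tibble(
    wolf_year = yrs,
    area_km2 = 500 + 15 * unname(N) + stats::rnorm(length(yrs), 0, 300)
  )
  fit <- fit_area(area, N, settings = sampler_settings("short", seed = 12))
  s <- summarize_draws(fit$draws, "d1")
  expect_true(s$conf.low <= 15 && 15 <= s$conf.high)
})

test_that("pack-size marginal likelihood integrates the latent Poisson correctly", {
  # brute-force deep sum oracle at one observation
  c0 <- 4; c1 <- 0; sigma <- 1; y <- 4.6; N <- 300
  mu <- pack_size_model(c0, c1, N)
  oracle <- log(sum(stats::dpois(1:200, mu) *
                      stats::dgamma(y, shape = (1:200)^2 / sigma^2,
                                    rate = (1:200) / sigma^2)))
  got <- wolfpolicy:::pack_size_loglik(c0, c1, sigma, y, N)
  expect_equal(got, oracle, tolerance = 1e-8)
  # non-positive mean is rejected with -Inf
  expect_identical(wolfpolicy:::pack_size_loglik(-1, 0, 1, y, N), -Inf)
})

test_that("pack-size and reproduction fits recover flat truths", {
  set.seed(33)
  yrs <- 2001:2012
  N <- stats::setNames(75 * exp(0.15 * (seq_along(yrs) - 1)), yrs)
  cfg <- simulation_config(years = yrs, c0 = 4, c1 = 0, e0 = stats::qlogis(0.7),
                           e1 = 0, pack_years = yrs)
  ds <- simulate_dataset(cfg, seed = 14)
  packs <- ds$packs[sample(nrow(ds$packs), 120), ]
  n_cov <- stats::setNames(ds$ground_truth$latent$N_true[ds$ground_truth$latent$state == "WI"], yrs)
  fit_c <- fit_pack_size(packs, n_cov, settings = sampler_settings("short", seed = 15))
  s_c <- summarize_draws(fit_c$draws, "c1")
  expect_true(s_c$conf.low <= 0 && 0 <= s_c$conf.high)
  fit_e <- fit_reproduction(packs, n_cov, settings = sampler_settings("short", seed = 16))
  s_e <- summarize_draws(fit_e$draws, "e1")
  expect_true(s_e$conf.low <= 0 && 0 <= s_e$conf.high)
})

test_that("density-dependence report computes fractions by draw counting", {
  mk_draws <- function(v) {
    chains <- list(matrix(v[1:(length(v) / 2)], ncol = 1),
                   matrix(v[(length(v) / 2 + 1):length(v)], ncol = 1))
    d <- posterior_draws(chains, "d1", sampler_settings("short"), 1)
    new_fit <- structure(list(draws = d, model = "area", slope = "d1",
                              data = tibble::tibble()), class = "dd_fit")
    new_fit
  }
  set.seed(9)
  # symmetric zero-centred draws: P about 0.5, verdict no evidence
  v <- c(stats::rnorm(500), -stats::rnorm(500))
  rep1 <- density_dependence_report(mk_draws(c(v, -v)), check_convergence = FALSE)
  expect_equal(rep1$p_negative, 0.5)
  expect_match(rep1$verdict, "no evidence")
  # all-negative draws
  rep2 <- density_dependence_report(mk_draws(-abs(stats::rnorm(1000)) - 0.01),
                                    check_convergence = FALSE)
  expect_equal(rep2$p_negative, 1)
  expect_match(rep2$verdict, "negative DD detected")
  # counting oracle
  v3 <- stats::rnorm(1000, -0.3)
  rep3 <- density_dependence_report(mk_draws(v3), check_convergence = FALSE)
  expect_equal(rep3$p_negative, sum(v3 < 0) / 1000)
  expect_equal(rep3$p_positive, sum(v3 > 0) / 1000)
})

test_that("report refuses unconverged submodel fits", {
  set.seed(10)
  chains <- list(matrix(stats::rnorm(200), ncol = 1),
                 matrix(stats::rnorm(200) + 100, ncol = 1))
  d <- posterior_draws(chains, "c1", sampler_settings("short"), 1)
  f <- structure(list(draws = d, model = "pack_size", slope = "c1",
                      data = tibble::tibble()), class = "dd_fit")
  expect_error(density_dependence_report(f), "convergence gate")
})
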