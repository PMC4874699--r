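test_that("deterministic limit reproduces exponential growth exactly", {
  cfg <- simulation_config(
    beta0 = c(log(1.2), log(1.2)), beta1 = 0, sigma_proc = 0,
    theta_min = 1, sigma_obs_min = 0, sigma_obs_max = 0, theta_max = 1,
    n_init = c(100, 100), D = matrix(0, 2, 18), H = matrix(0, 2, 18)
  )
  ds <- simulate_dataset(cfg, seed = 1)
  wi <- ds$state_year[ds$state_year$state == "WI", ]
  expect_equal(wi$n_obs_min, 100 * 1.2^(0:17))
  expect_equal(wi$n_obs_max, 100 * 1.2^(0:17))
  expect_equal(wi$culled, rep(0, 18))
})

test_that("simulation is reproducible from the seed", {
  cfg <- default_paperlike_config()
  d1 <- simulate_dataset(cfg, seed = 42)
  d2 <- simulate_dataset(cfg, seed = 42)
  expect_identical(d1$state_year, d2$state_year)
  expect_identical(d1$packs, d2$packs)
  expect_identical(d1$area, d2$area)
  d3 <- simulate_dataset(cfg, seed = 43)
  expect_false(identical(d1$state_year$n_obs_min, d3$state_year$n_obs_min))
  expect_equal(d1$ground_truth$seed, 42)
})

test_that("observed minimum counts have the mixture mean theta * N", {
  # Monte-Carlo check of the undercount identity E[y] = theta * N
  set.seed(123)
  y <- r_observation(20000, N_true = 500, theta = 0.8, sigma_obs = 10)
  mc_se <- stats::sd(y) / sqrt(length(y))
  expect_lt(abs(mean(y) - 400), 4 * mc_se + 0.5)
})

test_that("paper-like defaults encode the study conditions", {
  cfg <- default_paperlike_config()
  expect_lt(cfg$beta1, 0)
  expect_equal(cfg$beta0, c(0.16, 0.14))
  expect_equal(cfg$gamma, 1)
  expect_equal(length(cfg$years), 18)
  ds <- simulate_dataset(cfg, seed = 1)
  expect_true(all(ds$state_year$D >= 0 & ds$state_year$D <= 1))
  # no signal before the ninth wolf-year, partial and full years after
  early <- ds$state_year$D[ds$state_year$wolf_year < 2003]
  late <- ds$state_year$D[ds$state_year$wolf_year >= 2003]
  expect_true(all(early == 0))
  expect_true(any(late > 0 & late < 1) && any(late == 1))
  # the second state's final census is blanked; max counts only in state 1
  expect_true(is.na(ds$state_year$n_obs_min[ds$state_year$state == "MI" &
                                              ds$state_year$wolf_year == 2012]))
  expect_true(all(is.na(ds$state_year$n_obs_max[ds$state_year$state == "MI"])))
  # culling only when allowed
  expect_true(all(ds$state_year$culled[ds$state_year$D == 0 &
                                         ds$state_year$wolf_year > 1995] == 0))
})

test_that("default simulations reach the observed population scale", {
  # median final first-state population over seeds within the recovery range
  finals <- vapply(1:25, function(s) {
    ds <- simulate_dataset(default_paperlike_config(), seed = s)
    gt <- ds$ground_truth$latent
    gt$N_true[gt$state == "WI" & gt$wolf_year == 2012]
  }, numeric(1))
  expect_gt(stats::median(finals), 300)
  expect_lt(stats::median(finals), 2500)
})

test_that("ground truth lies inside the default prior support", {
  cfg <- default_paperlike_config()
  pri <- default_priors()
  expect_true(cfg$theta_min >= pri$theta_min$min && cfg$theta_min <= pri$theta_min$max)
  expect_true(cfg$theta_max >= pri$theta_max$min && cfg$theta_max <= pri$theta_max$max)
  expect_gt(cfg$gamma, pri$gamma$lower)
  expect_gt(cfg$sigma_proc, 0)
})

test_that("generated tables round-trip through the pipeline readers", {
  ds <- simulate_dataset(default_paperlike_config(), seed = 6)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  sy <- read_state_year(file.path(dir, "state_year.csv"))
  expect_equal(as.data.frame(sy), as.data.frame(ds$state_year))
  pp <- read_policy_periods(file.path(dir, "policy_periods.csv"))
  expect_equal(pp$start, ds$policy_periods$start)
  pk <- read_packs(file.path(dir, "packs.csv"))
  expect_equal(pk$size_obs, ds$packs$size_obs)
  ar <- read_area(file.path(dir, "area.csv"))
  expect_equal(ar$area_km2, ds$area$area_km2)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"), simplifyVector = TRUE)
  expect_equal(gt$seed, 6)
  # and the state-year table is accepted by the model layer unchanged
  expect_silent(wolfpolicy:::ssm_model_list(sy, default_priors(), 1e-3))
})

test_that("population hitting the over-culling floor is flagged, not an error", {
  cfg <- simulation_config(n_init = c(5, 5), culling_rate = 5,
                           beta0 = c(-0.5, -0.5))
  ds <- simulate_dataset(cfg, seed = 2)
  expect_true(is.logical(ds$ground_truth$extinct))
})
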