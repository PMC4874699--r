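# Shared fixtures and independent oracles. The oracles deliberately use
# different formulas/parameterizations than the package code they check.

# small 2-state x 4-year dataset with one missing count
toy_state_year <- function() {
  tibble::tibble(
    state = rep(c("A", "B"), each = 4),
    wolf_year = rep(2001:2004, 2),
    n_obs_min = c(50, 58, 61, 70, 40, 45, NA, 55),
    n_obs_max = c(60, 66, 75, 82, NA, NA, NA, NA),
    culled = c(0, 2, 0, 5, 0, 0, 3, 1),
    D = c(0, 0, 0.5, 1, 0, 0.25, 0.5, 0)
  )
}

toy_params <- function(data = toy_state_year()) {
  states <- sort(unique(data$state))
  years <- sort(unique(data$wolf_year))
  n_true <- matrix(c(55, 62, 68, 74, 44, 49, 53, 58), nrow = 2, byrow = TRUE,
                   dimnames = list(states, years))
  list(
    beta0 = stats::setNames(c(0.12, 0.10), states),
    beta1 = -0.05, gamma = 1.1, sigma_proc = 0.08,
    theta_min = 0.85, theta_max = 1.2,
    sigma_obs_min = 6, sigma_obs_max = 8,
    n_true = n_true
  )
}

# term-by-term brute-force log-posterior with hand-written densities
brute_force_logposterior <- function(params, data, priors = default_priors(),
                                     floor_eps = 1e-3) {
  ln_norm <- function(x, mean, sd) {
    -log(sd) - 0.5 * log(2 * pi) - (x - mean)^2 / (2 * sd^2)
  }
  ln_lognorm <- function(x, meanlog, sdlog) {
    ln_norm(log(x), meanlog, sdlog) - log(x)
  }
  lp <- 0
  for (b in params$beta0) lp <- lp + ln_norm(b, priors$beta0$mean, priors$beta0$sd)
  lp <- lp + ln_norm(params$beta1, priors$beta1$mean, priors$beta1$sd)
  lp <- lp + ln_norm(params$gamma, priors$gamma$mean, priors$gamma$sd) -
    log(1 - stats::pnorm(priors$gamma$lower, priors$gamma$mean, priors$gamma$sd))
  lp <- lp + log(2) + ln_norm(params$sigma_proc, 0, priors$sigma_proc$scale)
  lp <- lp + log(2) + ln_norm(params$sigma_obs_min, 0, priors$sigma_obs_min$scale)
  lp <- lp + log(2) + ln_norm(params$sigma_obs_max, 0, priors$sigma_obs_max$scale)
  lp <- lp - log(priors$theta_min$max - priors$theta_min$min)
  lp <- lp - log(priors$theta_max$max - priors$theta_max$min)

  nb_mass <- function(y, mean, sd) {
    # negative binomial via the size/prob parameterization
    size <- mean^2 / sd^2
    prob <- size / (size + mean)
    stats::dnbinom(y, size = size, prob = prob, log = TRUE)
  }

  for (s in sort(unique(data$state))) {
    ds <- data[data$state == s, ]
    ds <- ds[order(ds$wolf_year), ]
    for (i in seq_len(nrow(ds))) {
      Nt <- params$n_true[s, as.character(ds$wolf_year[i])]
      if (i == 1) {
        y1 <- ds$n_obs_min[!is.na(ds$n_obs_min)][1]
        lp <- lp + ln_lognorm(Nt, log(y1 / priors$n_init$theta_ref),
                              priors$n_init$sdlog)
      } else {
        Np <- params$n_true[s, as.character(ds$wolf_year[i - 1])]
        r <- params$beta0[[s]] + params$beta1 * ds$D[i]
        nd <- max(Np * exp(r) - params$gamma * ds$culled[i], floor_eps)
        lp <- lp + ln_lognorm(Nt, log(nd), params$sigma_proc)
      }
      if (!is.na(ds$n_obs_min[i])) {
        lp <- lp + nb_mass(ds$n_obs_min[i], params$theta_min * Nt,
                           params$sigma_obs_min)
      }
      if (!is.na(ds$n_obs_max[i])) {
        lp <- lp + nb_mass(ds$n_obs_max[i], params$theta_max * Nt,
                           params$sigma_obs_max)
      }
    }
  }
  lp
}

# natural-scale parameter vector in the canonical sampler ordering
pack_params <- function(params, states, years) {
  c(params$beta0[states], params$beta1, params$gamma, params$sigma_proc,
    params$theta_min, params$theta_max, params$sigma_obs_min,
    params$sigma_obs_max, as.vector(t(params$n_true[states, as.character(years)])))
}

# tiny fast paper-like config for smoke-level fits
small_sim_config <- function(...) {
  default_paperlike_config(...)
}
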