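#' Potential growth rate under a policy signal
#'
#' The annual log-scale potential growth rate (excluding culled animals) is
#' modelled as linear in the policy signal D, the proportion of the wolf-year
#' during which culling was legally allowed:
#' `r = beta0 + beta1 * D`.
#'
#' @param beta0 Baseline log-growth rate (state-specific intercept).
#' @param beta1 Signal-effect slope: change in r per unit of D.
#' @param D Signal covariate in \[0, 1\]; vectorized.
#' @return Growth rate(s) r.
#' @export
growth_rate <- function(beta0, beta1, D) {
  stopifnot(all(D >= 0 & D <= 1))
  beta0 + beta1 * D
}

#' Deterministic one-step population projection
#'
#' Exponential growth followed by removal of culled wolves scaled by the
#' additivity multiplier gamma (gamma < 1 compensatory, 1 additive, > 1
#' super-additive): `N_det = max(N_prev * exp(r) - gamma * H, floor_eps)`.
#' The floor keeps the lognormal process location defined when culling
#' exceeds the grown population.
#'
#' @param N_prev Previous true population size (> 0); vectorized.
#' @param r Growth rate.
#' @param H Number of wolves culled (>= 0).
#' @param gamma Additivity multiplier.
#' @param floor_eps Positive floor, default 1e-3 wolves.
#' @return Deterministic next population size.
#' @export
project_population <- function(N_prev, r, H, gamma, floor_eps = 1e-3) {
  stopifnot(all(N_prev > 0), all(H >= 0), floor_eps > 0)
  pmax(N_prev * exp(r) - gamma * H, floor_eps)
}

#' Lognormal process-error log-density
#'
#' True population size at t follows a lognormal distribution whose log-scale
#' location is the log of the deterministic projection and whose log-scale sd
#' is the process error `sigma_proc`.
#'
#' @param N_true True population size(s) (> 0).
#' @param N_det Deterministic projection(s) (> 0).
#' @param sigma_proc Process sd on the log scale (> 0).
#' @return Log-density (density with respect to N_true).
#' @export
process_logdensity <- function(N_true, N_det, sigma_proc) {
  stopifnot(all(N_true > 0), all(N_det > 0), sigma_proc > 0)
  stats::dlnorm(N_true, meanlog = log(N_det), sdlog = sigma_proc, log = TRUE)
}

#' Poisson-Gamma count-observation log-density
#'
#' An observed count is Poisson with a rate drawn from a Gamma distribution
#' whose mean is `theta * N_true` (theta the under- or overcount factor) and
#' whose sd is `sigma_obs` (shape m^2/sigma^2, rate m/sigma^2). Marginally
#' the count is negative binomial with mean `m = theta * N_true` and
#' variance `m + sigma_obs^2`, which is the closed form used here.
#'
#' @param n_obs Observed count(s), nonnegative integers.
#' @param N_true True population size(s) (> 0).
#' @param theta Count factor (> 0): in \[0, 1\] for minimum counts, \[1, 10\]
#'   for maximum counts.
#' @param sigma_obs Observation sd of the Gamma mixing layer (> 0).
#' @return Log marginal mass; `-Inf` where `theta * N_true <= 0`.
#' @export
observation_logdensity <- function(n_obs, N_true, theta, sigma_obs) {
  if (sigma_obs <= 0) stop("sigma_obs must be positive")
  stopifnot(all(n_obs >= 0), all(n_obs == round(n_obs)))
  n <- max(length(n_obs), length(N_true), length(theta))
  m <- rep_len(theta * N_true, n)
  y <- rep_len(n_obs, n)
  out <- rep(-Inf, n)
  ok <- m > 0
  if (any(ok)) {
    out[ok] <- stats::dnbinom(y[ok], size = (m[ok]^2) / sigma_obs^2,
                              mu = m[ok], log = TRUE)
  }
  out
}

#' Sample from the Poisson-Gamma observation layer
#'
#' Random-variate counterpart of [observation_logdensity()], used by the
#' synthetic-data generator.
#'
#' @inheritParams observation_logdensity
#' @param n Number of draws.
#' @return Integer vector of simulated counts.
#' @export
r_observation <- function(n, N_true, theta, sigma_obs) {
  if (sigma_obs <= 0) stop("sigma_obs must be positive")
  m <- theta * N_true
  stopifnot(all(m > 0))
  stats::rnbinom(n, size = (m^2) / sigma_obs^2, mu = m)
}

# canonical state/year layout of a state-year table; errors on ragged input
ssm_layout <- function(data) {
  d <- dplyr::arrange(tibble::as_tibble(data), .data$state, .data$wolf_year)
  states <- unique(d$state)
  split(d, factor(d$state, levels = states))
}

#' Joint log-posterior of the population-policy model
#'
#' Sums, over both states, the initial-condition prior for the first latent
#' population, the lognormal process terms for later years, the minimum-count
#' observation terms wherever a minimum count was recorded, the maximum-count
#' observation terms wherever a maximum count was recorded (Wisconsin-style
#' data has them for one state only), and the log prior densities of all
#' parameters. Years with missing observations contribute no observation term
#' but remain in the latent chain. Parameters outside the prior support give
#' `-Inf` rather than an error, so samplers can reject.
#'
#' @param params Named list with elements `beta0` (named vector, one entry
#'   per state), scalars `beta1`, `gamma`, `sigma_proc`, `theta_min`,
#'   `theta_max`, `sigma_obs_min`, `sigma_obs_max`, and `n_true`, a
#'   states-by-years matrix of latent population sizes with row names the
#'   state labels and column names the wolf-years.
#' @param data State-year tibble with columns `state`, `wolf_year`,
#'   `n_obs_min`, `n_obs_max`, `culled`, `D`, sorted by state and year
#'   (sorted internally regardless).
#' @param priors Prior list from [default_priors()] / [read_priors_yaml()].
#' @param floor_eps Over-culling floor passed to [project_population()].
#' @return Scalar log-posterior (unnormalized).
#' @export
joint_logposterior <- function(params, data, priors = default_priors(),
                               floor_eps = 1e-3) {
  by_state <- ssm_layout(data)
  states <- names(by_state)
  if (!all(states %in% names(params$beta0)) || !all(states %in% rownames(params$n_true))) {
    stop("params$beta0 and params$n_true must be labelled by the states in `data`")
  }

  if (params$sigma_proc <= 0 || params$sigma_obs_min <= 0 ||
      params$sigma_obs_max <= 0) {
    return(-Inf)
  }
  lp <- sum(prior_logdensity(params$beta0[states], priors$beta0)) +
    prior_logdensity(params$beta1, priors$beta1) +
    prior_logdensity(params$gamma, priors$gamma) +
    prior_logdensity(params$sigma_proc, priors$sigma_proc) +
    prior_logdensity(params$theta_min, priors$theta_min) +
    prior_logdensity(params$theta_max, priors$theta_max) +
    prior_logdensity(params$sigma_obs_min, priors$sigma_obs_min) +
    prior_logdensity(params$sigma_obs_max, priors$sigma_obs_max)
  if (!is.finite(lp)) return(-Inf)

  for (s in states) {
    ds <- by_state[[s]]
    N <- params$n_true[s, as.character(ds$wolf_year)]
    if (any(!is.finite(N)) || any(N <= 0)) return(-Inf)

    y1 <- ds$n_obs_min[which(!is.na(ds$n_obs_min))[1]]
    if (is.na(y1)) stop("state '", s, "' has no observed minimum count to anchor the initial latent population")
    lp <- lp + stats::dlnorm(N[1], meanlog = log(y1 / priors$n_init$theta_ref),
                             sdlog = priors$n_init$sdlog, log = TRUE)

    n_t <- nrow(ds)
    if (n_t >= 2) {
      r <- growth_rate(params$beta0[[s]], params$beta1, ds$D[-1])
      n_det <- project_population(N[-n_t], r, ds$culled[-1], params$gamma, floor_eps)
      lp <- lp + sum(process_logdensity(N[-1], n_det, params$sigma_proc))
    }

    has_min <- !is.na(ds$n_obs_min)
    if (any(has_min)) {
      lp <- lp + sum(observation_logdensity(ds$n_obs_min[has_min], N[has_min],
                                            params$theta_min, params$sigma_obs_min))
    }
    has_max <- !is.na(ds$n_obs_max)
    if (any(has_max)) {
      lp <- lp + sum(observation_logdensity(ds$n_obs_max[has_max], N[has_max],
                                            params$theta_max, params$sigma_obs_max))
    }
    if (!is.finite(lp)) return(-Inf)
  }
  unname(lp)
}

#' Read a state-year count table
#'
#' Expects columns `state`, `wolf_year`, `n_obs_min`, `n_obs_max`, `culled`,
#' and optionally `D` (joinable from the policy-timeline output otherwise).
#'
#' @param path CSV path.
#' @return State-year tibble.
#' @export
read_state_year <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE) |>
    dplyr::mutate(wolf_year = as.integer(.data$wolf_year))
}
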