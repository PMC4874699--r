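#' Simulation configuration
#'
#' All parameters of the generative model, with defaults matching the study
#' conditions: two states observed over the 18 wolf-years 1995-2012,
#' baseline growth rates 0.16 and 0.14, signal effect -0.04, full additivity
#' of culling (gamma = 1), moderate lognormal process noise, undercounted
#' minimum counts in both states and overcounted maximum counts in the
#' first state only, culling removals drawn only when allowed
#' (`H ~ Poisson(culling_rate * N_grown * D)`, tens of wolves at the
#' observed population scale), plus flat density-dependence truths for the
#' pack, reproduction and area side-models.
#'
#' @param states State labels (first state carries maximum counts).
#' @param years Integer wolf-year sequence.
#' @param beta0 Baseline log growth per state.
#' @param beta1 Signal-effect slope (change in r per unit D).
#' @param gamma Culling additivity multiplier.
#' @param sigma_proc Log-scale process sd.
#' @param theta_min,theta_max Under/overcount factors.
#' @param sigma_obs_min,sigma_obs_max Observation sds (Gamma mixing layer);
#'   0 gives the degenerate noise-free observation limit.
#' @param n_init Initial true population per state.
#' @param policy_periods Policy-period table used to derive D (ignored when
#'   `D` is given); default [default_policy_periods()].
#' @param D Optional states x years matrix of signal values overriding the
#'   policy-period computation.
#' @param H Optional states x years matrix of culling removals; when `NULL`
#'   removals are drawn by the Poisson rule.
#' @param culling_rate Rate constant of the culling rule (default 0.05).
#' @param c0,c1,sigma_pack_obs Pack-size model truth (mean `c0 + c1 * N`,
#'   +/- 1 wolf observation error).
#' @param e0,e1 Reproduction-probability truth (logit scale).
#' @param d0,d1,sigma_area Occupied-area truth (km^2; `d1` in km^2/wolf).
#' @param area_years Years with area records (default the 2000-2011
#'   analogue: 6th through second-to-last year).
#' @param pack_years Years with pack monitoring (default all but the last,
#'   mirroring pack data ending one year before the count series).
#' @param missing_min Optional tibble (`state`, `wolf_year`) of minimum
#'   counts to blank, emulating a skipped census.
#' @param floor_eps Over-culling floor.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(states = c("WI", "MI"), years = 1995:2012,
                              beta0 = c(0.16, 0.14), beta1 = -0.04,
                              gamma = 1, sigma_proc = 0.05,
                              theta_min = 0.9, theta_max = 1.1,
                              sigma_obs_min = 10, sigma_obs_max = 10,
                              n_init = c(75, 60),
                              policy_periods = default_policy_periods(states),
                              D = NULL, H = NULL, culling_rate = 0.05,
                              c0 = 4, c1 = 0, sigma_pack_obs = 1,
                              e0 = stats::qlogis(0.75), e1 = 0,
                              d0 = 500, d1 = 15, sigma_area = 300,
                              area_years = NULL, pack_years = NULL,
                              missing_min = NULL, floor_eps = 1e-3) {
  stopifnot(length(beta0) == length(states), length(n_init) == length(states),
            sigma_proc >= 0, sigma_obs_min >= 0, sigma_obs_max >= 0,
            theta_min >= 0, theta_min <= 1, theta_max >= 1, theta_max <= 10,
            all(n_init > 0))
  if (is.null(area_years)) {
    area_years <- if (length(years) > 7) years[6:(length(years) - 1)] else years
  }
  if (is.null(pack_years)) {
    pack_years <- if (length(years) > 1) years[-length(years)] else years
  }
  structure(
    list(states = states, years = as.integer(years), beta0 = beta0,
         beta1 = beta1, gamma = gamma, sigma_proc = sigma_proc,
         theta_min = theta_min, theta_max = theta_max,
         sigma_obs_min = sigma_obs_min, sigma_obs_max = sigma_obs_max,
         n_init = n_init, policy_periods = policy_periods, D = D, H = H,
         culling_rate = culling_rate, c0 = c0, c1 = c1,
         sigma_pack_obs = sigma_pack_obs, e0 = e0, e1 = e1,
         d0 = d0, d1 = d1, sigma_area = sigma_area,
         area_years = as.integer(area_years),
         pack_years = as.integer(pack_years),
         missing_min = missing_min, floor_eps = floor_eps),
    class = "simulation_config"
  )
}

#' Study-condition simulation configuration
#'
#' [simulation_config()] at its defaults, with the skipped final census of
#' the second state blanked (mirroring the one missing minimum count in the
#' study data). The policy-period table yields no signal before the ninth
#' wolf-year and a mixture of partial and full signal years afterwards.
#'
#' @param ... Overrides forwarded to [simulation_config()].
#' @return A `simulation_config`.
#' @export
default_paperlike_config <- function(...) {
  cfg <- simulation_config(...)
  if (is.null(cfg$missing_min)) {
    cfg$missing_min <- tibble::tibble(state = cfg$states[2],
                                      wolf_year = cfg$years[length(cfg$years)])
  }
  cfg
}

#' Synthetic 12-period policy timeline
#'
#' A synthetic stand-in for the study's authority-period table (which is not
#' reproduced in the available text): six culling-allowed intervals per
#' state on a shared calendar, starting in spring 2003, separated by
#' no-authority gaps — 12 allowed periods in total, producing partial- and
#' full-year signal values.
#'
#' @param states State labels.
#' @return Policy-period tibble (`state`, `start`, `end`, `culling_allowed`).
#' @export
default_policy_periods <- function(states = c("WI", "MI")) {
  windows <- tibble::tribble(
    ~start, ~end,
    "2003-04-01", "2004-01-31",
    "2004-11-01", "2005-08-09",
    "2006-04-01", "2006-08-15",
    "2007-03-12", "2008-09-29",
    "2009-01-15", "2009-06-30",
    "2012-01-27", "2012-04-14"
  )
  tidyr::expand_grid(state = states, windows) |>
    dplyr::mutate(start = as.Date(.data$start), end = as.Date(.data$end),
                  culling_allowed = TRUE) |>
    dplyr::select("state", "start", "end", "culling_allowed")
}

# truncated Poisson (>= 1) via inverse CDF
rpois_pos <- function(n, lambda) {
  u <- stats::runif(n, stats::ppois(0, lambda), 1)
  stats::qpois(u, lambda)
}

# observation draw honouring the degenerate sigma_obs = 0 limit
sim_obs <- function(N, theta, sigma_obs) {
  if (sigma_obs == 0) theta * N else r_observation(length(N), N, theta, sigma_obs)
}

#' Forward-simulate a complete synthetic dataset
#'
#' Simulates latent populations per state (lognormal process noise around
#' the exponential-with-culling skeleton), then minimum counts for all
#' states and maximum counts for the first state through the Poisson-Gamma
#' observation layer, then pack sizes, pack reproduction events and occupied
#' area from the density-dependence truths, using the first state's latent
#' population as the size covariate. Fully reproducible given `seed`; the
#' seed is recorded in the ground truth. With all noise parameters zero the
#' generated counts equal the deterministic skeleton exactly. A population
#' hitting the over-culling floor is flagged (`extinct`), not an error.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return A `synthetic_dataset` list of tibbles: `$state_year`,
#'   `$policy_periods`, `$packs`, `$area`, and `$ground_truth` (true
#'   parameters, latent trajectory, seed, extinction flag).
#' @export
simulate_dataset <- function(config, seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  states <- config$states; years <- config$years
  S <- length(states); T_ <- length(years)

  Dm <- config$D
  if (is.null(Dm)) {
    sig <- signal_covariates(config$policy_periods, years, states)
    Dm <- matrix(0, S, T_, dimnames = list(states, years))
    for (i in seq_len(nrow(sig))) {
      Dm[sig$state[i], as.character(sig$wolf_year[i])] <- sig$D[i]
    }
  } else {
    Dm <- matrix(Dm, S, T_, dimnames = list(states, years))
  }

  N <- matrix(NA_real_, S, T_, dimnames = list(states, years))
  Hm <- matrix(0, S, T_, dimnames = list(states, years))
  extinct <- FALSE
  for (s in seq_len(S)) {
    N[s, 1] <- config$n_init[s]
    for (t in 2:T_) {
      r <- growth_rate(config$beta0[s], config$beta1, Dm[s, t])
      grown <- N[s, t - 1] * exp(r)
      h <- if (!is.null(config$H)) {
        config$H[s, t]
      } else if (Dm[s, t] > 0) {
        stats::rpois(1, config$culling_rate * grown * Dm[s, t])
      } else 0
      Hm[s, t] <- h
      n_det <- max(grown - config$gamma * h, config$floor_eps)
      if (n_det == config$floor_eps) extinct <- TRUE
      N[s, t] <- if (config$sigma_proc == 0) {
        n_det
      } else {
        stats::rlnorm(1, log(n_det), config$sigma_proc)
      }
    }
  }

  state_year <- tidyr::expand_grid(state = states, wolf_year = years) |>
    dplyr::mutate(
      n_obs_min = NA_real_, n_obs_max = NA_real_,
      culled = 0, D = 0
    )
  for (i in seq_len(nrow(state_year))) {
    s <- state_year$state[i]; y <- as.character(state_year$wolf_year[i])
    state_year$culled[i] <- Hm[s, y]
    state_year$D[i] <- Dm[s, y]
    state_year$n_obs_min[i] <- sim_obs(N[s, y], config$theta_min, config$sigma_obs_min)
    if (s == states[1]) {
      state_year$n_obs_max[i] <- sim_obs(N[s, y], config$theta_max, config$sigma_obs_max)
      # census bounds are jointly reported and coherent: order the two draws
      lo <- min(state_year$n_obs_min[i], state_year$n_obs_max[i])
      hi <- max(state_year$n_obs_min[i], state_year$n_obs_max[i])
      state_year$n_obs_min[i] <- lo
      state_year$n_obs_max[i] <- hi
    }
  }
  if (!is.null(config$missing_min)) {
    for (i in seq_len(nrow(config$missing_min))) {
      sel <- state_year$state == config$missing_min$state[i] &
        state_year$wolf_year == config$missing_min$wolf_year[i]
      state_year$n_obs_min[sel] <- NA_real_
    }
  }

  # pack-level data, size covariate = first state's latent population
  n_cov <- N[1, ]
  packs <- purrr::map(config$pack_years, function(y) {
    Nt <- n_cov[as.character(y)]
    mu <- config$c0 + config$c1 * Nt
    if (mu <= 0) stop("pack-size mean non-positive at simulated population size")
    n_packs <- max(2L, round(Nt / max(mu, 1)))
    latent <- rpois_pos(n_packs, mu)
    size_obs <- stats::rgamma(n_packs,
                              shape = latent^2 / config$sigma_pack_obs^2,
                              rate = latent / config$sigma_pack_obs^2)
    p_rep <- reproduction_prob(config$e0, config$e1, Nt)
    tibble::tibble(
      pack_id = sprintf("%d-%03d", y, seq_len(n_packs)),
      wolf_year = y,
      size_obs = pmax(size_obs, 1e-6),
      reproduced = stats::rbinom(n_packs, 1, p_rep)
    )
  }) |> purrr::list_rbind()

  area <- tibble::tibble(
    wolf_year = config$area_years,
    area_km2 = pmax(
      stats::rnorm(length(config$area_years),
                   config$d0 + config$d1 * n_cov[as.character(config$area_years)],
                   config$sigma_area),
      1
    )
  )

  truth_pars <- config[c("beta0", "beta1", "gamma", "sigma_proc", "theta_min",
                         "theta_max", "sigma_obs_min", "sigma_obs_max",
                         "n_init", "culling_rate", "c0", "c1",
                         "sigma_pack_obs", "e0", "e1", "d0", "d1",
                         "sigma_area")]
  latent <- tidyr::expand_grid(state = states, wolf_year = years) |>
    dplyr::mutate(N_true = purrr::map2_dbl(
      .data$state, .data$wolf_year, function(s, y) N[s, as.character(y)]
    ))

  structure(
    list(state_year = state_year, policy_periods = config$policy_periods,
         packs = packs, area = area,
         ground_truth = list(parameters = truth_pars, latent = latent,
                             seed = seed, extinct = extinct)),
    class = "synthetic_dataset"
  )
}

#' Write a synthetic dataset to a directory
#'
#' Emits the five pipeline input CSVs (`state_year.csv`,
#' `policy_periods.csv`, `packs.csv`, `area.csv`, `signal.csv`) plus
#' `ground_truth.json`; the CSVs round-trip through the pipeline readers
#' unchanged.
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(ds$state_year, file.path(dir, "state_year.csv"))
  readr::write_csv(ds$policy_periods, file.path(dir, "policy_periods.csv"))
  readr::write_csv(ds$packs, file.path(dir, "packs.csv"))
  readr::write_csv(ds$area, file.path(dir, "area.csv"))
  sig <- ds$state_year |>
    dplyr::select("state", "wolf_year", "D")
  readr::write_csv(sig, file.path(dir, "signal.csv"))
  gt <- ds$ground_truth
  gt$latent <- as.list(gt$latent)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read pack and area tables
#'
#' @param path CSV path.
#' @return Tibble matching the generator's schema.
#' @export
read_packs <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE) |>
    dplyr::mutate(wolf_year = as.integer(.data$wolf_year),
                  reproduced = as.integer(.data$reproduced))
}

#' @rdname read_packs
#' @export
read_area <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE) |>
    dplyr::mutate(wolf_year = as.integer(.data$wolf_year))
}
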