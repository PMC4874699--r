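#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy posterior summaries
#'
#' Broom-style one-row-per-parameter summaries of fitted objects: posterior
#' mean (`estimate`), sd (`std.error`), equal-tailed 95% credible interval
#' and effective sample size.
#'
#' @param x A `posterior_draws`, `ssm_fit` or `dd_fit` object.
#' @param pars Optional subset of parameters; for `ssm_fit` the default is
#'   the hyperparameters (latent populations via [latent_trajectory()]).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.posterior_draws <- function(x, pars = NULL, ...) {
  summarize_draws(x, pars)
}

#' @rdname tidy.posterior_draws
#' @export
tidy.ssm_fit <- function(x, pars = NULL, ...) {
  summarize_draws(x$draws, pars %||% ssm_hyper_names(x$states))
}

#' @rdname tidy.posterior_draws
#' @export
tidy.dd_fit <- function(x, pars = NULL, ...) {
  summarize_draws(x$draws, pars)
}

#' One-row fit summaries
#'
#' @param x An `ssm_fit` or `dd_fit`.
#' @param ... Unused.
#' @return A one-row tibble with sampler provenance, the maximum PSRF over
#'   non-constant parameters and the convergence verdict.
#' @export
glance.ssm_fit <- function(x, ...) {
  gate <- convergence_gate(x$draws)
  tibble::tibble(
    n_states = length(x$states), n_years = length(x$years),
    n_chains = x$settings$n_chains, n_retained = dim(x$draws$draws)[1],
    thin = x$settings$thin, seed = x$draws$seed,
    max_psrf = suppressWarnings(max(gate$psrf, na.rm = TRUE)),
    converged = attr(gate, "overall_pass")
  )
}

#' @rdname glance.ssm_fit
#' @export
glance.dd_fit <- function(x, ...) {
  gate <- convergence_gate(x$draws)
  tibble::tibble(
    model = x$model, n_obs = nrow(x$data),
    n_chains = x$draws$settings$n_chains, n_retained = dim(x$draws$draws)[1],
    max_psrf = suppressWarnings(max(gate$psrf, na.rm = TRUE)),
    converged = attr(gate, "overall_pass")
  )
}

#' Plot the fitted latent-population trajectory
#'
#' Posterior mean and 95% credible band of the latent population per state,
#' with the observed minimum/maximum counts and culling removals overlaid —
#' the package analogue of the count-history figure.
#'
#' @param object An `ssm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ssm_fit <- function(object, ...) {
  traj <- latent_trajectory(object)
  obs <- object$data |>
    tidyr::pivot_longer(c("n_obs_min", "n_obs_max"), names_to = "series",
                        values_to = "count") |>
    dplyr::filter(!is.na(.data$count))
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$wolf_year)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$estimate)) +
    ggplot2::geom_point(data = obs, ggplot2::aes(y = .data$count, shape = .data$series)) +
    ggplot2::facet_wrap(~state, scales = "free_y") +
    ggplot2::labs(x = "wolf-year", y = "population size", shape = "count") +
    ggplot2::theme_minimal()
}

#' Plot the posterior of the policy-signal effect
#'
#' Density of the signal-effect slope beta1 with the negative region (growth
#' decline under a year-long signal) shaded.
#'
#' @param fit An `ssm_fit`.
#' @return A ggplot object.
#' @export
plot_signal_effect <- function(fit) {
  b1 <- draws_of(fit$draws, "beta1")
  dens <- stats::density(b1)
  dd <- tibble::tibble(x = dens$x, y = dens$y)
  ggplot2::ggplot(dd, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_area(data = dplyr::filter(dd, .data$x < 0), fill = "grey75") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "signal effect on growth rate (beta1)",
                  y = "posterior density") +
    ggplot2::theme_minimal()
}

#' Plot a density-dependence fit
#'
#' Observed responses against the population-size covariate with the
#' posterior-mean regression curve.
#'
#' @param object A `dd_fit`.
#' @param n_covariate Named population-size covariate used in the fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dd_fit <- function(object, n_covariate, ...) {
  s <- summarize_draws(object$draws)
  est <- stats::setNames(s$estimate, s$term)
  N <- cov_for_years(object$data$wolf_year, n_covariate)
  grid <- seq(min(N), max(N), length.out = 100)
  if (object$model == "pack_size") {
    dat <- tibble::tibble(N = N, y = object$data$size_obs)
    line <- tibble::tibble(N = grid, y = pack_size_model(est["c0"], est["c1"], grid))
    ylab <- "pack size"
  } else if (object$model == "reproduction") {
    dat <- tibble::tibble(N = N, y = object$data$reproduced)
    line <- tibble::tibble(N = grid, y = reproduction_prob(est["e0"], est["e1"], grid))
    ylab <- "P(reproduction)"
  } else {
    dat <- tibble::tibble(N = N, y = object$data$area_km2)
    line <- tibble::tibble(N = grid, y = est["d0"] + est["d1"] * grid)
    ylab <- "occupied area (km2)"
  }
  ggplot2::ggplot(dat, ggplot2::aes(.data$N, .data$y)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_line(data = line, colour = "firebrick") +
    ggplot2::labs(x = "population size", y = ylab) +
    ggplot2::theme_minimal()
}
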