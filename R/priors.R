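#' Default prior specification
#'
#' Priors for every parameter of the population-policy model. Coefficients of
#' the growth-rate regression get diffuse normals; scale parameters get
#' half-normals (scale 1 for the log-scale process sd, 50 for the count-scale
#' observation sds); the undercount factor `theta_min` is uniform on \[0, 1\]
#' and the overcount factor `theta_max` uniform on \[1, 10\]; the culling
#' additivity multiplier `gamma` gets an informative normal centred on full
#' additivity (mean 1, sd 0.25), truncated to positive values, reflecting
#' North American estimates of harvest additivity in wolves. The initial
#' latent population of each state is lognormal, centred on the first
#' observed minimum count divided by the prior mean of `theta_min` (0.5),
#' with log-scale sd `n_init$sdlog`.
#'
#' All hyperparameters can be overridden via `...` or loaded from YAML with
#' [read_priors_yaml()]; nothing is hard-coded downstream.
#'
#' @param ... Named entries replacing individual defaults, e.g.
#'   `beta1 = prior_normal(0, 5)`.
#' @return A named list of prior entries, each a list with a `family` field
#'   and its hyperparameters.
#' @export
default_priors <- function(...) {
  pri <- list(
    beta0 = prior_normal(0, 10),
    beta1 = prior_normal(0, 10),
    gamma = prior_truncnormal(1, 0.25, lower = 0),
    sigma_proc = prior_halfnormal(1),
    sigma_obs_min = prior_halfnormal(50),
    sigma_obs_max = prior_halfnormal(50),
    theta_min = prior_uniform(0, 1),
    theta_max = prior_uniform(1, 10),
    n_init = list(family = "lognormal_initial", sdlog = 1, theta_ref = 0.5)
  )
  over <- list(...)
  if (length(over) > 0) {
    bad <- setdiff(names(over), names(pri))
    if (length(bad) > 0) stop("unknown prior entries: ", paste(bad, collapse = ", "))
    pri[names(over)] <- over
  }
  pri
}

#' Prior constructors
#'
#' Small helpers building the prior entries consumed by [default_priors()]
#' and the samplers.
#'
#' @param mean,sd,scale,min,max,lower Hyperparameters of the respective family.
#' @return A list describing the prior.
#' @name prior_spec
NULL

#' @rdname prior_spec
#' @export
prior_normal <- function(mean, sd) list(family = "normal", mean = mean, sd = sd)

#' @rdname prior_spec
#' @export
prior_halfnormal <- function(scale) list(family = "halfnormal", scale = scale)

#' @rdname prior_spec
#' @export
prior_uniform <- function(min, max) list(family = "uniform", min = min, max = max)

#' @rdname prior_spec
#' @export
prior_truncnormal <- function(mean, sd, lower = 0) {
  list(family = "truncnormal", mean = mean, sd = sd, lower = lower)
}

#' Log-density of a prior entry
#'
#' @param x Value at which to evaluate.
#' @param spec A prior entry (see [prior_spec]).
#' @return Log prior density; `-Inf` outside support.
#' @export
prior_logdensity <- function(x, spec) {
  switch(spec$family,
    normal = stats::dnorm(x, spec$mean, spec$sd, log = TRUE),
    halfnormal = ifelse(
      x < 0, -Inf,
      log(2) + stats::dnorm(x, 0, spec$scale, log = TRUE)
    ),
    uniform = stats::dunif(x, spec$min, spec$max, log = TRUE),
    truncnormal = ifelse(
      x < spec$lower, -Inf,
      stats::dnorm(x, spec$mean, spec$sd, log = TRUE) -
        stats::pnorm(spec$lower, spec$mean, spec$sd, lower.tail = FALSE, log.p = TRUE)
    ),
    stop("unknown prior family: ", spec$family)
  )
}

#' Read / write a prior specification as YAML
#'
#' The YAML file carries one entry per parameter with its family and
#' hyperparameters, mirroring [default_priors()]. Unspecified parameters
#' keep their defaults on read.
#'
#' @param path Path to a YAML file.
#' @return For `read_priors_yaml()`, a complete prior list; for
#'   `write_priors_yaml()`, `path` invisibly.
#' @export
read_priors_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  pri <- default_priors()
  bad <- setdiff(names(raw), names(pri))
  if (length(bad) > 0) stop("unknown prior entries in ", path, ": ", paste(bad, collapse = ", "))
  for (nm in names(raw)) pri[[nm]] <- raw[[nm]]
  pri
}

#' @rdname read_priors_yaml
#' @param priors Prior list to serialize.
#' @export
write_priors_yaml <- function(priors, path) {
  yaml::write_yaml(priors, path)
  invisible(path)
}
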