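#' Sampler settings and presets
#'
#' The `"paper"` preset reproduces the study protocol: 8 chains, 100 000
#' iterations retained with thinning by 10, after 50 000 adaptation/update
#' iterations. The `"test"` preset (4 chains, 5 000 iterations, thin 5,
#' 2 000 adaptation) and the `"short"` preset (2 chains, 3 000 iterations,
#' thin 3, 1 500 adaptation) are desk-scale presets for simulation studies
#' and the auxiliary density-dependence fits.
#'
#' @param preset One of `"paper"`, `"test"`, `"short"`.
#' @param n_chains,n_adapt,n_iter,thin Overrides of the preset values.
#' @param seed Integer seed governing initialization and sampling.
#' @param target_accept Per-block acceptance rate targeted during
#'   adaptation (frozen afterwards to preserve detailed balance).
#' @param init_step Initial random-walk proposal sd on the sampling scale.
#' @return A `sampler_settings` list.
#' @export
sampler_settings <- function(preset = c("paper", "test", "short"),
                             n_chains = NULL, n_adapt = NULL, n_iter = NULL,
                             thin = NULL, seed = 1L, target_accept = 0.3,
                             init_step = 0.1) {
  preset <- match.arg(preset)
  def <- switch(preset,
    paper = list(n_chains = 8L, n_adapt = 50000L, n_iter = 100000L, thin = 10L),
    test = list(n_chains = 4L, n_adapt = 2000L, n_iter = 5000L, thin = 5L),
    short = list(n_chains = 2L, n_adapt = 1500L, n_iter = 3000L, thin = 3L)
  )
  out <- list(
    preset = preset,
    n_chains = as.integer(n_chains %||% def$n_chains),
    n_adapt = as.integer(n_adapt %||% def$n_adapt),
    n_iter = as.integer(n_iter %||% def$n_iter),
    thin = as.integer(thin %||% def$thin),
    seed = as.integer(seed),
    backend = "adaptive-rwm",
    target_accept = target_accept,
    init_step = init_step
  )
  stopifnot(out$n_chains >= 2, out$thin >= 1, out$n_iter >= out$thin)
  class(out) <- "sampler_settings"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Posterior draws container
#'
#' Wraps retained MCMC draws as an iterations x chains x parameters array
#' with settings and seed provenance, so diagnostics and reporting can be
#' re-run without refitting.
#'
#' @param chains List of per-chain matrices (retained iterations x
#'   parameters), identical dimensions.
#' @param param_names Character vector naming the parameter columns.
#' @param settings The [sampler_settings()] used.
#' @param seed Seed actually used.
#' @param acceptance Optional chains x parameters acceptance-rate matrix.
#' @return A `posterior_draws` object.
#' @export
posterior_draws <- function(chains, param_names, settings, seed,
                            acceptance = NULL) {
  stopifnot(length(chains) >= 1)
  n_ret <- nrow(chains[[1]])
  arr <- array(NA_real_, dim = c(n_ret, length(chains), length(param_names)),
               dimnames = list(NULL, NULL, param_names))
  for (c in seq_along(chains)) arr[, c, ] <- chains[[c]]
  structure(
    list(draws = arr, param_names = param_names, settings = settings,
         seed = seed, acceptance = acceptance),
    class = "posterior_draws"
  )
}

#' @export
print.posterior_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("<posterior_draws: %d retained iterations x %d chains x %d parameters (seed %s)>\n",
              d[1], d[2], d[3], x$seed))
  invisible(x)
}

#' Extract draws for one parameter
#'
#' @param x A `posterior_draws` object.
#' @param parameter Parameter name.
#' @param combine If `TRUE` (default) return one vector over all chains,
#'   else an iterations x chains matrix.
#' @return Numeric vector or matrix.
#' @export
draws_of <- function(x, parameter, combine = TRUE) {
  stopifnot(inherits(x, "posterior_draws"))
  if (!parameter %in% x$param_names) {
    stop("unknown parameter: ", parameter)
  }
  mat <- x$draws[, , parameter, drop = TRUE]
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = dim(x$draws)[2])
  if (combine) as.vector(mat) else mat
}

#' Convert posterior draws to a long tibble
#'
#' @param x A `posterior_draws` object.
#' @param ... Unused.
#' @return Tibble with columns `chain`, `iteration`, `parameter`, `value`.
#' @export
as_draws_tibble <- function(x, ...) {
  stopifnot(inherits(x, "posterior_draws"))
  d <- dim(x$draws)
  tidyr::expand_grid(parameter = x$param_names, chain = seq_len(d[2]),
                     iteration = seq_len(d[1])) |>
    dplyr::mutate(value = purrr::pmap_dbl(
      list(.data$parameter, .data$chain, .data$iteration),
      function(p, c, i) x$draws[i, c, p]
    )) |>
    dplyr::select("chain", "iteration", "parameter", "value")
}

#' Posterior summary for parameters
#'
#' Posterior mean, sample sd, equal-tailed 95% credible interval
#' (2.5/97.5 percentiles, type-7 quantiles) and a spectral effective sample
#' size for each requested parameter, pooling all chains.
#'
#' @param draws A `posterior_draws` object.
#' @param pars Character vector of parameters; default all.
#' @param conf_level Credible-interval mass (default 0.95).
#' @return Tibble with columns `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `ess`.
#' @export
summarize_draws <- function(draws, pars = NULL, conf_level = 0.95) {
  stopifnot(inherits(draws, "posterior_draws"))
  pars <- pars %||% draws$param_names
  a <- (1 - conf_level) / 2
  purrr::map(pars, function(p) {
    v <- draws_of(draws, p)
    q <- stats::quantile(v, c(a, 1 - a), names = FALSE)
    mat <- draws_of(draws, p, combine = FALSE)
    ess <- sum(apply(mat, 2, ess_chain))
    tibble::tibble(term = p, estimate = mean(v), std.error = stats::sd(v),
                   conf.low = q[1], conf.high = q[2], ess = ess)
  }) |>
    purrr::list_rbind()
}

# spectral ESS of a single chain; constant chains get ESS 0
ess_chain <- function(x) {
  v <- stats::var(x)
  if (!is.finite(v) || v == 0) return(0)
  s0 <- spectrum0_ar(x)
  if (!is.finite(s0) || s0 <= 0) return(0)
  min(length(x), length(x) * v / s0)
}

#' Generic blocked adaptive random-walk Metropolis sampler
#'
#' Component-wise Gaussian random-walk Metropolis with per-component
#' Robbins-Monro adaptation of the proposal scales towards
#' `settings$target_accept` during the adaptation phase; scales are frozen
#' afterwards so the retained draws target `logpost` exactly. Support
#' constraints are handled by `logpost` returning `-Inf` (rejection).
#' Deterministic given `settings$seed`.
#'
#' @param logpost Function taking a numeric parameter vector, returning a
#'   scalar log-density (up to a constant); `-Inf` outside support.
#' @param init Numeric vector of initial values, or an
#'   `n_chains x npar` matrix of per-chain initial values. Vector inits are
#'   jittered per chain. Initialization points giving non-finite log-density
#'   are re-jittered up to 50 times, then an error is raised.
#' @param settings A [sampler_settings()] object.
#' @param param_names Optional parameter names.
#' @param jitter_sd Sd of the initialization jitter.
#' @return A [posterior_draws()] object.
#' @export
sample_posterior <- function(logpost, init, settings = sampler_settings("test"),
                             param_names = NULL, jitter_sd = 0.1) {
  set.seed(settings$seed)
  if (is.null(dim(init))) {
    npar <- length(init)
    init_mat <- matrix(rep(init, each = settings$n_chains),
                       nrow = settings$n_chains)
  } else {
    init_mat <- init
    npar <- ncol(init)
    stopifnot(nrow(init) == settings$n_chains)
  }
  param_names <- param_names %||% names(init) %||% paste0("par", seq_len(npar))
  n_ret <- settings$n_iter %/% settings$thin
  chains <- vector("list", settings$n_chains)
  acc <- matrix(NA_real_, settings$n_chains, npar)

  for (c in seq_len(settings$n_chains)) {
    x <- init_mat[c, ]
    lp_cur <- logpost(x)
    tries <- 0
    while (!is.finite(lp_cur) && tries < 50) {
      x <- init_mat[c, ] + stats::rnorm(npar, 0, jitter_sd)
      lp_cur <- logpost(x)
      tries <- tries + 1
    }
    if (!is.finite(lp_cur)) {
      stop("initialization failed for chain ", c,
           ": log-posterior non-finite after 50 jittered retries (last value ",
           lp_cur, ")")
    }
    lstep <- rep(log(settings$init_step), npar)
    n_acc <- n_prop <- rep(0, npar)
    out <- matrix(NA_real_, n_ret, npar)
    ret <- 0L
    total <- settings$n_adapt + settings$n_iter
    for (it in seq_len(total)) {
      adapting <- it <= settings$n_adapt
      rm_gain <- if (adapting) it^-0.6 else 0
      for (k in seq_len(npar)) {
        xn <- x
        xn[k] <- x[k] + exp(lstep[k]) * stats::rnorm(1)
        lp_new <- logpost(xn)
        a <- if (is.finite(lp_new)) min(1, exp(lp_new - lp_cur)) else 0
        if (stats::runif(1) < a) {
          x <- xn
          lp_cur <- lp_new
          if (!adapting) n_acc[k] <- n_acc[k] + 1
        }
        if (adapting) {
          lstep[k] <- min(5, max(-12, lstep[k] + rm_gain * (a - settings$target_accept)))
        } else {
          n_prop[k] <- n_prop[k] + 1
        }
      }
      if (!adapting && (it - settings$n_adapt) %% settings$thin == 0 && ret < n_ret) {
        ret <- ret + 1L
        out[ret, ] <- x
      }
    }
    chains[[c]] <- out
    acc[c, ] <- ifelse(n_prop > 0, n_acc / n_prop, NA_real_)
  }
  posterior_draws(chains, param_names, settings, settings$seed, acceptance = acc)
}

#' Derived growth-rate and policy-signal summary
#'
#' Per state, summarizes the potential growth rate with no policy signal
#' (`r` at D = 0, the draws of `beta0[state]`) and under a year-long signal
#' (`r` at D = 1, draws of `beta0[state] + beta1`), and reports the posterior
#' probability that the signal effect `beta1` is negative, that it is
#' positive, and their ratio (how many times more likely a growth decline is
#' than an increase). Refuses to summarize draws failing the convergence
#' gate unless `check_convergence = FALSE`.
#'
#' @param fit An `ssm_fit` from [fit_state_space()], or a `posterior_draws`
#'   object holding `beta0[...]` and `beta1` parameters.
#' @param check_convergence Run [convergence_gate()] first (default TRUE).
#' @param psrf_threshold Gate threshold, see [convergence_gate()].
#' @return A `growth_summary` list: `$growth` tibble (state, signal,
#'   estimate, std.error, conf.low, conf.high), `$p_negative`, `$p_positive`,
#'   `$prob_ratio` (`Inf` reported with label `">max"`), `$ratio_label`.
#' @export
derived_growth_summary <- function(fit, check_convergence = TRUE,
                                   psrf_threshold = 1.1) {
  draws <- if (inherits(fit, "ssm_fit")) fit$draws else fit
  stopifnot(inherits(draws, "posterior_draws"))
  if (check_convergence) {
    gate <- convergence_gate(draws, psrf_threshold = psrf_threshold)
    if (!attr(gate, "overall_pass")) {
      failed <- gate$term[!gate$pass]
      stop("convergence gate failed for parameter(s): ",
           paste(utils::head(failed, 5), collapse = ", "),
           if (length(failed) > 5) ", ..." else "",
           "; rerun with longer chains or inspect diagnostics")
    }
  }
  b0_names <- grep("^beta0\\[", draws$param_names, value = TRUE)
  states <- sub("^beta0\\[(.*)\\]$", "\\1", b0_names)
  b1 <- draws_of(draws, "beta1")
  growth <- purrr::map2(b0_names, states, function(nm, st) {
    b0 <- draws_of(draws, nm)
    purrr::map2(list(b0, b0 + b1), c(0, 1), function(v, dd) {
      q <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
      tibble::tibble(state = st, signal_D = dd, estimate = mean(v),
                     std.error = stats::sd(v), conf.low = q[1], conf.high = q[2])
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  p_neg <- mean(b1 < 0)
  p_pos <- mean(b1 > 0)
  ratio <- if (p_pos == 0) Inf else p_neg / p_pos
  structure(
    list(growth = growth, p_negative = p_neg, p_positive = p_pos,
         prob_ratio = ratio,
         ratio_label = if (is.infinite(ratio)) ">max" else format(round(ratio, 2))),
    class = "growth_summary"
  )
}

#' @export
print.growth_summary <- function(x, ...) {
  cat("Potential growth rate by policy signal (posterior mean +/- sd [95% CI]):\n")
  g <- x$growth
  for (i in seq_len(nrow(g))) {
    cat(sprintf("  %s, D = %g: r = %.3f +/- %.3f [%.3f, %.3f]\n",
                g$state[i], g$signal_D[i], g$estimate[i], g$std.error[i],
                g$conf.low[i], g$conf.high[i]))
  }
  cat(sprintf("P(beta1 < 0) = %.3f; P(beta1 > 0) = %.3f; decline/increase ratio = %s\n",
              x$p_negative, x$p_positive, x$ratio_label))
  invisible(x)
}

#' Persist and reload posterior draws
#'
#' Draws are written as one CSV per chain plus a JSON manifest holding the
#' settings, seed and parameter registry, so diagnostics and reports can be
#' regenerated without refitting.
#'
#' @param draws A `posterior_draws` object.
#' @param dir Directory to create/use.
#' @return `save_draws()` returns `dir` invisibly; `load_draws()` a
#'   `posterior_draws` object.
#' @export
save_draws <- function(draws, dir) {
  stopifnot(inherits(draws, "posterior_draws"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(draws$draws)
  for (c in seq_len(d[2])) {
    mat <- draws$draws[, c, , drop = TRUE]
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = d[1])
    colnames(mat) <- draws$param_names
    readr::write_csv(tibble::as_tibble(mat), file.path(dir, sprintf("chain-%02d.csv", c)))
  }
  manifest <- list(
    n_chains = d[2], n_retained = d[1], param_names = draws$param_names,
    seed = draws$seed,
    settings = unclass(draws$settings)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_draws
#' @export
load_draws <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  chains <- purrr::map(seq_len(manifest$n_chains), function(c) {
    as.matrix(readr::read_csv(file.path(dir, sprintf("chain-%02d.csv", c)),
                              show_col_types = FALSE, progress = FALSE))
  })
  settings <- manifest$settings
  class(settings) <- "sampler_settings"
  posterior_draws(chains, manifest$param_names, settings, manifest$seed)
}
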