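#' Validate pipeline input tables
#'
#' Report-only checks on the assembled inputs: wolf-year contiguity per
#' state, non-negative counts, ordering of minimum and maximum counts where
#' both are present, complete reporting of culling removals, and the signal
#' covariate lying in \[0, 1\]. [run_pipeline()] enforces the outcome; this
#' function only reports it, naming the offending rows.
#'
#' @param tables List with at least `$state_year`; optionally `$packs`,
#'   `$area`, `$policy_periods`.
#' @return Tibble with columns `check`, `pass`, `detail`; attribute
#'   `overall_pass`.
#' @export
validate_inputs <- function(tables) {
  sy <- tibble::as_tibble(tables$state_year)
  rows <- list()
  add <- function(check, pass, detail = "") {
    rows[[length(rows) + 1]] <<- tibble::tibble(check = check, pass = pass,
                                                detail = detail)
  }

  gap_states <- sy |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(contiguous = all(diff(sort(.data$wolf_year)) == 1)) |>
    dplyr::filter(!.data$contiguous)
  add("year contiguity per state", nrow(gap_states) == 0,
      if (nrow(gap_states) > 0) paste("gaps in:", paste(gap_states$state, collapse = ", ")) else "")

  neg <- which(sy$n_obs_min < 0 | sy$n_obs_max < 0)
  add("non-negative counts", length(neg) == 0,
      if (length(neg) > 0) paste("negative count at row(s):", paste(neg, collapse = ", ")) else "")

  both <- which(!is.na(sy$n_obs_min) & !is.na(sy$n_obs_max))
  bad_order <- both[sy$n_obs_min[both] > sy$n_obs_max[both]]
  add("min <= max where both present", length(bad_order) == 0,
      if (length(bad_order) > 0) paste("ordering failure at row(s):", paste(bad_order, collapse = ", ")) else "")

  h_missing <- which(is.na(sy$culled) | sy$culled < 0)
  add("culling removals reported for every state-year", length(h_missing) == 0,
      if (length(h_missing) > 0) paste("missing/negative culled at row(s):", paste(h_missing, collapse = ", ")) else "")

  if ("D" %in% names(sy)) {
    d_bad <- which(is.na(sy$D) | sy$D < 0 | sy$D > 1)
    add("signal covariate D in [0, 1]", length(d_bad) == 0,
        if (length(d_bad) > 0) paste("out-of-range D at row(s):", paste(d_bad, collapse = ", ")) else "")
  } else {
    add("signal covariate D present or derivable", !is.null(tables$policy_periods),
        if (is.null(tables$policy_periods)) "no D column and no policy periods" else "D derived from policy periods")
  }

  if (!is.null(tables$packs)) {
    p <- tables$packs
    add("pack sizes positive", all(p$size_obs > 0), "")
    add("reproduction indicator binary", all(p$reproduced %in% c(0, 1)), "")
  }
  if (!is.null(tables$area)) {
    add("occupied area positive", all(tables$area$area_km2 > 0), "")
  }

  out <- purrr::list_rbind(rows)
  attr(out, "overall_pass") <- all(out$pass)
  out
}

#' Pipeline run configuration
#'
#' @param state_year State-year table (tibble) or CSV path.
#' @param policy_periods Policy-period table or CSV path; used to derive the
#'   signal covariate when `state_year` has no `D` column. Swapping this
#'   table (e.g. delisting dates instead of culling authority) changes only
#'   the covariate values, no code path.
#' @param packs,area Optional side-model tables or CSV paths.
#' @param priors Prior list or YAML path.
#' @param settings [sampler_settings()] for the state-space fit.
#' @param dd_settings Settings for the density-dependence fits.
#' @param out_dir Output directory (created); `NULL` for no file output.
#' @param seed Integer seed for the whole run.
#' @param check_convergence Gate reporting on diagnostics (default TRUE;
#'   when gating fails the report is stamped `NOT CONVERGED` rather than
#'   aborting).
#' @return A `run_config` list.
#' @export
run_config <- function(state_year, policy_periods = NULL, packs = NULL,
                       area = NULL, priors = default_priors(),
                       settings = sampler_settings("test"),
                       dd_settings = sampler_settings("short"),
                       out_dir = NULL, seed = 1L, check_convergence = TRUE) {
  structure(
    list(state_year = state_year, policy_periods = policy_periods,
         packs = packs, area = area, priors = priors, settings = settings,
         dd_settings = dd_settings, out_dir = out_dir, seed = as.integer(seed),
         check_convergence = check_convergence),
    class = "run_config"
  )
}

load_table <- function(x, reader) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) reader(x) else tibble::as_tibble(x)
}

#' Run the full analysis pipeline
#'
#' Policy timeline to signal covariate, state-space fit, density-dependence
#' fits, convergence diagnostics, and the final report: growth-rate
#' summaries at D = 0 and D = 1 per state (posterior mean, sd, 95% CI),
#' P(beta1 < 0) with the decline/increase probability ratio, additivity and
#' variance summaries, density-dependence verdicts, and the fitted
#' latent-population trajectory with its 95% credible band. Every reported
#' number is a deterministic function of the persisted draws, so reporting
#' is idempotent ([build_report()] can be re-run on a saved fit).
#'
#' @param config A [run_config()].
#' @return A `policy_report` list; with `out_dir` set, also writes
#'   `report.json`, `report.md`, `trajectories.csv` and a `draws/`
#'   directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  sy <- stage("load", load_table(config$state_year, read_state_year))
  periods <- stage("load", load_table(config$policy_periods, read_policy_periods))
  packs <- stage("load", load_table(config$packs, read_packs))
  area <- stage("load", load_table(config$area, read_area))
  priors <- if (is.character(config$priors)) {
    stage("priors", read_priors_yaml(config$priors))
  } else config$priors

  if (!"D" %in% names(sy)) {
    if (is.null(periods)) stop("pipeline stage 'policy_timeline' failed: no D column and no policy periods")
    sig <- stage("policy_timeline",
                 signal_covariates(periods, sort(unique(sy$wolf_year)),
                                   unique(sy$state)))
    sy <- dplyr::left_join(sy, sig[, c("state", "wolf_year", "D")],
                           by = c("state", "wolf_year"))
  }

  checks <- stage("validate", validate_inputs(list(state_year = sy, packs = packs,
                                                   area = area,
                                                   policy_periods = periods)))
  if (!attr(checks, "overall_pass")) {
    bad <- checks[!checks$pass, ]
    stop("pipeline stage 'validate' failed: ",
         paste(sprintf("%s (%s)", bad$check, bad$detail), collapse = "; "))
  }

  fit <- stage("fit", fit_state_space(sy, priors = priors,
                                      settings = config$settings,
                                      seed = config$seed))

  dd_fits <- list()
  if (!is.null(packs) || !is.null(area)) {
    first_state <- fit$states[1]
    cov_tbl <- sy[sy$state == first_state & !is.na(sy$n_obs_min), ]
    n_cov <- stats::setNames(cov_tbl$n_obs_min, cov_tbl$wolf_year)
    if (!is.null(packs)) {
      dd_fits$pack_size <- stage("density_dependence",
        fit_pack_size(packs, n_cov, settings = config$dd_settings))
      dd_fits$reproduction <- stage("density_dependence",
        fit_reproduction(packs, n_cov, settings = config$dd_settings))
    }
    if (!is.null(area)) {
      dd_fits$area <- stage("density_dependence",
        fit_area(area, n_cov, settings = config$dd_settings))
    }
  }

  report <- stage("report", build_report(fit, dd_fits,
                                         check_convergence = config$check_convergence))
  report$validation <- checks

  if (!is.null(config$out_dir)) {
    stage("write", write_report(report, fit, config$out_dir))
  }
  report
}

#' Assemble the policy report from fitted objects
#'
#' Deterministic post-processing of persisted draws; re-running it on the
#' same fit reproduces the report exactly.
#'
#' @param fit An `ssm_fit`.
#' @param dd_fits Named list of `dd_fit` objects (may be empty).
#' @param check_convergence Gate on [convergence_gate()]; a failed gate
#'   stamps the report `NOT CONVERGED` instead of summarizing derived
#'   quantities.
#' @return A `policy_report` list.
#' @export
build_report <- function(fit, dd_fits = list(), check_convergence = TRUE) {
  gate <- convergence_gate(fit$draws)
  converged <- attr(gate, "overall_pass")
  status <- if (!check_convergence || converged) "CONVERGED" else "NOT CONVERGED"

  growth <- derived_growth_summary(fit, check_convergence = FALSE)
  params <- summarize_draws(fit$draws, ssm_hyper_names(fit$states))
  dd <- if (length(dd_fits) > 0) {
    density_dependence_report(unname(dd_fits), check_convergence = FALSE)
  } else NULL
  structure(
    list(status = status, growth = growth$growth,
         p_beta1_negative = growth$p_negative,
         p_beta1_positive = growth$p_positive,
         prob_ratio = growth$prob_ratio, ratio_label = growth$ratio_label,
         parameters = params, density_dependence = dd,
         trajectories = latent_trajectory(fit),
         diagnostics = gate, seed = fit$draws$seed,
         settings = fit$settings),
    class = "policy_report"
  )
}

#' @export
print.policy_report <- function(x, ...) {
  cat("== Policy-signal growth report [", x$status, "] ==\n", sep = "")
  g <- x$growth
  for (i in seq_len(nrow(g))) {
    cat(sprintf("  %s, D = %g: r = %.3f +/- %.3f [%.3f, %.3f]\n",
                g$state[i], g$signal_D[i], g$estimate[i], g$std.error[i],
                g$conf.low[i], g$conf.high[i]))
  }
  cat(sprintf("  P(beta1 < 0) = %.3f; decline/increase ratio = %s\n",
              x$p_beta1_negative, x$ratio_label))
  if (!is.null(x$density_dependence)) {
    cat("  Density dependence:\n")
    d <- x$density_dependence
    for (i in seq_len(nrow(d))) {
      cat(sprintf("    %s (%s): %.4g [%.4g, %.4g] P(<0)=%.2f -> %s\n",
                  d$model[i], d$term[i], d$estimate[i], d$conf.low[i],
                  d$conf.high[i], d$p_negative[i], d$verdict[i]))
    }
  }
  invisible(x)
}

write_report <- function(report, fit, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$trajectories, file.path(out_dir, "trajectories.csv"))
  save_draws(fit$draws, file.path(out_dir, "draws"))
  json <- list(
    status = report$status,
    growth = report$growth,
    p_beta1_negative = report$p_beta1_negative,
    p_beta1_positive = report$p_beta1_positive,
    prob_ratio = if (is.finite(report$prob_ratio)) report$prob_ratio else report$ratio_label,
    parameters = report$parameters,
    density_dependence = report$density_dependence,
    diagnostics = report$diagnostics,
    seed = report$seed
  )
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  md <- utils::capture.output(print(report))
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(out_dir)
}
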