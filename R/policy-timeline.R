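#' Wolf-year interval bounds
#'
#' The annual census interval ("wolf-year") for year `t` runs from 15 April
#' of `t - 1` through 14 April of `t`, both endpoints included. The day count
#' is exact calendar arithmetic, so wolf-years containing a 29 February have
#' 366 days.
#'
#' @param t Integer vector of 4-digit calendar years indexing wolf-years.
#' @return A tibble with columns `wolf_year`, `start` (Date), `end` (Date)
#'   and `n_days` (integer, inclusive day count).
#' @examples
#' wolf_year_bounds(2003)
#' wolf_year_bounds(1995:1997)
#' @export
wolf_year_bounds <- function(t) {
  stopifnot(is.numeric(t), all(t == as.integer(t)), all(t >= 1000 & t <= 9999))
  t <- as.integer(t)
  start <- as.Date(sprintf("%d-04-15", t - 1L))
  end <- as.Date(sprintf("%d-04-14", t))
  tibble::tibble(
    wolf_year = t,
    start = start,
    end = end,
    n_days = as.integer(end - start) + 1L
  )
}

#' Validate a policy-period table
#'
#' Checks that each period has `start <= end` and that periods never overlap
#' within a state (periods for different states are independent). Abutting
#' periods sharing no day are allowed; because day counting is inclusive,
#' two periods in the same state may not share even a single calendar day.
#'
#' @param periods A data frame with columns `state`, `start`, `end`
#'   (Date or ISO-8601 strings) and `culling_allowed` (logical).
#' @return The validated tibble (dates parsed, invisibly usable downstream).
#' @export
validate_policy_periods <- function(periods) {
  req <- c("state", "start", "end", "culling_allowed")
  missing_cols <- setdiff(req, names(periods))
  if (length(missing_cols) > 0) {
    stop("policy-period table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  periods <- tibble::as_tibble(periods) |>
    dplyr::mutate(
      start = as.Date(.data$start),
      end = as.Date(.data$end),
      culling_allowed = as.logical(.data$culling_allowed)
    )
  bad <- which(periods$start > periods$end)
  if (length(bad) > 0) {
    stop("policy period(s) with start after end at row(s): ", paste(bad, collapse = ", "))
  }
  # overlap check within state: any shared calendar day is an overlap
  by_state <- split(seq_len(nrow(periods)), periods$state)
  for (idx in by_state) {
    if (length(idx) < 2) next
    ord <- idx[order(periods$start[idx])]
    for (k in seq_len(length(ord) - 1)) {
      i <- ord[k]; j <- ord[k + 1]
      if (periods$end[i] >= periods$start[j]) {
        stop(sprintf(
          "overlapping policy periods in state '%s': [%s..%s] and [%s..%s]",
          periods$state[i], periods$start[i], periods$end[i],
          periods$start[j], periods$end[j]
        ))
      }
    }
  }
  periods
}

# inclusive day-count of the intersection of [a1,a2] and [b1,b2]; 0 if disjoint
overlap_days <- function(a1, a2, b1, b2) {
  lo <- pmax(as.numeric(a1), as.numeric(b1))
  hi <- pmin(as.numeric(a2), as.numeric(b2))
  pmax(hi - lo + 1, 0)
}

#' Policy-signal covariate for one state and wolf-year
#'
#' Computes D, the proportion of wolf-year `t` during which culling was
#' legally allowed: allowed periods are clipped to the wolf-year, days are
#' counted inclusively of both endpoints, and the total is divided by the
#' exact length of the wolf-year. Periods with `culling_allowed = FALSE`
#' contribute nothing.
#'
#' @param periods Policy-period table (see [validate_policy_periods()]).
#' @param t Wolf-year index (single integer).
#' @param state State label to evaluate.
#' @return A one-row tibble with columns `state`, `wolf_year`,
#'   `days_allowed`, `n_days`, `D`.
#' @export
compute_signal <- function(periods, t, state) {
  periods <- validate_policy_periods(periods)
  wy <- wolf_year_bounds(t)
  p <- periods[periods$state == state & periods$culling_allowed, , drop = FALSE]
  days <- if (nrow(p) == 0) 0 else sum(overlap_days(p$start, p$end, wy$start, wy$end))
  tibble::tibble(
    state = state,
    wolf_year = as.integer(t),
    days_allowed = as.integer(days),
    n_days = wy$n_days,
    D = days / wy$n_days
  )
}

#' Signal covariate table for a range of wolf-years
#'
#' Vectorized driver over states and wolf-years; the workhorse behind the
#' policy-timeline stage of [run_pipeline()].
#'
#' @param periods Policy-period table.
#' @param years Integer vector of wolf-year indices.
#' @param states Character vector of state labels; defaults to the states
#'   present in `periods`.
#' @return Tibble with one row per state and wolf-year, columns as in
#'   [compute_signal()].
#' @export
signal_covariates <- function(periods, years, states = NULL) {
  periods <- validate_policy_periods(periods)
  if (is.null(states)) states <- sort(unique(periods$state))
  tidyr::expand_grid(state = states, wolf_year = as.integer(years)) |>
    purrr::pmap(function(state, wolf_year) compute_signal(periods, wolf_year, state)) |>
    purrr::list_rbind()
}

#' Read a policy-period CSV
#'
#' Expects columns `state`, `start`, `end` (ISO-8601 dates) and
#' `culling_allowed` (logical), and validates them.
#'
#' @param path Path to a CSV file.
#' @return Validated policy-period tibble.
#' @export
read_policy_periods <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE) |>
    validate_policy_periods()
}

#' Write a signal-covariate table to CSV
#'
#' @param signal Tibble from [signal_covariates()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_covariates <- function(signal, path) {
  readr::write_csv(signal, path)
  invisible(path)
}
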