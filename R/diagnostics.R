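#' Gelman-Rubin potential scale reduction factor
#'
#' Classic formulation: with m chains of length n, within-chain variance
#' `W` the mean of the per-chain sample variances and between-chain variance
#' `B = n * var(chain means)`,
#' `PSRF = sqrt( ((n-1)/n * W + B/n) / W )`.
#' The optional sampling-variability correction multiplies the pooled
#' variance by `(m + 1) / m` and subtracts `(n - 1) / (m * n)`.
#'
#' @param chains An iterations x chains numeric matrix (>= 2 chains,
#'   length >= 10), or a list of equal-length numeric vectors.
#' @param correct Apply the m-chain correction factor (default `FALSE`,
#'   matching the classic 1992 statistic).
#' @return The PSRF (scalar).
#' @export
gelman_rubin <- function(chains, correct = FALSE) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  stopifnot(is.matrix(chains), ncol(chains) >= 2, nrow(chains) >= 2)
  n <- nrow(chains)
  m <- ncol(chains)
  W <- mean(apply(chains, 2, stats::var))
  B <- n * stats::var(colMeans(chains))
  if (W == 0) stop("degenerate chains: zero within-chain variance")
  vhat <- (n - 1) / n * W + B / n
  if (correct) {
    sqrt((m + 1) / m * vhat / W - (n - 1) / (m * n))
  } else {
    sqrt(vhat / W)
  }
}

#' Spectral density at frequency zero
#'
#' Estimated from a low-order autoregressive approximation fitted by
#' Yule-Walker with AIC order selection: for an AR(p) fit with innovation
#' variance `s2` and coefficients `phi`, the long-run variance is
#' `s2 / (1 - sum(phi))^2`. Used by the Heidelberger-Welch test and the
#' effective sample size.
#'
#' @param x Numeric chain.
#' @param order_max Maximum AR order considered.
#' @return Scalar spectral density at zero (long-run variance).
#' @export
spectrum0_ar <- function(x, order_max = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (stats::var(x) == 0) return(0)
  order_max <- order_max %||% min(n - 1L, floor(10 * log10(n)))
  fit <- stats::ar(x, aic = TRUE, order.max = order_max, method = "yule-walker")
  if (fit$order == 0) fit$var.pred else fit$var.pred / (1 - sum(fit$ar))^2
}

#' Asymptotic Cramer-von Mises distribution function
#'
#' CDF of the limiting distribution of the Cramer-von Mises statistic,
#' evaluated by the standard Bessel-function series (four terms, adequate to
#' ~1e-5 for the quantiles used in stationarity testing).
#'
#' @param q Quantile(s), > 0.
#' @param eps Series truncation tolerance.
#' @return P(W <= q).
#' @export
pcramer <- function(q, eps = 1e-5) {
  log_eps <- log(eps)
  vapply(q, function(qq) {
    if (qq <= 0) return(0)
    tot <- 0
    for (k in 0:3) {
      z <- gamma(k + 0.5) * sqrt(4 * k + 1) / (gamma(k + 1) * pi^1.5 * sqrt(qq))
      u <- (4 * k + 1)^2 / (16 * qq)
      if (u <= -log_eps) tot <- tot + z * exp(-u) * besselK(u, 0.25)
    }
    min(1, max(0, tot))
  }, numeric(1))
}

#' Heidelberger-Welch stationarity and halfwidth test
#'
#' Stationarity: the Cramer-von Mises statistic of the standardized
#' cumulative-sum (Brownian-bridge) process, with long-run variance
#' estimated by [spectrum0_ar()] on the second half of the chain, is
#' compared to its asymptotic `alpha` critical value; if it fails, initial
#' 10% increments are discarded (up to 50%) and the test repeated.
#' Halfwidth: on the retained portion, the test passes if the
#' `(1 - alpha)` normal-theory halfwidth of the mean,
#' `z_{1-alpha/2} * sqrt(S0 / n_kept)`, is at most `eps * |mean|`.
#' A zero mean makes the halfwidth criterion not applicable (reported `NA`),
#' not a failure.
#'
#' @param chain Numeric vector of draws for one parameter (length >= 50).
#' @param alpha Test level (default 0.05).
#' @param eps Relative halfwidth tolerance (default 0.1).
#' @return List: `stationarity_passed`, `frac_discarded`, `n_kept`, `cvm`,
#'   `mean`, `halfwidth`, `halfwidth_passed` (`NA` when mean is zero).
#' @export
heidelberger_welch <- function(chain, alpha = 0.05, eps = 0.1) {
  chain <- as.numeric(chain)
  n_all <- length(chain)
  stopifnot(n_all >= 50)
  s0 <- spectrum0_ar(chain[(n_all %/% 2):n_all])
  starts <- unique(pmax(1L, floor(seq(0, 0.5, by = 0.1) * n_all) + 1L))
  passed <- FALSE
  frac <- NA_real_
  cvm <- NA_real_
  kept <- chain
  for (st in starts) {
    y <- chain[st:n_all]
    n <- length(y)
    ybar <- mean(y)
    if (s0 <= 0) break
    bb <- cumsum(y) - ybar * seq_len(n)
    cvm <- sum(bb * bb / (n * s0)) / n
    if (is.finite(cvm) && pcramer(cvm) < 1 - alpha) {
      passed <- TRUE
      frac <- (st - 1) / n_all
      kept <- y
      break
    }
  }
  if (!passed) {
    frac <- 0.5
    kept <- chain[(floor(0.5 * n_all) + 1L):n_all]
  }
  n_kept <- length(kept)
  ybar <- mean(kept)
  s0_kept <- spectrum0_ar(kept)
  hw <- stats::qnorm(1 - alpha / 2) * sqrt(s0_kept / n_kept)
  hw_passed <- if (ybar == 0) NA else is.finite(hw) && abs(hw / ybar) <= eps
  list(
    stationarity_passed = passed,
    frac_discarded = frac,
    n_kept = n_kept,
    cvm = cvm,
    mean = ybar,
    halfwidth = hw,
    halfwidth_passed = hw_passed
  )
}

#' Convergence gate over all parameters
#'
#' A parameter passes if its PSRF is below `psrf_threshold` and the
#' Heidelberger-Welch stationarity test passes on every chain. Parameters
#' held constant across all draws (e.g. fixed in the fit) are reported with
#' `psrf = NA` and pass by construction. Reporting functions consult this
#' gate before summarizing.
#'
#' @param draws A [posterior_draws()] object or `ssm_fit`.
#' @param psrf_threshold PSRF pass threshold (default 1.1, conventional).
#' @param hw_alpha Stationarity test level.
#' @return Tibble with columns `term`, `psrf`, `stationary_chains`,
#'   `n_chains`, `pass`; attribute `overall_pass` is the conjunction.
#' @export
convergence_gate <- function(draws, psrf_threshold = 1.1, hw_alpha = 0.05) {
  if (inherits(draws, "ssm_fit")) draws <- draws$draws
  stopifnot(inherits(draws, "posterior_draws"))
  n_chains <- dim(draws$draws)[2]
  rows <- purrr::map(draws$param_names, function(p) {
    mat <- draws_of(draws, p, combine = FALSE)
    if (all(mat == mat[1, 1])) {
      return(tibble::tibble(term = p, psrf = NA_real_,
                            stationary_chains = n_chains,
                            n_chains = n_chains, pass = TRUE))
    }
    psrf <- gelman_rubin(mat)
    stat_ok <- sum(vapply(seq_len(n_chains), function(c) {
      ch <- mat[, c]
      if (stats::var(ch) == 0) TRUE else heidelberger_welch(ch, alpha = hw_alpha)$stationarity_passed
    }, logical(1)))
    tibble::tibble(term = p, psrf = psrf, stationary_chains = stat_ok,
                   n_chains = n_chains,
                   pass = psrf < psrf_threshold && stat_ok == n_chains)
  })
  out <- purrr::list_rbind(rows)
  attr(out, "overall_pass") <- all(out$pass)
  out
}
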