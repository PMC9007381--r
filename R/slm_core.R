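#' Stochastic logistic model parameters
#'
#' Bundle of the per-OTU parameters of the stochastic logistic model (SLM)
#' with environmental noise,
#' \deqn{\dot\lambda = \frac{1}{\tau}\lambda\Big(1 - \frac{\lambda}{K}\Big)
#'   + \sqrt{\frac{\sigma}{\tau}}\,\lambda\,\xi(t),}
#' whose stationary abundance distribution (for \eqn{\sigma < 2}) is a Gamma
#' with shape \eqn{2/\sigma - 1} and rate \eqn{2/(\sigma K)}.
#'
#' Fields may be vectors (one entry per OTU); `sigma` and `tau` are recycled
#' against `K`.
#'
#' @param K carrying-capacity scale(s), in relative-abundance units; must be
#'   positive. Under compositional data `K` is known only up to a sample-wide
#'   constant, which cancels in all fluctuation statistics.
#' @param sigma environmental noise amplitude(s); the stationary distribution
#'   exists for `0 < sigma < 2` and the squared coefficient of variation of
#'   abundance is `sigma / (2 - sigma)`.
#' @param tau relaxation timescale(s), positive. All stationary quantities are
#'   independent of `tau`; it only matters for [simulate_sde()].
#'
#' @return An object of class `slm_params`: a list with numeric fields `K`,
#'   `sigma`, `tau` of common length.
#' @seealso [gamma_stationary_pdf()], [stationary_moments()],
#'   [sample_stationary()], [simulate_sde()]
#' @export
#' @examples
#' p <- slm_params(K = 1e-3, sigma = 0.9)
#' stationary_moments(p)
slm_params <- function(K, sigma, tau = 1) {
  if (!is.numeric(K) || length(K) < 1L || anyNA(K) || any(K <= 0)) {
    stop_invalid("`K` must be positive and finite")
  }
  if (!is.numeric(sigma) || anyNA(sigma) || any(sigma < 0) || any(sigma >= 2)) {
    stop_invalid("`sigma` must lie in [0, 2): the SLM has no stationary distribution for sigma >= 2")
  }
  if (!is.numeric(tau) || anyNA(tau) || any(tau <= 0)) {
    stop_invalid("`tau` must be positive")
  }
  n <- length(K)
  structure(
    list(K = as.numeric(K),
         sigma = rep_len(as.numeric(sigma), n),
         tau = rep_len(as.numeric(tau), n)),
    class = "slm_params"
  )
}

#' @export
print.slm_params <- function(x, ...) {
  n <- length(x$K)
  cat(sprintf("SLM parameters for %d OTU%s\n", n, if (n == 1) "" else "s"))
  df <- data.frame(K = x$K, sigma = x$sigma, tau = x$tau)
  print(utils::head(df, 10L), ...)
  if (n > 10L) cat(sprintf("... and %d more\n", n - 10L))
  invisible(x)
}

as_scalar_params <- function(params) {
  if (!inherits(params, "slm_params")) stop_invalid("`params` must be an `slm_params` object")
  if (length(params$K) != 1L) {
    stop_invalid("this operation needs scalar (single-OTU) parameters; got %d OTUs",
                 length(params$K))
  }
  params
}

require_noisy <- function(params) {
  # sigma = 0 is legal for the SDE (plain logistic) but degenerates the
  # stationary Gamma law (shape diverges), so the stationary ops reject it.
  if (any(params$sigma == 0)) {
    stop_invalid("`sigma` = 0: the stationary Gamma law is degenerate; only simulate_sde accepts the noiseless model")
  }
  params
}
gamma_shape <- function(params) 2 / params$sigma - 1
gamma_rate <- function(params) 2 / (params$sigma * params$K)

#' Stationary Gamma density of SLM abundance
#'
#' Probability density of the stationary abundance fluctuation distribution of
#' the SLM: a Gamma with shape \eqn{2/\sigma - 1} and rate
#' \eqn{2/(\sigma K)}.
#'
#' @param x abundance value(s), non-negative.
#' @param params scalar [slm_params()].
#' @return Density values, same length as `x`.
#' @export
#' @examples
#' gamma_stationary_pdf(0.5, slm_params(K = 1, sigma = 1)) # 2 * exp(-1)
gamma_stationary_pdf <- function(x, params) {
  params <- require_noisy(as_scalar_params(params))
  if (any(x < 0)) stop_invalid("abundance `x` must be non-negative")
  stats::dgamma(x, shape = gamma_shape(params), rate = gamma_rate(params))
}

#' Mean and variance of the stationary abundance distribution
#'
#' Closed-form stationary moments of the SLM:
#' mean \eqn{\langle\lambda\rangle = K(2-\sigma)/2} and variance
#' \eqn{\sigma\langle\lambda\rangle^2/(2-\sigma)}. The squared coefficient of
#' variation, `sigma / (2 - sigma)`, does not depend on `K` — across OTUs
#' sharing `sigma`, variance scales as the square of the mean (Taylor's law
#' with exponent 2).
#'
#' @param params [slm_params()]; vector parameters give vector moments.
#' @return List with numeric fields `mean` and `variance`.
#' @export
stationary_moments <- function(params) {
  if (!inherits(params, "slm_params")) stop_invalid("`params` must be an `slm_params` object")
  m <- params$K * (2 - params$sigma) / 2
  list(mean = m, variance = params$sigma * m^2 / (2 - params$sigma))
}

#' Sample the stationary abundance distribution
#'
#' @param params scalar [slm_params()].
#' @param n number of i.i.d. draws (>= 1).
#' @param seed optional integer seed; when given, the caller's RNG state is
#'   restored afterwards.
#' @return Numeric vector of `n` abundances.
#' @export
sample_stationary <- function(params, n, seed = NULL) {
  params <- require_noisy(as_scalar_params(params))
  check_scalar_number(n, "n", lower = 1)
  if (n != round(n)) stop_invalid("`n` must be an integer")
  with_seed_if(seed,
    stats::rgamma(n, shape = gamma_shape(params), rate = gamma_rate(params)))
}

# One stationary draw per OTU for vector parameters (used by the pair simulator).
sample_community <- function(params, seed = NULL) {
  if (!inherits(params, "slm_params")) stop_invalid("`params` must be an `slm_params` object")
  require_noisy(params)
  with_seed_if(seed,
    pmax(stats::rgamma(length(params$K), shape = 2 / params$sigma - 1,
                       rate = 2 / (params$sigma * params$K)),
         .Machine$double.xmin))
}

#' Simulate an SLM trajectory
#'
#' Euler–Maruyama (Itô) integration of the SLM stochastic differential
#' equation. Negative excursions produced by the discretization are clipped to
#' a floor of `1e-15 * K`; with `dt` well below `tau` the long-run marginal of
#' the trajectory matches the stationary Gamma law.
#'
#' The drift-only case `sigma = 0` (plain deterministic logistic growth) is
#' accepted here even though the stationary-law functions reject it.
#'
#' @param params scalar [slm_params()] (`sigma = 0` allowed).
#' @param lambda0 initial abundance, positive.
#' @param dt integration timestep; should be small relative to `tau`
#'   (a warning is emitted when `dt > tau / 10`).
#' @param n_steps number of Euler steps.
#' @param seed optional integer seed.
#' @return Numeric vector of length `n_steps + 1` starting at `lambda0`.
#' @export
simulate_sde <- function(params, lambda0, dt, n_steps, seed = NULL) {
  if (!inherits(params, "slm_params")) stop_invalid("`params` must be an `slm_params` object")
  if (length(params$K) != 1L) stop_invalid("`simulate_sde` integrates one OTU at a time")
  check_scalar_number(lambda0, "lambda0", lower = 0, strict_lower = TRUE)
  check_scalar_number(dt, "dt", lower = 0, strict_lower = TRUE)
  check_scalar_number(n_steps, "n_steps", lower = 1)
  if (dt > params$tau / 10) {
    warning(sprintf("dt = %g exceeds tau/10 = %g; discretization bias likely",
                    dt, params$tau / 10), call. = FALSE)
  }
  K <- params$K; sigma <- params$sigma; tau <- params$tau
  floor_val <- 1e-15 * K
  noise_amp <- sqrt(sigma * dt / tau)
  traj <- numeric(n_steps + 1L)
  traj[1L] <- lambda0
  lam <- lambda0
  xi <- with_seed_if(seed, stats::rnorm(n_steps))
  for (i in seq_len(n_steps)) {
    lam <- lam + lam * (1 - lam / K) / tau * dt + lam * noise_amp * xi[i]
    if (!is.finite(lam)) {
      stop_invalid("SDE integration diverged at step %d (dt too large?)", i)
    }
    if (lam < floor_val) lam <- floor_val
    traj[i + 1L] <- lam
  }
  traj
}

# Vectorized Euler-Maruyama over a community: one row per OTU, recording every
# `record_every` steps after `burn_in` steps. Used by the fixture generator.
sde_evolve_community <- function(K, sigma, tau, dt, n_record, record_every,
                                 burn_in, lambda0 = K) {
  S <- length(K)
  lam <- rep_len(lambda0, S)
  floor_val <- 1e-15 * K
  noise_amp <- sqrt(sigma * dt / tau)
  out <- matrix(0, nrow = S, ncol = n_record)
  total <- burn_in + n_record * record_every
  rec <- 0L
  for (i in seq_len(total)) {
    lam <- lam + lam * (1 - lam / K) / tau * dt + lam * noise_amp * stats::rnorm(S)
    bad <- lam < floor_val
    if (any(bad)) lam[bad] <- floor_val[bad]
    if (i > burn_in && (i - burn_in) %% record_every == 0L) {
      rec <- rec + 1L
      out[, rec] <- lam
    }
  }
  out
}

#' Fit Taylor's law to abundance means and variances
#'
#' Ordinary least-squares fit of `log(variance)` against `log(mean)` across
#' OTUs. Under the SLM with a common noise amplitude `sigma`, the variance is
#' proportional to the squared mean, so the slope (Taylor exponent) is exactly
#' 2 and the intercept is `log(sigma / (2 - sigma))`.
#'
#' @param means per-OTU abundance means, positive, length >= 3.
#' @param variances per-OTU abundance variances, positive, same length.
#' @return List with `slope`, `log_intercept`, and the underlying `lm` fit.
#' @export
taylor_law_fit <- function(means, variances) {
  if (length(means) != length(variances)) {
    stop_invalid("`means` and `variances` must have the same length")
  }
  if (length(means) < 3L) stop_invalid("need at least 3 OTUs to fit Taylor's law")
  if (any(means <= 0) || any(variances <= 0)) {
    stop_invalid("means and variances must be positive for the log-log fit")
  }
  fit <- stats::lm(log(variances) ~ log(means))
  co <- stats::coef(fit)
  list(slope = unname(co[2L]), log_intercept = unname(co[1L]), fit = fit)
}
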