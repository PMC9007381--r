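#' OTU count time series
#'
#' Carrier for a matrix of OTU read counts across ordered time points together
#' with the per-timepoint sequencing depths — the input to the sampling-
#' corrected variance estimator and to per-OTU SLM parameter estimation.
#'
#' @param counts integer matrix, OTUs x timepoints (rownames are OTU ids).
#' @param depths integer vector of total reads per timepoint; every entry must
#'   be >= 2 and at least as large as the corresponding column sum.
#' @param timepoints optional ordered labels (defaults to column names or
#'   indices).
#' @return An object of class `otu_time_series`.
#' @export
otu_time_series <- function(counts, depths, timepoints = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop_invalid("need at least 2 timepoints")
  check_count_vector(as.vector(counts), "counts")
  if (length(depths) != ncol(counts)) {
    stop_invalid("`depths` must have one entry per timepoint")
  }
  check_count_vector(depths, "depths")
  if (any(depths < 2)) stop_invalid("every sampling depth must be >= 2")
  cs <- colSums(counts)
  if (any(cs > depths)) {
    stop_invalid("column sums exceed the stated depths at timepoint(s) %s",
                 paste(which(cs > depths), collapse = ", "))
  }
  if (is.null(timepoints)) {
    timepoints <- colnames(counts)
    if (is.null(timepoints)) timepoints <- as.character(seq_len(ncol(counts)))
  }
  colnames(counts) <- as.character(timepoints)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("OTU_%06d", seq_len(nrow(counts)))
  }
  structure(list(counts = counts, depths = as.numeric(depths),
                 timepoints = timepoints),
            class = "otu_time_series")
}

#' Sampling-corrected variance of relative abundance
#'
#' Estimates the variance of an OTU's true relative abundance across time
#' from its counts `x(t)` and depths `N(t)`, removing the multinomial
#' sampling contribution:
#' \deqn{\widehat{var}(\lambda) = \frac{1}{|T|}\sum_t
#'   \frac{x(t)(x(t)-1)}{N(t)(N(t)-1)} -
#'   \Big(\frac{1}{|T|}\sum_t \frac{x(t)}{N(t)}\Big)^2.}
#' The estimate can be negative when many counts are 0 or 1; the value is
#' returned as-is and the caller decides whether to exclude the OTU.
#'
#' @param counts integer count vector for one OTU across timepoints.
#' @param depths depths `N(t)`, each >= 2, same length (>= 2 timepoints).
#' @return Scalar variance estimate (possibly negative).
#' @export
#' @examples
#' corrected_variance(c(1, 9), c(10, 10)) # 0.15
corrected_variance <- function(counts, depths) {
  check_count_vector(counts, "counts")
  if (length(counts) != length(depths)) {
    stop_invalid("`counts` and `depths` must have the same length")
  }
  if (length(counts) < 2L) stop_invalid("need at least 2 timepoints")
  if (any(depths < 2)) stop_invalid("every depth must be >= 2")
  mean(counts * (counts - 1) / (depths * (depths - 1))) - mean(counts / depths)^2
}

#' Estimate SLM parameters for one OTU from its time series
#'
#' Inverts the stationary-moment expressions: with
#' `m = mean(x/N)` and `v` the sampling-corrected variance, set
#' `c = v / m^2`, giving `sigma = 2c / (1 + c)` and `K = m (1 + c)`.
#' OTUs whose corrected variance is non-positive cannot be inverted and are
#' returned as excluded.
#'
#' @inheritParams corrected_variance
#' @return List with `mean`, `variance`, `K`, `sigma`, `excluded`. For
#'   excluded OTUs `K` and `sigma` are `NA`.
#' @export
#' @examples
#' # m = 0.5, v = 0.15 -> c = 0.6, sigma = 0.75, K = 0.8
#' estimate_K_sigma(c(1, 9), c(10, 10))
estimate_K_sigma <- function(counts, depths) {
  m <- mean(counts / depths)
  if (m == 0) stop_invalid("OTU never observed: cannot estimate parameters")
  v <- corrected_variance(counts, depths)
  if (v <= 0) {
    return(list(mean = m, variance = v, K = NA_real_, sigma = NA_real_,
                excluded = TRUE))
  }
  cv2 <- v / m^2
  list(mean = m, variance = v,
       K = m * (1 + cv2), sigma = 2 * cv2 / (1 + cv2),
       excluded = FALSE)
}

#' Per-OTU SLM parameter estimates for a whole time series
#'
#' Applies [estimate_K_sigma()] to every OTU of an [otu_time_series()].
#' OTUs never observed, or with non-positive corrected variance, are flagged
#' as excluded.
#'
#' @param series an [otu_time_series()].
#' @return Data frame with columns `otu`, `mean`, `variance`, `K`, `sigma`,
#'   `excluded`.
#' @export
estimate_slm_table <- function(series) {
  if (!inherits(series, "otu_time_series")) {
    stop_invalid("`series` must be an `otu_time_series` object")
  }
  rows <- lapply(seq_len(nrow(series$counts)), function(i) {
    cnt <- series$counts[i, ]
    if (sum(cnt) == 0) {
      return(data.frame(mean = 0, variance = NA_real_, K = NA_real_,
                        sigma = NA_real_, excluded = TRUE))
    }
    est <- estimate_K_sigma(cnt, series$depths)
    data.frame(mean = est$mean, variance = est$variance, K = est$K,
               sigma = est$sigma, excluded = est$excluded)
  })
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(otu = rownames(series$counts), stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' Maximum-likelihood fit of a truncated lognormal to carrying capacities
#'
#' Fits the lognormal density renormalized on `(cutoff_c, Inf)` to the values
#' above the cutoff. The cutoff models the hard detection limit imposed by
#' finite sampling depth (OTUs with `K` near or below `1/N_reads` go
#' unobserved), so only the observable upper tail is informative.
#' Optimization is Nelder–Mead followed by BFGS polish from a moment-based
#' start, on `(mu, log s)`; if both stages fail to converge a profile grid
#' search is used as fallback.
#'
#' @param K_values positive carrying-capacity estimates.
#' @param cutoff_c positive lower truncation threshold; values `<= cutoff_c`
#'   are dropped (at least 10 must remain).
#' @return List with `mu_logK`, `s_logK`, `cutoff_c`, `n_used`,
#'   `n_excluded`, `logLik`, `converged`.
#' @export
fit_truncated_lognormal <- function(K_values, cutoff_c) {
  check_scalar_number(cutoff_c, "cutoff_c", lower = 0, strict_lower = TRUE)
  if (any(K_values <= 0, na.rm = TRUE)) stop_invalid("`K_values` must be positive")
  x <- K_values[!is.na(K_values) & K_values > cutoff_c]
  if (length(x) < 10L) {
    stop_invalid("only %d values above the cutoff; need at least 10", length(x))
  }
  lx <- log(x)
  nll <- function(p) {
    mu <- p[1L]; s <- exp(p[2L])
    v <- -sum(stats::dlnorm(x, mu, s, log = TRUE)) +
      length(x) * stats::plnorm(cutoff_c, mu, s, lower.tail = FALSE, log.p = TRUE)
    if (!is.finite(v)) 1e12 else v
  }
  start <- c(mean(lx), log(stats::sd(lx)))
  f1 <- stats::optim(start, nll, method = "Nelder-Mead",
                     control = list(maxit = 5000, reltol = 1e-12))
  f2 <- tryCatch(
    stats::optim(f1$par, nll, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-12)),
    error = function(e) f1)
  best <- if (f2$value <= f1$value) f2 else f1
  converged <- (best$convergence == 0)
  if (!converged) {
    # profile grid fallback: coarse scan of s, closed-ish mu refit by optimize
    s_grid <- exp(seq(log(stats::sd(lx) / 4), log(stats::sd(lx) * 8), length.out = 60))
    prof <- vapply(s_grid, function(s) {
      o <- stats::optimize(function(mu) nll(c(mu, log(s))),
                           interval = mean(lx) + c(-10, 2) * s)
      o$objective
    }, numeric(1L))
    j <- which.min(prof)
    o <- stats::optimize(function(mu) nll(c(mu, log(s_grid[j]))),
                         interval = mean(lx) + c(-10, 2) * s_grid[j])
    if (prof[j] < best$value) {
      best <- list(par = c(o$minimum, log(s_grid[j])), value = prof[j],
                   convergence = 0L)
    }
    converged <- TRUE
  }
  list(mu_logK = best$par[1L], s_logK = exp(best$par[2L]), cutoff_c = cutoff_c,
       n_used = length(x),
       n_excluded = sum(!is.na(K_values)) - length(x),
       logLik = -best$value, converged = converged)
}

#' Maximum-likelihood fit of an exponential distribution to `sigma^2`
#'
#' The exponential MLE for the mean is the sample mean.
#'
#' @param sigma2_values positive squared noise amplitudes.
#' @return Scalar `mean_sigma2`.
#' @export
fit_exponential_sigma2 <- function(sigma2_values) {
  if (length(sigma2_values) == 0L) stop_invalid("`sigma2_values` is empty")
  if (anyNA(sigma2_values) || any(sigma2_values <= 0)) {
    stop_invalid("`sigma2_values` must be positive")
  }
  mean(sigma2_values)
}

#' Spearman correlation of abundances between two samples
#'
#' Rank correlation over the OTUs observed in at least one of the two samples,
#' with absences entered as zero counts and tied ranks averaged. This is the
#' statistic the `rho_K` calibration maps onto the carrying-capacity
#' correlation, so calibration and inference must share the convention.
#'
#' @param pair a [sample_pair()].
#' @return Scalar Spearman correlation.
#' @export
spearman_abundance_correlation <- function(pair) {
  pair <- check_sample_pair(pair)
  keep <- pair$in_A | pair$in_B
  if (sum(keep) < 3L) stop_invalid("need at least 3 OTUs observed in the union")
  a <- pair$counts_A[keep]; b <- pair$counts_B[keep]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop_invalid("Spearman correlation undefined: constant counts in one sample")
  }
  stats::cor(a, b, method = "spearman")
}

#' Quadratic calibration curve mapping Spearman correlation to rho_K
#'
#' @param a0,a1,a2 coefficients of `rho_K = a0 + a1 s + a2 s^2`.
#' @param valid_range numeric length-2 interval of Spearman values over which
#'   the curve was fitted; predictions outside it are flagged.
#' @param data optional data frame `(rho_K, s)` the curve was fitted to.
#' @return An object of class `calibration_curve`.
#' @export
calibration_curve <- function(a0, a1, a2, valid_range, data = NULL) {
  check_scalar_number(a0, "a0"); check_scalar_number(a1, "a1")
  check_scalar_number(a2, "a2")
  if (length(valid_range) != 2L || diff(valid_range) <= 0) {
    stop_invalid("`valid_range` must be a non-empty interval")
  }
  structure(list(a0 = a0, a1 = a1, a2 = a2,
                 valid_range = as.numeric(valid_range), data = data),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("rho_K ~ %.3f + %.3f s + %.3f s^2   (fitted for s in [%.3f, %.3f])\n",
              x$a0, x$a1, x$a2, x$valid_range[1L], x$valid_range[2L]))
  invisible(x)
}

#' Calibrate the Spearman-to-rho_K map by simulation
#'
#' Simulates an ensemble of community pairs with known `rho_K`, computes the
#' Spearman abundance correlation of each sampled pair, and fits the
#' least-squares quadratic `rho_K ~ s + s^2`. The default ensemble mirrors
#' the package's reference simulation: 100 same-community pairs (identical
#' `K`, abundance correlation spanning 0–0.5, ground truth `rho_K = 1`) plus
#' 100 across-community pairs with `rho_K` spanning 0.5–1.
#'
#' Alternatively, supply `pairs_data` (a data frame with columns `rho_K` and
#' `s`) to fit the quadratic to precomputed values directly.
#'
#' @param base_config [pair_config()] template for the simulated pairs.
#' @param rho_grid,n_pairs_per_rho,same_K_corr_grid ensemble layout, as in
#'   [generate_ensemble()].
#' @param seed optional integer seed.
#' @param pairs_data optional precomputed `(rho_K, s)` data frame; when given,
#'   no simulation is run.
#' @return A [calibration_curve()], with the per-pair `(rho_K, s)` data
#'   attached.
#' @export
calibrate_rho_spearman <- function(base_config = pair_config(rho_K = 1),
                                   rho_grid = seq(0.5, 1, length.out = 100),
                                   n_pairs_per_rho = 1,
                                   same_K_corr_grid = seq(0, 0.5, length.out = 100),
                                   seed = NULL, pairs_data = NULL) {
  if (is.null(pairs_data)) {
    if (length(unique(rho_grid)) < 3L && length(same_K_corr_grid) == 0L) {
      stop_invalid("need at least 3 distinct rho_K values to fit a quadratic")
    }
    ens <- generate_ensemble(base_config, rho_grid, n_pairs_per_rho,
                             same_K_corr_grid, seed = seed)
    pairs_data <- data.frame(
      rho_K = vapply(ens, function(p) p$config$rho_K, numeric(1L)),
      s = vapply(ens, function(p) {
        spearman_abundance_correlation(sample_pair(p$counts_A, p$counts_B))
      }, numeric(1L))
    )
  }
  if (!all(c("rho_K", "s") %in% names(pairs_data))) {
    stop_invalid("`pairs_data` must have columns `rho_K` and `s`")
  }
  fit <- stats::lm(rho_K ~ s + I(s^2), data = pairs_data)
  if (anyNA(stats::coef(fit))) stop_invalid("degenerate design: quadratic fit is rank-deficient")
  co <- unname(stats::coef(fit))
  calibration_curve(co[1L], co[2L], co[3L], range(pairs_data$s), data = pairs_data)
}

#' Infer rho_K for a sample pair from a calibration curve
#'
#' Evaluates the calibrated quadratic at the pair's Spearman abundance
#' correlation and clips the result to `[0, 1]`. When the Spearman value falls
#' outside the range the curve was fitted on, the estimate is extrapolated and
#' flagged (the quadratic is non-monotone, so extrapolation is unreliable).
#'
#' @param pair a [sample_pair()].
#' @param curve a [calibration_curve()].
#' @return List with `rho_K`, `s`, and logical `extrapolated`.
#' @export
infer_rho_K <- function(pair, curve) {
  if (!inherits(curve, "calibration_curve")) {
    stop_invalid("`curve` must be a `calibration_curve` object")
  }
  s <- spearman_abundance_correlation(pair)
  rho <- curve$a0 + curve$a1 * s + curve$a2 * s^2
  extra <- s < curve$valid_range[1L] || s > curve$valid_range[2L]
  if (extra) {
    warning(sprintf("Spearman correlation %.3f outside calibrated range [%.3f, %.3f]; rho_K extrapolated",
                    s, curve$valid_range[1L], curve$valid_range[2L]), call. = FALSE)
  }
  list(rho_K = min(max(rho, 0), 1), s = s, extrapolated = extra)
}
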