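#' Configuration for a simulated community pair
#'
#' Parameters of the generative model for a pair of communities: `S` OTUs per
#' community, log carrying capacities drawn from a bivariate normal with
#' correlation `rho_K`, a shared per-OTU noise amplitude with `sigma^2`
#' exponentially distributed, Gamma-distributed true abundances, and
#' multinomial read sampling at fixed depth.
#'
#' Defaults are the simulation conditions used throughout the package's own
#' analyses: `S = 1e4` OTUs, lognormal log-K parameters `mu_logK = -19`,
#' `s_logK = 5` (natural log), exponential mean 0.9 for `sigma^2`, and
#' `3e4` reads per sample.
#'
#' @param S total number of OTUs per community, including those too rare to be
#'   detected at the given depth.
#' @param rho_K Pearson correlation of log carrying capacities across the two
#'   communities, in `[-1, 1]`.
#' @param mu_logK,s_logK mean and standard deviation of `log K`.
#' @param mean_sigma2 mean of the exponential distribution of `sigma^2`
#'   (draws are rejected and redrawn until `sigma^2 < 4`, the stationarity
#'   bound).
#' @param n_reads_A,n_reads_B sequencing depths (multinomial trial counts).
#' @param abundance_corr target Pearson correlation of the Gamma abundance
#'   draws for same-K pairs (requires `rho_K = 1`); 0 gives independent draws.
#' @param seed optional integer seed recorded in the config and used by
#'   [generate_pair()].
#' @return An object of class `pair_config`.
#' @export
pair_config <- function(S = 1e4, rho_K = 1, mu_logK = -19, s_logK = 5,
                        mean_sigma2 = 0.9, n_reads_A = 3e4, n_reads_B = 3e4,
                        abundance_corr = 0, seed = NULL) {
  check_scalar_number(S, "S", lower = 1)
  check_scalar_number(rho_K, "rho_K", lower = -1, upper = 1)
  check_scalar_number(mu_logK, "mu_logK")
  check_scalar_number(s_logK, "s_logK", lower = 0, strict_lower = TRUE)
  check_scalar_number(mean_sigma2, "mean_sigma2", lower = 0, strict_lower = TRUE)
  check_scalar_number(n_reads_A, "n_reads_A", lower = 1)
  check_scalar_number(n_reads_B, "n_reads_B", lower = 1)
  check_scalar_number(abundance_corr, "abundance_corr", lower = 0, upper = 1,
                      strict_upper = TRUE)
  if (abundance_corr > 0 && rho_K != 1) {
    stop_invalid("correlated abundance draws (`abundance_corr` > 0) are only defined for same-K pairs (rho_K = 1)")
  }
  structure(
    list(S = as.integer(S), rho_K = rho_K, mu_logK = mu_logK, s_logK = s_logK,
         mean_sigma2 = mean_sigma2, n_reads_A = as.integer(n_reads_A),
         n_reads_B = as.integer(n_reads_B), abundance_corr = abundance_corr,
         seed = seed),
    class = "pair_config"
  )
}

check_pair_config <- function(config) {
  if (!inherits(config, "pair_config")) stop_invalid("`config` must be a `pair_config` object")
  config
}

#' Draw correlated carrying capacities for a community pair
#'
#' Generates `S` pairs `(K_A, K_B)` by exponentiating draws from a bivariate
#' normal whose marginals are `Normal(mu_logK, s_logK^2)` and whose
#' correlation is `rho_K`. With `rho_K = 1` the two vectors are identical.
#'
#' @param config [pair_config()].
#' @param seed optional integer seed.
#' @return List with positive numeric vectors `K_A`, `K_B` of length `S`.
#' @export
sample_carrying_capacities <- function(config, seed = NULL) {
  config <- check_pair_config(config)
  with_seed_if(seed, {
    z1 <- stats::rnorm(config$S)
    z2 <- stats::rnorm(config$S)
    logK_A <- config$mu_logK + config$s_logK * z1
    logK_B <- config$mu_logK + config$s_logK *
      (config$rho_K * z1 + sqrt(1 - config$rho_K^2) * z2)
    list(K_A = exp(logK_A), K_B = exp(logK_B))
  })
}

#' Draw per-OTU noise amplitudes
#'
#' `sigma^2` is drawn from an exponential distribution with mean
#' `mean_sigma2`; draws at or above 4 (which would violate the stationarity
#' condition `sigma < 2`) are rejected and redrawn, so the returned
#' `sigma = sqrt(sigma^2)` always admits a stationary Gamma law.
#'
#' @inheritParams sample_carrying_capacities
#' @return Numeric vector of `S` values in `(0, 2)`.
#' @export
sample_sigmas <- function(config, seed = NULL) {
  config <- check_pair_config(config)
  with_seed_if(seed, {
    s2 <- stats::rexp(config$S, rate = 1 / config$mean_sigma2)
    bad <- which(s2 >= 4)
    while (length(bad) > 0L) {
      s2[bad] <- stats::rexp(length(bad), rate = 1 / config$mean_sigma2)
      bad <- bad[s2[bad] >= 4]
    }
    sqrt(s2)
  })
}

# ---- Gaussian copula machinery for correlated same-K abundance draws --------

# Monte-Carlo estimate of the Pearson correlation of two Gamma(shape, 1)
# variates coupled through a Gaussian copula with latent correlation `latent`.
# Pearson correlation is scale-free, so only the (shared) shape matters.
copula_gamma_pearson <- function(latent, shape, n_mc = 3e4) {
  z1 <- stats::rnorm(n_mc)
  z2 <- latent * z1 + sqrt(1 - latent^2) * stats::rnorm(n_mc)
  stats::cor(stats::qgamma(stats::pnorm(z1), shape = shape),
             stats::qgamma(stats::pnorm(z2), shape = shape))
}

# Tabulate the latent -> Pearson map over a grid of shapes, returning a
# function (target, shape) -> latent correlation. Interpolation is linear in
# log(shape) across the grid and monotone in the latent correlation. Shapes
# are clamped to [0.05, 100]: below ~0.05 the Gamma quantile underflows double
# precision for most of the unit interval (such OTUs are unobservable anyway),
# above 100 the map is flat in the shape.
build_copula_calibration <- function(shapes, n_mc = 3e4) {
  lo <- max(min(shapes), 0.05)
  hi <- min(max(shapes), 100)
  if (hi <= lo) hi <- lo * 1.0001
  shape_grid <- exp(seq(log(lo), log(hi), length.out = 8L))
  latent_grid <- c(0.01, seq(0.1, 0.9, by = 0.1), 0.95, 0.99, 0.999)
  pearson <- vapply(shape_grid, function(sh) {
    vapply(latent_grid, copula_gamma_pearson, numeric(1L), shape = sh, n_mc = n_mc)
  }, numeric(length(latent_grid)))
  pearson <- apply(pearson, 2L, cummax)  # enforce monotonicity against MC noise
  nlat <- length(latent_grid)
  function(target, shape) {
    lsh <- pmin(pmax(log(shape), log(shape_grid[1L])), log(shape_grid[length(shape_grid)]))
    # per-OTU latent -> Pearson curves, interpolated linearly in log(shape)
    pe <- vapply(seq_len(nlat), function(j) {
      stats::approx(log(shape_grid), pearson[j, ], xout = lsh, rule = 2)$y
    }, numeric(length(lsh)))
    pe <- matrix(pe, nrow = length(lsh))
    j <- pmin(pmax(rowSums(pe <= target), 1L), nlat - 1L)
    idx <- cbind(seq_along(lsh), j)
    p_lo <- pe[idx]
    p_hi <- pe[cbind(seq_along(lsh), j + 1L)]
    frac <- pmin(pmax((target - p_lo) / pmax(p_hi - p_lo, 1e-12), 0), 1)
    latent_grid[j] + frac * (latent_grid[j + 1L] - latent_grid[j])
  }
}

#' Draw paired Gamma abundances for the two communities
#'
#' Each abundance is marginally Gamma with shape `2/sigma - 1` and rate
#' `2/(sigma * K)`. With `abundance_corr = 0` the two draws are independent;
#' with a positive target (allowed only when `K_A` and `K_B` are identical,
#' mimicking two snapshots of the same community) the draws are coupled by a
#' Gaussian copula whose latent correlation is calibrated numerically so the
#' Pearson correlation of the Gamma pair matches the target.
#'
#' @param K_A,K_B positive carrying-capacity vectors of equal length.
#' @param sigma shared noise-amplitude vector, values in (0, 2).
#' @param abundance_corr target Pearson correlation in `[0, 1)`.
#' @param seed optional integer seed.
#' @param copula_map optional precomputed calibration from
#'   `build_copula_calibration()` (reused across pairs by [generate_ensemble()]).
#' @return List with positive numeric vectors `lambda_A`, `lambda_B`.
#' @export
sample_abundance_pair <- function(K_A, K_B, sigma, abundance_corr = 0,
                                  seed = NULL, copula_map = NULL) {
  S <- length(K_A)
  if (length(K_B) != S || length(sigma) != S) {
    stop_invalid("`K_A`, `K_B` and `sigma` must be aligned vectors")
  }
  if (any(K_A <= 0) || any(K_B <= 0)) stop_invalid("carrying capacities must be positive")
  if (any(sigma <= 0) || any(sigma >= 2)) stop_invalid("`sigma` must lie in (0, 2)")
  check_scalar_number(abundance_corr, "abundance_corr", lower = 0, upper = 1,
                      strict_upper = TRUE)
  shape <- 2 / sigma - 1
  # Gamma draws at very small shapes can underflow double precision to an
  # exact 0; every OTU is present in a community by construction, so such
  # draws are floored at the smallest positive normalized double.
  pos <- function(x) pmax(x, .Machine$double.xmin)
  if (abundance_corr == 0) {
    return(with_seed_if(seed, list(
      lambda_A = pos(stats::rgamma(S, shape = shape, rate = 2 / (sigma * K_A))),
      lambda_B = pos(stats::rgamma(S, shape = shape, rate = 2 / (sigma * K_B)))
    )))
  }
  if (any(K_A != K_B)) {
    stop_invalid("correlated abundance draws are only defined for identical K vectors (same-community pairs)")
  }
  with_seed_if(seed, {
    if (is.null(copula_map)) copula_map <- build_copula_calibration(range(shape))
    latent <- copula_map(rep_len(abundance_corr, S), shape)
    z1 <- stats::rnorm(S)
    z2 <- latent * z1 + sqrt(1 - latent^2) * stats::rnorm(S)
    list(
      lambda_A = pos(stats::qgamma(stats::pnorm(z1), shape = shape, rate = 2 / (sigma * K_A))),
      lambda_B = pos(stats::qgamma(stats::pnorm(z2), shape = shape, rate = 2 / (sigma * K_B)))
    )
  })
}

#' Multinomial read sampling of a community
#'
#' Draws a read-count vector from `Multinomial(n_reads, lambda / sum(lambda))`:
#' the finite-depth sequencing step. The unknown compositional constant in the
#' abundances cancels in the normalization.
#'
#' @param lambda non-negative true abundances with a positive sum.
#' @param n_reads total read count (trials), >= 1.
#' @param seed optional integer seed.
#' @return Integer count vector summing to `n_reads`.
#' @export
multinomial_sample <- function(lambda, n_reads, seed = NULL) {
  if (!is.numeric(lambda) || length(lambda) == 0L || any(lambda < 0)) {
    stop_invalid("`lambda` must be a non-negative numeric vector")
  }
  if (sum(lambda) <= 0) stop_invalid("`lambda` must have a positive sum")
  check_scalar_number(n_reads, "n_reads", lower = 1)
  with_seed_if(seed,
    as.integer(stats::rmultinom(1L, size = n_reads, prob = lambda / sum(lambda))[, 1L]))
}

#' Generate one community pair
#'
#' Composes the full generative recipe: correlated log-normal carrying
#' capacities, shared exponential `sigma^2`, Gamma abundances, and multinomial
#' sampling at the configured depths. Before sampling, every OTU is present in
#' both communities (`lambda > 0`), so the pre-sampling overlap is exactly 1.
#'
#' @param config [pair_config()].
#' @param seed optional integer seed (falls back to `config$seed`).
#' @param copula_map optional precomputed copula calibration.
#' @return An object of class `community_pair`: list with `K_A`, `K_B`,
#'   `sigma`, `lambda_A`, `lambda_B`, `counts_A`, `counts_B`, and `config`.
#' @export
generate_pair <- function(config, seed = NULL, copula_map = NULL) {
  config <- check_pair_config(config)
  if (is.null(seed)) seed <- config$seed
  with_seed_if(seed, {
    Ks <- sample_carrying_capacities(config)
    sigma <- sample_sigmas(config)
    lam <- sample_abundance_pair(Ks$K_A, Ks$K_B, sigma,
                                 abundance_corr = config$abundance_corr,
                                 copula_map = copula_map)
    counts_A <- multinomial_sample(lam$lambda_A, config$n_reads_A)
    counts_B <- multinomial_sample(lam$lambda_B, config$n_reads_B)
    structure(
      list(K_A = Ks$K_A, K_B = Ks$K_B, sigma = sigma,
           lambda_A = lam$lambda_A, lambda_B = lam$lambda_B,
           counts_A = counts_A, counts_B = counts_B, config = config),
      class = "community_pair"
    )
  })
}

#' @export
print.community_pair <- function(x, ...) {
  cat(sprintf("Community pair: S = %d OTUs, rho_K = %g, abundance_corr = %g\n",
              x$config$S, x$config$rho_K, x$config$abundance_corr))
  cat(sprintf("  reads: %d / %d; observed richness: %d / %d\n",
              sum(x$counts_A), sum(x$counts_B),
              sum(x$counts_A > 0), sum(x$counts_B > 0)))
  invisible(x)
}

#' Generate an ensemble of community pairs
#'
#' Mixes "across-community" pairs (carrying capacities correlated at the
#' levels in `rho_grid`, independent abundance draws) with "same-community"
#' pairs (identical carrying capacities, abundance draws correlated at the
#' levels in `same_K_corr_grid`, mimicking two time points of one community).
#' The defaults produce a 200-pair ensemble: 100 same-community pairs with
#' abundance correlation spanning 0–0.5 and 100 across-community pairs with
#' `rho_K` spanning 0.5–1.
#'
#' @param base_config [pair_config()] carrying the shared parameters
#'   (`S`, log-K distribution, `mean_sigma2`, depths).
#' @param rho_grid `rho_K` values for across-community pairs.
#' @param n_pairs_per_rho pairs generated at each grid value.
#' @param same_K_corr_grid abundance-correlation values for same-community
#'   pairs (one pair each); empty vector for across-community pairs only.
#' @param seed optional integer seed.
#' @return List of [generate_pair()] results; each element carries an
#'   `origin` attribute, `"across"` or `"same_K"`.
#' @export
generate_ensemble <- function(base_config = pair_config(rho_K = 1),
                              rho_grid = seq(0.5, 1, length.out = 100),
                              n_pairs_per_rho = 1,
                              same_K_corr_grid = seq(0, 0.5, length.out = 100),
                              seed = NULL) {
  base_config <- check_pair_config(base_config)
  if (length(rho_grid) == 0L && length(same_K_corr_grid) == 0L) {
    stop_invalid("at least one of `rho_grid`, `same_K_corr_grid` must be non-empty")
  }
  check_scalar_number(n_pairs_per_rho, "n_pairs_per_rho", lower = 1)
  with_seed_if(seed, {
    pairs <- list()
    for (rho in rho_grid) {
      cfg <- base_config
      cfg$rho_K <- rho
      cfg$abundance_corr <- 0
      for (i in seq_len(n_pairs_per_rho)) {
        p <- generate_pair(cfg)
        attr(p, "origin") <- "across"
        pairs[[length(pairs) + 1L]] <- p
      }
    }
    if (length(same_K_corr_grid) > 0L) {
      # one shared calibration map: sigma^2 ~ Exp(mean_sigma2) truncated below 4
      # puts the Gamma shape 2/sigma - 1 essentially within (1e-3, 1e3)
      copula_map <- build_copula_calibration(c(1e-3, 1e3))
      for (r in same_K_corr_grid) {
        cfg <- base_config
        cfg$rho_K <- 1
        cfg$abundance_corr <- r
        p <- generate_pair(cfg, copula_map = copula_map)
        attr(p, "origin") <- "same_K"
        pairs[[length(pairs) + 1L]] <- p
      }
    }
    pairs
  })
}
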