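test_that("sampling-corrected variance reproduces hand arithmetic", {
  # counts (1,9), depths (10,10): (0 + 72/90)/2 - 0.5^2 = 0.15
  expect_equal(corrected_variance(c(1, 9), c(10, 10)), 0.15, tolerance = 1e-12)
  # a single count of 1: (0 + 0)/2 - 0.05^2 = -0.0025 (negative is legal)
  expect_equal(corrected_variance(c(1, 0), c(10, 10)), -0.0025, tolerance = 1e-12)
  # constant relative abundance at large depth: 499/1998 - 0.25 ~ -2.5e-4,
  # the pure-sampling variance removed down to the hypergeometric remainder
  expect_equal(corrected_variance(c(500, 500), c(1000, 1000)),
               500 * 499 / (1000 * 999) - 0.25, tolerance = 1e-12)
  expect_lt(abs(corrected_variance(c(500, 500), c(1000, 1000))), 3e-4)

  expect_error(corrected_variance(c(1, 2), c(10, 1)), "depth")
  expect_error(corrected_variance(c(1), c(10)), "timepoints")
})

test_that("corrected variance is unbiased under multinomial resampling", {
  lam <- c(0.02, 0.005, 0.001, 0.05, 0.01)  # fixed abundance trajectory
  depth <- 2000
  true_var <- mean(lam^2) - mean(lam)^2
  ests <- withr::with_seed(41, {
    vapply(1:2000, function(i) {
      counts <- rbinom(length(lam), depth, lam)
      corrected_variance(counts, rep(depth, length(lam)))
    }, numeric(1))
  })
  se <- stats::sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - true_var), 4 * se)
})

test_that("moment inversion recovers K and sigma", {
  # m = 0.5, v = 0.15 -> cv2 = 0.6 -> sigma = 0.75, K = 0.8
  est <- estimate_K_sigma(c(1, 9), c(10, 10))
  expect_equal(est$sigma, 0.75, tolerance = 1e-12)
  expect_equal(est$K, 0.8, tolerance = 1e-12)

  # inversion is the exact inverse of the stationary moments
  for (K in c(1e-4, 1e-2, 1)) {
    for (sigma in c(0.1, 0.9, 1.9)) {
      mom <- stationary_moments(slm_params(K = K, sigma = sigma))
      cv2 <- mom$variance / mom$mean^2
      expect_equal(2 * cv2 / (1 + cv2), sigma, tolerance = 1e-12)
      expect_equal(mom$mean * (1 + cv2), K, tolerance = 1e-12)
    }
  }

  excl <- estimate_K_sigma(c(1, 0), c(10, 10))
  expect_true(excl$excluded)
  expect_true(is.na(excl$K))
  expect_error(estimate_K_sigma(c(0, 0), c(10, 10)), "never observed")
})

test_that("simulated time series yield accurate per-OTU K and sigma estimates", {
  ts <- simulate_time_series(slm_params(K = rep(1e-3, 60), sigma = 0.8),
                             n_timepoints = 200, depth = 5e4, seed = 42)
  tab <- estimate_slm_table(ts)
  tab <- tab[tab$otu != "OTU_rest" & !tab$excluded, ]
  expect_gt(nrow(tab), 50)
  expect_lt(abs(stats::median(tab$K) / 1e-3 - 1), 0.10)
  expect_lt(abs(stats::median(tab$sigma) / 0.8 - 1), 0.15)
})

test_that("truncated-lognormal fit reduces to the closed form without truncation", {
  x <- withr::with_seed(43, rlnorm(500, meanlog = -2, sdlog = 1.5))
  # cutoff far below the sample: the truncation factor is numerically 1
  fit <- fit_truncated_lognormal(x, cutoff_c = min(x) * 1e-6)
  lx <- log(x)
  expect_equal(fit$mu_logK, mean(lx), tolerance = 1e-5)
  expect_equal(fit$s_logK, sqrt(mean((lx - mean(lx))^2)), tolerance = 1e-5)
  expect_equal(fit$n_used, 500L)
})

test_that("truncated-lognormal fit maximizes the truncated likelihood", {
  loglik <- function(x, c0, mu, s) {
    sum(stats::dlnorm(x, mu, s, log = TRUE)) -
      length(x) * stats::plnorm(c0, mu, s, lower.tail = FALSE, log.p = TRUE)
  }
  x <- withr::with_seed(44, rlnorm(3000, meanlog = -19, sdlog = 5))
  c0 <- 10^-6.5  # mild truncation: most of the mass retained
  fit <- fit_truncated_lognormal(x, c0)
  xt <- x[x > c0]
  expect_gte(loglik(xt, c0, fit$mu_logK, fit$s_logK),
             loglik(xt, c0, -19, 5))
})

test_that("truncated-lognormal recovery improves with sample size under mild truncation", {
  err <- vapply(c(500, 20000), function(n) {
    x <- withr::with_seed(45, rlnorm(n, meanlog = -10, sdlog = 2))
    f <- fit_truncated_lognormal(x, cutoff_c = exp(-10))  # cutoff at the median
    abs(f$mu_logK + 10) + abs(f$s_logK - 2)
  }, numeric(1))
  expect_lt(err[2], err[1])
  x <- withr::with_seed(46, rlnorm(2e4, meanlog = -10, sdlog = 2))
  f <- fit_truncated_lognormal(x, cutoff_c = exp(-10))
  expect_equal(f$mu_logK, -10, tolerance = 0.1)
  expect_equal(f$s_logK, 2, tolerance = 0.05)

  expect_error(fit_truncated_lognormal(c(1, 2, 3), 0.5), "at least 10")
})

test_that("exponential MLE for sigma^2 is the sample mean", {
  expect_equal(fit_exponential_sigma2(c(1, 2, 3)), 2)
  expect_equal(fit_exponential_sigma2(0.37), 0.37)
  draws <- withr::with_seed(47, rexp(1e5, rate = 1 / 0.93))
  expect_equal(fit_exponential_sigma2(draws), 0.93, tolerance = 0.01)
  expect_error(fit_exponential_sigma2(c(1, -1)), "positive")
})

test_that("Spearman abundance correlation follows the rank-then-Pearson oracle", {
  p_same <- sample_pair(c(5, 3, 1, 0), c(5, 3, 1, 0))
  expect_equal(spearman_abundance_correlation(p_same), 1)
  p_rev <- sample_pair(c(1, 2, 3), c(3, 2, 1))
  expect_equal(spearman_abundance_correlation(p_rev), -1)

  withr::with_seed(48, {
    for (rep in 1:100) {
      rc <- random_count_pair()
      keep <- rc$a > 0 | rc$b > 0
      if (sum(keep) < 3 || sd(rc$a[keep]) == 0 || sd(rc$b[keep]) == 0) next
      s <- spearman_abundance_correlation(sample_pair(rc$a, rc$b))
      oracle <- stats::cor(rank(rc$a[keep]), rank(rc$b[keep]))
      expect_equal(s, oracle, tolerance = 1e-12)
    }
  })

  expect_error(spearman_abundance_correlation(sample_pair(c(2, 2, 2), c(1, 2, 3))),
               "constant")
})

test_that("quadratic calibration inverts noiseless data exactly and is reproducible", {
  s <- seq(-0.2, 0.8, length.out = 30)
  rho <- 0.9 + 0.3 * s - 0.45 * s^2
  curve <- calibrate_rho_spearman(pairs_data = data.frame(rho_K = rho, s = s))
  expect_equal(curve$a0, 0.9, tolerance = 1e-10)
  expect_equal(curve$a1, 0.3, tolerance = 1e-10)
  expect_equal(curve$a2, -0.45, tolerance = 1e-10)
  expect_equal(curve$valid_range, range(s))

  cfg <- test_config()
  c1 <- calibrate_rho_spearman(cfg, rho_grid = seq(0.5, 1, length.out = 10),
                               same_K_corr_grid = seq(0, 0.5, length.out = 10),
                               seed = 49)
  c2 <- calibrate_rho_spearman(cfg, rho_grid = seq(0.5, 1, length.out = 10),
                               same_K_corr_grid = seq(0, 0.5, length.out = 10),
                               seed = 49)
  expect_equal(c1$a0, c2$a0)
  expect_equal(c1$data$s, c2$data$s)
})

test_that("rho_K inference evaluates the published-form quadratic and flags extrapolation", {
  curve <- calibration_curve(0.92, 0.34, -0.48, valid_range = c(-0.1, 0.6))
  p <- sample_pair(c(5, 3, 1, 0), c(5, 3, 1, 0))  # s = 1, outside range
  expect_warning(res <- infer_rho_K(p, curve), "extrapolated")
  expect_true(res$extrapolated)

  # evaluate the quadratic directly at s = 0 and s = 0.5
  expect_equal(0.92 + 0.34 * 0 - 0.48 * 0^2, 0.92)
  q5 <- 0.92 + 0.34 * 0.5 - 0.48 * 0.25
  expect_equal(q5, 0.97)
  curve_wide <- calibration_curve(0.92, 0.34, -0.48, valid_range = c(-1, 1.5))
  res5 <- infer_rho_K(sample_pair(c(4, 3, 2, 1), c(3, 4, 1, 2)), curve_wide)
  expect_equal(res5$rho_K, 0.92 + 0.34 * res5$s - 0.48 * res5$s^2, tolerance = 1e-12)
  expect_false(res5$extrapolated)

  # clipping to [0, 1]
  hi <- calibration_curve(1.2, 0, 0, valid_range = c(-1, 1.5))
  expect_equal(infer_rho_K(sample_pair(c(4, 3, 2, 1), c(3, 4, 1, 2)), hi)$rho_K, 1)
})

test_that("rho_K round-trips through calibration and inference on fresh pairs", {
  cfg <- pair_config(S = 5e3, n_reads_A = 1e4, n_reads_B = 1e4, rho_K = 1)
  curve <- calibrate_rho_spearman(cfg, rho_grid = seq(0.5, 1, length.out = 40),
                                  same_K_corr_grid = seq(0, 0.5, length.out = 40),
                                  seed = 50)
  for (rho in c(0.6, 0.8, 0.95)) {
    cfg_r <- cfg; cfg_r$rho_K <- rho
    est <- withr::with_seed(51 + round(100 * rho), {
      vapply(1:11, function(i) {
        p <- generate_pair(cfg_r)
        suppressWarnings(
          infer_rho_K(sample_pair(p$counts_A, p$counts_B), curve)$rho_K)
      }, numeric(1))
    })
    expect_lt(abs(stats::median(est) - rho), 0.05)
  }
})
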