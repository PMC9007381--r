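# Independent, deliberately naive re-implementations used as oracles.
# Everything here works on explicit index sets with scalar loops, sharing no
# code with the package implementation.

oracle_metrics <- function(nA, nB) {
  SA <- which(nA > 0)
  SB <- which(nB > 0)
  I <- intersect(SA, SB)
  U <- union(SA, SB)
  NA_tot <- sum(nA)
  NB_tot <- sum(nB)
  xA <- nA / NA_tot
  xB <- nB / NB_tot

  plogp <- function(v) if (v > 0) v * log(v) else 0

  # Shannon entropies for the effective Whittaker ratio
  HA <- 0; HB <- 0; Hm <- 0
  for (i in U) {
    HA <- HA - plogp(xA[i])
    HB <- HB - plogp(xB[i])
    Hm <- Hm - plogp((xA[i] + xB[i]) / 2)
  }

  mh_num <- 0; mh_den <- 0
  horn_num <- 0
  bc_shared <- 0
  for (i in U) {
    mh_num <- mh_num + xA[i] * xB[i]
    mh_den <- mh_den + xA[i]^2 + xB[i]^2
    horn_num <- horn_num + plogp(nA[i] + nB[i]) - plogp(nA[i]) - plogp(nB[i])
    bc_shared <- bc_shared + min(nA[i], nB[i])
  }
  horn_den <- plogp(NA_tot + NB_tot) - plogp(NA_tot) - plogp(NB_tot)

  if (length(I) > 0) {
    xhA <- nA[I] / sum(nA[I])
    xhB <- nB[I] / sum(nB[I])
    m <- (xhA + xhB) / 2
    kl <- function(p, q) {
      s <- 0
      for (j in seq_along(p)) if (p[j] > 0) s <- s + p[j] * log(p[j] / q[j])
      s
    }
    D <- sqrt((kl(xhA, m) + kl(xhB, m)) / 2)
    O <- (sum(nA[I]) / NA_tot + sum(nB[I]) / NB_tot) / 2
  } else {
    D <- NA_real_
    O <- 0
  }

  list(jaccard = length(I) / length(U),
       sorensen = 2 * length(I) / (length(SA) + length(SB)),
       whittaker = 2 * length(U) / (length(SA) + length(SB)),
       effective_whittaker = 2 * exp(Hm) / (exp(HA) + exp(HB)),
       morisita_horn = 2 * mh_num / mh_den,
       horn = horn_num / horn_den,
       bray_curtis = 1 - 2 * bc_shared / (NA_tot + NB_tot),
       dissimilarity = D,
       overlap = O)
}

oracle_binned_average <- function(x, y, n_bins, axis = "x") {
  ref <- if (axis == "x") x else y
  breaks <- seq(min(ref), max(ref), length.out = n_bins + 1)
  xm <- c(); ym <- c(); cnt <- c()
  for (b in seq_len(n_bins)) {
    if (b < n_bins) {
      inb <- ref >= breaks[b] & ref < breaks[b + 1]
    } else {
      inb <- ref >= breaks[b] & ref <= breaks[b + 1]
    }
    if (any(inb)) {
      xm <- c(xm, mean(x[inb])); ym <- c(ym, mean(y[inb])); cnt <- c(cnt, sum(inb))
    }
  }
  data.frame(x_mean = xm, y_mean = ym, count = cnt)
}

# Random sparse count pair with at least one read per sample.
random_count_pair <- function(max_otus = 20) {
  n <- sample(2:max_otus, 1)
  repeat {
    a <- rpois(n, lambda = sample(c(0.5, 2, 10), 1)) * rbinom(n, 1, 0.7)
    b <- rpois(n, lambda = sample(c(0.5, 2, 10), 1)) * rbinom(n, 1, 0.7)
    if (sum(a) > 0 && sum(b) > 0) return(list(a = a, b = b))
  }
}

# Small shared config for simulator-based tests.
test_config <- function(...) {
  args <- list(S = 2000, rho_K = 0.8, n_reads_A = 5e3, n_reads_B = 5e3)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(pair_config, args)
}
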