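#' Dissimilarity and overlap for an ensemble of pairs
#'
#' Computes the (overlap, dissimilarity) point of each pair — the raw material
#' of a dissimilarity–overlap curve (DOC). Pairs whose dissimilarity is
#' undefined (no shared OTU) are retained with `defined = FALSE`.
#'
#' Input pairs may be [sample_pair()] objects or [generate_pair()] results;
#' for the latter, ground-truth `rho_K` and the pair's origin are carried
#' through, and `use_true_abundances = TRUE` evaluates the metrics on the
#' pre-sampling abundance vectors instead of the read counts (in which case
#' every overlap is exactly 1).
#'
#' @param pairs list of `sample_pair` and/or `community_pair` objects.
#' @param use_true_abundances evaluate on true abundances rather than sampled
#'   counts (community pairs only).
#' @return An object of class `doc_result`: a data frame with columns
#'   `overlap`, `dissimilarity`, `defined`, `rho_K`, `origin`.
#' @export
compute_doc <- function(pairs, use_true_abundances = FALSE) {
  if (!is.list(pairs) || length(pairs) == 0L) stop_invalid("`pairs` must be a non-empty list")
  rows <- lapply(pairs, function(p) {
    rho <- NA_real_; origin <- "unknown"
    if (inherits(p, "community_pair")) {
      rho <- p$config$rho_K
      origin <- attr(p, "origin") %||% "simulated"
      sp <- if (use_true_abundances) {
        sample_pair(p$lambda_A, p$lambda_B, check_integer = FALSE)
      } else {
        sample_pair(p$counts_A, p$counts_B)
      }
    } else if (inherits(p, "sample_pair")) {
      if (use_true_abundances) stop_invalid("true abundances are only available for community pairs")
      sp <- p
    } else {
      stop_invalid("each element must be a `sample_pair` or `community_pair`")
    }
    d <- dissimilarity_rjsd(sp)
    data.frame(overlap = overlap(sp), dissimilarity = as.numeric(d),
               defined = !is.na(d), rho_K = rho, origin = origin,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("doc_result", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Binned average of a scatter
#'
#' Equal-width bins on the chosen axis over its observed range; within each
#' non-empty bin the mean of both variables is reported. Binning along `y`
#' follows the DOC convention of averaging along the dissimilarity axis to
#' resolve the high-overlap region.
#'
#' @param x,y numeric vectors of equal length.
#' @param n_bins number of equal-width bins (>= 1).
#' @param axis `"x"` or `"y"`: which variable defines the bins.
#' @return Data frame with `x_mean`, `y_mean`, `count`, and the bin edges as
#'   an attribute `breaks`; empty bins are omitted.
#' @export
binned_average <- function(x, y, n_bins = 20, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (length(x) != length(y)) stop_invalid("`x` and `y` must have the same length")
  check_scalar_number(n_bins, "n_bins", lower = 1)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < n_bins) stop_invalid("fewer points (%d) than bins (%d)", length(x), n_bins)
  ref <- if (axis == "x") x else y
  rng <- range(ref)
  if (diff(rng) == 0) {
    out <- data.frame(x_mean = mean(x), y_mean = mean(y), count = length(x))
    attr(out, "breaks") <- rng
    return(out)
  }
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  idx <- findInterval(ref, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  xm <- tapply(x, idx, mean)
  ym <- tapply(y, idx, mean)
  cnt <- tapply(x, idx, length)
  out <- data.frame(x_mean = as.numeric(xm), y_mean = as.numeric(ym),
                    count = as.integer(cnt))
  out <- out[order(as.integer(names(xm))), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "breaks") <- breaks
  out
}

#' Slope of the DOC in the high-overlap regime
#'
#' Least-squares slope of dissimilarity on overlap restricted to pairs with
#' overlap above a threshold, with a percentile bootstrap interval over pairs.
#' A negative slope with an interval excluding zero is the sampling-induced
#' DOC signature.
#'
#' @param doc a [compute_doc()] result.
#' @param overlap_threshold keep pairs with overlap strictly above this value.
#' @param n_bootstrap bootstrap resamples for the percentile interval.
#' @param seed optional integer seed.
#' @param conf confidence level of the percentile interval.
#' @return List with `slope`, `ci` (length 2), `n_pairs`, `n_undefined`.
#' @export
doc_slope_high_overlap <- function(doc, overlap_threshold = 0.9,
                                   n_bootstrap = 1000, seed = NULL,
                                   conf = 0.95) {
  if (!inherits(doc, "doc_result")) stop_invalid("`doc` must be a `doc_result`")
  check_scalar_number(overlap_threshold, "overlap_threshold", lower = 0, upper = 1)
  sub <- doc[doc$defined & doc$overlap > overlap_threshold, , drop = FALSE]
  n_undef <- sum(!doc$defined)
  if (nrow(sub) < 10L) {
    stop_invalid("only %d defined pairs above overlap %g; need at least 10",
                 nrow(sub), overlap_threshold)
  }
  slope_of <- function(d) {
    if (stats::var(d$overlap) == 0) return(0)
    unname(stats::coef(stats::lm(dissimilarity ~ overlap, data = d))[2L])
  }
  slope <- slope_of(sub)
  boots <- with_seed_if(seed, {
    vapply(seq_len(n_bootstrap), function(i) {
      slope_of(sub[sample.int(nrow(sub), replace = TRUE), , drop = FALSE])
    }, numeric(1L))
  })
  alpha <- (1 - conf) / 2
  list(slope = slope,
       ci = unname(stats::quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE)),
       n_pairs = nrow(sub), n_undefined = n_undef)
}

#' Binned beta-diversity measures against rho_K
#'
#' For each of the eight measures, the binned average of its per-pair value
#' against the pairs' ground-truth (or inferred) carrying-capacity
#' correlation. Undefined dissimilarities are dropped from that metric's
#' curve only.
#'
#' @param ensemble list of `community_pair` objects (or a list of
#'   `sample_pair`s accompanied by `rho_K`).
#' @param rho_K optional vector of correlations, one per pair, overriding the
#'   stored ground truth.
#' @param n_bins number of equal-width bins along `rho_K`.
#' @return Named list of [binned_average()] data frames, one per metric, plus
#'   a `per_pair` data frame of the raw values.
#' @export
metric_vs_rho_curves <- function(ensemble, rho_K = NULL, n_bins = 20) {
  if (!is.list(ensemble) || length(ensemble) == 0L) stop_invalid("`ensemble` must be a non-empty list")
  if (is.null(rho_K)) {
    rho_K <- vapply(ensemble, function(p) {
      if (inherits(p, "community_pair")) p$config$rho_K else NA_real_
    }, numeric(1L))
  }
  if (anyNA(rho_K)) stop_invalid("each pair needs a known or supplied rho_K")
  metric_names <- c("jaccard", "sorensen", "whittaker", "effective_whittaker",
                    "morisita_horn", "horn", "bray_curtis", "dissimilarity",
                    "overlap")
  vals <- lapply(ensemble, function(p) {
    sp <- if (inherits(p, "community_pair")) sample_pair(p$counts_A, p$counts_B) else p
    unlist(all_metrics(sp)[metric_names])
  })
  per_pair <- as.data.frame(do.call(rbind, vals))
  per_pair$rho_K <- rho_K
  curves <- lapply(metric_names, function(mn) {
    ok <- is.finite(per_pair[[mn]])
    binned_average(per_pair$rho_K[ok], per_pair[[mn]][ok],
                   n_bins = min(n_bins, max(1L, sum(ok))))
  })
  names(curves) <- metric_names
  c(curves, list(per_pair = per_pair))
}
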