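#' A pair of samples on a shared OTU index
#'
#' Container for two read-count vectors over a common OTU index, the input to
#' all pairwise beta-diversity measures. Derived quantities (read totals,
#' relative abundances, observed support sets) are computed once here.
#'
#' @param counts_A,counts_B non-negative count vectors of equal length. Each
#'   must contain at least one read. With `check_integer = FALSE`,
#'   non-integer abundances (e.g. true relative abundances rather than read
#'   counts) are accepted; all metrics are well defined on them.
#' @param otu_ids optional character vector of OTU identifiers.
#' @param check_integer require integer counts (default).
#' @return An object of class `sample_pair`.
#' @export
#' @examples
#' p <- sample_pair(c(3, 1, 0), c(2, 0, 2))
#' all_metrics(p)
sample_pair <- function(counts_A, counts_B, otu_ids = NULL, check_integer = TRUE) {
  if (length(counts_A) != length(counts_B)) {
    stop_invalid("`counts_A` and `counts_B` must have the same length")
  }
  if (check_integer) {
    check_count_vector(counts_A, "counts_A", allow_zero = FALSE)
    check_count_vector(counts_B, "counts_B", allow_zero = FALSE)
  } else {
    if (any(counts_A < 0) || any(counts_B < 0)) stop_invalid("counts must be non-negative")
    if (sum(counts_A) <= 0 || sum(counts_B) <= 0) stop_invalid("each sample needs a positive total")
  }
  if (!is.null(otu_ids) && length(otu_ids) != length(counts_A)) {
    stop_invalid("`otu_ids` must match the count vectors in length")
  }
  N_A <- sum(counts_A); N_B <- sum(counts_B)
  structure(
    list(counts_A = counts_A, counts_B = counts_B, otu_ids = otu_ids,
         N_A = N_A, N_B = N_B,
         x_A = counts_A / N_A, x_B = counts_B / N_B,
         in_A = counts_A > 0, in_B = counts_B > 0),
    class = "sample_pair"
  )
}

check_sample_pair <- function(pair) {
  if (!inherits(pair, "sample_pair")) stop_invalid("`pair` must be a `sample_pair` object")
  pair
}

#' @export
print.sample_pair <- function(x, ...) {
  cat(sprintf("Sample pair: %d OTUs; reads %s / %s; richness %d / %d; shared %d\n",
              length(x$counts_A), format(x$N_A), format(x$N_B),
              sum(x$in_A), sum(x$in_B), sum(x$in_A & x$in_B)))
  invisible(x)
}

#' Jaccard similarity
#'
#' Presence–absence similarity: the number of OTUs observed in both samples
#' over the number observed in either.
#'
#' @param pair a [sample_pair()].
#' @return Scalar in `[0, 1]`.
#' @export
jaccard <- function(pair) {
  pair <- check_sample_pair(pair)
  sum(pair$in_A & pair$in_B) / sum(pair$in_A | pair$in_B)
}

#' Sørensen similarity
#'
#' Twice the shared richness over the summed richness of the two samples.
#'
#' @inheritParams jaccard
#' @return Scalar in `[0, 1]`.
#' @export
sorensen <- function(pair) {
  pair <- check_sample_pair(pair)
  2 * sum(pair$in_A & pair$in_B) / (sum(pair$in_A) + sum(pair$in_B))
}

#' Whittaker index
#'
#' The ratio of gamma- to (mean) alpha-diversity on a richness basis:
#' `2 |union| / (|S_A| + |S_B|)`, ranging from 1 (identical supports) to 2
#' (disjoint supports).
#'
#' @inheritParams jaccard
#' @return Scalar in `[1, 2]`.
#' @export
whittaker <- function(pair) {
  pair <- check_sample_pair(pair)
  2 * sum(pair$in_A | pair$in_B) / (sum(pair$in_A) + sum(pair$in_B))
}

#' Effective Whittaker index
#'
#' Whittaker's gamma/alpha ratio with richness replaced by the exponential of
#' the Shannon entropy (Hill number of order 1), using the mixture
#' `m = (x_A + x_B) / 2` for the gamma part. For samples with disjoint
#' supports the value can exceed 1 (it approaches 2 for identical entropies).
#'
#' @inheritParams jaccard
#' @return Positive scalar.
#' @export
effective_whittaker <- function(pair) {
  pair <- check_sample_pair(pair)
  m <- (pair$x_A + pair$x_B) / 2
  2 * exp(-sum(xlogx(m))) / (exp(-sum(xlogx(pair$x_A))) + exp(-sum(xlogx(pair$x_B))))
}

#' Morisita–Horn similarity
#'
#' Abundance-based similarity `2 sum(x_A x_B) / (sum(x_A^2) + sum(x_B^2))`,
#' dominated by the most abundant OTUs.
#'
#' @inheritParams jaccard
#' @return Scalar in `[0, 1]`.
#' @export
morisita_horn <- function(pair) {
  pair <- check_sample_pair(pair)
  2 * sum(pair$x_A * pair$x_B) / (sum(pair$x_A^2) + sum(pair$x_B^2))
}

#' Horn similarity
#'
#' Information-theoretic overlap computed from raw counts:
#' `sum[(n_A + n_B) log(n_A + n_B) - n_A log n_A - n_B log n_B]` over OTUs,
#' normalized by the same expression evaluated on the read totals.
#'
#' @inheritParams jaccard
#' @return Scalar in `[0, 1]`.
#' @export
horn <- function(pair) {
  pair <- check_sample_pair(pair)
  nA <- pair$counts_A; nB <- pair$counts_B
  num <- sum(xlogx(nA + nB) - xlogx(nA) - xlogx(nB))
  den <- xlogx(pair$N_A + pair$N_B) - xlogx(pair$N_A) - xlogx(pair$N_B)
  num / den
}

#' Bray–Curtis dissimilarity
#'
#' `1 - 2 sum(min(n_A, n_B)) / (N_A + N_B)` on raw counts.
#'
#' @inheritParams jaccard
#' @return Scalar in `[0, 1]`.
#' @export
bray_curtis <- function(pair) {
  pair <- check_sample_pair(pair)
  1 - 2 * sum(pmin(pair$counts_A, pair$counts_B)) / (pair$N_A + pair$N_B)
}

#' Dissimilarity (root Jensen–Shannon divergence on shared OTUs)
#'
#' The dissimilarity of dissimilarity–overlap analysis: relative abundances
#' are renormalized on the OTUs observed in *both* samples, and the root
#' Jensen–Shannon divergence (natural log) of the renormalized vectors is
#' returned. Bounded by `sqrt(log 2) ~ 0.8326`.
#'
#' When the two samples share no OTU the measure is undefined; `NA` is
#' returned with attribute `reason = "empty_intersection"` rather than an
#' error, so batch analyses can skip and count such pairs.
#'
#' @inheritParams jaccard
#' @return Scalar in `[0, sqrt(log 2)]`, or `NA` with a `reason` attribute.
#' @export
dissimilarity_rjsd <- function(pair) {
  pair <- check_sample_pair(pair)
  shared <- pair$in_A & pair$in_B
  if (!any(shared)) {
    return(structure(NA_real_, reason = "empty_intersection"))
  }
  xa <- pair$counts_A[shared] / sum(pair$counts_A[shared])
  xb <- pair$counts_B[shared] / sum(pair$counts_B[shared])
  m <- (xa + xb) / 2
  kl <- function(x, y) sum(xlogx(x)) - sum(ifelse(x > 0, x * log(y), 0))
  d2 <- (kl(xa, m) + kl(xb, m)) / 2
  sqrt(max(d2, 0))  # guard tiny negative rounding
}

#' Overlap
#'
#' The mean, across the two samples, of the fraction of reads belonging to
#' OTUs observed in both samples. Applied to true (pre-sampling) abundances,
#' where every OTU is present, the overlap is exactly 1.
#'
#' @inheritParams jaccard
#' @return Scalar in `[0, 1]`.
#' @export
overlap <- function(pair) {
  pair <- check_sample_pair(pair)
  shared <- pair$in_A & pair$in_B
  (sum(pair$counts_A[shared]) / pair$N_A + sum(pair$counts_B[shared]) / pair$N_B) / 2
}

#' All eight beta-diversity measures of a sample pair
#'
#' @inheritParams jaccard
#' @return An object of class `beta_diversity`: a named list with fields
#'   `jaccard`, `sorensen`, `whittaker`, `effective_whittaker`,
#'   `morisita_horn`, `horn`, `bray_curtis`, `dissimilarity`, `overlap`, and
#'   `dissimilarity_reason` (`NA` unless the dissimilarity is undefined).
#' @export
all_metrics <- function(pair) {
  pair <- check_sample_pair(pair)
  d <- dissimilarity_rjsd(pair)
  structure(
    list(jaccard = jaccard(pair),
         sorensen = sorensen(pair),
         whittaker = whittaker(pair),
         effective_whittaker = effective_whittaker(pair),
         morisita_horn = morisita_horn(pair),
         horn = horn(pair),
         bray_curtis = bray_curtis(pair),
         dissimilarity = as.numeric(d),
         overlap = overlap(pair),
         dissimilarity_reason = if (is.na(d)) attr(d, "reason") else NA_character_),
    class = "beta_diversity"
  )
}

#' @export
print.beta_diversity <- function(x, ...) {
  vals <- unlist(x[setdiff(names(x), "dissimilarity_reason")])
  print(round(vals, 4), ...)
  if (!is.na(x$dissimilarity_reason)) {
    cat("dissimilarity undefined:", x$dissimilarity_reason, "\n")
  }
  invisible(x)
}

#' Pairwise beta-diversity over an OTU table
#'
#' Computes all eight measures for each requested pair of samples in a table,
#' in long format (one row per pair and metric).
#'
#' @param table an [otu_table()] (or plain counts matrix, OTUs x samples).
#' @param pairs two-column matrix or data frame of sample names/indices; the
#'   default compares all unordered pairs.
#' @return Data frame with columns `sample_A`, `sample_B`, `metric`, `value`,
#'   `defined`.
#' @export
beta_diversity_table <- function(table, pairs = NULL) {
  counts <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  ids <- colnames(counts)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(counts)))
  if (is.null(pairs)) {
    pairs <- t(utils::combn(ids, 2L))
  } else {
    pairs <- as.matrix(pairs)
    if (ncol(pairs) != 2L) stop_invalid("`pairs` must have two columns")
  }
  metric_names <- c("jaccard", "sorensen", "whittaker", "effective_whittaker",
                    "morisita_horn", "horn", "bray_curtis", "dissimilarity",
                    "overlap")
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1L]; b <- pairs[i, 2L]
    res <- all_metrics(sample_pair(counts[, a], counts[, b]))
    vals <- unlist(res[metric_names])
    out[[i]] <- data.frame(sample_A = a, sample_B = b, metric = metric_names,
                           value = unname(vals), defined = !is.na(vals),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
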