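#' OTU count table
#'
#' A validated integer matrix of read counts, OTUs x samples, with unique row
#' and column identifiers and optional free-form metadata.
#'
#' @param counts integer matrix (rows OTUs, columns samples).
#' @param otu_ids,sample_ids identifiers; default to the matrix dimnames.
#' @param metadata optional named list (seed, origin, etc.).
#' @return An object of class `otu_table`.
#' @export
otu_table <- function(counts, otu_ids = rownames(counts),
                      sample_ids = colnames(counts), metadata = list()) {
  counts <- as.matrix(counts)
  if (length(counts) > 0L) check_count_vector(as.vector(counts), "counts")
  if (is.null(otu_ids)) otu_ids <- sprintf("OTU_%06d", seq_len(nrow(counts)))
  if (is.null(sample_ids)) sample_ids <- sprintf("sample_%03d", seq_len(ncol(counts)))
  if (length(otu_ids) != nrow(counts) || length(sample_ids) != ncol(counts)) {
    stop_invalid("identifier lengths do not match the count matrix")
  }
  if (anyDuplicated(otu_ids)) stop_invalid("duplicate OTU ids")
  if (anyDuplicated(sample_ids)) stop_invalid("duplicate sample ids")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(otu_ids, sample_ids)
  structure(list(counts = counts, metadata = metadata), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d OTUs x %d samples; depths %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(utils::head(colSums(x$counts), 5L), collapse = ", ")))
  invisible(x)
}

#' Read an OTU table from a tab-separated file
#'
#' Expects a header row of sample identifiers and a first column of OTU
#' identifiers; all remaining cells must be non-negative integer counts.
#' Malformed cells are reported with their row and column.
#'
#' @param path file path.
#' @return An [otu_table()].
#' @export
read_otu_table <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_invalid("malformed table: need an id column plus at least one sample")
  ids <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(mat, 2L, as.numeric))), arr.ind = TRUE)[1L, ]
    stop_invalid("non-numeric count at OTU '%s', sample '%s'",
                 ids[bad[1L]], colnames(mat)[bad[2L]])
  }
  bad <- which(mat < 0 | mat != round(mat), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop_invalid("invalid count %g at OTU '%s', sample '%s'",
                 mat[bad[1L, 1L], bad[1L, 2L]], ids[bad[1L, 1L]],
                 colnames(mat)[bad[1L, 2L]])
  }
  otu_table(mat, otu_ids = ids, sample_ids = colnames(mat))
}

#' Write an OTU table as tab-separated text
#'
#' @param table an [otu_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path) {
  if (!inherits(table, "otu_table")) stop_invalid("`table` must be an `otu_table`")
  df <- data.frame(OTU_ID = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop samples below a sequencing-depth threshold
#'
#' Keeps samples whose total read count is strictly greater than `min_reads`
#' (low-depth samples carry too much sampling noise for the fluctuation
#' analyses). Column order of the retained samples is preserved.
#'
#' @param table an [otu_table()].
#' @param min_reads depth threshold (strict inequality).
#' @return Filtered [otu_table()]; `n_removed` is recorded in the metadata.
#'   A warning is emitted if nothing survives.
#' @export
filter_samples_by_depth <- function(table, min_reads) {
  if (!inherits(table, "otu_table")) stop_invalid("`table` must be an `otu_table`")
  check_scalar_number(min_reads, "min_reads", lower = 0)
  keep <- colSums(table$counts) > min_reads
  if (!any(keep)) warning("all samples fall at or below the depth threshold", call. = FALSE)
  meta <- table$metadata
  meta$n_removed_by_depth <- sum(!keep)
  otu_table(table$counts[, keep, drop = FALSE], metadata = meta)
}

#' Write a community pair with its ground truth
#'
#' Writes three files under `dir`: `<prefix>_counts.tsv` (OTU table with the
#' two samples), `<prefix>_truth.tsv` (per-OTU `K_A`, `K_B`, `sigma`,
#' `lambda_A`, `lambda_B`), and `<prefix>_meta.json` (the generating config,
#' including the seed).
#'
#' @param pair a [generate_pair()] result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_community_pair <- function(pair, dir, prefix = "pair") {
  if (!inherits(pair, "community_pair")) stop_invalid("`pair` must be a `community_pair`")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sprintf("OTU_%06d", seq_len(pair$config$S))
  counts_path <- file.path(dir, paste0(prefix, "_counts.tsv"))
  write_otu_table(otu_table(cbind(sample_A = pair$counts_A, sample_B = pair$counts_B),
                            otu_ids = ids), counts_path)
  truth_path <- file.path(dir, paste0(prefix, "_truth.tsv"))
  utils::write.table(
    data.frame(OTU_ID = ids, K_A = pair$K_A, K_B = pair$K_B, sigma = pair$sigma,
               lambda_A = pair$lambda_A, lambda_B = pair$lambda_B),
    truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta_path <- file.path(dir, paste0(prefix, "_meta.json"))
  jsonlite::write_json(unclass(pair$config), meta_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(c(counts = counts_path, truth = truth_path, meta = meta_path))
}

#' Simulate an OTU count time series from the SLM
#'
#' Integrates one SLM trajectory per OTU (Euler–Maruyama, recording snapshots
#' separated by `spacing` relaxation times after a burn-in) and sequences each
#' snapshot multinomially at the given depth. The focal OTUs' `K` are
#' interpreted as true relative abundances: a single filler row `OTU_rest`
#' absorbs the remaining reads so that the focal OTUs' multinomial marginals
#' are `Binomial(depth, lambda_i)` and estimation recovers `K` on its own
#' scale. The summed mean abundance of the focal OTUs must stay well below 1.
#'
#' @param params [slm_params()] with one entry per focal OTU.
#' @param n_timepoints number of sampled snapshots.
#' @param depth reads per snapshot.
#' @param spacing time between snapshots, in units of `tau`.
#' @param dt Euler timestep, in units of `tau`.
#' @param burn_in equilibration time before the first snapshot, in units of
#'   `tau`.
#' @param seed optional integer seed.
#' @return An [otu_time_series()] whose last row is the filler `OTU_rest`;
#'   the true per-OTU parameters are attached as attribute `truth`.
#' @export
simulate_time_series <- function(params, n_timepoints = 300, depth = 5e4,
                                 spacing = 2, dt = 0.05, burn_in = 50,
                                 seed = NULL) {
  if (!inherits(params, "slm_params")) stop_invalid("`params` must be an `slm_params` object")
  check_scalar_number(n_timepoints, "n_timepoints", lower = 2)
  check_scalar_number(depth, "depth", lower = 2)
  S <- length(params$K)
  with_seed_if(seed, {
    lam <- sde_evolve_community(
      K = params$K, sigma = params$sigma, tau = params$tau,
      dt = dt * min(params$tau), n_record = n_timepoints,
      record_every = max(1L, round(spacing / dt)),
      burn_in = max(1L, round(burn_in / dt)))
    tot <- colSums(lam)
    if (any(tot >= 1)) {
      stop_invalid("summed focal abundances reach %.3f >= 1: K values too large for the filler design", max(tot))
    }
    counts <- vapply(seq_len(n_timepoints), function(t) {
      stats::rmultinom(1L, size = depth, prob = c(lam[, t], 1 - tot[t]))[, 1L]
    }, integer(S + 1L))
    rownames(counts) <- c(sprintf("OTU_%06d", seq_len(S)), "OTU_rest")
    out <- otu_time_series(counts, depths = rep(depth, n_timepoints))
    attr(out, "truth") <- data.frame(otu = rownames(counts)[seq_len(S)],
                                     K = params$K, sigma = params$sigma)
    out
  })
}

#' Write an OTU time series (with depths) as tab-separated text
#'
#' The depths are stored as a final row `TOTAL_READS` so the file is a plain
#' OTU table; [read_otu_time_series()] reverses this.
#'
#' @param series an [otu_time_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_otu_time_series <- function(series, path) {
  if (!inherits(series, "otu_time_series")) stop_invalid("`series` must be an `otu_time_series`")
  mat <- rbind(series$counts, TOTAL_READS = as.integer(series$depths))
  colnames(mat) <- series$timepoints
  write_otu_table(otu_table(mat), path)
}

#' Read an OTU time series written by [write_otu_time_series()]
#'
#' @param path file path; must contain a `TOTAL_READS` row (otherwise depths
#'   are taken as the column sums).
#' @return An [otu_time_series()].
#' @export
read_otu_time_series <- function(path) {
  tab <- read_otu_table(path)
  counts <- tab$counts
  if ("TOTAL_READS" %in% rownames(counts)) {
    depths <- counts["TOTAL_READS", ]
    counts <- counts[rownames(counts) != "TOTAL_READS", , drop = FALSE]
  } else {
    depths <- colSums(counts)
  }
  otu_time_series(counts, depths = depths, timepoints = colnames(counts))
}

#' Generate a reproducible fixture bundle on disk
#'
#' Writes, under `dir`: a small ensemble of paired OTU tables with their
#' ground-truth sidecars, an SLM time-series table with known parameters, and
#' a JSON manifest recording the seed and every file's generating parameters.
#' Stage seeds are derived deterministically from the master seed, so the
#' bundle is byte-identical across runs.
#'
#' @param dir output directory.
#' @param pair_configs list of [pair_config()]s, one fixture pair each.
#' @param ts_params [slm_params()] for the time-series fixture.
#' @param n_timepoints,depth time-series dimensions.
#' @param seed master integer seed.
#' @return Path of the manifest file, invisibly.
#' @export
generate_fixtures <- function(dir,
                              pair_configs = list(pair_config(S = 500, rho_K = 0.8,
                                                              n_reads_A = 5e3,
                                                              n_reads_B = 5e3)),
                              ts_params = slm_params(K = rep(1e-3, 50), sigma = 0.8),
                              n_timepoints = 100, depth = 5e4, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = seed, pairs = list(), time_series = NULL)
  for (i in seq_along(pair_configs)) {
    cfg <- check_pair_config(pair_configs[[i]])
    cfg$seed <- seed + i
    pair <- generate_pair(cfg)
    prefix <- sprintf("pair_%02d", i)
    paths <- write_community_pair(pair, dir, prefix)
    manifest$pairs[[i]] <- list(prefix = prefix, config = unclass(cfg),
                                files = as.list(basename(paths)))
  }
  ts_seed <- seed + length(pair_configs) + 1L
  ts <- simulate_time_series(ts_params, n_timepoints = n_timepoints,
                             depth = depth, seed = ts_seed)
  ts_path <- file.path(dir, "time_series_counts.tsv")
  write_otu_time_series(ts, ts_path)
  truth <- attr(ts, "truth")
  utils::write.table(truth, file.path(dir, "time_series_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$time_series <- list(
    file = basename(ts_path), truth = "time_series_truth.tsv", seed = ts_seed,
    n_timepoints = n_timepoints, depth = depth,
    K = ts_params$K, sigma = ts_params$sigma)
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest_path)
}
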