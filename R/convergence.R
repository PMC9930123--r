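# QM-region-size scans, the +/-1 kcal/mol convergence criterion, and
# snapshot-ensemble statistics.

EDA_COMPONENTS <- c("elec", "pauli", "pol", "total", "disp", "ind")

component_vector <- function(result) {
  c(elec = result$e_elec, pauli = result$e_pauli, pol = result$e_pol,
    total = result$e_total, disp = result$e_disp, ind = result$e_ind)
}

#' Scan the EDA over QM-region sizes
#'
#' Runs [assemble_eda()] once per requested QM-water count (via
#' [partition_closest_n()]) and tabulates, for every component, the
#' deviation from the value at `reference_size`.  Per-size failures are
#' recorded and the scan continues; failed sizes have missing deviations.
#' Results are cached in `cache` (an environment) keyed by size and
#' configuration, so repeated calls are incremental.
#'
#' @param raw raw solvated system (see [generate_synthetic_snapshot()]).
#' @param sizes ascending QM-water counts.
#' @param reference_size size whose values anchor the deviations
#'   (default `max(sizes)`).
#' @param config an [eda_config()].
#' @param cache optional environment for incremental re-runs.
#' @return a `scan_result`: `sizes`, `results` (list of `eda_result` or
#'   error message), `reference_size`, `values` and `deviations` (size x
#'   component matrices, kcal/mol).
#' @export
run_scan <- function(raw, sizes, reference_size = max(sizes),
                     config = eda_config(), cache = NULL) {
  sizes <- as.integer(sizes)
  if (is.unsorted(sizes, strictly = TRUE)) {
    stop("sizes must be strictly ascending")
  }
  if (!reference_size %in% sizes) {
    stop("reference_size must be one of the scanned sizes")
  }
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  snap_key <- paste(length(raw$system$element),
                    format(sum(raw$system$xyz %*% c(1, exp(1), pi)),
                           digits = 17))
  cfg_key <- paste(snap_key, config$basis, config$method, config$embedding,
                   config$scf_tol_energy, sep = "|")
  results <- vector("list", length(sizes))
  names(results) <- as.character(sizes)
  for (k in seq_along(sizes)) {
    key <- paste0(cfg_key, "#", sizes[k])
    if (!is.null(cache[[key]])) {
      results[[k]] <- cache[[key]]
      next
    }
    res <- tryCatch({
      snap <- partition_closest_n(raw, sizes[k])
      assemble_eda(snap, config)
    }, error = function(e) structure(conditionMessage(e), class = "scan_error"))
    results[[k]] <- res
    cache[[key]] <- res
  }
  vals <- matrix(NA_real_, length(sizes), length(EDA_COMPONENTS),
                 dimnames = list(as.character(sizes), EDA_COMPONENTS))
  for (k in seq_along(sizes)) {
    if (inherits(results[[k]], "eda_result")) {
      vals[k, ] <- component_vector(results[[k]])
    }
  }
  ref <- vals[as.character(reference_size), ]
  dev <- sweep(vals, 2, ref, "-")
  structure(list(sizes = sizes, results = results,
                 reference_size = as.integer(reference_size),
                 values = vals, deviations = dev),
            class = "scan_result")
}

#' Smallest QM-region size converged within a tolerance band
#'
#' The smallest scanned size s such that, for s *and every larger scanned
#' size*, every component's deviation from the reference lies within
#' +/- `tolerance`.  Entering the band and leaving it again does not count;
#' series that never settle return `NA` (no convergence).
#'
#' @param scan a `scan_result`, or a plain matrix of deviations
#'   (rows = sizes in ascending order, rownames = sizes).
#' @param tolerance band half-width, kcal/mol.
#' @return integer size, or `NA_integer_` if no size qualifies.
#' @export
converged_size <- function(scan, tolerance = 1.0) {
  dev <- if (inherits(scan, "scan_result")) scan$deviations else as.matrix(scan)
  if (anyNA(dev)) {
    miss <- rownames(dev)[apply(dev, 1, anyNA)]
    stop("scan incomplete: missing deviations for size(s) ",
         paste(miss, collapse = ", "))
  }
  sizes <- as.integer(rownames(dev))
  within <- apply(abs(dev) <= tolerance, 1, all)
  ok <- rev(cumprod(rev(within))) == 1   # within for this and all larger sizes
  if (!any(ok)) return(NA_integer_)
  sizes[which(ok)[1]]
}

#' Ensemble statistics of EDA components
#'
#' Sample mean, standard deviation (n-1 denominator) and relative standard
#' deviation RSTD = 100 sigma / |mean| per component over a homogeneous set
#' of results.  An undefined RSTD (zero mean) is reported as `NA`.
#'
#' @param results list of `eda_result`s with identical configuration, or a
#'   numeric matrix/data.frame (rows = samples, columns = components).
#' @return a `sample_stats` data.frame with columns `component`, `mean`,
#'   `sigma`, `rstd`, `n`.
#' @export
sample_stats <- function(results) {
  X <- as_component_matrix(results)
  if (nrow(X) < 2L) stop("need at least 2 samples")
  m <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  rstd <- ifelse(m == 0, NA_real_, 100 * s / abs(m))
  structure(data.frame(component = colnames(X), mean = m, sigma = s,
                       rstd = rstd, n = nrow(X), row.names = NULL),
            class = c("sample_stats", "data.frame"))
}

as_component_matrix <- function(results) {
  if (is.matrix(results) || is.data.frame(results)) {
    return(as.matrix(results))
  }
  stopifnot(is.list(results))
  cfgs <- unique(vapply(results, function(r)
    paste(r$metadata$basis, r$metadata$method, r$metadata$embedding,
          r$metadata$n_qm_waters), character(1)))
  if (length(cfgs) > 1L) {
    stop("results have mixed configurations: ", paste(cfgs, collapse = " / "))
  }
  do.call(rbind, lapply(results, component_vector))
}

#' Convergence of running sample means over equispaced subsamples
#'
#' For k = 2, ..., n the k-geometry subsample takes index-equispaced
#' elements (for n = 100, k = 20: positions 1, 6, 11, ..., 96) and its
#' per-component mean is compared with the full-sample mean.  The smallest
#' k with all deviations inside +/- `tolerance` is flagged.
#'
#' @param results as in [sample_stats()], ordered by trajectory time.
#' @param tolerance band half-width, kcal/mol.
#' @return list with `k` (subsample sizes), `deviation` (k x component
#'   matrix) and `converged_k`.
#' @export
sample_mean_convergence <- function(results, tolerance = 1.0) {
  X <- as_component_matrix(results)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 samples")
  full <- colMeans(X)
  ks <- 2:n
  dev <- matrix(NA_real_, length(ks), ncol(X),
                dimnames = list(as.character(ks), colnames(X)))
  for (i in seq_along(ks)) {
    k <- ks[i]
    idx <- floor((0:(k - 1)) * n / k) + 1L
    dev[i, ] <- colMeans(X[idx, , drop = FALSE]) - full
  }
  ok <- apply(abs(dev) <= tolerance, 1, all)
  list(k = ks, deviation = dev,
       converged_k = if (any(ok)) ks[which(ok)[1]] else NA_integer_)
}

#' Export a scan as a tidy CSV
#' @param scan a `scan_result`.
#' @param path output path.
#' @export
write_scan_csv <- function(scan, path) {
  long <- expand.grid(size = scan$sizes, component = EDA_COMPONENTS,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$value <- as.vector(scan$values)
  long$deviation <- as.vector(scan$deviations)
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Export sample statistics as CSV
#' @param stats a `sample_stats`.
#' @param path output path.
#' @export
write_stats_csv <- function(stats, path) {
  utils::write.csv(stats, path, row.names = FALSE)
  invisible(path)
}
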