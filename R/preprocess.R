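#' Exclude the residual-water region from a spectrum
#'
#' Removes every point with `lo <= ppm <= hi` (default 4.7-5.2 ppm, the
#' residual water resonance); all other points are untouched.
#'
#' @param s A [raw_spectrum()].
#' @param lo,hi Window bounds in ppm, `lo < hi`.
#' @return A [raw_spectrum()] without the excluded points.
#' @export
exclude_water <- function(s, lo = 4.7, hi = 5.2) {
  stopifnot(inherits(s, "raw_spectrum"), lo < hi)
  keep <- s$ppm < lo | s$ppm > hi
  if (!any(keep)) stop("exclusion window covers the entire spectrum")
  if (all(keep)) return(s)
  raw_spectrum(s$ppm[keep], s$intensity[keep], s$sample_id,
               c(s$meta, list(water_excluded = c(lo = lo, hi = hi))))
}

#' Bin a spectrum into fixed-width buckets
#'
#' Buckets of constant width are laid down from the highest ppm of the axis.
#' The default aggregation is the SUM of point intensities per bucket, which
#' conserves total in-window signal exactly; `agg = "mean"` is available
#' but non-default. Buckets are half-open with points lying exactly on an
#' edge assigned to the higher-ppm bucket.
#'
#' @param s A [raw_spectrum()].
#' @param n_bins Number of buckets (default 4096). Use `NULL` to infer the
#'   count from the axis span and `bin_width`.
#' @param bin_width Bucket width in ppm (default 0.003).
#' @param agg `"sum"` (default, area-conserving) or `"mean"`.
#' @return An object of class `binned_spectrum` with fields `bin_edges`
#'   (descending, length `n_bins + 1`), `centers`, `values`, `sample_id`,
#'   `normalized`.
#' @export
bin_spectrum <- function(s, n_bins = 4096, bin_width = 0.003,
                         agg = c("sum", "mean")) {
  stopifnot(inherits(s, "raw_spectrum"))
  agg <- match.arg(agg)
  if (length(s$ppm) == 0) stop("empty spectrum")
  hi <- max(s$ppm)
  span <- hi - min(s$ppm)
  if (is.null(n_bins)) n_bins <- floor(span / bin_width + 1e-9)
  n_bins <- as.integer(n_bins)
  if (n_bins < 1) stop("n_bins must be >= 1")
  if (span + 1e-9 < n_bins * bin_width) {
    stop("spectrum axis spans less than n_bins * bin_width; ",
         "reduce n_bins or pass n_bins = NULL to infer it")
  }
  lo <- hi - n_bins * bin_width
  # bucket index counted from the high-ppm end; edge ties -> higher bucket
  k <- n_bins - floor((s$ppm - lo) / bin_width)
  k[s$ppm >= hi] <- 1L
  inside <- k >= 1L & k <= n_bins
  vals <- numeric(n_bins)
  sums <- tapply(s$intensity[inside], k[inside], sum)
  vals[as.integer(names(sums))] <- sums
  if (agg == "mean") {
    cnt <- numeric(n_bins)
    tab <- table(k[inside])
    cnt[as.integer(names(tab))] <- tab
    vals <- ifelse(cnt > 0, vals / pmax(cnt, 1), 0)
  }
  edges <- hi - bin_width * (0:n_bins)
  structure(
    list(bin_edges = edges, centers = (edges[-1] + edges[-(n_bins + 1)]) / 2,
         values = vals, sample_id = s$sample_id, normalized = FALSE),
    class = "binned_spectrum"
  )
}

#' @export
print.binned_spectrum <- function(x, ...) {
  cat(sprintf("<binned_spectrum> %s: %d bins, %.3f .. %.3f ppm%s\n",
              x$sample_id, length(x$values), x$bin_edges[1],
              x$bin_edges[length(x$bin_edges)],
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' Normalize a spectrum to the area of an internal reference signal
#'
#' Divides every intensity by the area of the reference region (default
#' -0.05..0.05 ppm, the TSP singlet at 0.0 ppm), so the post-normalization
#' reference area is 1 and the spectrum becomes invariant to global
#' dilution. For a raw spectrum the area is the trapezoidal integral over
#' the region; for a binned spectrum it is the sum of bucket values whose
#' centres fall in the region.
#'
#' @param s A [raw_spectrum()] or `binned_spectrum`.
#' @param ref_region Length-2 numeric, ppm bounds of the reference signal.
#' @return The normalized object (same class), flagged as normalized.
#' @export
normalize_to_reference <- function(s, ref_region = c(-0.05, 0.05)) {
  UseMethod("normalize_to_reference")
}

#' @export
normalize_to_reference.raw_spectrum <- function(s, ref_region = c(-0.05, 0.05)) {
  sel <- s$ppm >= ref_region[1] & s$ppm <= ref_region[2]
  if (sum(sel) < 2) stop("reference region holds fewer than 2 points (",
                         s$sample_id, ")")
  area <- .trapz(rev(s$ppm[sel]), rev(s$intensity[sel]))
  if (!is.finite(area) || area <= 0) {
    stop("non-positive reference area in sample '", s$sample_id,
         "': missing or corrupted reference signal")
  }
  raw_spectrum(s$ppm, s$intensity / area, s$sample_id,
               c(s$meta, list(normalized = TRUE, ref_area = area)))
}

#' @export
normalize_to_reference.binned_spectrum <- function(s, ref_region = c(-0.05, 0.05)) {
  sel <- s$centers >= ref_region[1] & s$centers <= ref_region[2]
  if (!any(sel)) stop("no buckets in the reference region (", s$sample_id, ")")
  area <- sum(s$values[sel])
  if (!is.finite(area) || area <= 0) {
    stop("non-positive reference area in sample '", s$sample_id,
         "': missing or corrupted reference signal")
  }
  s$values <- s$values / area
  s$normalized <- TRUE
  s
}

#' Globally align a spectrum to a reference peak
#'
#' Shifts the whole axis by a constant so that the tallest point within
#' `search` ppm of `ref_ppm` sits exactly at `ref_ppm` (default: the
#' alanine doublet at 1.479 ppm). The applied shift is recorded in the
#' spectrum metadata.
#'
#' @param s A [raw_spectrum()].
#' @param ref_ppm Reference chemical shift (ppm).
#' @param search Half-width of the peak search window (ppm).
#' @return The aligned [raw_spectrum()].
#' @export
align_global <- function(s, ref_ppm = 1.479, search = 0.05) {
  stopifnot(inherits(s, "raw_spectrum"))
  sel <- which(abs(s$ppm - ref_ppm) <= search)
  if (length(sel) < 3) stop("no points near the reference shift ", ref_ppm)
  win <- s$intensity[sel]
  if (max(win) - min(win) <= 0) {
    stop("no peak found near ", ref_ppm, " ppm (flat window)")
  }
  peak_ppm <- s$ppm[sel[which.max(win)]]
  shift <- ref_ppm - peak_ppm
  raw_spectrum(s$ppm + shift, s$intensity, s$sample_id,
               c(s$meta, list(alignment_shift = shift)))
}

#' Integrate a chemical-shift region with optional local baseline correction
#'
#' Trapezoidal integral of the intensity over `[lo, hi]`. With
#' `local_baseline = TRUE` (default) the straight line joining the region's
#' two endpoint intensities is subtracted first, which removes any linear
#' baseline under the peak exactly.
#'
#' @param s A [raw_spectrum()].
#' @param lo,hi Region bounds in ppm (`lo < hi`), or a one-row region
#'   data.frame with `lo`/`hi` columns passed as `lo`.
#' @param local_baseline Subtract the endpoint chord first?
#' @return The integral (intensity x ppm units).
#' @export
integrate_region <- function(s, lo, hi = NULL, local_baseline = TRUE) {
  stopifnot(inherits(s, "raw_spectrum"))
  if (is.data.frame(lo)) { hi <- lo$hi[1]; lo <- lo$lo[1] }
  if (lo >= hi) stop("region must have lo < hi")
  sel <- which(s$ppm >= lo & s$ppm <= hi)
  if (length(sel) < 3) {
    stop("region [", lo, ", ", hi, "] has fewer than 3 points on the axis")
  }
  x <- rev(s$ppm[sel])          # ascending for integration
  y <- rev(s$intensity[sel])
  total <- .trapz(x, y)
  if (!local_baseline) return(total)
  chord_area <- (y[1] + y[length(y)]) / 2 * (x[length(x)] - x[1])
  total - chord_area
}

#' Build a samples-by-regions feature table of peak integrals
#'
#' @param spectra List of [raw_spectrum()] sharing one identical axis.
#' @param regions Region table (`name`, `lo`, `hi`), pairwise disjoint.
#' @param labels Optional cohort label per spectrum.
#' @param local_baseline Passed to [integrate_region()].
#' @return A [feature_table()] with `scaling_state = "raw"`.
#' @export
build_feature_table <- function(spectra, regions, labels = NULL,
                                local_baseline = TRUE) {
  regions <- validate_regions(regions)
  stopifnot(length(spectra) >= 1)
  axis <- spectra[[1]]$ppm
  for (s in spectra) {
    if (length(s$ppm) != length(axis) || any(s$ppm != axis)) {
      stop("axis mismatch: spectrum '", s$sample_id,
           "' is not on the shared axis")
    }
  }
  mat <- matrix(0, nrow = length(spectra), ncol = nrow(regions),
                dimnames = list(vapply(spectra, `[[`, "", "sample_id"),
                                regions$name))
  for (i in seq_along(spectra)) {
    for (j in seq_len(nrow(regions))) {
      mat[i, j] <- integrate_region(spectra[[i]], regions$lo[j],
                                    regions$hi[j], local_baseline)
    }
  }
  feature_table(mat, labels = labels)
}

#' Construct a feature table
#'
#' A samples x features matrix with scaling-state bookkeeping. The state
#' may only move from `"raw"` to `"mean_centered"` or `"autoscaled"`; the
#' scaling parameters are stored so new samples can be transformed
#' identically ([apply_scaling()]).
#'
#' @param values Numeric matrix (rows = samples); row names are sample ids.
#' @param labels Optional cohort label per row.
#' @param scaling_state One of `"raw"`, `"mean_centered"`, `"autoscaled"`.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, labels = NULL, scaling_state = "raw") {
  values <- as.matrix(values)
  if (anyNA(values)) stop("feature table contains missing values")
  if (is.null(rownames(values))) rownames(values) <- as.character(seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("f", seq_len(ncol(values)))
  if (!is.null(labels) && length(labels) != nrow(values)) {
    stop("labels length must match the number of samples")
  }
  structure(list(values = values, labels = labels,
                 scaling_state = scaling_state,
                 center = NULL, scale = NULL),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features (%s)\n",
              nrow(x$values), ncol(x$values), x$scaling_state))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Mean-center a raw feature table
#'
#' @param t A raw [feature_table()].
#' @return The centered table, with the column means stored.
#' @export
mean_center <- function(t) {
  stopifnot(inherits(t, "feature_table"))
  if (t$scaling_state != "raw") stop("table is already ", t$scaling_state)
  ctr <- colMeans(t$values)
  t$values <- sweep(t$values, 2, ctr)
  t$center <- ctr
  t$scale <- NULL
  t$scaling_state <- "mean_centered"
  t
}

#' Autoscale a raw feature table
#'
#' Centers every column to mean zero and scales it to unit sample standard
#' deviation (unit-variance or "UV" scaling).
#'
#' @param t A raw [feature_table()].
#' @return The autoscaled table, with centers and scales stored.
#' @export
autoscale <- function(t) {
  stopifnot(inherits(t, "feature_table"))
  if (t$scaling_state != "raw") stop("table is already ", t$scaling_state)
  ctr <- colMeans(t$values)
  sds <- apply(t$values, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance feature(s): ",
         paste(colnames(t$values)[sds == 0], collapse = ", "))
  }
  t$values <- sweep(sweep(t$values, 2, ctr), 2, sds, "/")
  t$center <- ctr
  t$scale <- sds
  t$scaling_state <- "autoscaled"
  t
}

#' Apply a table's stored scaling parameters to new data
#'
#' @param t A scaled [feature_table()] (source of the parameters).
#' @param newdata Numeric matrix with the same columns, on the raw scale.
#' @return The transformed matrix.
#' @export
apply_scaling <- function(t, newdata) {
  stopifnot(inherits(t, "feature_table"))
  if (t$scaling_state == "raw") stop("table holds no scaling parameters")
  newdata <- as.matrix(newdata)
  out <- sweep(newdata, 2, t$center)
  if (!is.null(t$scale)) out <- sweep(out, 2, t$scale, "/")
  out
}

#' Read / write feature tables as TSV
#'
#' Layout: header row of feature names, first column `sample_id`, optional
#' second column `label`.
#'
#' @param path File path.
#' @return `read_feature_table` returns a raw [feature_table()].
#' @export
read_feature_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  labels <- NULL
  if ("label" %in% names(d)) { labels <- d$label; d$label <- NULL }
  m <- as.matrix(d[, setdiff(names(d), "sample_id"), drop = FALSE])
  rownames(m) <- d$sample_id
  feature_table(m, labels = labels)
}

#' @rdname read_feature_table
#' @param t A [feature_table()].
#' @export
write_feature_table <- function(t, path) {
  d <- data.frame(sample_id = rownames(t$values), check.names = FALSE,
                  stringsAsFactors = FALSE)
  if (!is.null(t$labels)) d$label <- t$labels
  d <- cbind(d, as.data.frame(t$values, check.names = FALSE))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
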