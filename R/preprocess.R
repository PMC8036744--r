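# Spectral preprocessing: convolution baseline removal, TIC normalization,
# peak picking to an aligned m/z axis, feature-matrix extraction.

#' Construct a single mass spectrum
#'
#' @param mz Strictly ascending m/z values (Da).
#' @param intensity Non-negative intensities, same length as `mz`.
#' @return A `mass_spectrum`.
#' @export
mass_spectrum <- function(mz, intensity) {
  if (length(mz) != length(intensity))
    stopf("mz and intensity lengths differ")
  if (is.unsorted(mz, strictly = TRUE))
    stopf("mz must be strictly ascending")
  if (any(intensity < 0))
    stopf("intensities must be >= 0")
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity)),
            class = "mass_spectrum")
}

#' Convolution baseline removal
#'
#' Estimates each spectrum's baseline as the moving-average-smoothed lower
#' envelope (rolling minimum, then rolling mean, both over `width` points),
#' subtracts it and clamps the result at zero.  Peaks narrower than about a
#' quarter of the window survive with their apex height intact; a flat
#' spectrum is removed entirely.
#'
#' @param x A `mass_spectrum` or an `ims_dataset`.
#' @param width Window width in points (default 20).
#' @param ... Unused.
#' @return Object of the same class with baseline-corrected intensities.
#' @export
remove_baseline <- function(x, width = 20L, ...) UseMethod("remove_baseline")

check_baseline_width <- function(width, n) {
  if (width < 1L) stopf("parameter error: width must be >= 1")
  if (width > n)
    stopf("parameter error: baseline width (%d) exceeds spectrum length (%d)",
          width, n)
}

#' @export
remove_baseline.mass_spectrum <- function(x, width = 20L, ...) {
  check_baseline_width(width, length(x$mz))
  x$intensity <- as.vector(cpp_remove_baseline(matrix(x$intensity, nrow = 1L),
                                               as.integer(width)))
  x
}

#' @export
remove_baseline.ims_dataset <- function(x, width = 20L, ...) {
  check_baseline_width(width, length(x$mz))
  x$intensities <- cpp_remove_baseline(x$intensities, as.integer(width))
  x$preprocessed <- c(x$preprocessed, "baseline")
  x
}

#' Total-ion-count normalization
#'
#' Scales intensities so each spectrum sums to `target_sum`.  A single
#' all-zero spectrum is an error; in batch (dataset) mode degenerate spectra
#' are dropped with a warning naming their pixels.
#'
#' @param x A `mass_spectrum` or an `ims_dataset`.
#' @param target_sum Positive target total intensity (default 1).
#' @param ... Unused.
#' @return Object of the same class, TIC-normalized.
#' @export
tic_normalize <- function(x, target_sum = 1.0, ...) UseMethod("tic_normalize")

#' @export
tic_normalize.mass_spectrum <- function(x, target_sum = 1.0, ...) {
  tot <- sum(x$intensity)
  if (tot <= 0)
    stopf("degenerate-spectrum error: total intensity is zero")
  x$intensity <- x$intensity * (target_sum / tot)
  x
}

#' @export
tic_normalize.ims_dataset <- function(x, target_sum = 1.0, ...) {
  tot <- rowSums(x$intensities)
  bad <- tot <= 0
  if (any(bad)) {
    ids <- x$pixels$spectrum[bad]
    warnf("dropping %d all-zero spectra (spectrum id: %s)", sum(bad),
          paste(utils::head(ids, 5L), collapse = ", "))
    x$intensities <- x$intensities[!bad, , drop = FALSE]
    x$pixels <- x$pixels[!bad, , drop = FALSE]
    tot <- tot[!bad]
  }
  x$intensities <- x$intensities * (target_sum / tot)
  x$preprocessed <- c(x$preprocessed, "tic")
  x
}

#' Run the standard preprocessing chain
#'
#' Baseline removal followed by TIC normalization, the canonical order for
#' MALDI-IMS profile data.
#'
#' @param dataset An `ims_dataset`.
#' @param width Baseline window width in points.
#' @param target_sum TIC target.
#' @return The preprocessed dataset.
#' @export
preprocess_dataset <- function(dataset, width = 20L, target_sum = 1.0) {
  tic_normalize(remove_baseline(dataset, width = width),
                target_sum = target_sum)
}

#' Construct a peak axis
#'
#' @param centers Strictly ascending, unique m/z centers (Da).
#' @param tolerance Half-width (Da) for assigning signal to a center.
#' @param occurrence Optional fraction of spectra in which each center was
#'   detected.
#' @return A `peak_axis`.
#' @export
peak_axis <- function(centers, tolerance = 0.25, occurrence = NULL) {
  if (length(centers) && is.unsorted(centers, strictly = TRUE))
    stopf("peak axis centers must be strictly ascending and unique")
  structure(list(centers = as.numeric(centers),
                 tolerance = as.numeric(tolerance),
                 occurrence = occurrence),
            class = "peak_axis")
}

#' @export
print.peak_axis <- function(x, ...) {
  cat(sprintf("<peak_axis> %d centers, tolerance %.3g Da\n",
              length(x$centers), x$tolerance))
  invisible(x)
}

#' @export
length.peak_axis <- function(x) length(x$centers)

#' Pick an aligned peak axis from a preprocessed dataset
#'
#' Detects per-spectrum local maxima above `snr_threshold` times the
#' spectrum's median-absolute-deviation noise, pools them over all spectra,
#' clusters the pooled m/z positions by single linkage with gap
#' `> bin_tolerance`, and keeps the intensity-weighted cluster centers that
#' occur in at least `min_occurrence` of spectra.
#'
#' @param dataset A preprocessed `ims_dataset`.
#' @param snr_threshold Signal-to-noise threshold (default 5).
#' @param bin_tolerance Single-linkage gap in Da (default 0.25).
#' @param min_occurrence Minimum fraction of spectra a peak must appear in
#'   (default 0.01).
#' @return A `peak_axis` with per-center occurrence rates.
#' @export
pick_peaks <- function(dataset, snr_threshold = 5, bin_tolerance = 0.25,
                       min_occurrence = 0.01) {
  if (!inherits(dataset, "ims_dataset") || nrow(dataset$intensities) == 0L)
    stopf("empty-input error: dataset has no spectra")
  pk <- cpp_detect_peaks(dataset$intensities, dataset$mz, snr_threshold)
  if (length(pk$mz) == 0L)
    return(peak_axis(numeric(0), tolerance = bin_tolerance))
  ord <- order(pk$mz)
  mzs <- pk$mz[ord]; ints <- pk$intensity[ord]; spec <- pk$spectrum[ord]
  cl <- cumsum(c(1L, diff(mzs) > bin_tolerance))
  centers <- vapply(split(seq_along(mzs), cl), function(idx)
    sum(mzs[idx] * ints[idx]) / sum(ints[idx]), 0)
  occurrence <- vapply(split(spec, cl), function(s)
    length(unique(s)), 0L) / nrow(dataset$intensities)
  keep <- occurrence >= min_occurrence
  centers <- centers[keep]; occurrence <- occurrence[keep]
  ord2 <- order(centers)
  peak_axis(unname(centers[ord2]), tolerance = bin_tolerance,
            occurrence = unname(occurrence[ord2]))
}

#' Extract a feature matrix on an aligned peak axis
#'
#' Each cell is the maximum intensity of the spectrum within plus/minus the
#' axis tolerance of the axis center (0 where the spectrum has no signal
#' there).  Row metadata (pixel, core, patient, and any subtype or
#' compartment labels) is joined from the dataset's sidecar tables.
#'
#' @param dataset A preprocessed `ims_dataset`.
#' @param axis A `peak_axis`.
#' @return An `ims_features` object: `values` matrix (spectra x features),
#'   `mz` centers, `meta` data frame.
#' @export
build_feature_matrix <- function(dataset, axis) {
  if (length(axis$centers) == 0L)
    stopf("parameter error: peak axis is empty")
  if (is.null(dataset$pixels$core_id) || anyNA(dataset$pixels$core_id))
    stopf("metadata-join error: spectrum metadata is missing core_id")
  start <- findInterval(axis$centers - axis$tolerance, dataset$mz) + 1L
  end <- findInterval(axis$centers + axis$tolerance, dataset$mz)
  values <- cpp_extract_features(dataset$intensities, start, end)
  colnames(values) <- sprintf("%.4f", axis$centers)
  meta <- dataset$pixels
  meta$subtype <- dataset$cores$subtype[match(meta$core_id, dataset$cores$core_id)]
  structure(list(values = values, mz = axis$centers, meta = meta,
                 tolerance = axis$tolerance,
                 compartment_labeled = dataset$compartment_labeled),
            class = "ims_features")
}

#' @export
print.ims_features <- function(x, ...) {
  cat(sprintf("<ims_features> %d spectra x %d features\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

# Subset rows of a feature matrix, keeping metadata in step.
fm_subset_rows <- function(fm, rows) {
  fm$values <- fm$values[rows, , drop = FALSE]
  fm$meta <- fm$meta[rows, , drop = FALSE]
  fm
}

# Labels used for a classification task on a feature matrix.
fm_labels <- function(fm, label = c("auto", "subtype", "compartment")) {
  label <- match.arg(label)
  if (label == "auto")
    label <- if (isTRUE(fm$compartment_labeled)) "compartment" else "subtype"
  y <- fm$meta[[label]]
  if (is.null(y) || anyNA(y))
    stopf("feature matrix has no complete '%s' labels", label)
  lev <- if (label == "subtype") SUBTYPE_LEVELS else COMPARTMENT_LEVELS
  factor(y, levels = intersect(lev, unique(y)))
}
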