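# Feature engineering: cross-dataset feature parity, scaling, stratified
# balanced subsets, and Gini-importance signature selection.

#' Match a peak axis to a reference axis (feature parity)
#'
#' Greedy nearest-pair matching in ascending order of absolute mass
#' difference: each source and reference center is used at most once, and
#' pairs at or beyond `max_diff` are rejected.  Unmatched centers on both
#' sides are reported.
#'
#' @param source A `peak_axis` (or numeric centers) to be mapped.
#' @param reference The reference `peak_axis` (or numeric centers).
#' @param max_diff Maximum allowed absolute difference in Da (default 0.25).
#' @return An `axis_mapping`: data frame `pairs` (source, reference, delta)
#'   plus `unmatched_source` and `unmatched_reference` center vectors.
#' @export
align_to_reference_axis <- function(source, reference, max_diff = 0.25) {
  src <- if (inherits(source, "peak_axis")) source$centers else as.numeric(source)
  ref <- if (inherits(reference, "peak_axis")) reference$centers else as.numeric(reference)
  if (length(ref) == 0L)
    stopf("parameter error: reference axis is empty")
  if (is.unsorted(src) || is.unsorted(ref))
    stopf("axes must be sorted")

  # candidate pairs: for each source center the reference centers bracketing it
  lo <- pmin(pmax(findInterval(src, ref), 1L), length(ref))
  hi <- pmin(lo + 1L, length(ref))
  cand <- unique(data.frame(s = rep(seq_along(src), 2L), r = c(lo, hi)))
  cand$delta <- abs(src[cand$s] - ref[cand$r])
  cand <- cand[cand$delta < max_diff, , drop = FALSE]
  cand <- cand[order(cand$delta, cand$s), , drop = FALSE]

  used_s <- logical(length(src)); used_r <- logical(length(ref))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    s <- cand$s[i]; r <- cand$r[i]
    if (!used_s[s] && !used_r[r]) {
      keep[i] <- TRUE; used_s[s] <- TRUE; used_r[r] <- TRUE
    }
  }
  pairs <- cand[keep, , drop = FALSE]
  pairs <- data.frame(source = src[pairs$s], reference = ref[pairs$r],
                      delta = pairs$delta)
  pairs <- pairs[order(pairs$reference), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 unmatched_source = src[!used_s],
                 unmatched_reference = ref[!used_r],
                 max_diff = max_diff),
            class = "axis_mapping")
}

#' @export
print.axis_mapping <- function(x, ...) {
  cat(sprintf("<axis_mapping> %d pairs (max |delta| %.3g Da), %d source / %d reference unmatched\n",
              nrow(x$pairs), x$max_diff, length(x$unmatched_source),
              length(x$unmatched_reference)))
  invisible(x)
}

#' Project a feature matrix onto the reference axis of a mapping
#'
#' Keeps the matched columns only and renames them to their reference
#' centers, so a model trained on this matrix applies directly to data on the
#' reference axis.
#'
#' @param fm An `ims_features` whose columns are the mapping's source centers.
#' @param mapping An `axis_mapping` from [align_to_reference_axis()].
#' @return The projected `ims_features` on the matched reference centers.
#' @export
apply_axis_mapping <- function(fm, mapping) {
  idx <- match(round(mapping$pairs$source, 6), round(fm$mz, 6))
  if (anyNA(idx))
    stopf("feature-parity error: mapping source centers not found in matrix; run align_to_reference_axis on this matrix's axis")
  fm$values <- fm$values[, idx, drop = FALSE]
  fm$mz <- mapping$pairs$reference
  colnames(fm$values) <- sprintf("%.4f", fm$mz)
  fm
}

#' Per-feature standardization
#'
#' Centers and scales each feature column (zero-spread features map to 0).
#' When `stats` from a training matrix are supplied they are applied instead
#' of being recomputed, so test data never influences scaling.
#'
#' @param fm An `ims_features`.
#' @param stats Optional data frame with columns `mz`, `center`, `spread`
#'   from a previous call.
#' @return List with `matrix` (the scaled `ims_features`) and `stats`.
#' @export
scale_features <- function(fm, stats = NULL) {
  if (nrow(fm$values) == 0L)
    stopf("empty-input error: feature matrix has no rows")
  if (is.null(stats)) {
    stats <- data.frame(mz = fm$mz,
                        center = colMeans(fm$values),
                        spread = apply(fm$values, 2L, sd))
    rownames(stats) <- NULL
  } else {
    if (length(stats$mz) != length(fm$mz) ||
        any(abs(stats$mz - fm$mz) > 1e-6))
      stopf("feature-parity error: scaling stats do not match the matrix axis")
  }
  spread <- ifelse(stats$spread > 0, stats$spread, 1)
  fm$values <- sweep(sweep(fm$values, 2L, stats$center), 2L, spread, "/")
  fm$values[, stats$spread <= 0] <- 0
  fm$scaled <- TRUE
  list(matrix = fm, stats = stats)
}

#' Build balanced stratified train/test subsets
#'
#' Replicates the balanced-dataset construction used for classifier training:
#' (i) all spectra of the most infrequent class are included; (ii) tumor
#' cores of every other class are sampled without replacement, adding their
#' spectra of that class, until the class first reaches the rarest class's
#' spectrum count (overshoot bounded by one core); (iii) this is repeated
#' `n_replicates` times on independent seed streams; (iv) each subset is
#' split into train/test at `train_frac`, stratified per class.
#'
#' The default split unit is the core (all spectra of a core on one side of
#' the split, preventing pixel-level leakage); `unit = "spectrum"` splits at
#' the spectrum level instead.
#'
#' @param fm A labeled `ims_features`.
#' @param n_replicates Number of independent subsets (default 3).
#' @param train_frac Training fraction (default 0.7).
#' @param unit `"core"` or `"spectrum"` split granularity.
#' @param label Label column: `"auto"`, `"subtype"` or `"compartment"`.
#' @param seed Integer seed.
#' @return List of `stratified_subset` objects with `train_rows`,
#'   `test_rows`, `sampled_cores`, `replicate_id`, `seed`.
#' @export
build_stratified_subsets <- function(fm, n_replicates = 3L, train_frac = 0.7,
                                     unit = c("core", "spectrum"),
                                     label = "auto", seed = 1L) {
  unit <- match.arg(unit)
  y <- fm_labels(fm, label)
  if (nlevels(y) < 2L)
    stopf("stratification error: need at least two classes")
  counts <- table(y)
  if (any(counts == 0L))
    stopf("stratification error: class with zero spectra")
  rare <- names(counts)[which.min(counts)]

  lapply(seq_len(n_replicates), function(r) {
    with_seed(derive_seed(seed, r), {
      rows <- which(y == rare)
      sampled_cores <- unique(fm$meta$core_id[rows])
      for (cls in setdiff(levels(y), rare)) {
        cls_rows <- which(y == cls)
        cores <- sample(unique(fm$meta$core_id[cls_rows]))
        got <- integer(0)
        for (co in cores) {
          got <- c(got, cls_rows[fm$meta$core_id[cls_rows] == co])
          if (length(got) >= counts[[rare]]) break
        }
        rows <- c(rows, got)
        sampled_cores <- union(sampled_cores, unique(fm$meta$core_id[got]))
      }
      split <- stratified_split(rows, y[rows], fm$meta$core_id[rows],
                                train_frac, unit)
      structure(list(train_rows = split$train, test_rows = split$test,
                     sampled_cores = sampled_cores, replicate_id = r,
                     seed = derive_seed(seed, r), unit = unit),
                class = "stratified_subset")
    })
  })
}

# Per-class train/test split.  Core unit: assign whole cores (within the
# class) so the test share of the class's rows is as close to 1 - train_frac
# as the core sizes allow; spectrum unit: sample rows directly.
stratified_split <- function(rows, y, core, train_frac, unit) {
  train <- integer(0); test <- integer(0)
  for (cls in levels(droplevels(y))) {
    idx <- rows[y == cls]
    target <- (1 - train_frac) * length(idx)
    if (unit == "spectrum") {
      ts <- sample(idx, round(target))
    } else {
      co <- core[match(idx, rows)]
      sizes <- table(co)
      ord <- sample(names(sizes))
      cum <- cumsum(as.numeric(sizes[ord]))
      k <- which.min(abs(cum - target))
      if (length(ord) > 1L && cum[k] >= length(idx)) k <- k - 1L
      ts <- idx[co %in% ord[seq_len(k)]]
      if (length(ts) == 0L && length(ord) > 1L) ts <- idx[co == ord[1L]]
    }
    test <- c(test, ts)
    train <- c(train, setdiff(idx, ts))
  }
  list(train = sort(train), test = sort(test))
}

#' Select the top Gini-importance feature signature
#'
#' Fits a random forest on the (scaled) training rows and ranks features by
#' mean impurity-decrease (Gini) importance; the top
#' `floor(fraction * n_features)` are retained, with ties at the cutoff
#' broken by ascending m/z.
#'
#' @param fm A labeled `ims_features` of training rows.
#' @param fraction Fraction of features to keep (default 0.25).
#' @param forest_size Number of trees (default 500).
#' @param label Label column (see [build_stratified_subsets()]).
#' @param seed Integer seed.
#' @return A `feature_signature`: `selected` (ascending m/z), `importance`
#'   (named, all features), `fraction`.
#' @export
select_top_features <- function(fm, fraction = 0.25, forest_size = 500L,
                                label = "auto", seed = 1L) {
  if (fraction <= 0 || fraction > 1)
    stopf("parameter error: fraction must be in (0, 1]")
  y <- droplevels(fm_labels(fm, label))
  if (nlevels(y) < 2L)
    stopf("degenerate-label error: training labels contain a single class")
  df <- as.data.frame(fm$values)
  names(df) <- sprintf("mz%d", seq_along(fm$mz))
  fit <- ranger::ranger(x = df, y = y, num.trees = forest_size,
                        importance = "impurity", seed = seed,
                        num.threads = 1L)
  imp <- as.numeric(fit$variable.importance)
  k <- floor(fraction * length(fm$mz))
  ord <- order(-imp, fm$mz)
  selected <- sort(fm$mz[ord[seq_len(k)]])
  structure(list(selected = selected,
                 importance = setNames(imp, sprintf("%.4f", fm$mz)),
                 fraction = fraction, forest_size = forest_size, seed = seed),
            class = "feature_signature")
}

#' @export
print.feature_signature <- function(x, ...) {
  cat(sprintf("<feature_signature> %d of %d features (fraction %.3g)\n",
              length(x$selected), length(x$importance), x$fraction))
  invisible(x)
}
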