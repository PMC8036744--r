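# Random-forest ensemble training, tuning, prediction and evaluation.

#' Random-forest hyperparameters
#'
#' @param trees Number of trees (default 500).
#' @param features_per_split Fraction of available features tried at each
#'   split (mtry = round(fraction * p), at least 1).
#' @param min_node_size Minimal node size.
#' @return An `rf_params` object.
#' @export
rf_params <- function(trees = 500L, features_per_split = 0.1,
                      min_node_size = 5L) {
  if (trees < 1L || min_node_size < 1L ||
      features_per_split <= 0 || features_per_split > 1)
    stopf("parameter error: invalid hyperparameters")
  structure(list(trees = as.integer(trees),
                 features_per_split = as.numeric(features_per_split),
                 min_node_size = as.integer(min_node_size)),
            class = "rf_params")
}

fit_forest <- function(values, y, params, seed, probability = TRUE) {
  df <- as.data.frame(values)
  names(df) <- sprintf("f%d", seq_len(ncol(values)))
  ranger::ranger(x = df, y = y, num.trees = params$trees,
                 mtry = max(1L, round(params$features_per_split * ncol(values))),
                 min.node.size = params$min_node_size,
                 probability = probability, seed = seed, num.threads = 1L)
}

forest_prob <- function(model, values, classes) {
  df <- as.data.frame(values)
  names(df) <- sprintf("f%d", seq_len(ncol(values)))
  p <- predict(model, data = df, num.threads = 1L)$predictions
  if (nrow(df) == 0L)
    return(matrix(numeric(0), 0L, length(classes),
                  dimnames = list(NULL, classes)))
  out <- matrix(0, nrow(p), length(classes), dimnames = list(NULL, classes))
  out[, colnames(p)] <- p
  out
}

#' Grid-search hyperparameter tuning with stratified cross-validation
#'
#' Evaluates a grid of `grid_resolution` values per tuned dimension
#' (features-per-split fraction log-spaced over `[0.05, 0.8]`; minimal node
#' size over 1/5/10/20) by stratified `cv_folds`-fold cross-validation and
#' returns the parameters with the best mean balanced accuracy.  Ties are
#' broken toward the smaller features-per-split fraction, then the smaller
#' node size.  The tree count is held fixed.
#'
#' @param fm A labeled (scaled, feature-selected) `ims_features` of training
#'   rows.
#' @param grid_resolution Grid points per dimension (default 4).
#' @param cv_folds Cross-validation folds (default 3).
#' @param trees Trees per cross-validation fit (default 200; the final
#'   learners use their own tree count).
#' @param label Label column (see [build_stratified_subsets()]).
#' @param seed Integer seed.
#' @return An `rf_params` with the winning combination and attributes
#'   `grid` (full results).
#' @export
tune_hyperparameters <- function(fm, grid_resolution = 4L, cv_folds = 3L,
                                 trees = 200L, label = "auto", seed = 1L) {
  y <- droplevels(fm_labels(fm, label))
  if (nlevels(y) < 2L)
    stopf("degenerate-label error: need at least two classes")
  if (any(table(y) < cv_folds))
    stopf("fold-construction error: every class must have at least cv_folds samples")

  fps_grid <- exp(seq(log(0.05), log(0.8), length.out = grid_resolution))
  mns_grid <- if (grid_resolution == 4L) c(1L, 5L, 10L, 20L) else
    unique(round(seq(1L, 20L, length.out = grid_resolution)))
  grid <- expand.grid(features_per_split = fps_grid,
                      min_node_size = mns_grid)
  grid <- grid[order(grid$features_per_split, grid$min_node_size), ]

  folds <- with_seed(derive_seed(seed, 1L), {
    f <- integer(length(y))
    for (cls in levels(y)) {
      idx <- sample(which(y == cls))
      f[idx] <- rep_len(seq_len(cv_folds), length(idx))
    }
    f
  })

  # classification predict breaks vote ties via the R RNG: score under a
  # fixed stream so tuning is reproducible
  grid$score <- with_seed(derive_seed(seed, 2L), vapply(seq_len(nrow(grid)), function(g) {
    params <- rf_params(trees, grid$features_per_split[g],
                        grid$min_node_size[g])
    accs <- vapply(seq_len(cv_folds), function(k) {
      tr <- folds != k
      fit <- fit_forest(fm$values[tr, , drop = FALSE], y[tr], params,
                        seed = derive_seed(seed, 100L + g * cv_folds + k),
                        probability = FALSE)
      pred <- predict(fit, data = {
        df <- as.data.frame(fm$values[!tr, , drop = FALSE])
        names(df) <- sprintf("f%d", seq_len(ncol(fm$values)))
        df
      }, num.threads = 1L)$predictions
      cm <- table(factor(y[!tr], levels = levels(y)),
                  factor(pred, levels = levels(y)))
      suppressWarnings(balanced_accuracy(cm))
    }, 0)
    mean(accs)
  }, 0))

  best <- grid[which.max(grid$score), ]  # grid pre-sorted for tie-breaks
  out <- rf_params(trees = 500L, features_per_split = best$features_per_split,
                   min_node_size = best$min_node_size)
  attr(out, "grid") <- grid
  out
}

# Tune on one subset's training rows, mirroring the member training
# representation: scale on train, select the signature on train, grid-search
# on the selected columns.
tune_on_subset <- function(fm, subset, fraction, label, grid_resolution,
                           cv_folds, trees, seed) {
  train_fm <- fm_subset_rows(fm, subset$train_rows)
  sc <- scale_features(train_fm)
  sig <- select_top_features(sc$matrix, fraction = fraction, label = label,
                             seed = derive_seed(seed, 1L))
  cols <- match(round(sig$selected, 6), round(fm$mz, 6))
  tf <- sc$matrix
  tf$values <- tf$values[, cols, drop = FALSE]
  tf$mz <- fm$mz[cols]
  tune_hyperparameters(tf, grid_resolution = grid_resolution,
                       cv_folds = cv_folds, trees = trees, label = label,
                       seed = derive_seed(seed, 2L))
}

# Train one ensemble member on a subset: scale on the training rows, select
# the Gini signature on the training rows, fit the probability forest.
train_member <- function(fm, subset, params, fraction, label, seed,
                         signature = NULL) {
  train_fm <- fm_subset_rows(fm, subset$train_rows)
  sc <- scale_features(train_fm)
  if (is.null(signature))
    signature <- select_top_features(sc$matrix, fraction = fraction,
                                     label = label, seed = seed)
  cols <- match(round(signature$selected, 6), round(fm$mz, 6))
  if (anyNA(cols))
    stopf("feature-parity error: signature centers missing from the matrix axis")
  y <- droplevels(fm_labels(sc$matrix, label))
  model <- fit_forest(sc$matrix$values[, cols, drop = FALSE], y, params,
                      seed = seed)
  structure(list(model = model, scale_stats = sc$stats,
                 signature = signature, signature_cols_mz = fm$mz[cols],
                 classes = levels(y), params = params, seed = seed,
                 label = label, train_rows = subset$train_rows,
                 test_rows = subset$test_rows,
                 replicate_id = subset$replicate_id),
            class = "ensemble_member")
}

member_prob <- function(member, fm) {
  if (length(member$scale_stats$mz) != length(fm$mz) ||
      any(abs(member$scale_stats$mz - fm$mz) > 1e-6))
    stopf("feature-parity error: matrix axis differs from the ensemble's reference axis; run align_to_reference_axis/apply_axis_mapping first")
  if (nrow(fm$values) == 0L)
    return(matrix(numeric(0), 0L, length(member$classes),
                  dimnames = list(NULL, member$classes)))
  sc <- scale_features(fm, stats = member$scale_stats)
  cols <- match(round(member$signature_cols_mz, 6), round(fm$mz, 6))
  forest_prob(member$model, sc$matrix$values[, cols, drop = FALSE],
              member$classes)
}

#' Train the triplicate subtype classifier ensemble
#'
#' One probability random forest per stratified subset, fit on that subset's
#' training rows restricted to its own Gini-selected signature (computed on
#' the training rows only); test rows are never touched during scaling,
#' selection or fitting.
#'
#' @param fm The labeled `ims_features` the subsets index into (raw,
#'   unscaled; on the reference axis).
#' @param subsets Exactly three subsets from [build_stratified_subsets()].
#' @param params An `rf_params`, e.g. from [tune_hyperparameters()].
#' @param fraction Signature fraction (default 0.25).
#' @param signatures Optional list of precomputed `feature_signature`s, one
#'   per subset (default: computed per member).
#' @param label Label column.
#' @param seed Integer seed.
#' @return A `model_ensemble` with three members.
#' @export
train_subtype_ensemble <- function(fm, subsets, params, fraction = 0.25,
                                   signatures = NULL, label = "subtype",
                                   seed = 1L) {
  if (length(subsets) != 3L)
    stopf("a model ensemble has exactly three members; got %d subsets",
          length(subsets))
  members <- lapply(seq_along(subsets), function(i)
    train_member(fm, subsets[[i]], params, fraction, label,
                 seed = derive_seed(seed, 10L + i),
                 signature = signatures[[i]] %||% NULL))
  structure(list(members = members, task = label, axis_mz = fm$mz,
                 params = params),
            class = "model_ensemble")
}

#' @export
print.model_ensemble <- function(x, ...) {
  cat(sprintf("<model_ensemble> task: %s, %d members, %d-feature axis\n",
              x$task, length(x$members), length(x$axis_mz)))
  invisible(x)
}

#' Per-spectrum class-probability predictions
#'
#' @param ensemble A `model_ensemble`.
#' @param fm An `ims_features` on the ensemble's reference axis (raw scale;
#'   each member applies its own training scaling statistics).
#' @return List with `per_member` (list of probability matrices, rows
#'   summing to 1) and `mean` (member-mean probability matrix).
#' @export
predict_spectra <- function(ensemble, fm) {
  per_member <- lapply(ensemble$members, member_prob, fm = fm)
  list(per_member = per_member,
       mean = Reduce(`+`, per_member) / length(per_member))
}

#' Aggregate spectrum predictions to core level
#'
#' The core label is the argmax of the mean probability simplex over the
#' core's spectra; ties are broken by the fixed class order C1 < C2 < C4 <
#' C5.
#'
#' @param prob Probability matrix (spectra x classes), e.g.
#'   `predict_spectra(...)$mean`.
#' @param core_ids Core identifier per spectrum row.
#' @return Data frame: `core_id`, `label`, one mean-probability column per
#'   class.
#' @export
aggregate_core_predictions <- function(prob, core_ids) {
  if (nrow(prob) != length(core_ids))
    stopf("metadata-join error: every spectrum must map to a core")
  if (anyNA(core_ids))
    stopf("metadata-join error: unmapped spectrum (core_id is NA)")
  classes <- colnames(prob)
  agg <- rowsum(prob, group = core_ids) / as.vector(table(core_ids)[
    sort(unique(core_ids))])
  label <- classes[apply(agg, 1L, which.max)]  # first max = lowest class order
  data.frame(core_id = rownames(agg), label = label,
             agg, row.names = NULL, check.names = FALSE)
}

#' Evaluate an ensemble on its held-out test rows
#'
#' Each member is evaluated on its own subset's test rows: one-vs-one AUC
#' (per pair and mean), balanced accuracy, macro false discovery rate and
#' the confusion matrix.  The report aggregates across the three replicates
#' (mean AUC, balanced accuracy mean and sd, macro-FDR mean).
#'
#' @param ensemble A `model_ensemble`.
#' @param fm The `ims_features` the members' row indices refer to.
#' @return An `evaluation_report`.
#' @export
evaluate_ensemble <- function(ensemble, fm) {
  per_member <- lapply(ensemble$members, function(m) {
    test_fm <- fm_subset_rows(fm, m$test_rows)
    prob <- member_prob(m, test_fm)
    y <- factor(as.character(fm_labels(test_fm, m$label)), levels = m$classes)
    pred <- factor(m$classes[apply(prob, 1L, which.max)], levels = m$classes)
    cm <- table(truth = y, prediction = pred)
    ovo <- auc_one_vs_one(prob, y)
    list(auc = ovo, confusion = cm,
         balanced_accuracy = suppressWarnings(balanced_accuracy(cm)),
         fdr = suppressWarnings(false_discovery_rate(cm)))
  })
  aucs <- vapply(per_member, function(x) x$auc$mean, 0)
  bas <- vapply(per_member, function(x) x$balanced_accuracy, 0)
  fdrs <- vapply(per_member, function(x) x$fdr$macro, 0)
  pair_tab <- per_member[[1L]]$auc$pairs
  if (length(per_member) > 1L)
    pair_tab$auc <- rowMeans(sapply(per_member, function(x) x$auc$pairs$auc))
  structure(list(mean_auc = mean(aucs), member_auc = aucs,
                 pair_auc = pair_tab,
                 balanced_accuracy_mean = mean(bas),
                 balanced_accuracy_sd = sd(bas),
                 fdr_macro_mean = mean(fdrs),
                 per_member = per_member),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> mean one-vs-one AUC %.3f | balanced accuracy %.3f +/- %.3f | macro FDR %.1f%%\n",
              x$mean_auc, x$balanced_accuracy_mean, x$balanced_accuracy_sd,
              100 * x$fdr_macro_mean))
  invisible(x)
}
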