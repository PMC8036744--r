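# End-to-end orchestration of the two-pronged workflow: subtype
# classification on the complete dataset, and again after consensus
# exclusion of stroma-origin spectra, sharing identical upstream artifacts.

#' Pipeline configuration
#'
#' Collects every module parameter and seed in one serializable object.
#' Synthetic inputs are described by [synth_config()]s; alternatively
#' `input_paths` may point at imzML/CSV files on disk.
#'
#' @param synth [synth_config()] for the subtype-labeled TMA.
#' @param stroma_synth [synth_config()] for the compartment-labeled dataset.
#' @param input_paths Optional named list (`imzml`, `cores`, `pixels`, and
#'   `stroma_imzml`, `stroma_cores`, `stroma_pixels`) overriding the
#'   synthetic generators.
#' @param baseline_width Convolution baseline window (points).
#' @param snr_threshold,bin_tolerance,min_occurrence Peak-picking settings.
#' @param parity_max_diff Feature-parity tolerance in Da (default 0.25).
#' @param signature_fraction Gini-signature fraction (default 0.25).
#' @param train_frac Training fraction of the stratified split (default 0.7).
#' @param split_unit `"core"` (leakage-safe default) or `"spectrum"`.
#' @param shared_signature Share the first stroma member's signature.
#' @param grid_resolution,cv_folds,tune_trees Hyperparameter tuning grid.
#' @param trees Trees of the final learners.
#' @param decoy_count Decoys in the synthetic peptide reference.
#' @param seed Master seed for all model-side randomness.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(),
                            stroma_synth = synth_stroma_config(),
                            input_paths = NULL,
                            baseline_width = 20L, snr_threshold = 5,
                            bin_tolerance = 0.25, min_occurrence = 0.01,
                            parity_max_diff = 0.25,
                            signature_fraction = 0.25, train_frac = 0.7,
                            split_unit = "core", shared_signature = FALSE,
                            grid_resolution = 4L, cv_folds = 3L,
                            tune_trees = 200L, trees = 500L,
                            decoy_count = 100L, seed = 1L) {
  structure(list(synth = synth, stroma_synth = stroma_synth,
                 input_paths = input_paths,
                 baseline_width = as.integer(baseline_width),
                 snr_threshold = snr_threshold,
                 bin_tolerance = bin_tolerance,
                 min_occurrence = min_occurrence,
                 parity_max_diff = parity_max_diff,
                 signature_fraction = signature_fraction,
                 train_frac = train_frac, split_unit = split_unit,
                 shared_signature = shared_signature,
                 grid_resolution = as.integer(grid_resolution),
                 cv_folds = as.integer(cv_folds),
                 tune_trees = as.integer(tune_trees),
                 trees = as.integer(trees),
                 decoy_count = as.integer(decoy_count),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# One classification prong: subsets -> tune (once, on replicate 1; the
# stroma-filtered prong reuses the tuned parameters, as only the subset
# construction, split and selection are repeated after exclusion) ->
# triplicate training -> held-out evaluation.
run_variant <- function(fm, cfg, seed, params = NULL) {
  subsets <- build_stratified_subsets(fm, n_replicates = 3L,
                                      train_frac = cfg$train_frac,
                                      unit = cfg$split_unit,
                                      label = "subtype",
                                      seed = derive_seed(seed, 1L))
  if (is.null(params)) {
    params <- tune_on_subset(fm, subsets[[1L]], cfg$signature_fraction,
                             "subtype", cfg$grid_resolution, cfg$cv_folds,
                             trees = cfg$tune_trees,
                             seed = derive_seed(seed, 2L))
    params$trees <- cfg$trees
  }
  ensemble <- train_subtype_ensemble(fm, subsets, params,
                                     fraction = cfg$signature_fraction,
                                     label = "subtype",
                                     seed = derive_seed(seed, 3L))
  list(subsets = subsets, params = params, ensemble = ensemble,
       report = evaluate_ensemble(ensemble, fm))
}

fm_subset_cols <- function(fm, mz_keep) {
  cols <- match(round(mz_keep, 6), round(fm$mz, 6))
  if (anyNA(cols))
    stopf("feature-parity error: requested centers missing from matrix")
  fm$values <- fm$values[, cols, drop = FALSE]
  fm$mz <- fm$mz[cols]
  fm
}

#' Run the full two-pronged subtype classification workflow
#'
#' Preprocesses the subtype-labeled and compartment-labeled datasets,
#' derives the reference peak axis, establishes feature parity, trains and
#' evaluates the subtype ensemble on the complete dataset, trains the stroma
#' ensemble and removes consensus-stroma spectra, retrains and re-evaluates
#' on the filtered dataset, and annotates the filtered-variant signature
#' against the peptide reference.  Both prongs share identical upstream
#' artifacts.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional run directory; when given, [write_report()] is
#'   called on the result.
#' @return A `pipeline_run` list: datasets' ground truth, the reference
#'   axis, parity mapping, both variants (subsets, tuned parameters,
#'   ensembles, evaluation reports), the stroma ensemble and decision log,
#'   peptide matches, the AUC comparison table, and the config with its
#'   hash.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  tma <- stage("simulate", {
    if (is.null(config$input_paths)) {
      list(sub = generate_tma(config$synth),
           str = generate_stroma_labeled(config$stroma_synth))
    } else {
      p <- config$input_paths
      list(sub = list(dataset = read_ims(p$imzml, p$cores, p$pixels),
                      truth = NULL),
           str = list(dataset = read_ims(p$stroma_imzml, p$stroma_cores,
                                         p$stroma_pixels),
                      truth = NULL))
    }
  })
  sub_ds <- stage("preprocess", preprocess_dataset(tma$sub$dataset,
                                                   width = config$baseline_width))
  tma$sub$dataset <- NULL   # raw spectra no longer needed; free the memory
  str_ds <- stage("preprocess-stroma", preprocess_dataset(tma$str$dataset,
                                                          width = config$baseline_width))
  tma$str$dataset <- NULL

  reference <- stage("peak-picking", pick_peaks(sub_ds,
                                                snr_threshold = config$snr_threshold,
                                                bin_tolerance = config$bin_tolerance,
                                                min_occurrence = config$min_occurrence))
  stroma_axis <- stage("peak-picking-stroma", pick_peaks(str_ds,
                                                         snr_threshold = config$snr_threshold,
                                                         bin_tolerance = config$bin_tolerance,
                                                         min_occurrence = config$min_occurrence))
  mapping <- stage("parity", align_to_reference_axis(stroma_axis, reference,
                                                     max_diff = config$parity_max_diff))

  fm_sub <- stage("features", build_feature_matrix(sub_ds, reference))
  fm_str <- stage("features-stroma", apply_axis_mapping(
    build_feature_matrix(str_ds, stroma_axis), mapping))

  complete <- stage("subtype-complete", run_variant(fm_sub, config,
                                                    derive_seed(config$seed, 100L)))

  stroma_ens <- stage("stroma-ensemble", train_stroma_ensemble(
    fm_str, fraction = config$signature_fraction,
    shared_signature = config$shared_signature,
    grid_resolution = config$grid_resolution, cv_folds = config$cv_folds,
    seed = derive_seed(config$seed, 200L)))
  excl <- stage("consensus-exclusion", consensus_exclude(
    stroma_ens, fm_subset_cols(fm_sub, mapping$pairs$reference)))
  fm_filtered <- fm_subset_rows(fm_sub, which(!excl$decisions$excluded))

  filtered <- stage("subtype-filtered", run_variant(fm_filtered, config,
                                                    derive_seed(config$seed, 300L),
                                                    params = complete$params))

  matches <- stage("annotation", {
    if (!is.null(tma$sub$truth)) {
      ref_list <- generate_peptide_reference(tma$sub$truth,
                                             decoy_count = config$decoy_count,
                                             seed = derive_seed(config$seed, 400L))
      match_peptides(filtered$ensemble$members[[1L]]$signature, ref_list)
    } else NULL
  })

  comparison <- data.frame(
    variant = c("complete", "stroma_excluded"),
    mean_auc = c(complete$report$mean_auc, filtered$report$mean_auc),
    balanced_accuracy = c(complete$report$balanced_accuracy_mean,
                          filtered$report$balanced_accuracy_mean),
    fdr_macro = c(complete$report$fdr_macro_mean,
                  filtered$report$fdr_macro_mean),
    n_spectra = c(nrow(fm_sub$values), nrow(fm_filtered$values)))

  run <- structure(list(truth = tma$sub$truth, stroma_truth = tma$str$truth,
                        reference_axis = reference, mapping = mapping,
                        complete = complete, filtered = filtered,
                        stroma_ensemble = stroma_ens,
                        exclusion = excl, matches = matches,
                        comparison = comparison,
                        config = config,
                        config_hash = object_hash(unclass(config))),
                   class = "pipeline_run")
  if (!is.null(out_dir)) write_report(run, out_dir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n")
  print(x$comparison)
  invisible(x)
}
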