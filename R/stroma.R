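# Consensus stroma filtering: three independently trained stroma-vs-malignant
# classifiers; a spectrum is excluded only when all three call it stromal.

#' Train the stroma-vs-malignant classifier ensemble
#'
#' Builds three balanced stratified subsets of a compartment-labeled feature
#' matrix (binary stratification over stroma/malignant), performs
#' Gini-signature selection per subset, and fits one probability forest per
#' subset.  When `params` is `NULL` the hyperparameters are grid-search
#' tuned on the first subset's training rows.
#'
#' @param fm A compartment-labeled `ims_features`, already parity-aligned to
#'   the reference axis (see [apply_axis_mapping()]).
#' @param params Optional `rf_params`; tuned when `NULL`.
#' @param fraction Signature fraction (default 0.25).
#' @param shared_signature When `TRUE`, the first member's signature is
#'   reused by all members instead of per-subset selection.
#' @param grid_resolution,cv_folds Tuning grid settings (used when `params`
#'   is `NULL`).
#' @param seed Integer seed.
#' @return A `model_ensemble` with task `"compartment"`.
#' @export
train_stroma_ensemble <- function(fm, params = NULL, fraction = 0.25,
                                  shared_signature = FALSE,
                                  grid_resolution = 4L, cv_folds = 3L,
                                  seed = 1L) {
  y <- fm_labels(fm, "compartment")
  if (nlevels(droplevels(y)) < 2L)
    stopf("degenerate-label error: need both stroma and malignant spectra")
  subsets <- build_stratified_subsets(fm, n_replicates = 3L,
                                      label = "compartment",
                                      seed = derive_seed(seed, 1L))
  if (is.null(params))
    params <- tune_on_subset(fm, subsets[[1L]], fraction, "compartment",
                             grid_resolution, cv_folds, trees = 200L,
                             seed = derive_seed(seed, 2L))
  members <- lapply(seq_along(subsets), function(i)
    train_member(fm, subsets[[i]], params, fraction, "compartment",
                 seed = derive_seed(seed, 10L + i)))
  if (shared_signature)
    for (i in 2:3) {
      members[[i]] <- train_member(fm, subsets[[i]], params, fraction,
                                   "compartment",
                                   seed = derive_seed(seed, 10L + i),
                                   signature = members[[1L]]$signature)
    }
  structure(list(members = members, task = "compartment", axis_mz = fm$mz,
                 params = params),
            class = "model_ensemble")
}

#' Consensus exclusion of stroma-origin spectra
#'
#' Each of the three members votes stroma when its stroma probability is at
#' least 0.5; a spectrum is excluded if and only if all three votes are
#' stroma.  The excluded set therefore equals the intersection of the three
#' members' stroma-predicted sets.
#'
#' @param ensemble A compartment-task `model_ensemble`.
#' @param fm An `ims_features` on the ensemble's reference axis (raw scale).
#' @return List with `matrix` (rows with unanimous stroma votes removed),
#'   `decisions` (data frame: spectrum, the three votes, excluded flag) and
#'   `removed_per_core`.
#' @export
consensus_exclude <- function(ensemble, fm) {
  if (ensemble$task != "compartment")
    stopf("ensemble task must be 'compartment'")
  if (length(ensemble$axis_mz) != length(fm$mz) ||
      any(abs(ensemble$axis_mz - fm$mz) > 1e-6))
    stopf("feature-parity error: matrix axis differs from the ensemble's; run align_to_reference_axis/apply_axis_mapping first")
  votes <- sapply(ensemble$members, function(m) {
    prob <- member_prob(m, fm)
    ifelse(prob[, "stroma"] >= 0.5, "stroma", "malignant")
  })
  votes <- matrix(votes, nrow = nrow(fm$values), ncol = 3L)
  excluded <- rowSums(votes == "stroma") == 3L
  decisions <- data.frame(spectrum = fm$meta$spectrum,
                          vote1 = votes[, 1L], vote2 = votes[, 2L],
                          vote3 = votes[, 3L], excluded = excluded)
  removed <- table(fm$meta$core_id[excluded])
  list(matrix = fm_subset_rows(fm, which(!excluded)),
       decisions = decisions,
       removed_per_core = removed)
}
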