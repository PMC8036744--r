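# Compartment-labeled toy data: two "compartments" with separable profiles,
# mixed within cores (as in tissue).
toy_compartment_matrix <- function(n_core = 6L, px = 12L, sep = 3,
                                   stroma_frac = 0.4, seed = 1L) {
  withr::local_seed(seed)
  rows <- list(); meta <- list()
  for (ci in seq_len(n_core)) {
    n_str <- round(stroma_frac * px)
    comp <- c(rep("stroma", n_str), rep("malignant", px - n_str))
    mu <- ifelse(comp == "stroma", sep, 0)
    vals <- cbind(rnorm(px, mu), rnorm(px, -mu), matrix(rnorm(px * 6), px))
    rows[[ci]] <- vals
    meta[[ci]] <- data.frame(spectrum = NA_integer_, x = seq_len(px), y = 1L,
                             core_id = sprintf("core%03d", ci),
                             patient_id = sprintf("P%03d", ci),
                             compartment = comp,
                             subtype = NA_character_,
                             stringsAsFactors = FALSE)
  }
  values <- do.call(rbind, rows)
  meta <- do.call(rbind, meta)
  meta$spectrum <- seq_len(nrow(meta))
  mz <- 1000 + seq_len(ncol(values))
  colnames(values) <- sprintf("%.4f", mz)
  structure(list(values = values, mz = mz, meta = meta, tolerance = 0.25,
                 compartment_labeled = TRUE),
            class = "ims_features")
}

test_that("stroma ensemble trains three members with distinct subsets and high AUC", {
  fm <- toy_compartment_matrix(seed = 31L)
  ens <- train_stroma_ensemble(fm, params = rf_params(100L, 0.5, 1L),
                               fraction = 0.5, seed = 7L)
  expect_length(ens$members, 3)
  expect_equal(ens$task, "compartment")
  train_sets <- lapply(ens$members, `[[`, "train_rows")
  expect_false(identical(train_sets[[1]], train_sets[[2]]) &&
                 identical(train_sets[[2]], train_sets[[3]]))
  # held-out binary AUC per member on separable data
  for (m in ens$members) {
    test_fm <- maldisubtype:::fm_subset_rows(fm, m$test_rows)
    prob <- maldisubtype:::member_prob(m, test_fm)
    y <- test_fm$meta$compartment
    auc <- auc_one_vs_one(prob, y)$mean
    expect_gte(auc, 0.99)
  }
  fm_one <- fm
  fm_one$meta$compartment <- "malignant"
  expect_error(train_stroma_ensemble(fm_one), "degenerate-label")
})

test_that("consensus exclusion removes exactly the unanimous-stroma spectra", {
  fm <- toy_compartment_matrix(seed = 33L)
  ens <- train_stroma_ensemble(fm, params = rf_params(100L, 0.5, 1L),
                               fraction = 0.5, seed = 3L)
  res <- consensus_exclude(ens, fm)
  votes <- as.matrix(res$decisions[, c("vote1", "vote2", "vote3")])
  expect_identical(res$decisions$excluded,
                   unname(rowSums(votes == "stroma") == 3L))
  # set identity: excluded = intersection of the members' stroma sets
  member_sets <- lapply(1:3, function(i) which(votes[, i] == "stroma"))
  expect_setequal(which(res$decisions$excluded),
                  Reduce(intersect, member_sets))
  # monotonicity: consensus removes a subset of any single member's set
  for (s in member_sets)
    expect_true(all(which(res$decisions$excluded) %in% s))
  expect_equal(nrow(res$matrix$values),
               nrow(fm$values) - sum(res$decisions$excluded))

  # exclusion recall/precision on separable toy data
  truth <- fm$meta$compartment == "stroma"
  got <- res$decisions$excluded
  expect_gte(sum(got & truth) / sum(truth), 0.9)
  expect_gte(sum(got & truth) / max(sum(got), 1), 0.9)
})

test_that("axis mismatch is rejected and no-stroma predictions leave data intact", {
  fm <- toy_compartment_matrix(seed = 35L)
  ens <- train_stroma_ensemble(fm, params = rf_params(100L, 0.5, 1L),
                               fraction = 0.5, seed = 5L)
  fm_shift <- fm
  fm_shift$mz <- fm$mz + 1
  expect_error(consensus_exclude(ens, fm_shift), "feature-parity")

  # a matrix of pure malignant-like signal: nothing excluded
  fm_mal <- fm
  keep <- fm$meta$compartment == "malignant"
  fm_mal <- maldisubtype:::fm_subset_rows(fm, which(keep))
  res <- consensus_exclude(ens, fm_mal)
  expect_lte(sum(res$decisions$excluded), 0.05 * nrow(fm_mal$values))
})

test_that("end-to-end stroma filtering works on synthetic imaging data", {
  # emulated stroma-annotation study scale: 19 patients / 35 cores
  cfg <- synth_config(n_patients = 19L,
                      cores_per_patient = c(rep(2L, 16L), rep(1L, 3L)),
                      pixels_per_core = c(5L, 5L), mz_range = c(900, 1100),
                      n_channels = 12L, n_subtype_markers = 4L,
                      n_stroma_markers = 4L, stroma_fraction = 0.4, seed = 51L)
  out <- generate_stroma_labeled(cfg)
  ds <- preprocess_dataset(out$dataset)
  axis <- pick_peaks(ds)
  fm <- build_feature_matrix(ds, axis)
  ens <- train_stroma_ensemble(fm, params = rf_params(150L, 0.3, 1L),
                               fraction = 0.5, seed = 8L)
  res <- consensus_exclude(ens, fm)
  truth <- fm$meta$compartment == "stroma"
  got <- res$decisions$excluded
  recall <- sum(got & truth) / sum(truth)
  precision <- sum(got & truth) / max(sum(got), 1)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
})
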