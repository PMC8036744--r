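# Shared small fixtures, generated in code.

# A small but structured TMA: 12 cores, 6x6 pixels, 15 channels over a
# narrow window -- enough to carry subtype and compartment signal while
# staying sub-second.
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_patients = 12L, cores_per_patient = 1L,
                   pixels_per_core = c(6L, 6L), mz_range = c(900, 1200),
                   n_channels = 15L, n_subtype_markers = 8L,
                   n_stroma_markers = 4L, stroma_fraction = 0.3,
                   seed = 42L)
  for (nm in names(defaults))
    if (is.null(args[[nm]])) args[[nm]] <- defaults[[nm]]
  do.call(synth_config, args)
}

# Cached tiny dataset + preprocessed form + feature matrix, shared across
# test files to keep the suite fast.
tiny_tma <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      out <- generate_tma(tiny_config())
      ds <- preprocess_dataset(out$dataset)
      axis <- pick_peaks(ds)
      cache <<- list(raw = out$dataset, truth = out$truth, ds = ds,
                     axis = axis, fm = build_feature_matrix(ds, axis))
    }
    cache
  }
})

# Feature matrix with controllable class structure for model-level tests:
# `n_core` cores per class, `px` spectra per core, features = informative
# class means plus noise columns.
toy_feature_matrix <- function(classes = c("C1", "C2", "C4", "C5"),
                               n_core = 4L, px = 10L, n_noise = 6L,
                               sep = 3, seed = 1L,
                               label_col = "subtype") {
  withr::local_seed(seed)
  n_inf <- length(classes)
  rows <- list(); meta <- list(); core_n <- 0L
  for (ci in seq_along(classes)) {
    for (k in seq_len(n_core)) {
      core_n <- core_n + 1L
      mu <- rep(0, n_inf); mu[ci] <- sep
      vals <- cbind(matrix(rnorm(px * n_inf, rep(mu, each = px)), px),
                    matrix(rnorm(px * n_noise), px))
      rows[[core_n]] <- vals
      meta[[core_n]] <- data.frame(
        spectrum = NA_integer_, x = seq_len(px), y = 1L,
        core_id = sprintf("core%03d", core_n),
        patient_id = sprintf("P%03d", core_n),
        compartment = NA_character_, stringsAsFactors = FALSE)
      meta[[core_n]][[label_col]] <- classes[ci]
    }
  }
  values <- do.call(rbind, rows)
  meta <- do.call(rbind, meta)
  meta$spectrum <- seq_len(nrow(meta))
  mz <- 1000 + seq_len(ncol(values))
  colnames(values) <- sprintf("%.4f", mz)
  structure(list(values = values, mz = mz, meta = meta, tolerance = 0.25,
                 compartment_labeled = label_col == "compartment"),
            class = "ims_features")
}

expect_simplex_rows <- function(p, tol = 1e-9) {
  expect_true(all(abs(rowSums(p) - 1) < tol))
}
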