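test_that("axis matching pairs nearest centers within tolerance", {
  m <- align_to_reference_axis(c(999.80, 1000.10, 1000.30), 1000.00)
  expect_equal(nrow(m$pairs), 1)
  expect_equal(m$pairs$source, 1000.10)
  expect_equal(m$pairs$reference, 1000.00)
  expect_equal(m$pairs$delta, 0.10)
  expect_setequal(m$unmatched_source, c(999.80, 1000.30))

  # reference center with nothing nearby is reported unmatched
  m2 <- align_to_reference_axis(c(900, 950), c(900.1, 1000))
  expect_equal(m2$unmatched_reference, 1000)

  # identical axes: identity mapping
  ax <- c(900, 950.5, 1000.25)
  m3 <- align_to_reference_axis(ax, ax)
  expect_equal(m3$pairs$source, ax)
  expect_equal(m3$pairs$reference, ax)
  expect_length(m3$unmatched_source, 0)
  expect_length(m3$unmatched_reference, 0)

  expect_error(align_to_reference_axis(ax, numeric(0)), "reference")
})

test_that("axis matching is injective and symmetric up to orientation", {
  withr::local_seed(3)
  for (rep in 1:20) {
    ref <- sort(runif(30, 900, 1100))
    src <- sort(c(ref + rnorm(30, 0, 0.08), runif(10, 900, 1100)))
    m <- align_to_reference_axis(src, ref)
    expect_false(any(duplicated(m$pairs$source)))
    expect_false(any(duplicated(m$pairs$reference)))
    expect_true(all(m$pairs$delta < 0.25))
    m_rev <- align_to_reference_axis(ref, src)
    expect_equal(nrow(m$pairs), nrow(m_rev$pairs))
    expect_equal(m$pairs$delta, sort(m_rev$pairs$delta)[order(order(m$pairs$delta))])
  }
})

test_that("feature scaling standardizes columns and honours provided stats", {
  fm <- toy_feature_matrix(n_core = 2L, px = 5L)
  fm$values[, 1] <- c(rep(1, 13), 2, 3, rep(1, 25))[seq_len(nrow(fm$values))]
  fm$values[, 2] <- 7  # constant column
  sc <- scale_features(fm)
  expect_equal(unname(colMeans(sc$matrix$values)), rep(0, ncol(fm$values)),
               tolerance = 1e-12)
  expect_true(all(sc$matrix$values[, 2] == 0))
  sds <- apply(sc$matrix$values, 2, sd)
  expect_equal(unname(sds[-2]), rep(1, ncol(fm$values) - 1), tolerance = 1e-12)

  # applying train stats to other data uses those stats, not the data's own
  fm_test <- toy_feature_matrix(n_core = 2L, px = 5L, seed = 9L)
  sc_test <- scale_features(fm_test, stats = sc$stats)
  manual <- (fm_test$values[, 3] - sc$stats$center[3]) / sc$stats$spread[3]
  expect_equal(unname(sc_test$matrix$values[, 3]), unname(manual))
})

test_that("stratified subsets include all of the rarest class and balance the rest", {
  # classes C1: 100 spectra/10 cores, C2: 40/4, C4: 20/2, C5: 30/3
  fm <- rbind_fm <- local({
    parts <- list(toy_feature_matrix("C1", n_core = 10L, px = 10L, seed = 1),
                  toy_feature_matrix("C2", n_core = 4L, px = 10L, seed = 2),
                  toy_feature_matrix("C4", n_core = 2L, px = 10L, seed = 3),
                  toy_feature_matrix("C5", n_core = 3L, px = 10L, seed = 4))
    values <- do.call(rbind, lapply(parts, `[[`, "values"))
    meta <- do.call(rbind, lapply(seq_along(parts), function(i) {
      m <- parts[[i]]$meta
      m$core_id <- paste0(m$core_id, "_", i)
      m
    }))
    meta$spectrum <- seq_len(nrow(meta))
    structure(list(values = values, mz = parts[[1]]$mz, meta = meta,
                   tolerance = 0.25, compartment_labeled = FALSE),
              class = "ims_features")
  })
  subs <- build_stratified_subsets(fm, n_replicates = 3L, seed = 11L)
  for (s in subs) {
    rows <- c(s$train_rows, s$test_rows)
    expect_false(any(duplicated(rows)))                    # no duplicates
    y <- fm$meta$subtype[rows]
    counts <- table(y)
    expect_equal(counts[["C4"]], 20)                       # rarest never subsampled
    # every other class sampled to >= 20 and < 20 + its max core size (10)
    expect_true(all(counts >= 20 & counts < 30))
    # per-class 70/30 split within one core's worth
    for (cls in names(counts)) {
      n_test <- sum(fm$meta$subtype[s$test_rows] == cls)
      expect_lte(abs(n_test - 0.3 * counts[[cls]]), 10)
      expect_gt(n_test, 0)
    }
    expect_length(intersect(s$train_rows, s$test_rows), 0)
  }
  # replicates differ in their sampled cores
  expect_false(identical(subs[[1]]$sampled_cores, subs[[2]]$sampled_cores) &&
                 identical(subs[[2]]$sampled_cores, subs[[3]]$sampled_cores))
  # determinism under the same seed
  subs2 <- build_stratified_subsets(fm, n_replicates = 3L, seed = 11L)
  expect_identical(lapply(subs, `[[`, "train_rows"),
                   lapply(subs2, `[[`, "train_rows"))
})

test_that("spectrum-level split hits 70/30 within one unit", {
  fm <- toy_feature_matrix(n_core = 3L, px = 10L)
  subs <- build_stratified_subsets(fm, n_replicates = 1L, unit = "spectrum",
                                   seed = 2L)
  s <- subs[[1]]
  y <- fm$meta$subtype
  for (cls in unique(y)) {
    n_cls <- sum(y[c(s$train_rows, s$test_rows)] == cls)
    n_test <- sum(y[s$test_rows] == cls)
    expect_lte(abs(n_test - 0.3 * n_cls), 1)
  }
})

test_that("cores are atomic under the core-level split", {
  fm <- toy_feature_matrix(n_core = 5L, px = 8L)
  s <- build_stratified_subsets(fm, n_replicates = 1L, seed = 3L)[[1]]
  train_cores <- unique(fm$meta$core_id[s$train_rows])
  test_cores <- unique(fm$meta$core_id[s$test_rows])
  expect_length(intersect(train_cores, test_cores), 0)
})

test_that("signature size is exactly floor(fraction x n_features)", {
  fm <- toy_feature_matrix(n_core = 3L, px = 5L, n_noise = 536L)  # 540 features
  expect_equal(ncol(fm$values), 540)
  sig <- select_top_features(fm, fraction = 0.25, forest_size = 60L, seed = 1L)
  expect_length(sig$selected, 135)
  expect_true(all(sig$selected %in% fm$mz))
  sig_all <- select_top_features(fm, fraction = 1, forest_size = 30L, seed = 1L)
  expect_length(sig_all$selected, ncol(fm$values))
  for (frac in c(0.1, 0.5, 0.33)) {
    sg <- select_top_features(fm, fraction = frac, forest_size = 30L, seed = 1L)
    expect_length(sg$selected, floor(frac * 540))
  }
  fm1 <- fm; fm1$meta$subtype <- "C1"
  expect_error(select_top_features(fm1, forest_size = 30L), "degenerate-label")
})

test_that("an informative feature outranks a pure-noise feature", {
  # feature 1 predicts the label, feature 2 is noise; stump-accuracy oracle
  # confirms the construction before the forest importance is compared
  withr::local_seed(7)
  for (rep in 1:5) {
    n <- 120
    y <- rep(c("C1", "C2"), each = n / 2)
    x1 <- rnorm(n, ifelse(y == "C1", 0, 2.5))
    x2 <- rnorm(n)
    stump_acc <- function(x) {
      thr <- mean(x)
      max(mean((x > thr) == (y == "C2")), mean((x <= thr) == (y == "C2")))
    }
    expect_gt(stump_acc(x1), stump_acc(x2))  # oracle: A separates, B doesn't
    fm <- structure(list(values = cbind(x1, x2), mz = c(1000, 1001),
                         meta = data.frame(spectrum = seq_len(n),
                                           core_id = paste0("c", seq_len(n)),
                                           patient_id = "p", subtype = y),
                         tolerance = 0.25, compartment_labeled = FALSE),
                    class = "ims_features")
    sig <- select_top_features(fm, fraction = 0.5, forest_size = 100L,
                               seed = rep)
    expect_gt(sig$importance[[1]], sig$importance[[2]])
    expect_equal(sig$selected, 1000)
  }
})

test_that("planted subtype markers are recovered by the selected signature", {
  recovered <- 0L; total <- 0L
  for (s in 1:5) {
    # signature budget floor(0.5 x 15) = 7 must be able to hold all planted
    # subtype markers (4) next to the 2 compartment markers
    cfg <- tiny_config(n_patients = 20L, n_subtype_markers = 4L,
                       n_stroma_markers = 2L, seed = 300L + s)
    out <- generate_tma(cfg)
    ds <- preprocess_dataset(out$dataset)
    axis <- pick_peaks(ds)
    fm <- build_feature_matrix(ds, axis)
    sc <- scale_features(fm)
    sig <- select_top_features(sc$matrix, fraction = 0.5, forest_size = 300L,
                               seed = s)
    mk <- out$truth$markers$mz[out$truth$markers$role == "subtype"]
    recovered <- recovered + sum(vapply(mk, function(m)
      any(abs(sig$selected - m) < 0.25), TRUE))
    total <- total + length(mk)
  }
  expect_gte(recovered / total, 0.9)
})
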