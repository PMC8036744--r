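test_that("generated TMA has one spectrum per pixel and is seed-reproducible", {
  cfg <- tiny_config(n_patients = 12L, cores_per_patient = 1L,
                     pixels_per_core = c(10L, 10L))
  out <- generate_tma(cfg)
  expect_equal(nrow(out$dataset$intensities), 12 * 100)
  expect_equal(nrow(out$dataset$pixels), 12 * 100)
  expect_equal(nrow(out$dataset$cores), 12)
  expect_true(all(out$dataset$intensities >= 0))

  out2 <- generate_tma(cfg)
  expect_identical(out$dataset$intensities, out2$dataset$intensities)
  expect_identical(out$dataset$pixels, out2$dataset$pixels)
  expect_identical(out$truth$markers, out2$truth$markers)

  out3 <- generate_tma(tiny_config(seed = 43L))
  expect_false(identical(out$dataset$intensities, out3$dataset$intensities))
})

test_that("config invariants are enforced", {
  expect_error(synth_config(subtype_proportions = c(C1 = .5, C2 = .5, C4 = .2, C5 = -.2)),
               "simplex")
  expect_error(synth_config(mz_range = c(3200, 800)), "mz_range")
  expect_error(synth_config(stroma_fraction = 1), "stroma_fraction")
  expect_error(synth_config(pixels_per_core = c(0L, 5L)), "pixels_per_core")
  expect_error(generate_stroma_labeled(tiny_config(stroma_fraction = 0)),
               "stroma_fraction")
})

test_that("planted channel centers lie inside the window and marker sets are disjoint", {
  tt <- tiny_tma()
  mk <- tt$truth$markers
  expect_true(all(mk$mz > 900 & mk$mz < 1200))
  expect_false(any(duplicated(mk$mz)))
  expect_setequal(unique(mk$role), c("subtype", "compartment"))
  # canonical channels present with their roles
  expect_true(976.490 %in% mk$mz[mk$role == "subtype"])
  expect_true(1106.719 %in% mk$mz[mk$class == "malignant"])
})

test_that("malignant-exclusive channel is near-silent in stroma", {
  tt <- tiny_tma()
  mal_mz <- tt$truth$markers$mz[tt$truth$markers$class == "malignant"][1]
  col <- which.min(abs(tt$fm$mz - mal_mz))
  stroma <- tt$fm$meta$compartment == "stroma"
  m_str <- mean(tt$fm$values[stroma, col])
  m_mal <- mean(tt$fm$values[!stroma, col])
  expect_lt(m_str, 0.10 * m_mal)
})

test_that("core subtype frequencies follow the configured proportions", {
  cfg <- tiny_config(n_patients = 150L, pixels_per_core = c(2L, 2L),
                     mz_range = c(900, 950), n_channels = 4L,
                     n_subtype_markers = 0L, n_stroma_markers = 2L,
                     seed = 5L)
  out <- generate_tma(cfg)
  counts <- table(factor(out$dataset$cores$subtype,
                         levels = c("C1", "C2", "C4", "C5")))
  p <- cfg$subtype_proportions[names(counts)]
  # 99% binomial bounds per class
  for (k in seq_along(counts)) {
    bounds <- qbinom(c(0.005, 0.995), 150, p[k])
    expect_gte(counts[[k]], bounds[1])
    expect_lte(counts[[k]], bounds[2])
  }
})

test_that("subtype marker fold-change is realized within 25% on malignant pixels", {
  tt <- tiny_tma()
  mk <- tt$truth$markers
  sub_mk <- mk[mk$role == "subtype", ]
  subtype_of <- tt$fm$meta$subtype
  mal <- tt$fm$meta$compartment == "malignant"
  ratios <- vapply(seq_len(nrow(sub_mk)), function(i) {
    col <- which.min(abs(tt$fm$mz - sub_mk$mz[i]))
    assoc <- subtype_of == sub_mk$class[i] & mal
    other <- subtype_of != sub_mk$class[i] & mal
    mean(tt$fm$values[assoc, col]) / mean(tt$fm$values[other, col])
  }, 0)
  eff <- tt$truth$config$effect_size
  expect_true(all(ratios > 0.75 * eff & ratios < 1.25 * eff))
})

test_that("per-spectrum TIC variation matches the configured CV", {
  out <- generate_tma(tiny_config(n_patients = 30L, tic_variation_cv = 0.3,
                                  seed = 9L))
  tot <- rowSums(out$dataset$intensities)
  cv <- sd(tot) / mean(tot)
  expect_gt(cv, 0.75 * 0.3)
  expect_lt(cv, 1.25 * 0.3)
})

test_that("stroma-labeled data has the requested compartment structure", {
  cfg <- synth_config(n_patients = 19L,
                      cores_per_patient = c(rep(2L, 16L), rep(1L, 3L)),
                      pixels_per_core = c(10L, 10L), mz_range = c(900, 1100),
                      n_channels = 10L, n_subtype_markers = 4L,
                      n_stroma_markers = 4L, stroma_fraction = 0.5, seed = 3L)
  out <- generate_stroma_labeled(cfg)
  expect_equal(nrow(out$dataset$cores), 35)
  expect_true(out$dataset$compartment_labeled)
  per_core <- tapply(out$dataset$pixels$compartment == "stroma",
                     out$dataset$pixels$core_id, sum)
  expect_true(all(per_core == 50))  # round(0.5 * 100), exact by construction
  # stroma is a contiguous-ish blob, not salt-and-pepper: most stroma pixels
  # have at least one stroma 4-neighbour
  px <- out$dataset$pixels[out$dataset$pixels$core_id == "core001", ]
  st <- px[px$compartment == "stroma", c("x", "y")]
  key <- paste(st$x, st$y)
  has_nb <- vapply(seq_len(nrow(st)), function(i) {
    any(paste(st$x[i] + c(1, -1, 0, 0), st$y[i] + c(0, 0, 1, -1)) %in% key)
  }, TRUE)
  expect_gt(mean(has_nb), 0.9)
})

test_that("denser native m/z sampling multiplies the native axis size", {
  c1 <- tiny_config(mz_range = c(900, 950), n_channels = 4L,
                    n_subtype_markers = 2L, n_stroma_markers = 2L,
                    n_patients = 2L)
  c16 <- tiny_config(mz_range = c(900, 950), n_channels = 4L,
                     n_subtype_markers = 2L, n_stroma_markers = 2L,
                     n_patients = 2L, mz_step = 0.25 / 16)
  d1 <- generate_tma(c1)$dataset
  d16 <- generate_stroma_labeled(c16)$dataset
  expect_equal(length(d16$mz) / length(d1$mz), 16, tolerance = 0.01)
})

test_that("nanostring panel construction, reproducibility and content factors", {
  labels <- rep(c("C1", "C2", "C4", "C5"), each = 2)
  p <- generate_nanostring_panel(8, labels, seed = 21)
  expect_s3_class(p, "nanostring_panel")
  expect_equal(ncol(p$counts), 8)
  expect_true(all(p$probe_class %in%
                    c("endogenous", "positive", "negative", "housekeeping")))
  expect_setequal(rownames(p$counts)[p$probe_class == "housekeeping"],
                  c("ACTB", "GAPDH", "GUSB", "TBP"))
  p2 <- generate_nanostring_panel(8, labels, seed = 21)
  expect_identical(p$counts, p2$counts)
  expect_error(generate_nanostring_panel(0, character(0)), "empty-input")
  expect_error(generate_nanostring_panel(3, labels), "length")

  # housekeeping counts track the injected per-sample content factor
  p_big <- generate_nanostring_panel(120, sample(c("C1", "C2", "C4", "C5"),
                                                 120, replace = TRUE),
                                     seed = 22)
  hk_gm <- apply(p_big$counts[p_big$probe_class == "housekeeping", ], 2,
                 function(x) exp(mean(log(x))))
  expect_gt(cor(hk_gm, p_big$truth$content, method = "spearman"), 0.9)
})

test_that("peptide reference covers planted markers and decoys stay far", {
  tt <- tiny_tma()
  ref <- generate_peptide_reference(tt$truth, decoy_count = 50, seed = 4)
  mk <- tt$truth$markers
  expect_equal(sum(!ref$is_decoy), nrow(mk))
  # true entries within 0.2 Da of their channel; canonical symbols preserved
  true_e <- ref[!ref$is_decoy, ]
  d <- vapply(true_e$mass, function(m) min(abs(m - mk$mz)), 0)
  expect_true(all(d < 0.2))
  expect_true("ACTA2" %in% true_e$symbol)
  expect_true("H1-2" %in% true_e$symbol)
  # decoys > 1 Da from every planted channel
  dd <- vapply(ref$mass[ref$is_decoy], function(m) min(abs(m - mk$mz)), 0)
  expect_true(all(dd > 1.0))
  # no decoys requested -> exactly one entry per planted channel
  ref0 <- generate_peptide_reference(tt$truth, decoy_count = 0, seed = 4)
  expect_equal(nrow(ref0), nrow(mk))
})
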