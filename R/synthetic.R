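# Synthetic spatial MALDI-IMS data with planted subtype and compartment
# markers.  The generator emulates a tissue-microarray acquisition: one mass
# spectrum per pixel on a shared (continuous-mode) m/z axis, cores carrying a
# molecular subtype, and a contiguous stroma compartment inside each core.

#' Configuration for the synthetic MALDI-IMS generator
#'
#' Defines the statistical structure of a simulated tissue-microarray (TMA)
#' acquisition: the m/z axis, the set of true peptide channels, which channels
#' carry subtype- or compartment-specific effects, and the noise model
#' (multiplicative log-normal peak noise, additive baseline with an
#' exponentially decaying profile, per-spectrum total-ion-count variation).
#'
#' @param n_patients Number of patients.
#' @param cores_per_patient Cores per patient; a single count or a vector of
#'   length `n_patients`.
#' @param pixels_per_core Grid dimensions `c(rows, cols)` of each core.
#' @param mz_range Acquisition window in Da, `c(low, high)`.
#' @param mz_step Spacing of the profile m/z axis in Da.
#' @param n_channels Number of true peptide channels planted in the window.
#' @param subtype_proportions Named simplex weights over the four molecular
#'   subtypes `C1` (mesenchymal), `C2` (immunoreactive), `C4` (differentiated)
#'   and `C5` (proliferative); cores draw their subtype from these weights.
#' @param n_subtype_markers Number of channels with subtype-specific effects
#'   (assigned round-robin over the four subtypes).
#' @param effect_size Multiplicative fold-change of a marker channel in its
#'   associated subtype (malignant pixels) or, for stroma-elevated channels,
#'   in stroma pixels.
#' @param stroma_fraction Fraction of pixels per core belonging to the stroma
#'   compartment; the stroma is a contiguous blob (thresholded smooth random
#'   field), not salt-and-pepper.
#' @param n_stroma_markers Number of compartment-specific channels; half are
#'   stroma-elevated, half malignant-exclusive.
#' @param stroma_suppression Residual fraction of a malignant-exclusive
#'   channel's height in stroma pixels.
#' @param mz_jitter_sd Per-core mass jitter of channel centers (Da), emulating
#'   calibration drift between acquisitions.
#' @param baseline_level Additive chemical-noise baseline intensity at the low
#'   end of the window; the baseline decays exponentially with m/z.
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   noise on per-pixel peak heights.
#' @param tic_variation_cv Coefficient of variation of the per-spectrum
#'   log-normal total-ion-count factor.
#' @param peak_fwhm Full width at half maximum of the Gaussian peak profile
#'   (Da).
#' @param channel_seed Seed fixing the molecular layout (channel centers, base
#'   heights, marker roles).  Two datasets generated with the same
#'   `channel_seed` share their underlying peptide species, so their picked
#'   peak axes can be matched by feature parity.
#' @param seed Seed for the realization (core subtypes, compartment geometry,
#'   jitter, noise).
#'
#' @return A validated object of class `synth_config`.
#' @export
synth_config <- function(n_patients = 30L,
                         cores_per_patient = 2L,
                         pixels_per_core = c(10L, 10L),
                         mz_range = c(800, 3200),
                         mz_step = 0.25,
                         n_channels = 540L,
                         subtype_proportions = c(C1 = 0.376, C2 = 0.276,
                                                 C4 = 0.158, C5 = 0.190),
                         n_subtype_markers = 20L,
                         effect_size = 3,
                         stroma_fraction = 0.3,
                         n_stroma_markers = 12L,
                         stroma_suppression = 0.02,
                         mz_jitter_sd = 0.05,
                         baseline_level = 10,
                         noise_cv = 0.2,
                         tic_variation_cv = 0.3,
                         peak_fwhm = 0.5,
                         channel_seed = 641L,
                         seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              cores_per_patient = as.integer(cores_per_patient),
              pixels_per_core = as.integer(pixels_per_core),
              mz_range = as.numeric(mz_range),
              mz_step = as.numeric(mz_step),
              n_channels = as.integer(n_channels),
              subtype_proportions = subtype_proportions,
              n_subtype_markers = as.integer(n_subtype_markers),
              effect_size = as.numeric(effect_size),
              stroma_fraction = as.numeric(stroma_fraction),
              n_stroma_markers = as.integer(n_stroma_markers),
              stroma_suppression = as.numeric(stroma_suppression),
              mz_jitter_sd = as.numeric(mz_jitter_sd),
              baseline_level = as.numeric(baseline_level),
              noise_cv = as.numeric(noise_cv),
              tic_variation_cv = as.numeric(tic_variation_cv),
              peak_fwhm = as.numeric(peak_fwhm),
              channel_seed = as.integer(channel_seed),
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

#' Stroma-annotation study configuration
#'
#' Convenience wrapper for the compartment-labeled companion dataset: 19
#' patients contributing 35 cores, with a higher stroma content than the TMA
#' default.  All other parameters are shared with [synth_config()] so the two
#' datasets describe the same peptide species.
#'
#' @param ... Overrides passed on to [synth_config()].
#' @return A `synth_config`.
#' @export
synth_stroma_config <- function(...) {
  args <- list(...)
  defaults <- list(n_patients = 19L,
                   cores_per_patient = c(rep(2L, 16L), rep(1L, 3L)),
                   stroma_fraction = 0.4,
                   seed = 2L)
  for (nm in names(defaults))
    if (is.null(args[[nm]])) args[[nm]] <- defaults[[nm]]
  do.call(synth_config, args)
}

validate_synth_config <- function(cfg) {
  p <- cfg$subtype_proportions
  if (length(p) != 4L || is.null(names(p)) || !setequal(names(p), SUBTYPE_LEVELS))
    stopf("configuration error: subtype_proportions must be named over %s",
          paste(SUBTYPE_LEVELS, collapse = "/"))
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stopf("configuration error: subtype_proportions must be a simplex (sum 1, all >= 0)")
  if (cfg$mz_range[1] >= cfg$mz_range[2])
    stopf("configuration error: mz_range low must be < high")
  if (cfg$stroma_fraction < 0 || cfg$stroma_fraction >= 1)
    stopf("configuration error: stroma_fraction must be in [0, 1)")
  if (cfg$n_patients < 1L || any(cfg$cores_per_patient < 1L))
    stopf("configuration error: need at least one patient and core")
  if (!length(cfg$cores_per_patient) %in% c(1L, cfg$n_patients))
    stopf("configuration error: cores_per_patient must be scalar or length n_patients")
  if (any(cfg$pixels_per_core < 1L) || length(cfg$pixels_per_core) != 2L)
    stopf("configuration error: pixels_per_core must be positive (rows, cols)")
  if (cfg$n_channels < 1L)
    stopf("configuration error: n_channels must be positive")
  if (cfg$n_subtype_markers + cfg$n_stroma_markers > cfg$n_channels)
    stopf("configuration error: more marker channels than channels")
  invisible(cfg)
}

# Canonical planted channels emulating peptides highlighted in HGSOC
# MALDI-IMS work: histone H1.2 (malignant-exclusive), COL1A1 (stroma-elevated)
# and ACTA2 (subtype-predictive, assigned to the mesenchymal class C1).
canonical_channels <- function() {
  data.frame(mz = c(1106.719, 836.359, 976.490),
             symbol = c("H1-2", "COL1A1", "ACTA2"),
             role = c("compartment", "compartment", "subtype"),
             class = c("malignant", "stroma", "C1"),
             stringsAsFactors = FALSE)
}

# Molecular layout: channel centers (jittered grid), base heights, and marker
# role assignment.  Deterministic given the channel_seed.
channel_layout <- function(cfg) {
  with_seed(cfg$channel_seed, {
    lo <- cfg$mz_range[1]; hi <- cfg$mz_range[2]
    n <- cfg$n_channels
    spacing <- (hi - lo) / (n + 1)
    centers <- lo + spacing * seq_len(n) + runif(n, -0.3, 0.3) * spacing
    heights <- rlnorm(n, meanlog = log(50), sdlog = 0.6)
    role <- rep("none", n)
    class <- rep(NA_character_, n)
    symbol <- sprintf("PROT%03d", seq_len(n))

    canon <- canonical_channels()
    canon <- canon[canon$mz > lo & canon$mz < hi, , drop = FALSE]
    for (i in seq_len(nrow(canon))) {
      j <- which.min(abs(centers - canon$mz[i]))
      centers[j] <- canon$mz[i]
      role[j] <- canon$role[i]
      class[j] <- canon$class[i]
      symbol[j] <- canon$symbol[i]
    }

    free <- which(role == "none")
    # subtype markers round-robin over classes (canonical ACTA2 already
    # occupies a C1 slot when in range)
    need_sub <- cfg$n_subtype_markers - sum(role == "subtype")
    if (need_sub > 0) {
      pick <- sample(free, need_sub)
      target <- table(factor(rep(SUBTYPE_LEVELS,
                                 length.out = cfg$n_subtype_markers),
                             levels = SUBTYPE_LEVELS))
      done <- table(factor(class[role == "subtype"], levels = SUBTYPE_LEVELS))
      remaining <- pmax(target - done, 0)
      pool <- rep(names(remaining), remaining)
      role[pick] <- "subtype"
      class[pick] <- rep(pool, length.out = need_sub)
    }
    free <- which(role == "none")
    need_str <- cfg$n_stroma_markers - sum(role == "compartment")
    if (need_str > 0) {
      pick <- sample(free, need_str)
      role[pick] <- "compartment"
      done_s <- sum(class[role == "compartment"] == "stroma", na.rm = TRUE)
      done_m <- sum(class[role == "compartment"] == "malignant", na.rm = TRUE)
      half <- ceiling(cfg$n_stroma_markers / 2)
      pool <- c(rep("stroma", max(0, half - done_s)),
                rep("malignant", max(0, cfg$n_stroma_markers - half - done_m)))
      pool <- rep(pool, length.out = need_str)
      class[pick] <- pool
    }
    # planted markers are clearly detectable peptides: floor their heights
    marker <- role != "none"
    heights[marker] <- pmax(heights[marker], rlnorm(sum(marker), log(80), 0.3))

    ord <- order(centers)
    data.frame(channel = seq_len(n), mz = centers[ord], height = heights[ord],
               role = role[ord], class = class[ord], symbol = symbol[ord],
               stringsAsFactors = FALSE)
  })
}

# Contiguous stroma blob: threshold a box-blurred Gaussian random field at the
# quantile giving round(fraction * n) stroma pixels.
stroma_mask <- function(nr, nc, fraction) {
  f <- matrix(rnorm(nr * nc), nr, nc)
  for (pass in 1:3) {
    g <- f
    for (i in seq_len(nr)) {
      ii <- max(1L, i - 1L):min(nr, i + 1L)
      for (j in seq_len(nc)) {
        jj <- max(1L, j - 1L):min(nc, j + 1L)
        g[i, j] <- mean(f[ii, jj])
      }
    }
    f <- g
  }
  n_stroma <- round(fraction * nr * nc)
  mask <- matrix(FALSE, nr, nc)
  if (n_stroma > 0)
    mask[order(f, decreasing = TRUE)[seq_len(n_stroma)]] <- TRUE
  mask
}

# Sparse Gaussian peak-shape basis: channels x axis points, each row a
# normalized-height profile at that channel's (jittered) center.
peak_basis <- function(centers, axis, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  halfw <- 4 * sigma
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  lo <- findInterval(centers - halfw, axis) + 1L
  hi <- findInterval(centers + halfw, axis)
  for (k in seq_along(centers)) {
    if (lo[k] > hi[k]) next
    cols <- lo[k]:hi[k]
    ii <- c(ii, rep.int(k, length(cols)))
    jj <- c(jj, cols)
    vv <- c(vv, exp(-((axis[cols] - centers[k])^2) / (2 * sigma^2)))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = vv,
                       dims = c(length(centers), length(axis)))
}

lnorm_sdlog <- function(cv) sqrt(log(1 + cv^2))

#' Generate a synthetic subtype-labeled TMA dataset
#'
#' Simulates one mass spectrum per pixel of every tissue core.  Each spectrum
#' is an additive baseline plus Gaussian-shaped peaks at per-core jittered
#' channel centers, with multiplicative log-normal noise on peak heights,
#' subtype-marker fold-changes in cores of the associated subtype (malignant
#' pixels only), compartment-marker effects in stroma pixels, and a
#' per-spectrum log-normal total-ion-count factor.  Fully reproducible from
#' the config seeds.
#'
#' @param config A [synth_config()].
#' @return A list with elements `dataset` (an `ims_dataset`: shared `mz` axis,
#'   `intensities` matrix of spectra by axis points, `pixels` and `cores`
#'   metadata tables) and `truth` (ground truth: per-core subtype, per-pixel
#'   compartment, planted marker table).
#' @export
generate_tma <- function(config) {
  validate_synth_config(config)
  layout <- channel_layout(config)
  axis <- seq(config$mz_range[1], config$mz_range[2], by = config$mz_step)

  cpp <- config$cores_per_patient
  if (length(cpp) == 1L) cpp <- rep(cpp, config$n_patients)
  n_cores <- sum(cpp)
  patient_of_core <- rep(sprintf("P%03d", seq_len(config$n_patients)), cpp)
  core_ids <- sprintf("core%03d", seq_len(n_cores))
  nr <- config$pixels_per_core[1]; nc <- config$pixels_per_core[2]
  npx <- nr * nc
  n_spec <- n_cores * npx

  baseline_curve <- config$baseline_level *
    exp(-(axis - config$mz_range[1]) / diff(config$mz_range))
  noise_floor_sd <- 0.05 * config$baseline_level
  s_noise <- lnorm_sdlog(config$noise_cv)
  s_tic <- lnorm_sdlog(config$tic_variation_cv)

  with_seed(config$seed, {
    subtype <- sample(SUBTYPE_LEVELS, n_cores, replace = TRUE,
                      prob = config$subtype_proportions[SUBTYPE_LEVELS])
    intensities <- matrix(0, n_spec, length(axis))
    pixels <- vector("list", n_cores)
    for (ci in seq_len(n_cores)) {
      mask <- if (config$stroma_fraction > 0)
        stroma_mask(nr, nc, config$stroma_fraction) else matrix(FALSE, nr, nc)
      compartment <- ifelse(as.vector(mask), "stroma", "malignant")
      centers_core <- layout$mz +
        if (config$mz_jitter_sd > 0) rnorm(nrow(layout), 0, config$mz_jitter_sd) else 0
      basis <- peak_basis(centers_core, axis, config$peak_fwhm)

      # per-pixel expected heights: base height x role multiplier
      mult <- matrix(1, npx, nrow(layout))
      is_stroma <- compartment == "stroma"
      sub_assoc <- layout$role == "subtype" & layout$class == subtype[ci]
      if (any(sub_assoc) && any(!is_stroma))
        mult[!is_stroma, sub_assoc] <- config$effect_size
      str_elev <- layout$role == "compartment" & layout$class == "stroma"
      mal_excl <- layout$role == "compartment" & layout$class == "malignant"
      if (any(is_stroma)) {
        mult[is_stroma, str_elev] <- config$effect_size
        mult[is_stroma, mal_excl] <- config$stroma_suppression
      }
      heights <- t(layout$height * t(mult)) *
        matrix(rlnorm(npx * nrow(layout), -s_noise^2 / 2, s_noise), npx)
      block <- as.matrix(heights %*% basis)
      block <- block + rep(baseline_curve, each = npx) +
        matrix(rnorm(npx * length(axis), 0, noise_floor_sd), npx)
      block <- block * rlnorm(npx, -s_tic^2 / 2, s_tic)
      block[block < 0] <- 0
      rows <- (ci - 1L) * npx + seq_len(npx)
      intensities[rows, ] <- block
      pixels[[ci]] <- data.frame(spectrum = rows,
                                 x = rep(seq_len(nc), each = nr),
                                 y = rep(seq_len(nr), nc),
                                 core_id = core_ids[ci],
                                 patient_id = patient_of_core[ci],
                                 compartment = compartment,
                                 stringsAsFactors = FALSE)
    }
    pixels <- do.call(rbind, pixels)
    cores <- data.frame(core_id = core_ids, patient_id = patient_of_core,
                        subtype = subtype, stringsAsFactors = FALSE)
    markers <- layout[layout$role != "none",
                      c("mz", "role", "class", "symbol", "height")]
    markers$effect <- ifelse(markers$role == "compartment" &
                               markers$class == "malignant",
                             config$stroma_suppression, config$effect_size)
    rownames(markers) <- NULL

    dataset <- structure(list(mz = axis, intensities = intensities,
                              pixels = pixels, cores = cores,
                              compartment_labeled = FALSE,
                              preprocessed = character(0)),
                         class = "ims_dataset")
    truth <- structure(list(cores = cores,
                            pixels = pixels[, c("spectrum", "core_id", "compartment")],
                            markers = markers,
                            config = config),
                       class = "ims_truth")
    list(dataset = dataset, truth = truth)
  })
}

#' Generate a compartment-labeled (stroma-annotated) dataset
#'
#' As [generate_tma()], but the result is tagged as compartment-labeled so
#' downstream stages treat the per-pixel stroma/malignant annotation as a
#' training label.  A denser native `mz_step` than the reference dataset's may
#' be configured to exercise feature-parity matching.
#'
#' @param config A [synth_config()] with `stroma_fraction > 0`.
#' @return As [generate_tma()].
#' @export
generate_stroma_labeled <- function(config) {
  if (config$stroma_fraction <= 0)
    stopf("configuration error: stroma_fraction must be > 0 for a stroma-labeled dataset")
  out <- generate_tma(config)
  out$dataset$compartment_labeled <- TRUE
  out
}

#' @export
print.ims_dataset <- function(x, ...) {
  cat(sprintf("<ims_dataset> %d spectra x %d m/z points (%.1f-%.1f Da)\n",
              nrow(x$intensities), length(x$mz), min(x$mz), max(x$mz)))
  cat(sprintf("  cores: %d  patients: %d  compartment-labeled: %s\n",
              nrow(x$cores), length(unique(x$cores$patient_id)),
              x$compartment_labeled))
  if (length(x$preprocessed))
    cat("  preprocessing:", paste(x$preprocessed, collapse = " -> "), "\n")
  invisible(x)
}
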