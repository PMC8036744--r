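# Synthetic NanoString-style count panels and peptide reference lists.

#' Generate a synthetic NanoString-style count panel
#'
#' Emulates an nCounter run: endogenous genes with subtype-shifted log-normal
#' counts, positive controls following a known geometric titration, negative
#' controls as low Poisson background, and the four housekeeping genes ACTB,
#' GAPDH, GUSB and TBP.  Every non-negative-control probe is multiplied by a
#' per-sample assay-efficiency factor (what positive-control normalization
#' removes) and every endogenous/housekeeping probe additionally by a
#' per-sample RNA-content factor (what housekeeping normalization removes).
#'
#' @param n_samples Number of samples (columns).
#' @param true_labels Character vector of length `n_samples` with subtype
#'   labels in `C1/C2/C4/C5`.
#' @param seed Integer seed.
#' @param n_signature Number of endogenous signature genes carrying
#'   subtype-specific shifts (assigned round-robin over the subtypes).
#' @param n_background Additional endogenous genes without subtype effect.
#' @param shift_log2 Log2 fold-change of a signature gene in its subtype.
#' @param noise_cv Coefficient of variation of multiplicative count noise.
#' @return A `nanostring_panel`: list with `counts` (probe x sample),
#'   `probe_class` (endogenous/positive/negative/housekeeping per probe) and
#'   `truth` (injected content/efficiency factors, expected log2 centroids
#'   over the signature genes, the true labels).
#' @export
generate_nanostring_panel <- function(n_samples, true_labels, seed = 1L,
                                      n_signature = 40L, n_background = 20L,
                                      shift_log2 = 1.5, noise_cv = 0.15) {
  if (n_samples < 1L)
    stopf("empty-input error: n_samples must be >= 1")
  if (length(true_labels) != n_samples)
    stopf("n_samples must equal length(true_labels)")
  if (!all(true_labels %in% SUBTYPE_LEVELS))
    stopf("true_labels must be in %s", paste(SUBTYPE_LEVELS, collapse = "/"))

  with_seed(seed, {
    hk_genes <- c("ACTB", "GAPDH", "GUSB", "TBP")
    sig_genes <- sprintf("SIG%03d", seq_len(n_signature))
    bg_genes <- sprintf("BGD%03d", seq_len(n_background))
    pos_names <- paste0("POS_", LETTERS[1:6])
    neg_names <- paste0("NEG_", LETTERS[1:8])
    pos_base <- 8192 / 4^(0:5)              # geometric titration ladder

    sig_class <- rep(SUBTYPE_LEVELS, length.out = n_signature)
    base_log2 <- rnorm(n_signature + n_background, mean = 7, sd = 1)
    hk_log2 <- rnorm(4, mean = 10, sd = 0.5)

    content <- rlnorm(n_samples, 0, lnorm_sdlog(0.5))
    efficiency <- rlnorm(n_samples, 0, lnorm_sdlog(0.10))
    s_noise <- lnorm_sdlog(noise_cv)
    noisy <- function(mu) mu * rlnorm(length(mu), -s_noise^2 / 2, s_noise)

    endo_log2 <- matrix(rep(base_log2, n_samples),
                        ncol = n_samples)
    for (s in seq_len(n_samples)) {
      hit <- which(sig_class == true_labels[s])
      endo_log2[hit, s] <- endo_log2[hit, s] + shift_log2
    }
    endo <- 2^endo_log2 *
      rep(content * efficiency, each = n_signature + n_background)
    hk <- 2^matrix(rep(hk_log2, n_samples), ncol = n_samples) *
      rep(content * efficiency, each = 4)
    pos <- matrix(rep(pos_base, n_samples), ncol = n_samples) *
      rep(efficiency, each = 6)
    neg <- matrix(rpois(8 * n_samples, 4), ncol = n_samples)

    counts <- rbind(matrix(noisy(endo), ncol = n_samples),
                    matrix(noisy(hk), ncol = n_samples),
                    matrix(noisy(pos), ncol = n_samples),
                    neg)
    counts <- round(pmax(counts, 0))
    rownames(counts) <- c(sig_genes, bg_genes, hk_genes, pos_names, neg_names)
    colnames(counts) <- sprintf("S%03d", seq_len(n_samples))
    probe_class <- c(rep("endogenous", n_signature + n_background),
                     rep("housekeeping", 4), rep("positive", 6),
                     rep("negative", 8))
    names(probe_class) <- rownames(counts)

    centroids <- sapply(SUBTYPE_LEVELS, function(s)
      base_log2[seq_len(n_signature)] + shift_log2 * (sig_class == s))
    rownames(centroids) <- sig_genes

    structure(list(counts = counts, probe_class = probe_class,
                   truth = list(content = content, efficiency = efficiency,
                                centroids = centroids,
                                labels = true_labels,
                                signature_genes = sig_genes)),
              class = "nanostring_panel")
  })
}

#' Generate a synthetic peptide reference list
#'
#' Emulates a processed nLC-MS/MS peptide list covering the planted marker
#' channels of a synthetic dataset: one entry per marker at a small mass
#' offset (well below the 1.0 Da matching tolerance), carrying the marker's
#' protein symbol, plus decoy entries placed more than 1.0 Da away from every
#' planted center.
#'
#' @param ground_truth An `ims_truth` from [generate_tma()].
#' @param decoy_count Number of decoy entries.
#' @param seed Integer seed.
#' @param offset_sd Standard deviation (Da) of the true entries' mass offsets;
#'   offsets are truncated at 0.2 Da.
#' @return A `peptide_reference`: data frame with columns `mass`, `sequence`,
#'   `symbol`, `is_decoy`.
#' @export
generate_peptide_reference <- function(ground_truth, decoy_count = 100L,
                                       seed = 1L, offset_sd = 0.05) {
  markers <- ground_truth$markers
  if (is.null(markers) || nrow(markers) == 0L)
    stopf("ground truth carries no planted marker channels")
  rng <- range(ground_truth$config$mz_range)

  with_seed(seed, {
    random_seq <- function(mass) {
      n <- max(5L, round(mass / 110))
      paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
                   replace = TRUE), collapse = "")
    }
    offs <- pmax(pmin(rnorm(nrow(markers), 0, offset_sd), 0.2), -0.2)
    entries <- data.frame(mass = markers$mz + offs,
                          sequence = vapply(markers$mz, random_seq, ""),
                          symbol = markers$symbol,
                          is_decoy = FALSE,
                          stringsAsFactors = FALSE)
    if (decoy_count > 0L) {
      decoys <- numeric(0)
      while (length(decoys) < decoy_count) {
        cand <- runif(decoy_count * 2, rng[1], rng[2])
        ok <- vapply(cand, function(m) min(abs(m - markers$mz)) > 1.0, TRUE)
        decoys <- c(decoys, cand[ok])
      }
      decoys <- decoys[seq_len(decoy_count)]
      entries <- rbind(entries,
                       data.frame(mass = decoys,
                                  sequence = vapply(decoys, random_seq, ""),
                                  symbol = sprintf("DECOY%03d", seq_len(decoy_count)),
                                  is_decoy = TRUE,
                                  stringsAsFactors = FALSE))
    }
    entries <- entries[order(entries$mass), ]
    rownames(entries) <- NULL
    structure(entries, class = c("peptide_reference", "data.frame"))
  })
}
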