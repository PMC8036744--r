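# Peptide annotation of discriminative m/z features against a processed
# nLC-MS/MS reference list.

#' Read a peptide reference list from CSV
#'
#' @param path CSV with columns `mass`, `sequence`, `symbol`.
#' @return A `peptide_reference`.
#' @export
read_peptide_reference <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("mass", "sequence", "symbol")
  if (!all(need %in% names(df)))
    stopf("reference CSV must have columns %s", paste(need, collapse = ", "))
  if (any(df$mass <= 0) || any(!nzchar(df$sequence)) || any(!nzchar(df$symbol)))
    stopf("invalid reference entries (non-positive mass or empty fields)")
  structure(df, class = c("peptide_reference", "data.frame"))
}

#' Match signature features to reference peptides by minimal mass difference
#'
#' Each feature is matched to the reference entry with the smallest absolute
#' mass difference, provided it is below `max_diff`; otherwise it is reported
#' unmatched.  When two references tie at the minimal difference the lower
#' mass is chosen and the match flagged ambiguous.  Matching is deterministic
#' and independent of the reference list's row order; several features may
#' match the same peptide.
#'
#' @param features A `feature_signature` or numeric vector of m/z values.
#' @param reference A `peptide_reference`.
#' @param max_diff Matching tolerance in Da (default 1.0).
#' @param tie_eps Differences within this of each other count as tied
#'   (default 1e-9 Da).
#' @return A `peptide_matches` data frame: `feature_mz`, `matched_mass`,
#'   `delta`, `symbol`, `sequence`, `ambiguous`, `matched`; with a `summary`
#'   attribute (n features, n matched, n distinct proteins).
#' @export
match_peptides <- function(features, reference, max_diff = 1.0,
                           tie_eps = 1e-9) {
  if (max_diff <= 0)
    stopf("parameter error: max_diff must be positive")
  mzs <- if (inherits(features, "feature_signature")) features$selected
         else as.numeric(features)
  if (nrow(reference) == 0L)
    stopf("reference list is empty")
  ref <- reference[order(reference$mass), , drop = FALSE]

  rows <- lapply(mzs, function(m) {
    d <- abs(ref$mass - m)
    dmin <- min(d)
    if (dmin >= max_diff)
      return(data.frame(feature_mz = m, matched_mass = NA_real_,
                        delta = NA_real_, symbol = NA_character_,
                        sequence = NA_character_, ambiguous = FALSE,
                        matched = FALSE))
    tied <- which(d <= dmin + tie_eps)
    pick <- tied[which.min(ref$mass[tied])]
    data.frame(feature_mz = m, matched_mass = ref$mass[pick],
               delta = d[pick], symbol = ref$symbol[pick],
               sequence = ref$sequence[pick],
               ambiguous = length(tied) > 1L, matched = TRUE)
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- list(
    n_features = length(mzs),
    n_matched = sum(out$matched),
    n_proteins = length(unique(out$symbol[out$matched])))
  class(out) <- c("peptide_matches", "data.frame")
  out
}

#' @export
print.peptide_matches <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("<peptide_matches> %d/%d features matched to %d distinct proteins\n",
              s$n_matched, s$n_features, s$n_proteins))
  print.data.frame(utils::head(x, 10L))
  invisible(x)
}
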