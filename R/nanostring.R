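# NanoString-style count normalization and nearest-centroid subtype
# labeling: background thresholding -> positive-control normalization ->
# housekeeping (CodeSet content) normalization -> log2.

HOUSEKEEPING_GENES <- c("ACTB", "GAPDH", "GUSB", "TBP")

as_panel <- function(counts, probe_class, truth = NULL) {
  structure(list(counts = counts, probe_class = probe_class, truth = truth),
            class = "nanostring_panel")
}

#' @export
print.nanostring_panel <- function(x, ...) {
  cat(sprintf("<nanostring_panel> %d probes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s: %d", names(table(x$probe_class)),
                            table(x$probe_class)), collapse = ", ")))
  invisible(x)
}

panel_rows <- function(panel, classes) which(panel$probe_class %in% classes)

#' Background thresholding
#'
#' Per sample, the background threshold is the mean of the negative-control
#' counts plus two (sample) standard deviations; every endogenous and
#' housekeeping count below it is raised to the threshold.  Control probes
#' are unchanged.  Idempotent.
#'
#' @param panel A `nanostring_panel`.
#' @return The thresholded panel.
#' @export
background_threshold <- function(panel) {
  neg <- panel$counts[panel_rows(panel, "negative"), , drop = FALSE]
  if (nrow(neg) < 2L)
    stopf("need at least 2 negative-control probes to estimate the background sd")
  t_s <- colMeans(neg) + 2 * apply(neg, 2L, sd)
  rows <- panel_rows(panel, c("endogenous", "housekeeping"))
  panel$counts[rows, ] <- pmax(panel$counts[rows, , drop = FALSE],
                               rep(t_s, each = length(rows)))
  attr(panel, "background_threshold") <- t_s
  panel
}

# Normalization factors from a set of control/reference rows: the grand
# arithmetic mean of the per-sample geometric means divided by each sample's
# geometric mean.
norm_factors <- function(counts) {
  g <- apply(counts, 2L, geometric_mean)
  mean(g) / g
}

#' Positive-control normalization
#'
#' Per sample, the geometric mean of the positive-control probes defines the
#' assay-efficiency scale; each sample's non-control (endogenous and
#' housekeeping) counts are multiplied by the grand mean of those geometric
#' means divided by the sample's own.
#'
#' @param panel A `nanostring_panel`.
#' @return The normalized panel, with the factors in
#'   `attr(, "positive_factors")`.
#' @export
positive_control_normalize <- function(panel) {
  pos <- panel$counts[panel_rows(panel, "positive"), , drop = FALSE]
  if (nrow(pos) < 1L)
    stopf("no positive-control probes present")
  if (any(pos <= 0))
    stopf("zero positive-control count: geometric mean undefined")
  f <- norm_factors(pos)
  rows <- panel_rows(panel, c("endogenous", "housekeeping"))
  panel$counts[rows, ] <- panel$counts[rows, , drop = FALSE] *
    rep(f, each = length(rows))
  attr(panel, "positive_factors") <- f
  panel
}

#' Housekeeping (CodeSet content) normalization
#'
#' Same factor construction as [positive_control_normalize()] but over the
#' four housekeeping genes (ACTB, GAPDH, GUSB, TBP); the factors are applied
#' to the endogenous and housekeeping counts, after which the per-sample
#' housekeeping geometric means are equal.
#'
#' @param panel A `nanostring_panel`.
#' @return The normalized panel, with factors in
#'   `attr(, "housekeeping_factors")`.
#' @export
housekeeping_normalize <- function(panel) {
  hk_rows <- which(panel$probe_class == "housekeeping")
  missing <- setdiff(HOUSEKEEPING_GENES, rownames(panel$counts)[hk_rows])
  if (length(missing))
    stopf("missing housekeeping gene(s): %s", paste(missing, collapse = ", "))
  hk <- panel$counts[rownames(panel$counts) %in% HOUSEKEEPING_GENES &
                       panel$probe_class == "housekeeping", , drop = FALSE]
  if (any(hk <= 0))
    stopf("zero housekeeping count: geometric mean undefined")
  f <- norm_factors(hk)
  rows <- panel_rows(panel, c("endogenous", "housekeeping"))
  panel$counts[rows, ] <- panel$counts[rows, , drop = FALSE] *
    rep(f, each = length(rows))
  attr(panel, "housekeeping_factors") <- f
  panel
}

#' Log2 expression from a normalized panel
#'
#' @param panel A thresholded, normalized `nanostring_panel` with all
#'   endogenous counts at least 1.
#' @return Matrix of log2 endogenous expression (genes x samples).
#' @export
log_transform <- function(panel) {
  endo <- panel$counts[panel_rows(panel, "endogenous"), , drop = FALSE]
  if (any(endo < 1))
    stopf("count < 1: background thresholding must precede the log transform")
  log2(endo)
}

#' Run the full normalization chain
#'
#' Background thresholding, positive-control normalization, housekeeping
#' normalization, log2 — in that order.
#'
#' @param panel A `nanostring_panel`.
#' @return Log2 endogenous expression matrix.
#' @export
nanostring_normalize <- function(panel) {
  log_transform(housekeeping_normalize(positive_control_normalize(
    background_threshold(panel))))
}

#' Nearest-centroid subtype assignment
#'
#' Labels each sample with the subtype whose centroid has the highest
#' Pearson correlation to the sample over the signature genes; ties are
#' broken by the class order C1 < C2 < C4 < C5.  This is a pluggable
#' stand-in classifier, not a reconstruction of any published signature.
#'
#' @param expression Log2 expression matrix (genes x samples).
#' @param centroids Matrix of per-subtype mean log2 expression (signature
#'   genes x C1/C2/C4/C5).
#' @return Data frame: `sample`, `label`, per-subtype correlation columns.
#' @export
assign_subtype_labels <- function(expression, centroids) {
  centroids <- as.matrix(centroids)[, SUBTYPE_LEVELS, drop = FALSE]
  genes <- rownames(centroids)
  missing <- setdiff(genes, rownames(expression))
  if (length(missing))
    stopf("missing signature gene(s): %s",
          paste(utils::head(missing, 5L), collapse = ", "))
  expr <- expression[genes, , drop = FALSE]
  cors <- cor(expr, centroids)                    # samples x subtypes
  label <- SUBTYPE_LEVELS[apply(cors, 1L, which.max)]  # first max wins ties
  out <- data.frame(sample = colnames(expression), label = label,
                    cors, row.names = NULL, check.names = FALSE)
  out
}
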