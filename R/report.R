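# Machine-readable run reports.

#' ROC curve coordinates for one class pair
#'
#' False/true positive rates over all score thresholds, restricted to
#' samples of the two classes, scoring on the class-i probability.
#'
#' @param scores Probability matrix (samples x classes).
#' @param labels True labels.
#' @param class_i,class_j The class pair.
#' @return Data frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_coordinates <- function(scores, labels, class_i, class_j) {
  keep <- labels %in% c(class_i, class_j)
  s <- scores[keep, class_i]
  y <- labels[keep] == class_i
  thr <- c(Inf, sort(unique(s), decreasing = TRUE))
  data.frame(threshold = thr,
             fpr = vapply(thr, function(t) mean(s[!y] >= t), 0),
             tpr = vapply(thr, function(t) mean(s[y] >= t), 0))
}

report_json <- function(run) {
  list(config_hash = run$config_hash,
       seed = run$config$seed,
       reference_axis_size = length(run$reference_axis$centers),
       parity = list(n_pairs = nrow(run$mapping$pairs),
                     n_unmatched_reference = length(run$mapping$unmatched_reference),
                     n_unmatched_source = length(run$mapping$unmatched_source)),
       variants = lapply(list(complete = run$complete,
                              stroma_excluded = run$filtered), function(v)
         list(mean_auc = v$report$mean_auc,
              member_auc = v$report$member_auc,
              balanced_accuracy_mean = v$report$balanced_accuracy_mean,
              balanced_accuracy_sd = v$report$balanced_accuracy_sd,
              fdr_macro_mean = v$report$fdr_macro_mean,
              params = unclass(v$params)[c("trees", "features_per_split",
                                           "min_node_size")],
              signature_size = length(v$ensemble$members[[1]]$signature$selected))),
       exclusion = list(n_excluded = sum(run$exclusion$decisions$excluded),
                        n_total = nrow(run$exclusion$decisions)),
       annotation = if (!is.null(run$matches)) attr(run$matches, "summary"))
}

#' Write a pipeline run report to a directory
#'
#' Emits `report.json` (metrics, parameters, provenance), `comparison.csv`
#' (mean AUC with vs without stroma exclusion), `signature.csv` (the
#' filtered variant's first-member signature), `axis.csv` (reference peak
#' axis with occurrence rates), `exclusion_decisions.csv` (the three votes
#' and the consensus flag per spectrum), `pair_auc.csv`, per-pair ROC
#' coordinate CSVs, `matches.csv`, and the config as `config.yaml`.
#'
#' @param run A `pipeline_run`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, `out_dir`.
#' @export
write_report <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_json(run), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.csv(run$comparison, file.path(out_dir, "comparison.csv"),
            row.names = FALSE)
  sig <- run$filtered$ensemble$members[[1]]$signature
  write.csv(data.frame(mz = sig$selected,
                       importance = sig$importance[sprintf("%.4f", sig$selected)]),
            file.path(out_dir, "signature.csv"), row.names = FALSE)
  write.csv(data.frame(center = run$reference_axis$centers,
                       occurrence_rate = run$reference_axis$occurrence),
            file.path(out_dir, "axis.csv"), row.names = FALSE)
  write.csv(run$mapping$pairs, file.path(out_dir, "parity.csv"),
            row.names = FALSE)
  write.csv(run$exclusion$decisions,
            file.path(out_dir, "exclusion_decisions.csv"), row.names = FALSE)
  write.csv(run$filtered$report$pair_auc, file.path(out_dir, "pair_auc.csv"),
            row.names = FALSE)
  if (!is.null(run$matches))
    write.csv(as.data.frame(run$matches), file.path(out_dir, "matches.csv"),
              row.names = FALSE)
  cfg <- rapply(unclass(run$config), function(x)
    if (is.null(x)) NULL else unclass(x), how = "replace")
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}
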