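#' Run the full burden-validation pipeline
#'
#' Convenience wrapper chaining score normalization, retention, gene- and
#' drug-level burden computation, gold-standard construction and stratified
#' ROC evaluation for one or more scoring methods and evaluation modes.
#'
#' @param cohort A `cohort_genotypes` object.
#' @param annotation Annotation data.frame ([read_annotation()]).
#' @param map A `drug_gene_map`.
#' @param catalog VDA catalog data.frame; coding records are removed here
#'   via [filter_noncoding()].
#' @param methods Scoring methods to run (default all six).
#' @param cutoff Retention threshold.
#' @param modes Gold-standard modes to evaluate.
#' @param ethnicity_map Superpopulation -> OMB label mapping.
#' @param strata Stratum types for [evaluate_cohort()].
#' @return List of class `gvb_result` with `summaries` (row-bound
#'   [evaluate_cohort()] output), `per_sample` (per-sample AUC per method and
#'   mode), `drug_burdens` and `gene_profiles` (per method), and
#'   `gold_standards` (per mode).
#' @export
run_gvb_pipeline <- function(cohort, annotation, map, catalog,
                             methods = scoring_method_names(),
                             cutoff = 0.7,
                             modes = c("non_specific", "ethnicity_specific"),
                             ethnicity_map = default_ethnicity_map(),
                             strata = c("all", "superpopulation")) {
  catalog_nc <- suppressMessages(filter_noncoding(catalog))
  gold <- lapply(stats::setNames(modes, modes), function(mode)
    build_gold_standards(cohort, catalog_nc, mode = mode,
                         ethnicity_map = ethnicity_map, map = map))
  gene_profiles <- list()
  drug_burdens <- list()
  summaries <- list()
  per_sample <- list()
  for (m in methods) {
    gp <- gene_burden_profile(cohort, annotation, m, cutoff)
    db <- drug_burden_profile(gp, map)
    gene_profiles[[m]] <- gp
    drug_burdens[[m]] <- db
    for (mode in modes) {
      summaries[[paste(m, mode)]] <-
        evaluate_cohort(db, gold[[mode]], cohort$samples, map = map,
                        strata = strata, method = m)
      ps <- per_sample_auc(db, gold[[mode]])
      ps$method <- m
      ps$mode <- mode
      per_sample[[paste(m, mode)]] <- ps
    }
  }
  structure(list(summaries = do.call(rbind, unname(summaries)),
                 per_sample = do.call(rbind, unname(per_sample)),
                 drug_burdens = drug_burdens,
                 gene_profiles = gene_profiles,
                 gold_standards = gold),
            class = "gvb_result")
}

#' @export
print.gvb_result <- function(x, ...) {
  cat("gvb_result:", length(x$gene_profiles), "method(s),",
      length(x$gold_standards), "mode(s)\n")
  agg <- x$summaries[x$summaries$stratum_type == "all", ]
  print(agg[, c("method", "mode", "n_samples", "auc_mean", "auc_sd")],
        row.names = FALSE)
  invisible(x)
}
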