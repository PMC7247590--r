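#' Rank sensitivity and specificity at a drug-rank threshold
#'
#' With drugs ranked ascending by burden (most deleterious first) and the top
#' `L` drugs called positive, sensitivity is the fraction of gold-standard
#' drugs among the calls, `|D_L intersect GS| / |GS|`, and specificity is
#' `1 - |D_L - GS| / |D - GS|`.
#'
#' @param ranked_drugs Character vector of all drugs, ordered ascending by
#'   burden.
#' @param gs Character vector of gold-standard drugs, or a `gold_standard`
#'   object; must be a nonempty proper subset of `ranked_drugs`.
#' @param L Integer threshold, `0 <= L <= |D|`.
#' @return Named numeric vector `c(sensitivity = , specificity = )`.
#' @export
sensitivity_specificity <- function(ranked_drugs, gs, L) {
  if (inherits(gs, "gold_standard")) gs <- gs$drugs
  gs <- unique(gs)
  check_gs(ranked_drugs, gs)
  if (L < 0 || L > length(ranked_drugs)) {
    stop("L must lie in [0, |D|]", call. = FALSE)
  }
  d_l <- ranked_drugs[seq_len(L)]
  sens <- length(intersect(d_l, gs)) / length(gs)
  spec <- 1 - length(setdiff(d_l, gs)) / (length(ranked_drugs) - length(gs))
  c(sensitivity = sens, specificity = spec)
}

check_gs <- function(drugs, gs) {
  extra <- setdiff(gs, drugs)
  if (length(extra)) {
    stop("gold-standard drug(s) absent from the ranked universe: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  if (length(gs) == 0L) {
    stop("gold standard is empty: sensitivity undefined", call. = FALSE)
  }
  if (length(gs) >= length(unique(drugs))) {
    stop("gold standard equals the drug universe: specificity undefined",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' ROC curve and AUC of a burden ranking against a gold standard
#'
#' Sweeps the distinct burden values ascending (lower burden = predicted
#' positive); drugs tied on burden enter the positive set together at one
#' threshold, so the curve never depends on input order. The AUC is the
#' trapezoidal area over (1 - specificity, sensitivity), identical to the
#' probability that a random gold-standard drug has a strictly lower burden
#' than a random other drug, with ties counted 1/2.
#'
#' @param burdens Named numeric vector drug_id -> burden in \[0,1\].
#' @param gs Gold-standard drugs (character vector or `gold_standard`).
#' @return Object of class `gvb_roc`: list with `points` (data.frame
#'   threshold, sensitivity, specificity; the first row is the empty call
#'   set) and `auc`.
#' @export
roc_auc <- function(burdens, gs) {
  if (inherits(gs, "gold_standard")) gs <- gs$drugs
  gs <- unique(gs)
  drugs <- names(burdens)
  if (is.null(drugs) || anyNA(burdens)) {
    stop("burdens must be a complete named vector", call. = FALSE)
  }
  check_gs(drugs, gs)
  pos <- drugs %in% gs
  thresholds <- sort(unique(burdens))
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  # cumulative TP/FP over tie blocks
  ord <- order(burdens)
  b_sorted <- burdens[ord]
  p_sorted <- pos[ord]
  block <- cumsum(!duplicated(b_sorted))
  tp <- cumsum(p_sorted)
  fp <- cumsum(!p_sorted)
  last <- !duplicated(block, fromLast = TRUE)
  sens <- c(0, tp[last] / n_pos)
  spec <- c(1, 1 - fp[last] / n_neg)
  pts <- data.frame(threshold = c(-Inf, thresholds),
                    sensitivity = sens, specificity = spec)
  x <- 1 - pts$specificity
  y <- pts$sensitivity
  auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  structure(list(points = pts, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "gvb_roc")
}

#' @export
print.gvb_roc <- function(x, ...) {
  cat("gvb_roc: AUC ", format(x$auc, digits = 4), " (", x$n_pos,
      " positives / ", x$n_neg, " negatives, ",
      nrow(x$points) - 1L, " thresholds)\n", sep = "")
  invisible(x)
}

#' Per-sample AUCs for a cohort
#'
#' @param drug_burdens data.frame from [drug_burden_profile()].
#' @param gs_set A `gold_standard_set`.
#' @return data.frame sample_id, auc, n_gs. Samples with an empty gold
#'   standard, a gold standard covering every drug, or excluded for unmapped
#'   ethnicity get `NA` AUC.
#' @export
per_sample_auc <- function(drug_burdens, gs_set) {
  stopifnot(inherits(gs_set, "gold_standard_set"))
  db <- as.data.table(drug_burdens)
  gs_dt <- as.data.table(gs_set$drugs)
  samples <- unique(db$sample_id)
  n_drugs <- length(unique(db$drug_id))
  res <- lapply(samples, function(s) {
    gsd <- gs_dt[sample_id == s, drug_id]
    n_gs <- length(gsd)
    if (s %in% gs_set$excluded_samples || n_gs == 0L || n_gs >= n_drugs) {
      return(data.frame(sample_id = s, auc = NA_real_, n_gs = n_gs))
    }
    b <- db[sample_id == s]
    data.frame(sample_id = s,
               auc = roc_auc(stats::setNames(b$value, b$drug_id), gsd)$auc,
               n_gs = n_gs)
  })
  do.call(rbind, res)
}

#' Cohort evaluation summaries by stratum
#'
#' Computes per-individual AUCs and aggregates their mean and sample
#' standard deviation (n - 1) over requested strata. Only samples with a
#' nonempty (and proper) gold standard enter an aggregate. ATC strata
#' restrict the drug universe to the drugs of one anatomical main group and
#' intersect each gold standard with it. Strata in which no sample is
#' evaluable are reported with `n_samples = 0` and flagged; single-sample
#' strata carry SD 0 and a degenerate flag.
#'
#' @param drug_burdens data.frame from [drug_burden_profile()].
#' @param gs_set A `gold_standard_set`.
#' @param samples Cohort sample sheet (sample_id, population,
#'   superpopulation).
#' @param map `drug_gene_map`; required for ATC strata (supplies the
#'   drug -> letter assignment).
#' @param strata Character vector among `"all"`, `"superpopulation"`,
#'   `"population"`, `"atc"`.
#' @param method Scoring-method label recorded in the output.
#' @return data.frame stratum_type, stratum, mode, method, n_samples,
#'   auc_mean, auc_sd, flag.
#' @export
evaluate_cohort <- function(drug_burdens, gs_set, samples, map = NULL,
                            strata = c("all", "superpopulation"),
                            method = NA_character_) {
  bad <- setdiff(strata, c("all", "superpopulation", "population", "atc"))
  if (length(bad)) {
    stop("unknown stratum type(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  psa <- per_sample_auc(drug_burdens, gs_set)
  psa <- merge(psa, samples, by = "sample_id")
  out <- list()
  summarize <- function(auc, type, label) {
    auc <- auc[!is.na(auc)]
    n <- length(auc)
    data.frame(stratum_type = type, stratum = label, mode = gs_set$mode,
               method = method, n_samples = n,
               auc_mean = if (n) mean(auc) else NA_real_,
               auc_sd = if (n > 1) stats::sd(auc) else if (n == 1) 0 else NA_real_,
               flag = if (n == 0) "no_evaluable_samples"
                      else if (n == 1) "degenerate_stratum" else "")
  }
  if ("all" %in% strata) out <- c(out, list(summarize(psa$auc, "all", "all")))
  for (type in intersect(c("superpopulation", "population"), strata)) {
    for (g in sort(unique(samples[[type]]))) {
      out <- c(out, list(summarize(psa$auc[psa[[type]] == g], type, g)))
    }
  }
  if ("atc" %in% strata) {
    if (is.null(map)) stop("ATC strata require a drug_gene_map", call. = FALSE)
    out <- c(out, list(evaluate_atc(drug_burdens, gs_set, map, gs_set$mode,
                                    method)))
  }
  do.call(rbind, out)
}

evaluate_atc <- function(drug_burdens, gs_set, map, mode, method) {
  atc <- map$atc[!is.na(map$atc)]
  letters_present <- sort(unique(atc))
  db <- as.data.table(drug_burdens)
  gs_dt <- as.data.table(gs_set$drugs)
  rows <- lapply(letters_present, function(letter) {
    drugs_l <- names(atc)[atc == letter]
    db_l <- db[drug_id %in% drugs_l]
    aucs <- c()
    for (s in unique(db_l$sample_id)) {
      if (s %in% gs_set$excluded_samples) next
      gsd <- intersect(gs_dt[sample_id == s, drug_id], drugs_l)
      if (length(gsd) == 0L || length(gsd) >= length(drugs_l)) next
      b <- db_l[sample_id == s]
      aucs <- c(aucs, roc_auc(stats::setNames(b$value, b$drug_id), gsd)$auc)
    }
    n <- length(aucs)
    data.frame(stratum_type = "atc", stratum = letter, mode = mode,
               method = method, n_samples = n,
               auc_mean = if (n) mean(aucs) else NA_real_,
               auc_sd = if (n > 1) stats::sd(aucs) else if (n == 1) 0 else NA_real_,
               flag = if (n == 0) "no_evaluable_samples"
                      else if (n == 1) "degenerate_stratum" else "")
  })
  do.call(rbind, rows)
}

#' Compare cohort-mean gene burdens between gene categories
#'
#' One-sided Mann-Whitney U test of whether the genes of category A have
#' systematically lower cohort-mean burdens than those of category B
#' (alternative: A shifted lower). The compared sets must be disjoint and
#' each contain at least two genes.
#'
#' @param mean_gvb Named numeric vector of cohort-mean gene burdens, as from
#'   [cohort_mean_gene_burden()].
#' @param categories Named list of gene-id character vectors.
#' @param pairs List of `c(name_a, name_b)` pairs to test; default all
#'   ordered pairs of distinct categories.
#' @param method Scoring-method label recorded in the output.
#' @return data.frame category_a, category_b, n_a, n_b, statistic, p_value,
#'   mean_gvb_a, mean_gvb_b, method.
#' @export
compare_gene_categories <- function(mean_gvb, categories, pairs = NULL,
                                    method = NA_character_) {
  if (is.null(pairs)) {
    nm <- names(categories)
    pairs <- list()
    for (a in nm) for (b in nm) if (a != b) pairs <- c(pairs, list(c(a, b)))
  }
  rows <- lapply(pairs, function(p) {
    ga <- intersect(categories[[p[1]]], names(mean_gvb))
    gb <- intersect(categories[[p[2]]], names(mean_gvb))
    if (length(ga) < 2L || length(gb) < 2L) {
      stop("category '", p[which.min(c(length(ga), length(gb)))],
           "' has fewer than 2 genes with burden values", call. = FALSE)
    }
    if (length(intersect(ga, gb))) {
      stop("categories '", p[1], "' and '", p[2],
           "' overlap; compared sets must be disjoint", call. = FALSE)
    }
    wt <- suppressWarnings(
      stats::wilcox.test(mean_gvb[ga], mean_gvb[gb], alternative = "less"))
    data.frame(category_a = p[1], category_b = p[2],
               n_a = length(ga), n_b = length(gb),
               statistic = unname(wt$statistic), p_value = wt$p.value,
               mean_gvb_a = mean(mean_gvb[ga]), mean_gvb_b = mean(mean_gvb[gb]),
               method = method)
  })
  do.call(rbind, rows)
}
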