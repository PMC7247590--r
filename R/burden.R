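#' Gene-wise variant burden of one variant-score multiset
#'
#' The GVB of a gene for one individual is the geometric mean of the
#' normalized deleteriousness scores of the retained nonsynonymous coding
#' variants the individual carries in that gene, and 1 when no variant is
#' retained. Lower values mean a more severely affected gene. Computed in
#' log space for numerical stability; a score of exactly 0 yields 0 (no
#' epsilon flooring).
#'
#' @param scores Numeric vector (possibly empty) of retained normalized
#'   scores, each in \[0,1\].
#' @return A single burden value in \[0,1\].
#' @export
#' @examples
#' gvb_gene(numeric(0))   # 1: unaffected gene
#' gvb_gene(c(0.2, 0.8))  # 0.4
gvb_gene <- function(scores) {
  if (length(scores) == 0L) return(1)
  if (anyNA(scores) || any(scores < 0 | scores > 1)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  if (any(scores == 0)) return(0)
  exp(mean(log(scores)))
}

#' Drug-level variant burden
#'
#' Geometric mean of gene-level burdens over exactly the drug's
#' pharmacokinetic and pharmacodynamic genes, all weighted equally.
#'
#' @param gene_burdens Named numeric vector of gene burdens in \[0,1\]
#'   (1 = unaffected).
#' @param drug_genes Nonempty character vector of the drug's gene ids; each
#'   must have a value in `gene_burdens`.
#' @return A single burden value in \[0,1\].
#' @export
#' @examples
#' gvb_drug(c(A = 0.25, B = 1), c("A", "B"))  # 0.5
gvb_drug <- function(gene_burdens, drug_genes) {
  drug_genes <- unique(drug_genes)
  if (length(drug_genes) == 0L) {
    stop("a drug must have at least one related gene", call. = FALSE)
  }
  missing <- setdiff(drug_genes, names(gene_burdens))
  if (length(missing)) {
    stop("no gene burden for gene(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  gvb_gene(unname(gene_burdens[drug_genes]))
}

#' Per-individual gene burden profile for a cohort
#'
#' Normalizes the raw scores of `method`, applies the deleteriousness
#' retention rule, then computes one gene burden per (sample, gene) pair.
#' Unaffected genes are not materialized (their burden is 1); use
#' [gene_burden_value()] or [gene_burden_matrix()] for dense lookups.
#'
#' @param cohort A `cohort_genotypes` object from [read_vcf()].
#' @param variants Annotation data.frame from [read_annotation()].
#' @param method One of [scoring_method_names()].
#' @param cutoff Retention threshold passed to [retain_deleterious()].
#' @return An object of class `gene_burden_profile`: list with `burdens`
#'   (data.frame sample_id, gene_id, value for affected pairs only),
#'   `samples`, `genes` (the full universes), `method` and `cutoff`.
#' @export
gene_burden_profile <- function(cohort, variants, method, cutoff = 0.7) {
  stopifnot(inherits(cohort, "cohort_genotypes"))
  norm <- normalize_scores(variants, method)
  norm <- norm[!duplicated(names(norm))]
  retained <- retain_deleterious(norm, variants, cutoff)

  ann <- as.data.table(variants)[, c("variant_id", "gene_id"), with = FALSE]
  ann <- ann[variant_id %in% names(retained)]
  ann[, score := retained[variant_id]]

  carried <- carrier_table(cohort)
  long <- merge(carried, ann, by = "variant_id", allow.cartesian = TRUE)
  if (nrow(long)) {
    burdens <- long[, .(value = gvb_gene(score)), by = .(sample_id, gene_id)]
  } else {
    burdens <- data.table(sample_id = character(), gene_id = character(),
                          value = numeric())
  }
  structure(list(burdens = as.data.frame(burdens),
                 samples = cohort$samples$sample_id,
                 genes = sort(unique(variants$gene_id)),
                 method = method, cutoff = cutoff),
            class = "gene_burden_profile")
}

#' @export
print.gene_burden_profile <- function(x, ...) {
  cat("gene_burden_profile [", x$method, ", cutoff ", x$cutoff, "]: ",
      length(x$samples), " samples x ", length(x$genes), " genes, ",
      nrow(x$burdens), " affected pairs\n", sep = "")
  invisible(x)
}

#' @rdname gene_burden_profile
#' @param profile A `gene_burden_profile`.
#' @param sample_id,gene_id Scalar ids to look up.
#' @export
gene_burden_value <- function(profile, sample_id, gene_id) {
  if (!gene_id %in% profile$genes) {
    stop("unknown gene: ", gene_id, call. = FALSE)
  }
  hit <- profile$burdens$sample_id == sample_id &
    profile$burdens$gene_id == gene_id
  if (any(hit)) profile$burdens$value[hit][1] else 1
}

#' @rdname gene_burden_profile
#' @export
gene_burden_matrix <- function(profile) {
  m <- matrix(1, nrow = length(profile$samples), ncol = length(profile$genes),
              dimnames = list(profile$samples, profile$genes))
  b <- profile$burdens
  if (nrow(b)) m[cbind(b$sample_id, b$gene_id)] <- b$value
  m
}

#' Cohort-mean gene burden
#'
#' Mean of the per-individual gene burden over all cohort samples, with
#' unaffected individuals counting as 1. This is the per-gene summary used
#' for gene-category comparisons.
#'
#' @param profile A `gene_burden_profile`.
#' @return Named numeric vector, one mean burden per gene.
#' @export
cohort_mean_gene_burden <- function(profile) {
  n <- length(profile$samples)
  b <- as.data.table(profile$burdens)
  means <- stats::setNames(rep(1, length(profile$genes)), profile$genes)
  if (nrow(b)) {
    agg <- b[, .(s = sum(value), k = .N), by = gene_id]
    means[agg$gene_id] <- (agg$s + (n - agg$k)) / n
  }
  means
}

#' Per-individual drug burden profile
#'
#' Aggregates gene burdens to one burden per (sample, drug) pair by the
#' geometric mean over each drug's gene set (deduplicated across relation
#' types). Drugs whose genes are all unaffected get burden 1. Every gene
#' referenced by the map must exist in the profile's annotation universe.
#'
#' @param profile A `gene_burden_profile`.
#' @param map A `drug_gene_map`.
#' @return data.frame with columns `sample_id`, `drug_id`, `value`, dense
#'   over all samples x drugs.
#' @export
drug_burden_profile <- function(profile, map) {
  stopifnot(inherits(profile, "gene_burden_profile"),
            inherits(map, "drug_gene_map"))
  rel <- unique(as.data.table(map$relations)[, .(drug_id, gene_id)])
  missing <- setdiff(rel$gene_id, profile$genes)
  if (length(missing)) {
    stop("drug-gene map references gene(s) absent from the annotation: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n_genes <- rel[, .(n_genes = .N), by = drug_id]
  b <- as.data.table(profile$burdens)
  dense <- CJ(sample_id = profile$samples, drug_id = n_genes$drug_id)
  if (nrow(b)) {
    hit <- merge(b, rel, by = "gene_id", allow.cartesian = TRUE)
    # log(0) = -Inf propagates to a drug burden of exactly 0
    agg <- hit[, .(log_sum = sum(log(value))), by = .(sample_id, drug_id)]
    agg <- merge(agg, n_genes, by = "drug_id")
    agg[, value := exp(log_sum / n_genes)]
    dense <- merge(dense, agg[, .(sample_id, drug_id, value)],
                   by = c("sample_id", "drug_id"), all.x = TRUE)
  } else {
    dense[, value := NA_real_]
  }
  dense[is.na(value), value := 1]
  as.data.frame(dense[order(sample_id, drug_id)])
}
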