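#' Default superpopulation-to-OMB ethnicity mapping
#'
#' Maps continental superpopulation codes to the OMB ethnicity labels used
#' by variant-drug-association catalogs. AMR is left unmapped by default
#' because admixed American panels have no single OMB label; samples from
#' unmapped superpopulations are excluded (and flagged) from
#' ethnicity-specific evaluation.
#'
#' @return Named character vector superpopulation -> OMB label (`NA` =
#'   unmapped).
#' @export
default_ethnicity_map <- function() {
  c(AFR = "African-American", EAS = "Asian", SAS = "Asian",
    EUR = "Caucasian", AMR = NA_character_)
}

#' Restrict a VDA catalog to noncoding associations
#'
#' Burdens are built from coding variants only, so associations whose variant
#' is itself coding are removed before evaluation to avoid trivial overlap.
#'
#' @param catalog data.frame of VDA records from [read_vda_catalog()].
#' @return The noncoding subset, same columns. Retained/removed counts are
#'   reported via `message()`; an all-coding catalog yields an empty result
#'   with a warning.
#' @export
filter_noncoding <- function(catalog) {
  keep <- catalog$region_class == "noncoding"
  message("VDA catalog: ", sum(keep), " noncoding retained, ",
          sum(!keep), " coding removed")
  if (!any(keep)) {
    warning("no noncoding VDA records remain after filtering", call. = FALSE)
  }
  catalog[keep, , drop = FALSE]
}

#' Build one individual's gold-standard drug set
#'
#' The gold standard of an individual is the set of drugs linked, through a
#' variant the individual carries, to a known variant-drug association. In
#' `ethnicity_specific` mode only associations labeled with the individual's
#' own OMB ethnicity (via `ethnicity_map`) count; associations with no
#' ethnicity label are excluded in that mode (configurable) because same-group
#' membership cannot be asserted for them. In `non_specific` mode all
#' associations count regardless of label.
#'
#' @param sample_id Sample identifier.
#' @param carried_variants Character vector of variant keys the individual
#'   carries.
#' @param superpopulation The individual's superpopulation code.
#' @param catalog Noncoding VDA records (see [filter_noncoding()]).
#' @param mode `"non_specific"` or `"ethnicity_specific"`.
#' @param ethnicity_map Named vector as [default_ethnicity_map()].
#' @param include_unspecified_specific Count unlabeled associations in
#'   ethnicity-specific mode? Default `FALSE`.
#' @return List of class `gold_standard` with `sample_id`, `mode`, `drugs`
#'   (character vector, possibly empty).
#' @export
build_gold_standard <- function(sample_id, carried_variants, superpopulation,
                                catalog, mode = c("non_specific", "ethnicity_specific"),
                                ethnicity_map = default_ethnicity_map(),
                                include_unspecified_specific = FALSE) {
  mode <- match.arg(mode)
  hit <- catalog$variant_id %in% carried_variants
  if (mode == "ethnicity_specific") {
    omb <- unname(ethnicity_map[superpopulation])
    if (is.null(omb) || length(omb) == 0L || is.na(omb)) {
      stop("superpopulation '", superpopulation,
           "' has no OMB ethnicity mapping; sample ", sample_id,
           " must be excluded from ethnicity-specific evaluation",
           call. = FALSE)
    }
    eth_ok <- !is.na(catalog$ethnicity) & catalog$ethnicity == omb
    if (include_unspecified_specific) eth_ok <- eth_ok | is.na(catalog$ethnicity)
    hit <- hit & eth_ok
  }
  structure(list(sample_id = sample_id, mode = mode,
                 drugs = sort(unique(catalog$drug_id[hit]))),
            class = "gold_standard")
}

#' Gold standards for a whole cohort
#'
#' Vectorized construction of per-individual gold standards. Samples whose
#' superpopulation is unmapped under `ethnicity_map` are excluded from
#' ethnicity-specific mode and reported in `excluded_samples` rather than
#' silently dropped. When a `drug_gene_map` is supplied, gold-standard drugs
#' are restricted to drugs present in the map (drugs without burden values
#' cannot be ranked).
#'
#' @inheritParams build_gold_standard
#' @param cohort A `cohort_genotypes` object.
#' @param map Optional `drug_gene_map` restricting the drug universe.
#' @return Object of class `gold_standard_set`: list with `drugs`
#'   (data.frame sample_id, drug_id), `mode`, `excluded_samples` (unmapped
#'   superpopulation under ethnicity-specific mode).
#' @export
build_gold_standards <- function(cohort, catalog,
                                 mode = c("non_specific", "ethnicity_specific"),
                                 ethnicity_map = default_ethnicity_map(),
                                 map = NULL,
                                 include_unspecified_specific = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(cohort, "cohort_genotypes"))
  samples <- cohort$samples
  excluded <- character()
  if (mode == "ethnicity_specific") {
    omb <- ethnicity_map[samples$superpopulation]
    unmapped <- is.na(omb) | is.na(names(omb))
    excluded <- samples$sample_id[unmapped]
  }
  cat_dt <- as.data.table(catalog)
  if (!is.null(map)) {
    cat_dt <- cat_dt[drug_id %in% unique(map$relations$drug_id)]
  }
  carried <- carrier_table(cohort)
  long <- merge(carried, cat_dt, by = "variant_id", allow.cartesian = TRUE)
  long <- merge(long, as.data.table(samples), by = "sample_id")
  if (mode == "ethnicity_specific") {
    long <- long[!sample_id %in% excluded]
    long[, omb := unname(default_or(ethnicity_map, superpopulation))]
    keep <- !is.na(long$ethnicity) & long$ethnicity == long$omb
    if (include_unspecified_specific) keep <- keep | is.na(long$ethnicity)
    long <- long[keep]
  }
  drugs <- unique(long[, .(sample_id, drug_id)])
  structure(list(drugs = as.data.frame(drugs[order(sample_id, drug_id)]),
                 mode = mode, excluded_samples = excluded),
            class = "gold_standard_set")
}

default_or <- function(map, keys) {
  out <- map[keys]
  names(out) <- keys
  out
}

#' @export
print.gold_standard_set <- function(x, ...) {
  cat("gold_standard_set [", x$mode, "]: ",
      length(unique(x$drugs$sample_id)), " samples with >=1 drug, ",
      nrow(x$drugs), " (sample, drug) pairs",
      if (length(x$excluded_samples)) paste0("; ", length(x$excluded_samples),
                                             " samples excluded (unmapped ethnicity)"),
      "\n", sep = "")
  invisible(x)
}

#' @rdname build_gold_standards
#' @param gs_set A `gold_standard_set`.
#' @param path Output TSV path (sample_id, mode, drug_id).
#' @export
write_gold_standards <- function(gs_set, path) {
  out <- data.frame(sample_id = gs_set$drugs$sample_id,
                    mode = gs_set$mode,
                    drug_id = gs_set$drugs$drug_id)
  write_tsv(out, path)
}
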