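#' @importFrom data.table data.table := .N .SD setDT setnames as.data.table rbindlist CJ
NULL

CONSEQUENCES <- c("nonsynonymous_coding", "synonymous_coding", "noncoding")
RELATION_TYPES <- c("enzyme", "transporter", "carrier", "target")
ATC_LETTERS <- c("A", "B", "C", "D", "G", "H", "J", "L", "M", "N", "P", "R", "S", "V")

read_tsv_strict <- function(path, required, label) {
  if (!file.exists(path)) {
    stop(label, " file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          na.strings = c(".", "", "NA"),
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(label, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = ".",
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read cohort genotypes from a VCF and a sample sheet
#'
#' Parses a VCF 4.x file (only the GT field is used) into per-variant carrier
#' sets. A sample carries a variant allele iff at least one ALT allele of the
#' matching index appears in its genotype; het/hom state is deliberately
#' collapsed to presence/absence, since the burden model is defined over
#' variant sets without dosage. Multiallelic records are decomposed into one
#' variant key per ALT allele. Variant keys are the VCF ID (rsID) when present
#' on a biallelic record, otherwise `chrom:pos:ref:alt` (1-based).
#'
#' @param path Path to an uncompressed or bgzipped VCF.
#' @param sample_sheet Path to a tab-delimited sheet with columns
#'   `sample_id`, `population`, `superpopulation` covering every VCF sample.
#' @return An object of class `cohort_genotypes`: a list with `samples`
#'   (data.frame of sample_id, population, superpopulation) and `carriers`
#'   (named list: variant key -> character vector of carrier sample ids).
#' @export
read_vcf <- function(path, sample_sheet) {
  sheet <- read_tsv_strict(sample_sheet,
                           c("sample_id", "population", "superpopulation"),
                           "sample sheet")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  vcf_samples <- colnames(gt)
  unknown <- setdiff(vcf_samples, sheet$sample_id)
  if (length(unknown)) {
    stop("sample(s) in VCF but not in sample sheet: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  carriers <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    alleles <- strsplit(gt[i, ], "[/|]")
    for (k in seq_along(alts)) {
      key <- variant_key(fix[i, "ID"], fix[i, "CHROM"], fix[i, "POS"],
                         fix[i, "REF"], alts[k],
                         multiallelic = length(alts) > 1L)
      hit <- vapply(alleles, function(a) any(a == as.character(k)), logical(1))
      carriers[[key]] <- unique(c(carriers[[key]], vcf_samples[hit]))
    }
  }
  structure(list(samples = sheet[, c("sample_id", "population", "superpopulation")],
                 carriers = carriers),
            class = "cohort_genotypes")
}

variant_key <- function(id, chrom, pos, ref, alt, multiallelic = FALSE) {
  if (!multiallelic && !is.na(id) && nzchar(id) && id != ".") id
  else paste(chrom, pos, ref, alt, sep = ":")
}

#' @export
print.cohort_genotypes <- function(x, ...) {
  cat("cohort_genotypes:", nrow(x$samples), "samples,",
      length(x$carriers), "variant keys\n")
  invisible(x)
}

#' Long (variant, sample) carrier table
#' @param cohort A `cohort_genotypes` object.
#' @return data.table with columns `variant_id`, `sample_id`.
#' @keywords internal
carrier_table <- function(cohort) {
  n <- lengths(cohort$carriers)
  data.table(variant_id = rep(names(cohort$carriers), n) %||% character(),
             sample_id = as.character(unlist(cohort$carriers,
                                             use.names = FALSE) %||% character()))
}

#' Read a variant annotation table
#'
#' Reads the tab-delimited annotation mapping variant alleles to genes,
#' consequence classes and raw scores of the six scoring methods. Cells that
#' cannot be parsed as numbers are treated as absent scores (the variant is
#' kept). One row describes one (variant, gene) pair; a variant overlapping
#' two genes appears as two rows.
#'
#' @param path Path to the TSV. Required columns: `variant_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `gene_id`, `consequence`, plus one column per
#'   method in [scoring_method_names()]. `.` or empty = missing.
#' @return data.frame of annotated variants.
#' @export
read_annotation <- function(path) {
  req <- c("variant_id", "chrom", "pos", "ref", "alt", "gene_id",
           "consequence", scoring_method_names())
  df <- read_tsv_strict(path, req, "annotation")
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  for (m in scoring_method_names()) {
    df[[m]] <- suppressWarnings(as.numeric(df[[m]]))
  }
  validate_annotation(df)
}

validate_annotation <- function(df) {
  bad <- setdiff(unique(df$consequence), CONSEQUENCES)
  if (length(bad)) {
    stop("unknown consequence value(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(CONSEQUENCES, collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(df[, c("variant_id", "gene_id")])
  if (any(dup)) {
    stop("duplicate (variant_id, gene_id) annotation row(s), e.g. ",
         df$variant_id[dup][1], " / ", df$gene_id[dup][1], call. = FALSE)
  }
  if (any(df$pos < 1L, na.rm = TRUE)) stop("pos must be >= 1", call. = FALSE)
  same <- !is.na(df$ref) & !is.na(df$alt) & df$ref == df$alt
  if (any(same)) stop("ref and alt must differ (", df$variant_id[same][1], ")",
                      call. = FALSE)
  df
}

#' @rdname read_annotation
#' @param variants Annotation data.frame to write.
#' @export
write_annotation <- function(variants, path) {
  write_tsv(variants, path)
}

#' Read a drug-gene relation map
#'
#' Relations of type enzyme, transporter or carrier are pharmacokinetic;
#' targets are pharmacodynamic. Relation types are carried for reporting but
#' never weight the burden aggregation; genes listed under several relation
#' types for one drug count once (set semantics).
#'
#' @param path TSV with columns `drug_id`, `gene_id`, `relation_type` and
#'   optionally `atc_main_group` (single ATC anatomical main-group letter).
#' @return An object of class `drug_gene_map`: list with `relations`
#'   (data.frame drug_id, gene_id, relation_type) and `atc` (named character
#'   vector drug_id -> letter, `NA` when unknown).
#' @export
read_drug_gene_map <- function(path) {
  df <- read_tsv_strict(path, c("drug_id", "gene_id", "relation_type"),
                        "drug-gene map")
  if (!"atc_main_group" %in% names(df)) df$atc_main_group <- NA_character_
  drug_gene_map(df)
}

#' @rdname read_drug_gene_map
#' @param relations data.frame with the same columns, built in code.
#' @export
drug_gene_map <- function(relations) {
  bad <- setdiff(unique(relations$relation_type), RELATION_TYPES)
  if (length(bad)) {
    stop("unknown relation_type value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  atc_vals <- relations$atc_main_group
  bad_atc <- setdiff(atc_vals[!is.na(atc_vals)], ATC_LETTERS)
  if (length(bad_atc)) {
    stop("unknown ATC main-group letter(s): ", paste(bad_atc, collapse = ", "),
         call. = FALSE)
  }
  rel <- unique(relations[, c("drug_id", "gene_id", "relation_type")])
  atc <- tapply(atc_vals, relations$drug_id, function(x) {
    u <- unique(x[!is.na(x)])
    if (length(u) > 1L) stop("conflicting ATC letters for one drug", call. = FALSE)
    if (length(u)) u else NA_character_
  })
  structure(list(relations = rel,
                 atc = stats::setNames(as.character(atc), names(atc))),
            class = "drug_gene_map")
}

#' @export
print.drug_gene_map <- function(x, ...) {
  cat("drug_gene_map:", length(unique(x$relations$drug_id)), "drugs,",
      length(unique(x$relations$gene_id)), "genes,",
      nrow(x$relations), "relations\n")
  invisible(x)
}

#' @rdname read_drug_gene_map
#' @param map A `drug_gene_map` to write back to TSV.
#' @export
write_drug_gene_map <- function(map, path) {
  df <- map$relations
  df$atc_main_group <- unname(map$atc[df$drug_id])
  write_tsv(df, path)
}

#' Read a variant-drug-association catalog
#'
#' One row links one variant to one drug-response association, classed as
#' coding or noncoding, with an optional OMB ethnicity label
#' (e.g. African-American, Asian, Caucasian); missing label = unspecified.
#' Exactly duplicated rows are dropped.
#'
#' @param path TSV with columns `variant_id`, `drug_id`, `region_class` and
#'   optionally `ethnicity`.
#' @return data.frame of VDA records.
#' @export
read_vda_catalog <- function(path) {
  df <- read_tsv_strict(path, c("variant_id", "drug_id", "region_class"),
                        "VDA catalog")
  if (!"ethnicity" %in% names(df)) df$ethnicity <- NA_character_
  bad <- setdiff(unique(df$region_class), c("coding", "noncoding"))
  if (length(bad)) {
    stop("unknown region_class value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unique(df[, c("variant_id", "drug_id", "region_class", "ethnicity")])
}

#' @rdname read_vda_catalog
#' @param catalog data.frame of VDA records to write.
#' @export
write_vda_catalog <- function(catalog, path) {
  write_tsv(catalog, path)
}

#' Write burdens in long format
#'
#' @param burdens data.frame with sample_id, an entity id column and `value`.
#' @param path Output TSV path.
#' @param method Scoring method label recorded in the `method` column.
#' @export
write_burdens <- function(burdens, path, method) {
  id_col <- intersect(c("gene_id", "drug_id"), names(burdens))[1]
  out <- data.frame(sample_id = burdens$sample_id,
                    entity_id = burdens[[id_col]],
                    method = method,
                    gvb = burdens$value)
  write_tsv(out, path)
}
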