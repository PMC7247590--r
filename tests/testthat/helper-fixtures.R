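# Independent oracles and tiny in-code fixtures shared across test files.

# naive product-then-root geometric mean (reference for the log-space path)
oracle_gm <- function(x) {
  if (length(x) == 0L) return(1)
  prod(x)^(1 / length(x))
}

# all-pairs concordance AUC with ties counted 1/2; positives are drugs whose
# burden should be LOW
oracle_auc <- function(burdens, positives) {
  pos <- burdens[names(burdens) %in% positives]
  neg <- burdens[!names(burdens) %in% positives]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p < n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

toy_annotation <- function() {
  data.frame(
    variant_id = c("rs1", "rs2", "rs3", "rs4", "rs5"),
    chrom = "chr1", pos = c(100L, 200L, 300L, 400L, 500L),
    ref = "A", alt = "G",
    gene_id = c("GENE1", "GENE1", "GENE2", "GENE2", "GENE3"),
    consequence = c("nonsynonymous_coding", "nonsynonymous_coding",
                    "nonsynonymous_coding", "synonymous_coding", "noncoding"),
    SIFT = c(0.03, 0.5, 0.9, 0.1, NA),
    MutationTaster = c(0.99, 0.4, 0.05, 0.8, NA),
    PolyPhen2_HDIV = c(1.0, 0.6, 0.1, 0.5, NA),
    PolyPhen2_HVAR = c(0.97, 0.55, 0.2, 0.5, NA),
    phyloP = c(7.5, 2.0, -1.0, 0.5, NA),
    GERPpp = c(6, 2, -2, 1, NA),
    stringsAsFactors = FALSE)
}

toy_cohort <- function(carriers = list(),
                       samples = data.frame(
                         sample_id = c("A1", "A2", "A3"),
                         population = c("p1", "p1", "p2"),
                         superpopulation = c("AFR", "AFR", "EUR"),
                         stringsAsFactors = FALSE)) {
  structure(list(samples = samples, carriers = carriers),
            class = "cohort_genotypes")
}

# 3-sample VCF with one biallelic and one triallelic record
write_toy_vcf <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  vcf <- file.path(dir, "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "A1", "A2", "A3", sep = "\t"),
    paste("chr1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/1", "0/0", "1/1", sep = "\t"),
    paste("chr1", "200", "rs2", "A", "C,T", ".", "PASS", ".", "GT",
          "0/1", "1/2", "2/2", sep = "\t")), vcf)
  sheet <- file.path(dir, "samples.tsv")
  writeLines(c("sample_id\tpopulation\tsuperpopulation",
               "A1\tp1\tAFR", "A2\tp1\tAFR", "A3\tp2\tEUR"), sheet)
  list(vcf = vcf, sheet = sheet)
}

toy_vda <- function() {
  data.frame(
    variant_id = c("rs1", "rs1", "rs2", "rs3", "rs9"),
    drug_id = c("d1", "d2", "d3", "d1", "d4"),
    region_class = c("noncoding", "noncoding", "noncoding", "coding",
                     "noncoding"),
    ethnicity = c("Caucasian", NA, "Asian", NA, "African-American"),
    stringsAsFactors = FALSE)
}

fixture_path <- function(...) {
  system.file("extdata", "fixture", ..., package = "gvburden", mustWork = TRUE)
}
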