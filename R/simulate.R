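#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the parameter set controlling [simulate_cohort()].
#' The defaults describe a desk-scale analogue of the study design the
#' pipeline targets: a population-structured cohort, pharmacogenes carrying
#' a mixture of benign and deleterious nonsynonymous variants scored by six
#' correlated in-silico methods, a bipartite drug-gene map with ATC letters,
#' and a variant-drug-association catalog in which planted noncoding markers
#' tag deleterious coding variants in the associated drug's genes (the
#' synthetic-association mechanism), alongside unlinked noise associations.
#'
#' @param seed Integer seed; fully determines every output.
#' @param n_individuals Cohort size.
#' @param populations data.frame with `label`, `superpopulation`,
#'   `proportion` (proportions sum to 1).
#' @param n_genes Number of genes; the first
#'   `round(core_gene_fraction * n_genes)` form a planted low-burden "core"
#'   pharmacogene category.
#' @param core_gene_fraction Fraction of genes in the core category.
#' @param core_common_variants Number of guaranteed common deleterious
#'   variants planted in every core gene (emulating the common functional
#'   polymorphism of core ADME pharmacogenes).
#' @param core_common_freq Allele-frequency range of those planted common
#'   variants.
#' @param variants_per_gene Poisson mean of background nonsynonymous
#'   variants per gene (at least 1 drawn).
#' @param synonymous_per_gene Synonymous variants per gene (scored but never
#'   burden-eligible).
#' @param allele_freq List: `shape1`, `shape2` of the Beta distribution of
#'   global allele frequencies and `pop_sd`, the SD of the per-population
#'   logit perturbation.
#' @param deleterious_fraction Probability a background variant is
#'   deleterious (core genes use `core_deleterious_fraction`).
#' @param core_deleterious_fraction Deleterious fraction inside core genes.
#' @param score_model List: Beta parameters of the background deleterious
#'   (`del_shape1/2`, moderate mass near 0.2), benign (`ben_shape1/2`, mass
#'   near 1) and planted-causal (`causal_shape1/2`, mass near 0.05) latent
#'   score components; `method_gamma`, per-method monotone power
#'   distortions; `jitter_sd`, per-method score noise; `missing_rate`,
#'   fraction of non-SIFT scores dropped; `phyloP_range`/`gerp_range`,
#'   native placement of the unbounded conservation scores.
#' @param n_drugs Number of drugs.
#' @param genes_per_drug Poisson mean of extra genes per drug beyond the
#'   first.
#' @param n_planted_vdas Noncoding marker associations tagging a deleterious
#'   coding variant in one gene of the associated drug.
#' @param fraction_ethnicity_specific Fraction of planted associations
#'   confined to one population (marker and causal frequency elevated only
#'   there; the association record carries that population's OMB label).
#' @param linkage_fidelity Probability that a marker carrier (in the target
#'   population, for ethnicity-specific plantings) also carries the causal
#'   coding variant. 0 makes planted associations indistinguishable from
#'   noise.
#' @param marker_freq Range (min, max) of marker allele frequencies.
#' @param ethnic_marker_freq Range of marker frequencies in the target
#'   population of ethnicity-specific plantings.
#' @param offtarget_marker_freq Marker frequency outside the target
#'   population (carriers there get no causal coupling).
#' @param causal_background_freq Carrier probability of a causal variant
#'   outside the marker coupling.
#' @param n_noise_vdas Noncoding associations with no coding linkage.
#' @param n_coding_vdas Coding-region associations (removed by
#'   [filter_noncoding()]).
#' @return Validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_individuals = 200L,
                             populations = data.frame(
                               label = c("pop_a", "pop_b", "pop_c"),
                               superpopulation = c("AFR", "EAS", "EUR"),
                               proportion = c(1 / 3, 1 / 3, 1 / 3)),
                             n_genes = 30L,
                             core_gene_fraction = 0.2,
                             core_common_variants = 3L,
                             core_common_freq = c(0.15, 0.3),
                             variants_per_gene = 8,
                             synonymous_per_gene = 2L,
                             allele_freq = list(shape1 = 0.6, shape2 = 12,
                                                pop_sd = 0.5),
                             deleterious_fraction = 0.15,
                             core_deleterious_fraction = 0.5,
                             score_model = list(del_shape1 = 4, del_shape2 = 18,
                                                ben_shape1 = 30, ben_shape2 = 2,
                                                causal_shape1 = 2,
                                                causal_shape2 = 38,
                                                method_gamma = c(
                                                  SIFT = 1, MutationTaster = 0.85,
                                                  PolyPhen2_HDIV = 1.15,
                                                  PolyPhen2_HVAR = 0.9,
                                                  phyloP = 1.1, GERPpp = 1),
                                                jitter_sd = 0.02,
                                                missing_rate = 0.02,
                                                phyloP_range = c(-5, 10),
                                                gerp_range = c(-8, 6.2)),
                             n_drugs = 60L,
                             genes_per_drug = 1.2,
                             n_planted_vdas = 30L,
                             fraction_ethnicity_specific = 0,
                             linkage_fidelity = 1,
                             marker_freq = c(0.08, 0.2),
                             ethnic_marker_freq = c(0.15, 0.3),
                             offtarget_marker_freq = 0.01,
                             causal_background_freq = 0.01,
                             n_noise_vdas = 8L,
                             n_coding_vdas = 5L) {
  cfg <- list(seed = as.integer(seed), n_individuals = as.integer(n_individuals),
              populations = populations, n_genes = as.integer(n_genes),
              core_gene_fraction = core_gene_fraction,
              core_common_variants = as.integer(core_common_variants),
              core_common_freq = core_common_freq,
              variants_per_gene = variants_per_gene,
              synonymous_per_gene = as.integer(synonymous_per_gene),
              allele_freq = allele_freq,
              deleterious_fraction = deleterious_fraction,
              core_deleterious_fraction = core_deleterious_fraction,
              score_model = score_model, n_drugs = as.integer(n_drugs),
              genes_per_drug = genes_per_drug,
              n_planted_vdas = as.integer(n_planted_vdas),
              fraction_ethnicity_specific = fraction_ethnicity_specific,
              linkage_fidelity = linkage_fidelity,
              marker_freq = marker_freq,
              ethnic_marker_freq = ethnic_marker_freq,
              offtarget_marker_freq = offtarget_marker_freq,
              causal_background_freq = causal_background_freq,
              n_noise_vdas = as.integer(n_noise_vdas),
              n_coding_vdas = as.integer(n_coding_vdas))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  if (abs(sum(cfg$populations$proportion) - 1) > 1e-8) {
    stop("population proportions must sum to 1", call. = FALSE)
  }
  fracs <- c(cfg$core_gene_fraction, cfg$deleterious_fraction,
             cfg$core_deleterious_fraction, cfg$fraction_ethnicity_specific,
             cfg$linkage_fidelity)
  if (any(fracs < 0 | fracs > 1)) {
    stop("all fractions and probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_planted_vdas + cfg$n_noise_vdas > cfg$n_drugs) {
    stop("infeasible config: n_planted_vdas + n_noise_vdas (",
         cfg$n_planted_vdas + cfg$n_noise_vdas,
         ") exceeds n_drugs (", cfg$n_drugs, ")", call. = FALSE)
  }
  if (cfg$n_individuals < 2L || cfg$n_genes < 2L || cfg$n_drugs < 2L) {
    stop("need at least 2 individuals, genes and drugs", call. = FALSE)
  }
  invisible(cfg)
}

clamp01 <- function(x, eps = 1e-6) pmin(pmax(x, eps), 1 - eps)

#' Simulate a full synthetic input bundle
#'
#' Generates, deterministically from `config$seed`, the five inputs the
#' pipeline consumes plus the planted truth: cohort genotypes, sample sheet,
#' variant annotation with six correlated raw scores, a drug-gene relation
#' map with ATC letters, and a VDA catalog in which planted noncoding markers
#' tag deleterious coding variants with probability `linkage_fidelity`.
#'
#' @param config A `synthetic_config`.
#' @return Object of class `gvb_simulation`: list with `config`, `samples`,
#'   `annotation`, `genotypes` (variant x sample allele-count matrix),
#'   `drug_map` (a `drug_gene_map`), `vda` (VDA catalog data.frame) and
#'   `truth` (planted associations and the core gene set).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_synthetic_config(config)
  set.seed(config$seed)
  cfg <- config

  ## --- samples ---------------------------------------------------------
  n_pop <- nrow(cfg$populations)
  counts <- diff(c(0, round(cumsum(cfg$populations$proportion) *
                              cfg$n_individuals)))
  samples <- data.frame(
    sample_id = sprintf("S%04d", seq_len(cfg$n_individuals)),
    population = rep(cfg$populations$label, counts),
    superpopulation = rep(cfg$populations$superpopulation, counts),
    stringsAsFactors = FALSE)

  ## --- genes -----------------------------------------------------------
  genes <- sprintf("G%03d", seq_len(cfg$n_genes))
  n_core <- round(cfg$core_gene_fraction * cfg$n_genes)
  core_genes <- genes[seq_len(n_core)]

  ## --- background variants --------------------------------------------
  sm <- cfg$score_model
  new_variant <- local({
    counter <- 0L
    function(gene, consequence, latent, freq = NA_real_) {
      counter <<- counter + 1L
      data.frame(variant_id = sprintf("rs%06d", counter),
                 chrom = paste0("chr", (match(gene, genes) - 1L) %% 3L + 1L),
                 pos = 100000L + match(gene, genes) * 10000L + counter * 7L,
                 ref = "A", alt = "G", gene_id = gene,
                 consequence = consequence, latent = latent,
                 freq_override = freq, stringsAsFactors = FALSE)
    }
  })
  rows <- list()
  for (g in genes) {
    frac <- if (g %in% core_genes) cfg$core_deleterious_fraction
            else cfg$deleterious_fraction
    if (g %in% core_genes) {
      # planted common functional polymorphism of the core category
      for (i in seq_len(cfg$core_common_variants)) {
        latent <- stats::rbeta(1, sm$del_shape1, sm$del_shape2)
        freq <- stats::runif(1, cfg$core_common_freq[1],
                             cfg$core_common_freq[2])
        rows <- c(rows, list(new_variant(g, "nonsynonymous_coding", latent,
                                         freq)))
      }
    }
    n_v <- max(1L, stats::rpois(1, cfg$variants_per_gene))
    for (i in seq_len(n_v)) {
      del <- stats::runif(1) < frac
      latent <- if (del) stats::rbeta(1, sm$del_shape1, sm$del_shape2)
                else stats::rbeta(1, sm$ben_shape1, sm$ben_shape2)
      rows <- c(rows, list(new_variant(g, "nonsynonymous_coding", latent)))
    }
    for (i in seq_len(cfg$synonymous_per_gene)) {
      latent <- stats::rbeta(1, sm$ben_shape1, sm$ben_shape2)
      rows <- c(rows, list(new_variant(g, "synonymous_coding", latent)))
    }
  }
  variants <- do.call(rbind, rows)

  ## per-population allele frequencies, genotypes
  p0 <- stats::rbeta(nrow(variants), cfg$allele_freq$shape1,
                     cfg$allele_freq$shape2)
  p0 <- ifelse(is.na(variants$freq_override), p0, variants$freq_override)
  p_pop <- matrix(NA_real_, nrow(variants), n_pop)
  for (k in seq_len(n_pop)) {
    p_pop[, k] <- clamp01(stats::plogis(
      stats::qlogis(clamp01(p0, 1e-4)) +
        stats::rnorm(nrow(variants), 0, cfg$allele_freq$pop_sd)), 1e-4)
  }
  variants$freq_override <- NULL
  pop_index <- match(samples$population, cfg$populations$label)
  genotypes <- matrix(0L, nrow(variants), cfg$n_individuals,
                      dimnames = list(variants$variant_id, samples$sample_id))
  for (k in seq_len(n_pop)) {
    idx <- which(pop_index == k)
    genotypes[, idx] <- stats::rbinom(nrow(variants) * length(idx), 2L,
                                      rep(p_pop[, k], length(idx)))
  }

  ## --- drug-gene map ---------------------------------------------------
  drugs <- sprintf("D%03d", seq_len(cfg$n_drugs))
  rel_rows <- list()
  drug_genes <- list()
  for (d in drugs) {
    n_g <- min(cfg$n_genes, 1L + stats::rpois(1, cfg$genes_per_drug))
    gs <- sample(genes, n_g)
    drug_genes[[d]] <- gs
    rel_rows[[d]] <- data.frame(
      drug_id = d, gene_id = gs,
      relation_type = sample(RELATION_TYPES, n_g, replace = TRUE),
      atc_main_group = sample(ATC_LETTERS, 1L),
      stringsAsFactors = FALSE)
  }
  drug_map <- drug_gene_map(do.call(rbind, rel_rows))

  ## --- planted and noise VDAs -----------------------------------------
  vda_drugs <- sample(drugs, cfg$n_planted_vdas + cfg$n_noise_vdas)
  planted_drugs <- vda_drugs[seq_len(cfg$n_planted_vdas)]
  noise_drugs <- setdiff(vda_drugs, planted_drugs)
  eth_labels <- default_ethnicity_map()[cfg$populations$superpopulation]

  marker_rows <- list()
  causal_rows <- list()
  marker_gt <- list()
  causal_gt <- list()
  truth_rows <- list()
  mcount <- 0L
  for (d in planted_drugs) {
    mcount <- mcount + 1L
    ethnic <- stats::runif(1) < cfg$fraction_ethnicity_specific
    target_pop <- if (ethnic) sample(seq_len(n_pop), 1L) else NA_integer_
    gene <- sample(drug_genes[[d]], 1L)
    causal_latent <- stats::rbeta(1, sm$causal_shape1, sm$causal_shape2)

    marker_id <- sprintf("rsM%05d", mcount)
    causal_id <- sprintf("rsC%05d", mcount)
    marker_rows[[mcount]] <- data.frame(
      variant_id = marker_id, chrom = "chrX",
      pos = 5000000L + mcount * 100L, ref = "C", alt = "T",
      gene_id = gene, consequence = "noncoding", latent = NA_real_,
      stringsAsFactors = FALSE)
    causal_rows[[mcount]] <- data.frame(
      variant_id = causal_id,
      chrom = paste0("chr", (match(gene, genes) - 1L) %% 3L + 1L),
      pos = 100000L + match(gene, genes) * 10000L + 9000L + mcount,
      ref = "G", alt = "C", gene_id = gene,
      consequence = "nonsynonymous_coding", latent = causal_latent,
      stringsAsFactors = FALSE)

    if (ethnic) {
      p_m <- ifelse(pop_index == target_pop,
                    stats::runif(1, cfg$ethnic_marker_freq[1],
                                 cfg$ethnic_marker_freq[2]),
                    cfg$offtarget_marker_freq)
    } else {
      p_m <- rep(stats::runif(1, cfg$marker_freq[1], cfg$marker_freq[2]),
                 cfg$n_individuals)
    }
    m_gt <- stats::rbinom(cfg$n_individuals, 2L, p_m)
    c_gt <- stats::rbinom(cfg$n_individuals, 2L,
                          cfg$causal_background_freq / 2)
    in_scope <- if (ethnic) pop_index == target_pop else rep(TRUE, cfg$n_individuals)
    couple <- m_gt > 0L & in_scope &
      stats::runif(cfg$n_individuals) < cfg$linkage_fidelity
    c_gt[couple] <- m_gt[couple]
    marker_gt[[mcount]] <- m_gt
    causal_gt[[mcount]] <- c_gt
    truth_rows[[mcount]] <- data.frame(
      marker_id = marker_id, causal_id = causal_id, drug_id = d,
      gene_id = gene,
      ethnicity = if (ethnic) unname(eth_labels[target_pop]) else NA_character_,
      target_population = if (ethnic) cfg$populations$label[target_pop]
                          else NA_character_,
      linkage_fidelity = cfg$linkage_fidelity,
      causal_latent = causal_latent, stringsAsFactors = FALSE)
  }

  noise_marker_rows <- list()
  noise_gt <- list()
  for (i in seq_along(noise_drugs)) {
    noise_marker_rows[[i]] <- data.frame(
      variant_id = sprintf("rsN%05d", i), chrom = "chrX",
      pos = 6000000L + i * 100L, ref = "G", alt = "A",
      gene_id = sample(genes, 1L), consequence = "noncoding",
      latent = NA_real_, stringsAsFactors = FALSE)
    p_m <- stats::runif(1, cfg$marker_freq[1], cfg$marker_freq[2])
    noise_gt[[i]] <- stats::rbinom(cfg$n_individuals, 2L, p_m)
  }

  extra_variants <- rbindlist(c(marker_rows, causal_rows, noise_marker_rows))
  extra_gt <- do.call(rbind, c(marker_gt, causal_gt, noise_gt))
  if (!is.null(extra_gt)) {
    rownames(extra_gt) <- extra_variants$variant_id
    colnames(extra_gt) <- samples$sample_id
    variants <- rbind(variants, as.data.frame(extra_variants))
    genotypes <- rbind(genotypes, extra_gt)
  }

  ## --- VDA catalog -----------------------------------------------------
  truth <- rbindlist(truth_rows)
  vda <- data.frame(variant_id = character(), drug_id = character(),
                    region_class = character(), ethnicity = character(),
                    stringsAsFactors = FALSE)
  if (nrow(truth)) {
    vda <- rbind(vda, data.frame(variant_id = truth$marker_id,
                                 drug_id = truth$drug_id,
                                 region_class = "noncoding",
                                 ethnicity = truth$ethnicity,
                                 stringsAsFactors = FALSE))
  }
  if (length(noise_drugs)) {
    vda <- rbind(vda, data.frame(
      variant_id = sprintf("rsN%05d", seq_along(noise_drugs)),
      drug_id = noise_drugs, region_class = "noncoding",
      ethnicity = NA_character_, stringsAsFactors = FALSE))
  }
  if (cfg$n_coding_vdas > 0L) {
    coding_pool <- variants$variant_id[variants$consequence ==
                                         "nonsynonymous_coding"]
    vda <- rbind(vda, data.frame(
      variant_id = sample(coding_pool, cfg$n_coding_vdas),
      drug_id = sample(drugs, cfg$n_coding_vdas, replace = TRUE),
      region_class = "coding", ethnicity = NA_character_,
      stringsAsFactors = FALSE))
  }

  ## --- raw scores ------------------------------------------------------
  annotation <- variants[, c("variant_id", "chrom", "pos", "ref", "alt",
                             "gene_id", "consequence")]
  coding <- variants$consequence != "noncoding"
  latent <- variants$latent
  for (m in scoring_method_names()) {
    gamma <- sm$method_gamma[[m]]
    d_m <- rep(NA_real_, nrow(variants))
    d_m[coding] <- pmin(pmax(
      clamp01(latent[coding])^gamma +
        stats::rnorm(sum(coding), 0, sm$jitter_sd), 0), 1)
    raw <- switch(m,
      SIFT = d_m,
      MutationTaster = 1 - d_m,
      PolyPhen2_HDIV = 1 - d_m,
      PolyPhen2_HVAR = 1 - d_m,
      phyloP = sm$phyloP_range[1] +
        (1 - d_m) * diff(sm$phyloP_range),
      GERPpp = sm$gerp_range[1] + (1 - d_m) * diff(sm$gerp_range))
    if (m != "SIFT" && sm$missing_rate > 0) {
      drop <- coding & stats::runif(nrow(variants)) < sm$missing_rate
      raw[drop] <- NA_real_
    }
    annotation[[m]] <- raw
  }
  annotation <- validate_annotation(annotation)

  structure(list(config = cfg, samples = samples, annotation = annotation,
                 genotypes = genotypes, drug_map = drug_map, vda = vda,
                 truth = list(planted = as.data.frame(truth),
                              core_genes = core_genes)),
            class = "gvb_simulation")
}

#' @export
print.gvb_simulation <- function(x, ...) {
  cat("gvb_simulation: ", nrow(x$samples), " samples, ",
      nrow(x$annotation), " variants, ",
      length(unique(x$drug_map$relations$drug_id)), " drugs, ",
      nrow(x$vda), " VDA records (seed ", x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Cohort genotypes of a simulation (in memory)
#'
#' @param sim A `gvb_simulation`.
#' @return A `cohort_genotypes` object equivalent to writing the VCF and
#'   reading it back.
#' @export
as_cohort_genotypes <- function(sim) {
  stopifnot(inherits(sim, "gvb_simulation"))
  carriers <- apply(sim$genotypes, 1, function(g)
    colnames(sim$genotypes)[g > 0L], simplify = FALSE)
  structure(list(samples = sim$samples, carriers = carriers),
            class = "cohort_genotypes")
}

#' Write a simulation bundle to disk
#'
#' Writes `cohort.vcf`, `samples.tsv`, `annotation.tsv`, `drug_gene.tsv`,
#' `vda.tsv`, `truth.json` and `manifest.json` under `dir`. Identical
#' configurations produce byte-identical files.
#'
#' @param sim A `gvb_simulation`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_bundle <- function(sim, dir) {
  stopifnot(inherits(sim, "gvb_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             samples = file.path(dir, "samples.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             drug_gene = file.path(dir, "drug_gene.tsv"),
             vda = file.path(dir, "vda.tsv"),
             truth = file.path(dir, "truth.json"),
             manifest = file.path(dir, "manifest.json"))
  write_sim_vcf(sim, paths["vcf"])
  write_tsv(sim$samples, paths["samples"])
  write_annotation(sim$annotation, paths["annotation"])
  write_drug_gene_map(sim$drug_map, paths["drug_gene"])
  write_vda_catalog(sim$vda, paths["vda"])
  jsonlite::write_json(sim$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  manifest <- c(list(generator = "gvburden"), sim$config)
  manifest$populations <- as.list(sim$config$populations)
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(paths)
}

write_sim_vcf <- function(sim, path) {
  ann <- sim$annotation
  ord <- order(ann$chrom, ann$pos, ann$variant_id)
  gt_chr <- c("0/0", "0/1", "1/1")
  gt <- matrix(gt_chr[sim$genotypes[ann$variant_id[ord], , drop = FALSE] + 1L],
               nrow = length(ord))
  body <- paste(ann$chrom[ord], ann$pos[ord], ann$variant_id[ord],
                ann$ref[ord], ann$alt[ord], ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  header <- c("##fileformat=VCFv4.2",
              "##source=gvburden_simulate",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sim$samples$sample_id),
                    collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Deterministic toy-scale simulation bundle
#'
#' A small fixed-seed simulation (20 individuals, 12 genes, 20 drugs) used
#' by unit tests and documentation examples. The bundle also ships as text
#' files under `inst/extdata/fixture/`; regeneration reproduces those files
#' byte for byte.
#'
#' @param dir Optional directory; when given, the bundle is also written
#'   there via [write_bundle()].
#' @return A `gvb_simulation`.
#' @export
small_fixture <- function(dir = NULL) {
  cfg <- synthetic_config(
    seed = 424242L, n_individuals = 20L, n_genes = 12L,
    core_gene_fraction = 0.25, variants_per_gene = 4,
    synonymous_per_gene = 1L, n_drugs = 20L, n_planted_vdas = 8L,
    fraction_ethnicity_specific = 0.5, n_noise_vdas = 4L, n_coding_vdas = 3L)
  sim <- simulate_cohort(cfg)
  if (!is.null(dir)) write_bundle(sim, dir)
  sim
}
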