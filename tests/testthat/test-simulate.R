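test_that("configuration validation catches infeasible settings before generation", {
  expect_error(synthetic_config(n_planted_vdas = 50, n_noise_vdas = 20,
                                n_drugs = 60), "infeasible")
  expect_error(synthetic_config(linkage_fidelity = 1.2), "\\[0, 1\\]")
  expect_error(synthetic_config(populations = data.frame(
    label = "p", superpopulation = "AFR", proportion = 0.5)), "sum to 1")
})

test_that("identical seeds produce byte-identical bundles; different seeds differ", {
  cfg <- synthetic_config(seed = 99L, n_individuals = 30L, n_genes = 10L,
                          n_drugs = 15L, n_planted_vdas = 6L,
                          n_noise_vdas = 3L, n_coding_vdas = 2L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_bundle(simulate_cohort(cfg), d1)
  write_bundle(simulate_cohort(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
  cfg2 <- synthetic_config(seed = 100L, n_individuals = 30L, n_genes = 10L,
                           n_drugs = 15L, n_planted_vdas = 6L,
                           n_noise_vdas = 3L, n_coding_vdas = 2L)
  d3 <- withr::local_tempdir()
  write_bundle(simulate_cohort(cfg2), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "cohort.vcf"))),
                         unname(tools::md5sum(file.path(d3, "cohort.vcf")))))
})

test_that("realized allele frequencies track the Beta model at n >= 500", {
  cfg <- synthetic_config(seed = 8L, n_individuals = 600L, n_genes = 20L,
                          n_planted_vdas = 0L, n_noise_vdas = 0L,
                          n_coding_vdas = 0L)
  sim <- simulate_cohort(cfg)
  background <- sim$annotation$variant_id[startsWith(sim$annotation$variant_id,
                                                     "rs0")]
  realized <- rowMeans(sim$genotypes[background, , drop = FALSE]) / 2
  # core genes carry planted common variants; compare the background mean
  # against the Beta mean allowing for the logit population perturbation
  expected <- cfg$allele_freq$shape1 /
    (cfg$allele_freq$shape1 + cfg$allele_freq$shape2)
  expect_lt(abs(mean(realized) - expected), 0.03)
  expect_false(anyNA(sim$genotypes))
  expect_true(all(sim$genotypes %in% 0:2))
})

test_that("ethnicity-specific plantings elevate marker frequency only in the target population", {
  cfg <- synthetic_config(seed = 21L, fraction_ethnicity_specific = 1)
  sim <- simulate_cohort(cfg)
  planted <- sim$truth$planted
  expect_true(all(!is.na(planted$target_population)))
  for (i in seq_len(nrow(planted))) {
    gt <- sim$genotypes[planted$marker_id[i], ]
    in_target <- sim$samples$population == planted$target_population[i]
    expect_gt(mean(gt[in_target] > 0), mean(gt[!in_target] > 0))
  }
})

test_that("marker carriers co-carry the causal variant exactly at full linkage fidelity", {
  cfg <- synthetic_config(seed = 13L, linkage_fidelity = 1,
                          causal_background_freq = 0)
  sim <- simulate_cohort(cfg)
  planted <- sim$truth$planted
  for (i in seq_len(nrow(planted))) {
    m <- sim$genotypes[planted$marker_id[i], ] > 0
    c <- sim$genotypes[planted$causal_id[i], ] > 0
    expect_true(all(c[m]))   # every marker carrier carries the causal
    expect_false(any(c[!m])) # and nobody else at zero background
  }
})

test_that("planted truth stays consistent with the drug-gene map", {
  sim <- small_fixture()
  planted <- sim$truth$planted
  rel <- sim$drug_map$relations
  for (i in seq_len(nrow(planted))) {
    expect_true(any(rel$drug_id == planted$drug_id[i] &
                      rel$gene_id == planted$gene_id[i]))
  }
  ann <- sim$annotation
  causal <- ann[match(planted$causal_id, ann$variant_id), ]
  expect_true(all(causal$consequence == "nonsynonymous_coding"))
  marker <- ann[match(planted$marker_id, ann$variant_id), ]
  expect_true(all(marker$consequence == "noncoding"))
  expect_true(all(is.na(marker$SIFT)))  # noncoding variants carry no scores
})

test_that("the shipped fixture is exactly the fixed-seed regeneration", {
  dir <- withr::local_tempdir()
  small_fixture(dir = dir)
  for (f in list.files(dir)) {
    expect_identical(unname(tools::md5sum(file.path(dir, f))),
                     unname(tools::md5sum(fixture_path(f))),
                     label = paste("md5 of", f))
  }
})

test_that("fixture runs end-to-end and emits one summary per mode", {
  sim <- small_fixture()
  res <- run_gvb_pipeline(as_cohort_genotypes(sim), sim$annotation,
                          sim$drug_map, sim$vda, methods = "SIFT")
  all_rows <- res$summaries[res$summaries$stratum == "all", ]
  expect_setequal(all_rows$mode, c("non_specific", "ethnicity_specific"))
  expect_true(all(all_rows$n_samples > 0))
  expect_true(all(res$per_sample$auc >= 0 & res$per_sample$auc <= 1,
                  na.rm = TRUE))
})

test_that("VCF written by the generator reads back to the in-memory carrier sets", {
  dir <- withr::local_tempdir()
  sim <- small_fixture(dir = dir)
  cohort <- read_vcf(file.path(dir, "cohort.vcf"),
                     file.path(dir, "samples.tsv"))
  mem <- as_cohort_genotypes(sim)
  carried_mem <- mem$carriers[lengths(mem$carriers) > 0]
  expect_setequal(names(cohort$carriers)[lengths(cohort$carriers) > 0],
                  names(carried_mem))
  for (v in names(carried_mem)) {
    expect_setequal(cohort$carriers[[v]], carried_mem[[v]])
  }
})
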