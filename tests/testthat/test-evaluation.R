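test_that("rank sensitivity and specificity follow the set definitions", {
  drugs <- c("d1", "d2", "d3", "d4")
  gs <- c("d1", "d3")
  expect_equal(sensitivity_specificity(drugs, gs, 2),
               c(sensitivity = 0.5, specificity = 0.5))
  expect_equal(sensitivity_specificity(drugs, gs, 0),
               c(sensitivity = 0, specificity = 1))
  expect_equal(sensitivity_specificity(drugs, gs, 4),
               c(sensitivity = 1, specificity = 0))
  expect_error(sensitivity_specificity(drugs, character(0), 1), "empty")
  expect_error(sensitivity_specificity(drugs, drugs, 1), "universe")
  expect_error(sensitivity_specificity(drugs, gs, 5), "\\[0, \\|D\\|\\]")
})

test_that("sensitivity/specificity identities hold across thresholds", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(4:25, 1)
    drugs <- paste0("d", seq_len(n))
    gs <- sample(drugs, sample(seq_len(n - 1), 1))
    for (L in c(0, sample(0:n, 3), n)) {
      ss <- sensitivity_specificity(drugs, gs, L)
      d_l <- drugs[seq_len(L)]
      # sensitivity + missed fraction = 1
      expect_equal(ss[["sensitivity"]] +
                     length(setdiff(gs, d_l)) / length(gs), 1)
      # specificity equals the true-negative fraction among D - GS
      tn <- length(setdiff(setdiff(drugs, gs), d_l))
      expect_equal(ss[["specificity"]], tn / (n - length(gs)))
    }
  }
})

test_that("ROC handles perfect rankings, full ties and the worked tie example", {
  perfect <- c(a = 0.1, b = 0.2, c = 0.8, d = 0.9)
  expect_equal(roc_auc(perfect, c("a", "b"))$auc, 1)
  flat <- c(a = 1, b = 1, c = 1)
  expect_equal(roc_auc(flat, "a")$auc, 0.5)
  # pairwise concordance with ties counted 1/2 over the 3 (pos, neg) pairs:
  # d2 loses to d1 (0), ties d3 (0.5), beats d4 (1) -> 1.5/3 = 0.5
  tied <- c(d1 = 0.1, d2 = 0.3, d3 = 0.3, d4 = 0.9)
  expect_equal(roc_auc(tied, "d2")$auc, oracle_auc(tied, "d2"),
               tolerance = 1e-12)
  expect_equal(roc_auc(tied, "d2")$auc, 0.5, tolerance = 1e-12)
  # curve endpoints
  pts <- roc_auc(tied, "d2")$points
  expect_equal(pts$sensitivity[1], 0)
  expect_equal(pts$specificity[1], 1)
  expect_equal(pts$sensitivity[nrow(pts)], 1)
  expect_equal(pts$specificity[nrow(pts)], 0)
})

test_that("trapezoidal AUC equals all-pairs concordance with half ties", {
  set.seed(202)
  for (i in 1:120) {
    n <- sample(3:30, 1)
    burdens <- setNames(sample(round(runif(n), 2)), paste0("d", seq_len(n)))
    gs <- sample(names(burdens), sample(seq_len(n - 1), 1))
    expect_equal(roc_auc(burdens, gs)$auc, oracle_auc(burdens, gs),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone burden transforms", {
  set.seed(9)
  burdens <- setNames(runif(15), paste0("d", 1:15))
  gs <- c("d1", "d4", "d9")
  a0 <- roc_auc(burdens, gs)$auc
  expect_equal(roc_auc(burdens^3, gs)$auc, a0)
  expect_equal(roc_auc(1 - exp(-burdens), gs)$auc, a0)
})

test_that("ROC cross-checks against an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(77)
  for (i in 1:10) {
    burdens <- setNames(round(runif(25), 2), paste0("d", 1:25))
    gs <- sample(names(burdens), 6)
    ref <- pROC::auc(pROC::roc(
      response = as.integer(names(burdens) %in% gs),
      predictor = burdens, direction = ">", quiet = TRUE))
    expect_equal(roc_auc(burdens, gs)$auc, as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("mean AUC over random gold standards is 0.5 under the permutation null", {
  set.seed(404)
  aucs <- replicate(400, {
    burdens <- setNames(runif(20), paste0("d", 1:20))
    roc_auc(burdens, sample(names(burdens), 4))$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("cohort summaries aggregate per-sample AUCs with n-1 SD and flags", {
  burdens <- expand.grid(sample_id = c("A1", "A2", "A3"),
                         drug_id = paste0("d", 1:10),
                         stringsAsFactors = FALSE)
  set.seed(1)
  burdens$value <- runif(nrow(burdens))
  samples <- data.frame(sample_id = c("A1", "A2", "A3"),
                        population = c("p1", "p1", "p2"),
                        superpopulation = c("AFR", "AFR", "EUR"))
  gs <- structure(list(drugs = data.frame(
    sample_id = rep(c("A1", "A2", "A3"), each = 2),
    drug_id = c("d1", "d2", "d1", "d3", "d2", "d5")),
    mode = "non_specific", excluded_samples = character()),
    class = "gold_standard_set")

  psa <- per_sample_auc(burdens, gs)
  out <- evaluate_cohort(burdens, gs, samples, strata = c("all", "population"))
  all_row <- out[out$stratum == "all", ]
  expect_equal(all_row$n_samples, 3L)
  expect_equal(all_row$auc_mean, mean(psa$auc))
  expect_equal(all_row$auc_sd, sd(psa$auc))
  p2 <- out[out$stratum == "p2", ]
  expect_equal(p2$auc_sd, 0)
  expect_equal(p2$flag, "degenerate_stratum")
  expect_error(evaluate_cohort(burdens, gs, samples, strata = "county"),
               "unknown stratum")

  # hand arithmetic on a known AUC triple
  fake <- data.frame(auc = c(0.6, 0.7, 0.8))
  expect_equal(mean(fake$auc), 0.7)
  expect_equal(sd(fake$auc), 0.1)
})

test_that("ATC strata restrict the drug universe and flag strata without gold standards", {
  map <- drug_gene_map(data.frame(
    drug_id = paste0("d", 1:6), gene_id = "g1", relation_type = "target",
    atc_main_group = rep(c("L", "N", "G"), each = 2)))
  burdens <- expand.grid(sample_id = c("A1", "A2"),
                         drug_id = paste0("d", 1:6),
                         stringsAsFactors = FALSE)
  burdens$value <- c(0.2, 0.9, 1, 1, 0.5, 0.4, 1, 1, 1, 1, 1, 1)
  samples <- data.frame(sample_id = c("A1", "A2"), population = "p",
                        superpopulation = "AFR")
  gs <- structure(list(drugs = data.frame(sample_id = c("A1", "A2"),
                                          drug_id = c("d1", "d1")),
                       mode = "non_specific",
                       excluded_samples = character()),
                  class = "gold_standard_set")
  out <- evaluate_cohort(burdens, gs, samples, map = map, strata = "atc")
  expect_setequal(out$stratum, c("L", "N", "G"))
  # GS drug d1 is in class L only; classes N and G have no evaluable sample
  expect_equal(out$n_samples[out$stratum == "L"], 2L)
  expect_equal(out$n_samples[out$stratum == "N"], 0L)
  expect_equal(out$flag[out$stratum == "G"], "no_evaluable_samples")
  expect_error(evaluate_cohort(burdens, gs, samples, strata = "atc"),
               "drug_gene_map")
})

test_that("gene-category comparison detects planted shifts and respects the null", {
  set.seed(12)
  low <- setNames(runif(20, 0.05, 0.15), paste0("lo", 1:20))
  high <- setNames(runif(20, 0.85, 0.95), paste0("hi", 1:20))
  res <- compare_gene_categories(c(low, high),
                                 list(core = names(low), other = names(high)),
                                 pairs = list(c("core", "other")))
  expect_lt(res$p_value, 0.005)
  expect_lt(res$mean_gvb_a, res$mean_gvb_b)

  # exchangeable data: one-sided p is near 0.5 on average
  ps <- replicate(40, {
    x <- setNames(runif(30), paste0("g", 1:30))
    compare_gene_categories(x, list(a = names(x)[1:15], b = names(x)[16:30]),
                            pairs = list(c("a", "b")))$p_value
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)

  expect_error(compare_gene_categories(
    c(low, high), list(a = names(low)[1], b = names(high)),
    pairs = list(c("a", "b"))), "fewer than 2")
  expect_error(compare_gene_categories(
    c(low, high), list(a = names(low), b = names(low)[1:5]),
    pairs = list(c("a", "b"))), "disjoint")
})
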