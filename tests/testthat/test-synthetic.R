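test_that("cohort generation is exactly reproducible from its seed", {
  spec <- synthetic_spec(n_cases = 40, n_controls = 40, n_snps = 30,
                         n_causal = 2, missing_rate = 0.05, seed = 123)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$geno$calls, c2$geno$calls)
  expect_identical(c1$pheno$attributes, c2$pheno$attributes)
  expect_identical(c1$pheno$class_label, c2$pheno$class_label)
  expect_identical(c1$truth$causal_snps, c2$truth$causal_snps)
  # a different seed changes the data
  c3 <- generate_cohort(synthetic_spec(n_cases = 40, n_controls = 40,
                                       n_snps = 30, n_causal = 2,
                                       missing_rate = 0.05, seed = 124))
  expect_false(identical(c1$geno$calls, c3$geno$calls))
  # requested class counts are met exactly
  expect_equal(sum(c1$pheno$class_label == "case"), 40)
  expect_equal(sum(c1$pheno$class_label == "control"), 40)
})

test_that("non-causal genotypes follow Hardy-Weinberg proportions", {
  spec <- synthetic_spec(n_cases = 1000, n_controls = 1000, n_snps = 12,
                         n_causal = 0, causal_effect = 1,
                         strata = data.frame(name = "S", proportion = 1,
                                             risk_multiplier = 1),
                         phenotype_effects = list(bmi_shift = 0, smoking_or = 1,
                                                  family_history_or = 1),
                         missing_rate = 0, seed = 55)
  cohort <- generate_cohort(spec)
  n <- length(cohort$geno$subject_ids)
  for (j in seq_len(ncol(cohort$geno$calls))) {
    p <- cohort$truth$maf[1, j]
    minor <- cohort$truth$alleles[j, 2]
    calls <- cohort$geno$calls[, j]
    minor_count <- (substr(calls, 1, 1) == minor) + (substr(calls, 2, 2) == minor)
    hw <- c(`0` = (1 - p)^2, `1` = 2 * p * (1 - p), `2` = p^2)
    for (g in 0:2) {
      expected <- hw[[as.character(g)]]
      tol <- 3 * sqrt(expected * (1 - expected) / n)
      expect_lt(abs(mean(minor_count == g) - expected), tol + 1e-9)
    }
  }
})

test_that("a zero-effect cohort yields uniform association p-values", {
  spec <- synthetic_spec(n_cases = 400, n_controls = 400, n_snps = 400,
                         n_causal = 0, causal_effect = 1,
                         strata = data.frame(name = c("A", "B"),
                                             proportion = c(0.5, 0.5),
                                             risk_multiplier = c(1, 1)),
                         phenotype_effects = list(bmi_shift = 0, smoking_or = 1,
                                                  family_history_or = 1),
                         missing_rate = 0, seed = 77)
  cohort <- generate_cohort(spec)
  coded <- encode_alleles(cohort$geno)
  filt <- association_filter(coded, cohort$pheno$class_label, alpha = 0.05)
  frac <- mean(filt$p < 0.05)
  tol <- 3 * sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(frac - 0.05), tol)
})

test_that("label permutation drives the pipeline to null AUC", {
  t <- toy_cohort_dataset(seed = 19, n_cases = 100, n_controls = 100,
                          n_snps = 50, causal_effect = 3, alpha = 0.01)
  d <- t$data
  set.seed(31)
  d$labels <- sample(d$labels)
  r <- cross_validate(model_spec("hybrid", C = 1, gamma = 0.05, tau = 1e-3),
                      d, folds = 5, seed = 6)
  n1 <- sum(d$labels == "case"); n0 <- sum(d$labels == "control")
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(r$auc - 0.5), 3 * se)
})

test_that("stronger causal effects are recovered more often", {
  recall_at <- function(effect, seeds) {
    mean(vapply(seeds, function(s) {
      t <- toy_cohort_dataset(seed = s, n_cases = 150, n_controls = 150,
                              n_snps = 60, n_causal = 3, causal_effect = effect,
                              alpha = 0.01)
      fit <- svmid3(t$data, C = 1, gamma = 1 / ncol(t$data$values), tau = 1e-3)
      recovery_report(t$cohort, fit$tree)$recall
    }, 0))
  }
  seeds <- 1:5
  recalls <- vapply(c(1.2, 2.5, 5), recall_at, 0, seeds = seeds)
  expect_true(all(diff(recalls) >= 0))
  expect_gt(recalls[3], recalls[1])
})

test_that("recovery reports precision and recall against the planted truth", {
  t <- toy_cohort_dataset(seed = 25, n_cases = 120, n_controls = 120,
                          n_snps = 40, n_causal = 3, causal_effect = 4,
                          alpha = 0.01)
  fit <- svmid3(t$data, C = 1, gamma = 1 / ncol(t$data$values), tau = 1e-3)
  rep <- recovery_report(t$cohort, fit$tree)
  expect_false(rep$degenerate)
  expect_gte(rep$recall, 0)
  expect_lte(rep$recall, 1)
  hits <- length(intersect(rep$selected, t$cohort$truth$causal_snps))
  expect_equal(rep$precision, hits / length(rep$selected))
  expect_equal(rep$recall, hits / 3)

  # single-leaf tree: degenerate, zeros with a flag
  leafy <- build_tree(t$data, tau = 1e9)
  rep0 <- recovery_report(t$cohort, leafy)
  expect_true(rep0$degenerate)
  expect_equal(c(rep0$precision, rep0$recall), c(0, 0))
})

test_that("written cohorts are read back by the standard readers", {
  cohort <- generate_cohort(synthetic_spec(n_cases = 20, n_controls = 20,
                                           n_snps = 10, n_causal = 1,
                                           missing_rate = 0.05, seed = 9))
  dir <- withr_like_tempdir()
  paths <- write_cohort(cohort, dir)
  expect_true(all(file.exists(paths)))
  geno <- read_ped_map(paths["ped"], paths["map"])
  expect_identical(geno$calls, cohort$geno$calls)
  pheno <- read_phenotypes(paths["phenotypes"], "status", "case", "control")
  expect_equal(pheno$class_label, cohort$pheno$class_label)
  expect_equal(pheno$attributes$bmi, cohort$pheno$attributes$bmi)
  manifest <- read_manifest(paths["manifest"])
  expect_equal(manifest, cohort$manifest)
})
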