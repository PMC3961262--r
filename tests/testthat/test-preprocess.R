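test_that("allele coding reproduces the ten-code table symmetrically", {
  coding <- allele_coding()
  expect_equal(coding[["AA"]], 1)
  expect_equal(coding[["TC"]], 6)
  expect_equal(coding[["CG"]], 9)
  expect_equal(coding[["AG"]], 4)
  expect_equal(coding[["GA"]], 4)
  # symmetry over all 16 ordered pairs
  for (x in c("A", "C", "G", "T")) for (y in c("A", "C", "G", "T")) {
    expect_equal(coding[[paste0(x, y)]], coding[[paste0(y, x)]])
  }
  # image over the 10 unordered pairs is exactly 1..10
  expect_setequal(unique(coding), 1:10)
  expect_length(unique(coding), 10)
})

test_that("encoding replaces calls by codes, keeps missing, rejects bad alleles", {
  calls <- matrix(c("AA", "TC", NA, "GG"), 2, 2,
                  dimnames = list(c("s1", "s2"), c("rs1", "rs2")))
  g <- genotype_table(c("s1", "s2"), c("rs1", "rs2"), calls)
  coded <- encode_alleles(g)
  expect_equal(unname(coded[, "rs1"]), c(1, 6))
  expect_true(is.na(coded["s1", "rs2"]))
  expect_equal(coded[["s2", "rs2"]], 10)

  g$calls[1, 1] <- "AN"
  expect_error(encode_alleles(g), "rs1")
})

test_that("chi-square filter matches closed form and handles degenerate SNPs", {
  # 2x2 closed form n(ad-bc)^2 / row/col products
  coded <- matrix(c(rep(1, 40), rep(5, 40)), ncol = 1)
  labels <- c(rep("case", 30), rep("control", 10), rep("case", 10), rep("control", 30))
  res <- association_filter(coded, labels, alpha = 0.005)
  expect_equal(res$chi2, 20.0, tolerance = 1e-12)
  expect_equal(res$df, 1L)
  expect_true(res$retained)

  # identical genotype distributions in cases and controls -> p = 1
  coded2 <- matrix(rep(c(1, 4, 10), 20), ncol = 1)
  labels2 <- rep(c("case", "control"), 30)
  res2 <- association_filter(coded2, labels2)
  expect_equal(res2$p, 1, tolerance = 1e-12)
  expect_false(res2$retained)

  # monomorphic SNP: undefined statistic, p = 1, not retained
  res3 <- association_filter(matrix(rep(5, 20), ncol = 1),
                             rep(c("case", "control"), 10))
  expect_true(is.na(res3$chi2))
  expect_equal(res3$p, 1)
  expect_false(res3$retained)
})

test_that("chi-square statistic agrees with chisq.test on random tables", {
  set.seed(101)
  for (i in 1:100) {
    r <- sample(2:4, 1)
    codes <- sample(1:10, r)
    x <- sample(codes, 60, replace = TRUE)
    y <- sample(c("case", "control"), 60, replace = TRUE, prob = c(0.5, 0.5))
    if (length(unique(y)) < 2 || length(unique(x)) < 2) next
    res <- association_filter(matrix(x, ncol = 1), y)
    ref <- suppressWarnings(stats::chisq.test(table(x, y), correct = FALSE))
    expect_equal(res$chi2, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(res$p, unname(ref$p.value), tolerance = 1e-9)
  }
})

test_that("retained set shrinks monotonically as alpha decreases", {
  d <- toy_cohort_dataset(seed = 21)
  alphas <- c(0.2, 0.05, 0.01, 0.005, 0.001)
  kept <- lapply(alphas, function(a) {
    f <- association_filter(d$coded, d$cohort$pheno$class_label, a)
    f$snp_id[f$retained]
  })
  for (i in seq_along(alphas)[-1]) {
    expect_true(all(kept[[i]] %in% kept[[i - 1]]))
  }
})

test_that("class-mean imputation fills by class, deletes hopeless attributes, preserves observed values", {
  values <- cbind(bmi = c(2, 4, NA, 10, NA, 14),
                  gone = c(NA, NA, NA, 1, 2, 3),
                  geno = c(1, 1, 4, NA, 10, 10))
  labels <- c("case", "case", "case", "control", "control", "control")
  d <- integrated_dataset(values,
                          c("phenotypic-numeric", "phenotypic-numeric", "genotypic"),
                          labels)
  out <- impute_class_mean(d)
  # case-class {2,4,NA} -> 3; control genotype mode of {10,10} -> 10
  expect_equal(out$values[3, "bmi"], 3)
  expect_equal(out$values[5, "bmi"], 12)
  expect_equal(out$values[4, "geno"], 10)
  # attribute with no observed case value is deleted and logged
  expect_false("gone" %in% out$attr_info$name)
  expect_equal(attr(out, "deleted"), "gone")
  # observed cells untouched; within-class mean of observed values preserved
  obs <- !is.na(values[, "bmi"])
  expect_equal(unname(out$values[obs, "bmi"]), unname(values[obs, "bmi"]))
  expect_equal(mean(out$values[labels == "case", "bmi"]),
               mean(values[labels == "case", "bmi"], na.rm = TRUE))

  # no missing values -> identity
  out2 <- impute_class_mean(out)
  expect_equal(out2$values, out$values)
})

test_that("discretization uses half-open bins with open ends", {
  edges <- c(22.5, 25.0, 29.9)
  expect_equal(discretize_numeric(21.0, edges), 1L)
  expect_equal(discretize_numeric(30.0, edges), 4L)
  expect_equal(discretize_numeric(29.95, edges), 4L)
  expect_equal(discretize_numeric(22.5, edges), 2L)   # lower edge joins upper bin
  expect_equal(discretize_numeric(c(10, 24, 27, 100), edges), c(1L, 2L, 3L, 4L))
  expect_error(discretize_numeric("x", edges), class = "snptree_format_error")
  expect_error(discretize_numeric(1, c(3, 2)), class = "snptree_config_error")
})

test_that("dataset assembly concatenates retained SNPs with phenotypes and projects", {
  d <- toy_cohort_dataset(seed = 31, n_snps = 30, alpha = 0.05)
  n_ret <- sum(d$filter$retained)
  expect_gt(n_ret, 0)
  full <- build_dataset(d$coded, d$cohort$pheno, d$filter)
  expect_equal(ncol(full$values), n_ret + 4)
  g <- build_dataset(d$coded, d$cohort$pheno, d$filter, projection = "genotype-only")
  expect_equal(ncol(g$values), n_ret)
  expect_true(all(g$attr_info$kind == "genotypic"))
  p <- build_dataset(d$coded, d$cohort$pheno, d$filter, projection = "phenotype-only")
  expect_equal(ncol(p$values), 4)
  # categorical phenotypes carry their level dictionaries
  expect_true("ethnicity" %in% names(p$levels))

  none <- d$filter; none$retained[] <- FALSE
  expect_error(build_dataset(d$coded[, 0, drop = FALSE], NULL, NULL,
                             labels = d$cohort$pheno$class_label),
               class = "snptree_data_error")
})

test_that("integrated datasets serialize to text and back unchanged", {
  d <- toy_cohort_dataset(seed = 41)$data
  path <- file.path(withr_like_tempdir(), "data.tsv")
  write_dataset(d, path)
  back <- read_dataset(path)
  expect_equal(back$values, d$values)
  expect_equal(back$attr_info, d$attr_info)
  expect_equal(back$labels, d$labels)
  expect_equal(back$levels, d$levels)
})
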