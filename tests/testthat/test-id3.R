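test_that("entropy matches hand values and rejects empty counts", {
  expect_equal(entropy(c(4, 0)), 0)
  expect_equal(entropy(c(4, 4)), 1)
  expect_equal(entropy(c(3, 5)),
               -(3 / 8) * log2(3 / 8) - (5 / 8) * log2(5 / 8))
  expect_equal(entropy(c(3, 5)), 0.954434, tolerance = 1e-6)
  expect_error(entropy(c(0, 0)), class = "snptree_data_error")
})

test_that("split scores agree with the brute-force partition oracle", {
  # parent (6,2): one pure group of 4 cases, one (2,2) group
  labels <- c(rep("case", 4), "case", "case", "control", "control")
  values <- c(rep("g1", 4), "g2", "g2", "g2", "g2")
  s <- split_score(values, labels, weight = 1)
  h_parent <- ref_entropy(labels)
  expect_equal(s$entropy_before, h_parent)
  expect_equal(s$information_gain, h_parent - 0.5 * 1, tolerance = 1e-12)
  expect_equal(s$split_information, 1)
  expect_equal(s$gain_ratio, s$information_gain)

  # perfect split of a balanced parent
  s2 <- split_score(rep(c("a", "b"), each = 4),
                    rep(c("case", "control"), each = 4), weight = 1)
  expect_equal(s2$information_gain, 1)
  expect_equal(s2$gain_ratio, 1)

  # randomized agreement with a direct recomputation
  set.seed(77)
  for (i in 1:50) {
    n <- sample(4:20, 1)
    v <- sample(letters[1:3], n, replace = TRUE)
    y <- sample(c("case", "control"), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- split_score(v, y, weight = 0.3)
    expect_equal(s$gain_ratio, ref_gain_ratio(v, y), tolerance = 1e-12)
    expect_equal(s$weighted_gain_ratio, 0.3 * s$gain_ratio)
    expect_gte(s$information_gain, 0)
    expect_lte(s$information_gain, s$entropy_before + 1e-12)
  }

  # weight zero and single-valued attributes score zero
  expect_equal(split_score(values, labels, weight = 0)$weighted_gain_ratio, 0)
  expect_equal(split_score(rep("a", 8), labels)$gain_ratio, 0)
})

test_that("a closed gate yields a single majority leaf", {
  d <- parity_dataset()
  tree <- build_tree(d, tau = 1e6)
  expect_equal(tree$type, "leaf")
  expect_equal(tree_size(tree), 1L)
  counts <- tree$counts
  expect_equal(tree$predicted_class,
               if (counts[["case"]] >= counts[["control"]]) "case" else "control")
  p <- predict(tree, d)
  expect_length(unique(as.character(p$class)), 1)
})

test_that("uniform weights at tau 0 reproduce the brute-force unweighted ID3", {
  set.seed(123)
  for (i in 1:60) {
    d <- random_small_dataset(sample(4:12, 1), sample(2:5, 1))
    tree <- build_tree(d, tau = 0)
    ref <- ref_id3(as.data.frame(apply(d$values, 2, as.character),
                                 stringsAsFactors = FALSE),
                   as.character(d$labels))
    expect_true(trees_match(tree, ref))
  }
})

test_that("the root splits on the informative attribute when its weight dominates", {
  d <- parity_dataset(n = 60)
  w <- c(signal = 0.7, noise1 = 0.1, noise2 = 0.1, noise3 = 0.1)
  tree <- build_tree(d, w, tau = 0)
  expect_equal(tree$split_attribute, "signal")
  # brute force: signal has the maximal weighted score at the root
  scores <- sapply(names(w), function(a) {
    w[[a]] * ref_gain_ratio(d$values[, a], as.character(d$labels))
  })
  expect_equal(names(which.max(scores)), "signal")
})

test_that("the tau axis spans [1e-3, 10] in 50 logarithmic steps", {
  taus <- tau_axis()
  expect_length(taus, 51)
  expect_identical(taus[1], 1e-3)
  expect_identical(taus[51], 10)
  ratios <- taus[-1] / taus[-51]
  expect_equal(ratios, rep(10^(4 / 50), 50), tolerance = 1e-9)
  expect_equal(ratios[1], 1.20226, tolerance = 1e-5)
})

test_that("building at tau equals pruning the gate-0 tree; gating is monotone", {
  d <- toy_cohort_dataset(seed = 71, n_cases = 60, n_controls = 60, n_snps = 25)$data
  base <- build_tree(d, tau = 0)
  sizes <- integer(0)
  for (tau in tau_axis(steps = 20)) {
    direct <- build_tree(d, tau = tau)
    pruned <- prune_tree(base, tau)
    expect_true(tree_equal(direct, pruned))
    sizes <- c(sizes, tree_size(direct))
  }
  expect_true(all(diff(sizes) <= 0))
  expect_equal(tree_size(build_tree(d, tau = Inf)), 1L)
})

test_that("leaves conserve the training subjects and paths never reuse attributes", {
  d <- toy_cohort_dataset(seed = 81, n_cases = 50, n_controls = 50, n_snps = 20)$data
  tree <- build_tree(d, tau = 0)
  rules <- extract_rules(tree)
  totals <- Reduce(`+`, lapply(rules, function(r) c(r$cases, r$controls)))
  expect_equal(totals, c(sum(d$labels == "case"), sum(d$labels == "control")))
  for (r in rules) {
    expect_false(anyDuplicated(names(r$conditions)) > 0)
  }
})

test_that("zero-weight attributes never appear in the tree", {
  d <- parity_dataset(n = 80)
  w <- c(signal = 0, noise1 = 1 / 3, noise2 = 1 / 3, noise3 = 1 / 3)
  tree <- build_tree(d, w, tau = 0)
  expect_false("signal" %in% tree_attributes(tree))
})

test_that("prediction follows paths, falls back on unseen categories, errors on missing values", {
  d <- parity_dataset(n = 40)
  tree <- build_tree(d, tau = 0)
  p <- predict(tree, d)
  # training predictions match each subject's leaf exactly (pure-leaf subjects score 0 or 1)
  expect_true(all(p$score >= 0 & p$score <= 1))
  rules <- extract_rules(tree)
  # rule list applied as a lookup reproduces predict()
  for (i in seq_len(nrow(d$values))) {
    hits <- vapply(rules, function(r) {
      all(as.character(d$values[i, names(r$conditions)]) == r$conditions)
    }, TRUE)
    expect_equal(sum(hits), 1L)
    expect_equal(rules[[which(hits)]]$predicted_class, as.character(p$class[i]))
  }

  # unseen category at the root: majority class of the whole training set
  nd <- d$values[1, , drop = FALSE]
  nd[1, tree$split_attribute] <- 99
  p2 <- predict(tree, nd)
  maj <- if (sum(d$labels == "case") >= sum(d$labels == "control")) "case" else "control"
  expect_equal(as.character(p2$class), maj)

  nd2 <- d$values[1, , drop = FALSE]
  nd2[1, tree$split_attribute] <- NA
  expect_error(predict(tree, nd2), tree$split_attribute)
})

test_that("pure-case leaves predict (case, 1.0)", {
  values <- cbind(a = c(1, 1, 2, 2))
  d <- integrated_dataset(values, "genotypic", c("case", "case", "control", "control"))
  tree <- build_tree(d, tau = 0)
  p <- predict(tree, d)
  expect_equal(as.character(p$class), c("case", "case", "control", "control"))
  expect_equal(p$score, c(1, 1, 0, 0))
})

test_that("tau grid search scores 51 taus by pooled CV and prefers larger tau on ties", {
  d <- toy_cohort_dataset(seed = 91, n_cases = 40, n_controls = 40, n_snps = 15)$data
  tg <- grid_search_tau(d, cv_folds = 3, seed = 4)
  expect_equal(nrow(tg$results), 51)
  expect_equal(tg$results$tau, tau_axis())
  best_auc <- max(tg$results$auc)
  ties <- tg$results$tau[tg$results$auc == best_auc]
  expect_equal(tg$best_tau, max(ties))
  # determinism
  tg2 <- grid_search_tau(d, cv_folds = 3, seed = 4)
  expect_identical(tg$results, tg2$results)
})

test_that("rule extraction and the text format round-trip trees", {
  # single leaf: one rule with empty condition, one text line
  d0 <- integrated_dataset(cbind(a = c(1, 1)), "genotypic", c("case", "control"))
  leaf <- build_tree(d0, tau = 1e9)
  r0 <- extract_rules(leaf)
  expect_length(r0, 1)
  expect_length(r0[[1]]$conditions, 0)
  expect_equal(length(strsplit(export_tree_text(leaf), "\n")[[1]]), 1)

  # one k-category split: k rules
  dk <- integrated_dataset(cbind(a = c(1, 1, 2, 2, 3, 3)), "genotypic",
                           c("case", "case", "control", "control", "case", "control"))
  tk <- build_tree(dk, tau = 0)
  expect_length(extract_rules(tk), 3)

  # rule shape: conjunction of attribute = value tests ending in a class
  d <- parity_dataset(n = 50)
  tree <- build_tree(d, tau = 0)
  df <- as.data.frame(extract_rules(tree))
  expect_true(all(grepl("=", df$condition[df$condition != "TRUE"])))
  expect_true(all(df$predicted_class %in% c("case", "control")))

  # export -> parse -> export is byte-identical; parsed tree is equal
  txt <- export_tree_text(tree)
  back <- parse_tree_text(txt)
  expect_identical(export_tree_text(back), txt)
  expect_true(tree_equal(tree, back))

  # two-space indentation per level on an explicit depth-2 tree
  d2 <- integrated_dataset(
    cbind(a = c(1, 1, 1, 1, 2, 2, 2, 2), b = c(1, 1, 2, 2, 1, 2, 1, 2)),
    rep("genotypic", 2),
    c("case", "case", "control", "control", rep("case", 4)))
  t2 <- build_tree(d2, tau = 0)
  txt2 <- export_tree_text(t2)
  expect_identical(export_tree_text(parse_tree_text(txt2)), txt2)
  lines <- strsplit(txt2, "\n")[[1]]
  depths <- nchar(sub("[^ ].*$", "", lines))
  expect_true(all(depths %% 2 == 0))
  expect_gte(max(depths), 2)
})
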