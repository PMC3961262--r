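# Independent brute-force oracles and small fixture builders used across
# the test files.  These deliberately avoid the package's own code paths.

# Fresh scratch directory per call (cleaned with the session tempdir).
withr_like_tempdir <- function() {
  d <- tempfile("snptree-test-")
  dir.create(d)
  d
}

# Exhaustive pairwise AUC: mean over all case-control pairs of
# I(case > control) + 0.5 * I(tie).
ref_auc <- function(scores, labels) {
  cs <- scores[labels == "case"]
  ct <- scores[labels == "control"]
  total <- 0
  for (a in cs) for (b in ct) total <- total + (a > b) + 0.5 * (a == b)
  total / (length(cs) * length(ct))
}

# Direct entropy / gain-ratio computation on a plain data.frame, used by
# the reference ID3.
ref_entropy <- function(y) {
  p <- table(y) / length(y)
  p <- p[p > 0]
  -sum(p * log2(p))
}

ref_gain_ratio <- function(x, y) {
  groups <- split(y, as.character(x))
  if (length(groups) < 2) return(0)
  n <- length(y)
  props <- sapply(groups, length) / n
  ig <- ref_entropy(y) - sum(props * sapply(groups, ref_entropy))
  si <- -sum(props * log2(props))
  if (si <= 0) 0 else max(ig, 0) / si
}

# Plain unweighted ID3 on a data.frame of categorical columns plus a
# case/control vector.  Splits whenever the best gain ratio is positive;
# selection ties break alphabetically (the package's documented policy).
# Returns nested lists structurally comparable with snptree trees.
ref_id3 <- function(df, y) {
  n_case <- sum(y == "case"); n_ctrl <- sum(y == "control")
  leaf <- function() list(type = "leaf",
                          counts = c(case = n_case, control = n_ctrl),
                          predicted_class = if (n_case >= n_ctrl) "case" else "control")
  if (n_case == 0 || n_ctrl == 0 || ncol(df) == 0) return(leaf())
  grs <- sapply(sort(names(df)), function(a) ref_gain_ratio(df[[a]], y))
  top <- max(grs)
  best <- names(grs)[grs >= top - 1e-12 * (1 + abs(top))][1]
  if (grs[[best]] <= 0) return(leaf())
  vals <- sort(unique(as.character(df[[best]])))
  branches <- list()
  for (v in vals) {
    sel <- as.character(df[[best]]) == v
    branches[[v]] <- ref_id3(df[sel, setdiff(names(df), best), drop = FALSE], y[sel])
  }
  list(type = "split", split_attribute = best, branches = branches)
}

# Structural comparison between a snptree id3_node and a ref_id3 tree.
trees_match <- function(pkg, ref) {
  if (pkg$type != ref$type) return(FALSE)
  if (pkg$type == "leaf") {
    return(all(pkg$counts[c("case", "control")] ==
                 ref$counts[c("case", "control")]))
  }
  if (pkg$split_attribute != ref$split_attribute) return(FALSE)
  if (!identical(sort(names(pkg$branches)), sort(names(ref$branches)))) return(FALSE)
  all(vapply(names(pkg$branches),
             function(v) trees_match(pkg$branches[[v]], ref$branches[[v]]), TRUE))
}

# Random small categorical dataset as an integrated_dataset (values are
# small integers; genotypic kind so everything is categorical).
random_small_dataset <- function(n_subjects, n_attrs, n_levels = 3) {
  values <- matrix(sample.int(n_levels, n_subjects * n_attrs, replace = TRUE),
                   n_subjects, n_attrs)
  colnames(values) <- sprintf("a%02d", seq_len(n_attrs))
  labels <- c("case", "control",
              sample(c("case", "control"), n_subjects - 2, replace = TRUE))
  integrated_dataset(values, rep("genotypic", n_attrs), labels)
}

# Deterministic toy dataset: label equals parity of attribute "signal",
# the other attributes are pure noise.
parity_dataset <- function(n = 40, n_noise = 3, seed = 42) {
  set.seed(seed)
  signal <- sample(1:4, n, replace = TRUE)
  values <- cbind(signal = signal,
                  matrix(sample(1:3, n * n_noise, replace = TRUE), n, n_noise))
  colnames(values) <- c("signal", sprintf("noise%d", seq_len(n_noise)))
  labels <- ifelse(signal %% 2 == 0, "case", "control")
  integrated_dataset(values, rep("genotypic", ncol(values)), labels)
}

# Small preprocessed cohort dataset for model-level tests: planted
# effects, no missingness left, numeric phenotype binned.
toy_cohort_dataset <- function(seed = 11, n_cases = 80, n_controls = 80,
                               n_snps = 40, n_causal = 3, causal_effect = 3,
                               alpha = 0.05, missing_rate = 0) {
  cohort <- generate_cohort(synthetic_spec(
    n_cases = n_cases, n_controls = n_controls, n_snps = n_snps,
    n_causal = n_causal, causal_effect = causal_effect,
    missing_rate = missing_rate, seed = seed))
  coded <- encode_alleles(cohort$geno)
  filt <- association_filter(coded, cohort$pheno$class_label, alpha)
  d <- build_dataset(coded, cohort$pheno, filt)
  d <- impute_class_mean(d)
  d <- apply_bins(d, list(bmi = c(22.5, 25, 29.9)))
  list(cohort = cohort, data = d, filter = filt, coded = coded)
}
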