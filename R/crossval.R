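# Stratified cross-validation with leakage-safe per-fold preprocessing,
# and the three-model x three-dataset comparison harness.

#' Specify a model for cross-validation
#'
#' @param type `"svm"` (stand-alone RBF SVM), `"id3"` (uniform-weight
#'   tree), or `"hybrid"` (SVM-derived weights driving the tree).
#' @param C,gamma SVM hyperparameters; `gamma = NULL` means `1/m` for `m`
#'   attributes.  Ignored when `tune_svm` is set.
#' @param tau split-gate threshold for tree models; ignored when
#'   `tune_tau` is set.
#' @param tune_svm run the C/gamma grid search inside each training fold.
#' @param tune_tau run the tau grid search inside each training fold.
#' @param svm_axes grid from [svm_parameter_grid()] when tuning.
#' @param tau_steps logarithmic steps for the inner tau grid.
#' @param inner_folds folds for the inner searches.
#' @return a `model_spec` list.
#' @export
model_spec <- function(type = c("hybrid", "svm", "id3"), C = 1, gamma = NULL,
                       tau = 1e-3, tune_svm = FALSE, tune_tau = FALSE,
                       svm_axes = svm_parameter_grid(), tau_steps = 50,
                       inner_folds = 3) {
  structure(list(type = match.arg(type), C = C, gamma = gamma, tau = tau,
                 tune_svm = tune_svm, tune_tau = tune_tau,
                 svm_axes = svm_axes, tau_steps = tau_steps,
                 inner_folds = inner_folds),
            class = "model_spec")
}

# Impute a held-out split from training-fold statistics.  Class-mean
# imputation needs the label, which is unknown for a test subject, so the
# pooled training mean (numeric) or mode (categorical/genotypic) is used.
impute_from_train <- function(train, test) {
  v <- test$values
  for (j in seq_len(ncol(v))) {
    if (!anyNA(v[, j])) next
    nm <- test$attr_info$name[j]
    obs <- train$values[, nm]
    obs <- obs[!is.na(obs)]
    fill <- if (test$attr_info$kind[j] == "phenotypic-numeric") mean(obs) else {
      tab <- table(obs)
      as.numeric(names(tab)[which.max(tab)])
    }
    v[is.na(v[, j]), j] <- fill
  }
  test$values <- v
  test
}

#' Discretize named numeric attributes of a dataset
#'
#' Applies [discretize_numeric()] to each attribute named in `bins`,
#' replacing its values by bin categories; other attributes are
#' untouched.
#'
#' @param data an [integrated_dataset()].
#' @param bins named list mapping attribute names to bin-edge vectors.
#' @return the dataset with the named columns discretized.
#' @export
apply_bins <- function(data, bins) {
  for (nm in names(bins)) {
    j <- match(nm, data$attr_info$name)
    if (is.na(j)) next
    data$values[, j] <- discretize_numeric(data$values[, j], bins[[nm]])
  }
  data
}

prepare_fold <- function(data, train_idx, test_idx, bins) {
  train <- impute_class_mean(subset_dataset(data, train_idx))
  test <- subset_dataset(data, test_idx)
  test <- subset_dataset(test, attrs = train$attr_info$name)  # drop deleted attrs
  test <- impute_from_train(train, test)
  if (length(bins)) {
    train <- apply_bins(train, bins)
    test <- apply_bins(test, bins)
  }
  list(train = train, test = test)
}

fit_fold_model <- function(spec, train, seed) {
  out <- list(spec = spec)
  if (spec$type %in% c("svm", "hybrid")) {
    sc <- scale_features(train$values)
    C <- spec$C; gamma <- spec$gamma %||% (1 / ncol(train$values))
    if (spec$tune_svm) {
      g <- grid_search_svm(sc$values, spec$svm_axes, spec$inner_folds,
                           seed = seed, labels = train$labels)
      C <- g$best$C; gamma <- g$best$gamma
    }
    out$svm <- train_svm(sc$values, train$labels, C, gamma)
    out$scaling <- sc
    if (spec$type == "hybrid") {
      out$weights <- extract_attribute_weights(out$svm, sc$values)
    }
  }
  if (spec$type %in% c("id3", "hybrid")) {
    w <- if (spec$type == "hybrid") out$weights else NULL
    tau <- spec$tau
    if (spec$tune_tau) {
      tg <- grid_search_tau(train, w, steps = spec$tau_steps,
                            cv_folds = spec$inner_folds, seed = seed)
      tau <- tg$best_tau
    }
    out$tau <- tau
    out$tree <- build_tree(train, w, tau)
  }
  out
}

predict_fold_model <- function(fitted, test) {
  if (fitted$spec$type == "svm") {
    dv <- decision_values(fitted$svm,
                          apply_scaling(test$values, fitted$scaling$min,
                                        fitted$scaling$range))
    list(class = ifelse(dv > 0, "case", "control"), score = dv)
  } else {
    p <- predict(fitted$tree, test)
    list(class = as.character(p$class), score = p$score)
  }
}

#' Stratified cross-validation of a model specification
#'
#' Subjects are assigned to stratified folds by seed; each fold is
#' predicted by a model trained on the remaining folds.  Imputation,
#' discretization, scaling, and any inner hyperparameter searches are
#' re-fit inside every training split, so no information leaks from the
#' held-out fold.  Held-out predictions are pooled and scored once.
#'
#' @param spec a [model_spec()].
#' @param data an [integrated_dataset()]; missing values allowed (imputed
#'   per fold).
#' @param folds number of folds (>= 2).
#' @param seed fold-assignment seed.
#' @param bins named list of bin edges applied to numeric attributes after
#'   imputation (see [discretize_numeric()]).
#' @param fold_ids optional precomputed fold assignment (overrides
#'   `folds`/`seed`), used to score several models on identical folds.
#' @return a [compute_metrics()] report with the pooled predictions in
#'   `attr(,"predictions")`.
#' @export
cross_validate <- function(spec, data, folds = 10, seed = 1, bins = list(),
                           fold_ids = NULL) {
  stopifnot(folds >= 2)
  fold_ids <- fold_ids %||% stratified_folds(data$labels, folds, seed)
  n <- nrow(data$values)
  cls <- rep(NA_character_, n)
  sco <- rep(NA_real_, n)
  for (k in sort(unique(fold_ids))) {
    tr <- which(fold_ids != k); te <- which(fold_ids == k)
    if (nlevels(droplevels(data$labels[tr])) < 2) {
      warning(sprintf("fold %d skipped: single-class training split", k))
      next
    }
    fd <- prepare_fold(data, tr, te, bins)
    fitted <- fit_fold_model(spec, fd$train, seed + k)
    p <- predict_fold_model(fitted, fd$test)
    cls[te] <- p$class
    sco[te] <- p$score
  }
  ok <- !is.na(cls)
  rep <- compute_metrics(cls[ok], sco[ok], data$labels[ok])
  attr(rep, "predictions") <- data.frame(subject = data$subjects,
                                         fold = fold_ids, class = cls,
                                         score = sco,
                                         truth = as.character(data$labels),
                                         stringsAsFactors = FALSE)
  rep
}

#' The three-model by three-dataset comparison experiment
#'
#' Cross-validates the stand-alone SVM, the stand-alone (uniform-weight)
#' ID3 tree, and the hybrid on the genotype-only, phenotype-only, and
#' integrated projections of the same cohort.  All nine cells share one
#' fold assignment so differences reflect the models, not the splits.
#' A projection that has no attributes (e.g. genotype-only with zero
#' retained SNPs) is reported as `NULL`.
#'
#' @param coded numeric coded-genotype matrix (subjects x SNPs), aligned
#'   with `pheno`.
#' @param pheno a [phenotype_table()] carrying the labels.
#' @param filter optional [association_filter()] result.
#' @param specs named list of the three [model_spec()]s; defaults to
#'   fixed-hyperparameter svm/id3/hybrid specs.
#' @param folds,seed cross-validation controls.
#' @param bins named bin-edge list for numeric phenotypes.
#' @return object of class `comparison_matrix`: models x datasets list of
#'   [compute_metrics()] reports.
#' @export
run_comparison <- function(coded, pheno, filter = NULL, specs = NULL,
                           folds = 10, seed = 1, bins = list()) {
  specs <- specs %||% list(svm = model_spec("svm"),
                           id3 = model_spec("id3"),
                           hybrid = model_spec("hybrid"))
  projections <- c("genotype-only", "phenotype-only", "integrated")
  labels <- as_class_factor(pheno$class_label)
  fold_ids <- stratified_folds(labels, folds, seed)
  cells <- list()
  for (proj in projections) {
    d <- tryCatch(build_dataset(coded, pheno, filter, projection = proj),
                  snptree_data_error = function(e) NULL)
    for (m in names(specs)) {
      cells[[m]][[proj]] <- if (is.null(d)) NULL else {
        cross_validate(specs[[m]], d, bins = bins, fold_ids = fold_ids)
      }
    }
  }
  structure(list(cells = cells, folds = folds, seed = seed),
            class = "comparison_matrix")
}

#' @export
as.data.frame.comparison_matrix <- function(x, ...) {
  rows <- list()
  for (m in names(x$cells)) for (p in names(x$cells[[m]])) {
    r <- x$cells[[m]][[p]]
    if (is.null(r)) next
    rows[[length(rows) + 1]] <- data.frame(
      model = m, dataset = p, accuracy = r$accuracy, precision = r$precision,
      recall = r$recall, auc = r$auc, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' @export
print.comparison_matrix <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.comparison_matrix <- function(x, ...) {
  datasets <- c("genotype-only", "phenotype-only", "integrated")
  out <- character(0)
  for (m in names(x$cells)) {
    out <- c(out, sprintf("%s (%d-fold CV, seed %d)", m, x$folds, x$seed),
             sprintf("%-20s %15s %15s %15s", "Performance", "Only-Genotype",
                     "Only-Phenotype", "Integrated"))
    fmt_row <- function(label, get, digits) {
      vals <- vapply(datasets, function(p) {
        r <- x$cells[[m]][[p]]
        if (is.null(r)) "-" else formatC(get(r), digits = digits, format = "f")
      }, "")
      sprintf("%-20s %15s %15s %15s", label, vals[1], vals[2], vals[3])
    }
    out <- c(out,
             fmt_row("Accuracy", function(r) r$accuracy, 2),
             fmt_row("Precision", function(r) r$precision, 2),
             fmt_row("Recall", function(r) r$recall, 2),
             fmt_row("AUC", function(r) r$auc, 3), "")
  }
  out
}

#' Write a comparison matrix as TSV
#' @param cm a `comparison_matrix`.
#' @param path output path.
#' @export
write_comparison_tsv <- function(cm, path) {
  utils::write.table(as.data.frame(cm), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
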