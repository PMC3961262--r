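# The hybrid model: an RBF-SVM supplies per-attribute weights that scale
# the gain ratio of a gate-thresholded ID3 tree.  `svmid3()` is the main
# fitting entry point and returns a classed object with the usual
# modelling methods.

#' Fit the hybrid SVM-weighted ID3 model
#'
#' Pipeline over an integrated dataset: (1) class-mean imputation if any
#' values are missing; (2) min-max scaling; (3) RBF-SVM hyperparameters
#' from the C/gamma grid search (42 combinations by default) unless both
#' `C` and `gamma` are given; (4) attribute weights
#' `w_j = |sum_i alpha_i y_i x_ij|`, normalized; (5) the split-gate
#' threshold from the tau grid search (51 values by default) unless `tau`
#' is given; (6) the final weighted ID3 tree on the full data.
#'
#' @param data an [integrated_dataset()]; numeric attributes should be
#'   discretized first (see [discretize_numeric()]) since the tree splits
#'   on categories.
#' @param C,gamma fixed SVM hyperparameters; leave `NULL` to grid-search.
#' @param tau fixed split gate; leave `NULL` to grid-search.
#' @param svm_axes C/gamma axes from [svm_parameter_grid()].
#' @param tau_min,tau_max,tau_steps tau axis, see [tau_axis()].
#' @param cv_folds stratified folds used by the grid searches.
#' @param seed seed for fold assignment.
#' @return an object of class `svmid3` with components `svm`, `weights`,
#'   `tree`, `tau`, the grid traces, and the scaling parameters.
#' @seealso [predict.svmid3()], [coef.svmid3()], [plot.svmid3()]
#' @examples
#' cohort <- generate_cohort(synthetic_spec(n_cases = 60, n_controls = 60,
#'                                          n_snps = 30, n_causal = 2,
#'                                          missing_rate = 0, seed = 7))
#' coded <- encode_alleles(cohort$geno)
#' data <- build_dataset(coded, cohort$pheno,
#'                       association_filter(coded, cohort$pheno$class_label, 0.05))
#' data <- impute_class_mean(data)
#' data <- apply_bins(data, list(bmi = c(22.5, 25, 29.9)))
#' fit <- svmid3(data, C = 2, gamma = 0.1, tau = 0.01)
#' fit
#' @export
svmid3 <- function(data, C = NULL, gamma = NULL, tau = NULL,
                   svm_axes = svm_parameter_grid(),
                   tau_min = 1e-3, tau_max = 10, tau_steps = 50,
                   cv_folds = 10, seed = 1) {
  cl <- match.call()
  if (anyNA(data$values)) data <- impute_class_mean(data)
  sc <- scale_features(data$values)
  svm_grid <- NULL
  if (is.null(C) || is.null(gamma)) {
    svm_grid <- grid_search_svm(sc$values, svm_axes, cv_folds, seed,
                                labels = data$labels)
    C <- svm_grid$best$C
    gamma <- svm_grid$best$gamma
  }
  svm <- train_svm(sc$values, data$labels, C, gamma)
  weights <- extract_attribute_weights(svm, sc$values)
  tau_grid <- NULL
  if (is.null(tau)) {
    tau_grid <- grid_search_tau(data, weights, tau_min, tau_max, tau_steps,
                                cv_folds, seed)
    tau <- tau_grid$best_tau
  }
  tree <- build_tree(data, weights, tau)
  structure(list(call = cl, svm = svm, svm_grid = svm_grid, weights = weights,
                 tau = tau, tau_grid = tau_grid, tree = tree, scaling = sc,
                 attr_info = data$attr_info, levels = data$levels,
                 n_subjects = nrow(data$values),
                 class_counts = count_classes(data$labels)),
            class = "svmid3")
}

#' @export
print.svmid3 <- function(x, ...) {
  cat("Hybrid SVM-weighted ID3 model\n")
  cat(sprintf("  training data: %d subjects (%d case / %d control), %d attributes\n",
              x$n_subjects, x$class_counts[["case"]], x$class_counts[["control"]],
              nrow(x$attr_info)))
  cat(sprintf("  SVM: C = %g, gamma = %g%s\n", x$svm$C, x$svm$gamma,
              if (is.null(x$svm_grid)) "" else
                sprintf(" (grid search over %d combinations, CV AUC %.3f)",
                        nrow(x$svm_grid$results), x$svm_grid$best$auc)))
  cat(sprintf("  split gate: tau = %g%s\n", x$tau,
              if (is.null(x$tau_grid)) "" else
                sprintf(" (grid search over %d values, CV AUC %.3f)",
                        nrow(x$tau_grid$results), x$tau_grid$best_auc)))
  cat(sprintf("  tree: %d nodes, depth %d, %d attributes used\n",
              tree_size(x$tree), tree_depth(x$tree),
              length(tree_attributes(x$tree))))
  invisible(x)
}

#' @export
summary.svmid3 <- function(object, ...) {
  print(object)
  cat("\nTop attribute weights:\n")
  top <- sort(unclass(object$weights), decreasing = TRUE)
  top <- top[seq_len(min(10, length(top)))]
  for (nm in names(top)) cat(sprintf("  %-20s %.4f\n", nm, top[[nm]]))
  cat(sprintf("\nDecision rules (%d):\n", length(extract_rules(object$tree))))
  print(extract_rules(object$tree))
  invisible(object)
}

#' Attribute weights of a fitted hybrid model
#' @param object an `svmid3` fit.
#' @param ... unused.
#' @return named numeric vector of normalized weights.
#' @export
coef.svmid3 <- function(object, ...) {
  stats::setNames(as.numeric(object$weights), names(object$weights))
}

#' Classify new subjects with a fitted hybrid model
#'
#' Prediction is by the fitted weighted ID3 tree: the leaf's majority
#' class and its case fraction as ranking score.
#'
#' @param object an `svmid3` fit.
#' @param newdata an [integrated_dataset()] or numeric matrix with the
#'   training attribute columns.
#' @param type `"class"`, `"score"`, or `"both"`.
#' @param ... unused.
#' @export
predict.svmid3 <- function(object, newdata, type = c("both", "class", "score"), ...) {
  type <- match.arg(type)
  p <- predict(object$tree, newdata)
  switch(type, class = p$class, score = p$score, both = p)
}

#' Plot grid-search traces of a fitted hybrid model
#'
#' Left: mean cross-validated AUC over the C/gamma grid (one line per C).
#' Right: pooled CV AUC against the split gate tau, with the selected tau
#' marked.  Panels without a stored grid are skipped.
#'
#' @param x an `svmid3` fit.
#' @param ... passed to `plot`.
#' @export
plot.svmid3 <- function(x, ...) {
  n_panels <- sum(!is.null(x$svm_grid), !is.null(x$tau_grid))
  if (n_panels == 0) {
    warning("no grid traces stored (both C/gamma and tau were fixed)")
    return(invisible(x))
  }
  old <- graphics::par(mfrow = c(1, n_panels))
  on.exit(graphics::par(old))
  if (!is.null(x$svm_grid)) {
    r <- x$svm_grid$results
    graphics::plot(NA, xlim = range(log10(r$gamma)), ylim = range(r$mean_auc),
                   xlab = "log10(gamma)", ylab = "mean CV AUC",
                   main = "SVM grid", ...)
    for (cc in unique(r$C)) {
      s <- r[r$C == cc, ]
      graphics::lines(log10(s$gamma), s$mean_auc, type = "b",
                      col = which(unique(r$C) == cc))
    }
    graphics::legend("bottomleft", legend = paste("C =", unique(r$C)),
                     col = seq_along(unique(r$C)), lty = 1, cex = 0.7)
  }
  if (!is.null(x$tau_grid)) {
    r <- x$tau_grid$results
    graphics::plot(r$tau, r$auc, log = "x", type = "b", xlab = "tau",
                   ylab = "pooled CV AUC", main = "tau grid", ...)
    graphics::abline(v = x$tau, lty = 2)
  }
  invisible(x)
}
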