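# RBF-SVM stage: min-max feature scaling, training (libsvm via e1071),
# the C/gamma grid search, and extraction of the normalized per-attribute
# weights that drive the weighted ID3 stage.

#' Min-max feature scaling
#'
#' Maps each attribute affinely onto `[0, 1]`; constant columns map to 0.
#' The returned parameters let held-out subjects be transformed identically
#' to the training data.
#'
#' @param values numeric matrix (subjects x attributes), no missing values.
#' @return list with the scaled `values` and per-attribute `min` / `range`.
#' @export
scale_features <- function(values) {
  stopifnot(!anyNA(values))
  mins <- apply(values, 2, min)
  rngs <- apply(values, 2, max) - mins
  list(values = apply_scaling(values, mins, rngs), min = mins, range = rngs)
}

#' Apply stored scaling parameters to a matrix
#' @param values numeric matrix with the same attribute columns.
#' @param mins,ranges parameters from [scale_features()].
#' @export
apply_scaling <- function(values, mins, ranges) {
  out <- sweep(values, 2, mins, "-")
  nz <- ranges > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, ranges[nz], "/")
  out[, !nz] <- 0
  out
}

#' Train the RBF-kernel soft-margin SVM
#'
#' Binary C-classification with kernel `k(u,v) = exp(-gamma * ||u-v||^2)`,
#' case as the positive class.  `C = 0` (the lower end of the search grid)
#' is remapped to `1e-6`: a zero-cost soft-margin problem is degenerate.
#'
#' @param scaled numeric matrix already scaled to `[0,1]`.
#' @param labels case/control per subject; both classes must be present.
#' @param C soft-margin cost.
#' @param gamma RBF width parameter, `> 0`.
#' @return object of class `rbf_svm` wrapping the fitted solver with
#'   support vectors, dual coefficients (`alpha_i * y_i`), and bias.
#' @export
train_svm <- function(scaled, labels, C, gamma) {
  labels <- as_class_factor(labels)
  if (nlevels(droplevels(labels)) < 2) stop_data("SVM training requires both classes")
  stopifnot(gamma > 0, C >= 0)
  fit <- e1071::svm(x = scaled, y = labels, scale = FALSE,
                    type = "C-classification", kernel = "radial",
                    gamma = gamma, cost = max(C, 1e-6))
  # libsvm orients decision values toward whichever class it saw first;
  # record the sign that makes "case" positive.
  sign_case <- if (fit$labels[1] == which(levels(labels) == "case")) 1 else -1
  structure(list(fit = fit, C = C, gamma = gamma, sign_case = sign_case,
                 n_features = ncol(scaled)),
            class = "rbf_svm")
}

#' Signed decision values of a trained SVM
#'
#' Positive values favour the case class; the sign of the value is the
#' predicted class and the value itself is the ranking score used for AUC.
#'
#' @param model an `rbf_svm`.
#' @param scaled matrix scaled with the training parameters.
#' @return numeric vector of decision values, case-positive.
#' @export
decision_values <- function(model, scaled) {
  p <- stats::predict(model$fit, scaled, decision.values = TRUE)
  model$sign_case * as.numeric(attr(p, "decision.values"))
}

#' @export
predict.rbf_svm <- function(object, newdata, ...) {
  dv <- decision_values(object, newdata)
  list(class = factor(ifelse(dv > 0, "case", "control"),
                      levels = c("control", "case")),
       score = dv)
}

#' @export
print.rbf_svm <- function(x, ...) {
  cat(sprintf("RBF SVM: C = %g, gamma = %g, %d support vectors, %d features\n",
              x$C, x$gamma, nrow(x$fit$SV), x$n_features))
  invisible(x)
}

#' The C/gamma search grid
#'
#' Gamma axis: consecutive powers of ten spanning `[gamma_min, gamma_max]`
#' inclusive.  C axis: `c_steps` equal increments spanning `[c_min, c_max]`
#' inclusive of both ends.  The defaults give a 7 x 6 = 42-combination
#' grid.
#'
#' @param gamma_min,gamma_max gamma range endpoints (powers of ten).
#' @param c_min,c_max C range endpoints.
#' @param c_steps number of linear steps on the C axis.
#' @return list with `gamma_values` and `c_values`.
#' @export
svm_parameter_grid <- function(gamma_min = 1e-4, gamma_max = 1e2,
                               c_min = 0, c_max = 10, c_steps = 5) {
  stopifnot(gamma_min > 0, gamma_max >= gamma_min, c_max >= c_min, c_steps >= 1)
  lo <- round(log10(gamma_min)); hi <- round(log10(gamma_max))
  list(gamma_values = 10^(lo:hi),
       c_values = seq(c_min, c_max, length.out = c_steps + 1))
}

#' Grid search over (gamma, C) by stratified cross-validation
#'
#' Every combination on the grid is scored by the mean held-out AUC of its
#' decision values over stratified folds.  A fold whose test split lacks a
#' class is skipped with a warning; a combination with every fold skipped
#' scores 0.  Ties on the best score are broken toward smaller C, then
#' smaller gamma.
#'
#' @param data an [integrated_dataset()] with no missing values, or a
#'   numeric matrix plus `labels`.
#' @param grid axes from [svm_parameter_grid()].
#' @param cv_folds number of stratified folds (>= 2).
#' @param seed integer seed for the fold assignment.
#' @param labels required when `data` is a bare matrix.
#' @return object of class `svm_grid`: data frame `results` (gamma, C,
#'   mean_auc, n_folds_used) and the `best` configuration.
#' @export
grid_search_svm <- function(data, grid = svm_parameter_grid(), cv_folds = 10,
                            seed = 1, labels = NULL) {
  stopifnot(cv_folds >= 2)
  if (inherits(data, "integrated_dataset")) {
    labels <- data$labels
    values <- data$values
  } else values <- as.matrix(data)
  labels <- as_class_factor(labels)
  folds <- stratified_folds(labels, cv_folds, seed)
  combos <- expand.grid(gamma = grid$gamma_values, C = grid$c_values,
                        KEEP.OUT.ATTRS = FALSE)
  mean_auc <- numeric(nrow(combos))
  n_used <- integer(nrow(combos))
  # fold-internal scaling: fixed per fold, shared across combinations
  fold_data <- lapply(seq_len(cv_folds), function(k) {
    tr <- folds != k
    sc <- scale_features(values[tr, , drop = FALSE])
    list(train = sc$values,
         test = apply_scaling(values[!tr, , drop = FALSE], sc$min, sc$range),
         y_train = labels[tr], y_test = labels[!tr])
  })
  for (i in seq_len(nrow(combos))) {
    aucs <- c()
    for (k in seq_len(cv_folds)) {
      fd <- fold_data[[k]]
      if (nlevels(droplevels(fd$y_train)) < 2 || nlevels(droplevels(fd$y_test)) < 2) {
        warning(sprintf("fold %d skipped: a split contains a single class", k))
        next
      }
      m <- train_svm(fd$train, fd$y_train, combos$C[i], combos$gamma[i])
      dv <- decision_values(m, fd$test)
      aucs <- c(aucs, auc_mann_whitney(dv, fd$y_test))
    }
    mean_auc[i] <- if (length(aucs)) mean(aucs) else 0
    n_used[i] <- length(aucs)
  }
  results <- cbind(combos, mean_auc = mean_auc, n_folds_used = n_used)
  ord <- order(-results$mean_auc, results$C, results$gamma)
  best <- results[ord[1], ]
  structure(list(results = results, gamma_values = grid$gamma_values,
                 c_values = grid$c_values,
                 best = list(C = best$C, gamma = best$gamma, auc = best$mean_auc),
                 cv_folds = cv_folds, seed = seed),
            class = "svm_grid")
}

#' @export
print.svm_grid <- function(x, ...) {
  cat(sprintf("SVM grid search: %d combinations (%d gamma x %d C), %d-fold CV\n",
              nrow(x$results), length(x$gamma_values), length(x$c_values), x$cv_folds))
  cat(sprintf("best: C = %g, gamma = %g (mean AUC %.3f)\n",
              x$best$C, x$best$gamma, x$best$auc))
  invisible(x)
}

#' Extract normalized attribute weights from a trained SVM
#'
#' Raw weight of attribute `j` is `|sum_i alpha_i y_i x_ij|` over the
#' support vectors — the magnitude of the pseudo-primal weight vector
#' formed from the dual coefficients.  Because the dual constraint forces
#' `sum_i alpha_i y_i = 0`, constant attributes get raw weight exactly 0.
#' Weights are normalized to sum to 1; an all-zero raw vector degenerates
#' to uniform weights.
#'
#' @param model an `rbf_svm` trained on `scaled`.
#' @param scaled the scaled training matrix (used for attribute names).
#' @return object of class `attribute_weights`: numeric vector summing to
#'   1, named by attribute, with the raw weights in `attr(,"raw")`.
#' @export
extract_attribute_weights <- function(model, scaled) {
  raw <- abs(as.numeric(crossprod(model$fit$coefs, model$fit$SV)))
  names(raw) <- colnames(scaled)
  w <- if (sum(raw) > 0) raw / sum(raw) else rep(1 / length(raw), length(raw))
  names(w) <- names(raw)
  structure(w, raw = raw, class = "attribute_weights")
}

#' @export
print.attribute_weights <- function(x, ...) {
  cat(sprintf("attribute_weights over %d attributes (top 5):\n", length(x)))
  top <- sort(unclass(x), decreasing = TRUE)[seq_len(min(5, length(x)))]
  for (nm in names(top)) cat(sprintf("  %-20s %.4f\n", nm, top[[nm]]))
  invisible(x)
}

#' Write attribute weights as TSV
#' @param weights an `attribute_weights` object.
#' @param path output path.
#' @export
write_weights_tsv <- function(weights, path) {
  utils::write.table(
    data.frame(attribute = names(weights), raw_weight = attr(weights, "raw"),
               normalized_weight = as.numeric(weights)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a grid-search trace as TSV
#' @param grid an `svm_grid` or `tau_grid` object.
#' @param path output path.
#' @export
write_grid_tsv <- function(grid, path) {
  utils::write.table(grid$results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
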