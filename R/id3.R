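# Weighted ID3: categorical decision tree where externally supplied
# per-attribute weights (here, SVM-derived) multiply the information-gain
# ratio, and a threshold tau on that weighted score gates every split.
# No pruning; all attributes are categorical (coded genotypes, discretized
# or level-coded phenotypes).

#' Shannon entropy of a class-count vector, in bits
#' @param class_counts nonnegative counts (sum > 0).
#' @return entropy `-sum p log2 p` over nonzero proportions.
#' @export
entropy <- function(class_counts) {
  if (any(class_counts < 0) || sum(class_counts) == 0) {
    stop_data("entropy undefined for counts %s", paste(class_counts, collapse = ","))
  }
  p <- class_counts[class_counts > 0] / sum(class_counts)
  -sum(p * log2(p))
}

count_classes <- function(labels) {
  c(case = sum(labels == "case"), control = sum(labels == "control"))
}

#' Weighted gain-ratio score of one categorical split
#'
#' Partitions the subset by attribute value and reports information gain
#' `IG = H(parent) - sum (n_v/n) H(child_v)`, split information
#' `SI = -sum (n_v/n) log2(n_v/n)`, gain ratio `GR = IG/SI` (0 when
#' `SI = 0`, i.e. a single observed value), and the weighted score
#' `weight * GR`.
#'
#' @param values categorical attribute values over the subset.
#' @param labels case/control labels over the subset.
#' @param weight nonnegative attribute weight.
#' @param attribute attribute name carried through for reporting.
#' @return list of class `split_score`.
#' @export
split_score <- function(values, labels, weight = 1, attribute = NA_character_) {
  stopifnot(length(values) == length(labels), length(values) > 0)
  h0 <- entropy(count_classes(labels))
  groups <- split(seq_along(values), as.character(values))
  n <- length(values)
  if (length(groups) < 2) {
    ig <- 0; si <- 0; gr <- 0
  } else {
    props <- vapply(groups, length, 0L) / n
    h_children <- vapply(groups, function(idx) entropy(count_classes(labels[idx])), 0)
    ig <- h0 - sum(props * h_children)
    ig <- max(ig, 0)  # guard tiny negative rounding
    si <- -sum(props * log2(props))
    gr <- if (si > 0) ig / si else 0
  }
  structure(list(attribute = attribute, entropy_before = h0,
                 information_gain = ig, split_information = si,
                 gain_ratio = gr, weight = weight,
                 weighted_gain_ratio = weight * gr),
            class = "split_score")
}

new_leaf <- function(counts) {
  pred <- if (counts[["case"]] >= counts[["control"]]) "case" else "control"
  structure(list(type = "leaf", counts = counts, predicted_class = pred,
                 case_fraction = counts[["case"]] / sum(counts)),
            class = "id3_node")
}

#' Build a weighted ID3 tree
#'
#' Recursively selects, among attributes unused on the current path, the
#' one maximizing the weighted gain ratio; splits only when that maximum
#' is both `>= tau` and `> 0`, with one branch per category value observed
#' in the node's subset.  Otherwise the node becomes a leaf carrying the
#' majority class and the case fraction.  Zero-weight attributes can never
#' be selected; no attribute repeats on a path; no pruning.  Selection
#' ties break lexicographically by attribute name.
#'
#' @param data an [integrated_dataset()] with no missing values (all
#'   columns treated as categorical).
#' @param weights [extract_attribute_weights()] vector aligned by name to
#'   the dataset's attributes; default uniform.
#' @param tau nonnegative gate on the weighted gain ratio.
#' @param max_depth optional depth cap (root = depth 0); default unlimited.
#' @return the root `id3_node`; split nodes store their `weighted_score`,
#'   leaves their class counts and case fraction.
#' @export
build_tree <- function(data, weights = NULL, tau = 0, max_depth = Inf) {
  stopifnot(tau >= 0, !anyNA(data$values))
  attrs <- data$attr_info$name
  if (is.null(weights)) {
    weights <- rep(1 / length(attrs), length(attrs))
    names(weights) <- attrs
  }
  if (!all(attrs %in% names(weights))) stop_config("weights missing for some attributes")
  vals <- data$values
  grow <- function(rows, used, depth) {
    labs <- data$labels[rows]
    counts <- count_classes(labs)
    if (counts[["case"]] == 0 || counts[["control"]] == 0 || depth >= max_depth) {
      return(new_leaf(counts))
    }
    cand <- setdiff(attrs, used)
    cand <- cand[order(cand)]  # lexicographic tie-break via stable which.max
    if (length(cand) == 0) return(new_leaf(counts))
    scores <- lapply(cand, function(a) {
      split_score(vals[rows, a], labs, weights[[a]], a)
    })
    wsc <- vapply(scores, `[[`, 0, "weighted_gain_ratio")
    # near-ties (within 1e-12 relative) count as exact ties and resolve
    # to the lexicographically first attribute
    top <- max(wsc)
    best <- which(wsc >= top - 1e-12 * (1 + abs(top)))[1]
    if (!(wsc[best] >= tau && wsc[best] > 0)) return(new_leaf(counts))
    a <- cand[best]
    groups <- split(rows, as.character(vals[rows, a]))
    groups <- groups[order(names(groups))]
    branches <- lapply(groups, grow, used = c(used, a), depth = depth + 1)
    structure(list(type = "split", split_attribute = a,
                   weighted_score = wsc[best], score = scores[[best]],
                   counts = counts, branches = branches),
              class = "id3_node")
  }
  root <- grow(seq_len(nrow(vals)), character(0), 0)
  attr(root, "attributes") <- attrs
  root
}

#' Prune a tree at a higher gate threshold
#'
#' The tree built at gate `tau` equals the tree built at gate 0 with every
#' split whose stored weighted score falls below `tau` collapsed to a
#' leaf; this makes scanning a tau grid cheap.
#'
#' @param tree an `id3_node` built with a smaller tau.
#' @param tau the new gate.
#' @return the pruned tree.
#' @export
prune_tree <- function(tree, tau) {
  if (tree$type == "leaf") return(tree)
  if (tree$weighted_score < tau) {
    out <- new_leaf(tree$counts)
    attr(out, "attributes") <- attr(tree, "attributes")
    return(out)
  }
  tree$branches <- lapply(tree$branches, prune_tree, tau = tau)
  tree
}

#' Number of nodes in a tree
#' @param tree an `id3_node`.
#' @export
tree_size <- function(tree) {
  if (tree$type == "leaf") return(1L)
  1L + sum(vapply(tree$branches, tree_size, 0L))
}

tree_depth <- function(tree) {
  if (tree$type == "leaf") return(0L)
  1L + max(vapply(tree$branches, tree_depth, 0L))
}

#' Attributes used anywhere in a tree
#' @param tree an `id3_node`.
#' @return character vector of split-attribute names.
#' @export
tree_attributes <- function(tree) {
  if (tree$type == "leaf") return(character(0))
  unique(c(tree$split_attribute,
           unlist(lapply(tree$branches, tree_attributes), use.names = FALSE)))
}

#' Classify subjects with an ID3 tree
#'
#' Follows branches by attribute value to a leaf; the leaf's majority
#' class is the prediction and its case fraction the ranking score.  A
#' category value unseen at a node falls through to a virtual leaf
#' carrying that node's own class distribution.  A missing (`NA`) value on
#' the path is an error naming the attribute.
#'
#' @param object an `id3_node` (the tree root).
#' @param newdata an [integrated_dataset()] or numeric matrix with named
#'   columns.
#' @param ... unused.
#' @return list with `class` (factor) and `score` (case fraction).
#' @export
predict.id3_node <- function(object, newdata, ...) {
  vals <- if (inherits(newdata, "integrated_dataset")) newdata$values else as.matrix(newdata)
  one <- function(node, i) {
    while (node$type == "split") {
      v <- vals[i, node$split_attribute]
      if (is.na(v)) {
        stop_data("missing value for attribute '%s' during prediction", node$split_attribute)
      }
      child <- node$branches[[as.character(v)]]
      if (is.null(child)) return(new_leaf(node$counts))  # unseen category
      node <- child
    }
    node
  }
  leaves <- lapply(seq_len(nrow(vals)), function(i) one(object, i))
  list(class = factor(vapply(leaves, `[[`, "", "predicted_class"),
                      levels = c("control", "case")),
       score = vapply(leaves, `[[`, 0, "case_fraction"))
}

#' @export
print.id3_node <- function(x, ...) {
  cat(sprintf("ID3 tree: %d nodes, depth %d, attributes used: %s\n",
              tree_size(x), tree_depth(x),
              paste(tree_attributes(x), collapse = ", ")))
  cat(export_tree_text(x))
  invisible(x)
}

#' The tau search grid for the split gate
#'
#' Geometric sequence of `steps + 1` values spanning
#' `[tau_min, tau_max]` inclusive (consecutive ratio
#' `(tau_max/tau_min)^(1/steps)`); the defaults give 51 values over
#' `[1e-3, 10]`.
#'
#' @param tau_min,tau_max range endpoints, `tau_min > 0`.
#' @param steps number of logarithmic steps (>= 1).
#' @return numeric vector of tau values.
#' @export
tau_axis <- function(tau_min = 1e-3, tau_max = 10, steps = 50) {
  stopifnot(tau_min > 0, tau_max > tau_min, steps >= 1)
  v <- exp(seq(log(tau_min), log(tau_max), length.out = steps + 1))
  v[1] <- tau_min; v[steps + 1] <- tau_max
  v
}

#' Grid search over the split-gate threshold tau
#'
#' Scores each tau on the axis by stratified cross-validation: per fold a
#' gate-0 tree is built on the training split once and pruned at each tau,
#' held-out predictions are pooled over folds, and the pooled AUC is the
#' tau's score.  Best tau is the argmax; ties go to the larger tau
#' (simpler tree).
#'
#' @param data an [integrated_dataset()] with no missing values.
#' @param weights attribute weights (default uniform).
#' @param tau_min,tau_max,steps axis parameters, see [tau_axis()].
#' @param cv_folds number of stratified folds.
#' @param seed fold-assignment seed.
#' @return object of class `tau_grid`: data frame `results` (tau, auc)
#'   and `best_tau`.
#' @export
grid_search_tau <- function(data, weights = NULL, tau_min = 1e-3, tau_max = 10,
                            steps = 50, cv_folds = 10, seed = 1) {
  taus <- tau_axis(tau_min, tau_max, steps)
  folds <- stratified_folds(data$labels, cv_folds, seed)
  n <- nrow(data$values)
  scores <- matrix(NA_real_, n, length(taus))
  preds <- matrix(NA_character_, n, length(taus))
  for (k in seq_len(cv_folds)) {
    tr <- folds != k
    if (nlevels(droplevels(data$labels[tr])) < 2) {
      warning(sprintf("fold %d skipped: single-class training split", k))
      next
    }
    base <- build_tree(subset_dataset(data, which(tr)), weights, tau = 0)
    test <- subset_dataset(data, which(!tr))
    for (t in seq_along(taus)) {
      p <- predict(prune_tree(base, taus[t]), test)
      scores[!tr, t] <- p$score
      preds[!tr, t] <- as.character(p$class)
    }
  }
  ok <- !is.na(scores[, 1])
  auc <- vapply(seq_along(taus), function(t) {
    auc_mann_whitney(scores[ok, t], data$labels[ok])
  }, 0)
  best <- length(taus) + 1 - which.max(rev(auc))  # ties -> larger tau
  structure(list(results = data.frame(tau = taus, auc = auc),
                 best_tau = taus[best], best_auc = auc[best],
                 cv_folds = cv_folds, seed = seed),
            class = "tau_grid")
}

#' @export
print.tau_grid <- function(x, ...) {
  cat(sprintf("tau grid search: %d values in [%g, %g], %d-fold CV\n",
              nrow(x$results), min(x$results$tau), max(x$results$tau), x$cv_folds))
  cat(sprintf("best: tau = %g (pooled AUC %.3f)\n", x$best_tau, x$best_auc))
  invisible(x)
}
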