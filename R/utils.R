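# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals never disturb the
#' caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Stratified fold assignment
#'
#' Assigns each subject to one of `k` folds so that class proportions are
#' preserved as closely as integer counts allow.  Deterministic for a given
#' seed.
#'
#' @param labels factor of class labels.
#' @param k number of folds.
#' @param seed integer seed controlling the shuffle.
#' @return integer vector of fold ids in `1..k`, one per subject.
#' @keywords internal
stratified_folds <- function(labels, k, seed) {
  stopifnot(k >= 2)
  folds <- integer(length(labels))
  with_seed(seed, {
    start <- 0L
    for (cl in levels(as.factor(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      # continue the cyclic assignment across classes so all k folds are
      # used even when a class has fewer than k members (k = n gives
      # leave-one-out)
      folds[idx] <- ((start + seq_along(idx) - 1L) %% k) + 1L
      start <- start + length(idx)
    }
  })
  folds
}

stop_data <- function(...) stop(errorCondition(sprintf(...), class = c("snptree_data_error", "error")))
stop_format <- function(...) stop(errorCondition(sprintf(...), class = c("snptree_format_error", "error")))
stop_config <- function(...) stop(errorCondition(sprintf(...), class = c("snptree_config_error", "error")))

# Class labels are kept as a factor with a fixed level order so that "case"
# is always the positive class downstream.
as_class_factor <- function(x) factor(as.character(x), levels = c("control", "case"))
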