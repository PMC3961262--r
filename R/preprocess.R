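# Preprocessing: symmetric allele coding, genotypic chi-square association
# filter, class-mean imputation, numeric discretization, and assembly of the
# integrated subjects x attributes dataset.

#' The symmetric ten-level allele coding
#'
#' Maps each of the ten unordered biallelic genotypes to an integer code
#' 1..10.  Both allele orders of a heterozygote receive the same code
#' (code(AG) = code(GA)), so the coding carries no parent-of-origin
#' assumption.
#'
#' @return named integer vector over all 16 ordered allele pairs.
#' @export
allele_coding <- function() {
  base <- c(AA = 1L, AT = 2L, AC = 3L, AG = 4L, TT = 5L, CT = 6L,
            GT = 7L, CC = 8L, GC = 9L, GG = 10L)
  full <- base
  for (p in names(base)) {
    rev <- paste0(substr(p, 2, 2), substr(p, 1, 1))
    full[rev] <- base[[p]]
  }
  full[order(names(full))]
}

#' Encode genotype calls numerically
#'
#' Replaces every call in a genotype table with its symmetric coding value
#' (see [allele_coding()]); missing calls stay `NA` for the imputation
#' stage.
#'
#' @param geno a [genotype_table()].
#' @param coding named integer vector over ordered allele pairs; defaults
#'   to [allele_coding()].
#' @return numeric matrix (`subjects x SNPs`) with values in 1..10 or `NA`.
#' @export
encode_alleles <- function(geno, coding = allele_coding()) {
  calls <- geno$calls
  known <- is.na(calls) | calls %in% names(coding)
  if (!all(known)) {
    bad <- which(!known, arr.ind = TRUE)[1, ]
    stop_format("uncodable call '%s' for subject %s, SNP %s",
                calls[bad[1], bad[2]],
                geno$subject_ids[bad[1]], geno$snp_ids[bad[2]])
  }
  coded <- matrix(unname(coding[calls]), nrow(calls), ncol(calls))
  dimnames(coded) <- dimnames(calls)
  storage.mode(coded) <- "double"
  coded
}

# Pearson chi-square on a contingency table after dropping all-zero rows
# and columns (the spec's category pooling).  Returns stat, df, p.
chisq_independence <- function(tab) {
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    return(list(stat = NA_real_, df = 0L, p = 1))
  }
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(stat = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Per-SNP genotypic chi-square association filter
#'
#' For each SNP, tests independence of the genotype-code distribution and
#' case/control status on the observed contingency table (categories are
#' the distinct codes actually seen; absent categories are pooled out,
#' reducing the degrees of freedom).  SNPs with `p < alpha` are retained.
#' Monomorphic SNPs have no defined statistic and are reported with
#' `p = 1`, not retained.
#'
#' @param coded numeric matrix of coded genotypes (`subjects x SNPs`),
#'   `NA` allowed (missing calls are dropped per SNP).
#' @param labels case/control factor or character vector, one per subject.
#' @param alpha retention threshold on the raw p-value (default 0.005).
#' @return data frame of class `association_filter` with columns `snp_id`,
#'   `chi2`, `df`, `p`, `retained`.
#' @export
association_filter <- function(coded, labels, alpha = 0.005) {
  stopifnot(alpha > 0, alpha < 1)
  labels <- as_class_factor(labels)
  snp_ids <- colnames(coded) %||% paste0("snp", seq_len(ncol(coded)))
  out <- data.frame(snp_id = snp_ids, chi2 = NA_real_, df = 0L, p = 1,
                    retained = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(coded))) {
    x <- coded[, j]
    ok <- !is.na(x)
    if (!any(ok)) next
    tab <- table(factor(x[ok]), labels[ok])
    res <- chisq_independence(unclass(tab))
    out$chi2[j] <- res$stat
    out$df[j] <- res$df
    out$p[j] <- res$p
  }
  out$retained <- out$p < alpha
  class(out) <- c("association_filter", "data.frame")
  out
}

#' Write association-filter results as TSV
#' @param filter result of [association_filter()].
#' @param path output path.
#' @export
write_filter_tsv <- function(filter, path) {
  utils::write.table(filter, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an integrated dataset
#'
#' The integrated dataset is the numeric `subjects x attributes` matrix the
#' classifiers consume: coded genotype columns (values 1..10), phenotype
#' columns (categorical levels coded as integers, numeric kept as-is), a
#' case/control label per subject, and per-attribute metadata.
#'
#' @param values numeric matrix, subjects in rows, attributes in columns.
#' @param kinds character vector per attribute: `"genotypic"`,
#'   `"phenotypic-categorical"`, or `"phenotypic-numeric"`.
#' @param labels case/control per subject.
#' @param subjects subject identifiers.
#' @param levels named list mapping categorical attribute names to their
#'   string levels (integer code i means `levels[[name]][i]`).
#' @return object of class `integrated_dataset`.
#' @export
integrated_dataset <- function(values, kinds, labels, subjects = NULL,
                               levels = list()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  subjects <- as.character(subjects %||% rownames(values) %||% seq_len(nrow(values)))
  labels <- as_class_factor(labels)
  stopifnot(length(kinds) == ncol(values), length(labels) == nrow(values))
  if (!all(kinds %in% c("genotypic", "phenotypic-categorical", "phenotypic-numeric"))) {
    stop_format("unknown attribute kind")
  }
  if (is.null(colnames(values))) colnames(values) <- paste0("attr", seq_len(ncol(values)))
  rownames(values) <- subjects
  structure(list(values = values,
                 attr_info = data.frame(name = colnames(values), kind = kinds,
                                        stringsAsFactors = FALSE),
                 labels = labels, subjects = subjects, levels = levels),
            class = "integrated_dataset")
}

#' @export
print.integrated_dataset <- function(x, ...) {
  k <- table(factor(x$attr_info$kind,
                    c("genotypic", "phenotypic-categorical", "phenotypic-numeric")))
  cat(sprintf(paste0("integrated_dataset: %d subjects (%d case / %d control), ",
                     "%d attributes (%d genotypic, %d categorical, %d numeric)"),
              nrow(x$values), sum(x$labels == "case"), sum(x$labels == "control"),
              ncol(x$values), k[1], k[2], k[3]), "\n")
  if (anyNA(x$values)) cat(sprintf("  %d missing values pending imputation\n",
                                   sum(is.na(x$values))))
  invisible(x)
}

# Row/column subsetting that keeps metadata aligned.
subset_dataset <- function(data, subjects = NULL, attrs = NULL) {
  v <- data$values
  lab <- data$labels
  sub <- data$subjects
  if (!is.null(subjects)) {
    v <- v[subjects, , drop = FALSE]
    lab <- lab[subjects]
    sub <- sub[subjects]
  }
  info <- data$attr_info
  if (!is.null(attrs)) {
    if (is.character(attrs)) attrs <- match(attrs, info$name)
    v <- v[, attrs, drop = FALSE]
    info <- info[attrs, , drop = FALSE]
  }
  integrated_dataset(v, info$kind, lab, sub,
                     levels = data$levels[intersect(names(data$levels), info$name)])
}

#' Class-mean imputation
#'
#' Replaces each missing numeric value by the mean of that attribute among
#' observed subjects of the same class, and each missing categorical or
#' genotypic value by the within-class mode.  An attribute for which some
#' class has no observed value at all cannot be imputed and is deleted;
#' deletions are recorded in the `deleted` attribute of the result.
#'
#' @param data an [integrated_dataset()] (missing values allowed).
#' @return the dataset with no missing values; deleted attribute names (if
#'   any) in `attr(result, "deleted")`.
#' @export
impute_class_mean <- function(data) {
  v <- data$values
  deleted <- character(0)
  classes <- levels(data$labels)
  for (j in seq_len(ncol(v))) {
    if (!anyNA(v[, j])) next
    kind <- data$attr_info$kind[j]
    for (cl in classes) {
      rows <- data$labels == cl
      miss <- rows & is.na(v[, j])
      if (!any(miss)) next
      obs <- v[rows & !is.na(v[, j]), j]
      if (length(obs) == 0) {
        deleted <- c(deleted, data$attr_info$name[j])
        break
      }
      v[miss, j] <- if (kind == "phenotypic-numeric") {
        mean(obs)
      } else {
        # mode; ties broken by smallest code for determinism
        tab <- table(obs)
        as.numeric(names(tab)[which.max(tab)])
      }
    }
  }
  keep <- setdiff(data$attr_info$name, deleted)
  out <- integrated_dataset(v[, keep, drop = FALSE],
                            data$attr_info$kind[match(keep, data$attr_info$name)],
                            data$labels, data$subjects,
                            levels = data$levels[intersect(names(data$levels), keep)])
  attr(out, "deleted") <- unique(deleted)
  out
}

#' Discretize a numeric attribute into ordered categories
#'
#' Maps values to half-open bins with open-ended first and last bins: with
#' edges `(e1, ..., ek)` the categories are `(-Inf, e1)`, `[e1, e2)`, ...,
#' `[ek, Inf)`, numbered from 1.  A value equal to an edge falls in the
#' higher bin.  The default BMI edges `(22.5, 25, 29.9)` give four
#' categories with BMI < 22.5 as category 1 and BMI >= 30 as category 4.
#'
#' @param x numeric vector (`NA` passes through).
#' @param bin_edges strictly increasing numeric vector of cut points.
#' @return integer vector of categories in `1..(length(bin_edges)+1)`.
#' @export
discretize_numeric <- function(x, bin_edges) {
  if (!is.numeric(x)) stop_format("discretize_numeric requires numeric input")
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop_config("bin edges must be strictly increasing")
  }
  findInterval(x, bin_edges, left.open = FALSE) + 1L
}

#' Assemble the integrated dataset from coded genotypes and phenotypes
#'
#' Concatenates the filter-retained genotype columns with the phenotype
#' columns.  Categorical phenotypes are converted to integer level codes
#' (levels stored in the dataset); numeric phenotypes enter as-is and can
#' be discretized afterwards.  Projections support the three-dataset
#' experiment design.
#'
#' @param coded numeric coded-genotype matrix (`subjects x SNPs`).
#' @param pheno a [phenotype_table()] row-aligned with `coded` (labels are
#'   taken from it), or `NULL` for genotype-only data.
#' @param filter optional [association_filter()] result; only retained
#'   SNPs are kept.
#' @param projection `"integrated"`, `"genotype-only"`, or
#'   `"phenotype-only"`.
#' @param labels required when `pheno` is `NULL`.
#' @return an [integrated_dataset()] (may contain `NA`s; impute next).
#' @export
build_dataset <- function(coded, pheno = NULL, filter = NULL,
                          projection = c("integrated", "genotype-only", "phenotype-only"),
                          labels = NULL) {
  projection <- match.arg(projection)
  if (!is.null(filter)) {
    coded <- coded[, filter$retained, drop = FALSE]
  }
  if (is.null(pheno)) {
    if (is.null(labels)) stop_config("labels required when no phenotype table is given")
    pv <- NULL; pk <- NULL; lv <- list()
  } else {
    labels <- pheno$class_label
    attrs <- pheno$attributes
    pv <- matrix(NA_real_, nrow(attrs), ncol(attrs),
                 dimnames = list(rownames(attrs), names(attrs)))
    pk <- character(ncol(attrs))
    lv <- list()
    for (j in seq_along(attrs)) {
      col <- attrs[[j]]
      if (is.numeric(col)) {
        pv[, j] <- col
        pk[j] <- "phenotypic-numeric"
      } else {
        levs <- sort(unique(col[!is.na(col)]))
        pv[, j] <- match(col, levs)
        pk[j] <- "phenotypic-categorical"
        lv[[names(attrs)[j]]] <- levs
      }
    }
  }
  g_n <- ncol(coded); p_n <- if (is.null(pv)) 0L else ncol(pv)
  values <- switch(projection,
    "integrated" = cbind(coded, pv),
    "genotype-only" = coded,
    "phenotype-only" = pv)
  kinds <- switch(projection,
    "integrated" = c(rep("genotypic", g_n), pk),
    "genotype-only" = rep("genotypic", g_n),
    "phenotype-only" = pk)
  if (is.null(values) || ncol(values) == 0) {
    stop_data("no attributes: zero retained SNPs and zero phenotypes")
  }
  integrated_dataset(values, kinds, labels, rownames(values),
                     levels = if (projection == "genotype-only") list() else lv)
}

#' Serialize an integrated dataset to delimited text
#'
#' Tab-separated values with a `#attr name kind [levels]` sidecar header
#' per attribute; [read_dataset()] restores an identical object.
#'
#' @param data an [integrated_dataset()].
#' @param path output path.
#' @export
write_dataset <- function(data, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (j in seq_len(ncol(data$values))) {
    nm <- data$attr_info$name[j]
    lv <- data$levels[[nm]]
    writeLines(paste(c("#attr", nm, data$attr_info$kind[j], lv), collapse = "\t"), con)
  }
  df <- data.frame(subject = data$subjects, label = as.character(data$labels),
                   data$values, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an integrated dataset written by [write_dataset()]
#' @param path input path.
#' @return an [integrated_dataset()].
#' @export
read_dataset <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#attr\t", lines)
  meta <- strsplit(lines[hdr], "\t")
  df <- utils::read.table(text = lines[!hdr], header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  kinds <- vapply(meta, `[[`, "", 3)
  levels <- list()
  for (m in meta) if (length(m) > 3) levels[[m[[2]]]] <- m[-(1:3)]
  values <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(values) <- df$subject
  integrated_dataset(values, kinds, df$label, df$subject, levels)
}
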