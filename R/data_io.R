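# Readers/writers for the pipeline's on-disk formats (PLINK text PED/MAP,
# delimited phenotype tables, two-column subject-id manifests) and subject
# matching across the genotype and phenotype tables.

#' Construct a genotype table
#'
#' A `genotype_table` holds biallelic SNP calls for a cohort: one unordered
#' allele pair (over A/C/G/T) or `NA` per subject x SNP.  Calls are stored
#' exactly as read; allele-order symmetry is applied at coding time, not
#' here, so I/O round-trips losslessly.
#'
#' @param subject_ids character vector of unique subject identifiers.
#' @param snp_ids character vector of unique SNP identifiers (rsIDs).
#' @param calls character matrix (`subjects x SNPs`) of two-letter allele
#'   pairs such as `"AG"`, or `NA` for missing calls.
#' @param snp_positions optional data frame with columns `chrom` and `pos`,
#'   one row per SNP.
#' @return an object of class `genotype_table`.
#' @export
genotype_table <- function(subject_ids, snp_ids, calls, snp_positions = NULL) {
  subject_ids <- as.character(subject_ids)
  snp_ids <- as.character(snp_ids)
  calls <- as.matrix(calls)
  if (anyDuplicated(subject_ids)) stop_format("duplicate subject ids in genotype table")
  if (anyDuplicated(snp_ids)) stop_format("duplicate SNP ids in genotype table")
  if (!identical(dim(calls), c(length(subject_ids), length(snp_ids)))) {
    stop_format("calls matrix is %d x %d but expected %d x %d",
                nrow(calls), ncol(calls), length(subject_ids), length(snp_ids))
  }
  ok <- is.na(calls) | grepl("^[ACGT][ACGT]$", calls)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop_format("invalid call '%s' for subject %s, SNP %s",
                calls[bad[1], bad[2]], subject_ids[bad[1]], snp_ids[bad[2]])
  }
  dimnames(calls) <- list(subject_ids, snp_ids)
  structure(list(subject_ids = subject_ids, snp_ids = snp_ids,
                 calls = calls, snp_positions = snp_positions),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d subjects x %d SNPs (%.1f%% missing)\n",
              length(x$subject_ids), length(x$snp_ids),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Construct a phenotype table
#'
#' @param subject_ids unique subject identifiers.
#' @param attributes data frame of phenotype columns (numeric or character),
#'   one row per subject; `NA` marks missing.
#' @param class_label per-subject label, one of `"case"`, `"control"`,
#'   `"unknown"`.
#' @return an object of class `phenotype_table`.
#' @export
phenotype_table <- function(subject_ids, attributes, class_label) {
  subject_ids <- as.character(subject_ids)
  if (anyDuplicated(subject_ids)) stop_format("duplicate subject ids in phenotype table")
  class_label <- as.character(class_label)
  if (!all(class_label %in% c("case", "control", "unknown"))) {
    stop_format("class labels must be case/control/unknown")
  }
  attributes <- as.data.frame(attributes, stringsAsFactors = FALSE)
  if (nrow(attributes) != length(subject_ids)) {
    stop_format("attribute rows (%d) do not match subjects (%d)",
                nrow(attributes), length(subject_ids))
  }
  rownames(attributes) <- subject_ids
  structure(list(subject_ids = subject_ids, attributes = attributes,
                 class_label = class_label),
            class = "phenotype_table")
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("phenotype_table: %d subjects, %d attributes (%d case / %d control / %d unknown)\n",
              length(x$subject_ids), ncol(x$attributes),
              sum(x$class_label == "case"), sum(x$class_label == "control"),
              sum(x$class_label == "unknown")))
  invisible(x)
}

#' Read genotypes from PLINK text PED/MAP files
#'
#' Whitespace-delimited PED rows carry six leading columns (family id,
#' subject id, father, mother, sex, phenotype) followed by two allele
#' columns per SNP; the MAP file supplies one row per SNP (chromosome,
#' rsID, genetic distance, base-pair position).  `"0"` alleles mark missing
#' calls.
#'
#' @param ped_path path to the PED file.
#' @param map_path path to the MAP file.
#' @return a [genotype_table()].
#' @export
read_ped_map <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop_format("PED file not found: %s", ped_path)
  if (!file.exists(map_path)) stop_format("MAP file not found: %s", map_path)
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos"))
  if (anyDuplicated(map$snp_id)) stop_format("duplicate SNP ids in MAP file")
  n_snp <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n_sub <- length(lines)
  calls <- matrix(NA_character_, n_sub, n_snp)
  ids <- character(n_sub)
  for (i in seq_len(n_sub)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6 + 2 * n_snp) {
      stop_format("PED row %d has %d fields; expected %d for a %d-SNP MAP",
                  i, length(f), 6 + 2 * n_snp, n_snp)
    }
    ids[i] <- f[2]
    a1 <- f[seq(7, by = 2, length.out = n_snp)]
    a2 <- f[seq(8, by = 2, length.out = n_snp)]
    bad <- !(a1 %in% c("A", "C", "G", "T", "0")) | !(a2 %in% c("A", "C", "G", "T", "0"))
    if (any(bad)) {
      j <- which(bad)[1]
      stop_format("PED row %d, SNP %s: allele outside {A,C,G,T,0}: '%s %s'",
                  i, map$snp_id[j], a1[j], a2[j])
    }
    miss <- a1 == "0" | a2 == "0"
    row <- paste0(a1, a2)
    row[miss] <- NA_character_
    calls[i, ] <- row
  }
  genotype_table(ids, map$snp_id, calls,
                 snp_positions = map[, c("chrom", "pos")])
}

#' Write a genotype table as PLINK text PED/MAP
#'
#' Inverse of [read_ped_map()]: re-reading the written pair reproduces the
#' table call-by-call.
#'
#' @param geno a [genotype_table()].
#' @param ped_path,map_path output paths.
#' @param labels optional factor of case/control labels written to the PED
#'   phenotype column as 2/1 (PLINK convention); otherwise 0.
#' @export
write_ped_map <- function(geno, ped_path, map_path, labels = NULL) {
  pos <- geno$snp_positions
  if (is.null(pos)) pos <- data.frame(chrom = 1L, pos = seq_along(geno$snp_ids))
  utils::write.table(data.frame(pos$chrom, geno$snp_ids, 0, pos$pos),
                     map_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  phe <- rep("0", length(geno$subject_ids))
  if (!is.null(labels)) phe <- ifelse(as.character(labels) == "case", "2", "1")
  con <- file(ped_path, "w")
  on.exit(close(con))
  for (i in seq_along(geno$subject_ids)) {
    row <- geno$calls[i, ]
    a1 <- ifelse(is.na(row), "0", substr(row, 1, 1))
    a2 <- ifelse(is.na(row), "0", substr(row, 2, 2))
    alleles <- character(2 * length(row))
    alleles[c(TRUE, FALSE)] <- a1
    alleles[c(FALSE, TRUE)] <- a2
    writeLines(paste(c("FAM", geno$subject_ids[i], "0", "0", "0", phe[i], alleles),
                     collapse = " "), con)
  }
  invisible(c(ped_path, map_path))
}

#' Read a phenotype table from delimited text
#'
#' Columns other than the subject-id and label columns are typed numeric
#' when every non-empty cell parses as a number, otherwise kept as
#' categorical strings.  Empty cells become `NA` and are left for the
#' class-mean imputation stage.
#'
#' @param path path to a delimited text file with a header row.
#' @param label_column name of the case/control column.
#' @param case_value,control_value values in `label_column` mapped to case
#'   and control; any other value becomes `"unknown"`.
#' @param id_column name of the subject-id column (default first column).
#' @param sep field separator (default `","`).
#' @return a [phenotype_table()].
#' @export
read_phenotypes <- function(path, label_column, case_value, control_value,
                            id_column = NULL, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"),
                          colClasses = "character", check.names = FALSE)
  if (is.null(id_column)) id_column <- names(df)[1]
  if (!label_column %in% names(df)) {
    stop_config("label column '%s' not found in %s", label_column, path)
  }
  if (anyDuplicated(df[[id_column]])) {
    stop_format("duplicate subject ids in %s", path)
  }
  raw <- df[[label_column]]
  lab <- ifelse(is.na(raw), "unknown",
                ifelse(raw == as.character(case_value), "case",
                       ifelse(raw == as.character(control_value), "control", "unknown")))
  attrs <- df[, setdiff(names(df), c(id_column, label_column)), drop = FALSE]
  for (nm in names(attrs)) {
    v <- attrs[[nm]]
    num <- suppressWarnings(as.numeric(v))
    if (all(is.na(num) == is.na(v))) attrs[[nm]] <- num
  }
  phenotype_table(df[[id_column]], attrs, lab)
}

#' Read a subject-id manifest
#'
#' Two-column delimited file mapping genotype subject ids to phenotype
#' subject ids; the mapping must be one-to-one over the listed pairs.
#'
#' @param path path to the manifest file (header with two columns).
#' @return data frame with columns `genotype_id` and `phenotype_id`.
#' @export
read_manifest <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop_format("manifest must have two columns")
  out <- data.frame(genotype_id = df[[1]], phenotype_id = df[[2]],
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$genotype_id) || anyDuplicated(out$phenotype_id)) {
    stop_format("manifest mapping is not one-to-one")
  }
  out
}

#' Match genotype and phenotype tables by subject id
#'
#' Restricts both tables to the subjects present in both under the manifest
#' mapping, ordered identically (by genotype id).  Subjects whose class
#' label is `"unknown"` are dropped: the downstream model is a supervised
#' binary classifier.
#'
#' @param geno a [genotype_table()].
#' @param pheno a [phenotype_table()].
#' @param manifest data frame as returned by [read_manifest()]; defaults to
#'   the identity mapping over the genotype ids.
#' @return list with elements `geno` and `pheno`, row-aligned.
#' @export
match_subjects <- function(geno, pheno, manifest = NULL) {
  if (is.null(manifest)) {
    manifest <- data.frame(genotype_id = geno$subject_ids,
                           phenotype_id = geno$subject_ids,
                           stringsAsFactors = FALSE)
  }
  keep <- manifest$genotype_id %in% geno$subject_ids &
    manifest$phenotype_id %in% pheno$subject_ids
  manifest <- manifest[keep, , drop = FALSE]
  if (nrow(manifest) > 0) {
    lab <- pheno$class_label[match(manifest$phenotype_id, pheno$subject_ids)]
    manifest <- manifest[lab != "unknown", , drop = FALSE]
  }
  if (nrow(manifest) == 0) stop_data("no subjects shared between genotype and phenotype tables")
  gi <- match(manifest$genotype_id, geno$subject_ids)
  pi <- match(manifest$phenotype_id, pheno$subject_ids)
  g <- genotype_table(geno$subject_ids[gi], geno$snp_ids,
                      geno$calls[gi, , drop = FALSE], geno$snp_positions)
  p <- phenotype_table(pheno$subject_ids[pi],
                       pheno$attributes[pi, , drop = FALSE],
                       pheno$class_label[pi])
  list(geno = g, pheno = p)
}
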