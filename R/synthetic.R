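# Seeded synthetic case-control cohorts with the structure the method
# assumes: an ethnically stratified population, Hardy-Weinberg genotypes
# with per-stratum allele frequencies, a handful of planted causal SNPs
# acting on case odds through a logistic risk model, class-shifted
# phenotypes, and uniform missingness.

#' Specify a synthetic cohort
#'
#' Defaults describe a 1/5-scale version of a multi-ethnic prostate-cancer
#' case-control study: 930 cases and 959 controls over three strata with
#' realistic relative risks, 2000 SNPs of which 5 are causal.
#'
#' @param n_cases,n_controls subject counts.
#' @param n_snps total SNPs; `n_causal` of them causal.
#' @param n_causal number of planted causal SNPs.
#' @param strata data frame with columns `name`, `proportion` (summing to
#'   1), `risk_multiplier` (odds multiplier on case risk).
#' @param allele_freq_range minor-allele-frequency interval in (0, 1);
#'   frequencies are drawn uniformly per stratum per SNP.
#' @param causal_effect per-minor-allele odds multiplier at causal SNPs
#'   (1 = null).
#' @param phenotype_effects list with `bmi_shift` (mean BMI difference of
#'   cases vs controls, kg/m^2), `smoking_or` and `family_history_or`
#'   (case vs control odds ratios of the binary phenotypes); zeros/ones
#'   give a null cohort.
#' @param missing_rate per-cell missingness probability for genotype calls
#'   and phenotype values.
#' @param seed integer seed; the cohort is fully reproducible from it.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_cases = 930, n_controls = 959, n_snps = 2000,
                           n_causal = 5,
                           strata = data.frame(
                             name = c("AA", "JAP", "LAT"),
                             proportion = rep(1 / 3, 3),
                             risk_multiplier = c(1.25, 0.8, 1.0)),
                           allele_freq_range = c(0.05, 0.5),
                           causal_effect = 1.8,
                           phenotype_effects = list(bmi_shift = 1.5,
                                                    smoking_or = 1.5,
                                                    family_history_or = 2.0),
                           missing_rate = 0.02, seed = 1) {
  stopifnot(n_causal <= n_snps, missing_rate >= 0, missing_rate < 1,
            abs(sum(strata$proportion) - 1) < 1e-8,
            allele_freq_range[1] > 0, allele_freq_range[2] < 1)
  structure(list(n_cases = n_cases, n_controls = n_controls, n_snps = n_snps,
                 n_causal = n_causal, strata = strata,
                 allele_freq_range = allele_freq_range,
                 causal_effect = causal_effect,
                 phenotype_effects = phenotype_effects,
                 missing_rate = missing_rate, seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic case-control cohort
#'
#' Per stratum, minor-allele frequencies are drawn uniformly in the
#' configured range and genotypes follow Hardy-Weinberg proportions.
#' Case/control status comes from a logistic model combining the stratum
#' risk multiplier and the per-minor-allele effects of the causal SNPs;
#' subjects are accumulated by bounded rejection sampling until the
#' requested class counts are reached.  BMI is then drawn normal per
#' class with the configured shift (controls: mean 26.5, sd 4.5);
#' smoking and family history are Bernoulli with class-dependent odds
#' (control prevalences 0.25 and 0.10).  Missingness is applied
#' uniformly at random.
#'
#' @param spec a [synthetic_spec()].
#' @return a `synthetic_cohort`: list with `geno` ([genotype_table()]),
#'   `pheno` ([phenotype_table()]), `manifest`, and `truth` (causal SNP
#'   ids and per-stratum allele frequencies).
#' @export
generate_cohort <- function(spec) {
  with_seed(spec$seed, {
    S <- nrow(spec$strata)
    n_total <- spec$n_cases + spec$n_controls
    snp_ids <- sprintf("rs%07d", sample.int(9.8e6, spec$n_snps))
    causal_ids <- if (spec$n_causal > 0) snp_ids[seq_len(spec$n_causal)] else character(0)
    maf <- matrix(stats::runif(S * spec$n_snps, spec$allele_freq_range[1],
                               spec$allele_freq_range[2]), S, spec$n_snps)
    # two distinct allele letters per SNP; column 1 = major, 2 = minor
    alleles <- t(vapply(seq_len(spec$n_snps),
                        function(j) sample(c("A", "C", "G", "T"), 2), character(2)))

    beta <- log(spec$causal_effect)
    target <- spec$n_cases / n_total
    mean_gen <- if (spec$n_causal > 0) {
      sum(2 * colMeans(maf[, seq_len(spec$n_causal), drop = FALSE]) * beta)
    } else 0
    intercept <- stats::qlogis(target) -
      sum(spec$strata$proportion * log(spec$strata$risk_multiplier)) - mean_gen

    stratum <- integer(0); label <- character(0)
    causal_g <- matrix(0L, 0, spec$n_causal)
    for (round in seq_len(30)) {
      need_case <- spec$n_cases - sum(label == "case")
      need_ctrl <- spec$n_controls - sum(label == "control")
      if (need_case <= 0 && need_ctrl <= 0) break
      B <- max(2 * (need_case + need_ctrl), 200)
      st <- sample.int(S, B, replace = TRUE, prob = spec$strata$proportion)
      cg <- matrix(0L, B, spec$n_causal)
      for (j in seq_len(spec$n_causal)) {
        cg[, j] <- stats::rbinom(B, 2, maf[st, j])
      }
      lp <- intercept + log(spec$strata$risk_multiplier)[st] +
        if (spec$n_causal > 0) as.numeric(cg %*% rep(beta, spec$n_causal)) else 0
      lab <- ifelse(stats::runif(B) < stats::plogis(lp), "case", "control")
      take <- c(which(lab == "case")[seq_len(min(need_case, sum(lab == "case")))],
                which(lab == "control")[seq_len(min(need_ctrl, sum(lab == "control")))])
      take <- take[!is.na(take)]
      stratum <- c(stratum, st[take])
      label <- c(label, lab[take])
      causal_g <- rbind(causal_g, cg[take, , drop = FALSE])
    }
    if (sum(label == "case") < spec$n_cases || sum(label == "control") < spec$n_controls) {
      stop_data("risk model could not yield the requested class counts")
    }
    ord <- sample.int(n_total)  # interleave cases and controls
    stratum <- stratum[ord]; label <- label[ord]
    causal_g <- causal_g[ord, , drop = FALSE]

    counts <- matrix(0L, n_total, spec$n_snps)
    if (spec$n_causal > 0) counts[, seq_len(spec$n_causal)] <- causal_g
    noncausal <- setdiff(seq_len(spec$n_snps), seq_len(spec$n_causal))
    for (s in seq_len(S)) {
      rows <- which(stratum == s)
      if (!length(rows)) next
      counts[rows, noncausal] <- matrix(
        stats::rbinom(length(rows) * length(noncausal), 2,
                      rep(maf[s, noncausal], each = length(rows))),
        length(rows), length(noncausal))
    }
    # minor-allele counts -> two-letter calls
    major <- matrix(alleles[, 1], n_total, spec$n_snps, byrow = TRUE)
    minor <- matrix(alleles[, 2], n_total, spec$n_snps, byrow = TRUE)
    a1 <- ifelse(counts == 2, minor, major)
    a2 <- ifelse(counts >= 1, minor, major)
    calls <- matrix(paste0(a1, a2), n_total, spec$n_snps)
    if (spec$missing_rate > 0) {
      calls[stats::runif(length(calls)) < spec$missing_rate] <- NA_character_
    }

    is_case <- label == "case"
    eff <- spec$phenotype_effects
    bmi <- stats::rnorm(n_total, 26.5 + ifelse(is_case, eff$bmi_shift %||% 0, 0), 4.5)
    odds_p <- function(p0, or) { o <- p0 / (1 - p0) * or; o / (1 + o) }
    smoking <- stats::rbinom(n_total, 1,
                             ifelse(is_case, odds_p(0.25, eff$smoking_or %||% 1), 0.25))
    famhist <- stats::rbinom(n_total, 1,
                             ifelse(is_case, odds_p(0.10, eff$family_history_or %||% 1), 0.10))
    attrs <- data.frame(ethnicity = spec$strata$name[stratum],
                        bmi = round(bmi, 1),
                        smoking = c("no", "yes")[smoking + 1],
                        family_history = c("no", "yes")[famhist + 1],
                        stringsAsFactors = FALSE)
    if (spec$missing_rate > 0) {
      for (j in seq_along(attrs)) {
        attrs[[j]][stats::runif(n_total) < spec$missing_rate] <- NA
      }
    }

    gids <- sprintf("G%05d", seq_len(n_total))
    pids <- sprintf("P%05d", seq_len(n_total))
    geno <- genotype_table(gids, snp_ids, calls)
    pheno <- phenotype_table(pids, attrs, label)
    manifest <- data.frame(genotype_id = gids, phenotype_id = pids,
                           stringsAsFactors = FALSE)
    structure(list(geno = geno, pheno = pheno, manifest = manifest,
                   truth = list(causal_snps = causal_ids, maf = maf,
                                alleles = alleles, stratum = stratum,
                                spec = spec)),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d subjects, %d SNPs (%d causal), strata %s\n",
              length(x$geno$subject_ids), length(x$geno$snp_ids),
              length(x$truth$causal_snps),
              paste(x$truth$spec$strata$name, collapse = "/")))
  invisible(x)
}

#' Write a cohort to disk in the formats the readers consume
#'
#' PED/MAP genotypes, phenotype CSV (label column `status` with values
#' `case`/`control`), manifest CSV, and a ground-truth JSON.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if absent).
#' @return named vector of the four file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ped = file.path(dir, "cohort.ped"), map = file.path(dir, "cohort.map"),
             phenotypes = file.path(dir, "phenotypes.csv"),
             manifest = file.path(dir, "manifest.csv"),
             truth = file.path(dir, "truth.json"))
  write_ped_map(cohort$geno, paths["ped"], paths["map"])
  df <- cbind(subject_id = cohort$pheno$subject_ids,
              cohort$pheno$attributes,
              status = cohort$pheno$class_label)
  utils::write.csv(df, paths["phenotypes"], row.names = FALSE, quote = FALSE, na = "")
  utils::write.csv(cohort$manifest, paths["manifest"], row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(causal_snps = cohort$truth$causal_snps,
                            strata = cohort$truth$spec$strata$name),
                       paths["truth"], auto_unbox = FALSE)
  paths
}

#' Causal-SNP recovery of a fitted tree
#'
#' Treats the SNP attributes appearing anywhere in the tree as "selected"
#' and reports precision (`|selected & causal| / |selected|`) and recall
#' (`|selected & causal| / |causal|`) against the cohort's planted causal
#' SNPs.  A tree selecting no SNPs is degenerate: both reported as 0 with
#' `degenerate = TRUE`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param tree an `id3_node` fitted on the cohort.
#' @return list with `selected`, `precision`, `recall`, `degenerate`.
#' @export
recovery_report <- function(cohort, tree) {
  selected <- intersect(tree_attributes(tree), cohort$geno$snp_ids)
  causal <- cohort$truth$causal_snps
  if (length(selected) == 0) {
    return(list(selected = character(0), precision = 0, recall = 0,
                degenerate = TRUE))
  }
  hit <- length(intersect(selected, causal))
  list(selected = selected,
       precision = hit / length(selected),
       recall = if (length(causal)) hit / length(causal) else NA_real_,
       degenerate = FALSE)
}
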