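#' Quality-control configuration
#'
#' Thresholds of the SNP/sample filter cascade. Defaults are the standard
#' GBS-panel criteria: individual and per-SNP genotype detection rate >= 0.90,
#' minor allele frequency >= 0.01, Hardy-Weinberg exact-test p >= 1e-6, and
#' autosomal markers only.
#'
#' `min_depth` and `min_q20` describe read-level genotyping criteria that are
#' applied upstream of a genotype matrix; they are accepted and recorded for
#' provenance but cannot be (and are not) enforced here.
#'
#' @param min_sample_call_rate,min_snp_call_rate,min_maf,hwe_p_threshold
#'   filter thresholds, all in `[0, 1]`.
#' @param autosomes_only drop markers whose chromosome is not in `autosomes`.
#' @param autosomes character vector of autosome labels (donkey default
#'   `"1"`..`"30"`).
#' @param min_depth,min_q20 provenance-only upstream criteria.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(min_sample_call_rate = 0.90, min_snp_call_rate = 0.90,
                      min_maf = 0.01, hwe_p_threshold = 1e-6,
                      autosomes_only = TRUE,
                      autosomes = as.character(1:30),
                      min_depth = 10, min_q20 = 0.95) {
  stopifnot(min_sample_call_rate >= 0, min_sample_call_rate <= 1,
            min_snp_call_rate >= 0, min_snp_call_rate <= 1,
            min_maf >= 0, min_maf <= 1,
            hwe_p_threshold >= 0, hwe_p_threshold <= 1)
  structure(list(min_sample_call_rate = min_sample_call_rate,
                 min_snp_call_rate = min_snp_call_rate,
                 min_maf = min_maf, hwe_p_threshold = hwe_p_threshold,
                 autosomes_only = autosomes_only, autosomes = autosomes,
                 min_depth = min_depth, min_q20 = min_q20),
            class = "qc_config")
}

#' Genotype call rates
#'
#' Fraction of non-missing entries in one variant column
#' (`snp_call_rate`) or one sample row (`sample_call_rate`).
#'
#' @param gm a [genotype_matrix()].
#' @param variant_index,sample_index column/row index (integer) or id
#'   (character).
#' @return A fraction in `[0, 1]`.
#' @export
snp_call_rate <- function(gm, variant_index) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (nrow(gm$dosage) == 0)
    stop("call rate undefined: no samples")
  if (is.character(variant_index))
    variant_index <- match(variant_index, gm$variants$id)
  mean(!is.na(gm$dosage[, variant_index]))
}

#' @rdname snp_call_rate
#' @export
sample_call_rate <- function(gm, sample_index) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (ncol(gm$dosage) == 0)
    stop("call rate undefined: no variants")
  if (is.character(sample_index))
    sample_index <- match(sample_index, gm$samples$id)
  mean(!is.na(gm$dosage[sample_index, ]))
}

#' Apply the SNP/sample quality-control cascade
#'
#' First drops samples whose overall genotype detection rate is below
#' `min_sample_call_rate`. On the remaining samples, each SNP criterion is
#' then evaluated on the full input marker set and the union of failures is
#' removed: call rate below `min_snp_call_rate`, minor allele frequency
#' (computed on called genotypes) below `min_maf`, Hardy-Weinberg exact-test
#' p-value below `hwe_p_threshold` (autosomal markers only; sex-linked
#' markers are excluded from the HWE test), and non-autosomal location when
#' `autosomes_only` is set.
#'
#' The per-criterion counts in the report are standalone tallies on the
#' input, so they may overlap and need not sum to `total - retained`; the
#' removed set is their union. This is the conventional presentation of a
#' PLINK-style filter table.
#'
#' @param gm a [genotype_matrix()].
#' @param cfg a [qc_config()].
#' @return A list with elements `genotypes` (the filtered
#'   [genotype_matrix()]) and `report` (class `qc_report`: `total_snps`,
#'   standalone counts `callrate_fail`, `maf_fail`, `hwe_fail`, `chrx`,
#'   `chry`, `other_nonautosomal`, plus `snps_retained` and
#'   `samples_removed`).
#' @export
apply_qc <- function(gm, cfg = qc_config()) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(cfg, "qc_config"))
  scr <- rowMeans(!is.na(gm$dosage))
  drop_samples <- which(scr < cfg$min_sample_call_rate)
  samples_removed <- gm$samples$id[drop_samples]
  if (length(drop_samples) == nrow(gm$samples))
    stop("QC removed every sample (min_sample_call_rate = ",
         cfg$min_sample_call_rate, ")")
  gms <- if (length(drop_samples))
    subset_genotypes(gm, sample_ids = gm$samples$id[-drop_samples]) else gm

  d <- gms$dosage
  n_called <- colSums(!is.na(d))
  callrate <- n_called / nrow(d)
  p <- colSums(d, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  maf <- pmin(p, 1 - p)
  maf[n_called == 0] <- NA

  is_auto <- gms$variants$chrom %in% cfg$autosomes
  hwe_p <- rep(NA_real_, ncol(d))
  if (any(is_auto & n_called > 0)) {
    idx <- which(is_auto & n_called > 0)
    het <- colSums(d[, idx, drop = FALSE] == 1L, na.rm = TRUE)
    hom_alt <- colSums(d[, idx, drop = FALSE] == 2L, na.rm = TRUE)
    hom_ref <- n_called[idx] - het - hom_alt
    key <- paste(hom_ref, het, hom_alt)
    uk <- !duplicated(key)
    pv <- vapply(which(uk), function(i)
      hwe_exact_test(hom_ref[i], het[i], hom_alt[i]), numeric(1))
    names(pv) <- key[uk]
    hwe_p[idx] <- pv[key]
  }

  fail_callrate <- callrate < cfg$min_snp_call_rate
  fail_maf <- !is.na(maf) & maf < cfg$min_maf
  fail_hwe <- !is.na(hwe_p) & hwe_p < cfg$hwe_p_threshold
  is_x <- gms$variants$chrom == "X"
  is_y <- gms$variants$chrom == "Y"
  fail_chrom <- if (cfg$autosomes_only) !is_auto else rep(FALSE, ncol(d))

  drop_v <- fail_callrate | fail_maf | fail_hwe | fail_chrom
  out <- subset_genotypes(gms, variants = !drop_v)
  report <- structure(list(
    total_snps = ncol(gm$dosage),
    callrate_fail = sum(fail_callrate),
    maf_fail = sum(fail_maf),
    hwe_fail = sum(fail_hwe),
    chrx = sum(is_x),
    chry = sum(is_y),
    other_nonautosomal = sum(!is_auto & !is_x & !is_y),
    snps_retained = ncol(out$dosage),
    samples_removed = samples_removed,
    config = cfg), class = "qc_report")
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("SNP quality control\n")
  cat(sprintf("  %-42s %d\n", "Total number of SNPs", x$total_snps))
  cat(sprintf("  %-42s %d\n",
              paste0("SNPs with MAF < ", x$config$min_maf), x$maf_fail))
  cat(sprintf("  %-42s %d\n",
              paste0("SNPs out of HWE (p < ", x$config$hwe_p_threshold, ")"),
              x$hwe_fail))
  cat(sprintf("  %-42s %d\n",
              paste0("SNPs with call rate < ", x$config$min_snp_call_rate),
              x$callrate_fail))
  cat(sprintf("  %-42s %d\n", "SNPs on chromosome X", x$chrx))
  cat(sprintf("  %-42s %d\n", "SNPs on chromosome Y", x$chry))
  cat(sprintf("  %-42s %d\n", "SNPs used after quality control",
              x$snps_retained))
  if (length(x$samples_removed))
    cat("  samples removed:", paste(x$samples_removed, collapse = ", "),
        "\n")
  invisible(x)
}

#' Tidy a QC report into a two-column table
#'
#' @param report a `qc_report` from [apply_qc()].
#' @return A data.frame with columns `criterion` and `n_snps`, shaped like a
#'   published SNP-filter table.
#' @export
qc_report_table <- function(report) {
  stopifnot(inherits(report, "qc_report"))
  data.frame(
    criterion = c("Total number of SNPs",
                  paste0("SNP with MAF < ", report$config$min_maf),
                  paste0("SNP not in Hardy-Weinberg equilibrium (p < ",
                         report$config$hwe_p_threshold, ")"),
                  paste0("SNP with callrate < ",
                         report$config$min_snp_call_rate),
                  "SNPs on chromosome X", "SNPs on chromosome Y",
                  "SNPs used after quality control"),
    n_snps = c(report$total_snps, report$maf_fail, report$hwe_fail,
               report$callrate_fail, report$chrx, report$chry,
               report$snps_retained),
    stringsAsFactors = FALSE)
}
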