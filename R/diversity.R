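#' Allele frequency of one locus
#'
#' @param dosage integer vector of alternate-allele dosages (0/1/2, `NA`
#'   missing) for one locus.
#' @return A list with `p` (alternate-allele frequency among called
#'   genotypes), `maf` (`min(p, 1 - p)`) and `n_called`.
#' @examples
#' locus_frequencies(c(0, 1, 2, 2, NA))  # p = 5/8
#' @export
locus_frequencies <- function(dosage) {
  called <- !is.na(dosage)
  n <- sum(called)
  if (n == 0) stop("allele frequency undefined: no called genotypes")
  p <- sum(dosage[called]) / (2 * n)
  list(p = p, maf = min(p, 1 - p), n_called = n)
}

check_freqs <- function(freqs) {
  if (any(freqs < 0)) stop("allele frequencies must be nonnegative")
  if (abs(sum(freqs) - 1) > 1e-9)
    stop("allele frequencies must sum to 1 (got ", sum(freqs), ")")
}

#' Polymorphism information content
#'
#' Botstein's marker-informativeness index:
#' `PIC = 1 - sum_i p_i^2 - sum_{i<j} 2 p_i^2 p_j^2`. For a biallelic locus
#' this is `1 - (p^2 + q^2) - 2 p^2 q^2`, with maximum 0.375 at p = 0.5.
#'
#' @param freqs numeric vector of allele frequencies summing to 1.
#' @return The PIC value.
#' @examples
#' pic(c(0.5, 0.5))  # 0.375
#' @export
pic <- function(freqs) {
  check_freqs(freqs)
  sq <- freqs^2
  s2 <- sum(sq)
  # sum_{i<j} p_i^2 p_j^2 = ((sum p^2)^2 - sum p^4) / 2
  cross <- (s2^2 - sum(sq^2)) / 2
  1 - s2 - 2 * cross
}

#' Expected heterozygosity
#'
#' Gene diversity `He = 1 - sum p_i^2`, the probability that a random
#' individual is heterozygous under Hardy-Weinberg proportions. By default no
#' small-sample correction is applied; set `n` to apply Nei's
#' `2n/(2n - 1)` unbiased correction.
#'
#' @param freqs allele frequencies summing to 1.
#' @param n optional number of diploid individuals for the unbiased
#'   correction.
#' @return He in `[0, 1]`.
#' @export
expected_heterozygosity <- function(freqs, n = NULL) {
  check_freqs(freqs)
  he <- 1 - sum(freqs^2)
  if (!is.null(n) && n > 0) he <- he * 2 * n / (2 * n - 1)
  he
}

#' Observed heterozygosity of one locus
#'
#' Fraction of called genotypes that are heterozygous.
#'
#' @param dosage dosage vector for one locus (0/1/2, `NA` missing).
#' @return Ho in `[0, 1]`.
#' @export
observed_heterozygosity <- function(dosage) {
  called <- !is.na(dosage)
  if (!any(called)) stop("Ho undefined: no called genotypes")
  mean(dosage[called] == 1)
}

#' Effective number of alleles
#'
#' `Ae = 1 / sum p_i^2`: the count of equifrequent alleles that would give
#' the same homozygosity.
#'
#' @param freqs allele frequencies summing to 1.
#' @return Ae, at least 1.
#' @export
effective_allele_number <- function(freqs) {
  check_freqs(freqs)
  1 / sum(freqs^2)
}

#' Proportion of polymorphic markers
#'
#' Fraction of loci whose minor allele frequency reaches `threshold`. At
#' `threshold = 0` the boundary convention is strict positivity (a locus
#' counts as polymorphic if any variation was seen at all).
#'
#' @param maf per-locus minor allele frequencies.
#' @param threshold polymorphism threshold in `[0, 0.5]`; the conventional
#'   default is 0.05.
#' @return PN in `[0, 1]`.
#' @export
proportion_polymorphic <- function(maf, threshold = 0.05) {
  stopifnot(threshold >= 0, threshold <= 0.5)
  if (length(maf) == 0) return(NaN)
  if (threshold == 0) mean(maf > 0) else mean(maf >= threshold)
}

#' Hardy-Weinberg exact test for a biallelic locus
#'
#' Two-sided exact test on observed genotype counts: conditional on the
#' allele counts, the number of heterozygotes follows the hypergeometric-type
#' HWE null; the p-value is the total probability of all heterozygote-count
#' outcomes no more probable than the observed one (the standard SNP exact
#' test, PLINK's default).
#'
#' The standard p-value is conservative because the whole probability of
#' the observed outcome is included; `midp = TRUE` applies the mid-p
#' adjustment (half the observed outcome's probability), whose null
#' distribution is approximately uniform.
#'
#' @param n_hom_ref,n_het,n_hom_alt observed genotype counts.
#' @param midp apply the mid-p adjustment (default `FALSE`, the standard
#'   exact test).
#' @return The exact p-value. A monomorphic table has a single outcome and
#'   p = 1.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt, midp = FALSE) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) stop("HWE test needs at least one genotype")
  n_alt <- 2 * n_hom_alt + n_het
  n_rare <- min(n_alt, 2 * n - n_alt)
  if (n_rare == 0) return(1)

  # P(het | n, n_rare) over het = n_rare, n_rare - 2, ...; computed by the
  # ratio recurrence from the mid het count for numerical stability
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  probs <- numeric(length(hets))
  mid_i <- which.min(abs(hets - n_rare * (2 * n - n_rare) / (2 * n)))
  probs[mid_i] <- 1
  if (mid_i < length(hets)) {
    for (i in mid_i:(length(hets) - 1)) {
      h <- hets[i]
      hr <- (n_rare - h) / 2          # rare-homozygotes at het = h
      hc <- n - h - hr
      # P(h + 2) / P(h)
      probs[i + 1] <- probs[i] * 4 * hr * hc / ((h + 2) * (h + 1))
    }
  }
  if (mid_i > 1) {
    for (i in mid_i:2) {
      h <- hets[i]
      hr <- (n_rare - h) / 2
      hc <- n - h - hr
      # P(h - 2) / P(h)
      probs[i - 1] <- probs[i] * h * (h - 1) / (4 * (hr + 1) * (hc + 1))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  if (is.na(p_obs)) stop("heterozygote count inconsistent with allele counts")
  p <- sum(probs[probs <= p_obs * (1 + 1e-12)])
  if (midp) p <- p - 0.5 * p_obs
  min(1, p)
}

#' Per-locus diversity table
#'
#' Computes `p`, `maf`, `ho`, `he`, `pic`, `ae`, `n_called` and `hwe_p` for
#' every marker of a genotype matrix (`NA` for all-missing loci; the HWE
#' exact test is run on autosomal markers).
#'
#' @param gm a [genotype_matrix()].
#' @param autosomes autosome labels for the HWE column.
#' @return A data.frame with one row per marker, prefixed by `chrom`, `pos`
#'   and `id`.
#' @export
locus_stats <- function(gm, autosomes = as.character(1:30)) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$dosage
  n_called <- colSums(!is.na(d))
  p <- ifelse(n_called > 0, colSums(d, na.rm = TRUE) / (2 * pmax(n_called, 1L)), NA)
  maf <- pmin(p, 1 - p)
  het <- colSums(d == 1L, na.rm = TRUE)
  ho <- ifelse(n_called > 0, het / pmax(n_called, 1L), NA)
  he <- 2 * p * (1 - p)
  pic_v <- 1 - (p^2 + (1 - p)^2) - 2 * p^2 * (1 - p)^2
  ae <- 1 / (p^2 + (1 - p)^2)
  hwe_p <- rep(NA_real_, ncol(d))
  idx <- which(gm$variants$chrom %in% autosomes & n_called > 0)
  if (length(idx)) {
    hom_alt <- colSums(d[, idx, drop = FALSE] == 2L, na.rm = TRUE)
    hom_ref <- n_called[idx] - het[idx] - hom_alt
    key <- paste(hom_ref, het[idx], hom_alt)
    uk <- !duplicated(key)
    pv <- vapply(which(uk), function(i)
      hwe_exact_test(hom_ref[i], het[idx][i], hom_alt[i]), numeric(1))
    names(pv) <- key[uk]
    hwe_p[idx] <- pv[key]
  }
  data.frame(chrom = gm$variants$chrom, pos = gm$variants$pos,
             id = gm$variants$id, p = p, maf = maf, ho = ho, he = he,
             pic = pic_v, ae = ae, n_called = n_called, hwe_p = hwe_p,
             stringsAsFactors = FALSE)
}

#' Population diversity summary
#'
#' Means of the per-locus statistics over all (typically QC-passed) markers,
#' the proportion of polymorphic markers at `pn_threshold`, and optionally
#' the LD-based effective population size.
#'
#' @param gm a [genotype_matrix()].
#' @param pn_threshold MAF threshold defining a polymorphic marker.
#' @param ne compute [ne_from_ld()] as well (slower; needs >= 2 loci).
#' @param autosomes autosome labels passed through to [locus_stats()].
#' @param ... further arguments to [ne_from_ld()].
#' @return A list of class `population_diversity` with `mean_maf`, `pn`,
#'   `mean_ho`, `mean_he`, `mean_pic`, `mean_ae`, `ne_ld` (or `NA`),
#'   `n_loci`, `n_samples`.
#' @export
diversity_summary <- function(gm, pn_threshold = 0.05, ne = FALSE,
                              autosomes = as.character(1:30), ...) {
  ls <- locus_stats(gm, autosomes = autosomes)
  ok <- ls$n_called > 0
  ne_ld <- if (ne) tryCatch(ne_from_ld(gm, ...)$ne, error = function(e) NA_real_)
           else NA_real_
  structure(list(
    mean_maf = mean(ls$maf[ok]),
    pn = proportion_polymorphic(ls$maf[ok], pn_threshold),
    pn_threshold = pn_threshold,
    mean_ho = mean(ls$ho[ok]),
    mean_he = mean(ls$he[ok]),
    mean_pic = mean(ls$pic[ok]),
    mean_ae = mean(ls$ae[ok]),
    ne_ld = ne_ld,
    n_loci = sum(ok),
    n_samples = nrow(gm$samples)), class = "population_diversity")
}

#' @export
print.population_diversity <- function(x, ...) {
  cat("Population genetic diversity (", x$n_samples, " samples, ",
      x$n_loci, " loci)\n", sep = "")
  cat(sprintf("  %-44s %.3f\n", "Minor Allele Frequency (MAF)", x$mean_maf))
  cat(sprintf("  %-44s %.3f\n",
              paste0("Proportion of Polymorphic Markers (PN, maf >= ",
                     x$pn_threshold, ")"), x$pn))
  cat(sprintf("  %-44s %.3f\n", "Observed Heterozygosity (Ho)", x$mean_ho))
  cat(sprintf("  %-44s %.3f\n", "Expected Heterozygosity (He)", x$mean_he))
  cat(sprintf("  %-44s %.3f\n", "Polymorphism Information Content (PIC)",
              x$mean_pic))
  cat(sprintf("  %-44s %.3f\n", "Effective Numbers of Alleles", x$mean_ae))
  if (!is.na(x$ne_ld))
    cat(sprintf("  %-44s %.1f\n", "Effective Population Size (Ne, LD)",
                x$ne_ld))
  invisible(x)
}

#' Per-pair Sved relation between LD and effective population size
#'
#' Inverts Sved's drift expectation `E[r2] = 1 / (1 + 4 N c)` for one locus
#' pair: `Ne = (1 / (4 c)) * (1 / r2_adj - 1)`.
#'
#' @param r2_adj sample-size-adjusted squared correlation.
#' @param c recombination fraction between the pair (Morgans, capped at 0.5
#'   by the caller).
#' @return The implied Ne (0 when `r2_adj = 1`).
#' @export
sved_ne <- function(r2_adj, c) {
  (1 / (4 * c)) * (1 / r2_adj - 1)
}

#' LD-based effective population size
#'
#' Computes the squared genotype correlation `r2` for every marker pair on
#' the same chromosome within `max_pair_dist`, adjusts for finite sample
#' size (`r2_adj = r2 - 1/(2n)`, floored at `r2_floor`), and converts each
#' pair's bp distance to a recombination fraction
#' `c = dist * recomb_rate_per_bp` (capped at 0.5). With the default
#' `method = "mean_r2"`, Sved's drift relation is inverted at the mean
#' adjusted r2 and the mean recombination fraction over pairs — the usual
#' approach of LD-based Ne software, robust to the near-zero r2 of unlinked
#' pairs. `method = "per_pair"` instead averages the per-pair inversions
#' ([sved_ne()]), which is dominated by low-LD pairs and mainly useful for
#' comparison.
#'
#' This is a deliberately simple member of the LD-based Ne estimator family;
#' it is sensitive to marker density, pair-distance window and family
#' structure, and is reported together with the pair count used.
#'
#' @param gm a [genotype_matrix()].
#' @param recomb_rate_per_bp genetic map density (default 1e-8, i.e. 1
#'   cM/Mb).
#' @param max_pair_dist maximum pair separation in bp.
#' @param maf_floor loci below this MAF are excluded.
#' @param r2_floor lower clamp for the adjusted r2.
#' @param method `"mean_r2"` (Sved inversion at the mean r2) or
#'   `"per_pair"` (mean of per-pair inversions).
#' @return A list with `ne`, `n_pairs` and `mean_r2_adj`.
#' @export
ne_from_ld <- function(gm, recomb_rate_per_bp = 1e-8, max_pair_dist = 1e6,
                       maf_floor = 0.05, r2_floor = 1e-3,
                       method = c("mean_r2", "per_pair")) {
  method <- match.arg(method)
  stopifnot(inherits(gm, "genotype_matrix"))
  ls <- locus_stats(gm)
  keep <- !is.na(ls$maf) & ls$maf >= maf_floor
  if (sum(keep) < 2) stop("Ne estimation needs >= 2 loci after MAF floor")
  gm2 <- subset_genotypes(gm, variants = keep)
  d <- gm2$dosage
  ne_sum <- 0; r2_sum <- 0; c_sum <- 0; n_pairs <- 0L
  for (ch in unique(gm2$variants$chrom)) {
    idx <- which(gm2$variants$chrom == ch)
    if (length(idx) < 2) next
    for (k in seq_len(length(idx) - 1)) {
      i1 <- idx[seq_len(length(idx) - k)]
      i2 <- idx[seq_len(length(idx) - k) + k]
      dist <- gm2$variants$pos[i2] - gm2$variants$pos[i1]
      in_win <- which(dist <= max_pair_dist)
      if (!length(in_win)) break
      A <- d[, i1[in_win], drop = FALSE]
      B <- d[, i2[in_win], drop = FALSE]
      M <- !is.na(A) & !is.na(B)
      Az <- ifelse(M, A, 0L); Bz <- ifelse(M, B, 0L)
      n <- colSums(M)
      sx <- colSums(Az); sy <- colSums(Bz)
      sxy <- colSums(Az * Bz)
      sxx <- colSums(Az^2); syy <- colSums(Bz^2)
      vx <- n * sxx - sx^2; vy <- n * syy - sy^2
      ok <- n >= 3 & vx > 0 & vy > 0
      if (!any(ok)) next
      r2 <- (n[ok] * sxy[ok] - sx[ok] * sy[ok])^2 / (vx[ok] * vy[ok])
      r2a <- pmax(r2 - 1 / (2 * n[ok]), r2_floor)
      cM <- pmin(dist[in_win][ok] * recomb_rate_per_bp, 0.5)
      ne_sum <- ne_sum + sum(sved_ne(r2a, cM))
      r2_sum <- r2_sum + sum(r2a)
      c_sum <- c_sum + sum(cM)
      n_pairs <- n_pairs + length(r2a)
    }
  }
  if (n_pairs == 0) stop("Ne estimation found no eligible locus pairs")
  ne <- if (method == "mean_r2")
    sved_ne(r2_sum / n_pairs, c_sum / n_pairs)
  else ne_sum / n_pairs
  list(ne = ne, n_pairs = n_pairs, mean_r2_adj = r2_sum / n_pairs)
}
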