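#' Kinship / distance matrix container
#'
#' @param values symmetric numeric matrix with sample ids as dimnames.
#' @param flavor `"G"` (genomic relationship) or `"IBS_distance"`.
#' @return A matrix of class `kinship_matrix` with a `flavor` attribute.
#' @export
kinship_matrix <- function(values, flavor = c("G", "IBS_distance")) {
  flavor <- match.arg(flavor)
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (max(abs(values - t(values))) > 1e-12)
    stop("kinship matrix must be symmetric")
  structure(values, flavor = flavor, class = c("kinship_matrix", "matrix"))
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat("kinship_matrix (", attr(x, "flavor"), "): ", nrow(x), " x ",
      ncol(x), " samples\n", sep = "")
  off <- x[upper.tri(x)]
  if (length(off))
    cat(sprintf("  off-diagonal range %.3f .. %.3f, mean %.3f\n",
                min(off), max(off), mean(off)))
  invisible(x)
}

#' VanRaden genomic relationship matrix
#'
#' Method-1 GRM: with `Z` the dosage matrix centered at twice the allele
#' frequency (`Z = X - 2p`, missing entries contributing 0, i.e. mean
#' imputation), `G = Z Z' / sum_j 2 p_j (1 - p_j)`. Frequencies are
#' estimated from the analyzed sample unless supplied. Monomorphic loci
#' carry no relationship information and are dropped.
#'
#' The diagonal is approximately `1 + F` per sample; parent-offspring pairs
#' have expectation ~0.5 and paternal half-sibs ~0.25 (shrunk slightly when
#' allele frequencies are estimated from a related sample). For each pair
#' the denominator sums `2 p (1 - p)` over the mutually called loci only, so
#' missing calls do not attenuate the estimate (the GCTA convention; with
#' complete data this is exactly `Z Z' / sum_j 2 p_j (1 - p_j)`).
#'
#' @param gm a [genotype_matrix()] with at least two samples.
#' @param allele_freq optional vector of alternate-allele frequencies, one
#'   per marker (e.g. founder frequencies); defaults to sample estimates.
#' @return A [kinship_matrix()] of flavor `"G"`.
#' @export
grm_vanraden <- function(gm, allele_freq = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (nrow(gm$samples) < 2) stop("GRM needs at least two samples")
  X <- gm$dosage
  n_called <- colSums(!is.na(X))
  p <- if (is.null(allele_freq))
    colSums(X, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  else allele_freq
  stopifnot(length(p) == ncol(X))
  poly <- n_called > 0 & p > 0 & p < 1
  if (!any(poly))
    stop("GRM denominator degenerate: all loci monomorphic")
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  M <- !is.na(X)
  Z <- sweep(X, 2, 2 * p)
  Z[!M] <- 0
  num <- tcrossprod(Z)
  W <- sweep(M, 2, 2 * p * (1 - p), "*")   # per-pair denominator weights
  den <- tcrossprod(W, M)
  den <- (den + t(den)) / 2
  if (any(den == 0))
    stop("GRM denominator degenerate: sample pair with no mutually ",
         "called polymorphic locus")
  G <- num / den
  G <- (G + t(G)) / 2
  dimnames(G) <- list(gm$samples$id, gm$samples$id)
  kinship_matrix(G, "G")
}

#' Identity-by-state genetic distance matrix
#'
#' For each sample pair, over the loci where both are called:
#' `D = 1 - (N_IBS2 + 0.5 N_IBS1) / N`, where IBS2 loci share both alleles
#' (identical genotypes) and IBS1 loci share exactly one. Equivalently
#' `D = mean(|x - y|) / 2` on dosages. Identical animals have D = 0,
#' opposite homozygotes at every locus D = 1.
#'
#' @param gm a [genotype_matrix()] with at least two samples.
#' @return A [kinship_matrix()] of flavor `"IBS_distance"` (zero diagonal).
#' @export
ibs_distance <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- nrow(gm$samples)
  if (n < 2) stop("IBS distance needs at least two samples")
  X <- gm$dosage
  D <- matrix(0, n, n, dimnames = list(gm$samples$id, gm$samples$id))
  for (i in seq_len(n - 1)) {
    xi <- X[i, ]
    for (j in seq(i + 1, n)) {
      cc <- !is.na(xi) & !is.na(X[j, ])
      if (!any(cc))
        stop("no mutually called loci for pair ", gm$samples$id[i], " / ",
             gm$samples$id[j])
      D[i, j] <- D[j, i] <- mean(abs(xi[cc] - X[j, cc])) / 2
    }
  }
  kinship_matrix(D, "IBS_distance")
}

#' Principal component analysis of a genotype matrix
#'
#' Centers each marker at twice its allele frequency and (by default)
#' scales it by `sqrt(2 p (1 - p))` — the smartpca normalization — with
#' missing entries set to the locus mean; eigendecomposes the sample-by-
#' sample covariance of the standardized data; and returns coordinates as
#' the top-`k` eigenvectors scaled by the square roots of their eigenvalues.
#' With `scale = "none"` only the centering is applied, in which case (for
#' complete data) the decomposed kernel is proportional to the VanRaden G
#' matrix and the two share an eigenspace exactly.
#'
#' The sign of each component is arbitrary.
#'
#' @param gm a [genotype_matrix()].
#' @param k number of components, `k < n_samples`.
#' @param scale `"locus"` (per-marker standardization) or `"none"`
#'   (centering only).
#' @return A list of class `pca_result`: `coords` (samples x k),
#'   `eigenvalues` (all, nonincreasing, clamped at 0), `var_explained`,
#'   `vectors` (all eigenvectors).
#' @export
pca_genotypes <- function(gm, k = 2, scale = c("locus", "none")) {
  scale <- match.arg(scale)
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- nrow(gm$samples)
  if (k >= n) stop("k must be smaller than the number of samples")
  X <- gm$dosage
  n_called <- colSums(!is.na(X))
  p <- colSums(X, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  poly <- n_called > 0 & p > 0 & p < 1
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(X, 2, 2 * p)
  Z[is.na(Z)] <- 0
  if (scale == "locus")
    Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  K <- tcrossprod(Z) / ncol(Z)
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k)
  dimnames(coords) <- list(gm$samples$id, paste0("PC", seq_len(k)))
  structure(list(coords = coords, eigenvalues = ev,
                 var_explained = ev / sum(ev),
                 vectors = e$vectors, k = k, scale = scale),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA of genotype matrix:", nrow(x$coords), "samples,", x$k,
      "components\n")
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * x$var_explained[seq_len(x$k)]),
            collapse = ", "), "\n")
  invisible(x)
}
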