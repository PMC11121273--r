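#' Construct a genotype matrix
#'
#' The central data structure of popconserve: a samples x variants table of
#' diploid biallelic SNP dosages (number of copies of the alternate allele,
#' coded 0/1/2, with `NA` for a missing call) together with a variant map and
#' per-sample metadata. All downstream stages (QC, diversity, ROH,
#' relatedness, family construction) consume and return this class.
#'
#' @param dosage integer or numeric matrix, samples in rows, variants in
#'   columns; entries must be 0, 1, 2 or `NA`.
#' @param samples data.frame with columns `id` (unique character labels) and
#'   `sex` (one of `"male"`, `"female"`, `"unknown"`).
#' @param variants data.frame with columns `chrom` (character; autosomes as
#'   `"1"`, `"2"`, ..., sex chromosomes `"X"`/`"Y"`), `pos` (1-based physical
#'   position in bp), `id` (marker name), `ref` and `alt` (single-character
#'   nucleotide codes). Within each chromosome positions must be strictly
#'   increasing.
#' @param provenance optional named list recording how the object was made
#'   (e.g. source file, allele-polarity convention); stored as an attribute
#'   and carried through subsetting.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `samples`, `variants`.
#' @examples
#' gm <- genotype_matrix(
#'   dosage   = matrix(c(0L, 1L, 2L, NA), nrow = 2),
#'   samples  = data.frame(id = c("s1", "s2"), sex = c("male", "female")),
#'   variants = data.frame(chrom = c("1", "1"), pos = c(100L, 250L),
#'                         id = c("snp1", "snp2"), ref = c("A", "C"),
#'                         alt = c("G", "T"))
#' )
#' gm
#' @export
genotype_matrix <- function(dosage, samples, variants, provenance = list()) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  variants$chrom <- as.character(variants$chrom)

  gm <- structure(
    list(dosage = dosage, samples = samples, variants = variants),
    class = "genotype_matrix",
    provenance = provenance
  )
  validate_genotype_matrix(gm)
  rownames(gm$dosage) <- samples$id
  colnames(gm$dosage) <- variants$id
  gm
}

validate_genotype_matrix <- function(gm) {
  stopifnot(is.list(gm), !is.null(gm$dosage))
  d <- gm$dosage
  if (nrow(d) != nrow(gm$samples))
    stop("dosage has ", nrow(d), " rows but ", nrow(gm$samples), " samples")
  if (ncol(d) != nrow(gm$variants))
    stop("dosage has ", ncol(d), " columns but ", nrow(gm$variants),
         " variants")
  bad <- !(d %in% c(0L, 1L, 2L, NA))
  if (any(bad))
    stop("dosage entries must be 0, 1, 2 or NA")
  req_s <- c("id", "sex")
  if (!all(req_s %in% names(gm$samples)))
    stop("samples must have columns: ", paste(req_s, collapse = ", "))
  if (anyDuplicated(gm$samples$id))
    stop("sample ids must be unique")
  if (nrow(gm$samples) && !all(gm$samples$sex %in% c("male", "female", "unknown")))
    stop("sample sex must be 'male', 'female' or 'unknown'")
  req_v <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(req_v %in% names(gm$variants)))
    stop("variants must have columns: ", paste(req_v, collapse = ", "))
  if (nrow(gm$variants)) {
    if (any(gm$variants$pos < 1))
      stop("variant positions must be >= 1 (1-based coordinates)")
    if (any(gm$variants$ref == gm$variants$alt))
      stop("ref and alt alleles must differ")
    unsorted <- tapply(gm$variants$pos, gm$variants$chrom,
                       function(p) any(diff(p) <= 0))
    if (any(unlist(unsorted)))
      stop("variant positions must be strictly increasing within each ",
           "chromosome")
  }
  invisible(gm)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  n_mis <- sum(is.na(x$dosage))
  cat("genotype_matrix:", nrow(x$samples), "samples x", nrow(x$variants),
      "variants\n")
  if (nrow(x$samples))
    cat("  sex:", sum(x$samples$sex == "male"), "male /",
        sum(x$samples$sex == "female"), "female /",
        sum(x$samples$sex == "unknown"), "unknown\n")
  if (nrow(x$variants))
    cat("  chromosomes:", length(unique(x$variants$chrom)), "\n")
  cat("  missing calls:",
      sprintf("%.2f%%", 100 * n_mis / max(1, length(x$dosage))), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by samples and/or variants
#'
#' Retains the original ordering of whichever samples and variants are kept;
#' the dosage table is sliced consistently with the metadata.
#'
#' @param gm a [genotype_matrix()].
#' @param sample_ids character vector of sample ids to keep (default: all).
#'   Unknown ids are an error.
#' @param variants one of: `NULL` (keep all), a logical vector over variants,
#'   an integer index vector, a character vector of variant ids, or a
#'   predicate `function(variants_df) -> logical`.
#' @return A `genotype_matrix` with the requested slice.
#' @export
subset_genotypes <- function(gm, sample_ids = NULL, variants = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  si <- seq_len(nrow(gm$samples))
  if (!is.null(sample_ids)) {
    idx <- match(sample_ids, gm$samples$id)
    if (anyNA(idx))
      stop("unknown sample id(s): ",
           paste(sample_ids[is.na(idx)], collapse = ", "))
    si <- sort(idx)  # preserve original sample order
  }
  vi <- seq_len(nrow(gm$variants))
  if (!is.null(variants)) {
    if (is.function(variants)) {
      keep <- variants(gm$variants)
      stopifnot(is.logical(keep), length(keep) == nrow(gm$variants))
      vi <- which(keep)
    } else if (is.logical(variants)) {
      stopifnot(length(variants) == nrow(gm$variants))
      vi <- which(variants)
    } else if (is.character(variants)) {
      idx <- match(variants, gm$variants$id)
      if (anyNA(idx))
        stop("unknown variant id(s): ",
             paste(variants[is.na(idx)], collapse = ", "))
      vi <- sort(idx)
    } else {
      vi <- sort(as.integer(variants))
      if (any(vi < 1 | vi > nrow(gm$variants)))
        stop("variant index out of range")
    }
  }
  genotype_matrix(
    dosage = gm$dosage[si, vi, drop = FALSE],
    samples = gm$samples[si, , drop = FALSE],
    variants = gm$variants[vi, , drop = FALSE],
    provenance = attr(gm, "provenance")
  )
}

#' Restrict a genotype matrix to autosomal markers
#'
#' @param gm a [genotype_matrix()].
#' @param autosomes character vector of chromosome labels counted as
#'   autosomes. The default covers the donkey autosome complement used
#'   throughout the package; pass another set for other karyotypes.
#' @return A `genotype_matrix` containing only markers on `autosomes`.
#' @export
autosomal <- function(gm, autosomes = as.character(1:30)) {
  subset_genotypes(gm, variants = gm$variants$chrom %in% autosomes)
}
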