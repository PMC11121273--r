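#' Read genotypes from a VCF file
#'
#' Consumes the GT field of a VCF (plain text or bgzipped) and returns a
#' [genotype_matrix()]. Dosage is the count of alternate alleles in the call;
#' `./.` (or `.|.`) becomes a missing value. Multiallelic records are not
#' representable in the biallelic dosage model and are skipped with a warning
#' (or rejected, see `multiallelic`).
#'
#' @param path path to a VCF file with GT genotypes.
#' @param multiallelic `"skip"` (drop such records with a warning) or
#'   `"error"`.
#' @return A `genotype_matrix`. Sample sex is `"unknown"` (VCF carries none).
#' @export
read_vcf <- function(path, multiallelic = c("skip", "error")) {
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) stop("no such file: ", path)
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("VCF parse error in ", path, ": ",
                             conditionMessage(e))
  )
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single record drops to a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    ids <- colnames(v@gt)[-1]
    if (is.null(ids)) ids <- character(0)
    return(genotype_matrix(
      dosage = matrix(integer(0), nrow = length(ids), ncol = 0),
      samples = data.frame(id = ids, sex = rep("unknown", length(ids)),
                           stringsAsFactors = FALSE),
      variants = data.frame(chrom = character(0), pos = integer(0),
                            id = character(0), ref = character(0),
                            alt = character(0), stringsAsFactors = FALSE),
      provenance = list(source = path, format = "vcf")))
  }
  multi <- grepl(",", fix$ALT) | nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L
  if (any(multi)) {
    if (multiallelic == "error")
      stop(sum(multi), " multiallelic/non-SNP record(s) in ", path)
    warning("skipping ", sum(multi), " multiallelic/non-SNP record(s) in ",
            path)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  keep <- which(!multi)
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]

  # dosage = number of "1" alleles; any missing allele -> NA
  allele1 <- substr(gt, 1, 1)
  allele3 <- substr(gt, 3, 3)
  dos <- (allele1 == "1") + (allele3 == "1")
  dos[allele1 == "." | allele3 == "." | is.na(gt)] <- NA
  dos <- matrix(as.integer(dos), nrow = nrow(gt),
                dimnames = dimnames(gt))

  vid <- fix$ID
  vid[is.na(vid) | vid == "."] <- paste0(fix$CHROM, "_", fix$POS)[
    is.na(vid) | vid == "."]
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         id = vid, ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  unsorted <- tapply(variants$pos, variants$chrom,
                     function(p) any(diff(p) <= 0))
  if (any(unlist(unsorted)))
    stop("VCF records not sorted by strictly increasing position within ",
         "chromosome(s): ",
         paste(names(which(unlist(unsorted))), collapse = ", "))
  genotype_matrix(
    dosage = t(dos),
    samples = data.frame(id = colnames(gt),
                         sex = rep("unknown", ncol(gt)),
                         stringsAsFactors = FALSE),
    variants = variants,
    provenance = list(source = path, format = "vcf")
  )
}

#' Write genotypes to a VCF file
#'
#' Emits a minimal VCF 4.2 with GT-only genotype columns, re-readable by
#' [read_vcf()] with identical dosages, ids and coordinates. Missing calls
#' serialize as `./.`.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write to ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=popconserve",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$samples$id), collapse = "\t")),
             con)
  if (nrow(gm$variants) == 0) return(invisible(path))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  m <- matrix("./.", nrow = nrow(gm$dosage), ncol = ncol(gm$dosage))
  called <- !is.na(gm$dosage)
  m[called] <- gt_code[as.character(gm$dosage[called])]
  lines <- paste(gm$variants$chrom, gm$variants$pos, gm$variants$id,
                 gm$variants$ref, gm$variants$alt, ".", "PASS", ".", "GT",
                 apply(m, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

sex_to_ped <- c(male = 1L, female = 2L, unknown = 0L)

#' Read genotypes from PLINK PED/MAP text files
#'
#' PED columns are FID IID PAT MAT SEX PHENO followed by two allele columns
#' per marker; MAP columns are chromosome, marker id, genetic position (cM)
#' and physical position (bp). PED sex 1 is male, 2 female, anything else
#' unknown; an allele pair `0 0` is a missing call.
#'
#' Plain PED text does not declare which allele is the alternate. The
#' alternate allele at each marker is taken as the minor-by-count allele over
#' all called genotypes, ties broken toward the lexicographically later
#' allele; the convention is recorded in the object's provenance so dosage
#' polarity is reproducible. Markers where only one allele is observed get a
#' placeholder alternate (`"N"`) and dosage 0 throughout.
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @return A [genotype_matrix()].
#' @export
read_plink_text <- function(ped_path, map_path) {
  for (p in c(ped_path, map_path))
    if (!file.exists(p)) stop("no such file: ", p)
  map <- utils::read.table(map_path, header = FALSE,
                           colClasses = c("character", "character",
                                          "numeric", "integer"))
  names(map) <- c("chrom", "id", "cm", "pos")
  ped <- utils::read.table(ped_path, header = FALSE,
                           colClasses = "character")
  n_allele_cols <- ncol(ped) - 6L
  if (n_allele_cols != 2L * nrow(map))
    stop("PED has ", n_allele_cols, " allele columns but MAP declares ",
         nrow(map), " markers (expected ", 2L * nrow(map), " columns)")
  n <- nrow(ped)
  m <- nrow(map)
  sex <- c("unknown", "male", "female")[
    match(ped[[5]], c("1", "2"), nomatch = 0L) + 1L]

  a1 <- as.matrix(ped[, 6L + 2L * seq_len(m) - 1L, drop = FALSE])
  a2 <- as.matrix(ped[, 6L + 2L * seq_len(m), drop = FALSE])
  a1[a1 == "0"] <- NA
  a2[a2 == "0"] <- NA

  dos <- matrix(NA_integer_, nrow = n, ncol = m)
  ref <- alt <- character(m)
  for (j in seq_len(m)) {
    obs <- c(a1[, j], a2[, j])
    obs <- obs[!is.na(obs)]
    alleles <- sort(unique(obs))
    if (length(alleles) > 2L)
      stop("marker ", map$id[j], " has >2 alleles in PED")
    if (length(alleles) == 0L) {
      ref[j] <- "A"; alt[j] <- "N"
      next
    }
    if (length(alleles) == 1L) {
      ref[j] <- alleles
      alt[j] <- "N"
      dos[, j] <- ifelse(is.na(a1[, j]) | is.na(a2[, j]), NA_integer_, 0L)
      next
    }
    counts <- c(sum(obs == alleles[1]), sum(obs == alleles[2]))
    # minor-by-count allele is alt; tie -> lexicographically later allele
    alt_j <- if (counts[2] <= counts[1]) alleles[2] else alleles[1]
    ref[j] <- setdiff(alleles, alt_j)
    alt[j] <- alt_j
    dos[, j] <- (a1[, j] == alt_j) + (a2[, j] == alt_j)
  }
  genotype_matrix(
    dosage = dos,
    samples = data.frame(id = ped[[2]], sex = sex, stringsAsFactors = FALSE),
    variants = data.frame(chrom = map$chrom, pos = map$pos, id = map$id,
                          ref = ref, alt = alt, stringsAsFactors = FALSE),
    provenance = list(source = ped_path, format = "ped",
                      alt_allele_rule = "minor-by-count, ties to later allele")
  )
}

#' Write genotypes to PLINK PED/MAP text files
#'
#' Missing calls serialize as `0 0`; sex as 1/2/0 for male/female/unknown.
#' The pair of files round-trips through [read_plink_text()] with identical
#' dosages provided the alternate allele is the minor allele at every marker
#' (the PED format itself carries no allele polarity).
#'
#' @param gm a [genotype_matrix()].
#' @param ped_path,map_path output file paths.
#' @return Invisibly, `c(ped_path, map_path)`.
#' @export
write_plink_text <- function(gm, ped_path, map_path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  utils::write.table(
    data.frame(gm$variants$chrom, gm$variants$id, 0, gm$variants$pos),
    map_path, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  n <- nrow(gm$samples)
  m <- nrow(gm$variants)
  a1 <- matrix("0", n, m)
  a2 <- matrix("0", n, m)
  if (m > 0 && n > 0) {
    refm <- matrix(gm$variants$ref, n, m, byrow = TRUE)
    altm <- matrix(gm$variants$alt, n, m, byrow = TRUE)
    d <- gm$dosage
    a1[!is.na(d) & d <= 1L] <- refm[!is.na(d) & d <= 1L]
    a1[!is.na(d) & d == 2L] <- altm[!is.na(d) & d == 2L]
    a2[!is.na(d) & d == 0L] <- refm[!is.na(d) & d == 0L]
    a2[!is.na(d) & d >= 1L] <- altm[!is.na(d) & d >= 1L]
  }
  geno <- matrix("", n, 2L * m)
  if (m > 0) {
    geno[, 2L * seq_len(m) - 1L] <- a1
    geno[, 2L * seq_len(m)] <- a2
  }
  ped <- cbind(gm$samples$id, gm$samples$id, "0", "0",
               as.character(sex_to_ped[gm$samples$sex]), "-9", geno)
  con <- tryCatch(file(ped_path, "w"),
                  error = function(e) stop("cannot write to ", ped_path,
                                           ": ", conditionMessage(e)))
  on.exit(close(con))
  if (n > 0) writeLines(apply(ped, 1, paste, collapse = " "), con)
  invisible(c(ped_path, map_path))
}
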