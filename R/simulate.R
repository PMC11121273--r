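#' Simulation configuration
#'
#' Parameters of the synthetic GBS-style population generator. The defaults
#' describe a small sire-structured conservation herd: 32 animals (4 males,
#' 28 females), 45,000 autosomal SNPs spread irregularly over 30 autosomes
#' totalling ~2.3 Gb, founder minor-allele frequencies uniform on
#' [`maf_min`, 0.5], three sire families, a planted autozygosity fraction of
#' 0.003 per animal realized as 1-11 Mb tracts, a 95% per-call genotyping
#' rate, and a sprinkling of X/Y markers so the sex-chromosome QC filter has
#' something to remove.
#'
#' @param n_males,n_females sampled animal counts by sex.
#' @param n_chrom autosome count.
#' @param chrom_length_bp per-autosome length in bp (all equal). The default
#'   makes the simulated autosomal genome total 2,302,664,700 bp, matching
#'   the donkey autosome length used by [froh()].
#' @param n_snps total autosomal marker count.
#' @param maf_min lower bound of the uniform founder allele-frequency law on
#'   `[maf_min, 0.5]`.
#' @param n_sire_families number of planted sire families (0 = unstructured
#'   population of founders).
#' @param n_assigned_females how many females are bred from family sires;
#'   the rest are unrelated founders (the "other" class downstream).
#' @param target_froh per-animal planted autozygosity fraction in `[0, 1]`.
#' @param tract_range_mb length-2 numeric, min/max planted tract length (Mb).
#' @param call_rate per-call genotype detection rate; either a scalar or a
#'   per-sample vector of length `n_males + n_females`.
#' @param n_x_snps,n_y_snps sex-chromosome marker counts appended solely to
#'   exercise the QC chromosome filter (genotypes are drawn i.i.d., not
#'   transmitted through the pedigree).
#' @param seed RNG seed; all output is deterministic given the seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_males = 4, n_females = 28, n_chrom = 30,
                       chrom_length_bp = 76755490, n_snps = 45000,
                       maf_min = 0.01, n_sire_families = 3,
                       n_assigned_females = 3, target_froh = 0.003,
                       tract_range_mb = c(1, 11), call_rate = 0.95,
                       n_x_snps = 1500, n_y_snps = 90, seed = 1) {
  cfg <- list(n_males = as.integer(n_males), n_females = as.integer(n_females),
              n_chrom = as.integer(n_chrom),
              chrom_length_bp = as.numeric(chrom_length_bp),
              n_snps = as.integer(n_snps), maf_min = maf_min,
              n_sire_families = as.integer(n_sire_families),
              n_assigned_females = as.integer(n_assigned_females),
              target_froh = target_froh, tract_range_mb = tract_range_mb,
              call_rate = call_rate, n_x_snps = as.integer(n_x_snps),
              n_y_snps = as.integer(n_y_snps), seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_males >= 0, n_females >= 0, n_chrom >= 1,
              chrom_length_bp > 0, n_snps >= 0,
              maf_min > 0, maf_min <= 0.5,
              n_sire_families >= 0, n_sire_families <= max(n_males, 1),
              n_assigned_females >= 0, n_assigned_females <= n_females,
              target_froh >= 0, target_froh <= 1,
              length(tract_range_mb) == 2, tract_range_mb[1] > 0,
              diff(tract_range_mb) >= 0,
              all(call_rate > 0), all(call_rate <= 1),
              n_x_snps >= 0, n_y_snps >= 0)
  })
  if (cfg$n_snps < cfg$n_chrom)
    stop("config error: n_snps (", cfg$n_snps,
         ") must be at least n_chrom (", cfg$n_chrom, ")")
  if (cfg$n_sire_families > 0 && cfg$n_sire_families > cfg$n_males)
    stop("config error: n_sire_families exceeds n_males")
  class(cfg) <- "sim_config"
  cfg
}

#' Plant a sire-family mating design
#'
#' Distributes the sampled males over `n_sire_families` families (males
#' sharing a family are made full sibs through an unsampled founder couple,
#' so their realized genomic kinship clears a 0.1 clustering threshold) and
#' assigns the first `n_assigned_females` females a sire drawn round-robin
#' from the families, each with her own unsampled founder dam, so paternal
#' half-sibs have expected genomic kinship ~0.25. Remaining females, and
#' males in singleton families, are unrelated founders.
#'
#' @param cfg a [sim_config()].
#' @return A data.frame pedigree with one row per individual (sampled
#'   animals and unsampled founder parents): columns `id`, `sex`, `sire`,
#'   `dam` (`NA` for founders), `family` (`NA` when not family-anchored) and
#'   `sampled`.
#' @export
plant_sire_families <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  male_ids <- if (cfg$n_males) sprintf("M%02d", seq_len(cfg$n_males)) else character(0)
  female_ids <- if (cfg$n_females) sprintf("F%02d", seq_len(cfg$n_females)) else character(0)
  ped <- data.frame(id = character(0), sex = character(0),
                    sire = character(0), dam = character(0),
                    family = integer(0), sampled = logical(0),
                    stringsAsFactors = FALSE)
  add <- function(id, sex, sire = NA_character_, dam = NA_character_,
                  family = NA_integer_, sampled = TRUE) {
    rbind(ped, data.frame(id = id, sex = sex, sire = sire, dam = dam,
                          family = family, sampled = sampled,
                          stringsAsFactors = FALSE))
  }
  if (cfg$n_sire_families == 0) {
    for (i in seq_along(male_ids)) ped <- add(male_ids[i], "male")
    for (i in seq_along(female_ids)) ped <- add(female_ids[i], "female")
    return(ped)
  }
  fam_of_male <- rep(seq_len(cfg$n_sire_families), length.out = cfg$n_males)
  # unsampled founder parents for families holding >= 2 males
  for (f in seq_len(cfg$n_sire_families)) {
    if (sum(fam_of_male == f) >= 2) {
      ped <- add(sprintf("FS%02d", f), "male", sampled = FALSE)
      ped <- add(sprintf("FD%02d", f), "female", sampled = FALSE)
    }
  }
  for (i in seq_along(male_ids)) {
    f <- fam_of_male[i]
    if (sum(fam_of_male == f) >= 2)
      ped <- add(male_ids[i], "male", sire = sprintf("FS%02d", f),
                 dam = sprintf("FD%02d", f), family = f)
    else
      ped <- add(male_ids[i], "male", family = f)
  }
  if (cfg$n_assigned_females > 0) {
    fam_of_female <- rep(seq_len(cfg$n_sire_families),
                         length.out = cfg$n_assigned_females)
    for (i in seq_len(cfg$n_assigned_females)) {
      f <- fam_of_female[i]
      fam_males <- male_ids[fam_of_male == f]
      sire <- fam_males[1 + (i - 1) %% length(fam_males)]
      dam_id <- sprintf("UD%02d", i)
      ped <- add(dam_id, "female", sampled = FALSE)
      ped <- add(female_ids[i], "female", sire = sire, dam = dam_id,
                 family = f)
    }
  }
  if (cfg$n_females > cfg$n_assigned_females)
    for (i in seq(cfg$n_assigned_females + 1, cfg$n_females))
      ped <- add(female_ids[i], "female")
  ped
}

# one gamete from a parent's two haplotypes; crossovers Poisson at 1 cM/Mb
# (Haldane, no interference), breakpoints uniform along the chromosome
recombine_gamete <- function(haps, chrom_index, chrom_pos, chrom_len) {
  gam <- integer(ncol(haps))
  for (ci in seq_along(chrom_index)) {
    idx <- chrom_index[[ci]]
    k <- stats::rpois(1, chrom_len / 1e8)
    start <- sample.int(2L, 1L)
    if (k == 0L) {
      gam[idx] <- haps[start, idx]
    } else {
      bp <- sort(stats::runif(k, 0, chrom_len))
      phase <- (start - 1L + findInterval(chrom_pos[[ci]], bp)) %% 2L + 1L
      gam[idx] <- haps[cbind(phase, idx)]
    }
  }
  gam
}

# Autozygous tracts totalling target_froh of the genome. Tracts are kept at
# least `sep` apart within a chromosome so each planted tract remains a
# distinct, unambiguous homozygous segment at sparse marker density; every
# tract length stays inside tract_range_mb (the residual below the minimum
# is dropped, a negligible fraction of the genome).
draw_tracts <- function(sample_id, cfg, sep = 2e6) {
  total <- cfg$n_chrom * cfg$chrom_length_bp
  remaining <- cfg$target_froh * total
  lo <- cfg$tract_range_mb[1] * 1e6
  hi <- cfg$tract_range_mb[2] * 1e6
  out <- list()
  used <- vector("list", cfg$n_chrom)
  while (remaining >= lo) {
    len <- min(stats::runif(1, lo, hi), remaining)
    placed <- FALSE
    for (try in 1:1000) {
      chrom <- sample.int(cfg$n_chrom, 1L)
      if (len > cfg$chrom_length_bp) break
      start <- floor(stats::runif(1, 1, cfg$chrom_length_bp - len + 1))
      end <- start + len - 1
      ivs <- used[[chrom]]
      clash <- !is.null(ivs) &&
        any(start - sep <= ivs[, 2] & end + sep >= ivs[, 1])
      if (!clash) {
        used[[chrom]] <- rbind(ivs, c(start, end))
        out[[length(out) + 1L]] <- data.frame(
          sample_id = sample_id, chrom = as.character(chrom),
          start = start, end = end, stringsAsFactors = FALSE)
        remaining <- remaining - len
        placed <- TRUE
        break
      }
    }
    if (!placed) break
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(sample_id = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0),
               stringsAsFactors = FALSE)
}

#' Simulate a pedigree-structured SNP genotype matrix
#'
#' Founder haplotypes are drawn in Hardy-Weinberg proportions at
#' alternate-allele frequencies uniform on `[maf_min, 0.5]`; non-founders are
#' produced by gene dropping with recombination (crossover count per
#' chromosome Poisson with mean equal to the map length at 1 cM/Mb,
#' breakpoint positions uniform). Autozygosity is planted explicitly: within
#' each drawn tract one haplotype is copied over the other, so every marker
#' inside is homozygous and the tract boundaries are exact ground truth for
#' ROH-recovery testing. Missingness is applied i.i.d. per call at rate
#' `1 - call_rate`. All output is deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return A list with elements `genotypes` (a [genotype_matrix()] of the
#'   sampled animals) and `truth` (class `true_pedigree`: `$pedigree`, the
#'   sampled-animal pedigree with planted family labels; `$tracts`, the
#'   planted autozygous tracts as sample/chrom/start/end; and
#'   `$founder_freq`, the founder alternate-allele frequency of each
#'   autosomal marker).
#' @examples
#' sim <- simulate_population(sim_config(n_snps = 600, n_chrom = 3,
#'                                       chrom_length_bp = 5e7,
#'                                       n_x_snps = 0, n_y_snps = 0))
#' sim$genotypes
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ped <- plant_sire_families(cfg)

  # variant map: counts per chromosome as even as possible, irregular spacing
  per_chrom <- rep(cfg$n_snps %/% cfg$n_chrom, cfg$n_chrom)
  extra <- cfg$n_snps %% cfg$n_chrom
  if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
  chrom <- rep(as.character(seq_len(cfg$n_chrom)), per_chrom)
  pos <- unlist(lapply(per_chrom, function(k)
    sort(sample.int(cfg$chrom_length_bp, k))))
  chrom_index <- split(seq_len(cfg$n_snps), factor(chrom, levels = as.character(seq_len(cfg$n_chrom))))
  chrom_pos <- split(pos, factor(chrom, levels = as.character(seq_len(cfg$n_chrom))))

  p_alt <- stats::runif(cfg$n_snps, cfg$maf_min, 0.5)
  nt <- c("A", "C", "G", "T")
  ref <- sample(nt, cfg$n_snps, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1L), character(1))

  haps <- new.env(parent = emptyenv())
  founder_haps <- function() {
    matrix(as.integer(stats::runif(2L * cfg$n_snps) <
                        rep(p_alt, each = 2L)), nrow = 2L)
  }
  for (i in seq_len(nrow(ped))) {
    ind <- ped[i, ]
    if (is.na(ind$sire)) {
      assign(ind$id, founder_haps(), envir = haps)
    } else {
      h <- rbind(
        recombine_gamete(get(ind$sire, envir = haps), chrom_index,
                         chrom_pos, cfg$chrom_length_bp),
        recombine_gamete(get(ind$dam, envir = haps), chrom_index,
                         chrom_pos, cfg$chrom_length_bp))
      assign(ind$id, h, envir = haps)
    }
  }

  sampled <- ped[ped$sampled, , drop = FALSE]
  tracts <- list()
  dos <- matrix(NA_integer_, nrow = nrow(sampled), ncol = cfg$n_snps)
  for (i in seq_len(nrow(sampled))) {
    id <- sampled$id[i]
    h <- get(id, envir = haps)
    if (cfg$target_froh > 0) {
      tr <- draw_tracts(id, cfg)
      tracts[[id]] <- tr
      for (r in seq_len(nrow(tr))) {
        idx <- chrom_index[[as.integer(tr$chrom[r])]]
        pp <- chrom_pos[[as.integer(tr$chrom[r])]]
        inside <- idx[pp >= tr$start[r] & pp <= tr$end[r]]
        h[2L, inside] <- h[1L, inside]
      }
    }
    dos[i, ] <- h[1L, ] + h[2L, ]
  }
  tracts <- if (length(tracts)) do.call(rbind, c(tracts, make.row.names = FALSE)) else
    data.frame(sample_id = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0), stringsAsFactors = FALSE)

  variants <- data.frame(chrom = chrom, pos = pos,
                         id = paste0("snp_", chrom, "_", pos),
                         ref = ref, alt = alt, stringsAsFactors = FALSE)

  # optional sex-chromosome markers: i.i.d. HWE draws, QC-filter fodder only
  for (sc in c("X", "Y")) {
    k <- if (sc == "X") cfg$n_x_snps else cfg$n_y_snps
    if (k == 0) next
    sp <- sort(sample.int(cfg$chrom_length_bp, k))
    fp <- stats::runif(k, cfg$maf_min, 0.5)
    g <- matrix(stats::rbinom(nrow(sampled) * k, 2L,
                              rep(fp, each = nrow(sampled))),
                nrow = nrow(sampled))
    rs <- sample(nt, k, replace = TRUE)
    as_ <- vapply(rs, function(r) sample(setdiff(nt, r), 1L), character(1))
    variants <- rbind(variants, data.frame(
      chrom = sc, pos = sp, id = paste0("snp_", sc, "_", sp),
      ref = rs, alt = as_, stringsAsFactors = FALSE))
    dos <- cbind(dos, g)
  }

  n_calls <- length(dos)
  rate <- if (length(cfg$call_rate) == 1) rep(cfg$call_rate, nrow(sampled)) else cfg$call_rate
  stopifnot(length(rate) == nrow(sampled))
  miss <- matrix(stats::runif(n_calls), nrow = nrow(sampled)) > rate
  dos[miss] <- NA_integer_

  gm <- genotype_matrix(
    dosage = dos,
    samples = data.frame(id = sampled$id, sex = sampled$sex,
                         stringsAsFactors = FALSE),
    variants = variants,
    provenance = list(source = "simulate_population", seed = cfg$seed))
  truth <- structure(list(pedigree = sampled, tracts = tracts,
                          founder_freq = p_alt, config = cfg),
                     class = "true_pedigree")
  list(genotypes = gm, truth = truth)
}
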