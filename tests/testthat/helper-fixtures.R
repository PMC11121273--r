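# Fixture builders and independent brute-force oracles. Every oracle here is
# written as directly as possible (loops, enumeration, literal formulas) and
# shares no code with the package implementations it checks.

rand_gm <- function(n = 10, m = 50, miss_rate = 0.1, seed = 1,
                    chroms = c("1", "2")) {
  set.seed(seed)
  p <- runif(m, 0.05, 0.95)
  d <- matrix(rbinom(n * m, 2, rep(p, each = n)), nrow = n)
  d[matrix(runif(n * m) < miss_rate, n, m)] <- NA_integer_
  chrom <- sort(rep_len(chroms, m))
  pos <- unlist(lapply(split(seq_len(m), chrom), function(i)
    sort(sample.int(1e6, length(i)))), use.names = FALSE)
  nt <- c("A", "C", "G", "T")
  ref <- sample(nt, m, TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1), character(1))
  genotype_matrix(
    dosage = d,
    samples = data.frame(id = sprintf("s%02d", 1:n),
                         sex = sample(c("male", "female"), n, TRUE)),
    variants = data.frame(chrom = chrom, pos = pos,
                          id = sprintf("v%03d", 1:m), ref = ref, alt = alt))
}

# like rand_gm but guarantees, at every marker, both alleles observed and the
# alt allele strictly minor by count -- the condition under which plain PED
# text (which carries no allele polarity) round-trips dosages exactly
rand_gm_pedsafe <- function(n = 10, m = 50, miss_rate = 0.1, seed = 1) {
  set.seed(seed)
  d <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    repeat {
      col <- rbinom(n, 2, runif(1, 0.1, 0.4))
      col[runif(n) < miss_rate] <- NA_integer_
      nc <- sum(!is.na(col))
      if (nc >= 2 && sum(col, na.rm = TRUE) > 0 &&
          sum(col, na.rm = TRUE) < nc)  # 0 < alt count < ref count
        break
    }
    d[, j] <- col
  }
  nt <- c("A", "C", "G", "T")
  ref <- sample(nt, m, TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1), character(1))
  genotype_matrix(
    dosage = d,
    samples = data.frame(id = sprintf("s%02d", 1:n),
                         sex = sample(c("male", "female"), n, TRUE)),
    variants = data.frame(chrom = rep("1", m), pos = sort(sample.int(1e6, m)),
                          id = sprintf("v%03d", 1:m), ref = ref, alt = alt))
}

# fixture with planted violations: 3 monomorphic (MAF 0) loci, 5 loci with
# call rate below 0.9, 2 X-linked loci, and one sample below 90% call rate
planted_qc_gm <- function() {
  n <- 32
  clean <- c(rep(0L, 8), rep(1L, 16), rep(2L, 8))   # HWE-balanced
  d <- matrix(rep(clean, 50), nrow = n)             # 50 loci
  d[, 41:43] <- 0L                                  # monomorphic -> MAF fail
  for (j in 44:48) d[1:5 + (j - 44), j] <- NA       # 5 low-call-rate loci
  d[n, 1:6] <- NA                                   # low-call-rate sample
  chrom <- c(rep("1", 48), "X", "X")
  pos <- c(seq(1e5, 48e5, by = 1e5), 1e5, 2e5)
  genotype_matrix(
    dosage = d,
    samples = data.frame(id = sprintf("s%02d", 1:n),
                         sex = rep(c("male", "female"), 16)),
    variants = data.frame(chrom = chrom, pos = pos,
                          id = sprintf("v%02d", 1:50),
                          ref = "A", alt = "G"))
}

# ---- brute-force statistics oracles ---------------------------------------

bf_freq <- function(dosage) {
  alt <- 0; tot <- 0
  for (x in dosage) if (!is.na(x)) { alt <- alt + x; tot <- tot + 2 }
  alt / tot
}

bf_pic <- function(freqs) {
  s <- 1
  for (i in seq_along(freqs)) s <- s - freqs[i]^2
  for (i in seq_along(freqs)) for (j in seq_along(freqs))
    if (i < j) s <- s - 2 * freqs[i]^2 * freqs[j]^2
  s
}

bf_he <- function(freqs) {
  s <- 1
  for (f in freqs) s <- s - f^2
  s
}

bf_ho <- function(dosage) {
  het <- 0; tot <- 0
  for (x in dosage) if (!is.na(x)) { tot <- tot + 1; if (x == 1) het <- het + 1 }
  het / tot
}

bf_ae <- function(freqs) {
  s <- 0
  for (f in freqs) s <- s + f^2
  1 / s
}

# full-enumeration HWE exact test: Levene-Haldane probability of every
# genotype configuration compatible with the observed allele counts
bf_hwe <- function(hr, het, ha) {
  n <- hr + het + ha
  n_alt <- 2 * ha + het
  lp <- function(hr2, het2, ha2) {
    lfactorial(n) - lfactorial(hr2) - lfactorial(het2) - lfactorial(ha2) +
      het2 * log(2) + lfactorial(n_alt) + lfactorial(2 * n - n_alt) -
      lfactorial(2 * n)
  }
  configs <- list()
  for (ha2 in 0:n) {
    het2 <- n_alt - 2 * ha2
    hr2 <- n - het2 - ha2
    if (het2 >= 0 && hr2 >= 0)
      configs[[length(configs) + 1]] <- c(hr2, het2, ha2)
  }
  probs <- vapply(configs, function(cf) exp(lp(cf[1], cf[2], cf[3])),
                  numeric(1))
  probs <- probs / sum(probs)
  obs <- vapply(configs, function(cf) cf[2] == het, logical(1))
  p_obs <- probs[obs]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

# per-pair IBS distance by explicit per-locus allele-sharing classification
bf_ibs_pair <- function(x, y) {
  ibs2 <- 0; ibs1 <- 0; n <- 0
  for (k in seq_along(x)) {
    if (is.na(x[k]) || is.na(y[k])) next
    n <- n + 1
    shared <- 2 - abs(x[k] - y[k])  # alleles shared by genotypes
    if (shared == 2) ibs2 <- ibs2 + 1
    if (shared == 1) ibs1 <- ibs1 + 1
  }
  1 - (ibs2 + 0.5 * ibs1) / n
}

# ---- naive exhaustive ROH scanner -----------------------------------------
# Re-derives window eligibility and qualifying maximal runs with plain loops.
bf_roh_chrom <- function(dosage, pos, params) {
  m <- length(dosage)
  het <- !is.na(dosage) & dosage == 1
  miss <- is.na(dosage)
  w <- min(params$window_snps, m)
  elig <- logical(m)
  for (j in seq_len(m)) {
    ok <- 0; tot <- 0
    for (s in max(1, j - w + 1):min(j, m - w + 1)) {
      win <- s:(s + w - 1)
      tot <- tot + 1
      if (sum(het[win]) <= params$window_het_allowance &&
          sum(miss[win]) <= params$max_missing_in_run) ok <- ok + 1
    }
    elig[j] <- (ok / tot) > params$window_overlap_frac
  }
  runs <- list()
  cur <- integer(0)
  hets_in_cur <- 0
  flush <- function(cur, runs) {
    # trim to called homozygous ends, then apply run criteria
    while (length(cur) && (het[cur[1]] || miss[cur[1]]))
      cur <- cur[-1]
    while (length(cur) && (het[cur[length(cur)]] || miss[cur[length(cur)]]))
      cur <- cur[-length(cur)]
    if (length(cur) >= params$min_snps) {
      span <- pos[cur[length(cur)]] - pos[cur[1]] + 1
      if (span >= params$min_length_bp)
        runs[[length(runs) + 1]] <- c(pos[cur[1]], pos[cur[length(cur)]],
                                      length(cur))
    }
    runs
  }
  for (j in seq_len(m)) {
    if (!elig[j]) {
      runs <- flush(cur, runs); cur <- integer(0); hets_in_cur <- 0
      next
    }
    if (length(cur) && (j != cur[length(cur)] + 1 ||
                        pos[j] - pos[cur[length(cur)]] > params$max_gap_bp)) {
      runs <- flush(cur, runs)
      cur <- integer(0); hets_in_cur <- 0
    }
    if (het[j] && hets_in_cur == params$max_het_in_run) {
      # het over budget: close the run, restart after this marker
      runs <- flush(cur, runs)
      cur <- integer(0); hets_in_cur <- 0
      next
    }
    if (het[j]) hets_in_cur <- hets_in_cur + 1
    cur <- c(cur, j)
  }
  runs <- flush(cur, runs)
  if (length(runs)) do.call(rbind, runs) else
    matrix(numeric(0), ncol = 3)
}

# reciprocal-overlap matching of detected segments against planted tracts
overlap_frac <- function(a_start, a_end, b_start, b_end) {
  ov <- max(0, min(a_end, b_end) - max(a_start, b_start) + 1)
  c(ov / (a_end - a_start + 1), ov / (b_end - b_start + 1))
}

recall_precision <- function(detected, truth, min_ro = 0.5) {
  hit_tr <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    det <- detected[detected$sample_id == truth$sample_id[i] &
                      detected$chrom == truth$chrom[i], , drop = FALSE]
    hit_tr[i] <- nrow(det) > 0 && any(vapply(seq_len(nrow(det)), function(k)
      all(overlap_frac(truth$start[i], truth$end[i],
                       det$start_bp[k], det$end_bp[k]) >= min_ro),
      logical(1)))
  }
  hit_det <- logical(nrow(detected))
  for (i in seq_len(nrow(detected))) {
    tt <- truth[truth$sample_id == detected$sample_id[i] &
                  truth$chrom == detected$chrom[i], , drop = FALSE]
    hit_det[i] <- nrow(tt) > 0 && any(vapply(seq_len(nrow(tt)), function(k)
      all(overlap_frac(detected$start_bp[i], detected$end_bp[i],
                       tt$start[k], tt$end[k]) >= min_ro),
      logical(1)))
  }
  list(recall = if (nrow(truth)) mean(hit_tr) else NA,
       precision = if (nrow(detected)) mean(hit_det) else NA)
}

# random additive tree + its exact leaf-to-leaf distance matrix (oracle for
# NJ consistency); built by sequential random joins, not via ape
rand_additive_tree <- function(n_taxa, seed) {
  set.seed(seed)
  tree <- ape::rtree(n_taxa, br = function(k) runif(k, 0.1, 1))
  D <- ape::cophenetic.phylo(tree)
  D <- D[order(rownames(D)), order(colnames(D))]
  list(tree = tree, D = D)
}

same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}
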