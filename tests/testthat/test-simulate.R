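small_cfg <- function(...) {
  args <- list(n_chrom = 4, chrom_length_bp = 5e7, n_snps = 4000,
               n_x_snps = 0, n_y_snps = 0)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

test_that("simulation is deterministic given the seed", {
  a <- simulate_population(small_cfg(seed = 99))
  b <- simulate_population(small_cfg(seed = 99))
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$truth$tracts, b$truth$tracts)
  c <- simulate_population(small_cfg(seed = 100))
  expect_false(identical(a$genotypes$dosage, c$genotypes$dosage))
})

test_that("planted autozygous tracts are fully homozygous and hit the target fraction", {
  cfg <- small_cfg(target_froh = 0.25, call_rate = 0.97, seed = 12)
  sim <- simulate_population(cfg)
  tr <- sim$truth$tracts
  expect_gt(nrow(tr), 0)
  # no overlap within a sample, bounds inside the chromosome
  for (id in unique(tr$sample_id)) {
    for (ch in unique(tr$chrom[tr$sample_id == id])) {
      t2 <- tr[tr$sample_id == id & tr$chrom == ch, ]
      t2 <- t2[order(t2$start), ]
      if (nrow(t2) > 1)
        expect_true(all(t2$start[-1] > t2$end[-nrow(t2)]))
      expect_true(all(t2$start >= 1 & t2$end <= cfg$chrom_length_bp))
    }
  }
  # every non-missing marker inside a tract is homozygous
  gm <- sim$genotypes
  for (i in seq_len(nrow(tr))) {
    vi <- gm$variants$chrom == tr$chrom[i] &
      gm$variants$pos >= tr$start[i] & gm$variants$pos <= tr$end[i]
    dos <- gm$dosage[gm$samples$id == tr$sample_id[i], vi]
    expect_false(any(dos == 1L, na.rm = TRUE))
  }
  # realized planted fraction matches the target
  total <- cfg$n_chrom * cfg$chrom_length_bp
  realized <- sapply(gm$samples$id, function(id)
    sum(tr$end[tr$sample_id == id] - tr$start[tr$sample_id == id] + 1)) / total
  expect_lt(abs(mean(realized) - 0.25), 0.01)
})

test_that("an unstructured population is consistent with Hardy-Weinberg equilibrium", {
  cfg <- small_cfg(n_sire_families = 0, n_assigned_females = 0,
                   target_froh = 0, call_rate = 1, n_snps = 1000,
                   n_males = 16, n_females = 16, seed = 21)
  sim <- simulate_population(cfg)
  d <- sim$genotypes$dosage
  pv <- apply(d, 2, function(col) {
    het <- sum(col == 1); ha <- sum(col == 2)
    hwe_exact_test(length(col) - het - ha, het, ha)
  })
  # exact-test p-values are conservative: the rejection rate at any nominal
  # level must not exceed it by more than sampling noise
  expect_lt(mean(pv < 0.05), 0.07)
  expect_lt(mean(pv < 0.01), 0.02)
})

test_that("founder allele-frequency spectrum follows the configured uniform law", {
  cfg <- small_cfg(n_sire_families = 0, n_assigned_females = 0,
                   target_froh = 0, call_rate = 1, n_snps = 10000,
                   n_males = 100, n_females = 100, maf_min = 0.01, seed = 31)
  sim <- simulate_population(cfg)
  p_hat <- colMeans(sim$genotypes$dosage) / 2
  # U(0.01, 0.5) moments, allowing for binomial sampling noise at n = 200
  expect_lt(abs(mean(p_hat) - 0.255), 0.01)
  expect_lt(abs(stats::sd(p_hat) - sqrt(0.49^2 / 12)), 0.02)
  # drift can push realized frequencies a little past the founder bounds,
  # but not far at n = 200
  expect_lt(max(p_hat), 0.7)
  expect_gt(mean(p_hat < 0.05), 0.05)  # low-frequency tail is populated
})

test_that("family planting mirrors the intended mating design", {
  ped <- plant_sire_families(small_cfg(n_males = 4, n_sire_families = 3,
                                       n_assigned_females = 28))
  sampled <- ped[ped$sampled, ]
  males <- sampled[sampled$sex == "male", ]
  # 3 families over 4 males: one family holds two (full-sib) males
  expect_equal(sort(table(males$family), decreasing = TRUE)[[1]], 2L)
  expect_equal(length(unique(males$family)), 3L)
  sibs <- males[males$family == names(which.max(table(males$family))), ]
  expect_equal(sibs$sire[1], sibs$sire[2])
  # every assigned female's sire is a sampled male of her family
  fem <- sampled[sampled$sex == "female", ]
  expect_true(all(fem$sire %in% males$id))
  expect_equal(unname(vapply(fem$sire, function(s)
    males$family[males$id == s], integer(1))), fem$family)

  # no families -> all founders
  ped0 <- plant_sire_families(small_cfg(n_sire_families = 0,
                                        n_assigned_females = 0))
  expect_true(all(is.na(ped0$sire)))
  expect_true(all(ped0$sampled))
})

test_that("configuration errors are rejected", {
  expect_error(sim_config(n_snps = 3, n_chrom = 10), "config error")
  expect_error(sim_config(n_sire_families = 5, n_males = 4))
  expect_error(sim_config(call_rate = 0))
  expect_error(sim_config(target_froh = 1.2))
})
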