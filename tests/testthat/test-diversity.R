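test_that("locus frequencies match direct allele counting", {
  lf <- locus_frequencies(c(0, 1, 2, 2, NA))
  expect_equal(lf$p, 0.625)
  expect_equal(lf$maf, 0.375)
  expect_equal(lf$n_called, 4L)

  expect_equal(locus_frequencies(rep(0, 6))$maf, 0)
  expect_equal(locus_frequencies(rep(1, 9))$p, 0.5)
  expect_equal(locus_frequencies(rep(1, 9))$maf, 0.5)
  expect_error(locus_frequencies(c(NA, NA)), "undefined")

  set.seed(71)
  for (rep in 1:50) {
    dos <- sample(c(0:2, NA), 30, replace = TRUE)
    if (all(is.na(dos))) next
    expect_equal(locus_frequencies(dos)$p, bf_freq(dos), tolerance = 1e-15)
  }
})

test_that("PIC, He, Ho and Ae match their defining formulas", {
  expect_equal(pic(c(0.5, 0.5)), 0.375)
  expect_equal(pic(1), 0)
  expect_equal(pic(c(0.9, 0.1)), 1 - 0.82 - 2 * 0.81 * 0.01)

  expect_equal(expected_heterozygosity(c(0.5, 0.5)), 0.5)
  expect_equal(expected_heterozygosity(c(0.9, 0.1)), 0.18)
  expect_equal(observed_heterozygosity(c(1, 1, 1, 1)), 1)
  expect_equal(observed_heterozygosity(c(0, 1, 2, 0, NA)), 0.25)

  expect_equal(effective_allele_number(c(0.5, 0.5)), 2)
  expect_equal(effective_allele_number(1), 1)
  expect_equal(effective_allele_number(c(0.9, 0.1)), 1 / 0.82)

  expect_error(pic(c(0.5, 0.6)), "sum to 1")
  expect_error(effective_allele_number(c(0.2, 0.2)), "sum to 1")

  # multi-allele frequency vectors against the brute-force double loop
  set.seed(72)
  for (rep in 1:50) {
    k <- sample(2:5, 1)
    f <- stats::runif(k); f <- f / sum(f)
    expect_equal(pic(f), bf_pic(f), tolerance = 1e-12)
    expect_equal(expected_heterozygosity(f), bf_he(f), tolerance = 1e-12)
    expect_equal(effective_allele_number(f), bf_ae(f), tolerance = 1e-12)
  }
})

test_that("per-locus statistics obey PIC <= He <= 2*MAF with equality at the extremes", {
  set.seed(73)
  p <- c(0, 0.5, runif(200))
  he <- 2 * p * (1 - p)
  pic_v <- vapply(p, function(pp) pic(c(pp, 1 - pp)), numeric(1))
  maf <- pmin(p, 1 - p)
  expect_true(all(pic_v <= he + 1e-12))
  expect_true(all(he <= 2 * maf + 1e-12))
  expect_equal(pic_v[p == 0], 0)
  expect_equal(he[p == 0], 2 * maf[p == 0])
  expect_equal(he[p == 0.5], 2 * maf[p == 0.5] - 0.5)  # He = 0.5 at MAF 0.5
})

test_that("proportion of polymorphic markers follows the threshold convention", {
  expect_equal(proportion_polymorphic(rep(0, 10)), 0)
  expect_equal(proportion_polymorphic(c(0, 0, 1e-6, 0.3), threshold = 0), 0.5)
  maf <- c(rep(0.2, 17), 0.01, 0.02, 0.04)  # 3 planted below 0.05
  expect_equal(proportion_polymorphic(maf, 0.05), 0.85)
})

test_that("the HWE exact test matches full enumeration", {
  expect_equal(hwe_exact_test(7, 0, 0), 1)
  expect_equal(hwe_exact_test(0, 2, 0), bf_hwe(0, 2, 0), tolerance = 1e-12)
  expect_equal(hwe_exact_test(5, 10, 5), bf_hwe(5, 10, 5), tolerance = 1e-10)

  set.seed(74)
  for (rep in 1:200) {
    n <- sample(1:25, 1)
    ha <- sample(0:n, 1)
    het <- sample(0:(n - ha), 1)
    hr <- n - ha - het
    expect_equal(hwe_exact_test(hr, het, ha), bf_hwe(hr, het, ha),
                 tolerance = 1e-10)
  }
  expect_error(hwe_exact_test(0, 0, 0), "at least one")
})

test_that("locus_stats agrees with brute-force per-locus recomputation", {
  gm <- rand_gm(n = 15, m = 60, miss_rate = 0.15, seed = 75)
  st <- locus_stats(gm, autosomes = c("1", "2"))
  for (j in seq_len(60)) {
    dos <- gm$dosage[, j]
    if (all(is.na(dos))) next
    p <- bf_freq(dos)
    expect_equal(st$p[j], p, tolerance = 1e-12)
    expect_equal(st$maf[j], min(p, 1 - p), tolerance = 1e-12)
    expect_equal(st$ho[j], bf_ho(dos), tolerance = 1e-12)
    expect_equal(st$he[j], bf_he(c(p, 1 - p)), tolerance = 1e-12)
    expect_equal(st$pic[j], bf_pic(c(p, 1 - p)), tolerance = 1e-12)
    expect_equal(st$ae[j], bf_ae(c(p, 1 - p)), tolerance = 1e-12)
    het <- sum(dos == 1, na.rm = TRUE); ha <- sum(dos == 2, na.rm = TRUE)
    expect_equal(st$hwe_p[j],
                 bf_hwe(sum(!is.na(dos)) - het - ha, het, ha),
                 tolerance = 1e-10)
  }
})

test_that("the Sved relation and the LD-based Ne estimator behave as expected", {
  expect_equal(sved_ne(1, 0.5), 0)
  expect_equal(sved_ne(0.2, 0.5), 2)   # (1/2) * (5 - 1)

  sim <- simulate_population(sim_config(
    n_males = 16, n_females = 16, n_sire_families = 0,
    n_assigned_females = 0, target_froh = 0, call_rate = 1,
    n_chrom = 4, chrom_length_bp = 5e7, n_snps = 2000,
    n_x_snps = 0, n_y_snps = 0, seed = 76))
  est <- ne_from_ld(sim$genotypes)
  expect_true(is.finite(est$ne) && est$ne > 0)
  expect_gt(est$n_pairs, 100)

  one <- subset_genotypes(sim$genotypes, variants = c(TRUE, rep(FALSE, 1999)))
  expect_error(ne_from_ld(one), ">= 2 loci")
})

test_that("the population summary averages QC-passed loci", {
  gm <- rand_gm(n = 20, m = 80, miss_rate = 0.05, seed = 77)
  st <- locus_stats(gm, autosomes = c("1", "2"))
  ds <- diversity_summary(gm, pn_threshold = 0.05, autosomes = c("1", "2"))
  expect_equal(ds$mean_maf, mean(st$maf))
  expect_equal(ds$mean_ho, mean(st$ho))
  expect_equal(ds$mean_pic, mean(st$pic))
  expect_equal(ds$pn, mean(st$maf >= 0.05))
  expect_equal(ds$n_loci, 80L)
})
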