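test_that("the VanRaden G matrix matches hand arithmetic on a tiny example", {
  # 2 samples x 3 loci, no missing
  d <- matrix(c(0L, 2L,
                1L, 1L,
                2L, 0L), nrow = 2)
  gm <- genotype_matrix(
    d, data.frame(id = c("a", "b"), sex = c("male", "female")),
    data.frame(chrom = "1", pos = c(100L, 200L, 300L),
               id = c("v1", "v2", "v3"), ref = "A", alt = "G"))
  # p = (0.5, 0.5, 0.5); Z = d - 1; denom = 3 * 2 * 0.25 = 1.5
  # Za = (-1, 0, 1), Zb = (1, 0, -1)
  G <- grm_vanraden(gm)
  expect_equal(unname(G["a", "a"]), 2 / 1.5, tolerance = 1e-12)
  expect_equal(unname(G["a", "b"]), -2 / 1.5, tolerance = 1e-12)
  expect_lt(max(abs(unclass(G) - t(unclass(G)))), 1e-15)
})

test_that("a duplicated sample has off-diagonal kinship equal to its diagonal", {
  gm <- rand_gm(n = 8, m = 200, miss_rate = 0, seed = 91)
  d2 <- rbind(gm$dosage, gm$dosage[3, ])
  gm2 <- genotype_matrix(
    d2, rbind(gm$samples, data.frame(id = "dup", sex = "female")),
    gm$variants)
  G <- grm_vanraden(gm2)
  expect_equal(unname(G["dup", "s03"]), unname(G["s03", "s03"]),
               tolerance = 1e-12)
  P <- pca_genotypes(gm2, k = 3)
  expect_equal(unname(P$coords["dup", ]), unname(P$coords["s03", ]),
               tolerance = 1e-8)
})

test_that("monomorphic-only input is a degenerate-denominator error", {
  gm <- genotype_matrix(
    matrix(0L, 3, 2),
    data.frame(id = c("a", "b", "c"), sex = "female"),
    data.frame(chrom = "1", pos = c(1L, 2L), id = c("v1", "v2"),
               ref = "A", alt = "G"))
  expect_error(grm_vanraden(gm), "monomorphic")
})

test_that("IBS distance equals the allele-sharing definition", {
  mk <- function(d) genotype_matrix(
    d, data.frame(id = c("a", "b"), sex = "female"),
    data.frame(chrom = "1", pos = seq_len(ncol(d)) * 100L,
               id = paste0("v", seq_len(ncol(d))), ref = "A", alt = "G"))
  # identical genotypes -> 0
  expect_equal(unname(ibs_distance(mk(matrix(c(0L, 0L, 1L, 1L, 2L, 2L),
                                             2)))["a", "b"]), 0)
  # opposite homozygotes -> 1
  expect_equal(unname(ibs_distance(mk(matrix(c(0L, 2L, 2L, 0L), 2)))["a", "b"]),
               1)
  # hand enumeration: genotypes (0,1), (2,1), (1,1) -> D = 1/3
  expect_equal(unname(ibs_distance(mk(matrix(c(0L, 1L, 2L, 1L, 1L, 1L),
                                             2)))["a", "b"]), 1 / 3)

  gm <- rand_gm(n = 7, m = 120, miss_rate = 0.2, seed = 92)
  D <- ibs_distance(gm)
  for (i in 1:6) for (j in (i + 1):7)
    expect_equal(unname(D[i, j]),
                 bf_ibs_pair(gm$dosage[i, ], gm$dosage[j, ]),
                 tolerance = 1e-12)
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0 & D <= 1))
})

test_that("PCA returns ordered eigenvalues, orthonormal axes, and separates planted subpopulations", {
  set.seed(93)
  n <- 20; m <- 400
  pA <- runif(m, 0.05, 0.95)
  pB <- pmin(pmax(pA + sample(c(-0.4, 0.4), m, TRUE), 0.02), 0.98)
  d <- rbind(
    matrix(rbinom(10 * m, 2, rep(pA, each = 10)), nrow = 10),
    matrix(rbinom(10 * m, 2, rep(pB, each = 10)), nrow = 10))
  gm <- genotype_matrix(
    d, data.frame(id = sprintf("s%02d", 1:n), sex = "female"),
    data.frame(chrom = "1", pos = seq_len(m) * 50L,
               id = paste0("v", 1:m), ref = "A", alt = "G"))
  P <- pca_genotypes(gm, k = 3)
  expect_true(all(diff(P$eigenvalues) <= 1e-9))
  expect_true(all(P$eigenvalues >= 0))
  V <- P$vectors[, 1:3]
  expect_equal(crossprod(V), diag(3), tolerance = 1e-8)
  pc1 <- P$coords[, 1]
  expect_true(max(pc1[1:10]) < min(pc1[11:20]) ||
                min(pc1[1:10]) > max(pc1[11:20]))
  expect_error(pca_genotypes(gm, k = 20), "smaller")
})

test_that("centering-only PCA reproduces the G-matrix eigenspace", {
  # exact equivalence holds for complete data, where the per-pair GRM
  # denominators coincide and G is proportional to the PCA kernel
  gm <- rand_gm(n = 12, m = 300, miss_rate = 0, seed = 94)
  G <- grm_vanraden(gm)
  P <- pca_genotypes(gm, k = 3, scale = "none")
  eg <- eigen(unclass(G), symmetric = TRUE)
  for (k in 1:3) {
    v1 <- eg$vectors[, k]
    v2 <- P$vectors[, k]
    expect_lt(abs(abs(sum(v1 * v2)) - 1), 1e-6)
  }
})

test_that("G and IBS similarity agree ordinally on a family-structured population", {
  sim <- simulate_population(sim_config(
    n_males = 4, n_females = 24, n_sire_families = 3,
    n_assigned_females = 24, n_chrom = 8, chrom_length_bp = 4e7,
    n_snps = 10000, target_froh = 0, n_x_snps = 0, n_y_snps = 0, seed = 95))
  G <- unclass(grm_vanraden(sim$genotypes))
  D <- unclass(ibs_distance(sim$genotypes))
  ut <- upper.tri(D)
  # raw IBS similarity carries per-individual homozygosity (row) effects
  # that the centered G removes, capping raw pairwise rank agreement
  expect_gt(stats::cor(G[ut], 1 - D[ut], method = "spearman"), 0.6)
  # after the standard Gower double-centering of the distance matrix the
  # two kinship orderings agree almost perfectly
  n <- nrow(D)
  J <- diag(n) - 1 / n
  S <- -0.5 * J %*% D %*% J
  expect_gt(stats::cor(G[ut], S[ut], method = "spearman"), 0.9)
})
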