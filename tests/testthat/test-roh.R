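empty_segments <- function() {
  data.frame(sample_id = character(0), chrom = character(0),
             start_bp = numeric(0), end_bp = numeric(0),
             n_snps = integer(0), length_bp = numeric(0))
}

# dense single-sample, single-chromosome fixture builder
roh_gm <- function(dosage, pos, chrom = "1", id = "s1") {
  genotype_matrix(
    dosage = matrix(as.integer(dosage), nrow = 1),
    samples = data.frame(id = id, sex = "female"),
    variants = data.frame(chrom = chrom, pos = as.integer(pos),
                          id = paste0("v", seq_along(pos)),
                          ref = "A", alt = "G"))
}

test_that("a densely covered planted tract is recovered as one segment", {
  set.seed(81)
  # 10 Mb homozygous tract (positions 5e6..15e6) inside a 30 Mb chromosome
  pos <- sort(sample.int(3e7, 600))
  dos <- rbinom(600, 2, 0.4)
  inside <- pos >= 5e6 & pos <= 15e6
  dos[inside] <- 2L * rbinom(sum(inside), 1, 0.4)   # hom only
  dos[!inside][seq(1, sum(!inside), by = 3)] <- 1L  # hets sprinkle outside
  gm <- roh_gm(dos, pos)
  segs <- detect_roh(gm, "s1", roh_params())
  expect_equal(nrow(segs), 1L)
  # marker-resolution bound accuracy: within a few local marker spacings
  spacing <- 3e7 / 600
  expect_lt(abs(segs$start_bp[1] - 5e6), 10 * spacing)
  expect_lt(abs(segs$end_bp[1] - 15e6), 10 * spacing)
})

test_that("heterozygous and marker-poor stretches yield no segments", {
  pos <- seq(1e5, 3e7, by = 1e5)
  expect_equal(nrow(detect_roh(roh_gm(rep(1L, length(pos)), pos), "s1",
                               roh_params())), 0L)
  # 2 Mb homozygous but only 5 markers: below min_snps
  gm <- roh_gm(c(1, 1, 0, 0, 0, 0, 0, 1, 1),
               c(1e5, 2e5, 1e6, 1.5e6, 2e6, 2.5e6, 3e6, 4e6, 4.1e6))
  expect_equal(nrow(detect_roh(gm, "s1",
                               roh_params(window_snps = 3, min_snps = 15))),
               0L)
})

test_that("the two-stage scanner agrees with the naive exhaustive scanner", {
  params <- roh_params(min_length_bp = 5e5, min_snps = 8, window_snps = 10,
                       max_gap_bp = 5e5)
  set.seed(82)
  for (rep in 1:25) {
    m <- sample(50:400, 1)
    pos <- sort(sample.int(2e7, m))
    dos <- rbinom(m, 2, runif(1, 0.2, 0.5))
    # plant a few homozygous runs of random extent
    for (k in seq_len(sample(0:3, 1))) {
      a <- sample(m, 1); b <- min(m, a + sample(10:80, 1))
      dos[a:b] <- 2L * rbinom(b - a + 1, 1, 0.5)
    }
    dos[runif(m) < 0.03] <- NA
    segs <- detect_roh(roh_gm(dos, pos), "s1", params)
    ref <- bf_roh_chrom(dos, pos, params)
    expect_equal(nrow(segs), nrow(ref))
    if (nrow(ref)) {
      expect_equal(segs$start_bp, ref[, 1])
      expect_equal(segs$end_bp, ref[, 2])
      expect_equal(segs$n_snps, as.integer(ref[, 3]))
    }
  }
})

test_that("runs are split at large marker gaps", {
  # 60 homozygous markers with a 2 Mb hole in the middle
  pos <- c(seq(1e6, 2.45e6, by = 5e4), seq(4.5e6, 5.95e6, by = 5e4))
  dos <- rep(0L, length(pos))
  segs <- detect_roh(roh_gm(dos, pos), "s1",
                     roh_params(min_length_bp = 1e6, min_snps = 15,
                                window_snps = 10, max_gap_bp = 1e6))
  expect_equal(nrow(segs), 2L)
  expect_true(all(segs$length_bp < 2e6))
})

test_that("raising the minimum run length never increases F_ROH", {
  sim <- simulate_population(sim_config(
    n_males = 2, n_females = 10, n_chrom = 4, chrom_length_bp = 5e7,
    n_snps = 4000, target_froh = 0.2, n_sire_families = 0,
    n_assigned_females = 0, n_x_snps = 0, n_y_snps = 0, seed = 83))
  L <- 4 * 5e7 / 1000
  froh_at <- function(min_len) {
    segs <- detect_roh_all(sim$genotypes,
                           roh_params(min_length_bp = min_len),
                           autosomes = as.character(1:4))
    froh_all(segs, sim$genotypes$samples$id, L = L)$froh
  }
  f1 <- froh_at(1e6); f2 <- froh_at(2e6); f4 <- froh_at(4e6)
  expect_true(all(f2 <= f1 + 1e-12))
  expect_true(all(f4 <= f2 + 1e-12))
})

test_that("F_ROH is total run length over autosome length, in Kb", {
  seg <- data.frame(sample_id = "s1", chrom = "1", start_bp = 1,
                    end_bp = 10660000, n_snps = 200,
                    length_bp = 10660000)
  r <- froh(seg, L = 2302664.694)
  expect_equal(r$froh, 10660 / 2302664.694)
  expect_equal(r$total_roh_length_kb, 10660)

  expect_equal(froh(empty_segments())$froh, 0)

  # segments tiling the whole autosome -> F_ROH = 1
  tile <- data.frame(sample_id = "s1", chrom = as.character(1:4),
                     start_bp = 1, end_bp = 5e7, n_snps = 100,
                     length_bp = 5e7)
  expect_equal(froh(tile, L = 4 * 5e7 / 1000)$froh, 1)
  expect_error(froh(tile, L = 0), "positive")
})

test_that("population ROH summaries bin lengths and chromosomes correctly", {
  set.seed(84)
  lens <- c(runif(36, 1e6, 5e6 - 1), runif(10, 5e6, 1e7 - 1),
            runif(3, 1e7, 1.2e7))
  segs <- data.frame(sample_id = sample(sprintf("s%d", 1:6), 49, TRUE),
                     chrom = sample(as.character(1:5), 49, TRUE),
                     start_bp = 1, end_bp = lens, n_snps = 30,
                     length_bp = lens)
  sm <- roh_summaries(segs, sprintf("s%d", 1:6), L = 2302664.694)
  expect_equal(sm$n_segments, 49L)
  expect_equal(sm$length_bins$count, c(36L, 10L, 3L))
  expect_equal(sm$length_bins$proportion[1], 36 / 49)
  expect_equal(sum(sm$per_chromosome$count), 49L)
  expect_equal(sum(sm$per_individual$n_individuals), 6L)
  expect_equal(nrow(sm$froh), 6L)

  empty <- roh_summaries(empty_segments(), sprintf("s%d", 1:3))
  expect_equal(empty$n_segments, 0L)
  expect_true(all(empty$froh$froh == 0))
})

test_that("unknown samples and unsorted input are rejected", {
  gm <- roh_gm(rep(0L, 20), seq(1e5, 2e6, by = 1e5))
  expect_error(detect_roh(gm, "nope", roh_params()), "unknown sample")
})
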