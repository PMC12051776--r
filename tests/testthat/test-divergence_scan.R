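gm_two_pop <- function(d1, d2) {
  n1 <- ncol(d1); n2 <- ncol(d2)
  genotype_matrix(
    chrom = rep("chr1", nrow(d1)), pos = seq_len(nrow(d1)) * 100L,
    ref = rep("A", nrow(d1)), alt = rep("T", nrow(d1)),
    dosage = cbind(d1, d2), phased = FALSE,
    samples = sprintf("s%d", seq_len(n1 + n2)),
    pop = c(rep("A", n1), rep("B", n2)),
    phenotype = c(rep("resistant", n1), rep("susceptible", n2)))
}

test_that("fixed differences give theta = 1 and no differentiation <= 0", {
  gm <- gm_two_pop(matrix(0L, 2, 5), matrix(2L, 2, 5))
  res <- fst_site(gm, "A", "B")
  expect_equal(res$theta, c(1, 1))
  # identical fully heterozygous groups: no among-population variance
  gm2 <- gm_two_pop(matrix(1L, 2, 6), matrix(1L, 2, 6))
  res2 <- fst_site(gm2, "A", "B")
  expect_true(all(res2$a == 0))
  expect_true(all(res2$theta <= 0))
})

test_that("HWE example matches the independently transcribed estimator", {
  # 10 + 10 samples, HWE counts at p1 = 0.2 (1 hom-alt, 2 het, 7 hom-ref)
  # and p2 = 0.8 (mirrored)
  d1 <- matrix(c(2L, rep(1L, 2), rep(0L, 7)), 1)
  d2 <- matrix(c(rep(2L, 7), rep(1L, 2), 0L), 1)
  res <- fst_site(gm_two_pop(d1, d2), "A", "B")
  o <- wc_fst_oracle(as.vector(d1), as.vector(d2))
  expect_equal(res$a, o$a, tolerance = 1e-14)
  expect_equal(res$b, o$b, tolerance = 1e-14)
  expect_equal(res$c, o$c, tolerance = 1e-14)
  expect_equal(res$theta, o$theta, tolerance = 1e-14)
})

test_that("fst_site matches the oracle on random tables with missing data", {
  set.seed(101)
  worst <- 0
  for (i in 1:100) {
    tab <- random_dosage_pair()
    res <- fst_site(gm_two_pop(tab$d1, tab$d2), "A", "B")
    for (s in seq_len(tab$S)) {
      o <- wc_fst_oracle(tab$d1[s, ], tab$d2[s, ])
      for (f in c("a", "b", "c", "theta")) {
        x <- res[[f]][s]; y <- o[[f]]
        if (is.na(y)) expect_true(is.na(x))
        else worst <- max(worst, abs(x - y))
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("fst_site is symmetric in group order and rejects bad groups", {
  set.seed(7)
  tab <- random_dosage_pair()
  gm <- gm_two_pop(tab$d1, tab$d2)
  ab <- fst_site(gm, "A", "B")
  ba <- fst_site(gm, "B", "A")
  expect_equal(ab$theta, ba$theta)
  expect_error(fst_site(gm, c("s1", "s2"), c("s2", "s3")), "overlap")
  expect_error(fst_site(gm, "s1", "B"), "at least 2")
})

test_that("windowed F_ST is the ratio of summed components", {
  set.seed(21)
  tab <- random_dosage_pair(max_n = 10, max_sites = 40)
  gm <- gm_two_pop(tab$d1, tab$d2)
  sr <- fst_site(gm, "A", "B")
  # single window over the whole input equals the global ratio of averages
  w <- fst_windowed(sr, window_size = 1e6, min_snps = 1)
  ok <- !is.na(sr$theta)
  expect_equal(w$value,
               sum(sr$a[ok]) / sum(sr$a[ok] + sr$b[ok] + sr$c[ok]))
  # a window holding exactly one usable site equals that site's theta
  w1 <- fst_windowed(sr[which(ok)[1], ], window_size = 100, min_snps = 1)
  expect_equal(w1$value[w1$n_snps == 1][1], sr$theta[ok][1])
  expect_error(fst_windowed(sr, window_size = 0), "positive")
})

test_that("windows below the SNP minimum are undefined", {
  d1 <- matrix(0L, 24, 5); d2 <- matrix(2L, 24, 5)
  sr <- fst_site(gm_two_pop(d1, d2), "A", "B")
  w24 <- fst_windowed(sr, window_size = 25000, min_snps = 25)
  expect_true(is.na(w24$value[1]))
  w_ok <- fst_windowed(sr, window_size = 25000, min_snps = 24)
  expect_equal(w_ok$value[1], 1)   # all fixed differences
})

test_that("top-quantile flagging handles distinct values, ties, monotone maps", {
  w <- data.frame(value = sample(seq(0.01, 1, length.out = 100)))
  f <- top_quantile_flags(w, 0.99)
  expect_equal(sum(f$top), 1L)
  expect_equal(which(f$top), which.max(w$value))
  # all-equal values: every window is at the threshold
  wt <- data.frame(value = rep(0.4, 50))
  expect_true(all(top_quantile_flags(wt, 0.99)$top))
  # flags invariant under a random monotone transformation
  set.seed(33)
  for (i in 1:10) {
    v <- runif(60)
    mono <- function(x) exp(2 * x) + 3 * x
    f1 <- top_quantile_flags(data.frame(value = v), 0.9)$top
    f2 <- top_quantile_flags(data.frame(value = mono(v)), 0.9)$top
    expect_identical(f1, f2)
  }
  expect_error(top_quantile_flags(data.frame(value = NA_real_)), "defined")
})

test_that("parallel divergence counts stay within bounds", {
  set.seed(55)
  sim <- simulate_demes(sweep_sim_params(
    n_diploids = 50, seq_length = 2e4, n_sites = 200, burn_in_gens = 50,
    selection_gens = 30, sample_per_deme = 12, sweep_pos = 7500,
    seed = 9))
  f <- write_sim_vcf(sim$hm, withr::local_tempfile(fileext = ".vcf"))
  gm <- read_vcf(f["vcf"], f["sample_map"])
  pd <- parallel_divergence_counts(gm, c("R1", "R2", "R3"),
                                   c("S1", "S2", "S3"),
                                   window_size = 5000, min_snps = 2)
  expect_true(all(pd$flag_count >= 0 & pd$flag_count <= 9))
  expect_equal(pd$n_comparisons[1], 9L)
  pd1 <- parallel_divergence_counts(gm, "R1", "S1", window_size = 5000,
                                    min_snps = 2)
  expect_true(all(pd1$flag_count %in% 0:1))
  expect_error(parallel_divergence_counts(gm, character(0), "S1"),
               "at least one")
})

test_that("without planted structure about 1% of windows are flagged", {
  set.seed(404)
  # neutral simulation, groups are arbitrary halves of one panmictic deme
  sim <- simulate_demes(sweep_sim_params(
    n_diploids = 100, seq_length = 1e5, n_sites = 1000, n_origins = 0,
    burn_in_gens = 150, selection_gens = 0, n_demes_resistant = 0,
    n_demes_susceptible = 1, sample_per_deme = 80, seed = 17))
  hm <- sim$hm
  gm <- genotype_matrix(
    chrom = hm$chrom, pos = hm$pos, ref = rep("A", length(hm$pos)),
    alt = rep("T", length(hm$pos)),
    dosage = t(hm$H[seq(1, 79, 2), ] + hm$H[seq(2, 80, 2), ]),
    phased = TRUE, samples = unique(hm$sample),
    pop = rep(c("X", "Y"), each = 20),
    phenotype = rep(c("resistant", "susceptible"), each = 20))
  sr <- fst_site(gm, "X", "Y")
  w <- fst_windowed(sr, window_size = 2000, min_snps = 2)
  f <- top_quantile_flags(w, 0.9)
  frac <- mean(f$top[!is.na(f$value)])
  expect_gt(frac, 0.02); expect_lt(frac, 0.35)
})
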