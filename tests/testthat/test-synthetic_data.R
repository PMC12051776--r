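small_params <- function(seed, ...) {
  args <- list(n_diploids = 50, seq_length = 1e4, n_sites = 100,
               burn_in_gens = 100, selection_gens = 40,
               n_demes_resistant = 1, n_demes_susceptible = 1,
               sample_per_deme = 20, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(sweep_sim_params, args)
}

test_that("the same seed reproduces the simulation bit-for-bit", {
  a <- simulate_demes(small_params(seed = 31))
  b <- simulate_demes(small_params(seed = 31))
  expect_identical(a$hm$H, b$hm$H)
  expect_identical(a$hm$pos, b$hm$pos)
  expect_identical(a$truth$final_freq, b$truth$final_freq)
  c <- simulate_demes(small_params(seed = 32))
  expect_false(identical(a$hm$H, c$hm$H))
})

test_that("a neutral allele at frequency 0.5 drifts without trend", {
  # s = 0, one origin at f0 = 0.5: the mean final frequency over
  # replicates stays at 0.5 (pure drift)
  final <- vapply(1:200, function(sd) {
    sim <- simulate_demes(sweep_sim_params(
      n_diploids = 30, seq_length = 5e3, n_sites = 20, s = 0, f0 = 0.5,
      n_origins = 1, burn_in_gens = 10, selection_gens = 20,
      n_demes_resistant = 1, n_demes_susceptible = 0,
      sample_per_deme = 10, resample_on_loss = FALSE, seed = sd),
      drop_monomorphic = FALSE)
    unname(sim$truth$final_freq[1])
  }, numeric(1))
  se <- sd(final) / sqrt(length(final))
  expect_lt(abs(mean(final) - 0.5), 2 * se + 1e-9)
})

test_that("strong dominant selection drives the allele to (near) fixation", {
  # with h = 1 the wild-type allele is shielded in heterozygotes and is
  # eliminated only algebraically; "effectively fixed" is > 0.9
  fixed <- vapply(1:20, function(sd) {
    sim <- simulate_demes(sweep_sim_params(
      n_diploids = 500, seq_length = 1e4, n_sites = 50, s = 0.5, h = 1,
      f0 = 0.1, burn_in_gens = 0, selection_gens = 400,
      n_demes_resistant = 1, n_demes_susceptible = 0,
      sample_per_deme = 10, resample_on_loss = FALSE, seed = sd),
      drop_monomorphic = FALSE)
    unname(sim$truth$final_freq[1]) > 0.9
  }, logical(1))
  expect_gte(mean(fixed), 0.95)
})

test_that("neutral demes sit at mutation-drift equilibrium heterozygosity", {
  N <- 50; S <- 100
  het <- vapply(1:200, function(sd) {
    sim <- simulate_demes(sweep_sim_params(
      n_diploids = N, seq_length = 1e4, n_sites = S, n_origins = 0,
      burn_in_gens = 2 * N, selection_gens = 0, n_demes_resistant = 0,
      n_demes_susceptible = 1, sample_per_deme = 2 * N, seed = sd),
      drop_monomorphic = FALSE)
    n <- nrow(sim$hm$H)
    p <- colMeans(sim$hm$H)
    mean(2 * p * (1 - p) * n / (n - 1))
  }, numeric(1))
  mu_site <- 6e-7 * 1e4 / S
  expected <- 4 * N * mu_site / (1 + 4 * N * mu_site)
  expect_lt(abs(mean(het) - expected) / expected, 0.15)
})

test_that("simulated VCF output is a faithful phased VCF", {
  sim <- simulate_demes(small_params(seed = 77))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  f <- write_sim_vcf(sim$hm, vcf)
  lines <- readLines(vcf)
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), ncol(sim$hm$H))
  gt <- strsplit(body[1], "\t")[[1]][-(1:9)]
  expect_true(all(grepl("^[01]\\|[01]$", gt)))
  pos <- as.integer(vapply(strsplit(body, "\t"), `[`, "", 2))
  expect_true(all(diff(pos) > 0) && all(pos >= 1))
  gm <- read_vcf(f["vcf"], f["sample_map"])
  hm2 <- to_haplotypes(gm, group_by = "population")
  expect_identical(hm2$H, sim$hm$H)
  expect_identical(hm2$pos, sim$hm$pos)
})

test_that("hard sweeps leave the expected local signatures", {
  hits <- c(pi = 0, seg = 0, h12 = 0, ehh = 0)
  n_rep <- 8
  for (sd in 1:n_rep) {
    sim <- simulate_demes(sweep_sim_params(
      n_diploids = 200, seq_length = 5e4, n_sites = 2000,
      sweep_pos = 2.5e4, burn_in_gens = 200, selection_gens = 60,
      n_demes_resistant = 1, n_demes_susceptible = 1,
      sample_per_deme = 30, seed = sd * 7L))
    hm <- sim$hm
    sp <- sim$truth$sweep_pos
    near <- list(chrom = "chr1", start = sp - 5e3, end = sp + 5e3)
    far <- list(chrom = "chr1", start = 4e4, end = 5e4)
    gr <- group_site_summary(hm, near, "R1")
    gs <- group_site_summary(hm, near, "S1")
    if (gr$pi < gs$pi) hits["pi"] <- hits["pi"] + 1
    if (gr$prop_segregating < gs$prop_segregating)
      hits["seg"] <- hits["seg"] + 1
    idx <- which(hm$pos >= sp - 5e3 & hm$pos <= sp + 5e3)
    hr <- h_statistics(hm, idx, "R1"); hs <- h_statistics(hm, idx, "S1")
    if (hr$H12 > hs$H12) hits["h12"] <- hits["h12"] + 1
    core <- hm$pos[which.min(abs(hm$pos - sp))]
    er <- tryCatch(ehh(hm, core, 1, "R1", min_ehh = 0),
                   error = function(e) NULL)
    es <- tryCatch(ehh(hm, core, 1, "S1", min_ehh = 0),
                   error = function(e) NULL)
    if (!is.null(er) && (is.null(es) ||
                         sum(er$ehh > 0.5) > sum(es$ehh > 0.5)))
      hits["ehh"] <- hits["ehh"] + 1
  }
  for (nm in names(hits)) expect_gte(hits[[nm]], ceiling(0.9 * n_rep) - 1)
})

test_that("F2 bulk counts reproduce the Mendelian expectation", {
  # dominant locus, survivors bulked: R-allele frequency 2/3 in the
  # resistant bulk, 0 in the susceptible bulk
  idx_r <- idx_s <- numeric(30)
  for (sd in 1:30) {
    sim <- simulate_f2_bulks(
      bsa_sim_params(seed = sd, n_sites = 3, mean_depth = 600,
                     causal_pos = 5e7),
      marker_map = c(1e7, 5e7, 9e7))
    si <- snp_index(sim$counts)
    at <- which(si$pos == 5e7)
    idx_r[sd] <- si$index_r[at]; idx_s[sd] <- si$index_s[at]
  }
  expect_lt(abs(mean(idx_r) - 2 / 3), 0.02)
  expect_lt(abs(mean(idx_s) - 0), 0.02)
})

test_that("a marker unlinked to the causal locus shows no skew", {
  deltas <- vapply(1:30, function(sd) {
    sim <- simulate_f2_bulks(
      bsa_sim_params(seed = sd * 3L, n_sites = 2, mean_depth = 200,
                     causal_pos = 9.9e7, rec_per_bp = 1e-7),
      marker_map = c(1e3, 9.9e7))  # ~10 Morgans apart: unlinked
    snp_index(sim$counts)$delta[1]
  }, numeric(1))
  expect_lt(abs(mean(deltas)), 3 * sd(deltas) / sqrt(length(deltas)) + 0.02)
})

test_that("bulk simulation respects seeds and class sizes", {
  a <- simulate_f2_bulks(bsa_sim_params(seed = 4, n_sites = 50))
  b <- simulate_f2_bulks(bsa_sim_params(seed = 4, n_sites = 50))
  expect_identical(a$counts, b$counts)
  expect_error(simulate_f2_bulks(
    bsa_sim_params(seed = 1, n_f2 = 60, n_f2_susceptible_bulk = 47)),
    "survivors")
})
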