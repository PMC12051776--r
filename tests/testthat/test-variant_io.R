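test_that("read_vcf parses records, depths, phase and missing calls", {
  vcf <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"))
  tab <- write_toy_sample_table(withr::local_tempfile(fileext = ".tsv"))
  gm <- read_vcf(vcf, tab)
  expect_equal(length(gm$pos), 3L)
  expect_equal(gm$samples, c("s1", "s2", "s3", "s4"))
  expect_equal(gm$pos, c(100L, 200L, 300L))
  expect_equal(unname(gm$dosage[1, ]), c(1L, 2L, 0L, NA))
  expect_equal(unname(gm$dosage[2, ]), c(0L, 1L, 2L, 0L))
  expect_equal(unname(gm$depth[1, ]), c(20L, 30L, 25L, 5L))
  expect_true(all(gm$phased[1, 1:3]))
  expect_false(any(gm$phased[2, ]))
  # phase order preserved: site 300 s1 is 1|0
  expect_equal(unname(gm$a1[3, "s1"]), 1L)
  expect_equal(unname(gm$a2[3, "s1"]), 0L)
})

test_that("read_vcf aligns dosage columns to the sample-table order", {
  vcf <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"))
  tab <- write_toy_sample_table(withr::local_tempfile(fileext = ".tsv"),
                                ids = c("s3", "s1", "s4", "s2"))
  gm <- read_vcf(vcf, tab)
  expect_equal(gm$samples, c("s3", "s1", "s4", "s2"))
  expect_equal(unname(gm$dosage[1, ]), c(0L, 1L, NA, 2L))
})

test_that("read_vcf warns on samples missing from the table", {
  vcf <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"))
  tab <- write_toy_sample_table(withr::local_tempfile(fileext = ".tsv"),
                                ids = c("s1", "s2", "s3"))
  expect_warning(gm <- read_vcf(vcf, tab), "s4")
  expect_equal(gm$samples, c("s1", "s2", "s3"))
})

test_that("malformed VCF records are reported with their line number", {
  vcf <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"),
                       lines_extra = "chr1\t400\t.\tA")
  tab <- write_toy_sample_table(withr::local_tempfile(fileext = ".tsv"))
  expect_error(read_vcf(vcf, tab), "line 9")
  vcf2 <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"),
                        lines_extra = paste0("chr1\tXX\t.\tA\tT\t.\t.\t.",
                                             "\tGT\t0|0\t0|0\t0|0\t0|0"))
  expect_error(read_vcf(vcf2, tab), "line 9.*POS")
})

make_gm <- function(dosage, depth = NULL, ref = NULL, alt = NULL,
                    phased = TRUE) {
  ns <- ncol(dosage)
  genotype_matrix(
    chrom = rep("chr1", nrow(dosage)),
    pos = seq_len(nrow(dosage)) * 100L,
    ref = ref %||% rep("A", nrow(dosage)),
    alt = alt %||% rep("T", nrow(dosage)),
    dosage = dosage, depth = depth, phased = phased,
    samples = sprintf("s%d", seq_len(ns)),
    pop = rep(c("P1", "P2"), length.out = ns),
    phenotype = rep(c("resistant", "susceptible"), length.out = ns))
}

test_that("filter_variants applies the depth-support rule", {
  dos <- matrix(1L, 3, 10)
  depth <- rbind(rep(5L, 10),                 # all below min_depth
                 c(rep(100L, 8), 3L, 3L),     # 8/10 in range = 0.8 >= 0.75
                 c(rep(100L, 7), 3L, 3L, 3L)) # 7/10 = 0.7 < 0.75
  gm <- make_gm(dos, depth = depth)
  suppressMessages(out <- filter_variants(gm))
  expect_equal(out$pos, 200L)
  expect_error(suppressMessages(
    filter_variants(make_gm(dos[1, , drop = FALSE],
                            depth = depth[1, , drop = FALSE]))),
    "review thresholds")
})

test_that("filter_variants drops indels and multiallelic records", {
  dos <- matrix(1L, 3, 4)
  depth <- matrix(50L, 3, 4)
  gm <- make_gm(dos, depth = depth, ref = c("A", "AT", "G"),
                alt = c("T,G", "A", "C"))
  suppressMessages(out <- filter_variants(gm))
  expect_equal(out$pos, 300L)   # multiallelic and indel dropped
})

test_that("filter_variants is idempotent", {
  set.seed(5)
  dos <- matrix(sample(c(0:2, NA), 200, replace = TRUE), 20, 10)
  depth <- matrix(sample(c(5L, 50L, 300L), 200, replace = TRUE,
                         prob = c(.15, .7, .15)), 20, 10)
  gm <- make_gm(dos, depth = depth)
  suppressMessages(once <- filter_variants(gm))
  suppressMessages(twice <- filter_variants(once))
  expect_equal(twice$pos, once$pos)
  expect_equal(twice$dosage, once$dosage)
})

test_that("to_haplotypes expands phased calls and drops unusable sites", {
  # 2 samples, phased 0|1 and 1|1 at one site -> haplotype column (0,1,1,1)
  gm <- genotype_matrix(chrom = "chr1", pos = 50L, ref = "A", alt = "T",
                        dosage = matrix(c(1L, 2L), 1), phased = TRUE,
                        samples = c("s1", "s2"), pop = c("P1", "P1"),
                        phenotype = c("resistant", "resistant"),
                        a1 = matrix(c(0L, 1L), 1),
                        a2 = matrix(c(1L, 1L), 1))
  hm <- to_haplotypes(gm)
  expect_equal(as.vector(hm$H), c(0L, 1L, 1L, 1L))
  # a site with an unphased sample is dropped and reported
  gm2 <- make_gm(matrix(c(1L, 1L, 0L, 2L), 2, 2),
                 phased = matrix(c(TRUE, FALSE, TRUE, TRUE), 2, 2))
  expect_message(hm2 <- to_haplotypes(gm2), "dropped 1")
  expect_equal(ncol(hm2$H), 1L)
  expect_error(suppressMessages(to_haplotypes(
    make_gm(matrix(c(NA, NA), 1, 2)))), "no fully phased")
})

test_that("haplotype allele frequencies match dosage frequencies", {
  set.seed(11)
  for (rep in 1:5) {
    sim <- simulate_demes(sweep_sim_params(
      n_diploids = 30, seq_length = 1e4, n_sites = 60, burn_in_gens = 30,
      selection_gens = 10, sample_per_deme = 10, n_demes_resistant = 1,
      n_demes_susceptible = 1, seed = rep))
    f <- write_sim_vcf(sim$hm, withr::local_tempfile(fileext = ".vcf"))
    gm <- read_vcf(f["vcf"], f["sample_map"])
    hm <- to_haplotypes(gm)
    dos_freq <- rowMeans(gm$dosage) / 2
    hap_freq <- colMeans(hm$H)
    expect_equal(unname(hap_freq), unname(dos_freq), tolerance = 1e-12)
  }
})

test_that("homozygous-everywhere samples give duplicated haplotype rows", {
  gm <- make_gm(matrix(c(0L, 2L, 2L, 0L), 2, 2))
  hm <- to_haplotypes(gm)
  expect_equal(hm$H[1, ], hm$H[2, ])
  expect_equal(hm$H[3, ], hm$H[4, ])
})

test_that("track writing round-trips TSV exactly and emits 0-based BED", {
  stats <- data.frame(chrom = "chr5", start = 100001L, end = 125000L,
                      value = c(pi / 7), n_snps = 31L)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_track(stats, tsv, "TSV")
  back <- read_track(tsv)
  expect_identical(back$value, stats$value)   # bit-exact round trip
  expect_identical(back$start, stats$start)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_track(stats, bed, "BED")
  fields <- strsplit(readLines(bed), "\t")[[1]]
  expect_equal(fields[1:3], c("chr5", "100000", "125000"))
  expect_error(write_track(stats, tsv, "GFF"))
  expect_error(write_track(stats[0, ], tsv, "TSV"), "empty")
  stats$bad <- NA_real_
  expect_warning(write_track(stats, tsv, "TSV"), "bad")
})
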