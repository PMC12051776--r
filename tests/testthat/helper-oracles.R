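# Independent oracles used by the unit and acceptance tests.  These are
# deliberately naive (scalar loops, pairwise enumeration) transcriptions of
# the defining formulas, kept free of any code from the package internals.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Weir & Cockerham (1984) two-population, biallelic, one site.
# d1, d2: integer dosage vectors (0/1/2, NA missing) for the two samples.
wc_fst_oracle <- function(d1, d2) {
  d1 <- d1[!is.na(d1)]; d2 <- d2[!is.na(d2)]
  n1 <- length(d1); n2 <- length(d2)
  if (n1 < 2 || n2 < 2) return(list(a = NA, b = NA, c = NA, theta = NA))
  r <- 2
  p1 <- sum(d1) / (2 * n1); p2 <- sum(d2) / (2 * n2)
  h1 <- sum(d1 == 1) / n1;  h2 <- sum(d2 == 1) / n2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  theta <- if (pbar <= 0 || pbar >= 1 || denom <= 0) NA else a / denom
  list(a = a, b = b, c = cc, theta = theta)
}

# Garud H-statistics by explicit pair counting over haplotype rows.
garud_oracle <- function(M) {
  n <- nrow(M)
  keys <- apply(M, 1, paste, collapse = "")
  counts <- sapply(unique(keys), function(k) sum(keys == k))
  p <- sort(as.numeric(counts) / n, decreasing = TRUE)
  H1 <- 0
  for (q in p) H1 <- H1 + q * q
  p1 <- p[1]; p2 <- if (length(p) > 1) p[2] else 0
  H12 <- (p1 + p2)^2
  if (length(p) > 2) for (q in p[3:length(p)]) H12 <- H12 + q * q
  H2 <- H1 - p1^2
  list(H1 = H1, H12 = H12, H2 = H2, h2_h1 = H2 / H1, p1 = p1, p2 = p2)
}

# nucleotide diversity: mean pairwise per-site difference over all
# unordered haplotype pairs
pi_oracle <- function(M) {
  n <- nrow(M); S <- ncol(M)
  tot <- 0; pairs <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(M[i, ] != M[j, ]) / S
    pairs <- pairs + 1
  }
  tot / pairs
}

# haplotype heterozygosity: probability two haplotypes drawn without
# replacement are distinct strings
hapdiv_oracle <- function(M) {
  n <- nrow(M)
  same <- 0; pairs <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (all(M[i, ] == M[j, ])) same <- same + 1
    pairs <- pairs + 1
  }
  1 - same / pairs
}

prop_seg_oracle <- function(M) {
  n <- nrow(M)
  seg <- 0
  for (j in seq_len(ncol(M))) {
    cnt <- sum(M[, j])
    if (cnt > 0 && cnt < n) seg <- seg + 1
  }
  seg / ncol(M)
}

# EHH by explicit pairwise comparison of haplotype slices from the core
# to each flanking marker
ehh_oracle <- function(H, core_idx, marker_idx, carriers) {
  rng <- if (marker_idx >= core_idx) core_idx:marker_idx
  else marker_idx:core_idx
  n <- length(carriers)
  same <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (all(H[carriers[i], rng] == H[carriers[j], rng])) same <- same + 1
  }
  same / choose(n, 2)
}

# random two-population dosage table with missing data
random_dosage_pair <- function(max_n = 20, max_sites = 50) {
  n1 <- sample(2:max_n, 1); n2 <- sample(2:max_n, 1)
  S <- sample(1:max_sites, 1)
  p <- runif(S, 0.05, 0.95)
  mk <- function(n) {
    d <- matrix(rbinom(S * n, 2, rep(p, n)), nrow = S)
    d[matrix(runif(S * n) < 0.1, S, n)] <- NA
    d
  }
  list(d1 = mk(n1), d2 = mk(n2), S = S)
}

# minimal haplotype_matrix around a plain 0/1 matrix
hm_from_matrix <- function(M, pos = NULL, group = NULL) {
  n <- nrow(M)
  if (is.null(pos)) pos <- seq_len(ncol(M)) * 10L
  if (is.null(group)) group <- rep("g", n)
  haplotype_matrix(M, chrom = "chr1", pos = pos,
                   sample = rep(sprintf("s%02d", seq_len(ceiling(n / 2))),
                                each = 2)[seq_len(n)],
                   group = group)
}

# hand-written multi-sample VCF for IO tests
write_toy_vcf <- function(path, lines_extra = NULL) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="DP">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3", "s4"), collapse = "\t"),
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT:DP\t0|1:20\t1|1:30\t0|0:25\t./.:5",
    "chr1\t200\t.\tG\tC\t.\tPASS\t.\tGT:DP\t0/0:15\t0/1:22\t1/1:18\t0/0:40",
    "chr1\t300\t.\tT\tA\t.\tPASS\t.\tGT:DP\t1|0:33\t0|0:12\t0|1:28\t1|1:19",
    lines_extra)
  writeLines(lines, path)
  path
}

write_toy_sample_table <- function(path, ids = c("s1", "s2", "s3", "s4")) {
  write.table(
    data.frame(sample_id = ids,
               population = rep(c("P1", "P2"), length.out = length(ids)),
               phenotype = rep(c("resistant", "susceptible"),
                               length.out = length(ids))),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
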