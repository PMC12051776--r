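## Haplotype-based sweep statistics: site-specific extended haplotype
## homozygosity (EHH), Garud's H1/H12/H2 scan, and within-group diversity
## and allele-frequency summaries.

#' Extended haplotype homozygosity around a core SNP
#'
#' Among the haplotypes of `group` carrying `core_allele` at the core SNP,
#' EHH at a flanking marker x is the probability that two randomly drawn
#' carrier haplotypes are identical at every marker from the core out to x
#' (inclusive): \eqn{EHH(x) = \sum_h \binom{n_h}{2} / \binom{n_c}{2}},
#' where the sum runs over the distinct extended haplotypes.  The curve is
#' computed separately leftward and rightward, equals 1 at the core, and is
#' non-increasing with distance.
#'
#' @param hm a [haplotype_matrix()] (one chromosome).
#' @param core_pos physical position (bp) of the core SNP; must match a
#'   site in `hm`.
#' @param core_allele `1` (alternate) or `0` (reference).
#' @param group group label; `NULL` uses all haplotypes.
#' @param max_extent maximum distance (bp) to extend on each side
#'   (`Inf` = to the chromosome end).
#' @param min_ehh stop extending a side once EHH drops below this value
#'   (the first sub-threshold marker is retained); `0` disables
#'   truncation.
#' @return object of class `ehh_curve`: data.frame with columns `pos`,
#'   `ehh`, `side` (`"left"`, `"core"`, `"right"`), plus attributes
#'   `core_pos`, `core_allele`, `n_core_haplotypes`, `group`.
#' @export
ehh <- function(hm, core_pos, core_allele = 1L, group = NULL,
                max_extent = Inf, min_ehh = 0.05) {
  rows <- group_rows(hm, group)
  core_idx <- which(hm$pos == core_pos)
  if (length(core_idx) != 1L)
    stop("core position ", core_pos, " not found (or not unique)")
  if (length(unique(hm$chrom)) > 1L)
    stop("ehh() expects a single-chromosome haplotype matrix")
  carriers <- rows[hm$H[rows, core_idx] == core_allele]
  n_c <- length(carriers)
  if (n_c < 2L)
    stop("fewer than 2 haplotypes carry allele ", core_allele,
         " at the core SNP")
  pair_total <- choose(n_c, 2)

  walk <- function(indices) {
    ids <- rep(1L, n_c)          # extended-haplotype class of each carrier
    out_pos <- integer(0); out_ehh <- numeric(0)
    for (j in indices) {
      if (abs(hm$pos[j] - core_pos) > max_extent) break
      key <- paste(ids, hm$H[carriers, j])
      ids <- match(key, unique(key))
      sz <- tabulate(ids)
      e <- sum(choose(sz, 2)) / pair_total
      out_pos <- c(out_pos, hm$pos[j]); out_ehh <- c(out_ehh, e)
      if (min_ehh > 0 && e < min_ehh) break
    }
    list(pos = out_pos, ehh = out_ehh)
  }
  right <- walk(seq(core_idx + 1L, length.out = ncol(hm$H) - core_idx))
  left <- walk(rev(seq_len(core_idx - 1L)))

  res <- rbind(
    data.frame(pos = rev(left$pos), ehh = rev(left$ehh),
               side = rep("left", length(left$pos))),
    data.frame(pos = core_pos, ehh = 1, side = "core"),
    data.frame(pos = right$pos, ehh = right$ehh,
               side = rep("right", length(right$pos))))
  attr(res, "core_pos") <- core_pos
  attr(res, "core_allele") <- core_allele
  attr(res, "n_core_haplotypes") <- n_c
  attr(res, "group") <- group
  class(res) <- c("ehh_curve", "data.frame")
  res
}

#' Plot an EHH curve (optionally against a second group's curve)
#'
#' @param x an `ehh_curve`.
#' @param y optional second `ehh_curve` drawn in red for contrast.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ehh_curve <- function(x, y = NULL, ...) {
  graphics::plot(x$pos, x$ehh, type = "l", ylim = c(0, 1),
                 xlab = "position (bp)", ylab = "EHH", ...)
  graphics::abline(v = attr(x, "core_pos"), lty = 3)
  if (!is.null(y)) graphics::lines(y$pos, y$ehh, col = "red")
  invisible(x)
}

#' Garud H-statistics for one SNP window
#'
#' Distinct haplotype strings over the window are counted within `group`;
#' with sorted frequencies \eqn{p_1 \ge p_2 \ge \dots}:
#' \eqn{H1 = \sum p_i^2}, \eqn{H12 = (p_1+p_2)^2 + \sum_{i\ge3} p_i^2},
#' \eqn{H2 = H1 - p_1^2} and the soft-sweep diagnostic \eqn{H2/H1}.  A
#' window with a single distinct haplotype gives H1 = H12 = 1, H2 = 0.
#'
#' @param hm a [haplotype_matrix()].
#' @param snp_window integer vector of site indices (contiguous range).
#' @param group group label; `NULL` uses all haplotypes.
#' @return one-row data.frame: `bp_start`, `bp_end`, `snp_start`,
#'   `snp_end`, `n_haps`, `H1`, `H12`, `H2`, `h2_h1`.
#' @references Garud, N.R. et al. (2015) Recent selective sweeps in North
#'   American Drosophila melanogaster show signatures of soft sweeps.
#'   PLoS Genetics 11:e1005004.
#' @export
h_statistics <- function(hm, snp_window, group = NULL) {
  if (length(snp_window) == 0L) stop("empty SNP window")
  rows <- group_rows(hm, group)
  if (length(rows) < 2L) stop("need at least 2 haplotypes in the group")
  p <- hap_freqs(hm$H[rows, snp_window, drop = FALSE])
  h <- garud_from_freqs(p)
  data.frame(snp_start = min(snp_window), snp_end = max(snp_window),
             bp_start = hm$pos[min(snp_window)],
             bp_end = hm$pos[max(snp_window)],
             n_haps = length(rows), H1 = h$H1, H12 = h$H12, H2 = h$H2,
             h2_h1 = h$h2_h1)
}

## sorted (desc) haplotype frequencies of the rows of a 0/1 matrix;
## frequency ties broken lexicographically on the haplotype string
hap_freqs <- function(M) {
  keys <- apply(M, 1L, paste, collapse = "")
  tab <- table(keys)
  tab <- tab[order(-as.integer(tab), names(tab))]
  as.numeric(tab) / nrow(M)
}

garud_from_freqs <- function(p) {
  H1 <- sum(p^2)
  p1 <- p[1]
  p2 <- if (length(p) >= 2) p[2] else 0
  H12 <- (p1 + p2)^2 + if (length(p) >= 3) sum(p[-(1:2)]^2) else 0
  H2 <- H1 - p1^2
  list(H1 = H1, H12 = H12, H2 = H2, h2_h1 = H2 / H1)
}

#' Sliding H12 scan over SNP windows
#'
#' Slides a window of `window_snps` consecutive SNPs along the chromosome.
#' The default step is physical -- the scan advances to the next SNP at
#' least `step` bp to the right (a dense, overlapping scan in the style of
#' "100-SNP windows with a 50 bp step"); `step_unit = "snps"` instead
#' advances by a fixed SNP count.  Each window gets the Garud statistics;
#' the top-quantile windows by H12 are flagged in column `top` (their
#' H2/H1 is the hard-vs-soft diagnostic).
#'
#' @param hm a [haplotype_matrix()] (single chromosome).
#' @param group group label; `NULL` uses all haplotypes.
#' @param window_snps SNPs per window (>= 2).
#' @param step step size, in SNPs or bp according to `step_unit`.
#' @param step_unit `"snps"` or `"bp"`.
#' @param quantile_prob quantile defining the top H12 windows.
#' @return data.frame of class `h_scan` (one row per window, columns as in
#'   [h_statistics()] plus `top`).
#' @export
h_scan <- function(hm, group = NULL, window_snps = 100, step = 50,
                   step_unit = c("bp", "snps"), quantile_prob = 0.99) {
  step_unit <- match.arg(step_unit)
  if (window_snps < 2) stop("window_snps must be >= 2")
  S <- ncol(hm$H)
  if (S < window_snps)
    stop("only ", S, " SNPs available; need at least ", window_snps)
  if (length(unique(hm$chrom)) > 1L)
    stop("h_scan() expects a single-chromosome haplotype matrix")
  if (step_unit == "snps") {
    starts <- seq(1L, S - window_snps + 1L, by = as.integer(step))
  } else {
    starts <- integer(0); cur <- 1L
    while (cur <= S - window_snps + 1L) {
      starts <- c(starts, cur)
      nxt <- which(hm$pos > hm$pos[cur] + step)
      if (length(nxt) == 0L) break
      cur <- nxt[1]
    }
  }
  rows <- group_rows(hm, group)
  res <- do.call(rbind, lapply(starts, function(s)
    h_statistics(hm, s:(s + window_snps - 1L), group = group)))
  thr <- stats::quantile(res$H12, probs = quantile_prob, names = FALSE,
                         type = 7)
  res$top <- res$H12 >= thr
  attr(res, "h12_threshold") <- thr
  attr(res, "group") <- group
  class(res) <- c("h_scan", "data.frame")
  res
}

#' Within-group diversity and allele-frequency summary for a region
#'
#' Summarises the haplotypes of one group over a genomic region:
#' * `pi` -- nucleotide diversity per site: the mean over region sites of
#'   the unbiased per-site heterozygosity \eqn{2p(1-p)\,n/(n-1)};
#' * `hap_diversity` -- whole-region haplotype heterozygosity
#'   \eqn{(1 - \sum q_k^2)\,n/(n-1)} over distinct region haplotypes;
#' * `prop_segregating` -- fraction of region sites polymorphic within the
#'   group;
#' * `mean_alt_freq` -- mean alternate-allele frequency across sites;
#' * `n_alt_major` -- number of sites with alternate-allele frequency
#'   above 0.5.
#'
#' @param hm a [haplotype_matrix()].
#' @param region `list(chrom =, start =, end =)` (1-based inclusive), or
#'   `NULL` for all sites.
#' @param group group label; `NULL` uses all haplotypes.
#' @return one-row data.frame of class `group_site_summary`.
#' @export
group_site_summary <- function(hm, region = NULL, group = NULL) {
  rows <- group_rows(hm, group)
  n <- length(rows)
  if (n < 2L) stop("need at least 2 haplotypes in the group")
  sites <- region_sites(hm, region)
  M <- hm$H[rows, sites, drop = FALSE]
  p <- colMeans(M)
  alt_count <- colSums(M)
  pi <- mean(2 * p * (1 - p) * n / (n - 1))
  q <- hap_freqs(M)
  hap_div <- (1 - sum(q^2)) * n / (n - 1)
  seg <- alt_count > 0L & alt_count < n
  out <- data.frame(
    chrom = if (is.null(region)) hm$chrom[sites[1]] else region$chrom,
    start = hm$pos[sites[1]], end = hm$pos[sites[length(sites)]],
    group = if (is.null(group)) "all" else group,
    n_haps = n, n_sites = length(sites),
    pi = pi, hap_diversity = hap_div,
    prop_segregating = mean(seg),
    mean_alt_freq = mean(p),
    n_alt_major = sum(p > 0.5),
    stringsAsFactors = FALSE)
  class(out) <- c("group_site_summary", "data.frame")
  out
}
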