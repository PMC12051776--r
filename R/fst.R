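## Weir-Cockerham (1984) F_ST: per-site variance components, windowed
## ratio-of-averages aggregation, top-quantile outlier flagging, and the
## multi-pair parallel-divergence tally.

#' Per-site Weir--Cockerham F_ST between two groups
#'
#' Computes the Weir--Cockerham (1984) moment estimator for a biallelic
#' locus at every site: among-population (`a`), among-individual-within-
#' population (`b`) and within-individual (`c`) variance components, and
#' \eqn{\theta = a/(a+b+c)}.  Missing genotypes are excluded site-wise, so
#' sample sizes vary by site.  \eqn{\theta} is `NA` when either group has
#' fewer than two called genotypes at the site, when the pooled sample is
#' monomorphic, or when \eqn{a+b+c \le 0}.
#'
#' @param gm a [genotype_matrix()].
#' @param group_a,group_b disjoint character vectors of sample ids, or a
#'   single population/phenotype label present in `gm`.
#' @return data.frame of class `fst_sites` with columns `chrom`, `pos`,
#'   `n_a`, `n_b` (called genotypes per group), `a`, `b`, `c`, `theta`.
#' @references Weir, B.S. & Cockerham, C.C. (1984) Estimating F-statistics
#'   for the analysis of population structure. Evolution 38:1358-1370.
#' @export
fst_site <- function(gm, group_a, group_b) {
  ga <- resolve_group(gm, group_a)
  gb <- resolve_group(gm, group_b)
  if (length(intersect(ga, gb)) > 0) stop("groups overlap")
  if (length(ga) < 2 || length(gb) < 2)
    stop("each group needs at least 2 samples")
  da <- gm$dosage[, ga, drop = FALSE]
  db <- gm$dosage[, gb, drop = FALSE]
  comp <- wc_components(da, db)
  out <- data.frame(chrom = gm$chrom, pos = gm$pos,
                    n_a = comp$n1, n_b = comp$n2,
                    a = comp$a, b = comp$b, c = comp$c,
                    theta = comp$theta, stringsAsFactors = FALSE)
  class(out) <- c("fst_sites", "data.frame")
  out
}

## map a label ("resistant", a population name) or explicit sample ids to
## sample ids
resolve_group <- function(gm, g) {
  if (length(g) == 1L && !(g %in% gm$samples)) {
    hit <- gm$samples[gm$pop == g | gm$phenotype == g]
    if (length(hit) == 0L) stop("no samples match group '", g, "'")
    return(hit)
  }
  miss <- setdiff(g, gm$samples)
  if (length(miss) > 0) stop("unknown samples: ", paste(miss, collapse = ", "))
  g
}

## vectorised two-population Weir-Cockerham components over site x sample
## dosage matrices (rows = sites)
wc_components <- function(d1, d2) {
  n1 <- rowSums(!is.na(d1))
  n2 <- rowSums(!is.na(d2))
  p1 <- rowSums(d1, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(d2, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(d1 == 1L, na.rm = TRUE) / n1
  h2 <- rowSums(d2 == 1L, na.rm = TRUE) / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  usable <- n1 >= 2 & n2 >= 2
  mono <- pbar <= 0 | pbar >= 1
  theta <- ifelse(usable & !mono & denom > 0, a / denom, NA_real_)
  a[!usable] <- NA_real_; b[!usable] <- NA_real_; cc[!usable] <- NA_real_
  list(n1 = n1, n2 = n2, a = a, b = b, c = cc, theta = theta)
}

#' Windowed ratio-of-averages F_ST
#'
#' Aggregates per-site Weir--Cockerham components over non-overlapping
#' tiling windows as \eqn{\sum a / \sum (a+b+c)} (ratio of averages).
#' Sites with undefined \eqn{\theta} do not contribute; windows with fewer
#' than `min_snps` usable sites get `value = NA`.
#'
#' @param site_results an `fst_sites` data.frame from [fst_site()].
#' @param window_size window width in bp.
#' @param min_snps minimum usable SNPs for a window value to be defined.
#' @return data.frame of class `fst_windows` with `chrom`, `start`, `end`
#'   (1-based inclusive), `n_snps`, `value`.
#' @export
fst_windowed <- function(site_results, window_size = 25000, min_snps = 25) {
  if (window_size <= 0) stop("window_size must be positive")
  sr <- site_results[!is.na(site_results$theta), , drop = FALSE]
  win <- make_tiling(site_results$chrom, site_results$pos, window_size)
  key <- paste(sr$chrom, (sr$pos - 1L) %/% as.integer(window_size))
  wkey <- paste(win$chrom, (win$start - 1L) %/% as.integer(window_size))
  sums_a <- tapply(sr$a, key, sum)
  sums_d <- tapply(sr$a + sr$b + sr$c, key, sum)
  cnt <- tapply(sr$a, key, length)
  idx <- match(wkey, names(cnt))
  win$n_snps <- ifelse(is.na(idx), 0L, as.integer(cnt[idx]))
  val <- as.numeric(sums_a[idx]) / as.numeric(sums_d[idx])
  val[win$n_snps < min_snps] <- NA_real_
  win$value <- val
  class(win) <- c("fst_windows", "data.frame")
  win
}

## tiling window skeleton covering [1, max(pos)] per chromosome
make_tiling <- function(chrom, pos, window_size) {
  window_size <- as.integer(window_size)
  out <- lapply(unique(chrom), function(chr) {
    pmax_ <- max(pos[chrom == chr])
    n_win <- (pmax_ - 1L) %/% window_size + 1L
    data.frame(chrom = chr,
               start = (seq_len(n_win) - 1L) * window_size + 1L,
               end = seq_len(n_win) * window_size,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Flag windows in the top quantile of a statistic
#'
#' The threshold is the linear-interpolation empirical quantile (R type 7)
#' of the defined window values; every window whose value is greater than
#' or equal to the threshold is flagged, so ties at the threshold are all
#' included.
#'
#' @param windows `fst_windows` (or any data.frame with a `value` column).
#' @param quantile_prob quantile defining "top" (0.99 = top 1%).
#' @return `windows` with a logical `top` column; the threshold is
#'   attached as attribute `"threshold"`.
#' @export
top_quantile_flags <- function(windows, quantile_prob = 0.99) {
  vals <- windows$value
  if (all(is.na(vals))) stop("no window has a defined value")
  thr <- stats::quantile(vals, probs = quantile_prob, na.rm = TRUE,
                         names = FALSE, type = 7)
  windows$top <- !is.na(vals) & vals >= thr
  attr(windows, "threshold") <- thr
  windows
}

#' Parallel-divergence tally across resistant/susceptible population pairs
#'
#' For every (resistant population, susceptible population) pair, computes
#' windowed Weir--Cockerham F_ST and flags the top-quantile windows; each
#' window's `flag_count` is the number of pairwise comparisons in which it
#' was flagged.  Windows flagged in every comparison ("consensus" windows,
#' `flag_count == |R| x |S|`) are the candidate targets of parallel
#' selection.
#'
#' @param gm a [genotype_matrix()].
#' @param resistant_pops,susceptible_pops population labels in `gm$pop`.
#' @inheritParams fst_windowed
#' @inheritParams top_quantile_flags
#' @return data.frame of class `parallel_divergence` with window
#'   coordinates, `flag_count`, `n_comparisons` and `consensus`.
#' @export
parallel_divergence_counts <- function(gm, resistant_pops, susceptible_pops,
                                       window_size = 25000, min_snps = 25,
                                       quantile_prob = 0.99) {
  if (length(resistant_pops) < 1 || length(susceptible_pops) < 1)
    stop("need at least one population on each side")
  for (p in c(resistant_pops, susceptible_pops))
    if (sum(gm$pop == p) < 2)
      stop("population '", p, "' has fewer than 2 samples")
  pairs <- expand.grid(r = resistant_pops, s = susceptible_pops,
                       stringsAsFactors = FALSE)
  base <- NULL
  flag_count <- NULL
  for (k in seq_len(nrow(pairs))) {
    sr <- fst_site(gm, gm$samples[gm$pop == pairs$r[k]],
                   gm$samples[gm$pop == pairs$s[k]])
    win <- fst_windowed(sr, window_size = window_size, min_snps = min_snps)
    win <- top_quantile_flags(win, quantile_prob = quantile_prob)
    if (is.null(base)) {
      base <- win[, c("chrom", "start", "end")]
      flag_count <- integer(nrow(win))
    }
    flag_count <- flag_count + as.integer(win$top)
  }
  base$flag_count <- flag_count
  base$n_comparisons <- nrow(pairs)
  base$consensus <- flag_count == nrow(pairs)
  class(base) <- c("parallel_divergence", "data.frame")
  base
}

#' @export
print.fst_sites <- function(x, ...) {
  cat("Weir-Cockerham per-site F_ST:", nrow(x), "sites,",
      sum(!is.na(x$theta)), "with defined theta\n")
  if (any(!is.na(x$theta)))
    cat(sprintf("  theta: mean %.4f, max %.4f\n",
                mean(x$theta, na.rm = TRUE), max(x$theta, na.rm = TRUE)))
  print(utils::head(as.data.frame(x)))
  invisible(x)
}

#' Plot windowed F_ST along the genome
#'
#' @param x an `fst_windows` data.frame.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fst_windows <- function(x, ...) {
  mid <- (x$start + x$end) / 2
  graphics::plot(mid, x$value, type = "h", xlab = "position (bp)",
                 ylab = expression(F[ST]), ...)
  if (!is.null(x$top)) graphics::points(mid[x$top], x$value[x$top],
                                        col = "red", pch = 19)
  invisible(x)
}
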