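## QTL-seq bulked-segregant mapping: per-bulk SNP-index, delta SNP-index,
## sliding-window smoothing, simulated null confidence envelope, and QTL
## interval calling.

#' Construct a two-bulk allele-count table
#'
#' @param chrom,pos site keys.
#' @param ref_r,alt_r reference / alternate read counts in the resistant
#'   bulk.
#' @param ref_s,alt_s the same for the susceptible bulk.
#' @return data.frame of class `bulk_counts`.
#' @export
bulk_counts <- function(chrom, pos, ref_r, alt_r, ref_s, alt_s) {
  stopifnot(all(c(ref_r, alt_r, ref_s, alt_s) >= 0))
  out <- data.frame(chrom = chrom, pos = as.integer(pos),
                    ref_r = as.integer(ref_r), alt_r = as.integer(alt_r),
                    ref_s = as.integer(ref_s), alt_s = as.integer(alt_s),
                    stringsAsFactors = FALSE)
  out <- out[order(factor(out$chrom, levels = unique(out$chrom)), out$pos), ]
  rownames(out) <- NULL
  class(out) <- c("bulk_counts", "data.frame")
  out
}

#' Read a two-bulk allele-count TSV
#'
#' Expects columns `chrom`, `pos`, `ref_r`, `alt_r`, `ref_s`, `alt_s`.
#' @param path TSV path.
#' @return a [bulk_counts()] table.
#' @export
read_bulk_counts <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  bulk_counts(d$chrom, d$pos, d$ref_r, d$alt_r, d$ref_s, d$alt_s)
}

#' Per-site SNP-index and delta SNP-index
#'
#' SNP-index per bulk is the alternate-read fraction
#' `alt / (ref + alt)`; delta is `index_r - index_s` (resistant minus
#' susceptible).  Sites where either bulk's depth is below `min_depth` are
#' masked (`NA`), not errors.  "Alternate" is taken as written in the
#' counts table; orient counts to the resistant-parent allele upstream if
#' parental genotypes are available.
#'
#' @param counts a [bulk_counts()] table.
#' @param min_depth minimum per-bulk depth for a site to be scored.
#' @return data.frame of class `snp_index` with `depth_r`, `depth_s`,
#'   `index_r`, `index_s`, `delta` appended.
#' @export
snp_index <- function(counts, min_depth = 10) {
  depth_r <- counts$ref_r + counts$alt_r
  depth_s <- counts$ref_s + counts$alt_s
  ok <- depth_r >= min_depth & depth_s >= min_depth
  index_r <- ifelse(ok, counts$alt_r / depth_r, NA_real_)
  index_s <- ifelse(ok, counts$alt_s / depth_s, NA_real_)
  out <- counts
  out$depth_r <- depth_r; out$depth_s <- depth_s
  out$index_r <- index_r; out$index_s <- index_s
  out$delta <- index_r - index_s
  class(out) <- c("snp_index", "data.frame")
  out
}

#' Simulated null confidence envelope for the delta SNP-index
#'
#' Monte-Carlo null distribution of delta at a given depth pair, following
#' the QTL-seq approach: per replicate and per bulk, `n_bulk` F2 genotypes
#' are drawn under Mendelian 1:2:1 segregation unlinked to the trait, the
#' bulk allele frequency is the mean dosage / 2, alternate reads are
#' Binomial(depth, frequency), and delta is the difference of the two
#' simulated indices.  The envelope is the pair of empirical
#' `(1-level)/2` and `1-(1-level)/2` quantiles.
#'
#' @param depth_r,depth_s read depths of the two bulks at the site.
#' @param n_bulk_r,n_bulk_s numbers of F2 individuals in each bulk.
#' @param replicates Monte-Carlo replicates (>= 100).
#' @param level envelope coverage (0.95 = 95%).
#' @param seed optional integer seed (local to this call).
#' @return named numeric vector `c(ci_low, ci_high)`.
#' @references Takagi, H. et al. (2013) QTL-seq: rapid mapping of
#'   quantitative trait loci in rice by whole genome resequencing of DNA
#'   from two bulked populations. Plant Journal 74:174-183.
#' @export
null_envelope <- function(depth_r, depth_s, n_bulk_r, n_bulk_s,
                          replicates = 10000, level = 0.95, seed = NULL) {
  if (replicates < 100)
    stop("replicates must be >= 100 for stable quantiles")
  if (depth_r < 1 || depth_s < 1) stop("depths must be >= 1")
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(set_rng_state(old)); set.seed(seed)
  }
  d <- null_delta_draws(depth_r, depth_s, n_bulk_r, n_bulk_s, replicates)
  alpha <- (1 - level) / 2
  q <- stats::quantile(d, probs = c(alpha, 1 - alpha), names = FALSE,
                       type = 7)
  c(ci_low = q[1], ci_high = q[2])
}

## vectorised null draws of delta; F2 dosage ~ Binomial(2, 1/2), so the sum
## over a bulk of n individuals is Binomial(2n, 1/2)
null_delta_draws <- function(depth_r, depth_s, n_bulk_r, n_bulk_s, n) {
  fr <- stats::rbinom(n, 2L * n_bulk_r, 0.5) / (2 * n_bulk_r)
  fs <- stats::rbinom(n, 2L * n_bulk_s, 0.5) / (2 * n_bulk_s)
  stats::rbinom(n, depth_r, fr) / depth_r -
    stats::rbinom(n, depth_s, fs) / depth_s
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
set_rng_state <- function(state) {
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
}

#' Attach per-site null envelopes to a SNP-index table
#'
#' Tabulates the null envelope once per distinct (depth_r, depth_s) pair
#' (rounded to `depth_bin`-wide bins to keep the table small at high site
#' counts) and assigns each scored site its envelope and a `significant`
#' flag (`delta > ci_high`).  An alternative `mode = "bootstrap"`
#' resamples observed deltas across sites instead of simulating the
#' Mendelian null.
#'
#' @param si a [snp_index()] table.
#' @param n_bulk_r,n_bulk_s bulk sizes.
#' @param replicates,level,seed as in [null_envelope()].
#' @param depth_bin width of the depth bins used for tabulation (1 =
#'   exact per-pair envelopes).
#' @param mode `"simulation"` (Mendelian null; default) or `"bootstrap"`
#'   (site-resampling of observed deltas, one genome-wide envelope).
#' @return `si` with `ci_low`, `ci_high`, `significant` columns.
#' @export
site_envelopes <- function(si, n_bulk_r, n_bulk_s, replicates = 10000,
                           level = 0.95, seed = NULL, depth_bin = 1,
                           mode = c("simulation", "bootstrap")) {
  mode <- match.arg(mode)
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(set_rng_state(old)); set.seed(seed)
  }
  alpha <- (1 - level) / 2
  si$ci_low <- NA_real_; si$ci_high <- NA_real_
  scored <- which(!is.na(si$delta))
  if (mode == "bootstrap") {
    # genome-wide envelope: resample observed deltas (centred, so that a
    # genome-wide signal does not inflate the null) with replacement
    centred <- si$delta[scored] - stats::median(si$delta[scored])
    draws <- sample(centred, replicates, replace = TRUE)
    q <- stats::quantile(draws, probs = c(alpha, 1 - alpha), names = FALSE,
                         type = 7)
    si$ci_low[scored] <- q[1]; si$ci_high[scored] <- q[2]
  } else {
    br <- pmax(1L, as.integer(round(si$depth_r / depth_bin)) *
                 as.integer(depth_bin))
    bs_ <- pmax(1L, as.integer(round(si$depth_s / depth_bin)) *
                  as.integer(depth_bin))
    key <- paste(br, bs_)
    for (k in unique(key[scored])) {
      idx <- scored[key[scored] == k]
      dpair <- c(br[idx[1]], bs_[idx[1]])
      env <- stats::quantile(
        null_delta_draws(dpair[1], dpair[2], n_bulk_r, n_bulk_s,
                         replicates),
        probs = c(alpha, 1 - alpha), names = FALSE, type = 7)
      si$ci_low[idx] <- env[1]; si$ci_high[idx] <- env[2]
    }
  }
  si$significant <- !is.na(si$delta) & si$delta > si$ci_high
  si
}

#' Sliding-window smoothing of the delta SNP-index
#'
#' Mean delta over sites in sliding windows (`window_size` wide, advanced
#' by `step`); windows with fewer than `min_sites` scored sites are
#' undefined.  When the input carries per-site envelopes, the window
#' envelope is the mean of the site envelopes over the same sites.
#'
#' @param si a [snp_index()] table (optionally with envelopes from
#'   [site_envelopes()]).
#' @param window_size window width (bp).
#' @param step step between window starts (bp); `step = window_size`
#'   gives a non-overlapping tiling.
#' @param min_sites minimum scored sites per window.
#' @return data.frame of class `delta_track`: `chrom`, `start`, `end`,
#'   `n_sites`, `window_delta` (+ `ci_low`, `ci_high`, `significant` when
#'   available).
#' @export
window_delta <- function(si, window_size = 1e6, step = 1e5,
                         min_sites = 10) {
  window_size <- as.integer(window_size); step <- as.integer(step)
  out <- lapply(unique(si$chrom), function(chr) {
    d <- si[si$chrom == chr, , drop = FALSE]
    span <- max(d$pos)
    starts <- seq(1L, max(1L, span), by = step)
    starts <- starts[starts <= span]
    rows <- lapply(starts, function(s0) {
      in_win <- d$pos >= s0 & d$pos < s0 + window_size & !is.na(d$delta)
      n <- sum(in_win)
      row <- data.frame(chrom = chr, start = s0,
                        end = s0 + window_size - 1L, n_sites = n,
                        window_delta = if (n >= min_sites)
                          mean(d$delta[in_win]) else NA_real_)
      if ("ci_high" %in% names(d)) {
        row$ci_low <- if (n >= min_sites)
          mean(d$ci_low[in_win], na.rm = TRUE) else NA_real_
        row$ci_high <- if (n >= min_sites)
          mean(d$ci_high[in_win], na.rm = TRUE) else NA_real_
      }
      row
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  if ("ci_high" %in% names(out))
    out$significant <- !is.na(out$window_delta) &
      out$window_delta > out$ci_high
  class(out) <- c("delta_track", "data.frame")
  out
}

#' Call QTL intervals from a smoothed delta track
#'
#' Maximal runs of consecutive windows whose smoothed delta exceeds the
#' upper envelope bound are merged into intervals.
#'
#' @param track a `delta_track` with `significant` column (from
#'   [window_delta()] on an envelope-annotated table).
#' @return data.frame of class `qtl_intervals`: `chrom`, `start`, `end`,
#'   `n_windows`, `peak_delta`, `peak_pos`.
#' @export
call_qtl <- function(track) {
  if (!"significant" %in% names(track))
    stop("track has no envelope; run site_envelopes() before window_delta()")
  res <- list()
  for (chr in unique(track$chrom)) {
    d <- track[track$chrom == chr, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    sig <- which(!is.na(d$significant) & d$significant)
    if (length(sig) == 0L) next
    # significant windows overlap (sliding scan); merge any whose spans
    # overlap into maximal intervals
    cur_start <- d$start[sig[1]]; cur_end <- d$end[sig[1]]
    members <- sig[1]
    flush <- function(run, s, e) {
      peak <- run[which.max(d$window_delta[run])]
      res[[length(res) + 1L]] <<- data.frame(
        chrom = chr, start = s, end = e, n_windows = length(run),
        peak_delta = d$window_delta[peak],
        peak_pos = (d$start[peak] + d$end[peak]) %/% 2L)
    }
    for (k in sig[-1]) {
      if (d$start[k] <= cur_end + 1L) {
        cur_end <- max(cur_end, d$end[k]); members <- c(members, k)
      } else {
        flush(members, cur_start, cur_end)
        cur_start <- d$start[k]; cur_end <- d$end[k]; members <- k
      }
    }
    flush(members, cur_start, cur_end)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               n_windows = integer(0), peak_delta = numeric(0),
               peak_pos = integer(0))
  class(out) <- c("qtl_intervals", "data.frame")
  out
}

#' Plot a smoothed delta SNP-index track with its envelope
#'
#' @param x a `delta_track`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.delta_track <- function(x, ...) {
  mid <- (x$start + x$end) / 2
  graphics::plot(mid, x$window_delta, type = "l", ylim = c(-1, 1),
                 xlab = "position (bp)",
                 ylab = expression(Delta * "SNP-index"), ...)
  if ("ci_high" %in% names(x)) {
    graphics::lines(mid, x$ci_high, col = "red", lty = 2)
    graphics::lines(mid, x$ci_low, col = "red", lty = 2)
  }
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}
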