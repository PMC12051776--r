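## Orchestration: a single entry point that runs simulate -> filter ->
## scan stages from a config (R list or YAML), writes every track to an
## output directory with a reproducibility manifest, and joins the
## evidence lines into a per-window convergence report.

#' Default pipeline configuration
#'
#' @return a nested list of stage parameters; override any entry via the
#'   `config` argument of [run_pipeline()].
#' @export
pipeline_defaults <- function() {
  list(
    seed = 1L,
    stages = c("simulate", "filter", "fst_scan", "window_fst",
               "parallel_div", "ehh", "hscan", "qtlseq", "report"),
    input = list(vcf = NULL, sample_map = NULL, bulk_counts = NULL),
    simulate = list(),           # overrides for sweep_sim_params()
    simulate_bsa = list(),       # overrides for bsa_sim_params()
    filter = list(min_depth = 10, max_depth = 250,
                  min_fraction_called = 0.75, biallelic_snps_only = TRUE),
    fst = list(window_size = 25000, min_snps = 25, quantile_prob = 0.99),
    hscan = list(window_snps = 100, step = 50, step_unit = "bp",
                 quantile_prob = 0.99),
    ehh = list(max_extent = Inf, min_ehh = 0.05),
    qtlseq = list(n_bulk_r = 48, n_bulk_s = 47, replicates = 10000,
                  level = 0.95, min_depth = 10, window_size = 1e6,
                  step = 1e5, min_sites = 10)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run the full sweep-scan / QTL-seq pipeline
#'
#' Executes the requested stages in dependency order.  With the
#' `"simulate"` stage enabled, deme haplotypes are simulated, written as a
#' phased VCF + sample map, and read back through the standard input path
#' (so the IO layer is exercised end-to-end); otherwise `input$vcf` and
#' `input$sample_map` are read.  Stage outputs are written as TSV/BED
#' tracks under `out_dir`, along with `manifest.json` recording
#' parameters, seeds and input checksums.  The `"report"` stage tallies,
#' for each genomic window, which evidence lines co-occur: a top-quantile
#' per-SNP F_ST site, a full parallel-divergence flag count, a top-1% H12
#' window in the resistant group, a resistant-over-susceptible EHH
#' contrast at the top-F_ST SNP, and overlap with a called QTL interval.
#'
#' @param config nested list (see [pipeline_defaults()]) or path to an
#'   equivalent YAML file.
#' @param out_dir output directory (created if needed).
#' @return object of class `sweepscan_run`: list with the computed tables
#'   (`gm`, `hm`, `fst_sites`, `fst_windows`, `parallel`, `ehh`, `hscan`,
#'   `qtl`, `report`, `truth`) and `paths` of the written files.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(pipeline_defaults(), config)
  stages <- cfg$stages
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  res <- list(config = cfg)
  note <- function(...) message("[sweepscan] ", ...)

  need_variants <- any(c("filter", "fst_scan", "window_fst", "parallel_div",
                         "ehh", "hscan", "report") %in% stages)
  if (need_variants && !("simulate" %in% stages) &&
      (is.null(cfg$input$vcf) || is.null(cfg$input$sample_map)))
    stop("variant stages requested but no simulate stage and no input VCF",
         "/sample map configured")
  if ("qtlseq" %in% stages && !("simulate" %in% stages) &&
      is.null(cfg$input$bulk_counts))
    stop("qtlseq stage requested but no bulk counts configured and no ",
         "simulate stage")

  vcf_path <- cfg$input$vcf; map_path <- cfg$input$sample_map
  bulk_path <- cfg$input$bulk_counts
  truth <- NULL

  if ("simulate" %in% stages) {
    sp <- do.call(sweep_sim_params,
                  merge_config(list(seed = cfg$seed), cfg$simulate))
    sim <- simulate_demes(sp)
    truth <- sim$truth
    vcf_path <- file.path(out_dir, "simulated.vcf")
    files <- write_sim_vcf(sim$hm, vcf_path)
    map_path <- files["sample_map"]
    utils::write.table(
      data.frame(deme = names(truth$final_freq),
                 final_sweep_freq = truth$final_freq,
                 sweep_pos = truth$sweep_pos),
      file.path(out_dir, "truth.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    paths <- c(paths, vcf = vcf_path, sample_map = unname(map_path),
               truth = file.path(out_dir, "truth.tsv"))
    note("simulate: ", ncol(sim$hm$H), " segregating sites, sweep at ",
         truth$sweep_pos, " bp")
    if ("qtlseq" %in% stages && is.null(bulk_path)) {
      bp <- do.call(bsa_sim_params,
                    merge_config(list(seed = cfg$seed + 1L),
                                 cfg$simulate_bsa))
      bsim <- simulate_f2_bulks(bp)
      bulk_path <- file.path(out_dir, "bulk_counts.tsv")
      write_track(bsim$counts, bulk_path, "TSV")
      truth$bsa <- bsim$truth
      paths <- c(paths, bulk_counts = bulk_path)
      note("simulate: F2 bulks at causal ", paste(bp$causal_pos,
                                                  collapse = ","), " bp")
    }
  }

  gm <- hm <- NULL
  if (need_variants) {
    gm <- read_vcf(vcf_path, map_path)
    note("read: ", length(gm$pos), " sites x ", length(gm$samples),
         " samples")
    if ("filter" %in% stages) {
      f <- cfg$filter
      if (is.null(gm$depth)) {
        note("filter: no depth fields; depth rule skipped")
        f$min_depth <- NULL; f$max_depth <- NULL
      }
      gm <- filter_variants(gm, min_depth = f$min_depth,
                            max_depth = f$max_depth,
                            min_fraction_called = f$min_fraction_called,
                            biallelic_snps_only = f$biallelic_snps_only)
    }
    hm <- to_haplotypes(gm)
    res$gm <- gm; res$hm <- hm
  }

  fst_sites <- fst_windows <- parallel <- ehh_res <- hs <- NULL
  if ("fst_scan" %in% stages) {
    fst_sites <- fst_site(gm, "resistant", "susceptible")
    fst_sites <- top_quantile_flags(
      transform(fst_sites, value = theta), cfg$fst$quantile_prob)
    p <- file.path(out_dir, "fst_sites.tsv")
    write_track(fst_sites, p, "TSV"); paths <- c(paths, fst_sites = p)
    note("fst_scan: ", sum(!is.na(fst_sites$theta)), " sites scored")
  }
  if ("window_fst" %in% stages || "parallel_div" %in% stages) {
    pops_r <- unique(gm$pop[gm$phenotype == "resistant"])
    pops_s <- unique(gm$pop[gm$phenotype == "susceptible"])
    if ("window_fst" %in% stages) {
      sr <- fst_site(gm, "resistant", "susceptible")
      fst_windows <- top_quantile_flags(
        fst_windowed(sr, cfg$fst$window_size, cfg$fst$min_snps),
        cfg$fst$quantile_prob)
      p <- file.path(out_dir, "fst_windows.tsv")
      write_track(fst_windows, p, "TSV"); paths <- c(paths, fst_windows = p)
    }
    if ("parallel_div" %in% stages) {
      parallel <- parallel_divergence_counts(
        gm, pops_r, pops_s, cfg$fst$window_size, cfg$fst$min_snps,
        cfg$fst$quantile_prob)
      p <- file.path(out_dir, "parallel_divergence.tsv")
      write_track(parallel, p, "TSV"); paths <- c(paths, parallel = p)
      note("parallel_div: max flag_count ", max(parallel$flag_count),
           " of ", parallel$n_comparisons[1])
    }
  }
  focal_pos <- NULL
  if (!is.null(fst_sites) && any(!is.na(fst_sites$theta)))
    focal_pos <- fst_sites$pos[which.max(fst_sites$theta)]
  if ("ehh" %in% stages && !is.null(focal_pos)) {
    hm_ph <- hm; hm_ph$group <- rep(gm$phenotype, each = 2L)
    ehh_res <- lapply(c(resistant = "resistant",
                        susceptible = "susceptible"), function(g) {
      # use the allele this group actually carries (>= 2 copies) at the
      # focal SNP; the contrast is haplotype length around each group's
      # own core allele
      col <- match(focal_pos, hm_ph$pos)
      alleles <- hm_ph$H[hm_ph$group == g, col]
      core_allele <- if (sum(alleles == 1L) >= 2L) 1L else 0L
      tryCatch(ehh(hm_ph, focal_pos, core_allele = core_allele, group = g,
                   max_extent = cfg$ehh$max_extent,
                   min_ehh = cfg$ehh$min_ehh),
               error = function(e) NULL)
    })
    keep <- !vapply(ehh_res, is.null, logical(1))
    if (any(keep)) {
      tab <- do.call(rbind, lapply(names(ehh_res)[keep], function(g)
        data.frame(group = g, chrom = hm$chrom[1],
                   pos = ehh_res[[g]]$pos, ehh = ehh_res[[g]]$ehh)))
      p <- file.path(out_dir, "ehh.tsv")
      write_track(tab, p, "TSV"); paths <- c(paths, ehh = p)
    }
  }
  if ("hscan" %in% stages) {
    hm_ph <- hm; hm_ph$group <- rep(gm$phenotype, each = 2L)
    hs <- tryCatch(
      h_scan(hm_ph, group = "resistant",
             window_snps = cfg$hscan$window_snps, step = cfg$hscan$step,
             step_unit = cfg$hscan$step_unit,
             quantile_prob = cfg$hscan$quantile_prob),
      error = function(e) { note("hscan skipped: ", conditionMessage(e)); NULL })
    if (!is.null(hs)) {
      hs$chrom <- hm$chrom[1]
      p <- file.path(out_dir, "h12_scan.tsv")
      write_track(transform(hs, start = bp_start, end = bp_end), p, "TSV")
      paths <- c(paths, hscan = p)
      note("hscan: ", nrow(hs), " windows, top H12 = ",
           sprintf("%.3f", max(hs$H12)))
    }
  }

  qtl <- qtl_track <- NULL
  if ("qtlseq" %in% stages) {
    counts <- read_bulk_counts(bulk_path)
    q <- cfg$qtlseq
    si <- snp_index(counts, min_depth = q$min_depth)
    si <- site_envelopes(si, q$n_bulk_r, q$n_bulk_s,
                         replicates = q$replicates, level = q$level,
                         seed = cfg$seed + 2L)
    qtl_track <- window_delta(si, q$window_size, q$step, q$min_sites)
    qtl <- call_qtl(qtl_track)
    p1 <- file.path(out_dir, "snp_index.tsv")
    p2 <- file.path(out_dir, "delta_windows.tsv")
    write_track(si, p1, "TSV"); write_track(qtl_track, p2, "TSV")
    paths <- c(paths, snp_index = p1, delta_windows = p2)
    if (nrow(qtl) > 0) {
      p3 <- file.path(out_dir, "qtl_intervals.bed")
      write_track(qtl, p3, "BED"); paths <- c(paths, qtl = p3)
    }
    note("qtlseq: ", nrow(qtl), " interval(s) called")
  }

  report <- NULL
  if ("report" %in% stages) {
    report <- convergence_report(
      fst_sites = fst_sites, fst_windows = fst_windows,
      parallel = parallel, hscan = hs, ehh_curves = ehh_res, qtl = qtl,
      window_size = cfg$fst$window_size)
    p <- file.path(out_dir, "convergence_report.tsv")
    # evidence lines whose stage did not run are all-NA; drop them from
    # the written track (they stay in the returned object)
    keep_cols <- !vapply(report, function(x) all(is.na(x)), logical(1))
    write_track(report[, keep_cols, drop = FALSE], p, "TSV")
    paths <- c(paths, report = p)
    note("report: top window ", report$chrom[1], ":", report$start[1], "-",
         report$end[1], " with ", report$evidence_n[1], " evidence line(s)")
  }

  manifest <- list(
    package = "sweepscan",
    version = as.character(utils::packageVersion("sweepscan")),
    seed = cfg$seed, config = cfg[setdiff(names(cfg), "stages")],
    stages = stages,
    input_checksums = as.list(tools::md5sum(
      Filter(function(p) !is.null(p) && file.exists(p),
             c(vcf_path, map_path, bulk_path)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  paths <- c(paths, manifest = file.path(out_dir, "manifest.json"))

  res <- c(res, list(fst_sites = fst_sites, fst_windows = fst_windows,
                     parallel = parallel, ehh = ehh_res, hscan = hs,
                     qtl = qtl, qtl_track = qtl_track, report = report,
                     truth = truth, paths = paths))
  class(res) <- "sweepscan_run"
  invisible(res)
}

#' Per-window convergence report
#'
#' Joins the evidence lines produced by the scan stages onto one window
#' grid and ranks windows by the number of co-occurring lines -- a
#' transparent tally, not a combined p-value.
#'
#' @param fst_sites per-site F_ST with a `top` column (or NULL).
#' @param fst_windows windowed F_ST with `top` (or NULL).
#' @param parallel parallel-divergence table (or NULL).
#' @param hscan `h_scan` result for the resistant group (or NULL).
#' @param ehh_curves named list with `resistant` / `susceptible`
#'   `ehh_curve`s at the focal SNP (or NULL).
#' @param qtl `qtl_intervals` (or NULL).
#' @param window_size report window grid (bp).
#' @return data.frame of class `convergence_report`, one row per window,
#'   ordered by decreasing `evidence_n`.
#' @export
convergence_report <- function(fst_sites = NULL, fst_windows = NULL,
                               parallel = NULL, hscan = NULL,
                               ehh_curves = NULL, qtl = NULL,
                               window_size = 25000) {
  grid <- NULL
  for (cand in list(parallel, fst_windows)) {
    if (!is.null(cand)) { grid <- cand[, c("chrom", "start", "end")]; break }
  }
  if (is.null(grid) && !is.null(fst_sites))
    grid <- make_tiling(fst_sites$chrom, fst_sites$pos, window_size)
  if (is.null(grid)) stop("no scan results to report on")

  overlaps <- function(chrom, s, e) {
    # logical per grid row: any [s,e] interval on the same chrom overlaps
    out <- rep(FALSE, nrow(grid))
    for (k in seq_along(s))
      out <- out | (grid$chrom == chrom[k] & grid$start <= e[k] &
                      grid$end >= s[k])
    out
  }
  ev <- data.frame(grid)
  ev$fst_site_top <- if (!is.null(fst_sites) && any(fst_sites$top)) {
    d <- fst_sites[fst_sites$top, ]
    overlaps(d$chrom, d$pos, d$pos)
  } else NA
  ev$fst_window_top <- if (!is.null(fst_windows) && any(fst_windows$top))
    overlaps(fst_windows$chrom[fst_windows$top],
             fst_windows$start[fst_windows$top],
             fst_windows$end[fst_windows$top]) else NA
  ev$parallel_consensus <- if (!is.null(parallel) && any(parallel$consensus))
    overlaps(parallel$chrom[parallel$consensus],
             parallel$start[parallel$consensus],
             parallel$end[parallel$consensus]) else NA
  ev$h12_top <- if (!is.null(hscan) && any(hscan$top)) {
    d <- hscan[hscan$top, ]
    overlaps(rep(grid$chrom[1], nrow(d)), d$bp_start, d$bp_end)
  } else NA
  ev$ehh_contrast <- if (!is.null(ehh_curves) &&
                         !is.null(ehh_curves$resistant) &&
                         !is.null(ehh_curves$susceptible)) {
    core <- attr(ehh_curves$resistant, "core_pos")
    res_area <- ehh_area(ehh_curves$resistant)
    sus_area <- ehh_area(ehh_curves$susceptible)
    if (res_area > sus_area)
      overlaps(grid$chrom[1], core, core) else rep(FALSE, nrow(grid))
  } else NA
  ev$qtl_overlap <- if (!is.null(qtl) && nrow(qtl) > 0)
    overlaps(qtl$chrom, qtl$start, qtl$end) else NA

  lines <- c("fst_site_top", "fst_window_top", "parallel_consensus",
             "h12_top", "ehh_contrast", "qtl_overlap")
  mat <- as.matrix(ev[, lines])
  ev$evidence_n <- rowSums(mat == TRUE, na.rm = TRUE)
  # windowed F_ST value as tie-break so that equally-evidenced windows
  # rank by divergence
  ev$fst_value <- if (!is.null(fst_windows))
    fst_windows$value[match(paste(ev$chrom, ev$start),
                            paste(fst_windows$chrom, fst_windows$start))]
  else NA_real_
  ord <- order(-ev$evidence_n, -ifelse(is.na(ev$fst_value), -Inf,
                                       ev$fst_value), ev$chrom, ev$start)
  ev <- ev[ord, ]
  rownames(ev) <- NULL
  class(ev) <- c("convergence_report", "data.frame")
  ev
}

## area under an EHH curve (trapezoid over bp), a scalar decay summary
ehh_area <- function(curve) {
  if (nrow(curve) < 2) return(0)
  sum(diff(curve$pos) * (utils::head(curve$ehh, -1) +
                           utils::tail(curve$ehh, -1)) / 2)
}

#' @export
print.sweepscan_run <- function(x, ...) {
  cat("sweepscan_run with outputs:\n")
  for (nm in names(x$paths)) cat(sprintf("  %-14s %s\n", nm, x$paths[nm]))
  if (!is.null(x$report)) {
    cat("top convergence windows:\n")
    print(utils::head(as.data.frame(x$report), 3))
  }
  invisible(x)
}
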