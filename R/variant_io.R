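## VCF and track input/output.  Parsing is delegated to vcfR; this layer
## validates records, aligns samples to the user's sample map, and converts
## calls into the dosage / haplotype containers used by the scans.

#' Read a multi-sample VCF into a genotype matrix
#'
#' Reads every record of a VCF (plain or gzipped) verbatim -- no filtering
#' is applied here -- and aligns the genotype columns to the samples listed
#' in a sample map.  Dosage is the count of non-reference alleles in the GT
#' call (`NA` when any allele is missing).  Phase (`|` vs `/`) and, for
#' phased calls, the allele order are preserved so that [to_haplotypes()]
#' can reconstruct haplotypes.
#'
#' @param path path to a VCF 4.x file, optionally gzip/bgzip compressed.
#' @param sample_table path to a tab-separated file with columns
#'   `sample_id`, `population`, `phenotype`, or a data.frame with those
#'   columns.  VCF samples absent from the table are dropped with a
#'   warning; the returned columns follow the table's order.
#'
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, sample_table) {
  if (is.character(sample_table)) {
    sample_table <- utils::read.table(sample_table, header = TRUE,
                                      sep = "\t", stringsAsFactors = FALSE)
  }
  need <- c("sample_id", "population", "phenotype")
  if (!all(need %in% names(sample_table)))
    stop("sample table must have columns: ", paste(need, collapse = ", "))
  validate_vcf_lines(path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt_raw <- vcf@gt
  vcf_samples <- colnames(gt_raw)[-1]
  extra <- setdiff(vcf_samples, sample_table$sample_id)
  if (length(extra) > 0)
    warning("VCF samples absent from sample table, excluded: ",
            paste(extra, collapse = ", "))
  missing_in_vcf <- setdiff(sample_table$sample_id, vcf_samples)
  if (length(missing_in_vcf) > 0)
    warning("sample table entries absent from VCF, ignored: ",
            paste(missing_in_vcf, collapse = ", "))
  keep_tab <- sample_table[sample_table$sample_id %in% vcf_samples, ,
                           drop = FALSE]
  if (nrow(keep_tab) == 0L) stop("no VCF sample appears in the sample table")
  samples <- keep_tab$sample_id

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, vcf_samples))
  gt <- gt[, samples, drop = FALSE]
  parsed <- parse_gt(gt)

  dp <- suppressWarnings(
    vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  if (is.null(dp) || all(is.na(dp))) {
    ad <- suppressWarnings(vcfR::extract.gt(vcf, element = "AD"))
    if (!is.null(ad) && !all(is.na(ad))) {
      dp <- matrix(vapply(strsplit(ad, ","), function(x)
        sum(suppressWarnings(as.numeric(x))), numeric(1)),
        nrow = nrow(ad), dimnames = dimnames(ad))
    } else dp <- NULL
  }
  if (!is.null(dp)) {
    if (is.null(dim(dp))) dp <- matrix(dp, nrow = nrow(fix),
                                       dimnames = list(NULL, vcf_samples))
    dp <- dp[, samples, drop = FALSE]
    mode(dp) <- "integer"
  }

  genotype_matrix(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                  ref = fix[, "REF"], alt = fix[, "ALT"],
                  dosage = parsed$dosage, depth = dp,
                  phased = parsed$phased, samples = samples,
                  pop = keep_tab$population,
                  phenotype = keep_tab$phenotype,
                  a1 = parsed$a1, a2 = parsed$a2)
}

## light structural validation so that a malformed record is reported with
## its 1-based line number (vcfR is permissive)
validate_vcf_lines <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  n_fields <- NA_integer_
  i <- 0L
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) break
    i <- i + 1L
    if (startsWith(ln, "##")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (startsWith(ln, "#CHROM")) { n_fields <- length(f); next }
    if (is.na(n_fields)) stop("VCF line ", i, ": data before #CHROM header")
    if (length(f) != n_fields)
      stop("malformed VCF line ", i, ": expected ", n_fields,
           " fields, found ", length(f))
    if (is.na(suppressWarnings(as.integer(f[2]))))
      stop("malformed VCF line ", i, ": non-numeric POS '", f[2], "'")
  }
  invisible(TRUE)
}

## GT strings -> dosage / phase / allele matrices
parse_gt <- function(gt) {
  dims <- dim(gt); dn <- dimnames(gt)
  core <- sub(":.*$", "", as.character(gt))
  phased <- grepl("|", core, fixed = TRUE)
  parts <- strsplit(core, "[|/]")
  a1 <- vapply(parts, function(x)
    if (length(x) >= 1) suppressWarnings(as.integer(x[1])) else NA_integer_,
    integer(1))
  a2 <- vapply(parts, function(x)
    if (length(x) >= 2) suppressWarnings(as.integer(x[2])) else NA_integer_,
    integer(1))
  dosage <- ifelse(is.na(a1) | is.na(a2), NA_integer_,
                   (a1 > 0L) + (a2 > 0L))
  shape <- function(v) { dim(v) <- dims; dimnames(v) <- dn; v }
  list(dosage = shape(dosage), phased = shape(phased),
       a1 = shape(a1), a2 = shape(a2))
}

#' Filter variants on biallelic-SNP status and depth support
#'
#' Retains a site iff (i) it is a biallelic SNP (single-nucleotide REF and
#' ALT; multiallelic records and indels dropped when
#' `biallelic_snps_only = TRUE`) and (ii) the fraction of samples whose
#' total read depth lies in `[min_depth, max_depth]` is at least
#' `min_fraction_called`.  Genotypes of samples outside the depth range at
#' retained sites are kept, not masked.  The counts of sites dropped per
#' rule are reported via `message()` and attached as attribute
#' `"filter_report"`.
#'
#' @param gm a [genotype_matrix()].
#' @param min_depth,max_depth inclusive per-sample depth bounds; set both to
#'   `NULL` to skip the depth rule.
#' @param min_fraction_called minimum fraction of samples in-depth-range.
#' @param biallelic_snps_only drop indels and multiallelic records.
#'
#' @return The filtered `genotype_matrix`.
#' @export
filter_variants <- function(gm, min_depth = 10, max_depth = 250,
                            min_fraction_called = 0.75,
                            biallelic_snps_only = TRUE) {
  n0 <- n_sites(gm)
  keep <- rep(TRUE, n0)
  report <- c(input = n0)
  if (biallelic_snps_only) {
    is_snp <- nchar(gm$ref) == 1L & nchar(gm$alt) == 1L &
      !grepl(",", gm$alt, fixed = TRUE) &
      gm$ref %in% c("A", "C", "G", "T") & gm$alt %in% c("A", "C", "G", "T")
    report["dropped_not_biallelic_snp"] <- sum(!is_snp)
    keep <- keep & is_snp
  }
  if (!is.null(min_depth) || !is.null(max_depth)) {
    if (is.null(gm$depth))
      stop("depth filter requested but no depth information available")
    lo <- if (is.null(min_depth)) 0 else min_depth
    hi <- if (is.null(max_depth)) Inf else max_depth
    ok <- !is.na(gm$depth) & gm$depth >= lo & gm$depth <= hi
    frac <- rowMeans(ok)
    depth_ok <- frac >= min_fraction_called
    report["dropped_depth"] <- sum(keep & !depth_ok)
    keep <- keep & depth_ok
  }
  report["retained"] <- sum(keep)
  if (!any(keep))
    stop("all ", n0, " sites removed by filtering; review thresholds")
  message(sprintf("filter_variants: %d in, %d retained (%s)", n0, sum(keep),
                  paste(sprintf("%s=%d", names(report)[-c(1, length(report))],
                                report[-c(1, length(report))]),
                        collapse = ", ")))
  out <- subset_gm(gm, sites = which(keep))
  attr(out, "filter_report") <- report
  out
}

#' Expand phased genotypes to a haplotype matrix
#'
#' Sites with any missing or unphased call are dropped (the count is
#' reported); at the remaining sites each diploid sample contributes its
#' two phased alleles as two haplotype rows.  The haplotype group label is
#' the sample's phenotype by default, or its population.
#'
#' @param gm a [genotype_matrix()] with phased calls.
#' @param group_by `"phenotype"` or `"population"`.
#' @return A [haplotype_matrix()].
#' @export
to_haplotypes <- function(gm, group_by = c("phenotype", "population")) {
  group_by <- match.arg(group_by)
  if (is.null(gm$a1) || is.null(gm$a2)) {
    # dosage-only input: hom calls are unambiguous; het order set to (0,1)
    gm$a1 <- ifelse(gm$dosage == 2L, 1L, 0L)
    gm$a2 <- ifelse(gm$dosage >= 1L, 1L, 0L)
  }
  ok <- rowSums(is.na(gm$dosage) | !gm$phased) == 0L
  n_drop <- sum(!ok)
  if (!any(ok)) stop("no fully phased, fully called sites")
  if (n_drop > 0)
    message("to_haplotypes: dropped ", n_drop,
            " sites with missing or unphased calls")
  sites <- which(ok)
  ns <- length(gm$samples)
  H <- matrix(0L, nrow = 2L * ns, ncol = length(sites))
  H[seq(1L, 2L * ns, by = 2L), ] <- t(gm$a1[sites, , drop = FALSE])
  H[seq(2L, 2L * ns, by = 2L), ] <- t(gm$a2[sites, , drop = FALSE])
  grp <- if (group_by == "phenotype") gm$phenotype else gm$pop
  haplotype_matrix(H, chrom = gm$chrom[sites], pos = gm$pos[sites],
                   sample = rep(gm$samples, each = 2L),
                   group = rep(unname(grp), each = 2L))
}

#' Write a statistics table as a BED or TSV track
#'
#' TSV output carries 1-based inclusive `start`/`end` (or `pos`) plus every
#' statistic column, and round-trips losslessly through [read_track()].
#' BED output is 0-based half-open with statistic columns appended after
#' the three coordinate fields.  Columns that are entirely `NA` are omitted
#' with a warning.
#'
#' @param stats data.frame with `chrom` and either `start`+`end` (1-based
#'   inclusive) or `pos` columns.
#' @param path output file path.
#' @param format `"TSV"` or `"BED"`.
#' @return `path`, invisibly.
#' @export
write_track <- function(stats, path, format = c("TSV", "BED")) {
  format <- match.arg(format)
  stats <- as.data.frame(stats)
  if (nrow(stats) == 0L) stop("empty statistics table")
  if (!"chrom" %in% names(stats)) stop("stats must have a 'chrom' column")
  empty <- vapply(stats, function(x) all(is.na(x)), logical(1))
  if (any(empty)) {
    warning("omitting all-NA column(s): ",
            paste(names(stats)[empty], collapse = ", "))
    stats <- stats[, !empty, drop = FALSE]
  }
  if (format == "TSV") {
    out <- stats
    dbl <- vapply(out, is.double, logical(1))
    # 17 significant digits so that doubles survive the round-trip exactly
    out[dbl] <- lapply(out[dbl], function(x)
      ifelse(is.na(x), NA_character_, sprintf("%.17g", x)))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    if (all(c("start", "end") %in% names(stats))) {
      bed <- data.frame(chrom = stats$chrom, start = stats$start - 1L,
                        end = stats$end)
      rest <- setdiff(names(stats), c("chrom", "start", "end"))
    } else if ("pos" %in% names(stats)) {
      bed <- data.frame(chrom = stats$chrom, start = stats$pos - 1L,
                        end = stats$pos)
      rest <- setdiff(names(stats), c("chrom", "pos"))
    } else stop("stats must have start/end or pos columns")
    bed <- cbind(bed, stats[, rest, drop = FALSE])
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read back a TSV track written by [write_track()]
#'
#' @param path TSV path.
#' @return data.frame with the original columns and types.
#' @export
read_track <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
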