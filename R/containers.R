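#' Genotype matrix with population and phenotype labels
#'
#' Constructs the diploid genotype container used by the divergence scans:
#' per-site alternate-allele dosages (0/1/2, `NA` = missing) for a set of
#' samples, together with a population label and a phenotype label
#' (`"resistant"` / `"susceptible"`) per sample.
#'
#' @param chrom character vector of chromosome names, one per site.
#' @param pos integer vector of 1-based physical positions (bp).
#' @param ref,alt single-character reference / alternate alleles per site.
#' @param dosage integer matrix, sites x samples, values in `{0,1,2,NA}`.
#' @param depth optional integer matrix of per-sample total read depth
#'   (sites x samples); `NA` where unknown.
#' @param phased logical matrix (sites x samples) marking phased calls, or a
#'   single logical recycled to all entries.
#' @param samples character vector of sample identifiers (columns of
#'   `dosage`).
#' @param pop character vector: population label per sample.
#' @param phenotype character vector: `"resistant"` or `"susceptible"` per
#'   sample.
#' @param a1,a2 optional integer matrices (sites x samples) holding the
#'   first and second allele of each phased call (0 = ref, 1 = alt); kept so
#'   that [to_haplotypes()] can preserve phase order.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(chrom, pos, ref, alt, dosage, depth = NULL,
                            phased = FALSE, samples, pop, phenotype,
                            a1 = NULL, a2 = NULL) {
  n_sites <- length(pos)
  stopifnot(length(chrom) == n_sites, length(ref) == n_sites,
            length(alt) == n_sites, nrow(dosage) == n_sites,
            ncol(dosage) == length(samples),
            length(pop) == length(samples),
            length(phenotype) == length(samples))
  pos <- as.integer(pos)
  if (any(pos < 1L)) stop("positions must be >= 1 (1-based bp)")
  ord <- order(factor(chrom, levels = unique(chrom)), pos)
  if (!identical(ord, seq_len(n_sites))) {
    chrom <- chrom[ord]; pos <- pos[ord]; ref <- ref[ord]; alt <- alt[ord]
    dosage <- dosage[ord, , drop = FALSE]
    if (!is.null(depth)) depth <- depth[ord, , drop = FALSE]
    if (is.matrix(phased)) phased <- phased[ord, , drop = FALSE]
    if (!is.null(a1)) a1 <- a1[ord, , drop = FALSE]
    if (!is.null(a2)) a2 <- a2[ord, , drop = FALSE]
  }
  for (chr in unique(chrom)) {
    p <- pos[chrom == chr]
    if (anyDuplicated(p)) stop("duplicate positions on ", chr)
  }
  bad <- !(dosage %in% c(0L, 1L, 2L, NA))
  if (any(bad, na.rm = TRUE)) stop("dosages must be 0, 1, 2 or NA")
  mode(dosage) <- "integer"
  if (!is.matrix(phased)) {
    phased <- matrix(as.logical(phased), n_sites, length(samples))
  }
  dimnames(dosage) <- list(NULL, samples)
  structure(list(chrom = chrom, pos = pos, ref = ref, alt = alt,
                 dosage = dosage, depth = depth, phased = phased,
                 a1 = a1, a2 = a2, samples = samples,
                 pop = setNames(as.character(pop), samples),
                 phenotype = setNames(as.character(phenotype), samples)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$pos), "sites x", length(x$samples),
      "samples\n")
  cat("  chromosomes:", paste(unique(x$chrom), collapse = ", "), "\n")
  cat("  populations:", paste(sprintf("%s (%d)", names(table(x$pop)),
                                      table(x$pop)), collapse = ", "), "\n")
  nmiss <- sum(is.na(x$dosage))
  cat(sprintf("  missing genotypes: %d (%.2f%%)\n", nmiss,
              100 * nmiss / length(x$dosage)))
  invisible(x)
}

n_sites <- function(gm) length(gm$pos)

#' Subset a genotype matrix by sites and/or samples
#'
#' @param gm a [genotype_matrix()].
#' @param sites logical or integer index over sites.
#' @param samples logical/integer index over samples, or sample names.
#' @return A `genotype_matrix`.
#' @export
subset_gm <- function(gm, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_along(gm$pos)
  if (is.null(samples)) samples <- seq_along(gm$samples)
  if (is.character(samples)) samples <- match(samples, gm$samples)
  genotype_matrix(gm$chrom[sites], gm$pos[sites], gm$ref[sites],
                  gm$alt[sites],
                  gm$dosage[sites, samples, drop = FALSE],
                  depth = if (!is.null(gm$depth))
                    gm$depth[sites, samples, drop = FALSE],
                  phased = gm$phased[sites, samples, drop = FALSE],
                  samples = gm$samples[samples],
                  pop = gm$pop[samples], phenotype = gm$phenotype[samples],
                  a1 = if (!is.null(gm$a1)) gm$a1[sites, samples, drop = FALSE],
                  a2 = if (!is.null(gm$a2)) gm$a2[sites, samples, drop = FALSE])
}

#' Phased haplotype matrix
#'
#' Binary haplotypes (0 = reference allele, 1 = alternate allele), two rows
#' per diploid sample, over strictly increasing physical positions on one or
#' more chromosomes.  This is the input to the EHH, H-statistic and
#' diversity computations.
#'
#' @param H integer matrix, haplotypes x sites, entries 0/1; row count even.
#' @param chrom chromosome name per site (length 1 is recycled).
#' @param pos 1-based physical position per site; strictly increasing within
#'   each chromosome.
#' @param sample sample identifier per haplotype row (each appearing twice).
#' @param group group label per haplotype row (population or
#'   resistant/susceptible).
#'
#' @return An object of class `haplotype_matrix`.
#' @export
haplotype_matrix <- function(H, chrom, pos, sample, group) {
  if (length(chrom) == 1L) chrom <- rep(chrom, length(pos))
  stopifnot(ncol(H) == length(pos), length(chrom) == length(pos),
            nrow(H) %% 2L == 0L, length(sample) == nrow(H),
            length(group) == nrow(H))
  if (!all(H %in% c(0L, 1L))) stop("haplotype entries must be 0/1")
  for (chr in unique(chrom)) {
    p <- pos[chrom == chr]
    if (any(diff(p) <= 0)) stop("positions not strictly increasing on ", chr)
  }
  mode(H) <- "integer"
  structure(list(H = H, chrom = chrom, pos = as.integer(pos),
                 sample = as.character(sample),
                 group = as.character(group)),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat("haplotype_matrix:", nrow(x$H), "haplotypes x", ncol(x$H), "sites\n")
  cat("  groups:", paste(sprintf("%s (%d)", names(table(x$group)),
                                 table(x$group)), collapse = ", "), "\n")
  invisible(x)
}

## rows of the haplotype matrix belonging to one group (or all, group = NULL)
group_rows <- function(hm, group) {
  if (is.null(group)) return(seq_len(nrow(hm$H)))
  rows <- which(hm$group == group)
  if (length(rows) == 0L) stop("no haplotypes in group '", group, "'")
  rows
}

## site indices of a region list(chrom =, start =, end =) (1-based inclusive)
region_sites <- function(hm, region) {
  if (is.null(region)) return(seq_along(hm$pos))
  idx <- which(hm$chrom == region$chrom & hm$pos >= region$start &
                 hm$pos <= region$end)
  if (length(idx) == 0L) stop("region contains no sites")
  idx
}
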