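## Synthetic data: forward Wright-Fisher simulation of multi-deme sweep
## histories, a phased-VCF writer for the simulated samples, and an F2
## bulked-segregant read-count simulator for a dominant resistance locus.

#' Parameters for the multi-deme sweep simulator
#'
#' Populations are simulated at reduced (rescaled) size: choose `n_diploids`,
#' `mu`, `rec` and `s` so that the composite parameters 4Nu, 4Nr and 2Ns
#' match the history being emulated.  Mutation is finite-sites binary
#' (0 <-> 1) on a lattice of `n_sites` potential sites spanning
#' `seq_length` bp; each lattice site absorbs the mutational target of
#' `seq_length / n_sites` bp.
#'
#' @param n_diploids diploid deme size N.
#' @param seq_length simulated chromosome length (bp).
#' @param n_sites lattice of potential SNP sites.
#' @param mu per-bp per-generation mutation rate.
#' @param rec per-bp per-generation recombination rate.
#' @param s selection coefficient of the resistance allele (>= 0).
#' @param h dominance of the resistance allele in `[0,1]`.
#' @param sweep_pos focal position (bp) of the selected site; default
#'   `0.375 * seq_length`.
#' @param n_origins number of independent origin haplotypes: 0 = neutral,
#'   1 = hard sweep, >= 2 = soft sweep.
#' @param f0 initial frequency contributed by each origin.
#' @param burn_in_gens neutral generations in the shared ancestral
#'   population before the demes split.
#' @param selection_gens generations each deme evolves after the split
#'   (selection acts in resistant demes only).
#' @param n_demes_resistant,n_demes_susceptible deme counts.
#' @param migration per-generation migration proportion between demes
#'   (0 disables; island model).
#' @param sample_per_deme haplotypes sampled per deme (even).
#' @param shared_origin if `TRUE` every resistant deme is seeded with the
#'   same ancestral origin haplotype(s) (the resistant haplotype spread
#'   between demes before selection -- parallel architecture); if `FALSE`
#'   each resistant deme draws independent origin backgrounds.
#'   Susceptible demes never carry the resistance mutation and evolve
#'   neutrally throughout.
#' @param resample_on_loss retry a resistant deme's selection phase when
#'   the sweep allele is lost (up to 20 tries; tries are recorded).
#' @param init `"beta"` starts the ancestral population at
#'   mutation-drift equilibrium (per-site frequencies drawn from the
#'   stationary Beta(theta, theta) density, theta = 4N x per-site mu);
#'   `"monomorphic"` starts from all-reference.
#' @param seed integer seed (mandatory for reproducibility).
#' @return list of class `sweep_sim_params`.
#' @export
sweep_sim_params <- function(n_diploids = 500, seq_length = 1e5,
                             n_sites = 4000, mu = 6e-7, rec = 8e-6,
                             s = 0.2, h = 0.5, sweep_pos = NULL,
                             n_origins = 1, f0 = 0.3,
                             burn_in_gens = 500, selection_gens = 45,
                             n_demes_resistant = 3,
                             n_demes_susceptible = 3, migration = 0,
                             sample_per_deme = 40, shared_origin = TRUE,
                             resample_on_loss = TRUE,
                             init = c("beta", "monomorphic"), seed) {
  init <- match.arg(init)
  # default focal position: window-interior, off-centre so that a 25 kb
  # analysis grid holds the footprint inside one window
  if (is.null(sweep_pos)) sweep_pos <- round(0.375 * seq_length)
  stopifnot(mu >= 0, rec >= 0, s >= 0, h >= 0, h <= 1,
            f0 * n_origins <= 1, sample_per_deme <= 2 * n_diploids,
            sample_per_deme %% 2 == 0, sweep_pos >= 1,
            sweep_pos <= seq_length, n_sites >= 2)
  if (missing(seed)) stop("a seed is required")
  p <- as.list(environment())
  class(p) <- "sweep_sim_params"
  p
}

#' Simulate multi-deme sweep/neutral haplotype data
#'
#' Runs a forward Wright--Fisher simulation: a shared ancestral population
#' is burnt in under neutrality, split into `n_demes_resistant +
#' n_demes_susceptible` demes (founders resampled with replacement), and
#' each deme then evolves independently; the resistance allele at
#' `sweep_pos` is under selection (fitnesses 1, 1+hs, 1+s) in resistant
#' demes only.  Sampled haplotypes from every deme are returned along with
#' a truth record.
#'
#' @param params a [sweep_sim_params()] object.
#' @param drop_monomorphic drop sites monomorphic across the whole sample
#'   (as a variant caller would).
#' @return list of class `deme_simulation` with elements `hm` (a
#'   [haplotype_matrix()]; groups are deme names `R1..`, `S1..`, phenotype
#'   labels in `$phenotype`) and `truth` (sweep site used, final
#'   population allele frequency per deme, retry counts, parameters).
#' @export
simulate_demes <- function(params, drop_monomorphic = TRUE) {
  stopifnot(inherits(params, "sweep_sim_params"))
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(params$seed)
  N <- params$n_diploids; n_hap <- 2L * N
  S <- params$n_sites; L <- params$seq_length
  pos <- as.integer(floor((seq_len(S) - 0.5) * L / S) + 1L)
  stopifnot(!anyDuplicated(pos))
  frac <- pos / L
  mu_site <- params$mu * L / S
  theta <- 4 * N * mu_site
  exp_xovers <- params$rec * L

  anc <- if (params$init == "beta") {
    p0 <- stats::rbeta(S, theta, theta)
    matrix(stats::rbinom(n_hap * S, 1L, rep(p0, each = n_hap)),
           nrow = n_hap, ncol = S)
  } else matrix(0L, n_hap, S)
  mode(anc) <- "integer"
  if (params$burn_in_gens > 0)
    anc <- wf_evolve(anc, params$burn_in_gens, mu_site, exp_xovers, frac,
                     -1L, 0, 0)

  sweep_idx <- which.min(abs(pos - params$sweep_pos))
  n_R <- params$n_demes_resistant; n_S <- params$n_demes_susceptible
  deme_names <- c(if (n_R) paste0("R", seq_len(n_R)),
                  if (n_S) paste0("S", seq_len(n_S)))
  is_resistant <- c(rep(TRUE, n_R), rep(FALSE, n_S))

  # the ancestral population never carries the resistance mutation itself
  anc[, sweep_idx] <- 0L

  # an origin is one haplotype background carrying the resistance
  # mutation; its initial carriers in a deme are identical-by-descent
  # copies of the donor row (a haplotype drifted/migrated to frequency f0
  # before selection begins).  With shared_origin the same donor
  # background(s) seed every resistant deme (the resistant haplotype
  # spread by migration); otherwise each deme draws fresh donors
  # (independent origins).
  draw_donors <- function() {
    dh <- anc[sample.int(n_hap, params$n_origins), , drop = FALSE]
    dh[, sweep_idx] <- 1L
    dh
  }
  shared_donors <- if (params$n_origins > 0 && params$shared_origin)
    draw_donors() else NULL
  origin_haps <- shared_donors
  seed_origins <- function(M, donor_haps) {
    n_per <- max(1L, round(params$f0 * n_hap))
    rows <- sample.int(n_hap, n_per * params$n_origins)
    for (o in seq_len(params$n_origins)) {
      grp <- rows[((o - 1L) * n_per + 1L):(o * n_per)]
      M[grp, ] <- matrix(donor_haps[o, ], length(grp), S, byrow = TRUE)
    }
    M
  }

  # demes are founded as full copies of the ancestral population (pure
  # subdivision, no founder bottleneck); divergence accrues only by drift
  # during the deme phase, keeping the neutral between-deme F_ST baseline
  # at ~t/2N
  founders <- function() anc

  evolve_deme <- function(M, selected) {
    wf_evolve(M, params$selection_gens, mu_site, exp_xovers, frac,
              if (selected) sweep_idx - 1L else -1L,
              if (selected) params$s else 0, params$h)
  }

  demes <- vector("list", length(deme_names))
  tries <- integer(length(deme_names))
  for (d in seq_along(deme_names)) {
    M0 <- founders()
    if (params$n_origins > 0 && is_resistant[d]) {
      donors <- if (params$shared_origin) shared_donors else draw_donors()
      if (!params$shared_origin)
        origin_haps <- rbind(origin_haps, donors)
      M0 <- seed_origins(M0, donors)
    }
    repeat {
      tries[d] <- tries[d] + 1L
      M <- evolve_deme(M0, is_resistant[d] && params$n_origins > 0 &&
                         params$s > 0)
      freq <- mean(M[, sweep_idx])
      lost <- is_resistant[d] && params$n_origins > 0 && params$s > 0 &&
        freq == 0
      if (!lost || !params$resample_on_loss || tries[d] >= 20L) break
    }
    demes[[d]] <- M
  }

  if (params$migration > 0 && length(demes) > 1) {
    # island-model exchange applied to the final generation: each
    # haplotype is replaced by one drawn from a random other deme with
    # probability `migration` per generation of the deme phase, i.e.
    # total replacement probability 1-(1-m)^T
    p_mig <- 1 - (1 - params$migration)^params$selection_gens
    for (d in seq_along(demes)) {
      repl <- which(stats::runif(n_hap) < p_mig)
      for (i in repl) {
        src <- sample(setdiff(seq_along(demes), d), 1L)
        demes[[d]][i, ] <- demes[[src]][sample.int(n_hap, 1L), ]
      }
    }
  }

  final_freq <- vapply(demes, function(M) mean(M[, sweep_idx]), numeric(1))
  names(final_freq) <- deme_names

  k <- params$sample_per_deme / 2L
  H <- NULL; samp <- character(0); grp <- character(0); phen <- character(0)
  for (d in seq_along(deme_names)) {
    ind <- sample.int(N, k)
    rows <- as.vector(rbind(2L * ind - 1L, 2L * ind))
    H <- rbind(H, demes[[d]][rows, , drop = FALSE])
    ids <- sprintf("%s_i%02d", deme_names[d], seq_len(k))
    samp <- c(samp, rep(ids, each = 2L))
    grp <- c(grp, rep(deme_names[d], 2L * k))
    phen <- c(phen, rep(if (is_resistant[d]) "resistant" else "susceptible",
                        2L * k))
  }

  keep <- seq_len(S)
  if (drop_monomorphic) {
    f <- colMeans(H)
    keep <- which(f > 0 & f < 1)
    if (length(keep) == 0L) stop("no segregating sites in the sample")
  }
  hm <- haplotype_matrix(H[, keep, drop = FALSE], chrom = "chr1",
                         pos = pos[keep], sample = samp, group = grp)
  hm$phenotype <- phen

  truth <- list(sweep_pos = pos[sweep_idx],
                sweep_site_retained = sweep_idx %in% keep,
                final_freq = final_freq, tries = tries,
                theta_site = theta, origin_haplotypes = origin_haps,
                params = params)
  structure(list(hm = hm, truth = truth), class = "deme_simulation")
}

#' @export
print.deme_simulation <- function(x, ...) {
  cat("deme_simulation:", nrow(x$hm$H), "haplotypes,", ncol(x$hm$H),
      "segregating sites\n")
  cat("  sweep site:", x$truth$sweep_pos, "bp; final allele frequency:\n")
  print(round(x$truth$final_freq, 3))
  invisible(x)
}

#' Write a haplotype matrix as a phased VCF plus sample map
#'
#' Writes plain-text VCF 4.2 with one diploid sample per consecutive row
#' pair and `|`-separated phased genotypes, and a tab-separated sample map
#' (`sample_id`, `population`, `phenotype`).  Reading the pair back with
#' [read_vcf()] and [to_haplotypes()] recovers the matrix exactly.
#'
#' @param hm a [haplotype_matrix()]; if it carries a `$phenotype` vector
#'   it is used for the sample map, otherwise groups starting with "R"
#'   map to resistant.
#' @param path output VCF path.
#' @param sample_map_path output TSV path (default: `path` with
#'   `.samples.tsv` appended).
#' @return invisibly, `c(vcf = path, sample_map = sample_map_path)`.
#' @export
write_sim_vcf <- function(hm, path,
                          sample_map_path = paste0(path, ".samples.tsv")) {
  n_hap <- nrow(hm$H)
  stopifnot(n_hap %% 2 == 0)
  first <- seq(1L, n_hap, by = 2L)
  samples <- hm$sample[first]
  if (anyDuplicated(samples)) stop("sample ids must pair consecutive rows")
  gt <- matrix(paste0(t(hm$H[first, , drop = FALSE]), "|",
                      t(hm$H[first + 1L, , drop = FALSE])),
               nrow = ncol(hm$H))
  header <- c("##fileformat=VCFv4.2",
              "##source=sweepscan_simulator",
              paste0("##contig=<ID=", unique(hm$chrom), ">"),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- paste(hm$chrom, hm$pos, ".", "A", "T", ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  phen <- if (!is.null(hm$phenotype)) hm$phenotype[first]
  else ifelse(startsWith(hm$group[first], "R"), "resistant", "susceptible")
  utils::write.table(
    data.frame(sample_id = samples, population = hm$group[first],
               phenotype = phen),
    sample_map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(vcf = path, sample_map = sample_map_path))
}

#' Parameters for the F2 bulked-segregant simulator
#'
#' @param n_f2_resistant_bulk,n_f2_susceptible_bulk bulk sizes (the
#'   defaults mirror a 48-resistant / 47-susceptible F2 design).
#' @param n_f2 size of the simulated F2 population the bulks are drawn
#'   from.
#' @param causal_pos position (bp) of the dominant resistance locus.
#' @param seq_length chromosome length (bp).
#' @param n_sites number of marker sites (uniformly scattered).
#' @param mean_depth mean sequencing depth per site per bulk (Poisson).
#' @param rec_per_bp recombination rate per bp per meiosis (Morgans/bp).
#' @param chrom chromosome name for the output table.
#' @param seed integer seed.
#' @return list of class `bsa_sim_params`.
#' @export
bsa_sim_params <- function(n_f2_resistant_bulk = 48,
                           n_f2_susceptible_bulk = 47, n_f2 = 300,
                           causal_pos = 5e7, seq_length = 1e8,
                           n_sites = 500, mean_depth = 60,
                           rec_per_bp = 2e-8, chrom = "chr5", seed) {
  stopifnot(n_f2_resistant_bulk >= 1, n_f2_susceptible_bulk >= 1,
            mean_depth >= 1, causal_pos >= 1, causal_pos <= seq_length)
  if (missing(seed)) stop("a seed is required")
  p <- as.list(environment())
  class(p) <- "bsa_sim_params"
  p
}

#' Simulate F2 bulked-segregant read counts for a dominant locus
#'
#' Simulates an F2 population from a resistant x susceptible cross (the
#' resistant parent carries allele 1 at every marker), with one meiosis
#' per gamete and Haldane recombination between adjacent loci.  Survivors
#' of selection carry at least one resistant allele at the causal locus
#' (dominant resistance); the resistant bulk is drawn from survivors and
#' the susceptible bulk from non-survivors.  Read counts per site and
#' bulk are Binomial(Poisson(mean_depth), bulk allele frequency).
#'
#' @param params a [bsa_sim_params()] object.
#' @param marker_map optional integer vector of marker positions (bp);
#'   default: `n_sites` positions uniformly drawn over the chromosome.
#' @return list of class `bsa_simulation` with `counts` (a
#'   [bulk_counts()] table) and `truth` (causal position, bulk allele
#'   frequencies at the causal locus, parameters).
#' @export
simulate_f2_bulks <- function(params, marker_map = NULL) {
  stopifnot(inherits(params, "bsa_sim_params"))
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(params$seed)
  if (is.null(marker_map))
    marker_map <- sort(sample.int(params$seq_length, params$n_sites))
  marker_map <- sort(unique(as.integer(marker_map)))
  if (any(params$causal_pos < min(marker_map)) ||
      any(params$causal_pos > max(marker_map)))
    stop("causal_pos must lie within the marker span")
  causal <- as.integer(params$causal_pos)   # one or more dominant loci
  loci <- sort(unique(c(marker_map, causal)))
  causal_idx <- match(causal, loci)
  nl <- length(loci)
  r_adj <- 0.5 * (1 - exp(-2 * params$rec_per_bp * diff(loci)))

  gametes <- function(n) {
    G <- matrix(0L, n, nl)
    G[, 1L] <- stats::rbinom(n, 1L, 0.5)
    for (j in 2:nl) {
      sw <- stats::rbinom(n, 1L, r_adj[j - 1L])
      G[, j] <- ifelse(sw == 1L, 1L - G[, j - 1L], G[, j - 1L])
    }
    G
  }
  dos <- gametes(params$n_f2) + gametes(params$n_f2)
  # dominant resistance: a carrier at any causal locus survives treatment
  survivor <- rowSums(dos[, causal_idx, drop = FALSE] >= 1L) > 0L
  if (sum(survivor) < params$n_f2_resistant_bulk)
    stop("only ", sum(survivor), " survivors; resistant bulk needs ",
         params$n_f2_resistant_bulk)
  if (sum(!survivor) < params$n_f2_susceptible_bulk)
    stop("only ", sum(!survivor), " non-survivors; susceptible bulk needs ",
         params$n_f2_susceptible_bulk)
  bulk_r <- sample(which(survivor), params$n_f2_resistant_bulk)
  bulk_s <- sample(which(!survivor), params$n_f2_susceptible_bulk)
  freq_r <- colMeans(dos[bulk_r, , drop = FALSE]) / 2
  freq_s <- colMeans(dos[bulk_s, , drop = FALSE]) / 2

  depth_r <- stats::rpois(nl, params$mean_depth)
  depth_s <- stats::rpois(nl, params$mean_depth)
  alt_r <- stats::rbinom(nl, depth_r, freq_r)
  alt_s <- stats::rbinom(nl, depth_s, freq_s)

  out_idx <- match(marker_map, loci)
  counts <- bulk_counts(chrom = params$chrom, pos = loci[out_idx],
                        ref_r = depth_r[out_idx] - alt_r[out_idx],
                        alt_r = alt_r[out_idx],
                        ref_s = depth_s[out_idx] - alt_s[out_idx],
                        alt_s = alt_s[out_idx])
  truth <- list(causal_pos = causal,
                causal_freq_r = freq_r[causal_idx],
                causal_freq_s = freq_s[causal_idx],
                n_survivors = sum(survivor), params = params)
  structure(list(counts = counts, truth = truth), class = "bsa_simulation")
}
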