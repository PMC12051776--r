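---
title: "Methods: sweep scans, QTL-seq mapping and the forward simulator"
author: "sweepscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sweep scans, QTL-seq mapping and the forward simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

# The scientific problem

Herbicide resistance in outcrossing weeds is a textbook case of rapid,
repeated adaptation: fields sprayed with the same compound impose intense
selection, and resistant populations are expected to carry the molecular
footprint of that selection.  `sweepscan` implements the inference stack
used to localise such a resistance locus from two complementary kinds of
evidence:

* **population-genomic scans** contrasting resistant and susceptible
  populations — per-SNP and windowed Weir–Cockerham $F_{ST}$, extended
  haplotype homozygosity (EHH), Garud's H1/H12/H2 statistics, and
  within-group diversity summaries; and
* **bulked-segregant QTL-seq mapping** in an F2 cross segregating for a
  dominant, large-effect resistance locus.

Every statistic can be exercised against a forward Wright–Fisher
simulator whose truth is known, so the whole pipeline is verifiable
without access to any particular resequencing dataset.

# Statistics

## Weir–Cockerham $F_{ST}$

For a biallelic site observed in two populations, `fst_site()` computes
the moment estimator variance components: $a$ (among populations), $b$
(among individuals within populations) and $c$ (within individuals), with
$\hat\theta = a/(a+b+c)$.  Missing genotypes are excluded site-wise, so
per-site sample sizes vary; $\hat\theta$ is undefined at pooled-monomorphic
sites, when either group has fewer than two called genotypes, or when the
denominator is non-positive.  Negative estimates are retained (the
estimator is unbiased around zero under no differentiation).

Windowed values (`fst_windowed()`) use the *ratio of averages*
$\sum a / \sum(a+b+c)$ over the usable sites of non-overlapping 25 kb
windows, requiring at least 25 SNPs — the ratio-of-averages form is the
standard choice because it weights sites by their information content and
is far less noisy than averaging per-site ratios.  A window inherits an
undefined value rather than a zero when it fails the SNP minimum.

`parallel_divergence_counts()` repeats the windowed scan for every
(resistant population × susceptible population) pair and counts, per
window, the number of pairwise comparisons in which the window reaches the
top 1% of the $F_{ST}$ distribution.  A window flagged in all $|R|\times|S|$
comparisons is evidence for a *parallel* architecture — the same diverged
haplotype in every resistant population.  The top-quantile threshold is
the linear-interpolation empirical quantile (R type 7) of the defined
window values, with ties at the threshold all flagged; the quantile
definition is fixed so results are reproducible.

## EHH

`ehh()` starts from a core SNP and a core allele and asks, among the
haplotypes of one group carrying that allele, how far identity extends:
at flanking marker $x$,
$EHH(x) = \sum_h \binom{n_h}{2} / \binom{n_c}{2}$ over the distinct
extended haplotypes $h$.  The curve equals 1 at the core and decays
monotonically in each direction.  Both group curves (resistant and
susceptible) at the same core SNP form the contrast of interest: slower
decay in the resistant group indicates a recent rise of a long shared
haplotype.  Extension stops at the chromosome end, at `max_extent`, or
once EHH drops below `min_ehh` (default 0.05, disable with 0); no
carrier-count decay threshold is applied.

## Garud H-statistics

Over a window of SNPs, with haplotype frequencies sorted
$p_1 \ge p_2 \ge \dots$: $H1 = \sum p_i^2$,
$H12 = (p_1+p_2)^2 + \sum_{i\ge3} p_i^2$ and $H2 = H1 - p_1^2$.  High H12
detects both hard and soft sweeps; the ratio $H2/H1$ separates them (soft
sweeps leave several frequent haplotypes, elevating $H2$).  `h_scan()`
slides 100-SNP windows along the chromosome.  The step is physical by
default — the next window starts at the first SNP at least 50 bp to the
right — which yields a dense, heavily overlapping scan whose top-1% H12
set forms a contiguous cluster at a sweep; a fixed SNP-count step is
available via `step_unit = "snps"` for sparser scans.  Frequency ties when
identifying the most common haplotype are broken lexicographically on the
haplotype string; this affects no numeric value, only which haplotype is
reported as dominant.

## Diversity summaries

`group_site_summary()` reports, per group and region: nucleotide
diversity $\pi$ (mean over sites of $2p(1-p)\,n/(n-1)$), whole-region
haplotype heterozygosity ($1-\sum q_k^2$, scaled $n/(n-1)$), the
proportion of segregating sites, the mean alternate-allele frequency and
the count of sites with alternate frequency above 0.5.  Both $\pi$ and
haplotype heterozygosity are emitted because "haplotype diversity" is used
ambiguously in the field; they are labelled unambiguously here.  A
completed sweep shows up as reduced $\pi$ and segregating proportion in
the resistant group, and (because reference assemblies typically derive
from susceptible material) an excess of high-frequency alternate alleles.

## QTL-seq

For two phenotype bulks sequenced to moderate depth, the per-site
SNP-index is the alternate-read fraction of each bulk and
$\Delta$SNP-index is their difference (resistant minus susceptible).
Sites with bulk depth below 10 are masked.  Significance uses a
*simulated null envelope* in the style of the original QTL-seq method:
for a given depth pair, each of 10,000 replicates draws the bulk
compositions under Mendelian 1:2:1 segregation unlinked to the trait,
then binomial read sampling, giving the null distribution of delta; the
2.5% and 97.5% empirical quantiles form the 95% envelope.  Envelopes are
tabulated once per distinct depth pair.  Because read counts are
discrete, the envelope bounds live on a grid of spacing $\approx 1/\text{depth}$;
seed-to-seed variation of the bounds is bounded by one grid step, and the
realised two-sided exceedance rate is slightly conservative (about 4.5%
at 60×).  A site-resampling bootstrap envelope is available as an
alternative (`mode = "bootstrap"`).  `window_delta()` smooths delta over
sliding windows (defaults 1 Mb / 100 kb, at least 10 sites — smoothing
parameters are artifact choices) and `call_qtl()` reports maximal runs of
windows whose smoothed delta exceeds the window-averaged upper envelope.

With a dominant resistance allele and survivors bulked, the F2
expectation at the causal site is an index of $2/3$ in the resistant bulk
(survivors are $\tfrac13$ RR + $\tfrac23$ Rr) and $0$ in the susceptible
bulk; this closed-form expectation anchors the calibration tests.

# The forward simulator

`simulate_demes()` implements a discrete-generation Wright–Fisher model
of diploid, obligately outcrossing demes with viability selection at one
site, uniform recombination and finite-sites binary mutation on a lattice
of potential SNP positions.  The generation loop is compiled (Rcpp) and
drawn entirely from R's RNG, so a seed reproduces a run bit-for-bit.

Design choices that matter:

* **Rescaled populations.**  Demes are small ($N = 500$ by default) with
  mutation, recombination and selection rates chosen to preserve the
  composite parameters $4N\mu$, $4Nr$ and $2Ns$ of the history being
  emulated; 100 kb of simulated sequence stands in for a Mb-scale region.
* **Shared ancestry.**  All demes split from one ancestral population
  after a neutral burn-in, as full copies (no founder bottleneck), so the
  neutral between-deme $F_{ST}$ baseline is $\approx t/2N$ for $t$
  post-split generations while shared ancestral variation keeps demes
  comparable — the situation in which an outlier scan is meaningful.
* **Equilibrium initialisation.**  Ancestral per-site frequencies are
  drawn from the stationary Beta($\theta$, $\theta$) density of the
  reversible two-allele mutation–drift process ($\theta = 4N\mu$ per
  site), which has exactly the equilibrium expected heterozygosity
  $4N\mu/(1+4N\mu)$; the burn-in then only needs to establish linkage
  structure, not diversity, so a few hundred generations suffice.  The
  mutation–drift-equilibrium property test validates this.
* **Sweep origins as haplotype copies.**  An origin is a single ancestral
  haplotype carrying the resistance mutation; its initial carriers are
  identical-by-descent copies at combined frequency `f0` per origin,
  seeded into resistant demes only (susceptible demes never receive the
  mutation and evolve neutrally, matching the scenario the scans are
  designed for).  With `shared_origin = TRUE` every resistant deme gets
  the *same* origin background — the parallel architecture in which one
  resistant haplotype spread between populations before selection;
  `FALSE` gives independent origins.  `n_origins = 1` is a hard sweep,
  `>= 2` a soft sweep, `0` pure neutrality.
* **Default study conditions.**  `N = 500`, 100 kb, 4,000 lattice sites,
  $\mu = 6\times10^{-7}$, $r = 8\times10^{-6}$ per bp per generation,
  $s = 0.2$, $h = 0.5$, `f0 = 0.3`, 500 burn-in + 45 selection
  generations, three resistant and three susceptible demes, 40 sampled
  haplotypes per deme.  These were chosen once so that a completed sweep
  leaves a footprint of roughly one 25 kb analysis window (the footprint
  scale is $\sim 1/(rT)$ for a sweep lasting $T$ generations) while the
  chromosome-wide map length keeps distant windows effectively unlinked
  from the sweep; the sweep then stands out against a neutral window
  baseline of $F_{ST} \approx t/2N \approx 0.06$.
* **Migration** (optional, default 0) is applied as an island-model
  exchange at sampling time with total probability $1-(1-m)^T$; the test
  suite's truth conditions are cleanest without gene flow.

What the simulator deliberately does *not* emulate: realistic demography
(growth, admixture, selfing), gene conversion, mutation-rate and
recombination-rate heterogeneity, multi-nucleotide variants, sequencing
or phasing error in the VCF path.  Passing the recovery tests therefore
shows the statistics behave correctly under the assumed history at desk
scale, not that any particular empirical dataset will show the same
signal strength.

`simulate_f2_bulks()` emulates the mapping cross: an F2 population from
fully homozygous parents (resistant parent carries allele 1 at every
marker), one Haldane meiosis per gamete, survival of paraquat treatment
for carriers of at least one resistant allele at the causal locus
(dominance is the design assumption), bulks of 48 resistant / 47
susceptible individuals by default, and Binomial(Poisson(depth), bulk
frequency) read counts.  Multiple causal positions are treated as
"resistant if carrying any" — useful for planting two unlinked loci.

# Pipeline and convergence report

`run_pipeline()` executes simulate → filter → scans → QTL-seq → report
from a config list or YAML file, writes every track as TSV/BED, and
records a `manifest.json` (package version, seed, full parameters, input
checksums) sufficient to reproduce a run exactly.  The variant filter
follows the resequencing convention of retaining biallelic SNPs whose
per-sample depth lies in [10, 250] in at least 75% of samples; genotypes
of the remaining samples at retained sites are kept, not masked.  The
convergence report joins five evidence lines onto one window grid — a
top-1% per-SNP $F_{ST}$ site, a top-1% windowed $F_{ST}$ value, a full
parallel-divergence flag count, a top-1% H12 window in the resistant
group, a resistant-over-susceptible EHH contrast at the top-$F_{ST}$ SNP,
and QTL-interval overlap when bulks are supplied — and ranks windows by
the count of co-occurring lines (ties broken by windowed $F_{ST}$).  The
tally is deliberately transparent: the scientific argument is by
intersection of independent evidence, not by a combined p-value.

# Numerical conventions and edge cases

* Coordinates: 1-based inclusive everywhere user-facing (TSV, function
  arguments); BED output is 0-based half-open.  TSV numeric columns are
  written with 17 significant digits and round-trip bit-exactly.
* Quantiles: R type 7 (linear interpolation) throughout; ties at a
  threshold are all flagged.
* Dosage is the count of non-reference alleles; multiallelic records get
  a non-reference dosage on input and are removed by the biallelic
  filter before analysis.
* `to_haplotypes()` drops any site with a missing or unphased call and
  reports the count; phase order is preserved from the VCF.
* Monomorphic pooled sites are excluded from $F_{ST}$ scans; windows
  report the count of usable SNPs alongside their value.
* All stochastic functions accept an explicit seed and restore the
  caller's RNG state.

# Problem sizes used in the validation suite

The oracle-equivalence checks use 500 random tables/windows with up to 20
samples and 50 sites, matched against naive pairwise-enumeration
implementations written independently of the package internals.  The
end-to-end sweep-recovery check runs 20 replicates of the default
six-deme scenario; the soft-versus-hard comparison runs 20 + 20
single-deme replicates (four origins at `f0 = 0.075` versus one origin at
`f0 = 0.3`, so the selected allele starts at the same total frequency and
both arms finish fixed; this experiment uses tighter linkage,
$r = 10^{-6}$, so the sweep footprint spans the 100-SNP scan windows —
the haplotype-frequency spectrum, not localisation, is what it measures);
the QTL-seq calibration draws a 10,000-replicate
envelope and 10,000 fresh null sites at 60× depth with 48/47 bulks, and
verifies the Mendelian 2/3 expectation at 600× averaged over 30 crosses.
These sizes were chosen as the smallest at which the statistical
contrasts are decisive.

# Known limitations

* The Weir–Cockerham estimator is implemented for exactly two groups
  (the contrasts the scans need); multi-group $\theta$ is out of scope.
* EHH is unpolarised (reference/alternate, not ancestral/derived), and no
  integrated statistics (iHS, XP-EHH) are computed.
* The null envelope conditions on observed depths; it does not model
  depth over-dispersion beyond Poisson or mapping bias between alleles.
* The simulator's finite-sites lattice means extremely high mutation
  rates produce back-mutation at a rate real sequence would not show.
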