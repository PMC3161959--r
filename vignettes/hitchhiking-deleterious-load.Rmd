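---
title: "Hitchhiking and the deleterious load: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hitchhiking and the deleterious load: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepload)
library(dplyr)
```

# The scientific question

When an advantageous mutation sweeps through a population, it drags linked
variation with it. Neutral polymorphism is removed wholesale; deleterious
polymorphism behaves differently, because deleterious alleles are
concentrated at low frequencies before the sweep. A sweep eliminates many
common (mostly neutral) alleles and raises some rare (disproportionately
deleterious) alleles to intermediate or high frequency. The observable
signature is an *increase in the ratio of deleterious to neutral
nonsynonymous SNPs* inside genomic regions affected by recent hitchhiking,
driven by a deficit of neutral SNPs rather than an excess of deleterious
ones.

sweepload provides every stage needed to study this signature end to end:
a forward simulator that generates the expectation, a conservation-based
classifier that labels nonsynonymous SNPs, recombination-stratified
regressions and region contrasts that measure the enrichment, a Poisson
scan for deleterious-SNP clusters, and a synthetic-data generator that
makes the whole pipeline testable with known ground truth.

# The Wright-Fisher simulator

`run_burn_in()`, `run_single_sweep()`, and `run_recurrent_sweeps()` iterate
a diploid Wright-Fisher population of `N` individuals. Each chromosome is a
set of infinite-sites mutations on the unit interval. Per generation:

1. **Fitness.** Each diploid's fitness is multiplicative over non-neutral
   sites: `1 + h s` heterozygous, `1 + s` homozygous. The dominance
   coefficient is `h = 0.5` throughout.
2. **Reproduction.** Each of the `2N` offspring chromosomes picks a parent
   individual with probability proportional to fitness and receives one
   gamete.
3. **Recombination.** A Poisson(`rho`) number of crossover events per
   population per generation is assigned to uniformly chosen gametes at
   uniform positions (`rho = N r`, with `r` per individual meiosis). The
   population-level rate is the model's given; assigning one crossover per
   event to a random gamete reproduces it with O(1) cost per meiosis.
   Recombination acts during gamete formation, i.e. between selection and
   mutation within a generation.
4. **Mutation.** New neutral, deleterious (and, in recurrent mode,
   advantageous) mutations arrive at Poisson(`theta_x / 2`) per class per
   generation at uniform positions on uniformly chosen chromosomes, where
   `theta_x = 4 N u_x`. Position collisions are redrawn.
5. **Bookkeeping.** Mutations reaching count `2N` are logged as fixed and
   stripped; this leaves relative fitnesses, and hence sampling
   probabilities, unchanged.

All selection and mutation parameters are population-scaled (`4Nu`, `4Ns`,
`N r`), so the standardized dynamics do not depend on `N` itself. The
reference conditions are `4Nu_n = 70`, `4Nu_d = 70`, `4Ns_d = -10`,
`4Ns_a = 100` (and `4Nu_a = 0.5` in recurrent mode) with `N = 1000`, a
burn-in of `20 N` generations, and samples of 100 chromosomes. The package
runs its own studies at `N = 200` with the scaled parameters held fixed,
which keeps a full single-sweep replicate near one second; the test suite
uses 50-100 replicates per contrast and the acceptance script 10-30. At
this `N` the qualitative contrasts (directions of ratio changes) are
stable; curve *levels* retain O(1/N) finite-population effects.

**Single sweeps** are conditioned on fixation: after the burn-in the state
is snapshotted, one advantageous mutation is injected at position 0.5 on a
single chromosome, and generations are iterated until it fixes; on loss
the snapshot is restored exactly and a fresh attempt is made (cap
`max_attempts = 10000`). The post-sweep sample is taken at the fixation
generation, together with a matched pre-sweep sample from the snapshot.
Because each mutation records its birth generation, the post-sweep sample
is also split into *standing* variation (sites predating the injection)
and new mutation. With `rho = 0`, every sampled chromosome descends from
the sweep haplotype, so standing heterozygosity is exactly zero at
sampling; total post-sweep diversity is not zero because mutation
continues during the sweep — roughly `theta * T / (2N)` with `T` the sweep
duration, about half the equilibrium level under the reference parameters.
The tests therefore assert the exact standing-variation statement plus a
strong reduction in total diversity, rather than literal zero.

**Recurrent sweeps** let advantageous mutations arise at rate
`theta_a / 2` per generation uniformly along the chromosome, during the
burn-in and afterwards, with a per-class spectrum sampled every `N`
generations. Samples are taken on the fixed schedule regardless of whether
a sweep is in progress.

**Choice of "intermediate" recombination.** The contrast of pre- versus
post-sweep ratios is sharpest when lineages experience on the order of one
crossover during the sweep. The sweep duration is roughly
`(8N / gamma_a) ln(2N)` generations, so crossovers per lineage per sweep
are approximately `rho` under the reference parameters — `rho = 1` is the
intermediate point of the default grid `{0, 0.1, 1, 10, 100}` and is the
value the package's own studies use.

# Frequency-spectrum estimators

`theta_estimates()` computes, from an unfolded spectrum over derived
counts `1..n-1`,

$$\theta_W = S / a_n, \qquad
\theta_\pi = \sum_i S_i \frac{2 i (n-i)}{n(n-1)}, \qquad
\theta_H = \sum_i S_i \frac{2 i^2}{n(n-1)},$$

which weight low-, intermediate-, and high-frequency derived variants and
all estimate `4Nu` under neutrality. Sites fixed in the sample are
substitutions and are excluded from spectra. Deleterious-to-neutral ratio
curves aggregate as the *ratio of replicate means*
(`aggregate_class_ratio()`): per-replicate ratios are unstable whenever a
replicate has no neutral polymorphism in a class, and means over hundreds
of replicates are what the curves display. Replicates with zero *mean*
denominator flag `NA` with a warning rather than propagating infinities.

# The conservation LRT classifier

A nonsynonymous SNP is called deleterious when three criteria all hold:
(1) its codon is significantly conserved by a likelihood-ratio test
(`p < 0.001`, strict), (2) the estimated nonsynonymous rate is below the
synonymous rate (`omega_hat < 1`), and (3) the derived amino acid is
absent from the orthologous position in all other (non-human) eutherian
mammals. Columns with fewer than 10 aligned eutherians are untestable.

The codon substitution model is deliberately minimal: 61 sense codons,
uniform stationary frequencies, single-nucleotide-change rates, synonymous
rate 1, nonsynonymous rate `omega`, stop codons disallowed. This is the
simplest process consistent with the neutral (`omega = 1`) versus
conserved (`omega` free) contrast the test requires; empirical codon
frequencies and among-site rate variation are out of scope. Under uniform
frequencies the synonymous flux per unit time is independent of `omega`,
so one constant normalisation puts branch lengths exactly in synonymous
substitutions per site; trees are rescaled (`scale_tree_ds()`) so the
tree-wide synonymous length is `dS = 12.2`, taken as a given parameter.
The reported `dn_hat` is `omega_hat * dS`.

Likelihoods are computed by pruning from tips to root with per-column
scaling; gaps and invalid codons are missing data. `omega` is maximised on
`[1e-4, 10]`: the batched route (`lrt_sites()`) evaluates a dense
121-point log-spaced grid shared across all columns (one symmetric
eigendecomposition per grid point) and refines each column's maximum by
quadratic interpolation in `log10(omega)`, accurate to well under 0.01
log-likelihood units — negligible against the chi-square(1) cutoff of
10.83 and, if anything, very slightly conservative. The per-site route
(`lrt_site()`) uses a bounded scalar optimizer at 1e-6 log-likelihood
tolerance; the two routes agree on calls. A p-value exactly at 0.001 is
*not* conserved.

Calibration is checked by simulation: columns generated under `omega = 1`
on a 16-taxon tree yield a conserved-call rate statistically compatible
with the nominal 0.001, and columns under `omega = 0.05` are called
conserved with high power, mirroring the reported ~72% sensitivity of
such tests on disease mutations as a property, not as a number to
reproduce.

# Recombination windows, the conservation offset, and the regressions

Recombination rates come from non-overlapping 400-kb windows: the genetic
map distance between the two most distant map points divided by their
physical distance. Windows are excluded when that span is at most 360 kb,
when the window lies within 10 Mb of a chromosome end or centromere edge,
or when it contains no aligned coding sequence. Retained windows are
ranked into ten equal-sized bins (`rec_bins()`).

Codons are stratified by the number of G/C nucleotides (`j = 0..3`)
because conservation covaries with both GC content and recombination. For
bin `i` and class `j` the offset cell is

$$s_{i,j} = fdel_j \cdot fcon_{i,j} / \overline{fcon}_j,$$

the class-wide deleterious fraction rescaled by the bin's relative
conservation density, clipped to `(10^{-6}, 1 - 10^{-6})`. This is a
reconstruction: the offset is defined here by the three quantities named
above and validated by parameter-recovery simulation only, never against
published regression coefficients. The same caveat applies to the
regression equations themselves, which the package takes as binomial
logistic models with the fixed offset `logit(s)`:

* recombination model: `logit P(del) = logit(s_ij) + b0 + b1 r_i`;
* hitchhiking model: adds `b2 h`, with `h = 1` for windows overlapping
  regions found by at least three selection tests and `h = 0` for windows
  overlapping none (others dropped);
* distance model: per-200-kb-bin deleterious fraction against the bin's
  distance (Mb, window midpoint convention: SNP position to nearest region
  edge) with no offset.

Fits use standard iteratively reweighted least squares via `glm()`; the
test suite checks every route against an independently coded Newton
maximiser of the binomial likelihood to 1e-6 and checks 95% Wald CI
coverage of planted coefficients. The biased-gene-conversion control
(`bgc_filter()`) removes A/T-to-G/C SNPs and SNPs in GC-class-0 codons
before refitting.

# Region contrasts, iHS windows, disease alleles, and the cluster scan

Hitchhiking regions are labelled intervals rounded *outwards* to the 10-kb
grid (nearest-rounding could shrink an interval past SNPs it contained).
`enrichment()` partitions classified SNPs by region overlap and reports
densities per kb of accessible CDS, the deleterious/neutral ratios, their
fold (an odds ratio), a normal CI on its log (the standard log-odds-ratio
interval; level configurable, 95% default, 90% used for display bars), a
two-proportion z-test, and a one-sided Fisher's exact test (upper
hypergeometric tail, enrichment direction). Frequency classes are
right-closed: rare `(0, 0.008]`, intermediate `(0.008, 0.059]`, common
`(0.059, 1]`; disease alleles use a separate 5% cutoff, with missing
frequencies set to zero (hence rare) by the stated convention.

`ihs_windows()` scores 100-kb windows by the fraction of SNPs with
`|iHS| > 2`, bins windows by SNP count in increments of 25 so SNP density
cannot masquerade as selection, applies an empirical top-fraction cutoff
within each bin (ties included), and excludes windows with fewer than 10
SNPs and bins with fewer than 100 windows (400 at the 0.25% cutoff).

`scan_clusters()` slides 1-Mb windows at 0.5-Mb steps, computes the
genome-average deleterious rate per accessible-CDS kb *from the data*,
scores each window with at least two deleterious SNPs by the Poisson upper
tail `P(X >= k)`, selects the most significant 2% of eligible windows
(ties at the boundary included — the selection follows the printed
significance threshold, i.e. smallest p), and merges overlapping or
boundary-sharing selections keeping the smallest-p representative.

Distances from SNPs to regions count the bases strictly between the SNP
and the interval (0 inside or immediately adjacent), the native convention
of the interval library underneath; at the 200-kb bin width the one-base
difference from an edge-inclusive convention is immaterial.

# The synthetic-data generator

`synth_config()` + `synth_genome()`, `synth_snps()`, `synth_alignments()`,
`synth_scores_and_diseases()` generate every pipeline input with known
ground truth; each generator is a pure function of (config, seed), with
truth stored in sidecar tables the pipeline never reads. Defaults describe
two 25-Mb chromosomes, ~3% coding in 300-codon genes, 85% of CDS
accessible, conservation increasing with codon GC class, a 1.2 cM/Mb map
with hotspots, eight 600-kb sweep regions per chromosome (~19% of the
genome) with method labels skewed toward few tests, and SNP counts scaled
to about a quarter of the real tabulations with the real deleterious
fraction. Analyses of these scaled genomes use a correspondingly scaled
2-Mb end/centromere buffer in place of the 10-Mb buffer used at real
chromosome scale.

Two modelling shortcuts are deliberate and documented: derived-allele
frequencies are drawn from class-specific Beta spectra (deleterious
strongly rare-skewed) rather than from a population-genetic diffusion, and
iHS scores are synthetic draws (wider spread inside sweep regions), not
haplotype statistics. Inside sweep regions *neutral and synonymous* SNPs
are thinned by `1/f` while deleterious placement stays uniform, matching
the mechanism seen in the data (neutral deficit, deleterious constancy)
and making the true fold equal `f` exactly. Consequently, passing recovery
tests demonstrate that the pipeline measures what the generator planted —
they do not validate population-genetic realism of linkage structure,
demography, or ascertainment in real data.

# Numerical choices and degenerate inputs

* Fisher, Poisson, hypergeometric, and chi-square tails use the stock R
  distribution functions; the tests pin them against enumeration and
  summation oracles (1e-12) because the analyses live in these tails.
* Empty Fisher margins return p = 1 with a message; zero-denominator
  ratios flag `NA` and are excluded with a count; degenerate z-tests
  (empty side) return `NA`.
* The likelihood pruning rescales per column; `lrt_stat` is clamped at 0
  (null nested in alternative) and `omega_hat` reported as 1 whenever the
  null is not beaten.
* Equal-sized binning breaks rate ties by rank order; bin sizes differ by
  at most one window.
* The simulator errors when every individual has non-positive fitness and
  when the fixation-conditioning attempt cap is exceeded.

# Known limitations

* Single dominance coefficient; no epistasis, population structure,
  growth, or bottlenecks — the simulator addresses the equilibrium model
  only.
* The codon model omits empirical codon frequencies and rate variation;
  genome-wide deleterious fractions from richer implementations are not
  comparable and are not targets.
* The regression equations and the offset estimator are reconstructions
  validated by recovery properties, not by published coefficients.
* Synthetic iHS tracks carry no linkage disequilibrium; region-detection
  power on real haplotype data is outside what the tests can show.
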