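---
title: "Methods: diversity, ROH and selection-signature scans in popgenscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, ROH and selection-signature scans in popgenscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

popgenscan analyses multi-sample diploid SNP data — the kind produced by
whole-genome resequencing of livestock or wildlife cohorts — for
within-population diversity, inbreeding, admixture, and signatures of
positive selection. This vignette documents the statistical models, the
defaults and why they were chosen, the numerical conventions, and what the
bundled simulator does and does not emulate.

## Genotype representation

All statistics operate on a `geno_matrix`: samples x variants alternate-allele
dosages in {0, 1, 2, NA}. Only biallelic SNPs are admitted; `read_vcf()`
skips multiallelic and indel records with a logged count, because every
implemented statistic is defined on two-allele frequencies or on
heterozygous/homozygous genotype classes. Phasing is ignored throughout:
no statistic here depends on haplotype order. Missing genotypes are excluded
site-wise from every frequency denominator (the convention shared by
VCFtools and PLINK), so a site's allele frequency in a population is
`(het + 2 * hom_alt) / (2 * n_called)` and is flagged undefined when no
genotype is called.

Genomic windows are half-open intervals `[start, start + window)` with
1-based starts at multiples of the step. This makes window membership
unambiguous (a SNP at a step boundary belongs to the window starting there,
not the one ending there) and makes the FST and Hp scans share a grid, which
the outlier-intersection step relies on.

## Diversity statistics

* **Pn** — the proportion of SNPs with minor-allele frequency strictly
  greater than 0.01, among sites with a defined frequency in the
  population. The threshold is strict because "polymorphic" is defined as
  MAF *exceeding* 1%.
* **Ho** — per genome, heterozygous calls over non-missing calls; population
  values are the mean and sample SD (n − 1 denominator, used for every
  mean ± SD in the package) over individuals.
* **He** — mean site-wise `2p(1-p)` over sites polymorphic in the
  population. This is the standard expected-heterozygosity definition from
  population allele frequencies; it deliberately avoids any tool-specific
  F-statistic internals.
* **π** — per site, the unbiased estimator `2p(1-p) * n/(n-1)` with `n` the
  called allele count (equivalently the mean pairwise difference among
  called alleles), summed over a 100-kb window and divided by the *full*
  window length in bp, monomorphic positions included — the VCFtools
  `--window-pi` dialect, stepped every 50 kb. Windows are emitted for every
  step-aligned start from the first SNP's window to the last SNP's
  position; empty windows report π = 0 with `n_snps = 0`, and trailing
  partial windows still divide by the nominal window length (this affects
  edge windows only and keeps per-window values comparable).
* **D** — for each sample pair, over mutually non-missing sites, the PLINK
  `--genome` similarity `DST = (IBS2 + 0.5 * IBS1)/N` and distance
  `D = 1 − DST`. This parenthesisation is the one that keeps DST within
  [0, 1]; the raw formula is sometimes printed without the enclosing
  parentheses, which would not.

## Runs of homozygosity

`detect_roh()` reimplements the PLINK-style two-phase scan:

1. a window of `scan_window_snps` (default 50) consecutive SNPs slides along
   each chromosome and *hits* when it contains at most
   `max_het_per_window` (1) heterozygous and `max_missing_per_window` (1)
   missing calls;
2. a SNP lies in a run when at least `window_hit_threshold` (0.05, the
   PLINK default) of the scanning windows covering it hit; maximal stretches
   of such SNPs are split at inter-SNP gaps above `max_gap` (1 Mb) and
   filtered by `min_snps` (50), `min_length` (100 kb) and `min_density`
   (1 SNP / 100 kb, applied as the segment-average density).

The het/missing thresholds are *maxima per scanning window*: a minimum
number of heterozygous calls inside a homozygosity run would be
contradictory. Segment ends are the first and last SNP positions of the run
and `length = end − start + 1`. Note one practical consequence of the strict
one-missing-call allowance: two missing calls falling within one scanning
window fail every window covering them, which can fragment an otherwise
clean run. This is faithful to the thresholds, not an artifact.

The detector is verified against an exhaustive brute-force implementation
of the same rules (naive loops over every window and every SNP) on hundreds
of random genomes spanning empty and segment-rich regimes, and its
monotonicity properties (stricter length or heterozygosity thresholds never
produce more or longer runs) are property-tested.

`F_ROH = sum(L_roh) / L_auto` with `L_auto` defaulting to 2.4 Gb, the
approximate autosomal genome length of the goat; it must be overridden for
synthetic genomes. Length classes partition (100 kb, ∞) at 150/250/400 kb
with boundary values in the lower class ("100–150" followed by ">150–250"
implies a closed upper bound on the first bin).

## Selection scans

**FST.** The per-site statistic is
`1 − (p1 q1 + p2 q2) / (2 pr qr)`, `pr = (p1 + p2)/2`: one minus the ratio
of the mean within-population heterozygosity to the pooled-frequency
heterozygosity. Concavity of `p(1−p)` keeps it within [0, 1]; sites fixed in
the pooled sample are undefined and skipped. Windows are 100 kb stepped
every 25 kb; windows with fewer than 30 qualifying SNPs are dropped; the
default window value is the unweighted mean of the site values
(`dialect = "site_mean"`).

That per-site form, averaged over windows, is a fine *ranking* statistic but
a poor *estimator* of the underlying differentiation: finite-sample noise
inflates it when true differentiation is small (with 10 samples per
population it reports ≈ 0.03 when the true value is 0.01), and the
pooled-frequency denominator compresses it when differentiation is large
(≈ 0.07 for a true 0.10). `dialect = "wc"` therefore provides the
Weir–Cockerham ratio-of-sums estimator per window, which corrects both
biases; it is the dialect used wherever the package checks that the scan
recovers a known drift parameter, and the recommended one whenever the
absolute FST level is the quantity of interest. The default stays
`"site_mean"` because the outlier-calling contract is rank-based and the
per-site form is the one stated with the method.

**Hp.** Pooled heterozygosity per window,
`Hp = 2 ΣnMaj ΣnMin / (ΣnMaj + ΣnMin)^2`, with `nMaj`/`nMin` the per-SNP
major/minor allele **counts** in the population. Counts, not frequencies:
with frequencies the statistic is identical when every site has the same
called sample size and loses its natural down-weighting of high-missingness
sites when it does not. Ties at `p = 0.5` assign the alternate allele as
minor, which cannot change Hp (it is symmetric in the two sums). Hp lies in
[0, 0.5], reaching 0.5 exactly when the summed counts balance.

**Z-standardisation and outliers.** Each scan is standardised genome-wide
per comparison/population — `z = (x − mean)/sd` over all its windows — and
the top `ceil(0.01 N)` ZFST windows are intersected with the bottom
`ceil(0.01 N)` ZHp windows by exact window identity (scans with slightly
different grids can only intersect on shared windows). Ties at the rank
boundary are broken deterministically by (chrom, start). Intersected
windows that overlap or abut merge into candidate regions, reported with
their peak ZFST and trough ZHp. Standardisation is per comparison, not
joint across comparisons, so each test population is judged against its own
genome-wide distribution.

## f3 / f4 statistics

`f3(A; B, C) = mean_site (a−b)(a−c)` and `f4(A, B; C, D) = mean_site
(a−b)(c−d)` on population allele frequencies, with sites dropped listwise
when any involved population is uncalled. Standard errors come from a
delete-one block jackknife on consecutive 500-SNP blocks (the trailing
partial block merges into the last full one), using the weighted-jackknife
variance so unequal block sizes are handled exactly; for equal blocks it
reduces to the classical formula, which the tests verify against the
analytic standard error of a mean. `Z = estimate / SE`.

No finite-sample bias correction is applied by default: under pure drift
`E[f3] = Var(a) > 0`, so the uncorrected statistic is conservative exactly
where the admixture test looks (significantly *negative* Z). A flag-gated
heterozygosity correction is available for users who want magnitudes
comparable across sample sizes; the package's own contract — the sign and Z
interpretation — is validated without it, including the property that
unadmixed simulated cohorts essentially never produce Z < −3.

## The cohort simulator

`simulate_genotypes()` draws, per SNP, an ancestral frequency
`p ~ Beta(1, 1)` by default, per-population frequencies from the
Balding–Nichols distribution `Beta(p(1−F)/F, (1−p)(1−F)/F)`, and genotypes
`Binomial(2, p_k)`. The model was chosen over a coalescent simulator
because its closed-form moments make the package's calibration checks
analytic — `E[p_k] = p`, `Var(p_k) = F p(1−p)`, so Weir–Cockerham window
FST should recover F and mean sample He over polymorphic sites has an
exact enumeration under weak drift — and because no implemented statistic
requires a linkage model. Defaults: 3 populations of 10 samples, 2
chromosomes of 10 Mb, 40,000 SNPs at uniform random positions, F = 0.05
(moderate livestock-breed differentiation), 1% missing calls.

Planted structure provides ground truth for recovery tests: sweep windows
resample the target population's frequency toward the ancestral major
allele with residual MAF at most a configured ceiling (depleting Hp and
elevating FST locally), and autozygous tracts force a named sample
homozygous for the population-major allele. The truth registry echoes the
planted coordinates exactly.

What the simulator does **not** emulate: linkage disequilibrium (sites are
independent given the frequencies, so background ROH arise only from the
planted tracts and allele-frequency chance, not from demography),
mutation-rate heterogeneity, sequencing or calling error, and related
individuals. Passing recovery tests therefore demonstrate the correctness
of the statistics and the detection rules under the assumed frequency
model, not robustness to every property of real resequencing data.

## Problem sizes and numerical conventions

The validation suite uses cohorts of 30–50 samples and 10,000–75,000 SNPs —
large enough that window scans contain thousands of windows (about 6,000
for the sweep-recovery check, with ten planted 100-kb sweeps) while the
whole suite runs in well under a minute per check. Drift recovery is
checked at F ∈ {0.01, 0.05, 0.1} with fixed seeds and a ±20% relative
band; sweep recovery requires ≥90% recall at the 1% intersection tails.
The planted-tract F_ROH identity is checked without missing calls (isolating
SNP-boundary discretisation, the quantity of interest) with tolerance one
maximum inter-SNP gap per tract, since run boundaries cannot be resolved
more finely than the local SNP spacing and flanking chance-homozygous SNPs
shift them by a few spacings.

Degenerate inputs fail loudly rather than silently: zero-variance scans
cannot be Z-standardised, populations with no variable site have no He,
pairs with no co-called site have no distance, and fewer than two jackknife
blocks is an error. Empty π windows are data (π = 0), not errors, because
the window grid is part of the scan's definition.
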