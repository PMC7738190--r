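---
title: "Methods: pool-seq differentiation scans in poolscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pool-seq differentiation scans in poolscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscan)
```

# The problem

Marine fish such as Atlantic herring combine enormous population sizes and
high gene flow with strong local adaptation. The consequence for population
genomics is a characteristic signature: genome-wide ("neutral")
differentiation between populations is minute — pairwise F~ST~ on the order
of 0.01–0.06 — while a modest number of loci under divergent selection show
allele-frequency differences of 0.5 or more between ecologically contrasting
groups. Pool-seq (sequencing pooled DNA of tens of individuals per
population) makes surveying dozens of populations affordable, at the cost of
observing read counts rather than genotypes.

`poolscan` implements the full analysis chain for this setting: corrected
allele frequencies, marker partitioning and PCA for population structure,
superpool contingency scans with inflation correction, clustering of
significant SNPs into independent loci, pool-based F~ST~, genetic-distance
trees, and haplotype summaries at inversion-like structural variants. A
synthetic-data module generates datasets with exactly this statistical
structure so that every stage can be validated end to end.

# Allele frequencies from pooled reads

A pool-seq frequency estimate is doubly sampled: `n` diploids are drawn from
the population, then `RD` reads are drawn from the pool. Neither `2n` nor
`RD` alone is the right sample size; the effective allele count

$$N_{\mathrm{eff}} = \frac{2n \cdot RD - 1}{2n + RD}$$

is bounded above by both and is the information-equivalent single-stage
count. `effective_count()` is strictly increasing in each argument and
approaches `2n` as depth grows. `corrected_frequency()` computes
`f = alt/RD` per pool × site cell together with `N_eff` and the fractional
corrected counts `f·N_eff` and `(1−f)·N_eff`. Two conventions are worth
stating:

* **N~eff~ stays fractional.** Rounding would discard information and no
  rounding rule is canonical.
* **Zero depth is missing data**, never frequency zero. Downstream steps
  (std, PCA, Nei distances) treat `NA` cells explicitly.

The correction rescales *counts*, not the ratio: `f` itself is unchanged,
which is what makes the per-site standard deviation identical whether
computed on raw ratios or corrected frequencies.

# Marker partitioning and PCA

The across-pool sample standard deviation (denominator `N−1`) of `f` at each
site summarizes how differentiated the site is. Its genome-wide distribution
motivates two marker sets:

* **undifferentiated**: `0.02 ≤ std ≤ 0.08` — informative but unremarkable
  sites that reflect drift and shared history;
* **highly differentiated**: `std ≥ 0.2` — the tail that, in this kind of
  survey, is dominated by selected loci.

Both require minor allele frequency `> 0.01` (computed from the across-pool
mean frequency) to exclude monomorphic sites and rare variants; sites
between the bands belong to neither set. Each set is then thinned to one
marker per fixed genomic window — 1 kb for the undifferentiated set, 10 kb
for the differentiated one, whose members are clustered by linkage — using
windows anchored at position 1 with the lowest-position site retained.
Anchored-window-first-site is one of several defensible readings of "one
marker per window"; it is chosen because it is deterministic and idempotent.

`pca_pools()` runs a covariance PCA (markers mean-centered across pools, no
variance scaling — frequencies share a scale, and unit-variance scaling
would up-weight near-monomorphic sites). Missing cells are imputed to the
marker mean, which is exactly neutral after centering. Scores come from the
SVD; variance explained is the squared singular value over the total; each
component is oriented so its largest-magnitude loading is positive, making
results invariant to marker order. `pca_silhouette()` quantifies how well a
pool grouping separates in PC space (mean silhouette width on the leading
components).

The expectation this machinery encodes — and what the tests verify on
synthetic data — is that superpool structure is essentially invisible on
undifferentiated markers (silhouette ≈ 0) and stark on differentiated ones
(silhouette > 0.9 in the packaged conditions).

# The superpool χ² scan

Power to detect a selected locus comes from contrasting *superpools*: the
read counts of all pools on each side of an ecological contrast are summed,
giving one 2×2 table (reference/alternate × superpool) per SNP.
`chi2_scan()` applies Pearson's χ² with 1 df, no continuity correction and
no minimum-expected-count rule beyond positive marginals — the test is a
screening statistic over millions of sites, not a small-sample inference —
and records the allele-frequency difference `dAF` alongside.

## Genomic inflation

The χ² null assumes all reads on one side are draws from a single binomial.
They are not: member pools differ by drift, so the statistics are inflated
even without selection. This is real inflation with a known cause, and it is
corrected by median-based genomic control: λ is the observed median χ² over
the χ²₁ median (0.4549), clamped below at 1, and every statistic is divided
by it. Median-based GC is robust to the selected tail precisely because the
median ignores it. On the packaged null conditions (20 pools of 35–110
diploids, F = 0.03, depth 50) raw λ is ≈ 2.9; the adjusted statistics have
empirical λ = 1 by construction and leave zero significant sites.

## Thresholding

After λ-adjustment, a Bonferroni correction over the `m` tested sites is
applied and sites with adjusted p < 10⁻¹⁰ are flagged. Whether the published
threshold of this analysis style applies to λ-adjusted, Bonferroni-adjusted,
or both-adjusted p-values is genuinely ambiguous in the literature; the
package makes the interpretation explicit and configurable
(`adjust = "both"` (default) | `"lambda"` | `"bonferroni"`), and the default
— λ then Bonferroni — is the most conservative reading. Both the threshold
and the correction mode are recorded as attributes of the returned scan.

# Independent loci

Significant SNPs are clustered into "independent loci" by three rules: a
locus spans ≥ 100 bp, contains ≥ 2 SNPs with raw p < 10⁻²⁰, and is ≥ 100 kb
from its neighbors. `cluster_loci()` realizes this as single-linkage merging
of significant SNPs while consecutive gaps are < 100 kb, followed by the
span and strong-SNP filters on each merged cluster. Two readings had to be
fixed:

* **Seeds vs filters.** The significance mask (adjusted p < 10⁻¹⁰) defines
  cluster membership; the raw p < 10⁻²⁰ rule filters *clusters*, not the
  seed set. This makes every rule independently checkable and both
  thresholds configurable.
* **Close loci merge rather than being discarded.** Merging is what single
  linkage does naturally, guarantees the output spacing, and never throws
  away signal; the alternative (dropping one of two nearby loci) is
  strictly less informative. Reported loci are provably ≥ 100 kb apart.

Locus boundaries are the member-SNP extremes with no padding.
`intersect_contrasts()` reports replicated signals between two scans as
≥ 1 bp interval overlaps at the locus level and exact position matches at
the SNP level. The clustering implementation is verified against a
brute-force merge-then-filter enumeration on hundreds of random instances.

# Pool F~ST~

`site_fst()` uses the classical π-based pooled estimator: within-pool
heterozygosity $\pi_k = \frac{RD_k}{RD_k-1} \, 2 f_k (1-f_k)$, $\pi_S$ the
pool average, $\pi_T$ the same on summed counts, and
$F_{ST} = (\pi_T - \pi_S)/\pi_T$. The `RD/(RD−1)` factor corrects the
downward bias of plug-in heterozygosity at finite depth; as depth grows the
estimator converges to the frequency-only classical value. The estimator is
symmetric in pools and invariant to swapping allele labels. Pool sizes can
optionally replace raw depth with `N_eff` in the correction factors
(`n_a`/`n_b`); the default uses raw depth, matching the estimator's textbook
form.

`sliding_fst()` applies the standard filter set (summed minor-allele count
≥ 10, per-pool depth in [10, 500], window/step 5 kb, covered fraction
≥ 0.7). Two deliberate conventions:

* **Covered fraction is over SNP sites only.** The original mpileup-based
  tooling counted covered *bases* including invariant sites; a counts-table
  pipeline has no invariant sites, so the fraction here is qualifying SNPs
  over all SNPs in the window. This is a documented divergence, not an
  approximation of the base-level quantity.
* **Negative site estimates are kept in window means** (they carry
  information about sampling noise); only the final reported window value is
  floored at 0, with the raw mean retained alongside. The pairwise matrix
  entries are floored the same way, so identical pools report 0.

On six simulated pools at F = 0.03 (n = 50, depth 60) the genome-wide mean
pairwise estimate lands around 0.02 — the Balding–Nichols pairwise
expectation F/2 ≈ 0.015 plus the finite pool-size contribution — inside the
0.01–0.06 range such surveys report.

# Distances, trees, and haplotype summaries

**Nei's standard distance** (1972) is computed over all loci jointly:
summed gene identities $J_{XY}, J_X, J_Y$ (both alleles of each biallelic
site), $I = J_{XY}/\sqrt{J_X J_Y}$, $D = -\ln I$. The ratio-of-sums form
matches the convention of the classic tools, not the per-locus-averaged
variant. Pairs are compared on their shared non-missing sites; an identity
of 0 (opposite fixation at every site) caps the distance at a configured
maximum with a warning rather than returning infinity.

**Neighbor joining** uses the canonical Saitou–Nei algorithm (via
`ape::nj()`). Negative branch lengths — an artifact of non-additive
distances — are floored at 0 with the deficit transferred to the sister
branch, preserving leaf-to-leaf path lengths where possible. On additive
matrices the output reproduces the generating tree exactly (topology and
branch lengths), which is the property the tests enforce up to 12 leaves.

**Bootstrap consensus**: SNP columns are resampled with replacement (same
count), each replicate yields a distance matrix and NJ tree, and the
majority-rule consensus keeps clades in > 50% of replicates with percentage
supports as node labels. Compatible minority clades are *not* greedily
added — strict majority is easier to reason about and matches the cited
convention. The replicate stream is a deterministic function of `seed`.

**Nucleotide diversity** divides the mean pairwise difference count by the
*monomorphic-inclusive* span of the region (`span_bp`), not by the SNP
count. Published per-bp diversities use region lengths; the SNP-only
denominator would be inflated by orders of magnitude.

**Inversion haplotype frequencies.** A polymorphic inversion segregates as
two diverged haplotype classes (N/S). Given two reference pool groups
assumed near-fixed for opposite classes, diagnostic markers are sites with
an absolute between-group mean frequency difference ≥ 0.8 (`diag_delta`,
the package's operationalization — no numeric rule is canonical), and a
pool's S-haplotype frequency is its mean frequency of the S-associated
allele across those markers. The estimate targets the allele-frequency
mixture $q\,p_S + (1-q)\,p_N$; with within-class residual frequencies of
0.95/0.05 this attenuates toward 0.5 by at most 0.045, which is why the
recovery tolerance of ±0.05 on `q` is attainable and honest.

# The synthetic-data generator

`simulate_truth()` + `simulate_pools()` emulate the survey's statistical
structure, not its biology:

* **Baseline**: ancestral frequencies `p0 ~ Uniform(0.05, 0.95)` (bounded
  away from fixation so the MAF filter stays exercised), pool frequencies
  independently Balding–Nichols,
  `p_k ~ Beta(p0(1−F)/F, (1−p0)(1−F)/F)`, so `Var(p_k) = F·p0(1−p0)`.
  F defaults to 0.03, matching the observed scale of baseline
  differentiation.
* **Sampling is two-stage**: `a ~ Binomial(2n, p_k)` chromosomes, then
  `RD ~ Poisson(depth)` (floored at 1) reads with
  `alt ~ Binomial(RD, a/2n)`. This is precisely the double sampling the
  N~eff~ correction exists for; a single-stage read binomial would make the
  correction vacuous.
* **Selected loci**: 50 runs of 5 consecutive sites, evenly spaced
  (≈ 1 Mb apart, far beyond the 100 kb merge distance), where superpool-A
  pools are shifted by `+Δ ~ Uniform(0.5, 0.7)`, clamped to [0.02, 0.98].
  The clamp attenuates realized shifts at high `p0`; tests that assert the
  shift therefore condition on sites where the clamp is inactive.
* **Inversion block**: a 2 Mb region where every site is near-fixed between
  classes (`p_S = 0.95`, `p_N = 0.05`, orientation randomized per site) and
  pool frequencies are the exact mixture given a per-pool S-frequency
  schedule `q`. The default schedule spans [0, 1] so the extreme pools are
  genuinely fixed and can serve as reference groups — mirroring real
  systems where some geographic regions are homozygous for one arrangement.
* **Defaults** are the study conditions: 20 pools of 35–110 diploids
  (sizes drawn uniformly), two 10-pool superpools, 50,000 sites over five
  10 Mb chromosomes at 1 kb spacing, depth 50.

What the generator does **not** emulate: linkage disequilibrium outside
planted loci and the inversion (sites are independent), recombinant
haplotypes within the inversion, sequencing error, reference bias, and any
demographic history beyond the star-shaped Balding–Nichols model. Passing
tests therefore demonstrate that the *statistical machinery* behaves as
specified under its own assumptions — they do not certify performance on
real data, where LD structure and artifacts add failure modes this model
cannot produce.

`simulate_haplotypes()` derives phased in-block haplotypes by mutating the
two ancestral arrangements independently per site with probability `theta`,
and `write_fixture()` emits sync counts, metadata, truth tables and a
phased VCF that round-trip through the package readers.

# Numerical choices and degenerate inputs

* Sync parsing reduces each site to ref + highest-count non-reference
  allele (ties broken A < C < G < T); sites with > 2 segregating
  nucleotides, or no alternate reads anywhere, are dropped with a count.
  `N` and deletion classes never contribute to depth.
* χ² marginal products are computed in doubles (integer read sums overflow
  32-bit range at realistic depths); zero column marginals skip the site.
* λ estimation refuses fewer than 1000 sites (the median of a thin scan is
  not a calibration) and never deflates (λ clamped at 1).
* PCA clamps `k` to the centered rank with a warning; Nei identities
  above 1 beyond 10⁻⁸ are an error (non-frequency input), identities
  exactly 0 are capped.
* Empty inputs are legal wherever they are meaningful: empty locus tables,
  empty marker classes, zero-site VCF regions (which still report 2N
  haplotypes).

# Problem sizes

The packaged validation exercises the pipeline at deliberately scaled
sizes: 50,000-site scans for null calibration and locus recovery, 20,000
sites for F~ST~ recovery, 10,000 sites with a 2,000-site inversion block
for haplotype summaries, 100–1000 bootstrap replicates for trees, and
500-instance randomized oracles for clustering. These sizes give stable
Monte-Carlo behaviour (the quantities asserted have sampling noise well
inside their tolerances) while keeping a full run in minutes on one core;
the same code paths scale linearly to survey-size inputs.

# Known limitations

* The scan assumes biallelic SNPs with a fixed reference; multiallelic
  sites are dropped at parse time.
* Genomic control corrects a scalar inflation; contrast-specific structure
  that inflates different genomic regions differently (e.g. inversions
  segregating within a superpool) is not modelled and will leave residual
  miscalibration inside such regions.
* The F~ST~ windowing cannot reproduce base-level covered fractions without
  invariant-site data (see above).
* `haplotype_frequency()` requires genuinely near-fixed reference groups;
  with intermediate reference pools the diagnostic-marker selection becomes
  noise-driven and the estimates biased. The error message for zero
  diagnostic markers points at the knob (`diag_delta`), but the remedy is
  better references, not a lower threshold.
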