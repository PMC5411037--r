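---
title: "Methods: population-genetic analysis of a two-basin deep-sea species"
author: "bathypop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-genetic analysis of a two-basin deep-sea species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bathypop)
```

# The scientific setting

bathypop analyses the spatial genetic structure of a marine species
sampled on both sides of a dispersal barrier — the motivating system is a
bathyal grenadier sampled at four Atlantic localities (three Mid-Atlantic
Ridge sections, MAR1–MAR3, and Rockall, ROC) and two Mediterranean ones
(MED1, MED2), genotyped at nine nuclear microsatellites (375 diploids)
and sequenced for a 613-bp mitochondrial COI fragment (193 sequences).
The shallow sill between the basins (the Strait of Gibraltar) is expected
to leave two signatures: strong mitochondrial differentiation with no
shared haplotypes, and weak but significant nuclear differentiation. The
package implements the complete analysis chain for such data: diversity
statistics, differentiation tests with FDR control, hierarchical AMOVA
with a grouping search, neutrality and bottleneck tests, a median-joining
haplotype network, a coalescent simulator of two-population divergence
scenarios, ABC scenario choice and divergence-time estimation, and
drift-based power analysis — all exercisable on synthetic data with
controlled truth.

# Estimators

## Diversity

Observed heterozygosity is the fraction of heterozygous individuals among
the scored ones; expected heterozygosity uses Nei's unbiased estimator
$H_E = \frac{2n}{2n-1}\left(1 - \sum_k p_k^2\right)$ on the $n$ scored
diploids of a cell. Total gene diversity $H_T$ applies the same form to
the pooled allele frequencies, which weights localities by their sample
sizes (the source publications do not state a weighting; this is the
natural one for pooled counts). Allelic richness is the rarefaction
estimator $R_s(g) = \sum_a \left[1 - \binom{N-N_a}{g}/\binom{N}{g}\right]$
on $g$ gene copies. A published table reports rarefaction "sample sizes"
in individuals; `allelicRichness()` takes `g` in gene copies and the
presumed mapping is two copies per diploid individual. Haplotype
diversity is $H_d = \frac{n}{n-1}(1 - \sum_i (c_i/n)^2)$ and nucleotide
diversity the mean pairwise proportion of differing sites with pairwise
deletion of `N`/`-` positions (the default of the distance software this
mirrors). All statistics are kept at full precision internally;
`diversityTable()` rounds only at the reporting layer (3 decimals for
$H_d$, 4 for $\pi$, mirroring the usual table precision).

## Inbreeding and Hardy–Weinberg tests

$F_{IS}$ is the Weir–Cockerham within-population $f$: per allele,
$b = \frac{n}{n-1}\left[p(1-p) - \frac{2n-1}{4n}h\right]$ and $c = h/2$,
with $f = 1 - \sum c / \sum (b + c)$ summed over alleles and loci, so
multilocus weighting follows the variance components rather than an
unweighted average. Hardy–Weinberg proportions are tested with the
two-sided conditional probability exact test (Levene's distribution);
two-allele cells are enumerated completely, larger ones use a seeded
Monte Carlo sample of random gene pairings (default $10^5$ draws — the
published analyses state a two-sided exact test but no sampling budget).

## Differentiation

`fstWeirCockerham()` implements the 1984 variance-component
$\hat\theta = \sum a / \sum (a+b+c)$ with components summed over alleles
and loci; negative estimates are reported as computed.  `phiSt()` is the
two-level AMOVA ratio on the matrix of pairwise nucleotide differences.
`jostDest()` uses the unbiased two-sample form
$D = \frac{k}{k-1}\,\frac{H'_T - H'_S}{1 - H'_S}$ with Nei–Chesser
corrections based on the harmonic mean number of gene copies; two samples
sharing no alleles give exactly 1. Multilocus $D$ defaults to the
arithmetic mean across loci (harmonic mean also reported). Note that on
finite samples with identical frequencies the unbiased estimator is
slightly negative — estimates are never truncated.

Significance everywhere is by label permutation (default 10,000,
seeded) rather than Markov-chain exact machinery: the null hypothesis is
the same and the procedure is simpler and exactly reproducible. Families
of pairwise tests are controlled by Benjamini–Hochberg FDR at
$\alpha \in \{0.05, 0.01, 0.001\}$, rendered as the usual one/two/three
stars.

## AMOVA and the grouping search

The three-level AMOVA partitions variance among groups, among localities
within groups, and within localities. For sequences the squared distance
is the pairwise difference count; for microsatellites each gene copy is
an entity with allele non-identity distance (an $F_{ST}$-analogue — the
analysis chain reports $F_{ST}$-family statistics throughout, so the
sum-of-squared-size-differences $R_{ST}$ metric is deliberately not
used), with variance components computed per locus and summed.
Permutation schemes follow the standard AMOVA conventions: localities
among groups for $F_{CT}$, individuals among localities within groups for
$F_{SC}$, individuals anywhere for $F_{ST}$. `groupingSearch()` ranks
candidate groupings by largest $F_{CT}$ (ties broken by smaller
$F_{SC}$). With six localities the $F_{CT}$ permutation space is small,
so its p-values are coarse — a property of the design, not the
implementation.

## Isolation by distance, PCA, p-distance

`mantelIbd()` regresses genetic on geographic distance over the lower
triangle and permutes unit labels; both raw and $g/(1-g)$-linearized
transforms are exposed. Raw is the default: the published mitochondrial
intercept (0.26) is on the raw $\Phi_{ST}$ scale. Geographic distances
are supplied by the user (shortest sea paths are out of scope).
`frequencyPca()` is a centred PCA of the locality-by-frequency table with
axis significance from permuting individuals among units.
`groupPDistance()` averages inter-group p-distances with a bootstrap over
alignment sites for the SE; by default each distinct haplotype enters
once ("haplotypes"), because the published 0.54% Atlantic–Mediterranean
divergence is only reproduced by haplotype-level averaging — sequence-
frequency weighting (also available) halves it, as the dominant
haplotypes sit one step apart.

## Neutrality and bottleneck tests

Tajima's $D$, Fu's $F_S$ and the Ramos-Onsins–Rozas $R_2$ use their
standard definitions; $F_S$ evaluates the Ewens sampling formula through
a log-space recurrence for the unsigned Stirling numbers of the first
kind, which is what keeps $n$ beyond ~60 (here up to 193) from
overflowing. P-values come from neutral coalescent simulation conditioned
on $n$ and $\theta_\pi$, lower-tailed as is conventional for detecting
expansion; $F_S$ is conventionally called significant at $p < 0.02$ (the
source analyses do not state their threshold; this cutoff is the cited
test's own convention).

`bottleneckTest()` simulates each locus at mutation–drift equilibrium
under SMM or TPM, with $\theta$ calibrated by bisection so the expected
allele count matches the observed one, keeping replicates that match the
observed count exactly (falling back to ±1 when matches are scarce). The
TPM defaults are 80% single-step mutations with multi-step variance 20 —
the midpoints of the commonly configured 70–90% / 10–30 ranges. A
one-tailed Wilcoxon signed-rank across loci tests excess (bottleneck) and
deficiency (expansion) separately; both one-tailed uses are exposed
because both readings occur in practice.

## Median-joining network

`medianJoiningNetwork()` collapses the alignment to distinct haplotypes,
builds the $\varepsilon$-relaxed minimum spanning network (links whose
weight is within $\varepsilon$ of the minimax path bottleneck), adds
median (per-site majority) vectors of linked triples whenever the median
shortens the minimum spanning tree of the node set, and finally prunes
median vectors that are no longer branching points. $\varepsilon = 0$ is
the default (the usual software default); tie-breaks among equal-cost
medians are lexicographic on the sequence for reproducibility. With
tree-like data and $\varepsilon = 0$ the output is the unique MST. Edge
`positions` are 1-based coordinates in the supplied alignment.

# The coalescent simulator and ABC

## Divergence scenarios

Four scenarios share one topology: an ancestral population of size
$N_{anc}$ splits $t$ generations ago into Atlantic-like and
Mediterranean-like populations with post-split sizes $Nb$, which switch
to the present sizes $N$ at time $t_1 < t$. Scenario 1 has no size change,
scenario 2 changes only MED, 3 only ATL, 4 both. Default priors:
$N_{ATL}$ 10–2×10⁶, $N_{MED}$ 10–5×10⁵, $t$ 1–7×10⁴, $t_1$ 1–2×10⁴
(conditioned $t_1 < t$ by redrawing $t_1$ given $t$, so the marginal of
$t$ stays uniform), $Nb$ 1–4×10⁴; microsatellite mean rate 1×10⁻⁶–5×10⁻⁴
per generation (per-locus rates Gamma with shape 2 around the mean,
clamped to [10⁻⁸, 10⁻²]), mtDNA rate 1×10⁻⁹–8×10⁻⁸ per site per
generation. $N_{anc}$ has no published prior; it defaults to sharing the
$N_{ATL}$ prior and is exposed independently.

The engine is a continuous-time backward coalescent with
piecewise-constant sizes (exact exponential waiting times — identical in
distribution to generation-by-generation drift but desk-fast).
Microsatellites mutate by ±1 steps (strict SMM by default, TPM optional)
with allele codes reflected into [50, 300]; mtDNA evolves under K2P with
ts:tv ratio 2 on a haploid genealogy whose effective size is the nuclear
size divided by 4 (maternal haploid scaling; the source is silent, this
is the standard choice).

## Summary statistics

A fixed, ordered 18-component vector (see `summaryStatNames()`): per
population the mean allele number, mean unbiased $H_E$, mean allele-size
variance, haplotype number, haplotype diversity, mean pairwise
differences and Tajima's $D$; between populations the Weir–Cockerham
$F_{ST}$, $\Phi_{ST}$, a shared-allele distance
$1 - \frac{1}{L}\sum_\ell\sum_a \min(p_{1a}, p_{2a})$ and the shared
haplotype count. Undefined components are `NA` and are masked (carry no
distance) after standardization. The exact statistic list used by the
original GUI pipeline is not published in the main text; this set follows
the cited recommendations and is configurable via `useStats`. By default
Tajima's $D$, the shared-allele distance and the shared-haplotype count
are held out of the ABC distance and reserved for the posterior-
predictive model check (`defaultHoldoutStats()`).

The fast C++ path computes the same vector as the R path
(`summaryStatistics()`); their agreement on complete data is asserted by
a test, and the R path additionally handles missing genotype calls by
per-locus exclusion.

## Model choice, posteriors, confidence, model check

`abcModelChoice()` standardizes statistics by the reference-table mean/sd
(median-absolute-deviation scaling was considered and rejected for
simplicity), retains the closest fraction (default 1%), and fits a
multinomial logistic regression of scenario on the centred summaries,
evaluated at the observed point; bootstrap CIs are optional.
`abcParameterPosterior()` performs local-linear regression adjustment on
parameters logit-transformed to their prior bounds with Epanechnikov
weights, so adjusted draws cannot leave the support; the mode comes from
a weighted Gaussian KDE with a Silverman bandwidth computed from the
weighted sd and effective sample size on the transformed scale. A
singular regression falls back to rejection with a warning.
`abcConfidence()` classifies pseudo-observed datasets from every scenario
and reports type I/II error rates for a focal scenario;
`abcModelCheck()` simulates from the weighted rejection posterior and
reports lower-tail posterior-predictive probabilities for the held-out
statistics plus PCA overlay coordinates. Years before present are
generations × 9 (the species' generation time, treated as a
configuration constant).

Desk-scale reproduction: the original analysis used 6×10⁶ simulations;
the package's tests use 5×10⁴ rows per scenario with the published
sampling design (85 + 97 diploids, 48 + 66 sequences of 613 bp) and
validate *properties* — self-classification of strong-size-change pods
and near-nominal credible-interval coverage — not the published posterior
numbers, which are not claimed at this scale.

# Power analysis

`powsimPower()` drifts base allele frequencies independently per locality
for $t$ generations (multinomial resampling of $2N_e$ gene copies),
samples the design's gene counts, and tests global allele-frequency
heterogeneity. The per-locus conditional null is generated by random
tables with fixed margins; the default global test refers the *summed*
per-locus $G$ to its own conditional null, which makes the test size
exact — combining the discrete per-locus p-values by Fisher's method
(also available) is badly conservative (measured size ≈ 0.005 at
$\alpha = 0.05$), which would defeat the calibration property the power
analysis is supposed to have. The drift level is set through
$F_{ST} = 1 - (1 - \frac{1}{2N_e})^t$; with $N_e = 3000$ a target of
0.0028 needs $t = 17$ generations.

# The synthetic study mimic

`generateStudyLikeDataset()` produces a six-locality dataset with known
truth:

* **mtDNA** is an explicit haplotype design, not a coalescent draw, so
  the network and diversity targets are construction-guaranteed (a
  coalescent mtDNA sample is available through `simulateScenario()`).
  Ten haplotypes over 11 variable sites (9 transitions, 2 transversions)
  form two haplogroups separated by a single A↔G transition at alignment
  position 91; per-locality counts reproduce the published per-locality
  haplotype diversities (e.g. (6,3,1) at MAR2 → 0.600, (46,2,1) at ROC →
  0.119) and the northern (MAR1/ROC) versus southern (MAR2/MAR3)
  substructure. The Mediterranean dominant haplotype carries 74% of the
  basin sample as published; the realized Atlantic dominant fraction is
  0.73 rather than the published 0.82 because the per-locality diversity
  targets take precedence (the published 82% counts extra reference
  sequences); the homogeneous-Atlantic variant uses 0.82 directly.
* **Nuclear genotypes** come from the two-population coalescent with
  both basins at $N = 5000$ and the split time calibrated so the realized
  between-basin $F_{ST}$ lands within ±30% of the 0.02 target (up to six
  proportional adjustments of $t$; failure raises an error). Per-locus
  $\theta$ spans 0.08–100, giving the wide published polymorphism range
  (2–35 alleles). Localities are random partitions of their basin's
  panmictic sample, so within-basin structure is zero by construction;
  1% of calls are set missing (the publication reports < 2%).

What the mimic does *not* emulate: linkage, null alleles, genotyping
error, selection at individual loci, geographic clines within basins, and
real mtDNA genealogical noise. Passing tests on the mimic therefore
demonstrate the statistical machinery, not robustness to those artefacts.
One power limit is worth noting: at the designed basin-level
$F_{ST} = 0.02$, the smallest locality (MAR2, n = 13) has little pairwise
power, so its cross-basin tests hover near $p \approx 0.05$; the
pairwise-pattern checks condition on the adequately sampled localities.

# Numerical choices and degenerate inputs

* Permutation p-values use $(1 + \#\{\text{sims} \ge \text{obs}\})/(1+B)$.
* Monomorphic cells: $H_E = H_O = 0$, $R_s = 1$, HWE $p = 1$ (flagged);
  monomorphic loci contribute zero Weir–Cockerham components and are
  skipped by the bottleneck test; $S = 0$ makes the neutrality statistics
  `NA`, never zero.
* Unscored cells are absent (`NA`), not zero.
* Sites with more than two states count in $S$ but are excluded from
  the transition/transversion classification with a warning.
* Microsatellite allele codes reflect at the [50, 300] boundaries during
  simulation; genepop encoding rejects codes above 999.
* The logit transform in the ABC posterior clamps draws a relative 10⁻⁹
  inside the prior bounds before transforming.
* Stirling numbers, Ewens probabilities and table probabilities are all
  computed in log space.

# Problem sizes used by the test-suite experiments

The suite runs the full pipeline at sizes a reviewer can rerun on a
laptop: the null-calibration check uses 200 replicate datasets of 24
sequences with 99 permutations each; the ABC experiments share one
2×10⁵-row reference table (5×10⁴ rows per scenario) at the published
sampling design and evaluate 100 pseudo-observed datasets each for
classification and for coverage; the power analysis uses 150–300
replicates of the six-locality design with 200 conditional tables per
locus; the neutrality oracle comparison covers 25 random alignments with
up to 12 sequences and 10 segregating sites.

# Known limitations

* Two terminal populations only in the divergence scenarios (the
  original analysis likewise pooled to ATL = MAR2+MAR3 vs MED);
  no migration after the split, no recombination, no selection.
* The $F_{CT}$ permutation test is coarse with few localities.
* The bottleneck test conditions on the observed allele count by
  rejection; loci whose count is rarely hit at the calibrated $\theta$
  fall back to ±1 matching.
* Full-fidelity reproduction of the published pairwise tables and ABC
  posteriors requires the deposited genotypes and orders of magnitude
  more simulation than the desk-scale defaults.
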