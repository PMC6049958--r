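---
title: "Models and methods behind tetrascan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tetrascan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

tetrascan implements the population-genomic and quantitative-genetic
toolkit needed to study rapid adaptation in an autotetraploid plant
system: several well-differentiated mountain demes, a pair of closely
related lowland "railway" demes adapted to disturbed corridor habitat,
one focal admixed population, and a related diploid species as
outgroup. Every statistic operates on allele *dosages* (0–4 copies per
individual) and population allele frequencies, never on phased
haplotypes, which is what makes the tetraploid setting tractable.

This vignette explains the models, the tunable parameters, the
synthetic-data generators, and the numerical and design choices.

## Allele frequencies and polarization

`estimate_frequencies()` computes, per site and population, the
frequency of the *derived* allele. The outgroup consensus (major)
allele is taken as ancestral; sites where the outgroup panel is missing
or polymorphic with minor-allele frequency above `max_outgroup_minor`
(default 0.2) are flagged unpolarizable and excluded from polarized
statistics. A population contributes a frequency at a site only when at
least `min_individuals` (default 5) individuals are genotyped there;
genotypes below a per-individual read depth of `min_depth` (default 4)
are treated as missing at VCF import. For sites missing from the
genotype-based panel, `read_count_fallback()` accepts pooled
population read counts and uses `ALT / total`; on simulated data at
matched depth this tracks genotype-based frequencies with correlation
above 0.92, which is the regime in which the fallback is trustworthy.

Polarization is an involution: flipping the outgroup allele maps every
frequency p to 1 − p, leaves G\_ST untouched, and flips the sign
structure feeding Fay & Wu's H. This is asserted as a property test.

## Windowed scans

Windows are fixed *SNP-count* blocks (default 25 usable SNPs), not
fixed bp spans, so every window carries the same amount of information
regardless of local SNP density. Usable SNPs are polarizable sites
non-missing in every population being scanned, which keeps the three
statistics on one shared grid. Windows are disjoint by default —
disjointness keeps empirical quantiles and jackknife blocks free of
double counting — and never span scaffolds; a `stride` argument
enables sliding windows when exploratory resolution matters more than
independence. Trailing remainders are emitted flagged `short`.

Per window:

* **G\_ST** = Σ(H\_T − H\_S) / ΣH\_T, with H\_S the unweighted mean
  within-population expected heterozygosity 2p(1−p) and H\_T computed
  from the unweighted mean frequency. The ratio-of-sums aggregation
  (rather than a mean of per-site ratios) is stable at low-diversity
  sites.
* **Tajima's D** uses the classical constants evaluated at a
  window-level chromosome count n, taken as the median per-site count
  (4 × genotyped individuals); per-site counts vary with missingness
  and the median is robust to it. θ\_π applies the n/(n−1) unbiasedness
  correction per site.
* **Fay & Wu's H** is the original unnormalized θ\_π − θ\_H form with
  θ\_H = Σ2p²·n/(n−1). The unnormalized form is appropriate because
  outliers are judged against empirical genome-wide quantiles, not a
  parametric null.

All three equal independent count-based oracles (explicit chromosome
enumeration) to 1e-9 on small panels; this is the package's core
correctness guarantee.

Outlier tails are fixed by the selection-scan logic: G\_ST upper tail
(differentiation), H and Tajima's D lower tails (excess high-frequency
derived variants; scarcity of rare variants). `empirical_threshold()`
uses inverse-ECDF order statistics and strict inequality, so a
degenerate constant distribution flags nothing.

## Gene-level aggregation and selection candidates

`genewise_aggregate()` assigns each gene the directed extreme of all
windows whose first-to-last-SNP bp span intersects the gene interval
(inclusive on both ends). `least_extreme_across()` then reduces over
several population comparisons conservatively: a gene scores only as
high as its weakest comparison. Aggregation is idempotent and the
candidate sets are monotone in the outlier quantiles, both asserted as
properties. The three-way railway-selection rule —
top-5% conservative G\_ST, H outlier in *every* railway population and
in *no* mountain population, with a Tajima's D mark when all railway
populations are also D outliers — is implemented in
`railway_selection_candidates()`. The top-5% G\_ST tail is computed
after the least-extreme reduction by default; computing it per
comparison first is possible by passing per-comparison tables through
`empirical_threshold()` directly, since the order is genuinely
ambiguous.

## ABBA-BABA introgression statistics

With derived frequencies p1, p2, p3, pO for the quartet
(((P1,P2),P3),O), the frequency-weighted site patterns are
abba = (1−p1)p2p3(1−pO) and baba = p1(1−p2)p3(1−pO).

* **Patterson's D** = Σ(abba−baba)/Σ(abba+baba).
* **f\_hom** divides Σ(abba−baba) by its value with P3 substituted in
  the P2 slot: the excess allele sharing scaled by complete
  replacement from a homogeneous donor.
* **f\_d** substitutes, per site, whichever of P2/P3 has the higher
  derived frequency, which stabilizes small-window estimates. Negative
  numerators are reported as 0: the estimator is meaningful only where
  D > 0, and a region with D ≤ 0 carries no introgression signal. A
  non-positive f\_hom denominator yields NA with a warning.

An *informative SNP* is biallelic, polarizable, non-missing in all
four quartet populations, with abba+baba > 0. Standard errors come
from a delete-one-block jackknife over contiguous blocks of 1000
informative SNPs (at least 10 blocks required); 1000 is large relative
to local LD scales yet leaves tens of blocks at genome scale.

Gene-level f\_d is reported only for genes with strictly more than 25
informative SNPs (`min_informative_snps_per_gene`); the inequality is
strict, so a gene with exactly 25 is omitted. `call_candidates()`
flags genes whose f\_d exceeds `fd_multiplier` (default 3) times the
corresponding quartet's genome-wide f\_hom in *all* supplied quartets.
Because the rule scales a per-gene quantity by a genome-wide one, it
degenerates when there is no genome-wide introgression: the threshold
collapses to zero and noise would be called. The caller therefore
requires each quartet's f\_hom to be positive and, when a jackknife SD
is available, larger than `min_z` (default 2) SDs — without a positive
genome-wide scale there are no candidates to call.

## Synthetic data

The generators define the study conditions under which every claim in
the test suite is evaluated.

* `simulate_panel()` draws an ancestral frequency per site (uniform by
  default) and per-population frequencies from a Balding–Nichols beta
  law, the minimal drift model that reproduces realistic
  differentiation; dosages are binomial in the ploidy. Defaults: 20
  tetraploid individuals per ingroup population with F = 0.25 (typical
  of well-separated outcrossing demes), and a 12-individual diploid
  outgroup with F = 0.5 (a diverged sister species). An optional clade
  level (clade F = 0.2, within-clade F = 0.05) makes deme pairs such
  as the two railway populations realistically correlated. The
  `"neutral"` ancestral law draws derived counts from the 1/i
  spectrum, the condition under which Tajima's D is centred at zero.
* `apply_introgression()` works at the frequency-track level: each
  target chromosome is covered by contiguous blocks of `tract_length`
  sites (default 1000), each independently replaced with probability
  α, replaced alleles being Bernoulli draws from the donor track.
  Dosages are decomposed onto chromosomes at random so unreplaced
  sites keep their original alleles; the truth mask is exact.
  Haplotype copying is unnecessary because every downstream statistic
  is frequency-based.
* `simulate_f2()` models tetraploid bivalent meiosis without double
  reduction (each gamete gets one recombining strand from each of two
  random homolog pairs), since the mapping machinery treats markers as
  dosage regressors and never models double reduction. Adjacent
  markers recombine at r = 0.01 by default, with independent
  assortment across scaffolds. Non-bolters are recorded at the
  experiment-end cutoff with a censoring flag.
* `simulate_expression()` produces negative-binomial counts over a
  seven-population design (2 railway, 4 mountain, 1 focal; 3
  replicates each); planted genes assign the focal class the mountain
  mean, the railway mean, or their geometric mean.

What the generators do *not* emulate: linkage disequilibrium within
populations (sites are exchangeable given their frequency tracks),
selection, sequencing error, mapping bias, double reduction, and
GC-content artefacts in expression counts. Passing tests therefore
demonstrate correctness and calibration of the estimators under the
stated sampling models, not robustness to those real-data phenomena.

## BSA mapping

Single-marker regression compares three encodings of tetraploid
dosage — additive (dosage), dominant (≥1 copy), recessive (4 copies);
simplex presence and the quadruplex state are the natural tetraploid
analogues of the diploid conventions. LOD = (n/2)·log10(RSS₀/RSS₁) =
−(n/2)·log10(1−R²), the classical form without a degrees-of-freedom
adjustment; the best model is the one maximizing LOD and the p-value
is the regression F-test. Missing genotypes drop only that marker's
rows (pairwise deletion), matching per-SNP simple-marker regression;
markers genotyped in under 40% of individuals are dropped entirely.
Censored phenotypes enter at the cutoff by default (`censoring =
"exclude"` is available for sensitivity analysis).

`permutation_threshold()` reports both the maximum of per-permutation
maximum LODs over 500 phenotype permutations — an unusually
conservative bar, preserved because it is the comparable headline
quantity — and the conventional 95th percentile.
`stepwise_mlm()` performs forward selection with partial F-tests,
skips collinear markers, and reports semi-partial correlations (the
square root of the R² increment when a marker is added last) plus each
marker's single-marker percent variance explained.

## Expression classification

Counts are normalized with median-of-ratios size factors (re-derived
here; an established implementation serves as a cross-check in the
test suite). Per gene, a one-way ANOVA across the three classes
(railway, mountain, focal) is followed by Tukey's HSD with the
Tukey–Kramer adjustment for the unbalanced groups (6 railway vs 12
mountain vs 3 focal samples). A gene is DE when p(RW−MT) < 0.05;
a DE gene is mountain-like when additionally p(BGS−RW) < 0.05 and
p(BGS−MT) > 0.5, railway-like in the mirrored case, intermediate
otherwise. The p > 0.5 similarity criterion is taken verbatim as a
Tukey p-value threshold, not as an equivalence test. That choice has a
computable consequence: under exact mean equality the probability that
a Tukey pairwise p-value exceeds 0.5 is
P(√2·|t| < q\_{0.5,3,df}) ≈ 0.73 at these group sizes, so roughly a
quarter of genuinely mountain-like genes land in "intermediate" by
construction. The classifier is therefore scored on the *accuracy of
the labels it assigns* (assigned labels are almost never wrong,
because a wrong label would require a significant difference where
means are equal) and on recovering the planted mountain:railway
ratio, which is preserved because both classes lose the same fraction
to the intermediate bin.

The flowering-time correlation scan averages normalized expression per
population, excludes the focal admixed population, filters genes to
normalized counts above 10 in at least one sample and to RW–MT
differential expression at p < 0.05 (the same Tukey p, for internal
consistency), and keeps the top 1% by |Pearson r| — the top 1% of the
*filtered* set, which is what the filtering-then-ranking order
implies; population means are not log-transformed (an option exists).
The focal population's deviation from each gene's trend is scored by
`residual_outlier_p()`: residuals are *orthogonal* distances to the
major-axis (total least squares) line — which makes the p-value
rotation invariant — σ is the root mean square of included residuals
about zero, and p = 2(1 − Φ(|d|/σ)). Vertical residuals are available
as an option.

qPCR relative expression uses the efficiency-aware ratio
(1+E\_t)^(−ΔCt\_t)/(1+E\_r)^(−ΔCt\_r) with first-order (delta-method)
propagation of technical-replicate Ct variances; the propagated SD
matches Monte-Carlo propagation within 5% in the tests.

## Numerical conventions and degenerate inputs

* Deterministic output: TSV writers render doubles at 6 significant
  digits; all generators are deterministic given (configuration,
  seed), and derived seeds stay below 2³¹.
* Quantiles are inverse-ECDF order statistics (`type = 1`); outlier
  flags use strict inequalities everywhere (frequency differences,
  informative-SNP thresholds, f\_d multipliers).
* G\_ST with ΣH\_T = 0, Tajima's D with S = 0 or n < 4, H with no
  segregating polarized site, D with no informative site: all NA
  rather than 0, so downstream quantile machinery skips them.
* Ties in best-model selection resolve in the order additive,
  dominant, recessive.
* A zero residual spread in `residual_outlier_p()` (collinear included
  points, detected at 1e-10 relative tolerance) yields p = 0 for any
  off-line point, p = 1 otherwise, with a warning.

## Problem sizes used by the test suite

The acceptance-style checks run at sizes chosen to make their
statistical claims decidable while staying desk-scale: quartet
parameter recovery on 50,000-site panels (α = 0, 0.10, 0.30);
candidate calling on a 1000-gene × 100-SNP genome with 30 planted
introgressed genes over a 10% admixture background, and twenty
300-gene null genomes for the false-positive rate; QTL recovery on
twenty replicates of 300 F2s × 500 markers with 500 permutations each;
expression recovery on 600 genes with 300 planted DE genes. Oracle
equivalence runs on panels of at most 10 individuals and 50 sites,
where explicit chromosome enumeration is feasible.

## Known limitations

* Frequency-track introgression cannot represent haplotype-scale LD
  decay around tracts; f\_d profiles near tract edges are sharper than
  in real data.
* The f\_hom plug-in estimator carries a small downward bias at finite
  sample size (the denominator uses p̂3 twice), visible only when the
  drift signal is weak relative to binomial sampling noise.
* Tetraploid meiosis ignores double reduction; at realistic rates this
  slightly underestimates segregation variance near centromeres.
* The expression model draws replicates independently within classes;
  population-level expression structure within a class is not
  simulated.
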