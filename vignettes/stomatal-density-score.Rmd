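---
title: "Methods: the functional stomatal-density score and its screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the functional stomatal-density score and its screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stomatrend)
```

## The problem

Stomatal density responds to CO₂, temperature and water availability, and a
decline over the industrial era has been documented phenotypically in
herbarium material. Whether that decline has a genetic component can be
asked directly when historical and modern genomes are available: genes of
the stomatal development pathway are exceptionally well characterised, and
for many of them the knock-out effect on density is known. `stomatrend`
implements that inference chain — from annotated variants to a
per-sample density proxy and its temporal, spatial and climatic
correlates — together with a synthetic-data generator that makes every
stage testable at desk scale.

## The score

For sample $s$ the functional stomatal-density score is

$$\mathrm{score}(s) \;=\; \sum_{g \in G} e_g \, I_g(s),$$

where $G$ is the set of genes with a known density effect,
$e_g = +1$ if loss of $g$ increases density and $-1$ if it decreases it,
and $I_g(s) \in \{0,1\}$ indicates that $s$ carries at least one
alternative allele at a putatively functional SNP (effect class LOF or
non-synonymous) assigned to $g$. Multiple functional SNPs in one gene
count once; missing genotypes never count as carriage; the all-reference
sample scores 0, anchoring the score to the reference accession in which
knock-out effects are characterised. In the study composition the effect
table holds 43 genes, 24 of them with nonzero effect (14 increase, 10
decrease); the packaged fixture reproduces that composition with curated
(synthetic stand-in) gene assignments.

Temporal change is measured on geographically matched pairs:
$\Delta = \mathrm{score}(\text{modern}) - \mathrm{score}(\text{historical})$,
summarised by the mean and a two-sided Wilcoxon signed-rank test against
zero. Because score deltas are small integers, ties and zeros dominate;
we drop zero deltas, use midranks, and compute the exact null
distribution by dynamic programming whenever at most 25 nonzero deltas
remain (the exact path is cross-checked in the tests against full
$2^n$ enumeration), otherwise a tie-corrected normal approximation with
continuity correction.

The key specificity control is the effect-label permutation: the
$\pm 1$ labels are shuffled across the nonzero-effect genes (composition
preserved; genotypes untouched) and the mean $\Delta$ recomputed each
time. Since the mean $\Delta$ is linear in the effect vector, the
indicator matrix is computed once and each permutation is an inner
product. The reported rank is the number of permuted means at or below
the observed one. An independent-redraw mode exists but the
composition-preserving shuffle is the default, as it tests the
assignment of labels to genes rather than the label mix.

## Effect classification and filters

SnpEff annotation terms (with or without the `_variant` suffix) map onto
six exhaustive classes with a fixed severity order
LOF > NONSYN > SYN > UTR > INTRON > OTHER; a variant annotated with terms
of several classes takes the most severe. "Intron" is claimed by both the
INTRON and OTHER groupings in common usage; the priority order resolves
it to INTRON, the more specific class. Unknown terms fall through to
OTHER with a warning rather than an error, so vocabulary drift in
annotation tools cannot crash a run.

SNPs are assigned to a gene only when the annotation names the gene's
first or second splice isoform, and the class is read from the first
isoform whenever it is annotated — regulatory variation on minor isoforms
is deliberately excluded. Filters run in the order: sample missingness
(> 50% removed), biallelic SNPs only (multi-allelic records and indels
dropped, not decomposed), then site missingness (> 15%) and
minor-allele carrier count (< 3 carriers removed) on the reduced matrix —
sample removal changes site statistics, so the order matters and is
logged. The carrier interpretation of `mac` (samples carrying the
alternative allele, not allele copies) follows the filter's wording in
the originating analysis; an allele-count mode is available. Site-quality
metrics use strict inequalities (`DP > 22`, `FS < 0.2`,
`-2 < ReadPosRankSum < 2`); a site missing a metric fails by default
(conservative), configurably passes. Dataset intersection matches on the
strict (chrom, pos, ref, alt) key; allele-swapped sites are excluded and
counted rather than harmonised, since a swap in like-processed datasets
indicates an upstream inconsistency.

## Control genes and empirical tests

Per-gene statistics scale with gene length through SNP counts, so every
focus gene is compared against genes of matched length: eligible controls
lie within ±2.5% of the focus gene's genomic span (span, not summed exon
length, because SNP assignment is also span-based), excluding all focus
genes. Within one draw each focus gene picks one control uniformly and
independently; duplicates across focus genes are allowed by default (a
no-duplicates mode exists). Group tests compare the focus-set mean with
1,000 control-set means; the empirical $P$ is the fraction of control
means at least as extreme, ties counting as extreme and no $+1$
smoothing — an outlier beyond every control yields an exact 0, which is a
legitimate resolution statement at 1,000 draws. Per-gene outliers are
flagged when the gene statistic reaches the 10th/90th percentile
(linear-interpolation convention, `quantile` type 7) of its own control
distribution.

## Population-genetic statistics

Per-site diversity is $\pi = c_{\mathrm{ref}} c_{\mathrm{alt}} /
\binom{n}{2}$ over called allele copies ($n$ = 2 × called samples; for
fully homozygous selfing data this differs from a haploid count only
through the $n/(n-1)$ factor, pinned down by the oracle tests). Genes are
summarised both by the maximum per-site $\pi$ and by $\pi$/bp (sum over
sites ÷ gene length, SNP-free positions invariant) — which of the two a
given figure of the originating analysis used is ambiguous, so both are
always reported. Watterson's $\theta$/bp is $S/(a_1 L)$. Tajima's $D$
uses non-overlapping 100-bp windows anchored at coordinate 1 (window size
is the only decomposition parameter the originating analysis states);
windows without segregating sites are undefined, genes average the $D$ of
their SNPs' windows (SNP-weighted), and $n < 4$ chromosomes is refused
because the variance constants are unstable. $F_{ST}$ is the
Weir–Cockerham (1984) estimator from diploid variance components;
negative per-SNP estimates are retained (truncation would bias the gene
mean upward), and the gene value is the mean of per-SNP ratio estimates,
not a ratio of sums, matching a per-gene-mean reporting convention.
Population schemes are pluggable label vectors; the temporal scheme
simply uses epoch as a two-population scheme. Climate- or
life-history-based schemes are built by k-means on standardised features
with $k \in 2..15$ selected by mean silhouette width and a single final
run at the chosen $k$ (no restarts, deliberately, matching a
single-clustering protocol; the seed is recorded).

## Pairing and climate

Pairing is greedy and sequential, not globally optimal: each historical
sample (in ascending-id order by default; by-year and seeded-random
policies exist, and the order genuinely changes results, so it is always
recorded) takes the nearest remaining modern sample on the WGS84
ellipsoid (Vincenty inverse; Karney fallback for near-antipodal
non-convergence). Formed pairs are then dropped — not re-pooled — when
farther than 500 km, when the modern year does not postdate the
historical one, or when region tags differ (island/mainland and similar
exclusions are data-driven tags, not hard-coded geography).

Climate series are monthly values per location, 1958–2017-style.
Temperature is annualised as the hottest month's value; precipitation is
seasonally decomposed (additive, period 12) and the trend component —
a centred 12-month moving average whose undefined half-window endpoints
are dropped, not padded — is averaged within years. Direction comes from
the OLS slope, significance from a two-sided Spearman correlation
(direction from the slope sign, not the test), BH-corrected within each
variable separately (the two variables feed separate downstream
analyses), significant at adjusted $P < 0.01$. A pair matches only when
both locations are significant in the same direction; everything else —
including one-sided significance and opposing directions — is unmatched.

## The synthetic study

The generator emulates the study inputs at desk scale. Defaults, chosen
once: 48 historical (years 1817–2002) and 96 modern (1992–2012) samples
uniform over a European-like box (35–63° N, −10–30° E); 43 focus genes
(24 effect genes, 14/10 split) of 800–4,000 bp and a 200-gene control
pool whose lengths are drawn within ±2% of focus lengths so ±2.5%
matching is always feasible; ~6 background SNPs per kb-scale gene with a
realistic class mixture, focus genes at half that background rate
(emulating purifying-selection depletion, so the constraint screen has a
signal), and 3 guaranteed functional SNPs per effect gene at base
alternative-allele frequency 0.15 — low enough that the per-gene
indicator does not saturate and the score stays informative. The
functional-allele frequency follows
$\mathrm{logit}^{-1}(\beta_0 + 0.06\,(\mathrm{lat}-\bar{\mathrm{lat}})
- e_g\,\delta\,[\text{modern}])$ with $\delta = 0.8$: a coordinated
density-decrease shift whose per-gene indicator displacement (~0.15) is
large enough for single-cohort recovery yet leaves per-pair deltas in the
single digits. Genotypes are homozygous (selfing) by default with a
configurable heterozygosity rate to exercise the dosage switch. Climate
is seasonal sinusoid + linear trend + AR(1) noise; true slopes are drawn
per location at SD 0.15 mm/yr (precipitation) and 0.05 °C/yr
(temperature), scales at which most locations reach significance over 60
years with both directions well represented — which the counterfactual
split needs. Ground truth is always emitted next to the data.

What the generator does *not* emulate: linkage between sites, coalescent
genealogies, mutation-model realism, population structure beyond the
single latitudinal cline, ascertainment differences between historical
and modern calling, or spatially correlated climate fields. Passing
tests therefore demonstrate correctness of the estimators and the
inference machinery under the stated generative model — not that real
herbarium data would yield the same effect sizes.

## Numerical choices and degenerate inputs

Empty filter results are statuses, not errors; a gene without SNPs
contributes zero counts and $(0, 0)$ diversity; constant climate series
yield an undefined correlation and direction "none"; an all-zero delta
vector leaves the signed-rank $P$ undefined rather than 1; a Fisher
table with a zero margin reports $P = 1$ with an undefined odds ratio;
the conditional-MLE odds ratio (the convention of `fisher.test`) is used
throughout. Exact-vs-approximate switches (signed-rank at 25 nonzero
deltas) and all seeds are part of the function signatures, and every
stochastic component is reproducible from a single seed.

## Problem sizes used in the checks

The packaged tests run the estimator oracles on 50 random 10-sample ×
20-site matrices; pairing properties on a 500-sample cohort; permutation
calibration on 200 null cohorts of 16+16 samples and 10 genes with 100
permutations each; recovery on 50 replicates of the default 48+96
cohort; and control-draw fidelity on 1,000 draws of 43 genes. These
sizes keep a full run in the minutes range on one CPU while leaving each
check statistically meaningful; they are stated here so that anyone
scaling the generator up knows which knobs were held where.

## Known limitations

The score treats all functional variants as equally and fully penetrant,
ignores heterozygous dosage by default (a dosage-weighted mode exists),
and inherits any annotation errors from the effect classification. The
greedy pairing is order-dependent by construction. Empirical $P$ values
are bounded below by 1/number-of-draws. The k-means scheme assumes
complete features and spherical clusters after standardisation. The
counterfactual climate split conditions on significance and therefore on
series length and noise level. In the default synthetic study the epoch
shift raises carriage in the decrease genes of the modern cohort towards
saturation, which flattens — and can flip — the modern-set latitude
correlation while the historical one stays positive; the unsigned cline
acts on all functional variants, so the score's latitudinal signal rests
only on the 14/10 imbalance of effect signs.
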