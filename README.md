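# stomatrend

Temporal genomics of stomatal development genes: from effect-annotated
variants in historical (herbarium) and modern plant genome cohorts to a
predicted direction of stomatal-density change.

Stomata — the epidermal pores plants use for gas exchange — are expected to
decline in density as atmospheric CO₂ rises, and herbarium collections
preserve a genomic record of the past two centuries in which to look for a
genetic component of that decline. `stomatrend` implements the full analysis
chain for this question in *Arabidopsis thaliana*-style data:

1. **Variant handling** — read SnpEff-annotated VCFs, classify effects into
   LOF / non-synonymous / synonymous / UTR / intron / other with a fixed
   severity order, apply site-quality (`DP > 22`, `FS < 0.2`,
   `|ReadPosRankSum| < 2`), carrier-count (`mac ≥ 3`) and missingness
   filters, and intersect datasets to shared SNPs.
2. **Constraint and adaptation screens** — per-gene π, SNPs/bp, Watterson's
   θ, windowed Tajima's *D* and Weir–Cockerham *F*<sub>ST</sub>, each
   compared against 1,000 length-matched (±2.5%) control gene sets with
   empirical outlier tests (group means and per-gene decile flags).
3. **Sample pairing** — greedy nearest-neighbour matching of historical to
   modern samples on WGS84 Vincenty geodesics, with a 500-km radius,
   chronological-order and region-exclusion rules.
4. **Climate trends** — per-location monthly series are annualised (month
   of maximum temperature; seasonally decomposed precipitation), tested by
   OLS slope + Spearman correlation, BH-corrected, and pairs classified by
   matching significant direction.
5. **The functional stomatal-density score** — per sample,

   score = Σ₍g₎ e_g · I_g,

   summing over the 24 genes with a known density effect, where
   e_g ∈ {+1, −1} encodes whether loss of gene *g* increases or decreases
   stomatal density and I_g indicates carriage of any putatively functional
   (LOF or non-synonymous) variant in *g*. Per-pair
   Δscore = score(modern) − score(historical) is tested by an exact
   signed-rank test, an effect-label permutation null, Fisher's exact odds
   under climate splits, and latitude correlations with modern
   subsampling.
6. **Synthetic data** — a generator emulating all inputs (annotated VCF,
   GFF3, gene-effect table, sample metadata, monthly climate) with a
   latitudinal allele-frequency cline, an epoch shift concentrated in
   effect genes, and seasonal climate with linear trends, so the whole
   pipeline is testable without any external download.

The packaged gene-effect table
(`inst/extdata/stomatal_gene_effects_synthetic.tsv`) is a curated
*synthetic* stand-in with the study composition: 43 stomatal-development
genes, 24 with density effects (14 loss-increases, 10 loss-decreases).

## Worked example

```r
library(stomatrend)

cfg   <- pipeline_config(synth = synth_config(seed = 1))
state <- run_pipeline(cfg)
str(state$report[c("n_pairs", "mean_delta", "wilcoxon_p",
                   "permutation_rank")])
#> List of 4
#>  $ n_pairs         : int 46
#>  $ mean_delta      : num -4.8
#>  $ wilcoxon_p      : num 3.35e-08
#>  $ permutation_rank: int 0
```

Read: of the 48 historical samples, 46 found a modern partner within
500 km. Because the default generator injects a coordinated
density-decrease shift into the modern cohort, the mean per-pair score
change is clearly negative (−4.8), the signed-rank test rejects a
symmetric-change null, and none of 100 effect-label permutations produces
a mean Δscore as low as the observed one (rank 0) — the decrease is tied
to the true gene–effect assignment, not to dataset structure. The
constraint screen on the same run
(`state$report$group_empirical_p$modern$pi_per_bp`) returns an empirical
*P* of 0: focus-gene diversity sits below all 1,000 length-matched
control-set means, emulating a purifying-selection signal.

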