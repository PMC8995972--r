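---
title: "Methods: simulation, mixed-model association and post-GWAS analysis in duckgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, mixed-model association and post-GWAS analysis in duckgwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duckgwas)
```

duckgwas implements a complete association workflow for egg-production
traits in a small, deeply sequenced duck cohort: a calibrated synthetic
genotype/phenotype generator, VCF input with site-level quality control,
kinship and REML variance components, a Wald association scan,
Bonferroni/empirical-FDR correction with inflation diagnostics, LD-based
confidence-interval delineation, haplotype-sharing group tests, and a
bootstrap test of regional reliability. This vignette records the methods
and the design decisions behind them, in the order data flows through the
pipeline.

## The synthetic cohort: what it emulates and what it does not

The generator's role is to provide inputs with the statistical features
the downstream methods depend on — realistic allele-frequency spectra,
linkage disequilibrium that decays with distance, block-like haplotype
structure with a long-tailed haplotype frequency spectrum, family-like
relatedness, and three correlated quantitative traits with known SNP
heritabilities — at desk scale (hundreds of individuals, thousands of
sites), rather than the millions of markers of a real sequencing panel.

### Genotypes: founder mosaics with ancestral LD

Each chromosome of each individual is a mosaic of a pool of
`n_founder_haplotypes` founder haplotypes: crossover points are placed by
a Poisson process at `recomb_rate_per_bp` and each segment copies a
founder drawn with fixed weights. Two structural choices matter:

* **Founder-level ("ancestral") LD.** Founder alleles are generated by
  thresholding a latent Gaussian AR(1) process along the chromosome
  (correlation `exp(-d / founder_ld_scale_bp)`, default scale 1 Mb) at
  per-site quantiles drawn from `Beta(maf_beta_params)`. Without this,
  founder alleles would be independent across sites and pairwise r²
  would be bounded near 1/K regardless of distance — no LD blocks, and
  the confidence-interval stage would degenerate to single SNPs. With
  it, r² decays smoothly from ~0.3 between adjacent sites (10 kb apart)
  to ~0.05 at 1 Mb, and delineated intervals come out in the
  0.1–2 Mb range typical of real regional associations.
* **Skewed founder weights.** Copying weights default to `w_k ∝ 1/k`, so
  a few founder haplotypes are common and many are rare. Within a
  confidence interval this produces exactly the sharing structure the
  haplotype stage looks for: a handful of high-frequency shared
  haplotypes above the 5% threshold and a heterogeneous "chaotic" tail.
  Uniform weights (available as an option) make every haplotype rare at
  the default pool size and sharing disappears.

The defaults — 166 individuals, two 10-Mb mock chromosomes named "25"
and "29" with 1,000 sites each, 100 founders, recombination 5×10⁻⁸ per
bp — are sized to the study cohort. One hundred founders keeps the
relatedness structure rich enough for variance-component estimation to
be well conditioned (with very few founders the kinship matrix is
effectively low-rank and REML estimates become erratic), while the
recombination rate sits in the range reported for avian
*micro*chromosomes, which recombine several-fold above the ~1 cM/Mb
genome average; both named mock chromosomes are microchromosomes.
Monomorphic sites are re-polymorphized by a single allele flip so every
emitted site is usable, and an optional per-cell `missing_rate`
exercises the QC path.

Planted causal loci (`causal_loci`) are always included as sites and are
given intermediate allele frequencies (uniform on 0.2–0.8): a locus
forced to explain a fixed variance fraction at extreme MAF would imply an
implausibly large per-allele effect, and could not survive the MAF filter
to be discoverable at all.

### Phenotypes: exact-moment construction

Each trait is built as *causal + polygenic + residual*. The phenotypic
correlation targets `C` are split into a genetic part `G = D C D`,
`D = diag(√h²)`, and a residual part `R = C − G`; both are checked for
positive semi-definiteness and an informative error names the offending
matrix when the targets are infeasible. Only phenotypic correlations are
specified by the study design, so sharing the correlation pattern between
the genetic and residual parts is a modeling choice, made explicit here.
When causal loci consume part of a trait's heritability the polygenic
part is rescaled (`Dg = diag(√(h² − causal share))`, keeping `Dg C Dg`
positive semi-definite by construction) and the residual absorbs the
difference, so total phenotypic covariance still hits `C`.

Components are constructed with **exact sample moments**, in the spirit
of `MASS::mvrnorm(empirical = TRUE)`: the polygenic scores (centred
dosages times random per-site effects) are residualized against the
causal components and recoloured so their sample covariance equals the
target exactly, and the residual is likewise orthogonalized and
recoloured. Consequently every replicate has realized heritabilities,
trait correlations, means and SDs exactly on target (the defaults encode
the study's estimates: h² = 0.15/0.20/0.22, correlations −0.73/−0.34/
0.59, AFE 136.95 ± 13.93 days, EP43w 151.27 ± 12.59 and EP66w
268.96 ± 24.37 eggs), while the *direction* of the polygenic effects
remains random. What stays genuinely stochastic — and is what the
calibration experiments measure — is how well REML re-estimates those
quantities through the kinship matrix, and how the association scan,
CI delineation and haplotype tests behave across seeds. Egg counts are
kept continuous by default (`round_counts = FALSE`) because the mixed
model treats them as Gaussian; rounding is available but makes the
calibration targets approximate.

What the generator does **not** emulate: sequencing error and genotype
uncertainty, selection and demography of a real breeding line,
non-Gaussian trait distributions, shared environment, and genome-scale
marker density. Passing tests therefore demonstrate correctness and
calibration of the *methods* under a faithful architecture, not
performance guarantees on any particular real dataset.

## Quality control

`filter_sites()` applies the study's marker criteria literally: biallelic
SNPs only, MAF strictly greater than 0.05 (a site at exactly 0.05 is
removed), missing fraction strictly below 0.1, with MAF computed on
non-missing calls. Optional site-quality thresholds (QUAL ≥ 30, QD ≥ 2,
MQ ≥ 40, FS ≤ 60) act only when the VCF carried those fields. "Only two
genotypes" in the study's criteria is read as "biallelic site"; the
alternative reading ("at least two genotype classes observed") coincides
with it on simulated data. Each removed site is tallied under the first
filter it violates so the report's counts sum to the input count.
Filtering is idempotent.

## Kinship and the mixed model

`compute_kinship()` uses the centred relatedness matrix
`K = (1/m) Σ (x_i − 2p̂_i)(x_i − 2p̂_i)ᵀ` — the convention of the standard
mixed-model GWAS tools (centred rather than MAF-standardized; the choice
is tagged on the object). Missing dosages are mean-imputed per site, here
and in the scan. The eigendecomposition is cached because every REML fit
and scan reuses it. No leave-one-chromosome-out kinship is used.

`fit_null_lmm()` maximizes the restricted likelihood over
`log₁₀λ ∈ [−5, 5]` (grid step 0.1, then `optimize()` in the bracketing
interval), with fixed effects and the residual variance profiled out in
closed form on the eigenbasis. Eigenvalues are trace-normalized to mean
1, making pve = λ̂/(λ̂+1) directly interpretable as SNP heritability.
Two numerical guards: a *flat* restricted likelihood (range < 10⁻⁶, as
with `K = I`, where λ is unidentifiable) is reported at the lower search
edge with `boundary = TRUE` and a warning, and any estimate within half a
decade of the search edge is likewise flagged.

As printed, the source model's error term would share the factor λτ⁻¹
with the polygenic term, which would leave λ unidentifiable; the
implementation uses the standard formulation ε ~ MVN(0, τ⁻¹Iₙ),
consistent with defining λ as the ratio between the polygenic and
residual variances.

`wald_scan()` tests each site by generalized least squares under
`λ̂K + I` with λ̂ held fixed from the null fit (score-test-like, one
eigendecomposition for the whole scan); `per_snp_lambda = TRUE`
re-optimizes λ under each site's alternative model for closer agreement
with exact per-marker REML at ~m times the cost. The Wald statistic uses
the t distribution with n − c − 1 degrees of freedom, so with λ = 0 the
scan reproduces ordinary least-squares t tests exactly — one of the
package's oracle cross-checks. Monomorphic sites are emitted with p = 1
and a flag rather than dropped, keeping record counts stable.

## Multiple testing and diagnostics

`empirical_fdr()` computes `q_i = p_i · m / rank(p_i)` with ranks by
ascending p (ties broken by genomic position for determinism), enforces
monotonicity by the step-up clamp and caps at 1 — with `m = length(p)`
this is exactly Benjamini–Hochberg, verified against `p.adjust()` in the
tests. The marker scope `m` is a parameter because the study applied the
correction chromosome-wide in places; `add_qvalues()` exposes genome and
per-chromosome scopes. No attempt is made to estimate the null
proportion π₀ (the formula fixes the numerator at m).

`inflation_qq()` reports the median-based genomic inflation factor
(median of the χ²₁ quantile transform over 0.4549364) and sorted
observed/expected −log₁₀p pairs. Zero p-values are clipped to the
smallest positive double with a warning.

## Confidence intervals by LD

`delineate_ci()` takes a window of total width `window_bp` (default 3 Mb,
read as ±1.5 Mb around the top SNP), computes r² between the top SNP and
every windowed site, and returns the span of sites with r² ≥ 0.4
(threshold configurable). r² is the squared Pearson correlation of
dosage vectors over pairwise-complete observations — composite
genotype-based LD, the default of the common command-line tools —
rather than haplotype D′-based measures. The interval's endpoints are
member positions, not window edges, so a tightly linked block yields a
sub-window interval. Raising the threshold can only narrow the interval;
an isolated top SNP collapses the interval to itself with a warning and
a flag. Members can additionally be masked by a significance threshold
(`p_max`) since regional reporting sometimes restricts to significant
linked sites; LD-only membership is the default.

## Haplotype sharing

`phase_window()` collects the two haplotype strings per individual at the
interval's loci — a pass-through when genotypes are phased, otherwise an
Excoffier–Slatkin EM over the multinomial haplotype-pair likelihood
(uniform initialization plus seeded random restarts, maximum-posterior
pair assignment, individuals with missing window genotypes excluded and
counted). The window is capped at 25 loci and enumeration at 16
heterozygous loci per individual; wider intervals are first thinned to
loci with r² > 0.8 to the top SNP, mirroring how the original analysis
handled a 318-locus interval.

`group_haplotypes()` collapses identical strings; strings carried by at
least `share_min_fraction` (default 5%) of sequences become named shared
groups in descending frequency, the rest pool into one chaotic group.
The source analyses never state a numeric sharing definition, so the 5%
default is this package's choice, pinned by fixture tests rather than by
published numbers. Each sequence carries its owner's phenotype, so an
individual homozygous for a shared haplotype contributes its phenotype
twice — reproducing (not correcting) the non-independence inherent in
published sequence counts of roughly twice the cohort size. Group means
are per-sequence means for the same reason.

`compare_groups()` runs a two-sided Welch t test by default (the test
variant in the source is unspecified; Welch is the robust choice, pooled
variance available by flag), supports merging several shared groups on
one side — as in the published merged-haplotypes comparison — and
comparing against the pooled remainder (`b = "rest"`). The pipeline
reports both the direct shared-vs-chaotic comparisons and a
shared-vs-rest scan; its headline `best_p` is the scan minimum, which is
the robust choice when causal carriers split across two shared groups.

## Bootstrap reliability

`bootstrap_gwas()` draws individuals with replacement B times (default
1,000; the all-replicate index matrix is drawn up front from the seed, so
reports are fully reproducible), and per replicate recomputes the kinship
matrix on the resampled panel, refits the null model, and rescans *only
the region's sites* — sufficient for the region-signal question and what
makes B = 1,000 feasible at desk scale. The significance threshold
defaults to the largest p-value among the region's originally
FDR-significant SNPs, matching how the published thresholds relate to
the reported tables, with a manual override; when nothing in the region
is significant the pipeline falls back to the region's top p-value so
the resampling question ("does this signal strength recur?") remains
well-posed. Replicates with a constant resampled trait are skipped and
counted, never silently dropped.

The decision rule is reproduced exactly as published: the regional
signal is called *reliable* when more than 95% of replicates show **no**
significant signal. This direction is the inverse of conventional
bootstrap support (where retaining the signal in most replicates would
indicate robustness); the report exposes both counts so either reading
can be applied, and the package deliberately does not guess at the
intended interpretation.

## Pipeline, determinism and problem sizes

`run_pipeline()` chains the stages (simulate/read → QC → kinship →
per-trait null fit, scan, FDR, inflation → CI → haplotype sharing →
bootstrap), writes each artifact as TSV/JSON under the output directory,
and finishes with a manifest listing parameters and MD5 checksums of
every file. Runs are byte-identical given the same configuration; plots
(ggplot2 Manhattan/Q-Q, behind a flag) are presentation-only and outside
that guarantee. Stage failures halt the run naming the stage and leave a
FAILED marker beside any partial outputs.

The validation suite sizes its experiments to the study's design points:
heritability recovery uses n = 500 with 4,000 sites over 30 replicates
per heritability value; trait-correlation calibration n = 1,000 over 20
replicates; the AFE location check n = 166 over 50 replicates; and the
end-to-end truth-recovery experiment runs the full pipeline on the
166-duck smoke design across 20 seeds, asking that the planted locus
fall inside the delineated interval and be detected by the haplotype
scan at p < 0.01 in at least 18 of them. These sizes make the whole
suite run in a couple of minutes on a single core while keeping
Monte-Carlo error well inside the stated tolerances.

## Known limitations

* Exact-moment phenotype construction means descriptive statistics of a
  single replicate match their targets exactly; studies of *sampling
  variability* of those descriptive statistics need the construction
  relaxed (a single switch point in `simulate_phenotypes()`), though
  estimator variability through the kinship (the interesting part) is
  preserved.
* λ is estimated under the null and reused across sites by default;
  strongly associated sites in small samples can see mild deflation
  relative to exact per-SNP REML (use `per_snp_lambda` when it matters).
* The proximal-contamination problem of mixed-model scans (the tested
  SNP also contributes to K) is reproduced, not solved: no LOCO option.
* The EM phaser is for short windows only (≤ 25 loci) — it replaces
  full-chromosome phasing tools by design, not in capability.
* Bootstrap thresholds derived from the observed scan make the test
  partly circular (as in the source procedure); the manual override
  exists for principled thresholds.
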