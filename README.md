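# duckgwas

Mixed-model genome-wide association for egg-production traits in laying
ducks, with the post-GWAS toolkit a small-cohort sequencing study needs:
LD-based confidence intervals around top signals, haplotype-sharing group
tests, and a bootstrap test of regional signal reliability. A calibrated
synthetic-data generator reproduces the study population's genetic
architecture so that every stage of the pipeline can be exercised and
validated without access to the original data.

The package targets quantitative geneticists working with small,
deep-sequenced cohorts (here: 166 ducks, three traits — age at first egg
AFE, and cumulative egg numbers to 43 and 66 weeks, EP43w/EP66w), where
single-marker significance is fragile and regional LD and haplotype
evidence carry much of the weight.

## The model

Association testing uses the univariate linear mixed model

    y = W α + x β + u + ε,
    u ~ MVN_n(0, λ τ⁻¹ K),   ε ~ MVN_n(0, τ⁻¹ I_n)

where `y` is a trait vector, `W` a fixed-effect design (intercept by
default), `x` the SNP dosage vector under test, `K` the centered genomic
relationship matrix computed from all panel SNPs, `λ` the ratio of
polygenic to residual variance and `τ⁻¹` the residual variance. `λ` is
estimated once under the null by REML (grid plus local refinement on
log₁₀λ, using the eigendecomposition of `K` so each candidate costs
O(n)), and each SNP is then tested with a Wald t statistic on n − c − 1
degrees of freedom under the fitted covariance `λ̂K + I`. SNP
heritability is reported as pve = λ̂/(λ̂+1) with `K` trace-normalized.

Multiple testing is handled two ways: the naïve Bonferroni threshold
`α/m`, and the rank-based empirical FDR `q_i = p_i · m / rank(p_i)`
(with the step-up monotonicity clamp this equals Benjamini–Hochberg;
the marker scope `m` can be genome-wide or chromosome-wide). Genomic
inflation `λ_gc` and Q-Q data diagnose stratification.

Around each trait's top SNP, the confidence interval (CI) is the span of
sites within a 3-Mb window whose r² with the top SNP reaches 0.4.
Haplotypes within the CI (taken from phase, or reconstructed by an
Excoffier–Slatkin EM for unphased input) are partitioned into *shared*
groups (identical strings above a frequency threshold) and a pooled
*chaotic* group, and group phenotype means are compared by Welch t tests.
Finally, the bootstrap test resamples individuals with replacement,
re-runs the regional scan B times, and reports how many replicates retain
a significant signal in the region.

## Worked example

The bundled smoke configuration simulates 166 ducks, 2,000 SNPs on two
10-Mb mock chromosomes, and one causal locus for EP43w at chromosome 25,
position 3,219,815 explaining 15% of phenotypic variance:

```r
library(duckgwas)
res <- run_pipeline(smoke_config(seed = 1), "demo_out")
print(res)
#> <result_bundle> 3 trait(s) in demo_out
#>   AFE    pve=0.075 top=29_3221597 p=0.00238 lambda_gc=0.961 CI=2050843-3625006
#>   EP43w  pve=0.202 top=25_3219815 p=0.000152 lambda_gc=0.966 CI=2991846-3922365
#>   EP66w  pve=0.117 top=29_9780104 p=0.000791 lambda_gc=0.996 CI=9597259-9893757
```

The EP43w row shows the pipeline recovering the planted architecture: the
REML fit estimates pve 0.202 against a true SNP heritability of 0.20, the
genome-wide top SNP is exactly the planted causal site 25_3219815, the
inflation factor is near 1, and the LD-delineated CI (0.93 Mb) covers the
locus. Drilling in:

```r
print(res$traits$EP43w$hapshare$grouping$groups)
#>         label                string   n pheno_mean
#> 1 haplotype 1 111111111111111111111 120   154.5832
#> 2 haplotype 2 111111111111010100101  37   152.6223
#> 3 haplotype 3 000000000000000000000  25   142.1182
#> 4     chaotic                  <NA> 150   149.8112
print(res$traits$EP43w$bootstrap)
#> <bootstrap_report> EP43w in 25:2991846-3922365 (84 sites)
#>   B = 50, p threshold = 0.000152
#>   without signal: 41, with signal: 9
#>   rule: reliable when no-signal count > 48 -> not-reliable
```

Among the 332 CI haplotype sequences, three shared haplotypes emerge; the
carriers of haplotype 3 lay ~12 fewer eggs by 43 weeks than haplotype 1
carriers — the planted effect seen through haplotype sharing (the best
shared-vs-rest Welch test here reaches p = 2.1e-04). The bootstrap report
counts the replicates in which the regional signal disappears under
resampling and applies the published decision rule; both counts are
reported so users may also read the conventional direction (many
signal-retaining replicates = support).

AFE and EP66w have no planted locus; their rows show what a purely
polygenic trait looks like at this scale: modest pve, top p-values in the
1e-3 range, and no FDR-significant region.

Every stage is also callable on its own (`simulate_genotypes`,
`read_vcf`, `filter_sites`, `compute_kinship`, `fit_null_lmm`,
`wald_scan`, `add_qvalues`, `inflation_qq`, `delineate_ci`,
`phase_window`, `group_haplotypes`, `compare_groups`, `bootstrap_gwas`),
and `inst/scripts/run_pipeline.R` wraps the pipeline for shell use with a
YAML config.

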