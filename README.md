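# halfloopr

Case/control genotype cohorts are usually analysed as if every case carried
the same disease signal. When the disease is genetically heterogeneous, a
*subset* of cases may share a pattern of differential expression across a
*subset* of variants that neither the remaining cases nor the controls
carry — a **bicluster**, or genetic subgroup. `halfloopr` implements a
complete pipeline for finding such subgroups in diploid genotype data and
exploiting them downstream, aimed at statistical geneticists working with
GWAS-style case/control cohorts (for example psychiatric-genetics
consortium data, where a replicable bipolar-disorder subgroup motivates the
design).

## The method

Genotypes at common SNPs (minor-allele frequency > 0.25) are one-hot
encoded into three binary **allele-combinations** per SNP (heterozygous,
homozygous-minor, homozygous-major). With case array `D` (M_D × N) and
control array `X` (M_X × N), the **half-loop score** of case j at column k
is

    Q[j,k] = [D←D][j,k] − [D←X][j,k],

the fraction of *other* cases sharing the cell's binary value minus the
fraction of controls sharing it. Row-scores `Σ_k Q[j,k]`, column-scores
`Σ_j Q[j,k]` and the **trace** `Q̄ = Σ_{j,k} Q[j,k]` summarise the
differential expression of the retained submatrix. Each iteration removes
the `max(1, round(γ·remaining))` cases and columns with the lowest scores
(γ = 0.5⁸ ≈ 0.004 by default); a bicluster shows up as an iteration range
where the trace exceeds its label-permutation null. Ancestry and other
continuous covariates are corrected twice over: Gaussian-kernel weights
replace the uniform sharing fractions, damping structure that is unevenly
distributed in covariate space, and the permutation null shuffles
case/control labels only within covariate bins.

Downstream, the package scores replication arms by projecting subjects onto
the bicluster's dominant SNP-wise principal component (covariate-adjusted
AUCs `A(i)`, `A′(i)` and the interval average `A̅′` against a shuffled
null), builds **bicluster-informed polygenic risk scores** (GWAS restricted
to the retained cases, greedy LD clumping at r² ≤ 0.1 within 500 kb,
p-value thresholding), converts AUCs to liability-scale R² given disease
prevalence, and tests gene-set over-representation of the retained
allele-combinations with hypergeometric and permutation statistics.

A deterministic synthetic-cohort generator (`simulate_arm()`,
`simulate_multi_arm()`) provides multi-arm cohorts with planted biclusters,
configurable inter-arm SNP overlap, ancestry covariates and BDI/BDII-style
subtype labels, so every statistical property of the pipeline can be
validated against known truth.

## Worked example

```r
library(halfloopr)

cfg <- synth_config(
  n_cases = 300, n_controls = 450, n_snps = 800, seed = 1,
  planted = list(case_fraction = 0.3, snp_fraction = 0.1, shift = 0.3),
  arms = list(list(snp_overlap = 0.85))
)
arms <- simulate_multi_arm(cfg)

ens <- null_ensemble(arms[[1]], n_trials = 32, seed = 1)
ens
#> <null_ensemble> 32 trials, peak z = 12.11 at iteration 256, overall p = 0.0303

pk <- peak_iteration(ens)          # iteration maximising the excess trace
members <- trace_members(ens$observed, pk)
length(members$J)                  # 90 retained cases, 86 of them planted

ex <- ens$iterations$trace - ens$iterations$null_mean
interval <- range(ens$iterations$iteration[ex >= 0.5 * max(ex)])
rc <- replication_curve(ens$observed, arms[[1]], arms[[2]], interval,
                        n_trials = 100, seed = 1)
rc
#> <replication_curve arm1 -> arm2> 120 iterations in [37, 266], Abar' = 0.597 (p = 0.009901)
```

The overall permutation p-value 0.0303 is the attainable minimum at 32
trials (1/33): the observed trace beats every label-shuffled trial. The
retained case set at the excess-trace peak essentially coincides with the
planted subgroup, and the subgroup's projection axis separates cases from
controls in the second arm (A̅′ = 0.597) far beyond its shuffled null
(p = 1/101). `autoplot(ens)` and `autoplot(rc)` draw the trace-z and AUC
curves; `tidy()`/`glance()` return the underlying tibbles.
`run_pipeline()` chains all stages (simulation or file input, discovery,
permutation test, replication, PRS, enrichment) from one YAML or list
configuration and writes seed-stamped TSV artifacts.

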