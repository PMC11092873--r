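---
title: "Covariate-corrected half-loop biclustering: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariate-corrected half-loop biclustering: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `halfloopr`, the
parameters that matter, the numerical and design choices that were
genuinely open, and what the synthetic test-bed does and does not
demonstrate about real data.

## The model

The object of inference is a **bicluster**: a subset 𝒥 of case-subjects
and a subset 𝒦 of allele-combination columns over which the cases in 𝒥
share a pattern of differential expression that is absent from the
controls. Genotypes at common biallelic SNPs are expanded one-hot into
three binary columns per SNP — heterozygous, homozygous-minor,
homozygous-major — so a "pattern" is a set of specific allele-combinations
shared at elevated frequency.

For case j and column k the half-loop score is

$$Q_{jk} = [D\!\leftarrow\! D]_{jk} - [D\!\leftarrow\! X]_{jk},$$

the (weighted) fraction of *other* cases whose binary value at k equals
case j's, minus the (weighted) fraction of controls whose value equals it.
"Sharing" is defined as equality of the binary value — both 1 or both 0 —
which makes $Q$ well defined at every cell and symmetric between the
presence and absence of a combination; a frequency deficit among cases is
as informative as an excess. Missing cells contribute zero and are removed
from every denominator; they never count as sharing.

The algorithm iterates: compute $Q$ on the retained case submatrix against
the full control array, form row-scores, column-scores and the trace
$\bar Q(i)$, then remove the $\max(1, \mathrm{round}(\gamma\,m))$ rows and
columns with the lowest scores. Controls are never removed. Rows and
columns belonging to a genuine bicluster survive the elimination, so a
bicluster manifests as a range of iterations where $\bar Q(i)$ exceeds its
permutation null.

Key properties exploited by the implementation:

* With uniform weights, $Q$ is a pure count statistic, so a full
  elimination run is $O\!\left(\sum_i M(i)N(i)\right)$ with incremental
  count updates (the C++ core also exploits that one-hot rows are
  one-third ones).
* The removal schedule depends only on $(M_D, N, \gamma)$, so label
  shuffles share the observed run's iteration schedule exactly — null
  traces align iteration by iteration without interpolation.

## Significance: the permutation null

The null hypothesis is that the case/control labels are independent of any
heterogeneity structure. Samples are drawn by permuting labels while
respecting proximity in covariate space: subjects are partitioned into
`n_bins` k-means clusters (default 8, fixed internal seed) on the
correction covariates, and labels are permuted within clusters, preserving
case and control counts per cluster. Per iteration the observed trace is
standardised against the null trials, $z(i)$, and assigned an add-one
empirical p-value $p(i) = (1 + \#\{\text{trials} \ge \text{obs}\})/(n+1)$.

The **overall** p-value uses the maximum of $z(i)$ over iterations as its
statistic, which controls multiplicity across the iteration index; each
trial's maximum is standardised against the other trials (leave-one-out)
so the observed and null maxima are exchangeable under H0. This was an
open choice (a trace-area statistic would also be defensible); the
max-statistic was chosen because detection is driven by the best-separated
iteration and because it reproduces the "overall p ≈ 1/#trials" behaviour
expected for a strong signal. With the default 64 trials the attainable
minimum is 1/65.

Two peak notions are deliberately distinct (`peak_iteration()`):

* **Identity** of the bicluster is estimated at the iteration maximising
  the *excess trace* $\bar Q(i) - \mathbb{E}_0[\bar Q(i)]$. The total
  differential expression above the null expectation is maximised when the
  retained submatrix matches the underlying structure: removing a
  signal-carrying row loses more excess than removing a background row,
  and on planted synthetic data the excess peak lands at the planted
  boundary.
* **Significance** uses $z(i)$. Deep into the elimination the null spread
  collapses, so $z(i)$ can keep growing after the retained set has shrunk
  to a strict subset of the structure; it is a good detector but a biased
  boundary estimator.

The near-peak plateau used for interval averages (replication, scramble
block, enrichment) is the contiguous set of iterations whose excess trace
is at least half its maximum — an algorithmic stand-in for reading a
significance plateau off the trace figure.

## Covariate correction

Two mechanisms, used together:

* **Kernel reweighting.** For each case, Gaussian-kernel weights
  $w(j,j') \propto \exp(-\|c_j - c_{j'}\|^2 / 2b^2)$ over standardised
  correction covariates replace the uniform sharing fractions (self-weight
  zero, weights renormalised over the retained, observed entries each
  iteration). Structure confined to one region of covariate space is then
  compared mostly against neighbours that share it, damping its apparent
  differential expression. The exact reweighting scheme was an open
  choice; a Gaussian kernel is the simplest faithful implementation of
  "compare against covariate-proximal subjects". Bandwidth `"auto"` is the
  median pairwise covariate distance of a deterministic subsample of at
  most 500 subjects; an empty correction set falls back to uniform
  weights.
* **Stratified shuffling**, described above, so the null respects the same
  covariate geometry.

Covariates for correction are chosen by a nested logistic model: candidates
are tested in index order (U1, U2, ...) and kept when the likelihood-ratio
test for their addition is significant at 0.05. On the synthetic
test-bed, a spurious "bicluster" induced by an ancestry cluster that is
over-represented among cases is suppressed by the kernel weights (lower
peak z than with uniform weights) — the property the correction exists
for. Discovery-stage defaults correct for U1–U2; replication and PRS
stages for U1–U6 plus U19, mirroring the common situation where the
training cohort supports fewer significant components than the combined
data.

## Replication

For iteration i, the retained columns are intersected with the replication
arm's panel, the training-case submatrix is column-centred (by the
retained-case means, stored with the axis), and its leading right-singular
vector $v(i)$ is taken (exact LAPACK SVD below ~2.6·10⁵ cells, else power
iteration with a deterministic start and 1e-12 tolerance). The sign of
$v(i)$ is fixed so the covariate-adjusted training AUC is at least 0.5.
All subjects are projected onto $v(i)$; scores are residualised on the
correction covariates by pooled least squares and compared by Mann-Whitney
AUC with ties counted one half. The interval average $\bar A'$ is tested
against label shuffles of the replication arm (one permutation per trial,
shared across iterations; residualisation is label-free, so shuffles only
permute the group split of fixed residual scores).

One empirical observation worth recording: when the retained case set is
*pure* (essentially all structure rows), the dominant PC captures
within-structure sampling noise, and replication AUCs are strongest
slightly *before* the excess peak, where the retained set still mixes
structure and background rows and the PC aligns with the between-group
contrast. The half-max plateau interval covers this regime, which is why
interval averages rather than single-iteration AUCs are reported.

## Polygenic risk scores

Summary statistics come from per-SNP logistic regression of label on
additive minor-allele dosage plus correction covariates (Wald tests;
monomorphic or non-converging SNPs dropped and counted). The
bicluster-informed statistics contrast only the retained cases 𝒥(i)
against all controls; at iteration 1 they coincide with the
population-wide statistics by construction. Clumping is the standard
greedy algorithm with the conventional parameters (r² ≤ 0.1 within 500 kb,
maf ≥ 0.05, info ≥ 0.9 when an info column exists), with r² computed from
a supplied genotype reference panel (the synthetic generator provides one;
a block-LD option exists for exercising the clump logic). Scores are
$\sum_k \beta_k \cdot \text{dosage}_{jk}$ over SNPs passing the p-value
threshold $\tilde p$; missing dosages are mean-imputed as 2·maf.

`prs_comparison(thresholds = "auto")` compares models at matched numbers
of SNPs (per-model thresholds at a fixed N_SNP grid), because the models'
p-value scales differ and the scientifically meaningful comparison is
AUC as a function of the number of SNPs used. Pooling across replication
arms residualises per arm, then ranks the pooled residuals (an open
choice; per-arm residualisation avoids absorbing between-arm offsets into
the covariate fit).

The liability-scale conversion maps AUC to the case-control score
difference in SD units, $d = \sqrt{2}\,\Phi^{-1}(\mathrm{AUC})$, to
observed-scale variance explained through the point-biserial correlation
at case fraction P, and then to the liability scale for prevalence K with
the usual case-control ascertainment adjustment. It is validated by a
round-trip simulation of the liability-threshold model (true R² = 0.10,
K = 0.01, n = 2·10⁵ recovers 0.10 within ±0.01), not by any hard-coded
constant. Default prevalences: 2% for the full phenotype, 1% for each
subtype.

## Gene-set over-representation

A gene is retained at iteration i when strictly more than half of its
originally annotated allele-combination columns survive in 𝒦(i); the gene
universe is every gene with at least one annotated column at iteration 1
(the universe choice was open; the annotation universe is the natural
conditioning set for the hypergeometric). Per pathway, the overlap count
κ(i,l) gets an upper-tail hypergeometric p-value, and κ is standardised
against the label-shuffled trials of the same ensemble; the average z̄
over an iteration interval and pathway collection gets an empirical
p-value from leave-one-out-standardised per-trial averages. Note that
label-shuffled trials retain a diluted copy of any real structure (the
planted rows are scattered over both label groups), so this null is
conservative — its right tail is heavier than an independent-data null.

## The synthetic test-bed

`simulate_arm()` draws control and background-case genotypes from
Hardy-Weinberg equilibrium at per-SNP allele frequencies uniform on
[0.25, 0.5] (the analysis targets common variants). The planted bicluster
takes an f-fraction of cases and a g-fraction of SNPs and either

* shifts the allele frequency by δ (`combo_mode = "frequency"`), giving an
  exchangeable, marginal-frequency signal — the right fixture for
  detection, calibration, recovery and replication studies; or
* plants a shared per-SNP signature genotype copied with a per-row
  coherence (`combo_mode = "signature"`, optionally two-tier via
  `core_fraction`), giving the core/adjacent row structure seen in real
  heterogeneous cohorts. Only this row-coherent structure can be destroyed
  by the within-column scramble (`scramble_submatrix()`): per-column
  permutation preserves within-block column margins exactly, so an
  exchangeable frequency-shift block is statistically invariant under it.
  The scramble experiments therefore use signature planting, and the
  scrambled block is the membership at the start of the half-max plateau
  (a large, mixed block), mirroring the practice of scrambling the largest
  near-peak submatrix.

Covariates come from a Gaussian mixture with optional case/control
imbalance across components (`confound_strength`); subtype labels default
to 65% BDI / 31% BDII with the planted subgroup's BDI probability raised
by 0.2 (enrichment, not purity, so composition curves drift rather than
jump). Multi-arm simulation shares a master panel, the planted SNPs and
per-SNP frequencies, and gives each replication arm a random subset of the
training panel at its target overlap coefficient plus private SNPs, so
replication strength degrades naturally with overlap.

### Problem sizes of the validation studies

Chosen once as desk-scale study conditions:

* oracle equivalence: 50 random instances up to 30×40, tolerance 1e-12;
* type-I calibration: 100 null cohorts of 200 cases / 300 controls / 500
  SNPs, 32 shuffles each — the fraction of overall p ≤ 0.05 must lie in
  [0.01, 0.12];
* planted recovery: f = 0.3, g = 0.1, δ = 0.3 at 400/600/1000, ten seeds;
* replication: the same planting at 300/450/800 with 80% overlap, interval
  = half-max plateau, 60-shuffle nulls; dropout degradation averaged over
  20 elimination seeds at keep fractions 0.8/0.5/0.3;
* PRS mixture: 600 cases / 300 controls / 1500 SNPs, 100 planted SNPs,
  δ = 0.18. The control-limited design and the weak per-SNP shift put the
  population-wide GWAS in the regime where its SNP ranking is noisy while
  the bicluster-restricted contrast is ~2.5× stronger per SNP — the regime
  in which concentrating the GWAS on the homogeneous subgroup pays;
* enrichment: 250/700/250 with one synthetic gene per SNP and a focus
  pathway holding the planted genes, 64 shuffles; deep column elimination
  (case and column counts decay together) so gene retention becomes
  discriminative;
* scramble: signature planting (coherence 0.35–1, 40% core) at
  200/300/500.

### What passing does and does not show

The generator has independent SNPs (no LD beyond the optional block
option), Gaussian covariates, exact HWE and clean labels. Passing the
test-bed shows the statistics are implemented correctly and calibrated
under the stated models; it does not show robustness to realistic LD
structure, genotyping batch effects, imputation artifacts, cryptic
relatedness or diagnostic misclassification, all of which real cohorts
have. The covariate correction is validated against mixture-type
confounding only.

## Numerical choices and degenerate inputs

* Ties in row/column elimination break by ascending original index, so
  traces are byte-reproducible.
* The removal count `max(1, round(γ·remaining))` guarantees termination
  below `γ·m < 1`.
* Columns with no observed controls, or with fewer than two observed
  cases, score zero (with a warning at the `compute_q` surface).
* A null trial with zero trace variance at an iteration yields z = 0 and
  is flagged rather than propagating NaN.
* `gamma` defaults to 0.5⁸ ≈ 0.0039; at desk scale this gives one row per
  iteration below 256 retained cases, and the per-iteration removal
  fraction is small enough that the trace is effectively continuous in i.
* The minor allele is designated from the sample itself when reading
  PLINK data; columns whose stored A1 is the sample-major allele are
  flipped on read.

## Known limitations

* The kernel reweighting implements the covariate correction in spirit;
  other weighting schemes (e.g. local label-proportion matching) may
  behave differently under strong confounding.
* The permutation null inherits diluted structure in every trial (see
  above); for very strong signals the empirical p saturates at its
  attainable minimum and the z-scale, not p, carries the information.
* The replication axis is a single principal component; multi-component
  extensions are out of scope.
* Gene-set results depend on the user-supplied annotation and GMT
  collections; no multiple-testing correction is applied across pathways
  (raw per-pathway p-values are reported).
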