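---
title: "Fine-scale population structure and polygenic score bias: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fine-scale population structure and polygenic score bias: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strataprs)
```

## The problem this package studies

Polygenic risk scores (PRS) are weighted sums of risk-allele dosages, with
weights taken from a discovery genome-wide association study (GWAS). When a
cohort that looks homogeneous actually contains fine-scale subpopulations —
for example a large mainland group and small insular groups separated by a
few thousandths of an Fst unit — the difference in mean PRS between the
groups need not track the difference in the observed phenotype. Genetic
drift creates real mean differences in genetic value; environment creates
mean differences in phenotype that the PRS cannot see; and residual
stratification can leak into the GWAS weights. The troubling case is a
*sign-discordant* trait: the PRS says one group should be lower while the
observed phenotype is higher, a pattern that survives even when the
subpopulation indicator is included as a GWAS covariate, because covariate
adjustment removes confounding of the per-variant effect estimates but
cannot remove a genuine environmental offset from the phenotype itself.

`strataprs` implements the full chain needed to study this quantitatively on
synthetic cohorts: cohort simulation, quality control, structure detection,
association, PRS construction, and the headline group-difference statistics.

## The group-difference statistics

For a trait, with the PRS rank-normalized within the validation group and the
phenotype rank-normalized after adjustment for sex, age and age²:

* `delta_prs` = mean(normalized PRS | non-mainland) − mean(normalized PRS | mainland)
* `delta_pheno` = the same contrast on the normalized phenotype (for binary
  traits, the prevalence difference)
* `BIAS` = |`delta_prs` − `delta_pheno`|

Both deltas are in within-cohort SD units, so a `delta_prs` of −0.5 means
the insular group's mean score sits half a standard deviation below the
mainland mean. `BIAS` measures how far the score's prediction of the group
contrast deviates from the observed contrast; across many traits it is
correlated against candidate per-trait confounders (discovery heritability,
the between-group heritability gap, variance explained by the PRS and its
between-group gap, and the number of score SNPs) with plain Pearson tests and
no multiplicity adjustment, since the scan is descriptive. Age and sex
composition differences are summarized descriptively, not tested: they are
distributions, not single numbers.

One deliberate reading is recorded here: the operands of `BIAS` are the two
*normalized-scale* deltas. The group-difference expressions are reused from
the delta definitions, and no other interpretation is computable on a common
scale.

## The cohort simulator

**Drift.** Subpopulation allele frequencies follow the Balding–Nichols
model: given a parent frequency `p` and drift coefficient `F`, the daughter
frequency is `Beta(p(1−F)/F, (1−p)(1−F)/F)`, which has mean `p` and variance
`F·p(1−p)`. Drift paths are hierarchical. Internal path steps with equal
prefixes are shared between subpopulations (a common intermediate ancestor);
the final step of each subpopulation is always its own independent draw, so
two subpopulations each declaring `fst_path = 0.01` are two independent
islands whose pairwise Hudson Fst is ≈ 0.01. An `F = 0` leaf copies its
parent exactly, which is how two labels over one panmictic population are
expressed. Frequencies are clipped to (0.001, 0.999) so no variant is
monomorphic by construction. This is deliberately the simplest model that
produces Fst-parameterized structure; there is no coalescent machinery, no
recombination map and, by default, no linkage disequilibrium (variants are
independent). Real genotype data have LD, so the pruning and clumping stages
are exercised in tests via duplicated-with-noise variants rather than by the
default simulator output.

**Traits.** A quantitative trait is
`y = Σ β_j g̃_j + covariates + env_offset[subpop] + e`, where `g̃` is the
dosage standardized by the *ancestral* frequency. Standardizing by the
ancestral rather than the subpopulation frequency is what makes drift induce
true between-group differences in genetic value — the mechanism the whole
analysis is about. Effect magnitudes are `sqrt(h2/m_causal)` so the genetic
variance is `h2` on the ancestral scale, and residual noise is `N(0, 1−h2)`.
Binary traits threshold the same liability at `Φ⁻¹(1−prevalence)` computed on
the offset-free scale, so a subpopulation offset of `d` liability SD moves
that group's prevalence to `1 − Φ(Φ⁻¹(1−prev) − d)`; the closed form is exact
when covariate effects are zero, and covariate effects inflate the liability
variance slightly otherwise (documented, accepted).

**Presets.** Three named scenarios fix the study conditions on a cohort of
1800 mainland + 600 non-mainland individuals, 2000 variants on 20
chromosomes, 20 causal variants, h² = 0.5:

* `height_like` — effect signs oriented so the non-mainland genetic mean is
  shifted *down*, plus an environmental offset of −0.3 SD in the same group:
  deltas expected sign-concordant.
* `bmi_like` — same negative genetic shift, but an environmental offset of
  +0.8 SD (a rapid environment-driven reversal, as when diet changes in one
  generation): deltas expected sign-discordant.
* `null` — both groups share the full drift path (identical frequencies), no
  offsets: deltas expected near zero.

The sign orientation is a property of the preset: the per-variant effect sign
is aligned against the realized frequency difference, which pins the
direction of the genetic contrast without changing its magnitude
distribution. Offset magnitudes are illustrative rather than calibrated to
any real cohort — the real-world genetic/environmental decomposition of such
contrasts is unknown — and were chosen once so the genetic contrast
(≈ −0.35 SD at these drift settings) is clearly dominated by the
environmental reversal in the discordant preset. Other defaults: age ~
Uniform(30, 80) years, sex ~ Bernoulli(0.5), modest sex/age covariate
effects; all configurable.

## Quality control

Variant filters mirror standard biobank practice: call rate ≥ 0.99, exact
Hardy–Weinberg p ≥ 1e-6, heterozygote count ≥ 5, MAF ≥ 0.01. The HWE test
is the exact conditional test on the heterozygote count given allele counts,
computed as a plain tail sum (no mid-p correction: conservative and directly
enumerable, which is what the test oracle does). The probabilities are
evaluated by the standard parity recurrence in log space — anchoring the
recurrence at the tail overflows a double already near n ≈ 2000 otherwise.
The test is applied cohort-wide, not within subpopulations; real structure
inflates HWE rejection (Wahlund effect), which is worth knowing when
interpreting QC counts on strongly structured cohorts.

LD pruning is the windowed `--indep-pairwise`-style procedure (50-variant
windows stepped by 5, r² > 0.2): within a window, the worst-offending pair
loses its lower-MAF member (ties: the later position), repeated until no
pair offends. The removal rule is an implementation choice — what matters,
and what is tested, is determinism and the pairwise guarantee on the
surviving set.

Relatedness uses method-of-moments IBD from IBS counts with
allele-frequency expectations, truncating the three IBD-state probabilities
to [0, 1] and renormalizing; `PI_HAT = P(IBD=2) + P(IBD=1)/2`, with pairs
above 0.125 broken greedily by dropping the individual in the most flagged
pairs. No finite-sample correction terms are applied; the duplicate,
unrelated and parent-offspring limits are recovered well within the
tolerances the tests assert.

## Structure detection and agreement

Genotypes are standardized per variant by `(g − 2p̂)/sqrt(2p̂(1−p̂))` with the
sample frequency (no posterior shrinkage — simpler and directly testable),
missing values mean-imputed after centering. PCA is the eigendecomposition
of the n×n covariance of that matrix; component signs are fixed by making
each component's largest-magnitude loading positive. t-SNE and UMAP are
*adapters* over the optional Rtsne/uwot packages — these embeddings are
established numerical methods and are deliberately not reimplemented; when
the backend package is absent the adapter raises an error naming it, and the
PCA path carries the analysis.

Cluster assignment automates what a human would do on the embedding:
k-means with 10 restarts at a fixed seed, clusters renamed by descending
size so the mainland analog is always `cluster1`. Agreement between a
clustering and reference labels is Cohen's kappa after mapping each cluster
to a reference category by majority vote; ties prefer the rarer reference
category, which favors distinct mappings (and reproduces the textbook
worked example exactly). The p-value is a one-sided large-sample normal
approximation for n ≥ 200 and otherwise a permutation test (default 10,000
permutations) in which the mapping is re-derived per permutation, so the
adaptivity of the mapping cannot bias the null.

## Association, PRS, and heritability

The discovery/validation split is stratified: within every cluster the two
halves differ by at most one individual, so both groups are represented
equally on both sides. Association is per-variant OLS (quantitative) or
IRLS logistic regression (binary) of the trait on dosage plus covariates —
sex, age, age², a configurable number of principal components, and the
cluster indicator. The PCs are fitted on the discovery half only and
projected onto the validation half, avoiding leakage. With no missing
dosages the OLS path residualizes both sides on the covariates once and
fits all variants vectorized; this is numerically identical to per-variant
`lm` (asserted in tests to 1e-10) and is what makes 20-replicate scenario
sweeps affordable. Logistic fits flag separation and non-convergence per
variant and excluded them from scores.

PRS construction is clumping + thresholding with the conservative defaults
p < 5×10⁻⁶, 1 Mb window (endpoints inclusive), r² < 0.1: survivors are
sorted by p (ties: position, then variant id), each index variant knocks out
later variants on its chromosome within the window *and* correlated above
the r² threshold in the LD reference. The LD reference is the discovery
genotypes — the validation half stays untouched until scoring. The score is
the standard per-variant weighted allelic sum Σ β_j·dosage_j; a phrase like
"adding the dosages and multiplying the sum by the effect size" is read this
way because a single multiplier across variants with different βs is
dimensionally incoherent. Allele orientation is resolved per variant (a
score built from the flipped encoding is identical), and missing dosages are
mean-imputed from the scored group's effect-allele frequency.

Rank-inverse-normal transformation uses the Blom offset,
`Φ⁻¹((r−0.375)/(n+0.25))`, with average ranks for ties; variance explained
is the difference in adjusted R² between `phenotype ~ PRS + covariates` and
`phenotype ~ covariates`, returned as-is even when slightly negative.
Heritability, where the confounder scan needs it, comes from Haseman–Elston
regression: the products of standardized phenotypes for all sample pairs
regressed on the corresponding GRM entries, slope = ĥ². It is cheap,
unbiased under the simulator's assumptions, and recovers h² = 0.5 to within
±0.1 in the mean of ten replicates at n = 2000, m = 5000 — adequate for a
correlate in the confounder scan, though noisier than a REML fit would be.

## Numerical and design choices worth knowing

* Every stochastic stage seeds its RNG with `derive_seed(master, stage_tag)`,
  so inserting a stage never perturbs another stage's stream, and the whole
  pipeline is byte-reproducible from one master seed.
* One shared split serves every trait in a phenome scan; trait-level
  failures (all-missing trait, degenerate fits) are caught, logged and
  skipped without aborting the scan.
* Zero-variance edge cases are defined, not fatal: r² of a constant dosage
  vector is 0 with a warning; rank-normalizing a constant vector returns
  zeros with a warning; an empty PRS model scores everyone 0.
* `delta_statistics` is antisymmetric under swapping the group labels, and
  `BIAS` recomputed from stored deltas is bit-exact — both are asserted.
* Problem sizes in the test-suite and acceptance sweeps (cohorts of 600–4000
  individuals, 600–20,000 variants, 10–20 replicates) were chosen so each
  statistical property has comfortable Monte-Carlo margin at desk scale;
  they are the package's own study conditions, stated here so results are
  read at the right n.

## What passing tests do and do not show

The simulator emulates drift-structured cohorts with independent variants,
Hardy–Weinberg genotypes, Gaussian residuals, and piecewise-constant
environmental offsets. Real cohorts add LD, assortment, ascertainment,
genotyping error, and environmental gradients that correlate with ancestry
continuously. Consequently the test suite demonstrates that the *machinery*
is correct and that the concordant/discordant mechanism behaves as designed
under its stated assumptions; it does not quantify how large PRS biases are
in any real population, and the preset magnitudes should not be quoted as
empirical estimates. The package's claim is methodological: given
fine-scale structure and group-specific environment, a PRS group contrast
can be made to disagree in sign with the phenotype contrast even with the
structure indicator included as a GWAS covariate — and the pipeline measures
exactly that.
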