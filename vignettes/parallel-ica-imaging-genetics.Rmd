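---
title: "Coupled ICA for imaging genetics: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled ICA for imaging genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Imaging-genetics studies ask which aggregates of genetic variants covary
with which features of brain structure across a cohort.  At the sample
sizes a neuroimaging study can afford (a few hundred subjects), per-SNP x
per-voxel mass-univariate testing is hopeless after multiplicity
correction.  Parallel ICA replaces it with a pair of matrix
decompositions.  Each modality's subjects x features matrix is modelled
as

    X_gene  ~ A_g S_g        X_brain ~ A_b S_b

where the sources `S` (K x features) are statistically independent
patterns — a collection of interrelated SNPs, or a spatial map of gray
matter volume — and the loading coefficients `A` (subjects x K) say how
much of each pattern a subject expresses.  The "parallel" part couples
the two unmixings: alongside each modality's Infomax entropy objective,
an extra term pushes up the squared correlation between the subject
loading columns of the currently best-correlated cross-modality
component pair.  Group inference then happens on loadings, not on raw
features: partial correlations between all genetic x brain loading pairs
(controlling for age, sex, ancestry axes and diagnosis), Bonferroni
control at `alpha / (K_gene * K_brain)`, post hoc group-difference
t-tests with Levene's variance check, and exploratory clinical
correlations.

`parafuse` implements that whole chain — genotype QC, voxel-matrix
preparation, MDL order selection, coupled Infomax, leave-5%-out
stability, the loading statistics, VEGAS-style gene-based p-values and
hypergeometric pathway enrichment — together with a linked synthetic
cohort generator with known ground truth, since no deposited cohort
exists to run the chain on.  The numbered scripts under `analysis/`
execute the stages in order on the default synthetic study.

## What the generator emulates, and what it does not

`synthetic_config()` defaults encode the study conditions the package is
exercised under: 198 adolescents of whom 63 are patients, exome-chip-like
dosages, two self-reported-ancestry subpopulations, a single linked
gene-brain component pair at a loading correlation of 0.34 (the scale of
the published association table), and a 0.5 SD patient-group shift on
the linked loading columns.  Desk-scale feature counts (2000 SNPs, a
12x12x12 voxel grid, K = 4 genetic / 3 brain components) keep every
stage runnable in seconds while leaving the estimation problems
non-trivial; these sizes were fixed once when the generator was written.

Mechanics worth knowing when interpreting results:

* **Genotypes.**  A latent Gaussian field (component signal plus noise,
  mixed with a per-block shared Gaussian for exchangeable within-block
  LD) is discretised per subpopulation to {0,1,2} at Hardy-Weinberg
  genotype proportions for Balding-Nichols allele frequencies
  (`fst = 0.1`, ancestral MAF uniform on 0.05-0.5, frequencies confined
  to the declared spectrum so requested markers stay polymorphic at
  realistic n).  Quantile discretisation keeps the component signal in
  the dosages while matching marginal MAF essentially exactly; the
  stored per-SNP target MAF is the subpopulation mixture mean, which is
  the quantity the realized dosages estimate.  The `latent_mode` switch
  skips discretisation and population structure entirely and is what the
  clean fusion-recovery tests use.
* **Noise scale.**  `noise_sd_*` is expressed relative to the
  root-mean-square amplitude of the noiseless signal matrix, so 0.5
  means "noise at half the typical signal amplitude" independent of grid
  size or sparsity.
* **LD strength.**  The default within-block latent correlation of 0.3
  yields dosage r-squared well below the 0.7 pruning cap, so on default
  data windowed pruning rarely removes anything — the pruning logic is
  exercised by planted high-LD pairs in the tests.  This mirrors exome
  arrays, where r-squared > 0.7 pairs are uncommon after QC.
* **Spatial sources** are 1-3 positive Gaussian blobs (sigma
  `blob_radius_vox`, default 1 voxel), centres of distinct components at
  least 4 sigma apart.  Positive sparse sources share the grid mean, so
  distinct sources carry a small negative correlation of order
  `-(sum_1)(sum_2)/p`; the default radius keeps it below 0.1 on the
  default grid.
* **Clinical scores** are linear in the first linked brain loading plus
  noise (r about 0.4), scaled like T-scores, to exercise the post hoc
  correlation stage.

What passing tests on this generator do **not** show: registration or
segmentation robustness (the pipeline consumes already-modulated maps),
haplotype-level LD (blocks are exchangeable, no recombination gradient),
rare-variant behaviour below MAF 0.05, scanner or site effects, and any
non-linear gene-brain coupling.

## Numerical and algorithmic choices

**MDL order selection** is the Wax-Kailath criterion on the sample
covariance eigenvalues with subjects as observations, no smoothness
correction.  Two practical consequences.  First, column centring (or
features >= subjects) produces numerically null eigenvalues; the
criterion is evaluated on the numerically nonzero spectrum, otherwise
the log of a zero eigenvalue poisons every tail.  Second, the white-tail
assumption means spatially smoothed noise inflates the estimate badly
(the demo data give 58 "components" after 4 mm smoothing versus 3
before); the analysis scripts therefore estimate the order on the
unsmoothed voxel matrix and decompose the smoothed one, and the
fusion stage accepts explicit `K` overrides.

**Infomax** uses the logistic nonlinearity with the natural-gradient
update over randomised mini-batches (batch 128), initial learning rate
`0.01 / log(K + 2)`, annealed by 0.9 when the epoch-level weight-change
direction turns by more than 60 degrees and by 0.985 per epoch once
annealing has begun.  An epoch that decreases the entropy objective is
rolled back and the rate halved, so the objective is non-decreasing over
accepted epochs.  Batch permutations for all epochs are drawn up front
from the seed, which makes runs bit-reproducible and lets the coupled
run share the exact update sequence with uncoupled runs.  Convergence is
declared when the relative Frobenius change of `W` over an accepted
epoch drops below `tol` (default 1e-5); at typical sizes this takes
200-400 epochs, so `max_epochs = 500`.

**Coupling.**  With whitened data `Z = Wh (X - mu)` and dewhitening `M`,
the loading matrix is `A = M W^-1` — an analytic function of the
unmixing matrix.  The coupling step therefore does gradient ascent of
`corr^2(a_g_i, a_b_j)` directly on the two relevant columns of the
inverse unmixing matrices, for the maximal-|r| pair with
`tau_link <= |r| <= r_cap` (defaults 0.25 and 0.95; the cap stops the
coupling from collapsing within-modality independence).  The step is
relative: `lambda` times the mean relative Infomax weight change of the
current epoch, so the coupling perturbation stays an order of magnitude
below the ICA update and vanishes as the ICA converges.  Backtracking
(up to 7 halvings) guarantees each applied step strictly increases the
target corr^2.  `lambda = 0` skips the step entirely, which is the
bit-for-bit decoupling contract the tests enforce.  One pair is coupled
per epoch by default (`n_couple` raises it); component indices are
assigned after the fact by explained variance, so linked pairs are
reported in final ordering with their correlations recomputable from the
stored loadings.

**Stability** reruns the fusion on repeated random 95% subsamples
(holdout 5%, the published protocol), matches subsample sources to the
full-sample sources by optimal |correlation| assignment (Hungarian
algorithm; exhaustive enumeration cross-checks it in tests), and calls a
component stable when its mean matched |correlation| reaches `tau_stab`.
The repeat count (10), matching statistic and threshold (0.8) are not
stated in the source literature; all three are configurable and echoed
in the report, and the report exposes both the percent-stable and the
mean-correlation summaries since either could be the quantity a study
reports.

**Genotype QC.**  Exact-thresholds-unknown filters default to
field-standard exome-array values: call rate >= 0.95, MAF >= 0.01, HWE
exact p >= 1e-6 in controls only.  The HWE test is the exact conditional
test, two-sided by summing probabilities not exceeding the observed
one, no mid-p.  LD pruning is greedy within windows of 50 SNPs advanced
by 5: the worst pair above r-squared 0.7 is broken by removing the
lower-MAF member (tie: the later position).  Stratification PCA centres
each SNP by its mean dosage and scales by `sqrt(p(1-p))` with the
smoothed frequency estimate `(1 + count)/(2 + 2n)`; centring by the
smoothed estimate itself would leave coherent column means and a
spurious dominant axis.  Ancestry axes are chosen by per-axis ANOVA
against self-reported ancestry (keep up to 2 with p < 0.05, ordered by
p).  The logistic pre-filter retains SNPs with uncorrected Wald
p < 0.1; separation or non-convergence falls back to a Firth-penalised
fit and otherwise excludes the SNP with a flag.  Missing dosages use
pairwise-complete statistics during QC and per-SNP mean imputation
immediately before fusion, which requires a complete matrix.

**Smoothing** is a separable Gaussian specified by FWHM
(`sigma = FWHM / sqrt(8 ln 2)` per axis in voxel units), truncated at 4
sigma, kernel renormalised to unit mass.  Boundaries use normalised
convolution — the zero-padded result divided by the smoothed indicator
of the grid — so constants are exactly invariant and interior signals
keep their total intensity; plain zero-padding would shade every
boundary voxel of a constant image.

**Gene-based test.**  The gene statistic is the sum of 1-df chi-squares
from the per-SNP p-values; the null simulates `z ~ MVN(0, Sigma_LD)` by
eigenfactor sampling (works for singular LD matrices, e.g. perfect LD)
with `Sigma` estimated from the cohort's own dosages rather than an
external reference panel — self-contained, at the cost of estimation
noise in small cohorts.  The p-value `(1 + exceedances)/(1 + n_sims)`
never returns 0; draws escalate (doubling, to `max_sims`) while fewer
than 10 exceedances have been seen.  Two input conventions are provided,
because the source literature does not say which was used: z-scored
component weights converted to two-sided normal p-values (the default in
the workflow) or externally supplied trait p-values such as the
pre-filter's.  Enrichment is the upper-tail hypergeometric probability
with the background defaulting to all genes carrying at least one fused
SNP, and Benjamini-Hochberg q-values via the step-up rule.

## Problem sizes used by the checks

The recovery benchmark runs the coupled decomposition on latent-mode
data with n = 200 subjects, 1000 SNPs, a 12x12x12 grid, K = 4/3, one
linked pair at r = 0.6 and noise at half signal amplitude, over 5 seeds;
the stability and noise-monotonicity checks use n = 80, 250 SNPs, an
8x8x8 grid and 3-5 repeats; the null calibrations use 500 genes x 2000
Monte-Carlo draws and 2000 SNPs x 500 subjects for the pre-filter.
These sizes were chosen to make each property measurable with
comfortable statistical margin.  Where a property is a noisy statistic
of a finite draw (e.g. a rank correlation with sampling error ~0.045),
the checks summarise the median over three independent draws rather
than betting on a single one.

## Known limitations

* The coupling update targets one (configurable) pair per epoch; data
  with several genuine cross-modality links of similar strength may
  converge to coupling whichever pair leads after early epochs.
* MDL on spatially smoothed data over-estimates the order by design
  (no smoothness correction); use the unsmoothed matrix or an explicit
  override, as the analysis scripts do.
* Cohort-estimated LD makes neighbouring genes' tests correlated and is
  noisy below ~100 subjects.
* The generator's LD is exchangeable within fixed blocks; methods whose
  behaviour depends on LD decay with distance will not be stressed by
  it.
* `converged = FALSE` on a coupled run means the coupling kept
  perturbing the weights within `max_epochs`; the decomposition is
  still usable (the trace shows both entropy terms plateauing), but the
  flag is reported honestly rather than suppressed.
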