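---
title: "GFRN pathway signatures and phenotyping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GFRN pathway signatures and phenotyping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its methods: the models behind
each stage, the parameters that matter, how the synthetic-data generator is
constructed, and the numerical and design choices made where the design was
genuinely open.

## The problem

The growth factor receptor network (GFRN) couples the EGFR, HER2 and IGF1R
receptors to the PI3K/AKT and RAS/RAF/MEK/ERK cascades. Its activation
state matters for therapy choice in breast cancer, but signaling cannot be
measured directly in archived tumor material. The workaround implemented
here is indirect: perturb one pathway at a time in normal mammary
epithelial cells (oncogene overexpression vs. GFP control), learn the
transcriptional fingerprint of each perturbation, and read those
fingerprints back out of tumor expression profiles as per-sample pathway
activities. Downstream, the seven activities condense into two phenotypes
(survival: HER2/IGF1R/AKT; growth: BAD/EGFR/KRAS/RAF1) and four subgroups
that track differential drug response.

## Signature model

For pathway $p$ with overexpression replicates $T_p$ and shared controls
$C$, the per-gene standardized effect is

$$d_g = \frac{\bar x_{g,T_p} - \bar x_{g,C}}{s_{g,\mathrm{pooled}}},$$

with the pooled standard deviation floored at $10^{-6}$ so constant genes
stay finite (they are then effectively ranked by their mean difference). A
$K$-gene signature takes the top $\lceil K/2\rceil$ genes by descending
$d$ as up-regulated and the top $\lfloor K/2\rfloor$ by ascending $d$ as
down-regulated; per-gene weights are the effects themselves. The anchor
gene — the overexpressed oncogene — is always included: if unselected it
replaces the weakest (smallest $|d|$) member of the side matching the sign
of its own effect.

This deterministic ranking stands in for the Bayesian variable-selection
machinery used in the original signature-generation toolchain, which is
defined in prior work and deliberately not reimplemented here. The
surrogate has the properties the downstream analysis relies on (balanced
directions, anchoring, monotone dependence on evidence strength) while
being exactly reproducible and testable in closed form.

**Ties** in the effect ranking are broken by lexicographic gene id — an
arbitrary but reproducible order; ties are measure-zero on continuous
data.

## Activity estimation

In a test cohort, sample $j$ receives the raw score

$$r_j = \frac{1}{K'}\sum_{g} \operatorname{sign}(w_g)\, z_{gj},$$

summing over the $K'$ signature genes present in the test matrix (missing
genes are dropped with a warning rather than imputed — imputation would
fabricate expression). Two adjustments mirror the adaptive options of the
original estimation tool:

* **Adaptive background** (default on): $z_{gj}$ is the gene's z-score
  *within the test cohort*, absorbing baseline expression differences
  between the training cell line and the tumor cohort. Off, z-scores are
  taken relative to the training controls' mean and SD.
* **Adaptive signature** (default off): per-gene signs are re-estimated in
  the cohort as the sign of the Spearman correlation between the gene's
  z-profile and the current score vector, iterated to a fixed point. A
  gene may flip at most once per run (and at most 20 sweeps are made), a
  bounded scheme chosen because the source material names the behavior but
  not an algorithm; boundedness makes termination and auditability
  trivial.

Raw scores are min–max rescaled per cohort to $[0,1]$: 0 is the least
active and 1 the most active sample. This makes activities cohort-relative
quantities — a deliberate property inherited from the estimation design; a
sample's activity is only meaningful within the cohort it was scored in.
If every score is identical the activities are set to 0.5 with a warning.
Phenotyping operates on the z-scaled activity matrix (per-pathway mean 0,
sample SD 1; the $n-1$ convention matches standard statistical software).

## Batch harmonization

Training replicates arrive in three sequencing batches; tumors arrive as a
fourth, distinct distribution. Both are handled by reference-batch
adjustment: per gene, a non-reference batch has a shared location offset
(the mean difference of group means vs. the reference, over groups present
in both) subtracted, and its residuals about the within-batch group means
rescaled to the reference batch's residual SD. The reference batch is
returned bit-identical, the group (pathway) design is protected because
each group keeps its own mean, and the operation is exactly idempotent —
properties asserted to $10^{-9}$ in the tests. Round 2 treats the whole
adjusted training set as the reference and the test cohort as one batch.

This exact moment-matching version was chosen over empirical-Bayes
shrinkage of batch parameters because its contract is verifiable in closed
form; an EB mode (`method = "eb"`, delegating to ComBat with a reference
batch) is available for users who prefer shrunken estimates at small batch
sizes. Round 2 uses no covariates: the test cohort has no training groups,
and protecting unknown tumor structure is the adaptive background's job.
Genes are intersected (not imputed) between train and test, since scoring
only needs shared genes.

## Length optimization and validation

Signature lengths are scanned over 25–500 in steps of 25, extended with
{5, 10, 15, 20} for HER2 and AKT (short signatures serve those two
pathways better). Each candidate length is scored by the Spearman
correlation between estimated activity and mapped validation proteins in
two cohorts. A candidate is admissible when every mapped correlation is
significant (raw $p < 0.05$, as the selection criterion uses uncorrected
correlation p values) in both cohorts with the expected sign, the
cell-line cohort correlation is at least 0.3 in magnitude, and $K \le
300$; among admissible lengths the best average expected-direction
correlation ($\rho \times$ expected sign) in the primary cohort wins, so
negatively-expected pairs (BAD vs. the AKT protein) contribute positively
when anti-correlated. With no admissible candidate the failure is flagged
with diagnostics, never silently replaced.

Orthogonal validation utilities follow the published conventions:
percentile-defined expression groups (high $\ge$ 90th percentile, low
$\le$ 10th; 80/20 for IGF1R) using the linear-interpolation percentile
definition with inclusive thresholds, and two-group Welch $t$-tests
(pooled-variance available by flag) for mutation-style contrasts.

## Phenotypes and subgroups

A sample is *survival* when the mean z-scaled activity of
{HER2, IGF1R, AKT} is at least that of {BAD, EGFR, KRAS, RAF1}, else
*growth*; exact ties (measure-zero) go to survival for determinism.
Subgroups come from k-means on the scaled AKT/HER2/BAD/EGFR activities
with 4 centers and 100 random starts (best within-cluster sum of squares),
seeded for reproducibility. Clusters take the majority phenotype of their
members; the expected 2/2 split is then ordered by the HER2 (survival
pair) or BAD (growth pair) centroid. If the split is not 2/2 — e.g. a
cohort that is effectively one phenotype — a structured warning fires and
each cluster is labelled by its nearest signed-unit archetype instead.

## Variance attribution

Cohort structure is summarized by gene-wise-centered, unscaled PCA over
samples (the `prcomp` convention; unscaled because expression is already
on a common log2(TPM+1) scale and scaling would inflate near-constant
genes). The first five components are retained. Components are related to
(a) pathway activities by Spearman correlation, (b) per-sample mean
expression (a library-size-like technical signal that typically dominates
PC1), and (c) labelling schemes via nested linear models: $PC \sim
\text{base}$ vs. $PC \sim \text{base} + \text{added}$, compared by
$R^2$ and the partial F-test. Categorical labels are treatment-coded with
the lexicographically first level as baseline; rank-deficient designs drop
aliased columns with a warning.

## Pharmacology

Dose–response curves use the two-parameter logistic
$Y = 1/(1+10^{(\log EC_{50}-X)\cdot h})$ with asymptotes fixed at 0 and 1
— the variable-slope form in which $Y$ rises with dose and equals 0.5 at
$X=\log EC_{50}$. Fitting is nonlinear least squares with a multi-start
grid (five $\log EC_{50}$ starts spanning the dose range × Hill slopes
{0.5, 1, 2}; best residual sum of squares kept), since the single
published equation pins the model but not the optimizer. Responses are
clipped to $[0, 1.5]$ with a warning outside $[0,1]$. Sensitivity is
$-\log EC_{50}$ (base 10, doses in log10 molar — the standard pharmacology
convention); it is reported only for converged fits whose $\log EC_{50}$
lies within the dose range ± 2 log units, otherwise the fit is flagged
(no-response, no-convergence, out-of-range) and the sensitivity is NA.
Downstream: Spearman correlation of sensitivity with activity (drugs with
fewer than three complete pairs excluded), Welch $t$-tests between
subgroups per drug with Benjamini–Hochberg correction within each
comparison family, and binarization at the per-drug mean with *strictly
above* reading as sensitive (the literal reading of "above the cutoff").

## The synthetic study

The generator reproduces the statistical skeleton of the emulated study
design on the log2(TPM+1) scale with additive Gaussian noise:

* **Training**: six overexpression replicates per pathway against twelve
  shared GFP controls (the study's replicate design, modulo per-pathway
  variation), spread over three batches; planted signature genes (100 per
  pathway by default, disjoint, half up/half down) shifted by ±2 log2
  units; non-reference batches get a per-gene additive shift (SD 0.5) and
  a multiplicative residual-scale distortion (0.8–1.25). The first gene of
  each pathway's block is named after the pathway, so the anchor is the
  oncogene itself.
* **Cohort**: planted activities are Beta(8, 2) in a sample's high arm and
  Beta(2, 8) in its low arm — separated but overlapping, which is what
  makes recovery a test rather than a tautology; HER2 (within survival)
  and BAD (within growth) follow the subgroup draw instead of the arm.
  Expression is baseline + sign × activity × effect + noise (SD 1), plus a
  cohort-wide per-gene shift distinct from the training batches. The
  planted phenotype label is *derived* from the planted activities by the
  max-mean arm rule, so label/activity consistency holds by construction,
  including degenerate compositions.
* **Proteins**: three validation proteins per pathway (receptor plus
  downstream/phospho forms, as pathway validation panels typically
  measure), each the planted activity plus noise (SD 0.3) — except BAD,
  which is validated solely through anti-correlation with the AKT protein
  (AKT activation inhibits BAD). Averaging several proteins is what makes
  the length-selection criterion sharp; BAD's single arm-level
  anti-correlation is nearly flat in list length, so its selected lengths
  wander more than the other pathways' — an inherent feature of that
  validation design, visible in the ensemble recovery rate.
* **Drugs**: ten drugs whose planted logEC50 (range −8 to −5) is linear in
  a driver — the survival-arm mean (3 drugs), growth-arm mean (3), HER2
  alone, BAD alone, or nothing (2 null drugs) — with six doses, four
  replicates and response noise SD 0.05.

What the generator does **not** emulate: read-level sequencing noise and
count overdispersion, gene–gene correlation beyond the planted signature
structure, partial overlap between pathway gene sets, RPPA normalization
artifacts, and clinical covariates. Passing the synthetic suite therefore
establishes that the pipeline's logic and numerics are correct under the
assumed generative model, not that the signatures themselves generalize to
real cohorts — that question needs the original data.

## Problem sizes and seeds

The test suite and acceptance script run at desk scale, chosen to keep a
full run in minutes while leaving the statistical checks well-powered:
unit fixtures use 400–800 genes and 40–120 samples; acceptance-level
checks use 1000 genes (50 planted per pathway), a 200-sample cohort for
activity/phenotype recovery, 100-sample and 55-sample cohorts (the latter
mirroring a typical cell-line panel) for the 50-seed length-selection
ensemble, 1119-sample activity tables for the phenotype-rule and cross-tab
fidelity checks, and 100 curves for EC50 recovery. All randomness flows
from explicit integer seeds; derived seeds are small fixed offsets.

## Known limitations

* Activities are cohort-relative ([0,1] by min–max): absolute comparisons
  across cohorts require joint scoring or shared anchoring samples.
* The deterministic signature surrogate has no posterior uncertainty; no
  credible intervals accompany activities.
* The phenotype rule is a hard argmax; samples near the arm-mean boundary
  carry no confidence measure.
* k-means subgrouping assumes four clusters; strongly unbalanced cohorts
  trigger the archetype fallback, which is a labelled heuristic.
* Dose–response fits assume full asymptotes (0 and 1); partial-response
  compounds are flagged rather than modelled with free asymptotes.
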