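---
title: "Methods: separating transcriptional and translational regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: separating transcriptional and translational regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(translevel)
```

## The problem

Polysome profiling yields, for each biological sample, two sequencing
libraries: total RNA, reflecting transcript abundance, and the
polysome-bound fraction, reflecting how much of each transcript is
engaged by ribosomes. Polysome counts cannot be compared across samples
directly — the number of ribosome-bound transcripts depends on how many
transcripts there were to begin with. The quantity of interest is
therefore the **translational ratio**

$$I_g = \log_2\frac{\text{poly}_g}{\text{total}_g},$$

how effectively transcripts of gene $g$ enter translation, and its
between-condition difference $\Delta TR_g = I_{g,i} - I_{g,j}$. A gene
whose $\Delta TR$ changes while its total-RNA abundance stays flat is
regulated translationally; a gene whose both fractions shift together is
regulated transcriptionally. This two-level contrast is the centre of
the package and of its validation suite.

## Count model and differential tests

Counts are modelled as negative binomial with gene mean $\mu_{gj} =
s_j \lambda_g$ and variance $\mu + \phi\mu^2$, where $s_j$ is a
library-size factor taken from raw column totals. No compositional
normalisation (TMM or median-ratio) is applied: the model of the data
makes no composition assumption, and the validation simulations keep
planted programs small relative to the library so that offset bias is
secondary. Users with strongly asymmetric regulation should be aware
that raw-total offsets absorb part of a one-sided program.

**Dispersion.** Per-gene dispersions are method-of-moments estimates on
the library-size-corrected scale, $\hat\phi_g = \max\{0, (s^2-\bar m)/
\bar m^2\}$, pooled across groups, then shrunk toward a common value:
$\hat\phi_g^{\text{shr}} = (d\,\hat\phi_g + w\,\hat\phi_c)/(d+w)$ with
$d$ the pooled residual degrees of freedom and prior weight $w = 20$ by
default — at 3 replicates per group the per-gene moment estimate is very
noisy, so the common value dominates. The common dispersion
$\hat\phi_c$ maximises the **Cox–Reid adjusted** profile likelihood
under a group-means model. The adjustment matters: the unadjusted
profile MLE is biased low at small replicate numbers (the fitted group
means consume degrees of freedom), and plugging a too-small dispersion
into the test inflates the type-I error well beyond its nominal level.
With the adjustment, the likelihood-ratio test's p < 0.05 rate on a
2000-gene null simulation (NB, $\phi = 0.1$, 3 vs 3) sits at ~0.05, as
the test suite verifies.

**Two-group test.** Per gene, nested NB GLMs (log link, offsets, fixed
shrunk dispersion) are fitted by IRLS; the likelihood-ratio statistic is
referred to $\chi^2_1$. The reported `logFC` is the log2 ratio of
offset-corrected group means with a 0.5 pseudo-count added to each group
mean, keeping fold changes finite when a group has zero counts.
All-zero genes are flagged and given $p = 1$, `logFC` 0.

**Interaction test for differential translation.** For two conditions,
the combined total and polysome counts are fitted per gene with mean
structure `fraction + condition + fraction:condition`. The interaction
coefficient, divided by $\log 2$, estimates $\Delta TR$; the
likelihood-ratio test of dropping it asks specifically whether the
poly/total ratio changed — a shared transcriptional shift moves the
condition main effect, not the interaction. On simulations with
translation-only regulation ($\Delta TR = 2$, 10% of genes), the test
recovers ≥ 80% of planted genes while ≥ 90% of those recoveries are
classified Stable by total-fraction DE, which is exactly the biological
contrast the method exists to expose.

**Classification.** Up: `logFC > 1` and `p < 0.05`; Down: `logFC < −1`
and `p < 0.05`; Stable: `−1 ≤ logFC ≤ 1`. The significance filter uses
raw p-values (FDR is reported alongside) and the Stable band is defined
by the threshold alone. The boundary case — a large fold change that
misses significance — belongs to no class as stated; such genes are
labelled `Unclassified` rather than silently folded into a class. The
same rule, applied to the $\Delta TR$ estimate, defines the
differential-translation classes; `delta_tr()` also provides a pure
threshold mode (no test) since a cutoff-only calling convention is
equally defensible at this level.

## Translational ratio details

TR is computed on the CPM scale with a pseudocount of 0.5 in both
numerator and denominator (zero counts occur; 0.5 keeps the ratio finite
and roughly centred), per condition from mean CPM by default, or paired
per biological replicate. CPM stands in for TPM throughout: transcript
lengths are outside the package's scope, and within-gene between-sample
comparisons are unaffected by the length term.

Before co-expression analysis at the translational level, TR values are
mapped back to the linear scale ($2^{TR}$) and each sample is rescaled
to sum to one million. Log-scale ratios can be negative and cannot
meaningfully be forced to a fixed total, so the package interprets the
"totalled one million" renormalisation on the linear ratio scale; the
log2 of the renormalised values is then used for network construction.

## Co-expression networks

The implementation is a deterministic, self-contained variant of
weighted correlation network analysis:

* **Soft threshold.** For each candidate power 1–20, connectivity
  $k_i = \sum_j a_{ij}$ is binned (10 equal-width bins) and
  $\log_{10}$ mean frequency is regressed on $\log_{10}$ mean $k$; the
  signed fit is $-\operatorname{sign}(\text{slope})\,R^2$. The smallest
  power with fit ≥ 0.8 is selected. Powers whose **mean connectivity
  falls below 1** are reported but ineligible: as $\beta$ grows any
  network, including pure noise, collapses toward zero connectivity,
  where the binned log–log fit drifts to spuriously high $R^2$ — a fit
  there carries no information about scale-free structure. On i.i.d.
  noise, all eligible powers score well below 0.8 and the function
  returns its maximum-fit power with a low-fit warning.
* **Adjacency and TOM.** Unsigned $|r|^\beta$ by default (signed
  available), topological overlap in the standard form
  $(\ell_{ij} + a_{ij})/(\min(k_i,k_j) + 1 - a_{ij})$.
* **Modules.** Average-linkage clustering of $1-\text{TOM}$ with a
  static cut at 0.99 of the maximum merge height; clusters below
  `min_module_size` (default 30) become `grey`. The static cut replaces
  the hybrid dynamic tree cut: it is fully specified, deterministic, and
  sufficient for planted-module recovery — the validation suite shows
  ARI = 1 on two planted blocks (100 genes, 16 samples) and four planted
  blocks (160 genes, 40 samples; resolving more blocks needs more
  samples, as chance correlations between the blocks' latent factors
  shrink only as $1/\sqrt{n}$). Module names come from a fixed colour list; they carry
  no meaning.
* **Eigengenes, module–trait, hubs.** The eigengene is the unit-norm
  first right singular vector of the standardized module expression,
  sign-aligned with the module's mean profile. Module–trait correlations
  use sample-level one-hot condition indicators and the closed-form
  two-sided p, $t = r\sqrt{n-2}/\sqrt{1-r^2}$ with $n-2$ df. At $n = 4$
  this transform gives $p(r{=}-0.98) = 0.020$ and $p(r{=}-0.97) =
  0.030$ — the regime in which condition-level correlations of a
  four-condition design live. Hub genes are the top 10 by kME.

## Cross-level module overlap

Transcription-level and translation-level partitions are compared on
their common gene universe: per non-grey module pair, the Jaccard index,
a one-sided hypergeometric p-value for the observed overlap, and BH
correction across pairs. A pair is *related* when Jaccard ≥ 5% **and**
FDR < 0.05. The hypergeometric test is the package's choice of
significance criterion for module overlap (the standard one for
cross-tabulated partitions); grey is a residual class and never paired.
On independent random partitions (1000 genes, 10 × 10 modules) the
procedure detects nothing in ≥ 95% of runs, while a planted shared
program of 80 genes is detected with Jaccard 0.67.

## Enrichment

Over/under-representation is hypergeometric against a user-supplied GMT
annotation, fully offline. Terms are first intersected with the analysis
universe; terms larger than 250 genes or overlapping the query in fewer
than 10 genes are excluded *before* testing, and BH runs within each
direction across the surviving terms. "Term size" means the number of
annotated genes in the term — the conventional reading — and the
intersection filter applies to the query∩term overlap. This replaces
calls to an online enrichment service so that the pipeline has no
network dependency; it does not propagate GO ancestry.

## Wet-lab formulas

Two closed-form calculations accompany the sequencing analysis:
relative electrolyte leakage, $100 \times \text{conductivity}_{\text{sample}}
/ \text{conductivity}_{\text{boiled}}$ (the sample may be measured
before or after freezing; both variants are accepted as labelled
inputs), and ΔΔCt relative expression with amplification efficiency
fixed at 2 and multiple reference genes (RPL2, EF-1-alpha, UBI style)
combined by the arithmetic mean of their Ct values — the geometric mean
on the linear scale, the natural choice when no weighting information is
available.

## The synthetic-data generator

`simulate_experiment()` emulates the structure of a hardening/stress
polysome-profiling experiment: four conditions, two fractions, three
biological replicates, two technical repeats per library (48 libraries
at defaults). Per gene, baseline log2 abundance is N(6, 2) on the CPM
scale and the baseline translational ratio is N(0, 0.5); NB dispersion
defaults to $\phi = 0.1$ and library sizes are log-normal around
5 × 10⁶ — typical magnitudes for bulk plant RNA-seq. Technical repeats
are binomially thinned halves of one latent library, reflecting
resequencing rather than independent biology (thinning preserves the NB
dispersion, which the tests verify against the var = µ + φµ² moment
identity). The condition-effect template mirrors the biology the
package targets: Hardening and Combo share most of their transcriptional
program (hardened plants keep their reprogrammed transcriptome), while
Stress carries mostly translational effects (a short shock acts through
translation before the transcriptome can follow). Planted programs are
disjoint across conditions within each level, so ground-truth
bookkeeping is exact; transcriptional and translational programs are
drawn independently and may overlap. Planted modules share a latent
factor per biological sample with a chosen fraction-loading pattern:
equal loadings appear only at the transcription level (they cancel in
the ratio), polysome-only loadings appear only at the translation
level.

What the generator does **not** emulate: transcript-length effects,
composition-heavy regulation (planted programs are minorities of the
library mass), batch effects, isoforms, and any real biological
correlation beyond the planted factors. Passing tests therefore show
that the methods recover the structure they model, under the noise
levels they assume — not that real tomato data meet those assumptions.

## Numerical choices and degenerate inputs

* IRLS runs at most 50 iterations to a 10⁻⁸ log-likelihood tolerance,
  with the linear predictor clamped to ±30; all-zero genes short-circuit.
* BH ties break deterministically by (p, gene id); all pipeline stages
  are deterministic, so a rerun with the same config is byte-identical
  (checked via MD5 in the manifest).
* Empty-vs-empty Jaccard is defined as 0 with a warning; constant genes
  are dropped (soft-threshold) or rejected (adjacency); constant traits
  yield NA correlations; a single-gene module's eigengene is its own
  standardized profile.
* The confounding check for transcription-only regulation uses 10
  replicates and high-expressed genes: the quantity under test is the
  *bias* of the ΔTR estimator, and at 3 replicates with $\phi = 0.1$
  the estimator's sampling noise alone (sd ≈ 0.5 log2 units) would
  swamp the ≤ 0.2 band regardless of bias.

## Validation problem sizes

The test suite and `scripts/acceptance.R` run at desk scale: 2000-gene
simulations for calibration/power/recovery, 500 genes × 10 replicates
for confounding control, 100–160 genes for module recovery, 1000-gene
universes for overlap nulls, and the shipped 150-gene fixture for the
end-to-end determinism check. These sizes keep each check seconds-fast
while leaving Monte-Carlo error well inside the asserted margins.

## Known limitations

Raw-total offsets (no compositional correction); chi-square reference
for the LRT rather than a small-sample F; no module merging by eigengene
similarity and no block-wise computation for very large gene sets; TE
(ribosome-footprint translational efficiency) is honoured as a mode
label only, since CDS-restricted counting is out of scope; enrichment
does not model the GO DAG. The module–trait p-values at condition-level
$n = 4$ are descriptive at best — with two degrees of freedom, only
near-perfect correlations reach nominal significance, and they should be
read as exploratory summaries, not inference.
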