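---
title: "Methods: the mirkd knockdown screen"
author: "mirkd authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the mirkd knockdown screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirkd)
```

# Scope and data model

`mirkd` implements a differential miRNA expression screen for two-group
knockdown designs measured on TaqMan-style low density array (LDA) cards,
together with the downstream target-scoring and ontology-enrichment
analysis. The central container is `CtExperiment`, a
`SummarizedExperiment` holding one assay of raw threshold cycles (CT) with
per-assay plate and duplicate-group annotation and per-sample
knockdown/control labels.

Two representation rules matter throughout:

* **"Undetermined" is a sentinel, never a number.** The instrument call for
  a well that never crosses threshold is stored as `NA`. It is not imputed
  as the maximum cycle, because the on/off rules below need to distinguish
  "not detected at all" from "detected late".
* **log2 expression is `maxCycle - CT`.** One PCR cycle corresponds to one
  doubling, so this scale is direction-preserving (higher value = higher
  abundance) and fold changes in cycles are log2 fold changes. The
  instrument maximum (default 40 cycles) is configurable because vendors
  differ; it is recorded in the object and in the output provenance.

# Normalization

## Cyclic LOESS, separately per plate

miRNA cards lack reliable housekeepers, so the screen normalizes to the
overall signal rather than to reference assays. Within each plate and for
every unordered sample pair \((i, j)\), the difference
\(M = x_i - x_j\) is smoothed against the abundance \(A = (x_i + x_j)/2\)
over commonly detected features, and half the fitted trend is subtracted
from sample \(i\) and added to sample \(j\). Passes over all pairs repeat
until the largest absolute fitted trend falls below `tol` (default
\(10^{-3}\) log2 units) or `maxIter` (default 3) passes have run.

Numerical choices:

* **Robust smoothing.** The loess fit uses the symmetric (redescending
  M-estimation) family. With a least-squares fit, a handful of strongly
  differential features drags the local trend estimate and biases the fold
  changes of unaffected features near the same abundance; robust weights
  suppress exactly this. Pairs whose difference vector is numerically
  constant are short-circuited to a constant fit because the robustness
  weights are undefined at zero residual scale.
* **Span 0.7, degree 1.** With only a few samples and a few hundred
  detected features per plate, smaller spans chase noise. Both are
  configurable.
* **Simultaneous (Jacobi-style) updates.** All pair corrections within one
  pass are computed on the same input and applied together. This makes the
  pass exactly equivariant under sample permutation and keeps the grand
  mean fixed on complete data; a sequential update would depend on column
  order.
* **Masked features.** Undetermined cells are excluded from fitting, but a
  feature detected in sample \(i\) and masked in \(j\) still receives
  sample \(i\)'s correction, evaluated at the abundance the feature shows
  (clamped to the fitted range). This keeps partially detected features
  normalizable. A pair must share at least `minCommon` (default 10)
  detected features.

## Quantile normalization

For the one-color expression-array stage, each sample's sorted values are
replaced by the across-sample mean of order statistics. Tied values receive
the mean of the order-statistic replacements they span, which makes the
map deterministic. On tie-free data the operation is idempotent; with ties
a second application can shift values again because tie-averaging changes
the column distributions — a property worth knowing when the input is
heavily discretized.

# Differential expression

## Detection rules

With the default CT cutoff of 34.5 cycles:

* an assay above the cutoff (or undetermined) in **every** sample of
  **both** groups is excluded as not expressed;
* an assay undetermined in all samples of one group and detected (CT at or
  below the cutoff) in all samples of the other is an **on/off candidate**;
* everything else is tested. A detected assay with an undetermined value in
  only some samples cannot be tested by the moderated t and is reported
  separately as untestable.

The boundary is deliberate: a CT of exactly 34.5 counts as detected, which
is what makes the degenerate on/off lower limit of 0 well defined.

## Moderated t-test

Per feature \(g\), `fitModeratedT()` computes the group-mean difference
(knockdown − control) and the pooled residual variance \(s_g^2\) with
\(d_g = n_1 + n_2 - 2\) degrees of freedom. The empirical-Bayes prior
\((d_0, s_0^2)\) is estimated by moment matching of \(\log s_g^2\) against
a scaled F distribution: with
\(e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)\), the mean of \(e_g\)
identifies \(s_0^2\) and the excess variance of \(e_g\) over
\(\psi'(d_g/2)\) identifies \(d_0\) through inversion of the trigamma
function (Newton iteration). The posterior variance
\(\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)\) yields

\[ t_g = \frac{\overline{x}_{g,\mathrm{kd}} - \overline{x}_{g,\mathrm{ctrl}}}
{\sqrt{\tilde s_g^2 (1/n_1 + 1/n_2)}} \sim t_{d_0 + d_g} . \]

Zero residual variances are floored at \(10^{-8}\) before taking logs —
relevant in tiny 2-vs-2 designs. Forcing `priorDf = 0` reduces the
statistic exactly to the classical pooled two-sample t (a tested
invariant); a design with one sample per group can only be analyzed in an
explicit common-variance mode (`priorDf`, `priorVar` supplied by the
caller). The test suite cross-checks the fit, including the estimated
\((d_0, s_0^2)\), against the independent limma implementation.

## Candidates, on/off bounds and duplicate concordance

Candidates are features with **raw** moderated-t p below 0.05; the
BH-adjusted p is reported alongside but does not gate the call. This
matches the screening rule the pipeline models, and its cost is made
explicit below.

For on/off candidates no ratio exists; substituting the detection cutoff
for the undetermined group gives the most conservative detectable value,
so the reported group-mean difference is a **lower limit** of the log2
fold change and the p-value is marked not calculable (`n.c.`).

Assays measured in duplicate must agree in fold-change sign; discordant
miRNAs are removed entirely (sign-only concordance — no magnitude rule —
with zero treated as concordant with either sign), and concordant
duplicates collapse to one record with the averaged fold change and the
smaller p.

For the expression-array stage, a gene is called only when every one of
its replicate probes is individually significant with a consistent sign.

# Single-assay qPCR

`ddctQuantify()` implements relative quantification:
\(\Delta CT = CT_{target} - \overline{CT}_{refs}\) (arithmetic mean over
reference genes, i.e. the geometric mean of their linear quantities),
\(\Delta\Delta CT\) relative to the calibrator-group mean, fold change
\(2^{-\Delta\Delta CT}\). Technical replicates are averaged on the CT
scale before \(\Delta CT\). `referenceStability()` ranks candidate
references by total CT variance decomposed into within-group and
between-group mean squares, ascending, with lexicographic tie-breaking.
`spearmanValidate()` correlates fold changes across platforms on mid-ranks;
the two-sided p is exact by full permutation enumeration for \(n \le 9\)
and uses the \(t_{n-2}\) approximation above that. The boundary is
documented rather than inherited from any particular software default.

# Target scoring and enrichment

Curated (evidence-classed) and predicted (context+-scored) interactions
share one table with a `source` tag. The filter first drops curated rows
below the evidence minimum (default: strong support only), then restricts
all rows to the expressed-gene background of the cellular context, and
reports both removal counts.

The signed gene score keeps the (negative) context+ score for interactions
of miRNAs **down**-regulated in the knockdown and flips it positive for
**up**-regulated miRNAs; per gene the scores are summed and the gene
passes at \(|\mathrm{sum}| \ge 0.4\) (default). The construction is
antisymmetric — flipping every direction negates every sum — and genes
targeted comparably from both directions cancel out. Term-level sums
aggregate the signed interaction scores of passing member genes; whether
sub-cutoff genes should contribute is genuinely ambiguous, so the default
excludes them and `includeAll = TRUE` restores them.

Enrichment is a local hypergeometric computation: per term, the upper-tail
probability of observing at least \(k\) list genes, with the EASE variant
(default) replacing \(k\) by \(k - 1\) so that single-gene overlaps are
never significant. Fold enrichment \((k/n)/(K/N)\) always uses the true
\(k\). The significance rule keeps terms with fold enrichment \(\ge 1.5\)
and raw \(p < 0.1\). The background defaults to the expressed-gene set,
not the whole annotation universe; counts from annotation services with
their own gene universes will differ accordingly.

# The synthetic-data generators

`simulateLda()` emulates the study conditions end to end: 664 distinct
miRNAs of which 72 are duplicated (736 assays on two plates), 2 knockdown
vs 2 control samples, Gaussian CT noise of 0.25 cycles, 21 planted effects
of which 6 are on/off, with effect magnitudes uniform in 1.5–4 log2 units.
Baseline CTs are uniform on (27, 41) with censoring at the instrument
maximum of 40: anything beyond is emitted as undetermined, which both
exercises the sentinel path and yields ~53–57% of miRNAs detected above
background — the realistic detection rate for these cards. Effect-carrying
miRNAs draw baselines from the detectable subrange (27, 31) so the planted
signal is measurable; on/off miRNAs place the silent group's latent CT
above the maximum cycle. All generators are pure functions of their
arguments including the seed (the caller's RNG stream is untouched), and
their outputs round-trip through the package's readers.

What the generator does **not** emulate: amplification-efficiency
differences between assays, correlated noise within a card, miRNA-family
cross-hybridization, and plate-specific intensity trends. Passing recovery
tests therefore demonstrate the pipeline's arithmetic and its behaviour
under honest noise, not robustness to every artifact of real cards.

# What the screen's error rates are — and are not

The raw-p candidate rule makes no multiplicity correction. With ~350–420
testable features and 21 true effects, the expected number of null
features passing \(p < 0.05\) is about 18 **at any noise level**, so the
observed false-discovery proportion of the screen on the synthetic design
is ~0.44 and the candidate list is systematically longer than the planted
truth (about 35 at low noise for 21 planted effects). This is a structural
property of raw-p screening at this scale, not an implementation artifact:
sensitivity for strong effects is essentially perfect (100% recovery of
planted \(|{\log_2}\mathrm{FC}| \ge 1.5\) effects across 20 replicates),
while specificity is bounded by \(\alpha \times\) the number of tested
nulls. Users who need FDR control should gate on the reported `p_adj`
column instead; the default reproduces the screening rule faithfully and
reports both.

Problem sizes used by the automated checks: 1,000-vector oracles for the
BH and moderated-t properties, 200 random configurations for the
hypergeometric oracles, \(8!\) permutation enumeration for the exact
Spearman p, and 20 seeded replicates of the full 736-assay screen.

# Known limitations

* Two-group designs only; no paired or multi-group contrasts.
* The on/off lower limit depends on the cutoff-substitution convention;
  other conventions (e.g. substituting the maximum cycle) give larger
  bounds. The choice is configurable and recorded.
* Enrichment counts depend on the supplied annotation and background and
  will not numerically match web services with private gene universes.
* Amplification-efficiency-corrected qPCR models (standard curves, Pfaffl)
  are out of scope; the ΔΔCT model assumes ~100% efficiency.
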