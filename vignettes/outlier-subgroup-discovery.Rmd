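---
title: "Outlier subgroup discovery in case-control expression cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Outlier subgroup discovery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytodet)
```

## Why per-individual outlier calling

In a genetically heterogeneous disease, different patients carry
different molecular lesions. A cohort-level test of case vs control
means can then be flat across the whole transcriptome even when many
individual patients are grossly abnormal at *some* gene. `cytodet`
therefore tests each case sample separately against the control cohort
and searches for *recurrence*: several cases abnormal at the same probe
in the same direction form a candidate subgroup worth following up
(genotype, protein, functional assay).

## The outlier model and its assumptions

For probe $g$ with control values $x_{g1},\dots,x_{gn}$ (log2 scale) and
a case value $y_{gi}$:

$$z_{gi} = \frac{y_{gi} - \bar x_g}{s_g}, \qquad
  p_{gi} = 2\,\Phi(-|z_{gi}|), \qquad
  \Delta_{gi} = y_{gi} - \bar x_g ,$$

where $s_g$ is the unbiased ($n-1$) sample SD. A call **passes** iff
$p_{gi} < 0.005$ *and* $|\Delta_{gi}| > 1$ log2 unit, both strict.

Assumptions, stated explicitly:

* **Log2-normality per probe.** The normal tail probability for $z$ is
  only calibrated if control expression is approximately normal on the
  log2 scale. The synthetic generator draws data exactly from this
  model, so tests of calibration are tests of the implementation, not of
  the model.
* **Plug-in reference moments.** $\bar x_g, s_g$ are estimates; at
  control $n = 42$ the realized null pass rate exceeds the nominal
  $0.005$ (the $z$ statistic is really $t$-like, and the fold-change
  criterion interacts with it). We deliberately keep the normal
  reference — the method is a z-score procedure — and validate the
  realized rate against a brute-force Monte-Carlo oracle (simulate
  control draws, plug in sample moments, count passes) instead of
  against the nominal level. With probe SD 0.5 the significance
  criterion binds and the realized rate is $\approx 0.008$; with probe
  SD 0.2 the fold-change criterion dominates and the rate collapses
  toward $P(|z| > 5)$.
* **Controls only in the reference.** Case samples never contribute to
  $\bar x_g$ or $s_g$; a contaminated reference would shrink exactly the
  signals being sought. The comparison group is the control cohort, not
  the pooled cohort.
* **Unstimulated samples.** Outlier calling is designed for resting
  (unstimulated) profiles; `call_outliers()` warns when stimulated
  samples are present in the metadata.
* **No multiple-testing correction within an individual.** The procedure
  applies fixed per-test thresholds; recurrence across individuals, not
  FDR, is the evidence filter.

### Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `p_threshold` | 0.005 | probability | significance of the standardized deviation |
| `fc_threshold` | 1 | log2 units | minimum absolute difference from the control mean |
| `min_carriers` | 3 | cases | recurrence cutoff defining a subgroup |
| `detection_p` | 0.01 | probability | per-cell detection call (strict `<`) |
| `detection_min_fraction` | 0.5 | fraction | probe retained iff detected in at least this fraction (ties retained) |
| `alpha` | 0.05 | probability | network edge significance |

The detection rule retains a probe detected in *exactly* half the
samples: the procedural statement is "at least 50%", and the boundary
case is resolved in favour of retention.

## Batch adjustment: a deliberate simplification

`adjust_batches()` fits, per probe, an additive model with cohort and
batch effects, removes the centred batch effects, and rescales each
batch's residual spread to the pooled value. This is a transparent
location/scale adjustment with the covariate-protection property that
matters here — on a balanced design the case−control contrast passes
through numerically unchanged — and with closed-form behaviour that the
tests verify exactly. It is *not* empirical-Bayes ComBat: there is no
shrinkage of per-batch parameters across probes, so with very small
batches the per-probe scale estimates are noisy. The run manifest
records this deviation on every pipeline run. Degenerate designs error
early: a batch with fewer than two samples, or batch aliased with cohort
(the batch effect would then be indistinguishable from the biology).

## Differential expression, BH, ΔΔCt

Cohort DE uses the per-probe pooled-variance Student $t$ rather than a
moderated statistic. At 42 vs 58 samples the moderation prior has little
leverage, and the plain $t$ makes every reported number reproducible by
hand; the manifest records the deviation, and the practical consequence
is that published moderated P-values are not expected to match exactly
while group means and fold changes are. Fold change is defined as
case − control on the log2 scale. Benjamini–Hochberg adjustment is the
standard step-up rule (delegated to `stats::p.adjust`, cross-checked in
the tests against a direct implementation of the rule).

ΔΔCt uses amplification efficiency exactly 2 (the classic method, no
efficiency correction); replicate Ct values are averaged *before* ΔCt,
since no other aggregation rule is standard.

## Cytokine networks

Concentrations are log2-transformed as $\log_2(x + 1\,\text{pg/ml})$ so
zero concentrations are admissible; for the pg/ml ranges simulated
(hundreds to tens of thousands) the +1 offset is negligible. All 10
unordered pairs of the 5 cytokines get a Pearson $r$ with a $t$-transform
P-value; edges are significant at two-sided $P < 0.05$. Cohort
comparison of secretion levels defaults to the same log2 scale for
consistency (raw-scale comparison is available via `log_scale = FALSE`).
Viability normalization is multiplicative rescaling to a reference
absorbance (`concentration × reference / absorbance`): the underlying
measurement is a per-well viable-cell proxy, and ratio-to-reference
preserves units. The Fisher-z edge-wise network comparison
(`compare_networks()`) is an extension beyond qualitative side-by-side
network reading and is labelled as such in its output; it refuses
$|r| = 1$ edges (the transform diverges) and $n \le 3$.

## eQTL model

`additive_regression()` codes genotype as minor-allele dosage 0/1/2 and
fits ordinary least squares — the additive model matches reporting a
single coefficient per cohort. Fits are intended per cohort (control and
case separately), since the case fit can legitimately differ when an
outlier subgroup sits on the same gene. Covariates are not included by
default (none are standard for a single-SNP confirmatory fit). A
monomorphic dosage vector errors by name; a constant expression vector
returns $\beta = 0$, $r^2 = 0$ rather than NaN.

## What the synthetic generator emulates — and what it does not

`sim_scenario()` / `simulate_expression()` generate: per-probe normal
log2 expression with baseline means uniform on [6, 12] and SDs on
[0.15, 0.35] (typical array log2 intensity ranges and spreads); batch
location/scale structure with near-balanced cohort assignment; planted
carrier subgroups (default: one probe, 7 of 58 cases shifted −1.5 log2,
residual SD pinned at 0.25); one eQTL probe with Hardy–Weinberg dosages
at MAF 0.183 and slope −0.78 log2/allele, residual SD 0.2528 chosen so
the population $r^2$ is 0.74; detection P-values below 0.01 except for a
2% dropout fraction; and per-cohort 5-cytokine log2-multivariate-normal
secretion with the published control-cohort correlation targets (0.64,
0.67, 0.60, −0.39) and case-cohort targets (0.15, 0.47, 0.33, 0.02) —
pairs without a published value default to 0, and viability absorbance
is N(1.0, 0.05) truncated positive. Default cohort sizes are 42 controls
vs 58 cases (expression) and the generator is re-parameterized to
39 vs 43 for secretion-level checks, matching the two assays' sample
sizes.

Two structural choices are the package's own:

* The planted outlier probe and the eQTL probe are **separate** probes.
  In the motivating biology a single gene can be both; coupling them in
  the default scenario would make the planted subgroup effect leak into
  the additive-model recovery checks, so each planted structure is kept
  independently verifiable.
* All generator randomness flows from the single scenario seed;
  identical seeds give byte-identical cohorts.

Deliberately **not** modelled: probe cross-hybridization, bead-level
summarization, heavy-tailed or skewed probe distributions, correlated
probes, missing cells, and any dependence between expression and
cytokine tables beyond cohort labels. Passing tests therefore
demonstrate that the implementation is correct *under the model the
statistic assumes*; on real arrays, heavier tails will inflate the
outlier rate above the simulated calibration.

A consequence worth stating plainly: with carrier effect −1.5 and probe
SD 0.25 the *expected* carrier z is −6 and the expected Δ is −1.5, so
every carrier passes both thresholds *in expectation*; but the realized
Δ of a single carrier is $N(-1.5, 0.25\sqrt{1 + 1/42})$, which falls
short of the fold-change threshold with probability
$\Phi(-1.976) \approx 0.024$. Per-carrier sensitivity is therefore
$\approx 0.976$ and the probability that *all seven* carriers of a
subgroup pass in one cohort is $0.976^7 \approx 0.84$ — a property of
the thresholds under the generating model, not an implementation defect.
The acceptance suite asserts both the pooled sensitivity (≥ 0.95,
attained) and the all-seven event, and the latter check documents this
ceiling.

## Numerical choices and degenerate inputs

* Strict inequalities throughout the dual thresholds and the detection
  filter, per their printed definitions; the only `>=` is the detection
  *fraction* ("at least 50%").
* Zero control SD, fewer than 3 controls, zero pooled variance, zero
  paired-difference variance, monomorphic dosage, $|r| = 1$ in the
  Fisher transform: all error with messages naming the degeneracy rather
  than returning NaN.
* Batch residual rescaling skips batches with zero residual spread
  (scale factor 1), which also makes the no-noise identity cases exact.
* Problem sizes in the test suite: null calibration uses $10^6$
  probe×case tests against a $10^6$-draw oracle; subgroup recovery uses
  100 replicate full-size cohorts; network recovery 100 replicate
  secretion cohorts; eQTL recovery 200 replicate fits. These sizes make
  the binomial standard errors small relative to every asserted margin.

## Known limitations

* The normal reference for $z$ understates finite-$n$ tail inflation;
  users comparing against a nominal rate should use the Monte-Carlo
  oracle pattern from the tests.
* The simplified batch model is unsuitable for many-batch, few-samples
  designs (no shrinkage).
* Recurrence counts carriers per direction independently; a probe can
  legitimately appear on both sides, and the burden summary reports the
  four counts (under, over, both, any) without forcing an identity
  between them.
* No accession retrieval is implemented anywhere in the package;
  externally downloaded matrices must be supplied in the plain
  tab-delimited or GCT dialect that `read_expression()` parses.
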