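---
title: "Methods: partial-correlation co-expression screening with covariate control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partial-correlation co-expression screening with covariate control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6Acoexpr)
```

## The model and its assumptions

The package estimates, for every candidate gene $y$ and every m6A regulator
$x$, the partial correlation

$$\rho_{xy \cdot D} = \operatorname{cor}\big(y - \hat y(D),\; x - \hat x(D)\big),$$

where $\hat y(D)$ and $\hat x(D)$ are ordinary least-squares fits of each
variable on the full control-gene matrix $D$ (one row per disease gene, an
intercept always included, since expression is not centered a priori). For a
single control variable this reduces to the classical first-order identity
$(r_{xy} - r_{xZ} r_{yZ}) / \sqrt{(1-r_{xZ}^2)(1-r_{yZ}^2)}$, implemented
separately as `pcor_first_order()`; the two routes agree to $10^{-10}$ and the
residual route is the primary one because only it generalizes to a
many-gene control set. Significance uses
$t = \rho\sqrt{n-k-2}\,/\sqrt{1-\rho^2}$ on $n-k-2$ degrees of freedom. The
$k$ in the degrees of freedom is the number of control genes actually
regressed out — after differential-expression gating of the control list, not
the nominal list length — because each regressed covariate costs one degree
of freedom regardless of where the list came from.

Assumptions inherited from this machinery: expression values are on a
log-like scale after upstream normalization (the package never renormalizes),
residual dependence is adequately captured linearly, and samples are
exchangeable (no batch or kinship structure). Under Gaussian residuals the
$t$ reference distribution is exact, which is why the simulated-null
calibration check can demand a rejection rate of $0.05 \pm 0.02$ rather than
a loose band.

## Tunable parameters

| Parameter | Default | Units | Why this default |
|---|---|---|---|
| `lfc_min` | 2 | log2 fold change | 4-fold change; the conventional stringent GEO2R-style gate. Strict inequality: exactly 2.0 is not called. |
| `de_alpha` | 0.05 | FDR | BH-adjusted threshold, strict. |
| `sd_min` | 0.1 | expression SD | flat-gene exclusion; inclusive (SD exactly 0.1 is removed). Sample SD ($n-1$ denominator) — the choice is immaterial at $n \approx 178$ but must be fixed. |
| `edge_rho_min` | 0.3 | coefficient | network-edge threshold, inclusive by default. |
| `gene_rho_min` | 0.35 | coefficient | the stricter threshold for calling a gene co-expressed. Both thresholds exist deliberately: practice uses both conventions, so both are configuration keys rather than one silently chosen. |
| `pcor_alpha` | 0.05 | p-value | the partial-correlation test's level. Applied on top of the coefficient threshold when `require_significance` is on (default); turning it off reproduces coefficient-only screening. No multiplicity correction is applied to screen p-values by default; `pcor_screen(p_adjust = TRUE)` adds BH. |
| `peak_width` | 100 | bp | fixed m6A peak window. |
| `comparator` | `">="` | — | `">"` also available; thresholds sit exactly on round values often enough that the convention matters. |

Magnitude, not sign, is compared against coefficient thresholds (negative
co-expression is kept, sign preserved on the edge), consistent with a
two-sided coefficient distribution.

## What the synthetic generator emulates

`simulate_expression()` draws, per sample: control genes $D_i \sim N(0,1)$; a
latent confounder $Z$ defined as the standardized mean of the *observed*
control genes; regulators $M_j = \gamma Z + \varepsilon$; direct targets
$\beta M_j + \varepsilon$ (source regulator assigned round-robin); confounded
targets $\gamma Z + \varepsilon$ with no direct term; and pure-noise genes.
Genes designated differentially expressed (by default the regulator and
control sets) receive a `de_shift` mean increase in case samples.

Three generator choices deserve justification:

* **$Z$ is the standardized mean of the observed controls.** Standardizing
  makes $\gamma$ a genuine unit-variance loading: a raw mean of $k$
  independent controls has variance $1/k$, so with a realistically sized
  control set (40 genes) the literal mean would carry variance
  $\gamma^2/40 \approx 0.016$ and the designed confounding would be
  negligible — the generator would no longer test what the method is for.
  Using the *observed* (post-shift) controls keeps $Z$ an exact linear
  function of $D$, which guarantees that residualizing on $D$ removes the
  confounding exactly rather than approximately.
* **DE shifts are applied to regulators before their targets are built**, so
  direct targets inherit their regulator's case/control shift — as real
  targets of a differentially expressed regulator would. Shifting the
  regulator after target construction would inject group variance into one
  side only and attenuate exactly the associations the generator is supposed
  to plant.
* **Defaults mirror a 178-sample islet study**: 178 samples (half cases), 15
  regulators, a 40-gene control set, $\beta = 0.6$, $\gamma = 0.8$, unit
  residual SD, and a DE shift of 3 log2 units (comfortably above the
  $|{\log}FC| > 2$ gate at these group sizes). With these values a direct
  target's expected partial correlation is
  $\beta/\sqrt{\beta^2 + 1} \approx 0.51$ — above the 0.35 call threshold by
  about three sampling standard deviations — while a confounded target's is 0.

What the generator does *not* emulate: normalization artifacts, batch
effects, heavy-tailed or count-like expression, correlated structure within
the control set, linkage disequilibrium between SNPs, or realistic gene
models (sites are assigned to genes by label, on a toy coordinate system with
genes spaced so windows never collide). Passing tests therefore demonstrate
that the estimator, thresholds and interval logic do what they claim under
the stated model — not that the model captures every property of microarray
data. The distributional form of normalized expression is a modelling choice
(Gaussian), made explicitly rather than inferred.

Gene names encode ground truth (`CTRL###`, `REG###`, `DIR###`, `CONF###`,
`NULL###`), so tests recover truth from names alone. All randomness flows
from a single integer seed; the annotation stage derives its own sub-stream
from a fixed offset of that seed, and equal seeds reproduce every table
bit-identically.

## Numerical and convention choices

* **Coordinates.** BED input is 0-based half-open; everything in memory and
  in TSVs is 1-based inclusive (VCF-like). Conversion happens once, at the
  BED reader: a width-1 record maps to `start + 1`, wider records to
  `ceiling((start + end) / 2)`. Strand is ignored throughout. Both genomic
  inputs must share a build; the package treats coordinates as an opaque
  common system and performs no liftover.
* **Peak windows** are centered on the site by default
  (`start = pos - floor(width/2)`, `end = start + width - 1`), with `left`
  and `right` anchors available, because the symmetric choice is the natural
  default when only "a window overlapping the site" is specified and the
  original anchoring convention is unknowable. Starts clip at 1 (the clipped
  window is then narrower). Overlapping windows of one gene are not merged —
  each site keeps its window — so SNP hits can be collapsed per (SNP, gene)
  to the nearest-site peak.
* **SNP containment** is closed-interval on both ends, matching the 1-based
  inclusive interval convention; the screen's default also requires the
  eQTL's target gene to equal the peak's gene (`same_gene`), with the looser
  any-target reading one flag away.
* **"Involving" an allele** counts a nucleotide appearing as either the
  assessed or the other allele — the only reading consistent with the
  shipped 13-SNP example, where six SNPs involve A but only five have A as
  the assessed allele.
* **Bonferroni** defaults to $m =$ the number of eQTL records screened in
  the run; when the input p-values are already adjusted upstream they pass
  through unchanged (`p_adjusted = TRUE`).
* **Degenerate inputs.** Residual variance of zero (a variable fully
  explained by the controls) raises an error rather than returning a silent
  0; $|\rho| = 1$ raises an infinite-statistic error; $n \le k + 2$ raises
  an insufficient-df error. Genes with missing values are dropped with a
  warning before any statistic, because pairwise-complete correlation would
  silently change the degrees of freedom. A gene with zero variance in both
  DE groups gets $p = 1$ with a warning. Computed coefficients are clipped
  to $[-1, 1]$ only within $10^{-12}$.
* **Gating order.** The DE gate is applied to the regulator and control
  lists before the screen (selecting the differentially expressed subset of
  each); candidate genes are all remaining detected genes, with an optional
  flag to DE-gate candidates too. This follows the strategy of gating the
  variable sets that define the model before estimating it.

## Problem sizes used in the checks

The test-suite and acceptance script use simulations sized to the method's
regime while staying quick to run: calibration pools ≥ 2000 null pairs at the
full study dimensions ($n = 178$, $k = 40$); recovery aggregates 50
simulations at those dimensions; oracle equivalence uses ~120 random
instances at $n \le 30$, $k \le 5$; the pipeline fixtures use 80–120 samples.

## Known limitations

* The screen is pairwise gene-versus-regulator; it is not a Gaussian
  graphical model and makes no claim about conditional independence among
  candidates.
* Welch's $t$ with BH is a deliberate, documented stand-in for an upstream
  moderated-$t$ DE analysis; with few samples per group a moderated test
  would be more powerful. The gate thresholds and FDR logic are unchanged by
  this substitution.
* Gene-level m6A status comes from the site file's own gene column;
  re-annotation against a gene model is out of scope, so symbol consistency
  across inputs is the caller's responsibility.
* Negative and positive co-expression are pooled by magnitude; analyses that
  need signed edge sets should filter on the preserved `rho` sign.
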