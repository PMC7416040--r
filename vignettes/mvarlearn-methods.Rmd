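---
title: "Directed connectivity of learning: models, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed connectivity of learning: models, simulation design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvarlearn)
```

# The scientific problem

`mvarlearn` studies how *directed* functional connectivity (dFC) between
brain regions reorganizes over the course of associative learning, and how
that reorganization differs between a healthy-control group (HC) and a
patient group (SCZ). The experimental setting is a block-design paradigm:
Encoding, Rest, Retrieval and Rest epochs of 27 s alternate over eight
cycles, sampled at TR = 3 s, so each epoch spans 9 volumes and a session
has 288 volumes. Learning over the eight retrieval blocks is negatively
accelerated, which motivates splitting the session into an *Early* phase
(cycles 1–4, the roughly linear regime of the learning curve) and a *Late*
phase (cycles 5–8, the asymptotic regime).

Because no subject-level data are deposited for this paradigm, the package
is built around a first-class synthetic-data module: a generator with known
ground truth feeds every analysis stage, so every estimator can be checked
against the quantity it is supposed to recover.

# Models

## Directed connectivity: first-order MVAR

The node signals are modeled as a multivariate autoregressive (MVAR)
process,

$$Z_t = c + \sum_{k=1}^{p} B_k Z_{t-k} + E_t,$$

with model order $p = 1$ by default: at TR = 3 s there is little defensible
temporal structure beyond one lag. The element $b_{ij}$ of $B_1$ measures
the influence of node $j$ at the previous volume on node $i$ at the current
volume — a Granger-style directed effect. Estimation is ordinary least
squares per target node; the per-coefficient $t = \hat b / \mathrm{se}$
quantifies the evidence that a directed influence is nonzero.

Two estimation modes are provided. The default, **bivariate**, fits a
separate two-node MVAR for each unordered node pair and reads off both
directed coefficients, mirroring the pairwise formulation this analysis
family typically uses. The **multivariate** mode fits all six nodes jointly
and reads the off-diagonal entries of $\hat B_1$. The modes answer subtly
different questions: pairwise coefficients are *marginal* effects and can
be driven by indirect paths or shared inputs, while joint coefficients are
*conditional* on the remaining nodes. See "Confounding in pairwise mode"
below for a consequence that shaped the package's calibration design.

Lagged predictor–response pairs are formed strictly within epochs: the
intervening Rest epochs make a lag-1 pair that straddles an epoch boundary
physiologically meaningless at this sampling rate, so segments never cross
boundaries and the first $p$ volumes of each segment act as predictors
only. For the same reason the generator restarts each epoch from the
process's stationary distribution: the analysis never uses cross-boundary
dependence, and restarting keeps epochs exchangeable. An intercept is
included in every regression (BOLD signal levels are arbitrary); a
per-segment demeaning flag is available instead. A configurable
hemodynamic offset (in volumes, default 0) can shift each analysis window
into its epoch.

The six analysis nodes are dlPFC, dACC, HPC, SP, FG and ITG, giving
$6 \times 5 = 30$ directed edges per condition–phase cell. Edge ordering in
every table is row-major by target then source and is stable across the
package.

## Learning curves: the Gompertz model

Recall performance (fraction of 9 items recalled per retrieval block) is
modeled per subject by the Gompertz function

$$f(t) = a\,e^{-e^{\,b - c\,t}},$$

with $a$ the asymptote (learning capacity), $c$ the per-block rate, and an
inflection at $t = b/c$. Two labeling conventions circulate for $b$ and
$c$ in this literature; the package implements the formula exactly as
written above and reports both the raw triple $(a, b, c)$ and the derived
inflection time $b/c$, so either convention can be read off without
ambiguity.

Fitting is bounded nonlinear least squares (`minpack.lm::nlsLM`,
Levenberg–Marquardt) with default bounds $a \in [0, 1.05]$,
$b \in [-10, 10]$, $c \in [0, 10]$. Initialization is data-driven —
$a_0 = \max_t f(t)$, and $(b_0, c_0)$ from the linearization
$\log(-\log(f/a_0)) = b - c\,t$ — with four additional fixed jitters of
that start (five starts in total, all deterministic: fitting never touches
the random-number stream). A bounded L-BFGS-B polish of the raw SSE serves
as fallback for any start where the L-M solver fails; the best converged
start wins. All-zero response vectors return a degenerate $a = 0$ fit
rather than an error, flagged as such; subjects with degenerate or
non-converged fits are excluded from parameter-level group tests and
counted.

## Group and covariate inference

Behavioral group structure is tested with the classical mixed (split-plot)
ANOVA — group between subjects, retrieval block within — with partial
$\eta^2$ per effect and an optional Greenhouse–Geisser correction (off by
default; the correction is reported alongside the uncorrected test rather
than replacing it). Group contrasts on fitted learning parameters use
Welch's $t$ with pooled-SD Cohen's $d$; Welch is the default throughout
because the group sizes (24 vs 31) and variances need not match.

Edge-wise dFC inference runs Welch's $t$ per directed edge and controls
the false discovery rate with Benjamini–Hochberg step-up. The FDR family
is the 30 edges of one condition–phase cell, by default corrected
separately per cell — the output structure presents four independent
significance rings — with a configuration switch for one global family
across all 120 tests. Covariate analyses are Pearson correlations per edge
(equivalent to the simple-regression slope test), BH-corrected within the
same family scope: antipsychotic dosage (PDD/DDD ratio) within the patient
group only, age and FSIQ across all subjects. Missing covariates are
excluded listwise per test and counted.

# What the generator emulates — and what it does not

The generator reproduces the *structure* of the study: two groups of 24
and 31 subjects; the 27 s / TR 3 s / 8-cycle block design; six nodes with
condition- and phase-specific lag-1 coupling; group differences confined
to chosen edges; Gompertz-governed recall with binomial item noise (9
items per block); and covariates with group-appropriate distributions
(FSIQ means and SDs per group, log-normal dosage ratio for patients only),
optionally linked to a generative coupling edge by a linear effect for
recovery testing.

The default coupling matrices place a weak background everywhere
(self-coupling 0.3, cross-coupling 0.05) and raise exactly six directed
edges to 0.3 in one group per condition–phase cell, with the direction of
the group difference encoding the qualitative pattern the pipeline is
meant to detect: reduced patient coupling within a
frontal–hippocampal–fusiform subnetwork during Early Encoding and on dlPFC
afferents during Late Encoding; increased patient coupling on dACC
afferents during Early Retrieval; and, during Late Retrieval, increased
coupling toward but reduced coupling from the dlPFC. All matrices have
spectral radius well below 1 (stationarity is validated at construction,
and the simulator refuses unstable matrices). Innovations are Gaussian
with SD 1 and the stationary mean is held at 100 arbitrary units.
Behavioral defaults give controls $a = 0.9$, $c = 0.8$, inflection at 2.5
blocks, and patients $a = 0.6$, $c = 0.55$, inflection near 3.6 blocks —
lower capacity, slower learning, later transition.

The generator does **not** emulate hemodynamic convolution (the MVAR is
applied to the simulated series directly, as it is to preprocessed BOLD in
practice; an optional exponential-smoothing stress test can be layered on,
off by default), physiological noise, motion, voxel-level spatial
structure (a minimal 4D NIfTI writer exists purely to exercise the ROI
extractor), or attrition. Passing tests therefore certify the estimators
and inference machinery on data satisfying the model's assumptions; they
do not certify robustness to the many ways real BOLD data violate them.

## Seeds and determinism

Every stochastic stage derives per-subject seeds from one master seed by a
fixed integer hash (`subject_seed()`), with disjoint salt offsets for the
time-series, behavioral and replicate-level streams. Identical
configuration and seed reproduce every table byte for byte.

# Confounding in pairwise mode, and the calibration design

During development the null calibration of the edge-wise group comparison
surfaced a genuine property of pairwise Granger-style estimation: an edge
whose *generative* coupling is identical in both groups can still carry a
systematic group difference in its *marginal* pairwise coefficient,
because indirect paths and shared drivers that differ between groups leak
into the two-node fit. A false-discovery proportion measured against
generative truth is therefore only well-defined under a coupling design in
which null edges are null under pairwise projection too.

`calibration_coupling_specs()` provides that design: three reciprocally
coupled, mutually uncoupled node pairs (coupling 0.3 in HC vs 0.05 in SCZ
on the six within-pair directed edges during Encoding; no cross-pair
coupling). The network decomposes into independent two-node blocks, so all
24 cross-block edges have exactly zero coefficients in both groups under
either estimation mode. `fdp_study()` uses it to measure the realized
false discovery proportion of the full pipeline — simulation through
segmentation, pairwise estimation, Welch tests and BH step-up — over
replicate cohorts. At 500 replicates the mean FDP sits below the nominal
$q = 0.05$ (consistent with the theoretical BH bound
$q \cdot m_0/m = 0.04$) with near-unit power on the six true edges.
This is what `scripts/acceptance.R` recomputes.

# Numerical choices and degenerate inputs

* **Stationary restarts.** The per-epoch initial state is drawn from the
  exact stationary distribution (mean $(I-B)^{-1}c$, covariance solving
  the discrete Lyapunov equation via vectorization), precomputed once per
  coupling spec.
* **OLS.** QR decomposition with an explicit rank check; rank-deficient
  designs (e.g. duplicated node signals) and under-determined fits are
  rejected with messages rather than silently pseudo-inverted.
* **Zero-variance edges** in the group comparison get $p = 1$ and a flag
  instead of a Welch failure; a zero effect sum of squares in the ANOVA
  reports $F = 0$, $p = 1$ even when its error term is also degenerate.
* **Segments** shorter than $p + 2$ after the hemodynamic offset are
  dropped with a warning; a cell with no usable segment is an error.
* **Gompertz bounds and ties.** The asymptote bound 1.05 leaves headroom
  above a perfect score so that saturated learners do not pin the solver
  to the boundary. Among multiple converged starts the smallest SSE wins;
  solver tolerances are $10^{-10}$.
* **BH ties** share the most favorable rank outcome (the standard monotone
  adjustment); the rejection mask is exactly the step-up rule.

# Known limitations

* The asymptote of a learning curve that is still rising at the final
  block is weakly identified: under binomial noise its NLS estimate is
  biased upward (about +0.04 to +0.08 for the default patient parameters,
  where the mean curve reaches only ~90% of its asymptote by block 8).
  Recovery tests therefore evaluate mean-asymptote accuracy on curves that
  plateau within the window and check only the sign of the group
  difference under the default parameters.
* Pairwise-mode coefficients are marginal quantities; the confounding
  described above is inherent to the method, not an implementation
  artifact. The multivariate mode is the appropriate tool when conditional
  effects are wanted.
* The mixed ANOVA assumes sphericity unless the Greenhouse–Geisser flag is
  set; neither a multivariate test nor mixed-effects alternatives are
  provided.
* The simulation study sizes used by the test suite (500 replicate
  cohorts for FDP calibration, 2000 null replicates for the $t$-test
  level, 50 seeds for consistency checks) were chosen to keep Monte-Carlo
  error comfortably below the margins being tested while remaining
  routine desk-scale computations.

# A worked example

```{r example, eval = FALSE}
cfg <- default_pipeline_config(seed = 1)
res <- run_pipeline(cfg, out_dir = "mvarlearn_out")

# four condition-phase cells, 30 directed edges each
sapply(res$edge_stats, nrow)

# edges the pipeline flags in Early Encoding
subset(res$edge_stats$Encoding_Early, significant,
       select = c(edge, diff, direction, q))

# behavioral group structure
res$anova
res$param_contrasts
```

The same pipeline is driven from the shell by
`inst/scripts/run-pipeline.R` (`--config`, `--out`, `--seed`), and the
calibration study by `scripts/acceptance.R`.
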