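# mvarlearn

Directed functional connectivity (dFC) of associative learning in
block-design brain-network time series: simulation with known ground
truth, first-order multivariate autoregressive (MVAR) estimation, Gompertz
learning-curve modeling, and edge-wise group inference with
Benjamini–Hochberg FDR control.

## Who this is for

Researchers analyzing task fMRI with Granger-style directed connectivity
who want a *tested* pipeline: every estimator in `mvarlearn` is exercised
against independent oracles and calibration simulations, and a built-in
synthetic-cohort generator reproduces the study structure (two groups of
24 and 31 subjects; alternating Encoding/Rest/Retrieval/Rest epochs of
27 s at TR = 3 s over 8 cycles; a six-node network — dlPFC, dACC, HPC, SP,
FG, ITG — with condition- and phase-specific coupling; recall behavior
with 9 items per retrieval block) so that all downstream stages are
testable without any data download.

## The models

**Directed connectivity.** Node signals follow an MVAR model

  Z_t = c + Σ_{k=1..p} B_k Z_{t−k} + E_t,  (default order p = 1)

where b_ij of B_1 is the lag-1 influence of node j on node i. Coefficients
are estimated by OLS per target node on within-epoch lagged pairs (epoch
boundaries are never crossed), pairwise per node pair by default (a joint
six-node mode is available), giving 30 directed coefficients per subject
for each of the four cells Encoding/Retrieval × Early/Late (cycles 1–4
vs 5–8). Per-coefficient t = b̂/se measures directed influence.

**Learning.** Per-block recall fractions follow the Gompertz curve
f(t) = a·exp(−exp(b − c·t)) — a the asymptote (learning capacity), c the
rate, inflection at t = b/c — fitted by bounded multi-start nonlinear
least squares. Group structure is tested by a mixed group × time ANOVA
with partial η², plus Welch t / Cohen's d contrasts on the fitted
parameters.

**Inference.** Welch two-sample t per directed edge, BH step-up across the
30-edge family of each condition–phase cell (q < 0.05 by default), with
signed difference and direction labels ("reduced/increased in SCZ");
Pearson covariate regressions per edge (antipsychotic PDD/DDD dosage
within patients; age and FSIQ across subjects), BH-corrected the same way.

## Worked example

```r
library(mvarlearn)
res <- run_pipeline(default_pipeline_config(seed = 1),
                    out_dir = "mvarlearn_out")

sapply(res$edge_stats, nrow)
#>  Encoding_Early Retrieval_Early   Encoding_Late  Retrieval_Late
#>              30              30              30              30

subset(res$edge_stats$Encoding_Early, significant,
       select = c(edge, diff, direction, q))
#>          edge  diff      direction        q
#> 2  HPC->dlPFC 0.290 reduced in SCZ 3.33e-07
#> 4   FG->dlPFC 0.130 reduced in SCZ 1.01e-02
#> 11 dlPFC->HPC 0.275 reduced in SCZ 2.82e-06
#> 12  dACC->HPC 0.254 reduced in SCZ 8.10e-04
#> 14    FG->HPC 0.210 reduced in SCZ 4.42e-04
#> 15   ITG->HPC 0.146 reduced in SCZ 3.71e-02
#> 21  dlPFC->FG 0.351 reduced in SCZ 3.33e-07
#> 23    HPC->FG 0.275 reduced in SCZ 2.82e-06
```

The generator plants reduced patient coupling on six
frontal–hippocampal–fusiform edges in Early Encoding; the pipeline
recovers them (edges 2, 11, 12, 14, 21, 23 above, all with the planted
"reduced in SCZ" direction and differences near the generative gap of
0.25), plus two marginal-effect edges picked up by pairwise estimation
through indirect paths (see the methods vignette on confounding in
pairwise mode).

```r
res$anova
#>       effect      F df1 df2     MSe partial_eta_sq          p
#> 1      group  99.18   1  53 0.08870         0.6517  9.720e-14
#> 2       time 165.58   7 371 0.02056         0.7575 5.202e-110
#> 3 group:time  13.96   7 371 0.02056         0.2085  4.400e-16
```

Both groups learn (time), patients recall less overall (group), and the
groups' learning trajectories diverge (group × time). The fitted asymptote
contrast (`res$param_contrasts`) recovers the planted capacity difference:
mean a = 0.92 (HC) vs 0.65 (SCZ), Cohen's d = 1.33.

All tables are also written as tab-delimited text (with provenance
headers) under the output directory, alongside the resolved YAML
configuration, per-subject time series, a run log, and machine-readable
"connectome ring" edge lists. A thin command-line wrapper lives at
`inst/scripts/run-pipeline.R` (`--config`, `--out`, `--seed`). ROI
sphere-averaged series can be extracted from 4D NIfTI images with
`extract_roi_timeseries()`.

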