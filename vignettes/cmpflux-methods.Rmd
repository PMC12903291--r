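---
title: "Methods: plasma metabolome chemometrics and CMP flux inference"
author: "cmpflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plasma metabolome chemometrics and CMP flux inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmpflux)
```

# Overview

`cmpflux` implements a three-armed analysis of two-group plasma
metabolomics data, as used in comparative physiology studies of
high-versus-low-elevation populations:

1. **Untargeted chemometrics** — missingness filtering, imputation, PCA,
   two-class OPLS-DA with cross-validated Q², VIP scoring, permutation
   validation, and selection of significantly differential metabolites
   (SDMs) by the VIP > 1 and P < 0.05 rule.
2. **Quantified panel statistics** — mean ± SEM, pooled Student's t, and
   percent-change reporting for a four-metabolite plasma panel (glucose,
   lactate, β-hydroxybutyrate, NADH).
3. **Stoichiometric flux inference** — relative fluxes over a ten-reaction
   central-metabolic-pathway (CMP) network under pseudo-steady-state mass
   balances, anchored to measured plasma concentrations and normalized to
   glucose uptake (r1 = 100).

A synthetic-data module generates all three input types with known ground
truth, so every statistical property of the pipeline is testable without
external data.

# The synthetic intensity model

LC-MS peak intensities are multiplicative, so the generator works on the
log2 scale: a metabolite baseline `b_j ~ N(base_log_mean, base_log_sd)`,
within-metabolite residuals `e_ij ~ N(0, base_log_sd)`, and a signed
planted effect `delta_j` added to the high group of each differential
metabolite, so the planted log2 group-mean difference equals `delta_j`
exactly. Intensities are `2^log2x`.

Defaults mirror the emulated study design: **6 samples per group**, **705
metabolites**, **222/705 ≈ 31.5 % differential** (split evenly up/down),
and a planted magnitude of 2 log2 units — a 4-fold change, typical of the
stronger differential features in untargeted plasma data. `base_log_mean =
20` and `base_log_sd = 1.5` put intensities around 10^6 with realistic
spread; `missing_rate = 0.1` reflects common post-alignment missingness.
Because the residual sd equals `base_log_sd`, t-test power on planted
effects follows the usual normal-theory formula, which the test suite uses
as an oracle.

Missingness is missing-completely-at-random by default; a left-censoring
mode (`missing_mode = "censor"`) makes low-intensity entries more likely to
be missing, which is closer to how real LC-MS data lose peaks. What the
generator does **not** emulate: retention-time structure, correlated
metabolite blocks, instrument drift, batch effects, and heavy-tailed
contamination. A pipeline that passes recovery tests here is validated for
its statistical logic, not for robustness to those artifacts.

The panel generator draws concentrations from a normal distribution
truncated at zero, parameterized by group mean and CV — the simplest model
consistent with mean ± SEM reporting. The default scenario plants the
reported contrasts (glucose +37 %, lactate −32 %, β-HB −33 %, NADH
unchanged; n = 8 per group). Low-group means (3.0, 2.5, 0.30, 0.010
µmol/mL) and CV = 0.15 are plausible plasma values chosen once; at n = 8
this CV yields pooled-t magnitudes of the same order as the reported panel
statistics.

# Chemometrics decisions

**Missingness filter.** A peak is removed only when its missing fraction
strictly exceeds 50 % in *every* group. This reading keeps metabolites
well-observed in one group only — which are biologically informative — and
makes the boundary case (exactly 50 %) a retention. The stricter any-group
rule is available via `rule = "any"`.

**Imputation.** Half-minimum per metabolite, the conventional stand-in for
below-detection-limit peaks; `min` and `zero` are available.

**Scaling.** Unit-variance (auto) scaling with mean centering is the
default for both PCA and OPLS-DA, the de-facto chemometrics standard;
Pareto is available. All models run on `log2(x + 1)` intensities.

**OPLS-DA.** The response is ±1, centered. Per orthogonal component the
PLS weight is computed, the y-orthogonal part of the loading extracted,
and X deflated; one predictive PLS component is then fit on the filtered
matrix. `n_orth = 1` is the default, standard for two-class models. R²Y is
computed on training data; Q² = 1 − PRESS/SS from **7-fold, group-stratified,
seeded** cross-validation in which scaling, filtering and fitting are all
re-estimated inside each fold — anything less re-uses test information.
The fold count is a conventional choice (the emulated workflow does not
state one). Component signs in PCA are fixed by the
largest-|loading|-positive convention so score plots reproduce.

**VIP** uses the predictive component only (the orthogonal components by
construction carry no class information); with one predictive component
`VIP_j = sqrt(p)·|w_j|` and `mean(VIP²) = 1` exactly, which the tests
assert to 1e-10. Which components a vendor platform uses is often
undocumented; predictive-only is the defensible choice and is stated here.

**Permutation validation** refits the *entire* model (including CV) under
label shuffling, default 200 permutations, with the add-one-corrected
empirical p-value `(1 + #(perm ≥ obs)) / (B + 1)` — valid, slightly
conservative, never zero. On null data the Q² permutation p-value is
uniform (checked by a KS test across 50 independent simulations).

**SDM selection** applies strict inequalities (VIP > 1 AND p < 0.05) with
pooled two-sided t-tests on log2 intensities; a VIP of exactly 1 is never
selected. Direction comes from the sign of the high-vs-low log2 fold
change, so up + down always partitions the selected set.

A note on redundancy: appending a duplicate metabolite column perturbs the
predictive score direction by O(1/p) under unit-variance scaling — small
but not zero. The suite asserts direction stability (correlation above
1 − 1e-3 at p = 200), which is the scale of the true effect.

# Panel statistics decisions

The t-test is pooled-variance Student (df = n₁ + n₂ − 2 = 14 at n = 8 per
group, which is what the emulated design implies); Welch is available via
`var_equal = FALSE`. The sign convention is **low minus high**: a
metabolite elevated at high elevation gets a negative t. Percent change is
relative to the low group. Normality (Shapiro–Wilk) and variance
homogeneity (two-sided F-ratio) are reported as advisory flags at
α = 0.05; the pipeline still runs the t-test and records the report, and
zero-variance groups are flagged as degenerate rather than raised as
errors. Published panel p-values in this literature are sometimes
internally inconsistent with their printed t and df; `cmpflux` always
computes exact two-sided p from the t distribution rather than
reproducing printed values.

# The flux model

## Network and roles

The packaged CMP network (`inst/extdata/cmp_network.json`) has ten
irreversible reactions: glycolysis (r1 glucose→G6P, r2 G6P→F6P, r4
F6P→2 GAP, r5 GAP→PEP + NADH, r6 PEP→pyruvate), the pentose-phosphate
branch (r3 G6P→PPP pool), lactate fermentation (r7 pyruvate + NADH→
lactate), the pyruvate-dehydrogenase link (r8 pyruvate→acetyl-CoA +
NADH), TCA oxidation (r9 acetyl-CoA→TCA products + 3 NADH) and
ketogenesis (r10 2 acetyl-CoA + NADH→β-HB). Six intermediates — G6P, F6P,
GAP, PEP, pyruvate, acetyl-CoA — are pseudo-steady-state nodes whose mass
balances are homogeneous constraints. Glucose, lactate, β-HB and NADH are
boundary-measured. NADH is deliberately a *measured* node, not a
pseudo-steady-state one: its plasma concentration is assayed, and cofactor
stoichiometry in the reactions carries it. The exact reaction list and
cofactor coefficients of any particular published network vary; this file
is a documented reconstruction satisfying the stated structural
constraints, and because the network is a data file, any other topology in
the same JSON/TSV layout drops in without code changes.

## Concentration→rate proxy

Plasma concentrations are static quantities; mapping them to relative
rates requires a modeling rule. `cmpflux` uses the simplest rule
consistent with normalization to glucose uptake: the net production rate
of a measured metabolite m is taken proportional to its concentration
ratio against the reference metabolite,

```
S_m · r = sign_m × scale × C_m / C_ref,        r_ref = scale = 100,
```

with sign +1 for net-produced outputs (lactate, β-HB, and NADH as a net
accumulation node) and −1 for consumed inputs (glucose). This is stated
prominently because it is an assumption, not a measurement; users with
actual boundary rates can supply them directly by editing the assembled
system, and the per-node `sign` field in the network file overrides the
topological inference. Only concentration ratios enter, so rescaling all
measurements (unit changes) provably leaves the solution unchanged.

## Solving, diagnostics, normalization

The system (6 balances + 1 anchor + 3 boundary equations for the default
network) is solved by SVD-based minimum-norm least squares with
tolerance-truncated rank (default 1e-8 relative to the anchor scale);
the solver is cross-checked against a dense pseudo-inverse oracle in the
tests. Diagnostics always report rank, equation/unknown counts, the
determinacy class (determined / overdetermined / underdetermined) and the
residual norm of the internal balances, so non-unique or inconsistent
systems are visible rather than silent. With `nonnegative = TRUE`,
irreversible fluxes are constrained ≥ 0 via nonnegative least squares
(reversible reactions are split into forward/backward parts); if the
constraints make the balances unattainable the violated equations are
named in the error. Normalization multiplies all fluxes by
`scale/flux(ref)` and then sets the reference exactly to the scale,
avoiding floating-point drift on the anchor; it is idempotent.

## Synthetic flux scenarios

Ground-truth vectors are sampled from the null space of the
internal-balance rows (so every pseudo-steady-state balance holds to
machine precision), rejected until all irreversible fluxes are strictly
positive, and scaled to r_ref = 100. Boundary concentrations are obtained
by inverting the proxy rule with a reference concentration of 5 µmol/mL
(a plausible plasma glucose level — the value cancels in the solve), then
multiplied by lognormal noise `exp(N(0, noise_frac))`. At noise 0 the
round trip recovers the truth to ~1e-14 relative error; at 5 % noise the
median relative error across the ten reactions stays within 10 %
(median ≈ 3–4 % over 50 scenarios in the test suite).

# Problem sizes and determinism

The test suite and acceptance script use study-scale chemometrics
problems (12 samples × 705 metabolites) for single fits, and smaller
matrices (12 × 40–80) for replicated calibration studies (50 permutation
runs, 20 null fits), which keeps the full suite under a minute while
leaving every statistical check at meaningful power. Every stochastic
stage takes an explicit seed; workflows derive per-stage seeds from one
global seed via a documented stage-name hash, so any stage can be re-run
in isolation bit-for-bit.

# Known limitations

- The concentration→rate proxy is an assumption; inferred fluxes are
  relative quantities conditional on it and on the network topology, not
  measurements. ¹³C flux analysis, FBA with objectives, thermodynamic and
  kinetic constraints are out of scope.
- OPLS-DA here is two-class with one predictive component; multi-class
  models and S-plot diagnostics are not implemented.
- The generator's independence across metabolites makes VIP/SDM recovery
  tests optimistic relative to real, correlated metabolomes.
- No multiple-testing correction is applied across the four panel
  metabolites, matching the emulated analysis; users comparing many
  quantified metabolites should add one.

# Worked example

```{r example, eval = FALSE}
net <- default_cmp_network()
scen <- generate_flux_scenario(net, seed = 7, noise_frac = 0)
S <- build_stoich_matrix(net)
sys <- assemble_balance_system(S, net, scen$measurements)
sol <- normalize_fluxes(solve_fluxes(sys, nonnegative = TRUE))
sol
export_flux_graph(net, sol, file.path(tempdir(), "flux_graph"))
```
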