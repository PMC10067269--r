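---
title: "Measuring epistasis along environmental gradients with epiScape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring epistasis along environmental gradients with epiScape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiScape)
```

# The measurement model

`epiScape` analyses head-to-head competition assays. Each assay competes one
genotype against a fixed fluorescently labelled reference strain in one
environment and records four flow-cytometry densities: competitor and
reference, before and after one growth cycle. The competitive index

$$\hat w = \ln\frac{D^f_{comp}/D^f_{ref}}{D^i_{comp}/D^i_{ref}}$$

is a log-ratio, so it is invariant to dilution and antisymmetric under
exchanging the two channels, and measurement errors that are multiplicative
on densities become additive on $\hat w$. Densities are accepted as positive
reals; zero or negative values are rejected outright rather than
pseudocounted, because the measurement model supplies no pseudocount rule.

Replicates are aggregated as unweighted means of per-replicate indices (not
as indices of pooled counts), with the standard error $s/\sqrt n$; a cell
measured once has no defined SE and is flagged. The two dye orientations
(GFP-labelled competitor vs mCherry-labelled competitor) are pooled by
default; `dyeSwapCheck()` regresses orientation-wise means against each other
(slope ≈ 1, intercept ≈ 0 for a neutral marker, with incremental F-tests for
environment and genotype structure in the discrepancies) and should be
consulted before pooling. Pooling is a switch in `summarizeFitness()`.

The central container, `FitnessLandscape`, extends `SummarizedExperiment`:
genotypes (resistance allele × knock-out allele) are rows, environments
(antibiotic µg/ml × temperature °C) are columns, and `w_mean`, `w_se`, `n`
are assays. All downstream statistics operate on this object.

# The five epistasis measures

Every (resistance allele ≠ WT, knock-out ≠ none, environment) triple defines
a four-genotype landscape {WT, A, B, AB} (`LandscapeSlice`); the default
design yields 15 per environment, 180 in all.

**Pairwise epistasis.** $\varepsilon = w_{AB} - w_A - w_B + w_{WT}$:
translation-invariant, linear under scaling, zero iff the slice is additive.

**Gamma.** For each focal mutation $m$, its effect on the background with no
mutation at the other locus is paired with its effect on each single-mutant
background; the pairs are pooled across focal mutations and summarized by one
Pearson correlation per environment. With two loci this base-vs-added pairing
is the only one available. The per-class variants (`"ABR"`, `"KO"`) restrict
the *focal* mutation only, leaving the added mutation free — the natural
reading of focusing on one mutational class. If either pooled vector has zero
variance the correlation is undefined; the value is reported as 1 when the
two vectors are element-wise identical (effects perfectly preserved, the
no-epistasis limit) and NA otherwise, both carrying a `degenerate` attribute.
Note that γ dilutes with landscape size: the pooled correlation over the
whole dataset involves more pairs than either class alone, so cross-class
comparisons of γ should be made cautiously.

**Sign epistasis.** With effects $s_{A0} = w_A - w_{WT}$,
$s_{A1} = w_{AB} - w_B$ (and symmetrically for B), a locus "flips" when both
effects are non-zero with opposite signs; both flipping is reciprocal sign
epistasis (the prerequisite for multiple peaks), exactly one is simple.
Comparisons use point estimates with exact zeros carrying no sign (a
configurable absolute tolerance exists, default 0); statistical uncertainty
enters only through the bootstrap layer: per bootstrap sample all slices are
re-classified, the per-environment category fractions are averaged over
samples, and a slice is "detected" for a category occurring in more than 5%
of samples.

**Roughness-to-slope.** The best additive plane over the four genotypes is
fitted by least squares; roughness is the RMS residual (dividing by the
number of genotypes, 4, not by residual degrees of freedom — with 4 points
and 3 parameters any df-corrected convention is a constant multiple, and this
one gives the testable closed form $|\varepsilon|/4$), slope is the mean of
the absolute locus coefficients (signs would cancel meaninglessly). The ratio
is 0 for additive slices, scale-invariant, `Inf` when the fitted plane is
flat but residuals are not, and defined as 0 in the completely flat 0/0 case.

**Diminishing returns.** Per environment and mutational class, effects are
regressed on the fitness of the background carrying them, pooled across the
class's mutations in a single regression; the slope is averaged over
bootstrap samples with a percentile interval, and "significant" means the
interval excludes zero. Backgrounds can be excluded for sensitivity analyses
(e.g. removing a hypersusceptible knock-out).

# Inference

The parametric bootstrap redraws every cell independently from
Normal($\hat w$, SE), the standard model for a mean of log-ratios. Cells with
$n = 1$ borrow the median SE of their environment and are flagged. Percentile
intervals use order-statistic (type-1) quantiles, which makes them exactly
equivariant under monotone transformations of the metric — interpolated
quantiles are not. The default is 1000 samples at level 0.95; the test suite
uses 200–500 for runtime. All draws derive from an explicit integer seed, and
the private-stream helper guarantees bit-identical streams without touching
the caller's RNG state.

Known behaviour worth stating plainly:

- With $n = 3$–4 replicates the plug-in SE is itself noisy, and
  Normal(mean, SE) ignores that; nominal 95% intervals for pairwise epistasis
  empirically cover slightly under 95% (the acceptance suite measures this at
  the 4-replicate condition, where coverage lands comfortably inside 90–99%).
  A t-based or studentized bootstrap would correct this but is deliberately
  out of scope (percentile only).
- The reported point for bootstrap mean fractions (e.g. mean reciprocal-sign
  fraction) is the mean of a discrete distribution and can fall outside its
  own percentile interval when the distribution is concentrated at 0 with a
  thin upper tail; the interval brackets the distribution, not the mean.
- The four corners of neighbouring slices share cells (the wild type appears
  in all 15 slices of an environment), so estimation errors — and any
  3-SE-exceedances in recovery checks — are correlated across slices rather
  than independent.

Per-environment metrics are regressed on a continuous predictor (antibiotic
concentration in µg/ml by default; temperature; or environmental quality)
with a closed-form simple OLS reporting slope, the slope F-test and adjusted
R²; a constant metric is reported as F = 0 rather than 0/0. Significance is
reported at α = 0.01 throughout. Environmental quality defaults to the mean
log growth of all competitor strains, $\ln(D^f_{comp}/D^i_{comp})$ averaged
over genotypes and replicates — the definition is an explicit package
assumption; reference-strain and combined-growth variants are selectable.
Cost-of-resistance contrasts compare each resistance allele against the
susceptible allele on the same knock-out background in antibiotic-free
environments, flagging a cost only when the whole percentile interval is
below zero.

# The linear-model suite

Per-replicate indices (not cell means) are the response, preserving residual
degrees of freedom. Factors use treatment coding with the wild-type reference
levels; temperature is an ordered factor with orthogonal polynomial (linear,
quadratic) contrasts; antibiotic concentration is an unordered factor in the
model suite — the coding under which concentration effects appear as
level-wise interaction coefficients with susceptible genotypes — but a
continuous covariate in the trend regressions; both are switches. The ladder
is additive → + $G_{rpoB} \times E_{AB}$ → + $G_{rpoB} \times G_{KO}$ with
nested F-tests $F = ((SSR_r - SSR_f)/\Delta df)/(SSR_f/df_f)$; for a single
added column this equals the squared t-statistic, which the tests verify.
Fits go through a QR solve (`lm.fit`) with rank-deficiency rejected by
column name. Second-order (G×G×E) designs are constructible through
`buildDesign()` but no selection procedure is provided.

# What the synthetic generator emulates — and what it does not

`scenario()` reproduces the study design: 4 resistance alleles × 6 knock-out
states (24 genotypes; the third resistance allele is labelled I572S, the
label used in all quantitative reporting, and is configurable), 4 rifampicin
concentrations (0, 4, 8, 10 µg/ml) × 3 temperatures (37, 40, 42 °C), 3–4
replicates per cell, reference strain *rpoB* H526Y. True fitness is additive
allele effects plus a pairwise interaction term, always relative to the
reference genotype (whose true index is exactly 0). Counts are emitted with
multiplicative lognormal noise, SD 0.05 per density channel by default, on
each of the four channels; the 20 h growth cycle is abstracted into a single
per-environment reference growth factor (no lag/exponential/stationary
structure). Effect scales follow the study's qualitative picture: resistance
effects of order 1–4 under antibiotic that overshadow knock-out effects of
order −1 to 0.2, with the waaP knock-out hypersusceptible to the antibiotic.
Dye orientation is neutral by default, with a bias knob for power-testing the
dye-swap check.

The named scenarios isolate one causal structure each: `additive` (no
interactions anywhere), `gxe_only` (strong antibiotic suppression of
susceptible alleles, zero G×G), `masking` (resistance rescues waaP under
antibiotic), `reciprocal_sign_at_zero_ab` (strong negative interactions
between the weak resistance allele and two mildly beneficial knock-outs, only
without antibiotic), `diminishing_returns` (interactions proportional to the
background's knock-out effect, giving an exact −0.4 pooled slope), and
`paper_like` (interactions decaying linearly with concentration, vanishing
above 8 µg/ml). Because the generator draws independent lognormal noise per
channel, it does not emulate shared plate/day effects, density-dependent
growth, or count-based (Poisson) error at low densities — so passing
recovery tests demonstrate correctness of the estimators under the stated
noise model, not robustness to structured real-world error.

# Problem sizes and numerical choices in the test suite

The suite exercises: exact identities on dyadic-rational fitness values
(chosen so floating-point addition is exact and "equals zero" can be asserted
identically); 1000 random slices against an explicit least-squares oracle at
1e-10; OLS against the normal equations at 1e-8; bootstrap calibration with
200 simulated datasets at 400 samples each; scenario discrimination over 20
seeds at 500 bootstrap samples; and null calibration of the nested F-test
with 500 replicates against the uniform distribution (Kolmogorov–Smirnov).
These sizes keep the full suite in the low minutes on one CPU while leaving
Monte-Carlo margins wide relative to the asserted thresholds.

# Limitations

Beyond the inference caveats above: the container is two-locus by
construction (no statistics needing > 2 loci, such as peak counts or adaptive
walks); no mixed-effects models or model selection; no FCS parsing, gating,
growth-curve or MIC estimation — counts arrive as tables; and intervals are
percentile-only.
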