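---
title: "Modelling the development of structural covariance networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the development of structural covariance networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnet)
```

# The problem

Structural covariance asks how the morphology of one cortical region
relates to another *across people*: if region A is thick in the same
individuals in whom region B is thick, the two covary, plausibly because
they mature together. `scnet` estimates such networks repeatedly along the
age axis of an accelerated longitudinal cohort and models how their
topology changes, without ever fitting an explicit longitudinal network
model — each network is a cross-sectional snapshot of a narrow age window.

This vignette explains the model and procedure, the parameters that matter,
what the synthetic generator does and does not emulate, and the numerical
and design choices that were genuinely open.

# The pipeline, stage by stage

## Residualization

Thickness of each region is regressed on sex, cohort and scanner across the
*full* sample and replaced by internally studentized residuals,
$e_i / (\hat\sigma\sqrt{1 - h_{ii}})$. Studentization matters because the
design is unbalanced (the scanner flag only switches on for one cohort's
final wave), so raw residuals have unequal variances across design cells.
Constant covariates are dropped with a warning rather than an error so that
single-cohort or single-scanner subsets keep working. A consequence of
studentization worth knowing: exact idempotence of residualization holds
only when leverages are constant (balanced designs); in unbalanced designs
a second pass changes values by a factor of order the leverage spread.

## Sliding age windows

Windows slide over the pooled, age-sorted *scans* (not participants): a
window of `bin_size` consecutive scans is placed at offsets 0, s, 2s, …
with step `s = round_half_up(step_fraction * bin_size)`, plus one terminal
window anchored at the oldest scans whenever the regular grid does not
reach the end of the pool. This convention is locked by tests because it is
the one that reproduces all three reference bin counts on a 366-scan pool
(16 bins at size 80 / step 25 %; 12 and 23 as the extremes over the nine
configurations). Each window then keeps one scan per participant — the scan
closest to the window's median age, with exact ties broken toward the
smaller scan id for determinism — and the bin's median age is recomputed
over the retained scans. Deduplication may leave a bin with fewer rows than
`bin_size`; we do not re-expand the window, since any re-expansion rule
would change the bin's age range and no convention recovers the reference
counts better.

## Bootstrap edge thresholding

Within each bin, participants are resampled with replacement `B` times and
the correlation matrix re-estimated. The edge-level evidence of a
consistently positive correlation is summarized as
$p = (\#\{b : r_b \le 0\} + 1)/(B + 1)$ — the add-one convention keeps p
strictly positive, which matters because Benjamini–Hochberg is then applied
across all region pairs and a zero p-value would survive any correction.
Surviving edges additionally need a positive point-estimate correlation
(the fraction of survivors that fail this guard is recorded as a
diagnostic); survivors are set to 1. A bootstrap replicate in which a
region is degenerate (zero variance) counts as $r_b = 0$, i.e. against
retention, so pathological inputs bias toward sparsity rather than NaN.

With default parameters the procedure retains essentially no edges among
independent regions (the test suite checks < 5 % under a complete null)
and retains an edge between duplicated regions with probability 1.

## Graph metrics

Only density and degree are used: bootstrap thresholding produces networks
of *varying* density, which confounds comparisons of higher-order metrics
across bins, so none are offered. Standardized degree uses the sample
(n − 1) SD; when all degrees are equal the z-degrees are defined as zero
(no hub can exist in a regular graph) rather than erroring, because tiny
test networks and empty bins do occur. Hubs require z > 1 (strict) in at
least two bins of a configuration, which suppresses one-bin flukes. Modular
densities (intra per module, inter per unordered pair) are divided by the
network's global density so that module-specific change can be read against
the global trend; when the global density is zero the normalized values are
NA and trajectory fits skip them.

## Trajectory models and selection

A per-bin metric series is modelled against bin median age with three
Gaussian maximum-likelihood fits: intercept-only, linear, and a natural
cubic spline with knots at the minimum, median and maximum age — two basis
functions beyond the intercept, i.e. exactly the flexibility of a rank-3
smooth (one bend: a peak or a trough). A penalized rank-3 smooth with
ML-selected smoothing spans the same small function space; we fit it
unpenalized, which makes AIC bookkeeping exact and removes a dependency,
and a cross-check test confirms the fitted curves agree with a rank-3
unpenalized cubic regression spline GAM. AIC counts the error variance as
an estimated parameter in all three models, so differences are internally
consistent; a more complex model is selected only when its AIC is at least
3 lower than *every* simpler model. The smooth term's p-value comes from
the F-test of the spline model against the null model and is
Benjamini–Hochberg-corrected within the nodal and modular batches of each
configuration. The peak age is the argmax of the fitted smooth on a dense
(401-point) grid over the observed age range, reported when the smooth is
selected, together with a flag for whether the maximum is interior.

Bin-level points are treated as independent observations although
overlapping windows share scans; this is a known approximation of the
sliding-window approach, which is why findings are only *reported* when
detected in more than half of the nine window configurations.

## Thinning rates and spatial surrogate tests

Per-region thinning rates are the age coefficients of random-intercept
linear mixed models (REML, via `lme4`) with sex, cohort and scanner as
fixed effects. Regions whose mixed model fails or does not converge fall
back to OLS with a flag — with singleton participants this is exact, since
the random intercept then absorbs nothing.

The correlation between the thinning map and a degree map is tested against
surrogate maps that preserve the thinning map's value distribution exactly
and its spatial autocorrelation approximately: permute, smooth with
inverse-distance weights over the k nearest neighbours (k from a small grid
including k = 0, i.e. no smoothing), keep the k whose binned variogram —
after rescaling the smoothed map to the source mean and SD, since smoothing
shrinks variance — best matches the source variogram, then rank-remap onto
the source values. The variogram uses 10 equal-count distance bins per
hemisphere. The p-value is again add-one, and by default compares absolute
correlation magnitudes (the empirical direction is recorded separately); a
signed one-sided alternative is available. Under independent maps the test
rejects at close to its nominal 5 % level (checked over 500 replicates).

## Sex stratification

The pipeline is re-run within each sex with cohort and scanner (not sex) as
covariates, full `bin_size` windows within the stratum, and the stratum's
own global density as the modular normalizer — which is also why modular
densities are never tested *across* sexes. Global trajectories are compared
with a shared model (one smooth plus a sex offset) versus separate smooths
per sex, under the same AIC ≥ 3 margin; separate-smooths-plus-offset was
chosen over an ordered-factor parameterization because it keeps the two
models strictly nested with an interpretable parameter count. Strata
smaller than the bin size skip the configuration with a warning; saturated
fits (more parameters than pooled bins) are recorded as unfittable rather
than selected.

# The synthetic generator

`generate_dataset()` draws from

$$y_{s,r,t} = \mu_r + d_s + \beta_{sex} + \beta_{coh} + \beta_{scan}
  + slope_r\,(a - a_0) + \lambda^g_r(a)\,F_t + \lambda^m(a)\,G_{m(r),t}
  + \varepsilon$$

with per-scan standard-normal factors (one global, one per module) whose
loadings carry a Gaussian bump in age. The bump is the single interpretable
knob that plants a covariance peak; explicit per-age covariance matrices
were rejected as high-dimensional and hard to reason about. Two cohorts
mirror a two-wave/long-gap and a three-wave/short-gap design; wave
retention is solved so the expected scan count hits the target (yielding
the familiar mix of one-, two- and three-scan participants), and the
scanner flag switches on only at the multi-wave cohort's final wave —
exactly the confound the residualization must remove. Regions of two
designated "hub" modules get a larger baseline global loading (hence higher
degree at all ages) and, via a negative coupling, steeper thinning slopes.

Default variance components (`subject_sd` 0.02 mm, `noise_sd` 0.12 mm,
global loading 0.015 mm baseline with a 0.08 mm bump, hub boost 0.035 mm,
module loadings 0.02/0.03 mm) were chosen by variance arithmetic so that
off-peak between-region correlations sit near the bootstrap retention
threshold at bin sizes 70–90 while peak correlations clearly exceed it:
this keeps the retained density mid-range off-peak and below saturation at
the peak, so the density trajectory actually carries the peak's location.
Thinning slopes default to −0.03 ± 0.003 mm/year, typical for this age
range.

What the generator does *not* emulate: image-level artifacts and motion,
non-Gaussian thickness distributions, spatially smooth gradients beyond the
module structure, nonlinear thinning, and dropout that is informative about
thickness. Passing tests therefore demonstrate the pipeline's statistical
behaviour under a factor-structured, Gaussian world — not robustness to
everything real data can do.

## A caveat discovered with this generator

With the planted coupling switched off, the thinning map and the oldest-bin
degree map are *not* independent: both are estimated from the same scans,
and their estimation errors share the factor structure. Empirically the
null distribution of their correlation is centred near −0.16 with all tail
exceedances negative, so the surrogate test — which randomizes one map's
spatial arrangement but cannot remove cross-map dependence — rejects at
roughly 15 % rather than 5 % in this configuration (a naive permutation
test behaves identically, confirming the surrogate machinery itself is
calibrated; see also the 5 %-level calibration under truly independent
maps). The practical reading: a weak negative thinning–degree correlation
can arise from shared-data dependence alone, and only clearly stronger
associations — like the planted coupling, which yields r around −0.4 to
−0.8 with p ≤ 0.02 — should be interpreted. It is consistent with this
caveat that even "control" contrasts on real cohorts (e.g. youngest-bin
correlations) tend to come out weakly negative rather than null.

# Problem sizes used by the tests

The suite exercises the full pipeline at 60 regions (30 per hemisphere,
7 modules), ~366 scans, B = 200 bootstrap resamples and 500 surrogates for
the headline recovery checks; calibration studies use 500 null series for
model selection, 500 replicates for the surrogate test, and 40 replicates
at B = 100 / 200 surrogates for the coupling-free null. End-to-end
determinism is checked by hashing all written outputs of two identical
runs. The defaults of `run_scn_pipeline()` (B = 1000, 1000 surrogates,
nine window configurations) reproduce the reference analysis settings.

# Known limitations

* Overlapping bins are modelled as independent points; consensus reporting
  mitigates but does not remove this.
* The smooth has at most one bend by construction; faster developmental
  dynamics would be mis-modelled (by design, given ~12–23 bins).
* The surrogate method is a simplified variogram-matcher; it preserves the
  value multiset exactly but matches autocorrelation only as well as the
  k-NN smoothing family allows.
* Map-correlation tests cannot detect or correct dependence *between* the
  two maps that does not run through spatial arrangement (see the caveat
  above).
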