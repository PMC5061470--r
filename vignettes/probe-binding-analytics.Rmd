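---
title: "Models and methods for quantitative chemical-probe characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for quantitative chemical-probe characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probetools)
```

probetools reimplements, as tested reusable functions, the four quantitative
assays that characterize a promiscuous small-molecule inhibitor against a
protein target panel — here a pan-bromodomain chemical probe profiled against
the human bromodomain (BRD) family:

1. thermal-shift (DSF) melt-curve fitting and ligand-induced ΔTm,
2. single-site isothermal titration calorimetry (ITC) in reverse geometry
   with full thermodynamic decomposition,
3. FRAP quantification of chromatin displacement in cells, and
4. viability dose–response and Chou–Talalay combination-index analysis.

Every input modality has a synthetic generator with serialized ground truth
(`gen_melt_plate()`, `gen_titration()`, `gen_frap_traces()`,
`gen_dose_grid()`), so each stage is exercised end to end by
parameter-recovery tests without any instrument download.

## Thermal shift (DSF)

A well's fluorescence trace is modeled as two-state unfolding with linear
native and denatured baselines:

$$y(T) = y_F(T) + \frac{y_U(T) - y_F(T)}{1 + e^{\Delta_u G(T)/RT}},
\qquad y_F(T) = a_F + b_F T,\; y_U(T) = a_U + b_U T.$$

The printed form of this model leaves the temperature dependence of
$\Delta_u G$ open; we adopt the standard van 't Hoff parametrization with
zero heat-capacity change,

$$\Delta_u G(T) = \Delta H_u \left(1 - \frac{T_K}{T_{m,K}}\right),$$

with temperatures in kelvin. Two parameters $(T_m, \Delta H_u)$ are then
identifiable from a single curve, and at $T = T_m$ the model passes through
the baseline midpoint exactly.

**Fitting.** For fixed $(T_m, \Delta H_u)$ the four baseline coefficients
enter linearly, so they are profiled out by linear least squares and only
the two nonlinear parameters are searched (variable projection), with
$\Delta H_u$ on the log scale so positivity is structural. The search is
Nelder–Mead (relative tolerance $10^{-12}$, restarted once from its own
solution; a degenerate-simplex exit at a lower SSE after a converged first
pass still counts as converged). Baselines are fitted jointly with the
transition rather than pre-fitted on fixed temperature windows — the windows
would be arbitrary, and the joint fit is exact on model data.

**Initialization.** $T_m^{(0)}$ is the temperature of the steepest rise of
a 5-point moving-average smoothed signal; $\Delta H_u^{(0)} = 100$ kcal/mol;
baselines start implicitly from the profile solve. These defaults are
config-exposed (`dsf_dh_init`).

**Degenerate inputs.** A curve whose total range is below
`dsf_noise_floor_mult` (default 5) times the median absolute successive
difference is flagged unfittable — flat wells produce `converged = FALSE`,
never an error, and are excluded (and listed) by `plate_summary()`. Curves
with a post-transition fluorescence decay — an aggregation artifact the
two-state model cannot represent — are clipped by
`truncate_post_transition()` at the global maximum plus a 5 °C margin.

**ΔTm.** Each sample replicate's shift is its midpoint minus the mean
midpoint of the same-plate ligand-free reference wells; replicates are
reported as mean ± sample SD (n−1). The plate design template
(`dtm_panel_plate_spec()`) mirrors the published panel: 12 proteins × 2
biotinylated probe variants × triplicate plus triplicate references.
References are averaged per plate; per-column pairing is not implemented.

## Single-site ITC in reverse geometry

The probe (ligand, concentration 13–25 μM) sits in the 0.2003-ml cell and
the protein (200–650 μM) in the syringe — a reverse titration, chosen in the
original experiments so the last injections measure pure dilution heat. The
schedule is a 0.3-μl control injection plus 38 × 1 μl at 15 °C. Finite
injections displace cell volume; the bookkeeping convention (shared by the
forward model and the fitter, so recovery tests are convention-invariant) is

$$[L]_{tot} = L_0\,\frac{1 - \Delta V/2V_0}{1 + \Delta V/2V_0},\qquad
  [P]_{tot} = P_{syr}\,\frac{\Delta V/V_0}{1 + \Delta V/2V_0}.$$

Site occupancy $\Theta$ is the physical root of the 1:1 mass-action
quadratic (evaluated in the cancellation-free form), cumulative heat is
$Q_i = N\Theta_i[L]_i\,\Delta H\,V_0$, and the per-injection heat applies
the displacement correction
$\Delta Q_i = Q_i - Q_{i-1} + \frac{dV_i}{V_0}\frac{Q_i+Q_{i-1}}{2}$.

**Dilution baseline.** `correct_dilution()` implements the published
convention: the mean of the last `itc_n_baseline` (default 2, configurable
to 1 to match the single-last-injection wording) per-μl heats is the
dilution baseline, subtracted in proportion to volume; the control
injection is always dropped. The *fit*, however, treats the
volume-proportional baseline as a fourth free parameter profiled linearly
together with ΔH at each candidate $(N, K_D)$. The two estimates coincide
for saturated titrations, but the joint estimate uses all injections
instead of anchoring on two noisy ones and is therefore the least-squares
efficient version of the same convention. Noiseless recovery is exact
(relative error < 10⁻⁴) either way.

**Weak binding.** A fit is labelled weak when the optimizer fails, the
fitted $K_D$ exceeds `weak_kd_nM` (50 μM), the c-value
$c = N[L]/K_D$ falls below `weak_c_value` (1), or the corrected heat series
never exceeds `itc_min_signal_ucal` (0.5 μcal). The published table prints
"Weak binding" without a criterion; this documented rule is configurable.

**Thermodynamics.** $\Delta G = RT\ln K_D = -RT\ln K_B$ and
$T\Delta S = \Delta H - \Delta G$ with $R = 1.9872\times10^{-3}$
kcal/(mol K) and $T = 288.15$ K. These derived quantities are exact
identities on every `binding_fit`. At this temperature the printed panel's
free energies are reproduced from the printed $K_D$ to 0.01 kcal/mol (one
panel row, BPTF, is internally consistent with its ΔH − TΔS but not with
its own printed $K_D$; it is reproduced through the former).

**What K_D precision the noise regime allows.** The synthetic generator's
0.1-μcal per-injection Gaussian noise is a documented convention (the
original instrument noise is unpublished). Under that convention the
Cramér–Rao bound for $K_D$ on this schedule is 14–23 % (1 SD) across
$c \in [5, 1000]$ — at high c the isotherm is nearly a step and carries
little $K_D$ information, at low c the signal is shallow. Median relative
$K_D$ errors of ~15–25 % in the noisy recovery tests are therefore the
information-theoretic floor, not an estimator deficiency; the reported
per-parameter SDs are honest, with ±3 SD covering the truth in ≥95 % of
runs. Reproducing the published ±2.8 nM on 41.8 nM would require an
effective noise near 0.03 μcal.

**Not modeled.** Raw power-thermogram integration, multi-site/competitive
models, ΔCp analysis, global multi-experiment fits. N is always free (the
original software may have fixed it for low-c titrations; this is not
stated).

## FRAP

Three regions are recorded per cell: bleached ROI $I_t$, whole nucleus
$T_t$, background $BG$. The double normalization

$$\mathrm{rel}(t) = \frac{(\bar T_{pre} - BG)(I_t - BG)}
                         {(T_t - BG)(\bar I_{pre} - BG)}$$

is implemented as the background-corrected ratio $(I_t-BG)/(T_t-BG)$
divided by its prebleach average — identical to the printed product form
when the prebleach signals are steady, and guaranteeing that the prebleach
frames of the output average to exactly 1 even under noise. The result is
invariant (to 10⁻¹⁰ in the property tests) under a joint multiplicative
gain or acquisition-bleaching factor on $I$ and $T$ and under additive
offsets captured by $BG$. `rescale_recovery()` then maps the first
post-bleach frame to 0 and the prebleach level to 1.

**Half-time.** The functional form behind the published half-times is not
stated; we fit a single exponential $y(t) = A(1 - e^{-kt})$ on post-bleach
frames (plateau $A$ profiled linearly, $k$ by Brent search on the log
scale) and report $t_{1/2} = \ln 2/k$, with a linear-interpolation crossing
of $A/2$ available as `method = "interpolation"`. The mobile fraction is
reported as the plateau of the rescaled curve — auxiliary output, since the
original work reports only half-times.

**Group comparison.** The original Methods say paired t-tests, the figure
captions say two-tailed t-tests; both are exposed
(`compare_groups(paired = )`, default unpaired) and neither is asserted to
be "the" published analysis. Identical zero-variance groups return
$t = 0, p = 1$ (the 0/0 case), and a zero-variance nonzero shift returns
$p = 0$ rather than an error.

**Generator.** Defaults follow the published acquisition: 0.25-s frames,
5 prescans, n = 30 cells, plus a bleach-depth parameter, an immobile
fraction and an optional linear acquisition drift applied jointly to
$I$ and $T$ *after* noise — gain drift multiplies everything the detector
sees above background, which is exactly the perturbation the double
normalization must cancel.

## Viability, dose–response and combination index

Plate readings are blanked and scaled to vehicle controls,
$(raw - blank)/(\overline{vehicle} - blank)$, clipped to [0, 1.5] with the
clip count logged; fraction affected is $f_a = 1 - \text{surviving}$.
Single agents get (i) a four-parameter logistic fit (top/bottom profiled
linearly; EC50 and Hill slope searched on the log scale) and (ii) the
median-effect regression
$\log\!\big(f_a/(1-f_a)\big) = m\log D - m\log D_m$.

The combination index at a checkerboard point $(d_1, d_2)$ with fraction
affected $f_a$ is

$$CI = \frac{d_1}{D_{x,1}} + \frac{d_2}{D_{x,2}},\qquad
  D_{x,i} = D_{m,i}\left(\frac{f_a}{1-f_a}\right)^{1/m_i},$$

the mutually exclusive two-term form — the conventional default for a
non-constant-ratio 8 × 8 checkerboard; the mutually nonexclusive cross-term
variant sits behind `cross_term = TRUE`, since the exclusivity assumption
used in the original software run is not stated. Boundary fractions are
clipped to [0.01, 0.99] for the regression and skipped (with a count) for
CI. Sham self-combinations give CI = 1 to 10⁻⁶ by construction, and CI is
invariant to a common scaling of both dose axes and $D_m$.

A useful orientation for interpreting the synthetic interaction modes:
Bliss independence undershoots Loewe additivity (CI > 1) below the
median-effect dose when Hill slopes are steep, and overshoots it (CI < 1)
for hyperbolic responses — the test suite pins both regimes against closed
forms.

qPCR fold changes use $2^{-\Delta\Delta C_T}$ against a housekeeping
reference and a control condition.

## The synthetic world — and what a green test does not establish

Generator defaults are the published experimental conditions wherever the
original work states them: the 25–96 °C ramp, 2 μM protein / 10 μM compound
panel design and triplicates (DSF); the 0.2003-ml cell, 0.3 + 38 × 1 μl
schedule, 15 °C, and the panel's concentration pairs as presets (ITC);
0.25-s frames, 5 prescans, 30 cells (FRAP); eight-point geometric dose
series spanning 0.7–11392 nM and 37–4728 nM (combinations). Unstated
magnitudes are fixed once as documented conventions: DSF reading spacing
0.5 °C (the ramp rate is printed, the reading interval is not), noise of
1 % of signal range (DSF), 0.1 μcal (ITC), 0.03 normalized units (FRAP),
and a 0.5 μcal/μl dilution offset.

All noise is additive i.i.d. Gaussian. Real melt curves show aggregation
decay, heteroscedastic dye response and well-to-well baseline variation;
real ITC data have correlated baseline drift and integration error; real
FRAP has shot noise scaling with intensity and cell-to-cell kinetic
heterogeneity; real checkerboards have edge effects. A green recovery test
therefore establishes correctness of the estimators *under the stated
model*, not robustness to instrument pathologies. Conversely the published
cellular results (growth IC50s, expression signatures, pull-down
enrichments) depend on undeposited raw data and are out of scope here.

**Seeding.** One top-level seed drives per-dataset child streams through
`child_seed(seed, stream) = (seed · 48271 + stream) mod (2³¹ − 1)`, so
adding a dataset never perturbs existing ones, and regeneration from a
serialized `synthetic_truth` is bit-identical.

## Numerical choices

- Gas constant $1.9872\times10^{-3}$ kcal/(mol K) everywhere, for
  consistency with the published free energies.
- Quadratic roots via the rationalized smaller-root form; degenerate zero
  concentrations return Θ = 0.
- Affinity bins (≤100 nM, 100 nM–1 μM, 1–10 μM, >10 μM) close on the
  tighter side: a 100 nM $K_D$ is in the strongest bin.
- Machine-readable TSV output uses ASCII hyphen-minus only.
- Configuration is a flat JSON file mirrored by `default_config()`
  (YAML is not available in this R stack); every documented tunable
  appears there with its default.

## Known limitations

- No three-state or ΔCp melt models; strongly sloped baselines plus very
  broad transitions can trade off against ΔHu.
- The ITC fitter assumes the single-site model generated the data; residual
  diagnostics, not the fit SDs, must be consulted for model misfit.
- FRAP analysis is purely empirical-exponential; no reaction–diffusion
  interpretation of $k$ is implied.
- Median-effect regression weights all log-doses equally; with fewer than
  five informative doses the CI inherits substantial $D_m$ uncertainty.
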