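---
title: "Organ-level preclinical dosimetry with predose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Organ-level preclinical dosimetry with predose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predose)
```

`predose` turns animal biodistribution measurements into organ-level dose
coefficients within the MIRD schema.  This vignette documents the model,
its assumptions, the tunable parameters, and the numerical and design
choices behind the implementation — the things a reader needs in order to
judge what a `predose` result does and does not mean.

## The dosimetric model

The mean absorbed dose coefficient of a target region $r_T$ over an
infinite dose-integration period is

$$d(r_T) = \sum_{r_S} \tilde a(r_S)\, S(r_T \leftarrow r_S),$$

where $\tilde a(r_S)$ (hours) is the time-integrated activity coefficient
(TIAC) of source region $r_S$ — the number of nuclear transformations in
$r_S$ per unit administered activity — and $S(r_T \leftarrow r_S)$
(Gy/(Bq·s)) is the user-supplied S-value for the phantom and radionuclide.
The hours-to-seconds conversion happens exactly once, inside
`absorbed_dose()`; everything upstream stays in hours, the unit organ-level
dosimetry software conventionally expects.

Equivalent dose weights the per-radiation-type partition of $d$ by the
radiation weighting factors $w_R$; effective dose is the tissue-weighted
sex average $e = \sum_T w_T (h_T^{M} + h_T^{F})/2$.  Effective dose is a
stochastic-risk metric defined for reference humans, so `effective_dose()`
refuses reports computed on a phantom whose recorded species is not human —
for animal phantoms the package reports absorbed or RBE-weighted dose only.
RBE-weighted dose has no consensus unit; the label (Gy, Gy-Eq or Sv) is a
configuration choice on `rbe_weighted_dose()`.

### Assumptions inherited from the protocol

* Anatomy is time-invariant and represented by a reference phantom; the
  activity is uniformly distributed within each source region.
* No radioactive progeny are modelled.
* Harvested tissue includes its blood content, so phantom source-region
  masses must be blood-inclusive, and blood residing in organs is never
  subtracted.
* The biodistribution, expressed as SUV, is equivalent across species and
  body masses.  This first-order equivalence is what licenses the
  transposition $a(r_S, T_i) = \overline{SUV}(r_S)_i\,
  M(r_S^{PH})/M(TB^{PH})\, e^{-\lambda_p T_i}$ from animal data onto any
  phantom; the exponential removes the decay correction inherent in the
  SUV definition, because the integrated quantity must be physical
  activity.  Same-species dosimetry uses the identical path (the mass
  ratio then simply re-scales within one species).

$\lambda_p$ is always the physical decay constant $\ln 2 / T_{1/2}$ (1/h),
derived from the half-life, and is never a fitted parameter.

## Measurement planning

Two schedule generators are provided, both parameterized by the
(anticipated) effective half-life $T_e$ with $1/T_e = 1/T_b + 1/T_p$:

* `plan_icru(te_h)`: the fixed multiples $T_e/3,\ 2T_e/3,\ 3T_e/2,\ 3T_e,\ 5T_e$.
* `plan_empirical(n, te_h)`: $T_i = T_{min} + (T_{max}-T_{min})
  \left(\tfrac{i-1}{n-1}\right)^{1.5}$ with $T_{min} = T_e/(n-1)$ and
  $T_{max} = 1.5\,n\,T_e/(0.15\,n+1)$.  The exponent 1.5 concentrates early
  points (resolving fast components) while the last point reaches several
  effective half-lives; gaps are provably non-decreasing.

Times are never rounded in computation, only at display (3 significant
figures).

## From measurements to SUV

Per-animal conversions are exact: $SUV = [\%IA/g] \cdot M_{body}/100$ (with
the inverse provided), and volume concentrations (%IA/mL) divide by tissue
density first (default 1 g/mL, per-region overrides available).  Replicates
aggregate to the arithmetic mean and *sample* standard deviation (n − 1
denominator — replicates are a sample; the protocol does not prescribe a
convention) at each time point.  Using each animal's own body mass is the
default; the population-mean-mass approximation is available as an explicit
option (`use_mean_mass = TRUE`) and is flagged in the output metadata,
since it is only appropriate when body masses are consistent.

Three total-body routes are supported:

1. a directly measured total-body series (image ROI or intact-animal
   counting): $a(TB)_i = \overline{SUV}(TB)_i\, e^{-\lambda_p T_i}$, no
   mass ratio needed;
2. the carcass route: the mass-weighted sum of carcass and excised-region
   SUV, with **all masses taken from the phantom** (sample masses are
   typically unknown); double counting of excised regions is rejected and
   a mass audit warns when carcass + excised masses miss the total-body
   mass by more than 0.5%;
3. the dose-calibrator route: whole-body readings divided by the
   immediately-post-administration reading are *already* decay-uncorrected
   fractions and are used as-is, with a warning (value retained) if a
   ratio exceeds 1.

For cross-species work the carcass sum uses the *animal* phantom's masses
while transposition uses the destination phantom — the SUV is the
species-invariant carrier between the two.  Replicate SDs propagate
through the carcass sum as a linear combination of independent terms; the
protocol itself prescribes no propagation rule, so this choice is
documented rather than normative.

## TIAC estimation

**Trapezoid** (`tiac_trapezoid()`): piecewise-linear area between the first
and last time points, plus $T_1 a(T_1)$ for the injection-to-first-point
interval (activity at injection approximately equals the first measured
point) and $a(T_n)/\lambda_p$ for the tail (elimination by physical decay
only — deliberately conservative).  The protocol's alternate head/tail
forms are an extension point, not implemented.

**Exponential regression** (`fit_exponentials()` + `tiac_from_fit()`): fits
$a(t) = \sum_\psi c_\psi e^{-(\lambda_{b,\psi} + \lambda_p)t}$ by weighted
nonlinear least squares and evaluates
$\tilde a = \sum_\psi c_\psi/(\lambda_{b,\psi}+\lambda_p)$ exactly.
Weights are $1/SD^2$ when every point carries a positive SD, else 1.

Numerical choices that matter:

* **Degrees of freedom.** Every candidate model must satisfy
  $n - 2\Psi \ge 1$; a bi-exponential therefore needs at least 5 points.
  Violations are errors, not warnings.
* **Deterministic multi-start.** Rates are log-spaced between
  $1/(10\,T_n)$ and $10/T_1$; amplitudes at fixed rates come from a
  non-negative (or unconstrained) linear solve; the best 16 starts by
  weighted sum of squares seed a box-constrained Levenberg–Marquardt
  refinement.  No RNG is used in fitting, so fits are reproducible
  bit-for-bit.
* **Positivity.** Amplitudes are constrained non-negative by default,
  which makes the model ignore a brief uptake phase (it usually
  contributes little to the TIAC); `constrain_positive = FALSE` releases
  this for radiopharmaceuticals with a substantial rising portion.
* **Amplitude cap.** Zero-time amplitudes are fractions of the
  administered activity and cannot exceed 1.  The fit enforces a cap
  (default 1.5, leaving noise headroom) because the bi-exponential
  likelihood on few points contains an unbounded flat ridge — an
  unresolvably fast component with $c \to \infty$, $\lambda \to \infty$
  that fits only the first point; the physical budget excludes it.
* **Model selection.** With `components = "auto"`, candidates
  $\Psi \in \{1,2,3\}$ passing the degrees-of-freedom rule are compared by
  the small-sample-corrected Akaike criterion with $k = 2\Psi$; scores
  within 2 units are ties resolved toward the smaller model.  The
  weighted RSS entering the criterion is floored at $10^{-20}$ of the
  weighted signal power so that, in the noiseless limit where several
  nested models fit to machine precision, the comparison is deterministic
  and the most parsimonious model wins.  Because the AICc correction
  requires $n - 2\Psi - 1 \ge 1$, a model whose residual degree of
  freedom is exactly 1 can be requested explicitly but never
  auto-selected.
* **Convergence.** Levenberg–Marquardt info codes 1–4 and 6–8 (the latter
  meaning tolerances below machine precision) count as converged; when
  several starts reach the same minimum the cleanly converged one is
  preferred over an iteration-capped one.

With no biological elimination the total-body TIAC reduces to the
radionuclide mean lifetime $1/\lambda_p$ (`tiac_physical_decay()`), and
for any region the TIAC can never exceed $1/\lambda_p$; `tiac_result()`
warns when an estimate violates this bound, which on physical inputs can
only come from measurement noise or double counting.

A delta-method standard error from the fit covariance is attached to
exponential TIACs when the covariance is available; it is labelled
non-normative — the protocol prescribes no uncertainty propagation.

## The voiding-bladder model

Direct bladder measurement conflicts with time-invariant anatomy, so the
bladder TIAC is derived from total-body clearance.  Between voids the
bladder content obeys $B'(t) = \sum_\psi f_{u,\psi} \lambda_{b,\psi}
e^{-(\lambda_{b,\psi}+\lambda_p)t} - \lambda_p B(t)$ and empties completely
every $T_V$ hours.  Integrating one voiding cycle and summing the exactly
geometric cycle series gives

$$\tilde a(Bladder) = \sum_\psi f_{u,\psi}
\left[\frac{1-e^{-\lambda_p T_V}}{\lambda_p}
- \frac{1-e^{-(\lambda_{b,\psi}+\lambda_p) T_V}}{\lambda_{b,\psi}+\lambda_p}\right]
\frac{1}{1-e^{-(\lambda_{b,\psi}+\lambda_p) T_V}}.$$

Here $f_{u,\psi} \in [0,1]$ (summing to at most 1) is the fraction of the
administered activity ultimately excreted in urine via clearance component
$\psi$ — a user input; no estimation procedure is provided.  The closed
form uses `expm1` so the $T_V \to 0$ limit (continuous voiding, TIAC
$\to 0$) is numerically clean; the $T_V \to \infty$ limit is
$f_u(1/\lambda_p - 1/(\lambda_b+\lambda_p))$, complete retention of
everything the bladder receives.  Because printed forms of this model are
easy to mis-transcribe, the implementation is certified against an
independent discrete simulator (`tiac_bladder_sim()`: classical
Runge–Kutta on the filling/decay ODE with instantaneous voiding, the
integral carried as a second state variable, geometric tail
extrapolation) — the test suite requires agreement within $10^{-4}$
relative over a 100-point random parameter grid, and typical agreement is
near $10^{-9}$.

Assigning $f_u > 0$ to a component with $\lambda_b = 0$ is an error: a
non-clearing component has no biological excretion to route.

## Rest of body

$\tilde a(RoB) = \tilde a(TB) - \sum \tilde a(r_S^*)$ over the explicitly
derived sources (bladder included).  A negative difference is an error
with a per-source breakdown by default; an opt-in clamp mode sets it to
zero with a warning.  Measured regions with no phantom counterpart are
deliberately left inside the rest of body rather than dropped.

## The synthetic-data generator

`kinetic_spec()`/`simulate_biodist()` realize the exact model class the
fitter assumes: per-region sums of exponentials in the decay-uncorrected
fraction of administered activity, with a reserved `Rest` region for the
unobserved remainder.  The generator emits (i) an ex vivo counting table
in %IA/g with per-animal body masses drawn from a normal distribution and
region masses scaled proportionally, (ii) a carcass dataset
(carcass = whole body minus the excised regions), and (iii) a whole-body
dose-calibrator ratio series — all derived from one ground truth, whose
closed-form TIACs are returned for recovery testing.  Measurement noise is
multiplicative log-normal with mean 1 and fixed CV, reflecting that
counting measurements are positive with roughly constant relative error.

Default study conditions follow the protocol's recommendations: 5 planned
time points, 3 animals per point, 5% CV, a 25 ± 2 g mouse.  The bundled
phantoms and S-value matrix are deliberately *toy* (synthetic, clearly
labelled): they have plausible masses and magnitudes but are not reference
phantoms or published S-value libraries, which users must supply from
their dosimetry software.

What passing the closed-loop tests shows — and what it does not: the
pipeline provably inverts its own model (conversions, transposition,
integration, dose algebra are correct, and under 5% noise the median TIAC
error over 200 replicates stays under 5%).  It does not validate the SUV
species-equivalence assumption, the absence of uptake phases, bladder
physiology, or any real radiopharmaceutical's kinetics, and the generator
has no physiologically-based realism beyond the exponential model class.

## Problem sizes and determinism

The test suite and the acceptance script run the Monte Carlo recovery at
200 replicates of a 5-point × 3-animal study, the bladder certification on
a 100-point random grid, and trapezoid convergence up to 129-point grids —
sizes chosen so the whole suite completes in well under a minute on a
laptop while keeping the statistical checks meaningful.  All stochastic
tests fix their seeds; all fitting is deterministic by construction.

## Known limitations

* Only organ-level (mean-dose) quantities: no voxel or sub-organ
  dosimetry, no Monte Carlo transport, no S-value or phantom generation.
* No radioactive-progeny ingrowth.
* No compartmental (SAAM-style) or Bayesian kinetic modelling; uptake
  phases are handled only by releasing the amplitude positivity
  constraint, not by dedicated uptake terms.
* $f_{u,\psi}$ and the voiding interval are user inputs; the package does
  not estimate them from data.
* The reference-value consistency check of computed coefficients against
  published tables is left to the investigator: the report prints values
  but bundles no reference data.
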