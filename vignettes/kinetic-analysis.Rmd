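---
title: "Kinetic analysis of multi-session immunoPET time-activity curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic analysis of multi-session immunoPET time-activity curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petkin)
```

`petkin` analyses regional time-activity curves (TACs) from dynamic
total-body PET with long-lived tracers such as ⁸⁹Zr-labelled minibodies.
This vignette is the package's account of the underlying science: the
models, the assumptions behind them, the tunable parameters, the
numerical choices, and what the synthetic-data machinery does and does
not establish.

## The measurement and its time base

The acquisition protocol is three sessions anchored to injection time:
a 90-min dynamic scan framed as 6 × 60 s, 16 × 30 s, 2 × 60 s,
12 × 120 s and 10 × 300 s (46 frames), then single 60-min frames
starting at 6 h and 48 h post-injection. All times in the package are
minutes post-injection, frames are stored as `(t_start, t_end)`, and
the representative time of a frame is its midpoint — the standard
convention for frame-averaged PET data. All concentrations are
kBq/ml, decay-corrected to injection time with the physical ⁸⁹Zr
half-life of 78.4 h.

Because late time points sit 1–2 days after the dynamic session, every
model evaluation that is compared to data is *frame-averaged
analytically* rather than sampled at midpoints: the earliest 30–60-s
frames change quickly relative to the ~5-min fast blood component, and
midpoint sampling would bias the fit of exactly those frames that carry
the most information about delivery. (Whether midpoint or
frame-averaged evaluation was used upstream of the package's design was
genuinely open; frame averaging was chosen because it matches the
data-generating process, and the late-time-point TACs are taken as the
full 60-min frames.)

## Input function

Whole-blood clearance is modelled as a triexponential,
\(C_p(t) = \sum_{j=1}^{3} A_j e^{-\lambda_j t}\), fitted by weighted
nonlinear least squares (Levenberg–Marquardt via `minpack.lm`) with the
same weighting scheme as the tissue fits, for consistency. The fit is
multimodal, so `fit_triexponential()` is multi-start: 8 rate triplets
log-spaced over \([1/2000, 1]\ \mathrm{min}^{-1}\), with amplitudes
initialised at each start from a non-negativity-clipped weighted linear
solve at the fixed rates. Half-lives \(\ln 2/\lambda_j\) are reported
ascending. A rate pinned at the zero bound with non-negligible
amplitude, or an amplitude collapsed to zero (a nested bi- or
mono-exponential), is flagged as degenerate rather than hidden.

The reference synthetic curve uses half-lives of 5.1 min, 55.9 min and
22.1 h. Amplitude fractions are fixed at (0.6, 0.3, 0.1) — a choice the
package makes once, since clearance half-lives alone do not pin the
amplitudes, with most of the tracer clearing through the fast
distribution phases and ~10% through terminal elimination. The scale
default of 3.7 kBq/ml corresponds to an ~18.5 MBq dose distributed in
roughly 5 l of blood.

The curve's analytic integral \(\int_0^t C_p\) underlies the Patlak
abscissa ("normalized time" \(\int_0^t C_p \, d\tau / C_p(t)\)), which
is provably monotone for any non-negative multiexponential.

## Compartment models

Three nested models are fitted per region, all sharing the
whole-region form

\[ C_{model}(t) = (1 - v_b)\,C_T(t) + v_b\,C_{wb}(t), \]

with \(v_b\) the fractional blood volume and \(C_T\) the tissue
response of the standard one- or two-tissue compartment system:

* **1T3P** (\(v_b, K_1, k_2\)): free tracer exchanges with blood.
* **2T4P** (\(+k_3\)): free tracer binds irreversibly — the natural
  simplification for a receptor-targeted tracer that is internalised.
* **2T5P** (\(+k_4\)): a return path from the bound compartment,
  required when labelled cells traffic back out of the tissue over a
  48-h window.

The two-tissue impulse response has eigenvalues
\(\alpha_{1,2} = \left[(k_2+k_3+k_4) \mp
\sqrt{(k_2+k_3+k_4)^2 - 4k_2k_4}\right]/2\) (the discriminant is a sum
of squares, hence never negative for non-negative rates). Because the
input is a sum of exponentials, every convolution is evaluated in
closed form, and frame averages come from the analytic antiderivative —
there is no ODE integration and no numerical convolution anywhere in
the fitting path. Near-coincident eigenvalue/rate pairs are routed to
the \(t e^{-\alpha t}\) limit form to avoid catastrophic cancellation;
an exactly repeated eigenvalue (possible only when \(k_3 = 0\) and
\(k_2 = k_4\)) is split by a relative nudge of \(10^{-9}\), an error
far below fitting tolerances. The closed form is verified in the test
suite against an independent `deSolve` solution of the ODE system to
\(10^{-6}\) relative on random parameter draws.

Two conventions deserve explicit statement:

* **Blood-volume complement.** The whole-region model multiplies the
  tissue term by \((1 - v_b)\) and uses *whole-blood* (not plasma)
  concentration in the \(v_b\) term, since the input is image-derived
  whole blood. A consequence worth knowing: the measured TAC of an
  irreversible region traps at the *apparent* rate \((1-v_b) K_i\), so
  the late Patlak slope of a whole-region TAC estimates
  \((1-v_b)K_i\), approaching \(K_i\) itself only as \(v_b \to 0\).
  The tests assert exactly this.
* **Weights.** Fit weights are
  \(w_i = \Delta t_i\, e^{-\lambda_{phys} t_{mid,i}}\) — the variance
  of decay-corrected counts grows with the decay factor and shrinks
  with frame duration — normalised to sum to the number of frames.
  Frames in the 6-h and 48-h sessions are divided by a further factor
  10 (configurable), reflecting the larger uncertainty of isolated
  late points. A multiplicative (down-weighting) rather than divisive
  decay convention was the open choice; it is the standard variance
  argument for decay-corrected data.

### Fitting

`fit_model()` minimises \(\sum_i w_i (C_i - \hat C_i)^2\) with
box constraints \(v_b \in [0, 0.6]\), \(K_1 \in [0, 2]\) ml/cm³/min,
\(k_2, k_3, k_4 \in [0, 1]\) min⁻¹ — physiologic ranges wide enough
that only genuinely degenerate fits saturate them (saturation is
flagged, not an error). Convergence uses relative tolerances of
\(10^{-10}\) with at most 500 iterations. Initialisation is
deterministic multi-start: a default physiologic start
(\(v_b = 0.05, K_1 = 0.01, k_2 = 0.01, k_3 = 10^{-3}, k_4 = 10^{-4}\))
plus quasi-random points log-spaced within bounds (linear for
\(v_b\)), generated from fixed irrational rotations so that repeated
fits are bit-identical without touching the RNG. Richer models
additionally warm-start from the reduced-model optimum with the extra
rate at zero, which guarantees the nesting inequality
\(\mathrm{WRSS}_{2T5P} \le \mathrm{WRSS}_{2T4P} \le
\mathrm{WRSS}_{1T3P}\) by construction. Five starts are the default; at
two starts, high-noise two-tissue fits occasionally land in a local
minimum with \(v_b\) at its upper bound, which the default avoids.

In high-blood-volume organs such as the spleen, \(K_1\) and \(k_2\)
trade off strongly against \(v_b\) (the correlation analysis below
makes this quantitative), and the remedy used in practice is to fix
\(v_b\) — `fit_model(..., fixed = c(vb = 0.4))` — which removes it from
the free-parameter count.

### Model selection

`aicc()` implements the small-sample-corrected criterion under a
Gaussian likelihood with unknown common variance,
\(AICc = n \ln(\mathrm{WRSS}/n) + 2k + 2k(k+1)/(n-k-1)\), with `n` the
number of fitted frames (48 for the full protocol — down-weighted late
frames still count as observations, the package's resolution of an
ambiguity in how `n` should be counted) and `k` only the free
parameters. AICc differences are invariant to a common rescaling of
the weights. Ties below \(10^{-9}\) go to the smaller model.

## SUV, TBR and Patlak

SUV is concentration divided by dose per body weight with the
universal water-equivalent convention 1 kg ≡ 1000 ml; SUVpeak averages
the 8 hottest voxels (~0.1 ml at 2.344-mm voxels). TBR is the
per-frame ratio of tissue to whole-blood concentration, with frames
below a blood positivity floor masked rather than divided. The Patlak
plot uses the *fitted* input function for both the abscissa and the
denominators — raw late blood frames are exactly the noisiest values in
the study. Because only two late points exist, the equilibrium
(linearity) time cannot be determined from this design; the window
start is therefore an explicit argument (default 30 min), never an
automatic claim.

## Identifiability

Practical identifiability is assessed three ways, all on the
frame-averaged model:

1. **Normalized sensitivities**
   \(S_j(t_i) = \partial C/\partial\theta_j \cdot \theta_j/C\),
   central finite differences with relative step \(10^{-3}\). For the
   reference regimes, \(|S_{k_4}|\) keeps growing through the 48-h
   session — the quantitative argument that two days of imaging are
   needed to identify washout.
2. **Correlation matrix** from \((J^\top W J)^{-1}\) at the fitted (or
   true) parameters; rank deficiency falls back to a pseudo-inverse
   with a degeneracy flag.
3. **Monte-Carlo bias/SD/RMSE**: `simulate_bias_sd()` generates
   replicates under the noise model, refits each (starting from the
   truth plus one random restart — a deliberate trade of exhaustive
   multi-start against replicate count), and reports per-parameter
   bias, SD and RMSE in percent. The SD uses the population (1/n)
   denominator so RMSE² = bias² + SD² holds as an identity. Reports
   with more than 20% replicate failures are flagged unreliable.

The noise model on the decay-corrected scale is Gaussian with
\(\sigma_i^2 = S_c^2\, C_{model}(t_i)\, e^{\lambda_{phys} t_{mid,i}} /
\Delta t_i\): variance proportional to the decay-*un*corrected count
rate and inversely proportional to frame duration. The exact
functional form used upstream of this package is not published; this
is the standard count-statistics argument, the scale \(S_c\) is
estimated per subject by `estimate_noise_scale()` (the value making the
mean standardized squared residual equal 1), and the variance function
is deliberately simple enough to replace. Simulated negative
concentrations are truncated at zero; at the default
\(S_c = 0.05\) the truncation rate is negligible on every frame of the
reference regimes.

## Exact small-sample statistics

With 5 cases and 3 controls, normal-approximate rank tests are
inappropriate. `exact_mann_whitney()` enumerates the null distribution
of U by the standard count recursion over all
\(\binom{n_1+n_2}{n_1}\) arrangements and doubles the smaller tail
(capped at 1). Under complete separation this gives the *minimum
attainable* two-tailed p: 2/56 ≈ 0.036 at 5-vs-3, 2/35 ≈ 0.057 at
4-vs-3, 2/20 = 0.1 at 3-vs-3 — the doubled-tail convention is the one
that reproduces these printed values exactly. Ties are an error by
design: the measurements are continuous, and silently applying a tie
correction would invalidate the exactness claim. (A pipeline-level
escape hatch, `on_ties = "na"`, exists because a degenerate metric —
K_i in a one-tissue region is identically zero — must not abort the
remaining comparisons.) Spearman's rho uses exact permutation
enumeration for \(n \le 9\) and the t approximation above that.
Bonferroni-adjusted p-values are computed as a sensitivity column but
do not drive the significance flag, mirroring pilot-study practice of
reporting uncorrected p at α = 0.05.

## The synthetic cohort generator

`generate_cohort()` draws per-subject microparameters log-normally
around archetype means (log-normal for positivity and the right skew of
physiologic rates), draws per-subject blood curves the same way, and
simulates all TACs — including a whole-blood TAC that is fitted, not
assumed, by the pipeline — under the noise model. Four archetypes are
provided as *scenario parameters, not biological claims*, chosen so
that the model-preference pattern of the motivating application is
reproducible as a testable scenario: a spleen-like region
(\(v_b = 0.4\), strong delivery, \(k_4 > 0\), 2T5P preferred, \(v_b\)
fixable), a bone-marrow-like region (moderate delivery, small
\(k_4\)), a lung-like region (low delivery, \(k_4 = 0\), 2T4P), and a
lymph-node-like region (slow delivery, fast binding, 1T3P). The
\(k_4 = 8\times10^{-4}\) min⁻¹ of the reversible archetypes places the
bound-compartment maximum near 20–22 h, inside the 12–24 h window
expected for this tracer class. The default case-group effect raises
bone-marrow \(k_3\) by 50%, giving truth-level K_i separation between
groups at small between-subject CV.

What passing tests on these data do show: the estimator chain
(input fit → compartment fit → selection → K_i/TBR/Patlak → exact
statistics) is correct, stable under the modelled noise, and
reproducible to the bit under a seed. What they do not show: anything
about real tissue — the generator has no cell-trafficking compartments,
no motion, no partial-volume or spillover effects, no air-fraction
issue in the lungs, and between-subject variation is a clean
log-normal. Conclusions about actual biology require actual data.

## Problem sizes and runtime choices

The test suite runs the convolution oracle on 100 random parameter
draws, the AICc-selection experiment on 100 noisy spleen-like
replicates (three models each), Monte-Carlo identifiability at 25
replicates, the noise-calibration check at 100–1000 replicates (no
fitting involved), and the end-to-end pipeline on a 5-vs-3 single-region
cohort — sizes chosen so the full suite completes in a few minutes on
one CPU while every rate or tolerance asserted is still estimated from
enough replicates to be stable.

## Known limitations

* The compartment models have no explicit cell-trafficking pathways;
  \(k_4\) absorbs trafficking phenomenologically.
* The liver's dual blood supply is not modelled (no dual-input model),
  and no plasma/whole-blood partition or metabolite correction is
  applied.
* The Patlak window is user-set; the package deliberately refuses to
  auto-detect equilibrium from two late points.
* Exact rank tests refuse tied data rather than correcting for ties.
* The noise model's functional form is an assumption (documented
  above), calibrated per subject only through its scale.
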