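# petkin

Kinetic analysis of dynamic total-body immunoPET time-activity curves.

`petkin` implements the quantitative pipeline used to analyse dynamic
total-body PET studies of long-lived immunoPET tracers — the motivating
application is an ⁸⁹Zr-labelled CD8-targeted minibody imaged over three
sessions (a 90-min dynamic scan plus 60-min scans at 6 h and 48 h
post-injection) in a small two-group cohort. It is aimed at PET
methodologists and quantitative imaging scientists who have regional
time-activity curves (TACs) in hand and want reproducible kinetic
modelling, model selection, and group statistics without any voxel-level
image handling.

## What it computes

* **Input function.** The whole-blood clearance is modelled as a
  triexponential, C_p(t) = Σⱼ Aⱼ e^(−λⱼt), fitted by multi-start
  weighted Levenberg–Marquardt least squares on frame-averaged
  predictions; half-lives ln 2/λⱼ are reported as initial /
  intermediate / terminal.
* **Compartment models.** Tissue TACs are forward-modelled as
  C(t) = (1 − v_b)·C_T(t) + v_b·C_wb(t), with C_T the one- or
  two-tissue impulse response (models 1T3P, 2T4P, 2T5P over
  v_b, K₁, k₂, k₃, k₄) convolved in closed form against the
  multiexponential input and averaged analytically over each frame.
  Fits minimise Σᵢ wᵢ(Cᵢ − Ĉᵢ)² with weights wᵢ ∝ Δtᵢ·e^(−λ_phys·t_i)
  (frame duration × decay), late sessions down-weighted by a factor 10.
* **Model selection.** AICc = n ln(WRSS/n) + 2k + 2k(k+1)/(n−k−1),
  counting only free parameters; ties go to the smaller model.
* **Macroparameters and graphical methods.** Net influx rate
  K_i = K₁k₃/(k₂+k₃); SUV and SUVpeak; tissue-to-blood ratios (TBR);
  Patlak analysis of TBR against normalized time ∫C_p dτ / C_p.
* **Identifiability.** Normalized sensitivity curves, the parameter
  correlation matrix from (JᵀWJ)⁻¹, a count-statistics noise model
  σᵢ² = S_c²·Cᵢ·e^(λ_phys·tᵢ)/Δtᵢ with per-subject scale estimation,
  and Monte-Carlo bias/SD/RMSE of the microparameters.
* **Group statistics.** Exact two-tailed Mann–Whitney U (null by full
  enumeration — appropriate for 5-vs-3 cohorts) and Spearman rank
  correlation with exact permutation p-values at small n.
* **Synthetic cohorts.** A generator that emulates the acquisition
  protocol (46 dynamic frames + 6-h and 48-h sessions), the blood
  clearance, four tissue archetypes and a configurable case-group
  effect, so every stage is testable without imaging data.

## Worked example

```r
library(petkin)

sched <- study_schedule()            # 46 dynamic frames + 6 h + 48 h
blood <- generate_blood()            # half-lives 5.1 min / 55.9 min / 22.1 h
blood_tac <- dplyr::mutate(sched, conc = eval_blood_frames(blood, sched))
fit_in <- fit_triexponential(blood_tac)
glance(fit_in)
#>       wrss     n converged degenerate half_life_initial_min ...
#> 1 1.05e-27    48 TRUE      FALSE                       5.10

# a noisy bone-marrow-like TAC, fitted with all three models
tac <- generate_tissue(
  kinetic_params(vb = 0.15, K1 = 0.25, k2 = 0.2, k3 = 0.03, k4 = 8e-4),
  blood, sched, Sc = 0.05, seed = 7
)
fits <- lapply(c("1T3P", "2T4P", "2T5P"),
               function(m) fit_model(tac, fit_in$curve, model = m))
select_model(fits)
#> <model_selection> selected: 2T5P
#>   model     k  wrss   aicc delta_aicc
#> 1 2T5P      5 0.144 -267.          0
#> 2 2T4P      4 4.94  -100.        167.
#> 3 1T3P      3 6.29   -91.0       177.

glance(select_model(fits)$best)$ki
#> [1] 0.0322    # net influx rate, ml/cm^3/min (truth: 0.0326)

# exact two-tailed Mann-Whitney at the cohort's group sizes
exact_mann_whitney(c(9.1, 5.2, 4.8, 4.4, 4.1), c(3.0, 2.6, 2.2))
#>       u p_value    n1    n2
#> 1    15  0.0357     5     3
```

The selection table reads: the reversible two-tissue model (2T5P) wins
decisively (ΔAICc > 160) on data generated with k₄ > 0, because the
simpler models cannot reproduce the late washout. The recovered K_i is
within 2% of the generating value, and the exact p-value 0.0357
(printed as 0.036) is the smallest attainable at 5-vs-3 — any complete
separation of the groups yields it.

A full cohort analysis — input fits, per-region model selection, K_i /
TBR / Patlak metrics and group comparisons written to a results
directory — runs through `run_pipeline()`; see `?run_pipeline` and the
methods vignette (`vignettes/kinetic-analysis.Rmd`).

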