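#' Standardized uptake value
#'
#' SUV is the ratio of the decay-corrected activity concentration to the
#' injected activity divided by body weight, with body weight interpreted
#' as a water-equivalent distribution volume (1 kg = 1000 ml), making the
#' value unitless.
#'
#' @param conc activity concentration in kBq/ml, decay-corrected to
#'   injection time.
#' @param dose_mbq injected activity in MBq (> 0).
#' @param weight_kg body weight in kg (> 0).
#' @return SUV, unitless; vectorised over `conc`.
#' @examples
#' suv(0.25, dose_mbq = 18.5, weight_kg = 74) # 1
#' @export
suv <- function(conc, dose_mbq, weight_kg) {
  if (!is.numeric(dose_mbq) || length(dose_mbq) != 1 || dose_mbq <= 0) {
    stop("`dose_mbq` must be a single value > 0", call. = FALSE)
  }
  if (!is.numeric(weight_kg) || length(weight_kg) != 1 || weight_kg <= 0) {
    stop("`weight_kg` must be a single value > 0", call. = FALSE)
  }
  # kBq/ml divided by (MBq * 1000 kBq/MBq) / (kg * 1000 ml/kg)
  conc * weight_kg / dose_mbq
}

#' Peak standardized uptake value
#'
#' Mean of the `n_hottest` largest voxel values within a region of
#' interest. With 2.344-mm isotropic voxels the default 8-voxel support
#' corresponds to about 0.1 ml.
#'
#' @param values voxel values (SUV or concentration).
#' @param n_hottest number of hottest voxels to average (default 8).
#' @return The mean of the `n_hottest` largest values.
#' @examples
#' suv_peak(1:10) # mean of 3..10 = 6.5
#' @export
suv_peak <- function(values, n_hottest = 8) {
  if (length(values) < n_hottest) {
    stop("need at least `n_hottest` (", n_hottest, ") values, got ",
         length(values), call. = FALSE)
  }
  mean(sort(values, decreasing = TRUE)[seq_len(n_hottest)])
}

#' Decay-correct measured concentrations to injection time
#'
#' Multiplies measured activity concentrations by `exp(lambda * t)` where
#' `lambda = log(2) / half-life` is the physical decay constant, so that
#' values reflect tracer amount rather than remaining radioactivity.
#'
#' @param conc measured (not yet corrected) concentrations.
#' @param t_min time post-injection in minutes (same length as `conc` or
#'   scalar).
#' @param isotope_half_life_h physical half-life in hours.
#' @return Decay-corrected concentrations.
#' @export
decay_correct <- function(conc, t_min, isotope_half_life_h = 78.4) {
  conc * exp(log(2) / (isotope_half_life_h * 60) * t_min)
}
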