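#' Region parameter archetypes for synthetic cohorts
#'
#' Default microparameter regimes for four lymphoid-tissue archetypes,
#' chosen as plausible scenario parameters that reproduce the
#' qualitative model-preference pattern of CD8-targeted minibody
#' kinetics (not as measurements): a high-blood-volume spleen-like
#' region with reversible trapping (2T5P preferred, `vb` fixable at
#' 0.4), a bone-marrow-like region with moderate delivery and slow
#' washout of bound tracer, a lung-like region with low delivery and
#' irreversible binding (2T4P), and a lymph-node-like region where slow
#' delivery and fast binding collapse to one-tissue (1T3P) kinetics.
#'
#' @return A tibble with columns `region`, `model`, `vb`, `K1`, `k2`,
#'   `k3`, `k4` and `fix_vb`.
#' @export
region_archetypes <- function() {
  tibble::tribble(
    ~region,        ~model,  ~vb,  ~K1,   ~k2,    ~k3,   ~k4,     ~fix_vb,
    "spleen",       "2T5P",  0.40, 0.60,  0.15,   0.015, 8e-4,    TRUE,
    "bone_marrow",  "2T5P",  0.15, 0.25,  0.20,   0.030, 8e-4,    FALSE,
    "lung",         "2T4P",  0.15, 0.02,  0.08,   0.010, 0,       FALSE,
    "lymph_node",   "1T3P",  0.05, 0.02,  0.005,  0,     0,       FALSE
  )
}

#' Configuration for a synthetic two-group cohort
#'
#' Bundles and validates everything [generate_cohort()] needs: group
#' sizes, region archetypes with between-subject coefficients of
#' variation, the blood-curve population (half-lives, amplitude
#' fractions, scale), the noise scale and a mandatory seed. The default
#' case-group effect raises bone-marrow `k3` by 50%, emulating
#' elevated net influx in the case group.
#'
#' @param n_case,n_control group sizes (default 5 and 3).
#' @param regions archetype table as from [region_archetypes()] (any
#'   subset of rows).
#' @param cv between-subject coefficient of variation of the kinetic
#'   parameters (log-normal; default 0.2).
#' @param blood_half_lives_min population blood half-lives in minutes.
#' @param blood_fractions amplitude fractions (positive, sum 1).
#' @param blood_scale blood concentration at t = 0 in kBq/ml.
#' @param blood_cv between-subject CV of the blood half-lives.
#' @param case_region,case_param,case_factor the case-group effect:
#'   `case_param` in `case_region` is multiplied by `case_factor`.
#' @param Sc TAC noise scale (see [noise_sigma()]); 0 for noiseless.
#' @param seed RNG seed (mandatory).
#' @param isotope_half_life_h physical half-life in hours.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_case = 5, n_control = 3,
                          regions = region_archetypes(),
                          cv = 0.2,
                          blood_half_lives_min = c(5.1, 55.9, 22.1 * 60),
                          blood_fractions = c(0.6, 0.3, 0.1),
                          blood_scale = 3.7,
                          blood_cv = 0.2,
                          case_region = "bone_marrow",
                          case_param = "k3",
                          case_factor = 1.5,
                          Sc = 0.05,
                          seed,
                          isotope_half_life_h = 78.4) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (n_case < 1 || n_control < 1) stop("both groups need >= 1 subject", call. = FALSE)
  if (cv < 0 || blood_cv < 0) stop("CVs must be >= 0", call. = FALSE)
  if (Sc < 0) stop("`Sc` must be >= 0", call. = FALSE)
  b <- default_bounds()
  for (i in seq_len(nrow(regions))) {
    p <- unlist(regions[i, c("vb", "K1", "k2", "k3", "k4")])
    if (any(p < b$lower) || any(p > b$upper)) {
      stop("region `", regions$region[i], "` means outside fitting bounds",
           call. = FALSE)
    }
    .check_model(regions$model[i])
  }
  if (!case_region %in% regions$region && nrow(regions) > 0 &&
      !is.na(case_region)) {
    # a case effect on an absent region is allowed but inert
  }
  structure(
    list(
      n_case = n_case, n_control = n_control, regions = regions, cv = cv,
      blood_half_lives_min = blood_half_lives_min,
      blood_fractions = blood_fractions, blood_scale = blood_scale,
      blood_cv = blood_cv, case_region = case_region,
      case_param = case_param, case_factor = case_factor,
      Sc = Sc, seed = as.integer(seed),
      isotope_half_life_h = isotope_half_life_h
    ),
    class = "cohort_config"
  )
}

# log-normal draw with mean m and coefficient of variation cv
.rlnorm_cv <- function(n, m, cv) {
  if (m == 0 || cv == 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate one noisy tissue time-activity curve
#'
#' Forward-models the TAC with [model_tac()] and adds zero-truncated
#' Gaussian noise with the [noise_sigma()] count-statistics variance
#' model. With `Sc = 0` the output equals the model TAC exactly. The
#' generating parameters and their Ki are attached as the `truth`
#' attribute.
#'
#' @inheritParams model_tac
#' @param Sc noise scale.
#' @param seed RNG seed (required when `Sc > 0`; caller RNG restored).
#' @param isotope_half_life_h physical half-life in hours.
#' @return A tibble (schedule + `conc`) with attribute `truth`, a list
#'   with `params` and `ki`.
#' @export
generate_tissue <- function(params, input, schedule, Sc = 0, seed = NULL,
                            model = "2T5P", isotope_half_life_h = 78.4) {
  sched <- validate_schedule(schedule)
  p <- .full_params(params, model)
  out <- model_tac(p, input, sched, model = model)
  if (Sc > 0) {
    if (is.null(seed)) stop("`seed` is required when Sc > 0", call. = FALSE)
    sig <- noise_sigma(out$conc, sched, Sc,
                       isotope_half_life_h = isotope_half_life_h)
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(seed)
    out$conc <- pmax(out$conc + stats::rnorm(length(sig), 0, sig), 0)
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }
  attr(out, "truth") <- list(params = p, ki = ki_macro(p))
  out
}

#' Generate a synthetic two-group cohort
#'
#' Draws per-subject kinetic parameters log-normally around the
#' archetype means (per-region CV as configured), applies the
#' case-group effect, draws a per-subject triexponential blood curve,
#' and simulates the region TACs plus a whole-blood TAC on the full
#' three-session schedule. Everything is reproducible from the
#' config seed; the caller's RNG state is restored.
#'
#' @param config a [cohort_config()].
#' @param schedule framing schedule (default [study_schedule()]).
#' @return A list with elements `tacs` (tibble `subject_id`, `region`,
#'   `t_start`, `t_end`, `conc`; the region `"blood"` holds the
#'   whole-blood TAC), `blood_curves` (named list of true
#'   [blood_curve()] objects per subject), `truth` (tibble of
#'   generating parameters and `ki` per subject and region), `subjects`
#'   (tibble `subject_id`, `group`) and `config`.
#' @export
generate_cohort <- function(config, schedule = study_schedule()) {
  stopifnot(inherits(config, "cohort_config"))
  sched <- validate_schedule(schedule)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  subjects <- tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(config$n_case + config$n_control)),
    group = rep(c("case", "control"), c(config$n_case, config$n_control))
  )
  b <- default_bounds()
  tacs <- list()
  truth <- list()
  blood_curves <- list()
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    grp <- subjects$group[i]
    # subject blood curve: half-lives drawn log-normally, order preserved
    hl <- sort(vapply(config$blood_half_lives_min, function(m) {
      .rlnorm_cv(1, m, config$blood_cv)
    }, numeric(1)))
    bc <- generate_blood(hl, config$blood_fractions, config$blood_scale)
    blood_curves[[sid]] <- bc
    # simulation seeds derived per subject/region, kept below 2^31
    sub_seed <- (config$seed %% 100000L) * 10000L + i * 101L

    # whole-blood TAC (frame-averaged curve + the same noise model)
    blood_tac <- dplyr::mutate(sched, conc = eval_blood_frames(bc, sched))
    if (config$Sc > 0) {
      sig <- noise_sigma(blood_tac$conc, sched, config$Sc,
                         isotope_half_life_h = config$isotope_half_life_h)
      set.seed(sub_seed)
      blood_tac$conc <- pmax(blood_tac$conc + stats::rnorm(length(sig), 0, sig), 0)
    }
    tacs[[length(tacs) + 1]] <- dplyr::mutate(
      blood_tac[, c("t_start", "t_end", "conc")],
      subject_id = sid, region = "blood", .before = 1
    )

    for (r in seq_len(nrow(config$regions))) {
      arch <- config$regions[r, ]
      means <- c(vb = arch$vb, K1 = arch$K1, k2 = arch$k2,
                 k3 = arch$k3, k4 = arch$k4)
      if (grp == "case" && identical(arch$region, config$case_region)) {
        means[[config$case_param]] <- means[[config$case_param]] * config$case_factor
      }
      set.seed(sub_seed + r)
      draw <- vapply(names(means), function(nm) {
        .rlnorm_cv(1, means[[nm]], config$cv)
      }, numeric(1))
      draw <- pmin(pmax(draw, b$lower), b$upper)
      draw[["vb"]] <- min(draw[["vb"]], 1)
      p <- .full_params(draw, arch$model)
      tac <- generate_tissue(
        p, bc, sched, Sc = config$Sc, seed = sub_seed + 100L + r,
        model = arch$model,
        isotope_half_life_h = config$isotope_half_life_h
      )
      tacs[[length(tacs) + 1]] <- dplyr::mutate(
        tac[, c("t_start", "t_end", "conc")],
        subject_id = sid, region = arch$region, .before = 1
      )
      truth[[length(truth) + 1]] <- tibble::tibble(
        subject_id = sid, group = grp, region = arch$region,
        model = arch$model,
        vb = p[["vb"]], K1 = p[["K1"]], k2 = p[["k2"]],
        k3 = p[["k3"]], k4 = p[["k4"]], ki = ki_macro(p)
      )
    }
  }
  list(
    tacs = dplyr::bind_rows(tacs),
    blood_curves = blood_curves,
    truth = dplyr::bind_rows(truth),
    subjects = subjects,
    config = config
  )
}
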