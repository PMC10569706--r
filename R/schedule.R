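#' Dynamic total-body acquisition schedule
#'
#' Builds the framing schedule of a multi-session total-body PET protocol:
#' a 90-min dynamic scan framed as 6 x 60 s, 16 x 30 s, 2 x 60 s,
#' 12 x 120 s and 10 x 300 s (46 frames), followed by two 60-min scans
#' starting at 6 h and 48 h post-injection. Times are minutes
#' post-injection; the late scans are separate sessions, so the schedule
#' contains gaps.
#'
#' @param include_late if `FALSE`, return only the 46 dynamic frames.
#' @return A tibble with one row per frame and columns `t_start`, `t_end`,
#'   `t_mid`, `dur` (all minutes) and `session`
#'   (`"dynamic"`, `"6h"` or `"48h"`).
#' @examples
#' sched <- study_schedule()
#' sum(sched$dur[sched$session == "dynamic"]) # 90 minutes
#' @export
study_schedule <- function(include_late = TRUE) {
  dur_s <- c(rep(60, 6), rep(30, 16), rep(60, 2), rep(120, 12), rep(300, 10))
  t_end <- cumsum(dur_s) / 60
  t_start <- t_end - dur_s / 60
  sched <- tibble::tibble(t_start = t_start, t_end = t_end, session = "dynamic")
  if (include_late) {
    late <- tibble::tibble(
      t_start = c(360, 2880), t_end = c(420, 2940), session = c("6h", "48h")
    )
    sched <- dplyr::bind_rows(sched, late)
  }
  dplyr::mutate(sched,
    t_mid = (.data$t_start + .data$t_end) / 2,
    dur = .data$t_end - .data$t_start,
    .after = "t_end"
  )
}

#' Validate a framing schedule
#'
#' Checks that a data frame is a well-formed framing schedule: `t_start`
#' and `t_end` columns in minutes, every frame of positive duration,
#' frames strictly ordered and non-overlapping (gaps allowed).
#'
#' @param schedule a data frame with `t_start` and `t_end` columns.
#' @return The schedule as a tibble with `t_mid` and `dur` columns added
#'   (invisibly usable in pipes); errors describe the first violation.
#' @export
validate_schedule <- function(schedule) {
  if (!is.data.frame(schedule) || !all(c("t_start", "t_end") %in% names(schedule))) {
    stop("`schedule` must be a data frame with `t_start` and `t_end` columns", call. = FALSE)
  }
  sched <- tibble::as_tibble(schedule)
  if (nrow(sched) == 0) stop("schedule has no frames", call. = FALSE)
  if (!all(is.finite(sched$t_start)) || !all(is.finite(sched$t_end))) {
    stop("frame times must be finite", call. = FALSE)
  }
  if (any(sched$t_end <= sched$t_start)) {
    stop("every frame must satisfy t_end > t_start", call. = FALSE)
  }
  if (is.unsorted(sched$t_start, strictly = TRUE)) {
    stop("frames must be strictly ordered by t_start", call. = FALSE)
  }
  if (nrow(sched) > 1 && any(sched$t_start[-1] < sched$t_end[-nrow(sched)])) {
    stop("frames must not overlap", call. = FALSE)
  }
  if (!"t_mid" %in% names(sched)) {
    sched$t_mid <- (sched$t_start + sched$t_end) / 2
  }
  if (!"dur" %in% names(sched)) {
    sched$dur <- sched$t_end - sched$t_start
  }
  sched
}

#' Read and write time-activity curves in the CSV interchange format
#'
#' The interchange format has exactly the columns `subject_id`, `region`,
#' `t_start_s`, `t_end_s`, `conc_kBq_ml`, with frame times in integer
#' seconds post-injection and activity concentrations in kBq/ml
#' decay-corrected to injection time. `read_tac_csv()` validates the
#' header strictly and returns times converted to minutes; integer-second
#' schedules round-trip bit-exactly through `write_tac_csv()`.
#'
#' @param path file path.
#' @param tacs a data frame with columns `subject_id`, `region`,
#'   `t_start`, `t_end` (minutes) and `conc` (kBq/ml).
#' @return `read_tac_csv()` returns a tibble with columns `subject_id`,
#'   `region`, `t_start`, `t_end` (minutes) and `conc`; `write_tac_csv()`
#'   returns `tacs` invisibly.
#' @export
read_tac_csv <- function(path) {
  expected <- c("subject_id", "region", "t_start_s", "t_end_s", "conc_kBq_ml")
  header <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  if (!identical(header, expected)) {
    stop(
      "TAC CSV header must be exactly: ", paste(expected, collapse = ", "),
      " (got: ", paste(header, collapse = ", "), ")",
      call. = FALSE
    )
  }
  raw <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    region = readr::col_character(),
    t_start_s = readr::col_double(),
    t_end_s = readr::col_double(),
    conc_kBq_ml = readr::col_double()
  ))
  if (any(raw$t_start_s != round(raw$t_start_s)) || any(raw$t_end_s != round(raw$t_end_s))) {
    stop("frame times in the TAC CSV must be integer seconds", call. = FALSE)
  }
  if (any(!is.finite(raw$conc_kBq_ml)) || any(raw$conc_kBq_ml < 0)) {
    stop("TAC concentrations must be finite and non-negative", call. = FALSE)
  }
  tibble::tibble(
    subject_id = raw$subject_id,
    region = raw$region,
    t_start = raw$t_start_s / 60,
    t_end = raw$t_end_s / 60,
    conc = raw$conc_kBq_ml
  )
}

#' @rdname read_tac_csv
#' @export
write_tac_csv <- function(tacs, path) {
  need <- c("subject_id", "region", "t_start", "t_end", "conc")
  if (!all(need %in% names(tacs))) {
    stop("`tacs` must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  t_start_s <- tacs$t_start * 60
  t_end_s <- tacs$t_end * 60
  if (any(abs(t_start_s - round(t_start_s)) > 1e-6) ||
      any(abs(t_end_s - round(t_end_s)) > 1e-6)) {
    stop("frame times must be representable as integer seconds", call. = FALSE)
  }
  out <- tibble::tibble(
    subject_id = tacs$subject_id,
    region = tacs$region,
    t_start_s = as.integer(round(t_start_s)),
    t_end_s = as.integer(round(t_end_s)),
    conc_kBq_ml = tacs$conc
  )
  readr::write_csv(out, path)
  invisible(tacs)
}

#' Subject metadata record
#'
#' One row of subject metadata: identifier, group label, injected
#' activity, body weight and the physical half-life of the isotope
#' (78.4 h for zirconium-89, which allows imaging out to 48 h and
#' beyond).
#'
#' @param subject_id subject identifier.
#' @param group group label, e.g. `"case"` or `"control"`.
#' @param dose_mbq injected activity in MBq (> 0).
#' @param weight_kg body weight in kg (> 0).
#' @param isotope_half_life_h physical isotope half-life in hours (> 0).
#' @return A one-row tibble.
#' @export
subject_record <- function(subject_id, group, dose_mbq, weight_kg,
                           isotope_half_life_h = 78.4) {
  if (!is.numeric(dose_mbq) || dose_mbq <= 0) stop("`dose_mbq` must be > 0", call. = FALSE)
  if (!is.numeric(weight_kg) || weight_kg <= 0) stop("`weight_kg` must be > 0", call. = FALSE)
  if (!is.numeric(isotope_half_life_h) || isotope_half_life_h <= 0) {
    stop("`isotope_half_life_h` must be > 0", call. = FALSE)
  }
  tibble::tibble(
    subject_id = as.character(subject_id), group = as.character(group),
    dose_mbq = dose_mbq, weight_kg = weight_kg,
    isotope_half_life_h = isotope_half_life_h
  )
}
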