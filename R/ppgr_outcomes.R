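#' Trapezoidal area under the glucose curve
#'
#' Integrates the piecewise-linear glucose trace over `[t0, t1]` (minutes),
#' with the interval endpoints obtained by interpolation, and returns the
#' area in mmol/L·h.
#'
#' @param series Tibble with `t_min` and `glucose` for one patient.
#' @param t0,t1 Integration bounds in minutes (`t0 < t1`).
#' @param strict Passed to [bg_at()]; when `FALSE`, an unavailable value makes
#'   the result `NA` instead of an error.
#' @return Area in mmol/L·h (scalar).
#' @export
trapezoid_auc <- function(series, t0, t1, strict = TRUE) {
  stopifnot(t1 > t0)
  inner <- series$t_min[series$t_min > t0 & series$t_min < t1]
  knots <- c(t0, inner, t1)
  vals <- bg_at(series, knots, strict = strict)
  if (anyNA(vals)) return(NA_real_)
  sum(diff(knots) * (head(vals, -1) + tail(vals, -1)) / 2) / 60
}

#' Incremental (positive) area above a baseline
#'
#' Trapezoidal integral of `max(BG(t) - baseline, 0)` over `[t0, t1]`.
#' Baseline-crossing points of the piecewise-linear trace are inserted
#' exactly before integrating, so segments dipping below the baseline
#' contribute zero rather than cancelling area — the positive-increment iAUC
#' convention of standard glycemic index methodology.
#'
#' @inheritParams trapezoid_auc
#' @param baseline Baseline glucose in mmol/L (typically the pre-meal value).
#' @return Incremental area in mmol/L·h (scalar, `>= 0`).
#' @export
incremental_auc <- function(series, t0, t1, baseline, strict = TRUE) {
  stopifnot(t1 > t0)
  inner <- series$t_min[series$t_min > t0 & series$t_min < t1]
  knots <- c(t0, inner, t1)
  vals <- bg_at(series, knots, strict = strict)
  if (anyNA(vals)) return(NA_real_)
  d <- vals - baseline
  # insert exact zero crossings between consecutive knots of opposite sign
  tt <- knots[1]
  vv <- d[1]
  for (i in seq_len(length(knots) - 1L)) {
    if ((d[i] < 0) != (d[i + 1L] < 0) && d[i] != 0 && d[i + 1L] != 0) {
      tc <- knots[i] + (knots[i + 1L] - knots[i]) * (0 - d[i]) / (d[i + 1L] - d[i])
      tt <- c(tt, tc)
      vv <- c(vv, 0)
    }
    tt <- c(tt, knots[i + 1L])
    vv <- c(vv, d[i + 1L])
  }
  pos <- pmax(vv, 0)
  sum(diff(tt) * (head(pos, -1) + tail(pos, -1)) / 2) / 60
}

#' Extract the postprandial glycemic response for one meal
#'
#' Computes the eight PPGR outcome measures from a patient's glucose trace:
#' pre-meal glucose `bg0 = BG(t)`, `bg60 = BG(t + 60)`, the peak `bgmax` over
#' the 3 h post-meal window (raw samples plus interpolated window edges),
#' `bgrise = bgmax - bg0`, total areas `auc60`/`auc120`, and incremental
#' areas `iauc60`/`iauc120` above the `bg0` baseline (positive increments
#' only). Areas are in mmol/L·h.
#'
#' @param series Tibble with `t_min` and `glucose` for one patient.
#' @param meal_start Meal start time in minutes on the series clock.
#' @param strict When `FALSE`, returns a row of `NA`s (with `ok = FALSE`)
#'   if any required part of the trace is unavailable.
#' @return One-row tibble `bg0`, `bg60`, `bgmax`, `bgrise`, `auc60`,
#'   `auc120`, `iauc60`, `iauc120`, `ok`.
#' @export
extract_ppgr <- function(series, meal_start, strict = TRUE) {
  t <- meal_start
  bg0 <- bg_at(series, t, strict = strict)
  bg60 <- bg_at(series, t + 60, strict = strict)
  edge180 <- bg_at(series, t + 180, strict = strict)
  in_win <- series$t_min >= t & series$t_min <= t + 180
  cand <- c(bg0, series$glucose[in_win], edge180)
  bgmax <- if (anyNA(cand)) NA_real_ else max(cand)
  auc60 <- trapezoid_auc(series, t, t + 60, strict = strict)
  auc120 <- trapezoid_auc(series, t, t + 120, strict = strict)
  iauc60 <- if (is.na(bg0)) NA_real_ else
    incremental_auc(series, t, t + 60, baseline = bg0, strict = strict)
  iauc120 <- if (is.na(bg0)) NA_real_ else
    incremental_auc(series, t, t + 120, baseline = bg0, strict = strict)
  out <- tibble::tibble(bg0 = bg0, bg60 = bg60, bgmax = bgmax,
                        bgrise = bgmax - bg0, auc60 = auc60, auc120 = auc120,
                        iauc60 = iauc60, iauc120 = iauc120)
  out$ok <- !anyNA(out)
  out
}

#' Detect diary misreporting at the patient level
#'
#' Flags a patient's diary as misreported when (a) every meal consists of a
#' single food item (a significant lack of food data), or (b) strictly more
#' than `max_rounded` meals have every item's weight a multiple of 100 g
#' (imprecise portion reporting). Flagged patients are removed wholesale from
#' modeling.
#'
#' @param diary Meal tibble from [read_diary()] (any subset of patients).
#' @param max_rounded Largest tolerated number of fully 100 g-rounded meals
#'   (default 5).
#' @return Tibble `patient_id`, `flagged`, `reason`
#'   (`single_item`/`rounded`/`NA`), `n_meals`.
#' @export
detect_misreporting <- function(diary, max_rounded = 5) {
  per_meal <- tibble::tibble(
    patient_id = diary$patient_id,
    single = vapply(diary$items, function(x) nrow(x) == 1L, logical(1)),
    rounded = vapply(diary$items,
                     function(x) all(x$grams %% 100 == 0), logical(1)))
  per_meal |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_meals = dplyr::n(),
      all_single = all(.data$single),
      n_rounded = sum(.data$rounded), .groups = "drop") |>
    dplyr::mutate(
      reason = dplyr::case_when(
        .data$all_single ~ "single_item",
        .data$n_rounded > max_rounded ~ "rounded",
        TRUE ~ NA_character_),
      flagged = !is.na(.data$reason)) |>
    dplyr::select("patient_id", "flagged", "reason", "n_meals")
}

#' Record-level filters on matched meals
#'
#' Removes, from the kept (non-excluded) matched meals, (1) records whose
#' meal contains a food item with undefined GI, and (2) records with more
#' than `carb_threshold` grams of carbohydrate but a small glycemic response,
#' defined as a mean incremental rate `iauc120 / 2 h` below `rate_threshold`.
#'
#' @param records Tibble with at least `gi_undefined` (logical), `carbo` (g)
#'   and `iauc120` (mmol/L·h) columns.
#' @param carb_threshold Carbohydrate threshold in grams (default 40).
#' @param rate_threshold Minimum mean incremental rate in mmol/L/h
#'   (default 0.3).
#' @return `records` with a `filter_reason` column (`NA` = kept); attribute
#'   `"filter_counts"` tallies removals per reason.
#' @export
filter_records <- function(records, carb_threshold = 40, rate_threshold = 0.3) {
  gi_undef <- records$gi_undefined
  small <- !gi_undef & records$carbo > carb_threshold &
    records$iauc120 / 2 < rate_threshold
  records$filter_reason <- dplyr::case_when(
    gi_undef ~ "gi_undefined",
    small ~ "small_ppgr",
    TRUE ~ NA_character_)
  attr(records, "filter_counts") <- c(
    gi_undefined = sum(gi_undef, na.rm = TRUE),
    small_ppgr = sum(small, na.rm = TRUE))
  records
}
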