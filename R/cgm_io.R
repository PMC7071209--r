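#' Read a continuous glucose monitoring (CGM) export
#'
#' Expects columns `patient_id`, `timestamp` (ISO-8601) and `glucose_mmol_l`.
#' Rows are sorted in time within patient; duplicated or non-monotone
#' timestamps and glucose values outside the sensor's plausible range
#' (1–30 mmol/L) are hard errors naming the offending line.
#'
#' @param path CSV file path.
#' @return Tibble `patient_id`, `time` (POSIXct, UTC), `glucose` (mmol/L),
#'   sorted by patient and time.
#' @export
read_cgm <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           patient_id = readr::col_character(),
                           timestamp = readr::col_datetime(),
                           glucose_mmol_l = readr::col_double()))
  raw$.line <- seq_len(nrow(raw)) + 1L  # header is line 1
  if (anyNA(raw$timestamp))
    stop("unparseable timestamp at line(s) ",
         paste(raw$.line[is.na(raw$timestamp)], collapse = ", "))
  bad_g <- is.na(raw$glucose_mmol_l) | raw$glucose_mmol_l < 1 |
    raw$glucose_mmol_l > 30
  if (any(bad_g))
    stop("glucose outside [1, 30] mmol/L at line(s) ",
         paste(raw$.line[bad_g], collapse = ", "))
  raw <- dplyr::arrange(raw, .data$patient_id, .data$timestamp, .data$.line)
  dup <- unlist(tapply(as.numeric(raw$timestamp), raw$patient_id,
                       function(x) c(FALSE, diff(x) <= 0)), use.names = FALSE)
  if (any(dup))
    stop("non-monotone or duplicate CGM timestamp at line(s) ",
         paste(raw$.line[dup], collapse = ", "))
  tibble::tibble(patient_id = raw$patient_id, time = raw$timestamp,
                 glucose = raw$glucose_mmol_l)
}

#' Read the paper-protocol meal-start records
#'
#' Expects columns `patient_id`, `timestamp` and `point_bg_mmol_l` (optional
#' fingerstick glucose, may be blank; carried through but not used in any
#' computation).
#'
#' @param path CSV file path.
#' @return Tibble `patient_id`, `time` (POSIXct), `point_bg`.
#' @export
read_protocol <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           patient_id = readr::col_character(),
                           timestamp = readr::col_datetime(),
                           point_bg_mmol_l = readr::col_double()))
  if (anyNA(raw$timestamp)) stop("unparseable protocol timestamp")
  dplyr::arrange(
    tibble::tibble(patient_id = raw$patient_id, time = raw$timestamp,
                   point_bg = raw$point_bg_mmol_l),
    .data$patient_id, .data$time)
}

#' Read an electronic meal diary
#'
#' One row per food item: `patient_id`, `timestamp`, `meal_type`
#' (breakfast/lunch/dinner/snack), `food_name`, `grams`. Items sharing a
#' patient, timestamp and meal type form one meal. Rows with non-positive
#' grams are rejected and reported via the `"rejected"` attribute (a tibble
#' with line numbers); an unknown meal type is a hard error.
#'
#' @param path CSV file path.
#' @return Tibble of meals: `patient_id`, `time`, `meal_type`, `meal_id` and a
#'   list-column `items` (tibbles with `food_name`, `grams`).
#' @export
read_diary <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           patient_id = readr::col_character(),
                           timestamp = readr::col_datetime(),
                           meal_type = readr::col_character(),
                           food_name = readr::col_character(),
                           grams = readr::col_double()))
  raw$.line <- seq_len(nrow(raw)) + 1L
  if (anyNA(raw$timestamp)) stop("unparseable diary timestamp")
  bad_type <- !raw$meal_type %in% c("breakfast", "lunch", "dinner", "snack")
  if (any(bad_type))
    stop("unknown meal_type '", raw$meal_type[bad_type][1], "' at line ",
         raw$.line[bad_type][1])
  rejected <- raw[is.na(raw$grams) | raw$grams <= 0, ]
  if (nrow(rejected))
    warning(nrow(rejected), " diary row(s) with non-positive grams rejected")
  raw <- raw[!(is.na(raw$grams) | raw$grams <= 0), ]
  meals <- raw |>
    dplyr::group_by(.data$patient_id, time = .data$timestamp,
                    meal_type = .data$meal_type) |>
    dplyr::summarise(items = list(tibble::tibble(food_name, grams)),
                     .groups = "drop") |>
    dplyr::arrange(.data$patient_id, .data$time)
  meals$meal_id <- paste0(meals$patient_id, "_m",
                          stats::ave(seq_len(nrow(meals)), meals$patient_id,
                                     FUN = seq_along))
  attr(meals, "rejected") <- tibble::tibble(line = rejected$.line)
  meals
}

#' Interpolated glucose at arbitrary times
#'
#' Linear interpolation on a single patient's glucose trace. Times within
#' 2.5 min (half the nominal sampling interval) before the first or after the
#' last sample take the edge sample's value; a query falling inside a sensor
#' gap longer than `max_gap_min` is undefined.
#'
#' @param series Tibble with `t_min` (strictly increasing minutes) and
#'   `glucose` for one patient.
#' @param t Numeric vector of query times in minutes.
#' @param max_gap_min Longest bridgeable sensor gap (default 20 min).
#' @param strict If `TRUE` (default), out-of-range queries and gap hits raise
#'   errors; if `FALSE` they yield `NA`, which callers map to a
#'   `cgm_unavailable` status.
#' @return Numeric vector of glucose values (mmol/L).
#' @export
bg_at <- function(series, t, max_gap_min = 20, strict = TRUE) {
  tt <- series$t_min
  g <- series$glucose
  n <- length(tt)
  stopifnot(n >= 1L)
  out <- rep(NA_real_, length(t))
  oob <- t < tt[1] - 2.5 | t > tt[n] + 2.5
  if (strict && any(oob))
    stop("time outside CGM span: ", paste(signif(t[oob], 6), collapse = ", "))
  before <- !oob & t <= tt[1]
  after <- !oob & t >= tt[n]
  out[before] <- g[1]
  out[after] <- g[n]
  mid <- !oob & !before & !after
  if (any(mid)) {
    i <- findInterval(t[mid], tt)
    gap <- tt[i + 1L] - tt[i]
    in_gap <- gap > max_gap_min & t[mid] > tt[i] & t[mid] < tt[i + 1L]
    if (strict && any(in_gap))
      stop("query inside a sensor gap longer than ", max_gap_min, " min")
    w <- (t[mid] - tt[i]) / gap
    v <- (1 - w) * g[i] + w * g[i + 1L]
    v[in_gap] <- NA_real_
    out[mid] <- v
  }
  out
}

#' Match protocol meal starts to diary records
#'
#' Each protocol entry is paired with the diary meal of minimal absolute time
#' difference within `max_gap_min`; protocol entries with no diary meal in
#' range are dropped. Each diary meal pairs with at most one protocol entry —
#' assignment is greedy by ascending time difference, so when two protocol
#' entries compete for one diary meal the closer one wins.
#'
#' @param protocol Tibble from [read_protocol()].
#' @param diary Meal tibble from [read_diary()].
#' @param max_gap_min Largest admissible protocol-to-diary separation
#'   (default 60 min).
#' @return Tibble of matched meals: `patient_id`, `meal_start` (the protocol
#'   time), `protocol_time`, `diary_time`, `meal_id`, `meal_type`, `items`,
#'   `point_bg`. Attribute `"unmatched"` counts dropped protocol entries.
#' @export
match_protocol_to_diary <- function(protocol, diary, max_gap_min = 60) {
  keep_i <- integer(0)  # protocol rows (global indices)
  keep_j <- integer(0)  # diary rows
  for (pid in unique(protocol$patient_id)) {
    pi <- which(protocol$patient_id == pid)
    di <- which(diary$patient_id == pid)
    if (!length(di)) next
    dt <- abs(outer(as.numeric(protocol$time[pi]),
                    as.numeric(diary$time[di]), "-")) / 60
    cand <- which(dt <= max_gap_min, arr.ind = TRUE)
    if (!nrow(cand)) next
    cand <- cand[order(dt[cand]), , drop = FALSE]
    prot_used <- rep(FALSE, length(pi))
    dia_used <- rep(FALSE, length(di))
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (prot_used[i] || dia_used[j]) next
      prot_used[i] <- TRUE
      dia_used[j] <- TRUE
      keep_i <- c(keep_i, pi[i])
      keep_j <- c(keep_j, di[j])
    }
  }
  res <- tibble::tibble(
    patient_id = protocol$patient_id[keep_i],
    meal_start = protocol$time[keep_i],
    protocol_time = protocol$time[keep_i],
    diary_time = diary$time[keep_j],
    meal_id = diary$meal_id[keep_j],
    meal_type = diary$meal_type[keep_j],
    items = diary$items[keep_j],
    point_bg = protocol$point_bg[keep_i])
  res <- dplyr::arrange(res, .data$patient_id, .data$meal_start)
  attr(res, "unmatched") <- nrow(protocol) - length(keep_i)
  res
}

#' Exclude meals with misreported or interfering start times
#'
#' Evaluates, in order and first-match-wins, the four timing exclusion rules
#' on interpolated glucose values around each matched meal start `t`:
#' \describe{
#'   \item{late_report}{`BG(t) - BG(t-60) > late_threshold` — the reported
#'     start falls on the rising peak, i.e. the meal was reported
#'     significantly later than it began.}
#'   \item{falling_edge}{`BG(t) >= BG(t+30) + edge_threshold` and
#'     `BG(t) <= BG(t-30) - edge_threshold` — the reported start sits on the
#'     falling edge of the postprandial peak.}
#'   \item{prior_meal}{another matched meal of the same patient starts within
#'     the open interval `(t - window, t)`.}
#'   \item{subsequent_meal}{another matched meal starts within `(t, t + window)`.}
#' }
#' Meals for which any required glucose value is unavailable (sensor gap or
#' outside the trace span) are excluded with reason `cgm_unavailable`.
#'
#' @param matched Matched meal tibble from [match_protocol_to_diary()].
#' @param cgm CGM tibble from [read_cgm()].
#' @param late_threshold Rise over the preceding hour flagging a late report
#'   (default 1.0 mmol/L).
#' @param edge_threshold Half-hour drop/rise margin for the falling-edge rule
#'   (default 0.5 mmol/L).
#' @param window_min Interference window for neighbouring meals (default
#'   60 min, endpoints open).
#' @return `matched` with an added `exclusion` column (`NA` = kept) and an
#'   attribute `"exclusion_counts"` (named integer vector per reason).
#' @export
apply_exclusion_rules <- function(matched, cgm, late_threshold = 1.0,
                                  edge_threshold = 0.5, window_min = 60) {
  matched$exclusion <- NA_character_
  for (pid in unique(matched$patient_id)) {
    rows <- which(matched$patient_id == pid)
    trace <- cgm[cgm$patient_id == pid, ]
    if (nrow(trace) == 0L) {
      matched$exclusion[rows] <- "cgm_unavailable"
      next
    }
    origin <- trace$time[1]
    series <- tibble::tibble(
      t_min = as.numeric(difftime(trace$time, origin, units = "mins")),
      glucose = trace$glucose)
    t <- as.numeric(difftime(matched$meal_start[rows], origin, units = "mins"))
    bg0 <- bg_at(series, t, strict = FALSE)
    bg_m60 <- bg_at(series, t - 60, strict = FALSE)
    bg_m30 <- bg_at(series, t - 30, strict = FALSE)
    bg_p30 <- bg_at(series, t + 30, strict = FALSE)
    for (k in seq_along(rows)) {
      others <- t[-k]
      reason <- if (anyNA(c(bg0[k], bg_m60[k], bg_m30[k], bg_p30[k]))) {
        "cgm_unavailable"
      } else if (bg0[k] - bg_m60[k] > late_threshold) {
        "late_report"
      } else if (bg0[k] >= bg_p30[k] + edge_threshold &&
                 bg0[k] <= bg_m30[k] - edge_threshold) {
        "falling_edge"
      } else if (any(others > t[k] - window_min & others < t[k])) {
        "prior_meal"
      } else if (any(others > t[k] & others < t[k] + window_min)) {
        "subsequent_meal"
      } else NA_character_
      matched$exclusion[rows[k]] <- reason
    }
  }
  reasons <- c("late_report", "falling_edge", "prior_meal", "subsequent_meal",
               "cgm_unavailable")
  counts <- vapply(reasons, function(r)
    sum(matched$exclusion == r, na.rm = TRUE), integer(1))
  attr(matched, "exclusion_counts") <- counts
  matched
}
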