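write_tmp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("CGM reader validates glucose range and time ordering", {
  ok <- write_tmp_csv(c(
    "patient_id,timestamp,glucose_mmol_l",
    "P1,2021-03-01T08:00:00Z,5.4",
    "P1,2021-03-01T08:05:00Z,5.6",
    "P1,2021-03-01T08:10:00Z,5.2"))
  cgm <- read_cgm(ok)
  expect_equal(nrow(cgm), 3)
  expect_equal(cgm$glucose, c(5.4, 5.6, 5.2))
  dup <- write_tmp_csv(c(
    "patient_id,timestamp,glucose_mmol_l",
    "P1,2021-03-01T08:00:00Z,5.4",
    "P1,2021-03-01T08:00:00Z,5.6"))
  expect_error(read_cgm(dup), "line.* 3")
  oor <- write_tmp_csv(c(
    "patient_id,timestamp,glucose_mmol_l",
    "P1,2021-03-01T08:00:00Z,0.4"))
  expect_error(read_cgm(oor), "\\[1, 30\\]")
})

test_that("diary reader groups items into meals and rejects bad rows", {
  path <- write_tmp_csv(c(
    "patient_id,timestamp,meal_type,food_name,grams",
    "P1,2021-03-01T08:00:00Z,breakfast,bread,80",
    "P1,2021-03-01T08:00:00Z,breakfast,apple,120",
    "P1,2021-03-01T13:00:00Z,lunch,rice,150",
    "P1,2021-03-01T13:00:00Z,lunch,cheese,0"))
  expect_warning(diary <- read_diary(path), "rejected")
  expect_equal(nrow(diary), 2)
  expect_equal(nrow(diary$items[[1]]), 2)
  expect_equal(attr(diary, "rejected")$line, 5L)
  bad <- write_tmp_csv(c(
    "patient_id,timestamp,meal_type,food_name,grams",
    "P1,2021-03-01T08:00:00Z,brunch,bread,80"))
  expect_error(read_diary(bad), "brunch")
})

test_that("interpolation is linear with edge tolerance and gap detection", {
  s <- make_series(c(0, 5, 10, 40), c(5.0, 6.0, 6.4, 5.0))
  expect_equal(bg_at(s, 5), 6.0)          # exact sample hit
  expect_equal(bg_at(s, 2.5), 5.5)        # midpoint of a segment
  expect_equal(bg_at(s, -2, ), 5.0)       # within the 2.5-min edge tolerance
  expect_equal(bg_at(s, 41.5), 5.0)
  expect_error(bg_at(s, -3), "outside")
  expect_error(bg_at(s, 25), "gap")       # inside the 30-min sensor gap
  expect_equal(bg_at(s, c(25, 5), strict = FALSE), c(NA, 6.0))
})

test_that("protocol entries match the nearest diary meal within the gap cap", {
  origin <- as.POSIXct("2021-03-01 00:00:00", tz = "UTC")
  protocol <- tibble::tibble(patient_id = "P1",
                             time = origin + c(8, 14) * 3600,
                             point_bg = c(5, 5))
  diary <- tibble::tibble(
    patient_id = "P1",
    time = origin + c(7 + 55 / 60, 9.5, 17) * 3600,
    meal_type = c("breakfast", "snack", "dinner"),
    meal_id = c("P1_m1", "P1_m2", "P1_m3"),
    items = replicate(3, tibble::tibble(food_name = "bread", grams = 50),
                      simplify = FALSE))
  m <- match_protocol_to_diary(protocol, diary, max_gap_min = 60)
  expect_equal(nrow(m), 1)                  # 14:00 has nothing within 60 min
  expect_equal(m$meal_id, "P1_m1")          # 07:55 is nearest to 08:00
  expect_equal(attr(m, "unmatched"), 1)
})

test_that("greedy matching assigns a contested diary meal to the closer entry", {
  origin <- as.POSIXct("2021-03-01 00:00:00", tz = "UTC")
  protocol <- tibble::tibble(patient_id = "P1",
                             time = origin + c(11.8, 12.4) * 3600,
                             point_bg = c(5, 5))
  diary <- tibble::tibble(
    patient_id = "P1", time = origin + 12 * 3600, meal_type = "lunch",
    meal_id = "P1_m1",
    items = list(tibble::tibble(food_name = "rice", grams = 100)))
  m <- match_protocol_to_diary(protocol, diary, max_gap_min = 60)
  expect_equal(nrow(m), 1)
  expect_equal(m$protocol_time, origin + 11.8 * 3600)
  expect_equal(attr(m, "unmatched"), 1)
})

test_that("matching is invariant under a global time translation", {
  cohort <- gen_cohort(generator_config(seed = 31, n_gdm = 3, n_control = 3,
                                        days = 2))
  m1 <- match_protocol_to_diary(cohort$protocol, cohort$diary)
  shift <- 86400 * 3 + 1234
  prot2 <- dplyr::mutate(cohort$protocol, time = time + shift)
  dia2 <- dplyr::mutate(cohort$diary, time = time + shift)
  m2 <- match_protocol_to_diary(prot2, dia2)
  expect_equal(m2$meal_id, m1$meal_id)
  expect_equal(as.numeric(m2$meal_start) - as.numeric(m1$meal_start),
               rep(shift, nrow(m1)))
})

flat_cohort_fixture <- function(meal_min, glucose_fun = function(t) rep(5, length(t))) {
  origin <- as.POSIXct("2021-03-01 00:00:00", tz = "UTC")
  t <- seq(0, 2000, by = 5)
  cgm <- tibble::tibble(patient_id = "P1", time = origin + t * 60,
                        glucose = glucose_fun(t))
  matched <- tibble::tibble(
    patient_id = "P1", meal_start = origin + meal_min * 60,
    protocol_time = origin + meal_min * 60,
    diary_time = origin + meal_min * 60,
    meal_id = paste0("P1_m", seq_along(meal_min)),
    meal_type = "lunch",
    items = replicate(length(meal_min),
                      tibble::tibble(food_name = "bread", grams = 50),
                      simplify = FALSE),
    point_bg = 5)
  list(matched = matched, cgm = cgm)
}

test_that("exclusion rules fire per their thresholds and order", {
  # late report: BG at reported start 1.2 above one hour earlier
  g_late <- function(t) 5 + 1.2 * pmax(pmin((t - 240) / 60, 1), 0) *
    pmax(pmin((360 - t) / 60, 1), 0)
  f <- flat_cohort_fixture(300, g_late)
  r <- apply_exclusion_rules(f$matched, f$cgm)
  expect_equal(r$exclusion, "late_report")
  # falling edge: 7.0 / 6.3 / 5.6 half-hour ladder (both 0.5 margins met)
  g_fall <- function(t) {
    anchor_t <- c(0, 480, 540, 570, 600, 630, 660, 2000)
    anchor_g <- c(5, 5, 7.0, 7.0, 6.3, 5.6, 5, 5)
    stats::approx(anchor_t, anchor_g, t)$y
  }
  f <- flat_cohort_fixture(600, g_fall)
  r <- apply_exclusion_rules(f$matched, f$cgm)
  expect_equal(r$exclusion, "falling_edge")
  # two meals 45 min apart on a flat trace: subsequent then prior
  f <- flat_cohort_fixture(c(900, 945))
  r <- apply_exclusion_rules(f$matched, f$cgm)
  expect_equal(r$exclusion, c("subsequent_meal", "prior_meal"))
  # isolated meals on a constant trace are all kept
  f <- flat_cohort_fixture(c(300, 600, 900))
  r <- apply_exclusion_rules(f$matched, f$cgm)
  expect_true(all(is.na(r$exclusion)))
})

test_that("a meal needing glucose outside the trace is cgm_unavailable", {
  f <- flat_cohort_fixture(30)  # t - 60 falls before the trace
  r <- apply_exclusion_rules(f$matched, f$cgm)
  expect_equal(r$exclusion, "cgm_unavailable")
})

test_that("every excluded meal carries exactly one reason and counts reconcile", {
  cohort <- gen_cohort(generator_config(seed = 77, n_gdm = 5, n_control = 5,
                                        days = 3))
  m <- match_protocol_to_diary(cohort$protocol, cohort$diary)
  r <- apply_exclusion_rules(m, cohort$cgm)
  counts <- attr(r, "exclusion_counts")
  expect_equal(sum(counts), sum(!is.na(r$exclusion)))
  expect_equal(sum(is.na(r$exclusion)) + sum(counts), nrow(m))
})
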