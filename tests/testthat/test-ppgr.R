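test_that("trapezoidal AUC matches closed forms and is additive", {
  flat <- make_series(seq(0, 120, 5), rep(5, 25))
  expect_equal(trapezoid_auc(flat, 0, 120), 10)
  ramp <- make_series(seq(0, 120, 5), 5 + seq(0, 120, 5) / 60)
  expect_equal(trapezoid_auc(ramp, 0, 120), 12)  # mean 6 mmol/L over 2 h
  # additive over adjacent intervals
  expect_equal(trapezoid_auc(ramp, 0, 47) + trapezoid_auc(ramp, 47, 120),
               trapezoid_auc(ramp, 0, 120))
})

test_that("AUCs agree with a dense-grid brute-force integrator", {
  set.seed(7)
  for (i in 1:25) {
    t <- seq(0, 180, by = 5)
    s <- make_series(t, 5 + cumsum(rnorm(length(t), 0, 0.4)))
    t0 <- runif(1, 0, 20)
    t1 <- t0 + runif(1, 60, 150)
    expect_equal(trapezoid_auc(s, t0, t1), dense_auc(s, t0, t1),
                 tolerance = 1e-6)
    b <- s$glucose[1] + runif(1, -0.5, 1)
    expect_equal(incremental_auc(s, t0, t1, baseline = b),
                 dense_auc(s, t0, t1, baseline = b), tolerance = 1e-6)
  }
})

test_that("incremental AUC clips below-baseline area exactly", {
  # constant at baseline: zero incremental area
  flat <- make_series(seq(0, 120, 5), rep(5, 25))
  expect_equal(incremental_auc(flat, 0, 120, baseline = 5), 0)
  # triangular excursion 0 -> 2 -> 0 above baseline over 120 min
  tri <- make_series(c(0, 60, 120), c(5, 7, 5))
  expect_equal(incremental_auc(tri, 0, 120, baseline = 5), 2)
  # second hour dips 1 below baseline and must contribute nothing
  dip <- make_series(c(0, 30, 60, 90, 120), c(5, 7, 5, 4, 4))
  expect_equal(incremental_auc(dip, 0, 120, baseline = 5),
               dense_auc(dip, 0, 120, baseline = 5), tolerance = 1e-6)
  # with baseline 0 it reduces to the plain trapezoid for positive traces
  expect_equal(incremental_auc(dip, 0, 120, baseline = 0),
               trapezoid_auc(dip, 0, 120))
  # non-increasing in the baseline
  b <- seq(3, 8, by = 0.5)
  vals <- vapply(b, function(bb) incremental_auc(dip, 0, 120, baseline = bb),
                 numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("PPGR extraction reproduces closed-form outcomes", {
  flat <- make_series(seq(0, 240, 5), rep(5, 49))
  r <- extract_ppgr(flat, 0)
  expect_equal(r$bg0, 5)
  expect_equal(r$bg60, 5)
  expect_equal(r$bgmax, 5)
  expect_equal(r$bgrise, 0)
  expect_equal(r$auc120, 10)
  expect_equal(r$iauc120, 0)
  # linear rise 5 -> 7 over the first hour, then flat
  t <- seq(0, 240, 5)
  rise <- make_series(t, pmin(5 + 2 * t / 60, 7))
  r <- extract_ppgr(rise, 0)
  expect_equal(r$bgmax, 7)
  expect_equal(r$bgrise, 2)
  expect_equal(r$iauc60, 1)      # triangle above baseline: 1 h * 2 / 2
  expect_equal(r$iauc120, 3)     # triangle + a full hour at +2
  expect_equal(r$auc120, 13)     # baseline rectangle (10) + incremental (3)
  expect_equal(r$iauc120, dense_auc(rise, 0, 120, baseline = 5),
               tolerance = 1e-6)
})

test_that("PPGR extraction is equivariant under constant trace shifts", {
  set.seed(12)
  t <- seq(0, 240, 5)
  s <- make_series(t, 5.5 + cumsum(rnorm(length(t), 0, 0.3)))
  r <- extract_ppgr(s, 10)
  shifted <- make_series(t, s$glucose + 2)
  r2 <- extract_ppgr(shifted, 10)
  expect_equal(r2$bg0, r$bg0 + 2)
  expect_equal(r2$bg60, r$bg60 + 2)
  expect_equal(r2$bgmax, r$bgmax + 2)
  expect_equal(r2$bgrise, r$bgrise)
  expect_equal(r2$iauc60, r$iauc60)
  expect_equal(r2$iauc120, r$iauc120)
  expect_equal(r2$auc120, r$auc120 + 4)
  # invariants of the record itself
  expect_gte(r$bgmax, r$bg60)
  expect_equal(r$bgrise, r$bgmax - r$bg0)
  expect_lte(r$iauc60, r$iauc120 + 1e-12)
  expect_lte(r$auc60, r$auc120)
  expect_lte(r$iauc120, r$auc120)
})

test_that("vectorized extraction equals the per-meal reference", {
  cohort <- gen_cohort(generator_config(seed = 5, n_gdm = 2, n_control = 2,
                                        days = 2))
  m <- match_protocol_to_diary(cohort$protocol, cohort$diary)
  m <- apply_exclusion_rules(m, cohort$cgm)
  kept <- m[is.na(m$exclusion), ]
  fast <- extract_ppgr_meals(kept, cohort$cgm)
  cols <- c("bg0", "bg60", "bgmax", "bgrise", "auc60", "auc120", "iauc60",
            "iauc120")
  for (k in seq_len(nrow(kept))) {
    tr <- cohort$cgm[cohort$cgm$patient_id == kept$patient_id[k], ]
    ser <- make_series(as.numeric(difftime(tr$time, tr$time[1],
                                           units = "mins")), tr$glucose)
    t <- as.numeric(difftime(kept$meal_start[k], tr$time[1], units = "mins"))
    ref <- extract_ppgr(ser, t, strict = FALSE)
    expect_equal(unlist(fast[k, cols]), unlist(ref[cols]), tolerance = 1e-10)
  }
})

test_that("misreporting detection flags single-item and rounded diaries", {
  mk_diary <- function(pid, items_per_meal, grams) {
    n <- length(items_per_meal)
    tibble::tibble(
      patient_id = pid,
      time = as.POSIXct("2021-03-01", tz = "UTC") + seq_len(n) * 14400,
      meal_type = "lunch", meal_id = paste0(pid, "_m", seq_len(n)),
      items = lapply(seq_len(n), function(i)
        tibble::tibble(food_name = paste0("f", seq_len(items_per_meal[i])),
                       grams = rep(grams[i], items_per_meal[i]))))
  }
  single <- mk_diary("P1", rep(1, 10), rep(137, 10))
  r <- detect_misreporting(single)
  expect_true(r$flagged)
  expect_equal(r$reason, "single_item")
  # 6 meals fully rounded to 100 g: flagged (strictly more than 5)
  rounded6 <- mk_diary("P2", rep(2, 8), c(rep(100, 6), 117, 93))
  r <- detect_misreporting(rounded6)
  expect_true(r$flagged)
  expect_equal(r$reason, "rounded")
  # exactly 5 rounded meals out of 20 is tolerated
  rounded5 <- mk_diary("P3", rep(2, 20), c(rep(200, 5), 80 + seq_len(15)))
  expect_false(detect_misreporting(rounded5)$flagged)
})

test_that("record filters remove undefined-GI and small-response records", {
  records <- tibble::tibble(
    meal_id = paste0("m", 1:4),
    gi_undefined = c(TRUE, FALSE, FALSE, FALSE),
    carbo = c(30, 50, 30, 60),
    iauc120 = c(1.0, 0.4, 0.1, 1.4))
  r <- filter_records(records)
  expect_equal(r$filter_reason, c("gi_undefined", "small_ppgr", NA, NA))
  counts <- attr(r, "filter_counts")
  expect_equal(unname(counts["gi_undefined"]), 1L)
  expect_equal(unname(counts["small_ppgr"]), 1L)
  expect_equal(sum(counts), sum(!is.na(r$filter_reason)))
  # the 0.3 mmol/L/h threshold is a rate: iauc120 of 0.6 over 2 h is kept
  edge <- filter_records(tibble::tibble(meal_id = "m", gi_undefined = FALSE,
                                        carbo = 50, iauc120 = 0.6))
  expect_true(is.na(edge$filter_reason))
})
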