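#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: a CGM-monitored
#' cohort of pregnant women (GDM and control groups) keeping electronic meal
#' diaries and paper protocols over several days, with a planted linear
#' relation between meal/patient features and the incremental glycemic
#' response, plus injected reporting errors that exercise the matching and
#' exclusion stages.
#'
#' The postprandial response of each meal is a gamma-shaped kernel peaking at
#' `kernel_peak_min` minutes, normalized to unit iAUC120 so that a meal's
#' amplitude is directly its noiseless iAUC120 in mmol/L·h. The amplitude of
#' meal *i* of patient *p* is
#' `intercept + beta %*% x_i + u_p + e_i`, with `u_p ~ N(0, patient_sd)` a
#' patient random effect and `e_i ~ N(0, noise_sd)` meal-level noise, clipped
#' below at a small positive value. `beta` may name any of the meal features
#' (`carbo`, `gl`, ...), `bg0` (the patient's basal glucose), or numeric
#' patient covariates such as `ogtt_1h`.
#'
#' @param seed Integer seed (mandatory; every draw derives from it).
#' @param n_gdm,n_control Patients per group.
#' @param days Monitoring days per patient.
#' @param meals_per_day Diary meals per day (anchored between 08:00 and
#'   19:30).
#' @param cgm_interval CGM sampling interval in minutes.
#' @param kernel_peak_min,kernel_shape Time-to-peak (minutes) and shape of
#'   the gamma response kernel.
#' @param beta Named true coefficient vector of the planted signal.
#' @param intercept Amplitude intercept (mmol/L·h).
#' @param noise_sd Meal-level amplitude noise SD (mmol/L·h).
#' @param patient_sd SD of the patient random effect (mmol/L·h).
#' @param sensor_sd,sensor_rho Stationary SD (mmol/L) and lag-1 (per sample)
#'   autocorrelation of the AR(1) sensor noise.
#' @param p_late Probability a meal's start is reported 35–50 min late (both
#'   protocol and diary), landing the reported start on the rising peak.
#' @param p_falling Probability the reported start lands on the falling edge
#'   of the peak (shift of `kernel_peak_min` + 28–35 min).
#' @param p_cluster Probability an extra snack is inserted 20–40 min after a
#'   meal, creating a prior/subsequent-meal interference pair.
#' @param p_missing_diary Probability a meal's diary record is lost (its
#'   protocol entry then finds no match and is dropped).
#' @param misreporter_fraction Fraction of patients emitting misreported
#'   diaries (half all-single-item, half 100 g-rounded).
#' @param basal_control,basal_gdm,basal_sd Basal glucose means per group and
#'   between-patient SD (mmol/L).
#' @return A `ppgr_gen_config` list.
#' @export
generator_config <- function(seed,
                             n_gdm = 30, n_control = 30,
                             days = 6, meals_per_day = 4, cgm_interval = 5,
                             kernel_peak_min = 45, kernel_shape = 5,
                             beta = c(carbo = 0.012, gl = 0.016, bg0 = -0.25),
                             intercept = 2.07,
                             noise_sd = 0.62, patient_sd = 0.2,
                             sensor_sd = 0.10, sensor_rho = 0.7,
                             p_late = 0.05, p_falling = 0.02,
                             p_cluster = 0.03, p_missing_diary = 0.02,
                             misreporter_fraction = 0.10,
                             basal_control = 4.5, basal_gdm = 5.2,
                             basal_sd = 0.45) {
  if (missing(seed)) stop("a seed is mandatory")
  probs <- c(p_late = p_late, p_falling = p_falling, p_cluster = p_cluster,
             p_missing_diary = p_missing_diary,
             misreporter_fraction = misreporter_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (kernel_peak_min <= 0 || kernel_shape <= 0 || cgm_interval <= 0)
    stop("kernel and sampling parameters must be positive")
  structure(list(seed = as.integer(seed), n_gdm = n_gdm,
                 n_control = n_control, days = days,
                 meals_per_day = meals_per_day, cgm_interval = cgm_interval,
                 kernel_peak_min = kernel_peak_min,
                 kernel_shape = kernel_shape, beta = beta,
                 intercept = intercept, noise_sd = noise_sd,
                 patient_sd = patient_sd, sensor_sd = sensor_sd,
                 sensor_rho = sensor_rho, p_late = p_late,
                 p_falling = p_falling, p_cluster = p_cluster,
                 p_missing_diary = p_missing_diary,
                 misreporter_fraction = misreporter_fraction,
                 basal_control = basal_control, basal_gdm = basal_gdm,
                 basal_sd = basal_sd),
            class = "ppgr_gen_config")
}

#' Postprandial response kernel
#'
#' Gamma-shaped incremental response `(t/tp)^a exp(a (1 - t/tp))`, supported
#' on (0, 240] minutes and normalized so its iAUC over the first 120 minutes
#' equals 1 mmol/L·h — meal amplitudes are therefore directly interpretable
#' as noiseless iAUC120 values.
#'
#' @param config A `ppgr_gen_config`.
#' @return A vectorized function of time-since-meal in minutes.
#' @export
meal_kernel <- function(config) {
  tp <- config$kernel_peak_min
  a <- config$kernel_shape
  raw <- function(s) ifelse(s > 0 & s <= 240, (s / tp)^a * exp(a * (1 - s / tp)), 0)
  grid <- seq(0, 120, by = 0.05)
  norm <- sum(raw(grid)) * 0.05 / 60  # fine-grid iAUC120 in mmol/L·h
  function(s) raw(s) / norm
}

# ---- internal samplers ------------------------------------------------------

# A compact food composition table spanning the GI strata: zero-carb animal
# foods, low/medium/high-GI plant foods, dairy, and two rare items whose GI
# the assignment hierarchy could not resolve (gi = NA).
gen_food_table <- function() {
  mk <- function(name, carb, prot, fat, fiber, starch_frac, gi, rule, weight) {
    n <- length(name)
    carb <- rep_len(carb, n); prot <- rep_len(prot, n)
    fat <- rep_len(fat, n); fiber <- rep_len(fiber, n)
    starch_frac <- rep_len(starch_frac, n)
    tibble::tibble(name = name, carb_per100 = carb, prot_per100 = prot,
                   fat_per100 = fat,
                   kcal_per100 = 4 * (carb + prot) + 9 * fat,
                   water_per100 = pmax(100 - carb - prot - fat - fiber, 0),
                   starch_per100 = carb * starch_frac, fiber_per100 = fiber,
                   gi = rep_len(gi, n), gi_rule = rep_len(rule, n),
                   sample_weight = rep_len(weight, n))
  }
  dplyr::bind_rows(
    # zero-carb block (assignment rule 2)
    mk(c("chicken breast", "beef steak", "pork chop", "salmon", "cod",
         "eggs", "butter", "sunflower oil", "hard cheese", "turkey",
         "herring", "mayonnaise"),
       c(0, 0, 0, 0, 0, 0.7, 0.8, 0, 2.0, 0, 0, 2.6),
       c(23, 26, 25, 20, 18, 13, 0.9, 0, 25, 22, 18, 1),
       c(2, 15, 14, 13, 0.7, 11, 81, 100, 30, 4, 14, 75),
       0, 0, 0, "zero_carb", 1),
    # high-GI staples (published GI)
    mk(c("white bread", "white rice", "mashed potato", "cornflakes",
         "buckwheat bread", "millet porridge", "watermelon", "honey",
         "boiled potato", "instant oatmeal"),
       c(49, 28, 15, 84, 45, 23, 7.5, 82, 17, 60),
       c(8, 2.7, 2, 7.5, 8, 3.5, 0.6, 0.3, 2, 11),
       c(3, 0.3, 4, 0.9, 2, 1.3, 0.2, 0, 0.1, 6),
       c(2.7, 0.4, 1.5, 3, 5, 1.3, 0.4, 0.2, 1.8, 8),
       c(0.9, 0.95, 0.9, 0.9, 0.9, 0.9, 0.05, 0, 0.9, 0.85),
       c(75, 73, 87, 81, 70, 71, 76, 61, 78, 79),
       "published", 1),
    # GI extremes among staples (published)
    mk(c("dates", "baguette", "rice porridge", "bean stew", "soy noodles",
         "whole-grain spaghetti", "quinoa"),
       c(69, 52, 26, 16, 21, 25, 21),
       c(2.5, 8, 2.5, 6, 14, 5.3, 4.4),
       c(0.4, 1.5, 3, 2.5, 2, 1.1, 1.9),
       c(7, 2.5, 0.5, 5, 3, 4, 2.8),
       c(0.05, 0.9, 0.9, 0.8, 0.85, 0.9, 0.85),
       c(100, 95, 88, 26, 18, 38, 35),
       "published", 1),
    # medium-GI foods (close match / subgroup mean)
    mk(c("rye bread", "boiled buckwheat", "pasta", "banana", "grapes",
         "beetroot", "muesli", "pearl barley", "sweet corn", "kefir drink"),
       c(42, 20, 25, 21, 16, 9, 60, 23, 19, 4.7),
       c(6.6, 3.6, 5.8, 1.1, 0.6, 1.6, 9, 3.1, 3.3, 3),
       c(1.2, 1.1, 1.1, 0.3, 0.2, 0.2, 6, 0.4, 1.4, 2),
       c(5.8, 2.7, 1.8, 2.6, 0.9, 2.8, 7, 3.8, 2.4, 0),
       c(0.85, 0.9, 0.9, 0.25, 0.02, 0.1, 0.75, 0.9, 0.6, 0),
       c(58, 51, 49, 51, 53, 64, 57, 46, 52, 41),
       c("close_match", "subgroup_mean"), 1),
    # low-GI foods
    mk(c("apple", "pear", "orange", "lentils", "chickpeas", "plain yogurt",
         "whole milk", "tomato", "cucumber", "carrot raw"),
       c(11.4, 15.2, 11.8, 20, 27, 6, 4.8, 3.9, 3.6, 9.6),
       c(0.3, 0.4, 0.9, 9, 8.9, 5, 3.2, 0.9, 0.7, 0.9),
       c(0.2, 0.1, 0.1, 0.4, 2.6, 3.2, 3.3, 0.2, 0.1, 0.2),
       c(2.4, 3.1, 2.4, 7.9, 7.6, 0, 0, 1.2, 0.5, 2.8),
       c(0.05, 0.05, 0.02, 0.85, 0.8, 0, 0, 0.05, 0.05, 0.1),
       c(36, 38, 43, 32, 28, 35, 39, 30, 15, 39),
       c("published", "close_match"), 1),
    # sweets / mixed dishes
    mk(c("milk chocolate", "biscuits", "apple pie", "fruit juice",
         "ice cream", "jam"),
       c(59, 67, 40, 10, 24, 69),
       c(7.7, 7.5, 3.5, 0.5, 3.5, 0.4),
       c(30, 12, 13, 0.1, 11, 0.1),
       c(3.4, 2.3, 1.7, 0.2, 0.7, 1),
       c(0.2, 0.75, 0.6, 0, 0.05, 0.02),
       c(45, 59, 44, 50, 51, 55),
       "subgroup_mean", 0.6),
    # rare dishes with unresolved GI (trigger the gi_undefined record filter)
    mk(c("jerusalem artichoke stew", "fern salad"),
       c(16, 7), c(2, 3), c(3, 4), c(3, 2), c(0.3, 0.1),
       NA_real_, NA_character_, 0.02))
}

gen_profiles <- function(config) {
  n <- config$n_gdm + config$n_control
  group <- c(rep("GDM", config$n_gdm), rep("control", config$n_control))
  gdm <- group == "GDM"
  rn <- function(mu_c, mu_g, sd, lo = -Inf, hi = Inf, digits = 1)
    round(pmin(pmax(rnorm(n, ifelse(gdm, mu_g, mu_c), sd), lo), hi), digits)
  profiles <- tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    group = group,
    age = rn(30, 32, 4.5, 18, 45, 0),
    weight = rn(68, 76, 10, 45, 130),
    bmi = rn(24.5, 27.5, 4, 16, 45),
    gestational_age = rn(28, 28, 3, 19, 36, 0),
    bp_systolic = rn(112, 118, 10, 85, 165, 0),
    bp_diastolic = rn(70, 74, 8, 50, 105, 0),
    ogtt_fasting = rn(4.4, 5.2, 0.45, 3.2, 7.5, 2),
    ogtt_1h = rn(6.6, 9.6, 1.6, 3.5, 14, 1),
    ogtt_2h = rn(6.0, 8.5, 1.5, 3.0, 13, 1),
    hba1c = rn(5.0, 5.3, 0.3, 4.0, 6.8, 2),
    fasting_insulin = rn(85, 110, 30, 20, 260, 0),
    cholesterol = rn(6.1, 6.3, 1.1, 3, 11, 1),
    hdl = rn(2.1, 2.0, 0.4, 0.8, 3.6, 1),
    ldl = rn(3.3, 3.4, 0.9, 1.2, 7, 1),
    triglycerides = rn(1.7, 2.1, 0.7, 0.4, 5.5, 1),
    leptin = rn(25, 31, 11, 3, 80),
    n_pregnancies = pmax(stats::rpois(n, 1.0) + 1L, 1L),
    n_abortions = stats::rpois(n, 0.4),
    n_deliveries = stats::rpois(n, 0.8),
    n_miscarriages = stats::rpois(n, 0.2),
    gdm_history = rbinom(n, 1, ifelse(gdm, 0.25, 0.05)),
    pcos = rbinom(n, 1, ifelse(gdm, 0.12, 0.06)),
    igt_history = rbinom(n, 1, ifelse(gdm, 0.15, 0.03)),
    family_diabetes = rbinom(n, 1, ifelse(gdm, 0.40, 0.20)),
    hypertension = rbinom(n, 1, 0.12),
    oc_pills = rbinom(n, 1, 0.3),
    smoking = rbinom(n, 1, 0.1))
  for (q in c("fruits", "sweets", "meat", "dairy", "bread", "vegetables",
              "soda", "activity"))
    for (w in c("before", "during"))
      profiles[[paste0(q, "_", w)]] <- sample(0:2, n, replace = TRUE,
                                              prob = c(0.25, 0.5, 0.25))
  basal <- rnorm(n, ifelse(gdm, config$basal_gdm, config$basal_control),
                 config$basal_sd)
  attr(profiles, "basal") <- pmin(pmax(basal, 3.2), 7.5)
  # a little missingness in the numeric block, to exercise imputation
  numeric_cols <- c("weight", "bmi", "fasting_insulin", "cholesterol", "hdl",
                    "ldl", "triglycerides", "leptin", "hba1c")
  for (col in numeric_cols)
    profiles[[col]][runif(n) < 0.02] <- NA_real_
  misrep <- runif(n) < config$misreporter_fraction
  attr(profiles, "misreporter") <- ifelse(
    misrep, rep_len(c("single_item", "rounded"), n), NA_character_)
  profiles
}

# Sample the items of one batch of meals (vectorized across the cohort).
# Meals are structured the way diary meals are: one carbohydrate staple whose
# portion is scaled to a satiety-driven carbohydrate target (so the amount of
# carbohydrate eaten is roughly independent of which staple was chosen, and
# the meal GI varies across the staples' wide GI range), plus 0-2 low-carb
# sides (protein, vegetables, dairy). Rare unresolved-GI dishes appear as
# occasional sides.
sample_meal_items <- function(n_meals, food, single_item = rep(FALSE, n_meals),
                              rounded = rep(FALSE, n_meals)) {
  staples <- which(food$carb_per100 >= 15 & !is.na(food$gi))
  sides <- which(food$carb_per100 < 15 | is.na(food$gi))
  side_w <- food$sample_weight[sides]

  staple_food <- sample(staples, n_meals, replace = TRUE)
  carb_target <- pmin(pmax(stats::rlnorm(n_meals, log(33), 0.58), 5), 120)
  staple_grams <- round(pmin(pmax(
    carb_target / food$carb_per100[staple_food] * 100, 20), 400))

  n_sides <- sample(0:2, n_meals, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  n_sides[single_item] <- 0L
  side_meal <- rep.int(seq_len(n_meals), n_sides)
  side_food <- sides[sample.int(length(sides), length(side_meal),
                                replace = TRUE, prob = side_w)]
  side_grams <- round(pmin(pmax(stats::rlnorm(length(side_meal),
                                              log(110), 0.40), 20), 300))

  items <- tibble::tibble(
    meal_idx = c(seq_len(n_meals), side_meal),
    food_idx = c(staple_food, side_food),
    grams = c(staple_grams, side_grams))
  items <- items[order(items$meal_idx), ]
  items$grams[rounded[items$meal_idx]] <-
    pmax(round(items$grams[rounded[items$meal_idx]] / 100) * 100, 100)
  items
}

# Vectorized composition of many meals at once (same arithmetic as
# meal_composition(), computed matrix-wise).
compose_items <- function(items, food, n_meals) {
  cols <- c(carbo = "carb_per100", prot = "prot_per100", fat = "fat_per100",
            kcal = "kcal_per100", water = "water_per100",
            starch = "starch_per100", fiber = "fiber_per100")
  w <- items$grams / 100
  mat <- as.matrix(food[items$food_idx, unname(cols)]) * w
  colnames(mat) <- names(cols)
  agg <- rowsum(mat, items$meal_idx, reorder = TRUE)
  out <- matrix(0, n_meals, ncol(mat), dimnames = list(NULL, names(cols)))
  out[as.integer(rownames(agg)), ] <- agg
  out <- tibble::as_tibble(out)
  gi_item <- food$gi[items$food_idx]
  carbo_i <- w * food$carb_per100[items$food_idx]
  undef <- rowsum((is.na(gi_item) & carbo_i > 0) * 1, items$meal_idx)[, 1] > 0
  gisum <- rowsum(ifelse(is.na(gi_item), 0, gi_item) * carbo_i,
                  items$meal_idx)[, 1]
  out$gi_undefined <- undef
  out$gi <- ifelse(undef, NA_real_,
                   ifelse(out$carbo > 0, gisum / out$carbo, 0))
  out$gl <- ifelse(undef, NA_real_, gisum / 100)
  out
}

#' Simulate one patient's CGM trace
#'
#' The trace is the patient's basal level plus one response kernel per meal
#' (amplitude in noiseless iAUC120 units) plus stationary AR(1) sensor noise,
#' sampled on a regular grid and clipped to the physiologic range
#' 2–25 mmol/L.
#'
#' @param basal Basal glucose (mmol/L).
#' @param meal_times_min True meal start times in minutes on the trace clock.
#' @param amplitudes Response amplitudes (mmol/L·h), one per meal.
#' @param config A `ppgr_gen_config`.
#' @param total_min Trace length in minutes (default: `days` full days).
#' @return Tibble `t_min`, `glucose`.
#' @export
gen_cgm_trace <- function(basal, meal_times_min, amplitudes, config,
                          total_min = config$days * 1440) {
  kern <- meal_kernel(config)
  t <- seq(0, total_min, by = config$cgm_interval)
  g <- rep(basal, length(t))
  for (i in seq_along(meal_times_min)) {
    t0 <- meal_times_min[i]
    sel <- which(t > t0 & t <= t0 + 240)
    g[sel] <- g[sel] + amplitudes[i] * kern(t[sel] - t0)
  }
  if (config$sensor_sd > 0) {
    innov <- rnorm(length(t), 0,
                   config$sensor_sd * sqrt(1 - config$sensor_rho^2))
    innov[1] <- rnorm(1, 0, config$sensor_sd)
    g <- g + as.numeric(stats::filter(innov, config$sensor_rho,
                                      method = "recursive"))
  }
  tibble::tibble(t_min = t, glucose = pmin(pmax(g, 2), 25))
}

#' Generate a complete synthetic cohort
#'
#' Draws patients (group-shifted covariates), daily meals with items from a
#' bundled food table, CGM traces built from the response kernel with a
#' planted linear iAUC120 signal, and the two reporting streams (electronic
#' diary, paper protocol) with injected errors: late and falling-edge start
#' times, interfering snack insertions, lost diary records, and misreporting
#' patients (all-single-item or 100 g-rounded diaries).
#'
#' @param config A `ppgr_gen_config` from [generator_config()].
#' @return List with `config`, `food_table`, `profiles`, `diary`, `protocol`,
#'   `cgm`, and `truth` (per-meal ground truth: true/reported times, injected
#'   error type, planted signal and realized amplitude). All components match
#'   the reader output formats, so a cohort written with [write_cohort()]
#'   round-trips through [read_cgm()], [read_diary()], [read_protocol()],
#'   [read_food_table()].
#' @export
gen_cohort <- function(config) {
  stopifnot(inherits(config, "ppgr_gen_config"))
  local_seed(config$seed, {
    origin <- as.POSIXct("2021-03-01 00:00:00", tz = "UTC")
    food <- gen_food_table()
    profiles <- gen_profiles(config)
    basal <- attr(profiles, "basal")
    misrep <- attr(profiles, "misreporter")
    n_pat <- nrow(profiles)
    u_pat <- rnorm(n_pat, 0, config$patient_sd)

    anchors <- seq(8, 19.5, length.out = config$meals_per_day) * 60
    meals <- list()
    for (p in seq_len(n_pat)) {
      for (d in seq_len(config$days)) {
        tt <- (d - 1) * 1440 + anchors +
          pmin(pmax(rnorm(config$meals_per_day, 0, 20), -40), 40)
        meals[[length(meals) + 1L]] <- tibble::tibble(
          patient = p, true_min = sort(tt), injected = "none")
      }
    }
    meals <- dplyr::bind_rows(meals)
    # interfering snack insertions
    clustered <- runif(nrow(meals)) < config$p_cluster
    if (any(clustered)) {
      snacks <- tibble::tibble(
        patient = meals$patient[clustered],
        true_min = meals$true_min[clustered] + runif(sum(clustered), 20, 40),
        injected = "cluster_snack")
      meals$injected[clustered] <- "cluster_base"
      meals <- dplyr::bind_rows(meals, snacks)
    }
    meals <- dplyr::arrange(meals, .data$patient, .data$true_min)
    n_meals <- nrow(meals)
    meals$meal_uid <- seq_len(n_meals)

    # timing errors (late / falling-edge reports), on ordinary meals only
    err <- rep("none", n_meals)
    eligible <- meals$injected == "none"
    draw <- runif(n_meals)
    err[eligible & draw < config$p_late] <- "late"
    err[eligible & draw >= config$p_late &
          draw < config$p_late + config$p_falling] <- "falling"
    shift <- numeric(n_meals)
    shift[err == "late"] <- runif(sum(err == "late"), 35, 50)
    shift[err == "falling"] <- config$kernel_peak_min +
      runif(sum(err == "falling"), 28, 35)
    meals$error <- ifelse(meals$injected == "cluster_snack", "cluster",
                          ifelse(meals$injected == "cluster_base",
                                 "cluster", err))
    meals$reported_min <- meals$true_min + shift

    # items and compositions
    is_snack <- meals$injected == "cluster_snack"
    single <- !is.na(misrep[meals$patient]) &
      misrep[meals$patient] == "single_item"
    rounded <- !is.na(misrep[meals$patient]) & misrep[meals$patient] == "rounded"
    items <- sample_meal_items(n_meals, food,
                               single_item = single | is_snack,
                               rounded = rounded)
    comp <- compose_items(items, food, n_meals)

    # planted signal and realized amplitude
    xbeta <- rep(0, n_meals)
    for (nm in names(config$beta)) {
      v <- if (nm %in% names(comp)) {
        val <- comp[[nm]]
        ifelse(is.na(val), 0, val)
      } else if (nm == "bg0") {
        basal[meals$patient]
      } else if (nm %in% names(profiles)) {
        col <- profiles[[nm]]
        col[is.na(col)] <- mean(col, na.rm = TRUE)
        col[meals$patient]
      } else stop("beta names unknown covariate: ", nm)
      xbeta <- xbeta + config$beta[[nm]] * v
    }
    signal <- config$intercept + xbeta + u_pat[meals$patient]
    amplitude <- pmax(signal + rnorm(n_meals, 0, config$noise_sd), 0.05)

    # diary: drop lost records; jitter the reported time slightly
    diary_min <- meals$reported_min + rnorm(n_meals, 0, 2)
    missing_diary <- runif(n_meals) < config$p_missing_diary
    slot <- pmin(pmax(ceiling(((meals$true_min %% 1440) / 60 - 5) / 4.5),
                      1), 4)
    meal_type <- ifelse(is_snack, "snack",
                        c("breakfast", "lunch", "dinner", "snack")[slot])

    item_rows <- tibble::tibble(
      patient_id = profiles$patient_id[meals$patient[items$meal_idx]],
      timestamp = origin + round(diary_min[items$meal_idx]) * 60,
      meal_type = meal_type[items$meal_idx],
      food_name = food$name[items$food_idx],
      grams = items$grams,
      meal_uid = items$meal_idx)
    item_rows <- item_rows[!missing_diary[item_rows$meal_uid], ]
    diary <- item_rows |>
      dplyr::group_by(.data$patient_id, time = .data$timestamp,
                      meal_type = .data$meal_type,
                      meal_uid = .data$meal_uid) |>
      dplyr::summarise(items = list(tibble::tibble(food_name, grams)),
                       .groups = "drop") |>
      dplyr::arrange(.data$patient_id, .data$time)
    diary$meal_id <- paste0(diary$patient_id, "_m",
                            stats::ave(seq_len(nrow(diary)), diary$patient_id,
                                       FUN = seq_along))

    protocol <- tibble::tibble(
      patient_id = profiles$patient_id[meals$patient],
      time = origin + round(meals$reported_min) * 60,
      point_bg = round(basal[meals$patient] + rnorm(n_meals, 0, 0.3), 1))
    protocol <- dplyr::arrange(protocol, .data$patient_id, .data$time)

    cgm <- dplyr::bind_rows(lapply(seq_len(n_pat), function(p) {
      sel <- meals$patient == p
      trace <- gen_cgm_trace(basal[p], meals$true_min[sel], amplitude[sel],
                             config)
      tibble::tibble(patient_id = profiles$patient_id[p],
                     time = origin + trace$t_min * 60,
                     glucose = round(trace$glucose, 2))
    }))

    truth <- tibble::tibble(
      meal_uid = meals$meal_uid,
      patient_id = profiles$patient_id[meals$patient],
      meal_id = diary$meal_id[match(meals$meal_uid, diary$meal_uid)],
      true_time = origin + meals$true_min * 60,
      reported_time = origin + round(meals$reported_min) * 60,
      error = meals$error,
      diary_missing = missing_diary,
      carbo = comp$carbo, gl = comp$gl, gi_undefined = comp$gi_undefined,
      basal = basal[meals$patient],
      patient_effect = u_pat[meals$patient],
      signal = signal, amplitude = amplitude,
      misreporter = misrep[meals$patient])
    diary$meal_uid <- NULL

    list(config = config, food_table = dplyr::select(food, -"sample_weight"),
         profiles = profiles, diary = diary, protocol = protocol, cgm = cgm,
         truth = truth)
  })
}

#' Write a synthetic cohort as the five CSV pipeline inputs
#'
#' Writes `cgm.csv`, `diary.csv`, `protocol.csv`, `food_table.csv`,
#' `patients.csv` and the ground-truth sidecar `ground_truth.csv` into `dir`,
#' in exactly the formats the package readers expect.
#'
#' @param cohort Result of [gen_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  iso <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  readr::write_csv(
    dplyr::transmute(cohort$cgm, .data$patient_id, timestamp = iso(.data$time),
                     glucose_mmol_l = .data$glucose),
    file.path(dir, "cgm.csv"))
  diary_long <- tidyr::unnest(cohort$diary, "items")
  readr::write_csv(
    dplyr::transmute(diary_long, .data$patient_id, timestamp = iso(.data$time),
                     .data$meal_type, .data$food_name, .data$grams),
    file.path(dir, "diary.csv"))
  readr::write_csv(
    dplyr::transmute(cohort$protocol, .data$patient_id,
                     timestamp = iso(.data$time),
                     point_bg_mmol_l = .data$point_bg),
    file.path(dir, "protocol.csv"))
  readr::write_csv(cohort$food_table, file.path(dir, "food_table.csv"))
  readr::write_csv(cohort$profiles, file.path(dir, "patients.csv"))
  truth <- cohort$truth
  truth$true_time <- iso(truth$true_time)
  truth$reported_time <- iso(truth$reported_time)
  readr::write_csv(truth, file.path(dir, "ground_truth.csv"))
  invisible(dir)
}

#' Expected attainable Pearson correlation under the generative model
#'
#' Returns `sqrt(signal variance / total outcome variance)` — the ceiling a
#' correctly specified model approaches on held-out patients. The signal
#' variance of the planted linear predictor is estimated by regenerating a
#' large sample of meals and patients from the configured distributions; the
#' noise variance adds the meal-level amplitude noise, the patient random
#' effect (unpredictable for new patients), and an analytic term for the
#' AR(1) sensor noise propagated through the trapezoidal iAUC120 computation
#' (baseline subtraction included; the positive-part clipping is ignored,
#' which is accurate while responses stay above baseline).
#'
#' @param config A `ppgr_gen_config`.
#' @param n_mc Monte Carlo sample size for the signal-variance estimate.
#' @param detail If `TRUE`, return the variance components as well.
#' @return The expected Pearson R (scalar), or a list when `detail = TRUE`.
#' @export
theoretical_r <- function(config, n_mc = 20000, detail = FALSE) {
  stopifnot(inherits(config, "ppgr_gen_config"))
  comps <- local_seed(config$seed + 104729L, {
    food <- gen_food_table()
    items <- sample_meal_items(n_mc, food)
    comp <- compose_items(items, food, n_mc)
    n_pat <- config$n_gdm + config$n_control
    n_mc_gdm <- round(n_mc * config$n_gdm / n_pat)
    mc_config <- generator_config(seed = 1, n_gdm = n_mc_gdm,
                                  n_control = n_mc - n_mc_gdm,
                                  basal_control = config$basal_control,
                                  basal_gdm = config$basal_gdm,
                                  basal_sd = config$basal_sd)
    profiles <- gen_profiles(mc_config)
    ord <- sample.int(n_mc)  # mix groups across the meal sample
    basal <- attr(profiles, "basal")[ord]
    xbeta <- rep(0, n_mc)
    for (nm in names(config$beta)) {
      v <- if (nm %in% names(comp)) ifelse(is.na(comp[[nm]]), 0, comp[[nm]])
      else if (nm == "bg0") basal
      else if (nm %in% names(profiles)) {
        col <- profiles[[nm]]
        col[is.na(col)] <- mean(col, na.rm = TRUE)
        col[ord]
      } else stop("beta names unknown covariate: ", nm)
      xbeta <- xbeta + config$beta[[nm]] * v
    }
    # keep only meals that survive the GI-undefined record filter
    var(xbeta[!comp$gi_undefined])
  })
  m <- floor(120 / config$cgm_interval) + 1L
  h <- config$cgm_interval / 60
  w <- c(h / 2, rep(h, m - 2L), h / 2)
  w[1] <- w[1] - 2  # baseline subtraction: iAUC ~ sum w_i eps_i
  rho_mat <- config$sensor_rho^abs(outer(seq_len(m), seq_len(m), "-"))
  var_sensor <- config$sensor_sd^2 * drop(t(w) %*% rho_mat %*% w)
  var_noise <- config$noise_sd^2 + config$patient_sd^2 + var_sensor
  r <- if (comps + var_noise == 0) 1 else sqrt(comps / (comps + var_noise))
  if (detail)
    list(r = r, var_signal = comps, var_meal_noise = config$noise_sd^2,
         var_patient = config$patient_sd^2, var_sensor = var_sensor)
  else r
}
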