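# Shared fixtures and independent oracles.

make_series <- function(t_min, glucose) {
  tibble::tibble(t_min = t_min, glucose = glucose)
}

# Brute-force dense-grid integrator: integrates the piecewise-linear trace
# (optionally clipped at a baseline) by midpoint sums on a very fine grid.
# Independent of bg_at()/trapezoid_auc(): uses stats::approx directly.
dense_auc <- function(series, t0, t1, baseline = NULL, n = 200001) {
  grid <- seq(t0, t1, length.out = n)
  v <- stats::approx(series$t_min, series$glucose, grid, rule = 2)$y
  if (!is.null(baseline)) v <- pmax(v - baseline, 0)
  mid <- (v[-1] + v[-n]) / 2
  sum(mid * diff(grid)) / 60
}

# A tiny validated food table for composition tests.
tiny_food_db <- function() {
  tibble::tibble(
    name = c("bread", "rice", "apple", "cheese", "mystery"),
    carb_per100 = c(50, 28, 11.4, 2, 20),
    prot_per100 = c(8, 2.7, 0.3, 25, 2),
    fat_per100 = c(3, 0.3, 0.2, 30, 1),
    kcal_per100 = c(259, 125.5, 48.6, 378, 97),
    water_per100 = c(36.3, 68.6, 85.7, 43, 74),
    starch_per100 = c(45, 26.6, 0.6, 0, 5),
    fiber_per100 = c(2.7, 0.4, 2.4, 0, 3),
    gi = c(75, 73, 36, 0, NA),
    gi_rule = c("published", "published", "published", "zero_carb", NA))
}

# Random meals over the tiny db (mystery excluded unless asked).
random_meal <- function(n_items = sample(1:3, 1), with_undefined = FALSE) {
  foods <- c("bread", "rice", "apple", "cheese")
  if (with_undefined) foods <- c(foods, "mystery")
  tibble::tibble(food_name = sample(foods, n_items, replace = TRUE),
                 grams = round(runif(n_items, 20, 300)))
}

# A small processed synthetic cohort shared across model tests (cached).
small_design <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cohort <- gen_cohort(generator_config(seed = 2024, n_gdm = 8,
                                            n_control = 8, days = 3))
      cache <<- process_cohort(cohort, pipeline_config(".", "."))$design
    }
    cache
  }
})
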