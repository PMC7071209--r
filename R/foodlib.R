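#' Glycemic index assignment rules
#'
#' Ordered names of the five-rule hierarchy used to assign a dietary glycemic
#' index (GI) to a food item: a published GI; GI 0 for foods with less than
#' 5 g carbohydrate per 100 g; a published GI of a closely matching food; the
#' mean GI of a food subgroup; and an expert default (0, 50, or a nominated
#' value). The first applicable rule wins.
#'
#' @format Character vector of rule identifiers, in precedence order.
#' @export
gi_rules <- c("published", "zero_carb", "close_match", "subgroup_mean",
              "expert_default")

#' Assign a glycemic index to a food item
#'
#' Applies the five-rule assignment hierarchy in fixed order: (1) a published
#' GI; (2) GI = 0 when the item's carbohydrate content is below 5 g/100 g;
#' (3) the published GI of a close match; (4) the mean GI of a food subgroup;
#' (5) an expert default. The first rule with an available candidate fires and
#' is recorded in `gi_rule`. If no rule applies the GI stays undefined (`NA`)
#' and downstream record filters remove meals containing the item.
#'
#' @param item A one-row tibble or named list with at least `name` and
#'   `carb_per100` (grams of carbohydrate per 100 g).
#' @param published_gi,close_match_gi,subgroup_mean_gi,expert_default Optional
#'   candidate GI values for the corresponding rules (`NULL` or `NA` = not
#'   available). Candidates must be in `[0, 150]`.
#' @return The item as a one-row tibble with `gi` and `gi_rule` set
#'   (`gi_rule = NA` when no rule applied).
#' @examples
#' item <- tibble::tibble(name = "chicken breast", carb_per100 = 0.4)
#' assign_gi(item) # zero-carb rule: gi = 0
#' @export
assign_gi <- function(item, published_gi = NULL, close_match_gi = NULL,
                      subgroup_mean_gi = NULL, expert_default = NULL) {
  item <- tibble::as_tibble(as.list(item)[!vapply(item, is.null, logical(1))])
  stopifnot(nrow(item) == 1L, "carb_per100" %in% names(item))
  if (is.na(item$carb_per100) || item$carb_per100 < 0 || item$carb_per100 > 100)
    stop("invalid carbohydrate content for '", item$name, "'")
  check_gi <- function(g, what) {
    if (is.null(g) || is.na(g)) return(NULL)
    if (!is.numeric(g) || g < 0 || g > 150)
      stop(what, " GI candidate out of range [0, 150]: ", g)
    as.numeric(g)
  }
  published <- check_gi(published_gi, "published")
  close     <- check_gi(close_match_gi, "close-match")
  subgroup  <- check_gi(subgroup_mean_gi, "subgroup-mean")
  default   <- check_gi(expert_default, "expert-default")

  gi <- NA_real_
  rule <- NA_character_
  if (!is.null(published)) {
    gi <- published; rule <- "published"
  } else if (item$carb_per100 < 5) {
    gi <- 0; rule <- "zero_carb"
  } else if (!is.null(close)) {
    gi <- close; rule <- "close_match"
  } else if (!is.null(subgroup)) {
    gi <- subgroup; rule <- "subgroup_mean"
  } else if (!is.null(default)) {
    gi <- default; rule <- "expert_default"
  }
  item$gi <- gi
  item$gi_rule <- rule
  item
}

#' Glycemic index of a complex dish
#'
#' Carbohydrate-weighted mean of ingredient GIs:
#' \deqn{gi = \sum_i gi_i \, carbo_i / \sum_i carbo_i}
#' where \eqn{carbo_i} is the carbohydrate contributed by ingredient *i* per
#' 100 g of dish (`mass_fraction * carb_per100`). A dish with zero total
#' carbohydrate has GI 0 by convention, consistent with the zero-carb
#' assignment rule for simple foods.
#'
#' @param ingredients Tibble with columns `gi`, `carb_per100` and
#'   `mass_fraction` (fractions summing to 1), one row per ingredient; a
#'   `name` column improves error messages.
#' @return Dish GI (dimensionless scalar).
#' @export
dish_gi <- function(ingredients) {
  stopifnot(nrow(ingredients) >= 1L,
            all(c("gi", "carb_per100", "mass_fraction") %in% names(ingredients)))
  if (abs(sum(ingredients$mass_fraction) - 1) > 1e-9)
    stop("ingredient mass fractions must sum to 1")
  carbo <- ingredients$mass_fraction * ingredients$carb_per100
  if (any(is.na(ingredients$gi) & carbo > 0)) {
    bad <- ingredients$name[is.na(ingredients$gi) & carbo > 0]
    stop("undefined GI for ingredient(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (sum(carbo) <= 0) return(0)
  sum(ingredients$gi * carbo, na.rm = TRUE) / sum(carbo)
}

#' Nutrient composition, GI and GL of a meal
#'
#' Resolves each consumed item against a food table and accumulates nutrient
#' totals for the consumed portion. The meal GI is the carbohydrate-weighted
#' mean of item GIs; the glycemic load is
#' \deqn{gl = \frac{1}{100}\sum_i gi_i \, carbo_i}
#' with \eqn{carbo_i} the grams of carbohydrate contributed by item *i*, so
#' that `gl == gi * carbo / 100` holds exactly. A meal containing any item
#' with undefined GI is returned with `gi_undefined = TRUE` (and `NA` GI/GL);
#' such meals stay in the matching stage and are removed later by the record
#' filter.
#'
#' @param items Tibble with columns `food_name` and `grams` (> 0).
#' @param db Food table as returned by [read_food_table()].
#' @return One-row tibble: `carbo`, `prot`, `fat`, `kcal`, `water`, `starch`,
#'   `fiber` (grams or kcal in the consumed portion), `gi`, `gl`, and the
#'   logical flag `gi_undefined`.
#' @export
meal_composition <- function(items, db) {
  stopifnot(nrow(items) >= 1L, all(c("food_name", "grams") %in% names(items)))
  if (any(items$grams <= 0)) stop("item grams must be positive")
  idx <- match(items$food_name, db$name)
  if (anyNA(idx))
    stop("unknown food item(s): ",
         paste(unique(items$food_name[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  foods <- db[idx, ]
  w <- items$grams / 100
  totals <- lapply(c(carbo = "carb_per100", prot = "prot_per100",
                     fat = "fat_per100", kcal = "kcal_per100",
                     water = "water_per100", starch = "starch_per100",
                     fiber = "fiber_per100"),
                   function(col) sum(w * foods[[col]]))
  out <- tibble::as_tibble(totals)
  carbo_i <- w * foods$carb_per100
  gi_undefined <- any(is.na(foods$gi) & carbo_i > 0)
  if (gi_undefined) {
    out$gi <- NA_real_
    out$gl <- NA_real_
  } else if (out$carbo <= 0) {
    out$gi <- 0
    out$gl <- 0
  } else {
    out$gi <- sum(foods$gi * carbo_i, na.rm = TRUE) / sum(carbo_i)
    out$gl <- sum(foods$gi * carbo_i, na.rm = TRUE) / 100
  }
  out$gi_undefined <- gi_undefined
  out
}

#' Read and validate a food composition table
#'
#' Expected columns: `name`, `carb_per100`, `prot_per100`, `fat_per100`,
#' `kcal_per100`, `water_per100`, `starch_per100`, `fiber_per100`, `gi`
#' (blank = undefined) and `gi_rule`. Per-100 g values must be non-negative,
#' carbohydrate at most 100 g/100 g, GI within `[0, 150]`, and any item
#' assigned by the zero-carb rule must carry GI 0.
#'
#' @param path CSV file path.
#' @return Validated tibble, one row per food item.
#' @export
read_food_table <- function(path) {
  db <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          name = readr::col_character(),
                          gi_rule = readr::col_character(),
                          .default = readr::col_double()))
  validate_food_table(db)
}

#' @rdname read_food_table
#' @param db A food table already in memory.
#' @export
validate_food_table <- function(db) {
  need <- c("name", "carb_per100", "prot_per100", "fat_per100", "kcal_per100",
            "water_per100", "starch_per100", "fiber_per100", "gi", "gi_rule")
  missing_cols <- setdiff(need, names(db))
  if (length(missing_cols))
    stop("food table missing column(s): ", paste(missing_cols, collapse = ", "))
  per100 <- c("carb_per100", "prot_per100", "fat_per100", "kcal_per100",
              "water_per100", "starch_per100", "fiber_per100")
  for (col in per100)
    if (any(db[[col]] < 0, na.rm = TRUE)) stop("negative values in ", col)
  if (any(db$carb_per100 > 100, na.rm = TRUE))
    stop("carb_per100 exceeds 100 g/100 g")
  if (any(db$gi < 0 | db$gi > 150, na.rm = TRUE))
    stop("gi outside [0, 150]")
  zc <- !is.na(db$gi_rule) & db$gi_rule == "zero_carb"
  if (any(zc & (is.na(db$gi) | db$gi != 0)))
    stop("zero_carb items must have gi = 0")
  bad_rule <- !is.na(db$gi_rule) & !db$gi_rule %in% gi_rules
  if (any(bad_rule))
    stop("unknown gi_rule: ", paste(unique(db$gi_rule[bad_rule]), collapse = ", "))
  tibble::as_tibble(db)
}
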