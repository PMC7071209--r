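#' Read a feature specification
#'
#' The feature spec is a YAML file declaring the patient-level variables that
#' enter the design matrix: for each variable its `name`, `block` (a free
#' grouping label such as `patient_numeric`, `history`, `questionnaire`),
#' `type` (`numeric`, `binary`, `ordinal`, `categorical`) and, for ordinal and
#' categorical variables, the admissible `levels`. Ordinal questionnaire items
#' (levels 0/1/2) are dummy-encoded like unordered categoricals; binary
#' variables pass through as 0/1.
#'
#' @param path Path to the YAML spec. Defaults to the fixture spec shipped
#'   with the package.
#' @return A tibble with columns `name`, `block`, `type` and a list-column
#'   `levels`.
#' @export
read_feature_spec <- function(path = system.file("extdata", "feature_spec.yaml",
                                                 package = "ppgr")) {
  raw <- yaml::read_yaml(path)
  vars <- raw$variables
  spec <- tibble::tibble(
    name = vapply(vars, `[[`, character(1), "name"),
    block = vapply(vars, `[[`, character(1), "block"),
    type = vapply(vars, `[[`, character(1), "type"),
    levels = lapply(vars, function(v) v$levels))
  bad <- !spec$type %in% c("numeric", "binary", "ordinal", "categorical")
  if (any(bad)) stop("unknown feature type: ",
                     paste(unique(spec$type[bad]), collapse = ", "))
  need_lv <- spec$type %in% c("ordinal", "categorical")
  if (any(need_lv & vapply(spec$levels, is.null, logical(1))))
    stop("ordinal/categorical variables need declared levels")
  spec
}

#' Group-mean imputation of patient features
#'
#' Replaces each missing value by the mean of its column within the patient's
#' group (GDM or control). Ordinal and binary columns are imputed with the
#' group mean rounded to the nearest admissible level so the result remains
#' encodable. If a column is entirely missing within one group, the overall
#' column mean is used with a warning.
#'
#' @param profiles Patient tibble with a non-missing `group` column.
#' @param spec Feature spec from [read_feature_spec()].
#' @return `profiles` with all spec-listed columns complete.
#' @export
impute_group_mean <- function(profiles, spec) {
  if (anyNA(profiles$group)) stop("group label must be present for all patients")
  for (i in seq_len(nrow(spec))) {
    nm <- spec$name[i]
    if (!nm %in% names(profiles) || spec$type[i] == "categorical") next
    x <- profiles[[nm]]
    if (!anyNA(x)) next
    overall <- mean(x, na.rm = TRUE)
    for (g in unique(profiles$group)) {
      sel <- profiles$group == g & is.na(x)
      if (!any(sel)) next
      gx <- x[profiles$group == g]
      fill <- if (all(is.na(gx))) {
        warning("column '", nm, "' all-missing in group ", g,
                "; falling back to overall mean")
        overall
      } else mean(gx, na.rm = TRUE)
      if (spec$type[i] %in% c("ordinal", "binary")) {
        lv <- if (spec$type[i] == "binary") c(0, 1) else
          as.numeric(unlist(spec$levels[[i]]))
        fill <- lv[which.min(abs(lv - fill))]
      }
      x[sel] <- fill
    }
    profiles[[nm]] <- x
  }
  profiles
}

#' One-hot encoding of categorical and ordinal variables
#'
#' Replaces every ordinal or categorical variable in the spec by one 0/1
#' column per declared level, named `variable_value` (e.g. `fruits_1`).
#' Numeric and binary variables pass through untouched. Observed values
#' outside the declared level set are an error naming the variable and value.
#' Using the declared (not merely observed) level set keeps the expanded
#' column roster identical across data subsets, which matters when encoding
#' train and test splits consistently.
#'
#' @param profiles Patient tibble (typically after [impute_group_mean()]).
#' @param spec Feature spec from [read_feature_spec()].
#' @return The expanded tibble; attribute `"encoded_columns"` lists the
#'   feature columns (in deterministic order) that the spec contributes.
#' @export
one_hot <- function(profiles, spec) {
  out <- profiles
  feature_cols <- character(0)
  for (i in seq_len(nrow(spec))) {
    nm <- spec$name[i]
    if (!nm %in% names(out)) stop("spec variable '", nm, "' absent from data")
    if (spec$type[i] %in% c("numeric", "binary")) {
      feature_cols <- c(feature_cols, nm)
      next
    }
    lv <- unlist(spec$levels[[i]])
    x <- out[[nm]]
    bad <- !is.na(x) & !as.character(x) %in% as.character(lv)
    if (any(bad))
      stop("value '", x[bad][1], "' of variable '", nm,
           "' outside declared levels")
    for (l in lv) {
      col <- paste0(nm, "_", l)
      out[[col]] <- as.numeric(!is.na(x) & as.character(x) == as.character(l))
      feature_cols <- c(feature_cols, col)
    }
    out[[nm]] <- NULL
  }
  attr(out, "encoded_columns") <- feature_cols
  out
}

#' Assemble the per-meal design matrix
#'
#' Joins kept meals, their nutrient compositions, extracted PPGR outcomes and
#' encoded patient profiles into one modeling table: one row per kept meal,
#' meal-composition features (including `gi` and `gl` in the `with_gigl` arm),
#' the pre-meal glucose `bg0` as a context feature, all encoded patient
#' features, and the seven predicted PPGR outcomes.
#'
#' @param meals Tibble of kept meals with `patient_id` and `meal_id`.
#' @param compositions Tibble with `meal_id` and the nutrient columns of
#'   [meal_composition()].
#' @param ppgr_records Tibble with `meal_id` and the outcome columns of
#'   [extract_ppgr()].
#' @param profiles Encoded patient tibble from [one_hot()] (must carry the
#'   `"encoded_columns"` attribute or be accompanied by `spec`).
#' @param spec Feature spec (used to recover the encoded column roster when
#'   the attribute is absent).
#' @param arm `"with_gigl"` (default) or `"without_gigl"`; the latter drops
#'   the `gi` and `gl` columns and nothing else.
#' @return A `ppgr_design` object: list with `data` (tibble), `features`,
#'   `meal_features`, `outcomes` (character vectors) and `arm`.
#' @export
assemble_design <- function(meals, compositions, ppgr_records, profiles,
                            spec = NULL, arm = c("with_gigl", "without_gigl")) {
  arm <- match.arg(arm)
  enc <- attr(profiles, "encoded_columns")
  if (is.null(enc)) {
    if (is.null(spec)) stop("profiles lack encoded-column roster; pass spec")
    enc <- attr(one_hot(profiles[0, , drop = FALSE], spec), "encoded_columns")
  }
  orphan <- setdiff(unique(meals$patient_id), profiles$patient_id)
  if (length(orphan))
    stop("meal(s) without patient profile: ", paste(orphan, collapse = ", "))
  meal_feats <- c("gi", "gl", "carbo", "prot", "fat", "kcal", "water",
                  "starch", "fiber")
  outcomes <- c("bg60", "bgmax", "bgrise", "auc60", "auc120", "iauc60",
                "iauc120")
  data <- meals |>
    dplyr::select("patient_id", "meal_id") |>
    dplyr::inner_join(dplyr::select(compositions, "meal_id",
                                    dplyr::all_of(meal_feats)),
                      by = "meal_id") |>
    dplyr::inner_join(dplyr::select(ppgr_records, "meal_id", "bg0",
                                    dplyr::all_of(outcomes)),
                      by = "meal_id") |>
    dplyr::inner_join(dplyr::select(profiles, "patient_id",
                                    dplyr::all_of(enc)),
                      by = "patient_id") |>
    dplyr::arrange(.data$patient_id, .data$meal_id)
  features <- c(meal_feats, "bg0", enc)
  if (arm == "without_gigl") {
    features <- setdiff(features, c("gi", "gl"))
    meal_feats <- setdiff(meal_feats, c("gi", "gl"))
    data$gi <- NULL
    data$gl <- NULL
  }
  if (anyNA(data[features]))
    stop("design matrix contains missing values after imputation/encoding")
  new_design(data, features, meal_feats, outcomes, arm)
}

new_design <- function(data, features, meal_features, outcomes, arm) {
  stopifnot(!anyDuplicated(c(features, outcomes)))
  structure(list(data = tibble::as_tibble(data), features = features,
                 meal_features = meal_features, outcomes = outcomes,
                 arm = arm),
            class = "ppgr_design")
}

#' @export
print.ppgr_design <- function(x, ...) {
  cat("<ppgr_design> ", nrow(x$data), " meals, ",
      length(unique(x$data$patient_id)), " patients, ",
      length(x$features), " features, arm: ", x$arm, "\n", sep = "")
  invisible(x)
}

#' Restrict a design matrix to one modeling arm
#'
#' Dropping the GI/GL arm removes the `gi` and `gl` columns and any
#' polynomial children built from them (e.g. `gi^2`, `carbo x gl`).
#'
#' @param design A `ppgr_design`.
#' @param arm Target arm.
#' @return The restricted `ppgr_design`.
#' @export
arm_restrict <- function(design, arm = c("with_gigl", "without_gigl")) {
  arm <- match.arg(arm)
  if (arm == "with_gigl") {
    design$arm <- arm
    return(design)
  }
  drop <- vapply(design$features, function(f) {
    tokens <- sub("\\^2$", "", strsplit(f, " x ", fixed = TRUE)[[1]])
    any(tokens %in% c("gi", "gl"))
  }, logical(1))
  dropped <- design$features[drop]
  design$features <- setdiff(design$features, dropped)
  design$meal_features <- setdiff(design$meal_features, dropped)
  design$data <- design$data[setdiff(names(design$data), dropped)]
  design$arm <- arm
  design
}
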