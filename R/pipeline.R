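#' Vectorized meal compositions
#'
#' Computes [meal_composition()] for every meal of a tibble at once
#' (matrix-wise, identical arithmetic), which is what the pipeline uses on
#' cohort-sized inputs.
#'
#' @param meals Tibble with `meal_id` and an `items` list-column.
#' @param db Food table.
#' @return Tibble: `meal_id`, nutrient totals, `gi`, `gl`, `gi_undefined`.
#' @export
meal_compositions <- function(meals, db) {
  n <- nrow(meals)
  counts <- vapply(meals$items, nrow, integer(1))
  items <- tibble::tibble(
    meal_idx = rep.int(seq_len(n), counts),
    food_name = unlist(lapply(meals$items, `[[`, "food_name")),
    grams = unlist(lapply(meals$items, `[[`, "grams")))
  idx <- match(items$food_name, db$name)
  if (anyNA(idx))
    stop("unknown food item(s): ",
         paste(unique(items$food_name[is.na(idx)]), collapse = ", "))
  items$food_idx <- idx
  dplyr::bind_cols(tibble::tibble(meal_id = meals$meal_id),
                   compose_items(items, db, n))
}

#' Extract PPGR outcomes for a set of matched meals
#'
#' Runs [extract_ppgr()] for every meal against its patient's CGM trace
#' (non-strict: meals whose required trace window is unavailable come back
#' with `ok = FALSE` and are dropped downstream with reason
#' `cgm_unavailable`).
#'
#' @param meals Tibble with `patient_id`, `meal_id` and `meal_start`
#'   (POSIXct).
#' @param cgm CGM tibble from [read_cgm()].
#' @return Tibble: `meal_id` plus the [extract_ppgr()] columns.
#' @export
extract_ppgr_meals <- function(meals, cgm) {
  cols <- c("bg0", "bg60", "bgmax", "bgrise", "auc60", "auc120", "iauc60",
            "iauc120")
  out <- matrix(NA_real_, nrow(meals), length(cols),
                dimnames = list(NULL, cols))
  for (pid in unique(meals$patient_id)) {
    trace <- cgm[cgm$patient_id == pid, ]
    sel <- which(meals$patient_id == pid)
    if (nrow(trace) == 0L) next
    origin <- trace$time[1]
    tt <- as.numeric(difftime(trace$time, origin, units = "mins"))
    gg <- trace$glucose
    t <- as.numeric(difftime(meals$meal_start[sel], origin, units = "mins"))
    gapless <- all(diff(tt) <= 20)
    if (gapless) {
      out[sel, ] <- fast_extract(tt, gg, t)
    } else {
      series <- tibble::tibble(t_min = tt, glucose = gg)
      for (k in seq_along(sel)) {
        rec <- extract_ppgr(series, t[k], strict = FALSE)
        out[sel[k], ] <- unlist(rec[cols])
      }
    }
  }
  res <- tibble::as_tibble(out)
  res$ok <- stats::complete.cases(out)
  dplyr::bind_cols(tibble::tibble(meal_id = meals$meal_id), res)
}

# Fast PPGR extraction on a gapless trace; same arithmetic as extract_ppgr()
# (linear interpolation, exact baseline-crossing insertion) without the
# per-meal container overhead.
fast_extract <- function(tt, gg, t) {
  n <- length(t)
  out <- matrix(NA_real_, n, 8)
  lo <- tt[1] - 2.5
  hi <- tt[length(tt)] + 2.5
  itp <- function(x) {
    y <- approx(tt, gg, pmin(pmax(x, tt[1]), tt[length(tt)]))$y
    y[x < lo | x > hi] <- NA_real_
    y
  }
  bg0 <- itp(t)
  bg60 <- itp(t + 60)
  bg180 <- itp(t + 180)
  for (k in seq_len(n)) {
    if (is.na(bg0[k]) || is.na(bg180[k])) next
    i0 <- findInterval(t[k], tt)
    i180 <- findInterval(t[k] + 180, tt)
    idx <- seq.int(i0 + 1L, i180)
    idx <- idx[tt[idx] > t[k] & tt[idx] <= t[k] + 180]
    win_t <- c(t[k], tt[idx], t[k] + 180)
    win_g <- c(bg0[k], gg[idx], bg180[k])
    bgmax <- max(win_g)
    in120 <- win_t <= t[k] + 120
    k120 <- c(win_t[in120], t[k] + 120)
    v120 <- c(win_g[in120], itp(t[k] + 120))
    trap <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2) / 60
    in60 <- k120 <= t[k] + 60
    k60 <- c(k120[in60], t[k] + 60)
    v60 <- c(v120[in60], bg60[k])
    iauc <- function(x, y, b) {
      d <- y - b
      s <- d[-length(d)] * d[-1] < 0
      if (any(s)) {
        i <- which(s)
        xc <- x[i] + (x[i + 1] - x[i]) * d[i] / (d[i] - d[i + 1])
        ord <- order(c(x, xc))
        allx <- c(x, xc)[ord]
        alld <- c(d, rep(0, length(xc)))[ord]
      } else {
        allx <- x
        alld <- d
      }
      p <- pmax(alld, 0)
      sum(diff(allx) * (head(p, -1) + tail(p, -1)) / 2) / 60
    }
    out[k, ] <- c(bg0[k], bg60[k], bgmax, bgmax - bg0[k],
                  trap(k60, v60), trap(k120, v120),
                  iauc(k60, v60, bg0[k]), iauc(k120, v120, bg0[k]))
  }
  out
}

#' Pipeline configuration
#'
#' Bundles input/output locations, the modeling plan and every tunable
#' threshold of the pipeline. Thresholds default to the study values: 60 min
#' matching cap, 1.0 mmol/L late-report rise, 0.5 mmol/L falling-edge margin,
#' 60 min interference window, 0.1 Spearman prefilter, 0.3 mmol/L/h
#' small-PPGR rate on meals above 40 g carbohydrate.
#'
#' @param input_dir Directory holding (or receiving, for `simulate`) the five
#'   CSV inputs.
#' @param out_dir Directory for stage artifacts.
#' @param generator Optional `ppgr_gen_config` enabling the `simulate` stage.
#' @param feature_spec Path to the feature-spec YAML (default: bundled spec).
#' @param outcomes,arms,methods Modeling plan for the `fit` stage.
#' @param polynomial Add degree-2 polynomial meal features?
#' @param split_fraction,k,seed Split and CV settings.
#' @param max_gap_min,late_threshold,edge_threshold,window_min,carb_threshold,rate_threshold,prefilter_threshold,alpha_enter,max_rounded
#'   Stage thresholds (see the stage functions).
#' @return A `ppgr_pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, out_dir, generator = NULL,
                            feature_spec = NULL,
                            outcomes = "iauc120",
                            arms = c("with_gigl", "without_gigl"),
                            methods = c("stepwise", "omp"),
                            polynomial = FALSE, split_fraction = 0.7, k = 10,
                            seed = 1, max_gap_min = 60, late_threshold = 1.0,
                            edge_threshold = 0.5, window_min = 60,
                            carb_threshold = 40, rate_threshold = 0.3,
                            prefilter_threshold = 0.1, alpha_enter = 0.05,
                            max_rounded = 5) {
  cfg <- list(input_dir = input_dir, out_dir = out_dir, generator = generator,
              feature_spec = feature_spec, outcomes = outcomes, arms = arms,
              methods = methods, polynomial = polynomial,
              split_fraction = split_fraction, k = k, seed = seed,
              max_gap_min = max_gap_min, late_threshold = late_threshold,
              edge_threshold = edge_threshold, window_min = window_min,
              carb_threshold = carb_threshold, rate_threshold = rate_threshold,
              prefilter_threshold = prefilter_threshold,
              alpha_enter = alpha_enter, max_rounded = max_rounded)
  cfg$hash <- rlang::hash(cfg[!names(cfg) %in%
                                c("input_dir", "out_dir", "hash")])
  structure(cfg, class = "ppgr_pipeline_config")
}

read_cohort_dir <- function(dir) {
  need <- c("cgm.csv", "diary.csv", "protocol.csv", "food_table.csv",
            "patients.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("missing input file(s) ", paste(missing, collapse = ", "),
         "; run the 'simulate' stage first or point input_dir at real data")
  profiles <- readr::read_csv(file.path(dir, "patients.csv"),
                              show_col_types = FALSE)
  list(cgm = read_cgm(file.path(dir, "cgm.csv")),
       diary = read_diary(file.path(dir, "diary.csv")),
       protocol = read_protocol(file.path(dir, "protocol.csv")),
       food_table = read_food_table(file.path(dir, "food_table.csv")),
       profiles = profiles)
}

#' Run the matching, filtering and assembly chain in memory
#'
#' Applies, in order: protocol-to-diary matching, the four timing exclusion
#' rules, patient-level misreporting removal, PPGR outcome extraction, meal
#' composition, the record-level filters (undefined GI; small response to a
#' high-carbohydrate meal), patient-feature imputation and encoding, and
#' design-matrix assembly (with-GI/GL arm).
#'
#' @param cohort List with `cgm`, `diary`, `protocol`, `food_table`,
#'   `profiles` — e.g. from [gen_cohort()] or [read_cohort_dir] artifacts.
#' @param config A `ppgr_pipeline_config` (thresholds; modeling fields
#'   unused here).
#' @param spec Parsed feature spec (default: bundled).
#' @return List: `matched` (with exclusion labels), `misreporting`, `records`
#'   (matched + composition + outcomes + filter reasons), `design`
#'   (`ppgr_design`), and `counts` (named tallies that reconcile:
#'   matched = kept + excluded, final = rows of the design).
#' @export
process_cohort <- function(cohort, config = pipeline_config(".", "."),
                           spec = read_feature_spec(
                             config$feature_spec %||%
                               system.file("extdata", "feature_spec.yaml",
                                           package = "ppgr"))) {
  matched <- match_protocol_to_diary(cohort$protocol, cohort$diary,
                                     max_gap_min = config$max_gap_min)
  matched <- apply_exclusion_rules(matched, cohort$cgm,
                                   late_threshold = config$late_threshold,
                                   edge_threshold = config$edge_threshold,
                                   window_min = config$window_min)
  kept <- matched[is.na(matched$exclusion), ]
  mis <- detect_misreporting(cohort$diary, max_rounded = config$max_rounded)
  flagged <- mis$patient_id[mis$flagged]
  n_misrep <- sum(kept$patient_id %in% flagged)
  kept <- kept[!kept$patient_id %in% flagged, ]
  outcomes <- extract_ppgr_meals(kept, cohort$cgm)
  comp <- meal_compositions(kept, cohort$food_table)
  records <- kept |>
    dplyr::select("patient_id", "meal_id", "meal_start") |>
    dplyr::inner_join(comp, by = "meal_id") |>
    dplyr::inner_join(outcomes, by = "meal_id")
  n_not_ok <- sum(!records$ok)
  records <- filter_records(records[records$ok, ],
                            carb_threshold = config$carb_threshold,
                            rate_threshold = config$rate_threshold)
  filter_counts <- attr(records, "filter_counts")
  final <- records[is.na(records$filter_reason), ]
  profiles <- one_hot(impute_group_mean(cohort$profiles, spec), spec)
  design <- assemble_design(final, comp, outcomes, profiles, spec = spec,
                            arm = "with_gigl")
  counts <- c(protocol_entries = nrow(cohort$protocol),
              unmatched = attr(matched, "unmatched"),
              matched = nrow(matched),
              attr(matched, "exclusion_counts"),
              kept_after_exclusion = nrow(matched) -
                sum(!is.na(matched$exclusion)),
              misreporter_patients = length(flagged),
              misreporter_records = n_misrep,
              cgm_incomplete_records = n_not_ok,
              filter_counts,
              final_records = nrow(final))
  list(matched = matched, misreporting = mis, records = records,
       design = design, counts = counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

need_artifact <- function(path, stage) {
  if (!file.exists(path))
    stop("missing artifact '", basename(path), "'; run stage '", stage,
         "' first")
  path
}

iso_utc <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

write_design <- function(design, out_dir) {
  readr::write_csv(design$data, file.path(out_dir, "design.csv"))
  yaml::write_yaml(list(features = design$features,
                        meal_features = design$meal_features,
                        outcomes = design$outcomes, arm = design$arm),
                   file.path(out_dir, "design_columns.yaml"))
}

read_design <- function(out_dir) {
  meta <- yaml::read_yaml(need_artifact(
    file.path(out_dir, "design_columns.yaml"), "features"))
  data <- readr::read_csv(need_artifact(file.path(out_dir, "design.csv"),
                                        "features"), show_col_types = FALSE)
  new_design(data, unlist(meta$features), unlist(meta$meal_features),
             unlist(meta$outcomes), meta$arm)
}

#' Run pipeline stages
#'
#' Orchestrates the analysis as file-based stages, each reading its
#' predecessors' CSV artifacts from `config$out_dir` and writing its own:
#' `simulate` (synthetic inputs into `input_dir`), `ingest` (validation),
#' `match` (matching + exclusion report), `ppgr` (outcome extraction),
#' `features` (filters + design matrix), `fit` (stepwise and regularized
#' models + comparison table), `report` (evaluation tables, a
#' predicted-vs-observed scatter table for iAUC120, and a run log with
#' stage counts, seeds and the configuration hash). `all` runs everything
#' in order.
#'
#' @param config A `ppgr_pipeline_config`.
#' @param stage One of `simulate`, `ingest`, `match`, `ppgr`, `features`,
#'   `fit`, `report`, `all`.
#' @return Invisibly, the stage's main artifact (varies by stage).
#' @export
run_pipeline <- function(config, stage = "all") {
  stage <- match.arg(stage, c("simulate", "ingest", "match", "ppgr",
                              "features", "fit", "report", "all"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (stage == "all") {
    stages <- c(if (!is.null(config$generator)) "simulate",
                "ingest", "match", "ppgr", "features", "fit", "report")
    for (s in stages) run_pipeline(config, s)
    return(invisible(config$out_dir))
  }
  out <- config$out_dir
  if (stage == "simulate") {
    if (is.null(config$generator))
      stop("simulate stage needs a generator config")
    cohort <- gen_cohort(config$generator)
    write_cohort(cohort, config$input_dir)
    return(invisible(cohort))
  }
  if (stage == "ingest") {
    cohort <- read_cohort_dir(config$input_dir)
    yaml::write_yaml(list(
      n_patients = length(unique(cohort$profiles$patient_id)),
      n_cgm_samples = nrow(cohort$cgm),
      n_diary_meals = nrow(cohort$diary),
      n_protocol_entries = nrow(cohort$protocol),
      n_foods = nrow(cohort$food_table)),
      file.path(out, "ingest_log.yaml"))
    return(invisible(cohort))
  }
  cohort <- read_cohort_dir(config$input_dir)
  if (stage == "match") {
    matched <- match_protocol_to_diary(cohort$protocol, cohort$diary,
                                       max_gap_min = config$max_gap_min)
    matched <- apply_exclusion_rules(matched, cohort$cgm,
                                     late_threshold = config$late_threshold,
                                     edge_threshold = config$edge_threshold,
                                     window_min = config$window_min)
    report <- dplyr::transmute(
      matched, .data$patient_id, meal_start = iso_utc(.data$meal_start),
      .data$meal_id,
      status = ifelse(is.na(.data$exclusion), "kept", "excluded"),
      reason = .data$exclusion)
    readr::write_csv(report, file.path(out, "matched.csv"))
    yaml::write_yaml(c(list(unmatched = attr(matched, "unmatched")),
                       as.list(attr(matched, "exclusion_counts"))),
                     file.path(out, "match_log.yaml"))
    return(invisible(matched))
  }
  if (stage == "ppgr") {
    m <- readr::read_csv(need_artifact(file.path(out, "matched.csv"), "match"),
                         show_col_types = FALSE,
                         col_types = readr::cols(
                           meal_start = readr::col_datetime()))
    kept <- m[m$status == "kept", ]
    rec <- extract_ppgr_meals(kept, cohort$cgm)
    rec <- dplyr::bind_cols(dplyr::select(kept, "patient_id"), rec)
    rec$meal_start <- iso_utc(kept$meal_start)
    readr::write_csv(rec, file.path(out, "ppgr.csv"))
    return(invisible(rec))
  }
  if (stage == "features") {
    res <- process_cohort(cohort, config)
    write_design(res$design, out)
    readr::write_csv(
      dplyr::transmute(res$records, .data$patient_id, .data$meal_id,
                       .data$carbo, .data$iauc120,
                       status = ifelse(is.na(.data$filter_reason), "kept",
                                       "removed"),
                       reason = .data$filter_reason),
      file.path(out, "filter_report.csv"))
    yaml::write_yaml(as.list(res$counts), file.path(out, "feature_log.yaml"))
    return(invisible(res$design))
  }
  if (stage == "fit") {
    design <- read_design(out)
    cmp <- run_comparison(design, outcomes = config$outcomes,
                          arms = config$arms, methods = config$methods,
                          polynomial = config$polynomial,
                          split_fraction = config$split_fraction,
                          k = config$k, seed = config$seed,
                          alpha_enter = config$alpha_enter)
    readr::write_csv(cmp$table, file.path(out, "comparison.csv"))
    model_dir <- file.path(out, "models")
    dir.create(model_dir, showWarnings = FALSE)
    for (key in names(cmp$models))
      write_model(cmp$models[[key]],
                  file.path(model_dir, paste0(gsub("[^A-Za-z0-9_.]", "_", key),
                                              ".yaml")))
    return(invisible(cmp))
  }
  if (stage == "report") {
    need_artifact(file.path(out, "comparison.csv"), "fit")
    design <- read_design(out)
    scatter <- NULL
    key <- file.path(out, "models", "iauc120.with_gigl.omp.yaml")
    if (file.exists(key)) {
      model <- read_model(key)
      split <- grouped_split(arm_restrict(design, model$arm),
                             fraction = config$split_fraction,
                             seed = config$seed)
      pred <- predict(model, split$test)
      scatter <- tibble::tibble(
        patient_id = split$test$data$patient_id,
        meal_id = split$test$data$meal_id,
        observed = split$test$data$iauc120, predicted = pred,
        large_error = abs(pred - split$test$data$iauc120) > 1.0)
      readr::write_csv(scatter, file.path(out, "scatter_iauc120.csv"))
    }
    counts <- if (file.exists(file.path(out, "feature_log.yaml")))
      yaml::read_yaml(file.path(out, "feature_log.yaml")) else list()
    yaml::write_yaml(list(config_hash = config$hash, seed = config$seed,
                          counts = counts),
                     file.path(out, "run_log.yaml"))
    return(invisible(scatter))
  }
}
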