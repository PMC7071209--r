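# A small fully synthetic regression design for solver tests.
toy_design <- function(n = 120, p = 6, seed = 99, beta = NULL,
                       noise = 0.5, n_patients = 12) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  if (is.null(beta)) beta <- c(1.5, -1, 0.5, rep(0, p - 3))
  y <- drop(x %*% beta) + rnorm(n, 0, noise)
  data <- tibble::as_tibble(as.data.frame(x))
  data$patient_id <- rep(paste0("P", seq_len(n_patients)),
                         length.out = n)
  data$y <- y
  ppgr:::new_design(data, paste0("x", 1:p), character(0), "y", "with_gigl")
}

test_that("column normalization centers and scales to unit l2 norm", {
  x <- cbind(a = c(1, 2, 3), b = c(2, 2, 2))
  expect_warning(norm <- normalize_columns(x), "zero-norm")
  expect_equal(colnames(norm$x), "a")
  expect_equal(norm$x[, "a"], c(-1, 0, 1) / sqrt(2))
  expect_equal(unname(norm$center["a"]), 2)
  expect_equal(unname(norm$scale["a"]), sqrt(2))
  # an already centered unit-norm column is a fixed point
  fixed <- cbind(u = c(-1, 0, 1) / sqrt(2))
  norm2 <- normalize_columns(fixed)
  expect_equal(norm2$x[, "u"], fixed[, "u"])
})

test_that("the Spearman prefilter keeps informative features only", {
  set.seed(5)
  n <- 1000
  y <- rnorm(n)
  x <- cbind(same = y, noise = rnorm(n), const = rep(1, n),
             mono = exp(y) + rnorm(n, 0, 0.1))
  kept <- spearman_prefilter(x, y, threshold = 0.1)
  expect_true("same" %in% kept)
  expect_true("mono" %in% kept)       # rank correlation sees monotone links
  expect_false("noise" %in% kept)
  expect_false("const" %in% kept)
  # threshold 0 retains every non-constant feature
  expect_setequal(spearman_prefilter(x, y, threshold = 0),
                  c("same", "noise", "mono"))
})

test_that("grouped splits separate patients deterministically", {
  d <- toy_design(n = 100, n_patients = 10)
  s <- grouped_split(d, fraction = 0.7, seed = 3)
  expect_equal(nrow(s$train$data) + nrow(s$test$data), 100)
  expect_length(intersect(unique(s$train$data$patient_id),
                          unique(s$test$data$patient_id)), 0)
  expect_equal(length(unique(s$train$data$patient_id)), 7)
  s2 <- grouped_split(d, fraction = 0.7, seed = 3)
  expect_identical(s$train$data, s2$train$data)
  one <- ppgr:::design_subset(d, d$data$patient_id == "P1")
  expect_error(grouped_split(one), "single-patient")
})

test_that("grouped k-fold partitions patients into disjoint folds", {
  pid <- rep(paste0("P", 1:20), each = 5)
  folds <- grouped_kfold(pid, k = 10, seed = 2)
  expect_equal(sort(unique(folds)), 1:10)
  per_fold <- table(folds[!duplicated(pid)])
  expect_true(all(per_fold == 2))     # 20 patients over 10 folds
  # a patient's rows always share a fold
  expect_true(all(tapply(folds, pid, function(f) length(unique(f))) == 1))
  expect_identical(folds, grouped_kfold(pid, k = 10, seed = 2))
  expect_error(grouped_kfold(pid, k = 30), "fewer patients")
})

test_that("OMP with full support reproduces the least-squares solution", {
  d <- toy_design(n = 80, p = 5)
  xy <- ppgr:::design_xy(d, "y")
  norm <- normalize_columns(xy$x)
  yc <- xy$y - mean(xy$y)
  path <- omp_path(norm$x, yc, max_nonzero = 5)
  ols <- qr.coef(qr(norm$x), yc)
  expect_equal(path[, 5], ols, tolerance = 1e-6)
  # the greedy path finds the planted support first
  expect_setequal(names(which(path[, 3] != 0)), c("x1", "x2", "x3"))
})

test_that("the LARS-lasso path matches glmnet and ends at least squares", {
  d <- toy_design(n = 150, p = 8, noise = 1)
  xy <- ppgr:::design_xy(d, "y")
  norm <- normalize_columns(xy$x)
  yc <- xy$y - mean(xy$y)
  path <- lars_lasso_path(norm$x, yc)
  # alpha -> 0: the end of the path is the OLS solution
  ols <- qr.coef(qr(norm$x), yc)
  expect_equal(path$beta[, ncol(path$beta)], ols, tolerance = 1e-6)
  expect_equal(lasso_at(path, 1e-12)[, 1], ols, tolerance = 1e-6)
  # interior solutions agree with glmnet (objective lambda' = lambda / n)
  n <- nrow(norm$x)
  for (lam in c(2, 0.5, 0.05)) {
    ours <- lasso_at(path, lam)[, 1]
    g <- glmnet::glmnet(norm$x, yc, alpha = 1,
                        lambda = sort(c(lam / n, 10^seq(-6, 0, by = 0.25)),
                                      decreasing = TRUE),
                        standardize = FALSE, intercept = FALSE,
                        thresh = 1e-12)
    theirs <- as.numeric(coef(g, s = lam / n, exact = FALSE))[-1]
    expect_equal(unname(ours), theirs, tolerance = 1e-4)
  }
  # above lambda_max the solution is identically zero
  expect_true(all(lasso_at(path, path$lambda[1] * 1.1) == 0))
})

test_that("stepwise regression selects a perfect predictor and stops", {
  set.seed(21)
  n <- 60
  data <- tibble::tibble(patient_id = rep(paste0("P", 1:6), each = 10),
                         x1 = rnorm(n), x2 = rnorm(n))
  data$y <- 2 + 3 * data$x1
  d <- ppgr:::new_design(data, c("x1", "x2"), character(0), "y", "with_gigl")
  fit <- stepwise_forward(d, "y")
  expect_equal(fit$trace$variable[1], "x1")
  expect_equal(fit$trace$r[1], 1, tolerance = 1e-9)
  expect_equal(nrow(fit$trace), 1)    # x2 adds nothing significant
  expect_equal(unname(fit$model$coef["x1"]), 3, tolerance = 1e-9)
  expect_equal(fit$model$intercept, 2, tolerance = 1e-9)
})

test_that("stepwise trace is monotone and invariant to row order", {
  d <- toy_design(n = 200, p = 6, noise = 1)
  fit <- stepwise_forward(d, "y")
  expect_true(all(diff(fit$trace$r2) > -1e-12))
  # adjusted R2 matches its definition at each step
  n <- nrow(d$data)
  expect_equal(fit$trace$adj_r2,
               1 - (1 - fit$trace$r2) * (n - 1) / (n - fit$trace$step - 1))
  perm <- ppgr:::design_subset(d, sample(n))
  fit2 <- stepwise_forward(perm, "y")
  expect_equal(fit2$trace$variable, fit$trace$variable)
  expect_equal(fit2$trace$r2, fit$trace$r2)
})

test_that("rank-deficient stepwise candidates are skipped with a warning", {
  d <- toy_design(n = 80, p = 4)
  d$data$x4 <- d$data$x1        # duplicate column
  expect_warning(fit <- stepwise_forward(d, "y"), "rank-deficient")
  expect_false(all(c("x1", "x4") %in% fit$trace$variable))
})

test_that("grid search selects by cross-validated r2 and refits", {
  d <- toy_design(n = 200, p = 6, n_patients = 20, noise = 0.6)
  m <- fit_regularized(d, "y", method = "omp", grid = 1:6, k = 5, seed = 7)
  expect_s3_class(m, "ppgr_model")
  expect_setequal(names(coef(m))[1:3], c("x1", "x2", "x3"))
  expect_equal(which.max(m$cv$mean_cv_r2), m$hyper)
  # a one-point grid is the direct fit at that grid point
  m1 <- fit_regularized(d, "y", method = "omp", grid = 3, k = 5, seed = 7)
  expect_equal(m1$hyper, 3)
  expect_equal(sum(coef(m1) != 0), 3)
  expect_error(fit_regularized(d, "y", method = "omp", grid = integer(0)),
               "empty")
})

test_that("training is untouched by test-set outcomes (no leakage)", {
  d <- toy_design(n = 200, p = 5, n_patients = 20)
  s <- grouped_split(d, fraction = 0.7, seed = 1)
  m1 <- fit_regularized(s$train, "y", method = "omp", grid = 1:5, k = 5,
                        seed = 11)
  shuffled <- s
  shuffled$test$data$y <- sample(shuffled$test$data$y)
  m2 <- fit_regularized(shuffled$train, "y", method = "omp", grid = 1:5,
                        k = 5, seed = 11)
  expect_identical(serialize(m1, NULL), serialize(m2, NULL))
})

test_that("evaluation reports correlation, MAE and large-error fraction", {
  d <- toy_design(n = 100, p = 4)
  s <- grouped_split(d, seed = 2)
  m <- fit_regularized(s$train, "y", method = "omp", grid = 1:4, k = 4,
                       seed = 2)
  # identity predictions
  ident <- m
  ev <- evaluate(m, s$test)
  expect_true(ev$pearson_r > 0.9)
  expect_gte(ev$mae, 0)
  expect_equal(ev$n_test, nrow(s$test$data))
  # shift law: adding a constant leaves R at 1, MAE at the constant
  m$intercept <- m$intercept + 2
  obs <- s$test$data$y
  pred <- predict(m, s$test)
  expect_equal(cor(pred, obs), evaluate(ident, s$test)$pearson_r)
  expect_equal(mean(abs(pred - obs)),
               mean(abs(predict(ident, s$test) + 2 - obs)))
})

test_that("polynomial expansion covers the meal block and arm restriction", {
  d <- small_design()
  p0 <- length(d$features)
  dp <- add_polynomial(d)
  k <- length(d$meal_features)
  expect_equal(length(dp$features), p0 + k + k * (k - 1) / 2)
  expect_equal(dp$data[["carbo^2"]], dp$data$carbo^2)
  expect_equal(dp$data[["gi x gl"]], dp$data$gi * dp$data$gl)
  # dropping the GI/GL arm removes their polynomial children too
  d2 <- arm_restrict(dp, "without_gigl")
  expect_false(any(grepl("(^| )gi( |\\^|$)|(^| )gl( |\\^|$)", d2$features)))
  expect_true("carbo^2" %in% d2$features)
  # with 3 meal features the expansion adds 3 squares + 3 products
  d3 <- d
  d3$meal_features <- c("carbo", "prot", "fat")
  expect_equal(length(add_polynomial(d3)$features), p0 + 6)
})

test_that("models round-trip through their text serialization", {
  d <- toy_design(n = 100, p = 4)
  m <- fit_regularized(d, "y", method = "lasso", k = 4, seed = 3)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(predict(m2, d), predict(m, d), tolerance = 1e-9)
  expect_equal(m2$method, m$method)
})

test_that("ridge and elastic net run through the same grid machinery", {
  d <- toy_design(n = 150, p = 5, n_patients = 15)
  for (meth in c("ridge", "elastic_net")) {
    m <- fit_regularized(d, "y", method = meth, k = 5, seed = 4)
    ev <- evaluate(m, d)
    expect_true(ev$pearson_r > 0.8)
  }
})

test_that("the comparison table covers outcomes x arms x methods", {
  d <- small_design()
  cmp <- run_comparison(d, outcomes = c("iauc120", "bgrise"),
                        methods = c("stepwise", "omp"),
                        grids = list(omp = 1:5), k = 4, seed = 5)
  expect_equal(nrow(cmp$table), 2 * 2 * 2)
  expect_true(all(cmp$table$n_coefficients >= 0))
  expect_length(cmp$models, 8)
})
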