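#' Spearman correlation prefilter
#'
#' Retains features whose absolute Spearman rank correlation with the outcome
#' exceeds `threshold`; constant columns are dropped. Computed on the training
#' split only — applying it to held-out data would leak outcome information.
#'
#' @param x Numeric feature matrix (training rows).
#' @param y Outcome vector.
#' @param threshold Retention threshold on `|r|` (default 0.1).
#' @return Character vector of retained column names.
#' @export
spearman_prefilter <- function(x, y, threshold = 0.1) {
  sds <- apply(x, 2, sd)
  keep <- colnames(x)[sds > 0]
  if (!length(keep)) return(character(0))
  r <- suppressWarnings(cor(x[, keep, drop = FALSE], y, method = "spearman"))
  keep[!is.na(r) & abs(r) > threshold]
}

#' Center and l2-normalize design columns
#'
#' Each column is centered by its (training) mean and divided by the l2 norm
#' of the centered column. The constants are returned for verbatim reuse on
#' validation and test rows; zero-norm (constant) columns are dropped with a
#' warning.
#'
#' @param x Numeric matrix of training rows.
#' @return List with `x` (normalized matrix), `center`, `scale` (named
#'   vectors over the kept columns).
#' @export
normalize_columns <- function(x) {
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  scale <- sqrt(colSums(xc^2))
  keep <- scale > 1e-12
  if (!all(keep))
    warning("dropping zero-norm column(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
  list(x = sweep(xc[, keep, drop = FALSE], 2, scale[keep], "/"),
       center = center[keep], scale = scale[keep])
}

apply_normalization <- function(x, norm) {
  cols <- names(norm$center)
  sweep(sweep(x[, cols, drop = FALSE], 2, norm$center), 2, norm$scale, "/")
}

#' Patient-grouped train/test split
#'
#' Partitions patients (never rows) so that the training side holds
#' approximately `fraction` of the rows and no patient appears on both sides.
#' Deterministic given `seed`.
#'
#' @param design A `ppgr_design`.
#' @param fraction Target fraction of rows on the training side (default 0.7).
#' @param seed Integer seed.
#' @return List with `train` and `test` (`ppgr_design` objects).
#' @export
grouped_split <- function(design, fraction = 0.7, seed = 1) {
  pid <- design$data$patient_id
  patients <- unique(pid)
  if (length(patients) < 2L) stop("cannot split a single-patient cohort")
  shuffled <- local_seed(seed, sample(patients))
  rows_per <- table(pid)[shuffled]
  target <- fraction * length(pid)
  cum <- cumsum(rows_per)
  n_train <- which.min(abs(cum - target))
  n_train <- max(1L, min(n_train, length(patients) - 1L))
  train_pat <- shuffled[seq_len(n_train)]
  list(train = design_subset(design, pid %in% train_pat),
       test = design_subset(design, !pid %in% train_pat))
}

#' Patient-grouped k-fold assignment
#'
#' Patients are shuffled (deterministically given `seed`) and dealt
#' round-robin into `k` folds, so every validation fold contains only
#' patients absent from its training folds.
#'
#' @param patient_id Character vector, one entry per row.
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return Integer vector of fold labels (1..k), one per row.
#' @export
grouped_kfold <- function(patient_id, k = 10, seed = 1) {
  patients <- unique(patient_id)
  if (length(patients) < k)
    stop("fewer patients (", length(patients), ") than folds (", k, ")")
  shuffled <- local_seed(seed, sample(patients))
  fold_of <- setNames(rep_len(seq_len(k), length(patients)), shuffled)
  unname(fold_of[patient_id])
}

# ---- sparse solvers ---------------------------------------------------------

#' Orthogonal matching pursuit path
#'
#' Greedy sparse regression on centered, l2-normalized columns: at each step
#' the column most correlated with the current residual enters the support,
#' and the coefficients are refit by ordinary least squares on the support.
#' Because supports are nested, one pass yields the coefficient vectors for
#' every support size up to `max_nonzero`.
#'
#' @param x Normalized feature matrix.
#' @param y Centered outcome vector.
#' @param max_nonzero Largest support size.
#' @return Matrix `p x max_nonzero`; column `s` holds the coefficients of the
#'   size-`s` model.
#' @export
omp_path <- function(x, y, max_nonzero) {
  p <- ncol(x)
  max_nonzero <- min(max_nonzero, p, nrow(x) - 1L)
  coefs <- matrix(0, p, max_nonzero,
                  dimnames = list(colnames(x), NULL))
  support <- integer(0)
  r <- y
  for (s in seq_len(max_nonzero)) {
    score <- abs(drop(crossprod(x, r)))
    if (length(support)) score[support] <- -Inf
    j <- which.max(score)
    support <- c(support, j)
    b <- qr.coef(qr(x[, support, drop = FALSE]), y)
    b[is.na(b)] <- 0
    r <- y - drop(x[, support, drop = FALSE] %*% b)
    coefs[support, s] <- b
  }
  coefs
}

#' LARS path with the lasso modification
#'
#' Least-angle regression on centered, unit-norm columns, with the lasso
#' modification (a coefficient crossing zero leaves the active set), yielding
#' the exact piecewise-linear lasso coefficient path for the objective
#' \deqn{\tfrac12 \lVert y - X\beta\rVert_2^2 + \lambda \lVert\beta\rVert_1.}
#' The recorded knots run from \eqn{\lambda_{max} = \max_j |x_j^\top y|} down
#' to (numerically) zero, where the path reaches the least-squares solution.
#'
#' @param x Normalized feature matrix.
#' @param y Centered outcome vector.
#' @param max_steps Safety cap on path steps.
#' @return List with `lambda` (decreasing knot values) and `beta`
#'   (`p x length(lambda)` coefficient matrix).
#' @export
lars_lasso_path <- function(x, y, max_steps = 8 * ncol(x) + 10) {
  n <- nrow(x)
  p <- ncol(x)
  tol <- 1e-10
  beta <- rep(0, p)
  r <- y
  cvec <- drop(crossprod(x, r))
  bigC <- max(abs(cvec))
  lambdas <- bigC
  betas <- list(beta)
  active <- which.max(abs(cvec))
  step <- 0L
  while (bigC > tol && step < max_steps && length(active)) {
    step <- step + 1L
    sA <- sign(cvec[active])
    xa <- x[, active, drop = FALSE] * rep(sA, each = n)
    g <- crossprod(xa)
    w <- tryCatch(solve(g, rep(1, length(active))),
                  error = function(e) NULL)
    if (is.null(w)) break  # degenerate active set
    anorm <- 1 / sqrt(sum(w))
    w <- w * anorm
    u <- drop(xa %*% w)
    a <- drop(crossprod(x, u))
    gamma_max <- bigC / anorm
    inactive <- setdiff(seq_len(p), active)
    jnext <- NA_integer_
    gamma <- gamma_max
    if (length(inactive)) {
      g1 <- (bigC - cvec[inactive]) / (anorm - a[inactive])
      g2 <- (bigC + cvec[inactive]) / (anorm + a[inactive])
      cand <- c(g1, g2)
      cand[!is.finite(cand) | cand <= tol] <- Inf
      if (any(is.finite(cand))) {
        kmin <- which.min(cand)
        if (cand[kmin] < gamma) {
          gamma <- cand[kmin]
          jnext <- inactive[(kmin - 1L) %% length(inactive) + 1L]
        }
      }
    }
    d <- rep(0, p)
    d[active] <- sA * w
    drop_j <- NA_integer_
    cross <- -beta[active] / d[active]
    cross[!is.finite(cross) | cross <= tol] <- Inf
    if (any(is.finite(cross)) && min(cross) < gamma) {
      gamma <- min(cross)
      drop_j <- active[which.min(cross)]
      jnext <- NA_integer_
    }
    beta <- beta + gamma * d
    r <- r - gamma * u
    cvec <- drop(crossprod(x, r))
    bigC <- max(abs(cvec))
    if (!is.na(drop_j)) {
      beta[drop_j] <- 0
      active <- setdiff(active, drop_j)
      if (!length(active) && bigC > tol) active <- which.max(abs(cvec))
    } else if (!is.na(jnext)) {
      active <- c(active, jnext)
    }
    lambdas <- c(lambdas, bigC)
    betas <- c(betas, list(beta))
  }
  list(lambda = lambdas,
       beta = matrix(unlist(betas), nrow = p,
                     dimnames = list(colnames(x), NULL)))
}

#' Lasso coefficients at given penalties from a LARS path
#'
#' The lasso solution is piecewise linear in the penalty, so coefficients at
#' arbitrary `lambda` values are exact linear interpolations between path
#' knots.
#'
#' @param path Result of [lars_lasso_path()].
#' @param lambda Numeric vector of penalty values.
#' @return Matrix `p x length(lambda)`.
#' @export
lasso_at <- function(path, lambda) {
  p <- nrow(path$beta)
  out <- matrix(0, p, length(lambda), dimnames = list(rownames(path$beta), NULL))
  kl <- path$lambda
  for (i in seq_along(lambda)) {
    l <- lambda[i]
    if (l >= kl[1]) next  # all-zero solution
    if (l <= kl[length(kl)]) {
      out[, i] <- path$beta[, length(kl)]
      next
    }
    k <- max(which(kl >= l))
    w <- (kl[k] - l) / (kl[k] - kl[k + 1L])
    out[, i] <- (1 - w) * path$beta[, k] + w * path$beta[, k + 1L]
  }
  out
}

default_grid <- function(method, p = Inf) {
  switch(method,
         omp = seq_len(min(30, p)),
         lars_lasso = ,
         lasso = ,
         ridge = 10^seq(-4, 1, length.out = 20),
         elastic_net = expand.grid(alpha = 10^seq(-4, 1, length.out = 20),
                                   l1_ratio = c(0.1, 0.5, 0.9)),
         stop("unknown method: ", method))
}

# Coefficient matrix (p x n_grid) for one method on normalized x, centered y.
fit_method_grid <- function(x, y, method, grid) {
  n <- nrow(x)
  if (method == "omp") {
    path <- omp_path(x, y, max_nonzero = max(grid))
    sizes <- pmin(grid, ncol(path))
    return(path[, sizes, drop = FALSE])
  }
  if (method == "lars_lasso") {
    path <- lars_lasso_path(x, y)
    return(lasso_at(path, grid))
  }
  glmnet_coefs <- function(alpha, lambdas) {
    # fit on a descending path covering the requested values; glmnet is
    # unreliable when handed a single lambda
    path <- sort(unique(c(lambdas,
                          10^seq(log10(max(lambdas) * 100),
                                 log10(max(min(lambdas), 1e-10)),
                                 length.out = 30))),
                 decreasing = TRUE)
    fit <- glmnet::glmnet(x, y, alpha = alpha, lambda = path,
                          standardize = FALSE, intercept = FALSE,
                          thresh = 1e-10)
    b <- as.matrix(coef(fit, s = lambdas, exact = FALSE))[-1, , drop = FALSE]
    rownames(b) <- colnames(x)
    b
  }
  if (method %in% c("lasso", "ridge"))
    return(glmnet_coefs(if (method == "lasso") 1 else 0, grid / n))
  if (method == "elastic_net") {
    out <- matrix(0, ncol(x), nrow(grid), dimnames = list(colnames(x), NULL))
    for (l1 in unique(grid$l1_ratio)) {
      rows <- which(grid$l1_ratio == l1)
      out[, rows] <- glmnet_coefs(l1, grid$alpha[rows] / n)
    }
    return(out)
  }
  stop("unknown method: ", method)
}

#' Fit a regularized PPGR model with grouped cross-validated grid search
#'
#' For each grid point (support size for OMP; penalty `alpha` for the
#' penalized methods; penalty and l1 ratio for the elastic net) the mean
#' coefficient-of-determination (r²) over grouped k-fold validation folds is
#' computed, with the Spearman prefilter and the column normalization refit
#' inside each fold's training part so no validation information leaks into
#' feature selection or scaling. The best grid point (largest mean CV r²) is
#' then refit on the full training split.
#'
#' @param train A `ppgr_design` holding the training split.
#' @param outcome Name of the outcome column.
#' @param method One of `"omp"`, `"lars_lasso"`, `"lasso"`, `"ridge"`,
#'   `"elastic_net"`.
#' @param grid Hyperparameter grid; `NULL` uses the method default (OMP:
#'   support sizes 1–30; penalized methods: 20 log-spaced penalties from
#'   1e-4 to 10; elastic net additionally l1 ratios 0.1/0.5/0.9).
#' @param k Number of grouped CV folds (default 10).
#' @param seed Integer seed controlling fold assignment.
#' @param prefilter_threshold Spearman prefilter threshold (default 0.1).
#' @return A `ppgr_model`: selected columns, coefficients, normalization
#'   constants, chosen hyperparameters and the CV score table.
#' @export
fit_regularized <- function(train, outcome, method = "omp", grid = NULL,
                            k = 10, seed = 1, prefilter_threshold = 0.1) {
  stopifnot(inherits(train, "ppgr_design"))
  method <- match.arg(method,
                      c("omp", "lars_lasso", "lasso", "ridge", "elastic_net"))
  xy <- design_xy(train, outcome)
  if (is.null(grid)) grid <- default_grid(method, p = ncol(xy$x))
  n_grid <- if (is.data.frame(grid)) nrow(grid) else length(grid)
  if (n_grid == 0L) stop("empty hyperparameter grid")
  folds <- grouped_kfold(xy$patient_id, k = k, seed = seed)
  scores <- matrix(NA_real_, k, n_grid)
  for (f in seq_len(k)) {
    tr <- folds != f
    feats <- spearman_prefilter(xy$x[tr, , drop = FALSE], xy$y[tr],
                                threshold = prefilter_threshold)
    if (!length(feats)) next
    norm <- normalize_columns(xy$x[tr, feats, drop = FALSE])
    if (!length(norm$center)) next
    ybar <- mean(xy$y[tr])
    b <- fit_method_grid(norm$x, xy$y[tr] - ybar, method, grid)
    xval <- apply_normalization(xy$x[!tr, , drop = FALSE], norm)
    pred <- sweep(xval %*% b, 2, -ybar)  # add back training mean
    scores[f, ] <- apply(pred, 2, function(p) r2_score(xy$y[!tr], p))
  }
  mean_scores <- colMeans(scores, na.rm = TRUE)
  if (all(is.na(mean_scores))) stop("cross-validation produced no usable fold")
  best <- which.max(mean_scores)
  if (max(mean_scores, na.rm = TRUE) < 0)
    warning("best cross-validated r^2 is negative")
  # final refit on the full training split
  feats <- spearman_prefilter(xy$x, xy$y, threshold = prefilter_threshold)
  norm <- normalize_columns(xy$x[, feats, drop = FALSE])
  ybar <- mean(xy$y)
  best_grid <- if (is.data.frame(grid)) grid[best, , drop = FALSE] else
    grid[best]
  b <- fit_method_grid(norm$x, xy$y - ybar, method, best_grid)[, 1]
  cv_table <- tibble::tibble(grid_index = seq_len(n_grid),
                             mean_cv_r2 = mean_scores)
  if (is.data.frame(grid)) cv_table <- dplyr::bind_cols(tibble::as_tibble(grid),
                                                        cv_table)
  else cv_table$grid_value <- grid
  new_ppgr_model(outcome = outcome, arm = train$arm, method = method,
                 columns = names(norm$center), center = norm$center,
                 scale = norm$scale, coef = b, intercept = ybar,
                 hyper = best_grid, cv = cv_table, seed = seed)
}

new_ppgr_model <- function(outcome, arm, method, columns, center, scale,
                           coef, intercept, hyper = NULL, cv = NULL,
                           trace = NULL, seed = NA_integer_) {
  structure(list(outcome = outcome, arm = arm, method = method,
                 columns = columns, center = center, scale = scale,
                 coef = coef, intercept = intercept, hyper = hyper,
                 cv = cv, trace = trace, seed = seed),
            class = "ppgr_model")
}

#' @export
print.ppgr_model <- function(x, ...) {
  cat("<ppgr_model> ", x$method, " for ", x$outcome, " (", x$arm, "), ",
      sum(x$coef != 0), " nonzero coefficient(s)\n", sep = "")
  invisible(x)
}

#' Selected features of a fitted model
#' @param object A `ppgr_model`.
#' @param ... Unused.
#' @return Named vector of nonzero coefficients (normalized-column scale).
#' @export
coef.ppgr_model <- function(object, ...) {
  object$coef[object$coef != 0]
}

#' Predict PPGR outcomes from a fitted model
#'
#' Applies the stored normalization constants to the new rows and the stored
#' coefficients; no refitting takes place.
#'
#' @param object A `ppgr_model`.
#' @param newdata A `ppgr_design` or a tibble containing the model's columns.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.ppgr_model <- function(object, newdata, ...) {
  data <- if (inherits(newdata, "ppgr_design")) newdata$data else newdata
  x <- as.matrix(data[object$columns])
  xn <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  drop(xn %*% object$coef) + object$intercept
}

# ---- stepwise track ---------------------------------------------------------

#' Forward stepwise linear regression
#'
#' Greedy forward selection on the raw (unnormalized) feature columns: at
#' each step the variable whose entry maximizes the model R² is added, and
#' selection stops when the entering variable's partial-F p-value exceeds
#' `alpha_enter`. There is no removal step. Ties in R² gain are broken by
#' column order, and the trace records R, R², adjusted R² and the residual
#' standard error after every step. Rank-deficient candidates (columns lying
#' in the span of the current model) are skipped.
#'
#' @param design A `ppgr_design`.
#' @param outcome Name of the outcome column.
#' @param alpha_enter Entry threshold on the partial-F p-value (default 0.05).
#' @param max_steps Optional cap on the number of entered variables.
#' @return List with `trace` (tibble, one row per step) and `model`
#'   (a `ppgr_model` with `method = "stepwise"` carrying the trace).
#' @export
stepwise_forward <- function(design, outcome, alpha_enter = 0.05,
                             max_steps = Inf) {
  xy <- design_xy(design, outcome)
  x <- xy$x
  y <- xy$y
  n <- nrow(x)
  if (n < 3L) stop("too few rows for stepwise regression")
  selected <- character(0)
  q <- matrix(1 / sqrt(n), n, 1)  # orthonormal basis, intercept first
  ry <- y - q %*% crossprod(q, y)
  rss <- sum(ry^2)
  tss <- sum((y - mean(y))^2)
  trace <- list()
  skipped <- 0L
  repeat {
    cand <- setdiff(colnames(x), selected)
    if (!length(cand) || length(selected) + 2L >= n) break
    xc <- x[, cand, drop = FALSE]
    xt <- xc - q %*% crossprod(q, xc)
    den <- colSums(xt^2)
    ok <- den > 1e-10 * pmax(colSums(xc^2), 1)
    skipped <- skipped + sum(!ok)
    gain <- rep(-Inf, length(cand))
    gain[ok] <- drop(crossprod(xt[, ok, drop = FALSE], ry))^2 / den[ok]
    j <- which.max(gain)
    if (!is.finite(gain[j]) || gain[j] <= 0) break
    df2 <- n - length(selected) - 2L
    rss_new <- rss - gain[j]
    fstat <- gain[j] / (rss_new / df2)
    pval <- pf(fstat, 1, df2, lower.tail = FALSE)
    if (pval > alpha_enter) break
    qnew <- xt[, j] / sqrt(den[j])
    q <- cbind(q, qnew)
    ry <- ry - qnew * sum(qnew * ry)
    rss <- rss_new
    selected <- c(selected, cand[j])
    p <- length(selected)
    r2 <- 1 - rss / tss
    trace[[p]] <- tibble::tibble(
      step = p, variable = cand[j], r = sqrt(max(r2, 0)), r2 = r2,
      adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p - 1),
      std_error = sqrt(rss / (n - p - 1)), partial_f_p = pval)
    if (p >= max_steps) break
  }
  if (skipped > 0L)
    warning(skipped, " rank-deficient candidate evaluation(s) skipped")
  trace <- if (length(trace)) dplyr::bind_rows(trace) else
    tibble::tibble(step = integer(), variable = character(), r = double(),
                   r2 = double(), adj_r2 = double(), std_error = double(),
                   partial_f_p = double())
  fit <- lm.fit(cbind(`(Intercept)` = 1, x[, selected, drop = FALSE]), y)
  b <- fit$coefficients[-1]
  b[is.na(b)] <- 0
  model <- new_ppgr_model(
    outcome = outcome, arm = design$arm, method = "stepwise",
    columns = selected,
    center = setNames(rep(0, length(selected)), selected),
    scale = setNames(rep(1, length(selected)), selected),
    coef = b, intercept = unname(fit$coefficients[1]), trace = trace)
  list(trace = trace, model = model)
}

# ---- polynomial features ----------------------------------------------------

#' Add degree-2 polynomial features of the meal-composition block
#'
#' Appends squares (`carbo^2`) and pairwise products (`carbo x gl`) of the
#' meal-composition columns only. Restricting a polynomial design to the
#' without-GI/GL arm with [arm_restrict()] also drops the polynomial children
#' of `gi` and `gl`.
#'
#' @param design A `ppgr_design`.
#' @param meal_features Columns to expand (default: the design's
#'   meal-composition block).
#' @return The augmented `ppgr_design` (attribute `polynomial = TRUE`).
#' @export
add_polynomial <- function(design, meal_features = design$meal_features) {
  stopifnot(all(meal_features %in% design$features))
  data <- design$data
  added <- character(0)
  for (i in seq_along(meal_features)) {
    a <- meal_features[i]
    sq <- paste0(a, "^2")
    data[[sq]] <- data[[a]]^2
    added <- c(added, sq)
    if (i < length(meal_features)) {
      for (b in meal_features[(i + 1):length(meal_features)]) {
        nm <- paste(a, "x", b)
        data[[nm]] <- data[[a]] * data[[b]]
        added <- c(added, nm)
      }
    }
  }
  design$data <- data
  design$features <- c(design$features, added)
  design$polynomial <- TRUE
  design
}

# ---- evaluation -------------------------------------------------------------

#' Evaluate a fitted model on held-out patients
#'
#' Reports the Pearson correlation between predictions and observations, the
#' mean absolute error, the coefficient of determination, the test size, the
#' number of nonzero coefficients, and the fraction of predictions whose
#' absolute error exceeds `error_threshold` (reported for every outcome;
#' meaningful on the mmol/L·h scale of iAUC120).
#'
#' @param model A `ppgr_model`.
#' @param test A `ppgr_design` of held-out rows.
#' @param error_threshold Large-error cutoff (default 1.0, outcome units).
#' @return One-row tibble: `outcome`, `arm`, `method`, `pearson_r`, `mae`,
#'   `r2`, `n_test`, `n_coefficients`, `frac_large_error`.
#' @export
evaluate <- function(model, test, error_threshold = 1.0) {
  obs <- test$data[[model$outcome]]
  pred <- predict(model, test)
  r <- if (sd(pred) == 0 || sd(obs) == 0) NA_real_ else cor(pred, obs)
  tibble::tibble(
    outcome = model$outcome, arm = model$arm, method = model$method,
    pearson_r = r, mae = mean(abs(pred - obs)), r2 = r2_score(obs, pred),
    n_test = length(obs), n_coefficients = sum(model$coef != 0),
    frac_large_error = mean(abs(pred - obs) > error_threshold))
}

#' Compare modeling arms, methods and outcomes
#'
#' Runs the two modeling tracks over every combination of outcome, arm and
#' method: the stepwise track is fit on all rows (its R is the in-sample
#' model R, as conventional for stepwise inventories), while regularized
#' methods are fit on a patient-grouped 70/30 training split and evaluated
#' on the held-out patients. Optionally augments the design with degree-2
#' polynomial meal features first; the without-GI/GL arm then also loses the
#' polynomial children of `gi`/`gl`.
#'
#' @param design A `ppgr_design` assembled in the with-GI/GL arm.
#' @param outcomes Outcome columns to model (default: all seven).
#' @param arms Arms to run.
#' @param methods Methods to run (any of `stepwise`, `omp`, `lars_lasso`,
#'   `lasso`, `ridge`, `elastic_net`).
#' @param polynomial Add polynomial meal features first?
#' @param split_fraction,k,seed Split fraction, CV folds and seed for the
#'   regularized track.
#' @param grids Optional named list of per-method hyperparameter grids.
#' @param alpha_enter Stepwise entry threshold.
#' @return List with `table` (one row per outcome x arm x method) and
#'   `models` (named list of fitted `ppgr_model`s).
#' @export
run_comparison <- function(design, outcomes = design$outcomes,
                           arms = c("with_gigl", "without_gigl"),
                           methods = c("stepwise", "omp"),
                           polynomial = FALSE, split_fraction = 0.7,
                           k = 10, seed = 1, grids = list(),
                           alpha_enter = 0.05) {
  stopifnot(design$arm == "with_gigl")
  if (polynomial) design <- add_polynomial(design)
  rows <- list()
  models <- list()
  for (arm in arms) {
    d <- arm_restrict(design, arm)
    split <- grouped_split(d, fraction = split_fraction, seed = seed)
    for (outcome in outcomes) {
      for (method in methods) {
        key <- paste(outcome, arm, method, sep = ".")
        if (method == "stepwise") {
          fit <- stepwise_forward(d, outcome, alpha_enter = alpha_enter)
          final <- tail(fit$trace, 1)
          rows[[key]] <- tibble::tibble(
            outcome = outcome, arm = arm, method = method,
            polynomial = polynomial, track = "all_data",
            n_coefficients = nrow(fit$trace),
            r = if (nrow(final)) final$r else NA_real_,
            mae = NA_real_)
          models[[key]] <- fit$model
        } else {
          model <- fit_regularized(split$train, outcome, method = method,
                                   grid = grids[[method]], k = k, seed = seed)
          ev <- evaluate(model, split$test)
          rows[[key]] <- tibble::tibble(
            outcome = outcome, arm = arm, method = method,
            polynomial = polynomial, track = "test",
            n_coefficients = ev$n_coefficients, r = ev$pearson_r,
            mae = ev$mae)
          models[[key]] <- model
        }
      }
    }
  }
  list(table = dplyr::bind_rows(rows), models = models)
}

#' Write / read a fitted model as plain text
#'
#' Serializes a `ppgr_model` (coefficients, normalization constants,
#' hyperparameters, arm, seed) to YAML.
#'
#' @param model A `ppgr_model`.
#' @param path Output file.
#' @return `read_model` returns the restored `ppgr_model`.
#' @export
write_model <- function(model, path) {
  obj <- list(outcome = model$outcome, arm = model$arm, method = model$method,
              columns = model$columns,
              center = as.list(model$center), scale = as.list(model$scale),
              coef = as.list(model$coef), intercept = model$intercept,
              hyper = if (is.data.frame(model$hyper))
                as.list(model$hyper) else model$hyper,
              seed = model$seed)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- yaml::read_yaml(path)
  new_ppgr_model(outcome = obj$outcome, arm = obj$arm, method = obj$method,
                 columns = unlist(obj$columns),
                 center = unlist(obj$center), scale = unlist(obj$scale),
                 coef = unlist(obj$coef), intercept = obj$intercept,
                 hyper = obj$hyper, seed = obj$seed)
}
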