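#' Build the covariate-exploration feature table
#'
#' Assembles the patient-level table used by the PCA and boosted-tree
#' stages: total daily dose, urea, post-transplant time, age and the
#' haematological counts as features, the plasma MPA trough as target,
#' and optionally the first-visit saliva concentration. When saliva is
#' included, rows default to first visits only (saliva exists only
#' there); otherwise every patient-visit contributes a row.
#'
#' @param cohort a `pk_cohort` or its observation data.frame
#' @param include_saliva add the `SALIVA` feature and restrict to rows
#'   where it is present
#' @param rows `"visits"` (all patient-visits) or `"first"` (first
#'   visit per patient)
#' @return data.frame with target column `MPA` and feature columns
#' @export
feature_table <- function(cohort, include_saliva = FALSE,
                          rows = if (include_saliva) "first" else "visits") {
  d <- if (inherits(cohort, "pk_cohort")) cohort$data else cohort
  rows <- match.arg(rows, c("visits", "first"))
  if (rows == "first") d <- d[d$OCC == 1, ]
  feats <- c("TDD", "UREA", "PTP", "AGE", "WBC", "RBC", "PLT")
  if (include_saliva) {
    if (!"SALIVA" %in% names(d) || all(is.na(d$SALIVA)))
      stop("saliva column absent or empty; run generate_saliva() first", call. = FALSE)
    d <- d[!is.na(d$SALIVA), ]
    feats <- c(feats, "SALIVA")
  }
  missing <- setdiff(c(feats, "DV"), names(d))
  if (length(missing))
    stop("feature table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  out <- d[, feats]
  out$MPA <- d$DV
  if (anyNA(out)) stop("feature table contains missing values", call. = FALSE)
  out
}

.default_grid <- function() {
  expand.grid(nrounds = c(100, 300), max_depth = c(2, 3), eta = c(0.1, 0.3))
}

#' Gradient-boosted tree regression of plasma MPA with Shapley attributions
#'
#' Fits gradient-boosted regression trees to the feature table on an
#' 80/20 train/test split, tunes hyperparameters by 5-fold
#' cross-validated MSE over a declared grid, and computes exact
#' tree-path Shapley attributions for every prediction. Feature
#' importance is the mean absolute attribution; additivity
#' (attributions sum to prediction minus baseline) holds to
#' single-precision accuracy.
#'
#' Uses the current RNG state for the split and folds; seed with
#' [set.seed()].
#'
#' @param table a [feature_table()] (target column `MPA`)
#' @param grid data.frame of candidate `nrounds`, `max_depth`, `eta`
#' @param train_frac training fraction (default 0.8)
#' @param n_folds cross-validation folds (default 5)
#' @param split optional pre-computed list with `train`/`test` row
#'   indices and a `folds` assignment, for paired comparisons
#' @return an object of class `ml_report`: test `mse` and `r2`, CV
#'   table, best hyperparameters, Shapley attribution matrix, ranking
#'   by mean |attribution| and the fitted booster
#' @export
fit_boosted <- function(table, grid = .default_grid(), train_frac = 0.8,
                        n_folds = 5, split = NULL) {
  if (nrow(table) < 30) stop("need at least 30 rows", call. = FALSE)
  y <- table$MPA
  if (stats::var(y) == 0) stop("degenerate target: zero variance", call. = FALSE)
  x <- as.matrix(table[, setdiff(names(table), "MPA")])
  n <- nrow(x)
  if (is.null(split)) {
    train <- sort(sample.int(n, floor(train_frac * n)))
    split <- list(train = train, test = setdiff(seq_len(n), train),
                  folds = sample(rep_len(seq_len(n_folds), length(train))))
  }
  xtr <- x[split$train, , drop = FALSE]; ytr <- y[split$train]
  xte <- x[split$test, , drop = FALSE];  yte <- y[split$test]

  cv_mse <- vapply(seq_len(nrow(grid)), function(g) {
    errs <- vapply(seq_len(n_folds), function(f) {
      in_f <- split$folds == f
      dtr <- xgboost::xgb.DMatrix(xtr[!in_f, , drop = FALSE],
                                  label = ytr[!in_f], nthread = 1)
      fit <- xgboost::xgb.train(
        params = list(max_depth = grid$max_depth[g], eta = grid$eta[g],
                      objective = "reg:squarederror", nthread = 1),
        data = dtr, nrounds = grid$nrounds[g], verbose = 0)
      pred <- stats::predict(fit, xgboost::xgb.DMatrix(xtr[in_f, , drop = FALSE],
                                                       nthread = 1))
      mean((ytr[in_f] - pred)^2)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  best <- which.min(cv_mse)

  dtrain <- xgboost::xgb.DMatrix(xtr, label = ytr, nthread = 1)
  model <- xgboost::xgb.train(
    params = list(max_depth = grid$max_depth[best], eta = grid$eta[best],
                  objective = "reg:squarederror", nthread = 1),
    data = dtrain, nrounds = grid$nrounds[best], verbose = 0)
  dtest <- xgboost::xgb.DMatrix(xte, nthread = 1)
  pred_te <- stats::predict(model, dtest)
  mse <- mean((yte - pred_te)^2)
  r2 <- 1 - sum((yte - pred_te)^2) / sum((yte - mean(yte))^2)

  dall <- xgboost::xgb.DMatrix(x, nthread = 1)
  shap <- stats::predict(model, dall, predcontrib = TRUE)
  contrib <- shap[, setdiff(colnames(shap), c("BIAS", "(Intercept)")), drop = FALSE]
  importance <- sort(colMeans(abs(contrib)), decreasing = TRUE)

  structure(list(
    mse = mse, r2 = r2,
    cv = cbind(grid, cv_mse = cv_mse), best_params = grid[best, ],
    shap = shap, prediction = stats::predict(model, dall),
    importance = importance, ranking = names(importance),
    split = split, model = model, features = colnames(x)),
    class = "ml_report")
}

#' @export
print.ml_report <- function(x, ...) {
  cat(sprintf("Boosted-tree regression: test MSE = %.4g, R2 = %.3f\n", x$mse, x$r2))
  cat("Feature ranking (mean |Shapley attribution|):\n")
  print(round(x$importance, 4))
  invisible(x)
}

#' Principal component analysis of the feature table
#'
#' Principal axes of the correlation matrix of the standardised
#' features plus the plasma MPA target (the loading-plot view of which
#' covariates move together with drug levels). Component signs are
#' fixed by making the largest-magnitude loading of each component
#' positive.
#'
#' @param table a [feature_table()]
#' @param n_components number of components to retain (default 2)
#' @return list with `loadings` (features x components), `var_explained`
#'   (per retained component), `eigenvalues` (all), `scores`
#' @export
run_pca <- function(table, n_components = 2) {
  x <- as.matrix(table)
  if (n_components > ncol(x))
    stop("n_components exceeds the number of features", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  eig <- pc$sdev^2
  load <- pc$rotation[, seq_len(n_components), drop = FALSE]
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(n_components)) {     # deterministic sign convention
    k <- which.max(abs(load[, j]))
    if (load[k, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(loadings = load, var_explained = eig[seq_len(n_components)] / sum(eig),
       eigenvalues = eig, scores = scores)
}

#' Paired boosted-tree fits with and without saliva
#'
#' Fits the boosted-tree model on identical splits and folds, once with
#' the saliva feature and once without, and reports the ranking shift
#' and the change in held-out R2 attributable to saliva.
#'
#' @param table a [feature_table()] that includes a `SALIVA` column
#' @param ... passed to [fit_boosted()]
#' @return list with `with_saliva`, `without_saliva` (both
#'   `ml_report`s), `delta_r2` and the two rankings
#' @export
compare_with_saliva <- function(table, ...) {
  if (!"SALIVA" %in% names(table))
    stop("table has no SALIVA column", call. = FALSE)
  n <- nrow(table)
  train <- sort(sample.int(n, floor(0.8 * n)))
  split <- list(train = train, test = setdiff(seq_len(n), train),
                folds = sample(rep_len(seq_len(5), length(train))))
  fit_w <- fit_boosted(table, split = split, ...)
  fit_wo <- fit_boosted(table[, setdiff(names(table), "SALIVA")],
                        split = split, ...)
  list(with_saliva = fit_w, without_saliva = fit_wo,
       delta_r2 = fit_w$r2 - fit_wo$r2,
       ranking_with = fit_w$ranking, ranking_without = fit_wo$ranking)
}
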