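ml_cohort <- function(seed = 50, ratio_cv = 0.1) {
  set.seed(seed)
  generate_saliva(generate_cohort(), ratio_cv = ratio_cv)
}

test_that("the feature table is assembled without missing values", {
  co <- ml_cohort()
  tab <- feature_table(co)
  expect_equal(nrow(tab), 209)
  expect_true(all(c("TDD", "UREA", "PTP", "AGE", "WBC", "RBC", "PLT", "MPA")
                  %in% names(tab)))
  expect_false(anyNA(tab))
  tab_s <- feature_table(co, include_saliva = TRUE)
  expect_equal(nrow(tab_s), 65)
  expect_true("SALIVA" %in% names(tab_s))
  co_nosal <- ml_cohort()
  co_nosal$data$SALIVA <- NA_real_
  expect_error(feature_table(co_nosal, include_saliva = TRUE), "saliva")
})

test_that("dose dominates the attribution ranking on dose-driven data", {
  tab <- feature_table(dose_driven_cohort(seed = 60))
  set.seed(1)
  rep <- fit_boosted(tab)
  expect_equal(rep$ranking[1], "TDD")
  expect_lte(rep$r2, 1)
  expect_true(all(sort(rep$ranking) == sort(rep$features)))
})

test_that("Shapley attributions are additive and the fit is deterministic", {
  tab <- feature_table(ml_cohort(seed = 61))
  set.seed(2)
  rep <- fit_boosted(tab)
  # additivity: contributions (incl. baseline) sum to the prediction
  gap <- max(abs(rowSums(rep$shap) - rep$prediction))
  expect_lt(gap / max(abs(rep$prediction)), 1e-6)
  set.seed(2)
  rep2 <- fit_boosted(tab)
  expect_identical(rep$prediction, rep2$prediction)
  expect_identical(rep$importance, rep2$importance)
})

test_that("a pure-noise target yields no out-of-sample skill", {
  tab <- feature_table(ml_cohort(seed = 62))
  r2s <- vapply(1:5, function(s) {
    set.seed(s)
    tab$MPA <- rnorm(nrow(tab))
    fit_boosted(tab)$r2
  }, numeric(1))
  expect_true(all(r2s <= 0.1))
})

test_that("degenerate inputs are rejected", {
  tab <- feature_table(ml_cohort(seed = 63))
  tab$MPA <- 1
  expect_error(fit_boosted(tab), "zero variance")
  expect_error(fit_boosted(tab[1:10, ]), "at least 30 rows")
})

test_that("PCA matches a direct eigendecomposition of the correlation matrix", {
  tab <- feature_table(ml_cohort(seed = 64))
  pca <- run_pca(tab, n_components = 3)
  eig <- eigen(cor(as.matrix(tab)), symmetric = TRUE)
  expect_equal(pca$eigenvalues, eig$values, tolerance = 1e-8)
  expect_equal(pca$var_explained, (eig$values / sum(eig$values))[1:3],
               tolerance = 1e-8)
  # loadings orthonormal
  expect_equal(crossprod(pca$loadings), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  # full reconstruction is exact
  x <- scale(as.matrix(tab))
  pc_full <- prcomp(as.matrix(tab), center = TRUE, scale. = TRUE)
  expect_equal(pc_full$x %*% t(pc_full$rotation), unclass(x),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(run_pca(tab, n_components = 99), "exceeds")
})

test_that("two perfectly correlated features load identically on PC1", {
  set.seed(5)
  z <- rnorm(100)
  tab <- data.frame(f1 = z, f2 = 2 * z + 3, f3 = rnorm(100))
  pca <- run_pca(tab, n_components = 3)
  expect_equal(pca$loadings["f1", 1], pca$loadings["f2", 1], tolerance = 1e-10)
  expect_lt(pca$eigenvalues[3], 1e-10)  # the duplicated direction collapses
})

test_that("dose and plasma level align in sign on the first component", {
  tab <- feature_table(dose_driven_cohort(seed = 65))
  pca <- run_pca(tab)
  l1 <- pca$loadings[, 1]
  expect_gt(l1["TDD"] * l1["MPA"], 0)
})

test_that("saliva takes over the ranking when included, dose otherwise", {
  co <- dose_driven_cohort(seed = 66, ratio_cv = 0.1)
  tab <- feature_table(co, include_saliva = TRUE)
  set.seed(3)
  cmp <- compare_with_saliva(tab)
  expect_equal(cmp$ranking_with[1], "SALIVA")
  expect_equal(cmp$ranking_without[1], "TDD")
  # identical seeds give identical paired reports
  set.seed(3)
  cmp2 <- compare_with_saliva(tab)
  expect_identical(cmp$with_saliva$prediction, cmp2$with_saliva$prediction)
  expect_identical(cmp$delta_r2, cmp2$delta_r2)
})

test_that("an uninformative saliva column contributes no skill", {
  co <- ml_cohort(seed = 67)
  tab <- feature_table(co, include_saliva = TRUE)
  set.seed(9)
  tab$SALIVA <- exp(rnorm(nrow(tab)))   # pure noise
  cmp <- compare_with_saliva(tab)
  expect_lt(abs(cmp$delta_r2), 0.35)    # no systematic gain beyond CV noise
  expect_error(compare_with_saliva(tab[, setdiff(names(tab), "SALIVA")]),
               "SALIVA")
})
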