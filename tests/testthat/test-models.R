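# Desk-scale grids so the full suite runs in seconds.
small_grids <- function() {
  list(ridge = lapply(c(0.01, 1), function(l) list(lambda = l)),
       lasso = lapply(c(0.01, 0.5), function(l) list(lambda = l)),
       random_forest = list(list(n_trees = 25L, max_depth = 5)),
       gradient_boosting = list(list(n_rounds = 30L, learning_rate = 0.1,
                                     max_depth = 3L)),
       svm = list(list(C = 1, epsilon = 0.1)),
       neural_network = list(list(hidden = 8L)))
}

test_that("build_features appends exact products on the recorded scale", {
  gen <- toy_cohort(n = 80, seed = 1)
  tbl <- gen$cohort

  raw <- build_features(tbl, target = "GWW", scale_mode = "raw")
  expect_equal(raw$X[, "PSD_LVEF"], tbl$PSD * tbl$LVEF, ignore_attr = TRUE)
  expect_equal(raw$X[, "age_HTN"], tbl$age * tbl$HTN, ignore_attr = TRUE)
  expect_true(all(raw$X[tbl$HTN == 0, "age_HTN"] == 0))

  # explicit raw product: PSD 50 ms x LVEF 60% = 3000
  tbl2 <- tbl; tbl2$PSD[1] <- 50; tbl2$LVEF[1] <- 60
  raw2 <- build_features(tbl2, target = "GWW", scale_mode = "raw")
  expect_equal(unname(raw2$X[1, "PSD_LVEF"]), 3000)

  # z-scored mode: a patient at the PSD mean has PSD_LVEF = 0
  tbl3 <- tbl; tbl3$PSD[1] <- mean(tbl$PSD[-1]) # then recompute below
  z <- build_features(tbl, target = "GWE", scale_mode = "zscored")
  zpsd <- (tbl$PSD - mean(tbl$PSD)) / sd(tbl$PSD)
  zlvef <- (tbl$LVEF - mean(tbl$LVEF)) / sd(tbl$LVEF)
  expect_equal(z$X[, "PSD_LVEF"], zpsd * zlvef, ignore_attr = TRUE)
  expect_equal(mean(z$y), 0, tolerance = 1e-10)

  tbl$PSD[2] <- NA
  expect_error(build_features(tbl, "GWW"), "missing")
  expect_error(build_features(gen$cohort[, 1:4], "GWW"), "missing parent")
})

test_that("evaluate matches hand arithmetic", {
  expect_equal(unname(evaluate(c(1, 2, 3), c(1, 2, 3))), c(1, 0, 0))
  y <- c(1, 2, 3)
  expect_equal(unname(evaluate(rep(mean(y), 3), y)[1]), 0)
  m <- evaluate(c(1, 2, 5), y)
  expect_equal(unname(m), c(-1, sqrt(4 / 3), 2 / 3), tolerance = 1e-12)
  expect_error(evaluate(c(1, 1), c(2, 2)), "zero-variance")
})

test_that("ridge at vanishing penalty equals OLS; lasso at huge penalty is null", {
  set.seed(2)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- X %*% c(1, -2, 0.5, 0) + rnorm(50, 0, 0.1)
  r <- ridge_fit(X, y, lambda = 1e-10)
  ols <- coef(lm(y ~ X))
  expect_equal(unname(r$coefficients), unname(ols[-1]), tolerance = 1e-6)
  expect_equal(r$intercept, unname(ols[1]), tolerance = 1e-6)

  l <- hfpefmed:::lasso_fit(X, as.numeric(y), lambda = 1e3)
  expect_true(all(l$coefficients == 0))
})

test_that("every learner fits and predicts sanely on a smooth target", {
  set.seed(3)
  n <- 120
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- as.numeric(X %*% c(1, -1, 0.5)) + rnorm(n, 0, 0.3)
  idx <- 1:90
  fits <- list(
    forest = forest_fit(X[idx, ], y[idx], n_trees = 40, seed = 1),
    gbm = gbm_fit(X[idx, ], y[idx], n_rounds = 60, seed = 1),
    svr = svr_fit(X[idx, ], y[idx]),
    mlp = mlp_fit(X[idx, ], y[idx], epochs = 300, seed = 1))
  for (nm in names(fits)) {
    m <- evaluate(predict(fits[[nm]], X[-idx, ]), y[-idx])
    expect_gt(m[["r2"]], 0.3)
  }
})

test_that("fit_suite recovers a realizable linear target (R^2 > 0.99)", {
  set.seed(4)
  X <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- as.numeric(X %*% c(1, 2, -1, 0.5))
  rep <- fit_suite(X, y, cv_spec = list(outer_k = 5, repeats = 1, inner_k = 3),
                   seed = 1, algorithms = "ridge", grids = small_grids())
  expect_gt(rep$summary$r2[1], 0.99)
  expect_s3_class(rep$final_model, "linear_model")
})

test_that("fit_suite on pure noise reports near-zero CV R^2", {
  set.seed(5)
  X <- matrix(rnorm(200 * 4), 200, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- rnorm(200)
  rep <- fit_suite(X, y, cv_spec = list(outer_k = 5, repeats = 1, inner_k = 3),
                   seed = 2, algorithms = "ridge", grids = small_grids())
  expect_lt(rep$summary$r2[1], 0.1)
})

test_that("a planted R^2 = 0.6 signal is recovered within 0.1 at n = 150", {
  set.seed(6)
  gen <- toy_cohort(n = 150, seed = 6)
  tbl <- gen$cohort
  # outcome built from PSD with signal fraction 0.6 on the z scale
  zpsd <- scale(tbl$PSD)[, 1]
  tbl$GWW <- sqrt(0.6) * zpsd + rnorm(150, 0, sqrt(0.4))
  fm <- build_features(tbl, target = "GWW")
  rep <- fit_suite(fm, cv_spec = list(outer_k = 5, repeats = 2, inner_k = 3),
                   seed = 3, algorithms = "ridge")
  expect_lt(abs(rep$summary$r2[1] - 0.6), 0.1)
})

test_that("all six algorithms complete a nested-CV pass with valid metrics", {
  set.seed(7)
  gen <- toy_cohort(n = 70, seed = 7)
  fm <- build_features(gen$cohort, target = "GWE")
  rep <- fit_suite(fm, cv_spec = list(outer_k = 3, repeats = 1, inner_k = 2),
                   seed = 4, grids = small_grids())
  expect_setequal(rep$summary$algorithm,
                  c("ridge", "lasso", "random_forest", "gradient_boosting",
                    "svm", "neural_network"))
  expect_true(all(is.finite(rep$summary$rmse)))
  expect_true(all(rep$summary$rmse >= 0))
  expect_true(all(rep$summary$r2 <= 1))
  expect_equal(rep$selected_final, "ridge")

  # determinism
  rep2 <- fit_suite(fm, cv_spec = list(outer_k = 3, repeats = 1, inner_k = 2),
                    seed = 4, grids = small_grids())
  expect_identical(rep$summary, rep2$summary)
})

test_that("nested CV never scores a model on rows its inner selection saw", {
  set.seed(8)
  X <- matrix(rnorm(60 * 3), 60, 3, dimnames = list(NULL, paste0("x", 1:3)))
  y <- rnorm(60)
  rep <- fit_suite(X, y, cv_spec = list(outer_k = 4, repeats = 2, inner_k = 3),
                   seed = 5, algorithms = "ridge", grids = small_grids())
  for (f in rep$folds) {
    expect_length(intersect(f$test_idx, f$inner_idx), 0)
  }
  # outer folds within a repeat partition all rows
  reps <- split(rep$folds, vapply(rep$folds, `[[`, numeric(1), "repeat_i"))
  for (r in reps) {
    expect_setequal(unlist(lapply(r, `[[`, "test_idx")), 1:60)
  }
})
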