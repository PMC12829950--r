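# Engineered feature matrix and the six-algorithm regression suite with
# nested cross-validation.

engineered_terms <- function() {
  list(PSD_LVEF = c("PSD", "LVEF"), age_HTN = c("age", "HTN"),
       eGFR_BNP = c("eGFR", "BNP"), RWT_E_to_e = c("RWT", "E_to_e"),
       GLS_LVMI = c("GLS", "LVMI"))
}

#' Build the engineered feature matrix
#'
#' Appends the five clinically motivated interaction terms (PSD_LVEF,
#' age_HTN, eGFR_BNP, RWT_E_to_e, GLS_LVMI) to the baseline features. In
#' the default `"zscored"` mode continuous parents (and the target) are
#' z-scored *before* the products are taken, so no term dominates a
#' regularized fit; `"raw"` keeps clinical units for sensitivity analysis.
#' Binary columns are never rescaled.
#'
#' @param table Complete cohort data.frame.
#' @param target `"GWW"` or `"GWE"`.
#' @param scale_mode `"zscored"` (default) or `"raw"`.
#' @param base_features Parent features (default [baseline_columns()]).
#' @return `feature_matrix` object: `X` (n x p matrix, engineered columns
#'   last), `y`, `target`, `scale_mode`, `scaling` (means/sds used),
#'   `engineered` (names).
#' @export
build_features <- function(table, target = "GWW", scale_mode = "zscored",
                           base_features = baseline_columns()) {
  terms <- engineered_terms()
  parents <- unique(unlist(terms))
  missing_cols <- setdiff(c(base_features, parents, target), names(table))
  if (length(missing_cols) > 0)
    stopf("missing parent column(s): %s", paste(missing_cols, collapse = ", "))
  d <- table[, unique(c(base_features, parents)), drop = FALSE]
  if (anyNA(d) || anyNA(table[[target]]))
    stopf("feature/target columns contain missing values")
  scaling <- list(means = NULL, sds = NULL)
  if (scale_mode == "zscored") {
    cont <- names(d)[!vapply(d, is_binary, logical(1))]
    z <- zscore(d, cont)
    d <- z$table
    scaling <- list(means = z$means, sds = z$sds)
    y <- (table[[target]] - mean(table[[target]])) / sd(table[[target]])
  } else if (scale_mode == "raw") {
    y <- table[[target]]
  } else stopf("scale_mode must be 'zscored' or 'raw'")
  for (nm in names(terms)) {
    d[[nm]] <- d[[terms[[nm]][1]]] * d[[terms[[nm]][2]]]
  }
  structure(list(X = as.matrix(d[, c(base_features, names(terms))]),
                 y = y, target = target, scale_mode = scale_mode,
                 scaling = scaling, engineered = names(terms)),
            class = "feature_matrix")
}

#' Regression metrics
#'
#' `R^2 = 1 - SS_res / SS_tot`, `RMSE = sqrt(mean residual^2)`,
#' `MAE = mean |residual|`.
#'
#' @param pred Predictions; `y` observed values (non-constant for R^2).
#' @return Named numeric: r2, rmse, mae.
#' @export
evaluate <- function(pred, y) {
  if (var(y) == 0) stopf("zero-variance response; R^2 undefined")
  res <- y - pred
  c(r2 = 1 - sum(res^2) / sum((y - mean(y))^2),
    rmse = sqrt(mean(res^2)), mae = mean(abs(res)))
}

#' Default hyperparameter grids
#'
#' Version-controlled grids for the six algorithms: ridge/lasso penalties
#' log-spaced 1e-3..1e3; forest 200 trees, depth 3/5/unbounded; boosting
#' learning rate 0.01/0.1; RBF-SVR C 0.1/1/10; MLP hidden sizes 8/16.
#'
#' @return Named list of per-algorithm parameter grids.
#' @export
default_grids <- function() {
  list(
    ridge = lapply(10^seq(-3, 3, length.out = 7), function(l) list(lambda = l)),
    lasso = lapply(10^seq(-3, 3, length.out = 7), function(l) list(lambda = l)),
    random_forest = lapply(c(3, 5, Inf), function(d)
      list(n_trees = 200L, max_depth = d)),
    gradient_boosting = lapply(c(0.01, 0.1), function(lr)
      list(n_rounds = 100L, learning_rate = lr, max_depth = 3L)),
    svm = lapply(c(0.1, 1, 10), function(C) list(C = C, epsilon = 0.1)),
    neural_network = lapply(c(8L, 16L), function(h) list(hidden = h))
  )
}

fit_algorithm <- function(alg, X, y, par, seed) {
  switch(alg,
    ridge = ridge_fit(X, y, lambda = par$lambda),
    lasso = lasso_fit(X, y, lambda = par$lambda),
    random_forest = forest_fit(X, y, n_trees = par$n_trees,
                               max_depth = par$max_depth, seed = seed),
    gradient_boosting = gbm_fit(X, y, n_rounds = par$n_rounds,
                                learning_rate = par$learning_rate,
                                max_depth = par$max_depth, seed = seed),
    svm = svr_fit(X, y, C = par$C, epsilon = par$epsilon),
    neural_network = mlp_fit(X, y, hidden = par$hidden, seed = seed),
    stopf("unknown algorithm: %s", alg))
}

make_folds <- function(n, k, seed) {
  set.seed(seed)
  split(sample.int(n), rep_len(seq_len(k), n))
}

#' Fit the six-algorithm suite with nested cross-validation
#'
#' Outer `outer_k`-fold CV repeated `repeats` times; within each outer
#' training fold an inner `inner_k`-fold grid search selects each
#' algorithm's hyperparameters, the algorithm is refit on the whole outer
#' training fold and scored on the held-out outer fold (R^2, RMSE, MAE).
#' No model is ever scored on rows its inner selection saw. The final
#' deployed model is, by declared policy, ridge refit on all data at the
#' modal inner-selected penalty (interpretability over metric-argmax).
#' Everything is seed-deterministic.
#'
#' The published protocol is 5x10 nested CV over all six algorithms; pass a
#' smaller `cv_spec` / `grids` / `algorithms` for desk-scale runs.
#'
#' @param features A `feature_matrix` from [build_features()] (or a plain
#'   matrix, then `target` must be supplied).
#' @param target Response vector when `features` is a matrix.
#' @param cv_spec List: `outer_k` (5), `repeats` (10), `inner_k` (5).
#' @param seed Integer seed.
#' @param algorithms Subset of the six algorithm names.
#' @param grids Hyperparameter grids (default [default_grids()]).
#' @return `model_report` list: per-algorithm per-fold metrics, metric
#'   means, selected hyperparameters, `selected_final = "ridge"`,
#'   `final_model` (`linear_model`), fold index bookkeeping.
#' @export
fit_suite <- function(features, target = NULL,
                      cv_spec = list(outer_k = 5L, repeats = 10L, inner_k = 5L),
                      seed = 42L,
                      algorithms = c("ridge", "lasso", "random_forest",
                                     "gradient_boosting", "svm",
                                     "neural_network"),
                      grids = default_grids()) {
  if (inherits(features, "feature_matrix")) {
    X <- features$X; y <- features$y
  } else {
    X <- as.matrix(features); y <- target
  }
  n <- nrow(X)
  if (n < 30) stopf("need n >= 30, got %d", n)
  if (anyNA(y) || var(y) == 0) stopf("degenerate target")
  cv <- modifyList(list(outer_k = 5L, repeats = 10L, inner_k = 5L), cv_spec)

  per_fold <- list()
  chosen <- list()
  fold_log <- list()
  for (alg in algorithms) per_fold[[alg]] <- list()
  fold_id <- 0L
  for (rep_i in seq_len(cv$repeats)) {
    folds <- make_folds(n, cv$outer_k, derive_seed(seed, rep_i))
    for (fo in seq_len(cv$outer_k)) {
      fold_id <- fold_id + 1L
      test_idx <- folds[[fo]]
      train_idx <- setdiff(seq_len(n), test_idx)
      inner_folds <- make_folds(length(train_idx), cv$inner_k,
                                derive_seed(seed, 100L * rep_i + fo))
      fold_log[[fold_id]] <- list(repeat_i = rep_i, outer_fold = fo,
                                  test_idx = test_idx,
                                  inner_idx = train_idx)
      for (alg in algorithms) {
        grid <- grids[[alg]]
        inner_rmse <- vapply(grid, function(par) {
          errs <- vapply(seq_len(cv$inner_k), function(fi) {
            val <- train_idx[inner_folds[[fi]]]
            tr <- setdiff(train_idx, val)
            mod <- fit_algorithm(alg, X[tr, , drop = FALSE], y[tr], par,
                                 derive_seed(seed, 7L * fold_id + fi))
            sqrt(mean((predict(mod, X[val, , drop = FALSE]) - y[val])^2))
          }, numeric(1))
          mean(errs)
        }, numeric(1))
        best <- which.min(inner_rmse)
        mod <- fit_algorithm(alg, X[train_idx, , drop = FALSE], y[train_idx],
                             grid[[best]], derive_seed(seed, 13L * fold_id))
        met <- evaluate(predict(mod, X[test_idx, , drop = FALSE]), y[test_idx])
        per_fold[[alg]][[fold_id]] <- c(met, fold = fold_id)
        chosen[[alg]] <- c(chosen[[alg]], best)
      }
    }
  }
  metrics <- lapply(per_fold, function(fl) do.call(rbind, fl))
  summary <- do.call(rbind, lapply(algorithms, function(alg) {
    m <- metrics[[alg]]
    data.frame(algorithm = alg, r2 = mean(m[, "r2"]), rmse = mean(m[, "rmse"]),
               mae = mean(m[, "mae"]), stringsAsFactors = FALSE)
  }))
  # Modal inner-selected ridge penalty, refit on all rows: the final model.
  ridge_choice <- if ("ridge" %in% algorithms) {
    tab <- table(chosen[["ridge"]])
    as.integer(names(tab)[which.max(tab)])
  } else 4L
  lam <- grids[["ridge"]][[ridge_choice]]$lambda
  final <- ridge_fit(X, y, lambda = lam)
  structure(list(summary = summary, per_fold = metrics,
                 selected_hyper = chosen, selected_final = "ridge",
                 final_model = final, final_lambda = lam,
                 cv_spec = cv, seed = seed, folds = fold_log,
                 columns = colnames(X)),
            class = "model_report")
}
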