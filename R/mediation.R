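# Per-subtype nonlinear mediation analysis: three nested regressions,
# difference-method indirect effects, mediation ratios, and bias-corrected
# bootstrap confidence intervals.

#' Default mediation covariate set
#'
#' age, sex, HTN, DM, CAD, RD, SBP, DBP, LVMI, LVEF, GLS — the published
#' adjustment set.
#'
#' @return Character vector.
#' @export
mediation_covariates <- function() {
  c("age", "sex", "HTN", "DM", "CAD", "RD", "SBP", "DBP", "LVMI", "LVEF", "GLS")
}

#' Specify one mediation analysis
#'
#' @param exposure,mediator,outcome Column names (exposure and mediator must
#'   not appear among the covariates).
#' @param covariates Adjustment columns (default [mediation_covariates()]).
#' @param include_square Add squared exposure/mediator terms.
#' @param include_interaction Add the exposure x mediator term to Model 3.
#' @param n_boot Bootstrap replicates (>= 200 recommended for inference).
#' @param ci_level Confidence level in (0, 1).
#' @param seed Integer seed.
#' @param subset Optional cluster index restricting the analysis set.
#' @return A validated `mediation_spec` list.
#' @export
mediation_spec <- function(exposure, mediator = "PSD", outcome,
                           covariates = mediation_covariates(),
                           include_square = FALSE,
                           include_interaction = FALSE,
                           n_boot = 1000L, ci_level = 0.95, seed = 1L,
                           subset = NULL) {
  if (exposure %in% covariates)
    stopf("exposure %s must not appear among covariates", exposure)
  if (mediator %in% covariates)
    stopf("mediator %s must not appear among covariates", mediator)
  if (n_boot < 1) stopf("n_boot must be >= 1")
  if (ci_level <= 0 || ci_level >= 1) stopf("ci_level must lie in (0,1)")
  structure(list(exposure = exposure, mediator = mediator, outcome = outcome,
                 covariates = covariates, include_square = include_square,
                 include_interaction = include_interaction,
                 n_boot = as.integer(n_boot), ci_level = ci_level,
                 seed = as.integer(seed), subset = subset),
            class = "mediation_spec")
}

# Analysis-set preparation: subset rows, check completeness, z-score the
# continuous columns (binary flags left untouched) within the subset.
mediation_data <- function(table, spec) {
  if (!is.null(spec$subset)) {
    if (!"cluster" %in% names(table)) stopf("subset requested but no cluster column")
    table <- table[table$cluster == spec$subset, , drop = FALSE]
  }
  cols <- c(spec$exposure, spec$mediator, spec$outcome, spec$covariates)
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols) > 0)
    stopf("column(s) absent: %s", paste(missing_cols, collapse = ", "))
  d <- table[, cols, drop = FALSE]
  if (anyNA(d)) stopf("mediation columns contain missing values; run QC first")
  cont <- cols[!vapply(d, is_binary, logical(1))]
  for (cn in cont) {
    s <- sd(d[[cn]])
    if (s <= 0) stopf("zero-variance column: %s", cn)
    d[[cn]] <- (d[[cn]] - mean(d[[cn]])) / s
  }
  d
}

# Model-matrix builders for the three models. `shift` adds h to the
# exposure column before construction (for numeric partial derivatives).
mm_model1 <- function(d, spec, shift = 0) {
  x <- d[[spec$exposure]] + shift
  X <- cbind(1, x)
  nm <- c("(Intercept)", spec$exposure)
  if (spec$include_square) { X <- cbind(X, x^2); nm <- c(nm, paste0(spec$exposure, "^2")) }
  for (cv in spec$covariates) { X <- cbind(X, d[[cv]]); nm <- c(nm, cv) }
  colnames(X) <- nm
  X
}

mm_model3 <- function(d, spec, shift = 0) {
  x <- d[[spec$exposure]] + shift
  m <- d[[spec$mediator]]
  X <- cbind(1, x, m)
  nm <- c("(Intercept)", spec$exposure, spec$mediator)
  if (spec$include_square) {
    X <- cbind(X, x^2, m^2)
    nm <- c(nm, paste0(spec$exposure, "^2"), paste0(spec$mediator, "^2"))
  }
  if (spec$include_interaction) {
    X <- cbind(X, x * m)
    nm <- c(nm, paste(spec$exposure, spec$mediator, sep = ":"))
  }
  for (cv in spec$covariates) { X <- cbind(X, d[[cv]]); nm <- c(nm, cv) }
  colnames(X) <- nm
  X
}

ols_fit <- function(X, y) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    drop <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stopf("rank-deficient design; collinear column(s): %s",
          paste(drop, collapse = ", "))
  }
  beta <- qr.coef(qr_x, y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qr_x))
  se <- sqrt(diag(XtXinv) * sigma2)
  names(se) <- colnames(X)
  list(coef = beta, se = se, residuals = as.numeric(res), sigma2 = sigma2)
}

# Average partial derivative of X(d) %*% beta w.r.t. the exposure,
# numerically with step h (0.01 SD). Collapses to the exposure coefficient
# in the linear case.
apd_exposure <- function(builder, d, spec, beta, h = 0.01) {
  X0 <- builder(d, spec, shift = 0)
  X1 <- builder(d, spec, shift = h)
  mean((X1 - X0) %*% beta) / h
}

#' Fit the three mediation models
#'
#' Model 1: outcome ~ exposure + covariates (total effect c);
#' Model 2: mediator ~ exposure + covariates (path a);
#' Model 3: outcome ~ exposure + mediator + covariates (direct effect c'
#' and mediator path b). Squared and interaction terms are appended when
#' the spec requests them. All continuous variables are z-scored within the
#' analysis subset, so coefficients are per-SD effects.
#'
#' @param table Cohort data.frame.
#' @param spec A [mediation_spec()].
#' @return List with `data` (standardized analysis set), per-model `coef` /
#'   `se`, and `n_used`.
#' @export
fit_three_models <- function(table, spec) {
  d <- mediation_data(table, spec)
  n <- nrow(d)
  p <- length(spec$covariates) + 3 + 2 * spec$include_square + spec$include_interaction
  if (n <= p + 5) stopf("n (%d) too small for %d regressors", n, p)
  X1 <- mm_model1(d, spec)
  X3 <- mm_model3(d, spec)
  y <- d[[spec$outcome]]
  m <- d[[spec$mediator]]
  f1 <- ols_fit(X1, y)
  f2 <- ols_fit(X1, m)   # Model 2 shares the Model-1 design, target = mediator
  f3 <- ols_fit(X3, y)
  list(data = d, spec = spec, n_used = n,
       model1 = f1, model2 = f2, model3 = f3)
}

#' Point estimates of total, direct and indirect effects
#'
#' The total effect `c` is the exposure effect in Model 1 and the direct
#' effect `c'` the exposure effect in Model 3; both are average partial
#' derivatives over the sample (numeric step 0.01 SD), which reduce to the
#' plain coefficients in the linear case. Indirect = c - c' (difference
#' method); with shared covariates and no nonlinear terms this equals the
#' product of coefficients a*b exactly. Mediation ratio = indirect / c,
#' reported as `NA` with `ratio_undefined = TRUE` when |c| < 1e-12, and
#' flagged `ratio_over_100` when inconsistent mediation pushes it past 1.
#'
#' @param models Output of [fit_three_models()].
#' @return List: `total_effect`, `direct_effect`, `indirect_effect`,
#'   `mediation_ratio`, `path_a`, `path_b`, flags, `n_used`.
#' @export
indirect_effect <- function(models) {
  spec <- models$spec
  d <- models$data
  cc <- apd_exposure(mm_model1, d, spec, models$model1$coef)
  cp <- apd_exposure(mm_model3, d, spec, models$model3$coef)
  ind <- cc - cp
  a <- models$model2$coef[spec$exposure]
  b <- models$model3$coef[spec$mediator]
  undefined <- abs(cc) < 1e-12
  ratio <- if (undefined) NA_real_ else ind / cc
  list(total_effect = cc, direct_effect = cp, indirect_effect = ind,
       mediation_ratio = ratio, ratio_undefined = undefined,
       ratio_over_100 = isTRUE(!undefined && abs(ratio) > 1),
       path_a = unname(a), path_b = unname(b), n_used = models$n_used)
}

# Bias-corrected percentile interval: z0 from the fraction of replicates
# below the point estimate (clamped off 0/1), endpoints at the
# pnorm(2 z0 +/- z_{alpha/2}) percentiles. With exactly half the
# replicates below the estimate, z0 = 0 and the interval is the plain
# percentile interval.
bc_interval <- function(boot, point, ci_level) {
  B <- length(boot)
  frac <- mean(boot < point)
  frac <- min(max(frac, 1 / (B + 1)), B / (B + 1))
  z0 <- qnorm(frac)
  alpha <- 1 - ci_level
  zq <- qnorm(c(alpha / 2, 1 - alpha / 2))
  probs <- pnorm(2 * z0 + zq)
  list(z0 = z0, probs = probs,
       ci = unname(quantile(boot, probs, type = 7)))
}

#' Bias-corrected bootstrap CI for the indirect effect
#'
#' Resamples rows of the analysis set with replacement and replays the
#' *full* estimation pipeline on each replicate — re-standardizing the
#' continuous variables within the resample before refitting Models 1 and
#' 3 — so the replicate distribution reflects the standardized estimator
#' actually reported (z-scoring within each replicate also makes the
#' average partial derivative equal the exposure coefficient exactly,
#' including under squared/interaction terms). The bias-corrected
#' interval: with `z0 = qnorm(fraction of replicates below the point
#' estimate)` the CI endpoints are the `pnorm(2 z0 +/- z_{alpha/2})`
#' percentiles of the replicate distribution. Replicates whose fits fail
#' (rank-deficient resample) are dropped and counted; more than 10%
#' failures aborts.
#'
#' @param table Cohort data.frame.
#' @param spec A [mediation_spec()].
#' @return A `mediation_result` list: point effects, ratio, bootstrap
#'   summary, `ci_lower`, `ci_upper`, `z0`, `significant`, `n_used`,
#'   `n_boot_failed`.
#' @export
bootstrap_ci <- function(table, spec) {
  models <- fit_three_models(table, spec)
  pt <- indirect_effect(models)
  d <- models$data
  n <- nrow(d)
  # raw numeric matrix of all involved columns; continuous ones are
  # re-standardized inside every replicate
  cols <- c(spec$exposure, spec$mediator, spec$outcome, spec$covariates)
  M <- as.matrix(d[, cols, drop = FALSE])
  cont <- vapply(cols, function(cn) !is_binary(d[[cn]]), logical(1))
  i_x <- 1L; i_m <- 2L; i_y <- 3L
  i_cov <- if (length(cols) > 3) 4:length(cols) else integer(0)
  ones <- rep(1, n)
  p1 <- 2L + spec$include_square + length(i_cov)
  p3 <- 3L + 2L * spec$include_square + spec$include_interaction +
    length(i_cov)
  set.seed(spec$seed)
  boot <- rep(NA_real_, spec$n_boot)
  for (bi in seq_len(spec$n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    Mb <- M[idx, , drop = FALSE]
    ok <- TRUE
    for (j in which(cont)) {
      s <- sd(Mb[, j])
      if (s <= 0) { ok <- FALSE; break }
      Mb[, j] <- (Mb[, j] - mean(Mb[, j])) / s
    }
    if (!ok) next
    x <- Mb[, i_x]; m <- Mb[, i_m]; y <- Mb[, i_y]
    Xc <- Mb[, i_cov, drop = FALSE]
    X1b <- if (spec$include_square) cbind(ones, x, x^2, Xc) else
      cbind(ones, x, Xc)
    X3b <- cbind(ones, x, m)
    if (spec$include_square) X3b <- cbind(X3b, x^2, m^2)
    if (spec$include_interaction) X3b <- cbind(X3b, x * m)
    if (length(i_cov)) X3b <- cbind(X3b, Xc)
    b1 <- tryCatch(.lm.fit(X1b, y), error = function(e) NULL)
    b3 <- tryCatch(.lm.fit(X3b, y), error = function(e) NULL)
    if (is.null(b1) || is.null(b3) || b1$rank < p1 || b3$rank < p3) next
    # within-replicate z-scoring makes the APD equal the coefficient
    boot[bi] <- b1$coefficients[2] - b3$coefficients[2]
  }
  failed <- sum(is.na(boot))
  if (failed > 0.1 * spec$n_boot)
    stopf("bootstrap: %d/%d replicates failed to fit", failed, spec$n_boot)
  boot <- boot[!is.na(boot)]
  B <- length(boot)
  bc <- bc_interval(boot, pt$indirect_effect, spec$ci_level)
  z0 <- bc$z0
  ci <- bc$ci
  structure(c(pt, list(
    boot_mean = mean(boot), boot_sd = sd(boot), n_boot = B,
    n_boot_failed = failed, z0 = z0,
    ci_lower = ci[1], ci_upper = ci[2],
    significant = ci[1] > 0 || ci[2] < 0,
    exposure = spec$exposure, mediator = spec$mediator,
    outcome = spec$outcome, subset = spec$subset)),
    class = "mediation_result")
}

#' Mediation grid over subtypes, exposures and outcomes
#'
#' Runs [bootstrap_ci()] independently within each subtype for every
#' exposure x outcome cell (mediator fixed, PSD by default) — the published
#' per-subtype protocol with eGFR/BNP as exposures and GWW/GWE as outcomes.
#' When the exposure is eGFR the near-collinear RD flag is dropped from the
#' covariates with a warning. Subtypes too small for a cell are skipped
#' with the reason recorded.
#'
#' @param table Cohort data.frame.
#' @param labels Cluster labels (one per row of `table`).
#' @param exposures,outcomes Character vectors of columns.
#' @param mediator Mediator column (default "PSD").
#' @param covariates Adjustment set.
#' @param n_boot,ci_level,seed,include_square,include_interaction Passed to
#'   each cell's [mediation_spec()].
#' @return A `mediation_grid` list: `results` (long data.frame, one row per
#'   cell: effects, ratio, CI, n, significant), `indirect_matrix` and
#'   `ratio_matrix` (heatmap tables, rows = subtype x exposure, cols =
#'   outcomes), `skipped`.
#' @export
run_grid <- function(table, labels, exposures = c("eGFR", "BNP"),
                     outcomes = c("GWW", "GWE"), mediator = "PSD",
                     covariates = mediation_covariates(),
                     n_boot = 1000L, ci_level = 0.95, seed = 42L,
                     include_square = FALSE, include_interaction = FALSE) {
  table$cluster <- labels
  subtypes <- sort(unique(labels))
  rows <- list(); skipped <- list()
  for (st in subtypes) {
    for (ex in exposures) {
      covs <- setdiff(covariates, c(ex, mediator))
      if (ex == "eGFR" && "RD" %in% covs) {
        warnf("dropping RD from covariates (near-collinear with exposure eGFR)")
        covs <- setdiff(covs, "RD")
      }
      # binary covariates nearly constant within this subtype would make a
      # large share of bootstrap resamples rank-deficient; drop them
      sub_rows <- table[labels == st, , drop = FALSE]
      sparse <- covs[vapply(covs, function(cv) {
        x <- sub_rows[[cv]]
        is_binary(x) && min(sum(x == 0), sum(x == 1)) < 5
      }, logical(1))]
      if (length(sparse) > 0) {
        warnf("subtype %s: dropping near-constant covariate(s) %s",
              st, paste(sparse, collapse = ", "))
        covs <- setdiff(covs, sparse)
      }
      for (oc in outcomes) {
        n_st <- sum(labels == st)
        need <- length(covs) + 10
        if (n_st < need) {
          skipped[[length(skipped) + 1]] <- data.frame(
            subtype = st, exposure = ex, outcome = oc,
            reason = sprintf("n=%d < %d", n_st, need))
          next
        }
        spec <- mediation_spec(ex, mediator, oc, covs,
                               include_square = include_square,
                               include_interaction = include_interaction,
                               n_boot = n_boot, ci_level = ci_level,
                               seed = derive_seed(seed, st * 100 +
                                                    match(ex, exposures) * 10 +
                                                    match(oc, outcomes)),
                               subset = st)
        r <- bootstrap_ci(table, spec)
        rows[[length(rows) + 1]] <- data.frame(
          subtype = st, exposure = ex, mediator = mediator, outcome = oc,
          total = r$total_effect, direct = r$direct_effect,
          indirect = r$indirect_effect, ratio = r$mediation_ratio,
          ci_lower = r$ci_lower, ci_upper = r$ci_upper,
          n = r$n_used, significant = r$significant)
      }
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else NULL
  grid <- list(results = results,
               skipped = if (length(skipped)) do.call(rbind, skipped) else NULL)
  if (!is.null(results)) {
    key <- paste(results$subtype, results$exposure, sep = ":")
    grid$indirect_matrix <- tapply(results$indirect,
                                   list(key, results$outcome), identity)
    grid$ratio_matrix <- tapply(results$ratio,
                                list(key, results$outcome), identity)
  }
  class(grid) <- "mediation_grid"
  grid
}
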