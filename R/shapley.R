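# Shapley additive attributions: closed form for linear models,
# permutation sampling with interventional (reference-replacement)
# marginalization otherwise; rankings and dependence profiles.

new_attribution <- function(base_value, values) {
  fo <- rank_order(values)
  structure(list(base_value = base_value, values = values,
                 feature_order = fo),
            class = "attribution_matrix")
}

rank_order <- function(values) {
  imp <- colMeans(abs(values))
  nm <- colnames(values)
  nm[order(-imp, nm)]
}

#' Exact Shapley values for a linear model
#'
#' For an additive linear model the Shapley attribution of feature j on row
#' i is `beta_j * (x_ij - mean_ref(x_j))` and the base value is the model
#' prediction at the reference means — local accuracy holds to machine
#' precision.
#'
#' @param model List with `intercept` and named `coefficients` (one per
#'   column of `X`).
#' @param X Numeric matrix of rows to explain.
#' @param reference Numeric matrix, the background sample (typically the
#'   training rows).
#' @return An `attribution_matrix`: `base_value`, `values` (n x p),
#'   `feature_order`.
#' @export
shapley_exact_linear <- function(model, X, reference) {
  X <- as.matrix(X); reference <- as.matrix(reference)
  if (nrow(reference) == 0) stopf("reference sample is empty")
  beta <- model$coefficients[colnames(X)]
  if (anyNA(beta)) stopf("model lacks coefficients for some features")
  mu <- colMeans(reference)[colnames(X)]
  vals <- sweep(X, 2, mu, "-") %*% diag(beta, length(beta))
  colnames(vals) <- colnames(X)
  base <- model$intercept + sum(beta * mu)
  new_attribution(base, vals)
}

#' Sampling Shapley values for an arbitrary prediction function
#'
#' Permutation-sampling estimator with interventional marginalization: for
#' each sampled permutation a reference row is drawn and features are
#' switched from the reference value to the explained row's value in
#' permutation order; the prediction increments are the marginal
#' contributions. Unbiased in expectation, seed-deterministic; the Monte
#' Carlo error of each attribution (and of local accuracy) shrinks as
#' `1/sqrt(n_perm)`.
#'
#' @param predict_fn Function mapping a numeric matrix to predictions.
#' @param X Rows to explain (numeric matrix with column names).
#' @param reference Background sample matrix.
#' @param n_perm Permutations per explained row (>= 1).
#' @param n_ref Reference draws averaged per permutation (variance
#'   reduction; total chains per row = `n_perm * n_ref`).
#' @param seed Integer seed.
#' @return An `attribution_matrix` with `base_value` = mean prediction over
#'   the full reference sample.
#' @export
shapley_sampling <- function(predict_fn, X, reference, n_perm = 200L,
                             n_ref = 10L, seed = 1L) {
  X <- as.matrix(X); reference <- as.matrix(reference)
  if (n_perm < 1) stopf("n_perm must be >= 1")
  p <- ncol(X)
  n <- nrow(X)
  base <- mean(predict_fn(reference))
  if (!all(is.finite(base))) stopf("non-finite predictions on reference")
  vals <- matrix(0, n, p, dimnames = list(NULL, colnames(X)))
  set.seed(seed)
  n_chain <- n_perm * n_ref
  for (i in seq_len(n)) {
    perms <- replicate(n_perm, sample.int(p), simplify = FALSE)
    zidx <- sample.int(nrow(reference), n_chain, replace = TRUE)
    # Batch all intermediate points: n_chain blocks of (p + 1) rows each.
    pts <- matrix(0, n_chain * (p + 1), p)
    for (k in seq_len(n_chain)) {
      perm <- perms[[(k - 1) %/% n_ref + 1]]
      cur <- reference[zidx[k], ]
      off <- (k - 1) * (p + 1)
      pts[off + 1, ] <- cur
      for (s in seq_len(p)) {
        cur[perm[s]] <- X[i, perm[s]]
        pts[off + 1 + s, ] <- cur
      }
    }
    colnames(pts) <- colnames(X)
    pr <- predict_fn(pts)
    if (!all(is.finite(pr))) stopf("non-finite predictions during sampling")
    contrib <- numeric(p)
    for (k in seq_len(n_chain)) {
      perm <- perms[[(k - 1) %/% n_ref + 1]]
      off <- (k - 1) * (p + 1)
      inc <- diff(pr[(off + 1):(off + p + 1)])
      contrib[perm] <- contrib[perm] + inc
    }
    vals[i, ] <- contrib / n_chain
  }
  new_attribution(base, vals)
}

#' Feature importance ranking
#'
#' Features in descending order of mean absolute attribution; ties break
#' alphabetically.
#'
#' @param attr An `attribution_matrix`.
#' @return data.frame: `feature`, `mean_abs_attribution`, in rank order.
#' @export
rank_features <- function(attr) {
  imp <- colMeans(abs(attr$values))
  ord <- order(-imp, names(imp))
  data.frame(feature = names(imp)[ord],
             mean_abs_attribution = unname(imp[ord]),
             stringsAsFactors = FALSE)
}

#' Dependence profile of one feature
#'
#' Pairs each feature value with its attribution (sorted by the feature)
#' and reports the Pearson correlation `r` (and `r^2`) between them — the
#' scale on which published dependence plots quantify (non)linearity.
#'
#' @param attr An `attribution_matrix`.
#' @param X The matrix the attributions were computed on.
#' @param feature Column name.
#' @return List: `profile` (data.frame x/attribution sorted by x), `r`,
#'   `r_squared` (`NA` with `constant = TRUE` for a constant feature).
#' @export
dependence_profile <- function(attr, X, feature) {
  X <- as.matrix(X)
  if (!feature %in% colnames(X)) stopf("feature %s not in X", feature)
  x <- X[, feature]
  a <- attr$values[, feature]
  if (sd(x) == 0) {
    return(list(profile = data.frame(x = x, attribution = a)[order(x), ],
                r = NA_real_, r_squared = NA_real_, constant = TRUE))
  }
  r <- if (sd(a) == 0) 0 else cor(x, a)
  ord <- order(x)
  list(profile = data.frame(x = x[ord], attribution = a[ord]),
       r = r, r_squared = r^2, constant = FALSE)
}
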