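# Patient subtyping: k-means (k-means++ / Lloyd) with restarts, silhouette
# k-selection, PCA variance accounting, bootstrap ARI stability, and
# Table-1-style two-group comparison.

# Squared Euclidean distances from every row of X to every row of C.
sqdist_to_centers <- function(X, C) {
  xx <- rowSums(X^2)
  cc <- rowSums(C^2)
  outer(xx, cc, "+") - 2 * X %*% t(C)
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- sqdist_to_centers(X, centers[1, , drop = FALSE])[, 1]
  for (j in seq_len(k - 1)) {
    p <- pmax(d2, 0)
    if (sum(p) <= 0) p <- rep(1, n)
    centers[j + 1, ] <- X[sample.int(n, 1, prob = p), ]
    d2 <- pmin(d2, sqdist_to_centers(X, centers[j + 1, , drop = FALSE])[, 1])
  }
  centers
}

lloyd <- function(X, centers, max_iter = 300L) {
  n <- nrow(X); k <- nrow(centers)
  labels <- rep(0L, n)
  reseeds <- 0L
  for (it in seq_len(max_iter)) {
    D <- sqdist_to_centers(X, centers)
    new_labels <- max.col(-D, ties.method = "first")
    # Empty cluster: re-seed its centroid at the point farthest from its
    # assigned centroid (logged via reseeds counter).
    for (j in seq_len(k)) {
      if (!any(new_labels == j)) {
        far <- which.max(D[cbind(seq_len(n), new_labels)])
        centers[j, ] <- X[far, ]
        new_labels[far] <- j
        reseeds <- reseeds + 1L
      }
    }
    converged <- all(new_labels == labels) && it > 1
    labels <- new_labels
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(X[labels == j, , drop = FALSE])
    }
    if (converged) break
  }
  D <- sqdist_to_centers(X, centers)
  labels <- max.col(-D, ties.method = "first")
  inertia <- sum(D[cbind(seq_len(n), labels)])
  list(labels = labels, centers = centers, inertia = inertia,
       iterations = it, reseeds = reseeds)
}

#' Fit k-means with k-means++ restarts
#'
#' Lloyd's algorithm with k-means++ initialization, best of `n_init`
#' restarts by within-cluster sum of squares; deterministic given `seed`.
#' Empty clusters are re-seeded at the farthest point (count reported).
#'
#' @param X Numeric matrix (rows = patients), typically z-scored.
#' @param k Number of clusters (>= 2).
#' @param n_init Number of restarts (default 10).
#' @param seed Integer seed.
#' @param max_iter Lloyd iteration cap (default 300).
#' @return An object of class `cluster_result`: `k`, `labels` (0-based),
#'   `centroids` (k x p, z-space), `inertia`, `iterations`, `reseeds`,
#'   `seed`.
#' @export
kmeans_fit <- function(X, k, n_init = 10L, seed = 1L, max_iter = 300L) {
  X <- as.matrix(X)
  if (k <= 1) stopf("k must be >= 2, got %d", k)
  if (nrow(X) <= k) stopf("need more points (%d) than clusters (%d)", nrow(X), k)
  if (anyNA(X)) stopf("X contains missing values")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_init)) {
    fit <- lloyd(X, kmeanspp_init(X, k), max_iter)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  structure(list(k = k, labels = best$labels - 1L, centroids = best$centers,
                 inertia = best$inertia, iterations = best$iterations,
                 reseeds = best$reseeds, seed = seed),
            class = "cluster_result")
}

#' Mean silhouette score
#'
#' Mean over points of `(b - a) / max(a, b)` with Euclidean distances;
#' singleton clusters score 0 for their point.
#'
#' @param X Numeric matrix.
#' @param labels Cluster labels (any coding; >= 2 non-empty clusters).
#' @return Mean silhouette width.
#' @export
silhouette_mean <- function(X, labels) {
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2) stopf("silhouette needs >= 2 clusters")
  if (length(labels) < 3) stopf("silhouette needs n >= 3")
  sil <- cluster::silhouette(labels, dist(as.matrix(X)))
  mean(sil[, "sil_width"])
}

#' Silhouette-based k selection
#'
#' Computes the mean silhouette for each candidate `k`, refitting k-means
#' per candidate; ties (within `tol`) break toward smaller k (parsimony).
#'
#' @inheritParams kmeans_fit
#' @param ks Candidate cluster counts (default 2:6).
#' @param tol Tie tolerance on the silhouette scale.
#' @return List: `k` (selected), `silhouette_by_k` (named vector).
#' @export
select_k <- function(X, ks = 2:6, n_init = 10L, seed = 1L, tol = 1e-8) {
  scores <- vapply(ks, function(k) {
    fit <- kmeans_fit(X, k, n_init = n_init, seed = derive_seed(seed, k))
    silhouette_mean(X, fit$labels)
  }, numeric(1))
  names(scores) <- ks
  best <- ks[which(scores >= max(scores) - tol)[1]]
  list(k = best, silhouette_by_k = scores)
}

#' PCA variance fractions
#'
#' Eigenvalues of the covariance of `X`, each divided by their sum.
#' Rank-deficient inputs zero-pad the trailing fractions. 2-D projection
#' coordinates are returned for plotting.
#'
#' @param X Numeric matrix (z-scored for the subtyping use).
#' @return List: `fractions` (length p, non-increasing, sums to 1),
#'   `scores2d` (n x 2 projection).
#' @export
pca_variance <- function(X) {
  X <- as.matrix(X)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  fr <- rep(0, ncol(X))
  fr[seq_along(ev)] <- ev / sum(ev)
  sc <- pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE]
  list(fractions = fr, scores2d = sc)
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions from the pair-counting
#' contingency table; 1 for identical partitions (up to relabeling), ~0 for
#' independent ones.
#'
#' @param a,b Two label vectors of equal length.
#' @return ARI in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stopf("label vectors differ in length")
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (abs(maxi - expected) < .Machine$double.eps) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Bootstrap stability of a clustering
#'
#' For each iteration: resample rows with replacement, refit k-means,
#' assign *all* original points to the nearest resampled centroid, and
#' compute the ARI of that predicted partition against the reference
#' partition (the prediction-strength construction; ARI is invariant to
#' label permutation, so no explicit relabeling is needed).
#'
#' @inheritParams kmeans_fit
#' @param n_boot Number of bootstrap iterations (published protocol: 1000).
#' @param reference Optional `cluster_result` to test against; default fits
#'   one from the same seed.
#' @return Numeric vector of `n_boot` ARI values.
#' @export
bootstrap_stability <- function(X, k, n_boot = 100L, seed = 1L,
                                n_init = 5L, reference = NULL) {
  X <- as.matrix(X)
  if (n_boot < 1) stopf("n_boot must be >= 1")
  if (is.null(reference)) reference <- kmeans_fit(X, k, n_init = 10L, seed = seed)
  n <- nrow(X)
  vapply(seq_len(n_boot), function(bi) {
    set.seed(derive_seed(seed, 1000L + bi))
    idx <- sample.int(n, n, replace = TRUE)
    fit <- kmeans_fit(X[idx, , drop = FALSE], k, n_init = n_init,
                      seed = derive_seed(seed, 2000L + bi))
    D <- sqdist_to_centers(X, fit$centroids)
    pred <- max.col(-D, ties.method = "first")
    adjusted_rand_index(pred, reference$labels)
  }, numeric(1))
}

#' Full subtyping run
#'
#' Z-scores the clustering variables, selects k by silhouette (or uses a
#' fixed k), fits k-means, and attaches PCA variance fractions and
#' bootstrap ARI stability.
#'
#' @param table Cohort data.frame with the clustering variables complete.
#' @param vars Clustering variables (default [clustering_variables()]).
#' @param k Fixed k, or `"auto"` for silhouette selection over 2:6.
#' @param n_boot Bootstrap stability iterations.
#' @param seed Integer seed.
#' @return `cluster_result` augmented with `silhouette_by_k`,
#'   `pca_variance_fractions`, `pca_scores`, `stability_ari`, `vars`,
#'   `scaling` (means/sds).
#' @export
subtype_cohort <- function(table, vars = clustering_variables(), k = "auto",
                           n_boot = 100L, seed = 42L) {
  z <- zscore(table, vars)
  X <- as.matrix(z$table[, vars])
  if (identical(k, "auto")) {
    sel <- select_k(X, seed = seed)
    k <- sel$k
    sil <- sel$silhouette_by_k
  } else {
    sil <- setNames(NA_real_, k)
  }
  fit <- kmeans_fit(X, k, seed = seed)
  if (is.na(sil[1])) {
    sil <- setNames(silhouette_mean(X, fit$labels), k)
  }
  pv <- pca_variance(X)
  fit$silhouette_by_k <- sil
  fit$pca_variance_fractions <- pv$fractions
  fit$pca_scores <- pv$scores2d
  fit$stability_ari <- if (n_boot > 0)
    bootstrap_stability(X, k, n_boot = n_boot, seed = seed, reference = fit)
  else numeric(0)
  fit$vars <- vars
  fit$scaling <- list(means = z$means, sds = z$sds)
  fit
}

summary_mean_sd <- function(x) sprintf("%.1f ± %.1f", mean(x), sd(x))
summary_median_iqr <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7)
  sprintf("%.1f (%.1f–%.1f)", q[2], q[1], q[3])
}

#' Two-group comparison table (Table-1 style)
#'
#' For each continuous variable, a Shapiro-Wilk normality gate (alpha 0.05
#' in both groups) chooses a Welch t-test (reported mean +/- sd) or a
#' Mann-Whitney U test (median \[Q1-Q3\]). Binary variables get a
#' chi-square test, switching to Fisher's exact test when any expected cell
#' count is below 5 (reported n (%)). Constant variables are flagged and
#' skipped.
#'
#' @param table Cohort data.frame.
#' @param labels Two-group labels (each group n >= 3).
#' @param variables Variables to compare; default all numeric + binary
#'   cohort columns present.
#' @return data.frame: variable, type, group summaries, test, statistic,
#'   p_value.
#' @export
compare_clusters <- function(table, labels, variables = NULL) {
  groups <- sort(unique(labels))
  if (length(groups) != 2) stopf("exactly 2 groups required, got %d", length(groups))
  if (min(table(labels)) < 3) stopf("each group needs n >= 3")
  if (is.null(variables)) {
    variables <- intersect(c(cohort_numeric_columns(), cohort_binary_columns()),
                           names(table))
  }
  rows <- lapply(variables, function(v) {
    x <- table[[v]]
    g1 <- x[labels == groups[1]]; g2 <- x[labels == groups[2]]
    if (length(unique(x)) < 2) {
      return(data.frame(variable = v, type = "constant",
                        summary_0 = as.character(x[1]), summary_1 = as.character(x[1]),
                        test = "skipped (constant)", statistic = NA_real_,
                        p_value = NA_real_, stringsAsFactors = FALSE))
    }
    if (is_binary(x)) {
      tab <- rbind(c(sum(g1 == 1), sum(g1 == 0)), c(sum(g2 == 1), sum(g2 == 0)))
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        tst <- fisher.test(tab)
        test <- "Fisher exact"; statv <- NA_real_
      } else {
        tst <- suppressWarnings(chisq.test(tab, correct = TRUE))
        test <- "Chi-square"; statv <- unname(tst$statistic)
      }
      s1 <- sprintf("%d (%.1f)", sum(g1 == 1), 100 * mean(g1 == 1))
      s2 <- sprintf("%d (%.1f)", sum(g2 == 1), 100 * mean(g2 == 1))
      return(data.frame(variable = v, type = "binary", summary_0 = s1,
                        summary_1 = s2, test = test, statistic = statv,
                        p_value = tst$p.value, stringsAsFactors = FALSE))
    }
    normal <- function(g) {
      if (length(unique(g)) < 3) return(FALSE)
      shapiro.test(g)$p.value >= 0.05
    }
    if (normal(g1) && normal(g2)) {
      tst <- t.test(g1, g2)
      data.frame(variable = v, type = "continuous",
                 summary_0 = summary_mean_sd(g1), summary_1 = summary_mean_sd(g2),
                 test = "Welch t", statistic = unname(tst$statistic),
                 p_value = tst$p.value, stringsAsFactors = FALSE)
    } else {
      tst <- suppressWarnings(wilcox.test(g1, g2))
      data.frame(variable = v, type = "continuous",
                 summary_0 = summary_median_iqr(g1), summary_1 = summary_median_iqr(g2),
                 test = "Mann-Whitney U", statistic = unname(tst$statistic),
                 p_value = tst$p.value, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
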