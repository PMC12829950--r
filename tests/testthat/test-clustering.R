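test_that("k-means recovers separable clouds exactly", {
  set.seed(1)
  X <- rbind(matrix(rnorm(60, 0, 0.3), ncol = 2),
             matrix(rnorm(60, 10, 0.3), ncol = 2))
  truth <- rep(0:1, each = 30)
  fit <- kmeans_fit(X, 2, seed = 1)
  expect_equal(adjusted_rand_index(fit$labels, truth), 1)
  expect_error(kmeans_fit(X, 1), "k must be")
})

test_that("k-means matches the brute-force optimum on the 1-D instance", {
  X <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1)
  oracle <- brute_force_kmeans2(X)
  fit <- kmeans_fit(X, 2, seed = 3)
  expect_equal(fit$inertia, oracle$inertia)      # brute force says 4
  expect_equal(oracle$inertia, 4)
  expect_setequal(as.numeric(fit$centroids), c(1, 11))
})

test_that("k-means inertia is the best over restarts and never worse than one", {
  set.seed(2)
  X <- matrix(rnorm(200), ncol = 2)
  multi <- kmeans_fit(X, 3, n_init = 20, seed = 5)
  single <- kmeans_fit(X, 3, n_init = 1, seed = 6)
  expect_lte(multi$inertia, single$inertia + 1e-10)
})

test_that("silhouette matches the hand-expanded 4-point case", {
  X <- matrix(c(0, 1, 10, 11), ncol = 1)
  lab <- c(0, 0, 1, 1)
  # hand computation: a(0)=1, b(0)=(10+11)/2 -> s=9.5/10.5, etc.
  s0 <- (10.5 - 1) / 10.5; s1 <- (9.5 - 1) / 9.5
  expect_equal(silhouette_mean(X, lab), mean(c(s0, s1, s1, s0)))

  set.seed(3)
  far <- rbind(matrix(rnorm(100, 0, 0.2), ncol = 2),
               matrix(rnorm(100, 50, 0.2), ncol = 2))
  expect_gt(silhouette_mean(far, rep(1:2, each = 50)), 0.9)

  blob <- matrix(rnorm(1000), ncol = 2)
  expect_lt(abs(silhouette_mean(blob, sample(1:2, 500, TRUE))), 0.1)

  expect_error(silhouette_mean(X, rep(1, 4)), "2 clusters")
})

test_that("pca_variance handles duplication, isotropy and normalization", {
  set.seed(4)
  x <- rnorm(100)
  dup <- cbind(x, x)
  fr <- pca_variance(dup)$fractions
  expect_equal(fr, c(1, 0), tolerance = 1e-12)

  iso <- matrix(rnorm(3e5), ncol = 3)
  fr3 <- pca_variance(iso)$fractions
  expect_equal(fr3, rep(1 / 3, 3), tolerance = 0.01)

  any_x <- matrix(rnorm(200), ncol = 4)
  expect_equal(sum(pca_variance(any_x)$fractions), 1, tolerance = 1e-10)
})

test_that("ARI matches closed-form cases and the pair-counting oracle", {
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(0, 1, 1, 1)), 0)
  set.seed(5)
  for (i in 1:10) {
    a <- sample(0:2, 12, TRUE); b <- sample(0:2, 12, TRUE)
    expect_equal(adjusted_rand_index(a, b), ari_oracle(a, b), tolerance = 1e-12)
    expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(b, a))
  }
})

test_that("bootstrap stability separates structure from noise", {
  set.seed(6)
  sep <- rbind(matrix(rnorm(100, 0, 0.2), ncol = 2),
               matrix(rnorm(100, 10, 0.2), ncol = 2))
  ari_sep <- bootstrap_stability(sep, 2, n_boot = 20, seed = 7)
  expect_true(all(ari_sep == 1))

  # null case in the analysis dimension (8 clustering variables)
  blob <- matrix(rnorm(200 * 8), ncol = 8)
  ari_blob <- bootstrap_stability(blob, 2, n_boot = 30, seed = 8)
  expect_lt(mean(ari_blob), 0.5)
  expect_true(all(ari_blob >= -1 & ari_blob <= 1))
})

test_that("Table-1 preset cluster contrasts run in the published direction", {
  gen <- generate_cohort(synthetic_spec(n_patients = 150, seed = 12))
  z <- zscore(gen$cohort, clustering_variables())
  fit <- kmeans_fit(as.matrix(z$table[, clustering_variables()]), 2, seed = 12)
  co <- gen$cohort
  hi_psd <- which.max(tapply(co$PSD, fit$labels, mean)) - 1
  lo_psd <- 1 - hi_psd
  m <- function(v, g) mean(co[[v]][fit$labels == g])
  expect_lt(m("eGFR", hi_psd), m("eGFR", lo_psd))
  expect_gt(m("BNP", hi_psd), m("BNP", lo_psd))
})

test_that("compare_clusters chooses tests and detects planted differences", {
  # Table-1 female 2x2 margin: 27/43 vs 15/41 -> p < 0.05
  sex <- c(rep(1, 27), rep(0, 16), rep(1, 15), rep(0, 26))
  lab <- rep(0:1, c(43, 41))
  tbl <- data.frame(sex = sex)
  cmp <- compare_clusters(tbl, lab, "sex")
  expect_lt(cmp$p_value, 0.05)
  expect_equal(cmp$type, "binary")

  # 3-SD shift, n = 40/group: overwhelming evidence
  set.seed(9)
  tbl2 <- data.frame(age = c(rnorm(40, 0), rnorm(40, 3)))
  cmp2 <- compare_clusters(tbl2, rep(0:1, each = 40), "age")
  expect_lt(cmp2$p_value, 1e-6)
  expect_equal(cmp2$test, "Welch t")

  # skewed data routes to Mann-Whitney with median[IQR] summaries
  tbl3 <- data.frame(BNP = exp(c(rnorm(40, 0, 1), rnorm(40, 1.5, 1))))
  cmp3 <- compare_clusters(tbl3, rep(0:1, each = 40), "BNP")
  expect_equal(cmp3$test, "Mann-Whitney U")
  expect_match(cmp3$summary_0, "\\(")

  # constant variable flagged, not tested
  tbl4 <- data.frame(RWT = rep(0.4, 80))
  cmp4 <- compare_clusters(tbl4, rep(0:1, each = 40), "RWT")
  expect_match(cmp4$test, "skipped")
  expect_error(compare_clusters(tbl2, rep(0, 80)), "2 groups")
})

test_that("p-values are uniform under label permutation (KS, alpha 0.01)", {
  set.seed(10)
  x <- rnorm(60)
  pvals <- vapply(1:200, function(i) {
    lab <- sample(rep(0:1, each = 30))
    compare_clusters(data.frame(age = x), lab, "age")$p_value
  }, numeric(1))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("select_k breaks ties toward smaller k and finds k = 2", {
  set.seed(11)
  X <- rbind(matrix(rnorm(120, 0, 0.5), ncol = 2),
             matrix(rnorm(120, 8, 0.5), ncol = 2))
  sel <- select_k(X, ks = 2:4, seed = 11)
  expect_equal(sel$k, 2)
  expect_length(sel$silhouette_by_k, 3)
})
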