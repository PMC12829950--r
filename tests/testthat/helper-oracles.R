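# Independent oracles used by the tests. These deliberately take different
# computational routes than the package implementation.

# Exhaustive k=2 partition search: minimal within-cluster SSE over all
# assignments of the points to two non-empty clusters.
brute_force_kmeans2 <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  best <- list(inertia = Inf)
  for (mask in 1:(2^n - 2)) {
    lab <- as.integer(intToBits(mask))[1:n]
    inertia <- 0
    cents <- list()
    for (g in 0:1) {
      pts <- X[lab == g, , drop = FALSE]
      mu <- colMeans(pts)
      inertia <- inertia + sum(sweep(pts, 2, mu, "-")^2)
      cents[[g + 1]] <- mu
    }
    if (inertia < best$inertia) {
      best <- list(inertia = inertia, labels = lab,
                   centroids = do.call(rbind, cents))
    }
  }
  best
}

# ARI from first principles: pair-counting agreement with the expected
# index written out explicitly.
ari_oracle <- function(a, b) {
  n <- length(a)
  pairs <- combn(n, 2)
  same_a <- a[pairs[1, ]] == a[pairs[2, ]]
  same_b <- b[pairs[1, ]] == b[pairs[2, ]]
  n11 <- sum(same_a & same_b); n00 <- sum(!same_a & !same_b)
  npairs <- ncol(pairs)
  sum_a <- sum(same_a); sum_b <- sum(same_b)
  index <- n11
  expected <- sum_a * sum_b / npairs
  maximum <- (sum_a + sum_b) / 2
  if (abs(maximum - expected) < 1e-12) return(1)
  (index - expected) / (maximum - expected)
}

# Exact Shapley values by enumerating all 2^p coalitions, with the
# interventional value function v(S) = mean over reference rows of
# f(x_S, z_{S^c}).
exhaustive_shapley <- function(predict_fn, x, reference) {
  reference <- as.matrix(reference)
  p <- length(x)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  v <- apply(subsets, 1, function(S) {
    pts <- reference
    pts[, S] <- matrix(x[S], nrow(reference), sum(S), byrow = TRUE)
    mean(predict_fn(pts))
  })
  key <- apply(subsets, 1, function(S) paste0("S", paste(which(S), collapse = ",")))
  vmap <- as.list(setNames(v, key))
  phi <- numeric(p)
  for (j in seq_len(p)) {
    others <- setdiff(seq_len(p), j)
    for (sz in 0:(p - 1)) {
      combos <- if (sz == 0) list(integer(0)) else
        asplit(combn(others, sz), 2)
      w <- factorial(sz) * factorial(p - sz - 1) / factorial(p)
      for (S in combos) {
        k_with <- paste0("S", paste(sort(c(S, j)), collapse = ","))
        k_without <- paste0("S", paste(sort(S), collapse = ","))
        phi[j] <- phi[j] + w * (vmap[[k_with]] - vmap[[k_without]])
      }
    }
  }
  phi
}

# ICC(2,1) point estimate via R's aov() two-way ANOVA (independent route
# to the mean squares).
icc21_aov_oracle <- function(pairs) {
  long <- data.frame(
    y = c(pairs$reading_1, pairs$reading_2),
    subj = factor(rep(seq_len(nrow(pairs)), 2)),
    rater = factor(rep(1:2, each = nrow(pairs))))
  tab <- summary(aov(y ~ subj + rater, data = long))[[1]]
  msr <- tab["subj", "Mean Sq"]; msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  n <- nrow(pairs); k <- 2
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Small complete synthetic cohort for tests that just need shaped data.
toy_cohort <- function(n = 120, seed = 5, ...) {
  generate_cohort(synthetic_spec(n_patients = n, seed = seed, ...))
}
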