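# Regression learners behind the model suite. Ridge is a closed-form
# solve; lasso wraps glmnet; the tree/forest/boosting/SVR/MLP learners are
# self-contained implementations (no CART/SVM/NN package is assumed).

#' Ridge regression (closed form)
#'
#' Minimizes `||y - b0 - X beta||^2 + lambda ||beta||^2` with an
#' unpenalized intercept. At `lambda -> 0` this is exactly ordinary least
#' squares.
#'
#' @param X Numeric matrix; `y` numeric response; `lambda` penalty.
#' @return `linear_model` object: `intercept`, named `coefficients`.
#' @export
ridge_fit <- function(X, y, lambda = 1) {
  X <- as.matrix(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm, "-")
  beta <- solve(crossprod(Xc) + diag(lambda, ncol(X)), crossprod(Xc, y - ym))
  beta <- as.numeric(beta)
  names(beta) <- colnames(X)
  structure(list(intercept = ym - sum(beta * xm), coefficients = beta,
                 lambda = lambda),
            class = "linear_model")
}

#' @export
predict.linear_model <- function(object, newdata, ...) {
  as.numeric(as.matrix(newdata)[, names(object$coefficients), drop = FALSE] %*%
               object$coefficients + object$intercept)
}

lasso_fit <- function(X, y, lambda = 0.1) {
  fit <- glmnet::glmnet(as.matrix(X), y, alpha = 1, lambda = lambda,
                        standardize = FALSE)
  beta <- as.numeric(coef(fit))
  structure(list(intercept = beta[1],
                 coefficients = setNames(beta[-1], colnames(X)),
                 lambda = lambda),
            class = "linear_model")
}

# ---- CART regression tree -------------------------------------------------

# Best split of one node: scan each candidate feature with cumulative sums
# over the sorted response; returns NULL when no split reduces SSE.
best_split <- function(X, y, feats, min_leaf) {
  n <- length(y)
  best <- NULL
  sse0 <- sum(y^2) - n * mean(y)^2
  for (j in feats) {
    ord <- order(X[, j])
    xs <- X[ord, j]; ys <- y[ord]
    cs <- cumsum(ys); tot <- cs[n]
    nl <- seq_len(n - 1)
    valid <- which(xs[-n] < xs[-1] & nl >= min_leaf & (n - nl) >= min_leaf)
    if (length(valid) == 0) next
    sse <- sse0 - (cs[valid]^2 / valid + (tot - cs[valid])^2 / (n - valid) -
                     tot^2 / n)
    i <- valid[which.min(sse)]
    gain <- sse0 - min(sse)
    if (gain > 1e-12 && (is.null(best) || gain > best$gain)) {
      best <- list(feature = j, threshold = (xs[i] + xs[i + 1]) / 2,
                   gain = gain)
    }
  }
  best
}

grow_tree <- function(X, y, depth, max_depth, min_leaf, mtry) {
  if (depth >= max_depth || length(y) < 2 * min_leaf || sd(y) == 0) {
    return(list(leaf = TRUE, value = mean(y)))
  }
  feats <- if (mtry < ncol(X)) sample.int(ncol(X), mtry) else seq_len(ncol(X))
  sp <- best_split(X, y, feats, min_leaf)
  if (is.null(sp)) return(list(leaf = TRUE, value = mean(y)))
  left <- X[, sp$feature] <= sp$threshold
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       left = grow_tree(X[left, , drop = FALSE], y[left], depth + 1,
                        max_depth, min_leaf, mtry),
       right = grow_tree(X[!left, , drop = FALSE], y[!left], depth + 1,
                         max_depth, min_leaf, mtry))
}

predict_tree <- function(node, X) {
  n <- nrow(X)
  out <- numeric(n)
  recurse <- function(node, idx) {
    if (node$leaf) { out[idx] <<- node$value; return(invisible()) }
    go_left <- X[idx, node$feature] <= node$threshold
    if (any(go_left)) recurse(node$left, idx[go_left])
    if (any(!go_left)) recurse(node$right, idx[!go_left])
  }
  if (n > 0) recurse(node, seq_len(n))
  out
}

#' Random forest regressor (bagged CART)
#'
#' Bootstrap-aggregated regression trees with per-node feature subsampling
#' (`mtry = max(1, p/3)` by default).
#'
#' @param X Matrix; `y` response.
#' @param n_trees Trees (default 200); `max_depth` depth cap (Inf = grown
#'   to `min_leaf`); `min_leaf` minimum leaf size; `mtry` features tried
#'   per split; `seed` RNG seed.
#' @return `rf_model` object.
#' @export
forest_fit <- function(X, y, n_trees = 200L, max_depth = Inf, min_leaf = 5L,
                       mtry = NULL, seed = 1L) {
  X <- as.matrix(X)
  if (is.null(mtry)) mtry <- max(1L, floor(ncol(X) / 3))
  set.seed(seed)
  trees <- lapply(seq_len(n_trees), function(b) {
    idx <- sample.int(nrow(X), nrow(X), replace = TRUE)
    grow_tree(X[idx, , drop = FALSE], y[idx], 0L, max_depth, min_leaf, mtry)
  })
  structure(list(trees = trees, columns = colnames(X)), class = "rf_model")
}

#' @export
predict.rf_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$columns, drop = FALSE]
  rowMeans(vapply(object$trees, function(tr) predict_tree(tr, X),
                  numeric(nrow(X))))
}

#' Gradient-boosted regression trees
#'
#' Stagewise least-squares boosting with shallow CART base learners.
#'
#' @param X Matrix; `y` response; `n_rounds` boosting rounds;
#'   `learning_rate` shrinkage; `max_depth` base-tree depth; `min_leaf`
#'   leaf size; `seed` RNG seed.
#' @return `gbm_model` object.
#' @export
gbm_fit <- function(X, y, n_rounds = 100L, learning_rate = 0.1,
                    max_depth = 3L, min_leaf = 5L, seed = 1L) {
  X <- as.matrix(X)
  set.seed(seed)
  f0 <- mean(y)
  resid <- y - f0
  trees <- vector("list", n_rounds)
  for (m in seq_len(n_rounds)) {
    tr <- grow_tree(X, resid, 0L, max_depth, min_leaf, ncol(X))
    resid <- resid - learning_rate * predict_tree(tr, X)
    trees[[m]] <- tr
  }
  structure(list(f0 = f0, trees = trees, learning_rate = learning_rate,
                 columns = colnames(X)), class = "gbm_model")
}

#' @export
predict.gbm_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$columns, drop = FALSE]
  pred <- rep(object$f0, nrow(X))
  for (tr in object$trees) pred <- pred + object$learning_rate * predict_tree(tr, X)
  pred
}

# ---- RBF support vector regression ---------------------------------------

rbf_kernel <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  exp(-gamma * pmax(d2, 0))
}

#' Epsilon-insensitive RBF support vector regression
#'
#' Representer-form SVR `f(x) = sum_i alpha_i K(x_i, x) + b` trained by
#' subgradient descent on `C * sum eps_loss + 0.5 alpha' K alpha` with a
#' decaying step size. Deterministic; adequate for the suite's desk-scale
#' comparisons.
#'
#' @param X Matrix (expected standardized); `y` response; `C` loss weight;
#'   `epsilon` insensitivity tube; `gamma` RBF width (default `1/p`);
#'   `n_iter` descent steps.
#' @return `svr_model` object.
#' @export
svr_fit <- function(X, y, C = 1, epsilon = 0.1, gamma = NULL, n_iter = 300L) {
  X <- as.matrix(X)
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  K <- rbf_kernel(X, X, gamma)
  n <- nrow(X)
  alpha <- numeric(n); b <- mean(y)
  eta0 <- 1 / (C * n)
  best <- list(obj = Inf, alpha = alpha, b = b)
  for (t in seq_len(n_iter)) {
    f <- as.numeric(K %*% alpha) + b
    r <- y - f
    active <- abs(r) > epsilon
    g <- -C * sign(r) * active
    obj <- C * sum(pmax(abs(r) - epsilon, 0)) + 0.5 * sum(alpha * (K %*% alpha))
    if (obj < best$obj) best <- list(obj = obj, alpha = alpha, b = b)
    eta <- eta0 / sqrt(t)
    alpha <- alpha - eta * as.numeric(K %*% (g + alpha))
    b <- b - eta * sum(g)
  }
  structure(list(alpha = best$alpha, b = best$b, gamma = gamma,
                 X = X, columns = colnames(X)), class = "svr_model")
}

#' @export
predict.svr_model <- function(object, newdata, ...) {
  Xn <- as.matrix(newdata)[, object$columns, drop = FALSE]
  as.numeric(rbf_kernel(Xn, object$X, object$gamma) %*% object$alpha + object$b)
}

# ---- One-hidden-layer MLP -------------------------------------------------

#' One-hidden-layer neural network regressor
#'
#' tanh hidden layer, linear output, squared loss, full-batch Adam with a
#' small L2 penalty; weights are seed-deterministic.
#'
#' @param X Matrix (expected standardized); `y` response; `hidden` hidden
#'   units; `epochs` Adam steps; `lr` learning rate; `l2` weight decay;
#'   `seed` RNG seed.
#' @return `mlp_model` object.
#' @export
mlp_fit <- function(X, y, hidden = 8L, epochs = 500L, lr = 0.01,
                    l2 = 1e-4, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  set.seed(seed)
  W1 <- matrix(rnorm(p * hidden, 0, 1 / sqrt(p)), p, hidden)
  b1 <- numeric(hidden)
  W2 <- matrix(rnorm(hidden, 0, 1 / sqrt(hidden)), hidden, 1)
  b2 <- mean(y)
  params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  mom <- lapply(params, function(p) p * 0)
  vel <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  for (t in seq_len(epochs)) {
    H <- tanh(sweep(X %*% params$W1, 2, params$b1, "+"))
    pred <- as.numeric(H %*% params$W2) + params$b2
    err <- (pred - y) / n
    gW2 <- crossprod(H, err) + l2 * params$W2
    gb2 <- sum(err)
    dH <- (err %*% t(params$W2)) * (1 - H^2)
    gW1 <- crossprod(X, dH) + l2 * params$W1
    gb1 <- colSums(dH)
    grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
    for (nm in names(params)) {
      mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * grads[[nm]]
      vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * grads[[nm]]^2
      mhat <- mom[[nm]] / (1 - beta1^t)
      vhat <- vel[[nm]] / (1 - beta2^t)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  structure(c(params, list(columns = colnames(X))), class = "mlp_model")
}

#' @export
predict.mlp_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$columns, drop = FALSE]
  H <- tanh(sweep(X %*% object$W1, 2, object$b1, "+"))
  as.numeric(H %*% object$W2) + object$b2
}
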