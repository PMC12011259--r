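# Small feed-forward ("BP") network for biomass prediction.
#
# One hidden layer trained by full-batch backpropagation with Adam.
# Implemented from first principles: the estimator must be deterministic
# given a seed, support both sigmoid and ReLU hidden activations and both
# MSE and binary-crossentropy-on-scaled-targets losses, and clamp outputs
# at zero — a combination no lightweight dependency provides.

mlp_act <- function(z, activation) {
  switch(activation,
         sigmoid = 1 / (1 + exp(-z)),
         relu = pmax(z, 0))
}

mlp_act_grad <- function(z, a, activation) {
  switch(activation,
         sigmoid = a * (1 - a),
         relu = (z > 0) * 1)
}

#' Feature matrix for the network
#'
#' DBH (cm), height (m), age (years) and a one-hot encoding of the region
#' code 0-5 — the measured covariates a stand inventory always carries.
#'
#' @param trees Data.frame with columns `dbh`, `height`, `age`, `region`.
#' @return Numeric matrix with 9 columns.
#' @export
mlp_features <- function(trees) {
  if (!is.data.frame(trees)) stopf("`trees` must be a data.frame")
  for (col in c("dbh", "height", "age", "region"))
    if (!col %in% names(trees)) stopf("missing required feature: %s", col)
  if (any(!trees$region %in% 0:5)) stopf("region codes must be integers 0-5")
  onehot <- outer(trees$region, 0:5, `==`) * 1
  colnames(onehot) <- paste0("region", 0:5)
  cbind(dbh = trees$dbh, height = trees$height, age = trees$age, onehot)
}

#' Fit the feed-forward biomass network
#'
#' Single hidden layer, full-batch Adam, fixed epoch budget (no early
#' stopping randomness): identical seed and data give bit-identical
#' predictions. Inputs are z-scored; targets are z-scored under the MSE
#' loss or min-max scaled into (0, 1) under the binary-crossentropy
#' variant (which pairs with a sigmoid output unit).
#'
#' @param trees Data.frame with `dbh`, `height`, `age`, `region`.
#' @param mass Observed biomass, kg, non-negative.
#' @param hidden Hidden layer width, default 16.
#' @param activation `"sigmoid"` (default) or `"relu"`.
#' @param loss `"mse"` (default) or `"binary_crossentropy"`.
#' @param epochs Training epochs, default 1500.
#' @param learning_rate Adam step size, default 0.02.
#' @param seed Integer seed for weight initialization (mandatory).
#' @return Object of class `"mlp_estimator"`.
#' @export
fit_mlp <- function(trees, mass, hidden = 16L,
                    activation = c("sigmoid", "relu"),
                    loss = c("mse", "binary_crossentropy"),
                    epochs = 1500L, learning_rate = 0.02, seed) {
  activation <- match.arg(activation)
  loss <- match.arg(loss)
  if (missing(seed)) stopf("`seed` is required for reproducible training")
  assert_non_negative(mass, "mass")
  if (!is.numeric(hidden) || hidden < 1L) stopf("`hidden` must be >= 1")
  X <- mlp_features(trees)
  if (nrow(X) != length(mass)) stopf("trees and mass lengths differ")
  if (nrow(X) < 3L) stopf("at least 3 training records are required")

  x_center <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd)
  x_scale[x_scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, `/`)

  if (loss == "mse") {
    y_center <- mean(mass); y_scale <- stats::sd(mass)
    if (y_scale == 0) y_scale <- 1
    ys <- (mass - y_center) / y_scale
  } else {
    y_center <- min(mass); y_scale <- max(mass) - min(mass)
    if (y_scale == 0) y_scale <- 1
    eps <- 1e-3  # keep targets strictly inside (0,1)
    ys <- pmin(pmax((mass - y_center) / y_scale, eps), 1 - eps)
  }

  d <- ncol(Xs); h <- as.integer(hidden); n <- nrow(Xs)
  init_sd1 <- if (activation == "relu") sqrt(2 / d) else sqrt(1 / d)
  params <- with_seed(seed, list(
    W1 = matrix(stats::rnorm(d * h, sd = init_sd1), d, h),
    b1 = rep(0, h),
    W2 = matrix(stats::rnorm(h, sd = sqrt(1 / h)), h, 1),
    b2 = 0))

  # Adam state
  m <- lapply(params, function(p) p * 0)
  v <- lapply(params, function(p) p * 0)
  b1a <- 0.9; b2a <- 0.999; eps_a <- 1e-8

  forward <- function(P, X) {
    Z1 <- sweep(X %*% P$W1, 2, P$b1, `+`)
    H <- mlp_act(Z1, activation)
    Z2 <- drop(H %*% P$W2) + P$b2
    out <- if (loss == "binary_crossentropy") 1 / (1 + exp(-Z2)) else Z2
    list(Z1 = Z1, H = H, out = out)
  }

  for (it in seq_len(epochs)) {
    fw <- forward(params, Xs)
    # with a sigmoid output under BCE the output-layer gradient reduces to
    # (p - y)/n, the same algebraic form as MSE's 2(yhat - y)/n
    dZ2 <- if (loss == "binary_crossentropy") (fw$out - ys) / n
           else 2 * (fw$out - ys) / n
    grads <- list(
      W1 = NULL, b1 = NULL,
      W2 = crossprod(fw$H, dZ2),
      b2 = sum(dZ2))
    dH <- matrix(dZ2, ncol = 1) %*% t(params$W2)
    dZ1 <- dH * mlp_act_grad(fw$Z1, fw$H, activation)
    grads$W1 <- crossprod(Xs, dZ1)
    grads$b1 <- colSums(dZ1)
    for (nm in names(params)) {
      m[[nm]] <- b1a * m[[nm]] + (1 - b1a) * grads[[nm]]
      v[[nm]] <- b2a * v[[nm]] + (1 - b2a) * grads[[nm]]^2
      mh <- m[[nm]] / (1 - b1a^it)
      vh <- v[[nm]] / (1 - b2a^it)
      params[[nm]] <- params[[nm]] - learning_rate * mh / (sqrt(vh) + eps_a)
    }
  }

  fw <- forward(params, Xs)
  structure(list(params = params, activation = activation, loss = loss,
                 layer_sizes = c(d, h, 1L), epochs = as.integer(epochs),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, y_scale = y_scale,
                 train_loss = mean((fw$out - ys)^2), n = n),
            class = "mlp_estimator")
}

#' @param object A fitted `"mlp_estimator"`.
#' @param trees Data.frame of tree records (see [mlp_features()]).
#' @param ... Unused.
#' @rdname fit_mlp
#' @export
predict.mlp_estimator <- function(object, trees, ...) {
  X <- mlp_features(trees)
  Xs <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, `/`)
  P <- object$params
  Z1 <- sweep(Xs %*% P$W1, 2, P$b1, `+`)
  H <- mlp_act(Z1, object$activation)
  out <- drop(H %*% P$W2) + P$b2
  if (object$loss == "binary_crossentropy") out <- 1 / (1 + exp(-out))
  pmax(out * object$y_scale + object$y_center, 0)  # biomass cannot go negative
}

#' @export
print.mlp_estimator <- function(x, ...) {
  cat(sprintf("Feed-forward biomass network %s, %s activation, %s loss\n",
              paste(x$layer_sizes, collapse = "-"), x$activation, x$loss))
  cat(sprintf("  trained %d epochs on %d stems (seed %d), scaled train MSE %.5g\n",
              x$epochs, x$n, x$seed, x$train_loss))
  invisible(x)
}
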