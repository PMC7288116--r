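# Three-layer back-propagation network (tanh hidden, linear output) for
# per-tree yield regression, trained by Levenberg-Marquardt (default) or
# Adam, with validation-based early stopping and hidden-size selection.

#' Split sample indices into train / validation / test sets
#'
#' Shuffles `1:n` and cuts it into disjoint sets whose sizes follow the
#' fractions with largest-remainder rounding (sizes always sum to `n`).
#'
#' @param n number of samples (>= 8).
#' @param fractions train/validation/test fractions summing to 1.
#' @param seed integer RNG seed.
#' @return a list with integer vectors `train`, `val`, `test`.
#' @examples
#' lengths(split_data(160, seed = 1))  # 96 24 40
#' @export
split_data <- function(n, fractions = c(0.60, 0.15, 0.25), seed = 1L) {
  if (n < 8) stop("need at least 8 samples to split", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("`fractions` must sum to 1", call. = FALSE)
  exact <- n * fractions
  sizes <- floor(exact)
  rem <- exact - sizes
  short <- n - sum(sizes)
  if (short > 0) {
    bump <- order(rem, decreasing = TRUE)[seq_len(short)]
    sizes[bump] <- sizes[bump] + 1
  }
  idx <- with_seed(seed, sample.int(n))
  ends <- cumsum(sizes)
  list(train = sort(idx[seq_len(sizes[1])]),
       val = sort(idx[(ends[1] + 1):ends[2]]),
       test = sort(idx[(ends[2] + 1):ends[3]]))
}

# pack/unpack parameters <-> flat vector
.net_pack <- function(w1, b1, w2, b2) c(as.numeric(w1), b1, w2, b2)
.net_unpack <- function(theta, m, h) {
  list(w1 = matrix(theta[seq_len(h * m)], h, m),
       b1 = theta[h * m + seq_len(h)],
       w2 = theta[h * m + h + seq_len(h)],
       b2 = theta[h * m + 2 * h + 1])
}

# forward pass: X (n x m) -> list(yhat, A) with A the hidden activations
.net_forward <- function(theta, X, m, h) {
  p <- .net_unpack(theta, m, h)
  A <- tanh(sweep(X %*% t(p$w1), 2, p$b1, "+"))
  list(yhat = as.numeric(A %*% p$w2 + p$b2), A = A)
}

# Jacobian of yhat wrt theta, n x (h*m + 2h + 1), column order matching
# .net_pack
.net_jacobian <- function(theta, X, A, m, h) {
  p <- .net_unpack(theta, m, h)
  n <- nrow(X)
  S <- (1 - A^2) * matrix(p$w2, n, h, byrow = TRUE)  # d yhat / d preact
  J <- matrix(0, n, h * m + 2 * h + 1)
  for (k in seq_len(h))
    J[, seq.int((k - 1) * m + 1, k * m)] <- S[, k] * X
  J[, h * m + seq_len(h)] <- S
  J[, h * m + h + seq_len(h)] <- A
  J[, h * m + 2 * h + 1] <- 1
  J
}

# Levenberg-Marquardt fit of the penalized squared error
# sum(r^2) + alpha * |theta|^2 (alpha = 0 gives plain MSE training).
# The linear output layer is warm-started by ridge regression on the random
# hidden activations, so training begins at a sensibly regularized model and
# validation-based early stopping refines from there.
# Returns the parameter vector with the best validation MSE along the path.
# The damped update solves (J'J + (alpha+lambda) I) delta = J'r - alpha*theta;
# when n_params > n_samples it goes through the Woodbury identity
# (J'J + cI)^{-1} = (I - J'(JJ' + cI)^{-1} J) / c, which is exact and keeps
# the cost at O(n^2 p).
.fit_lm <- function(X, y, Xv, yv, h, max_epochs, patience, seed,
                    lambda = 1e-2, alpha = 0.5) {
  m <- ncol(X); n <- nrow(X)
  np <- h * m + 2 * h + 1
  theta <- with_seed(seed, c(stats::rnorm(h * m, 0, 0.5 / sqrt(m)),
                             stats::rnorm(h, 0, 0.1),
                             stats::rnorm(h, 0, 0.5 / sqrt(h)),
                             0))
  p0 <- .net_unpack(theta, m, h)
  A0 <- tanh(sweep(X %*% t(p0$w1), 2, p0$b1, "+"))
  G <- crossprod(cbind(A0, 1))
  diag(G) <- diag(G) + alpha + 1e-6
  theta[(h * m + h + 1):np] <- solve(G, crossprod(cbind(A0, 1), y))

  obj <- function(r, th) sum(r^2) + alpha * sum(th^2)
  fw <- .net_forward(theta, X, m, h)
  r <- y - fw$yhat
  sse <- obj(r, theta)
  val_mse <- function(th) {
    if (!nrow(Xv)) return(NA_real_)
    mean((yv - .net_forward(th, Xv, m, h)$yhat)^2)
  }
  best <- list(theta = theta, val = val_mse(theta))
  if (is.na(best$val)) best$val <- sse / n
  stall <- 0L
  trace <- numeric(0)
  for (epoch in seq_len(max_epochs)) {
    J <- .net_jacobian(theta, X, fw$A, m, h)
    JJt <- if (np > n) tcrossprod(J)
    accepted <- FALSE
    for (try in 1:30) {   # spans 1e-12..1e12 damping from any start
      cc <- alpha + lambda
      g <- as.numeric(crossprod(J, r)) - alpha * theta
      delta <- if (np > n) {
        M <- JJt
        diag(M) <- diag(M) + cc
        (g - as.numeric(crossprod(J, solve(M, J %*% g)))) / cc
      } else {
        M <- crossprod(J)
        diag(M) <- diag(M) + cc
        as.numeric(solve(M, g))
      }
      cand <- theta + delta
      fw2 <- .net_forward(cand, X, m, h)
      r2 <- y - fw2$yhat
      sse2 <- obj(r2, cand)
      if (is.finite(sse2) && sse2 < sse) {
        theta <- cand; fw <- fw2; r <- r2
        rel <- (sse - sse2) / max(sse, .Machine$double.eps)
        sse <- sse2
        lambda <- max(lambda / 10, 1e-12)
        accepted <- TRUE
        vm <- val_mse(theta)
        if (is.na(vm)) vm <- sse / n
        trace <- c(trace, vm)
        if (vm < best$val - 1e-12) {
          best <- list(theta = theta, val = vm)
          stall <- 0L
        } else stall <- stall + 1L
        if (rel < 1e-10) return(c(best, list(trace = trace)))
        break
      }
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
    if (!accepted || stall >= patience) break
  }
  c(best, list(trace = trace))
}

# full-batch Adam fallback on the same architecture
.fit_adam <- function(X, y, Xv, yv, h, max_epochs, patience, seed,
                      lr = 0.01) {
  m <- ncol(X); n <- nrow(X)
  theta <- with_seed(seed, c(stats::rnorm(h * m, 0, 1 / sqrt(m)),
                             stats::rnorm(h, 0, 0.1),
                             stats::rnorm(h, 0, 1 / sqrt(h)),
                             0))
  mo <- ve <- numeric(length(theta))
  b1c <- 0.9; b2c <- 0.999; eps <- 1e-8
  val_mse <- function(th) {
    if (!nrow(Xv)) return(NA_real_)
    mean((yv - .net_forward(th, Xv, m, h)$yhat)^2)
  }
  best <- list(theta = theta, val = val_mse(theta))
  if (is.na(best$val)) best$val <- Inf
  stall <- 0L
  trace <- numeric(0)
  for (t in seq_len(max_epochs)) {
    fw <- .net_forward(theta, X, m, h)
    r <- y - fw$yhat
    # gradient of mean squared error
    g <- -2 / n * as.numeric(crossprod(.net_jacobian(theta, X, fw$A, m, h),
                                       r))
    mo <- b1c * mo + (1 - b1c) * g
    ve <- b2c * ve + (1 - b2c) * g^2
    mhat <- mo / (1 - b1c^t); vhat <- ve / (1 - b2c^t)
    theta <- theta - lr * mhat / (sqrt(vhat) + eps)
    vm <- val_mse(theta)
    if (is.na(vm)) vm <- mean(r^2)
    trace <- c(trace, vm)
    if (vm < best$val - 1e-12) {
      best <- list(theta = theta, val = vm); stall <- 0L
    } else stall <- stall + 1L
    if (stall >= patience) break
  }
  c(best, list(trace = trace))
}

#' Train the three-layer yield prediction network
#'
#' Architecture `m -> h -> 1` with tanh (tansig) hidden units and a linear
#' (purelin) output. Hidden size follows `h = ceiling(sqrt(m + n_out)) + a`
#' with the adjustment constant `a` either fixed (1-10) or selected by
#' validation RMSE (`a = "auto"`). Inputs (and the target) are z-scored on
#' the training split only; the network is trained to minimize squared error
#' with Levenberg-Marquardt (default) or Adam, with early stopping on the
#' validation MSE.
#'
#' With the default optimizer the objective carries a small weight-decay
#' term (`regularization * |theta|^2`, the regularized performance function
#' familiar from classic neural-network toolboxes) and the linear output
#' layer is warm-started by ridge regression on the initial random hidden
#' activations; both stabilize nets whose parameter count exceeds the
#' training-set size, which is the normal regime for the 70+-feature input
#' modes on orchard-sized samples.
#'
#' @param x numeric feature matrix (samples x features), no missing values.
#' @param y numeric target vector (kg).
#' @param a hidden-size adjustment constant: integer in 1-10 or `"auto"`.
#' @param hidden explicit hidden node count, overriding the `a` rule.
#' @param optimizer `"lm"` (Levenberg-Marquardt) or `"adam"`.
#' @param split train/validation/test fractions (sum 1).
#' @param max_epochs,patience training length and early-stopping patience
#'   (accepted steps without validation improvement).
#' @param regularization weight-decay coefficient on the standardized scale
#'   (Levenberg-Marquardt only; 0 disables it).
#' @param seed integer RNG seed controlling the split and initialization.
#' @return an object of class `bpann` holding the weights, the input/target
#'   standardization parameters, the split indices, the chosen `a`/`h` and a
#'   training log. Use [predict.bpann()] and [regression_metrics()].
#' @export
bpann_train <- function(x, y, a = "auto", hidden = NULL,
                        optimizer = c("lm", "adam"),
                        split = c(0.60, 0.15, 0.25),
                        max_epochs = 200L, patience = 15L,
                        regularization = 0.5, seed = 1L) {
  optimizer <- match.arg(optimizer)
  x <- as.matrix(x)
  if (anyNA(x) || anyNA(y))
    stop("missing values in features or target; exclude or impute first",
         call. = FALSE)
  if (nrow(x) != length(y)) stop("nrow(x) != length(y)", call. = FALSE)
  m <- ncol(x)
  if (sum(apply(x, 2, stats::sd) > 0) < 2)
    stop("need at least 2 varying features", call. = FALSE)
  idx <- split_data(nrow(x), split, seed)
  center <- colMeans(x[idx$train, , drop = FALSE])
  scale <- apply(x[idx$train, , drop = FALSE], 2, stats::sd)
  scale[scale == 0] <- 1
  Xs <- sweep(sweep(x, 2, center, "-"), 2, scale, "/")
  y_center <- mean(y[idx$train])
  y_scale <- stats::sd(y[idx$train])
  if (y_scale == 0) y_scale <- 1
  ys <- (y - y_center) / y_scale

  Xtr <- Xs[idx$train, , drop = FALSE]; ytr <- ys[idx$train]
  Xv <- Xs[idx$val, , drop = FALSE]; yv <- ys[idx$val]
  fitter <- if (optimizer == "lm") {
    function(...) .fit_lm(..., alpha = regularization)
  } else .fit_adam

  cand <- if (!is.null(hidden)) {
    data.frame(a = NA_integer_, h = as.integer(hidden))
  } else if (identical(a, "auto")) {
    data.frame(a = 1:10, h = as.integer(ceiling(sqrt(m + 1)) + 1:10))
  } else {
    if (!is.numeric(a) || a < 1 || a > 10)
      stop("`a` must be \"auto\" or an integer in 1-10", call. = FALSE)
    data.frame(a = as.integer(a), h = as.integer(ceiling(sqrt(m + 1)) + a))
  }
  fits <- lapply(seq_len(nrow(cand)), function(k)
    fitter(Xtr, ytr, Xv, yv, cand$h[k], max_epochs, patience,
           seed = (abs(seed) %% 1e6) * 100 + k))
  vals <- vapply(fits, function(f) f$val, numeric(1))
  k <- which.min(vals)
  structure(list(theta = fits[[k]]$theta, m = m, h = cand$h[k],
                 a = cand$a[k], center = center, scale = scale,
                 y_center = y_center, y_scale = y_scale,
                 split = idx, optimizer = optimizer, seed = seed,
                 val_mse = vals[k], val_mse_by_a = vals,
                 trace = fits[[k]]$trace,
                 feature_names = colnames(x)),
            class = "bpann")
}

#' Predict yields with a trained network
#'
#' Deterministic forward pass; the standardization parameters stored at
#' training time are applied (never refit on new data).
#'
#' @param object a `bpann` model.
#' @param newdata feature matrix with `object$m` columns.
#' @param ... unused.
#' @return numeric vector of predictions on the original target scale (kg).
#' @export
predict.bpann <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$m)
    stop("feature length ", ncol(newdata), " does not match model (",
         object$m, ")", call. = FALSE)
  Xs <- sweep(sweep(newdata, 2, object$center, "-"), 2, object$scale, "/")
  yh <- .net_forward(object$theta, Xs, object$m, object$h)$yhat
  yh * object$y_scale + object$y_center
}

#' @export
print.bpann <- function(x, ...) {
  cat("<bpann> ", x$m, " -> ", x$h, " -> 1 (tansig/purelin), optimizer ",
      x$optimizer,
      if (!is.na(x$a)) paste0(", a = ", x$a),
      ", val MSE ", signif(x$val_mse, 4), "\n", sep = "")
  invisible(x)
}

#' Regression accuracy metrics (R-squared, RMSE, relative average deviation)
#'
#' `R2 = 1 - SS_res/SS_tot`, `RMSE = sqrt(mean((y - yhat)^2))`, and the
#' per-sample relative deviation `RAD_i = |yhat_i - y_i| / y_i * 100`
#' aggregated as mean, max and min. RAD entries require `y > 0`;
#' non-positive truths are dropped from the RAD aggregates.
#'
#' @param y_true,y_pred numeric vectors of equal length (>= 2).
#' @return a list with `R2` (`NA` and `r2_defined = FALSE` when `y_true` has
#'   zero variance), `RMSE`, `RAD_avg`, `RAD_max`, `RAD_min`, `n`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 2)
    stop("`y_true` and `y_pred` must have equal length >= 2", call. = FALSE)
  ss_tot <- sum((y_true - mean(y_true))^2)
  ss_res <- sum((y_true - y_pred)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  rad <- abs(y_pred - y_true) / y_true * 100
  rad <- rad[y_true > 0]
  list(R2 = r2, r2_defined = ss_tot > 0,
       RMSE = sqrt(mean((y_true - y_pred)^2)),
       RAD_avg = if (length(rad)) mean(rad) else NA_real_,
       RAD_max = if (length(rad)) max(rad) else NA_real_,
       RAD_min = if (length(rad)) min(rad) else NA_real_,
       n = length(y_true))
}
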