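# Multilayer perceptron (n_inputs -> n_hidden tanh -> 1 linear) trained with
# full-batch Levenberg-Marquardt, validation-based early stopping, and a
# plain gradient-descent fallback. Inputs and targets are z-scored on the
# training set.

#' MLP training configuration
#'
#' Defaults follow the study protocol: 10 hidden nodes, at most 100 training
#' iterations, MSE goal 0.00004 (on standardized targets), learning rate 0.1
#' (used only by the gradient-descent fallback — Levenberg-Marquardt has no
#' learning rate), and at most 18 consecutive validation failures.
#'
#' @param n_hidden Hidden-layer size (default 10).
#' @param max_epochs Maximum training iterations (default 100).
#' @param mse_goal Stop when training MSE falls below this (default 4e-5).
#' @param learning_rate Step size of the gradient-descent fallback
#'   (default 0.1).
#' @param max_fail Maximum consecutive validation-error increases
#'   (default 18).
#' @param seed Seed for weight initialization (uniform in `[-0.5, 0.5]`).
#' @param use_lm Use Levenberg-Marquardt updates (`TRUE`, default) or plain
#'   gradient descent.
#' @return An object of class `mlp_config`.
#' @export
mlp_config <- function(n_hidden = 10, max_epochs = 100, mse_goal = 4e-5,
                       learning_rate = 0.1, max_fail = 18, seed = 1,
                       use_lm = TRUE) {
  if (!is_count(n_hidden) || !is_count(max_epochs) || !is_count(max_fail)) {
    stopf("'n_hidden', 'max_epochs' and 'max_fail' must be positive integers")
  }
  if (mse_goal <= 0 || learning_rate <= 0) {
    stopf("'mse_goal' and 'learning_rate' must be positive")
  }
  structure(list(n_hidden = as.integer(n_hidden),
                 max_epochs = as.integer(max_epochs), mse_goal = mse_goal,
                 learning_rate = learning_rate, max_fail = as.integer(max_fail),
                 seed = as.integer(seed), use_lm = isTRUE(use_lm)),
            class = "mlp_config")
}

.mlp_unpack <- function(theta, p, h) {
  W1 <- matrix(theta[seq_len(p * h)], nrow = p, ncol = h)
  b1 <- theta[p * h + seq_len(h)]
  w2 <- theta[p * h + h + seq_len(h)]
  b2 <- theta[p * h + 2 * h + 1]
  list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
}

.mlp_forward <- function(theta, X, p, h) {
  w <- .mlp_unpack(theta, p, h)
  Z <- tanh(sweep(X %*% w$W1, 2, w$b1, "+"))
  list(yhat = drop(Z %*% w$w2) + w$b2, Z = Z, w = w)
}

# Jacobian of predictions w.r.t. parameters; rows = observations.
.mlp_jacobian <- function(fw, X, p, h) {
  n <- nrow(X)
  A <- (1 - fw$Z^2) * matrix(fw$w$w2, n, h, byrow = TRUE)  # n x h
  J <- matrix(0, n, p * h + 2 * h + 1)
  # W1 is stored column-major (p x h): entry (k, j) sits at (j-1)*p + k
  for (j in seq_len(h)) {
    J[, (j - 1) * p + seq_len(p)] <- X * A[, j]
  }
  J[, p * h + seq_len(h)] <- A
  J[, p * h + h + seq_len(h)] <- fw$Z
  J[, p * h + 2 * h + 1] <- 1
  J
}

#' Train a multilayer perceptron with Levenberg-Marquardt
#'
#' Architecture `ncol(x_train) -> n_hidden (tanh) -> 1 (linear)`. Inputs and
#' targets are z-scored on the training data; weights start uniform in
#' `[-0.5, 0.5]` from the config seed. Each epoch attempts one
#' Levenberg-Marquardt step (`lambda` starts at 1e-3, x10 on a rejected
#' step, /10 on an accepted one), so training MSE never increases across
#' accepted steps. Training stops at `max_epochs`, when training MSE reaches
#' `mse_goal`, after `max_fail` consecutive validation-error increases, or
#' when damping escalation fails; the returned weights are those with the
#' best validation error (or the final weights without a validation set).
#'
#' @param x_train Numeric matrix or data frame of training inputs.
#' @param y_train Numeric training targets.
#' @param x_val,y_val Optional validation set for early stopping.
#' @param cfg An [mlp_config()].
#' @return An object of class `mlp_model` with the weights, standardization
#'   parameters and a per-epoch training history.
#' @seealso [predict_mlp()]
#' @export
train_mlp <- function(x_train, y_train, x_val = NULL, y_val = NULL,
                      cfg = mlp_config()) {
  stopifnot(inherits(cfg, "mlp_config"))
  X <- as.matrix(x_train)
  storage.mode(X) <- "double"
  y <- as.numeric(y_train)
  if (nrow(X) != length(y)) stopf("'x_train' rows must match 'y_train'")
  if (nrow(X) < 2) stopf("need at least 2 training points")
  p <- ncol(X)
  h <- cfg$n_hidden

  x_mu <- colMeans(X)
  x_sd <- apply(X, 2, stats::sd)
  x_sd[!is.finite(x_sd) | x_sd == 0] <- 1
  y_mu <- mean(y)
  y_sd <- stats::sd(y)
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  Xs <- sweep(sweep(X, 2, x_mu), 2, x_sd, "/")
  ys <- (y - y_mu) / y_sd

  has_val <- !is.null(x_val) && !is.null(y_val) && length(y_val) > 0
  if (has_val) {
    Xv <- sweep(sweep(as.matrix(x_val), 2, x_mu), 2, x_sd, "/")
    yv <- (as.numeric(y_val) - y_mu) / y_sd
  }

  np <- p * h + 2 * h + 1
  theta <- with_seed(cfg$seed, stats::runif(np, -0.5, 0.5))
  lambda <- 1e-3
  n <- nrow(Xs)

  fw <- .mlp_forward(theta, Xs, p, h)
  mse <- mean((fw$yhat - ys)^2)
  best_val <- Inf
  best_theta <- theta
  fail_count <- 0L
  history <- data.frame(epoch = integer(0), mse = numeric(0),
                        val_mse = numeric(0))
  stop_reason <- "max_epochs"

  for (epoch in seq_len(cfg$max_epochs)) {
    if (mse <= cfg$mse_goal) {
      stop_reason <- "mse_goal"
      break
    }
    if (cfg$use_lm) {
      r <- fw$yhat - ys
      J <- .mlp_jacobian(fw, Xs, p, h)
      JtJ <- crossprod(J)
      g <- crossprod(J, r)
      accepted <- FALSE
      for (try in 1:30) {
        delta <- tryCatch(
          solve(JtJ + lambda * diag(np), -g),
          error = function(e) NULL)
        if (!is.null(delta)) {
          theta_new <- theta + drop(delta)
          fw_new <- .mlp_forward(theta_new, Xs, p, h)
          mse_new <- mean((fw_new$yhat - ys)^2)
          if (is.finite(mse_new) && mse_new < mse) {
            theta <- theta_new
            fw <- fw_new
            mse <- mse_new
            lambda <- max(lambda / 10, 1e-12)
            accepted <- TRUE
            break
          }
        }
        lambda <- lambda * 10
        if (lambda > 1e10) break
      }
      if (!accepted) {
        stop_reason <- "lm_stalled"
        break
      }
    } else {
      r <- fw$yhat - ys
      J <- .mlp_jacobian(fw, Xs, p, h)
      grad <- 2 * crossprod(J, r) / n
      theta <- theta - cfg$learning_rate * drop(grad)
      fw <- .mlp_forward(theta, Xs, p, h)
      mse <- mean((fw$yhat - ys)^2)
    }

    val_mse <- NA_real_
    if (has_val) {
      val_mse <- mean((.mlp_forward(theta, Xv, p, h)$yhat - yv)^2)
      if (val_mse < best_val) {
        best_val <- val_mse
        best_theta <- theta
        fail_count <- 0L
      } else {
        fail_count <- fail_count + 1L
        if (fail_count >= cfg$max_fail) {
          history <- rbind(history, data.frame(epoch = epoch, mse = mse,
                                               val_mse = val_mse))
          stop_reason <- "max_fail"
          break
        }
      }
    }
    history <- rbind(history, data.frame(epoch = epoch, mse = mse,
                                         val_mse = val_mse))
  }

  final_theta <- if (has_val && is.finite(best_val)) best_theta else theta
  structure(list(
    weights = .mlp_unpack(final_theta, p, h), theta = final_theta,
    n_inputs = p, n_hidden = h, input_names = colnames(X),
    x_mu = x_mu, x_sd = x_sd, y_mu = y_mu, y_sd = y_sd,
    history = history, stop_reason = stop_reason, cfg = cfg
  ), class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf(
    "<mlp_model> %d -> %d (tanh) -> 1, %d epochs, stop: %s, final MSE %.3g\n",
    x$n_inputs, x$n_hidden, nrow(x$history), x$stop_reason,
    if (nrow(x$history)) x$history$mse[nrow(x$history)] else NA))
  invisible(x)
}

#' Predict from a trained MLP
#'
#' Deterministic forward pass; the training-set standardization is applied to
#' the inputs and inverted on the output.
#'
#' @param model An `mlp_model` from [train_mlp()].
#' @param x New inputs (matrix or data frame with `model$n_inputs` columns).
#' @return Numeric vector of estimates on the original target scale.
#' @export
predict_mlp <- function(model, x) {
  stopifnot(inherits(model, "mlp_model"))
  X <- as.matrix(x)
  if (ncol(X) != model$n_inputs) {
    stopf("'x' has %d columns but the model expects %d", ncol(X),
          model$n_inputs)
  }
  Xs <- sweep(sweep(X, 2, model$x_mu), 2, model$x_sd, "/")
  fw <- .mlp_forward(model$theta, Xs, model$n_inputs, model$n_hidden)
  fw$yhat * model$y_sd + model$y_mu
}
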