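test_that("SNR follows the sum-of-squares definition", {
  expect_equal(snr(c(0, 2), c(1, 1)), 0)              # signal SS 2, resid SS 2
  expect_equal(snr(1:10, 1:10), 100)                  # zero residual: capped
  expect_equal(snr(1:10, rep(5.5, 10)), 0)            # estimate at the mean
  a <- c(1, 2, 3, 4)
  expect_equal(snr(a, a + 0.1), 10 * log10(5 / 0.04))
  expect_error(snr(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(snr(1:3, 1:4), "equal length")
})

test_that("univariate mapping reports r, R2 and SNR", {
  x <- seq(70, 100, length.out = 20)
  res <- univariate_map(x, 2 * x)
  expect_equal(res$pearson_r, 1)
  expect_equal(res$snr_db, 100)
  expect_equal(unname(res$coefficients), c(0, 2), tolerance = 1e-10)
  # orthogonalized noise: r near zero
  set.seed(5)
  y <- rnorm(100)
  x2 <- rnorm(100)
  y_perp <- residuals(lm(y ~ x2))
  res2 <- univariate_map(x2, y_perp)
  expect_lt(abs(res2$pearson_r), 1e-10)
  expect_equal(res2$r_squared, res2$pearson_r^2)
  expect_error(univariate_map(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("contiguous folds partition the data and rotate validation", {
  f <- make_folds(10, 5)
  expect_equal(lengths(f$folds), rep(2, 5))
  expect_equal(sort(unlist(f$folds)), 1:10)
  expect_identical(make_folds(10, 5), make_folds(10, 5))
  # contiguity in repetition order
  expect_true(all(vapply(f$folds, function(b) all(diff(b) == 1), logical(1))))
  f2 <- make_folds(13, 5)
  expect_equal(sum(lengths(f2$folds)), 13)
  expect_lte(diff(range(lengths(f2$folds))), 1)
  fs1 <- make_folds(20, 5, seed = 3, shuffle = TRUE)
  fs2 <- make_folds(20, 5, seed = 3, shuffle = TRUE)
  expect_identical(fs1, fs2)
  expect_equal(sort(unlist(fs1$folds)), 1:20)
  expect_error(make_folds(3, 5), ">= k")
})

test_that("stepwise selection finds the true support", {
  set.seed(6)
  X <- as.data.frame(matrix(rnorm(100 * 6), ncol = 6))
  names(X) <- c("RMS_pct", "MAV_pct", "MNF_pct", "MDF_pct", "IMNF_pct",
                "IMDF_pct")
  y <- 2 * X$IMDF_pct + rnorm(100, sd = 0.5)
  sw <- stepwise_mlr(X, y)
  expect_identical(sw$selected, "IMDF_pct")
  expect_gte(sw$r_squared, univariate_map(X$IMDF_pct, y)$r_squared)
  expect_match(sw$equation, "^Power% = [0-9.]+ × IMDF% [+−] [0-9.]+$")
  # collinear duplicate: exactly one of the pair enters
  Xd <- X
  Xd$DUP_pct <- X$IMDF_pct
  swd <- stepwise_mlr(Xd, y)
  expect_equal(sum(c("IMDF_pct", "DUP_pct") %in% swd$selected), 1)
  expect_error(stepwise_mlr(X[1:5, ], y[1:5]), ">= 10")
})

test_that("stepwise selection on pure noise usually stays intercept-only", {
  # uncorrected forward selection over six candidates keeps the intercept
  # with probability ~0.95^6 ~ 0.74; assert the computed behaviour
  set.seed(7)
  kept <- vapply(1:100, function(i) {
    X <- as.data.frame(matrix(rnorm(40 * 6), ncol = 6))
    names(X) <- paste0("F", 1:6, "_pct")
    y <- rnorm(40)
    sw <- suppressWarnings(stepwise_mlr(X, y))
    length(sw$selected) == 0
  }, logical(1))
  expect_gte(mean(kept), 0.60)
  # intercept-only model scores 0 dB by construction
  X <- as.data.frame(matrix(rnorm(40 * 2), ncol = 2))
  names(X) <- c("A_pct", "B_pct")
  set.seed(100)
  y <- rnorm(40)
  sw <- suppressWarnings(stepwise_mlr(X, y, p_enter = 1e-12))
  expect_length(sw$selected, 0)
  expect_equal(sw$snr_db, 0)
})

test_that("LM training matches the least-squares oracle on linear data", {
  set.seed(10)
  x <- matrix(runif(200, -2, 2), ncol = 1)
  y <- 3 * x[, 1] + 1 + rnorm(200, sd = 0.1)
  tr <- 1:150
  va <- 151:200
  m <- train_mlp(x[tr, , drop = FALSE], y[tr], x[va, , drop = FALSE], y[va],
                 mlp_config(seed = 1))
  ols <- lm(yy ~ xx, data = data.frame(xx = x[tr, 1], yy = y[tr]))
  mse_mlp <- mean((predict_mlp(m, x[va, , drop = FALSE]) - y[va])^2)
  mse_ols <- mean((predict(ols, data.frame(xx = x[va, 1])) - y[va])^2)
  expect_lt(mse_mlp, 1.1 * mse_ols)
  # training MSE is non-increasing across accepted LM steps
  expect_true(all(diff(m$history$mse) <= 1e-12))
})

test_that("the MLP learns a quadratic map", {
  r2s <- vapply(1:10, function(s) {
    set.seed(s)
    x <- matrix(runif(200, -1, 1), ncol = 1)
    y <- x[, 1]^2
    tr <- 1:150
    va <- 151:200
    m <- train_mlp(x[tr, , drop = FALSE], y[tr], x[va, , drop = FALSE],
                   y[va], mlp_config(seed = s))
    yh <- predict_mlp(m, x[va, , drop = FALSE])
    1 - sum((y[va] - yh)^2) / sum((y[va] - mean(y[va]))^2)
  }, numeric(1))
  expect_gt(median(r2s), 0.95)
})

test_that("MLP training honours its stopping contracts", {
  set.seed(11)
  x <- matrix(rnorm(100), ncol = 1)
  y <- 2 * x[, 1] + rnorm(100, sd = 0.05)
  # goal above the initial MSE: stops within one epoch
  m <- train_mlp(x, y, cfg = mlp_config(mse_goal = 100, seed = 1))
  expect_lte(nrow(m$history), 1)
  expect_equal(m$stop_reason, "mse_goal")
  # deterministic under a fixed seed
  m1 <- train_mlp(x, y, cfg = mlp_config(seed = 4))
  m2 <- train_mlp(x, y, cfg = mlp_config(seed = 4))
  expect_identical(m1$theta, m2$theta)
  expect_identical(predict_mlp(m1, x), predict_mlp(m2, x))
  # epoch cap respected
  m3 <- train_mlp(x, y, cfg = mlp_config(max_epochs = 5, seed = 2))
  expect_lte(nrow(m3$history), 5)
  # gradient-descent fallback uses the configured learning rate
  m4 <- train_mlp(x, y, cfg = mlp_config(use_lm = FALSE, max_epochs = 20,
                                         seed = 2))
  expect_equal(nrow(m4$history), 20)
})

test_that("MLP forward pass behaves like its weights say", {
  set.seed(12)
  x <- matrix(rnorm(60), ncol = 2)
  y <- x[, 1] + x[, 2]
  m <- train_mlp(x, y, cfg = mlp_config(max_epochs = 2, seed = 1))
  # zero hidden->output weights: constant output at the (unstandardized) bias
  m0 <- m
  p <- m$n_inputs
  h <- m$n_hidden
  m0$theta[(p * h + h + 1):(p * h + 2 * h)] <- 0         # w2
  m0$theta[length(m0$theta)] <- 0.5                      # b2
  out <- predict_mlp(m0, x)
  expect_equal(out, rep(0.5 * m$y_sd + m$y_mu, nrow(x)))
  expect_error(predict_mlp(m, x[, 1, drop = FALSE]), "expects")
})

test_that("cross-validated comparison pools one estimate per point", {
  co <- simulate_feature_cohort(6, 10, coupling = "linear", seed = 2)
  cmp <- compare_linear_nonlinear(co, co$power_pct, folds = 5,
                                  cfg = mlp_config(seed = 2))
  expect_equal(length(cmp$mlp$estimated), nrow(co))
  expect_false(anyNA(cmp$mlp$estimated))
  expect_s3_class(cmp$line_test, "line_comparison")
  # deterministic rerun
  cmp2 <- compare_linear_nonlinear(co, co$power_pct, folds = 5,
                                   cfg = mlp_config(seed = 2))
  expect_identical(cmp$mlp$estimated, cmp2$mlp$estimated)
  expect_identical(cmp$linear$equation, cmp2$linear$equation)
  expect_error(compare_linear_nonlinear(co[1:10, ], co$power_pct[1:10]),
               ">= 25")
})

test_that("univariate R2 equals stepwise R2 when one predictor enters", {
  set.seed(13)
  x <- rnorm(60)
  y <- 1.5 * x + rnorm(60, sd = 0.4)
  X <- data.frame(ONLY_pct = x)
  sw <- stepwise_mlr(X, y)
  expect_identical(sw$selected, "ONLY_pct")
  expect_equal(sw$r_squared, univariate_map(x, y)$r_squared,
               tolerance = 1e-12)
})

test_that("feature cohorts have the advertised coupling structure", {
  co_l <- simulate_feature_cohort(10, 20, coupling = "linear", seed = 3)
  co_n <- simulate_feature_cohort(10, 20, coupling = "nonlinear", seed = 3)
  expect_equal(nrow(co_l), 200)
  expect_identical(co_l$IMDF_pct, co_n$IMDF_pct)   # same features, new map
  # linear world: residual of the true linear form is pure noise
  res_l <- co_l$power_pct -
    (100 + 0.7 * (co_l$IMDF_pct - 100) + 0.2 * (co_l$MNF_pct - 100))
  expect_lt(sd(res_l), 3.5)
  res_n <- co_n$power_pct -
    (100 + 0.7 * (co_n$IMDF_pct - 100) + 0.2 * (co_n$MNF_pct - 100))
  expect_gt(sd(res_n), sd(res_l))
})
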