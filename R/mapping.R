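# Mapping percent power loss from percent sEMG changes: univariate and
# forward-stepwise multiple linear regression, cross-validated MLP, the
# signal-to-noise ratio score, and the linear-vs-nonlinear comparison.

.snr_cap_db <- 100

#' Signal-to-noise ratio of estimated versus actual series
#'
#' `10 log10( sum((a - mean(a))^2) / sum((a - e)^2) )` in dB: the actual
#' series' variability about its mean over the estimation residual. A
#' numerically zero residual is capped at +100 dB; a constant estimate at the
#' actual mean scores exactly 0 dB.
#'
#' @param actual Actual values.
#' @param estimated Estimated values (same length, >= 2).
#' @return SNR in dB.
#' @examples
#' snr(c(0, 2), c(1, 1))   # 0 dB
#' @export
snr <- function(actual, estimated) {
  n <- length(actual)
  if (n < 2 || length(estimated) != n) {
    stopf("'actual' and 'estimated' must have equal length >= 2")
  }
  ss_sig <- sum((actual - mean(actual))^2)
  if (ss_sig <= 0) stopf("SNR undefined: actual series has zero variance")
  ss_res <- sum((actual - estimated)^2)
  if (ss_res <= ss_sig * 1e-12) return(.snr_cap_db)
  min(10 * log10(ss_sig / ss_res), .snr_cap_db)
}

.mapping_result <- function(actual, estimated, coefficients = NULL,
                            method = "linear", extra = list()) {
  r <- stats::cor(actual, estimated)
  structure(c(list(actual = actual, estimated = estimated,
                   pearson_r = r, r_squared = r^2,
                   snr_db = snr(actual, estimated),
                   coefficients = coefficients, method = method), extra),
            class = "mapping_result")
}

#' @export
print.mapping_result <- function(x, ...) {
  cat(sprintf("<mapping_result> %s: n = %d, r = %.3f, R2 = %.3f, SNR = %.3f dB\n",
              x$method, length(x$actual), x$pearson_r, x$r_squared, x$snr_db))
  if (!is.null(x$equation)) cat(" ", x$equation, "\n")
  invisible(x)
}

#' Univariate linear map from one percent feature to percent power
#'
#' Ordinary least squares of `y_pct` on `x_pct`; reports Pearson r (signed),
#' R-squared, the fitted coefficients, and the SNR of the fitted versus
#' actual series.
#'
#' @param x_pct Percent feature series.
#' @param y_pct Percent power series.
#' @return A `mapping_result`.
#' @export
univariate_map <- function(x_pct, y_pct) {
  if (length(x_pct) != length(y_pct) || length(x_pct) < 3) {
    stopf("need >= 3 paired points")
  }
  if (stats::sd(x_pct) == 0) stopf("degenerate fit: 'x_pct' has zero variance")
  fit <- stats::lm(y_pct ~ x_pct)
  res <- .mapping_result(y_pct, stats::fitted(fit),
                         coefficients = stats::coef(fit),
                         method = "univariate")
  # report the signed x-y correlation (cor(actual, fitted) loses the sign
  # and is unstable for a near-zero slope)
  res$pearson_r <- stats::cor(x_pct, y_pct)
  res$r_squared <- res$pearson_r^2
  res
}

# Regression equation string in the reporting format
# "Power% = 0.176 x IMNF% + 0.064 x MNF% + 32.473".
.equation_string <- function(coefs, terms, response = "Power%") {
  label <- function(nm) paste0(sub("_pct$", "", nm), "%")
  if (length(terms) == 0) {
    return(sprintf("%s = %.3f", response, coefs[["(Intercept)"]]))
  }
  b <- coefs[terms]
  lead <- sprintf("%s%.3f × %s", if (b[1] < 0) "−" else "", abs(b[1]),
                  label(terms[1]))
  rest <- if (length(terms) > 1) {
    paste(sprintf(" %s %.3f × %s", ifelse(b[-1] < 0, "−", "+"), abs(b[-1]),
                  vapply(terms[-1], label, "")), collapse = "")
  } else ""
  intercept <- coefs[["(Intercept)"]]
  sprintf("%s = %s%s %s %.3f", response, lead, rest,
          if (intercept < 0) "−" else "+", abs(intercept))
}

#' Forward-stepwise multiple linear regression
#'
#' Forward selection with backward checks on partial t-test p-values: the
#' candidate with the smallest p below `p_enter` enters; after each entry any
#' selected predictor whose p exceeds `p_remove` is dropped. Aliased
#' (collinear-duplicate) candidates never enter. If no predictor meets the
#' entry threshold an intercept-only model is returned with a warning.
#'
#' @param x_pct Data frame of percent feature predictors (typically RMS_pct,
#'   MAV_pct, MNF_pct, MDF_pct, IMNF_pct, IMDF_pct).
#' @param y_pct Percent power series (>= 10 points).
#' @param p_enter,p_remove Entry/removal p thresholds (0.05 / 0.10).
#' @return A `mapping_result` with fields `selected`, `equation` and `model`.
#' @export
stepwise_mlr <- function(x_pct, y_pct, p_enter = 0.05, p_remove = 0.10) {
  X <- as.data.frame(x_pct)
  if (nrow(X) != length(y_pct)) stopf("'x_pct' rows must match 'y_pct'")
  if (nrow(X) < 10) stopf("need >= 10 points for stepwise selection")
  candidates <- names(X)
  selected <- character(0)
  dat <- cbind(X, .y = y_pct)

  term_p <- function(vars, of) {
    fml <- stats::reformulate(vars, response = ".y")
    sm <- summary(stats::lm(fml, data = dat))$coefficients
    if (!of %in% rownames(sm)) return(1)    # aliased
    sm[of, 4]
  }

  visited <- character(0)
  repeat {
    pool <- setdiff(candidates, selected)
    if (length(pool) == 0) break
    pv <- vapply(pool, function(v) term_p(c(selected, v), v), numeric(1))
    if (min(pv) >= p_enter) break
    entering <- pool[which.min(pv)]
    selected <- c(selected, entering)
    # backward pass
    repeat {
      if (length(selected) <= 1) break
      ps <- vapply(selected, function(v) term_p(selected, v), numeric(1))
      worst <- which.max(ps)
      if (ps[worst] <= p_remove) break
      selected <- selected[-worst]
    }
    key <- paste(sort(selected), collapse = "|")
    if (key %in% visited) break            # cycle guard
    visited <- c(visited, key)
  }

  if (length(selected) == 0) {
    warning("no predictor met the entry threshold; intercept-only model")
    fit <- stats::lm(.y ~ 1, data = dat)
  } else {
    fit <- stats::lm(stats::reformulate(selected, response = ".y"),
                     data = dat)
  }
  est <- as.numeric(stats::fitted(fit))
  extra <- list(selected = selected,
                equation = .equation_string(stats::coef(fit), selected),
                model = fit)
  if (length(selected) == 0) {
    # constant estimate: r undefined, SNR is exactly 0 dB by construction
    return(structure(c(list(actual = y_pct, estimated = est, pearson_r = 0,
                            r_squared = 0, snr_db = snr(y_pct, est),
                            coefficients = stats::coef(fit),
                            method = "stepwise_mlr"), extra),
                     class = "mapping_result"))
  }
  res <- .mapping_result(y_pct, est, coefficients = stats::coef(fit),
                         method = "stepwise_mlr", extra = extra)
  res$r_squared <- summary(fit)$r.squared
  res
}

#' Contiguous k-fold split in repetition order
#'
#' Partitions `1:n_points` into `k` contiguous blocks of near-equal size
#' (the protocol's four training segments plus one validation segment when
#' `k = 5`); each block validates exactly once as the folds rotate.
#' `shuffle = TRUE` permutes the indices first (seeded).
#'
#' @param n_points Number of data points (>= k).
#' @param k Number of folds (default 5).
#' @param seed Seed used only when shuffling.
#' @param shuffle Permute before blocking (default `FALSE`).
#' @return An object of class `cv_folds`: a list with `folds` (list of k
#'   validation index vectors), `n`, `k`.
#' @export
make_folds <- function(n_points, k = 5, seed = 1, shuffle = FALSE) {
  if (!is_count(n_points) || !is_count(k) || n_points < k) {
    stopf("'n_points' must be an integer >= k")
  }
  idx <- seq_len(n_points)
  if (shuffle) idx <- with_seed(seed, sample(idx))
  sizes <- rep(n_points %/% k, k) + (seq_len(k) <= n_points %% k)
  folds <- split(idx, rep(seq_len(k), times = sizes))
  structure(list(folds = unname(folds), n = n_points, k = k),
            class = "cv_folds")
}

#' Compare linear and non-linear mapping of power loss
#'
#' Fits the forward-stepwise multiple linear regression on all points
#' (reported as the regression equation) and a cross-validated MLP (each of
#' the `k` contiguous blocks is validated once by a network trained on the
#' other blocks; out-of-fold estimates are pooled), then scores both with
#' Pearson r and SNR, and compares the two actual-versus-estimated regression
#' lines with slope and intercept F tests.
#'
#' @param features Data frame holding the percent predictor columns.
#' @param power_pct Percent power series (>= 25 points).
#' @param folds Number of folds or a [make_folds()] object (default 5).
#' @param cfg An [mlp_config()].
#' @param predictors Predictor column names (default the six percent
#'   features).
#' @return An object of class `mapping_comparison` with elements `linear`,
#'   `mlp` (both `mapping_result`) and `line_test`
#'   (a [compare_regression_lines()] result).
#' @export
compare_linear_nonlinear <- function(features, power_pct, folds = 5,
                                     cfg = mlp_config(),
                                     predictors = c("RMS_pct", "MAV_pct",
                                                    "MNF_pct", "MDF_pct",
                                                    "IMNF_pct", "IMDF_pct")) {
  if (!all(predictors %in% names(features))) {
    stopf("missing predictor columns: %s",
          paste(setdiff(predictors, names(features)), collapse = ", "))
  }
  X <- as.data.frame(features)[predictors]
  y <- as.numeric(power_pct)
  n <- length(y)
  if (n < 25) stopf("need >= 25 points")
  if (!inherits(folds, "cv_folds")) folds <- make_folds(n, folds)

  linear <- stepwise_mlr(X, y)

  est_mlp <- rep(NA_real_, n)
  for (i in seq_along(folds$folds)) {
    val <- folds$folds[[i]]
    tr <- setdiff(seq_len(n), val)
    fold_cfg <- cfg
    fold_cfg$seed <- derive_seed(cfg$seed, i)
    m <- train_mlp(X[tr, , drop = FALSE], y[tr],
                   X[val, , drop = FALSE], y[val], fold_cfg)
    est_mlp[val] <- predict_mlp(m, X[val, , drop = FALSE])
  }
  mlp <- .mapping_result(y, est_mlp, method = "mlp_cv")

  line_test <- compare_regression_lines(y, linear$estimated, y, est_mlp)
  structure(list(linear = linear, mlp = mlp, line_test = line_test,
                 folds = folds),
            class = "mapping_comparison")
}

#' @export
print.mapping_comparison <- function(x, ...) {
  cat("<mapping_comparison>\n")
  cat(sprintf("  stepwise MLR: r = %.3f, R2 = %.3f, SNR = %.3f dB\n",
              x$linear$pearson_r, x$linear$r_squared, x$linear$snr_db))
  cat(sprintf("    %s\n", x$linear$equation))
  cat(sprintf("  MLP (cross-validated): r = %.3f, SNR = %.3f dB\n",
              x$mlp$pearson_r, x$mlp$snr_db))
  cat(sprintf("  line comparison: slope F = %.2f (p = %.3g), intercept F = %.2f (p = %.3g)\n",
              x$line_test$F_slope, x$line_test$p_slope,
              x$line_test$F_intercept, x$line_test$p_intercept))
  invisible(x)
}

#' Feature-level synthetic cohort for mapping evaluation
#'
#' Generates pooled per-repetition percent-change tables (the six percent
#' features plus percent power) for a cohort, with a known feature-to-power
#' map: `coupling = "linear"` makes percent power an affine function of the
#' features plus noise; `coupling = "nonlinear"` adds a centered quadratic
#' and an interaction term, so only a non-linear learner can capture the full
#' map. Used to evaluate mapping methods without resynthesizing raw sEMG.
#'
#' All trajectories decline/grow along a per-subject latent fatigue ramp with
#' autocorrelated disturbances, mimicking pooled IME percent tables.
#'
#' @param n_subjects Number of subjects (default 40).
#' @param n_reps Repetitions per subject (default 30).
#' @param coupling `"nonlinear"` (default) or `"linear"`.
#' @param noise_sd SD of the power noise in percent points (default 3).
#' @param seed RNG seed.
#' @return Data frame with `subject`, `rep`, the six `_pct` feature columns
#'   and `power_pct`.
#' @export
simulate_feature_cohort <- function(n_subjects = 40, n_reps = 30,
                                    coupling = c("nonlinear", "linear"),
                                    noise_sd = 3, seed = 1) {
  coupling <- match.arg(coupling)
  if (!is_count(n_subjects) || !is_count(n_reps)) {
    stopf("'n_subjects' and 'n_reps' must be positive integers")
  }
  with_seed(seed, {
    rows <- lapply(seq_len(n_subjects), function(s) {
      f <- (seq_len(n_reps) - 1) / (n_reps - 1)
      ar <- function(sd) {
        e <- stats::rnorm(n_reps, sd = sd)
        as.numeric(stats::filter(e, 0.6, method = "recursive"))
      }
      u <- pmin(pmax(f + ar(0.05), 0), 1.2)
      imnf <- 100 - 28 * u + stats::rnorm(n_reps, sd = 2.0)
      imdf <- 100 - 30 * u + stats::rnorm(n_reps, sd = 1.5)
      mnf <- 100 - 18 * u + stats::rnorm(n_reps, sd = 3.0)
      mdf <- 100 - 20 * u + stats::rnorm(n_reps, sd = 2.5)
      rms <- 100 + 18 * u + stats::rnorm(n_reps, sd = 3.0)
      mav <- 100 + 15 * u + stats::rnorm(n_reps, sd = 3.0)
      linear_part <- 100 + 0.7 * (imdf - 100) + 0.2 * (mnf - 100)
      a <- (imdf - 85) / 15       # centered, ~[-1, 1]
      b <- (rms - 109) / 9
      nonlin_part <- 6 * (a^2 - 0.5) + 5 * a * b
      gamma <- if (coupling == "nonlinear") 1 else 0
      power <- linear_part + gamma * nonlin_part +
        stats::rnorm(n_reps, sd = noise_sd)
      data.frame(subject = s, rep = seq_len(n_reps), RMS_pct = rms,
                 MAV_pct = mav, MNF_pct = mnf, MDF_pct = mdf,
                 IMNF_pct = imnf, IMDF_pct = imdf, power_pct = power)
    })
    do.call(rbind, rows)
  })
}
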