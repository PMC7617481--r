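# Linear-nonlinear neural-response prediction: noise-power inclusion,
# PCA + Lasso + rectified sigmoid fitting, and CC_norm scoring.

#' Signal/noise power decomposition of repeated-trial responses
#'
#' Standard across-trial decomposition for N trials y_i(t):
#' `SP = (var(sum_i y_i) - sum_i var(y_i)) / (N * (N - 1))` estimates the
#' repeatable signal power, and `NP = mean_i var(y_i) - SP` the trial
#' noise power.
#'
#' @param rates `n_trials x n_bins` matrix of responses.
#' @return A list with `signal_power`, `noise_power`, `total_power`.
#' @export
signal_noise_power <- function(rates) {
  stopifnot(is.matrix(rates), nrow(rates) >= 2)
  N <- nrow(rates)
  sp <- (stats::var(colSums(rates)) - sum(apply(rates, 1, stats::var))) /
    (N * (N - 1))
  tp <- mean(apply(rates, 1, stats::var))
  list(signal_power = sp, noise_power = tp - sp, total_power = tp)
}

#' Noise-power inclusion filter
#'
#' Keeps a neuron when its noise-to-signal power ratio is below the
#' threshold (published cut-off 60); neurons with non-positive estimated
#' signal power have an infinite ratio and are excluded.
#'
#' @param rates `n_neurons x n_trials x n_bins` array (or a
#'   `reference_neuron_set`).
#' @param threshold Maximal noise-to-signal power ratio.
#' @return Logical inclusion mask with attribute `ratio`.
#' @export
noise_power_filter <- function(rates, threshold = 60) {
  if (inherits(rates, "reference_neuron_set")) rates <- rates$rates
  stopifnot(length(dim(rates)) == 3L)
  if (dim(rates)[2] < 2) stop("need at least 2 trials")
  ratio <- vapply(seq_len(dim(rates)[1]), function(n) {
    dec <- signal_noise_power(matrix(rates[n, , ], dim(rates)[2]))
    if (dec$signal_power <= 0) Inf else dec$noise_power / dec$signal_power
  }, numeric(1))
  mask <- ratio < threshold
  attr(mask, "ratio") <- ratio
  mask
}

#' Normalised correlation coefficient of a prediction
#'
#' `CC_abs` is the Pearson correlation between the prediction and the
#' trial-averaged response; `CC_max = sqrt(SP / var(mean response))` is the
#' best correlation attainable given trial-to-trial noise (signal-power
#' formulation), and `CC_norm = CC_abs / CC_max`. Undefined (flagged via
#' `NA`) when the prediction has zero variance or the signal-power
#' estimate is non-positive.
#'
#' @param prediction Numeric vector of predicted rates.
#' @param rates `n_trials x n_bins` matrix of observed responses.
#' @return A list of class `fit_score`: `cc_abs`, `cc_norm`, `cc_max`,
#'   `n_trials`.
#' @export
cc_norm <- function(prediction, rates) {
  stopifnot(is.matrix(rates), nrow(rates) >= 2,
            length(prediction) == ncol(rates))
  ybar <- colMeans(rates)
  dec <- signal_noise_power(rates)
  cc_max <- if (dec$signal_power <= 0 || stats::var(ybar) <= 0) NA_real_ else
    sqrt(dec$signal_power / stats::var(ybar))
  cc_abs <- if (stats::sd(prediction) == 0 || stats::sd(ybar) == 0) NA_real_ else
    stats::cor(prediction, ybar)
  structure(
    list(cc_abs = cc_abs,
         cc_norm = if (is.na(cc_max) || is.na(cc_abs)) NA_real_ else
           cc_abs / cc_max,
         cc_max = cc_max, n_trials = nrow(rates)),
    class = "fit_score"
  )
}

# Rectified sigmoid output nonlinearity.
rect_sigmoid <- function(x, a, b, c, d) pmax(0, a / (1 + exp((c - x) / b)) + d)

# Fit the rectified sigmoid y ~ rect_sigmoid(x) by nonlinear least
# squares; returns a prediction function, or NULL on failure.
fit_rect_sigmoid <- function(x, y) {
  sx <- stats::sd(x)
  if (sx == 0) return(NULL)
  start <- list(a = max(y) - min(y) + 1e-6, b = sx / 2,
                c = stats::median(x), d = min(y))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ pmax(0, a / (1 + exp((c - x) / b)) + d),
      data = data.frame(x = x, y = y), start = start,
      control = minpack.lm::nls.lm.control(maxiter = 100)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NULL)
  co <- as.list(stats::coef(fit))
  list(coef = co,
       predict = function(xn) rect_sigmoid(xn, co$a, co$b, co$c, co$d))
}

#' Default alpha grid for the sparse linear stage
#'
#' Forty values log-spaced between 10^1 and 10^-5.
#' @return Numeric vector of length 40.
#' @export
alpha_grid <- function() 10^seq(1, -5, length.out = 40)

#' Fit the linear-nonlinear readout for one neuron
#'
#' Hidden activity is reduced to the first `min(200, rank)` principal
#' components fitted on the training rows, a Lasso linear map is fitted
#' for each regularisation strength on the grid, the strength maximising
#' the mean validation CC_norm across k folds (k = 5) of the combined
#' linear-nonlinear mapping is selected, and finally a rectified sigmoid
#' `max(0, a / (1 + exp((c - x)/b)) + d)` is fitted to the linear output
#' by nonlinear least squares. If the sigmoid degrades validation CC_norm
#' by more than `sigmoid_tolerance` the linear stage alone is used
#' (recorded in the result).
#'
#' @param hidden_activity `n_bins x n_units` matrix of model activity
#'   aligned with the response bins.
#' @param rates `n_trials x n_bins` matrix of one neuron's responses.
#' @param splits A list with integer bin indices `train` and `test`
#'   (defaults: last fifth of bins held out, mimicking 3 of 15 clips).
#' @param alphas Regularisation grid (default [alpha_grid()]).
#' @param k_folds Cross-validation folds within the training rows.
#' @param n_components Maximal number of principal components (default
#'   200).
#' @param sigmoid_tolerance Allowed CC_norm degradation before the
#'   linear-only fallback.
#' @return A list of class `ln_readout`: `alpha`, `coef` (on PCs),
#'   `intercept`, `sigmoid` coefficients (or `NULL`), `used_sigmoid`,
#'   `pca` (the `prcomp` basis), `cv` (per-alpha mean validation CC_norm),
#'   `test_score` (a `fit_score` on the held-out bins), and `predict`
#'   (function of new hidden activity).
#' @export
fit_ln <- function(hidden_activity, rates, splits = NULL,
                   alphas = alpha_grid(), k_folds = 5, n_components = 200,
                   sigmoid_tolerance = 0.02) {
  stopifnot(is.matrix(hidden_activity), is.matrix(rates),
            nrow(hidden_activity) == ncol(rates))
  T_ <- nrow(hidden_activity)
  if (is.null(splits)) {
    test <- seq.int(floor(T_ * 0.8) + 1, T_)
    splits <- list(train = setdiff(seq_len(T_), test), test = test)
  }
  tr <- splits$train
  te <- splits$test
  y_mean <- colMeans(rates)
  pca <- stats::prcomp(hidden_activity[tr, , drop = FALSE], center = TRUE)
  k <- min(n_components, sum(pca$sdev > 1e-10))
  project <- function(rows) {
    stats::predict(pca, hidden_activity[rows, , drop = FALSE])[, seq_len(k),
                                                               drop = FALSE]
  }
  Xtr <- project(tr)
  if (any(apply(Xtr, 2, stats::sd) == 0) || stats::sd(y_mean[tr]) == 0) {
    stop("degenerate variance in predictors or responses")
  }
  folds <- rep_len(seq_len(k_folds), length(tr))
  cv_scores <- matrix(NA_real_, k_folds, length(alphas))
  for (f in seq_len(k_folds)) {
    in_f <- tr[folds != f]
    out_f <- tr[folds == f]
    Xf <- project(in_f)
    fit <- glmnet::glmnet(Xf, y_mean[in_f], alpha = 1, lambda = alphas,
                          standardize = TRUE)
    lin_in <- stats::predict(fit, Xf)
    lin_out <- stats::predict(fit, project(out_f))
    for (a in seq_along(alphas)) {
      sg <- fit_rect_sigmoid(lin_in[, a], y_mean[in_f])
      pred <- if (is.null(sg)) lin_out[, a] else sg$predict(lin_out[, a])
      sc <- cc_norm(pred, rates[, out_f, drop = FALSE])
      cv_scores[f, a] <- sc$cc_norm
    }
  }
  cv_mean <- colMeans(cv_scores, na.rm = TRUE)
  best_a <- which.max(cv_mean)
  fit <- glmnet::glmnet(Xtr, y_mean[tr], alpha = 1, lambda = alphas,
                        standardize = TRUE)
  lin_tr <- stats::predict(fit, Xtr)[, best_a]
  sg <- fit_rect_sigmoid(lin_tr, y_mean[tr])
  # linear-only fallback when the sigmoid hurts validation performance
  used_sigmoid <- !is.null(sg)
  if (used_sigmoid) {
    val_lin <- mean(vapply(seq_len(k_folds), function(f) {
      out_f <- tr[folds == f]
      p <- stats::predict(fit, project(out_f))[, best_a]
      cc_norm(p, rates[, out_f, drop = FALSE])$cc_norm
    }, numeric(1)), na.rm = TRUE)
    if (is.finite(val_lin) && is.finite(cv_mean[best_a]) &&
        cv_mean[best_a] < val_lin - sigmoid_tolerance) {
      used_sigmoid <- FALSE
    }
  }
  predict_fun <- function(act_rows) {
    Xn <- stats::predict(pca, act_rows)[, seq_len(k), drop = FALSE]
    lin <- drop(stats::predict(fit, Xn)[, best_a])
    if (used_sigmoid) sg$predict(lin) else lin
  }
  pred_test <- predict_fun(hidden_activity[te, , drop = FALSE])
  structure(
    list(alpha = alphas[best_a],
         coef = drop(fit$beta[, best_a]), intercept = fit$a0[best_a],
         sigmoid = if (used_sigmoid) sg$coef else NULL,
         used_sigmoid = used_sigmoid, n_components = k, pca = pca,
         cv = data.frame(alpha = alphas, cc_norm = cv_mean),
         test_score = cc_norm(pred_test, rates[, te, drop = FALSE]),
         predict = predict_fun, splits = splits),
    class = "ln_readout"
  )
}

#' @export
print.ln_readout <- function(x, ...) {
  cat(sprintf(
    "<ln_readout> alpha %.3g, %d PCs, sigmoid %s; held-out CC_norm %.3f (CC_abs %.3f)\n",
    x$alpha, x$n_components, if (x$used_sigmoid) "yes" else "no (linear fallback)",
    x$test_score$cc_norm, x$test_score$cc_abs
  ))
  invisible(x)
}

#' Fit LN readouts for a population of reference neurons
#'
#' Applies [noise_power_filter()] then [fit_ln()] per retained neuron.
#'
#' @param hidden_activity `n_bins x n_units` model activity.
#' @param neurons A `reference_neuron_set` (or bare rates array).
#' @param ... Passed to [fit_ln()].
#' @return A `data.frame` with per-neuron `alpha`, `cc_abs`, `cc_norm`,
#'   `cc_max`, `used_sigmoid`, `included`; attribute `fits` holds the
#'   `ln_readout` objects of included neurons.
#' @export
fit_ln_population <- function(hidden_activity, neurons, ...) {
  rates <- if (inherits(neurons, "reference_neuron_set")) neurons$rates else neurons
  mask <- noise_power_filter(rates)
  fits <- vector("list", dim(rates)[1])
  rows <- lapply(seq_len(dim(rates)[1]), function(n) {
    if (!mask[n]) {
      return(data.frame(neuron = n, alpha = NA_real_, cc_abs = NA_real_,
                        cc_norm = NA_real_, cc_max = NA_real_,
                        used_sigmoid = NA, included = FALSE))
    }
    f <- fit_ln(hidden_activity, matrix(rates[n, , ], dim(rates)[2]), ...)
    fits[[n]] <<- f
    data.frame(neuron = n, alpha = f$alpha, cc_abs = f$test_score$cc_abs,
               cc_norm = f$test_score$cc_norm, cc_max = f$test_score$cc_max,
               used_sigmoid = f$used_sigmoid, included = TRUE)
  })
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  out
}
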