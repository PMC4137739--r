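#' Root mean square error
#'
#' `sqrt(mean((observed - predicted)^2))`, in the units of the response
#' (percent BRPP throughout this package).
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return nonnegative scalar.
#' @export
rms <- function(observed, predicted) {
  if (length(observed) == 0L) stop("'observed' is empty")
  if (length(observed) != length(predicted))
    stop("'observed' and 'predicted' must have equal length")
  sqrt(mean((observed - predicted)^2))
}

#' Squared correlation between observed and predicted values
#'
#' Two conventions are in routine QSAR use and both are reported by the
#' package: `"ss"` is the coefficient of determination
#' `1 - SSres/SStot`, and `"pearson"` is the squared Pearson correlation.
#' They coincide for in-sample OLS predictions with an intercept but differ
#' for cross-validated or external predictions.
#'
#' @param observed,predicted numeric vectors of equal length, `n >= 3`.
#' @param mode `"ss"` or `"pearson"`.
#' @return scalar; at most 1 (the `"ss"` mode can be negative for
#'   predictions worse than the mean).
#' @export
r_squared <- function(observed, predicted, mode = c("ss", "pearson")) {
  mode <- match.arg(mode)
  if (length(observed) != length(predicted))
    stop("'observed' and 'predicted' must have equal length")
  if (length(observed) < 3L) stop("need at least 3 observations")
  if (stats::sd(observed) == 0)
    stop("undefined statistic: 'observed' is constant")
  if (mode == "ss") {
    1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
  } else {
    stats::cor(observed, predicted)^2
  }
}

#' Leave-one-out cross-validation
#'
#' For each sample k the model is refit on the other n - 1 samples with
#' identical settings and used to predict sample k. The held-out response
#' never enters its own prediction. Returns the LOO predictions together
#' with the cross-validated squared correlation
#' (`R2cv = cor(loo predictions, observed)^2`) and the LOO RMS.
#'
#' @param x descriptor matrix (rows are compounds).
#' @param y numeric response.
#' @param fit a function `function(x, y)` returning a fitted model whose
#'   `predict(model, newdata)` yields numeric predictions; it must be
#'   deterministic given its data.
#' @param predict_fun prediction function, default [stats::predict()].
#' @return list with elements `predictions`, `r_squared_cv`, `rms_cv`.
#' @examples
#' # intercept-only recipe on y = (1, 2, 3): LOO predictions are the
#' # leave-one-out means (2.5, 2.0, 1.5)
#' fit <- function(x, y) structure(list(mu = mean(y)), class = "meanfit")
#' predict.meanfit <- function(object, newdata, ...) {
#'   rep(object$mu, nrow(newdata))
#' }
#' loo_cv(matrix(0, 3, 1), c(1, 2, 3), fit,
#'        predict_fun = function(m, nd) rep(m$mu, nrow(nd)))$predictions
#' @export
loo_cv <- function(x, y, fit, predict_fun = stats::predict) {
  x <- as_descriptor_matrix(x)
  n <- length(y)
  if (nrow(x) != n) stop("'x' and 'y' must have matching rows")
  if (n < 3L) stop("need at least 3 samples for leave-one-out")
  preds <- numeric(n)
  for (k in seq_len(n)) {
    m <- tryCatch(fit(x[-k, , drop = FALSE], y[-k]), error = function(e)
      stop("leave-one-out refit failed at sample ", k, ": ",
           conditionMessage(e), call. = FALSE))
    preds[k] <- as.numeric(predict_fun(m, x[k, , drop = FALSE]))
  }
  list(predictions = preds,
       r_squared_cv = if (stats::sd(preds) == 0) 0 else stats::cor(y, preds)^2,
       rms_cv = rms(y, preds))
}

# exact leave-one-out predictions for OLS with intercept via the PRESS
# identity e_k / (1 - h_k); equals the explicit n-refit loop in exact
# arithmetic
press_loo_ols <- function(X, y) {
  Xi <- cbind(1, X)
  qrX <- qr(Xi)
  if (qrX$rank < ncol(Xi)) stop("singular design in leave-one-out")
  res <- qr.resid(qrX, y)
  h <- rowSums(qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]^2)
  loo_res <- res / (1 - h)
  y - loo_res
}
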