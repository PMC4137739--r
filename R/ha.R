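#' Ordinary least squares fit on a fixed descriptor set
#'
#' Fits `y ~ X` with an intercept and returns the coefficient table and the
#' diagnostics the heuristic algorithm reports: the multiple correlation
#' coefficient \eqn{R^2 = 1 - SS_{res}/SS_{tot}}, the overall F statistic
#' \eqn{F = (R^2/k) / ((1-R^2)/(n-k-1))}, and the residual standard
#' deviation \eqn{s = \sqrt{SS_{res}/(n-k-1)}}.
#'
#' @param x numeric matrix of selected descriptors (no missing values).
#' @param y numeric response (percent BRPP).
#' @return an object of class `ha_model` (with an empty selection trace);
#'   see [ha_fit()] for the fields and available methods.
#' @export
fit_ols <- function(x, y) {
  x <- as_descriptor_matrix(x)
  y <- response_values(y, nrow(x))
  n <- nrow(x); k <- ncol(x)
  if (n <= k + 1L)
    stop("refusing to fit: need n > k + 1 (n = ", n, ", k = ", k, ")")
  if (anyNA(x) || anyNA(y)) stop("missing values in design or response")
  Xi <- cbind("(Intercept)" = 1, x)
  qrX <- qr(Xi)
  if (qrX$rank < ncol(Xi))
    stop("singular design: descriptors are linearly dependent")
  cf <- qr.coef(qrX, y)
  fitted <- as.vector(Xi %*% cf)
  res <- y - fitted
  ssres <- sum(res^2)
  sstot <- sum((y - mean(y))^2)
  df <- n - k - 1L
  s2 <- ssres / df
  XtX_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(pmax(diag(XtX_inv), 0) * s2)
  names(se) <- names(cf)
  r2 <- 1 - ssres / sstot
  fstat <- if (k > 0) (r2 / k) / ((1 - r2) / df) else NA_real_
  structure(list(
    descriptors = colnames(x),
    coefficients = cf,
    se = se,
    t_values = cf / se,
    r_squared = r2,
    f_statistic = fstat,
    s = sqrt(s2),
    n_train = n,
    df_residual = df,
    fitted_values = fitted,
    residuals = res,
    y = y,
    selection = NULL,
    r_squared_cv = NA_real_,
    cv_predictions = NULL,
    removed = NULL
  ), class = "ha_model")
}

#' Fit a BRPP model by the heuristic algorithm
#'
#' The heuristic algorithm (HA) builds a multiple linear regression by
#' (i) pretreating the candidate descriptors ([pretreat()]),
#' (ii) ranking the survivors by absolute correlation with the response
#' ([rank_by_correlation()]), and (iii) forward selection down the ranked
#' list under a collinearity cap: a candidate whose absolute pairwise
#' correlation with any already-selected descriptor exceeds
#' `max_intercorrelation` is never admitted to the model. After each trial
#' addition the model is refit by OLS; a candidate is kept only if it
#' raises the leave-one-out cross-validated \eqn{R^2_{cv}} (computed by the
#' exact PRESS identity). Selection stops at `max_descriptors` or when no
#' admissible candidate improves \eqn{R^2_{cv}}.
#'
#' @param x candidate descriptor table or matrix (training compounds).
#' @param y a [response_vector()] or numeric response (percent), aligned to
#'   the rows of `x`.
#' @param rules [pretreatment_rules()], or `NULL` if `x` is already
#'   pretreated.
#' @param max_intercorrelation collinearity cap on \eqn{|r|} between any two
#'   selected descriptors (default 0.8).
#' @param max_descriptors cap on the model size; defaults to `n/3` so the
#'   cross-validation guard, not the cap, normally ends selection.
#' @return an object of class `ha_model`: list with the selected
#'   `descriptors`, `coefficients` (including `"(Intercept)"`), standard
#'   errors `se`, `t_values`, diagnostics `r_squared`, `f_statistic`, `s`,
#'   `r_squared_cv`, LOO `cv_predictions`, the per-step `selection` trace,
#'   and the pretreatment `removed` log. Methods: `print`, `summary`,
#'   `coef`, `predict`, `fitted`, `residuals`, `plot`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(100 * 10), 100, 10,
#'             dimnames = list(NULL, paste0("D", 1:10)))
#' y <- 50 + 2 * x[, 1] - 3 * x[, 2] + rnorm(100, 0, 0.5)
#' m <- ha_fit(x, y)
#' m$descriptors
#' @export
ha_fit <- function(x, y, rules = pretreatment_rules(),
                   max_intercorrelation = 0.8, max_descriptors = NULL) {
  x <- as_descriptor_matrix(x)
  yv <- response_values(y, nrow(x))
  stopifnot(max_intercorrelation > 0, max_intercorrelation <= 1)
  removed <- NULL
  if (!is.null(rules)) {
    x <- pretreat(x, yv, rules)
    removed <- attr(x, "removed")
    x <- as_descriptor_matrix(x)
  }
  n <- nrow(x)
  if (is.null(max_descriptors)) max_descriptors <- max(1L, n %/% 3L)
  if (max_descriptors < 1L) stop("'max_descriptors' must be at least 1")
  ranked <- rank_by_correlation(x, yv)
  rmat <- abs(stats::cor(x))
  rvec <- as.vector(stats::cor(x, yv)); names(rvec) <- colnames(x)

  selected <- character()
  best_cv <- -Inf
  trace <- list()
  step <- 0L
  repeat {
    if (length(selected) >= max_descriptors) break
    added <- FALSE
    for (cand in setdiff(ranked, selected)) {
      if (length(selected) > 0 &&
          any(rmat[cand, selected] > max_intercorrelation)) {
        trace[[length(trace) + 1L]] <- list(
          step = step + 1L, descriptor = cand, r = unname(rvec[cand]),
          admissible = FALSE, accepted = FALSE,
          reason = "collinearity cap")
        next
      }
      trial <- c(selected, cand)
      cv <- tryCatch({
        loo_pred <- press_loo_ols(x[, trial, drop = FALSE], yv)
        if (stats::sd(loo_pred) == 0) 0 else stats::cor(yv, loo_pred)^2
      }, error = function(e) NA_real_)
      ok <- !is.na(cv) && (cv > best_cv || length(selected) == 0L)
      trace[[length(trace) + 1L]] <- list(
        step = step + 1L, descriptor = cand, r = unname(rvec[cand]),
        admissible = TRUE, accepted = ok,
        r_squared = tryCatch(
          fit_ols(x[, trial, drop = FALSE], yv)$r_squared,
          error = function(e) NA_real_),
        r_squared_cv = cv)
      if (ok) {
        selected <- trial
        best_cv <- cv
        step <- step + 1L
        added <- TRUE
        break
      }
    }
    if (!added) break
  }
  if (length(selected) == 0L)
    stop("forward selection found no admissible descriptor")

  fit <- fit_ols(x[, selected, drop = FALSE], yv)
  loo_pred <- press_loo_ols(x[, selected, drop = FALSE], yv)
  fit$r_squared_cv <- if (stats::sd(loo_pred) == 0) 0 else
    stats::cor(yv, loo_pred)^2
  fit$cv_predictions <- loo_pred
  fit$selection <- do.call(rbind, lapply(trace, function(s)
    data.frame(step = s$step, descriptor = s$descriptor, r = s$r,
               admissible = s$admissible, accepted = s$accepted,
               r_squared = if (is.null(s$r_squared)) NA_real_ else s$r_squared,
               r_squared_cv = if (is.null(s$r_squared_cv)) NA_real_ else
                 s$r_squared_cv,
               stringsAsFactors = FALSE)))
  fit$removed <- removed
  fit
}

#' @export
print.ha_model <- function(x, digits = 4, ...) {
  cat("Heuristic-algorithm linear BRPP model\n")
  cat(sprintf("  %d descriptors selected from n = %d training compounds\n",
              length(x$descriptors), x$n_train))
  print(signif(x$coefficients, digits))
  cat(sprintf("  R2 = %.*f, F = %.*f, s = %.*f", digits, x$r_squared,
              digits, x$f_statistic, digits, x$s))
  if (!is.na(x$r_squared_cv))
    cat(sprintf(", R2cv = %.*f", digits, x$r_squared_cv))
  cat("\n")
  invisible(x)
}

#' @export
summary.ha_model <- function(object, ...) {
  ct <- cbind(Estimate = object$coefficients,
              `Std. Error` = object$se,
              `t value` = object$t_values,
              `Pr(>|t|)` = 2 * stats::pt(abs(object$t_values),
                                         object$df_residual,
                                         lower.tail = FALSE))
  structure(list(coefficients = ct, r_squared = object$r_squared,
                 f_statistic = object$f_statistic, s = object$s,
                 r_squared_cv = object$r_squared_cv,
                 n_train = object$n_train,
                 df_residual = object$df_residual,
                 removed = object$removed),
            class = "summary.ha_model")
}

#' @export
print.summary.ha_model <- function(x, ...) {
  cat("Heuristic-algorithm linear BRPP model\n\nCoefficients:\n")
  stats::printCoefmat(x$coefficients, ...)
  cat(sprintf("\nR2 = %.4f, F = %.3f on %d residual df, s = %.4f, R2cv = %.4f\n",
              x$r_squared, x$f_statistic, x$df_residual, x$s, x$r_squared_cv))
  if (!is.null(x$removed)) {
    counts <- vapply(x$removed, length, integer(1))
    cat("Pretreatment removed:",
        paste(sprintf("%s %d", names(counts), counts), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.ha_model <- function(object, ...) object$coefficients

#' @rdname ha_fit
#' @param object,newdata an `ha_model` and a descriptor table/matrix whose
#'   columns include the selected descriptors.
#' @param ... unused.
#' @export
predict.ha_model <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted_values)
  newdata <- as_descriptor_matrix(newdata)
  miss <- setdiff(object$descriptors, colnames(newdata))
  if (length(miss) > 0)
    stop("newdata lacks selected descriptor(s): ", paste(miss, collapse = ", "))
  X <- newdata[, object$descriptors, drop = FALSE]
  as.vector(cbind(1, X) %*% object$coefficients)
}

#' @export
fitted.ha_model <- function(object, ...) object$fitted_values

#' @export
residuals.ha_model <- function(object, ...) object$residuals

#' @export
plot.ha_model <- function(x, ...) {
  graphics::plot(x$y, x$fitted_values,
                 xlab = "observed BRPP (%)", ylab = "fitted BRPP (%)",
                 main = "Heuristic-algorithm model", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Write the forward-selection trace as JSON
#'
#' One record per candidate considered: step, descriptor, correlation with
#' the response, admissibility under the collinearity cap, and the trial
#' model's R-squared and cross-validated R-squared.
#'
#' @param model an `ha_model` from [ha_fit()].
#' @param path output path.
#' @export
write_selection_trace <- function(model, path) {
  stopifnot(inherits(model, "ha_model"))
  if (is.null(model$selection)) stop("model has no selection trace")
  jsonlite::write_json(model$selection, path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
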