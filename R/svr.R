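#' Gaussian (RBF) kernel
#'
#' `exp(-gamma * ||u - v||^2)`. For two vectors the scalar similarity in
#' (0, 1] is returned; for two matrices, the Gram matrix of their rows.
#'
#' @param u,v numeric vectors of equal length, or matrices with the same
#'   number of columns.
#' @param gamma kernel width parameter, `> 0`; larger values make
#'   similarity more local.
#' @return scalar or `nrow(u) x nrow(v)` matrix.
#' @examples
#' rbf_kernel(c(0, 0), c(1, 0), gamma = 0.035)  # exp(-0.035)
#' @export
rbf_kernel <- function(u, v, gamma) {
  stopifnot(gamma > 0)
  if (is.matrix(u) || is.matrix(v)) {
    u <- rbind(u); v <- rbind(v)
    if (ncol(u) != ncol(v)) stop("dimension mismatch between 'u' and 'v'")
    d2 <- outer(rowSums(u^2), rowSums(v^2), "+") - 2 * tcrossprod(u, v)
    exp(-gamma * pmax(d2, 0))
  } else {
    if (length(u) != length(v)) stop("dimension mismatch between 'u' and 'v'")
    exp(-gamma * sum((u - v)^2))
  }
}

# Gram matrix for the supported kernels
kernel_gram <- function(u, v, kernel, gamma, degree) {
  switch(kernel,
         rbf = rbf_kernel(rbind(u), rbind(v), gamma),
         linear = tcrossprod(rbind(u), rbind(v)),
         polynomial = (tcrossprod(rbind(u), rbind(v)) + 1)^degree,
         stop("unknown kernel: ", kernel))
}

# Solve the epsilon-SVR dual by exact pairwise updates (compiled core).
#
# In terms of beta_i = a_i - a_i* in [-C, C] with sum(beta) = 0, the dual is
#   min 1/2 beta' K beta - y' beta + eps * sum |beta_i|.
# Each iteration picks the maximally KKT-violating pair (i, j) and minimizes
# the (convex, piecewise-quadratic) objective exactly along the feasible
# direction e_i - e_j, so the equality constraint is preserved by
# construction and the objective never increases.
solve_svr_dual <- function(K, y, cost, epsilon, tol = 1e-6, max_iter = 1e5) {
  sol <- .solve_svr_dual_cpp(K, as.numeric(y), cost, epsilon, tol,
                             as.integer(max_iter))
  if (!sol$converged && sol$iterations >= max_iter)
    stop(sprintf(paste0("SVR dual solver did not converge within %d ",
                        "iterations (KKT violation %.3e)"),
                 max_iter, sol$kkt_violation))
  sol
}

#' Fit epsilon-insensitive support vector regression
#'
#' Fits the support-vector regression model
#' \deqn{f(x) = \sum_i (a_i - a_i^*) K(x, x_i) + b}
#' by solving the dual of the epsilon-insensitive problem — box constraints
#' \eqn{0 \le a_i, a_i^* \le C} and equality \eqn{\sum_i (a_i - a_i^*) = 0}
#' — with exact pairwise coordinate updates up to a KKT tolerance.
#' Residuals inside the epsilon tube incur no loss; the penalty `cost`
#' trades tube violations against model flatness.
#'
#' Descriptors are standardized to zero mean and unit variance on the
#' training set by default (the statistics are stored and applied to new
#' rows), since Gaussian-kernel distances are meaningless across descriptors
#' of mixed physical units; the response stays in percent. The default
#' hyperparameters (`gamma` 0.035, `epsilon` 0.173, `cost` 130) are the
#' tuned optima of the BRPP study this package re-implements.
#'
#' @param x descriptor matrix (training compounds), no missing values.
#' @param y numeric response or [response_vector()] (percent BRPP).
#' @param gamma Gaussian kernel width, `> 0` (per squared standardized
#'   distance unit).
#' @param epsilon half-width of the insensitive tube, in response units
#'   (percent), `>= 0`.
#' @param cost penalty C, `> 0`.
#' @param kernel `"rbf"` (default), `"linear"`, or `"polynomial"`.
#' @param degree polynomial degree (polynomial kernel only).
#' @param scale standardize descriptors on the training set (default TRUE).
#' @param tol KKT tolerance of the dual solver (response units).
#' @param max_iter iteration cap for pairwise updates.
#' @return an object of class `svr_model`: list with `dual_coef`
#'   (\eqn{a_i - a_i^*} per training sample), `offset` b, `support`
#'   (indices of nonzero dual coefficients), `hyperparameters`, the stored
#'   (standardized) training inputs, scaling statistics, `fitted_values`,
#'   `iterations` and final `kkt_violation`. Methods: `print`, `predict`,
#'   `fitted`, `residuals`, `plot`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(30 * 2), 30, 2)
#' y <- 50 + 10 * sin(x[, 1]) + rnorm(30)
#' m <- svr_fit(x, y, gamma = 0.5, epsilon = 0.5, cost = 10)
#' rms(y, predict(m, x))
#' @export
svr_fit <- function(x, y, gamma = 0.035, epsilon = 0.173, cost = 130,
                    kernel = c("rbf", "linear", "polynomial"), degree = 3,
                    scale = TRUE, tol = 1e-6, max_iter = 1e5) {
  kernel <- match.arg(kernel)
  x <- as_descriptor_matrix(x)
  y <- response_values(y, nrow(x))
  if (nrow(x) < 2L) stop("need at least 2 training samples")
  if (anyNA(x) || anyNA(y)) stop("missing values in descriptors or response")
  stopifnot(gamma > 0, epsilon >= 0, cost > 0)
  if (scale) {
    center <- colMeans(x)
    scl <- apply(x, 2L, stats::sd)
    if (any(scl == 0))
      stop("zero-variance descriptor(s) cannot be standardized: ",
           paste(colnames(x)[scl == 0], collapse = ", "))
    xs <- sweep(sweep(x, 2L, center), 2L, scl, "/")
  } else {
    center <- NULL; scl <- NULL; xs <- x
  }
  K <- kernel_gram(xs, xs, kernel, gamma, degree)
  sol <- solve_svr_dual(K, y, cost, epsilon, tol = tol, max_iter = max_iter)
  fitted <- as.vector(K %*% sol$beta) + sol$b
  structure(list(
    x = xs,
    center = center,
    scale = scl,
    dual_coef = sol$beta,
    offset = sol$b,
    support = which(abs(sol$beta) > 1e-8),
    hyperparameters = list(gamma = gamma, epsilon = epsilon, cost = cost,
                           kernel = kernel, degree = degree),
    y = y,
    fitted_values = fitted,
    residuals = y - fitted,
    iterations = sol$iterations,
    kkt_violation = sol$kkt_violation,
    tol = tol
  ), class = "svr_model")
}

#' @rdname svr_fit
#' @param object,newdata an `svr_model` and descriptor rows to predict
#'   (matching the training dimension); predictions are the support-vector
#'   expansion and may fall outside \[0, 100\].
#' @param ... unused.
#' @export
predict.svr_model <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted_values)
  newdata <- as_descriptor_matrix(newdata)
  if (ncol(newdata) != ncol(object$x))
    stop("dimension mismatch: model expects ", ncol(object$x),
         " descriptors, got ", ncol(newdata))
  if (!is.null(object$center))
    newdata <- sweep(sweep(newdata, 2L, object$center), 2L, object$scale, "/")
  hp <- object$hyperparameters
  Knew <- kernel_gram(newdata, object$x, hp$kernel, hp$gamma, hp$degree)
  as.vector(Knew %*% object$dual_coef) + object$offset
}

#' @export
print.svr_model <- function(x, digits = 4, ...) {
  hp <- x$hyperparameters
  cat("Epsilon-insensitive support vector regression (", hp$kernel,
      " kernel)\n", sep = "")
  cat(sprintf("  n = %d, support vectors = %d\n", length(x$y),
              length(x$support)))
  cat(sprintf("  gamma = %g, epsilon = %g, cost = %g, offset b = %.*f\n",
              hp$gamma, hp$epsilon, hp$cost, digits, x$offset))
  cat(sprintf("  training RMS = %.*f, KKT violation = %.2e (%d iterations)\n",
              digits, sqrt(mean(x$residuals^2)), x$kkt_violation,
              x$iterations))
  invisible(x)
}

#' @export
fitted.svr_model <- function(object, ...) object$fitted_values

#' @export
residuals.svr_model <- function(object, ...) object$residuals

#' @export
coef.svr_model <- function(object, ...) {
  c(setNames(object$dual_coef,
             paste0("beta_", seq_along(object$dual_coef))),
    offset = object$offset)
}

#' @export
plot.svr_model <- function(x, ...) {
  graphics::plot(x$y, x$fitted_values,
                 xlab = "observed BRPP (%)", ylab = "fitted BRPP (%)",
                 main = "SVR model", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' KKT certificate for a fitted SVR model
#'
#' Verifies the optimality conditions of the dual solution: box
#' feasibility (every \eqn{|a_i - a_i^*| \le C}), the equality constraint
#' (dual coefficients sum to 0 within solver tolerance), and complementary
#' slackness — samples strictly inside the epsilon tube carry zero dual
#' coefficient, and coefficients at the C bound occur only for residuals at
#' or beyond the tube edge.
#'
#' @param model an `svr_model`.
#' @param tol slack allowed in the complementarity checks (response units);
#'   defaults to the model's solver tolerance.
#' @return list with `ok` plus the individual checks `box_ok`,
#'   `equality_residual`, `inside_tube_zero_ok`, `at_bound_ok` and the
#'   solver's final `kkt_violation`.
#' @export
svr_kkt_check <- function(model, tol = NULL) {
  stopifnot(inherits(model, "svr_model"))
  if (is.null(tol)) tol <- max(model$tol, 1e-8)
  beta <- model$dual_coef
  C <- model$hyperparameters$cost
  eps <- model$hyperparameters$epsilon
  # residuals relative to the expansion without loosening by b errors
  r <- model$y - model$fitted_values
  box_ok <- all(abs(beta) <= C + 1e-8 * C)
  eq_res <- abs(sum(beta))
  slack <- max(tol, 10 * model$kkt_violation)
  inside <- abs(r) < eps - slack
  inside_tube_zero_ok <- all(abs(beta[inside]) <= 1e-6 * C)
  at_bound <- abs(abs(beta) - C) <= 1e-8 * C
  at_bound_ok <- all(abs(r[at_bound]) >= eps - slack)
  list(ok = box_ok && eq_res <= 1e-8 * C * length(beta) &&
         inside_tube_zero_ok && at_bound_ok,
       box_ok = box_ok,
       equality_residual = eq_res,
       inside_tube_zero_ok = inside_tube_zero_ok,
       at_bound_ok = at_bound_ok,
       kkt_violation = model$kkt_violation)
}

#' Serialize an SVR model to JSON
#'
#' Stores hyperparameters, dual coefficients, offset, standardization
#' statistics and the (standardized) training inputs; [read_svr_json()]
#' reconstructs a model whose predictions equal the original's.
#'
#' @param model an `svr_model`.
#' @param path output path.
#' @export
write_svr_json <- function(model, path) {
  stopifnot(inherits(model, "svr_model"))
  payload <- list(
    hyperparameters = model$hyperparameters,
    dual_coef = model$dual_coef,
    offset = model$offset,
    center = model$center,
    scale = model$scale,
    x = unname(unclass(model$x)),
    descriptor_names = colnames(model$x),
    y = model$y
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_svr_json
#' @export
read_svr_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  xs <- as.matrix(p$x)
  colnames(xs) <- p$descriptor_names
  hp <- p$hyperparameters
  K <- kernel_gram(xs, xs, hp$kernel, hp$gamma, hp$degree)
  fitted <- as.vector(K %*% p$dual_coef) + p$offset
  structure(list(
    x = xs, center = p$center, scale = p$scale,
    dual_coef = p$dual_coef, offset = p$offset,
    support = which(abs(p$dual_coef) > 1e-8),
    hyperparameters = hp, y = p$y,
    fitted_values = fitted, residuals = p$y - fitted,
    iterations = NA_integer_, kkt_violation = NA_real_, tol = 1e-6
  ), class = "svr_model")
}
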