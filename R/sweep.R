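# default hyperparameter grids: log-spaced, centered on the tuned optima
# of the BRPP study (gamma 0.035, epsilon 0.173 %, cost 130)
default_svr_grids <- function() {
  list(gamma = c(0.001, 0.0035, 0.01, 0.035, 0.1, 0.35, 1),
       epsilon = c(0.01, 0.05, 0.173, 0.5, 1.5, 5, 15),
       cost = c(1, 4.2, 13, 42, 130, 420, 1000))
}

# LOO RMS of an SVR configuration; NA if any inner fit fails
svr_loo_rms <- function(x, y, gamma, epsilon, cost, tol = 1e-4) {
  tryCatch(
    loo_cv(x, y, function(xt, yt)
      svr_fit(xt, yt, gamma = gamma, epsilon = epsilon, cost = cost,
              tol = tol))$rms_cv,
    error = function(e) NA_real_)
}

#' Sweep one SVR hyperparameter against the LOO error
#'
#' Evaluates the leave-one-out RMS on a grid of values for one of `gamma`,
#' `epsilon`, `cost`, holding the other two fixed. Grid points whose fit
#' fails are recorded as `NA` and excluded from the argmin; ties go to the
#' smallest value.
#'
#' @param x descriptor matrix (training compounds).
#' @param y numeric response (percent).
#' @param parameter which hyperparameter to sweep.
#' @param grid strictly increasing positive values to evaluate.
#' @param gamma,epsilon,cost the fixed values of the other parameters
#'   (defaults are the study optima).
#' @param tol solver KKT tolerance used inside the sweep.
#' @return object of class `svr_sweep`: data frame `results` with columns
#'   `value`, `cv_rms`; `best_value`; `parameter`.
#' @export
svr_sweep <- function(x, y, parameter = c("gamma", "epsilon", "cost"), grid,
                      gamma = 0.035, epsilon = 0.173, cost = 130,
                      tol = 1e-4) {
  parameter <- match.arg(parameter)
  if (length(grid) == 0L) stop("'grid' is empty")
  grid <- sort(unique(as.numeric(grid)))
  hp <- list(gamma = gamma, epsilon = epsilon, cost = cost)
  cv <- vapply(grid, function(v) {
    hp[[parameter]] <- v
    svr_loo_rms(x, y, hp$gamma, hp$epsilon, hp$cost, tol = tol)
  }, numeric(1))
  if (all(is.na(cv))) stop("sweep failed at every grid point")
  best <- grid[which.min(cv)]  # which.min skips NA, first minimum = smallest
  structure(list(parameter = parameter,
                 results = data.frame(value = grid, cv_rms = cv),
                 best_value = best),
            class = "svr_sweep")
}

#' @export
print.svr_sweep <- function(x, ...) {
  cat("SVR hyperparameter sweep over '", x$parameter, "' (LOO RMS, %):\n",
      sep = "")
  print(x$results, row.names = FALSE, ...)
  cat("best value:", x$best_value, "\n")
  invisible(x)
}

#' Export a sweep as CSV
#'
#' Writes the grid value / LOO RMS pairs, suitable for plotting the error
#' curve of the sweep.
#'
#' @param sweep an `svr_sweep`.
#' @param path output path.
#' @export
write_sweep_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "svr_sweep"))
  utils::write.csv(sweep$results, path, row.names = FALSE)
  invisible(path)
}

#' Coordinate-wise hyperparameter search for SVR
#'
#' Cyclically sweeps `gamma`, then `epsilon`, then `cost` against the
#' leave-one-out RMS, updating the incumbent after each sweep. The
#' incumbent value is always included among the evaluated points, so the
#' incumbent LOO RMS never increases between rounds. The search stops when
#' a full round leaves all three values unchanged, or after `max_rounds`.
#'
#' @inheritParams svr_sweep
#' @param gamma,epsilon,cost starting values.
#' @param grids named list with elements `gamma`, `epsilon`, `cost`
#'   (strictly increasing positive vectors); see `default_svr_grids` in the
#'   package source for the defaults.
#' @param max_rounds maximum number of full rounds.
#' @return list of class `coordinate_search` with the tuned `gamma`,
#'   `epsilon`, `cost`, the final `cv_rms`, the number of `rounds` run, and
#'   the per-round `sweeps`.
#' @export
coordinate_search <- function(x, y, gamma = 0.035, epsilon = 0.173,
                              cost = 130, grids = default_svr_grids(),
                              max_rounds = 3, tol = 1e-4) {
  stopifnot(all(c("gamma", "epsilon", "cost") %in% names(grids)),
            max_rounds >= 1)
  hp <- list(gamma = gamma, epsilon = epsilon, cost = cost)
  sweeps <- list()
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    prev <- hp
    round_sweeps <- list()
    for (par in c("gamma", "epsilon", "cost")) {
      g <- sort(unique(c(grids[[par]], hp[[par]])))
      sw <- svr_sweep(x, y, parameter = par, grid = g,
                      gamma = hp$gamma, epsilon = hp$epsilon,
                      cost = hp$cost, tol = tol)
      hp[[par]] <- sw$best_value
      round_sweeps[[par]] <- sw
    }
    sweeps[[rounds]] <- round_sweeps
    if (identical(prev, hp) || rounds >= max_rounds) break
  }
  final <- svr_loo_rms(x, y, hp$gamma, hp$epsilon, hp$cost, tol = tol)
  structure(list(gamma = hp$gamma, epsilon = hp$epsilon, cost = hp$cost,
                 cv_rms = final, rounds = rounds, sweeps = sweeps),
            class = "coordinate_search")
}

#' @export
print.coordinate_search <- function(x, ...) {
  cat(sprintf(paste0("Coordinate search (%d round%s): gamma = %g, ",
                     "epsilon = %g, cost = %g; LOO RMS = %.4f\n"),
              x$rounds, if (x$rounds == 1) "" else "s",
              x$gamma, x$epsilon, x$cost, x$cv_rms))
  invisible(x)
}
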