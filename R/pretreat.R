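#' Pretreatment thresholds for descriptor filtering
#'
#' The heuristic algorithm discards candidate descriptors before selection
#' according to four rules: (1) descriptors not possessed by every compound
#' (any missing value); (2) descriptors whose values barely change across
#' compounds; (3) descriptors whose one-variable regression against the
#' response has F below a floor; (4) descriptors whose one-variable slope
#' \eqn{|t|} is below a floor.
#'
#' @param min_variance variance threshold for rule 2. Default `1e-8`,
#'   which removes numerically constant columns without touching
#'   informative ones.
#' @param f_floor F-statistic floor for rule 3 (default 1.0).
#' @param t_floor \eqn{|t|} floor for rule 4. The default 0.1 makes rule 4 a
#'   pass-through filter unless raised.
#' @param drop_incomplete apply rule 1 (default `TRUE`).
#' @return list of class `pretreatment_rules`.
#' @export
pretreatment_rules <- function(min_variance = 1e-8, f_floor = 1.0,
                               t_floor = 0.1, drop_incomplete = TRUE) {
  stopifnot(min_variance >= 0, f_floor >= 0, t_floor >= 0,
            is.logical(drop_incomplete))
  structure(list(min_variance = min_variance, f_floor = f_floor,
                 t_floor = t_floor, drop_incomplete = drop_incomplete),
            class = "pretreatment_rules")
}

#' Apply the four pretreatment rules to a descriptor table
#'
#' Removes descriptors per [pretreatment_rules()], preserving the original
#' column order of the survivors. The removal log is attached as attribute
#' `"removed"`, a list of descriptor names keyed by rule
#' (`incomplete`, `low_variance`, `low_f`, `low_t`).
#'
#' The one-variable F statistic for a descriptor with sample correlation r
#' to the response is \eqn{F = (n-2) r^2 / (1-r^2)}, and its slope t value
#' is the signed square root, \eqn{t = r \sqrt{n-2} / \sqrt{1-r^2}}.
#'
#' @param x descriptor table or numeric matrix.
#' @param y a [response_vector()] or numeric response aligned to the rows
#'   of `x`.
#' @param rules a [pretreatment_rules()] object.
#' @return the surviving columns of `x` (a `descriptor_table`) with the
#'   removal log attached; errors if no descriptor survives.
#' @export
pretreat <- function(x, y, rules = pretreatment_rules()) {
  x <- as_descriptor_matrix(x)
  y <- response_values(y, nrow(x))
  stopifnot(inherits(rules, "pretreatment_rules"))
  removed <- list(incomplete = character(), low_variance = character(),
                  low_f = character(), low_t = character())
  keep <- rep(TRUE, ncol(x))
  names(keep) <- colnames(x)

  if (rules$drop_incomplete) {
    bad <- colSums(is.na(x)) > 0L
    removed$incomplete <- colnames(x)[bad]
    keep[bad] <- FALSE
  } else if (anyNA(x[, keep, drop = FALSE])) {
    stop("missing values present; set drop_incomplete = TRUE or impute first")
  }

  v <- apply(x, 2L, stats::var)
  bad <- keep & !is.na(v) & v < rules$min_variance
  removed$low_variance <- colnames(x)[bad]
  keep[bad] <- FALSE

  n <- nrow(x)
  if (n > 2L && any(keep)) {
    r <- as.vector(stats::cor(x[, keep, drop = FALSE], y))
    r2 <- pmin(r^2, 1 - 1e-15)
    f1 <- (n - 2) * r2 / (1 - r2)
    t1 <- sign(r) * sqrt(f1)
    idx <- which(keep)
    bad_f <- idx[f1 < rules$f_floor]
    removed$low_f <- colnames(x)[bad_f]
    keep[bad_f] <- FALSE
    still <- idx[f1 >= rules$f_floor]
    bad_t <- still[abs(t1[f1 >= rules$f_floor]) < rules$t_floor]
    removed$low_t <- colnames(x)[bad_t]
    keep[bad_t] <- FALSE
  }

  if (!any(keep)) {
    counts <- vapply(removed, length, integer(1))
    stop("all descriptors removed by pretreatment (",
         paste(sprintf("%s: %d", names(counts), counts), collapse = ", "), ")")
  }
  out <- descriptor_table(x[, keep, drop = FALSE])
  attr(out, "removed") <- removed
  out
}

# extract the numeric response (optionally restricted to the training split)
response_values <- function(y, n = NULL, split = NULL) {
  if (inherits(y, "response_vector")) {
    if (!is.null(split)) y <- y[y$split == split, , drop = FALSE]
    y <- y$brpp
  }
  y <- as.numeric(y)
  if (!is.null(n) && length(y) != n)
    stop("response length (", length(y), ") does not match rows (", n, ")")
  y
}

#' Rank descriptors by absolute correlation with the response
#'
#' Orders descriptor names by decreasing \eqn{|r|} (Pearson) against the
#' response; ties are broken by original column order. The table must be
#' pretreated (no missing values, no zero-variance columns).
#'
#' @inheritParams pretreat
#' @return character vector of descriptor names, strongest first.
#' @export
rank_by_correlation <- function(x, y) {
  x <- as_descriptor_matrix(x)
  y <- response_values(y, nrow(x))
  if (anyNA(x)) stop("missing values present; run pretreat() first")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance descriptor(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "),
         " (run pretreat() first)")
  r <- as.vector(stats::cor(x, y))
  colnames(x)[order(-abs(r), seq_along(r))]
}
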