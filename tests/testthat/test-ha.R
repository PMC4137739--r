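test_that("fit_ols reproduces closed-form and oracle solutions", {
  # y = 2x + 1 exactly
  x <- matrix(1:5, 5, 1, dimnames = list(NULL, "x"))
  y <- 2 * (1:5) + 1
  m <- fit_ols(x, y)
  expect_equal(unname(m$coefficients), c(1, 2), tolerance = 1e-12)
  expect_equal(m$r_squared, 1, tolerance = 1e-12)
  expect_equal(m$s, 0, tolerance = 1e-10)

  # random designs match the normal-equations oracle to 1e-10
  for (seed in c(1, 2, 3)) {
    inst <- make_instance(30, 3, seed = seed)
    m <- fit_ols(inst$x, inst$y)
    expect_equal(unname(m$coefficients),
                 unname(normal_equations(inst$x, inst$y)),
                 tolerance = 1e-10)
    # standard errors and t agree with lm's summary
    sm <- summary(lm(inst$y ~ inst$x))$coefficients
    expect_equal(unname(m$se), unname(sm[, "Std. Error"]), tolerance = 1e-8)
    expect_equal(unname(m$t_values), unname(sm[, "t value"]),
                 tolerance = 1e-8)
    expect_equal(unname(m$t_values), unname(m$coefficients / m$se))
  }
})

test_that("fit_ols diagnostics satisfy their identities", {
  inst <- make_instance(40, 4, seed = 21, noise = 5)
  m <- fit_ols(inst$x, inst$y)
  n <- 40; k <- 4
  # R2 equals squared Pearson correlation of fitted vs observed
  expect_equal(m$r_squared, cor(inst$y, m$fitted_values)^2, tolerance = 1e-10)
  expect_equal(m$f_statistic,
               (m$r_squared / k) / ((1 - m$r_squared) / (n - k - 1)),
               tolerance = 1e-12)
  expect_equal(m$s, sqrt(sum(m$residuals^2) / (n - k - 1)), tolerance = 1e-12)
})

test_that("fit_ols refuses degenerate designs", {
  x <- matrix(rnorm(12), 4, 3)
  expect_error(fit_ols(x, rnorm(4)), "n > k")
  xd <- cbind(a = rnorm(20), b = 0)
  xd <- cbind(xd, c = xd[, "a"])
  expect_error(fit_ols(xd, rnorm(20)), "singular|dependent")
})

test_that("forward selection respects the collinearity cap", {
  # two copies of the same column: at most one enters
  set.seed(8)
  n <- 60
  base <- rnorm(n)
  x <- cbind(c1 = base, c2 = base,
             matrix(rnorm(n * 5), n, 5,
                    dimnames = list(NULL, paste0("z", 1:5))))
  y <- 50 + 6 * base + rnorm(n)
  m <- ha_fit(x, y, rules = NULL)
  expect_lte(sum(c("c1", "c2") %in% m$descriptors), 1L)

  # every returned model: max pairwise |r| among selected <= cap
  for (seed in 1:5) {
    inst <- make_instance(50, 12, seed = 100 + seed, noise = 3)
    m <- ha_fit(inst$x, inst$y, rules = NULL, max_intercorrelation = 0.8)
    if (length(m$descriptors) > 1) {
      cm <- abs(cor(inst$x[, m$descriptors]))
      diag(cm) <- 0
      expect_lte(max(cm), 0.8)
    }
  }
})

test_that("forward selection recovers a planted sparse signal", {
  set.seed(42)
  n <- 100
  x <- matrix(rnorm(n * 22), n, 22,
              dimnames = list(NULL, sprintf("D%02d", 1:22)))
  y <- 50 + 2 * x[, "D01"] - 3 * x[, "D02"] + rnorm(n, 0, 1)
  m <- ha_fit(x, y)
  expect_true(all(c("D01", "D02") %in% m$descriptors))
})

test_that("greedy selection never beats exhaustive best-subset R2", {
  for (seed in c(4, 14, 24)) {
    inst <- make_instance(40, 8, seed = seed, noise = 4)
    m <- ha_fit(inst$x, inst$y, rules = NULL, max_descriptors = 3)
    k <- length(m$descriptors)
    # exhaustive search over all subsets of the same size
    best <- -Inf
    for (sub in combn(colnames(inst$x), k, simplify = FALSE)) {
      r2 <- fit_ols(inst$x[, sub, drop = FALSE], inst$y)$r_squared
      if (r2 > best) best <- r2
    }
    expect_lte(m$r_squared, best + 1e-12)
  }
})

test_that("ha_fit predictions, residuals and trace are coherent", {
  inst <- make_instance(60, 10, seed = 31, noise = 3)
  m <- ha_fit(inst$x, inst$y, rules = NULL)
  expect_equal(predict(m, inst$x), m$fitted_values)
  expect_equal(residuals(m), inst$y - m$fitted_values)
  expect_s3_class(m$selection, "data.frame")
  expect_equal(sum(m$selection$accepted), length(m$descriptors))
  # selection trace serializes to JSON
  p <- withr::local_tempfile(fileext = ".json")
  write_selection_trace(m, p)
  expect_true(jsonlite::validate(paste(readLines(p), collapse = "")))
  expect_error(predict(m, inst$x[, 1, drop = FALSE]), "lacks")
})

test_that("noiseless linear data yields an exact training fit", {
  set.seed(2)
  x <- matrix(rnorm(50 * 8), 50, 8,
              dimnames = list(NULL, paste0("D", 1:8)))
  y <- 10 + 4 * x[, 1] - 2 * x[, 2] + x[, 3]
  m <- ha_fit(x, y)
  expect_gt(m$r_squared, 1 - 1e-6)
})
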