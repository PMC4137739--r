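test_that("rms follows its definition", {
  expect_equal(rms(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rms(c(3, 4), c(0, 0)), sqrt(25 / 2))
  set.seed(6)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(rms(a, b), sqrt(sum((a - b)^2) / 50), tolerance = 1e-12)
  expect_error(rms(numeric(), numeric()), "empty")
  expect_error(rms(1:3, 1:4), "equal length")
})

test_that("r_squared modes behave and coincide for in-sample OLS", {
  y <- c(1, 2, 3, 5)
  expect_equal(r_squared(y, y, "ss"), 1)
  expect_equal(r_squared(y, y, "pearson"), 1)
  expect_error(r_squared(rep(1, 5), rnorm(5)), "constant")

  inst <- make_instance(30, 3, seed = 13, noise = 4)
  m <- fit_ols(inst$x, inst$y)
  expect_equal(r_squared(inst$y, m$fitted_values, "ss"),
               r_squared(inst$y, m$fitted_values, "pearson"),
               tolerance = 1e-10)

  # the published training-set fit quality from the packaged tables
  fx <- load_paper_fixture()
  tr <- fx$table2[fx$table2$split == "train", ]
  expect_equal(round(r_squared(tr$brpp, tr$ha_pred, "ss"), 2), 0.85)
})

test_that("leave-one-out predictions match hand and brute-force oracles", {
  # intercept-only recipe on y = (1, 2, 3): LOO means are (2.5, 2.0, 1.5)
  meanfit <- function(x, y) structure(list(mu = mean(y)), class = "mf")
  out <- loo_cv(matrix(0, 3, 1), c(1, 2, 3), meanfit,
                predict_fun = function(m, nd) rep(m$mu, nrow(nd)))
  expect_equal(out$predictions, c(2.5, 2.0, 1.5))

  # OLS recipe equals an independent explicit-refit loop
  inst <- make_instance(25, 3, seed = 77, noise = 3)
  ols_recipe <- function(x, y) fit_ols(x, y)
  got <- loo_cv(inst$x, inst$y, ols_recipe)
  manual <- vapply(seq_len(25), function(k) {
    cf <- normal_equations(inst$x[-k, , drop = FALSE], inst$y[-k])
    sum(c(1, inst$x[k, ]) * cf)
  }, numeric(1))
  expect_equal(got$predictions, manual, tolerance = 1e-9)
  expect_equal(got$r_squared_cv, cor(inst$y, manual)^2, tolerance = 1e-9)

  # the PRESS shortcut used inside forward selection equals the honest loop
  press <- qsarbind:::press_loo_ols(inst$x, inst$y)
  expect_equal(press, got$predictions, tolerance = 1e-8)
})

test_that("the held-out response never influences its own LOO prediction", {
  inst <- make_instance(20, 2, seed = 55, noise = 2)
  ols_recipe <- function(x, y) fit_ols(x, y)
  base <- loo_cv(inst$x, inst$y, ols_recipe)$predictions
  k <- 7
  y2 <- inst$y
  y2[k] <- y2[k] + 500  # gross outlier in the held-out sample
  perturbed <- loo_cv(inst$x, y2, ols_recipe)$predictions
  expect_equal(perturbed[k], base[k], tolerance = 1e-9)
  # and a memorizing recipe cannot leak: honest refits differ from y
  expect_gt(rms(inst$y, base), 0)
})

test_that("loo_cv propagates inner failures with the sample index", {
  bad <- function(x, y) stop("boom")
  expect_error(loo_cv(matrix(rnorm(10), 5, 2), rnorm(5), bad),
               "sample 1")
})
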