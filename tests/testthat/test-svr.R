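test_that("the Gaussian kernel evaluates correctly", {
  u <- c(1, 2, 3)
  expect_equal(rbf_kernel(u, u, gamma = 0.5), 1.0)
  # unit squared distance at the default width
  expect_equal(rbf_kernel(c(0, 0), c(1, 0), gamma = 0.035), exp(-0.035))
  expect_equal(exp(-0.035), 0.96561, tolerance = 1e-5)
  # symmetry and monotonicity in gamma
  v <- c(4, 0, -1)
  expect_equal(rbf_kernel(u, v, 0.2), rbf_kernel(v, u, 0.2))
  expect_lt(rbf_kernel(u, v, 0.4), rbf_kernel(u, v, 0.2))
  expect_error(rbf_kernel(c(1, 2), c(1, 2, 3), 0.1), "dimension")
  # matrix form agrees with elementwise evaluation
  A <- matrix(rnorm(6), 2, 3); B <- matrix(rnorm(9), 3, 3)
  G <- rbf_kernel(A, B, 0.3)
  expect_equal(G[2, 3], rbf_kernel(A[2, ], B[3, ], 0.3))
})

test_that("constant responses give an empty expansion and b = c", {
  x <- matrix(rnorm(20), 10, 2)
  m <- svr_fit(x, rep(42, 10), gamma = 0.1, epsilon = 0.5, cost = 10)
  expect_equal(unname(m$dual_coef), rep(0, 10))
  expect_equal(m$offset, 42)
  expect_equal(predict(m, x), rep(42, 10))
  expect_length(m$support, 0)
})

test_that("tight-tube SVR interpolates smooth 1-D data", {
  x <- matrix(seq(0, 1, length.out = 10), 10, 1)
  y <- x[, 1]
  # tiny gamma puts the RBF in its near-linear regime
  m <- svr_fit(x, y, gamma = 1e-3, epsilon = 0.01, cost = 1000,
               scale = FALSE, tol = 1e-8)
  expect_lt(max(abs(predict(m, x) - y)), 0.01 + 1e-4)
})

test_that("the support-vector expansion matches a hand evaluation", {
  xtr <- matrix(c(0, 0, 1, 0, 0, 2), 3, 2, byrow = TRUE)
  model <- structure(list(
    x = xtr, center = NULL, scale = NULL,
    dual_coef = c(0.5, -0.2, 0.1), offset = 3,
    support = 1:3,
    hyperparameters = list(gamma = 0.25, epsilon = 0.1, cost = 1,
                           kernel = "rbf", degree = 3),
    y = c(0, 0, 0), fitted_values = NULL, residuals = NULL,
    iterations = 0L, kkt_violation = 0, tol = 1e-6), class = "svr_model")
  xnew <- matrix(c(1, 1), 1, 2)
  hand <- 0.5 * exp(-0.25 * 2) - 0.2 * exp(-0.25 * 1) + 0.1 * exp(-0.25 * 2) + 3
  expect_equal(predict(model, xnew), hand, tolerance = 1e-15)
  expect_error(predict(model, matrix(1, 1, 3)), "dimension mismatch")
})

test_that("dual solutions agree with an independent SVR implementation", {
  skip_if_not_installed("e1071")
  set.seed(42)
  worst <- 0
  for (rep in 1:20) {
    n <- sample(10:30, 1); p <- sample(2:5, 1)
    x <- matrix(rnorm(n * p), n, p)
    # standardized-scale response so the tolerance is in natural units
    y <- as.vector(scale(sin(x[, 1]) + 0.5 * x[, 2] + rnorm(n, 0, 0.2)))
    gam <- runif(1, 0.05, 1)
    C <- 10^runif(1, -0.5, 2)
    eps <- runif(1, 0.01, 0.3)
    m <- svr_fit(x, y, gamma = gam, epsilon = eps, cost = C,
                 scale = FALSE, tol = 1e-8)
    ref <- e1071::svm(x, y, type = "eps-regression", kernel = "radial",
                      gamma = gam, cost = C, epsilon = eps, scale = FALSE,
                      tolerance = 1e-6)
    worst <- max(worst, max(abs(predict(m, x) - predict(ref, x))))
    kkt <- svr_kkt_check(m)
    expect_true(kkt$ok)
  }
  expect_lt(worst, 1e-3)
})

test_that("every fit carries a valid KKT certificate", {
  set.seed(17)
  for (rep in 1:5) {
    n <- 25
    x <- matrix(rnorm(n * 3), n, 3)
    y <- 50 + 20 * sin(x[, 1]) + rnorm(n, 0, 3)
    m <- svr_fit(x, y, gamma = 0.2, epsilon = 1, cost = 50)
    kkt <- svr_kkt_check(m)
    expect_true(kkt$box_ok)
    expect_lte(kkt$equality_residual, 1e-8 * 50 * n)
    expect_true(kkt$inside_tube_zero_ok)
    expect_true(kkt$at_bound_ok)
  }
})

test_that("enlarging the tube never increases the support-vector count", {
  set.seed(4)
  x <- matrix(rnorm(40 * 2), 40, 2)
  y <- 50 + 15 * x[, 1]^2 + rnorm(40, 0, 2)
  eps_grid <- c(0.1, 0.5, 1, 2, 5, 10)
  nsv <- vapply(eps_grid, function(e)
    length(svr_fit(x, y, gamma = 0.2, epsilon = e, cost = 30)$support),
    numeric(1))
  expect_true(all(diff(nsv) <= 0))
})

test_that("predictions are equivariant under training-row permutation", {
  set.seed(12)
  x <- matrix(rnorm(30 * 3), 30, 3)
  y <- 40 + 10 * x[, 2] + rnorm(30)
  xnew <- matrix(rnorm(15), 5, 3)
  m1 <- svr_fit(x, y, gamma = 0.1, epsilon = 0.5, cost = 20, tol = 1e-8)
  perm <- sample(30)
  m2 <- svr_fit(x[perm, ], y[perm], gamma = 0.1, epsilon = 0.5, cost = 20,
                tol = 1e-8)
  expect_equal(predict(m1, xnew), predict(m2, xnew), tolerance = 1e-5)
})

test_that("JSON serialization round-trips predictions exactly", {
  set.seed(9)
  x <- matrix(rnorm(20 * 2), 20, 2)
  y <- 30 + 5 * x[, 1] + rnorm(20)
  m <- svr_fit(x, y, gamma = 0.3, epsilon = 0.2, cost = 10)
  p <- withr::local_tempfile(fileext = ".json")
  write_svr_json(m, p)
  m2 <- read_svr_json(p)
  xnew <- matrix(rnorm(10), 5, 2)
  expect_equal(predict(m2, xnew), predict(m, xnew), tolerance = 1e-12)
})
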