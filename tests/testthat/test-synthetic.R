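test_that("generation is deterministic and leaves the caller's RNG alone", {
  sp <- synthetic_spec(n_compounds = 30, n_descriptors = 20, seed = 5)
  d1 <- generate_synthetic(sp)
  set.seed(123); before <- rnorm(1)
  set.seed(123)
  d2 <- generate_synthetic(sp)
  after <- rnorm(1)
  expect_identical(d1$table, d2$table)
  expect_identical(d1$response$brpp, d2$response$brpp)
  expect_identical(d1$truth$support, d2$truth$support)
  expect_equal(before, after)  # RNG state restored around generation
})

test_that("noiseless linear data is exactly identifiable on the support", {
  sp <- synthetic_spec(n_compounds = 50, n_descriptors = 30, support_size = 4,
                       coefficients = c(3, -2, 1.5, -1), noise_sd = 0,
                       nonlinear_fraction = 0, seed = 9)
  d <- generate_synthetic(sp)
  X <- unclass(d$table)[, d$truth$support]
  m <- fit_ols(X, d$response$brpp)
  expect_equal(unname(m$coefficients[-1]), sp$coefficients, tolerance = 1e-8)
  expect_equal(unname(m$coefficients[1]), 50, tolerance = 1e-8)
})

test_that("collinear blocks are strongly correlated enough to trip the cap", {
  for (seed in 1:20) {
    sp <- synthetic_spec(n_compounds = 70, n_descriptors = 30,
                         collinear_blocks = list(list(size = 4,
                                                      correlation = 0.95)),
                         seed = seed)
    d <- generate_synthetic(sp)
    block <- d$truth$block_columns[[1]]
    cm <- abs(cor(unclass(d$table)[, block]))
    expect_gte(min(cm[upper.tri(cm)]), 0.8)
  }
})

test_that("near-constant and missing columns are exactly as requested", {
  sp <- synthetic_spec(n_compounds = 40, n_descriptors = 25,
                       near_constant_count = 3, missing_rate = 0.2, seed = 2)
  d <- generate_synthetic(sp)
  X <- unclass(d$table)
  vars <- apply(X, 2, var)
  expect_identical(sort(colnames(X)[!is.na(vars) &
                                      vars < pretreatment_rules()$min_variance]),
                   sort(d$truth$near_constant_columns))
  expect_length(d$truth$near_constant_columns, 3L)
  expect_identical(sort(colnames(X)[colSums(is.na(X)) > 0]),
                   sort(d$truth$missing_columns))
  expect_length(d$truth$missing_columns, 5L)  # 20% of 25
  # the support never overlaps the nuisance columns
  expect_length(intersect(d$truth$support,
                          c(d$truth$near_constant_columns,
                            d$truth$missing_columns,
                            unlist(d$truth$block_columns))), 0L)
})

test_that("infeasible specifications are refused", {
  sp <- synthetic_spec(n_compounds = 20, n_descriptors = 10, support_size = 8,
                       coefficients = rep(1, 8), near_constant_count = 3,
                       seed = 1)
  expect_error(generate_synthetic(sp), "infeasible")
})

test_that("the study-scale preset has the study's shape and calibration", {
  sp <- paper_scale_preset(seed = 3)
  expect_equal(sp$n_compounds, 70)
  expect_equal(sp$support_size, 6)
  d1 <- generate_synthetic(sp)
  d2 <- generate_synthetic(paper_scale_preset(seed = 3))
  expect_identical(d1$table, d2$table)

  # the true model's training R2 is calibrated to ~0.85 (median, 20 seeds)
  r2 <- vapply(1:20, function(s) {
    d <- generate_synthetic(paper_scale_preset(seed = s))
    fit_ols(unclass(d$table)[, d$truth$support], d$response$brpp)$r_squared
  }, numeric(1))
  expect_lt(abs(median(r2) - 0.85), 0.05)
})

test_that("nonlinear fraction preserves signal variance while hiding it
           from a linear fit", {
  sp0 <- synthetic_spec(n_compounds = 4000, n_descriptors = 8,
                        support_size = 3, coefficients = c(5, -4, 3),
                        noise_sd = 0, nonlinear_fraction = 0, seed = 8)
  sp1 <- sp0; sp1$nonlinear_fraction <- 1
  d0 <- generate_synthetic(sp0); d1 <- generate_synthetic(sp1)
  v0 <- var(d0$response$brpp); v1 <- var(d1$response$brpp)
  expect_lt(abs(v1 / v0 - 1), 0.15)
  # the pure nonlinear signal is (near-)orthogonal to the linear space
  X <- unclass(d1$table)[, d1$truth$support]
  m <- fit_ols(X, d1$response$brpp)
  expect_lt(m$r_squared, 0.1)
})
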