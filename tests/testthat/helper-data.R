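# small random regression instances used across test files
make_instance <- function(n, p, seed, noise = 1, intercept = 50) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("S%02d", seq_len(n)),
                              sprintf("D%02d", seq_len(p))))
  beta <- rnorm(p)
  y <- intercept + as.vector(x %*% beta) + rnorm(n, 0, noise)
  list(x = x, y = y, beta = beta, intercept = intercept)
}

# independent OLS oracle: normal equations, nothing shared with fit_ols
normal_equations <- function(x, y) {
  Xi <- cbind(1, x)
  solve(crossprod(Xi), crossprod(Xi, y))[, 1]
}
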