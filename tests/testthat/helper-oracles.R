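# Independent oracles: direct double-precision summation of the estimating
# functions (valid away from the overflow region) and small random datasets.

naive_mgmm <- function(ds, b1) {
  sum(ds$y * exp(-b1 * ds$x) * (ds$g - mean(ds$g)))
}

naive_lgmm <- function(ds, b1) {
  sum(ds$g * ds$y) -
    sum(ds$y) * sum(ds$g * exp(b1 * ds$x)) / sum(exp(b1 * ds$x))
}

# Unprofiled moment conditions (two equations in beta0/beta0', beta1).
naive_mgmm_moments <- function(ds, b0, b1) {
  r <- ds$y * exp(-b1 * ds$x)
  c(sum(r - b0), sum(ds$g * (r - b0)))
}

rand_ds <- function(n, seed, prev = 0.3) {
  set.seed(seed)
  iv_dataset(g = rnorm(n), x = rnorm(n), y = rbinom(n, 1, prev))
}

expect_signed_log_equal <- function(val, target, tol = 1e-9) {
  expect_s3_class(val, "signed_log")
  expect_equal(as.numeric(val), target, tolerance = tol)
}
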