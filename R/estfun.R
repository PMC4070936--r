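# Profiled MGMM and LGMM estimating functions, evaluated in signed log space.
#
# Both moment systems have two conditions in (beta0, beta1); the nuisance
# intercept is eliminated analytically, so each method reduces to a single
# estimating function of beta1 (the log causal risk ratio):
#
#   MGMM (multiplicative error):  f(b1) = sum_i y_i exp(-b1 x_i) (g_i - gbar)
#   LGMM (additive error):        f(b1) = sum_i g_i y_i
#                                   - (sum_i y_i) sum_i g_i exp(b1 x_i)
#                                                / sum_i exp(b1 x_i)
#
# For LGMM the evaluable log-space form multiplies through by the (positive)
# normalising sum S0 = sum_i exp(b1 x_i):
#   F(b1) = sum_j [sum_i g_i y_i - (sum_i y_i) g_j] exp(b1 x_j) = f(b1) * S0,
# a single signed log-sum-exp, from which log|f| = log|F| - log S0.

.METHODS <- c("MGMM", "LGMM")

.match_method <- function(method) {
  match.arg(toupper(method), .METHODS)
}

#' Profiled MGMM estimating function
#'
#' Evaluates `sum_i y_i * exp(-beta1 * x_i) * (g_i - mean(g))`, the
#' structural-mean-model form of the multiplicative-error moment conditions
#' with the intercept profiled out.  Only individuals with `y = 1`
#' contribute.  Computation is in signed log space so the value is finite and
#' well-signed over the full scan range `|beta1| <= 50`.
#'
#' If no individual has `y = 1` the function is identically zero and an exact
#' zero is returned for every `beta1`.
#'
#' @param ds An [iv_dataset()].
#' @param beta1 Scalar log causal risk ratio at which to evaluate.
#' @return A [signed_log()] value.
#' @examples
#' mgmm_estfun(toy_fixture("twopoint"), log(2))  # -0.25
#' @export
mgmm_estfun <- function(ds, beta1) {
  ds <- .check_iv_data(ds)
  w <- ds$y * (ds$g - mean(ds$g))
  signed_logsumexp(w, -beta1 * ds$x)
}

#' Profiled LGMM estimating function
#'
#' Evaluates
#' `sum_i g_i y_i - sum_i y_i * sum_i g_i exp(beta1 x_i) / sum_i exp(beta1 x_i)`,
#' the additive-error moment conditions with the intercept profiled out, with
#' every exponential sum carried in signed log space.
#'
#' @inheritParams mgmm_estfun
#' @return A [signed_log()] value.
#' @export
lgmm_estfun <- function(ds, beta1) {
  ds <- .check_iv_data(ds)
  ny <- sum(ds$y)
  if (ny == 0L) return(signed_log(0L, -Inf))
  A <- sum(ds$g * ds$y)
  num <- signed_logsumexp(A - ny * ds$g, beta1 * ds$x)
  logS0 <- .logsumexp(beta1 * ds$x)
  signed_log(num$sign, num$logmag - logS0)
}

#' Profiled intercepts of the two moment systems
#'
#' `mgmm_beta0()` returns `mean(y * exp(-beta1 * x))`, the multiplicative
#' model's baseline risk at `x = 0` (0 when there are no cases).
#' `lgmm_beta0prime()` returns
#' `log(sum(y)) - log(sum(exp(beta1 * x)))`, the additive model's log
#' baseline risk; it is undefined without at least one case.
#'
#' @inheritParams mgmm_estfun
#' @return A numeric scalar.
#' @export
mgmm_beta0 <- function(ds, beta1) {
  ds <- .check_iv_data(ds)
  if (sum(ds$y) == 0L) return(0)
  exp(.logsumexp(-beta1 * ds$x[ds$y == 1L]) - log(nrow(ds)))
}

#' @rdname mgmm_beta0
#' @export
lgmm_beta0prime <- function(ds, beta1) {
  ds <- .check_iv_data(ds)
  if (sum(ds$y) == 0L)
    stop("degenerate data: y is identically 0, log baseline risk undefined")
  log(sum(ds$y)) - .logsumexp(beta1 * ds$x)
}

# Vectorised evaluation over a beta1 grid.  Equivalent to calling the scalar
# estimating function at each grid point, but restructured as chunked matrix
# operations with a per-grid-point log-shift (row maximum) so that no
# exponential overflows.  Returns sign and log|f| per grid point.
.estfun_grid <- function(ds, method, beta_grid, chunk_cells = 4e6) {
  method <- .match_method(method)
  nb <- length(beta_grid)
  if (sum(ds$y) == 0L)
    return(list(sign = integer(nb), logmag = rep(-Inf, nb)))
  if (method == "MGMM") {
    keep <- ds$y == 1L
    w <- (ds$g - mean(ds$g))[keep]
    xx <- ds$x[keep]
    esign <- -1
  } else {
    ny <- sum(ds$y)
    w <- sum(ds$g * ds$y) - ny * ds$g
    xx <- ds$x
    esign <- 1
  }
  m <- length(xx)
  sgn <- integer(nb)
  logmag <- numeric(nb)
  chunk <- max(1L, as.integer(chunk_cells %/% max(m, 1L)))
  # weight columns: signed, absolute (for the cancellation test), and for
  # LGMM a column of ones giving the normalising sum S0 in the same product
  wmat <- if (method == "LGMM") cbind(w, abs(w), 1) else cbind(w, abs(w))
  xmin <- min(xx); xmax <- max(xx)
  for (start in seq(1L, nb, by = chunk)) {
    idx <- start:min(start + chunk - 1L, nb)
    cc <- esign * beta_grid[idx]
    # exact per-row maximum of the exponents c * x: exp(E - rmax) <= 1
    rmax <- pmax(cc * xmin, cc * xmax)
    W <- exp(cc %o% xx - rmax)
    P <- W %*% wmat
    v <- P[, 1L]
    vabs <- P[, 2L]
    z <- vabs == 0 | abs(v) <= .EPS_CANCEL * vabs
    sgn[idx] <- as.integer(ifelse(z, 0, sign(v)))
    lm_chunk <- ifelse(z, -Inf, rmax + log(abs(v)))
    if (method == "LGMM") {
      # divide out the positive normalising sum S0 to recover f itself
      logS0 <- rmax + log(P[, 3L])
      lm_chunk <- lm_chunk - logS0
    }
    logmag[idx] <- lm_chunk
  }
  list(sign = sgn, logmag = logmag)
}

# Scalar dispatch used by root refinement.
.estfun <- function(ds, method, beta1) {
  if (.match_method(method) == "MGMM") mgmm_estfun(ds, beta1)
  else lgmm_estfun(ds, beta1)
}
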