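# Signed log-space arithmetic.
#
# The profiled estimating functions involve sums of terms w_i * exp(e_i) with
# exponents as large as |beta1| * max|x|, far beyond double-precision range
# when the scan covers |beta1| <= 50.  Values are therefore carried as a sign
# in {-1, 0, +1} plus the natural log of the magnitude.

# Relative cancellation threshold: when the positive and negative parts of a
# signed sum agree in log-magnitude to within this epsilon, the sum is
# declared exactly zero.  This is the double-precision limit and makes sign
# counting on the scan grid deterministic.
.EPS_CANCEL <- 1e-14

#' Construct a signed log-space value
#'
#' Represents a real number as `sign * exp(logmag)`, with `sign = 0`
#' (and `logmag = -Inf`) encoding an exact zero.
#'
#' @param sign Integer in `{-1, 0, 1}`.
#' @param logmag Natural log of the absolute value; `-Inf` when `sign` is 0.
#' @return An object of class `"signed_log"` with elements `sign` and
#'   `logmag`.
#' @seealso [signed_logsumexp()]
#' @export
signed_log <- function(sign, logmag) {
  sign <- as.integer(sign)
  stopifnot(length(sign) == 1L, length(logmag) == 1L, sign %in% c(-1L, 0L, 1L))
  if (sign == 0L) logmag <- -Inf
  structure(list(sign = sign, logmag = as.numeric(logmag)),
            class = "signed_log")
}

#' @export
as.double.signed_log <- function(x, ...) {
  if (x$sign == 0L) 0 else x$sign * exp(x$logmag)
}

#' @export
format.signed_log <- function(x, ...) {
  if (x$sign == 0L) return("0 (exact)")
  sprintf("%s exp(%.6g)", if (x$sign > 0L) "+" else "-", x$logmag)
}

#' @export
print.signed_log <- function(x, ...) {
  cat("<signed_log> ", format(x), "\n", sep = "")
  invisible(x)
}

# log(sum(exp(v))) without overflow; -Inf for empty or all -Inf input.
.logsumexp <- function(v) {
  if (!length(v)) return(-Inf)
  m <- max(v)
  if (!is.finite(m)) return(m) # all -Inf, or an Inf dominates
  m + log(sum(exp(v - m)))
}

# log(1 - exp(-d)) for d > 0, accurate for both small and large d.
.log1mexp <- function(d) {
  if (d > log(2)) log1p(-exp(-d)) else log(-expm1(-d))
}

#' Signed log-sum-exp
#'
#' Computes `sum(weights * exp(exponents))` without intermediate overflow or
#' underflow, returning the result in sign/log-magnitude form.  Positive- and
#' negative-weight terms are accumulated separately with the usual
#' log-sum-exp shift and combined by a log-difference.  When the two parts
#' cancel to within a relative log-difference of `1e-14`, the result is an
#' exact zero (so that downstream sign counting is deterministic).
#'
#' @param weights Numeric vector; any signs, zeros are dropped.
#' @param exponents Numeric vector of the same length.
#' @return A [signed_log()] value.
#' @examples
#' signed_logsumexp(c(1, 1), c(1000, 1000))   # + exp(1000 + log 2)
#' signed_logsumexp(c(1, -1), c(0, 0))        # exact zero
#' @export
signed_logsumexp <- function(weights, exponents) {
  if (length(weights) != length(exponents))
    stop("'weights' and 'exponents' must have equal length")
  if (anyNA(weights) || anyNA(exponents))
    stop("NA/NaN input to signed_logsumexp()")
  keep <- weights != 0
  weights <- weights[keep]
  exponents <- exponents[keep]
  if (!length(weights)) return(signed_log(0L, -Inf))
  pos <- weights > 0
  logP <- .logsumexp(log(weights[pos]) + exponents[pos])
  logN <- .logsumexp(log(-weights[!pos]) + exponents[!pos])
  if (logN == -Inf) return(signed_log(1L, logP))
  if (logP == -Inf) return(signed_log(-1L, logN))
  d <- logP - logN
  if (is.nan(d) || abs(d) < .EPS_CANCEL) return(signed_log(0L, -Inf))
  if (d > 0) signed_log(1L, logP + .log1mexp(d)) else
    signed_log(-1L, logN + .log1mexp(-d))
}
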