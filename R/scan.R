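# Grid-scan identification diagnostic: evaluate the profiled estimating
# function over a beta1 grid, count sign changes, refine the bracketed roots,
# and classify the dataset as having no, one, or multiple solutions.

.STATUSES <- c("NO_SOLUTION", "UNIQUE", "MULTIPLE")

#' Scan grid specification
#'
#' The diagnostic grid over the log causal risk ratio.  The default covers
#' `beta1` from -50 to 50 in steps of 0.1 (1001 points), wide enough that
#' risk-ratio solutions of practical interest cannot fall outside it.
#'
#' @param lo,hi Grid endpoints (`lo < hi`).
#' @param step Positive step; the grid is `lo, lo + step, ...` with `hi`
#'   always included as the final point.
#' @return An object of class `"grid_spec"`.
#' @export
grid_spec <- function(lo = -50, hi = 50, step = 0.1) {
  if (!(lo < hi)) stop("'lo' must be less than 'hi'")
  if (step <= 0 || step > (hi - lo) / 10)
    stop("'step' must be positive and at most (hi - lo)/10")
  structure(list(lo = lo, hi = hi, step = step), class = "grid_spec")
}

.grid_points <- function(grid) {
  pts <- seq(grid$lo, grid$hi, by = grid$step)
  if (pts[length(pts)] < grid$hi - 1e-12 * max(1, abs(grid$hi)))
    pts <- c(pts, grid$hi)
  pts
}

#' Count sign changes in a sign sequence
#'
#' Exact zeros are removed first; the count is the number of adjacent
#' opposite-sign pairs in the remaining sequence.  A run of zeros flanked by
#' opposite signs therefore contributes exactly one change (a grid point
#' landing on a root counts as one crossing, not two).
#'
#' @param signs Integer vector with values in `{-1, 0, 1}`.
#' @return Non-negative integer.
#' @examples
#' count_sign_changes(c(1, 0, -1, 0, 1))  # 2
#' @export
count_sign_changes <- function(signs) {
  if (!all(signs %in% c(-1, 0, 1))) stop("'signs' must be in {-1, 0, 1}")
  s <- signs[signs != 0]
  if (length(s) < 2L) return(0L)
  sum(s[-1L] != s[-length(s)])
}

#' Classify identification status from a sign-change count
#'
#' No sign change means no parameter value satisfies the moment condition;
#' one change means a unique solution (the parameter is identified); two or
#' more changes mean multiple solutions (lack of identification).
#'
#' @param n_changes Non-negative integer count of sign changes.
#' @return One of `"NO_SOLUTION"`, `"UNIQUE"`, `"MULTIPLE"`.
#' @export
classify_status <- function(n_changes) {
  if (n_changes < 0) stop("'n_changes' must be non-negative")
  if (n_changes == 0) "NO_SOLUTION" else if (n_changes == 1) "UNIQUE"
  else "MULTIPLE"
}

# Bisection on the sign of the estimating function; endpoints must have
# strictly opposite signs.
.bisect <- function(ds, method, lo, hi, sa, tol = 1e-8) {
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    sm <- .estfun(ds, method, mid)$sign
    if (sm == 0L) return(mid)
    if (sm == sa) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Refine a bracketed root of the estimating function
#'
#' Bisection to absolute tolerance `1e-8` in `beta1`.  The estimating
#' function must have strictly opposite signs at `lo` and `hi`; bisection is
#' used (rather than secant-type updates) because the scanned functions can
#' be far from locally linear near weakly identified roots.
#'
#' @param ds An [iv_dataset()].
#' @param method `"MGMM"` or `"LGMM"`.
#' @param lo,hi Bracket endpoints.
#' @param tol Absolute tolerance on `beta1`.
#' @return The refined root (a scalar inside `(lo, hi)`).
#' @export
refine_root <- function(ds, method, lo, hi, tol = 1e-8) {
  ds <- .check_iv_data(ds)
  method <- .match_method(method)
  if (!(lo < hi)) stop("'lo' must be less than 'hi'")
  sa <- .estfun(ds, method, lo)$sign
  sb <- .estfun(ds, method, hi)$sign
  if (sa == 0L || sb == 0L || sa == sb)
    stop("invalid bracket: estimating function signs at 'lo' and 'hi' ",
         "must be strictly opposite")
  .bisect(ds, method, lo, hi, sa, tol)
}

#' Scan the estimating function and classify identification
#'
#' Evaluates the profiled estimating function of `method` at every grid
#' point, records the sign pattern, counts sign changes, refines each
#' bracketed root by bisection, and classifies the dataset via
#' [classify_status()].  Exact grid zeros flanked by opposite signs are
#' reported as the root of that crossing; zeros flanked by equal signs (or at
#' the grid boundary) are tangency-type roots and are reported without
#' contributing a sign change.
#'
#' A dataset with no cases (`y` identically 0) has an identically zero
#' estimating function; the scan then carries no information and is returned
#' with status `"NO_SOLUTION"` and `degenerate = TRUE`.
#'
#' @param ds An [iv_dataset()] with non-constant `g`.
#' @param method `"MGMM"` or `"LGMM"`.
#' @param grid A [grid_spec()].
#' @return An object of class `"iv_scan"`: list with elements `grid`
#'   (evaluation points), `signs`, `logmag`, `n_sign_changes`, `roots`
#'   (ascending), `status`, `method`, `degenerate`.
#' @examples
#' ds <- generate_dataset(dgp_config(n = 5000, rho2 = 0.5, seed = 1))
#' scan_estfun(ds, "MGMM")
#' @export
scan_estfun <- function(ds, method, grid = grid_spec()) {
  ds <- .check_iv_data(ds)
  method <- .match_method(method)
  if (!inherits(grid, "grid_spec")) stop("'grid' must be a grid_spec")
  if (stats::var(ds$g) == 0) stop("degenerate instrument: 'g' is constant")
  pts <- .grid_points(grid)
  ev <- .estfun_grid(ds, method, pts)
  signs <- ev$sign
  n_changes <- count_sign_changes(signs)
  degenerate <- all(signs == 0L)
  roots <- numeric(0)
  if (!degenerate) {
    nz <- which(signs != 0L)
    s <- signs[nz]
    if (length(s) >= 2L) {
      for (k in which(s[-1L] != s[-length(s)])) {
        a <- nz[k]; b <- nz[k + 1L]
        if (b - a > 1L) {
          roots <- c(roots, mean(pts[(a + 1L):(b - 1L)]))
        } else {
          roots <- c(roots, .bisect(ds, method, pts[a], pts[b], s[k]))
        }
      }
    }
    # tangency roots: zero runs flanked by equal signs or touching a boundary
    r <- rle(signs == 0L)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      left <- if (starts[j] > 1L) signs[starts[j] - 1L] else NA_integer_
      right <- if (ends[j] < length(signs)) signs[ends[j] + 1L] else NA_integer_
      if (is.na(left) || is.na(right) || left == right)
        roots <- c(roots, mean(pts[starts[j]:ends[j]]))
    }
    roots <- sort(roots)
  }
  structure(list(grid = pts, signs = signs, logmag = ev$logmag,
                 n_sign_changes = n_changes, roots = roots,
                 status = classify_status(n_changes), method = method,
                 degenerate = degenerate),
            class = "iv_scan")
}

#' @export
print.iv_scan <- function(x, ...) {
  cat(sprintf("<iv_scan> %s over [%.4g, %.4g] (%d points)\n",
              x$method, x$grid[1], x$grid[length(x$grid)], length(x$grid)))
  cat(sprintf("  sign changes: %d  ->  status %s%s\n", x$n_sign_changes,
              x$status, if (x$degenerate) " (degenerate: function is identically zero)" else ""))
  if (length(x$roots))
    cat("  roots (beta1):", paste(sprintf("%.4f", x$roots), collapse = ", "),
        "\n  roots (CRR):  ", paste(sprintf("%.4f", exp(x$roots)), collapse = ", "),
        "\n")
  invisible(x)
}

#' Export the estimating-function curve
#'
#' Tabulates the estimating function over the grid for plotting, on either
#' the `beta1` (log risk ratio) scale or the `crr` scale where the parameter
#' column is `exp(beta1)`.  Function values whose magnitude exceeds
#' double-precision range are reported as signed `Inf` with `overflow = TRUE`.
#'
#' @inheritParams scan_estfun
#' @param scale `"beta1"` or `"crr"` for the parameter column.
#' @return A data frame with columns `parameter`, `estfun`, `overflow`.
#' @export
estfun_curve <- function(ds, method, grid = grid_spec(),
                         scale = c("beta1", "crr")) {
  ds <- .check_iv_data(ds)
  method <- .match_method(method)
  scale <- match.arg(scale)
  pts <- .grid_points(grid)
  ev <- .estfun_grid(ds, method, pts)
  over <- is.finite(ev$logmag) & ev$logmag > log(.Machine$double.xmax)
  val <- ifelse(ev$sign == 0L, 0, ev$sign * exp(pmin(ev$logmag, 710)))
  val[over] <- ev$sign[over] * Inf
  data.frame(parameter = if (scale == "crr") exp(pts) else pts,
             estfun = val, overflow = over)
}
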