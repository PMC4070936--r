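# Point estimation: GMM/SMM roots (or squared-moment minimisation when no
# root exists), the parametric two-stage and ratio comparators,
# instrument-strength statistics, and the instrument-outcome Wald test.

#' Instrument strength statistics
#'
#' `R^2` and the F statistic from the ordinary least-squares regression of
#' the exposure on the instrument (with intercept).  For this simple
#' regression `R^2 = cor(g, x)^2` and `F = (n - 2) R^2 / (1 - R^2)`; `F` is
#' `Inf` when the fit is exact.
#'
#' @param ds An [iv_dataset()] with `n >= 3` and non-constant `g`.
#' @return A list of class `"iv_strength"` with elements `r2`, `f_stat`, `n`.
#' @export
instrument_strength <- function(ds) {
  ds <- .check_iv_data(ds)
  n <- nrow(ds)
  if (n < 3L) stop("need at least 3 observations for an F statistic")
  if (stats::var(ds$g) == 0) stop("degenerate instrument: 'g' is constant")
  r2 <- if (stats::var(ds$x) == 0) 0 else stats::cor(ds$g, ds$x)^2
  f <- if (1 - r2 < .Machine$double.eps) Inf else (n - 2) * r2 / (1 - r2)
  structure(list(r2 = r2, f_stat = f, n = n), class = "iv_strength")
}

#' @export
print.iv_strength <- function(x, ...) {
  cat(sprintf("<iv_strength> R^2 = %.4g, F = %.4g (n = %d)\n",
              x$r2, x$f_stat, x$n))
  invisible(x)
}

.stop_convergence <- function(label, detail) {
  stop(structure(class = c("ivcrr_convergence_error", "error", "condition"),
                 list(message = sprintf(
                   "log-linear model did not converge (%s): %s", label, detail),
                   call = NULL)))
}

# Log-link binomial GLM of y on a single covariate z, with explicit starting
# values (intercept at the log prevalence, slope 0, which is always feasible).
# glm.fit's iteratively reweighted scoring includes step-halving; failures
# and non-convergence surface as a classed condition.
.fit_log_glm <- function(y, z, label) {
  if (all(y == y[1]))
    stop(sprintf("degenerate data: 'y' is constant, cannot fit %s", label))
  fit <- tryCatch(
    stats::glm(y ~ z, family = stats::binomial(link = "log"),
               start = c(log(mean(y)), 0),
               control = stats::glm.control(maxit = 100, epsilon = 1e-10)),
    error = function(e) .stop_convergence(label, conditionMessage(e)))
  if (!fit$converged)
    .stop_convergence(label, sprintf("IRLS not converged in %d iterations",
                                     fit$control$maxit))
  # a fitted risk at 1 means the log-link mean hit the boundary of its
  # parameter space (e.g. perfect separation): the MLE does not exist
  if (any(stats::fitted(fit) >= 1 - 1e-8) || max(abs(stats::coef(fit))) > 25)
    .stop_convergence(label, "estimates diverged to the parameter-space boundary")
  fit
}

.new_estimate <- function(method, beta1_hat, se = NA_real_,
                          multiplicity_flag = "NOT_CHECKED",
                          roots = NULL, objective_minimum = NA_real_) {
  ci <- if (is.finite(se)) {
    exp(beta1_hat + c(-1, 1) * stats::qnorm(0.975) * se)
  } else c(NA_real_, NA_real_)
  structure(list(method = method, beta1_hat = beta1_hat,
                 crr_hat = exp(beta1_hat), se = se,
                 ci_low = ci[1], ci_high = ci[2],
                 multiplicity_flag = multiplicity_flag, roots = roots,
                 objective_minimum = objective_minimum),
            class = "iv_estimate")
}

#' @export
print.iv_estimate <- function(x, ...) {
  cat(sprintf("<iv_estimate> %s\n", x$method))
  cat(sprintf("  log CRR = %.4f, CRR = %.4f", x$beta1_hat, x$crr_hat))
  if (is.finite(x$se))
    cat(sprintf(", 95%% CI (CRR) = (%.4f, %.4f)", x$ci_low, x$ci_high))
  else cat(", CI not provided")
  cat("\n")
  if (!identical(x$multiplicity_flag, "NOT_CHECKED")) {
    cat(sprintf("  identification: %s", x$multiplicity_flag))
    if (length(x$roots) > 1L)
      cat(" - all roots (beta1): ",
          paste(sprintf("%.4f", x$roots), collapse = ", "), sep = "")
    if (is.finite(x$objective_minimum))
      cat(sprintf(" - squared-moment minimum %.4g", x$objective_minimum))
    cat("\n")
  }
  invisible(x)
}

# 2x2 just-identified GMM sandwich variance at (beta0, beta1); returns the
# standard error of beta1 or NA when the derivative matrix is (numerically)
# singular or the computation leaves double-precision range.
.gmm_se <- function(ds, method, beta1) {
  n <- nrow(ds)
  g <- ds$g; x <- ds$x; y <- ds$y
  if (method == "MGMM") {
    e <- -beta1 * x
    if (max(e[y == 1L], -Inf) > 700) return(NA_real_)
    r <- numeric(n)
    r[y == 1L] <- exp(e[y == 1L]) # avoid 0 * Inf from non-case rows
    b0 <- mean(r)
    m1 <- r - b0
    m2 <- g * m1
    G <- -matrix(c(1, mean(x * r), mean(g), mean(g * x * r)), 2L, 2L,
                 byrow = TRUE)
  } else {
    b0p <- lgmm_beta0prime(ds, beta1)
    e <- b0p + beta1 * x
    if (max(e) > 700) return(NA_real_)
    mu <- exp(e)
    m1 <- y - mu
    m2 <- g * m1
    G <- -matrix(c(mean(mu), mean(x * mu), mean(g * mu), mean(g * x * mu)),
                 2L, 2L, byrow = TRUE)
  }
  if (!all(is.finite(G)) || !all(is.finite(m2))) return(NA_real_)
  if (!is.finite(kappa(G)) || kappa(G) > 1e12) return(NA_real_)
  Omega <- crossprod(cbind(m1, m2)) / n
  Ginv <- tryCatch(solve(G), error = function(e) NULL)
  if (is.null(Ginv)) return(NA_real_)
  V <- Ginv %*% Omega %*% t(Ginv) / n
  se <- suppressWarnings(sqrt(V[2, 2]))
  if (!is.finite(se)) NA_real_ else se
}

#' GMM/SMM point estimate of the log causal risk ratio
#'
#' Runs [scan_estfun()] and reports a point estimate together with the
#' identification status, which is the primary output: a point estimate
#' under `"MULTIPLE"` or `"NO_SOLUTION"` should not be interpreted on its
#' own.
#'
#' When the scan finds at least one root, the estimate is the root of
#' smallest magnitude (ties resolved to the smaller value) and all roots are
#' attached.  When no root exists, the estimate minimises the squared scaled
#' estimating function `(f(beta1)/n)^2` over the grid with local refinement,
#' and the attained minimum is reported.  Standard errors use the
#' just-identified two-moment sandwich evaluated at the estimate; when the
#' derivative matrix is numerically singular no SE or CI is provided.
#'
#' @inheritParams scan_estfun
#' @return An object of class `"iv_estimate"` with elements `method`,
#'   `beta1_hat`, `crr_hat`, `se`, `ci_low`, `ci_high` (CRR scale),
#'   `multiplicity_flag`, `roots`, `objective_minimum`.
#' @export
gmm_estimate <- function(ds, method, grid = grid_spec()) {
  ds <- .check_iv_data(ds)
  method <- .match_method(method)
  sc <- scan_estfun(ds, method, grid)
  if (sc$degenerate)
    stop("degenerate data: estimating function is identically zero, ",
         "no information on the causal risk ratio")
  n <- nrow(ds)
  if (length(sc$roots)) {
    b1 <- sc$roots[order(abs(sc$roots), sc$roots)][1]
    obj <- NA_real_
    flag <- sc$status
  } else {
    i <- which.min(sc$logmag)
    lo <- sc$grid[max(1L, i - 1L)]
    hi <- sc$grid[min(length(sc$grid), i + 1L)]
    opt <- stats::optimize(function(b) .estfun(ds, method, b)$logmag,
                           c(lo, hi), tol = 1e-10)
    b1 <- opt$minimum
    obj <- exp(2 * (opt$objective - log(n)))
    flag <- "NO_SOLUTION"
  }
  .new_estimate(method, b1, se = .gmm_se(ds, method, b1),
                multiplicity_flag = flag, roots = sc$roots,
                objective_minimum = obj)
}

#' Two-stage (parametric) estimate of the log causal risk ratio
#'
#' Stage 1 regresses the exposure on the instrument by ordinary least
#' squares; stage 2 regresses the binary outcome on the stage-1 fitted
#' values in a log-link binomial GLM.  The slope of stage 2 estimates the
#' log causal risk ratio.  The reported 95% CI uses the stage-2 model-based
#' standard error and ignores first-stage uncertainty (an approximation,
#' flagged as such).
#'
#' @param ds An [iv_dataset()] with non-constant `g` and non-constant `y`.
#' @return An `"iv_estimate"` (see [gmm_estimate()]); `multiplicity_flag`
#'   is `"NOT_CHECKED"` since the parametric likelihood has a unique optimum.
#' @export
two_stage_estimate <- function(ds) {
  ds <- .check_iv_data(ds)
  if (stats::var(ds$g) == 0) stop("degenerate instrument: 'g' is constant")
  stage1 <- stats::lm(x ~ g, data = ds)
  xhat <- stats::fitted(stage1)
  fit2 <- .fit_log_glm(ds$y, xhat, "second-stage regression on fitted exposure")
  sm <- summary(fit2)$coefficients
  .new_estimate("TWO_STAGE", sm["z", "Estimate"], se = sm["z", "Std. Error"])
}

#' Ratio (Wald) estimate of the log causal risk ratio
#'
#' The slope of the log-link binomial GLM of the outcome on the instrument
#' divided by the OLS slope of the exposure on the instrument.  With a
#' single instrument this coincides with the two-stage estimate, because the
#' stage-2 covariate is an exact affine function of the instrument.  The 95%
#' CI uses the delta method treating the two stage regressions as
#' independent.
#'
#' @inheritParams two_stage_estimate
#' @return An `"iv_estimate"`.
#' @export
ratio_estimate <- function(ds) {
  ds <- .check_iv_data(ds)
  if (stats::var(ds$g) == 0) stop("degenerate instrument: 'g' is constant")
  den_fit <- stats::lm(x ~ g, data = ds)
  bx <- stats::coef(den_fit)[["g"]]
  se_x <- summary(den_fit)$coefficients["g", "Std. Error"]
  if (!is.finite(bx) || abs(bx) < 1e-12)
    stop("weak-instrument error: instrument-exposure slope is numerically 0")
  num_fit <- .fit_log_glm(ds$y, ds$g, "instrument-outcome regression")
  bg <- stats::coef(num_fit)[["z"]]
  se_g <- summary(num_fit)$coefficients["z", "Std. Error"]
  se <- sqrt(se_g^2 / bx^2 + bg^2 * se_x^2 / bx^4)
  .new_estimate("RATIO", bg / bx, se = se)
}

#' Wald test of the instrument-outcome association
#'
#' Tests the slope of the log-link binomial GLM of the outcome on the
#' instrument.  Under the IV assumptions, absence of this association is
#' equivalent to the causal null, so the test remains meaningful even when
#' the causal risk ratio itself is poorly identified.
#'
#' @param ds An [iv_dataset()].
#' @return An object of class `"htest"` with the Wald `z` statistic and
#'   two-sided p-value.
#' @export
iv_outcome_test <- function(ds) {
  ds <- .check_iv_data(ds)
  fit <- .fit_log_glm(ds$y, ds$g, "instrument-outcome regression")
  sm <- summary(fit)$coefficients
  z <- sm["z", "Estimate"] / sm["z", "Std. Error"]
  structure(list(
    statistic = c(z = z),
    p.value = 2 * stats::pnorm(-abs(z)),
    estimate = c("log RR per unit of instrument" = sm["z", "Estimate"]),
    method = "Wald test of the instrument-outcome association (log-linear model)",
    data.name = deparse(substitute(ds))), class = "htest")
}
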