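# Datasets and the synthetic data-generating process.

#' Construct an instrumental-variable dataset
#'
#' Bundles aligned vectors for one analysis: a (single, possibly continuous)
#' instrument `g`, an exposure `x`, and a binary outcome `y`.
#'
#' @param g Numeric vector, the instrument.
#' @param x Numeric vector, the exposure.
#' @param y Vector of 0/1 outcomes.
#' @return A data frame of class `"iv_data"` with columns `g`, `x`, `y`.
#' @examples
#' iv_dataset(g = c(0, 0, 1, 1), x = c(0, 1, 0, 1), y = c(0, 1, 0, 1))
#' @export
iv_dataset <- function(g, x, y) {
  g <- as.numeric(g); x <- as.numeric(x)
  n <- length(g)
  if (n < 2L || length(x) != n || length(y) != n)
    stop("'g', 'x' and 'y' must have equal length >= 2")
  if (anyNA(g) || anyNA(x) || anyNA(y) || any(!is.finite(g)) || any(!is.finite(x)))
    stop("missing or non-finite values in dataset")
  if (!all(y %in% c(0, 1)))
    stop("'y' must contain only 0 and 1")
  structure(data.frame(g = g, x = x, y = as.integer(y)),
            class = c("iv_data", "data.frame"))
}

.check_iv_data <- function(ds) {
  if (!all(c("g", "x", "y") %in% names(ds)))
    stop("dataset must have columns 'g', 'x', 'y'")
  ds
}

#' @export
print.iv_data <- function(x, ...) {
  cat(sprintf("<iv_data> n = %d, cases = %d (prevalence %.3f)\n",
              nrow(x), sum(x$y), mean(x$y)))
  if (stats::var(x$g) > 0 && nrow(x) >= 3) {
    s <- instrument_strength(x)
    cat(sprintf("  instrument: R^2 = %.4g, F = %.4g\n", s$r2, s$f_stat))
  } else {
    cat("  instrument: constant (degenerate)\n")
  }
  invisible(x)
}

#' Configuration of the synthetic data-generating process
#'
#' The generator draws, per individual,
#' `g ~ N(0, rho2)`, `x ~ N(g, 1 - rho2)`,
#' `y ~ Bernoulli(min(exp(beta0 + beta1 * x), 1))`,
#' so the exposure has unit marginal variance, `rho2` is the squared
#' population correlation between instrument and exposure, `exp(beta1)` is
#' the causal risk ratio, and `exp(beta0)` the risk at `x = 0`.  The defaults
#' `beta0 = -3`, `beta1 = 0.2` give an outcome prevalence of about 5%.
#'
#' @param n Number of individuals (>= 2).
#' @param rho2 Squared instrument-exposure correlation, in `[0, 1)`.
#' @param beta0 Log baseline risk.
#' @param beta1 Log causal risk ratio.
#' @param seed Non-negative integer seed; the draw is deterministic given the
#'   full configuration.
#' @return An object of class `"dgp_config"`.
#' @export
dgp_config <- function(n, rho2, beta0 = -3, beta1 = 0.2, seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("'n' must be an integer >= 2")
  if (!is.numeric(rho2) || rho2 < 0 || rho2 >= 1)
    stop("'rho2' must lie in [0, 1)")
  if (seed < 0) stop("'seed' must be non-negative")
  if (exp(beta0) > 0.5)
    warning("exp(beta0) > 0.5: risk truncation at 1 will be heavy")
  structure(list(n = n, rho2 = rho2, beta0 = beta0, beta1 = beta1,
                 seed = seed), class = "dgp_config")
}

#' Generate a synthetic dataset
#'
#' Draws one dataset from the model described in [dgp_config()].  The risk
#' `exp(beta0 + beta1 * x)` is truncated at 1 exactly as written (no
#' rejection); the number of truncated individuals is recorded in the
#' `"n_truncated"` attribute.  The caller's RNG state is left untouched.
#'
#' @param config A [dgp_config()].
#' @return An [iv_dataset()] with attributes `"config"` and `"n_truncated"`.
#' @examples
#' ds <- generate_dataset(dgp_config(n = 1000, rho2 = 0.1, seed = 7))
#' mean(ds$y)
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "dgp_config")) stop("'config' must be a dgp_config")
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
  }
  set.seed(config$seed)
  g <- stats::rnorm(config$n, 0, sqrt(config$rho2))
  x <- stats::rnorm(config$n, g, sqrt(1 - config$rho2))
  risk <- exp(config$beta0 + config$beta1 * x)
  y <- stats::rbinom(config$n, 1L, pmin(risk, 1))
  ds <- iv_dataset(g, x, y)
  attr(ds, "config") <- config
  attr(ds, "n_truncated") <- sum(risk > 1)
  ds
}

#' Small hand-computable fixture datasets
#'
#' A documented catalogue of tiny datasets used in worked examples and unit
#' tests:
#' \describe{
#'   \item{`"allzero"`}{`g = (0,1,0,1)`, `x = (0,1,2,3)`, `y = (0,0,0,0)`:
#'     no cases, so every estimating function is identically zero.}
#'   \item{`"twopoint"`}{`g = (0,1)`, `x = (0,1)`, `y = (1,1)`.}
#'   \item{`"balanced4"`}{`g = (0,0,1,1)`, `x = (0,1,0,1)`, `y = (0,1,0,1)`.}
#'   \item{`"wedge3"`}{`g = (0,1,1)`, `x = (0,2,0)`, `y = (1,1,0)`: the
#'     profiled multiplicative estimating function is
#'     `-2/3 + exp(-2*b1)/3`, with closed-form root `b1 = -log(2)/2`.}
#' }
#'
#' @param name Fixture name.
#' @return An [iv_dataset()].
#' @export
toy_fixture <- function(name) {
  switch(as.character(name),
    allzero   = iv_dataset(g = c(0, 1, 0, 1), x = c(0, 1, 2, 3),
                           y = c(0, 0, 0, 0)),
    twopoint  = iv_dataset(g = c(0, 1), x = c(0, 1), y = c(1, 1)),
    balanced4 = iv_dataset(g = c(0, 0, 1, 1), x = c(0, 1, 0, 1),
                           y = c(0, 1, 0, 1)),
    wedge3    = iv_dataset(g = c(0, 1, 1), x = c(0, 2, 0), y = c(1, 1, 0)),
    stop(sprintf("unknown fixture '%s'", name))
  )
}

#' Read or write a dataset as CSV
#'
#' The dialect is a comma-separated UTF-8 file with the exact header line
#' `g,x,y`, no row names, and `y` written as integers.  On read, `y` is
#' validated to contain only 0 and 1 and malformed values are reported with
#' their line number.
#'
#' @param path File path.
#' @param ds An [iv_dataset()].
#' @return `read_iv_csv()` returns an [iv_dataset()]; `write_iv_csv()`
#'   invisibly returns `path`.
#' @export
read_iv_csv <- function(path) {
  header <- readLines(path, n = 1L)
  if (!identical(trimws(header), "g,x,y"))
    stop(sprintf("parse error in '%s': expected header 'g,x,y', found '%s'",
                 path, trimws(header)))
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  num <- lapply(raw, function(col) suppressWarnings(as.numeric(col)))
  for (nm in c("g", "x", "y")) {
    bad <- which(is.na(num[[nm]]))
    if (length(bad))
      stop(sprintf("parse error in '%s': non-numeric '%s' value on line %d",
                   path, nm, bad[1] + 1L))
  }
  bad_y <- which(!(num$y %in% c(0, 1)))
  if (length(bad_y))
    stop(sprintf("validation error in '%s': y = %s on line %d is not in {0,1}",
                 path, format(num$y[bad_y[1]]), bad_y[1] + 1L))
  iv_dataset(num$g, num$x, num$y)
}

#' @rdname read_iv_csv
#' @export
write_iv_csv <- function(ds, path) {
  ds <- .check_iv_data(ds)
  out <- data.frame(g = ds$g, x = ds$x, y = as.integer(ds$y))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
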