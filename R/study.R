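# Simulation-study engine: run the (rho2, n) lattice of synthetic-data
# replicates, classify each replicate's identification status for the
# requested methods, and tabulate percentages, mean F, and Monte-Carlo
# standard errors.

#' Simulation-study configuration
#'
#' The default lattice crosses the instrument strengths
#' `rho2 = 0.001, 0.002, 0.005, 0.01, 0.02, 0.03, 0.05, 0.1` with sample
#' sizes `5000, 10000, 20000, 50000` at `beta0 = -3`, `beta1 = 0.2`.  The
#' default of 1000 replicates per condition keeps the full lattice at desk
#' scale; Monte-Carlo standard errors are reported so reduced-replication
#' results can be compared against larger runs.
#'
#' @param rho2_list Instrument strengths, each in `[0, 1)`.
#' @param n_list Sample sizes.
#' @param reps Replicates per condition (>= 100 for meaningful Monte-Carlo
#'   SEs; smaller values draw a warning).
#' @param beta0,beta1 Structural parameters of the generator.
#' @param grid [grid_spec()] used for every scan.
#' @param master_seed Integer; per-replicate seeds are derived as
#'   `(master_seed * 48271 + 1000003 * (condition - 1) + (replicate - 1))
#'   mod (2^31 - 1)`, so any single replicate is reproducible in isolation
#'   and different master seeds give disjoint replicate streams.
#' @param methods Subset of `c("MGMM", "LGMM")`.
#' @return An object of class `"study_config"`.
#' @export
study_config <- function(rho2_list = c(0.001, 0.002, 0.005, 0.01, 0.02,
                                       0.03, 0.05, 0.1),
                         n_list = c(5000, 10000, 20000, 50000),
                         reps = 1000, beta0 = -3, beta1 = 0.2,
                         grid = grid_spec(), master_seed = 1L,
                         methods = c("MGMM", "LGMM")) {
  stopifnot(all(rho2_list >= 0 & rho2_list < 1), all(n_list >= 2),
            reps >= 1, inherits(grid, "grid_spec"))
  methods <- match.arg(methods, .METHODS, several.ok = TRUE)
  if (reps < 100)
    warning("fewer than 100 replicates: Monte-Carlo SEs will be unreliable")
  structure(list(rho2_list = rho2_list, n_list = as.integer(n_list),
                 reps = as.integer(reps), beta0 = beta0, beta1 = beta1,
                 grid = grid, master_seed = as.integer(master_seed),
                 methods = methods),
            class = "study_config")
}

# Deterministic per-replicate seed, bound to (condition, replicate) indices
# rather than to execution order.  The master seed is spread by a large
# multiplier so that nearby master seeds yield disjoint replicate streams;
# all arithmetic stays exact in doubles (products < 2^53).
.derive_seed <- function(master_seed, cond_idx, rep_idx) {
  m <- 2147483647
  ((master_seed %% m) * 48271 + 1000003 * (cond_idx - 1) + (rep_idx - 1)) %% m
}

#' Run the identification simulation study
#'
#' For each `(rho2, n)` condition and replicate: generate a dataset, compute
#' instrument strength, scan the estimating function of each requested
#' method, and classify the identification status.  Results are aggregated
#' into one row per `(rho2, n, method)` with the percentage of replicates in
#' each status, the mean first-stage F statistic (over all replicates,
#' unconditional on status), the binomial Monte-Carlo standard error of the
#' modal percentage, and the number of replicates used.  Per-replicate
#' errors are caught, counted in the `"n_errors"` attribute, and excluded
#' from the percentages; they are never silently dropped.
#'
#' @param cfg A [study_config()].
#' @param verbose Log per-condition progress (with timing) to stderr.
#' @return A data frame of class `"iv_study"` with columns `rho2`, `n`,
#'   `method`, `pct_no_solution`, `pct_one_solution`, `pct_multiple`,
#'   `mean_f`, `mc_se`, `reps_used`, and attributes `"config"`,
#'   `"n_errors"`, `"n_degenerate"`.
#' @export
run_study <- function(cfg, verbose = FALSE) {
  if (!inherits(cfg, "study_config")) stop("'cfg' must be a study_config")
  conds <- expand.grid(rho2 = cfg$rho2_list, n = cfg$n_list,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(conds) * length(cfg$methods))
  n_errors <- 0L
  n_degenerate <- 0L
  out_i <- 0L
  for (ci in seq_len(nrow(conds))) {
    rho2 <- conds$rho2[ci]; n <- conds$n[ci]
    t0 <- proc.time()[["elapsed"]]
    counts <- matrix(0L, length(cfg$methods), 3L,
                     dimnames = list(cfg$methods, .STATUSES))
    fsum <- 0; used <- 0L
    for (r in seq_len(cfg$reps)) {
      seed <- .derive_seed(cfg$master_seed, ci, r)
      ok <- tryCatch({
        ds <- generate_dataset(dgp_config(n, rho2, cfg$beta0, cfg$beta1,
                                          seed = seed))
        f <- instrument_strength(ds)$f_stat
        st <- character(length(cfg$methods))
        for (mi in seq_along(cfg$methods)) {
          sc <- scan_estfun(ds, cfg$methods[mi], cfg$grid)
          if (sc$degenerate) n_degenerate <- n_degenerate + 1L
          st[mi] <- sc$status
        }
        list(f = f, st = st)
      }, error = function(e) NULL)
      if (is.null(ok)) { n_errors <- n_errors + 1L; next }
      used <- used + 1L
      fsum <- fsum + ok$f
      for (mi in seq_along(cfg$methods))
        counts[mi, ok$st[mi]] <- counts[mi, ok$st[mi]] + 1L
    }
    for (mi in seq_along(cfg$methods)) {
      pct <- if (used > 0L) 100 * counts[mi, ] / used else
        stats::setNames(rep(NA_real_, 3L), .STATUSES)
      phat <- max(pct) / 100
      out_i <- out_i + 1L
      rows[[out_i]] <- data.frame(
        rho2 = rho2, n = n, method = cfg$methods[mi],
        pct_no_solution = pct[["NO_SOLUTION"]],
        pct_one_solution = pct[["UNIQUE"]],
        pct_multiple = pct[["MULTIPLE"]],
        mean_f = if (used > 0L) fsum / used else NA_real_,
        mc_se = 100 * sqrt(phat * (1 - phat) / used),
        reps_used = used)
    }
    if (verbose)
      message(sprintf("rho2 = %-6g n = %-6d done in %.1f s", rho2, n,
                      proc.time()[["elapsed"]] - t0))
  }
  tbl <- do.call(rbind, rows[seq_len(out_i)])
  rownames(tbl) <- NULL
  structure(tbl, config = cfg, n_errors = n_errors,
            n_degenerate = n_degenerate,
            class = c("iv_study", "data.frame"))
}

.STUDY_COLS <- c("rho2", "n", "method", "pct_no_solution", "pct_one_solution",
                 "pct_multiple", "mean_f", "mc_se", "reps_used")

#' Read or write a study table as CSV
#'
#' Fixed nine-column schema (`rho2, n, method, pct_no_solution,
#' pct_one_solution, pct_multiple, mean_f, mc_se, reps_used`).  Percentages
#' and the mean F statistic are written at one-decimal precision (the
#' resolution at which such tables are conventionally reported); `mc_se` at
#' three decimals.  Reading restores exactly the written values.
#'
#' @param tbl An `"iv_study"` table from [run_study()].
#' @param path File path.
#' @return `read_study_table()` returns the table; `write_study_table()`
#'   invisibly returns `path`.
#' @export
write_study_table <- function(tbl, path) {
  stopifnot(all(.STUDY_COLS %in% names(tbl)))
  out <- tbl[, .STUDY_COLS]
  for (col in c("pct_no_solution", "pct_one_solution", "pct_multiple",
                "mean_f"))
    out[[col]] <- round(out[[col]], 1)
  out$mc_se <- round(out$mc_se, 3)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_study_table
#' @export
read_study_table <- function(path) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(tbl), .STUDY_COLS))
    stop(sprintf("parse error in '%s': expected columns %s", path,
                 paste(.STUDY_COLS, collapse = ", ")))
  structure(tbl, class = c("iv_study", "data.frame"))
}

#' Read a study configuration from YAML
#'
#' Maps a YAML file with any subset of the [study_config()] fields
#' (`rho2_list`, `n_list`, `reps`, `beta0`, `beta1`, `master_seed`,
#' `methods`, and `grid: {lo, hi, step}`) onto a configuration; unspecified
#' fields keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw), c("rho2_list", "n_list", "reps", "beta0",
                                      "beta1", "master_seed", "methods"))]
  if (!is.null(raw$grid))
    args$grid <- do.call(grid_spec, raw$grid)
  do.call(study_config, args)
}
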