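#' Monte-Carlo standard error of an empirical coverage proportion
#'
#' The binomial standard error \eqn{100\sqrt{p(1-p)/n}} in percentage
#' points. At the nominal level p = 0.95 with 10 000 replications this is
#' about 0.22, so empirical coverage outside roughly \[94.6, 95.4\] (a
#' two-standard-error band) is unexpected for a well-calibrated interval.
#'
#' @param p Proportion in \[0, 1\].
#' @param n_reps Number of replications (>= 1).
#' @return Standard error in percentage points.
#' @examples
#' mc_error(0.95, 1e4)
#' @export
mc_error <- function(p, n_reps) {
  if (any(p < 0 | p > 1)) stop("'p' must be in [0, 1]", call. = FALSE)
  if (any(n_reps < 1)) stop("'n_reps' must be >= 1", call. = FALSE)
  100 * sqrt(p * (1 - p) / n_reps)
}

covers <- function(lower, upper, x) {
  # closed interval: endpoint hits count (probability-zero ties, but fixed
  # for determinism)
  lower <= x & x <= upper
}

#' Empirical coverage of all interval methods under one scenario
#'
#' Runs `n_reps` replications of the scenario's data-generating process.
#' Each replication simulates a meta-analysis ([simulate_meta()]), fits the
#' random-effects model by REML, and builds the confidence and prediction
#' interval for every method in [meta_methods()]. Confidence-interval
#' coverage counts replications whose interval contains the true mean
#' `scenario$theta`; prediction-interval coverage counts those containing
#' the independently drawn new-study effect. Intervals are closed.
#'
#' Replications where the REML iteration fails to converge are counted in
#' `n_failed` and excluded from every denominator. A prediction interval
#' that an individual method cannot form in a given replication (the
#' Kenward-Roger rule `df - 1 > 0` can fail) is excluded from that cell's
#' denominator only; `n_used` records each cell's effective count.
#'
#' Reproducibility: replication `r` uses the `r`-th L'Ecuyer-CMRG
#' substream derived from `seed` via [parallel::nextRNGStream()], so
#' results are bit-identical for a given seed regardless of how the work
#' is chunked. The caller's RNG state is restored on exit.
#'
#' @param scenario A [meta_scenario()].
#' @param n_reps Number of replications (default 10 000).
#' @param alpha One minus the interval level (default 0.05).
#' @param seed Integer seed; defaults to the scenario's `seed` field.
#' @return A data frame with one row per method and interval kind (12
#'   rows): columns `k`, `nu`, `pattern`, `method`, `kind`, `coverage`
#'   (percent), `n_reps`, `n_used`, `n_failed`, `mean_i2` (percent) and
#'   `mc_err`.
#' @examples
#' run_scenario(meta_scenario(k = 3, nu_ratio = 10, seed = 7), n_reps = 50)
#' @export
run_scenario <- function(scenario, n_reps = 10000L, alpha = 0.05,
                         seed = scenario$seed) {
  stopifnot(inherits(scenario, "meta_scenario"))
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 1L) {
    stop("'n_reps' must be >= 1", call. = FALSE)
  }
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must be in (0, 1)", call. = FALSE)
  }
  if (is.null(seed)) {
    stop("a seed is required (set it in the scenario or pass 'seed')",
         call. = FALSE)
  }
  level <- 1 - alpha
  methods <- meta_methods()
  nm <- length(methods)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  old_kind <- RNGkind()[1L]
  on.exit({
    RNGkind(old_kind)
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  stream <- get(".Random.seed", envir = globalenv())

  ci_hits <- ci_n <- pi_hits <- pi_n <- stats::setNames(integer(nm), methods)
  n_failed <- 0L
  i2_sum <- 0
  for (r in seq_len(n_reps)) {
    assign(".Random.seed", stream, envir = globalenv())
    sim <- simulate_meta(scenario)
    stream <- parallel::nextRNGStream(stream)
    fit <- tryCatch(fit_reml(sim$studies), error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      n_failed <- n_failed + 1L
      next
    }
    i2_sum <- i2_sum + i_squared(sim$studies)
    for (m in methods) {
      ve <- meta_variance(m, sim$studies, fit)
      ci <- confidence_interval(fit, ve, level)
      ci_n[m] <- ci_n[m] + 1L
      if (covers(ci$lower, ci$upper, scenario$theta)) {
        ci_hits[m] <- ci_hits[m] + 1L
      }
      pi <- tryCatch(prediction_interval(fit, ve, level),
                     error = function(e) NULL)
      if (!is.null(pi)) {
        pi_n[m] <- pi_n[m] + 1L
        if (covers(pi$lower, pi$upper, sim$new_effect)) {
          pi_hits[m] <- pi_hits[m] + 1L
        }
      }
    }
  }
  mean_i2 <- if (n_reps > n_failed) i2_sum / (n_reps - n_failed) else NA_real_
  cell <- function(kind, hits, n) {
    cov <- ifelse(n > 0L, 100 * hits / n, NA_real_)
    data.frame(k = scenario$k, nu = scenario$nu_ratio,
               pattern = scenario$pattern, method = methods, kind = kind,
               coverage = cov, n_reps = n_reps, n_used = n,
               n_failed = n_failed, mean_i2 = mean_i2,
               mc_err = ifelse(n > 0L, mc_error(pmin(1, hits / pmax(n, 1L)), pmax(n, 1L)),
                               NA_real_))
  }
  out <- rbind(cell("confidence", ci_hits, ci_n),
               cell("prediction", pi_hits, pi_n))
  rownames(out) <- NULL
  out
}

grid_keys <- c("k", "nu", "pattern", "theta", "sigma2", "n_within",
               "reps", "alpha", "seed")

load_grid_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("grid config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("'config' must be a list or a file path",
                             call. = FALSE)
  unknown <- setdiff(names(config), grid_keys)
  if (length(unknown) > 0L) {
    stop("unknown grid config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults <- list(theta = 1, sigma2 = 0.1, n_within = 30L,
                   pattern = "balanced", reps = 10000L, alpha = 0.05)
  config <- utils::modifyList(defaults, config)
  for (key in c("k", "nu", "seed")) {
    if (is.null(config[[key]])) {
      stop("grid config is missing required key '", key, "'", call. = FALSE)
    }
  }
  if (any(config$reps < 1)) stop("'reps' must be >= 1", call. = FALSE)
  config
}

#' Run a grid of coverage scenarios
#'
#' Expands the cross product of `k`, `nu` and `pattern` from a grid
#' configuration (a list, or a path to a YAML file such as the bundled
#' `inst/extdata/default_grid.yaml`) and runs [run_scenario()] for each
#' combination. Scenario `i` (in expansion order) uses the derived seed
#' `(seed + 7919 * i) mod (2^31 - 1)`, so every cell is reproducible in
#' isolation.
#'
#' @param config List or YAML path with keys `k`, `nu`, `pattern`,
#'   `theta`, `sigma2`, `n_within`, `reps`, `alpha`, `seed` (unknown keys
#'   are an error; `k`, `nu` and `seed` are required).
#' @param verbose Print one progress line per scenario (default TRUE).
#' @return An object of class `"coverage_table"`: a list with `cells`
#'   (the row-bound [run_scenario()] results) and `config`.
#' @examples
#' tbl <- run_grid(list(k = 3, nu = 10, reps = 20, seed = 1),
#'                 verbose = FALSE)
#' subset(tbl$cells, method == "HK")
#' @export
run_grid <- function(config, verbose = TRUE) {
  config <- load_grid_config(config)
  grid <- expand.grid(k = config$k, nu = config$nu,
                      pattern = config$pattern,
                      stringsAsFactors = FALSE)
  cells <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    seed_i <- (config$seed + 7919 * i) %% 2147483647
    sc <- meta_scenario(k = grid$k[i], nu_ratio = grid$nu[i],
                        theta = config$theta, sigma2 = config$sigma2,
                        n_within = config$n_within,
                        pattern = grid$pattern[i], seed = seed_i)
    if (verbose) {
      message(sprintf("scenario %d/%d: k=%d nu=%g %s (seed %d, %d reps)",
                      i, nrow(grid), sc$k, sc$nu_ratio, sc$pattern,
                      seed_i, config$reps))
    }
    cells[[i]] <- tryCatch(
      run_scenario(sc, n_reps = config$reps, alpha = config$alpha),
      error = function(e) {
        stop("scenario k=", sc$k, " nu=", sc$nu_ratio, " pattern=",
             sc$pattern, " failed: ", conditionMessage(e), call. = FALSE)
      })
  }
  structure(list(cells = do.call(rbind, cells), config = config),
            class = "coverage_table")
}

#' @export
print.coverage_table <- function(x, ...) {
  cat("Coverage table:", nrow(x$cells), "cells over",
      nrow(unique(x$cells[c("k", "nu", "pattern")])), "scenarios (",
      x$config$reps, "reps each, seed", x$config$seed, ")\n")
  invisible(x)
}

#' Wide-format coverage table for one heterogeneity level
#'
#' Reshapes the cells for a given `nu` into the conventional report shape:
#' method rows (a confidence-interval block, a prediction-interval block
#' and an average-I-squared row) with one column per number of studies,
#' grouped by imbalance pattern.
#'
#' @param tbl A `"coverage_table"` from [run_grid()] or a cells data frame.
#' @param nu The heterogeneity ratio to extract.
#' @return A data frame with columns `pattern`, `block`, `method` and one
#'   `k=<value>` column per study count.
#' @export
coverage_wide <- function(tbl, nu) {
  cells <- if (inherits(tbl, "coverage_table")) tbl$cells else tbl
  cells <- cells[cells$nu == nu, , drop = FALSE]
  if (nrow(cells) == 0L) stop("no cells with nu = ", nu, call. = FALSE)
  ks <- sort(unique(cells$k))
  kcols <- paste0("k=", ks)
  out <- list()
  for (p in unique(cells$pattern)) {
    sub <- cells[cells$pattern == p, , drop = FALSE]
    for (kind in c("confidence", "prediction")) {
      block <- if (kind == "confidence") "CI" else "PI"
      for (m in meta_methods()) {
        row <- sub[sub$kind == kind & sub$method == m, , drop = FALSE]
        vals <- row$coverage[match(ks, row$k)]
        out[[length(out) + 1L]] <- stats::setNames(
          data.frame(p, block, m, t(vals)),
          c("pattern", "block", "method", kcols))
      }
    }
    i2row <- sub[sub$kind == "confidence" & sub$method == "N", , drop = FALSE]
    out[[length(out) + 1L]] <- stats::setNames(
      data.frame(p, "I2", "mean", t(i2row$mean_i2[match(ks, i2row$k)])),
      c("pattern", "block", "method", kcols))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

write_atomic <- function(writer, path) {
  tmp <- tempfile(pattern = basename(path), tmpdir = dirname(path))
  ok <- FALSE
  on.exit(if (!ok) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path)) {
    stop("could not move temporary output to ", path, call. = FALSE)
  }
  ok <- TRUE
  invisible(path)
}

#' Write coverage reports to disk
#'
#' Writes one wide, human-readable tab-delimited table per heterogeneity
#' level (`coverage_nu<value>.tsv`, shaped by [coverage_wide()]) plus a
#' machine-readable long-format file `coverage_long.tsv` holding every
#' cell at full numeric precision. Files are written atomically (to a
#' temporary file in the target directory, then renamed), so no partial
#' output survives an error.
#'
#' @param tbl A `"coverage_table"` from [run_grid()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_coverage_report <- function(tbl, outdir) {
  stopifnot(inherits(tbl, "coverage_table"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  long <- tbl$cells
  num <- vapply(long, is.numeric, logical(1))
  long[num] <- lapply(long[num], function(x) sprintf("%.17g", x))
  p <- file.path(outdir, "coverage_long.tsv")
  write_atomic(function(tmp) {
    utils::write.table(long, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }, p)
  paths <- c(paths, p)
  for (nu in sort(unique(tbl$cells$nu), decreasing = TRUE)) {
    wide <- coverage_wide(tbl, nu)
    p <- file.path(outdir, sprintf("coverage_nu%g.tsv", nu))
    write_atomic(function(tmp) {
      utils::write.table(format(wide, digits = 4), tmp, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read back a long-format coverage report
#'
#' @param path Path to a `coverage_long.tsv` written by
#'   [write_coverage_report()].
#' @return The cells data frame with numeric columns restored at full
#'   precision.
#' @export
read_coverage_report <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(k = "integer", nu = "numeric",
                                   pattern = "character",
                                   method = "character", kind = "character",
                                   coverage = "numeric",
                                   n_reps = "integer", n_used = "integer",
                                   n_failed = "integer",
                                   mean_i2 = "numeric", mc_err = "numeric"))
}
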