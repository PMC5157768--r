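#' Create a set of studies for meta-analysis
#'
#' A `study_set` holds the observed data of a random-effects meta-analysis:
#' one effect estimate per study together with its within-study sampling
#' variance (treated as known by the model). Exactly one of `se` or `var`
#' must be supplied.
#'
#' @param effects Numeric vector of study effect estimates (outcome-scale
#'   units, e.g. a mean difference or log odds ratio).
#' @param se Numeric vector of within-study standard errors.
#' @param var Numeric vector of within-study variances (alternative to `se`).
#' @param labels Optional character vector of unique study labels; defaults
#'   to `"study_1"`, `"study_2"`, ...
#'
#' @return An object of class `"study_set"`: a list with components
#'   `labels`, `effects`, `variances` and `k` (the number of studies).
#' @examples
#' s <- study_set(c(0.2, -0.1, 0.4), se = c(0.1, 0.2, 0.15))
#' s$k
#' @export
study_set <- function(effects, se = NULL, var = NULL, labels = NULL) {
  if (is.null(se) == is.null(var)) {
    stop("supply exactly one of 'se' or 'var'", call. = FALSE)
  }
  effects <- as.numeric(effects)
  variances <- if (is.null(var)) as.numeric(se)^2 else as.numeric(var)
  k <- length(effects)
  if (k < 2L) {
    stop("a meta-analysis needs at least 2 studies (got ", k, ")", call. = FALSE)
  }
  if (length(variances) != k) {
    stop("'effects' and '", if (is.null(var)) "se" else "var",
         "' must have the same length", call. = FALSE)
  }
  if (anyNA(effects) || any(!is.finite(effects))) {
    bad <- which(!is.finite(effects))[1L]
    stop("non-finite effect estimate in row ", bad, call. = FALSE)
  }
  if (anyNA(variances) || any(!is.finite(variances)) || any(variances <= 0)) {
    bad <- which(!is.finite(variances) | variances <= 0)[1L]
    stop("within-study variance must be finite and > 0 (row ", bad, ")",
         call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- paste0("study_", seq_len(k))
  }
  labels <- as.character(labels)
  if (length(labels) != k || anyDuplicated(labels)) {
    stop("'labels' must be ", k, " unique study labels", call. = FALSE)
  }
  structure(
    list(labels = labels, effects = effects, variances = variances, k = k),
    class = "study_set"
  )
}

#' @export
print.study_set <- function(x, ...) {
  cat("Study set with", x$k, "studies\n")
  print(data.frame(study = x$labels, effect = x$effects,
                   se = sqrt(x$variances)), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.study_set <- function(x, ...) {
  data.frame(study = x$labels, effect = x$effects,
             se = sqrt(x$variances), var = x$variances)
}

#' Read study-level data from a delimited file
#'
#' Reads a comma- or tab-delimited table with a header row and columns
#' `study`, `effect` and exactly one of `se` or `var`. Row numbers in error
#' messages refer to data rows, counting the first row after the header
#' as row 1.
#'
#' @param path Path to the input file.
#' @param effect_col,se_col,var_col Column names to use for the effect
#'   estimate, standard error and variance.
#' @param study_col Column name holding the study labels. If absent,
#'   labels are generated.
#'
#' @return A [study_set()].
#' @export
read_studies <- function(path, effect_col = "effect", se_col = "se",
                         var_col = "var", study_col = "study") {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, strip.white = TRUE)
  if (!effect_col %in% names(d)) {
    stop("missing required column '", effect_col, "' in ", path, call. = FALSE)
  }
  has_se <- se_col %in% names(d)
  has_var <- var_col %in% names(d)
  if (has_se == has_var) {
    stop("input must contain exactly one of the columns '", se_col,
         "' or '", var_col, "'", call. = FALSE)
  }
  eff <- suppressWarnings(as.numeric(d[[effect_col]]))
  if (anyNA(eff)) {
    stop("malformed effect value in row ", which(is.na(eff))[1L],
         " of ", path, call. = FALSE)
  }
  scale <- suppressWarnings(as.numeric(d[[if (has_se) se_col else var_col]]))
  if (anyNA(scale)) {
    stop("malformed ", if (has_se) "standard error" else "variance",
         " in row ", which(is.na(scale))[1L], " of ", path, call. = FALSE)
  }
  labels <- if (study_col %in% names(d)) as.character(d[[study_col]]) else NULL
  if (has_se) {
    study_set(eff, se = scale, labels = labels)
  } else {
    study_set(eff, var = scale, labels = labels)
  }
}

#' Diastolic blood pressure meta-analysis of seven hypertension trials
#'
#' Study-level results from seven randomised trials of anti-hypertensive
#' treatment versus control (ANBP, COOP, EWPH, HDFP, MRC1, MRC2, STOP).
#' The effect is the difference between treatment arms in diastolic blood
#' pressure (mmHg): `"post"` gives the post-treatment difference adjusted
#' for baseline (substantial heterogeneity expected), `"pre"` the baseline
#' difference (homogeneity expected). Values are at the 2-decimal precision
#' of the published report.
#'
#' @param period `"post"` (default) or `"pre"`.
#' @return A [study_set()] with 7 studies.
#' @examples
#' fit_reml(dbp_meta("post"))
#' @export
dbp_meta <- function(period = c("post", "pre")) {
  period <- match.arg(period)
  path <- system.file("extdata", paste0("dbp_", period, ".csv"),
                      package = "metacover", mustWork = TRUE)
  read_studies(path)
}
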