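# Fold changes of rate constants between conditions (mutant vs wildtype,
# mismatched vs perfectly complementary target) with bootstrap intervals.

get_param_est <- function(fit, param) {
  if (inherits(fit, "slicing_fit")) {
    if (!param %in% c("kon", "kslice", "kphase2", "Fa"))
      stop("unknown slicing parameter: ", param, call. = FALSE)
    if (!param %in% fit$free)
      stop(sprintf("parameter %s is fixed by a constraint in this fit", param),
           call. = FALSE)
    unclass(fit$params)[[param]]
  } else if (inherits(fit, "dissociation_fit")) {
    if (!param %in% fit$free)
      stop("unknown dissociation parameter: ", param, call. = FALSE)
    fit[[param]]
  } else stop("fit must be a slicing_fit or dissociation_fit", call. = FALSE)
}

get_param_draws <- function(fit, param) {
  if (is.null(fit$boot) || !param %in% colnames(fit$boot)) return(NULL)
  fit$boot[, param]
}

#' Fold change of a rate constant between two fits
#'
#' Ratio of point estimates `a / b`, with a percentile interval obtained by
#' pairing independent bootstrap draws from each fit. Ratios are formed in
#' log space and exponentiated, so intervals are asymmetric as expected for
#' positive rate constants. A parameter fixed by a constraint in either fit
#' cannot be compared.
#'
#' @param fit_a,fit_b Two fits of the same kind (`slicing_fit` or
#'   `dissociation_fit`), both converged (an unconverged fit is tolerated
#'   with a warning when both fits share identical constraints).
#' @param param Parameter name (e.g. `"kslice"`, `"koff"`).
#' @param level Confidence level for the ratio interval.
#' @param seed Integer seed used when pairing bootstrap draws.
#' @param label_a,label_b Labels for the numerator and denominator.
#' @return An object of class `fold_change` with `ratio`, `ci`, labels, and
#'   the `includes_one` flag (the non-significance convention).
#' @export
fold_change <- function(fit_a, fit_b, param, level = 0.95, seed = 1,
                        label_a = "a", label_b = "b") {
  if (!identical(class(fit_a), class(fit_b)))
    stop("fits must be of the same kind", call. = FALSE)
  if (!isTRUE(fit_a$converged) || !isTRUE(fit_b$converged)) {
    if (identical(fit_a$constraints, fit_b$constraints))
      warning("comparing fits of which at least one is flagged unconverged",
              call. = FALSE)
    else
      stop("both fits must be converged (or share identical constraints)",
           call. = FALSE)
  }
  ea <- get_param_est(fit_a, param)
  eb <- get_param_est(fit_b, param)
  if (eb <= 0) stop("denominator estimate must be positive", call. = FALSE)
  ratio <- ea / eb
  ci <- NULL
  da <- get_param_draws(fit_a, param)
  db <- get_param_draws(fit_b, param)
  if (!is.null(da) && !is.null(db)) {
    if (length(da) * length(db) <= 250000) {
      # the two draw sets are independent, so the exact convolution (all
      # pairwise ratios) is available and carries no extra pairing noise
      lr <- as.vector(outer(log(da), log(db), "-"))
    } else {
      set.seed(seed)
      n <- max(length(da), length(db))
      lr <- log(da[sample.int(length(da), n, replace = TRUE)]) -
        log(db[sample.int(length(db), n, replace = TRUE)])
    }
    q <- stats::quantile(lr, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                         names = FALSE)
    # basic (reflected) interval around the point ratio, in log space
    ci <- c(lower = min(exp(2 * log(ratio) - q[2]), ratio),
            upper = max(exp(2 * log(ratio) - q[1]), ratio),
            level = level)
  }
  structure(list(ratio = ratio, ci = ci, param = param,
                 label_a = label_a, label_b = label_b,
                 includes_one = if (is.null(ci)) NA else
                   ci[["lower"]] <= 1 && 1 <= ci[["upper"]]),
            class = "fold_change")
}

#' @export
print.fold_change <- function(x, ...) {
  cat(sprintf("Fold change in %s (%s / %s): %.4g", x$param, x$label_a,
              x$label_b, x$ratio))
  if (!is.null(x$ci))
    cat(sprintf("  [%.4g, %.4g] at %g%%%s", x$ci[["lower"]], x$ci[["upper"]],
                100 * x$ci[["level"]],
                if (isTRUE(x$includes_one)) "  (interval includes 1)" else ""))
  cat("\n")
  invisible(x)
}

#' Table of kslice fold changes relative to a reference fit
#'
#' One fold change per non-reference label, relative to the reference
#' (e.g. mismatched targets vs the perfectly complementary target, or
#' mutants vs wildtype). Comparisons whose interval includes 1 are flagged,
#' mirroring the convention of graying out non-significant fold changes.
#'
#' @param fits Named list of `slicing_fit` objects; names must be unique.
#' @param reference Name of the reference fit.
#' @param param Parameter to compare (default `"kslice"`).
#' @param level,seed Interval settings passed to [fold_change()].
#' @return A data frame with one row per comparison: `label`, `ratio`,
#'   `lower`, `upper`, `includes_one`.
#' @export
relative_kslice_table <- function(fits, reference, param = "kslice",
                                  level = 0.95, seed = 1) {
  stopifnot(is.list(fits), !is.null(names(fits)))
  if (anyDuplicated(names(fits)))
    stop("duplicate labels in fits", call. = FALSE)
  if (!reference %in% names(fits))
    stop("reference label not found", call. = FALSE)
  others <- setdiff(names(fits), reference)
  rows <- lapply(others, function(lb) {
    fc <- fold_change(fits[[lb]], fits[[reference]], param, level = level,
                      seed = seed, label_a = lb, label_b = reference)
    data.frame(label = lb, ratio = fc$ratio,
               lower = if (is.null(fc$ci)) NA_real_ else fc$ci[["lower"]],
               upper = if (is.null(fc$ci)) NA_real_ else fc$ci[["upper"]],
               includes_one = fc$includes_one)
  })
  if (!length(rows))
    return(data.frame(label = character(0), ratio = numeric(0),
                      lower = numeric(0), upper = numeric(0),
                      includes_one = logical(0)))
  do.call(rbind, rows)
}
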