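# File formats and run configuration. Plain TSV in, JSON results out; time in
# seconds everywhere, concentrations in nM for slicing and pM for titration.

#' Read a slicing dataset from TSV
#'
#' Expects columns `enzyme_nM`, `time_s`, `fraction_sliced`, and optionally
#' `replicate`; one time course per distinct enzyme concentration.
#'
#' @param path Path to a tab-separated file.
#' @param ST Total target concentration, nM (not stored in the table);
#'   default 0.05 nM, the standard assay concentration.
#' @return A [slicing_dataset()].
#' @export
read_slicing_table <- function(path, ST = 0.05) {
  df <- read_tsv_checked(path, c("enzyme_nM", "time_s", "fraction_sliced"))
  bad <- which(df$fraction_sliced < 0 | df$fraction_sliced > 1)
  if (length(bad))
    stop("fraction_sliced outside [0, 1] at data rows: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(df$replicate)) df$replicate <- 1L
  tcs <- lapply(split(df, df$enzyme_nM), function(d) {
    d <- d[order(d$replicate, d$time_s), ]
    suppressWarnings(slicing_timecourse(
      reaction_condition(d$enzyme_nM[1], ST), d$time_s, d$fraction_sliced,
      d$replicate))
  })
  slicing_dataset(unname(tcs), label = basename(path))
}

#' Write a slicing dataset to TSV
#'
#' @param dataset A [slicing_dataset()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_slicing_table <- function(dataset, path) {
  pts <- dataset_points(dataset)
  out <- data.frame(enzyme_nM = pts$Eall, time_s = pts$time_s,
                    fraction_sliced = pts$fsliced, replicate = pts$replicate)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a titration curve from TSV
#'
#' Expects columns `dilution_factor` and `fraction_bound`.
#'
#' @param path Path to a tab-separated file.
#' @param targetT Total target concentration, pM.
#' @return A [titration_curve()].
#' @export
read_titration_table <- function(path, targetT) {
  df <- read_tsv_checked(path, c("dilution_factor", "fraction_bound"))
  titration_curve(targetT, df$dilution_factor, df$fraction_bound)
}

#' Write a titration curve to TSV
#' @param curve A [titration_curve()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_titration_table <- function(curve, path) {
  out <- data.frame(dilution_factor = curve$points$DF,
                    fraction_bound = curve$points$fbound)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dissociation time course from TSV
#'
#' Expects columns `time_s` and `fraction_bound`.
#'
#' @param path Path to a tab-separated file.
#' @return A [dissociation_timecourse()].
#' @export
read_dissociation_table <- function(path) {
  df <- read_tsv_checked(path, c("time_s", "fraction_bound"))
  dissociation_timecourse(df$time_s, df$fraction_bound)
}

#' Write a dissociation time course to TSV
#' @param tc A [dissociation_timecourse()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_dissociation_table <- function(tc, path) {
  out <- data.frame(time_s = tc$points$time_s,
                    fraction_bound = tc$points$fbound)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, encoding = "UTF-8"),
    error = function(e) stop("schema error reading ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (cl in required)
    if (!is.numeric(df[[cl]]))
      stop("schema error in ", path, ": column ", cl, " is not numeric",
           call. = FALSE)
  df
}

#' Serialize a fit result to JSON
#'
#' Machine-readable record of estimates, intervals, objective, convergence,
#' applied constraints/fallbacks, and bootstrap settings.
#'
#' @param fit A `slicing_fit`, `titration_fit`, or `dissociation_fit`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
fit_to_json <- function(fit, path = NULL) {
  ci_list <- if (!is.null(fit$ci))
    apply(fit$ci, 1, function(r) as.list(r), simplify = FALSE) else NULL
  x <- if (inherits(fit, "slicing_fit")) {
    list(kind = "slicing_fit", estimates = unclass(fit$params),
         free = fit$free, ci = ci_list, objective = fit$objective,
         converged = fit$converged,
         constraints = unclass(fit$constraints),
         fallbacks = fit$fallback_log, loss = fit$loss,
         bootstrap = fit$boot_settings)
  } else if (inherits(fit, "titration_fit")) {
    list(kind = "titration_fit",
         estimates = list(stock_pM = fit$stock, KD_pM = fit$KD,
                          Fmax = fit$Fmax),
         fmax_fixed = fit$fmax_fixed, ci = ci_list,
         converged = fit$converged, preset = fit$preset$name)
  } else if (inherits(fit, "dissociation_fit")) {
    list(kind = "dissociation_fit",
         estimates = list(koff_per_s = fit$koff, A = fit$A, B = fit$B),
         ci = ci_list, converged = fit$converged,
         non_identifiable = fit$non_identifiable)
  } else stop("unsupported fit object", call. = FALSE)
  x$package_version <- as.character(utils::packageVersion("slicekin"))
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Default run configuration
#'
#' The effective defaults of the whole pipeline in one list: guess-stage and
#' ODE-stage initializations/bounds exactly as printed, loss choice, solver
#' tolerances, bootstrap settings, noise default, and unit declarations.
#' Useful for logging so a default run is distinguishable from an overridden
#' one.
#'
#' @param ... Named overrides, applied on top of the defaults.
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    units = list(time = "s", slicing_conc = "nM", titration_conc = "pM",
                 kon = "/nM/s", rates = "/s"),
    guess_stage = guess_stage_spec(FALSE),
    guess_stage_slow = guess_stage_spec(TRUE),
    ode_stage = ode_stage_spec(),
    loss = "l1",
    huber_delta = 1e-4,
    solver = list(method = "bdf", rtol = 1e-8, atol = 1e-10),
    bootstrap = list(n_boot = 200, level = 0.95, seed = 1),
    noise_sd_default = 0.02,
    diffusion_limit = 0.1,
    slow_mode_threshold = 0.3,
    plateau_threshold = 0.75)
  ov <- list(...)
  if (length(ov)) {
    cfg <- utils::modifyList(cfg, ov)
    attr(cfg, "overridden") <- names(ov)
  }
  class(cfg) <- "run_config"
  cfg
}
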