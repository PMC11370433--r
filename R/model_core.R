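#' @useDynLib slicekin, .registration = TRUE
#' @importFrom stats median quantile rnorm runif sd setNames
#' @importFrom utils modifyList
NULL

# Units are fixed package-wide: concentrations in nM (pM in the titration
# module), time in s, kon in /nM/s, first-order constants in /s.

#' Kinetic parameters of the single-turnover slicing model
#'
#' Bundles the four parameters of the two-population slicing model: `kon`, the
#' RISC-target association rate constant (/nM/s); `kslice`, the slicing rate
#' constant of the functionally intact population (/s); `kphase2`, the slow
#' slicing rate constant of the defective population (/s); and `Fa`, the
#' fraction of RISC that is functionally intact (first-phase amplitude).
#'
#' @param kon Association rate constant, /nM/s. Must be >= 0.
#' @param kslice First-phase slicing rate constant, /s. Must be >= 0.
#' @param kphase2 Defective-population slicing rate constant, /s. Must be >= 0.
#' @param Fa Fraction of functionally intact RISC, in \[0, 1\].
#' @return An object of class `kinetic_params`.
#' @examples
#' kinetic_params(kon = 0.02, kslice = 5e-3, kphase2 = 1e-5, Fa = 0.9)
#' @export
kinetic_params <- function(kon, kslice, kphase2, Fa) {
  stopifnot(is.numeric(kon), is.numeric(kslice), is.numeric(kphase2),
            is.numeric(Fa), length(kon) == 1L, length(kslice) == 1L,
            length(kphase2) == 1L, length(Fa) == 1L)
  if (kon < 0 || kslice < 0 || kphase2 < 0)
    stop("rate constants must be non-negative", call. = FALSE)
  if (Fa < 0 || Fa > 1)
    stop("Fa must lie in [0, 1]", call. = FALSE)
  structure(list(kon = kon, kslice = kslice, kphase2 = kphase2, Fa = Fa),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Slicing kinetic parameters:\n")
  cat(sprintf("  kon     = %.4g /nM/s\n", x$kon))
  cat(sprintf("  kslice  = %.4g /s\n", x$kslice))
  cat(sprintf("  kphase2 = %.4g /s\n", x$kphase2))
  cat(sprintf("  Fa      = %.4g\n", x$Fa))
  invisible(x)
}

#' Reaction condition for a single-turnover slicing assay
#'
#' @param Eall Total RISC concentration (intact + defective), nM.
#' @param ST Total target concentration, nM.
#' @return An object of class `reaction_condition`.
#' @details Single-turnover analysis assumes enzyme excess; a warning is
#'   issued when `Eall < 10 * ST`.
#' @export
reaction_condition <- function(Eall, ST) {
  stopifnot(is.numeric(Eall), is.numeric(ST), length(Eall) == 1L,
            length(ST) == 1L)
  if (Eall <= 0 || ST <= 0)
    stop("Eall and ST must be positive", call. = FALSE)
  if (Eall < 10 * ST)
    warning("Eall < 10 * ST: single-turnover (enzyme excess) assumption weak",
            call. = FALSE)
  structure(list(Eall = Eall, ST = ST), class = "reaction_condition")
}

#' A slicing progress curve at one RISC concentration
#'
#' @param condition A [reaction_condition()].
#' @param times Observation times, s; non-negative and strictly increasing
#'   within a replicate.
#' @param fsliced Fraction of target sliced at each time, in \[0, 1\].
#' @param replicate Optional replicate identifier per point.
#' @return An object of class `slicing_timecourse`.
#' @export
slicing_timecourse <- function(condition, times, fsliced, replicate = NULL) {
  stopifnot(inherits(condition, "reaction_condition"),
            length(times) == length(fsliced))
  if (is.null(replicate)) replicate <- rep(1L, length(times))
  stopifnot(length(replicate) == length(times))
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  for (r in unique(replicate)) {
    tr <- times[replicate == r]
    if (any(diff(tr) <= 0))
      stop("times must be strictly increasing within a replicate",
           call. = FALSE)
  }
  bad <- which(fsliced < 0 | fsliced > 1)
  if (length(bad))
    stop("fraction sliced outside [0, 1] at rows: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(condition = condition,
                 points = data.frame(time_s = times, fsliced = fsliced,
                                     replicate = replicate)),
            class = "slicing_timecourse")
}

#' A concentration-series slicing dataset sharing one parameter set
#'
#' @param timecourses List of [slicing_timecourse()] objects; all must share
#'   the same total target concentration `ST`.
#' @param label Free-text label (enzyme/guide/target identity).
#' @return An object of class `slicing_dataset`.
#' @export
slicing_dataset <- function(timecourses, label = "") {
  if (inherits(timecourses, "slicing_timecourse"))
    timecourses <- list(timecourses)
  stopifnot(is.list(timecourses), length(timecourses) >= 1L,
            all(vapply(timecourses, inherits, logical(1),
                       "slicing_timecourse")))
  STs <- vapply(timecourses, function(tc) tc$condition$ST, numeric(1))
  if (diff(range(STs)) > 1e-12 * max(STs))
    stop("all time courses must share the same total target concentration ST",
         call. = FALSE)
  structure(list(timecourses = timecourses, label = label),
            class = "slicing_dataset")
}

#' @export
print.slicing_dataset <- function(x, ...) {
  cat(sprintf("Slicing dataset%s: %d time course(s), ST = %.4g nM\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$timecourses), x$timecourses[[1]]$condition$ST))
  for (tc in x$timecourses)
    cat(sprintf("  Eall = %6.3g nM: %d points, t in [%.3g, %.3g] s\n",
                tc$condition$Eall, nrow(tc$points), min(tc$points$time_s),
                max(tc$points$time_s)))
  invisible(x)
}

# Stacked solve: K conditions as 6-state blocks [E, S, ES, Ep, EpS, P] sharing
# one parameter set; one lsode call per evaluation. Returns a 3-d array
# [time, species, condition].
solve_stacked <- function(params, Eall_vec, ST, times, rtol = 1e-8,
                          atol = 1e-10) {
  K <- length(Eall_vec)
  y0 <- numeric(6 * K)
  for (b in seq_len(K)) {
    y0[6 * (b - 1) + 1] <- params$Fa * Eall_vec[b]        # E
    y0[6 * (b - 1) + 2] <- ST                             # S
    y0[6 * (b - 1) + 4] <- (1 - params$Fa) * Eall_vec[b]  # Ep
  }
  t0 <- times
  prepend <- t0[1] > 0
  if (prepend) t0 <- c(0, t0)
  out <- deSolve::ode(y = y0, times = t0, func = "slicekin_derivs",
                      parms = c(params$kon, params$kslice, params$kphase2),
                      dllname = "slicekin", initfunc = "slicekin_initmod",
                      method = "lsode", mf = 22, rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop(sprintf("ODE integration failed near t = %.6g s",
                 out[nrow(out), 1]), call. = FALSE)
  m <- out[, -1, drop = FALSE]
  if (prepend) m <- m[-1, , drop = FALSE]
  # negative overshoot within solver tolerance is clamped; worse is an error
  clamp <- max(1e-12, 100 * atol)
  if (any(m < -clamp))
    stop(sprintf("negative concentration beyond tolerance (min %.3g nM)",
                 min(m)), call. = FALSE)
  m[m < 0] <- 0
  dim(m) <- c(length(times), 6L, K)
  dimnames(m) <- list(NULL, c("E", "S", "ES", "Eprime", "EprimeS", "P"), NULL)
  m
}

#' Simulate a single-turnover slicing time course
#'
#' Integrates the two-population mass-action scheme (intact RISC binds and
#' slices with `kon`/`kslice`; defective RISC binds with the same `kon` but
#' slices with `kphase2`) from the initial state `E = Fa*Eall`,
#' `Eprime = (1-Fa)*Eall`, `S = ST`, all complexes and product zero, using a
#' stiff backward-differentiation (BDF) integrator.
#'
#' @param params A [kinetic_params()] object.
#' @param condition A [reaction_condition()] object.
#' @param times Sorted, non-negative output times, s.
#' @param rtol,atol Solver tolerances (relative; absolute in nM).
#' @return A data frame of class `species_state` with columns `t`, `E`, `S`,
#'   `ES`, `Eprime`, `EprimeS`, `P` and the derived `fsliced`.
#' @examples
#' p <- kinetic_params(0.02, 0.01, 0, Fa = 1)
#' st <- simulate_timecourse(p, reaction_condition(5, 0.05), c(0, 30, 60))
#' st$fsliced
#' @export
simulate_timecourse <- function(params, condition, times, rtol = 1e-8,
                                atol = 1e-10) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(condition, "reaction_condition"))
  if (length(times) < 1L || any(diff(times) <= 0) || times[1] < 0)
    stop("times must be non-negative and strictly increasing", call. = FALSE)
  m <- solve_stacked(params, condition$Eall, condition$ST, times,
                     rtol = rtol, atol = atol)
  df <- as.data.frame(m[, , 1, drop = TRUE])
  if (length(times) == 1L) df <- as.data.frame(as.list(m[1, , 1]))
  df <- cbind(t = times, df)
  df$fsliced <- apply(df, 1, function(r)
    fraction_sliced_num(r[["P"]], r[["S"]], r[["ES"]], r[["EprimeS"]]))
  class(df) <- c("species_state", "data.frame")
  df
}

fraction_sliced_num <- function(P, S, ES, EprimeS) {
  tot <- P + S + ES + EprimeS
  if (tot <= 0) stop("fraction sliced undefined: all target pools are zero",
                     call. = FALSE)
  P / tot
}

#' Fraction of target sliced at a state
#'
#' `Fsliced = P / (P + S + ES + EprimeS)`: product over total target summed
#' across free, complexed, and sliced pools.
#'
#' @param state A `species_state` row set (as returned by
#'   [simulate_timecourse()]) or any data frame / list with components `P`,
#'   `S`, `ES`, `EprimeS`.
#' @return Numeric fraction(s) in \[0, 1\].
#' @export
fraction_sliced <- function(state) {
  mapply(fraction_sliced_num, state$P, state$S, state$ES, state$EprimeS)
}

#' Pseudo-steady-state closed form for the fraction sliced
#'
#' The two-phase approximation used to seed the ODE fit:
#' \deqn{F = F_a (1 - e^{-t / (1/(k_{on} E_{all}) + 1/k_{slice})})
#'          + (1-F_a)(1 - e^{-k_{phase2} t})}
#' The observed first-phase rate is the harmonic combination of the binding
#' rate `kon*Eall` and the slicing rate `kslice`, as expected when the
#' enzyme-substrate complex is at pseudo-steady state.
#'
#' @param params A [kinetic_params()] object.
#' @param Eall Total RISC concentration, nM.
#' @param t Time(s), s; must be non-negative.
#' @return Fraction(s) sliced in \[0, 1\].
#' @export
psa_fraction_sliced <- function(params, Eall, t) {
  stopifnot(inherits(params, "kinetic_params"))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  if (params$kon * Eall <= 0 || params$kslice <= 0)
    stop("kon * Eall and kslice must be positive", call. = FALSE)
  psa_formula(params$kon, params$kslice, params$kphase2, params$Fa, Eall, t)
}

psa_formula <- function(kon, kslice, kphase2, Fa, Eall, t) {
  tau <- 1 / (kon * Eall) + 1 / kslice
  Fa * (1 - exp(-t / tau)) + (1 - Fa) * (1 - exp(-kphase2 * t))
}

#' Closed-form fraction sliced for the sequential two-step limit
#'
#' Analytic solution of `S -> ES -> P` with pseudo-first-order binding rate
#' `ka = kon * Eall` (valid when enzyme is in large excess and Fa = 1), used
#' as an independent oracle for the ODE integrator:
#' \deqn{F(t) = 1 - \frac{k_{slice} e^{-k_a t} - k_a e^{-k_{slice} t}}
#'                      {k_{slice} - k_a}}
#' with the confluent limit \eqn{1 - (1 + k t) e^{-k t}} when the two rates
#' are equal.
#'
#' @param ka Pseudo-first-order binding rate, /s (> 0).
#' @param kslice Slicing rate constant, /s (> 0).
#' @param t Time(s), s.
#' @return Fraction(s) in \[0, 1\].
#' @export
analytic_sequential_oracle <- function(ka, kslice, t) {
  stopifnot(ka > 0, kslice > 0, all(t >= 0))
  if (abs(ka - kslice) < 1e-12 * max(ka, kslice)) {
    k <- (ka + kslice) / 2
    return(1 - (1 + k * t) * exp(-k * t))
  }
  1 - (kslice * exp(-ka * t) - ka * exp(-kslice * t)) / (kslice - ka)
}
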