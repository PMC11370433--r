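# Synthetic datasets with known ground truth, emulating the study design:
# single-turnover slicing with 0.05 nM radiolabeled target and a RISC
# dilution series at 2, 5, 10 nM; titrations of limiting RISC against 1-2 nM
# target; cold-chase dissociation curves with background. Additive Gaussian
# noise on the fraction scale stands in for gel/phosphorimager quantification
# error.

#' Noise model for synthetic data
#'
#' Additive Gaussian noise on the fraction scale, clipped to \[0, 1\].
#'
#' @param sd Standard deviation on the fraction scale (>= 0), default 0.02.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sd = 0.02, seed = 1) {
  stopifnot(is.numeric(sd), length(sd) == 1L, sd >= 0)
  structure(list(kind = "additive-gaussian", sd = sd, seed = as.integer(seed)),
            class = "noise_model")
}

apply_noise <- function(y, noise) {
  if (noise$sd == 0) return(y)
  pmin(pmax(y + stats::rnorm(length(y), 0, noise$sd), 0), 1)
}

default_time_grid <- function(truth, Eall_series, n = 12) {
  t_lo <- 1 / (truth$kon * min(Eall_series))
  t_hi <- 5 / max(truth$kslice, 1.67e-6)
  if (t_hi <= t_lo) t_hi <- 10 * t_lo
  exp(seq(log(t_lo), log(t_hi), length.out = n))
}

#' Generate a synthetic slicing dataset
#'
#' Simulates the ODE model over a RISC dilution series and adds clipped
#' Gaussian noise. Defaults reproduce the assay design: 0.05 nM target,
#' RISC at 2, 5, and 10 nM, 12 log-spaced time points spanning the binding
#' timescale `1/(kon * min Eall)` to five first-phase lifetimes
#' `5 / max(kslice, 1.67e-6)`.
#'
#' @param truth A [kinetic_params()] object (embedded in the result's
#'   `truth` attribute for recovery tests).
#' @param Eall_series Total RISC concentrations, nM.
#' @param ST Total target concentration, nM.
#' @param times Time grid, s (shared across the series); default as above.
#' @param noise A [noise_model()].
#' @return A [slicing_dataset()] with attributes `truth` and `noise`.
#' @examples
#' truth <- kinetic_params(0.02, 5e-3, 1e-5, 0.9)
#' ds <- generate_slicing_dataset(truth, noise = noise_model(sd = 0))
#' @export
generate_slicing_dataset <- function(truth, Eall_series = c(2, 5, 10),
                                     ST = 0.05, times = NULL,
                                     noise = noise_model()) {
  stopifnot(inherits(truth, "kinetic_params"), inherits(noise, "noise_model"))
  if (is.null(times)) times <- default_time_grid(truth, Eall_series)
  if (length(times) == 0L) stop("time grid is empty", call. = FALSE)
  set.seed(noise$seed)
  tcs <- lapply(Eall_series, function(E) {
    cond <- reaction_condition(E, ST)
    st <- simulate_timecourse(truth, cond, times)
    slicing_timecourse(cond, times, apply_noise(st$fsliced, noise))
  })
  ds <- slicing_dataset(tcs, label = "synthetic")
  attr(ds, "truth") <- truth
  attr(ds, "noise") <- noise
  ds
}

#' Generate a synthetic titration curve
#'
#' @param truth List with `stock` (pM), `KD` (pM), `Fmax`.
#' @param targetT Total target concentration, pM.
#' @param DF_series Distinct dilution factors in (0, 1\].
#' @param noise A [noise_model()].
#' @return A [titration_curve()] with attributes `truth` and `noise`.
#' @export
generate_titration <- function(truth = list(stock = 5e4, KD = 30, Fmax = 1),
                               targetT = 1000, DF_series = (1 / 3)^(0:5),
                               noise = noise_model(sd = 0.03)) {
  stopifnot(inherits(noise, "noise_model"))
  y <- predict_fbound_quadratic(truth$stock, DF_series, targetT, truth$KD,
                                truth$Fmax)
  set.seed(noise$seed)
  cv <- titration_curve(targetT, DF_series, apply_noise(y, noise))
  attr(cv, "truth") <- truth
  attr(cv, "noise") <- noise
  cv
}

#' Generate a synthetic dissociation time course
#'
#' @param truth List with `A`, `koff` (/s), `B`.
#' @param times Chase times, s.
#' @param noise A [noise_model()].
#' @return A [dissociation_timecourse()] with attributes `truth` and `noise`.
#' @export
generate_dissociation <- function(truth = list(A = 0.7, koff = 1e-3, B = 0.05),
                                  times = seq(0, 5000, length.out = 12),
                                  noise = noise_model()) {
  stopifnot(inherits(noise, "noise_model"))
  y <- predict_fbound_exponential(truth$A, truth$koff, truth$B, times)
  set.seed(noise$seed)
  tc <- dissociation_timecourse(times, apply_noise(y, noise),
                                chase = "synthetic 1000-fold cold-target chase")
  attr(tc, "truth") <- truth
  attr(tc, "noise") <- noise
  tc
}
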