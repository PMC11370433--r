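# Active RISC stock quantification: ligand-depletion (quadratic) binding
# isotherm fit to filter-binding titration data, and radiolabel-ratio
# quantification against a duplex standard of known concentration.
# Units here are pM (stock, KD, targetT), matching the printed presets.

#' A filter-binding titration curve
#'
#' @param targetT Total radiolabeled target concentration, pM.
#' @param DF Dilution factors of the RISC stock, distinct values in (0, 1\].
#' @param fbound Fraction of target bound at each dilution, in \[0, 1\].
#' @return An object of class `titration_curve`.
#' @export
titration_curve <- function(targetT, DF, fbound) {
  stopifnot(is.numeric(targetT), length(targetT) == 1L, targetT > 0,
            length(DF) == length(fbound))
  if (any(DF <= 0 | DF > 1)) stop("DF must lie in (0, 1]", call. = FALSE)
  if (anyDuplicated(DF)) stop("DF values must be distinct", call. = FALSE)
  if (any(fbound < 0 | fbound > 1))
    stop("fbound must lie in [0, 1]", call. = FALSE)
  structure(list(targetT = targetT,
                 points = data.frame(DF = DF, fbound = fbound)),
            class = "titration_curve")
}

#' Quadratic (ligand-depletion) binding isotherm
#'
#' Fraction of target bound when RISC at concentration `stock * DF` binds a
#' target present at comparable concentration, so depletion cannot be
#' neglected:
#' \deqn{F = F_{max} \frac{(s + T + K_D) - \sqrt{(s + T + K_D)^2 - 4 s T}}
#'                        {2T}, \quad s = stock \cdot DF}
#' The discriminant is clamped at zero (within a relative tolerance of 1e-9)
#' to absorb floating-point loss at the stoichiometric corner.
#'
#' @param stock RISC stock concentration, pM.
#' @param DF Dilution factor(s).
#' @param targetT Total target concentration, pM (> 0).
#' @param KD Dissociation constant, pM.
#' @param Fmax Maximal bound fraction at the plateau.
#' @return Predicted bound fraction(s), in \[0, Fmax\].
#' @export
predict_fbound_quadratic <- function(stock, DF, targetT, KD, Fmax) {
  stopifnot(all(stock >= 0), all(DF >= 0), targetT > 0, all(KD >= 0),
            all(Fmax >= 0))
  s <- stock * DF
  b <- s + targetT + KD
  disc <- b^2 - 4 * s * targetT
  bad <- disc < -1e-9 * pmax(b^2, 1)
  if (any(bad))
    stop("negative discriminant beyond rounding tolerance", call. = FALSE)
  disc[disc < 0] <- 0
  Fmax * (b - sqrt(disc)) / (2 * targetT)
}

#' Printed presets for the titration fit
#'
#' `"miR-200b"`: stock initialized at 1e5 pM in (0, 1e6); KD initialized at
#' 10^1.5 pM in (10^0.5, 10^2.5), fit in log space; Fmax fixed at 1; default
#' targetT 1000 pM. `"let-7a"`: stock in (0, 2e6); KD in (1e-10, 1e10), log
#' space; Fmax initialized at 0.9 in (0, 1); default targetT 2000 pM.
#'
#' @param preset `"miR-200b"` or `"let-7a"`.
#' @return A list of initializations and bounds.
#' @export
titration_preset <- function(preset = c("miR-200b", "let-7a")) {
  preset <- match.arg(preset)
  if (preset == "miR-200b")
    list(name = preset, targetT = 1000,
         stock = list(init = 1e5, lower = 0, upper = 1e6),
         KD = list(init = 10^1.5, lower = 10^0.5, upper = 10^2.5),
         Fmax = list(fixed = 1))
  else
    list(name = preset, targetT = 2000,
         stock = list(init = 1e5, lower = 0, upper = 2e6),
         KD = list(init = 10^1.5, lower = 1e-10, upper = 1e10),
         Fmax = list(init = 0.9, lower = 0, upper = 1))
}

#' Fit a titration curve to the quadratic isotherm
#'
#' Levenberg-Marquardt least squares with `KD` optimized as log10 and `stock`
#' in natural scale, under the per-guide preset bounds. Because the
#' depletion-dominated regime (`KD` well below `targetT`) carries a stock/KD
#' ridge with local optima, the preset initialization is supplemented by a
#' deterministic ladder of restarts and the best fit is kept.
#'
#' @param curve A [titration_curve()].
#' @param preset Guide preset name (see [titration_preset()]) or a preset
#'   list with overrides.
#' @param n_boot,level,seed Residual-bootstrap interval settings
#'   (`n_boot = 0` skips intervals).
#' @return An object of class `titration_fit` with `stock`, `KD`, `Fmax`,
#'   optional percentile intervals, and the preset used.
#' @export
fit_titration <- function(curve, preset = "miR-200b", n_boot = 200,
                          level = 0.95, seed = 1) {
  stopifnot(inherits(curve, "titration_curve"))
  ps <- if (is.character(preset)) titration_preset(preset) else preset
  pts <- curve$points
  if (nrow(pts) < 4)
    warning("fewer than 4 titration points; fit may be poorly determined",
            call. = FALSE)
  if (diff(range(pts$fbound)) < 1e-9)
    stop("flat titration curve: stock not identifiable", call. = FALSE)
  fmax_fixed <- !is.null(ps$Fmax$fixed)
  free <- c("stock", "lKD", if (!fmax_fixed) "Fmax")
  lo <- c(stock = ps$stock$lower, lKD = log10(ps$KD$lower),
          if (!fmax_fixed) c(Fmax = ps$Fmax$lower))
  hi <- c(stock = ps$stock$upper, lKD = log10(ps$KD$upper),
          if (!fmax_fixed) c(Fmax = ps$Fmax$upper))
  predict_x <- function(x, DF)
    predict_fbound_quadratic(x[["stock"]], DF, curve$targetT, 10^x[["lKD"]],
                             if (fmax_fixed) ps$Fmax$fixed else x[["Fmax"]])
  # the depletion-dominated regime has a stock/KD ridge with local optima, so
  # the printed initialization is supplemented with a deterministic ladder of
  # restarts; the best (lowest SSE) fit is kept, printed init first on ties
  stock0s <- unique(c(ps$stock$init,
                      10^seq(3, log10(ps$stock$upper), length.out = 6)))
  lKD0s <- unique(pmin(pmax(c(log10(ps$KD$init), 0, 3), lo[["lKD"]]),
                       hi[["lKD"]]))
  fit <- NULL
  for (s0 in stock0s) for (k0 in lKD0s) {
    x0 <- c(stock = s0, lKD = k0, if (!fmax_fixed) c(Fmax = ps$Fmax$init))
    cand <- suppressWarnings(minpack.lm::nls.lm(
      par = x0, lower = lo, upper = hi,
      fn = function(x) predict_x(x, pts$DF) - pts$fbound,
      control = minpack.lm::nls.lm.control(maxiter = 200)))
    if (is.null(fit) || sum(cand$fvec^2) < sum(fit$fvec^2) * (1 - 1e-9))
      fit <- cand
  }
  fitted <- predict_x(fit$par, pts$DF)
  out_par <- function(x) c(stock = x[["stock"]], KD = 10^x[["lKD"]],
                           Fmax = if (fmax_fixed) ps$Fmax$fixed else x[["Fmax"]])
  est <- out_par(fit$par)
  ci <- NULL; draws <- NULL
  if (n_boot > 0) {
    if (n_boot < 20) stop("n_boot must be 0 or at least 20", call. = FALSE)
    free_nat <- c("stock", "KD", if (!fmax_fixed) "Fmax")
    draws <- boot_refit_draws(
      n_boot = n_boot, seed = seed, group = rep(1L, nrow(pts)),
      fitted = fitted, residuals = pts$fbound - fitted, par_names = free_nat,
      refit = function(y) {
        f <- minpack.lm::nls.lm(par = fit$par, lower = lo, upper = hi,
                                fn = function(x) predict_x(x, pts$DF) - y,
                                control = minpack.lm::nls.lm.control(maxiter = 60))
        out_par(f$par)[free_nat]
      })
    ci <- basic_ci(draws, as.list(est), level, natural_scale = "Fmax")
  }
  structure(list(stock = est[["stock"]], KD = est[["KD"]],
                 Fmax = est[["Fmax"]], fmax_fixed = fmax_fixed,
                 free = free, ci = ci, boot = draws,
                 converged = fit$info %in% 1:4, preset = ps,
                 fitted = fitted, residuals = pts$fbound - fitted,
                 curve = curve), class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf("Titration fit (preset %s): %s\n", x$preset$name,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  active stock = %.5g pM\n", x$stock))
  cat(sprintf("  KD           = %.4g pM\n", x$KD))
  cat(sprintf("  Fmax         = %.4g%s\n", x$Fmax,
              if (x$fmax_fixed) " (fixed)" else ""))
  if (!is.null(x$ci))
    for (p in rownames(x$ci))
      cat(sprintf("  %s CI: [%.4g, %.4g]\n", p, x$ci[p, "lower"],
                  x$ci[p, "upper"]))
  invisible(x)
}

#' RISC concentration from guide radioactivity
#'
#' The concentration of a radiolabeled-guide RISC preparation relative to the
#' guide-passenger duplex standard of known concentration:
#' `duplex_conc * signal_risc / signal_duplex`.
#'
#' @param signal_risc Background-corrected guide signal in the purified RISC,
#'   arbitrary units.
#' @param signal_duplex Background-corrected guide signal in the duplex
#'   standard, same units (> 0).
#' @param duplex_conc Known duplex concentration, nM.
#' @return RISC concentration, nM.
#' @export
concentration_from_radioactivity <- function(signal_risc, signal_duplex,
                                             duplex_conc) {
  if (any(signal_risc < 0) || any(signal_duplex <= 0) || any(duplex_conc < 0))
    stop("signals must be non-negative and signal_duplex positive",
         call. = FALSE)
  duplex_conc * signal_risc / signal_duplex
}

#' @describeIn unit_helpers picomolar to nanomolar
#' @export
pM_to_nM <- function(x) x / 1000

#' Unit conversion helpers at the package boundary
#'
#' Slicing works in nM, titration in pM.
#'
#' @param x Concentration value(s).
#' @name unit_helpers
#' @export
nM_to_pM <- function(x) x * 1000
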