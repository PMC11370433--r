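# Independent numerical oracles, deliberately distinct from the package's
# solver: fixed-step RK4 integrators and a root-finding equilibrium solver.

# full two-population bimolecular scheme
rk4_full_scheme <- function(kon, kslice, kphase2, Fa, Eall, ST, times,
                            n_per_unit = 50) {
  f <- function(y) {
    b1 <- kon * y[1] * y[2]; b2 <- kon * y[4] * y[2]
    c(-b1 + kslice * y[3], -b1 - b2, b1 - kslice * y[3],
      -b2 + kphase2 * y[5], b2 - kphase2 * y[5],
      kslice * y[3] + kphase2 * y[5])
  }
  y <- c(Fa * Eall, ST, 0, (1 - Fa) * Eall, 0, 0)
  out <- numeric(length(times))
  tprev <- 0
  for (i in seq_along(times)) {
    dt <- times[i] - tprev
    if (dt > 0) {
      n <- max(20L, ceiling(dt * n_per_unit))
      h <- dt / n
      for (j in seq_len(n)) {
        k1 <- f(y); k2 <- f(y + h / 2 * k1); k3 <- f(y + h / 2 * k2)
        k4 <- f(y + h * k3)
        y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
    }
    out[i] <- y[6] / ST
    tprev <- times[i]
  }
  out
}

# linear two-step scheme S -> ES -> P at pseudo-first-order rate ka
rk4_two_step <- function(ka, kslice, t_end, n = 60000) {
  f <- function(y) c(-ka * y[1], ka * y[1] - kslice * y[2], kslice * y[2])
  y <- c(1, 0, 0)
  h <- t_end / n
  for (j in seq_len(n)) {
    k1 <- f(y); k2 <- f(y + h / 2 * k1); k3 <- f(y + h / 2 * k2)
    k4 <- f(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  y[3]
}

# equilibrium R + T <-> RT solved by root finding for given totals and KD
equilibrium_fbound <- function(Rtot, Ttot, KD, Fmax = 1) {
  g <- function(RT) (Rtot - RT) * (Ttot - RT) - KD * RT
  RT <- stats::uniroot(g, c(0, min(Rtot, Ttot)), tol = 1e-12)$root
  Fmax * RT / Ttot
}

truth_default <- function() kinetic_params(0.02, 5e-3, 1e-5, 0.9)

quiet_condition <- function(Eall, ST) suppressWarnings(reaction_condition(Eall, ST))
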