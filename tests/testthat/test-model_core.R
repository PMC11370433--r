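test_that("constructors enforce domain invariants", {
  expect_error(kinetic_params(-1, 0.1, 0, 0.5), "non-negative")
  expect_error(kinetic_params(0.1, 0.1, 0, 1.5), "Fa")
  expect_error(reaction_condition(0, 0.05), "positive")
  expect_warning(reaction_condition(0.2, 0.05), "single-turnover")
  expect_error(slicing_timecourse(quiet_condition(5, 0.05), c(0, 10, 10),
                                  c(0, 0.1, 0.2)), "strictly increasing")
  expect_error(slicing_timecourse(quiet_condition(5, 0.05), c(0, 10),
                                  c(0, 1.2)), "outside")
  tc1 <- slicing_timecourse(quiet_condition(5, 0.05), c(10, 20), c(0.1, 0.2))
  tc2 <- slicing_timecourse(quiet_condition(5, 0.10), c(10, 20), c(0.1, 0.2))
  expect_error(slicing_dataset(list(tc1, tc2)), "same total target")
})

test_that("fraction sliced is the printed ratio of pools", {
  expect_equal(fraction_sliced(list(P = 0, S = 0.05, ES = 0, EprimeS = 0)), 0)
  expect_equal(fraction_sliced(list(P = 0.05, S = 0, ES = 0, EprimeS = 0)), 1)
  # hand evaluation: 0.02 / (0.02 + 0.02 + 0.005 + 0.005)
  expect_equal(
    fraction_sliced(list(P = 0.02, S = 0.02, ES = 0.005, EprimeS = 0.005)),
    0.4)
  expect_error(fraction_sliced(list(P = 0, S = 0, ES = 0, EprimeS = 0)),
               "undefined")
})

test_that("simulation starts at zero and conserves mass", {
  p <- kinetic_params(0.02, 5e-3, 1e-5, 0.9)
  cond <- quiet_condition(5, 0.05)
  times <- c(0, 10^seq(0, 4, length.out = 30))
  st <- simulate_timecourse(p, cond, times)
  expect_identical(st$fsliced[1], 0)
  # three conservation sums, relative 1e-8
  target <- st$S + st$ES + st$EprimeS + st$P
  expect_lt(max(abs(target - 0.05)) / 0.05, 1e-8)
  intact <- st$E + st$ES
  expect_lt(max(abs(intact - 0.9 * 5)) / (0.9 * 5), 1e-8)
  defect <- st$Eprime + st$EprimeS
  expect_lt(max(abs(defect - 0.1 * 5)) / (0.1 * 5), 1e-8)
  # monotone progress
  expect_true(all(diff(st$fsliced) >= -1e-10))
})

test_that("ODE solution matches independent integrators in the excess limit", {
  # full-scheme RK4 oracle at 100x excess (depletion still visible)
  st <- simulate_timecourse(kinetic_params(0.02, 0.01, 0, 1),
                            quiet_condition(5, 0.05), c(30, 60, 120))
  oracle <- rk4_full_scheme(0.02, 0.01, 0, 1, 5, 0.05, c(30, 60, 120))
  expect_lt(max(abs(st$fsliced - oracle)), 1e-6)
  # frozen oracle value at t = 60 s
  expect_equal(st$fsliced[2], 0.3901745, tolerance = 1e-6)
  # sequential closed form valid at 1000x excess: agreement within 1e-4
  tt <- 10^seq(0, 3.2, length.out = 50)
  st2 <- simulate_timecourse(kinetic_params(0.02, 0.01, 0, 1),
                             quiet_condition(5, 0.005), tt)
  expect_lt(max(abs(st2$fsliced - analytic_sequential_oracle(0.1, 0.01, tt))),
            1e-4)
})

test_that("asymptotic fraction sliced equals Fa when kphase2 = 0", {
  st <- simulate_timecourse(kinetic_params(0.02, 5e-3, 0, 0.8),
                            quiet_condition(5, 0.005), c(1e5, 5e5))
  expect_lt(abs(st$fsliced[2] - 0.8), 1e-3)
})

test_that("pseudo-steady-state closed form behaves as printed", {
  p <- kinetic_params(0.02, 0.01, 3.33e-6, 0.9)
  expect_equal(psa_fraction_sliced(p, 5, 0), 0)
  # direct arithmetic: 0.9*(1 - exp(-100/110)) + 0.1*(1 - exp(-3.33e-4))
  expect_equal(psa_fraction_sliced(p, 5, 100), 0.5374320, tolerance = 1e-6)
  # both phases saturate
  expect_equal(psa_fraction_sliced(p, 5, 1e8), 1, tolerance = 1e-9)
  # non-decreasing in t
  tt <- seq(0, 5000, length.out = 200)
  expect_true(all(diff(psa_fraction_sliced(p, 5, tt)) >= 0))
  expect_error(psa_fraction_sliced(p, 5, -1), "non-negative")
})

test_that("PSA and ODE agree when binding and slicing timescales separate", {
  # kon*Eall = 0.2 /s >> kslice = 2e-3 /s (100x), kphase2 * t << 1
  p <- kinetic_params(0.02, 2e-3, 1.67e-6, 0.95)
  tt <- 10^seq(1, 3.3, length.out = 20)
  st <- simulate_timecourse(p, quiet_condition(10, 0.05), tt)
  expect_lt(max(abs(st$fsliced - psa_fraction_sliced(p, 10, tt))), 0.02)
})

test_that("sequential-reaction oracle matches brute-force integration", {
  expect_equal(analytic_sequential_oracle(0.1, 0.01, 0), 0)
  # confluent limit ka = kslice = k
  k <- 0.05; t <- 37
  expect_equal(analytic_sequential_oracle(k, k, t),
               1 - (1 + k * t) * exp(-k * t))
  # brute force: fixed-grid RK4 of the linear two-step scheme
  expect_equal(analytic_sequential_oracle(0.1, 0.01, 60),
               rk4_two_step(0.1, 0.01, 60), tolerance = 1e-8)
  expect_true(all(analytic_sequential_oracle(0.1, 0.01,
                                             c(0, 1, 10, 100, 1e4)) >= 0))
})

test_that("solver reports integration failures with context", {
  expect_error(simulate_timecourse(truth_default(), quiet_condition(5, 0.05),
                                   c(10, 5)), "strictly increasing")
})
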