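test_that("guess stage returns printed defaults on degenerate data", {
  tt <- c(10, 100, 1000)
  tcs <- lapply(c(2, 5, 10), function(E)
    slicing_timecourse(quiet_condition(E, 0.05), tt, rep(0, 3)))
  g <- initial_guess_fit(slicing_dataset(tcs))
  # all-zero data: failure fallback with the slow-mode initialization
  expect_equal(g$kon, 0.02)
  expect_equal(g$kslice, 1.67e-5)
  expect_equal(g$kphase2, 3.33e-6)
  expect_equal(g$Fa, 0.85)
  expect_identical(attr(g, "stage_log")$status, "failed_fallback")
})

test_that("guess stage recovers parameters from noiseless closed-form data", {
  truth <- truth_default()
  # grid long enough to resolve the slow second phase (1/kphase2 = 1e5 s)
  tt <- exp(seq(log(5), log(3e5), length.out = 14))
  tcs <- lapply(c(2, 5, 10), function(E) slicing_timecourse(
    quiet_condition(E, 0.05), tt, psa_fraction_sliced(truth, E, tt)))
  ds <- slicing_dataset(tcs)
  g <- initial_guess_fit(ds)
  expect_lt(attr(g, "stage_log")$rss, 1e-6)
  for (p in c("kon", "kslice", "kphase2"))
    expect_lt(abs(unclass(g)[[p]] / unclass(truth)[[p]] - 1), 0.01)
  expect_lt(abs(g$Fa - truth$Fa), 0.01)
})

test_that("slow-mode initialization auto-triggers on slow reactions", {
  truth <- kinetic_params(0.02, 3e-5, 1.67e-6, 0.9)
  tt <- exp(seq(log(10), log(3000), length.out = 10))
  ds <- generate_slicing_dataset(truth, times = tt, noise = noise_model(sd = 0))
  maxF <- max(vapply(ds$timecourses, function(tc) max(tc$points$fsliced),
                     numeric(1)))
  expect_lt(maxF, 0.3)
  g <- initial_guess_fit(ds)
  expect_true(attr(g, "stage_log")$slow)
})

test_that("ODE fit recovers truth from noiseless data", {
  truth <- truth_default()
  ds <- generate_slicing_dataset(truth, noise = noise_model(sd = 0))
  f <- fit_ode_model(ds)
  expect_true(f$converged)
  expect_lt(abs(f$params$kslice / truth$kslice - 1), 0.01)
  expect_lt(abs(f$params$kon / truth$kon - 1), 0.05)
  expect_lt(abs(f$params$Fa - truth$Fa), 0.01)
})

test_that("objective vanishes when parameters are held at truth", {
  truth <- kinetic_params(0.02, 5e-3, 0, 0.9)
  ds <- generate_slicing_dataset(truth, noise = noise_model(sd = 0))
  cons <- fit_constraints(fix_kon_at_diffusion_limit = FALSE,
                          fix_kphase2_zero = TRUE, fix_Fa = 0.9)
  g <- kinetic_params(0.02, 5e-3, 1e-5, 0.9)
  cons2 <- fit_constraints(fix_kphase2_zero = TRUE, fix_Fa = 0.9)
  f <- fit_ode_model(ds, guesses = g, constraints = cons2)
  expect_lt(f$objective, 1e-6)
  expect_false("kphase2" %in% f$free)
  expect_false("Fa" %in% f$free)
})

test_that("guesses outside the ODE-stage bounds are rejected", {
  ds <- generate_slicing_dataset(truth_default(), noise = noise_model(sd = 0))
  bad <- kinetic_params(0.02, 5e-3, 1e-5, 0.5)   # Fa below 0.6 floor
  expect_error(fit_ode_model(ds, guesses = bad), "outside")
})

test_that("estimates are invariant to time-course and point ordering", {
  truth <- truth_default()
  ds <- generate_slicing_dataset(truth, noise = noise_model(sd = 0.02, seed = 4))
  # reorder courses
  ds_r <- ds
  ds_r$timecourses <- rev(ds$timecourses)
  g <- kinetic_params(0.02, 5e-3, 1e-5, 0.9)
  f1 <- fit_ode_model(ds, guesses = g)
  f2 <- fit_ode_model(ds_r, guesses = g)
  for (p in c("kon", "kslice", "kphase2", "Fa"))
    expect_equal(unclass(f1$params)[[p]], unclass(f2$params)[[p]],
                 tolerance = 1e-6)
  # reorder replicate blocks within a course
  tt <- ds$timecourses[[1]]$points$time_s
  fs <- ds$timecourses[[1]]$points$fsliced
  cond <- ds$timecourses[[1]]$condition
  tc_ab <- slicing_timecourse(cond, c(tt, tt), c(fs, rev(rev(fs))),
                              replicate = rep(1:2, each = length(tt)))
  tc_ba <- slicing_timecourse(cond, c(tt, tt), c(fs, fs),
                              replicate = rep(2:1, each = length(tt)))
  ds_a <- slicing_dataset(list(tc_ab), label = "a")
  ds_b <- slicing_dataset(list(tc_ba), label = "b")
  fa <- fit_ode_model(ds_a, guesses = g)
  fb <- fit_ode_model(ds_b, guesses = g)
  expect_equal(fa$params$kslice, fb$params$kslice, tolerance = 1e-6)
})

test_that("bootstrap intervals are reproducible and degenerate without noise", {
  truth <- truth_default()
  ds <- generate_slicing_dataset(truth, noise = noise_model(sd = 0))
  f <- fit_ode_model(ds)
  f1 <- estimate_confidence_intervals(ds, f, n_boot = 25, seed = 42)
  f2 <- estimate_confidence_intervals(ds, f, n_boot = 25, seed = 42)
  expect_identical(f1$ci, f2$ci)
  expect_identical(f1$boot, f2$boot)
  # noiseless residuals: interval half-width below 1% of the estimate
  hw <- (f1$ci["kslice", "upper"] - f1$ci["kslice", "lower"]) / 2
  expect_lt(hw, 0.01 * f1$params$kslice)
  expect_error(estimate_confidence_intervals(ds, f, n_boot = 10), "at least 20")
  # fixed parameters carry no interval
  cons <- fit_constraints(fix_kphase2_zero = TRUE)
  fc <- fit_ode_model(ds, constraints = cons)
  fc <- estimate_confidence_intervals(ds, fc, n_boot = 25, seed = 1)
  expect_false("kphase2" %in% rownames(fc$ci))
})

test_that("recovery degrades monotonically with noise", {
  truth <- truth_default()
  sds <- c(0, 0.01, 0.02, 0.05)
  med <- vapply(sds, function(s) {
    errs <- vapply(1:6, function(seed) {
      ds <- generate_slicing_dataset(truth,
                                     noise = noise_model(sd = s, seed = seed))
      f <- fit_ode_model(ds)
      abs(f$params$kslice / truth$kslice - 1)
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med) >= -1e-8))
})

test_that("dilution series disentangles kon and kslice", {
  # kon*Eall = kslice at 5 nM: a single concentration cannot separate binding
  # from slicing; the ridge drives kon onto the diffusion limit and the
  # unidentifiability trigger fires. The three-concentration design resolves
  # both parameters.
  truth <- kinetic_params(0.02, 0.1, 1e-5, 0.9)
  tt <- exp(seq(log(2), log(500), length.out = 12))
  ds1 <- generate_slicing_dataset(truth, Eall_series = 5, times = tt,
                                  noise = noise_model(0.02, 21))
  ds3 <- generate_slicing_dataset(truth, Eall_series = c(2, 5, 10),
                                  times = tt, noise = noise_model(0.02, 21))
  f1 <- estimate_confidence_intervals(ds1, suppressWarnings(fit_ode_model(ds1)),
                                      n_boot = 40, seed = 5)
  f3 <- estimate_confidence_intervals(ds3, suppressWarnings(fit_ode_model(ds3)),
                                      n_boot = 40, seed = 5)
  f1b <- apply_fallbacks(f1, ds1)
  f3b <- apply_fallbacks(f3, ds3)
  expect_true(f1b$constraints$fix_kon_at_diffusion_limit)
  expect_false(f3b$constraints$fix_kon_at_diffusion_limit)
  expect_lt(abs(f3$params$kon / truth$kon - 1), 0.3)
  expect_lt(abs(f3$params$kslice / truth$kslice - 1), 0.15)
})

test_that("fallbacks pass well-determined fits through unchanged", {
  truth <- truth_default()
  tt <- exp(seq(log(5), log(2e5), length.out = 14))
  ds <- generate_slicing_dataset(truth, times = tt,
                                 noise = noise_model(sd = 0.01, seed = 6))
  f <- fit_ode_model(ds)
  f <- estimate_confidence_intervals(ds, f, n_boot = 40, seed = 6)
  fb <- apply_fallbacks(f, ds)
  expect_identical(fb$fallback_log, character(0))
  expect_identical(fb$params, f$params)
})
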