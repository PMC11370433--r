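# lightweight stand-in fits with controlled estimates and bootstrap draws
make_fake_slicing_fit <- function(kslice, draws_factor = NULL, seed = 1) {
  f <- structure(list(
    params = kinetic_params(0.02, kslice, 1e-5, 0.9),
    free = c("kon", "kslice", "kphase2", "Fa"),
    converged = TRUE,
    constraints = fit_constraints(),
    boot = NULL), class = "slicing_fit")
  if (!is.null(draws_factor)) {
    set.seed(seed)
    f$boot <- cbind(kslice = kslice * exp(rnorm(200, 0, draws_factor)),
                    kon = rep(0.02, 200))
  }
  f
}

test_that("fold change of identical fits is one", {
  a <- make_fake_slicing_fit(0.01, draws_factor = 0.1, seed = 1)
  b <- make_fake_slicing_fit(0.01, draws_factor = 0.1, seed = 2)
  fc <- fold_change(a, b, "kslice", seed = 3)
  expect_equal(fc$ratio, 1)
  expect_true(fc$ci[["lower"]] <= 1 && 1 <= fc$ci[["upper"]])
  expect_true(fc$includes_one)
})

test_that("fold change recovers constructed ratios and is antisymmetric", {
  a <- make_fake_slicing_fit(0.01, draws_factor = 0.05, seed = 1)
  b <- make_fake_slicing_fit(0.001, draws_factor = 0.05, seed = 2)
  fc <- fold_change(a, b, "kslice")
  expect_equal(fc$ratio, 10)
  fc_rev <- fold_change(b, a, "kslice")
  expect_equal(fc$ratio * fc_rev$ratio, 1)
  expect_false(fc$includes_one)
})

test_that("interval width shrinks as bootstrap spread vanishes", {
  widths <- vapply(c(0.2, 0.05, 0.01, 0.001), function(s) {
    a <- make_fake_slicing_fit(0.01, draws_factor = s, seed = 1)
    b <- make_fake_slicing_fit(0.002, draws_factor = s, seed = 2)
    fc <- fold_change(a, b, "kslice")
    fc$ci[["upper"]] - fc$ci[["lower"]]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("fixed parameters cannot be compared", {
  a <- make_fake_slicing_fit(0.01)
  b <- make_fake_slicing_fit(0.002)
  b$free <- setdiff(b$free, "kslice")
  b$constraints <- fit_constraints()
  expect_error(fold_change(a, b, "kslice"), "fixed")
  c <- make_fake_slicing_fit(0.002)
  c$converged <- FALSE
  # identical constraints: allowed with a warning
  expect_warning(fold_change(a, c, "kslice"), "unconverged")
  # differing constraints plus non-convergence: refused
  c$constraints <- fit_constraints(fix_kphase2_zero = TRUE)
  expect_error(fold_change(a, c, "kslice"), "converged")
})

test_that("relative kslice table flags null-crossing comparisons", {
  ref <- make_fake_slicing_fit(0.01, draws_factor = 0.05, seed = 1)
  two <- make_fake_slicing_fit(0.02, draws_factor = 0.05, seed = 2)
  ten <- make_fake_slicing_fit(0.1, draws_factor = 0.05, seed = 3)
  near <- make_fake_slicing_fit(0.0102, draws_factor = 0.05, seed = 4)
  tab <- relative_kslice_table(list(wt = ref, x2 = two, x10 = ten,
                                    nearwt = near), reference = "wt")
  expect_equal(sort(tab$label), c("nearwt", "x10", "x2"))
  expect_equal(tab$ratio[tab$label == "x2"], 2)
  expect_equal(tab$ratio[tab$label == "x10"], 10)
  expect_true(tab$includes_one[tab$label == "nearwt"])
  expect_false(tab$includes_one[tab$label == "x10"])
  expect_error(relative_kslice_table(list(a = ref, a = two), "a"), "duplicate")
  empty <- relative_kslice_table(list(wt = ref), "wt")
  expect_equal(nrow(empty), 0)
})

test_that("end-to-end fold change from fitted synthetic pair", {
  wt_truth <- truth_default()
  mut_truth <- kinetic_params(0.02, 1e-3, 1e-5, 0.9)
  ds_wt <- generate_slicing_dataset(wt_truth,
                                    noise = noise_model(sd = 0.02, seed = 11))
  ds_mut <- generate_slicing_dataset(mut_truth,
                                     noise = noise_model(sd = 0.02, seed = 12))
  f_wt <- estimate_confidence_intervals(ds_wt, fit_ode_model(ds_wt),
                                        n_boot = 50, seed = 11)
  f_mut <- estimate_confidence_intervals(ds_mut, fit_ode_model(ds_mut),
                                         n_boot = 50, seed = 12)
  fc <- fold_change(f_wt, f_mut, "kslice", label_a = "WT", label_b = "mut")
  expect_lt(abs(fc$ratio / 5 - 1), 0.25)
  expect_true(fc$ci[["lower"]] <= 5 && 5 <= fc$ci[["upper"]])
})
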