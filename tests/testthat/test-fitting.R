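test_that("objective_D is the summed squared misfit of both moduli", {
  p926 <- default_table3_params(0.926)
  w <- 2 * pi * c(0.5, 1, 2, 5)
  ds <- synthesize_dataset(p926, 0.926, w)
  expect_equal(objective_D(ds, p926), 0)                 # perfect fit
  # one point with residuals (1, 2): D = 1 + 4
  one <- modulus_dataset("one", 0.926, c(w[1L], w[2L]),
                         storage = storage_modulus_bmd(p926, 0.926, c(w[1L], w[2L])) - c(1, 0),
                         loss = loss_modulus_bmd(p926, 0.926, c(w[1L], w[2L])) - c(2, 0))
  expect_equal(objective_D(one, p926), 5)
  # mismatched parameter rows: brute-force summation oracle
  p604 <- default_table3_params(0.604)
  ds604 <- synthesize_dataset(p604, 0.604, w)
  D <- 0
  for (k in seq_along(w)) {
    D <- D + (storage_modulus_bmd(p926, 0.604, w[k]) - ds604$storage[k])^2 +
      (loss_modulus_bmd(p926, 0.604, w[k]) - ds604$loss[k])^2
  }
  expect_gt(D, 0)
  expect_equal(objective_D(ds604, p926), D)
})

test_that("r_squared is 1 for perfect fits, 0 for the channel mean, and errors on zero variance", {
  p <- default_table3_params(0.862)
  w <- 2 * pi * c(0.5, 1, 2, 5)
  ds <- synthesize_dataset(p, 0.862, w)
  expect_equal(unname(r_squared(ds, p)), c(1, 1, 1))
  # a constant model equal to each channel mean gives R2 = 0 per channel
  const_fit <- structure(list(equilibrium = mean(ds$storage),
                              amp_storage = 1e-12, amp_loss = 1e-12,
                              weights = 0.5, relaxation_times = 1),
                         class = "dma_fit")
  r2 <- r_squared(ds, const_fit)
  expect_equal(unname(r2["r2_storage"]), 0, tolerance = 1e-6)
  flat <- modulus_dataset("flat", 0.8, c(1, 2), c(100, 100), c(10, 20))
  expect_error(r_squared(flat, p), "zero variance")
})

test_that("noise-free spectra are recovered to <1% from a dense grid", {
  truth <- prony_series(500, weights = c(0.1, 0.15, 0.2, 0.1),
                        relaxation_times = c(0.01, 0.1, 1, 10))
  w <- dense_omega_grid(truth$relaxation_times)
  ds <- dataset_from_spectrum(truth, w)
  fit <- fit_prony(ds, order = 4, mode = "prony", seed = 1)
  expect_true(fit$converged)
  expect_equal(fit$relaxation_times, truth$relaxation_times, tolerance = 1e-2)
  expect_equal(fit$weights, truth$weights, tolerance = 1e-2)
  expect_equal(fit$equilibrium, truth$equilibrium_modulus, tolerance = 1e-2)
  expect_equal(fit$amp_storage, truth$instantaneous_modulus, tolerance = 1e-2)
  # perfect-fit attainability
  expect_lt(fit$objective_D, 1e-6 * sum(ds$storage^2))
})

test_that("a single branch is recovered exactly from its loss-peak closed form", {
  truth <- prony_series(400, 600, weights = 0.4, relaxation_times = 0.5)
  w <- dense_omega_grid(0.5, n = 2001L)
  loss <- loss_modulus(truth, w)
  # closed-form inversion oracle: tau = 1/argmax(E''), E0*g = 2*max(E'')
  tau_hat <- 1 / w[which.max(loss)]
  amp_hat <- 2 * max(loss)
  expect_equal(tau_hat, 0.5, tolerance = 1e-2)
  expect_equal(amp_hat, 240, tolerance = 1e-3)
  ds <- dataset_from_spectrum(truth, dense_omega_grid(0.5, n = 25L))
  fit <- fit_prony(ds, order = 1, mode = "prony",
                   config = fit_config(n_starts = 8), seed = 2)
  expect_equal(fit$relaxation_times, tau_hat, tolerance = 1e-2)
  expect_equal(fit$amp_storage * fit$weights, amp_hat, tolerance = 1e-2)
})

test_that("fits respect constraints, improve on every start, and are seed-deterministic", {
  truth <- prony_series(500, weights = c(0.1, 0.15, 0.2, 0.1),
                        relaxation_times = c(0.01, 0.1, 1, 10))
  w <- dense_omega_grid(truth$relaxation_times)
  set.seed(42)
  ds <- modulus_dataset("noisy", 0.8, w,
                        storage_modulus(truth, w) * (1 + rnorm(30, 0, 0.02)),
                        loss_modulus(truth, w) * (1 + rnorm(30, 0, 0.02)))
  for (mode in c("prony", "reduced")) {
    fit <- fit_prony(ds, order = 4, mode = mode,
                     config = fit_config(n_starts = 12), seed = 5)
    expect_true(all(fit$relaxation_times > 0))
    expect_true(all(fit$weights > 0 & fit$weights < 1))
    expect_false(is.unsorted(fit$relaxation_times))
    expect_true(all(fit$objective_D <= fit$start_objectives + 1e-9))
    fit2 <- fit_prony(ds, order = 4, mode = mode,
                      config = fit_config(n_starts = 12), seed = 5)
    expect_identical(fit, fit2)
    fit3 <- fit_prony(ds, order = 4, mode = mode,
                      config = fit_config(n_starts = 12), seed = 6)
    expect_false(identical(fit3$start_objectives, fit$start_objectives))
  }
})

test_that("under-determined datasets trigger an identifiability warning, not an error", {
  p <- default_table3_params(0.735)
  ds <- synthesize_dataset(p, 0.735, 2 * pi * c(0.5, 1, 2, 5))
  expect_warning(fit <- fit_prony(ds, order = 4, seed = 1),
                 "identifiability")
  expect_true(fit$identifiability_warning)
  expect_lt(fit$objective_D, 1e-6 * sum(ds$storage^2))   # still interpolates
  # a determined problem stays silent
  w30 <- 2 * pi * exp(seq(log(0.05), log(50), length.out = 30))
  expect_no_warning(fit_prony(synthesize_dataset(p, 0.735, w30),
                              order = 4, config = fit_config(4), seed = 1))
})

test_that("reduced-mode fits report a representative row reproducing the fitted curves", {
  p <- default_table3_params(0.926)
  w30 <- 2 * pi * exp(seq(log(0.05), log(50), length.out = 30))
  ds <- synthesize_dataset(p, 0.926, w30, sample_id = "rep")
  fit <- fit_prony(ds, order = 4, mode = "reduced",
                   config = fit_config(16), seed = 3)
  expect_s3_class(fit$params, "bmd_params")
  # the representative row evaluates to the same curves as the fit object
  expect_equal(storage_modulus_bmd(fit$params, 0.926, w30),
               bonedma:::.predict_moduli(fit, w30)$storage, tolerance = 1e-10)
  expect_equal(loss_modulus_bmd(fit$params, 0.926, w30),
               bonedma:::.predict_moduli(fit, w30)$loss, tolerance = 1e-10)
  expect_equal(objective_D(ds, fit$params), fit$objective_D, tolerance = 1e-8)
})

test_that("power-law fits are exact on exact data and match their log-log start", {
  pl <- fit_powerlaw(c(1, 2), c(10, 40))
  expect_equal(pl$coefficient, 10)
  expect_equal(pl$exponent, 2)
  expect_equal(pl$r_squared, 1)
  flat <- fit_powerlaw(c(0.5, 0.8, 1.3), c(7, 7, 7))
  expect_equal(flat$exponent, 0, tolerance = 1e-10)
  expect_equal(flat$coefficient, 7, tolerance = 1e-10)
  rho <- reference_bmds()$bmd
  exact <- fit_powerlaw(rho, 1213.482 * rho^2.039)
  expect_equal(exact$coefficient, 1213.482, tolerance = 1e-9)
  expect_equal(exact$exponent, 2.039, tolerance = 1e-9)
  expect_equal(exact$r_squared, 1, tolerance = 1e-12)
  expect_error(fit_powerlaw(c(1, -2), c(3, 4)), "positive")
})

test_that("steady-state extraction averages the configured tail of a sweep", {
  mk <- function(times, storage, loss)
    structure(list(sample_id = "s", frequency = 1, times = times,
                   storage = storage, loss = loss), class = "dma_sweep")
  const <- mk(0:99, rep(500, 100), rep(50, 100))
  expect_equal(extract_steady_state(const),
               c(storage = 500, loss = 50))
  step <- mk(0:99, c(rep(900, 75), rep(400, 25)), rep(40, 100))
  expect_equal(unname(extract_steady_state(step)["storage"]), 400)
  # transient sweep: tail mean within 0.5% of the plateau
  tt <- 0:1200
  tr <- mk(tt, 800 * (1 - 0.2 * exp(-tt / 120)), rep(30, 1201))
  expect_equal(unname(extract_steady_state(tr)["storage"]), 800,
               tolerance = 5e-3)
  # closed-form mean of the exponential over the tail window [900, 1200]
  remnant <- 0.2 * 120 / 300 * (exp(-900 / 120) - exp(-1200 / 120))
  expect_equal(unname(extract_steady_state(tr)["storage"]),
               mean(800 * (1 - 0.2 * exp(-(900:1200) / 120))), tolerance = 1e-6)
  expect_lt(abs(unname(extract_steady_state(tr)["storage"]) - 800 * (1 - remnant)),
            1e-3 * 800)
  expect_error(extract_steady_state(const, tail_fraction = 0), "0, 1")
  expect_error(extract_steady_state(mk(0:2, 1:3, 1:3)), "4 time points")
})

test_that("global fits recover a shared constitutive law across densities", {
  truth <- bmd_params(50, 2, 1.2, 12, -4.7, weights = c(0.3, 0.4),
                      relaxation_times = c(0.05, 2))
  rho <- c(0.6, 0.7, 0.8, 0.9)
  w <- 2 * pi * exp(seq(log(0.05), log(50), length.out = 12))
  datasets <- lapply(seq_along(rho), function(i)
    synthesize_dataset(truth, rho[i], w, sample_id = paste0("s", i)))
  gf <- fit_bmd_global(datasets, order = 2, config = fit_config(16), seed = 4)
  expect_gt(gf$r2_joint, 0.999)
  expect_true(all(gf$r2$r2_joint > 0.999))
  expect_true(all(gf$params$weights > 0 & gf$params$weights < 1))
  expect_lt(gf$objective_D,
            1e-6 * sum(vapply(datasets, function(d) sum(d$storage^2), 1)))
})
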