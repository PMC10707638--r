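test_that("the default study reproduces the nine-sample design exactly", {
  study <- make_study(study_config(sampling_interval = 60))
  expect_equal(nrow(study$samples), 9L)
  expect_equal(length(study$sweeps), 36L)                # 4 sweeps per sample
  # canine-region cervical sample carries the highest density
  canine_cerv <- subset(study$samples, tooth_region == "region1_canine" &
                          root_depth == "cervical")
  expect_equal(canine_cerv$bmd, 0.926)
  ref <- reference_bmds()
  expect_equal(study$samples$bmd, ref$bmd)
  expect_equal(study$samples$tooth_region, ref$tooth_region)
  # one sample per design cell
  expect_equal(anyDuplicated(study$samples[c("tooth_region", "root_depth")]), 0L)
  # trabecular numbers attach by density lookup
  tab2 <- reference_trabecular_numbers()
  expect_equal(study$samples$trabecular_number,
               tab2$trabecular_number[match(study$samples$bmd, tab2$bmd)])
  expect_equal(trabecular_number(0.926), 0.142)
  # every sweep carries the protocol constants
  expect_true(all(vapply(study$sweeps, function(s) s$temperature_c, 1) == 25))
  expect_true(all(vapply(study$sweeps, function(s) s$preload_mn, 1) == 0.5))
  expect_true(all(vapply(study$sweeps, function(s) s$force_amplitude_n, 1) == 5))
  expect_error(study_config(bmds = c(0.6, 0.7)), "9 values")
})

test_that("studies are reproducible from the seed and vary across seeds", {
  cfg <- function(s) study_config(seed = s, sampling_interval = 120)
  s1 <- make_study(cfg(11))
  s2 <- make_study(cfg(11))
  s3 <- make_study(cfg(12))
  expect_identical(s1$sweeps, s2$sweeps)
  expect_false(identical(s1$sweeps[[1L]]$storage, s3$sweeps[[1L]]$storage))
})

test_that("reference parameter rows are looked up verbatim by density", {
  p926 <- default_table3_params(0.926)
  expect_equal(p926$amp_A, 48.810)
  expect_equal(p926$exp_m, -38.381)
  expect_equal(p926$exp_n, -6.959)
  expect_equal(p926$amp_B, 14.580)
  expect_equal(p926$exp_q, -7.91)
  p604 <- default_table3_params(0.604)
  expect_equal(p604$amp_A, 9.604)
  expect_equal(p604$amp_B, 12.081)
  expect_equal(p604$relaxation_times[4L], 0.549)
  expect_error(default_table3_params(0.5), "no reference parameter row")
})

test_that("simulated sweeps follow the transient-plus-noise model exactly", {
  cfg0 <- study_config(noise_cv = 0, transient_depth = 0)
  sample <- list(sample_id = "x", bmd = 0.926)
  p <- default_table3_params(0.926)
  sw <- simulate_sweep(sample, p, frequency = 1, cfg0, seed = 1)
  w <- 2 * pi * 1
  expect_equal(sw$storage, rep(storage_modulus_bmd(p, 0.926, w), 1201L))
  expect_equal(sw$loss, rep(loss_modulus_bmd(p, 0.926, w), 1201L))
  # saturating exponential: value at t = tau_r is depth/e below/above plateau
  cfg2 <- study_config(noise_cv = 0, transient_depth = 0.2,
                       transient_time = 120)
  sw2 <- simulate_sweep(sample, p, 1, cfg2, seed = 1)
  i120 <- which(sw2$times == 120)
  expect_equal(sw2$storage[i120],
               storage_modulus_bmd(p, 0.926, w) * (1 - 0.2 / exp(1)))
  expect_equal(sw2$loss[i120],
               loss_modulus_bmd(p, 0.926, w) * (1 + 0.2 / exp(1)))
})

test_that("tail means converge to the steady state within the standard-error bound", {
  cfg <- study_config()                                  # noise CV 2%, 1 Hz grid
  sample <- list(sample_id = "x", bmd = 0.926)
  p <- default_table3_params(0.926)
  E_ss <- storage_modulus_bmd(p, 0.926, 2 * pi * 1)
  n_tail <- sum(seq(0, 1200) >= 900)
  bound <- 3 * cfg$noise_cv / sqrt(n_tail) * E_ss        # 3-sigma on the mean
  hits <- vapply(1:10, function(s) {
    sw <- simulate_sweep(sample, p, 1, cfg, seed = s)
    abs(extract_steady_state(sw)[["storage"]] - E_ss)
  }, numeric(1L))
  expect_true(mean(hits <= bound) >= 0.9)                # ~99.7% nominal
  # and exactly in the noise-free limit (up to the transient remnant)
  sw0 <- simulate_sweep(sample, p,
                        1, study_config(noise_cv = 0), seed = 1)
  expect_equal(extract_steady_state(sw0)[["storage"]], E_ss, tolerance = 1e-4)
})

test_that("generated series stay positive at moderate noise", {
  study <- make_study(study_config(noise_cv = 0.1, sampling_interval = 10,
                                   seed = 3))
  expect_true(all(vapply(study$sweeps,
                         function(s) all(s$storage > 0) && all(s$loss > 0),
                         logical(1L))))
})

test_that("power-law-mode steady states are monotone in density, matching the observed correlations", {
  f <- c(0.5, 1, 2, 5)
  cfg <- study_config(noise_cv = 0, param_source = "powerlaw",
                      sampling_interval = 120)
  study <- make_study(cfg)
  for (fr in f) {
    sel <- vapply(study$sweeps, function(s) s$frequency == fr, logical(1L))
    sw <- study$sweeps[sel]
    bmd <- vapply(sw, function(s) s$bmd, numeric(1L))
    ss <- vapply(sw, extract_steady_state, numeric(2L))
    o <- order(bmd)
    expect_true(all(diff(ss["storage", o]) >= 0))        # E' rises with BMD
    expect_true(all(diff(ss["loss", o]) <= 0))           # E'' falls with BMD
  }
})

test_that("a noise-free study round-trips through the reduced fit (identifiable quantities)", {
  f12 <- exp(seq(log(0.05), log(50), length.out = 12))
  cfg <- study_config(noise_cv = 0, frequencies = f12, sampling_interval = 120)
  study <- make_study(cfg)
  for (id in c("R1_cervical", "R3_apical")) {
    sw <- study$sweeps[vapply(study$sweeps, function(s) s$sample_id == id,
                              logical(1L))]
    bmd <- sw[[1L]]$bmd
    truth <- default_table3_params(bmd)
    ds <- dataset_from_sweeps(sw, id, bmd)
    fit <- fit_prony(ds, order = 4, mode = "reduced",
                     config = fit_config(16), seed = 2)
    a_eq <- truth$amp_A * bmd^truth$exp_m
    a_s <- truth$amp_A * bmd^truth$exp_n
    a_l <- truth$amp_B * bmd^truth$exp_q
    expect_equal(fit$equilibrium, a_eq, tolerance = 1e-2)
    # amplitudes are gauge-coupled to the weights; their products and sums are
    # the identifiable quantities
    expect_equal(fit$amp_storage * sum(fit$weights), a_s * sum(truth$weights),
                 tolerance = 1e-2)
    expect_equal(fit$amp_loss * sum(fit$weights), a_l * sum(truth$weights),
                 tolerance = 1e-2)
    expect_equal(sort(fit$amp_storage * fit$weights),
                 sort(a_s * truth$weights), tolerance = 1e-2)
  }
})

test_that("study CSV writing and reading round-trip the sweep data", {
  cfg <- study_config(noise_cv = 0.02, sampling_interval = 300, seed = 5)
  study <- make_study(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dma_csv(study, path)
  back <- read_dma_csv(path)
  expect_equal(nrow(back$samples), 9L)
  expect_equal(length(back$sweeps), 36L)
  expect_equal(sort(unique(back$samples$bmd)), sort(reference_bmds()$bmd))
  key <- function(s) paste(s$sample_id, s$frequency)
  orig <- study$sweeps[order(vapply(study$sweeps, key, character(1L)))]
  got <- back$sweeps[order(vapply(back$sweeps, key, character(1L)))]
  for (i in seq_along(orig)) {
    expect_equal(got[[i]]$storage, orig[[i]]$storage)
    expect_equal(got[[i]]$loss, orig[[i]]$loss)
    expect_equal(got[[i]]$times, orig[[i]]$times)
  }
  # missing columns are named
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("sample_id,bmd_g_cm3\nA,0.7", bad)
  expect_error(read_dma_csv(bad), "frequency_hz")
})
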