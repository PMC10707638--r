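# Reference values of the nine-sample mandibular study: densities by tooth
# region x root depth, trabecular number by density, and the per-sample
# constitutive parameter rows used as simulation ground truth.

.study_regions <- c("region1_canine", "region2_premolar", "region3_molar")
.study_depths <- c("cervical", "middle", "apical")

.reference_design <- data.frame(
  tooth_region = rep(.study_regions, each = 3L),
  root_depth = rep(.study_depths, times = 3L),
  bmd = c(0.926, 0.766, 0.735,   # canine region
          0.862, 0.652, 0.616,   # premolar region
          0.826, 0.638, 0.604),  # molar region
  stringsAsFactors = FALSE)

.reference_trabecular <- data.frame(
  bmd = c(0.604, 0.616, 0.638, 0.652, 0.735, 0.766, 0.826, 0.862, 0.926),
  trabecular_number = c(0.061, 0.065, 0.068, 0.072, 0.078, 0.082,
                        0.089, 0.094, 0.142))

# Fitted fourth-order constitutive rows, one per density:
# A, m, n, B, q, g1..g4, tau1..tau4 (verbatim, unsorted).
.table3_rows <- list(
  "0.926" = c(48.810, -38.381,  -6.959, 14.580,  -7.910,
              0.999, 0.972, 0.581, 0.996, 0.022, 0.431, 0.103, 3.844),
  "0.766" = c(17.970, -14.076,  -4.305, 15.373,   6.701,
              0.405, 0.383, 0.828, 0.735, 0.126, 0.045, 0.533, 0.012),
  "0.735" = c( 3.291, -17.421,  -8.118,  3.368, -10.786,
              0.497, 0.741, 0.892, 0.437, 0.038, 0.008, 0.552, 0.131),
  "0.862" = c(31.947, -22.076, -10.058, 27.237,  -3.148,
              0.999, 0.839, 0.500, 0.023, 0.522, 0.023, 0.111, 0.003),
  "0.652" = c(12.497,  -9.331,  -0.762, 12.082,  -4.441,
              0.625, 0.688, 0.999, 0.554, 0.112, 0.519, 0.024, 0.519),
  "0.616" = c( 9.568,  -7.677,  -3.609, 11.994,  -4.790,
              0.584, 0.890, 0.578, 0.997, 0.042, 0.010, 0.145, 0.584),
  "0.826" = c(22.326, -18.518,  -3.935, 45.121,  -0.156,
              0.998, 0.629, 0.815, 0.999, 0.021, 0.077, 0.259, 1.057),
  "0.638" = c( 2.834, -11.381,  -5.005, 12.816,  -4.790,
              0.824, 0.959, 0.527, 0.520, 0.011, 0.581, 0.142, 0.044),
  "0.604" = c( 9.604,  -6.369,  -3.774, 12.081,  -4.758,
              0.479, 0.808, 0.503, 0.970, 0.041, 0.011, 0.128, 0.549))

#' Reference densities of the nine-sample study
#'
#' Bone mineral densities (g/cm^3) of the nine cube samples, one per
#' (tooth region, root depth) cell of the mandibular sampling design:
#' canine, premolar and molar regions crossed with cervical, middle and
#' apical root depths.
#'
#' @return A data frame with columns `tooth_region`, `root_depth`, `bmd`.
#' @seealso [reference_trabecular_numbers()], [default_table3_params()]
#' @export
reference_bmds <- function() .reference_design

#' Trabecular number by bone mineral density
#'
#' The trabecular count density (1/pixel) measured for each study density.
#' [trabecular_number()] looks densities up by monotone linear
#' interpolation (constant beyond the tabulated range), so synthetic
#' studies at non-tabulated densities still receive a plausible value.
#'
#' @return A data frame with columns `bmd` and `trabecular_number`.
#' @export
reference_trabecular_numbers <- function() .reference_trabecular

#' @rdname reference_trabecular_numbers
#' @param bmd Density(ies) in g/cm^3.
#' @export
trabecular_number <- function(bmd) {
  if (!is.numeric(bmd) || any(!is.finite(bmd)) || any(bmd <= 0))
    stop("'bmd' must be positive and finite")
  stats::approx(.reference_trabecular$bmd, .reference_trabecular$trabecular_number,
                xout = bmd, rule = 2L)$y
}

#' Reference constitutive parameter row for a study density
#'
#' Returns the fitted fourth-order constitutive parameters
#' \eqn{(A, m, n, B, q, g_i, \tau_i)} for one of the nine study densities,
#' verbatim (weights and relaxation times in tabulated order). These rows
#' are the simulation ground truth of the synthetic study.
#'
#' @param bmd One of the nine study densities (g/cm^3); matched to within
#'   1e-9.
#' @return A [bmd_params()] object with `bmd` attached.
#' @examples
#' default_table3_params(0.926)
#' @export
default_table3_params <- function(bmd) {
  if (!is.numeric(bmd) || length(bmd) != 1L || !is.finite(bmd))
    stop("'bmd' must be a single number")
  keys <- as.numeric(names(.table3_rows))
  hit <- which(abs(keys - bmd) <= 1e-9)
  if (length(hit) != 1L)
    stop(sprintf("no reference parameter row for BMD = %g; available: %s",
                 bmd, paste(sort(keys), collapse = ", ")))
  v <- .table3_rows[[hit]]
  bmd_params(v[1L], v[2L], v[3L], v[4L], v[5L],
             weights = v[6:9], relaxation_times = v[10:13],
             bmd = keys[hit])
}

#' Reference equilibrium-modulus-density power law
#'
#' The fitted relation between the equilibrium modulus and bone mineral
#' density across the nine samples,
#' \eqn{E_\infty = 1213.482\,\rho^{2.039}} MPa (\eqn{r^2 = 0.877}).
#'
#' @return A [power_law_fit()] object.
#' @export
default_powerlaw <- function() power_law_fit(1213.482, 2.039, 0.877)

# Fixed constitutive parameter set of the "powerlaw" generation mode: the
# equilibrium term follows the reference power law (m = n so the dynamic
# storage amplitude scales the same way, keeping E' increasing in density),
# the loss amplitude uses the lowest-density reference row's B with a
# negative exponent (loss decreasing in density), and a well-separated
# four-branch spectrum spanning 0.01-10 s.
.powerlaw_mode_params <- function() {
  pl <- default_powerlaw()
  bmd_params(amp_A = pl$coefficient, exp_m = pl$exponent, exp_n = pl$exponent,
             amp_B = 12.081, exp_q = -4.758,
             weights = c(0.05, 0.08, 0.10, 0.07),
             relaxation_times = c(0.01, 0.1, 1, 10))
}

#' Synthetic DMA study configuration
#'
#' Defines the conditions of a simulated dynamic-mechanical-analysis study.
#' The defaults reproduce the reference experiment: nine cube samples (one
#' per tooth-region x root-depth cell, densities from [reference_bmds()]),
#' each swept at 0.5, 1, 2 and 5 Hz for 20 minutes at 25 degrees C, sampled
#' every second, with 2% multiplicative measurement noise and an initial
#' saturating-exponential transient whose depth grows with density (denser
#' samples showed the fastest early rise).
#'
#' @param bmds Nine densities (g/cm^3), one per design cell, in the row
#'   order of [reference_bmds()]. Length must equal the 9-cell design.
#' @param frequencies Drive frequencies in Hz (default 0.5, 1, 2, 5).
#' @param sweep_duration Sweep length in seconds (default 1200).
#' @param sampling_interval Sampling interval in seconds (default 1).
#' @param noise_cv Coefficient of variation of multiplicative Gaussian
#'   noise on each modulus reading (default 0.02).
#' @param transient_depth Fractional depth `c` of the start-up transient,
#'   a single value in `[0, 1)`, or `NULL` (default) for the density rule
#'   `0.05 + 0.15 * (rho - min) / (max - min)`.
#' @param transient_time Transient time constant in seconds (default 120).
#' @param param_source `"table3"`: each sample is generated from its
#'   reference constitutive row; `"powerlaw"`: all samples share one fixed
#'   spectrum whose equilibrium term follows [default_powerlaw()] (used for
#'   density-monotonicity checks and power-law recovery).
#' @param omega_convention Frequency-variable convention, see
#'   [freq_to_omega()].
#' @param seed Integer seed making the whole study reproducible.
#' @return A list of class `"study_config"`.
#' @export
study_config <- function(bmds = NULL, frequencies = c(0.5, 1, 2, 5),
                         sweep_duration = 1200, sampling_interval = 1,
                         noise_cv = 0.02, transient_depth = NULL,
                         transient_time = 120,
                         param_source = c("table3", "powerlaw"),
                         omega_convention = c("angular", "hz"),
                         seed = 1L) {
  design <- .reference_design
  if (is.null(bmds)) {
    bmds <- design$bmd
  } else {
    if (length(bmds) != nrow(design))
      stop(sprintf("'bmds' must supply %d values, one per design cell",
                   nrow(design)))
    if (any(!is.finite(bmds)) || any(bmds <= 0))
      stop("all densities must be positive and finite")
  }
  if (any(!is.finite(frequencies)) || any(frequencies <= 0) ||
      length(frequencies) < 1L)
    stop("'frequencies' must be positive and finite")
  if (!is.numeric(noise_cv) || noise_cv < 0)
    stop("'noise_cv' must be >= 0")
  if (!is.null(transient_depth) &&
      (!is.numeric(transient_depth) || length(transient_depth) != 1L ||
       transient_depth < 0 || transient_depth >= 1))
    stop("'transient_depth' must be in [0, 1) or NULL")
  if (sweep_duration <= 0 || sampling_interval <= 0 ||
      sampling_interval > sweep_duration)
    stop("invalid sweep duration / sampling interval")
  if (transient_time <= 0) stop("'transient_time' must be positive")
  structure(list(bmds = as.numeric(bmds),
                 frequencies = as.numeric(frequencies),
                 sweep_duration = as.numeric(sweep_duration),
                 sampling_interval = as.numeric(sampling_interval),
                 noise_cv = as.numeric(noise_cv),
                 transient_depth = transient_depth,
                 transient_time = as.numeric(transient_time),
                 param_source = match.arg(param_source),
                 omega_convention = match.arg(omega_convention),
                 temperature_c = 25, preload_mn = 0.5, force_amplitude_n = 5,
                 seed = as.integer(seed)),
            class = "study_config")
}

# Transient depth c for one sample under the config rule.
.transient_depth_for <- function(config, bmd) {
  if (!is.null(config$transient_depth)) return(config$transient_depth)
  rng <- range(config$bmds)
  if (diff(rng) == 0) return(0.05)
  0.05 + 0.15 * (bmd - rng[1L]) / (rng[2L] - rng[1L])
}

# Constitutive parameters generating one sample's sweeps.
.params_for_sample <- function(config, bmd) {
  if (config$param_source == "table3") default_table3_params(bmd)
  else .powerlaw_mode_params()
}

#' Simulate one DMA frequency sweep
#'
#' Generates the time-resolved storage and loss moduli of one sample held at
#' a single drive frequency: the steady-state values come from the
#' constitutive model ([storage_modulus_bmd()], [loss_modulus_bmd()]) at
#' \eqn{\omega = 2\pi f}; the start-up transient is a saturating
#' exponential of depth `c` and time constant `transient_time` (storage
#' rises into its plateau, loss relaxes down onto it); and each reading is
#' perturbed by independent multiplicative Gaussian noise:
#' \deqn{E'(t) = E'_{ss}\,(1 - c\,e^{-t/\tau_r})(1 + \epsilon_t), \quad
#'       E''(t) = E''_{ss}\,(1 + c\,e^{-t/\tau_r})(1 + \epsilon'_t).}
#'
#' @param sample One row of the study sample table (list or data frame row
#'   with `sample_id` and `bmd`).
#' @param params A [bmd_params()] object generating the steady state.
#' @param frequency Drive frequency in Hz, positive.
#' @param config A [study_config()].
#' @param seed Integer seed for the noise realisation.
#' @return An object of class `"dma_sweep"` with the protocol metadata,
#'   `times` (s), `storage` and `loss` series (MPa).
#' @export
simulate_sweep <- function(sample, params, frequency, config, seed = 1L) {
  stopifnot(inherits(params, "bmd_params"), inherits(config, "study_config"))
  if (!is.numeric(frequency) || length(frequency) != 1L || frequency <= 0)
    stop("'frequency' must be a single positive number")
  bmd <- .check_rho(sample$bmd)
  omega <- freq_to_omega(frequency, config$omega_convention)
  E_s <- storage_modulus_bmd(params, bmd, omega)
  E_l <- loss_modulus_bmd(params, bmd, omega)
  times <- seq(0, config$sweep_duration, by = config$sampling_interval)
  cc <- .transient_depth_for(config, bmd)
  decay <- exp(-times / config$transient_time)
  set.seed(seed)
  storage <- E_s * (1 - cc * decay)
  loss <- E_l * (1 + cc * decay)
  if (config$noise_cv > 0) {
    storage <- storage * (1 + stats::rnorm(length(times), 0, config$noise_cv))
    loss <- loss * (1 + stats::rnorm(length(times), 0, config$noise_cv))
  }
  structure(list(sample_id = as.character(sample$sample_id),
                 bmd = bmd, frequency = frequency,
                 temperature_c = config$temperature_c,
                 preload_mn = config$preload_mn,
                 force_amplitude_n = config$force_amplitude_n,
                 times = times, storage = storage, loss = loss),
            class = "dma_sweep")
}

#' @export
print.dma_sweep <- function(x, ...) {
  cat(sprintf(
    "DMA sweep '%s' at %g Hz (%g s, %d points, %g degC): E' tail ~ %.4g MPa, E'' tail ~ %.4g MPa\n",
    x$sample_id, x$frequency, max(x$times), length(x$times), x$temperature_c,
    mean(utils::tail(x$storage, 10L)), mean(utils::tail(x$loss, 10L))))
  invisible(x)
}

#' Generate a complete synthetic DMA study
#'
#' Builds the sample table (one sample per tooth-region x root-depth cell,
#' densities and trabecular numbers from the reference tables) and simulates
#' one sweep per sample and drive frequency via [simulate_sweep()]. The
#' whole study is a deterministic function of `config$seed`.
#'
#' @param config A [study_config()].
#' @return A list of class `"dma_study"`: `samples` (data frame with
#'   `sample_id`, `tooth_region`, `root_depth`, `bmd`,
#'   `trabecular_number`), `sweeps` (list of `"dma_sweep"`), and the
#'   `config`.
#' @examples
#' study <- make_study(study_config(noise_cv = 0, sampling_interval = 60))
#' nrow(study$samples)   # 9
#' length(study$sweeps)  # 36
#' @export
make_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  design <- .reference_design
  samples <- data.frame(
    sample_id = sprintf("R%d_%s", rep(1:3, each = 3L), design$root_depth),
    tooth_region = design$tooth_region,
    root_depth = design$root_depth,
    bmd = config$bmds,
    trabecular_number = trabecular_number(config$bmds),
    stringsAsFactors = FALSE)

  set.seed(config$seed)
  n_sweeps <- nrow(samples) * length(config$frequencies)
  sweep_seeds <- sample.int(.Machine$integer.max %/% 4L, n_sweeps)
  sweeps <- vector("list", n_sweeps)
  k <- 0L
  for (i in seq_len(nrow(samples))) {
    params <- .params_for_sample(config, samples$bmd[i])
    for (f in config$frequencies) {
      k <- k + 1L
      sweeps[[k]] <- simulate_sweep(samples[i, ], params, f, config,
                                    seed = sweep_seeds[k])
    }
  }
  structure(list(samples = samples, sweeps = sweeps, config = config),
            class = "dma_study")
}

#' @export
print.dma_study <- function(x, ...) {
  cat(sprintf("Synthetic DMA study: %d samples, %d sweeps (%s Hz), noise CV %g\n",
              nrow(x$samples), length(x$sweeps),
              paste(x$config$frequencies, collapse = "/"),
              x$config$noise_cv))
  print(x$samples, row.names = FALSE)
  invisible(x)
}

.dma_csv_columns <- c("sample_id", "bmd_g_cm3", "frequency_hz", "time_s",
                      "storage_modulus_mpa", "loss_modulus_mpa")

#' Read and write the DMA study CSV interchange format
#'
#' Long-format CSV with one row per time point and columns `sample_id`,
#' `bmd_g_cm3`, `frequency_hz`, `time_s`, `storage_modulus_mpa`,
#' `loss_modulus_mpa` (comma-separated, '.' decimal, UTF-8). This is the
#' dialect the fitting pipeline ingests; protocol metadata not represented
#' in it (temperature, preload) is restored from defaults on read.
#'
#' @param study A `"dma_study"` from [make_study()] (or any list with
#'   `samples` and `sweeps`).
#' @param path CSV file path.
#' @return `write_dma_csv()` returns `path` invisibly; `read_dma_csv()`
#'   returns a `"dma_study"`-shaped list (without simulation config).
#' @export
write_dma_csv <- function(study, path) {
  rows <- lapply(study$sweeps, function(s) {
    data.frame(sample_id = s$sample_id, bmd_g_cm3 = s$bmd,
               frequency_hz = s$frequency, time_s = s$times,
               storage_modulus_mpa = s$storage,
               loss_modulus_mpa = s$loss, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dma_csv
#' @export
read_dma_csv <- function(path) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop("input CSV is empty or malformed; expected columns: ",
                        paste(.dma_csv_columns, collapse = ", "),
                        call. = FALSE))
  missing_cols <- setdiff(.dma_csv_columns, names(df))
  if (length(missing_cols) > 0L)
    stop("input CSV is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L)
    stop("input CSV contains no data rows")
  key <- interaction(df$sample_id, df$frequency_hz, drop = TRUE)
  sweeps <- lapply(split(df, key), function(d) {
    d <- d[order(d$time_s), ]
    structure(list(sample_id = d$sample_id[1L], bmd = d$bmd_g_cm3[1L],
                   frequency = d$frequency_hz[1L],
                   temperature_c = 25, preload_mn = 0.5,
                   force_amplitude_n = 5,
                   times = d$time_s, storage = d$storage_modulus_mpa,
                   loss = d$loss_modulus_mpa),
              class = "dma_sweep")
  })
  names(sweeps) <- NULL
  first <- !duplicated(df$sample_id)
  samples <- data.frame(sample_id = df$sample_id[first],
                        bmd = df$bmd_g_cm3[first],
                        stringsAsFactors = FALSE)
  samples$trabecular_number <- trabecular_number(samples$bmd)
  structure(list(samples = samples, sweeps = sweeps, config = NULL),
            class = "dma_study")
}
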