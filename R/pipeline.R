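#' Percent change between two modulus levels
#'
#' The comparison statistic used for frequency-ladder and density
#' contrasts: `100 * (b - a) / a`, vectorised.
#'
#' @param series_a Baseline value(s) in MPa, positive.
#' @param series_b Comparison value(s) in MPa.
#' @return Percent change(s).
#' @examples
#' percent_change(100, 112)  # 12
#' @export
percent_change <- function(series_a, series_b) {
  if (any(!is.finite(series_a)) || any(series_a <= 0))
    stop("'series_a' must be positive and finite")
  100 * (series_b - series_a) / series_a
}

#' Run the full DMA analysis pipeline
#'
#' End-to-end workflow: ingest a measured study (CSV path or
#' `"dma_study"`) or simulate one from `config`; extract per-sweep
#' steady-state moduli; fit the generalized Maxwell model to every sample
#' ([fit_prony()]); fit the equilibrium-modulus-density power law across
#' samples ([fit_powerlaw()]) using each sample's fitted equilibrium
#' modulus (the zero-frequency limit of its storage model); and tabulate
#' percent changes of the steady-state moduli across each sample's
#' frequency ladder. With `mode = "global"` a joint shared-exponent
#' constitutive fit ([fit_bmd_global()]) is added.
#'
#' The run is deterministic for fixed inputs and `seed` (per-sample fit
#' seeds are derived from it). With fewer than two samples the power-law
#' stage is skipped with a warning.
#'
#' @param input A CSV path (see [read_dma_csv()]), a `"dma_study"`, or
#'   `NULL` to simulate from `config`.
#' @param config A [study_config()] used when `input` is `NULL` (and for
#'   the frequency-variable convention otherwise).
#' @param order Model order for the per-sample fits; default 4.
#' @param mode `"reduced"` for per-sample fits only, `"global"` to add the
#'   joint constitutive fit.
#' @param tail_fraction Steady-state window, see [extract_steady_state()].
#' @param fit_cfg A [fit_config()] for all fitting stages.
#' @param seed Integer master seed for the fitting stages.
#' @param out_dir Optional directory; when given, writes `report.json`,
#'   `params.csv`, `powerlaw.json` and `changes.csv` there.
#' @return An object of class `"study_report"`: `samples`, `fits` (named
#'   list of `"dma_fit"`), `equilibrium_table`, `power_law`,
#'   `modulus_change_table`, `steady_states`, optional `global_fit`, and
#'   `seed`.
#' @export
run_pipeline <- function(input = NULL, config = study_config(), order = 4L,
                         mode = c("reduced", "global"), tail_fraction = 0.25,
                         fit_cfg = fit_config(), seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  study <- if (is.null(input)) {
    make_study(config)
  } else if (is.character(input)) {
    read_dma_csv(input)
  } else if (inherits(input, "dma_study")) {
    input
  } else {
    stop("'input' must be a CSV path, a dma_study, or NULL")
  }
  convention <- if (!is.null(study$config)) study$config$omega_convention
                else config$omega_convention

  ids <- vapply(study$sweeps, function(s) s$sample_id, character(1L))
  by_sample <- split(study$sweeps, ids)
  # preserve the sample-table order
  by_sample <- by_sample[intersect(study$samples$sample_id, names(by_sample))]

  steady <- do.call(rbind, lapply(by_sample, function(sw) {
    ss <- vapply(sw, extract_steady_state, numeric(2L),
                 tail_fraction = tail_fraction)
    data.frame(sample_id = sw[[1L]]$sample_id, bmd = sw[[1L]]$bmd,
               frequency_hz = vapply(sw, function(s) s$frequency, numeric(1L)),
               storage_ss_mpa = ss["storage", ], loss_ss_mpa = ss["loss", ],
               stringsAsFactors = FALSE)
  }))
  rownames(steady) <- NULL
  steady <- steady[order(match(steady$sample_id, study$samples$sample_id),
                         steady$frequency_hz), ]

  fits <- list()
  datasets <- list()
  for (i in seq_along(by_sample)) {
    sw <- by_sample[[i]]
    id <- names(by_sample)[i]
    ds <- dataset_from_sweeps(sw, id, sw[[1L]]$bmd,
                              tail_fraction = tail_fraction,
                              convention = convention)
    datasets[[id]] <- ds
    fits[[id]] <- fit_prony(ds, order = order, mode = "reduced",
                            config = fit_cfg, seed = seed + i)
  }

  equilibrium_table <- data.frame(
    sample_id = names(fits),
    bmd = vapply(fits, function(f) f$bmd, numeric(1L)),
    equilibrium_modulus_mpa = vapply(fits, function(f) f$equilibrium,
                                     numeric(1L)),
    stringsAsFactors = FALSE)
  rownames(equilibrium_table) <- NULL

  power_law <- NULL
  if (nrow(equilibrium_table) >= 2L) {
    power_law <- fit_powerlaw(equilibrium_table$bmd,
                              equilibrium_table$equilibrium_modulus_mpa)
  } else {
    warning("fewer than 2 samples: power-law stage skipped", call. = FALSE)
  }

  changes <- do.call(rbind, lapply(split(steady, steady$sample_id), function(d) {
    d <- d[order(d$frequency_hz), ]
    lo <- 1L; hi <- nrow(d)
    data.frame(sample_id = d$sample_id[1L], bmd = d$bmd[1L],
               freq_low_hz = d$frequency_hz[lo],
               freq_high_hz = d$frequency_hz[hi],
               storage_change_pct = percent_change(d$storage_ss_mpa[lo],
                                                   d$storage_ss_mpa[hi]),
               loss_change_pct = percent_change(d$loss_ss_mpa[lo],
                                                d$loss_ss_mpa[hi]),
               stringsAsFactors = FALSE)
  }))
  changes <- changes[match(names(fits), changes$sample_id), ]
  rownames(changes) <- NULL

  global_fit <- NULL
  if (mode == "global") {
    if (length(datasets) >= 2L) {
      global_fit <- fit_bmd_global(unname(datasets), order = order,
                                   config = fit_cfg, seed = seed)
    } else {
      warning("fewer than 2 samples: global constitutive fit skipped",
              call. = FALSE)
    }
  }

  report <- structure(
    list(samples = study$samples, fits = fits, datasets = datasets,
         steady_states = steady, equilibrium_table = equilibrium_table,
         power_law = power_law, modulus_change_table = changes,
         global_fit = global_fit, order = as.integer(order),
         seed = as.integer(seed)),
    class = "study_report")
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("DMA study report: %d samples fitted (order %d)\n",
              length(x$fits), x$order))
  tab <- params_table(x)
  print(tab[, c("sample_id", "BMD", "equilibrium_mpa", "r2_joint")],
        row.names = FALSE, digits = 6)
  if (!is.null(x$power_law)) {
    cat("Equilibrium-modulus power law:  ")
    cat(sprintf("E_inf = %.6g * rho^%.6g  (r^2 = %.4f)\n",
                x$power_law$coefficient, x$power_law$exponent,
                x$power_law$r_squared))
  }
  cat("Steady-state percent change, lowest -> highest frequency:\n")
  print(x$modulus_change_table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Parameter table of a study report
#'
#' One row per fitted sample in the tabulated layout `A, m, n, B, q,
#' g1..gk, tau1..tauk` plus diagnostics. Single-sample rows are
#' representatives (see [fit_prony()]): only the amplitude products are
#' identifiable from one sample.
#'
#' @param report A `"study_report"` from [run_pipeline()].
#' @return A data frame.
#' @export
params_table <- function(report) {
  stopifnot(inherits(report, "study_report"))
  do.call(rbind, lapply(report$fits, function(f) {
    p <- f$params
    row <- data.frame(sample_id = f$sample_id, BMD = f$bmd,
                      A = p$amp_A, m = p$exp_m, n = p$exp_n,
                      B = p$amp_B, q = p$exp_q, stringsAsFactors = FALSE)
    for (i in seq_len(p$order)) row[[paste0("g", i)]] <- p$weights[i]
    for (i in seq_len(p$order)) row[[paste0("tau", i)]] <- p$relaxation_times[i]
    row$equilibrium_mpa <- f$equilibrium
    row$objective_D <- f$objective_D
    row$r2_storage <- f$r2_storage
    row$r2_loss <- f$r2_loss
    row$r2_joint <- f$r2_joint
    row$converged <- f$converged
    row$identifiability_warning <- f$identifiability_warning
    row
  })) -> tab
  rownames(tab) <- NULL
  tab
}

.powerlaw_json <- function(pl) {
  if (is.null(pl)) return(NULL)
  list(coefficient_mpa = pl$coefficient, exponent = pl$exponent,
       r_squared = pl$r_squared)
}

#' Serialize a study report
#'
#' Writes `report.json` (full report), `params.csv` (parameter table),
#' `powerlaw.json` and `changes.csv` into `out_dir`. Output is
#' byte-reproducible for identical reports.
#'
#' @param report A `"study_report"`.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_study_report <- function(report, out_dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- params_table(report)
  utils::write.csv(tab, file.path(out_dir, "params.csv"), row.names = FALSE)
  utils::write.csv(report$modulus_change_table,
                   file.path(out_dir, "changes.csv"), row.names = FALSE)
  jsonlite::write_json(.powerlaw_json(report$power_law),
                       file.path(out_dir, "powerlaw.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  payload <- list(
    n_samples = length(report$fits),
    order = report$order,
    seed = report$seed,
    samples = report$samples,
    parameters = tab,
    equilibrium_table = report$equilibrium_table,
    power_law = .powerlaw_json(report$power_law),
    modulus_change_table = report$modulus_change_table,
    steady_states = report$steady_states)
  if (!is.null(report$global_fit)) {
    gf <- report$global_fit
    payload$global_fit <- list(
      params = jsonlite::fromJSON(write_bmd_params(gf$params)),
      objective_D = gf$objective_D, r2_joint = gf$r2_joint,
      converged = gf$converged)
  }
  jsonlite::write_json(payload, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       null = "null")
  invisible(out_dir)
}

#' Diagnostic plots for study results
#'
#' `plot.study_report()` draws the fitted equilibrium modulus against
#' density with the fitted power-law curve; `plot_fit()` overlays one
#' sample's fitted storage/loss curves on its steady-state data points
#' (log-frequency axis).
#'
#' @param x A `"study_report"`.
#' @param ... Passed to [graphics::plot()].
#' @return The input, invisibly.
#' @export
plot.study_report <- function(x, ...) {
  et <- x$equilibrium_table
  graphics::plot(et$bmd, et$equilibrium_modulus_mpa,
                 xlab = expression(rho ~ (g/cm^3)),
                 ylab = "Equilibrium modulus (MPa)",
                 pch = 19, ...)
  if (!is.null(x$power_law)) {
    rr <- seq(min(et$bmd), max(et$bmd), length.out = 100L)
    graphics::lines(rr, equilibrium_powerlaw(rr, x$power_law), lty = 2)
  }
  invisible(x)
}

#' @rdname plot.study_report
#' @param fit A `"dma_fit"`.
#' @param dataset The [modulus_dataset()] the fit was computed from.
#' @export
plot_fit <- function(fit, dataset, ...) {
  stopifnot(inherits(fit, "dma_fit"), inherits(dataset, "modulus_dataset"))
  wgrid <- exp(seq(log(min(dataset$omega) / 2), log(max(dataset$omega) * 2),
                   length.out = 200L))
  p <- .predict_moduli(fit, wgrid)
  ylim <- range(dataset$storage, dataset$loss, p$storage, p$loss)
  graphics::plot(dataset$omega, dataset$storage, log = "x", pch = 19,
                 ylim = ylim, xlab = expression(omega ~ (rad/s)),
                 ylab = "Modulus (MPa)", ...)
  graphics::points(dataset$omega, dataset$loss, pch = 17)
  graphics::lines(wgrid, p$storage, lty = 1)
  graphics::lines(wgrid, p$loss, lty = 2)
  graphics::legend("right", c("E' data", "E'' data", "E' fit", "E'' fit"),
                   pch = c(19, 17, NA, NA), lty = c(NA, NA, 1, 2), bty = "n")
  invisible(fit)
}
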