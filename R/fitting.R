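#' Frequency-domain modulus dataset for one sample
#'
#' The per-sample fitting data: storage and loss moduli measured (or
#' extracted as sweep steady states, see [extract_steady_state()]) at a set
#' of angular frequencies. Points are stored sorted by ascending frequency;
#' duplicate frequencies are rejected.
#'
#' @param sample_id Sample identifier (single string).
#' @param bmd Bone mineral density \eqn{\rho} in g/cm^3, positive.
#' @param omega Angular frequencies in rad/s, positive, at least 2 distinct.
#' @param storage Storage moduli \eqn{E'} in MPa, positive; same length.
#' @param loss Loss moduli \eqn{E''} in MPa, positive; same length.
#' @return An object of class `"modulus_dataset"`.
#' @seealso [fit_prony()], [objective_D()], [r_squared()]
#' @export
modulus_dataset <- function(sample_id, bmd, omega, storage, loss) {
  if (!is.character(sample_id) || length(sample_id) != 1L)
    stop("'sample_id' must be a single string")
  bmd <- .check_rho(bmd)
  omega <- as.numeric(omega)
  storage <- as.numeric(storage)
  loss <- as.numeric(loss)
  n <- length(omega)
  if (n < 2L) stop("a modulus dataset needs at least 2 frequency points")
  if (length(storage) != n || length(loss) != n)
    stop("'omega', 'storage' and 'loss' must have equal length")
  if (any(!is.finite(omega)) || any(omega <= 0))
    stop("all frequencies must be positive and finite")
  if (any(!is.finite(storage)) || any(storage <= 0) ||
      any(!is.finite(loss)) || any(loss <= 0))
    stop("all moduli must be positive and finite")
  o <- order(omega)
  omega <- omega[o]
  if (any(diff(omega) == 0)) stop("frequencies must be distinct")
  structure(list(sample_id = sample_id, bmd = bmd, omega = omega,
                 storage = storage[o], loss = loss[o], n = n),
            class = "modulus_dataset")
}

#' @export
print.modulus_dataset <- function(x, ...) {
  cat(sprintf("Modulus dataset '%s': BMD = %.3f g/cm^3, %d frequency points\n",
              x$sample_id, x$bmd, x$n))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.modulus_dataset <- function(x, ...) {
  data.frame(omega_rad_s = x$omega, storage_mpa = x$storage,
             loss_mpa = x$loss)
}

#' Generate a modulus dataset from constitutive parameters
#'
#' Evaluates the BMD constitutive model at the requested frequencies,
#' optionally perturbing each modulus with independent multiplicative
#' Gaussian noise of coefficient of variation `noise_cv`. Used for
#' generate-then-fit recovery experiments.
#'
#' @param params A [bmd_params()] object.
#' @param bmd Density \eqn{\rho} in g/cm^3.
#' @param omega Angular frequencies in rad/s, positive.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (0 = exact).
#' @param seed Optional integer seed used when `noise_cv > 0`.
#' @param sample_id Identifier for the resulting dataset.
#' @return A [modulus_dataset()].
#' @export
synthesize_dataset <- function(params, bmd, omega, noise_cv = 0,
                               seed = NULL, sample_id = "synthetic") {
  stopifnot(inherits(params, "bmd_params"))
  if (!is.numeric(noise_cv) || length(noise_cv) != 1L || noise_cv < 0)
    stop("'noise_cv' must be a single non-negative number")
  s <- storage_modulus_bmd(params, bmd, omega)
  l <- loss_modulus_bmd(params, bmd, omega)
  if (noise_cv > 0) {
    if (!is.null(seed)) set.seed(seed)
    s <- s * (1 + stats::rnorm(length(s), 0, noise_cv))
    l <- l * (1 + stats::rnorm(length(l), 0, noise_cv))
    s <- pmax(s, 1e-6 * max(s))
    l <- pmax(l, 1e-6 * max(l))
  }
  modulus_dataset(sample_id, bmd, omega, s, l)
}

# Predicted (storage, loss) curves of any fitted/parametric model at the
# dataset's density. Internal dispatch hub shared by objective_D and
# r_squared.
.predict_moduli <- function(model, omega, rho = NULL) {
  if (inherits(model, "bmd_params")) {
    if (is.null(rho)) rho <- model$bmd
    if (is.null(rho)) stop("a density 'rho' is required for bmd_params")
    list(storage = storage_modulus_bmd(model, rho, omega),
         loss = loss_modulus_bmd(model, rho, omega))
  } else if (inherits(model, "dma_fit")) {
    D <- outer(omega^2, model$relaxation_times^2)
    s_amp <- model$amp_storage * model$weights
    l_amp <- model$amp_loss * model$weights
    list(storage = as.vector(model$equilibrium + (D / (1 + D)) %*% s_amp),
         loss = as.vector((outer(omega, model$relaxation_times) / (1 + D)) %*% l_amp))
  } else if (inherits(model, "prony_series") ||
             inherits(model, "maxwell_branches")) {
    list(storage = storage_modulus(model, omega),
         loss = loss_modulus(model, omega))
  } else {
    stop("unsupported model class: ", paste(class(model), collapse = "/"))
  }
}

#' Sum-of-squares misfit between a dataset and a constitutive model
#'
#' The least-squares objective minimised by the fitting routines,
#' \deqn{D = \sum_k \left[(E'_{fit}(\omega_k) - E'_{exp,k})^2 +
#'   (E''_{fit}(\omega_k) - E''_{exp,k})^2\right]} in MPa^2, evaluating the
#' model at the dataset's density.
#'
#' @param dataset A [modulus_dataset()].
#' @param model A [bmd_params()] object, a fit returned by [fit_prony()],
#'   or a [prony_series()] / [maxwell_branches()] spectrum.
#' @return The scalar objective \eqn{D \ge 0} (MPa^2).
#' @export
objective_D <- function(dataset, model) {
  stopifnot(inherits(dataset, "modulus_dataset"))
  p <- .predict_moduli(model, dataset$omega, rho = dataset$bmd)
  sum((p$storage - dataset$storage)^2) + sum((p$loss - dataset$loss)^2)
}

#' Coefficients of determination of a modulus fit
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} per channel, with \eqn{SS_{tot}} taken
#' about that channel's mean; the joint value pools storage and loss
#' residuals and total sums of squares (each channel centred on its own
#' mean). Values never exceed 1 and may be negative for models worse than
#' the channel mean.
#'
#' @inheritParams objective_D
#' @return Named numeric vector `c(r2_storage, r2_loss, r2_joint)`.
#' @export
r_squared <- function(dataset, model) {
  stopifnot(inherits(dataset, "modulus_dataset"))
  p <- .predict_moduli(model, dataset$omega, rho = dataset$bmd)
  ss_res_s <- sum((p$storage - dataset$storage)^2)
  ss_res_l <- sum((p$loss - dataset$loss)^2)
  ss_tot_s <- sum((dataset$storage - mean(dataset$storage))^2)
  ss_tot_l <- sum((dataset$loss - mean(dataset$loss))^2)
  if (ss_tot_s == 0 || ss_tot_l == 0)
    stop("undefined R-squared: a modulus channel has zero variance")
  c(r2_storage = 1 - ss_res_s / ss_tot_s,
    r2_loss = 1 - ss_res_l / ss_tot_l,
    r2_joint = 1 - (ss_res_s + ss_res_l) / (ss_tot_s + ss_tot_l))
}

#' Fitting configuration
#'
#' @param n_starts Number of multi-start initialisations (default 32).
#' @param ftol Relative objective tolerance terminating each local
#'   optimisation (default 1e-10).
#' @param max_iter Maximum Levenberg-Marquardt iterations per start
#'   (default, and optimizer cap, 1024).
#' @return A list of class `"fit_config"`.
#' @export
fit_config <- function(n_starts = 32L, ftol = 1e-10, max_iter = 1024L) {
  if (!is.numeric(n_starts) || n_starts < 1L)
    stop("'n_starts' must be a positive integer")
  structure(list(n_starts = as.integer(n_starts), ftol = ftol,
                 max_iter = as.integer(min(max_iter, 1024L))),
            class = "fit_config")
}

# Multi-start initial parameter vector on the transformed (unconstrained)
# scale. Relaxation times are seeded log-spaced across
# [0.1/omega_max, 10/omega_min] with log-normal jitter; amplitudes from the
# data extremes.
.prony_start <- function(dataset, order, mode) {
  w <- dataset$omega
  tau0 <- exp(seq(log(0.1 / max(w)), log(10 / min(w)), length.out = order)) *
    exp(stats::rnorm(order, 0, 0.5))
  S <- dataset$storage; L <- dataset$loss
  span <- max(max(S) - min(S), 1e-3 * max(S))
  if (mode == "prony") {
    Einf0 <- min(S) * stats::runif(1, 0.6, 1)
    Ei0 <- ((span + 2 * max(L)) / order) * exp(stats::rnorm(order, 0, 0.5))
    c(log(Einf0), log(Ei0), log(tau0))
  } else {
    aeq0 <- min(S) * stats::runif(1, 0.6, 1)
    li0 <- (2 * max(L) / order) * exp(stats::rnorm(order, 0, 0.5))
    r0 <- span / max(sum(li0), 1e-12) * exp(stats::rnorm(1, 0, 0.3))
    c(log(aeq0), log(r0), log(li0), log(tau0))
  }
}

# Residual vector (storage then loss) at a transformed parameter vector.
.prony_residual <- function(theta, dataset, order, mode) {
  w <- dataset$omega
  if (mode == "prony") {
    Einf <- exp(theta[1L])
    Ei <- exp(theta[2L:(order + 1L)])
    tau <- exp(theta[(order + 2L):(2L * order + 1L)])
    s_amp <- Ei; l_amp <- Ei; eq <- Einf
  } else {
    eq <- exp(theta[1L])
    r <- exp(theta[2L])
    li <- exp(theta[3L:(order + 2L)])
    tau <- exp(theta[(order + 3L):(2L * order + 2L)])
    s_amp <- r * li; l_amp <- li
  }
  D <- outer(w^2, tau^2)
  ps <- as.vector(eq + (D / (1 + D)) %*% s_amp)
  pl <- as.vector((outer(w, tau) / (1 + D)) %*% l_amp)
  c(ps - dataset$storage, pl - dataset$loss)
}

#' Fit a generalized Maxwell model to frequency-domain moduli
#'
#' Identifies an order-`order` relaxation spectrum from a sample's storage
#' and loss moduli by minimising [objective_D()] with multi-start local
#' Levenberg-Marquardt optimisation. The constraints \eqn{\tau_i > 0} and
#' \eqn{0 < g_i < 1} are enforced exactly by the parameterisation (log and
#' ratio transforms), so every returned parameter set satisfies them
#' strictly. Relaxation times are returned sorted ascending, and the result
#' is deterministic for a fixed `(dataset, order, mode, config, seed)`.
#'
#' Two parameterisations are offered:
#' \describe{
#'   \item{`"reduced"` (default)}{the single-sample form of the BMD
#'     constitutive model: independent equilibrium modulus, dynamic storage
#'     amplitude and loss amplitude (the lumped values \eqn{A\rho^m},
#'     \eqn{A\rho^n}, \eqn{B\rho^q}) sharing one weight/time spectrum.
#'     From one sample only the per-branch products amplitude x weight are
#'     identifiable, so weights are reported under a fixed-sum gauge
#'     (\eqn{\sum g_i = 1/2}); the products `amp_storage * weights` and
#'     `amp_loss * weights` are gauge-free.}
#'   \item{`"prony"`}{the classical spectrum with the Prony identity
#'     \eqn{E_0 = E_\infty + \sum E_i} built in, sharing the amplitude
#'     \eqn{E_0} between both channels. Here the weights themselves are
#'     identifiable; use this mode for spectrum recovery.}
#' }
#'
#' When the dataset provides fewer observations (2 per frequency) than free
#' parameters the fit still runs but is flagged and a warning is emitted:
#' the parameters then interpolate the data without being uniquely
#' determined.
#'
#' @param dataset A [modulus_dataset()].
#' @param order Model order (number of Maxwell branches), >= 1; default 4.
#' @param mode `"reduced"` or `"prony"` (see Details).
#' @param config A [fit_config()].
#' @param seed Integer seed controlling the multi-start initialisations.
#' @return An object of class `"dma_fit"`: fields `equilibrium`,
#'   `amp_storage`, `amp_loss`, `weights`, `relaxation_times`, `params`
#'   (a representative [bmd_params()] row), `objective_D`, `r2_storage`,
#'   `r2_loss`, `r2_joint`, `n_starts`, `converged`, `seed`,
#'   `identifiability_warning`, plus the per-start initial and final
#'   objective values.
#' @examples
#' sp <- prony_series(500, weights = c(0.2, 0.2), relaxation_times = c(0.1, 2))
#' ds <- modulus_dataset("s", 0.8, omega = 10^seq(-1.5, 2.5, length.out = 20),
#'                       storage = storage_modulus(sp, 10^seq(-1.5, 2.5, length.out = 20)),
#'                       loss = loss_modulus(sp, 10^seq(-1.5, 2.5, length.out = 20)))
#' fit <- fit_prony(ds, order = 2, mode = "prony", config = fit_config(8), seed = 1)
#' @export
fit_prony <- function(dataset, order = 4L, mode = c("reduced", "prony"),
                      config = fit_config(), seed = 1L) {
  stopifnot(inherits(dataset, "modulus_dataset"),
            inherits(config, "fit_config"))
  mode <- match.arg(mode)
  order <- as.integer(order)
  if (order < 1L) stop("'order' must be >= 1")
  npar <- if (mode == "prony") 2L * order + 1L else 2L * order + 2L
  nobs <- 2L * dataset$n
  ident_warn <- npar > nobs
  if (ident_warn)
    warning(sprintf(paste0(
      "identifiability: %d free parameters but only %d observations ",
      "(%d frequencies x 2 moduli); fitted parameters are not uniquely ",
      "determined"), npar, nobs, dataset$n), call. = FALSE)

  ctrl <- minpack.lm::nls.lm.control(ftol = config$ftol, ptol = 1e-12,
                                     maxiter = config$max_iter)
  set.seed(seed)
  best <- NULL
  best_D <- Inf
  start_obj <- final_obj <- rep(NA_real_, config$n_starts)
  for (k in seq_len(config$n_starts)) {
    th0 <- .prony_start(dataset, order, mode)
    start_obj[k] <- sum(.prony_residual(th0, dataset, order, mode)^2)
    # Under-determined fits (fewer observations than parameters) get a tiny
    # ridge pulling toward the start: the optimizer then needs m >= n and
    # returns the zero-misfit solution closest to its initialisation, making
    # the degenerate case deterministic.
    fn <- if (ident_warn) {
      function(theta, dataset, order, mode)
        c(.prony_residual(theta, dataset, order, mode), 1e-6 * (theta - th0))
    } else {
      .prony_residual
    }
    res <- tryCatch(
      minpack.lm::nls.lm(par = th0, fn = fn, dataset = dataset,
                         order = order, mode = mode, control = ctrl),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$deviance)) next
    D_k <- sum(.prony_residual(res$par, dataset, order, mode)^2)
    final_obj[k] <- D_k
    if (D_k < best_D) {
      best <- res
      best_D <- D_k
    }
  }
  if (is.null(best)) stop("all multi-start optimisations failed")

  th <- best$par
  if (mode == "prony") {
    Einf <- exp(th[1L])
    Ei <- exp(th[2L:(order + 1L)])
    tau <- exp(th[(order + 2L):(2L * order + 1L)])
    E0 <- Einf + sum(Ei)
    g <- Ei / E0
    eq <- Einf; a_s <- E0; a_l <- E0
  } else {
    eq <- exp(th[1L])
    r <- exp(th[2L])
    li <- exp(th[3L:(order + 2L)])
    tau <- exp(th[(order + 3L):(2L * order + 2L)])
    # fixed-sum gauge: sum(g) = 1/2 keeps every weight strictly inside (0, 1)
    g <- 0.5 * li / sum(li)
    a_l <- sum(li) / 0.5
    a_s <- r * a_l
  }
  o <- order(tau)
  tau <- tau[o]; g <- g[o]

  fit <- structure(
    list(mode = mode, order = order, sample_id = dataset$sample_id,
         bmd = dataset$bmd, equilibrium = eq, amp_storage = a_s,
         amp_loss = a_l, weights = g, relaxation_times = tau,
         params = NULL, objective_D = best_D,
         n_starts = config$n_starts,
         converged = best$info %in% 1:3, seed = as.integer(seed),
         identifiability_warning = ident_warn,
         start_objectives = start_obj, final_objectives = final_obj),
    class = "dma_fit")
  fit$params <- .representative_params(eq, a_s, a_l, g, tau, dataset$bmd)
  r2 <- r_squared(dataset, fit)
  fit$r2_storage <- unname(r2["r2_storage"])
  fit$r2_loss <- unname(r2["r2_loss"])
  fit$r2_joint <- unname(r2["r2_joint"])
  fit
}

# One representative of the (non-unique) constitutive parameter row that
# reproduces the fitted amplitudes at density rho: A = equilibrium with
# m = 0, n chosen so A*rho^n equals the dynamic storage amplitude, and
# B = loss amplitude with q = 0. At rho = 1 the power terms collapse and no
# exact representative exists unless the two storage amplitudes coincide.
.representative_params <- function(equilibrium, amp_storage, amp_loss,
                                   g, tau, rho) {
  if (abs(log(rho)) > 1e-8) {
    n <- log(amp_storage / equilibrium) / log(rho)
  } else {
    n <- 0
    if (abs(amp_storage - equilibrium) > 1e-8 * equilibrium)
      warning("no exact constitutive representative at rho = 1; ",
              "storage amplitude differs from the equilibrium modulus",
              call. = FALSE)
  }
  bmd_params(amp_A = equilibrium, exp_m = 0, exp_n = n, amp_B = amp_loss,
             exp_q = 0, weights = g, relaxation_times = tau, bmd = rho)
}

#' @export
print.dma_fit <- function(x, ...) {
  cat(sprintf(
    "Generalized Maxwell fit ('%s' mode, order %d) for sample '%s' (BMD %.3f)\n",
    x$mode, x$order, x$sample_id, x$bmd))
  cat(sprintf(
    "  E_eq = %.4g MPa, storage amplitude = %.4g MPa, loss amplitude = %.4g MPa\n",
    x$equilibrium, x$amp_storage, x$amp_loss))
  print(data.frame(g = x$weights, tau_s = x$relaxation_times),
        row.names = FALSE)
  cat(sprintf("  D = %.4g MPa^2, R2 (storage/loss/joint) = %.5f / %.5f / %.5f\n",
              x$objective_D, x$r2_storage, x$r2_loss, x$r2_joint))
  if (x$identifiability_warning)
    cat("  note: under-determined fit (fewer observations than parameters)\n")
  invisible(x)
}

#' Prony spectrum of a fitted model
#'
#' For a `"prony"`-mode fit this is exact. For a `"reduced"`-mode fit the
#' storage channel is reproduced exactly while the spectrum's loss channel
#' uses the storage amplitude, which matches the data only when the fitted
#' storage/loss amplitude ratio is 1.
#'
#' @param fit A `"dma_fit"` from [fit_prony()].
#' @return A [prony_series()] object.
#' @export
as_prony_series <- function(fit) {
  stopifnot(inherits(fit, "dma_fit"))
  prony_series(fit$equilibrium, fit$amp_storage,
               weights = fit$weights,
               relaxation_times = fit$relaxation_times)
}

#' Fit a modulus-density power law
#'
#' Fits \eqn{E = a\,\rho^b} to paired observations by ordinary least squares
#' on \eqn{(\ln\rho, \ln E)}, then refines \eqn{(a, b)} by nonlinear least
#' squares on the original scale, where the reported \eqn{r^2} is also
#' computed. For data that are exact on the log-log scale both stages agree
#' and \eqn{r^2 = 1} to machine precision.
#'
#' @param bmds Densities \eqn{\rho} in g/cm^3, positive, length >= 2.
#' @param moduli Moduli in MPa, positive, same length.
#' @return A [power_law_fit()] object.
#' @examples
#' fit_powerlaw(c(1, 2), c(10, 40))  # a = 10, b = 2
#' @export
fit_powerlaw <- function(bmds, moduli) {
  rho <- as.numeric(bmds)
  E <- as.numeric(moduli)
  if (length(rho) != length(E) || length(rho) < 2L)
    stop("need at least 2 (bmd, modulus) pairs of equal length")
  if (any(!is.finite(rho)) || any(rho <= 0) ||
      any(!is.finite(E)) || any(E <= 0))
    stop("all densities and moduli must be positive and finite")

  ll <- stats::lm(log(E) ~ log(rho))
  a0 <- exp(stats::coef(ll)[[1L]])
  b0 <- stats::coef(ll)[[2L]]
  res <- minpack.lm::nls.lm(
    par = c(log_a = log(a0), b = b0),
    fn = function(th) exp(th[1L]) * rho^th[2L] - E,
    control = minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14,
                                         maxiter = 1024L))
  a <- exp(res$par[[1L]])
  b <- res$par[[2L]]
  ss_res <- sum((a * rho^b - E)^2)
  ss_tot <- sum((E - mean(E))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else if (ss_res <= 1e-12) 1 else NA_real_
  power_law_fit(a, b, r_squared = max(0, min(1, r2)))
}

#' Steady-state moduli of a frequency sweep
#'
#' Averages each modulus over the final `tail_fraction` of the sweep
#' duration, discarding the initial transient so that a single steady-state
#' (storage, loss) pair per frequency enters the frequency-domain fit.
#'
#' @param sweep A `"dma_sweep"` (see [simulate_sweep()]), with >= 4 time
#'   points.
#' @param tail_fraction Fraction of the sweep duration to average over,
#'   in (0, 1]; default 0.25.
#' @return Named vector `c(storage = ..., loss = ...)` in MPa.
#' @export
extract_steady_state <- function(sweep, tail_fraction = 0.25) {
  stopifnot(inherits(sweep, "dma_sweep"))
  if (!is.numeric(tail_fraction) || length(tail_fraction) != 1L ||
      tail_fraction <= 0 || tail_fraction > 1)
    stop("'tail_fraction' must be in (0, 1]")
  if (length(sweep$times) < 4L)
    stop("sweep must have at least 4 time points")
  span <- max(sweep$times) - min(sweep$times)
  keep <- sweep$times >= max(sweep$times) - tail_fraction * span
  if (!any(keep)) stop("empty tail window")
  c(storage = mean(sweep$storage[keep]), loss = mean(sweep$loss[keep]))
}

#' Build a per-sample fitting dataset from its frequency sweeps
#'
#' Extracts the steady-state moduli of each sweep belonging to the sample
#' and assembles them into a [modulus_dataset()] at the corresponding
#' angular frequencies.
#'
#' @param sweeps List of `"dma_sweep"` objects (one per drive frequency).
#' @param sample_id,bmd Sample identity and density.
#' @param tail_fraction Passed to [extract_steady_state()].
#' @param convention Frequency-variable convention, see [freq_to_omega()].
#' @return A [modulus_dataset()].
#' @export
dataset_from_sweeps <- function(sweeps, sample_id, bmd, tail_fraction = 0.25,
                                convention = "angular") {
  if (length(sweeps) < 2L) stop("need sweeps at >= 2 frequencies")
  ss <- vapply(sweeps, extract_steady_state, numeric(2L),
               tail_fraction = tail_fraction)
  f <- vapply(sweeps, function(s) s$frequency, numeric(1L))
  modulus_dataset(sample_id, bmd, freq_to_omega(f, convention),
                  storage = ss["storage", ], loss = ss["loss", ])
}
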