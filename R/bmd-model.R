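#' BMD-parameterised constitutive parameters
#'
#' Parameter set of the density-dependent generalized Maxwell constitutive
#' model for cancellous alveolar bone,
#' \deqn{E'(\rho,\omega) = A\rho^m + A\rho^{n}\sum_i g_i
#'   \frac{\tau_i^2\omega^2}{1+\tau_i^2\omega^2}, \qquad
#'   E''(\rho,\omega) = B\rho^{q}\sum_i g_i
#'   \frac{\tau_i\omega}{1+\tau_i^2\omega^2},}
#' with \eqn{\rho} the bone mineral density in g/cm^3. \eqn{A\rho^m} is the
#' equilibrium modulus, \eqn{A\rho^{n}} the dynamic storage amplitude and
#' \eqn{B\rho^{q}} the loss amplitude; the three amplitudes are treated as
#' mutually independent (use [bmd_to_prony()] to check whether a parameter
#' set also satisfies the classical Prony identity).
#'
#' Weights and relaxation times are stored in the order given (not sorted),
#' so tabulated parameter rows round-trip verbatim; fitted spectra are
#' sorted by the fitting routines themselves.
#'
#' @param amp_A Amplitude \eqn{A} (MPa), positive.
#' @param exp_m Equilibrium-modulus exponent \eqn{m} (dimensionless).
#' @param exp_n Dynamic storage-amplitude exponent (dimensionless; distinct
#'   from the model order).
#' @param amp_B Loss amplitude \eqn{B} (MPa), positive.
#' @param exp_q Loss-amplitude exponent \eqn{q} (dimensionless).
#' @param weights Dimensionless weights \eqn{g_i}, each strictly in (0, 1).
#'   The study model is fourth order (4 weights), but any order >= 1 is
#'   accepted so reduced fits can be represented.
#' @param relaxation_times Relaxation times \eqn{\tau_i} (s), positive.
#' @param bmd Optional BMD (g/cm^3) this row was fitted at.
#' @return An object of class `"bmd_params"`.
#' @seealso [storage_modulus_bmd()], [loss_modulus_bmd()],
#'   [default_table3_params()], [write_bmd_params()]
#' @export
bmd_params <- function(amp_A, exp_m, exp_n, amp_B, exp_q,
                       weights, relaxation_times, bmd = NULL) {
  g <- as.numeric(weights)
  tau <- as.numeric(relaxation_times)
  if (length(g) != length(tau) || length(g) < 1L)
    stop("'weights' and 'relaxation_times' must have equal positive length")
  if (any(!is.finite(g)) || any(g <= 0) || any(g >= 1))
    stop("all weights g_i must lie strictly in (0, 1)")
  if (any(!is.finite(tau)) || any(tau <= 0))
    stop("all relaxation times tau_i must be positive")
  for (nm in c("amp_A", "amp_B")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive number", nm))
  }
  for (nm in c("exp_m", "exp_n", "exp_q")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("'%s' must be a single finite number", nm))
  }
  if (!is.null(bmd)) {
    if (!is.numeric(bmd) || length(bmd) != 1L || !is.finite(bmd) || bmd <= 0)
      stop("'bmd' must be a single positive number or NULL")
    bmd <- as.numeric(bmd)
  }
  structure(
    list(amp_A = as.numeric(amp_A), exp_m = as.numeric(exp_m),
         exp_n = as.numeric(exp_n), amp_B = as.numeric(amp_B),
         exp_q = as.numeric(exp_q), weights = g, relaxation_times = tau,
         order = length(g), bmd = bmd),
    class = "bmd_params")
}

#' @export
print.bmd_params <- function(x, ...) {
  cat(sprintf(
    "BMD constitutive parameters (order %d%s):\n  A = %.4g MPa, m = %.4g, n = %.4g, B = %.4g MPa, q = %.4g\n",
    x$order,
    if (is.null(x$bmd)) "" else sprintf(", fitted at BMD %.3f g/cm^3", x$bmd),
    x$amp_A, x$exp_m, x$exp_n, x$amp_B, x$exp_q))
  print(data.frame(g = x$weights, tau_s = x$relaxation_times),
        row.names = FALSE)
  invisible(x)
}

.check_rho <- function(rho) {
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho <= 0)
    stop("'rho' must be a single positive bone mineral density in g/cm^3")
  as.numeric(rho)
}

#' Density-dependent storage and loss moduli
#'
#' Evaluate the BMD-parameterised constitutive model (see [bmd_params()])
#' at density `rho` and angular frequency `omega`. At \eqn{\omega = 0} the
#' storage modulus reduces to the equilibrium term \eqn{A\rho^m} and the
#' loss modulus vanishes.
#'
#' @param params A [bmd_params()] object.
#' @param rho Bone mineral density \eqn{\rho} in g/cm^3, positive scalar.
#' @param omega Angular frequency(ies) in rad/s, non-negative; vectorised.
#' @return Modulus in MPa per element of `omega`.
#' @examples
#' p <- default_table3_params(0.926)
#' storage_modulus_bmd(p, 0.926, freq_to_omega(c(0.5, 1, 2, 5)))
#' @export
storage_modulus_bmd <- function(params, rho, omega) {
  stopifnot(inherits(params, "bmd_params"))
  rho <- .check_rho(rho)
  omega <- .check_omega(omega)
  .storage_sum(params$amp_A * rho^params$exp_m,
               params$amp_A * rho^params$exp_n * params$weights,
               params$relaxation_times, omega)
}

#' @rdname storage_modulus_bmd
#' @export
loss_modulus_bmd <- function(params, rho, omega) {
  stopifnot(inherits(params, "bmd_params"))
  rho <- .check_rho(rho)
  omega <- .check_omega(omega)
  .loss_sum(params$amp_B * rho^params$exp_q * params$weights,
            params$relaxation_times, omega)
}

#' Prony spectrum implied by a BMD parameter row at a given density
#'
#' Collapses the density dependence at a fixed \eqn{\rho}: equilibrium
#' modulus \eqn{A\rho^m}, instantaneous (dynamic storage) amplitude
#' \eqn{A\rho^{n}}, and the row's weights and relaxation times. The storage
#' channel of the returned spectrum reproduces the constitutive storage
#' modulus exactly; note the constitutive loss channel carries its own
#' amplitude \eqn{B\rho^q}, not \eqn{A\rho^n}. A warning is emitted when the
#' implied spectrum violates the classical Prony identity (tabulated rows
#' generally do, since their amplitudes were fitted independently).
#'
#' @inheritParams storage_modulus_bmd
#' @param warn_inconsistent Warn when the Prony identity fails?
#' @return A [prony_series()] object.
#' @export
bmd_to_prony <- function(params, rho, warn_inconsistent = TRUE) {
  stopifnot(inherits(params, "bmd_params"))
  rho <- .check_rho(rho)
  sp <- prony_series(params$amp_A * rho^params$exp_m,
                     params$amp_A * rho^params$exp_n,
                     weights = params$weights,
                     relaxation_times = params$relaxation_times)
  if (warn_inconsistent) prony_consistent(sp, warn = TRUE)
  sp
}

#' Power-law relation between a modulus and bone mineral density
#'
#' Container for a fitted relation \eqn{E = a\,\rho^{b}} (modulus in MPa,
#' \eqn{\rho} in g/cm^3), as used for the equilibrium-modulus-density law of
#' cancellous bone, plus its coefficient of determination on the original
#' (not log) scale.
#'
#' @param coefficient Prefactor \eqn{a} in MPa, positive.
#' @param exponent Dimensionless exponent \eqn{b}.
#' @param r_squared Coefficient of determination in `[0, 1]`, or `NA` when
#'   undefined (zero variance in the response).
#' @return An object of class `"power_law_fit"`.
#' @seealso [equilibrium_powerlaw()], [fit_powerlaw()], [default_powerlaw()]
#' @export
power_law_fit <- function(coefficient, exponent, r_squared = NA_real_) {
  if (!is.numeric(coefficient) || length(coefficient) != 1L ||
      !is.finite(coefficient) || coefficient <= 0)
    stop("'coefficient' must be a single positive number")
  if (!is.numeric(exponent) || length(exponent) != 1L || !is.finite(exponent))
    stop("'exponent' must be a single finite number")
  if (!is.na(r_squared) &&
      (!is.numeric(r_squared) || length(r_squared) != 1L ||
       r_squared < 0 || r_squared > 1))
    stop("'r_squared' must be in [0, 1] or NA")
  structure(list(coefficient = as.numeric(coefficient),
                 exponent = as.numeric(exponent),
                 r_squared = as.numeric(r_squared)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power law: E = %.6g * rho^%.6g  (r^2 = %s)\n",
              x$coefficient, x$exponent,
              if (is.na(x$r_squared)) "NA" else sprintf("%.4f", x$r_squared)))
  invisible(x)
}

#' Evaluate a modulus-density power law
#'
#' @param rho Bone mineral density(ies) in g/cm^3, positive.
#' @param fit A [power_law_fit()] object.
#' @return Modulus \eqn{a\,\rho^b} in MPa per element of `rho`.
#' @export
equilibrium_powerlaw <- function(rho, fit) {
  stopifnot(inherits(fit, "power_law_fit"))
  if (!is.numeric(rho) || any(!is.finite(rho)) || any(rho <= 0))
    stop("'rho' must be positive and finite")
  fit$coefficient * as.numeric(rho)^fit$exponent
}

#' Serialize BMD constitutive parameters to JSON
#'
#' Field names follow the tabulated parameter-row layout: `A`, `m`, `n`,
#' `B`, `q`, `g1..gk`, `tau1..tauk`, and `BMD` when known.
#'
#' @param params A [bmd_params()] object.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `write_bmd_params()`: the JSON string, invisibly when written to
#'   a file. `read_bmd_params()`: a `bmd_params` object.
#' @export
write_bmd_params <- function(params, path = NULL) {
  stopifnot(inherits(params, "bmd_params"))
  ord <- params$order
  fields <- c(
    list(A = params$amp_A, m = params$exp_m, n = params$exp_n,
         B = params$amp_B, q = params$exp_q),
    stats::setNames(as.list(params$weights), paste0("g", seq_len(ord))),
    stats::setNames(as.list(params$relaxation_times),
                    paste0("tau", seq_len(ord))))
  if (!is.null(params$bmd)) fields$BMD <- params$bmd
  js <- jsonlite::toJSON(fields, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname write_bmd_params
#' @param x A JSON string, or the path of a file written by
#'   `write_bmd_params()`.
#' @export
read_bmd_params <- function(x) {
  obj <- jsonlite::fromJSON(x)
  need <- c("A", "m", "n", "B", "q")
  if (!all(need %in% names(obj)))
    stop("missing fields: ", paste(setdiff(need, names(obj)), collapse = ", "))
  gk <- sort(names(obj)[grepl("^g[0-9]+$", names(obj))])
  tk <- sort(names(obj)[grepl("^tau[0-9]+$", names(obj))])
  if (length(gk) == 0L || length(gk) != length(tk))
    stop("expected matching g1..gk and tau1..tauk fields")
  gk <- gk[order(as.integer(sub("^g", "", gk)))]
  tk <- tk[order(as.integer(sub("^tau", "", tk)))]
  bmd_params(obj$A, obj$m, obj$n, obj$B, obj$q,
             weights = unlist(obj[gk], use.names = FALSE),
             relaxation_times = unlist(obj[tk], use.names = FALSE),
             bmd = if ("BMD" %in% names(obj)) obj$BMD else NULL)
}
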