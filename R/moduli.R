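#' Relaxation modulus of the generalized Maxwell solid
#'
#' Evaluates \eqn{E(t) = E_\infty + \sum_i E_i e^{-t/\tau_i}} (MPa), the
#' stress-relaxation response to a unit step strain. For a Prony spectrum the
#' branch moduli are \eqn{E_i = g_i E_0}. `E(0)` equals the instantaneous
#' modulus of a spectrum obeying the Prony identity, and \eqn{E(t)} decays
#' monotonically to \eqn{E_\infty}.
#'
#' @param spectrum A [prony_series()] or [maxwell_branches()] object.
#' @param t Time(s) in seconds, non-negative; vectorised.
#' @return Relaxation modulus in MPa, one value per element of `t`.
#' @examples
#' b <- maxwell_branches(100, 200, 200)  # tau = 1 s
#' relaxation_modulus(b, c(0, 1))        # 300, 100 + 200*exp(-1)
#' @export
relaxation_modulus <- function(spectrum, t) {
  UseMethod("relaxation_modulus")
}

.check_time <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop("'t' must be non-negative and finite")
  as.numeric(t)
}

.relax_sum <- function(E_inf, E_i, tau, t) {
  decay <- exp(-outer(t, 1 / tau))      # |t| x order
  as.vector(E_inf + decay %*% E_i)
}

#' @export
relaxation_modulus.prony_series <- function(spectrum, t) {
  t <- .check_time(t)
  .relax_sum(spectrum$equilibrium_modulus,
             spectrum$weights * spectrum$instantaneous_modulus,
             spectrum$relaxation_times, t)
}

#' @export
relaxation_modulus.maxwell_branches <- function(spectrum, t) {
  t <- .check_time(t)
  .relax_sum(spectrum$equilibrium_modulus, spectrum$branch_moduli,
             spectrum$relaxation_times, t)
}

.check_omega <- function(omega) {
  if (!is.numeric(omega) || any(!is.finite(omega)) || any(omega < 0))
    stop("'omega' must be non-negative and finite")
  as.numeric(omega)
}

.storage_sum <- function(E_inf, E_i, tau, omega) {
  D <- outer(omega^2, tau^2)            # (omega tau)^2
  as.vector(E_inf + (D / (1 + D)) %*% E_i)
}

.loss_sum <- function(E_i, tau, omega) {
  D <- outer(omega^2, tau^2)
  as.vector((outer(omega, tau) / (1 + D)) %*% E_i)
}

#' Storage modulus of the generalized Maxwell solid
#'
#' The in-phase (elastic) component of the complex modulus under oscillatory
#' strain at angular frequency \eqn{\omega} (rad/s),
#' \deqn{E'(\omega) = E_\infty + E_0 \sum_i g_i
#'   \frac{\tau_i^2\omega^2}{1 + \tau_i^2\omega^2}.}
#' \eqn{E'} rises monotonically from \eqn{E_\infty} at \eqn{\omega = 0} to
#' \eqn{E_\infty + E_0 \sum_i g_i} in the high-frequency limit. The
#' equivalent branch form \eqn{E_\infty + \sum_i E_i
#' \tau_i^2\omega^2/(1+\tau_i^2\omega^2)} is used for
#' `maxwell_branches` input; both agree exactly for corresponding parameters.
#'
#' @param spectrum A [prony_series()] or [maxwell_branches()] object.
#' @param omega Angular frequency(ies) in rad/s, non-negative; vectorised.
#'   For a DMA drive frequency `f` in Hz use `omega = 2 * pi * f` (see
#'   [freq_to_omega()]).
#' @return Storage modulus \eqn{E'} in MPa per element of `omega`.
#' @export
storage_modulus <- function(spectrum, omega) {
  UseMethod("storage_modulus")
}

#' @export
storage_modulus.prony_series <- function(spectrum, omega) {
  omega <- .check_omega(omega)
  .storage_sum(spectrum$equilibrium_modulus,
               spectrum$weights * spectrum$instantaneous_modulus,
               spectrum$relaxation_times, omega)
}

#' @export
storage_modulus.maxwell_branches <- function(spectrum, omega) {
  omega <- .check_omega(omega)
  .storage_sum(spectrum$equilibrium_modulus, spectrum$branch_moduli,
               spectrum$relaxation_times, omega)
}

#' Loss modulus of the generalized Maxwell solid
#'
#' The out-of-phase (viscous) component of the complex modulus,
#' \deqn{E''(\omega) = E_0 \sum_i g_i
#'   \frac{\tau_i\omega}{1 + \tau_i^2\omega^2},}
#' the standard Debye form: each branch contributes a peak of height
#' \eqn{E_0 g_i / 2} at \eqn{\omega = 1/\tau_i}, and \eqn{E''} vanishes in
#' both the zero- and infinite-frequency limits.
#'
#' @inheritParams storage_modulus
#' @return Loss modulus \eqn{E''} in MPa per element of `omega`.
#' @export
loss_modulus <- function(spectrum, omega) {
  UseMethod("loss_modulus")
}

#' @export
loss_modulus.prony_series <- function(spectrum, omega) {
  omega <- .check_omega(omega)
  .loss_sum(spectrum$weights * spectrum$instantaneous_modulus,
            spectrum$relaxation_times, omega)
}

#' @export
loss_modulus.maxwell_branches <- function(spectrum, omega) {
  omega <- .check_omega(omega)
  .loss_sum(spectrum$branch_moduli, spectrum$relaxation_times, omega)
}

#' Convert a DMA drive frequency to the model frequency variable
#'
#' The oscillatory forward models take an angular frequency in rad/s; a DMA
#' instrument reports the drive frequency in Hz. The default convention is
#' \eqn{\omega = 2\pi f}. Setting `convention = "hz"` uses \eqn{\omega = f}
#' instead, provided for sensitivity checks of the frequency-variable
#' convention.
#'
#' @param frequency_hz Drive frequency in Hz.
#' @param convention `"angular"` (default, \eqn{\omega = 2\pi f}) or `"hz"`
#'   (\eqn{\omega = f}).
#' @return Frequency variable passed to the modulus functions.
#' @export
freq_to_omega <- function(frequency_hz, convention = c("angular", "hz")) {
  convention <- match.arg(convention)
  if (any(!is.finite(frequency_hz)) || any(frequency_hz < 0))
    stop("'frequency_hz' must be non-negative and finite")
  if (convention == "angular") 2 * pi * frequency_hz else frequency_hz
}
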