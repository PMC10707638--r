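#' Prony-series relaxation spectrum
#'
#' Canonical spectral representation of a generalized Maxwell solid,
#' \deqn{E(t) = E_\infty + E_0 \sum_i g_i e^{-t/\tau_i},}
#' where \eqn{E_\infty} is the equilibrium (long-time) modulus, \eqn{E_0}
#' the instantaneous (glassy) modulus, \eqn{g_i \in (0,1)} dimensionless
#' branch weights and \eqn{\tau_i > 0} relaxation times in seconds.
#'
#' The stored form is canonical: relaxation times are sorted ascending and
#' branches whose times coincide within a relative 1e-9 are merged by summing
#' their weights, so spectra fitted by different routes are directly
#' comparable.
#'
#' When `instantaneous_modulus` is omitted it is derived from the standard
#' Prony identity \eqn{E_0 = E_\infty / (1 - \sum_i g_i)}, which requires
#' \eqn{\sum_i g_i < 1}. An explicit `instantaneous_modulus` is accepted even
#' when it violates that identity (the BMD constitutive model treats the
#' equilibrium and dynamic amplitudes as independent); use
#' [prony_consistent()] to check.
#'
#' @param equilibrium_modulus Equilibrium modulus \eqn{E_\infty} (MPa),
#'   non-negative.
#' @param instantaneous_modulus Instantaneous modulus \eqn{E_0} (MPa),
#'   positive, or `NULL` to derive it from the Prony identity.
#' @param weights Dimensionless branch weights \eqn{g_i}, each strictly in
#'   (0, 1).
#' @param relaxation_times Branch relaxation times \eqn{\tau_i} (s), positive.
#'
#' @return An object of class `"prony_series"` with fields
#'   `equilibrium_modulus`, `instantaneous_modulus`, `weights`,
#'   `relaxation_times` and `order`.
#' @seealso [maxwell_branches()], [to_prony()], [from_prony()],
#'   [storage_modulus()], [loss_modulus()], [relaxation_modulus()]
#' @examples
#' sp <- prony_series(100, 200, weights = 0.5, relaxation_times = 1)
#' storage_modulus(sp, omega = 1)  # 150
#' @export
prony_series <- function(equilibrium_modulus, instantaneous_modulus = NULL,
                         weights, relaxation_times) {
  g <- as.numeric(weights)
  tau <- as.numeric(relaxation_times)
  if (length(g) != length(tau) || length(g) < 1L)
    stop("'weights' and 'relaxation_times' must have equal positive length")
  if (any(!is.finite(g)) || any(g <= 0) || any(g >= 1))
    stop("all weights g_i must lie strictly in (0, 1)")
  if (any(!is.finite(tau)) || any(tau <= 0))
    stop("all relaxation times tau_i must be positive")
  if (!is.numeric(equilibrium_modulus) || length(equilibrium_modulus) != 1L ||
      !is.finite(equilibrium_modulus) || equilibrium_modulus < 0)
    stop("'equilibrium_modulus' must be a single non-negative number")
  if (is.null(instantaneous_modulus)) {
    gs <- sum(g)
    if (gs >= 1)
      stop("invalid spectrum: sum(g_i) must be < 1 to derive E0 = E_inf/(1 - sum(g_i))")
    if (equilibrium_modulus <= 0)
      stop("'equilibrium_modulus' must be positive to derive the instantaneous modulus")
    instantaneous_modulus <- equilibrium_modulus / (1 - gs)
  }
  if (!is.numeric(instantaneous_modulus) || length(instantaneous_modulus) != 1L ||
      !is.finite(instantaneous_modulus) || instantaneous_modulus <= 0)
    stop("'instantaneous_modulus' must be a single positive number")

  o <- order(tau)
  tau <- tau[o]
  g <- g[o]
  # merge branches whose relaxation times coincide within relative 1e-9
  if (length(tau) > 1L) {
    mt <- tau[1L]; mg <- g[1L]
    out_t <- numeric(0); out_g <- numeric(0)
    for (i in seq_along(tau)[-1L]) {
      if (tau[i] - mt <= 1e-9 * mt) {
        mg <- mg + g[i]
      } else {
        out_t <- c(out_t, mt); out_g <- c(out_g, mg)
        mt <- tau[i]; mg <- g[i]
      }
    }
    tau <- c(out_t, mt)
    g <- c(out_g, mg)
    if (any(g >= 1))
      stop("merging coincident relaxation times produced a weight >= 1")
  }

  structure(
    list(equilibrium_modulus = equilibrium_modulus,
         instantaneous_modulus = instantaneous_modulus,
         weights = g,
         relaxation_times = tau,
         order = length(g)),
    class = "prony_series")
}

#' @export
print.prony_series <- function(x, ...) {
  cat(sprintf("Prony series (order %d): E_inf = %.4g MPa, E0 = %.4g MPa\n",
              x$order, x$equilibrium_modulus, x$instantaneous_modulus))
  print(data.frame(g = x$weights, tau_s = x$relaxation_times),
        row.names = FALSE)
  invisible(x)
}

#' Check the Prony identity between instantaneous and equilibrium modulus
#'
#' For a spectrum whose amplitudes obey the classical generalized Maxwell
#' construction, \eqn{E_0 = E_\infty / (1 - \sum_i g_i)}. Constitutive
#' parameter sets fitted with independent equilibrium and dynamic amplitudes
#' need not satisfy it; this checker reports (and optionally warns about)
#' violations instead of rejecting such spectra.
#'
#' @param spectrum A [prony_series()] object.
#' @param tol Relative tolerance on the identity.
#' @param warn Emit a warning when the identity fails?
#' @return `TRUE` if the identity holds within `tol` (this requires
#'   \eqn{\sum g_i < 1}), else `FALSE`.
#' @export
prony_consistent <- function(spectrum, tol = 1e-6, warn = FALSE) {
  stopifnot(inherits(spectrum, "prony_series"))
  gs <- sum(spectrum$weights)
  ok <- FALSE
  if (gs < 1) {
    implied <- spectrum$equilibrium_modulus / (1 - gs)
    ok <- abs(implied - spectrum$instantaneous_modulus) <=
      tol * abs(spectrum$instantaneous_modulus)
  }
  if (!ok && warn)
    warning("spectrum violates the Prony identity E0 = E_inf/(1 - sum(g_i)); ",
            "equilibrium and dynamic amplitudes are being treated as independent",
            call. = FALSE)
  ok
}

#' Generalized Maxwell branch parameterisation
#'
#' The mechanical-element form of the generalized Maxwell solid: a parallel
#' equilibrium spring \eqn{E_\infty} plus `n` Maxwell branches, branch `i`
#' being a spring \eqn{E_i} (MPa) in series with a dashpot \eqn{\eta_i}
#' (MPa s), giving relaxation time \eqn{\tau_i = \eta_i / E_i}. Branches are
#' stored sorted by ascending relaxation time.
#'
#' @param equilibrium_modulus Equilibrium modulus \eqn{E_\infty} (MPa).
#' @param branch_moduli Branch spring moduli \eqn{E_i} (MPa), positive.
#' @param branch_viscosities Branch dashpot viscosities \eqn{\eta_i}
#'   (MPa s), positive; same length as `branch_moduli`.
#' @return An object of class `"maxwell_branches"` with the derived
#'   `relaxation_times`.
#' @seealso [to_prony()], [from_prony()]
#' @export
maxwell_branches <- function(equilibrium_modulus, branch_moduli,
                             branch_viscosities) {
  E <- as.numeric(branch_moduli)
  eta <- as.numeric(branch_viscosities)
  if (length(E) != length(eta) || length(E) < 1L)
    stop("'branch_moduli' and 'branch_viscosities' must have equal positive length")
  if (any(!is.finite(E)) || any(E <= 0))
    stop("all branch moduli E_i must be positive")
  if (any(!is.finite(eta)) || any(eta <= 0))
    stop("all branch viscosities eta_i must be positive")
  if (!is.numeric(equilibrium_modulus) || length(equilibrium_modulus) != 1L ||
      !is.finite(equilibrium_modulus) || equilibrium_modulus < 0)
    stop("'equilibrium_modulus' must be a single non-negative number")
  tau <- eta / E
  o <- order(tau)
  structure(
    list(equilibrium_modulus = equilibrium_modulus,
         branch_moduli = E[o],
         branch_viscosities = eta[o],
         relaxation_times = tau[o]),
    class = "maxwell_branches")
}

#' @export
print.maxwell_branches <- function(x, ...) {
  cat(sprintf("Generalized Maxwell model (%d branches): E_inf = %.4g MPa\n",
              length(x$branch_moduli), x$equilibrium_modulus))
  print(data.frame(E_MPa = x$branch_moduli, eta_MPa_s = x$branch_viscosities,
                   tau_s = x$relaxation_times), row.names = FALSE)
  invisible(x)
}

#' Convert between branch and Prony parameterisations
#'
#' `to_prony()` maps branch parameters to the Prony form using
#' \eqn{E_0 = E_\infty + \sum_i E_i} and \eqn{g_i = E_i / E_0};
#' `from_prony()` inverts it with \eqn{E_i = g_i E_0} and
#' \eqn{\eta_i = E_i \tau_i}. The round trip is the identity (to relative
#' 1e-12) for spectra that satisfy the Prony identity; `from_prony()` rejects
#' spectra with \eqn{\sum g_i \ge 1}, whose implied equilibrium modulus would
#' be non-positive, and warns when the identity fails.
#'
#' @param branches A [maxwell_branches()] object.
#' @param spectrum A [prony_series()] object.
#' @return `to_prony()` a `prony_series`; `from_prony()` a
#'   `maxwell_branches`.
#' @examples
#' b <- maxwell_branches(100, branch_moduli = 100, branch_viscosities = 100)
#' to_prony(b)  # E0 = 200, g = 0.5, tau = 1
#' @export
to_prony <- function(branches) {
  stopifnot(inherits(branches, "maxwell_branches"))
  E0 <- branches$equilibrium_modulus + sum(branches$branch_moduli)
  prony_series(branches$equilibrium_modulus, E0,
               weights = branches$branch_moduli / E0,
               relaxation_times = branches$relaxation_times)
}

#' @rdname to_prony
#' @export
from_prony <- function(spectrum) {
  stopifnot(inherits(spectrum, "prony_series"))
  if (sum(spectrum$weights) >= 1)
    stop("invalid spectrum: sum(g_i) >= 1 implies a non-positive equilibrium modulus")
  prony_consistent(spectrum, warn = TRUE)
  E <- spectrum$weights * spectrum$instantaneous_modulus
  maxwell_branches(spectrum$equilibrium_modulus,
                   branch_moduli = E,
                   branch_viscosities = E * spectrum$relaxation_times)
}
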