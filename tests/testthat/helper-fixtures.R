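# Shared fixtures: consistent random spectra and dense frequency grids for
# generate-then-fit experiments.

random_spectrum <- function(seed, order = 4L, tau_range = c(0.02, 5)) {
  set.seed(seed)
  g <- runif(order, 0.05, 0.2)
  # keep sum(g) < 1 so the Prony identity defines E0
  g <- g / max(1.2 * sum(g), 1)
  tau <- sort(exp(runif(order, log(tau_range[1L]), log(tau_range[2L]))))
  # enforce separation so branches stay distinct after canonical merging
  tau <- tau * cumprod(c(1, rep(1.5, order - 1L)))
  prony_series(runif(1L, 200, 900), weights = g, relaxation_times = tau)
}

dense_omega_grid <- function(tau, n = 30L) {
  exp(seq(log(0.1 / max(tau)), log(10 / min(tau)), length.out = n))
}

dataset_from_spectrum <- function(spectrum, omega, bmd = 0.8, id = "sim") {
  modulus_dataset(id, bmd, omega,
                  storage = storage_modulus(spectrum, omega),
                  loss = loss_modulus(spectrum, omega))
}

# Independent term-by-term oracles: plain scalar loops, no shared code with
# the package's vectorised forward models.
oracle_storage <- function(E_inf, E_amp, g, tau, omega) {
  acc <- E_inf
  for (i in seq_along(g))
    acc <- acc + E_amp * g[i] * tau[i]^2 * omega^2 / (1 + tau[i]^2 * omega^2)
  acc
}

oracle_loss <- function(E_amp, g, tau, omega) {
  acc <- 0
  for (i in seq_along(g))
    acc <- acc + E_amp * g[i] * tau[i] * omega / (1 + tau[i]^2 * omega^2)
  acc
}
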