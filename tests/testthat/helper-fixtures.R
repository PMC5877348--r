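# Shared fixtures: tiny photocycles and spectra built in code.

rel_err <- function(est, truth) abs(est - truth) / abs(truth)

# photocycle with Gaussian-band difference spectra on a small grid
toy_cycle <- function(tau_ms = c(0.5, 5), wl = seq(400, 710, 10),
                      centers = c(480, 560), amp = 0.2) {
  delta <- t(vapply(centers, function(c0)
    amp * exp(-((wl - c0) / 40)^2) - amp * exp(-((wl - 540) / 40)^2),
    numeric(length(wl))))
  sequential_photocycle(tau_ms, delta, wl)
}

# rate (generator) matrix of the irreversible chain including the
# returned-ground sink, for the matrix-exponential oracle
chain_rate_matrix <- function(tau_ms) {
  k <- 1 / (tau_ms * 1e-3)
  n <- length(k)
  Q <- matrix(0, n + 1, n + 1)
  for (i in seq_len(n)) {
    Q[i, i] <- -k[i]
    Q[i + 1, i] <- k[i]
  }
  Q
}

# oracle populations via Matrix::expm applied to the initial vector
expm_populations <- function(tau_ms, times_s) {
  Q <- chain_rate_matrix(tau_ms)
  n <- length(tau_ms)
  vapply(times_s, function(t)
    as.numeric(Matrix::expm(Q * t) %*% c(1, rep(0, n)))[seq_len(n)],
    numeric(n))
}
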