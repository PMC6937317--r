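# Independent oracles and fixture builders shared across the suite.

# Direct time-domain Morlet convolution: closed-form kernel
#   h(t) = 2 sigma_f sqrt(2 pi) exp(-2 pi^2 sigma_f^2 t^2) exp(2 pi i f t)
# (inverse Fourier transform of the positive-frequency Gaussian window used
# by the spectral-domain path), truncated at +/- 6 envelope SDs.
morlet_direct <- function(x, fs, f, sigma) {
  sigma_f <- f / sigma
  sigma_t <- 1 / (2 * pi * sigma_f)
  half <- ceiling(6 * sigma_t * fs)
  tt <- (-half:half) / fs
  h <- 2 * sigma_f * sqrt(2 * pi) * exp(-2 * pi^2 * sigma_f^2 * tt^2) *
    exp(2i * pi * f * tt) / fs
  n <- length(x)
  out <- complex(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - half):min(n, i + half)
    out[i] <- sum(x[j] * h[i - j + half + 1L])
  }
  out
}

# Double-sum evaluation of the debiased WPLI^2 via outer products (used in
# the large-scale oracle-equivalence sweep; loop form lives in the package).
dwpli2_outer <- function(I) {
  o <- outer(I, I)
  num <- sum(o) - sum(diag(o))
  den <- sum(abs(o)) - sum(abs(diag(o)))
  if (den == 0) return(NA_real_)
  num / den
}

# Rayleigh test p-value (Wilkie approximation) for circular uniformity.
rayleigh_p <- function(theta) {
  n <- length(theta)
  R <- Mod(mean(exp(1i * theta)))
  Z <- n * R^2
  exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
               (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
}

# Cross-spectrum-set fixture: per-trial amplitude/phase model shared by both
# alignment events (exchangeable null) or with a phase-locked "beta" event.
make_cs <- function(n_trials = 30L, n_freqs = 23L, locked = FALSE,
                    lock_phase = pi / 2, lock_jitter = 0.1) {
  draw <- function(phase = NULL, jitter = 0.3) {
    ph <- phase %||% stats::runif(n_trials, 0, 2 * pi)
    jit <- matrix(stats::rnorm(n_trials * n_freqs, 0, jitter), n_trials, n_freqs)
    amp <- matrix(stats::rexp(n_trials * n_freqs) + 0.2, n_trials, n_freqs)
    matrix(complex(modulus = amp, argument = ph + jit), n_trials, n_freqs)
  }
  at_beta <- if (locked) {
    draw(phase = stats::rnorm(n_trials, lock_phase, lock_jitter))
  } else {
    draw()
  }
  structure(
    list(at_start = draw(), at_beta = at_beta,
         freqs = seq(17, by = 0.5, length.out = n_freqs),
         trial_ids = seq_len(n_trials), pair = c("a", "b")),
    class = "cross_spectrum_set"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

unwrap_phase <- function(p) {
  dp <- diff(p)
  dp <- ((dp + pi) %% (2 * pi)) - pi
  cumsum(c(p[1L], dp))
}

# Small fast session config: fs = 200 (no resampling cost, no artifacts).
fast_config <- function(...) {
  sim_config(fs = 200, ...)
}

# Hand-built trial table with a chosen odor/correct pattern.
toy_trials <- function(n, odors = rep(c("A", "B"), length.out = n),
                       correct = rep(TRUE, n), spacing = 10, duration = 1) {
  starts <- 10 + (seq_len(n) - 1L) * spacing
  df <- data.frame(trial = seq_len(n), nose_poke_start = starts,
                   nose_poke_end = starts + duration, odor = odors,
                   side = ifelse(correct, "L", "R"), correct = correct,
                   stringsAsFactors = FALSE)
  df$licks <- replicate(n, matrix(numeric(0), ncol = 2L), simplify = FALSE)
  df
}

# Artifact mask with given epochs (matrix or vector pairs).
toy_mask <- function(epochs, channel = "AP") {
  ep <- if (is.null(epochs)) {
    matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  } else {
    matrix(epochs, ncol = 2L, byrow = TRUE, dimnames = list(NULL, c("start", "end")))
  }
  structure(list(channel = channel, epochs = ep, threshold = 1,
                 band = c(90, 250), fs = 1000), class = "artifact_mask")
}
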