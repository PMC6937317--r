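#' Debiased WPLI-squared functional connectivity
#'
#' Phase synchronization between structure pairs is measured with the
#' weighted phase lag index (WPLI), built from the imaginary part of the
#' per-trial cross-spectral density and therefore blind to instantaneous
#' (volume-conducted) interactions:
#' \deqn{WPLI = |E[I(S_{12})]| / E[|I(S_{12})|]}
#' Because sensitivity depends on trial count, the production estimator is
#' the debiased WPLI-square,
#' \deqn{WPLI^2 = \frac{\sum_k \sum_{j \ne k} I(S_k) I(S_j)}
#'                     {\sum_k \sum_{j \ne k} |I(S_k) I(S_j)|}}
#' which has expectation ~0 for independent phases at any N (and can go
#' slightly negative). The pipeline computes the connectivity increase
#' from nose-poke start to the per-trial time of maximal beta amplitude
#' and tests it with a band-maximum surrogate statistic.
#'
#' @name connectivity
NULL

#' Select the standard trial window (11th-40th clean trial)
#'
#' @param trials trial table.
#' @param excluded integer vector of artifact-excluded trial indices.
#' @return the 11th through 40th non-excluded trial indices, in session
#'   order (30 trials). Errors when fewer than 40 clean trials exist.
#' @export
select_trials <- function(trials, excluded = integer(0)) {
  clean <- trials$trial[!(trials$trial %in% excluded)]
  if (length(clean) < 40L) {
    stop("need >= 40 artifact-free trials, have ", length(clean),
         " (short by ", 40L - length(clean), ")")
  }
  clean[11L:40L]
}

#' Weighted phase lag index at one frequency
#'
#' @param s12 complex per-trial cross-spectra (or their imaginary parts)
#'   at a single frequency.
#' @return index in `[0, 1]`, or `NA` when every imaginary part is
#'   exactly zero (undefined: purely instantaneous coupling).
#' @export
wpli <- function(s12) {
  if (length(s12) < 2L) stop("wpli needs at least 2 trials")
  I <- if (is.complex(s12)) Im(s12) else s12
  den <- mean(abs(I))
  if (den == 0) return(NA_real_)
  abs(mean(I)) / den
}

#' Debiased WPLI-squared at one frequency
#'
#' Production path uses the O(N) algebraic identity
#' `((sum I)^2 - sum I^2) / ((sum |I|)^2 - sum I^2)`, exactly equal to the
#' pairwise double sum over `j != k`.
#'
#' @inheritParams wpli
#' @return debiased index in `[-1, 1]` (negative values are legitimate
#'   debiasing output), or `NA` when the denominator vanishes.
#' @export
debiased_wpli2 <- function(s12) {
  if (length(s12) < 2L) stop("debiased_wpli2 needs at least 2 trials")
  I <- if (is.complex(s12)) Im(s12) else s12
  si <- sum(I); si2 <- sum(I^2); sa <- sum(abs(I))
  den <- sa^2 - si2
  if (den == 0) return(NA_real_)
  (si^2 - si2) / den
}

# O(N^2) reference implementation of the printed double sum (test oracle
# and documentation of the definition; not used on the production path).
debiased_wpli2_pairwise <- function(s12) {
  I <- if (is.complex(s12)) Im(s12) else s12
  n <- length(I)
  num <- den <- 0
  for (k in seq_len(n)) {
    for (j in seq_len(n)[-k]) {
      num <- num + I[k] * I[j]
      den <- den + abs(I[k] * I[j])
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

#' Event-locked cross-spectra for one structure pair
#'
#' The cross-spectral density of a trial at an alignment event is the
#' wavelet coefficient of channel `a` times the conjugate coefficient of
#' channel `b` at the single time point of the event.
#'
#' @param tfmap_a,tfmap_b [morlet_tfmap()] of the two channels on a
#'   common grid.
#' @param start_times,beta_times per-trial event times (s): nose-poke
#'   start and time of maximal beta amplitude.
#' @param trial_ids trial indices the rows correspond to.
#' @param pair character pair of structure labels.
#' @return object of class `cross_spectrum_set`: complex matrices
#'   `at_start`, `at_beta` (trial x frequency), `freqs`, `trial_ids`,
#'   `pair`.
#' @export
event_cross_spectra <- function(tfmap_a, tfmap_b, start_times, beta_times,
                                trial_ids, pair = c("a", "b")) {
  stopifnot(length(start_times) == length(beta_times),
            length(start_times) == length(trial_ids))
  i_start <- tfmap_time_index(tfmap_a, start_times)
  i_beta <- tfmap_time_index(tfmap_a, beta_times)
  cs <- function(idx) tfmap_a$coeffs[idx, , drop = FALSE] *
    Conj(tfmap_b$coeffs[idx, , drop = FALSE])
  structure(
    list(at_start = cs(i_start), at_beta = cs(i_beta),
         freqs = tfmap_a$freqs, trial_ids = trial_ids, pair = pair),
    class = "cross_spectrum_set"
  )
}

#' Per-frequency WPLI-squared difference between alignment events
#'
#' @param cs a `cross_spectrum_set`.
#' @return list with per-frequency `wpli2_start`, `wpli2_beta`, `diff`
#'   (`beta - start`) and `max_diff` over the band.
#' @export
wpli2_difference <- function(cs) {
  w_start <- apply(cs$at_start, 2L, debiased_wpli2)
  w_beta <- apply(cs$at_beta, 2L, debiased_wpli2)
  d <- w_beta - w_start
  list(freqs = cs$freqs, wpli2_start = w_start, wpli2_beta = w_beta,
       diff = d, max_diff = max(d, na.rm = TRUE))
}

# Vectorized debiased WPLI^2 from per-surrogate column sums.
# si, si2, sa: n_surrogate x n_freq matrices of sum(I), sum(I^2), sum(|I|).
wpli2_from_sums <- function(si, si2, sa) {
  den <- sa^2 - si2
  out <- (si^2 - si2) / den
  out[den == 0] <- NA_real_
  out
}

#' Surrogate max-statistic test of the connectivity increase
#'
#' Tests whether the band-maximum of the WPLI-squared difference
#' (time-of-maximal-beta minus nose-poke-start) exceeds chance, following
#' the two-condition nonparametric framework of Maris & Fries: each
#' surrogate randomly exchanges, per trial (all frequencies together), the
#' cross-spectra of the two alignment events, the difference's band
#' maximum is recomputed, and the p-value is the fraction of surrogate
#' maxima strictly above the observed maximum. Using the band maximum
#' corrects for the multiple frequencies tested.
#'
#' @param cs a `cross_spectrum_set` (both events over identical trials).
#' @param n_surrogates number of random exchanges, default 2000.
#' @param seed RNG seed (the test is deterministic given the seed).
#' @param smoothed if `TRUE`, return `(b + 1) / (n + 1)` instead of the
#'   raw fraction, guaranteeing a positive p-value.
#' @param pooled if `TRUE`, surrogates reshuffle the pooled set of 2N
#'   cross-spectra into two groups instead of exchanging within trials.
#' @return list: `p`, `observed_max`, `surrogate_max` (vector),
#'   `n_trials`, `n_surrogates`.
#' @export
surrogate_test <- function(cs, n_surrogates = 2000L, seed = 1L,
                           smoothed = FALSE, pooled = FALSE) {
  if (n_surrogates < 100L) {
    warning("n_surrogates < 100: p-value resolution too coarse for alpha = 0.01")
  }
  IA <- Im(cs$at_beta) # trial x freq
  IB <- Im(cs$at_start)
  n_tr <- nrow(IA)
  obs <- max(wpli2_from_sums(
    rbind(colSums(IA)), rbind(colSums(IA^2)), rbind(colSums(abs(IA)))
  ) - wpli2_from_sums(
    rbind(colSums(IB)), rbind(colSums(IB^2)), rbind(colSums(abs(IB)))
  ), na.rm = TRUE)
  surr_max <- with_seed(seed, {
    if (!pooled) {
      # per-trial exchange: M[s, t] = 1 keeps trial t's labels, 0 swaps them
      M <- matrix(stats::runif(n_surrogates * n_tr) < 0.5, n_surrogates, n_tr)
      sums_for <- function(X, Y) {
        # group "beta" takes X where kept, Y where swapped
        list(si = M %*% X + (!M) %*% Y,
             si2 = M %*% X^2 + (!M) %*% Y^2,
             sa = M %*% abs(X) + (!M) %*% abs(Y))
      }
      ga <- sums_for(IA, IB)
      gb <- sums_for(IB, IA)
      d <- wpli2_from_sums(ga$si, ga$si2, ga$sa) -
        wpli2_from_sums(gb$si, gb$si2, gb$sa)
      apply(d, 1L, max, na.rm = TRUE)
    } else {
      pool <- rbind(IA, IB)
      vapply(seq_len(n_surrogates), function(s) {
        pick <- sample.int(2L * n_tr, n_tr)
        X <- pool[pick, , drop = FALSE]
        Y <- pool[-pick, , drop = FALSE]
        max(wpli2_from_sums(rbind(colSums(X)), rbind(colSums(X^2)),
                            rbind(colSums(abs(X)))) -
              wpli2_from_sums(rbind(colSums(Y)), rbind(colSums(Y^2)),
                              rbind(colSums(abs(Y)))), na.rm = TRUE)
      }, numeric(1))
    }
  })
  b <- sum(surr_max > obs)
  p <- if (smoothed) (b + 1) / (n_surrogates + 1) else b / n_surrogates
  list(p = p, observed_max = obs, surrogate_max = surr_max,
       n_trials = n_tr, n_surrogates = as.integer(n_surrogates))
}

#' Connectivity for every structure pair of one session
#'
#' Resamples and decomposes each channel, locates the per-trial time of
#' maximal beta amplitude from the MAD-normalized structure-average map,
#' selects the 11th-40th clean trials, and runs the WPLI-squared
#' difference + surrogate test for every unordered structure pair.
#'
#' @param recording a `session_recording`.
#' @param masks per-channel `artifact_mask` list (connectivity exclusion
#'   windows are applied).
#' @param n_surrogates surrogates per pair.
#' @param seed master seed; each pair uses a derived child seed.
#' @param analysis_fs,freqs,sigma analysis grid parameters.
#' @param exclude structures excluded from the time-of-max average.
#' @return `data.frame` with one row per pair: `structure_a`,
#'   `structure_b`, `max_diff`, `p_surrogate`, `n_trials`; per-frequency
#'   curves attached as a list column `curves`.
#' @export
session_connectivity <- function(recording, masks = list(),
                                 n_surrogates = 2000L, seed = 1L,
                                 analysis_fs = 200, freqs = beta_freq_grid(),
                                 sigma = 5 * pi, exclude = c("Hipp", "Cereb")) {
  chans <- colnames(recording$signals)
  if (length(chans) < 2L) stop("need at least 2 channels for connectivity")
  ds <- lapply(chans, function(ch) {
    resample_signal(recording$signals[, ch], recording$fs, analysis_fs)
  })
  names(ds) <- chans
  tfmaps <- lapply(ds, morlet_tfmap, fs = analysis_fs, freqs = freqs, sigma = sigma)
  excluded <- excluded_trials_connectivity(recording$trials, masks)
  ids <- select_trials(recording$trials, excluded)
  rows <- match(ids, recording$trials$trial)
  beta_times <- vapply(rows, function(r) {
    time_of_max_beta(tfmaps, ds, recording$trials[r, , drop = FALSE],
                     exclude = exclude)
  }, numeric(1))
  start_times <- recording$trials$nose_poke_start[rows]
  pairs <- utils::combn(chans, 2L)
  out <- vector("list", ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    cs <- event_cross_spectra(tfmaps[[a]], tfmaps[[b]], start_times,
                              beta_times, ids, pair = c(a, b))
    st <- surrogate_test(cs, n_surrogates = n_surrogates,
                         seed = child_seed(seed, k))
    out[[k]] <- data.frame(structure_a = a, structure_b = b,
                           max_diff = st$observed_max, p_surrogate = st$p,
                           n_trials = st$n_trials, stringsAsFactors = FALSE)
    out[[k]]$curves <- list(wpli2_difference(cs))
  }
  do.call(rbind, out)
}

#' Network summary of a session's pairwise connectivity
#'
#' @param results `data.frame` from [session_connectivity()] (columns
#'   `structure_a`, `structure_b`, `p_surrogate`).
#' @param alpha significance level, default 0.01.
#' @return list: `pair_significant` (data.frame with `significant` flag),
#'   `structure_proportion` (named vector: per structure, the proportion
#'   of its pairs that are significant), `hub_index` (proportion of
#'   significant pairs among all tested pairs).
#' @export
network_summary <- function(results, alpha = 0.01) {
  if (is.null(results) || nrow(results) == 0L) stop("no connectivity results to summarize")
  sig <- results$p_surrogate < alpha
  structs <- sort(unique(c(results$structure_a, results$structure_b)))
  prop <- vapply(structs, function(s) {
    on <- results$structure_a == s | results$structure_b == s
    mean(sig[on])
  }, numeric(1))
  list(
    pair_significant = data.frame(structure_a = results$structure_a,
                                  structure_b = results$structure_b,
                                  p_surrogate = results$p_surrogate,
                                  significant = sig, stringsAsFactors = FALSE),
    structure_proportion = prop,
    hub_index = mean(sig),
    alpha = alpha
  )
}
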