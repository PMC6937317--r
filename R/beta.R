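#' Per-trial normalized beta amplitude
#'
#' The headline measure of the pipeline. For each trial, the raw beta
#' amplitude is the time-average over `[nose_poke_end - 0.4, nose_poke_end
#' + 0.1]` s of the per-time-point maximum wavelet amplitude across the
#' 17-28 Hz grid. It is normalized by a per-trial baseline: the median of
#' the same measure over clean non-overlapping 500 ms periods inside a
#' 240 s window centered on nose-poke start, excluding other trials' nose
#' pokes and all lick intervals (each extended by 200 ms) and artifact
#' epochs (extended by 2 s). The reported *beta amplitude* is the natural
#' logarithm of the raw/baseline ratio: 0 means no change from baseline.
#'
#' @name beta_amplitude
NULL

# Mean of the frequency-max amplitude over [t0, t1] (closed window, grid
# indices). `fmax` is the precomputed per-time frequency-max series.
window_mean_fmax <- function(fmax, fs, t0, t1, n_time) {
  i0 <- as.integer(round(t0 * fs)) + 1L
  i1 <- as.integer(round(t1 * fs)) + 1L
  if (i0 < 1L || i1 > n_time) stop("analysis window [", t0, ", ", t1, "] s extends beyond the recording")
  mean(fmax[i0:i1])
}

#' Raw beta amplitude of one trial
#'
#' @param tfmap a [morlet_tfmap()] on the beta grid covering the trial
#'   window.
#' @param nose_poke_end trial nose-poke end time (s).
#' @param window window relative to nose-poke end (s), default
#'   `c(-0.4, 0.1)`.
#' @return scalar amplitude in wavelet units.
#' @export
trial_raw_beta <- function(tfmap, nose_poke_end, window = c(-0.4, 0.1)) {
  fmax <- tfmap_freqmax(tfmap)
  window_mean_fmax(fmax, tfmap$fs, nose_poke_end + window[1L],
                   nose_poke_end + window[2L], length(fmax))
}

#' Baseline beta amplitude of one trial
#'
#' Tiles the (recording-clipped) 240 s window centered on the trial's
#' nose-poke start with non-overlapping 500 ms periods anchored at the
#' window's left edge (partial trailing period dropped), discards periods
#' intersecting any *other* trial's nose-poke interval or any lick
#' interval extended by 200 ms, or any artifact epoch extended by 2 s,
#' and returns the median of the per-period frequency-max/time-average
#' amplitudes.
#'
#' @param tfmap a [morlet_tfmap()] on the beta grid.
#' @param trial one row of the trial table.
#' @param trials full trial table (for other nose pokes and licks).
#' @param epochs artifact epoch matrix (`[start, end)` s), possibly 0-row.
#' @param window_length baseline window length (s), default 240.
#' @param period period length (s), default 0.5.
#' @return list `(baseline, n_periods)`; `baseline` is `NA` (flagged
#'   undefined) when no period survives.
#' @export
trial_baseline <- function(tfmap, trial, trials, epochs = NULL,
                           window_length = 240, period = 0.5) {
  fmax <- tfmap_freqmax(tfmap)
  trial_baseline_fmax(fmax, tfmap$fs, length(fmax), trial, trials, epochs,
                      window_length, period)
}

# Same, from a precomputed frequency-max series (fast path for sessions).
trial_baseline_fmax <- function(fmax, fs, n_time, trial, trials, epochs,
                                window_length = 240, period = 0.5) {
  dur <- n_time / fs
  w0 <- max(0, trial$nose_poke_start - window_length / 2)
  w1 <- min(dur, trial$nose_poke_start + window_length / 2)
  n_per <- floor((w1 - w0) / period)
  if (n_per < 1L) return(list(baseline = NA_real_, n_periods = 0L))
  p_start <- w0 + (seq_len(n_per) - 1L) * period
  p_end <- p_start + period

  other <- trials[trials$trial != trial$trial, , drop = FALSE]
  ex_start <- other$nose_poke_start - 0.2
  ex_end <- other$nose_poke_end + 0.2
  lick_mat <- do.call(rbind, trials$licks)
  if (!is.null(lick_mat) && nrow(lick_mat)) {
    ex_start <- c(ex_start, lick_mat[, 1L] - 0.2)
    ex_end <- c(ex_end, lick_mat[, 2L] + 0.2)
  }
  if (!is.null(epochs) && nrow(epochs)) {
    ex_start <- c(ex_start, epochs[, 1L] - 2)
    ex_end <- c(ex_end, epochs[, 2L] + 2)
  }
  keep <- vapply(seq_len(n_per), function(i) {
    !any(intervals_overlap(p_start[i], p_end[i], ex_start, ex_end))
  }, logical(1))
  if (!any(keep)) return(list(baseline = NA_real_, n_periods = 0L))
  amps <- vapply(which(keep), function(i) {
    i0 <- as.integer(round(p_start[i] * fs)) + 1L
    i1 <- min(as.integer(round(p_end[i] * fs)), n_time)
    mean(fmax[i0:i1])
  }, numeric(1))
  list(baseline = stats::median(amps), n_periods = sum(keep))
}

#' Per-trial beta measures for a whole session
#'
#' For each channel: resample to the analysis rate, decompose on the beta
#' grid, then compute raw amplitude, baseline and log-normalized beta
#' amplitude per trial. Trials excluded by [excluded_trials_beta()] (or
#' with an undefined baseline) carry `NA` measures and an `excluded` /
#' `undefined` flag.
#'
#' @param recording a `session_recording`.
#' @param masks list of per-channel `artifact_mask` (may be empty).
#' @param analysis_fs analysis sampling rate (Hz), default 200.
#' @param freqs beta frequency grid, default [beta_freq_grid()].
#' @param sigma wavelet parameter, default `5 * pi`.
#' @param channels channels to analyze (default all in the recording).
#' @return `data.frame` with one row per structure x trial: `structure`,
#'   `trial`, `raw`, `baseline`, `beta_amplitude`, `n_baseline_periods`,
#'   `excluded`, `undefined`.
#' @export
compute_session_beta <- function(recording, masks = list(), analysis_fs = 200,
                                 freqs = beta_freq_grid(), sigma = 5 * pi,
                                 channels = NULL) {
  channels <- channels %||% colnames(recording$signals)
  missing_ch <- setdiff(channels, colnames(recording$signals))
  if (length(missing_ch)) {
    warning("missing channel(s) skipped: ", paste(missing_ch, collapse = ", "))
    channels <- setdiff(channels, missing_ch)
  }
  trials <- recording$trials
  excluded <- excluded_trials_beta(trials, masks)
  out <- vector("list", length(channels))
  for (ci in seq_along(channels)) {
    ch <- channels[ci]
    x <- resample_signal(recording$signals[, ch], recording$fs, analysis_fs)
    tfm <- morlet_tfmap(x, analysis_fs, freqs, sigma = sigma)
    fmax <- tfmap_freqmax(tfm)
    n_time <- length(fmax)
    ep <- if (length(masks)) pooled_epochs(masks) else NULL
    raw <- baseline <- beta <- rep(NA_real_, nrow(trials))
    n_per <- integer(nrow(trials))
    for (i in seq_len(nrow(trials))) {
      if (trials$trial[i] %in% excluded) next
      raw[i] <- window_mean_fmax(fmax, analysis_fs,
                                 trials$nose_poke_end[i] - 0.4,
                                 trials$nose_poke_end[i] + 0.1, n_time)
      bl <- trial_baseline_fmax(fmax, analysis_fs, n_time,
                                trials[i, , drop = FALSE], trials, ep)
      baseline[i] <- bl$baseline
      n_per[i] <- bl$n_periods
      if (!is.na(bl$baseline) && bl$baseline > 0) {
        beta[i] <- log(raw[i] / bl$baseline)
      }
    }
    out[[ci]] <- data.frame(
      structure = ch, trial = trials$trial, raw = raw, baseline = baseline,
      beta_amplitude = beta, n_baseline_periods = n_per,
      excluded = trials$trial %in% excluded,
      undefined = !(trials$trial %in% excluded) & is.na(beta),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Group trials into 20-trial blocks balanced by odor
#'
#' Greedy scan: the n-th presentation of an odor goes to block
#' `ceiling(n / 10)`, so each complete block holds exactly 10 trials of
#' each odor, as contiguous as the pseudo-random odor order permits.
#' Blocks missing a full 10+10 complement are dropped.
#'
#' @param trials trial table.
#' @param measures optional output of [compute_session_beta()] for
#'   per-block median beta amplitudes.
#' @return `data.frame` with one row per block (x structure when
#'   `measures` given): `block`, `performance`, `n_trials`, plus
#'   `structure` and `median_beta` when measures are supplied. The member
#'   trial indices are attached as a list column `trials`.
#' @export
make_blocks <- function(trials, measures = NULL) {
  odors <- trials$odor
  occ <- stats::ave(seq_along(odors), odors, FUN = seq_along)
  block <- ceiling(occ / 10)
  counts <- table(block, odors)
  complete <- as.integer(rownames(counts))[apply(counts, 1L, function(r) all(r == 10))]
  if (!length(complete)) {
    out <- data.frame(block = integer(0), performance = numeric(0),
                      n_trials = integer(0))
    out$trials <- list()
    return(out)
  }
  complete <- sort(complete)
  rows <- lapply(complete, function(b) {
    member <- trials$trial[block == b]
    data.frame(block = b,
               performance = mean(trials$correct[block == b]),
               n_trials = length(member))
  })
  out <- do.call(rbind, rows)
  out$trials <- lapply(complete, function(b) trials$trial[block == b])
  if (is.null(measures)) return(out)
  per_struct <- lapply(unique(measures$structure), function(s) {
    ms <- measures[measures$structure == s, ]
    o <- out
    o$structure <- s
    o$median_beta <- vapply(o$trials, function(tt) {
      stats::median(ms$beta_amplitude[ms$trial %in% tt], na.rm = TRUE)
    }, numeric(1))
    o
  })
  do.call(rbind, per_struct)
}

#' Time of maximal beta amplitude for one trial
#'
#' Each eligible structure's time-frequency amplitude map is normalized by
#' the raw MAD of its (downsampled) signal, the normalized maps are
#' averaged across structures, and the time of the global maximum over the
#' beta grid is located in the window from `max(nose_poke_end - 0.4,
#' nose_poke_start)` to `nose_poke_end + 0.1` (the window start falls back
#' to trial start for trials shorter than 400 ms). Hippocampus and
#' cerebellum are excluded by default (no task beta). Ties break toward
#' the earliest time and lowest frequency.
#'
#' @param tfmaps named list of per-structure [morlet_tfmap()] at the
#'   analysis rate.
#' @param raw_signals named list/matrix of the corresponding downsampled
#'   voltage series (for MAD normalization).
#' @param trial one row of the trial table.
#' @param exclude structures ineligible for the average, default
#'   `c("Hipp", "Cereb")`.
#' @return time (s) of maximal normalized beta amplitude.
#' @export
time_of_max_beta <- function(tfmaps, raw_signals, trial,
                             exclude = c("Hipp", "Cereb")) {
  eligible <- setdiff(names(tfmaps), exclude)
  if (!length(eligible)) stop("no eligible structures for time_of_max_beta")
  tfm1 <- tfmaps[[eligible[1L]]]
  fs <- tfm1$fs
  t0 <- max(trial$nose_poke_end - 0.4, trial$nose_poke_start)
  t1 <- trial$nose_poke_end + 0.1
  i0 <- as.integer(round(t0 * fs)) + 1L
  i1 <- min(as.integer(round(t1 * fs)) + 1L, length(tfm1$times))
  acc <- 0
  for (s in eligible) {
    m <- if (is.matrix(raw_signals)) raw_signals[, s] else raw_signals[[s]]
    acc <- acc + Mod(tfmaps[[s]]$coeffs[i0:i1, , drop = FALSE]) / mad_raw(m)
  }
  flat <- which.max(acc) # column-major: earliest time within lowest freq first
  t_idx <- (flat - 1L) %% nrow(acc) + 1L
  tfm1$times[i0 + t_idx - 1L]
}
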