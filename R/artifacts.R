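#' High-frequency movement artifact detection
#'
#' Brief broadband transients (head bumps, abrupt movements) concentrate
#' energy above 90 Hz. They are detected per channel, at the native sampling
#' rate, by thresholding the frequency-averaged 90-250 Hz wavelet power at
#' `median + 25 * MAD` of its own time course (raw MAD, no consistency
#' factor). The extreme multiplier makes the detector insensitive to
#' ongoing physiological activity while catching transients tens of times
#' the background RMS.
#'
#' @param x numeric voltage series at native sampling rate (no
#'   downsampling before detection).
#' @param fs sampling rate in Hz; must exceed 500 Hz so the 90-250 Hz
#'   band sits below Nyquist.
#' @param band detection band in Hz, default `c(90, 250)`.
#' @param n_freqs number of linearly spaced wavelet frequencies spanning
#'   the band (default 20).
#' @param sigma wavelet parameter for the detection map (default `3 * pi`,
#'   broader in frequency / sharper in time than the analysis value).
#' @param mad_mult threshold multiplier (default 25).
#' @param channel optional structure label stored in the mask.
#' @return object of class `artifact_mask`: list with `channel`, `epochs`
#'   (matrix of half-open `[start, end)` intervals in seconds, possibly
#'   0-row), `threshold`, `band`, `fs`.
#' @export
detect_artifacts <- function(x, fs, band = c(90, 250), n_freqs = 20L,
                             sigma = 3 * pi, mad_mult = 25, channel = NA_character_) {
  if (fs <= 500) stop("fs must exceed 500 Hz for 90-250 Hz artifact detection (got ", fs, ")")
  freqs <- seq(band[1L], band[2L], length.out = n_freqs)
  tfm <- morlet_tfmap(x, fs, freqs, sigma = sigma)
  pw <- rowMeans(Mod(tfm$coeffs)^2)
  med <- stats::median(pw)
  thr <- med + mad_mult * mad_raw(pw)
  above <- pw > thr
  epochs <- if (any(above)) {
    runs <- true_runs(above)
    cbind(start = (runs[, 1L] - 1L) / fs, end = runs[, 2L] / fs)
  } else {
    matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
  }
  structure(
    list(channel = channel, epochs = epochs, threshold = thr,
         band = band, fs = fs),
    class = "artifact_mask"
  )
}

#' @export
print.artifact_mask <- function(x, ...) {
  cat(sprintf("<artifact_mask> channel %s: %d epoch(s), threshold %.4g\n",
              x$channel, nrow(x$epochs), x$threshold))
  invisible(x)
}

# Pool epochs from a list of artifact_mask objects into one matrix.
pooled_epochs <- function(masks) {
  eps <- lapply(masks, function(m) m$epochs)
  eps <- eps[vapply(eps, nrow, integer(1)) > 0L]
  if (!length(eps)) {
    return(matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  do.call(rbind, eps)
}

#' Trials excluded from beta amplitude analysis
#'
#' A trial is excluded iff any channel has an artifact epoch intersecting
#' the 2.5 s window starting 1 s before nose-poke start, i.e.
#' `[nose_poke_start - 1, nose_poke_start + 1.5)`. Intersection is
#' half-open, so an epoch ending exactly at the window start does not
#' exclude.
#'
#' @param trials trial table (`data.frame` with at least `trial`,
#'   `nose_poke_start`).
#' @param masks list of `artifact_mask` objects (one per channel).
#' @return integer vector of excluded trial indices (values of
#'   `trials$trial`).
#' @export
excluded_trials_beta <- function(trials, masks) {
  win_start <- trials$nose_poke_start - 1
  win_end <- trials$nose_poke_start + 1.5
  excluded_by_windows(trials, masks, win_start, win_end)
}

#' Trials excluded from connectivity analysis
#'
#' A trial is excluded iff any artifact epoch on any channel intersects a
#' 2 s window centered on nose-poke start or on nose-poke end
#' (`[event - half_width, event + half_width)` with `half_width = 1` s by
#' default). The centering of the "2-second window around" each event is
#' configurable via `half_width`.
#'
#' @inheritParams excluded_trials_beta
#' @param half_width half-width of the window around each event (s).
#' @return integer vector of excluded trial indices.
#' @export
excluded_trials_connectivity <- function(trials, masks, half_width = 1) {
  win_start <- c(trials$nose_poke_start - half_width, trials$nose_poke_end - half_width)
  win_end <- c(trials$nose_poke_start + half_width, trials$nose_poke_end + half_width)
  tid <- c(trials$trial, trials$trial)
  ep <- pooled_epochs(masks)
  if (nrow(ep) == 0L) return(integer(0))
  hit <- vapply(seq_along(win_start), function(i) {
    any(intervals_overlap(ep[, 1L], ep[, 2L], win_start[i], win_end[i]))
  }, logical(1))
  sort(unique(tid[hit]))
}

excluded_by_windows <- function(trials, masks, win_start, win_end) {
  ep <- pooled_epochs(masks)
  if (nrow(ep) == 0L) return(integer(0))
  hit <- vapply(seq_along(win_start), function(i) {
    any(intervals_overlap(ep[, 1L], ep[, 2L], win_start[i], win_end[i]))
  }, logical(1))
  sort(unique(trials$trial[hit]))
}

#' Export artifact masks as a tidy table
#'
#' @param masks list of `artifact_mask` objects.
#' @return `data.frame` with columns channel, start, end, threshold.
#' @export
masks_to_table <- function(masks) {
  rows <- lapply(masks, function(m) {
    if (nrow(m$epochs) == 0L) return(NULL)
    data.frame(channel = m$channel, start = m$epochs[, 1L],
               end = m$epochs[, 2L], threshold = m$threshold)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(channel = character(0), start = numeric(0),
                      end = numeric(0), threshold = numeric(0)))
  }
  do.call(rbind, rows)
}
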