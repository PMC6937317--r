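#' Simulation configuration
#'
#' Describes one synthetic recording session of the two-alternative choice
#' odor discrimination task: multichannel 1/f background noise, a
#' respiration-locked slow component on olfactory channels, beta bursts
#' with Gaussian envelopes ending near nose-poke end whose per-trial gain
#' is controllable, optional cross-channel burst phase coupling, and brief
#' broadband movement artifacts.
#'
#' @param structures character vector of channel labels; conventional brain
#'   structure names are OB, AP, PP, OT, Stri, Hipp, Cereb. Hipp and Cereb
#'   never receive beta bursts (they show no task beta in vivo).
#' @param fs sampling rate in Hz, `>= 200` (`> 500` required when
#'   artifacts are simulated).
#' @param n_trials trials per session (real sessions run ~80-100).
#' @param trial_duration_range min/max odor sampling duration in seconds;
#'   max must be `< 2` (trials longer than 2 s do not occur in the task).
#' @param inter_trial_interval_min minimum inter-trial interval (s),
#'   `>= 7` as imposed by the task apparatus.
#' @param noise_exponent slope alpha of the 1/f^alpha background.
#' @param respiration_freq respiration rate in Hz (~2 Hz at rest).
#' @param beta_freq burst carrier frequency in Hz, inside 17-28.
#' @param burst_envelope_sd Gaussian envelope SD in seconds.
#' @param burst_center_offset envelope center relative to nose-poke end
#'   (s); the default -0.15 places burst energy inside the
#'   `[-400, +100]` ms analysis window.
#' @param burst_amp burst peak amplitude at gain 1, in multiples of the
#'   background noise RMS.
#' @param burst_gain default dimensionless per-trial gain multiplier
#'   (`>= 0`); a schedule can be passed to [generate_session()].
#' @param coupled_pairs `data.frame(a, b, offset, jitter)` of structure
#'   pairs whose burst phases are locked: channel `b`'s burst phase equals
#'   channel `a`'s minus `offset` (radians) plus `N(0, jitter^2)` noise, so
#'   the cross-spectrum `S_ab` of a coupled pair has phase `offset`.
#' @param artifact_rate broadband artifact events per minute.
#' @param artifact_amplitude artifact RMS in multiples of background RMS.
#' @param latent_performance default probability correct per trial.
#' @param seed integer RNG seed; identical config + seed gives
#'   bit-identical sessions.
#' @return object of class `sim_config` (validated list).
#' @export
sim_config <- function(structures = c("OB", "AP", "PP", "Stri"),
                       fs = 1000,
                       n_trials = 80L,
                       trial_duration_range = c(0.5, 1.9),
                       inter_trial_interval_min = 7,
                       noise_exponent = 1,
                       respiration_freq = 2,
                       beta_freq = 25,
                       burst_envelope_sd = 0.12,
                       burst_center_offset = -0.15,
                       burst_amp = 2,
                       burst_gain = 1,
                       coupled_pairs = NULL,
                       artifact_rate = 0,
                       artifact_amplitude = 20,
                       latent_performance = 0.8,
                       seed = 1L) {
  cfg <- list(
    structures = structures, fs = fs, n_trials = as.integer(n_trials),
    trial_duration_range = trial_duration_range,
    inter_trial_interval_min = inter_trial_interval_min,
    noise_exponent = noise_exponent, respiration_freq = respiration_freq,
    beta_freq = beta_freq, burst_envelope_sd = burst_envelope_sd,
    burst_center_offset = burst_center_offset, burst_amp = burst_amp,
    burst_gain = burst_gain, coupled_pairs = coupled_pairs,
    artifact_rate = artifact_rate, artifact_amplitude = artifact_amplitude,
    latent_performance = latent_performance, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fail <- function(field, msg) stop("invalid sim_config field `", field, "`: ", msg, call. = FALSE)
  if (anyDuplicated(cfg$structures)) fail("structures", "labels must be unique")
  if (cfg$fs < 200) fail("fs", "must be >= 200 Hz")
  if (cfg$artifact_rate > 0 && cfg$fs <= 500) {
    fail("fs", "must exceed 500 Hz when artifacts are simulated")
  }
  if (cfg$n_trials < 1L) fail("n_trials", "must be >= 1")
  tdr <- cfg$trial_duration_range
  if (length(tdr) != 2L || tdr[1L] <= 0 || tdr[1L] > tdr[2L]) {
    fail("trial_duration_range", "must be increasing positive (min, max)")
  }
  if (tdr[2L] >= 2) fail("trial_duration_range", "max must be < 2 s")
  if (cfg$inter_trial_interval_min < 7) fail("inter_trial_interval_min", "must be >= 7 s")
  if (cfg$beta_freq < 17 || cfg$beta_freq > 28) fail("beta_freq", "must lie in [17, 28] Hz")
  if (cfg$beta_freq >= 100) fail("beta_freq", "must be below Nyquist of the 200 Hz analysis rate")
  if (cfg$burst_gain < 0) fail("burst_gain", "must be >= 0")
  if (cfg$burst_envelope_sd <= 0) fail("burst_envelope_sd", "must be positive")
  if (cfg$artifact_amplitude <= 0) fail("artifact_amplitude", "must be positive")
  if (!is.null(cfg$coupled_pairs)) {
    cp <- cfg$coupled_pairs
    need <- c("a", "b", "offset", "jitter")
    if (!is.data.frame(cp) || !all(need %in% names(cp))) {
      fail("coupled_pairs", "must be a data.frame with columns a, b, offset, jitter")
    }
    if (!all(c(cp$a, cp$b) %in% cfg$structures)) {
      fail("coupled_pairs", "pair members must be listed in structures")
    }
  }
  invisible(cfg)
}

# Channels that carry beta bursts / the respiration component.
beta_structures <- function(structures) setdiff(structures, c("Hipp", "Cereb"))
olfactory_structures <- function(structures) intersect(structures, c("OB", "AP", "PP", "OT"))

# 1/f^alpha Gaussian noise with unit RMS, by spectral shaping of white noise.
noise_1f <- function(n, fs, alpha) {
  w <- stats::rnorm(n)
  if (alpha == 0) return(w)
  # shape at the next 2-3-5-smooth length (mixed-radix FFT stays fast for
  # arbitrary session lengths), then truncate
  m <- stats::nextn(n)
  X <- stats::fft(c(w, numeric(m - n)))
  k <- 0:(m - 1L)
  f <- pmin(k, m - k) * fs / m # |frequency| per bin
  H <- c(0, f[-1L]^(-alpha / 2)) # kill DC
  x <- Re(stats::fft(X * H, inverse = TRUE))[seq_len(n)] / m
  x / stats::sd(x)
}

#' Generate one synthetic session
#'
#' Builds the trial event table (nose pokes, odors, choices, licks), then
#' synthesizes each channel as 1/f background noise, plus a
#' respiration-locked ~2 Hz component on olfactory channels, plus one beta
#' burst per trial on beta-expressing channels with the scheduled gain.
#' Coupled structure pairs share burst phase up to the configured offset
#' and jitter; uncoupled channels draw independent phases each trial.
#'
#' @param config a [sim_config()].
#' @param gain_schedule optional numeric vector (length `n_trials`) of
#'   per-trial burst gains, overriding `config$burst_gain`.
#' @param perf_schedule optional numeric vector of per-trial latent
#'   probability correct, overriding `config$latent_performance`.
#' @param rat_id,session_label metadata strings.
#' @return list with elements `recording` (class `session_recording`) and
#'   `truth` (class `ground_truth`: per-trial gains per structure, pair
#'   offsets, artifact intervals, latent performance, intended label).
#' @export
generate_session <- function(config, gain_schedule = NULL, perf_schedule = NULL,
                             rat_id = "rat1", session_label = "S1") {
  validate_sim_config(config)
  n_tr <- config$n_trials
  gains <- gain_schedule %||% rep(config$burst_gain, n_tr)
  if (length(gains) != n_tr) {
    stop("gain_schedule length (", length(gains), ") != n_trials (", n_tr, ")")
  }
  if (any(gains < 0)) stop("invalid sim_config field `burst_gain`: schedule must be >= 0")
  perf <- perf_schedule %||% rep(config$latent_performance, n_tr)
  if (length(perf) == 1L) perf <- rep(perf, n_tr)

  with_seed(config$seed, {
    trials <- simulate_trial_table(config, perf)
    dur <- trials$nose_poke_end[n_tr] + 10 # 10 s tail after last trial
    n <- as.integer(ceiling(dur * config$fs))
    tvec <- (seq_len(n) - 1L) / config$fs

    bstruct <- beta_structures(config$structures)
    phases <- draw_burst_phases(config, bstruct, n_tr)

    signals <- matrix(0, nrow = n, ncol = length(config$structures),
                      dimnames = list(NULL, config$structures))
    gain_mat <- matrix(0, nrow = n_tr, ncol = length(config$structures),
                       dimnames = list(NULL, config$structures))
    centers <- trials$nose_poke_end + config$burst_center_offset
    for (s in config$structures) {
      x <- noise_1f(n, config$fs, config$noise_exponent)
      if (s %in% olfactory_structures(config$structures)) {
        x <- x + respiration_component(n, config$fs, config$respiration_freq)
      }
      if (s %in% bstruct) {
        x <- x + burst_train(tvec, centers, config$burst_envelope_sd,
                             config$beta_freq, gains * config$burst_amp,
                             phases[, s])
        gain_mat[, s] <- gains
      }
      signals[, s] <- x
    }

    recording <- structure(
      list(signals = signals, fs = config$fs, trials = trials,
           metadata = list(rat_id = rat_id, session_label = session_label,
                           seed = config$seed)),
      class = "session_recording"
    )
    truth <- structure(
      list(gains = gain_mat, burst_phases = phases,
           coupled_pairs = config$coupled_pairs,
           burst_centers = centers,
           artifact_intervals = matrix(numeric(0), ncol = 2L,
                                       dimnames = list(NULL, c("start", "end"))),
           latent_performance = perf,
           session_label = session_label),
      class = "ground_truth"
    )
    list(recording = recording, truth = truth)
  })
}

# Trial event table: nose-poke intervals with >= iti_min spacing, balanced
# pseudo-random odor order, Bernoulli(correct | latent performance) choices,
# lick intervals on rewarded trials.
simulate_trial_table <- function(config, perf) {
  n_tr <- config$n_trials
  durs <- stats::runif(n_tr, config$trial_duration_range[1L], config$trial_duration_range[2L])
  itis <- config$inter_trial_interval_min + stats::runif(n_tr, 0, 1.5)
  starts <- 10 + cumsum(itis) - itis[1L] + c(0, cumsum(durs[-n_tr]))
  ends <- starts + durs
  # balanced pseudo-random odor order (shuffled half/half)
  odors <- sample(rep(c("A", "B"), length.out = n_tr))
  correct <- stats::runif(n_tr) < perf
  target <- ifelse(odors == "A", "L", "R")
  side <- ifelse(correct, target, ifelse(target == "L", "R", "L"))
  no_resp <- !correct & stats::runif(n_tr) < 0.1
  side[no_resp] <- "none"
  licks <- vector("list", n_tr)
  for (i in seq_len(n_tr)) {
    licks[[i]] <- if (correct[i]) {
      matrix(c(ends[i] + 0.4, ends[i] + 2.4), ncol = 2L,
             dimnames = list(NULL, c("start", "end")))
    } else {
      matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
    }
  }
  df <- data.frame(trial = seq_len(n_tr), nose_poke_start = starts,
                   nose_poke_end = ends, odor = odors, side = side,
                   correct = correct, stringsAsFactors = FALSE)
  df$licks <- licks
  df
}

# Per-trial, per-structure burst phases honoring coupled pairs.
draw_burst_phases <- function(config, bstruct, n_tr) {
  phases <- matrix(stats::runif(n_tr * length(bstruct), 0, 2 * pi),
                   nrow = n_tr, ncol = length(bstruct),
                   dimnames = list(NULL, bstruct))
  cp <- config$coupled_pairs
  if (!is.null(cp)) {
    for (i in seq_len(nrow(cp))) {
      a <- cp$a[i]; b <- cp$b[i]
      if (!(a %in% bstruct) || !(b %in% bstruct)) next
      phases[, b] <- phases[, a] - cp$offset[i] +
        stats::rnorm(n_tr, 0, cp$jitter[i])
    }
  }
  phases
}

# Respiration-locked slow wave: sinusoid with random-walk frequency jitter.
respiration_component <- function(n, fs, f0, amp = 0.6) {
  fj <- f0 + cumsum(stats::rnorm(n, 0, 0.02 / sqrt(fs)))
  fj <- pmax(fj, 0.5 * f0)
  amp * sin(cumsum(2 * pi * fj / fs))
}

# Sum of Gaussian-envelope beta bursts, one per trial.
burst_train <- function(tvec, centers, env_sd, f, amps, phis) {
  fs <- 1 / (tvec[2L] - tvec[1L])
  out <- numeric(length(tvec))
  half <- as.integer(ceiling(4 * env_sd * fs))
  for (i in seq_along(centers)) {
    if (amps[i] == 0) next
    c_idx <- as.integer(round(centers[i] * fs)) + 1L
    idx <- max(1L, c_idx - half):min(length(tvec), c_idx + half)
    tt <- tvec[idx] - centers[i]
    out[idx] <- out[idx] +
      amps[i] * exp(-tt^2 / (2 * env_sd^2)) * cos(2 * pi * f * tt + phis[i])
  }
  out
}

#' Inject broadband movement artifacts
#'
#' Adds brief (20-200 ms) transients of 90-250 Hz band-limited noise to
#' every channel at the configured rate and amplitude (same intervals on
#' all channels, independent noise realizations), and records the intervals
#' in the ground truth.
#'
#' @param session list `(recording, truth)` from [generate_session()].
#' @param config the [sim_config()] used (fields `artifact_rate`,
#'   `artifact_amplitude`, `fs`).
#' @param times optional explicit artifact onset times (s), overriding the
#'   Poisson draw.
#' @param seed RNG seed for artifact placement (default derived from the
#'   config seed).
#' @return the session with artifacts added and
#'   `truth$artifact_intervals` filled.
#' @export
inject_artifacts <- function(session, config, times = NULL, seed = NULL) {
  if (config$artifact_amplitude <= 0) {
    stop("invalid sim_config field `artifact_amplitude`: must be positive")
  }
  if (config$fs <= 500) stop("invalid sim_config field `fs`: must exceed 500 Hz for artifacts")
  rec <- session$recording
  n <- nrow(rec$signals)
  dur <- n / rec$fs
  with_seed(seed %||% child_seed(config$seed, 101L), {
    if (is.null(times)) {
      n_art <- stats::rpois(1L, config$artifact_rate * dur / 60)
      times <- sort(stats::runif(n_art, 1, dur - 1))
    }
    if (!length(times)) return(session)
    widths <- stats::runif(length(times), 0.02, 0.2)
    iv <- cbind(start = times, end = pmin(times + widths, dur))
    for (j in seq_len(ncol(rec$signals))) {
      rms <- stats::sd(rec$signals[, j])
      for (i in seq_len(nrow(iv))) {
        idx <- (as.integer(iv[i, 1L] * rec$fs) + 1L):as.integer(iv[i, 2L] * rec$fs)
        rec$signals[idx, j] <- rec$signals[idx, j] +
          band_noise(length(idx), rec$fs, 90, min(250, rec$fs / 2 - 10)) *
            config$artifact_amplitude * rms
      }
    }
    session$recording <- rec
    session$truth$artifact_intervals <- rbind(session$truth$artifact_intervals, iv)
    session
  })
}

# Band-limited unit-RMS noise with a Tukey-like taper (broadband transient).
band_noise <- function(n, fs, f_lo, f_hi) {
  if (n < 4L) return(stats::rnorm(n))
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  k <- 0:(n - 1L)
  f <- pmin(k, n - k) * fs / n
  H <- as.numeric(f >= f_lo & f <= f_hi)
  x <- Re(stats::fft(X * H, inverse = TRUE)) / n
  taper <- stats::dnorm(seq(-2, 2, length.out = n)) / stats::dnorm(0)
  x <- x * taper
  x / sqrt(mean(x^2))
}

#' Generate a labeled learning sequence of sessions
#'
#' Produces a list of sessions whose latent performance and burst-gain
#' trajectories follow a named behavioral scenario:
#' * `acquisition` — performance climbs ~0.5 to ~0.9 across sessions while
#'   burst gain grows with it (first odor pair learning);
#' * `transfer` — same shape but faster, with gain reset low at the start
#'   (new odor pair under a known rule);
#' * `recall` — two test sessions with gains and performance retained at
#'   their learned maxima;
#' * `reversal` — first session: performance collapses below chance while
#'   gain stays at its learned maximum (the animal applies the old
#'   odor-side rule), then gain dips near chance-level behavior and both
#'   recover as the reversed rule is acquired.
#'
#' Within every session the per-trial gain and latent performance ramp up
#' over the first ~15 trials (warm-up dynamics observed at criterion), the
#' ramp rising from 30% to 100% of the session level.
#'
#' @param config a [sim_config()]; its `coupled_pairs`, if any, get their
#'   phase jitter scaled down as the session gain grows when
#'   `couple_with_gain = TRUE`, so phase coupling strengthens with
#'   learning.
#' @param scenario one of `"acquisition"`, `"transfer"`, `"recall"`,
#'   `"reversal"`.
#' @param n_sessions number of sessions (defaults per scenario).
#' @param gain_max session-level gain at full learning.
#' @param couple_with_gain logical; scale coupling jitter inversely with
#'   the session gain.
#' @param jitter_range range of coupling jitter (radians) mapped from
#'   lowest to highest session gain.
#' @return list of sessions (each `(recording, truth)`), with
#'   `truth$session_label` holding the scenario-intended label.
#' @export
generate_learning_sequence <- function(config, scenario,
                                       n_sessions = NULL, gain_max = 2.5,
                                       couple_with_gain = TRUE,
                                       jitter_range = c(0.3, 2.8)) {
  scenarios <- c("acquisition", "transfer", "recall", "reversal")
  if (!scenario %in% scenarios) {
    stop("unknown scenario `", scenario, "`; valid scenarios: ",
         paste(scenarios, collapse = ", "))
  }
  plan <- scenario_plan(scenario, n_sessions, gain_max)
  n_s <- length(plan$perf)
  out <- vector("list", n_s)
  for (s in seq_len(n_s)) {
    cfg_s <- config
    cfg_s$seed <- child_seed(config$seed, s)
    ramp <- session_ramp(config$n_trials)
    gain_tr <- plan$gain[s] * ramp
    perf_tr <- 0.5 + (plan$perf[s] - 0.5) * ramp
    if (scenario == "reversal" && s == 1L) {
      # old rule applied confidently: below-chance from ~trial 6 on,
      # burst gain already at its learned level
      perf_tr <- ifelse(seq_len(config$n_trials) <= 5L, 0.5, plan$perf[1L])
      gain_tr <- plan$gain[1L] * ramp
    }
    if (couple_with_gain && !is.null(cfg_s$coupled_pairs)) {
      rng <- range(plan$gain)
      frac <- if (diff(rng) > 0) (plan$gain[s] - rng[1L]) / diff(rng) else 1
      cfg_s$coupled_pairs$jitter <-
        jitter_range[2L] - (jitter_range[2L] - jitter_range[1L]) * frac
    }
    ses <- generate_session(cfg_s, gain_schedule = gain_tr,
                            perf_schedule = perf_tr,
                            session_label = plan$labels[s])
    ses$truth$intended_performance <- plan$perf[s]
    ses$truth$intended_gain <- plan$gain[s]
    out[[s]] <- ses
  }
  out
}

scenario_plan <- function(scenario, n_sessions, gain_max) {
  switch(scenario,
    acquisition = {
      n <- n_sessions %||% 8L
      # sub-criterion plateau-free climb, then three clearly-at-criterion
      # days so the intended LC1 day is unambiguous under Bernoulli noise
      # pre-criterion days stay clearly below the 80% block criterion
      # (<= 0.65) so Bernoulli noise at block size 30 cannot fake a
      # criterion day; at-criterion days sit at 0.92
      perf <- if (n > 3L) {
        c(seq(0.5, 0.65, length.out = n - 3L), rep(0.92, 3L))
      } else {
        rep(0.92, n)
      }
      gain <- seq(0.15 * gain_max, gain_max, length.out = n)
      list(perf = perf, gain = gain, labels = acquisition_labels(perf))
    },
    transfer = {
      n <- n_sessions %||% 4L
      perf <- if (n > 3L) {
        c(seq(0.6, 0.68, length.out = n - 3L), rep(0.92, 3L))
      } else {
        rep(0.92, n)
      }
      gain <- seq(0.25 * gain_max, gain_max, length.out = n)
      list(perf = perf, gain = gain, labels = acquisition_labels(perf))
    },
    recall = {
      n <- n_sessions %||% 2L
      list(perf = rep(0.9, n), gain = rep(gain_max, n),
           labels = paste0("T", seq_len(n)))
    },
    reversal = {
      n <- n_sessions %||% 6L
      # below chance, then near chance with low gain, then recovery
      perf <- c(0.25, seq(0.45, 0.55, length.out = max(n - 3L, 1L)), 0.8, 0.9)[seq_len(n)]
      gain <- c(gain_max, seq(0.4 * gain_max, 0.5 * gain_max,
                              length.out = max(n - 3L, 1L)),
                0.8 * gain_max, gain_max)[seq_len(n)]
      list(perf = perf, gain = gain,
           labels = paste0("S", seq_len(n)))
    }
  )
}

# Intended S/LC labels from the planned session performances (>= 0.8 run of 3).
acquisition_labels <- function(perf) {
  n <- length(perf)
  hit <- perf >= 0.8
  lc1 <- NA_integer_
  for (s in seq_len(max(n - 2L, 0L))) {
    if (all(hit[s:(s + 2L)])) { lc1 <- s; break }
  }
  labels <- paste0("S", seq_len(n))
  if (!is.na(lc1)) {
    at <- lc1:n
    labels[at] <- paste0("LC", seq_along(at))
    if (lc1 > 1L) labels[lc1 - 1L] <- "LC0"
  }
  labels
}

# Warm-up multiplier: linear 0.3 -> 1 over the first 15 trials, flat after.
session_ramp <- function(n_trials, ramp_trials = 15L, floor = 0.3) {
  pmin(floor + (1 - floor) * (seq_len(n_trials) - 1L) / (ramp_trials - 1L), 1)
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf(
    "<session_recording> %s / %s: %d channels (%s), %.1f s @ %g Hz, %d trials\n",
    x$metadata$rat_id, x$metadata$session_label, ncol(x$signals),
    paste(colnames(x$signals), collapse = ", "),
    nrow(x$signals) / x$fs, x$fs, nrow(x$trials)
  ))
  invisible(x)
}
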