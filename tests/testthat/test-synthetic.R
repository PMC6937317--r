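test_that("config validation names the offending field", {
  expect_error(sim_config(fs = 150), "fs")
  expect_error(sim_config(trial_duration_range = c(0.5, 2.5)), "trial_duration_range")
  expect_error(sim_config(inter_trial_interval_min = 3), "inter_trial_interval_min")
  expect_error(sim_config(beta_freq = 35), "beta_freq")
  expect_error(sim_config(burst_gain = -1), "burst_gain")
  expect_error(sim_config(structures = c("OB", "OB")), "structures")
  expect_error(sim_config(coupled_pairs = data.frame(a = "OB", b = "XX",
                                                     offset = 0, jitter = 0)),
               "coupled_pairs")
  expect_error(sim_config(artifact_rate = 2, fs = 400), "fs")
})

test_that("same config + seed is bit-identical; trial structure honors the task", {
  cfg <- fast_config(n_trials = 12L, seed = 33L)
  s1 <- generate_session(cfg)
  s2 <- generate_session(cfg)
  expect_identical(s1$recording$signals, s2$recording$signals)
  expect_identical(s1$recording$trials, s2$recording$trials)

  tr <- s1$recording$trials
  expect_true(all(tr$nose_poke_end - tr$nose_poke_start < 2))
  expect_true(all(tr$nose_poke_start[-1] - tr$nose_poke_end[-12] >= 7))
  expect_equal(as.vector(table(tr$odor)), c(6, 6))
  expect_true(all(diff(tr$nose_poke_start) > 0))
})

test_that("zero gain schedule injects no beta: trial-end power equals baseline", {
  cfg <- fast_config(structures = "Stri", n_trials = 15L, seed = 9L)
  ses <- generate_session(cfg, gain_schedule = rep(0, 15))
  tfm <- morlet_tfmap(ses$recording$signals[, 1], 200, beta_freq_grid())
  fmax <- lfpbeta:::tfmap_freqmax(tfm)
  tr <- ses$recording$trials
  win_pow <- vapply(seq_len(15), function(i) {
    idx <- round((tr$nose_poke_end[i] - 0.4) * 200):round((tr$nose_poke_end[i] + 0.1) * 200)
    mean(fmax[idx])
  }, numeric(1))
  expect_lt(abs(mean(win_pow) / mean(fmax) - 1), 0.15)
})

test_that("coupled pair with zero jitter has constant cross-spectrum phase", {
  cp <- data.frame(a = "OB", b = "AP", offset = pi / 2, jitter = 0)
  cfg <- fast_config(structures = c("OB", "AP"), n_trials = 12L, seed = 14L,
                     coupled_pairs = cp, burst_gain = 3)
  ses <- generate_session(cfg)
  tf <- lapply(c("OB", "AP"), function(ch) {
    morlet_tfmap(ses$recording$signals[, ch], 200, beta_freq_grid())
  })
  idx <- lfpbeta:::tfmap_time_index(tf[[1]], ses$truth$burst_centers)
  col <- which(tf[[1]]$freqs == cfg$beta_freq)
  s12 <- tf[[1]]$coeffs[idx, col] * Conj(tf[[2]]$coeffs[idx, col])
  expect_lt(1 - Mod(mean(exp(1i * Arg(s12)))), 0.01) # circular variance
  expect_lt(abs(mean(Arg(s12)) - pi / 2), 0.15)
})

test_that("uncoupled phases are uniform (Rayleigh) in most seeds", {
  pass <- vapply(1:40, function(sd) {
    cfg <- fast_config(structures = c("OB", "AP"), n_trials = 12L,
                       seed = 1000L + sd, burst_gain = 3)
    ses <- generate_session(cfg)
    tf <- lapply(c("OB", "AP"), function(ch) {
      morlet_tfmap(ses$recording$signals[, ch], 200, beta_freq_grid())
    })
    idx <- lfpbeta:::tfmap_time_index(tf[[1]], ses$truth$burst_centers)
    col <- which(tf[[1]]$freqs == cfg$beta_freq)
    s12 <- tf[[1]]$coeffs[idx, col] * Conj(tf[[2]]$coeffs[idx, col])
    rayleigh_p(Arg(s12)) > 0.05
  }, logical(1))
  expect_gte(mean(pass), 0.9)
})

test_that("background spectrum follows the configured 1/f slope", {
  for (alpha in c(0.8, 1.2)) {
    set.seed(3)
    x <- lfpbeta:::noise_1f(2^16, 200, alpha)
    n <- length(x)
    P <- Mod(stats::fft(x))[2:(n / 2)]^2
    f <- (1:(n / 2 - 1)) * 200 / n
    keep <- f >= 1 & f <= 60
    # bin log-log periodogram into octaves before fitting
    bins <- cut(log(f[keep]), 24)
    lp <- tapply(log(P[keep]), bins, mean)
    lf <- tapply(log(f[keep]), bins, mean)
    slope <- stats::coef(stats::lm(lp ~ lf))[2]
    expect_lt(abs(slope + alpha), 0.2)
  }
})

test_that("artifact injection: zero-rate identity, bookkeeping, amplitude error", {
  cfg <- sim_config(structures = "AP", n_trials = 4L, seed = 2L,
                    artifact_rate = 0, artifact_amplitude = 20)
  ses <- generate_session(cfg)
  same <- inject_artifacts(ses, cfg, times = numeric(0))
  expect_identical(same$recording$signals, ses$recording$signals)

  bad <- cfg; bad$artifact_amplitude <- 0
  expect_error(inject_artifacts(ses, bad), "artifact_amplitude")

  two <- inject_artifacts(ses, cfg, times = c(12, 25))
  expect_equal(nrow(two$truth$artifact_intervals), 2L)
  expect_true(all(two$truth$artifact_intervals[, "end"] <=
                    nrow(ses$recording$signals) / 1000))
})

test_that("learning scenarios follow their stated trajectories", {
  cfg <- fast_config(structures = "AP", n_trials = 24L, seed = 6L)
  expect_error(generate_learning_sequence(cfg, "warp"), "acquisition")

  acq <- generate_learning_sequence(cfg, "acquisition", n_sessions = 6)
  perf <- vapply(acq, function(s) s$truth$intended_performance, numeric(1))
  expect_true(all(diff(perf) >= 0))
  expect_equal(perf[1], 0.5)
  expect_gte(perf[6], 0.9)
  expect_equal(vapply(acq, function(s) s$truth$session_label, character(1))[4:6],
               c("LC1", "LC2", "LC3"))

  # reversal session 1: below-chance performance at learned-maximum gain
  rev <- generate_learning_sequence(cfg, "reversal", gain_max = 2)
  p1 <- session_performance(rev[[1]]$recording$trials)
  expect_lt(p1, 0.5)
  expect_equal(rev[[1]]$truth$intended_gain, 2)
  expect_equal(max(rev[[1]]$truth$gains[, "AP"]), 2)

  # recall retains the learned gain level
  rec <- generate_learning_sequence(cfg, "recall", gain_max = 2)
  expect_equal(vapply(rec, function(s) s$truth$intended_gain, numeric(1)), c(2, 2))

  # within-session warm-up ramp over the first 15 trials
  g <- acq[[6]]$truth$gains[, "AP"]
  expect_true(all(diff(g[1:15]) > 0))
  expect_equal(g[15], max(g))
})
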