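test_that("raw beta amplitude: stationary ridge, zero signal, in-window burst", {
  fs <- 200
  t <- (0:(fs * 60 - 1)) / fs
  tfm <- morlet_tfmap(cos(2 * pi * 22 * t), fs, beta_freq_grid())
  expect_lt(abs(trial_raw_beta(tfm, 30) - 1), 0.01)

  tfm0 <- morlet_tfmap(numeric(fs * 10), fs, beta_freq_grid())
  expect_equal(trial_raw_beta(tfm0, 5), 0)
  expect_error(trial_raw_beta(tfm0, 9.95), "window")

  # burst of peak amplitude 3 on a floor of 1, centered in-window
  env <- 1 + 2 * exp(-((t - 29.85)^2) / (2 * 0.12^2))
  tfb <- morlet_tfmap(env * cos(2 * pi * 22 * t), fs, beta_freq_grid())
  v <- trial_raw_beta(tfb, 30)
  expect_gt(v, 1); expect_lt(v, 3)
  # brute-force oracle: loop over the map, per-time max then mean
  amp <- Mod(tfb$coeffs)
  idx <- round(29.6 * fs):round(30.1 * fs) + 1L
  oracle <- mean(vapply(idx, function(i) max(amp[i, ]), numeric(1)))
  expect_equal(v, oracle, tolerance = 1e-12)
})

test_that("baseline self-normalizes a stationary sinusoid and flags degenerate windows", {
  fs <- 200
  t <- (0:(fs * 120 - 1)) / fs
  tfm <- morlet_tfmap(cos(2 * pi * 22 * t), fs, beta_freq_grid())
  trials <- toy_trials(3, spacing = 30)
  bl <- trial_baseline(tfm, trials[2, ], trials)
  expect_lt(abs(bl$baseline - 1), 0.01)
  expect_lt(abs(log(trial_raw_beta(tfm, trials$nose_poke_end[2]) / bl$baseline)), 0.02)

  # whole window consumed by a lick interval -> undefined, flagged
  trials2 <- trials
  trials2$licks[[2]] <- matrix(c(0, 130), ncol = 2)
  bl2 <- trial_baseline(tfm, trials2[2, ], trials2)
  expect_true(is.na(bl2$baseline))
  expect_equal(bl2$n_periods, 0L)
})

test_that("baseline drops periods near other nose pokes, licks and artifacts", {
  fs <- 200
  t <- (0:(fs * 100 - 1)) / fs
  tfm <- morlet_tfmap(cos(2 * pi * 22 * t), fs, beta_freq_grid())
  trials <- toy_trials(3, spacing = 30) # starts 10, 40, 70
  n_all <- trial_baseline(tfm, trials[2, ], trials)$n_periods
  ep <- matrix(c(50, 51), ncol = 2) # artifact: excluded with +/- 2 s extension
  n_art <- trial_baseline(tfm, trials[2, ], trials, epochs = ep)$n_periods
  # 5 s blocked ([48, 53)) -> 10 fewer periods (500 ms each)
  expect_equal(n_all - n_art, 10L)

  # scale invariance of the full measure
  cfg <- fast_config(structures = "AP", n_trials = 8L, seed = 31L)
  ses <- generate_session(cfg)
  m1 <- compute_session_beta(ses$recording)
  ses$recording$signals <- ses$recording$signals * 40
  m2 <- compute_session_beta(ses$recording)
  expect_equal(m1$beta_amplitude, m2$beta_amplitude, tolerance = 1e-10)
})

test_that("compute_session_beta skips excluded trials and warns on missing channels", {
  cfg <- fast_config(structures = "AP", n_trials = 6L, seed = 12L)
  ses <- generate_session(cfg)
  tr3 <- ses$recording$trials$nose_poke_start[3]
  masks <- list(toy_mask(c(tr3 - 0.5, tr3 - 0.4), "AP"))
  m <- compute_session_beta(ses$recording, masks)
  expect_true(m$excluded[m$trial == 3])
  expect_true(is.na(m$beta_amplitude[m$trial == 3]))
  expect_false(any(m$excluded[m$trial != 3]))
  expect_warning(compute_session_beta(ses$recording, channels = c("AP", "OB")),
                 "OB")
})

test_that("beta amplitude increases monotonically with injected gain", {
  gains <- rep(c(1, 2, 3), each = 10)
  cfg <- fast_config(structures = "AP", n_trials = 30L, seed = 44L)
  ses <- generate_session(cfg, gain_schedule = gains)
  m <- compute_session_beta(ses$recording)
  med <- tapply(m$beta_amplitude, gains, stats::median)
  expect_true(all(diff(med) > 0))
  expect_gt(stats::cor(gains, m$beta_amplitude, method = "spearman"), 0.8)
})

test_that("make_blocks: alternation, odor-run spill, short sessions", {
  tr <- toy_trials(40) # alternating A/B
  b <- make_blocks(tr)
  expect_equal(b$block, c(1L, 2L))
  expect_equal(b$trials[[1]], 1:20)
  expect_equal(b$trials[[2]], 21:40)
  expect_equal(b$performance, c(1, 1))

  # run of 15 consecutive A: A-occurrences 11-15 spill into block 2
  odors <- c(rep("A", 15), rep("B", 10), rep("A", 5), rep("B", 10))
  tr2 <- toy_trials(40, odors = odors, correct = rep(c(TRUE, FALSE), 20))
  b2 <- make_blocks(tr2)
  expect_equal(b2$block, c(1L, 2L))
  expect_equal(b2$trials[[1]], c(1:10, 16:25))   # first 10 A, first 10 B
  expect_equal(b2$trials[[2]], c(11:15, 26:40))  # spilled A + rest
  expect_equal(vapply(b2$trials, length, integer(1)), c(20L, 20L))

  expect_equal(nrow(make_blocks(toy_trials(19))), 0L)
})

test_that("make_blocks attaches per-structure median beta", {
  tr <- toy_trials(40)
  meas <- data.frame(structure = "AP", trial = 1:40,
                     beta_amplitude = c(rep(1, 20), rep(3, 20)))
  b <- make_blocks(tr, meas)
  expect_equal(b$median_beta, c(1, 3))
  expect_equal(b$structure, c("AP", "AP"))
})

test_that("time_of_max_beta finds the burst peak and honors short trials", {
  cfg <- fast_config(structures = c("OB", "AP"), n_trials = 6L, seed = 19L,
                     burst_gain = 4)
  ses <- generate_session(cfg)
  rec <- ses$recording
  ds <- lapply(colnames(rec$signals), function(ch) rec$signals[, ch])
  names(ds) <- colnames(rec$signals)
  tfmaps <- lapply(ds, morlet_tfmap, fs = 200, freqs = beta_freq_grid())
  for (i in c(2, 5)) {
    tm <- time_of_max_beta(tfmaps, ds, rec$trials[i, ])
    expect_lt(abs(tm - ses$truth$burst_centers[i]), 0.05)
  }

  # identical maps: averaging identity
  one <- time_of_max_beta(tfmaps["OB"], ds["OB"], rec$trials[2, ])
  both <- time_of_max_beta(list(OB = tfmaps$OB, X = tfmaps$OB),
                           list(OB = ds$OB, X = ds$OB), rec$trials[2, ])
  expect_equal(one, both)

  # trial shorter than 400 ms: search window starts at trial start
  short <- rec$trials[2, ]
  short$nose_poke_start <- short$nose_poke_end - 0.1
  tm_s <- time_of_max_beta(tfmaps, ds, short)
  expect_gte(tm_s, short$nose_poke_start - 0.5 / 200) # grid rounding: half sample

  # MAD normalization: channel rescaling leaves the answer unchanged
  ds2 <- ds; ds2$OB <- ds$OB * 30
  tf2 <- tfmaps; tf2$OB$coeffs <- tfmaps$OB$coeffs * 30
  expect_equal(time_of_max_beta(tf2, ds2, rec$trials[2, ]),
               time_of_max_beta(tfmaps, ds, rec$trials[2, ]))

  expect_error(time_of_max_beta(tfmaps["OB"], ds, rec$trials[1, ],
                                exclude = c("OB", "Hipp", "Cereb")),
               "eligible")
})
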