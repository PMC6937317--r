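test_that("select_trials applies the 11th-40th clean-trial rule", {
  tr <- toy_trials(80)
  expect_equal(select_trials(tr), 11:40)
  # exclusions shift the window: hand-enumerated expectation
  expect_equal(select_trials(tr, excluded = c(5L, 12L)), c(13:42))
  expect_error(select_trials(toy_trials(35)), "short by 5")
})

test_that("wpli matches the printed formula on hand-computed cases", {
  # identical phase lag pi/2, equal amplitude
  expect_equal(wpli(complex(modulus = 1, argument = rep(pi / 2, 10))), 1)
  expect_equal(wpli(c(1i, -1i)), 0)
  expect_equal(wpli(complex(imaginary = c(2, 1, -1))), 0.5)
  expect_true(is.na(wpli(complex(real = c(1, 2, 3)))))
  expect_error(wpli(1i), "2 trials")
})

test_that("debiased WPLI^2 matches the printed double sum", {
  expect_equal(debiased_wpli2(complex(modulus = 1, argument = rep(pi / 2, 7))), 1)
  # {1, -1}: numerator 2*(1*-1) = -2, denominator 2 -> -1 (debiasing goes negative)
  expect_equal(debiased_wpli2(c(1i, -1i)), -1)
  expect_true(is.na(debiased_wpli2(complex(real = c(1, 2)))))
  set.seed(1)
  for (n in c(2, 5, 30)) {
    I <- rnorm(n)
    expect_equal(debiased_wpli2(complex(imaginary = I)),
                 lfpbeta:::debiased_wpli2_pairwise(complex(imaginary = I)),
                 tolerance = 1e-13)
  }
})

test_that("debiased estimator is centered at 0 for independent phases", {
  set.seed(10)
  v <- replicate(400, debiased_wpli2(complex(modulus = 1,
                                             argument = runif(30, 0, 2 * pi))))
  expect_lt(abs(mean(v)), 0.03)
  # biased WPLI on the same construction is strictly positive in expectation
  w <- replicate(400, wpli(complex(modulus = 1, argument = runif(30, 0, 2 * pi))))
  expect_gt(mean(w), 0.05)
})

test_that("debiased WPLI^2 is consistent: concentrates on its plateau as N grows", {
  # under fixed lag pi/2 with phase jitter sd 1, the population value is
  # (E[I]/E[|I|])^2; Monte-Carlo oracle for it:
  set.seed(4)
  I_big <- sin(rnorm(2e5, pi / 2, 1))
  plateau <- (mean(I_big) / mean(abs(I_big)))^2
  draws <- lapply(c(10, 30, 100), function(n) {
    replicate(300, debiased_wpli2(complex(modulus = 1,
                                          argument = rnorm(n, pi / 2, 1))))
  })
  means <- vapply(draws, mean, numeric(1))
  sds <- vapply(draws, stats::sd, numeric(1))
  expect_true(all(abs(means - plateau) < 0.05)) # ~unbiased at every N
  expect_true(all(diff(sds) < 0))               # variance shrinks with N
  # and the plateau itself rises toward 1 as the lag jitter shrinks
  set.seed(5)
  m_by_jitter <- vapply(c(1, 0.5, 0.1), function(s) {
    mean(replicate(300, debiased_wpli2(complex(modulus = 1,
                                               argument = rnorm(30, pi / 2, s)))))
  }, numeric(1))
  expect_true(all(diff(m_by_jitter) > 0))
  expect_gt(m_by_jitter[3], 0.95)
})

test_that("zero-lag (volume-conducted) coupling yields no spurious connectivity", {
  # purely instantaneous coupling: imaginary parts exactly zero
  expect_true(is.na(debiased_wpli2(complex(real = rexp(30)))))
  # near-zero-lag with symmetric jitter: WPLI^2 stays near 0, p above alpha
  set.seed(6)
  n <- 30
  ph <- rnorm(n, 0, 0.2)
  cs <- structure(list(
    at_start = matrix(complex(modulus = 1, argument = runif(n * 23, 0, 2 * pi)), n, 23),
    at_beta = matrix(complex(modulus = 1, argument = rep(ph, 23)), n, 23),
    freqs = beta_freq_grid(), trial_ids = 1:n, pair = c("a", "b")
  ), class = "cross_spectrum_set")
  w <- apply(cs$at_beta, 2, debiased_wpli2)
  expect_lt(max(abs(w)), 0.2)
})

test_that("wpli2_difference isolates event-specific coupling", {
  set.seed(11)
  null_means <- replicate(25, mean(wpli2_difference(make_cs(locked = FALSE))$diff))
  expect_lt(abs(mean(null_means)), 0.1) # null difference fluctuates around 0
  d0 <- wpli2_difference(make_cs(locked = FALSE))

  cs1 <- make_cs(locked = TRUE, lock_jitter = 0.05)
  d1 <- wpli2_difference(cs1)
  expect_gt(d1$max_diff, 0.6)
  expect_gt(d1$max_diff, max(abs(d0$diff)))
  expect_equal(d1$diff, d1$wpli2_beta - d1$wpli2_start)
})

test_that("surrogate test: determinism, strong effect, strict inequality, smoothing", {
  set.seed(21)
  cs <- make_cs(locked = TRUE, lock_jitter = 0.05)
  s1 <- surrogate_test(cs, n_surrogates = 500, seed = 77)
  s2 <- surrogate_test(cs, n_surrogates = 500, seed = 77)
  expect_identical(s1$p, s2$p)
  expect_identical(s1$surrogate_max, s2$surrogate_max)
  expect_equal(s1$p, 0) # observed max far above all surrogates
  s3 <- surrogate_test(cs, n_surrogates = 500, seed = 77, smoothed = TRUE)
  expect_equal(s3$p, 1 / 501)
  expect_warning(surrogate_test(cs, n_surrogates = 50, seed = 1), "resolution")
  # pooled-reshuffle variant agrees on the obvious effect
  s4 <- surrogate_test(cs, n_surrogates = 200, seed = 5, pooled = TRUE)
  expect_lt(s4$p, 0.05)
})

test_that("session_connectivity recovers injected coupling and only it", {
  cp <- data.frame(a = "OB", b = "AP", offset = pi / 2, jitter = 0.15)
  cfg <- fast_config(structures = c("OB", "AP", "Stri"), n_trials = 52L,
                     seed = 71L, coupled_pairs = cp, burst_gain = 3)
  ses <- generate_session(cfg)
  res <- session_connectivity(ses$recording, n_surrogates = 500, seed = 3)
  expect_equal(nrow(res), 3L)
  row_ob_ap <- res$structure_a == "OB" & res$structure_b == "AP"
  expect_lt(res$p_surrogate[row_ob_ap], 0.01)
  expect_gt(res$max_diff[row_ob_ap], 0.4)
  expect_true(all(res$p_surrogate[!row_ob_ap] > 0.05))

  net <- network_summary(res, alpha = 0.01)
  expect_equal(net$hub_index, 1 / 3)
  expect_equal(unname(net$structure_proportion[c("OB", "AP", "Stri")]),
               c(1 / 2, 1 / 2, 0))
})

test_that("network_summary combinatorics", {
  res <- data.frame(
    structure_a = c("OB", "OB", "AP"), structure_b = c("AP", "PP", "PP"),
    p_surrogate = c(0.001, 0.5, 0.5)
  )
  net <- network_summary(res)
  expect_equal(net$hub_index, 1 / 3)
  expect_equal(unname(net$structure_proportion[c("AP", "OB", "PP")]),
               c(1 / 2, 1 / 2, 0))
  all0 <- res; all0$p_surrogate <- 0
  expect_equal(network_summary(all0)$hub_index, 1)
  expect_error(network_summary(res[0, ]), "no connectivity")
})
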