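test_that("percept sequences follow the programmed reversal probability", {
  prof <- participant_profile()

  cfg0 <- paradigm_config(condition = "disambiguation", exo_reversal_prob = 0,
                          seed = 1)
  s0 <- simulate_percept_sequence(cfg0, prof, 100)
  expect_equal(sum(s0$true_label == "reversal"), 0)
  expect_equal(length(unique(s0$percept)), 1)

  cfg1 <- paradigm_config(condition = "disambiguation", exo_reversal_prob = 1,
                          seed = 1)
  s1 <- simulate_percept_sequence(cfg1, prof, 100)
  expect_equal(sum(s1$true_label == "reversal"), 99)
  expect_true(all(s1$percept[-1] != s1$percept[-100]))

  # empirical fraction within the 99% binomial interval at n = 10,000
  cfg <- paradigm_config(condition = "disambiguation", seed = 42)
  s <- simulate_percept_sequence(cfg, prof, 10001)
  frac <- mean(s$true_label == "reversal")
  half <- stats::qnorm(0.995) * sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(frac - 0.30), half)

  # ambiguity condition draws from the observer's endogenous probability
  cfga <- paradigm_config(condition = "ambiguity", seed = 5)
  profa <- participant_profile(endo_reversal_prob = 0.1)
  sa <- simulate_percept_sequence(cfga, profa, 5001)
  expect_lt(abs(mean(sa$true_label == "reversal") - 0.1),
            stats::qnorm(0.995) * sqrt(0.1 * 0.9 / 5000))

  # label law: reversal iff the percept changes
  expect_equal(as.character(sa$true_label),
               ifelse(sa$percept[-1] != sa$percept[-5001],
                      "reversal", "stable"))
})

test_that("percept sequences are reproducible from the seed", {
  cfg <- paradigm_config(condition = "disambiguation", seed = 7)
  prof <- participant_profile()
  s1 <- simulate_percept_sequence(cfg, prof, 500)
  s2 <- simulate_percept_sequence(cfg, prof, 500)
  expect_identical(s1, s2)
  s3 <- simulate_percept_sequence(cfg, prof, 500, seed = 8)
  expect_false(identical(s1$percept, s3$percept))
})

test_that("response simulation applies lapse, error, and latency models", {
  cfg <- paradigm_config(seed = 3)
  prof <- participant_profile()
  s <- simulate_percept_sequence(cfg, prof, 101)

  all_lapse <- simulate_responses(
    s, participant_profile(lapse_prob = 1), cfg)
  expect_true(all(all_lapse$response_key == "none"))
  expect_true(all(is.na(all_lapse$latency_ms)))

  clean <- simulate_responses(
    s, participant_profile(lapse_prob = 0, error_prob = 0), cfg)
  expect_equal(clean$response_key, as.character(s$true_label))

  fixed <- simulate_responses(
    s, participant_profile(lapse_prob = 0, error_prob = 0,
                           rt_mean = 600, rt_sd = 0), cfg)
  expect_true(all(fixed$latency_ms == 600))

  # latencies stay in the response window
  wide <- simulate_responses(
    s, participant_profile(lapse_prob = 0, rt_mean = 600, rt_sd = 2000), cfg)
  expect_true(all(wide$latency_ms >= 0 & wide$latency_ms <= 1400,
                  na.rm = TRUE))
})

test_that("reversal rate is reversals per block divided by block minutes", {
  b <- data.frame(response_key = rep("reversal", 56), latency_ms = 600)
  expect_equal(compute_reversal_rate(b, 7), 8)

  none <- data.frame(response_key = rep("stable", 30), latency_ms = 600)
  expect_equal(compute_reversal_rate(none, 7), 0)

  two_blocks <- data.frame(
    response_key = rep("reversal", 14), latency_ms = 600,
    block = rep(1:2, c(8, 6)))
  expect_equal(compute_reversal_rate(two_blocks, 7), (8 / 7 + 6 / 7) / 2)

  # presses outside the validity window do not count
  early <- data.frame(response_key = rep("reversal", 10),
                      latency_ms = rep(c(100, 600), 5))
  expect_equal(compute_reversal_rate(early, 1), 5)

  expect_warning(r0 <- compute_reversal_rate(
    data.frame(response_key = character(0), latency_ms = numeric(0)), 7))
  expect_equal(r0, 0)
})

test_that("simulated EEG carries the destabilization signature linearly", {
  n_tr <- 60
  cfg <- paradigm_config(condition = "ambiguity", n_trials_per_block = n_tr,
                         seed = 11)
  base <- list(endo_reversal_prob = 0.4, blink_rate = 0,
               lapse_prob = 0, error_prob = 0)
  profs <- lapply(c(0, 2.5, 5), function(e) {
    do.call(participant_profile, c(base, list(effect_strength = e)))
  })
  s <- simulate_percept_sequence(cfg, profs[[1]], n_tr + 1, seed = 21)
  r <- simulate_responses(s, profs[[1]], cfg, seed = 22)
  recs <- lapply(profs, function(p)
    simulate_eeg_recording(s, r, cfg, p, seed = 23))

  # mean reversal-minus-stable difference at Pz inside the plateau of the
  # effect window, computed directly on the raw recording
  mean_diff_pz <- function(rec) {
    onsets <- rec$events$sample[rec$events$type == "stim_onset"]
    fs <- rec$sfreq
    win <- (round(0.45 * fs)):(round(1.25 * fs))
    per_trial <- vapply(seq_len(n_tr), function(tr) {
      mean(rec$voltages["Pz", onsets[tr] + win + 1])
    }, numeric(1))
    rev <- s$true_label == "reversal"
    mean(per_trial[rev]) - mean(per_trial[!rev])
  }
  d <- vapply(recs, mean_diff_pz, numeric(1))
  # identical seeds cancel the noise exactly: differences of differences
  # isolate the injected amplitude, and doubling the strength doubles it
  expect_equal(d[3] - d[1], 2 * (d[2] - d[1]), tolerance = 1e-8)
  expect_equal(d[2] - d[1], 2.5, tolerance = 1e-6)
  # and the measured difference itself is the amplitude up to noise
  expect_equal(d[3], 5, tolerance = 1.5)
})

test_that("null recordings carry no reversal information in the first stimulus window", {
  n_tr <- 80
  cfg <- paradigm_config(condition = "ambiguity", n_trials_per_block = n_tr,
                         seed = 31)
  prof <- participant_profile(effect_strength = 0, endo_reversal_prob = 0.5,
                              blink_rate = 0, lapse_prob = 0, error_prob = 0)
  s <- simulate_percept_sequence(cfg, prof, n_tr + 1, seed = 32)
  r <- simulate_responses(s, prof, cfg, seed = 33)
  rec <- simulate_eeg_recording(s, r, cfg, prof, seed = 34)
  onsets <- rec$events$sample[rec$events$type == "stim_onset"]
  fs <- rec$sfreq
  win <- (round(0.3 * fs)):(round(0.9 * fs))
  per_trial <- vapply(seq_len(n_tr), function(tr) {
    mean(rec$voltages["Pz", onsets[tr] + win + 1])
  }, numeric(1))
  rev <- s$true_label == "reversal"
  tt <- stats::t.test(per_trial[rev], per_trial[!rev])
  expect_gt(tt$p.value, 0.01)
})

test_that("blink generation respects the blink rate and vEOG flag", {
  cfg <- paradigm_config(n_trials_per_block = 20, seed = 41)
  prof0 <- participant_profile(blink_rate = 0)
  s <- simulate_percept_sequence(cfg, prof0, 21, seed = 42)
  r <- simulate_responses(s, prof0, cfg, seed = 43)
  rec0 <- simulate_eeg_recording(s, r, cfg, prof0, seed = 44)
  expect_lt(max(abs(rec0$voltages["vEOG", ])), 20)

  prof1 <- participant_profile(blink_rate = 15)
  rec1 <- simulate_eeg_recording(s, r, cfg, prof1, seed = 44)
  expect_gt(max(rec1$voltages["vEOG", ]), 100)

  no_veog <- simulate_eeg_recording(s, r, cfg, prof1, seed = 44,
                                    include_veog = FALSE)
  expect_true(is.na(no_veog$veog_channel))
  expect_equal(nrow(no_veog$voltages), 32)
})

test_that("recordings are bit-identical under a fixed seed and validated", {
  cfg <- paradigm_config(n_trials_per_block = 10, seed = 51)
  prof <- participant_profile()
  s <- simulate_percept_sequence(cfg, prof, 11)
  r <- simulate_responses(s, prof, cfg)
  a <- simulate_eeg_recording(s, r, cfg, prof, seed = 52)
  b <- simulate_eeg_recording(s, r, cfg, prof, seed = 52)
  expect_identical(a$voltages, b$voltages)
  expect_identical(a$events, b$events)

  # marker indices increase and stay inside the recording
  expect_true(all(diff(a$events$sample[a$events$type == "stim_onset"]) > 0))
  expect_true(all(a$events$sample >= 0 &
                    a$events$sample < ncol(a$voltages)))

  bad_cfg <- paradigm_config(n_channels = 8, seed = 1)
  expect_error(simulate_eeg_recording(s, r, bad_cfg, prof),
               "montage")
  expect_error(paradigm_config(exo_reversal_prob = 1.2), "probability")
})
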