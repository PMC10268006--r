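test_that("band-pass attenuates out-of-band components and passes the band", {
  fs <- 250
  t <- seq(0, 40, by = 1 / fs)
  mont <- standard_montage_32()
  n_ch <- nrow(mont)
  mid <- seq(3000, 7000)

  # 50 Hz line component: stopband attenuation beyond 20 dB
  v <- matrix(rep(sin(2 * pi * 50 * t), each = n_ch), n_ch)
  rownames(v) <- mont$name
  rec <- make_rec(v, fs)
  out <- bandpass_and_rereference(rec, preproc_config())
  # re-reference removes common signal; inspect the filter alone
  filt <- revforecast:::zero_phase_bandpass(v[1, , drop = FALSE], fs,
                                            c(0.01, 25))
  expect_lt(max(abs(filt[1, mid])), 10^(-20 / 20))

  # 10 Hz passband essentially untouched
  v10 <- matrix(sin(2 * pi * 10 * t), 1)
  f10 <- revforecast:::zero_phase_bandpass(v10, fs, c(0.01, 25))
  expect_equal(max(abs(f10[1, mid])), 1, tolerance = 0.02)

  # DC removed by the 0.01 Hz high-pass
  vdc <- matrix(7, 1, length(t))
  fdc <- revforecast:::zero_phase_bandpass(vdc, fs, c(0.01, 25))
  expect_lt(mean(abs(fdc[1, mid])), 0.05)
})

test_that("mastoid re-referencing removes common-mode signal", {
  fs <- 250
  mont <- standard_montage_32()
  sig <- sin(2 * pi * 5 * seq(0, 20, by = 1 / fs))
  v <- matrix(rep(sig, each = nrow(mont)), nrow(mont))
  rownames(v) <- mont$name
  out <- bandpass_and_rereference(make_rec(v, fs), preproc_config())
  expect_lt(max(abs(out$voltages)), 1e-8)

  no_ref <- make_rec(v[-match("TP9", mont$name), , drop = FALSE], fs,
                     ch_names = mont$name[-match("TP9", mont$name)])
  expect_error(bandpass_and_rereference(no_ref, preproc_config()), "TP9")
})

test_that("ICA removes exactly the injected blink component", {
  set.seed(8)
  fs <- 250
  n <- 20000
  n_src <- 8
  ch <- c("Fp1", "Fp2", "F3", "F4", "Cz", "Pz", "O1", "O2")
  # independent super-gaussian sources, random stable mixing
  S <- matrix(stats::rexp(n_src * n) * sign(stats::rnorm(n_src * n)), n_src)
  A <- matrix(stats::rnorm(n_src * n_src, sd = 0.5), n_src)
  diag(A) <- 2
  X <- A %*% S

  blink <- numeric(n)
  starts <- seq(1000, n - 500, by = 1700)
  shape <- 80 * (1 - cos(2 * pi * seq_len(75) / 76))
  for (s in starts) blink[s:(s + 74)] <- shape
  proj <- c(1, 0.95, 0.4, 0.4, 0.1, 0.02, 0, 0)
  Xb <- X + outer(proj, blink)
  v <- rbind(Xb, blink + stats::rnorm(n, 0, 2))
  rownames(v) <- c(ch, "vEOG")

  cfg <- preproc_config(ica_n_components = NULL, ica_decim = 2)
  # blink-free recording: the vEOG carries only sensor noise, so no
  # component reaches the correlation threshold
  clean_rec <- make_rec(rbind(X, stats::rnorm(n, 0, 2)), fs,
                        ch_names = c(ch, "vEOG"), veog = "vEOG")
  res0 <- suppressWarnings(remove_blink_components(clean_rec, cfg))
  expect_length(res0$report$removed, 0)

  rec <- make_rec(v, fs, ch_names = c(ch, "vEOG"), veog = "vEOG")
  res <- suppressWarnings(remove_blink_components(rec, cfg))
  expect_length(res$report$removed, 1)
  expect_gt(abs(res$report$removed_correlations), 0.9)
  # cleaning lowers the frontal blink contamination
  pre <- abs(cor(rec$voltages["Fp1", ], blink))
  post <- abs(cor(res$recording$voltages["Fp1", ], blink))
  expect_lt(post, pre / 2)
  # non-blink channels keep their content
  expect_gt(cor(res$recording$voltages["Pz", ], Xb[which(ch == "Pz"), ]), 0.95)

  # unreachable threshold removes nothing
  cfg_hi <- preproc_config(ica_corr_threshold = 1.01,
                           ica_n_components = NULL, ica_decim = 2)
  res_hi <- suppressWarnings(remove_blink_components(rec, cfg_hi))
  expect_length(res_hi$report$removed, 0)
})

test_that("epoching rejects on strict peak-to-peak threshold crossing", {
  fs <- 250
  soa <- 350                       # 1400 ms at 250 Hz
  n_stim <- 11
  n <- 100 + n_stim * soa + 300
  mont <- standard_montage_32()
  v <- matrix(0, nrow(mont), n)
  rownames(v) <- mont$name
  onsets <- 100 + (seq_len(n_stim) - 1) * soa
  ev <- data.frame(sample = onsets, type = "stim_onset", id = seq_len(n_stim))

  ptps <- c(90, 95, 99, 100, 101, 110, 150, 80, 70, 60)
  for (i in seq_along(ptps)) {
    at <- onsets[i] + 150
    v[3, at + 1] <- ptps[i] / 2
    v[3, at + 2] <- -ptps[i] / 2
  }
  rec <- make_rec(v, fs, events = ev)
  # epochs restricted to the first-stimulus window so each spike belongs
  # to exactly one epoch and the counting oracle applies directly
  ep <- epoch_and_reject(rec, preproc_config(epoch_window = c(0, 1000)))
  expect_equal(nrow(ep$info), 10)
  expect_equal(sum(ep$info$rejected), 3)
  expect_equal(which(ep$info$rejected), which(ptps > 100))

  # on the full overlapping grid an epoch also sees its successor's
  # stimulus window, so a spike rejects both epochs it belongs to
  ep_full <- epoch_and_reject(rec, preproc_config())
  over <- ptps > 100
  expect_equal(which(ep_full$info$rejected),
               which(over | c(over[-1], FALSE)))

  # all-zero recording: nothing rejected
  ep0 <- epoch_and_reject(make_rec(matrix(0, nrow(mont), n),
                                   fs, ch_names = mont$name, events = ev),
                          preproc_config())
  expect_equal(sum(ep0$info$rejected), 0)

  # an epoch extending past the recording end is dropped with a warning
  short <- make_rec(v[, 1:(onsets[n_stim] + 100)], fs, events = ev)
  expect_warning(ep_s <- epoch_and_reject(short, preproc_config()),
                 "dropped")
  expect_lt(nrow(ep_s$info), 10)
})

test_that("raising the rejection threshold never increases rejections", {
  ep <- sim_epochs(effect = 0, n_trials = 30, seed = 77, lapse = 0,
                   error = 0, blink_rate = 20)
  counts <- vapply(c(40, 80, 100, 160, 320), function(thr) {
    prof <- participant_profile(blink_rate = 20)
    sim <- simulate_participant(prof, "ambiguity", 30, seed = 77)
    rec <- bandpass_and_rereference(sim$recording,
                                    preproc_config(reject_ptp = thr))
    sum(epoch_and_reject(rec, preproc_config(reject_ptp = thr))$info$rejected)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[1], 0)
})

test_that("baseline correction subtracts the pre-second-stimulus mean", {
  fs <- 250
  n_samp <- 700
  dat <- array(0, c(3, 4, n_samp))
  dat[1, , ] <- 7
  times <- seq(-400, by = 4, length.out = n_samp)
  dat[2, , ] <- rep(times, each = 4)           # ramp equal to t
  dat[3, , ] <- -3
  ep <- make_epochs(dat, labels = rep("stable", 3), times = times)
  out <- baseline_correct(ep, preproc_config())
  expect_true(all(abs(out$data[1, , ]) < 1e-12))
  # ramp: value at the window centre (1390 ms) is the subtracted mean
  centre_idx <- which.min(abs(times - 1390))
  expect_lt(abs(out$data[2, 1, centre_idx]), 2 + 1e-9)
  expect_true(all(abs(out$data[3, , ]) < 1e-12))

  # idempotent: a second pass subtracts zero
  twice <- baseline_correct(out, preproc_config())
  expect_equal(twice$data, out$data, tolerance = 1e-12)

  # window outside the epoch errors
  short <- make_epochs(dat[, , 1:100, drop = FALSE], rep("stable", 3),
                       times = times[1:100])
  expect_error(baseline_correct(short, preproc_config()), "baseline")
})

test_that("trial labeling follows the validity window and latest-press rule", {
  dat <- array(0, c(4, 2, 10))
  ep <- make_epochs(dat, labels = rep("unlabeled", 4))
  behav <- data.frame(
    trial = c(1, 2, 2, 3, 4),
    response_key = c("stable", "stable", "reversal", "reversal", "wrong"),
    latency_ms = c(600, 300, 900, 100, 500))
  out <- label_trials(ep, behav, preproc_config())
  expect_equal(out$info$label,
               c("stable",    # single valid press
                 "reversal",  # latest of two valid presses wins
                 "invalid",   # 100 ms: before the 150 ms validity bound
                 "invalid"))  # wrong key

  # labels partition the trials
  expect_equal(sum(table(out$info$label)), nrow(out$info))

  # a press after the response window is invalid
  late <- data.frame(trial = 1:4, response_key = "reversal",
                     latency_ms = c(1401, 1400, 150, 149))
  out2 <- label_trials(ep, late, preproc_config())
  expect_equal(out2$info$label,
               c("invalid", "reversal", "reversal", "invalid"))

  expect_error(label_trials(ep, behav[behav$trial != 2, ],
                            preproc_config()), "missing trials")
})

test_that("invalid-label fraction matches the behavioral noise model", {
  n_tr <- 400
  lapse <- 0.05
  err <- 0.05
  ep <- sim_epochs(effect = 0, n_trials = n_tr, seed = 13,
                   lapse = lapse, error = err)
  frac <- mean(!(ep$info$label %in% c("reversal", "stable")))
  p <- lapse + err
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n_tr))
})

test_that("participants below 5 reversals per minute are excluded", {
  expect_equal(exclude_low_rate_participants(c(A = 8.2, B = 3.4, C = 5.0)),
               c("A", "C"))
  expect_warning(none <- exclude_low_rate_participants(c(A = 0, B = 0)))
  expect_length(none, 0)
})

test_that("the preprocessing chain records its fixed order", {
  ep <- sim_epochs(effect = 0, n_trials = 12, seed = 3, lapse = 0, error = 0)
  steps <- ep$provenance
  expected <- c("bandpass", "rereference", "epoch_reject", "baseline", "label")
  expect_equal(intersect(steps, expected), expected)
  expect_true(which(steps == "bandpass") < which(steps == "epoch_reject"))
  expect_true(which(steps == "epoch_reject") < which(steps == "baseline"))
  expect_true(which(steps == "baseline") < which(steps == "label"))
})
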