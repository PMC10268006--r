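#' Paradigm configuration
#'
#' Timing and design parameters of the discontinuous onset paradigm: 1000 ms
#' lattice presentations separated by 400 ms blank inter-stimulus intervals,
#' blocks of about 300 trials (roughly 7 min), and two experimental
#' conditions — `"ambiguity"` (ambiguous lattice, endogenous reversals) and
#' `"disambiguation"` (disambiguated lattice variants swapped by the program
#' with a 30% programmed reversal rate).
#'
#' @param stim_duration Stimulus presentation time in ms.
#' @param isi_duration Inter-stimulus interval in ms.
#' @param n_trials_per_block Trials per experimental block.
#' @param n_blocks Number of blocks.
#' @param condition `"ambiguity"` or `"disambiguation"`.
#' @param exo_reversal_prob Programmed per-transition reversal probability in
#'   the disambiguation condition.
#' @param sampling_rate EEG sampling rate in Hz. 250 Hz keeps simulations
#'   desk-sized; 1000 Hz mirrors typical acquisition.
#' @param n_channels Number of EEG channels (must match the montage).
#' @param seed Optional integer seed attached to the configuration.
#' @return A list of class `paradigm_config`.
#' @export
paradigm_config <- function(stim_duration = 1000,
                            isi_duration = 400,
                            n_trials_per_block = 300,
                            n_blocks = 1,
                            condition = c("ambiguity", "disambiguation"),
                            exo_reversal_prob = 0.30,
                            sampling_rate = 250,
                            n_channels = 32,
                            seed = NULL) {
  condition <- match.arg(condition)
  assert_pos(stim_duration, "stim_duration")
  assert_pos(isi_duration, "isi_duration")
  assert_prob(exo_reversal_prob, "exo_reversal_prob")
  assert_pos(sampling_rate, "sampling_rate")
  if (n_blocks < 0) stop("`n_blocks` must be >= 0", call. = FALSE)
  cfg <- list(stim_duration = stim_duration, isi_duration = isi_duration,
              n_trials_per_block = n_trials_per_block, n_blocks = n_blocks,
              condition = condition, exo_reversal_prob = exo_reversal_prob,
              sampling_rate = sampling_rate, n_channels = n_channels,
              seed = seed)
  class(cfg) <- "paradigm_config"
  cfg
}

#' Generative parameters of one simulated observer
#'
#' Houses the destabilization construct (a gradual weakening of the neural
#' representation of the current percept before an endogenous reversal) as
#' an additive, low-frequency amplitude shift over parietal channels, plus a
#' simple behavioral noise model (response latency, lapses, wrong keys) and
#' an ocular artifact rate.
#'
#' @param endo_reversal_prob Per-transition probability of an endogenous
#'   reversal in the ambiguity condition. The default 0.28 corresponds to a
#'   reversal rate of about 12 per minute at the paradigm's 42.9 trials/min.
#' @param effect_strength Amplitude (microvolt) of the destabilization
#'   signature added to ambiguity reversal trials; 0 gives a null observer.
#' @param effect_topography Named channel-weight vector (unitless); default
#'   bilateral parietal, see [parietal_topography()].
#' @param effect_window Interval in ms relative to onset of the stimulus
#'   preceding the indicated reversal over which the signature is present
#'   (default spans that stimulus and the following inter-stimulus interval).
#' @param rt_mean,rt_sd Response latency distribution in ms after onset of
#'   the second stimulus of a pair (truncated normal, clipped to the
#'   response window).
#' @param lapse_prob Probability of giving no response in a trial.
#' @param error_prob Probability of pressing a wrong (non-task) button.
#' @param blink_rate Eye blinks per minute.
#' @param reversal_response_amp Amplitude (microvolt) of the post-onset
#'   reversal-locked component added after onset of the stimulus in which
#'   the reversed percept is established.
#' @param exo_response_gain Multiplier applied to `reversal_response_amp`
#'   in the disambiguation condition, where the physically changed stimulus
#'   evokes a larger reversal response than an endogenous reversal.
#' @return A list of class `participant_profile`.
#' @export
participant_profile <- function(endo_reversal_prob = 0.28,
                                effect_strength = 0,
                                effect_topography = parietal_topography(),
                                effect_window = c(300, 1400),
                                rt_mean = 600,
                                rt_sd = 120,
                                lapse_prob = 0.03,
                                error_prob = 0.02,
                                blink_rate = 12,
                                reversal_response_amp = 2,
                                exo_response_gain = 2) {
  assert_prob(endo_reversal_prob, "endo_reversal_prob")
  assert_prob(lapse_prob, "lapse_prob")
  assert_prob(error_prob, "error_prob")
  assert_pos(effect_strength, "effect_strength", strict = FALSE)
  assert_pos(rt_mean, "rt_mean")
  assert_pos(rt_sd, "rt_sd", strict = FALSE)
  assert_pos(blink_rate, "blink_rate", strict = FALSE)
  stopifnot(length(effect_window) == 2, effect_window[1] < effect_window[2])
  prof <- list(endo_reversal_prob = endo_reversal_prob,
               effect_strength = effect_strength,
               effect_topography = effect_topography,
               effect_window = effect_window,
               rt_mean = rt_mean, rt_sd = rt_sd,
               lapse_prob = lapse_prob, error_prob = error_prob,
               blink_rate = blink_rate,
               reversal_response_amp = reversal_response_amp,
               exo_response_gain = exo_response_gain)
  class(prof) <- "participant_profile"
  prof
}

#' Simulate a sequence of percepts across stimulus presentations
#'
#' Each consecutive pair of presentations forms one trial; the transition is
#' a reversal (percept changes) independently with the programmed
#' probability in the disambiguation condition, or with the observer's
#' endogenous probability in the ambiguity condition.
#'
#' @param config A [paradigm_config()].
#' @param profile A [participant_profile()].
#' @param n_stimuli Number of stimulus presentations (>= 2).
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A list of class `percept_sequence` with elements `percept`
#'   (factor `A`/`B`, length `n_stimuli`) and `true_label` (factor
#'   `reversal`/`stable`, length `n_stimuli - 1`).
#' @export
simulate_percept_sequence <- function(config, profile, n_stimuli,
                                      seed = config$seed) {
  stopifnot(inherits(config, "paradigm_config"),
            inherits(profile, "participant_profile"))
  if (n_stimuli < 2) stop("`n_stimuli` must be >= 2", call. = FALSE)
  p_rev <- switch(config$condition,
                  ambiguity = profile$endo_reversal_prob,
                  disambiguation = config$exo_reversal_prob)
  assert_prob(p_rev, "reversal probability")
  with_seed(seed, {
    first <- sample(c("A", "B"), 1)
    flips <- stats::runif(n_stimuli - 1) < p_rev
    percept <- character(n_stimuli)
    percept[1] <- first
    for (i in seq_len(n_stimuli - 1)) {
      percept[i + 1] <- if (flips[i]) setdiff(c("A", "B"), percept[i]) else percept[i]
    }
    out <- list(
      percept = factor(percept, levels = c("A", "B")),
      true_label = factor(ifelse(flips, "reversal", "stable"),
                          levels = c("reversal", "stable"))
    )
    class(out) <- "percept_sequence"
    out
  })
}

#' Simulate button presses for a percept sequence
#'
#' One behavioral record per trial (consecutive stimulus pair): with
#' `lapse_prob` no key is pressed; with `error_prob` a wrong (non-task) key;
#' otherwise the key matching the true transition. Latencies are drawn from
#' a normal distribution truncated (clipped) to the response window
#' `[0, stim_duration + isi_duration]` ms after onset of the pair's second
#' stimulus.
#'
#' @param seq A `percept_sequence`.
#' @param profile A [participant_profile()].
#' @param config A [paradigm_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A data.frame with columns `trial`, `true_label`, `response_key`
#'   (`reversal`/`stable`/`none`/`wrong`), `latency_ms` (`NA` when no
#'   response).
#' @export
simulate_responses <- function(seq, profile, config, seed = config$seed) {
  stopifnot(inherits(seq, "percept_sequence"))
  n <- length(seq$true_label)
  if (n < 1) stop("percept sequence has no trials", call. = FALSE)
  win_end <- config$stim_duration + config$isi_duration
  with_seed(seed, {
    u <- stats::runif(n)
    key <- as.character(seq$true_label)
    key[u < profile$lapse_prob + profile$error_prob] <- "wrong"
    key[u < profile$lapse_prob] <- "none"
    lat <- stats::rnorm(n, profile$rt_mean, profile$rt_sd)
    lat <- pmin(pmax(lat, 0), win_end)
    lat[key == "none"] <- NA_real_
    data.frame(
      trial = seq_len(n),
      true_label = as.character(seq$true_label),
      response_key = key,
      latency_ms = lat,
      stringsAsFactors = FALSE
    )
  })
}

# -- internal signal primitives -----------------------------------------

# 1/f^alpha (power) noise, unit variance, via spectral shaping; a slow
# random amplitude envelope makes the sources super-gaussian (as cortical
# band-limited activity is), which also keeps them identifiable for ICA
pink_noise <- function(n, alpha = 1, fs = 250, f_floor = 0.1,
                       modulated = TRUE) {
  spec <- stats::fft(stats::rnorm(n))
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f[f > fs / 2] <- fs - f[f > fs / 2]          # two-sided frequency axis
  gain <- pmax(f, f_floor)^(-alpha / 2)
  gain[1] <- 0                                  # no DC
  x <- Re(stats::fft(spec * gain, inverse = TRUE)) / n
  if (modulated) {
    env <- moving_avg(abs(stats::rnorm(n)), max(2L, as.integer(fs)))
    x <- x * (0.4 + env)
  }
  as.numeric(x / stats::sd(x))
}

# centred moving average via cumulative sums (edges use shorter windows)
moving_avg <- function(x, k) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- k %/% 2
  lo <- pmax(seq_len(n) - half - 1, 0)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo + 1]) / (hi - lo)
}

# unit-peak gaussian bump evaluated on a ms axis
gauss_bump <- function(t_ms, center, width) {
  exp(-((t_ms - center)^2) / (2 * width^2))
}

# plateau envelope over [w1, w2] ms with raised-cosine ramps
plateau_envelope <- function(t_ms, w1, w2, ramp = 100) {
  env <- numeric(length(t_ms))
  up <- t_ms >= w1 & t_ms < w1 + ramp
  flat <- t_ms >= w1 + ramp & t_ms <= w2 - ramp
  down <- t_ms > w2 - ramp & t_ms <= w2
  env[up] <- 0.5 * (1 - cos(pi * (t_ms[up] - w1) / ramp))
  env[flat] <- 1
  env[down] <- 0.5 * (1 - cos(pi * (w2 - t_ms[down]) / ramp))
  env
}

#' Simulate a continuous multichannel EEG recording
#'
#' Generates a continuous recording for one observer and one condition with
#' the statistical structure the downstream analysis assumes:
#'
#' * background noise: spatially correlated 1/f ("pink") noise, a posterior
#'   10 Hz oscillation with a slowly varying envelope, and white sensor
#'   noise;
#' * identical stimulus-evoked components on every presentation;
#' * a reversal-locked post-onset component after onset of the second
#'   stimulus of reversal trials (scaled up in the disambiguation condition,
#'   where the stimulus itself changes);
#' * in ambiguity reversal trials only, the destabilization signature:
#'   `effect_strength * effect_topography` over `effect_window` of the
#'   stimulus preceding the indicated reversal and the following
#'   inter-stimulus interval;
#' * eye blinks projected onto frontal channels, plus a vEOG channel.
#'
#' Event markers (`stim_onset`, `stim_offset`, `response`) use 0-based
#' sample indices into the recording.
#'
#' @param seq A `percept_sequence`.
#' @param responses Behavioral data.frame from [simulate_responses()].
#' @param config A [paradigm_config()].
#' @param profile A [participant_profile()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @param montage Montage data.frame; must have `config$n_channels` rows.
#' @param include_veog Append a vEOG channel carrying the blink signal.
#' @param noise_rms RMS amplitudes (microvolt) of the pink, alpha, and white
#'   background components.
#' @return A list of class `continuous_recording`: `voltages`
#'   (channels x samples, microvolt), `sfreq`, `ch_names`, `events`
#'   (data.frame `sample`, `type`, `id`), `veog_channel`, `condition`,
#'   `montage`, `provenance`.
#' @export
simulate_eeg_recording <- function(seq, responses, config, profile,
                                   seed = config$seed,
                                   montage = standard_montage_32(),
                                   include_veog = TRUE,
                                   noise_rms = c(pink = 5, alpha = 3, white = 1.5)) {
  stopifnot(inherits(seq, "percept_sequence"),
            inherits(config, "paradigm_config"),
            inherits(profile, "participant_profile"))
  n_stim <- length(seq$percept)
  n_trials <- n_stim - 1
  if (nrow(responses) != n_trials) {
    stop("trial counts of percept sequence and responses disagree",
         call. = FALSE)
  }
  if (nrow(montage) != config$n_channels) {
    stop(sprintf("montage has %d channels but config requests %d",
                 nrow(montage), config$n_channels), call. = FALSE)
  }
  fs <- config$sampling_rate
  soa_ms <- config$stim_duration + config$isi_duration
  lead_in <- ms_to_samples(config$isi_duration, fs)
  soa <- ms_to_samples(soa_ms, fs)
  stim_len <- ms_to_samples(config$stim_duration, fs)
  n_samples <- lead_in + n_stim * soa
  n_ch <- nrow(montage)
  onsets <- lead_in + (seq_len(n_stim) - 1L) * soa     # 0-based

  topo <- profile$effect_topography
  if (!is.null(names(topo))) {
    missing <- setdiff(names(topo), montage$name)
    if (length(missing) > 0) {
      stop("effect topography names channels absent from the montage: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    w_eff <- stats::setNames(numeric(n_ch), montage$name)
    w_eff[names(topo)] <- topo
  } else {
    if (length(topo) != n_ch) {
      stop("unnamed effect topography must have one weight per channel",
           call. = FALSE)
    }
    w_eff <- topo
  }

  with_seed(seed, {
    ## background noise: spatially mixed pink sources
    src <- matrix(0, n_ch, n_samples)
    for (k in seq_len(n_ch)) src[k, ] <- pink_noise(n_samples, fs = fs)
    mix <- exp(-montage_distances(montage)^2 / (2 * 0.45^2))
    mix <- mix / sqrt(rowSums(mix^2))            # preserve unit source scale
    v <- (mix %*% src) * noise_rms[["pink"]]

    ## posterior 10 Hz oscillation with slow random envelope
    t_sec <- (seq_len(n_samples) - 1) / fs
    env <- moving_avg(abs(stats::rnorm(n_samples)), 2 * as.integer(fs))
    alpha_sig <- sin(2 * pi * 10 * t_sec + stats::runif(1, 0, 2 * pi)) * env
    alpha_sig <- alpha_sig / sqrt(mean(alpha_sig^2))   # unit RMS at the peak
    alpha_topo <- topography_at(montage, 0, -0.85, width = 0.6)
    v <- v + outer(alpha_topo, alpha_sig) * noise_rms[["alpha"]]

    ## white sensor noise
    v <- v + matrix(stats::rnorm(n_ch * n_samples), n_ch) * noise_rms[["white"]]

    ## stimulus-evoked components, identical on every presentation
    ev_ms <- (seq_len(soa) - 1) * 1000 / fs
    topo_occ <- topography_at(montage, 0, -0.9)
    topo_cen <- topography_at(montage, 0, 0.1)
    topo_par <- topography_at(montage, 0, -0.45)
    evoked <- outer(topo_occ, -4.0 * gauss_bump(ev_ms, 100, 25)) +
      outer(topo_cen, 5.0 * gauss_bump(ev_ms, 200, 40)) +
      outer(topo_par, 3.0 * gauss_bump(ev_ms, 380, 80))
    for (s in onsets) {
      idx <- (s + 1):(s + soa)
      v[, idx] <- v[, idx] + evoked
    }

    ## reversal-locked post-onset component on the pair's second stimulus
    amp_rev <- profile$reversal_response_amp *
      if (config$condition == "disambiguation") profile$exo_response_gain else 1
    rev_resp <- outer(topo_par, amp_rev * gauss_bump(ev_ms, 400, 90))
    rev_trials <- which(seq$true_label == "reversal")
    for (tr in rev_trials) {
      s <- onsets[tr + 1]                        # onset of the pair's S_i+1
      idx <- (s + 1):(s + soa)
      v[, idx] <- v[, idx] + rev_resp
    }

    ## destabilization signature: ambiguity reversal trials only, added over
    ## effect_window of the stimulus PRECEDING the indicated reversal
    if (config$condition == "ambiguity" && profile$effect_strength > 0) {
      env_eff <- plateau_envelope(ev_ms, profile$effect_window[1],
                                  profile$effect_window[2])
      eff <- outer(w_eff * profile$effect_strength, env_eff)
      for (tr in rev_trials) {
        s <- onsets[tr]                          # onset of the pair's S_i
        idx <- (s + 1):(s + soa)
        v[, idx] <- v[, idx] + eff
      }
    }

    ## eye blinks: frontal projection + vEOG channel
    duration_min <- n_samples / fs / 60
    n_blinks <- stats::rpois(1, profile$blink_rate * duration_min)
    blink_len <- ms_to_samples(300, fs)
    blink_shape <- 0.5 * (1 - cos(2 * pi * seq_len(blink_len) / (blink_len + 1)))
    veog_sig <- numeric(n_samples)
    if (n_blinks > 0) {
      starts <- sort(sample.int(n_samples - blink_len, n_blinks, replace = TRUE))
      for (s in starts) veog_sig[s:(s + blink_len - 1)] <-
          veog_sig[s:(s + blink_len - 1)] + 150 * blink_shape
    }
    blink_topo <- 0.5 * topography_at(montage, 0, 1.05, width = 0.45)
    v <- v + outer(blink_topo, veog_sig)

    ch_names <- montage$name
    veog_channel <- NA_character_
    if (include_veog) {
      veog <- veog_sig + stats::rnorm(n_samples, 0, 3)
      v <- rbind(v, veog)
      ch_names <- c(ch_names, "vEOG")
      veog_channel <- "vEOG"
    }
    rownames(v) <- ch_names

    ## event markers (0-based samples)
    resp_rows <- which(responses$response_key != "none")
    resp_samples <- onsets[responses$trial[resp_rows] + 1L] +
      ms_to_samples(responses$latency_ms[resp_rows], fs)
    events <- rbind(
      data.frame(sample = onsets, type = "stim_onset", id = seq_len(n_stim)),
      data.frame(sample = onsets + stim_len, type = "stim_offset",
                 id = seq_len(n_stim)),
      if (length(resp_rows) > 0) {
        data.frame(sample = resp_samples, type = "response",
                   id = responses$trial[resp_rows])
      }
    )
    events <- events[order(events$sample, events$type), ]
    rownames(events) <- NULL

    rec <- list(voltages = v, sfreq = fs, ch_names = ch_names,
                events = events, veog_channel = veog_channel,
                condition = config$condition, montage = montage,
                provenance = "simulated")
    class(rec) <- "continuous_recording"
    rec
  })
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %d channels x %d samples @ %g Hz (%s)\n",
              nrow(x$voltages), ncol(x$voltages), x$sfreq, x$condition))
  cat(sprintf("  events: %d | vEOG: %s | provenance: %s\n",
              nrow(x$events), x$veog_channel,
              paste(x$provenance, collapse = " -> ")))
  invisible(x)
}

#' Reversal rate in reversals per minute
#'
#' Counts trials whose valid response indicates a reversal, divides by the
#' block duration in minutes, and averages across blocks. Validity follows
#' the response-labeling rule: a task key (`reversal`/`stable`) pressed
#' between `valid_start` ms after onset of the pair's second stimulus and
#' the end of the following inter-stimulus interval.
#'
#' @param responses Behavioral data.frame (columns `response_key`,
#'   `latency_ms`, optional `block`).
#' @param block_duration_min Block duration in minutes.
#' @param valid_window Validity window in ms after onset of the pair's
#'   second stimulus, default `c(150, 1400)`.
#' @return Mean reversal rate (reversals / minute) across blocks.
#' @export
#' @examples
#' b <- data.frame(response_key = rep("reversal", 56), latency_ms = 600)
#' compute_reversal_rate(b, block_duration_min = 7)  # 8 per minute
compute_reversal_rate <- function(responses, block_duration_min,
                                  valid_window = c(150, 1400)) {
  assert_pos(block_duration_min, "block_duration_min")
  if (nrow(responses) == 0) {
    warning("no behavioral records; reversal rate is 0")
    return(0)
  }
  valid_rev <- responses$response_key == "reversal" &
    !is.na(responses$latency_ms) &
    responses$latency_ms >= valid_window[1] &
    responses$latency_ms <= valid_window[2]
  block <- responses$block %||% rep(1L, nrow(responses))
  per_block <- tapply(valid_rev, block, sum)
  mean(per_block / block_duration_min)
}
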