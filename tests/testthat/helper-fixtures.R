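# Fixtures are built in code: small recordings and epoch sets with known
# structure, so every expectation has a hand-computable answer.

# continuous recording from an explicit voltage matrix
make_rec <- function(voltages, sfreq = 250, ch_names = rownames(voltages),
                     events = data.frame(sample = integer(0),
                                         type = character(0),
                                         id = integer(0)),
                     veog = NA_character_, condition = "ambiguity") {
  rownames(voltages) <- ch_names
  rec <- list(voltages = voltages, sfreq = sfreq, ch_names = ch_names,
              events = events, veog_channel = veog, condition = condition,
              montage = standard_montage_32(), provenance = "fixture")
  class(rec) <- "continuous_recording"
  rec
}

# labeled epoch set from an explicit trials x channels x samples array
make_epochs <- function(data, labels, sfreq = 250, times = NULL,
                        ch_names = NULL, rejected = NULL,
                        condition = "ambiguity") {
  n <- dim(data)[1]
  if (is.null(times)) times <- seq(-400, by = 1000 / sfreq,
                                   length.out = dim(data)[3])
  if (is.null(ch_names)) ch_names <- paste0("ch", seq_len(dim(data)[2]))
  dimnames(data) <- list(NULL, ch_names, NULL)
  ep <- list(data = data, times = times,
             info = data.frame(trial = seq_len(n), condition = condition,
                               label = labels,
                               rejected = rejected %||% rep(FALSE, n)),
             sfreq = sfreq, ch_names = ch_names,
             montage = standard_montage_32(), provenance = "fixture")
  class(ep) <- "epoch_set"
  ep
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# toy decodable epoch set: two class-mean patterns +/- noise over the
# default analysis window; channels named from the montage so ablation
# subsets resolve
make_decodable_epochs <- function(n_trials = 48, n_ch = 8, n_samp = 175,
                                  signal = 1, noise_sd = 0, p_rev = 0.5,
                                  seed = 1, ch_names = NULL, sfreq = 250) {
  set.seed(seed)
  ch_names <- ch_names %||% standard_montage_32()$name[seq_len(n_ch)]
  labels <- ifelse(stats::runif(n_trials) < p_rev, "reversal", "stable")
  pat <- outer(stats::rnorm(n_ch), stats::rnorm(n_samp))
  pat <- pat / max(abs(pat))
  dat <- array(stats::rnorm(n_trials * n_ch * n_samp, sd = noise_sd),
               c(n_trials, n_ch, n_samp))
  for (i in seq_len(n_trials)) {
    s <- if (labels[i] == "reversal") signal else -signal
    dat[i, , ] <- dat[i, , ] + s * pat +
      outer(seq_len(n_ch), seq_len(n_samp), function(a, b) 0.1 * a)
  }
  make_epochs(dat, labels, sfreq = sfreq,
              times = seq(300, by = 1000 / sfreq, length.out = n_samp),
              ch_names = ch_names)
}

# one simulated participant-condition, preprocessed and labeled
sim_epochs <- function(effect = 0, condition = "ambiguity", n_trials = 60,
                       seed = 1, endo = 0.28, exo = 0.30, blink_rate = 0,
                       run_ica = FALSE, lapse = 0.03, error = 0.02, ...) {
  prof <- participant_profile(effect_strength = effect,
                              endo_reversal_prob = endo,
                              blink_rate = blink_rate,
                              lapse_prob = lapse, error_prob = error, ...)
  sim <- simulate_participant(prof, condition, n_trials, seed = seed,
                              exo_reversal_prob = exo)
  suppressWarnings(
    preprocess_participant(sim$recording, sim$behav, run_ica = run_ica)
  )$epochs
}
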