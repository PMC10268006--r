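#' Preprocessing configuration
#'
#' Parameters of the fixed preprocessing chain: zero-phase band-pass
#' 0.01-25 Hz, re-reference to the mastoid average (TP9/TP10), ICA-based
#' blink removal using the 1-10 Hz filtered vEOG with a component
#' correlation threshold of r = 0.8, peak-to-peak rejection at 100 microvolt,
#' baseline correction over -60..+40 ms around onset of the pair's second
#' stimulus, response validity from 150 ms after that onset to the end of
#' the following inter-stimulus interval, and a minimum reversal rate of
#' 5/min for participant inclusion.
#'
#' @param bandpass Band-pass edges in Hz.
#' @param reference Mastoid reference pair (channel names).
#' @param veog_bandpass Band used to filter the vEOG before correlating it
#'   with independent components.
#' @param ica_corr_threshold Absolute component-vEOG correlation above which
#'   a component is removed.
#' @param reject_ptp Peak-to-peak rejection threshold in microvolt
#'   (strictly greater rejects; an epoch exactly at the threshold is kept).
#' @param baseline_window Baseline window in ms relative to onset of the
#'   pair's second stimulus.
#' @param response_valid_start Earliest valid response latency (ms after
#'   onset of the pair's second stimulus).
#' @param min_reversal_rate Minimum reversals/min for inclusion.
#' @param epoch_window Epoch extent in ms relative to onset of the pair's
#'   first stimulus, half-open `[start, end)`.
#' @param hp_order,lp_order Butterworth orders of the high- and low-pass
#'   halves of the band-pass (applied forward-backward, so the effective
#'   order doubles).
#' @param ica_decim Decimation factor for ICA estimation (the unmixing is
#'   estimated on every `ica_decim`-th sample and applied to all samples).
#' @param ica_maxit,ica_tol FastICA iteration cap and convergence tolerance.
#' @param ica_n_components PCA dimension reduction before ICA: a fraction in
#'   (0, 1) keeps the leading components explaining that share of variance
#'   (low-variance directions of spatially smoothed EEG are
#'   indistinguishable from Gaussian noise and carry no separable sources);
#'   an integer keeps that many components; `NULL` keeps the full rank.
#' @param ica_seed Seed of the deterministic ICA initialization.
#' @return A list of class `preproc_config`.
#' @export
preproc_config <- function(bandpass = c(0.01, 25),
                           reference = c("TP9", "TP10"),
                           veog_bandpass = c(1, 10),
                           ica_corr_threshold = 0.8,
                           reject_ptp = 100,
                           baseline_window = c(-60, 40),
                           response_valid_start = 150,
                           min_reversal_rate = 5,
                           epoch_window = c(-400, 2400),
                           hp_order = 2, lp_order = 4,
                           ica_decim = 4, ica_maxit = 100, ica_tol = 1e-4,
                           ica_n_components = 0.99, ica_seed = 1902) {
  stopifnot(length(bandpass) == 2, bandpass[1] < bandpass[2],
            length(veog_bandpass) == 2, veog_bandpass[1] < veog_bandpass[2],
            length(epoch_window) == 2, epoch_window[1] < epoch_window[2])
  assert_pos(reject_ptp, "reject_ptp")
  assert_pos(ica_corr_threshold, "ica_corr_threshold")
  cfg <- list(bandpass = bandpass, reference = reference,
              veog_bandpass = veog_bandpass,
              ica_corr_threshold = ica_corr_threshold,
              reject_ptp = reject_ptp, baseline_window = baseline_window,
              response_valid_start = response_valid_start,
              min_reversal_rate = min_reversal_rate,
              epoch_window = epoch_window,
              hp_order = hp_order, lp_order = lp_order,
              ica_decim = ica_decim, ica_maxit = ica_maxit,
              ica_tol = ica_tol, ica_n_components = ica_n_components,
              ica_seed = ica_seed)
  class(cfg) <- "preproc_config"
  cfg
}

# zero-phase band-pass of a channels x samples matrix; the band is applied
# as a high-pass + low-pass cascade, which stays numerically stable for
# corner frequencies as low as 0.01 Hz
zero_phase_bandpass <- function(v, fs, band, hp_order = 2, lp_order = 4) {
  nyq <- fs / 2
  if (band[2] >= nyq) stop("low-pass edge must be below Nyquist", call. = FALSE)
  hp <- signal::butter(hp_order, band[1] / nyq, type = "high")
  lp <- signal::butter(lp_order, band[2] / nyq, type = "low")
  t(apply(v, 1, function(x) {
    x <- x - mean(x)
    signal::filtfilt(lp, signal::filtfilt(hp, x))
  }))
}

#' Band-pass filter and re-reference a recording
#'
#' Applies the zero-phase (forward-backward) Butterworth band-pass to every
#' EEG channel and re-expresses all EEG channels relative to the average of
#' the mastoid pair. A vEOG channel, if present, is neither band-passed
#' with the EEG band nor re-referenced (it is only used for blink
#' detection, with its own filter).
#'
#' @param rec A `continuous_recording`.
#' @param cfg A [preproc_config()].
#' @return The filtered, re-referenced `continuous_recording`.
#' @export
bandpass_and_rereference <- function(rec, cfg = preproc_config()) {
  stopifnot(inherits(rec, "continuous_recording"))
  missing_ref <- setdiff(cfg$reference, rec$ch_names)
  if (length(missing_ref) > 0) {
    stop("reference channels missing from recording: ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  }
  eeg_idx <- setdiff(seq_along(rec$ch_names),
                     match(rec$veog_channel, rec$ch_names, nomatch = 0))
  v <- rec$voltages
  v[eeg_idx, ] <- zero_phase_bandpass(v[eeg_idx, , drop = FALSE], rec$sfreq,
                                      cfg$bandpass, cfg$hp_order, cfg$lp_order)
  ref <- colMeans(v[match(cfg$reference, rec$ch_names), , drop = FALSE])
  v[eeg_idx, ] <- sweep(v[eeg_idx, , drop = FALSE], 2, ref)
  rec$voltages <- v
  rec$provenance <- c(rec$provenance, "bandpass", "rereference")
  rec
}

# symmetric FastICA (logcosh contrast) on whitened data; deterministic init
fastica_unmix <- function(Z, maxit, tol, seed) {
  k <- nrow(Z)
  n <- ncol(Z)
  W <- with_seed(seed, qr.Q(qr(matrix(stats::rnorm(k * k), k))))
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), k) %*%
      t(e$vectors) %*% W
  }
  W <- sym_decorrelate(W)
  delta <- Inf
  for (it in seq_len(maxit)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    gprime <- rowMeans(1 - G^2)
    W_new <- (G %*% t(Z)) / n - diag(gprime, k) %*% W
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(1 - abs(rowSums(W_new * W))))
    W <- W_new
    if (delta < tol) break
  }
  list(W = W, iterations = it, delta = delta, converged = delta < tol)
}

#' Remove blink-correlated independent components
#'
#' Decomposes the EEG channels (reference pair and vEOG excluded) with a
#' FastICA-class decomposition and correlates every component time course
#' with the vEOG (falling back to Fp1 when no vEOG channel is designated).
#' Both sides of the correlation are band-passed to the blink band
#' (1-10 Hz) first, so broadband background activity in a component does
#' not dilute its blink correlation. Components whose absolute Pearson
#' correlation exceeds the threshold are subtracted from the data via
#' their back-projection.
#'
#' @param rec A `continuous_recording` (band-passed and re-referenced).
#' @param cfg A [preproc_config()].
#' @return A list with elements `recording` (cleaned
#'   `continuous_recording`) and `report` (removed component indices, their
#'   correlations, all component correlations, convergence info).
#' @export
remove_blink_components <- function(rec, cfg = preproc_config()) {
  stopifnot(inherits(rec, "continuous_recording"))
  veog_name <- if (!is.na(rec$veog_channel)) rec$veog_channel else "Fp1"
  if (!veog_name %in% rec$ch_names) {
    stop("neither a vEOG channel nor Fp1 is available for blink detection",
         call. = FALSE)
  }
  nyq <- rec$sfreq / 2
  bp <- signal::butter(2, cfg$veog_bandpass / nyq, type = "pass")
  veog_f <- signal::filtfilt(bp, rec$voltages[veog_name, ] -
                               mean(rec$voltages[veog_name, ]))

  drop_ch <- c(cfg$reference, rec$veog_channel)
  ica_idx <- which(!(rec$ch_names %in% drop_ch))
  X <- rec$voltages[ica_idx, , drop = FALSE]
  mu <- rowMeans(X)
  Xc <- X - mu

  dec <- max(1L, as.integer(cfg$ica_decim))
  sub <- seq(1, ncol(Xc), by = dec)
  C <- (Xc[, sub] %*% t(Xc[, sub])) / (length(sub) - 1)
  e <- eigen(C, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-8
  ncomp <- cfg$ica_n_components %||% sum(keep)
  if (ncomp < 1) {               # variance fraction
    cum <- cumsum(e$values) / sum(e$values)
    ncomp <- which(cum >= ncomp)[1]
  }
  keep <- seq_len(min(sum(keep), ncomp))
  K <- diag(1 / sqrt(e$values[keep]), length(keep)) %*% t(e$vectors[, keep, drop = FALSE])

  fit <- fastica_unmix(K %*% Xc[, sub], cfg$ica_maxit, cfg$ica_tol,
                       cfg$ica_seed)
  if (!all(is.finite(fit$W))) {
    stop(sprintf(
      "ICA decomposition failed numerically (residual change %.2e after %d iterations)",
      fit$delta, fit$iterations), call. = FALSE)
  }
  if (!fit$converged) {
    warning(sprintf(
      "ICA stopped at maxit with residual change %.2e (tolerance %.0e); the rotation criterion rarely settles on the near-gaussian background subspace and the decomposition remains usable",
      fit$delta, cfg$ica_tol))
  }

  unmix <- fit$W %*% K              # components x channels
  S <- unmix %*% Xc                 # component time courses, full length
  mixing <- MASS_ginv(unmix)        # channels x components
  # both sides of the correlation live in the blink band
  Sf <- t(apply(S, 1, function(x) signal::filtfilt(bp, x - mean(x))))
  r <- as.numeric(stats::cor(t(Sf), veog_f))
  removed <- which(abs(r) > cfg$ica_corr_threshold)

  if (length(removed) > 0) {
    rec$voltages[ica_idx, ] <- rec$voltages[ica_idx, ] -
      mixing[, removed, drop = FALSE] %*% S[removed, , drop = FALSE]
  }
  rec$provenance <- c(rec$provenance, "ica_blink_removal")
  report <- list(removed = removed, removed_correlations = r[removed],
                 correlations = r, n_components = nrow(S),
                 veog_source = veog_name, iterations = fit$iterations,
                 converged = fit$converged)
  list(recording = rec, report = report)
}

# Moore-Penrose pseudoinverse (small matrices only)
MASS_ginv <- function(A, tol = 1e-10) {
  s <- svd(A)
  pos <- s$d > max(s$d) * tol
  s$v[, pos, drop = FALSE] %*% diag(1 / s$d[pos], sum(pos)) %*%
    t(s$u[, pos, drop = FALSE])
}

#' Cut epochs on the trial grid and flag artifact trials
#'
#' One epoch per consecutive stimulus pair, spanning `epoch_window`
#' (default -400..2400 ms, half-open) relative to onset of the pair's first
#' stimulus, so the pair's first stimulus occupies 0-1000 ms, the
#' inter-stimulus interval 1000-1400 ms, and the second stimulus
#' 1400-2400 ms. An epoch is flagged rejected iff any EEG channel's
#' peak-to-peak amplitude within it strictly exceeds `reject_ptp`. Epochs
#' extending past either end of the recording are dropped with a warning.
#' A vEOG channel is not carried into the epochs.
#'
#' @param rec A `continuous_recording` with `stim_onset` events.
#' @param cfg A [preproc_config()].
#' @return A list of class `epoch_set`: `data` (trials x channels x
#'   samples), `times` (ms relative to first-stimulus onset), `info`
#'   (per-trial data.frame with `trial`, `condition`, `label`, `rejected`),
#'   `sfreq`, `ch_names`, `montage`, `provenance`.
#' @export
epoch_and_reject <- function(rec, cfg = preproc_config()) {
  stopifnot(inherits(rec, "continuous_recording"))
  onsets <- rec$events$sample[rec$events$type == "stim_onset"]
  if (length(onsets) < 2) stop("need at least two stimulus onsets", call. = FALSE)
  onsets <- sort(onsets)
  fs <- rec$sfreq
  rel <- seq(ms_to_samples(cfg$epoch_window[1], fs),
             ms_to_samples(cfg$epoch_window[2], fs) - 1L)
  times <- rel * 1000 / fs
  anchors <- onsets[-length(onsets)]          # pair's first stimulus, 0-based
  ok <- anchors + rel[1] >= 0 & anchors + rel[length(rel)] <= ncol(rec$voltages) - 1
  if (any(!ok)) {
    warning(sprintf("%d epoch(s) extend past the recording and were dropped",
                    sum(!ok)))
  }
  keep_tr <- which(ok)
  eeg_idx <- setdiff(seq_along(rec$ch_names),
                     match(rec$veog_channel, rec$ch_names, nomatch = 0))
  ch_names <- rec$ch_names[eeg_idx]
  dat <- array(NA_real_, c(length(keep_tr), length(eeg_idx), length(rel)),
               dimnames = list(NULL, ch_names, NULL))
  rejected <- logical(length(keep_tr))
  for (i in seq_along(keep_tr)) {
    idx <- anchors[keep_tr[i]] + rel + 1L      # to 1-based columns
    ep <- rec$voltages[eeg_idx, idx, drop = FALSE]
    dat[i, , ] <- ep
    ptp <- apply(ep, 1, function(x) max(x) - min(x))
    rejected[i] <- any(ptp > cfg$reject_ptp)
  }
  info <- data.frame(trial = keep_tr,
                     condition = rec$condition,
                     label = "unlabeled",
                     rejected = rejected,
                     stringsAsFactors = FALSE)
  ep <- list(data = dat, times = times, info = info, sfreq = fs,
             ch_names = ch_names, montage = rec$montage,
             provenance = c(rec$provenance, "epoch_reject"))
  class(ep) <- "epoch_set"
  ep
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$sfreq))
  cat(sprintf("  labels: %s | rejected: %d\n",
              paste(sprintf("%s=%d", names(table(x$info$label)),
                            table(x$info$label)), collapse = " "),
              sum(x$info$rejected)))
  invisible(x)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean amplitude over the baseline
#' window (default -60..+40 ms around onset of the pair's second stimulus,
#' i.e. 1340..1440 ms on the epoch time axis) from the whole epoch.
#'
#' @param ep An `epoch_set`.
#' @param cfg A [preproc_config()].
#' @param second_onset_ms Onset of the pair's second stimulus on the epoch
#'   time axis (ms).
#' @return The baseline-corrected `epoch_set`.
#' @export
baseline_correct <- function(ep, cfg = preproc_config(),
                             second_onset_ms = 1400) {
  stopifnot(inherits(ep, "epoch_set"))
  win <- second_onset_ms + cfg$baseline_window
  sel <- which(ep$times >= win[1] & ep$times <= win[2])
  if (length(sel) == 0) {
    stop("baseline window lies outside the epoch time axis", call. = FALSE)
  }
  base <- apply(ep$data[, , sel, drop = FALSE], c(1, 2), mean)
  ep$data <- ep$data - array(base, dim(ep$data))
  ep$provenance <- c(ep$provenance, "baseline")
  ep
}

#' Label trials from behavioral responses
#'
#' A trial is labeled `reversal` or `stable` from the latest task-key press
#' inside the validity window (from `response_valid_start` ms after onset
#' of the pair's second stimulus to the end of the following
#' inter-stimulus interval). Trials with no press in the window, or only
#' wrong-key presses, are labeled `invalid` and excluded from all analyses.
#'
#' @param ep An `epoch_set`.
#' @param behav Behavioral data.frame with columns `trial`, `response_key`,
#'   `latency_ms`; multiple rows per trial are allowed (repeated presses).
#' @param cfg A [preproc_config()].
#' @param response_window_end End of the validity window in ms after onset
#'   of the pair's second stimulus (stimulus duration + interval).
#' @return The labeled `epoch_set`.
#' @export
label_trials <- function(ep, behav, cfg = preproc_config(),
                         response_window_end = 1400) {
  stopifnot(inherits(ep, "epoch_set"))
  missing_tr <- setdiff(ep$info$trial, behav$trial)
  if (length(missing_tr) > 0) {
    stop("behavioral log is missing trials: ",
         paste(utils::head(missing_tr, 5), collapse = ", "), call. = FALSE)
  }
  lab <- vapply(ep$info$trial, function(tr) {
    rows <- behav[behav$trial == tr &
                    behav$response_key %in% c("reversal", "stable") &
                    !is.na(behav$latency_ms) &
                    behav$latency_ms >= cfg$response_valid_start &
                    behav$latency_ms <= response_window_end, , drop = FALSE]
    if (nrow(rows) == 0) "invalid" else rows$response_key[which.max(rows$latency_ms)]
  }, character(1))
  ep$info$label <- lab
  ep$provenance <- c(ep$provenance, "label")
  ep
}

#' Apply the minimum-reversal-rate inclusion rule
#'
#' Participants with fewer than `min_rate` reversals per minute are
#' excluded ("less than" excludes, so a rate exactly at the threshold is
#' retained).
#'
#' @param rates Named numeric vector of reversal rates (reversals/min).
#' @param min_rate Inclusion threshold.
#' @return Character vector of retained participant names.
#' @export
#' @examples
#' exclude_low_rate_participants(c(A = 8.2, B = 3.4, C = 5.0))  # A and C
exclude_low_rate_participants <- function(rates, min_rate = 5) {
  stopifnot(is.numeric(rates), all(rates >= 0, na.rm = TRUE))
  kept <- names(rates)[!is.na(rates) & rates >= min_rate]
  if (length(kept) == 0) warning("no participants meet the inclusion rule")
  kept
}

# indices of trials usable for analysis: validly labeled and not rejected
valid_trials <- function(ep) {
  which(ep$info$label %in% c("reversal", "stable") & !ep$info$rejected)
}

# drop channels from an epoch set (used by the ablation analysis)
drop_channels <- function(ep, channels) {
  keep <- setdiff(ep$ch_names, channels)
  if (length(keep) < 4) {
    stop("channel removal would leave fewer than 4 channels", call. = FALSE)
  }
  sel <- match(keep, ep$ch_names)
  ep$data <- ep$data[, sel, , drop = FALSE]
  ep$ch_names <- keep
  ep
}
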