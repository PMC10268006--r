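#' End-to-end run configuration
#'
#' Bundles the paradigm, cohort, preprocessing, and decoding parameters of
#' a full simulated study. The default cohort mirrors the study design the
#' pipeline is meant to recover: 15 observers, 8 of whom carry a parietal
#' destabilization signature in the ambiguity condition ("effect"
#' observers) and 7 of whom are null observers.
#'
#' @param n_participants Cohort size.
#' @param n_effect Number of effect observers (the first `n_effect`
#'   participants carry the destabilization signature).
#' @param effect_strength Signature amplitude in microvolt for effect
#'   observers.
#' @param trials_per_condition Trials per participant and condition.
#' @param n_blocks Blocks per condition (must be >= 1; trials are split
#'   evenly across blocks).
#' @param sampling_rate EEG sampling rate in Hz.
#' @param endo_reversal_prob Endogenous per-transition reversal probability.
#' @param blink_rate Blinks per minute (0 disables ocular artifacts and the
#'   ICA step).
#' @param run_ica Run ICA blink removal during preprocessing.
#' @param classifier_spec Registered classifier name.
#' @param n_boot Bootstrap replicates per accuracy distribution.
#' @param run_ablation Run the electrode-subset ablation on the indicative
#'   participants.
#' @param seed Master seed; every stochastic draw in the run is derived
#'   from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_participants = 15, n_effect = 8,
                       effect_strength = 2.0, trials_per_condition = 240,
                       n_blocks = 1, sampling_rate = 250,
                       endo_reversal_prob = 0.28, blink_rate = 12,
                       run_ica = TRUE, classifier_spec = "linear",
                       n_boot = 1000, run_ablation = TRUE, seed = 1) {
  cfg <- list(n_participants = n_participants, n_effect = n_effect,
              effect_strength = effect_strength,
              trials_per_condition = trials_per_condition,
              n_blocks = n_blocks, sampling_rate = sampling_rate,
              endo_reversal_prob = endo_reversal_prob,
              blink_rate = blink_rate, run_ica = run_ica,
              classifier_spec = classifier_spec, n_boot = n_boot,
              run_ablation = run_ablation, seed = seed)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  if (cfg$n_blocks < 1) stop("`n_blocks` must be >= 1", call. = FALSE)
  if (cfg$n_participants < 1) stop("`n_participants` must be >= 1", call. = FALSE)
  if (cfg$n_effect < 0 || cfg$n_effect > cfg$n_participants) {
    stop("`n_effect` must be between 0 and `n_participants`", call. = FALSE)
  }
  if (cfg$trials_per_condition < 8) {
    stop("`trials_per_condition` must be >= 8", call. = FALSE)
  }
  assert_prob(cfg$endo_reversal_prob, "endo_reversal_prob")
  assert_pos(cfg$effect_strength, "effect_strength", strict = FALSE)
  assert_pos(cfg$sampling_rate, "sampling_rate")
  invisible(cfg)
}

#' Read a run configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; absent keys keep their
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configurations",
         call. = FALSE)
  }
  vals <- yaml::read_yaml(path)
  keep <- intersect(names(vals), names(formals(run_config)))
  do.call(run_config, vals[keep])
}

#' Simulate one participant in one condition
#'
#' Percept sequence, button presses, and continuous EEG, all derived from
#' one seed.
#'
#' @param profile A [participant_profile()].
#' @param condition `"ambiguity"` or `"disambiguation"`.
#' @param n_trials Number of trials (stimulus pairs).
#' @param sampling_rate EEG sampling rate in Hz.
#' @param seed Integer seed.
#' @param ... Further arguments passed to [paradigm_config()].
#' @return List with `recording`, `behav`, `seq`, `config`.
#' @export
simulate_participant <- function(profile, condition, n_trials,
                                 sampling_rate = 250, seed = 1, ...) {
  cfg <- paradigm_config(condition = condition,
                         n_trials_per_block = n_trials,
                         sampling_rate = sampling_rate, seed = seed, ...)
  seq <- simulate_percept_sequence(cfg, profile, n_stimuli = n_trials + 1,
                                   seed = derive_seed(seed, "percepts"))
  behav <- simulate_responses(seq, profile, cfg,
                              seed = derive_seed(seed, "responses"))
  rec <- simulate_eeg_recording(seq, behav, cfg, profile,
                                seed = derive_seed(seed, "eeg"))
  list(recording = rec, behav = behav, seq = seq, config = cfg)
}

#' Preprocess one recording into labeled epochs
#'
#' The fixed chain: band-pass filter, mastoid re-reference, ICA blink
#' removal (optional), epoching with peak-to-peak rejection, baseline
#' correction, response-validity labeling. The order is recorded in the
#' epoch set's provenance.
#'
#' @param rec A `continuous_recording`.
#' @param behav Behavioral data.frame for labeling.
#' @param cfg A [preproc_config()].
#' @param run_ica Run ICA blink removal.
#' @return List with `epochs` (labeled `epoch_set`) and `qc` (rejection
#'   fractions before/after validity labeling, removed ICA components).
#' @export
preprocess_participant <- function(rec, behav, cfg = preproc_config(),
                                   run_ica = TRUE) {
  rec <- bandpass_and_rereference(rec, cfg)
  ica_report <- NULL
  if (run_ica) {
    cleaned <- remove_blink_components(rec, cfg)
    rec <- cleaned$recording
    ica_report <- cleaned$report
  }
  ep <- epoch_and_reject(rec, cfg)
  ep <- baseline_correct(ep, cfg)
  ep <- label_trials(ep, behav, cfg)
  valid <- ep$info$label %in% c("reversal", "stable")
  qc <- list(
    n_trials = nrow(ep$info),
    frac_rejected_all = mean(ep$info$rejected),
    frac_rejected_valid = if (any(valid)) mean(ep$info$rejected[valid]) else NA,
    frac_invalid = mean(!valid),
    ica_removed = ica_report$removed %||% integer(0),
    ica_correlations = ica_report$removed_correlations %||% numeric(0)
  )
  list(epochs = ep, qc = qc)
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Simulate -> preprocess -> reversal-rate exclusion -> group GFP and
#' pointwise statistics -> temporal region of interest -> per-participant
#' four-fold decoding in both windows and conditions -> bootstrap accuracy
#' distributions, KS separability, indicative selection, accuracy ratios,
#' window correlation -> electrode-subset ablation on the indicative
#' participants. Every stochastic draw derives from the master seed.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory; when given, the report is
#'   written as `report.json` plus TSV tables (`gfp_traces.tsv`,
#'   `stats_<condition>.tsv`, `decoding.tsv`, `separability.tsv`,
#'   `ablation.tsv`).
#' @param verbose Print stage progress.
#' @return A list of class `run_report`; see the elements `reversal_rates`,
#'   `included`, `roi`, `gfp_stats`, `decoding`, `separability`,
#'   `indicative`, `ablation`, `provenance`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         verbose = FALSE) {
  validate_run_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  master <- config$seed
  pids <- sprintf("P%02d", seq_len(config$n_participants))
  pp_cfg <- preproc_config()
  conditions <- c("ambiguity", "disambiguation")

  profiles <- stats::setNames(lapply(seq_along(pids), function(i) {
    participant_profile(
      endo_reversal_prob = config$endo_reversal_prob,
      effect_strength = if (i <= config$n_effect) config$effect_strength else 0,
      blink_rate = config$blink_rate
    )
  }), pids)

  ## simulate + preprocess
  say("simulating and preprocessing %d participants", length(pids))
  cohort <- list()
  qc <- list()
  rates <- stats::setNames(numeric(length(pids)), pids)
  block_min <- config$trials_per_condition * 1.4 / 60
  for (pid in pids) {
    cohort[[pid]] <- list()
    for (cond in conditions) {
      sim <- simulate_participant(
        profiles[[pid]], cond, config$trials_per_condition,
        sampling_rate = config$sampling_rate,
        seed = derive_seed(master, "simulate", pid, cond))
      prep <- preprocess_participant(
        sim$recording, sim$behav, pp_cfg,
        run_ica = config$run_ica && config$blink_rate > 0)
      cohort[[pid]][[cond]] <- prep$epochs
      qc[[paste(pid, cond, sep = ".")]] <- prep$qc
      if (cond == "ambiguity") {
        rates[pid] <- compute_reversal_rate(sim$behav, block_min)
      }
    }
  }

  included <- exclude_low_rate_participants(rates, pp_cfg$min_reversal_rate)
  say("included %d / %d participants", length(included), length(pids))

  ## group GFP + pointwise statistics per condition
  gfp_traces <- list()
  gfp_stats <- list()
  for (cond in conditions) {
    rev_mat <- NULL; stab_mat <- NULL
    for (pid in included) {
      g <- compute_gfp(compute_erp(cohort[[pid]][[cond]]))
      rev_mat <- rbind(rev_mat, g$reversal)
      stab_mat <- rbind(stab_mat, g$stable)
    }
    rownames(rev_mat) <- rownames(stab_mat) <- included
    times <- cohort[[included[1]]][[cond]]$times
    gfp_traces[[cond]] <- list(reversal = rev_mat, stable = stab_mat,
                               times = times)
    gfp_stats[[cond]] <- pointwise_stats(rev_mat - stab_mat, times)
  }
  roi <- select_temporal_roi(gfp_stats[["ambiguity"]])
  say("temporal ROI: [%g, %g] ms (%s)", roi$start, roi$end, roi$source)

  ## per-participant decoding, both conditions x both windows
  decoding <- list()
  dec_rows <- list()
  for (pid in included) {
    for (cond in conditions) {
      for (win in c("roi", "isi")) {
        window <- if (win == "roi") c(roi$start, roi$end) else "isi"
        res <- train_and_evaluate(
          cohort[[pid]][[cond]], window = window,
          classifier_spec = config$classifier_spec,
          seed = derive_seed(master, "decode", pid, cond, win))
        decoding[[pid]][[cond]][[win]] <- res
        dec_rows[[length(dec_rows) + 1]] <- data.frame(
          participant = pid, condition = cond, window = win,
          median_accuracy = res$median_accuracy)
      }
    }
  }
  decoding_table <- do.call(rbind, dec_rows)

  ## separability: bootstrap + KS per participant and window
  sep_rows <- list()
  for (pid in included) {
    row <- list(participant = pid)
    for (win in c("roi", "isi")) {
      boots <- lapply(conditions, function(cond) {
        bootstrap_accuracy_distribution(
          decoding[[pid]][[cond]][[win]]$pairs, n_boot = config$n_boot,
          seed = derive_seed(master, "bootstrap", pid, cond, win))
      })
      ks <- ks_separability(boots[[1]], boots[[2]])
      tag <- if (win == "roi") "si" else "isi"
      row[[paste0("ks_", tag)]] <- ks$statistic
      row[[paste0("ks_", tag, "_p")]] <- ks$p.value
      row[[paste0("ratio_", tag)]] <-
        decoding[[pid]][["ambiguity"]][[win]]$median_accuracy /
        decoding[[pid]][["disambiguation"]][[win]]$median_accuracy
    }
    sep_rows[[length(sep_rows) + 1]] <- as.data.frame(row)
  }
  separability <- do.call(rbind, sep_rows)
  indicative <- select_indicative(separability)
  separability$indicative <- separability$participant %in% indicative
  corr <- if (nrow(separability) >= 5) window_correlation(separability) else NULL
  say("indicative participants: %s", paste(indicative, collapse = ", "))

  ## electrode-subset ablation on the indicative participants
  ablation <- NULL
  if (config$run_ablation && length(indicative) > 0) {
    say("ablation over %d electrode subsets", length(electrode_subsets()))
    ablation <- ablate_and_rank(
      cohort, participants = indicative,
      window = c(roi$start, roi$end),
      classifier_spec = config$classifier_spec,
      seed = master)
  }

  report <- list(
    config = unclass(config),
    reversal_rates = rates,
    included = included,
    qc = qc,
    gfp_traces = gfp_traces,
    gfp_stats = gfp_stats,
    roi = unclass(roi),
    decoding = decoding,
    decoding_table = decoding_table,
    separability = separability,
    window_correlation = corr,
    indicative = indicative,
    ablation = ablation,
    provenance = list(package = "revforecast",
                      version = as.character(utils::packageVersion("revforecast")),
                      master_seed = master)
  )
  class(report) <- "run_report"
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d participants (%d included), master seed %d\n",
              x$config$n_participants, length(x$included),
              x$provenance$master_seed))
  cat(sprintf("  ROI: [%g, %g] ms (%s)\n", x$roi$start, x$roi$end, x$roi$source))
  for (cond in names(x$gfp_traces)) {
    tab <- x$decoding_table
    m <- tab$median_accuracy[tab$condition == cond & tab$window == "roi"]
    cat(sprintf("  mean median accuracy (%s, ROI window): %.1f%%\n",
                cond, 100 * mean(m)))
  }
  cat(sprintf("  indicative: %s\n",
              if (length(x$indicative)) paste(x$indicative, collapse = ", ")
              else "none"))
  invisible(x)
}

#' Persist a run report
#'
#' Writes `report.json` (summary numbers and provenance) plus the TSV
#' tables of GFP traces, pointwise statistics, decoding accuracies,
#' separability, and ablation ratios.
#'
#' @param report A `run_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, file) {
    utils::write.table(df, file.path(out_dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  gfp_long <- do.call(rbind, lapply(names(report$gfp_traces), function(cond) {
    tr <- report$gfp_traces[[cond]]
    do.call(rbind, lapply(c("reversal", "stable"), function(lab) {
      m <- tr[[lab]]
      data.frame(participant = rep(rownames(m), each = ncol(m)),
                 condition = cond, label = lab,
                 time_ms = rep(tr$times, nrow(m)),
                 gfp = as.numeric(t(m)))
    }))
  }))
  wt(gfp_long, "gfp_traces.tsv")
  for (cond in names(report$gfp_stats)) {
    wt(report$gfp_stats[[cond]], sprintf("stats_%s.tsv", cond))
  }
  wt(report$decoding_table, "decoding.tsv")
  wt(report$separability, "separability.tsv")
  if (!is.null(report$ablation)) wt(report$ablation$ratios, "ablation.tsv")
  summary <- list(
    config = report$config,
    reversal_rates = as.list(report$reversal_rates),
    included = report$included,
    roi = report$roi,
    mean_median_accuracy = lapply(split(
      report$decoding_table$median_accuracy,
      paste(report$decoding_table$condition, report$decoding_table$window,
            sep = ".")), mean),
    indicative = report$indicative,
    window_correlation = report$window_correlation,
    ablation_summary = if (!is.null(report$ablation)) report$ablation$summary,
    provenance = report$provenance
  )
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
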