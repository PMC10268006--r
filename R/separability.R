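#' Bootstrap distribution of classification accuracy
#'
#' Pools the per-trial (prediction, truth) pairs from all four evaluation
#' sets, then repeatedly (default 1000 times) draws 70% of the pairs with
#' replacement and computes an accuracy value, yielding a per-participant,
#' per-condition, per-window accuracy distribution. The draw size is
#' `ceiling(frac * N)`.
#'
#' @param pairs Data.frame with columns `truth` and `prediction` (a
#'   `decoding_result$pairs`), or a logical vector of per-trial
#'   correctness.
#' @param n_boot Number of bootstrap replicates.
#' @param frac Fraction of pairs drawn per replicate.
#' @param seed Integer seed.
#' @return Numeric vector of `n_boot` accuracies in `[0, 1]`.
#' @export
bootstrap_accuracy_distribution <- function(pairs, n_boot = 1000,
                                            frac = 0.70, seed = 1) {
  correct <- if (is.data.frame(pairs)) pairs$prediction == pairs$truth else pairs
  n <- length(correct)
  if (n == 0) stop("no evaluation pairs", call. = FALSE)
  if (n < 10) warning("fewer than 10 pairs; bootstrap distribution unstable")
  m <- ceiling(frac * n)
  with_seed(seed, {
    idx <- sample.int(n, m * n_boot, replace = TRUE)
    colMeans(matrix(correct[idx], nrow = m, ncol = n_boot))
  })
}

#' Two-sample Kolmogorov-Smirnov separability
#'
#' Sup-norm distance between the empirical CDFs of the two bootstrap
#' accuracy distributions (ambiguity vs. disambiguation), in `[0, 1]`,
#' with the asymptotic two-sided p-value. The statistic is the separability
#' measure; the p-value is ancillary (bootstrap samples are not
#' independent draws).
#'
#' @param amb,dis Numeric accuracy samples.
#' @return List with `statistic` and `p.value`.
#' @export
ks_separability <- function(amb, dis) {
  kt <- suppressWarnings(stats::ks.test(amb, dis, exact = FALSE))
  list(statistic = unname(kt$statistic), p.value = unname(kt$p.value))
}

#' Select indicative participants
#'
#' A participant is indicative when the bootstrap accuracy distributions of
#' the two conditions are separable with a KS statistic of at least 0.8 in
#' either analysis window (first-stimulus window or inter-stimulus
#' interval).
#'
#' @param results Data.frame with columns `participant`, `ks_si`, `ks_isi`.
#' @param threshold KS threshold (inclusive).
#' @return Character vector of indicative participant ids.
#' @export
#' @examples
#' select_indicative(data.frame(participant = c("a", "b"),
#'                              ks_si = c(0.85, 0.79), ks_isi = c(0.3, 0.79)))
select_indicative <- function(results, threshold = 0.8) {
  stopifnot(all(c("participant", "ks_si", "ks_isi") %in% names(results)))
  ind <- results$ks_si >= threshold | results$ks_isi >= threshold
  as.character(results$participant[ind])
}

#' Correlation of separability across analysis windows
#'
#' Rank (Spearman) correlation between per-participant KS statistics of the
#' first-stimulus window and the inter-stimulus interval; the Pearson
#' correlation is reported alongside.
#'
#' @param results Data.frame with columns `ks_si`, `ks_isi`.
#' @return List with `rho`, `p.value` (Spearman) and `pearson_r`,
#'   `pearson_p`. Constant inputs give `NA` with a warning.
#' @export
window_correlation <- function(results) {
  stopifnot(all(c("ks_si", "ks_isi") %in% names(results)))
  if (nrow(results) < 5) {
    stop("window correlation needs >= 5 participants", call. = FALSE)
  }
  x <- results$ks_si
  y <- results$ks_isi
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant KS statistics; correlation undefined")
    return(list(rho = NA_real_, p.value = NA_real_,
                pearson_r = NA_real_, pearson_p = NA_real_))
  }
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  pe <- stats::cor.test(x, y, method = "pearson")
  list(rho = unname(sp$estimate), p.value = sp$p.value,
       pearson_r = unname(pe$estimate), pearson_p = pe$p.value)
}

#' Electrode-subset ablation of the decoding protocol
#'
#' Reruns the full decoding protocol with each named electrode subset
#' removed from both training and evaluation (plus a no-removal baseline),
#' on both conditions over the first-stimulus region of interest, and
#' reports the per-participant and mean accuracy ratio
#' (ambiguity / disambiguation) per subset. The disambiguation condition
#' serves as the control: the trial before an exogenously induced reversal
#' carries no information about it.
#'
#' @param cohort Named list (one element per participant) of lists with
#'   elements `ambiguity` and `disambiguation`, each a labeled `epoch_set`.
#' @param participants Participants to analyze (default all of `cohort`;
#'   typically the indicative set).
#' @param subsets Named list of electrode subsets
#'   (default [electrode_subsets()]).
#' @param window Analysis window (`temporal_roi` or `c(start, end)` ms).
#' @param classifier_spec Registered classifier name.
#' @param seed Integer master seed.
#' @param include_baseline Include the `none` (no removal) baseline row.
#' @return A list of class `ablation_result`: `ratios` (data.frame
#'   `subset`, `participant`, `accuracy_ambiguity`,
#'   `accuracy_disambiguation`, `ratio`) and `summary` (per-subset mean and
#'   SD of the ratio).
#' @export
ablate_and_rank <- function(cohort, participants = names(cohort),
                            subsets = electrode_subsets(),
                            window = c(300, 700),
                            classifier_spec = "linear", seed = 1,
                            include_baseline = TRUE) {
  if (length(participants) == 0) stop("no participants to ablate", call. = FALSE)
  run_list <- c(if (include_baseline) list(none = character(0)), subsets)
  rows <- list()
  for (sub_name in names(run_list)) {
    for (pid in participants) {
      accs <- vapply(c("ambiguity", "disambiguation"), function(cond) {
        ep <- cohort[[pid]][[cond]]
        ep_sub <- if (length(run_list[[sub_name]]) > 0) {
          drop_channels(ep, run_list[[sub_name]])
        } else ep
        res <- train_and_evaluate(ep_sub, window = window,
                                  classifier_spec = classifier_spec,
                                  seed = derive_seed(seed, "decode", pid,
                                                     cond, "roi"))
        res$median_accuracy
      }, numeric(1))
      rows[[length(rows) + 1]] <- data.frame(
        subset = sub_name, participant = pid,
        accuracy_ambiguity = accs[["ambiguity"]],
        accuracy_disambiguation = accs[["disambiguation"]],
        ratio = accs[["ambiguity"]] / accs[["disambiguation"]])
    }
  }
  ratios <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(ratios, ratios$subset), function(df) {
    data.frame(subset = df$subset[1],
               mean_ratio = mean(df$ratio), sd_ratio = stats::sd(df$ratio),
               mean_accuracy_ambiguity = mean(df$accuracy_ambiguity))
  }))
  rownames(summ) <- NULL
  out <- list(ratios = ratios, summary = summ, window = window)
  class(out) <- "ablation_result"
  out
}

#' @export
print.ablation_result <- function(x, ...) {
  cat("<ablation_result> mean accuracy ratio (ambiguity / disambiguation):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
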