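#' Event-related potentials per label
#'
#' Arithmetic mean over validly labeled, non-rejected trials, separately
#' for reversal and stable trials. An empty cell is flagged missing (`NULL`
#' entry), never zero-filled.
#'
#' @param ep A labeled `epoch_set`.
#' @return A list of class `erp_set`: matrices `reversal` and `stable`
#'   (channels x samples, microvolt, or `NULL`), `n` (trial counts),
#'   `times`, `ch_names`.
#' @export
compute_erp <- function(ep) {
  stopifnot(inherits(ep, "epoch_set"))
  out <- list(times = ep$times, ch_names = ep$ch_names,
              n = c(reversal = 0L, stable = 0L))
  for (lab in c("reversal", "stable")) {
    idx <- which(ep$info$label == lab & !ep$info$rejected)
    out$n[lab] <- length(idx)
    out[[lab]] <- if (length(idx) == 0) NULL else {
      m <- apply(ep$data[idx, , , drop = FALSE], c(2, 3), mean)
      rownames(m) <- ep$ch_names
      m
    }
  }
  class(out) <- "erp_set"
  out
}

#' Global field power
#'
#' Spatial standard deviation of the scalp field at every time point:
#' `gfp(t) = sqrt( sum_j (v_j(t) - vbar(t))^2 / n )` over the `n`
#' electrodes, in its population (divide-by-n) form. A reference-free
#' measure of overall field strength: non-negative, invariant to adding a
#' common offset to all electrodes, and equivariant under scaling.
#'
#' @param erp Channels x samples matrix (microvolt), or an `erp_set` (in
#'   which case both label traces are returned).
#' @return Numeric vector of GFP values per time point (for a matrix), or
#'   a list with elements `reversal`/`stable` (for an `erp_set`).
#' @export
#' @examples
#' compute_gfp(matrix(c(1, 2, 6), ncol = 1))  # sqrt(14/3)
compute_gfp <- function(erp) {
  if (inherits(erp, "erp_set")) {
    return(list(reversal = if (!is.null(erp$reversal)) compute_gfp(erp$reversal),
                stable = if (!is.null(erp$stable)) compute_gfp(erp$stable)))
  }
  stopifnot(is.matrix(erp))
  if (nrow(erp) < 2) {
    stop("GFP needs at least 2 electrodes", call. = FALSE)
  }
  vbar <- colMeans(erp)
  sqrt(colMeans(sweep(erp, 2, vbar)^2))
}

#' Pointwise GFP difference (reversal minus stable)
#'
#' @param reversal,stable GFP traces on identical time axes.
#' @return Difference trace `reversal - stable`.
#' @export
gfp_difference <- function(reversal, stable) {
  if (length(reversal) != length(stable)) {
    stop("GFP traces have different time axes", call. = FALSE)
  }
  reversal - stable
}

#' Group GFP difference with standard error
#'
#' @param reversal_mat,stable_mat Participants x time matrices of
#'   per-participant GFP traces.
#' @return List with `diffs` (participants x time), `mean`, `se`.
#' @export
group_gfp_difference <- function(reversal_mat, stable_mat) {
  stopifnot(all(dim(reversal_mat) == dim(stable_mat)))
  diffs <- reversal_mat - stable_mat
  list(diffs = diffs,
       mean = colMeans(diffs),
       se = apply(diffs, 2, stats::sd) / sqrt(nrow(diffs)))
}

#' Pointwise group statistics on GFP differences
#'
#' At every time point, a paired two-sided t-test of reversal versus stable
#' GFP across participants, with the paired Cohen's d
#' (`mean(diff) / sd(diff)`). P-values are reported uncorrected; readers
#' judge significant runs by their extent. Zero-variance time points are
#' masked `NA`.
#'
#' @param diffs Participants x time matrix of per-participant GFP
#'   difference traces (reversal minus stable).
#' @param times Time axis in ms.
#' @return A data.frame of class `pointwise_stats` with columns `time_ms`,
#'   `t`, `p`, `d`.
#' @export
pointwise_stats <- function(diffs, times) {
  stopifnot(is.matrix(diffs), ncol(diffs) == length(times))
  n <- nrow(diffs)
  if (n < 2) stop("pointwise statistics need >= 2 participants", call. = FALSE)
  m <- colMeans(diffs)
  s <- apply(diffs, 2, stats::sd)
  zero_var <- s < .Machine$double.eps^0.5 * pmax(abs(m), 1)
  s[zero_var] <- NA_real_
  tval <- m / (s / sqrt(n))
  pval <- 2 * stats::pt(-abs(tval), df = n - 1)
  d <- m / s
  d[!is.na(d) & abs(m) < .Machine$double.eps] <- 0
  out <- data.frame(time_ms = times, t = tval, p = pval, d = d)
  # all-identical differences of exactly zero: d is 0, not undefined
  all_zero <- zero_var & abs(m) < .Machine$double.eps
  out$d[all_zero] <- 0
  class(out) <- c("pointwise_stats", "data.frame")
  out
}

#' Data-driven temporal region of interest
#'
#' The decoding window over the pair's first stimulus: starting from the
#' first physiologically plausible time point (>= `min_latency` ms after
#' stimulus onset) where the pointwise p-value falls below `alpha`, rounded
#' down to the nearest `granularity` ms, and extending `width` ms to match
#' the inter-stimulus interval length. When no time point is significant,
#' the configured default window is returned with a warning.
#'
#' @param stats A `pointwise_stats` data.frame covering the first-stimulus
#'   window.
#' @param alpha Significance level.
#' @param min_latency Earliest plausible onset (ms after stimulus onset).
#' @param si_window Extent of the first-stimulus presentation on the epoch
#'   time axis (ms).
#' @param width Window length in ms.
#' @param granularity Rounding grid in ms.
#' @param default Fallback window.
#' @return A list of class `temporal_roi`: `start`, `end` (ms), `source`
#'   (`"data"` or `"default"`).
#' @export
select_temporal_roi <- function(stats, alpha = 0.05, min_latency = 150,
                                si_window = c(0, 1000), width = 400,
                                granularity = 100, default = c(300, 700)) {
  stopifnot(inherits(stats, "pointwise_stats"))
  cand <- stats[stats$time_ms >= min_latency &
                  stats$time_ms <= si_window[2] &
                  !is.na(stats$p) & stats$p < alpha, , drop = FALSE]
  if (nrow(cand) == 0) {
    warning("no significant time point in the first-stimulus window; ",
            "falling back to the default region of interest")
    roi <- list(start = default[1], end = default[1] + width,
                source = "default")
  } else {
    start <- floor(min(cand$time_ms) / granularity) * granularity
    roi <- list(start = start, end = start + width, source = "data")
  }
  class(roi) <- "temporal_roi"
  roi
}

#' @export
print.temporal_roi <- function(x, ...) {
  cat(sprintf("<temporal_roi> [%g, %g] ms (%s)\n", x$start, x$end, x$source))
  invisible(x)
}
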