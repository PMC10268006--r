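#' Four-fold evaluation plan over trials in acquisition order
#'
#' Trials are kept in temporal order and split into four contiguous
#' quarters; each quarter serves once as the evaluation set (25%) while the
#' remaining three quarters (75%) are used for training. Remainder trials
#' go to the last quarter. The four evaluation sets partition the trials.
#'
#' @param trials Integer vector of trial indices in acquisition order, or a
#'   labeled `epoch_set` (in which case the validly labeled, non-rejected
#'   trials are used).
#' @return A list of class `fold_plan`; each element has `train` and `eval`
#'   index vectors (into `trials`).
#' @export
#' @examples
#' lengths(lapply(make_folds(1:10), `[[`, "eval"))  # 2 2 2 4
make_folds <- function(trials) {
  if (inherits(trials, "epoch_set")) trials <- valid_trials(trials)
  n <- length(trials)
  if (n < 8) stop("need at least 8 trials to build 4 folds", call. = FALSE)
  q <- n %/% 4
  bounds <- c(0, q, 2 * q, 3 * q, n)
  folds <- lapply(1:4, function(k) {
    ev <- (bounds[k] + 1):bounds[k + 1]
    list(train = trials[-ev], eval = trials[ev])
  })
  class(folds) <- "fold_plan"
  folds
}

#' Oversample the minority class in a training set
#'
#' The minority class is resampled with replacement (seeded) until both
#' classes have equal counts; evaluation data are never touched.
#'
#' @param idx Training trial indices.
#' @param labels Class labels aligned with `idx` (`"reversal"`/`"stable"`).
#' @param seed Integer seed.
#' @return Index vector containing `idx` plus resampled minority indices.
#' @export
balance_classes <- function(idx, labels, seed = NULL) {
  stopifnot(length(idx) == length(labels))
  tab <- table(factor(labels, levels = c("reversal", "stable")))
  if (any(tab == 0)) {
    stop("both classes must be present in the training set", call. = FALSE)
  }
  if (tab[1] == tab[2]) return(idx)
  minority <- names(tab)[which.min(tab)]
  deficit <- abs(diff(as.numeric(tab)))
  pool <- idx[labels == minority]
  extra <- with_seed(seed, pool[sample.int(length(pool), deficit, replace = TRUE)])
  c(idx, extra)
}

#' Min-max normalize one trial to [0, 1]
#'
#' The minimum and maximum are taken jointly over all channels and samples
#' of that single trial, so after normalization every trial spans exactly
#' `[0, 1]`. A constant trial carries no contrast and is set to 0.5
#' everywhere, with a warning.
#'
#' @param x Numeric vector or channels x samples matrix of one trial.
#' @return Normalized object of the same shape.
#' @export
normalize_trial <- function(x) {
  rng <- range(x)
  if (!all(is.finite(rng))) stop("non-finite values in trial", call. = FALSE)
  if (rng[1] == rng[2]) {
    warning("constant trial; normalized values set to 0.5")
    x[] <- 0.5
    return(x)
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

# ---- classifier registry ----------------------------------------------

classifier_registry <- new.env(parent = emptyenv())

#' Register a decoding classifier
#'
#' A classifier is a pair of functions: `fit(X, y, seed)` receiving a
#' trials x features matrix and 0/1 labels (1 = reversal) and returning a
#' model object, and `predict(model, X)` returning hard 0/1 predictions.
#'
#' @param name Classifier name used in `classifier_spec`.
#' @param fit,predict Functions as described above.
#' @return `name`, invisibly.
#' @export
register_classifier <- function(name, fit, predict) {
  assign(name, list(fit = fit, predict = predict), envir = classifier_registry)
  invisible(name)
}

get_classifier <- function(name) {
  if (!exists(name, envir = classifier_registry)) {
    stop(sprintf("unknown classifier '%s'; registered: %s", name,
                 paste(ls(classifier_registry), collapse = ", ")),
         call. = FALSE)
  }
  get(name, envir = classifier_registry)
}

# shrinkage-regularized linear discriminant, computed in the span of the
# training data (economy SVD), so feature dimension far above trial count
# is handled without forming a features x features covariance
fit_shrinkage_lda <- function(X, y, gamma = 0.1) {
  mu0 <- colMeans(X[y == 0, , drop = FALSE])
  mu1 <- colMeans(X[y == 1, , drop = FALSE])
  Xc <- X
  Xc[y == 0, ] <- sweep(X[y == 0, , drop = FALSE], 2, mu0)
  Xc[y == 1, ] <- sweep(X[y == 1, , drop = FALSE], 2, mu1)
  n <- nrow(X); d <- ncol(X)
  sv <- svd(Xc, nu = 0)
  lam <- sv$d^2 / n                       # covariance eigenvalues in-span
  total_var <- sum(lam)
  nu <- total_var / d                     # shrinkage target: nu * I
  g <- max(0, min(1, gamma))
  a <- pmax((1 - g) * lam + g * nu, 1e-12)  # regularized in-span eigenvalues
  c0 <- max(g * nu, 1e-12)                  # out-of-span eigenvalue
  m <- mu1 - mu0
  V <- sv$v
  coef_in <- crossprod(V, m)              # coordinates of m in the span
  w <- V %*% (coef_in * (1 / a - 1 / c0)) + m / c0
  b <- -sum(w * (mu0 + mu1)) / 2
  list(w = as.numeric(w), b = b)
}

predict_shrinkage_lda <- function(model, X) {
  score <- as.numeric(X %*% model$w) + model$b
  as.integer(score > 0)                   # tie (score == 0) -> stable
}

register_classifier(
  "linear",
  fit = function(X, y, seed = NULL) fit_shrinkage_lda(X, y, gamma = 0.1),
  predict = predict_shrinkage_lda
)

# flatten the analysis window of selected trials into trials x features
window_features <- function(ep, trials, window) {
  if (identical(window, "isi")) window <- c(1000, 1400)
  stopifnot(length(window) == 2, window[1] < window[2])
  sel <- which(ep$times >= window[1] & ep$times < window[2])
  if (length(sel) == 0) stop("analysis window outside the epoch", call. = FALSE)
  X <- ep$data[trials, , sel, drop = FALSE]
  dim(X) <- c(length(trials), dim(ep$data)[2] * length(sel))
  X
}

#' Run the four-fold single-trial decoding protocol
#'
#' For each fold: training trials are shuffled (seeded), the minority class
#' oversampled to balance, every trial min-max normalized to `[0, 1]`
#' within the analysis window, and the classifier fitted; hard 0/1
#' predictions are then made on the untouched evaluation quarter (no
#' resampling, no shuffling, per-trial normalization only). Reported are
#' the four fold accuracies, their median, and the pooled per-trial
#' (prediction, truth) pairs that feed the bootstrap analysis.
#'
#' @param ep A labeled `epoch_set`.
#' @param window Analysis window: `c(start, end)` in ms on the epoch time
#'   axis (half-open), a `temporal_roi`, or `"isi"` for the inter-stimulus
#'   interval 1000-1400 ms.
#' @param classifier_spec Name of a registered classifier (default
#'   `"linear"`, a shrinkage-regularized linear discriminant on the
#'   flattened window).
#' @param seed Integer seed controlling shuffling and resampling.
#' @param folds Optional `fold_plan`; built from `ep` when omitted.
#' @return A list of class `decoding_result`: `fold_accuracy` (4 values),
#'   `median_accuracy`, `pairs` (data.frame `trial`, `truth`, `prediction`,
#'   `fold`), `window`, `classifier`, `n_trials`.
#' @export
train_and_evaluate <- function(ep, window, classifier_spec = "linear",
                               seed = 1, folds = NULL) {
  stopifnot(inherits(ep, "epoch_set"))
  if (inherits(window, "temporal_roi")) window <- c(window$start, window$end)
  clf <- get_classifier(classifier_spec)
  if (is.null(folds)) folds <- make_folds(ep)
  all_trials <- unique(unlist(lapply(folds, function(f) c(f$train, f$eval))))
  X_all <- window_features(ep, all_trials, window)
  if (!all(is.finite(X_all))) stop("non-finite features", call. = FALSE)
  row_of <- match(seq_len(dim(ep$data)[1]), all_trials)
  labels <- ep$info$label
  to_y <- function(tr) as.integer(labels[tr] == "reversal")

  fold_acc <- numeric(length(folds))
  pairs <- vector("list", length(folds))
  for (k in seq_along(folds)) {
    tr_idx <- folds[[k]]$train
    ev_idx <- folds[[k]]$eval
    tr_idx <- with_seed(derive_seed(seed, "shuffle", k),
                        tr_idx[sample.int(length(tr_idx))])
    tr_idx <- balance_classes(tr_idx, labels[tr_idx],
                              seed = derive_seed(seed, "balance", k))
    Xtr <- X_all[row_of[tr_idx], , drop = FALSE]
    Xtr <- t(apply(Xtr, 1, normalize_trial))
    Xev <- X_all[row_of[ev_idx], , drop = FALSE]
    Xev <- t(apply(Xev, 1, normalize_trial))
    model <- clf$fit(Xtr, to_y(tr_idx), seed = derive_seed(seed, "fit", k))
    pred <- clf$predict(model, Xev)
    truth <- to_y(ev_idx)
    fold_acc[k] <- mean(pred == truth)
    pairs[[k]] <- data.frame(trial = ev_idx, truth = truth,
                             prediction = pred, fold = k)
  }
  res <- list(fold_accuracy = fold_acc,
              median_accuracy = stats::median(fold_acc),
              pairs = do.call(rbind, pairs),
              window = if (identical(window, "isi")) c(1000, 1400) else window,
              classifier = classifier_spec,
              n_trials = length(all_trials))
  class(res) <- "decoding_result"
  res
}

#' Median of the four fold accuracies
#'
#' With four values this is the mean of the two middle order statistics.
#'
#' @param result A `decoding_result` or a numeric vector of 4 accuracies.
#' @return Median accuracy (proportion in `[0, 1]`).
#' @export
#' @examples
#' median_accuracy(c(0.4, 0.5, 0.6, 0.7))  # 0.55
median_accuracy <- function(result) {
  acc <- if (inherits(result, "decoding_result")) result$fold_accuracy else result
  if (length(acc) != 4) stop("expected 4 fold accuracies", call. = FALSE)
  stats::median(acc)
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> %s | window [%g, %g) ms | folds: %s | median %.1f%%\n",
              x$classifier, x$window[1], x$window[2],
              paste(sprintf("%.1f%%", 100 * x$fold_accuracy), collapse = " "),
              100 * x$median_accuracy))
  invisible(x)
}
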