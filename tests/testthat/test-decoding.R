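test_that("folds are contiguous quarters that partition the trials", {
  f100 <- make_folds(1:100)
  expect_equal(vapply(f100, function(f) length(f$eval), numeric(1)),
               rep(25, 4))
  f10 <- make_folds(1:10)
  expect_equal(vapply(f10, function(f) length(f$eval), numeric(1)),
               c(2, 2, 2, 4))
  for (folds in list(f100, f10)) {
    evals <- lapply(folds, `[[`, "eval")
    expect_equal(sort(unlist(evals)), seq_along(unlist(evals)))
    for (f in folds) {
      expect_length(intersect(f$train, f$eval), 0)
      expect_setequal(c(f$train, f$eval), unlist(evals))
    }
  }
  # evaluation quarters preserve acquisition order
  expect_equal(f100[[2]]$eval, 26:50)
  expect_error(make_folds(1:7), "at least 8")
})

test_that("class balancing oversamples the minority with replacement", {
  idx <- 1:100
  labels <- rep(c("reversal", "stable"), c(30, 70))
  out <- balance_classes(idx, labels, seed = 3)
  expect_length(out, 140)
  expect_equal(sum(labels[out] == "reversal"), 70)
  expect_equal(sum(labels[out] == "stable"), 70)
  # resampled indices come from the original minority set only
  expect_true(all(out[101:140] %in% idx[labels == "reversal"]))
  # already balanced: identity
  bal <- rep(c("reversal", "stable"), 50)
  expect_identical(balance_classes(idx, bal), idx)
  expect_error(balance_classes(1:5, rep("stable", 5)), "both classes")
})

test_that("trial normalization maps every trial onto [0, 1]", {
  x <- matrix(seq(-5, 5, by = 0.5), 3)      # 21 values spanning [-5, 5]
  n <- normalize_trial(x)
  expect_equal(range(n), c(0, 1))
  expect_equal(n[x == 0], 0.5)
  # affine rescaling of the input does not change the output
  expect_equal(normalize_trial(3 * x + 100), n, tolerance = 1e-12)
  expect_warning(flat <- normalize_trial(matrix(2, 3, 3)), "constant")
  expect_true(all(flat == 0.5))
  expect_error(normalize_trial(matrix(c(1, NA), 1)), "non-finite")
})

test_that("median accuracy is the even-count median of four folds", {
  expect_equal(median_accuracy(c(0.5, 0.6, 0.6, 0.7)), 0.6)
  expect_equal(median_accuracy(c(0.4, 0.5, 0.6, 0.7)), 0.55)
  expect_equal(median_accuracy(rep(0.8, 4)), 0.8)
  expect_error(median_accuracy(c(0.5, 0.6)), "4 fold")
})

test_that("perfectly separable classes are decoded at 100% on every fold", {
  ep <- make_decodable_epochs(n_trials = 48, signal = 1, noise_sd = 0,
                              seed = 2)
  res <- train_and_evaluate(ep, c(300, 1000), seed = 1)
  expect_equal(res$fold_accuracy, rep(1, 4))
  expect_equal(res$median_accuracy, 1)
  expect_equal(nrow(res$pairs), 48)
})

test_that("consistent class relabeling leaves accuracy unchanged", {
  ep <- make_decodable_epochs(n_trials = 60, signal = 0.4, noise_sd = 1,
                              seed = 3)
  res <- train_and_evaluate(ep, c(300, 1000), seed = 9)
  flipped <- ep
  flipped$info$label <- ifelse(ep$info$label == "reversal",
                               "stable", "reversal")
  res_f <- train_and_evaluate(flipped, c(300, 1000), seed = 9)
  expect_equal(res$fold_accuracy, res_f$fold_accuracy)
})

test_that("decoding results are deterministic in data and seeds", {
  ep <- make_decodable_epochs(n_trials = 40, signal = 0.3, noise_sd = 1,
                              seed = 4)
  a <- train_and_evaluate(ep, c(300, 1000), seed = 11)
  b <- train_and_evaluate(ep, c(300, 1000), seed = 11)
  expect_identical(a, b)
  # the seed feeds shuffling and resampling only; evaluation trials and
  # their truth labels are fixed by the fold plan
  c <- train_and_evaluate(ep, c(300, 1000), seed = 12)
  expect_identical(a$pairs$trial, c$pairs$trial)
  expect_identical(a$pairs$truth, c$pairs$truth)
})

test_that("evaluation trials never influence training statistics", {
  ep <- make_decodable_epochs(n_trials = 40, signal = 0.5, noise_sd = 1,
                              seed = 5)
  folds <- make_folds(ep)
  res <- train_and_evaluate(ep, c(300, 1000), seed = 1, folds = folds)
  # every evaluation trial appears exactly once across the pooled pairs
  expect_equal(sort(res$pairs$trial), seq_len(40))
  # perturbing an evaluation trial leaves the other folds' accuracy alone
  ep2 <- ep
  ev1 <- folds[[1]]$eval[1]
  ep2$data[ev1, , ] <- ep2$data[ev1, , ] + 50
  res2 <- train_and_evaluate(ep2, c(300, 1000), seed = 1, folds = folds)
  expect_equal(res$fold_accuracy[-1], res2$fold_accuracy[-1])
})

test_that("chance level is 50% when labels are independent of the data", {
  # balanced label sequences: expected accuracy is exactly 1/2 regardless
  # of any classifier bias, so the mean over runs settles at chance
  accs <- unlist(lapply(1:3, function(s) {
    ep <- make_decodable_epochs(n_trials = 160, signal = 0, noise_sd = 1,
                                p_rev = 0.5, seed = s)
    train_and_evaluate(ep, c(300, 1000), seed = s)$fold_accuracy
  }))
  n_eval <- 3 * 160
  expect_lt(abs(mean(accs) - 0.5), 2.5 * sqrt(0.25 / n_eval))
})

test_that("unknown classifiers and bad windows are rejected", {
  ep <- make_decodable_epochs(n_trials = 16, seed = 6)
  expect_error(train_and_evaluate(ep, c(300, 1000), "does_not_exist"),
               "unknown classifier")
  expect_error(train_and_evaluate(ep, c(5000, 5400), seed = 1),
               "window")
  ep$data[1, 1, 1] <- Inf
  expect_error(train_and_evaluate(ep, c(300, 1000), seed = 1),
               "non-finite")
})

test_that("custom classifiers can be registered and used", {
  register_classifier("majority",
    fit = function(X, y, seed = NULL) list(maj = round(mean(y))),
    predict = function(model, X) rep(model$maj, nrow(X)))
  ep <- make_decodable_epochs(n_trials = 24, signal = 1, noise_sd = 0,
                              seed = 7)
  res <- train_and_evaluate(ep, c(300, 1000), "majority", seed = 1)
  expect_true(all(res$fold_accuracy >= 0 & res$fold_accuracy <= 1))
})
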