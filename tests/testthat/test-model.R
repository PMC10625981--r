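# small encoded datasets built directly from integer sequences
toy_encoded <- function(ids, vocab_rows = 20L) {
  n <- length(ids)
  max_len <- max(lengths(ids), 1L)
  m <- matrix(0L, n, max_len)
  for (i in seq_len(n)) if (length(ids[[i]]) > 0) m[i, seq_along(ids[[i]])] <- ids[[i]]
  structure(list(ids = m, lengths = lengths(ids), retained = rep(TRUE, n),
                 max_len = max_len, vocab_rows = vocab_rows, vocab_hash = "toy"),
            class = "cvd_encoded")
}

# a linearly separable toy corpus: token 5 marks the positive class
separable_toy <- function(n = 300, seed = 1, vocab_rows = 12L) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), length.out = n)
    ids <- lapply(seq_len(n), function(i) {
      base <- sample(6:11, sample(4:8, 1), replace = TRUE)
      if (y[i] == 1) base[sample(length(base), 1)] <- 5L
      base
    })
    list(enc = toy_encoded(ids, vocab_rows), y = y)
  })
}

test_that("the dense cascade halves in width down to the output neuron", {
  cfg <- model_config(64, 128, 0.15, n_dense = 4, dense_max_dim = 64)
  expect_equal(cfg$dense_dims, c(64L, 32L, 16L, 8L))
  cfg <- model_config(32, 16, 0, n_dense = 6, dense_max_dim = 16)
  expect_equal(cfg$dense_dims, c(16L, 8L, 4L, 2L, 1L, 1L))
  expect_error(model_config(lstm_dropout = 1.5), class = "cvdnotes_config_error")
  expect_error(model_config(embedding_dim = -4), class = "cvdnotes_config_error")
})

test_that("the parameter-count formula matches the allocated weights", {
  for (w in c(Inf, 24, 6)) {
    cfg <- preset_config(w, vocab_rows = 500L)
    m <- build_model(cfg, seed = 1)
    allocated <- sum(vapply(m$weights, length, numeric(1)))
    expect_equal(count_params(cfg), allocated)
  }
  # the bidirectional layer carries two full sets of LSTM kernels
  cfg <- preset_config(24, vocab_rows = 500L)
  expect_equal(dim(m$weights$u_fwd), dim(m$weights$u_bwd))
  expect_equal(nrow(build_model(cfg, seed = 1)$weights$u_fwd),
               4 * 128)
})

test_that("forward probabilities are strictly inside (0, 1)", {
  toy <- separable_toy(80, seed = 3)
  m <- build_model(model_config(8, 8, 0, 2, 8, 0, vocab_rows = 12L), seed = 2)
  fit <- train_blstm(m, toy$enc, toy$y, toy$enc, toy$y,
                     train_config(seed = 1), max_epochs = 1, patience = 1)
  p <- predict(fit, toy$enc)
  expect_true(all(p > 0 & p < 1))
  # the all-padding (empty) sequence still yields a valid probability
  empty <- toy_encoded(list(integer(0), c(5L, 6L)), vocab_rows = 12L)
  pe <- predict(fit, empty)
  expect_true(all(pe > 0 & pe < 1))
})

test_that("backpropagation matches finite differences", {
  toy <- separable_toy(24, seed = 5)
  cfg <- model_config(6, 5, 0, 2, 6, 0, vocab_rows = 12L)
  m <- build_model(cfg, seed = 7)
  ccfg <- cvdnotes:::.cfg_for_cpp(cfg)
  g <- cvdnotes:::cpp_blstm_grad(m$weights, ccfg, toy$enc$ids,
                                 as.integer(toy$enc$lengths),
                                 as.numeric(toy$y))
  loss_at <- function(w) cvdnotes:::cpp_blstm_grad(w, ccfg, toy$enc$ids,
                                                   as.integer(toy$enc$lengths),
                                                   as.numeric(toy$y))$loss
  set.seed(2)
  h <- 2e-2
  for (nm in c("w_fwd", "u_bwd", "embedding", "dense_w1", "out_w", "b_fwd")) {
    idx <- sample(length(m$weights[[nm]]), 3)
    for (i in idx) {
      wp <- m$weights; wp[[nm]][i] <- wp[[nm]][i] + h
      wm <- m$weights; wm[[nm]][i] <- wm[[nm]][i] - h
      fd <- (loss_at(wp) - loss_at(wm)) / (2 * h)
      an <- g$grads[[nm]][i]
      expect_lt(abs(fd - an), 2e-2 * max(1, abs(fd), abs(an)))
    }
  }
})

test_that("early stopping halts after patience epochs without improvement", {
  toy <- separable_toy(60, seed = 9)
  m <- build_model(model_config(8, 8, 0, 2, 8, 0, vocab_rows = 12L), seed = 1)
  # a vanishing learning rate freezes the model, so the validation loss is
  # constant and training stops right after the first patience window
  frozen <- train_config(initial_lr = 1e-12, seed = 1)
  fit <- train_blstm(m, toy$enc, toy$y, toy$enc, toy$y, frozen,
                     max_epochs = 50, patience = 1)
  expect_equal(nrow(fit$history), 2)
  fit3 <- train_blstm(m, toy$enc, toy$y, toy$enc, toy$y, frozen,
                      max_epochs = 50, patience = 3)
  expect_equal(nrow(fit3$history), 4)
  # and the history never exceeds max_epochs
  fit2 <- train_blstm(m, toy$enc, toy$y, toy$enc, toy$y,
                      train_config(seed = 1), max_epochs = 3)
  expect_lte(nrow(fit2$history), 3)
  expect_error(train_blstm(m, toy_encoded(list(), 12L), integer(0), toy$enc,
                           toy$y, train_config(seed = 1)),
               class = "cvdnotes_config_error")
})

test_that("a separable toy corpus is fitted to low loss within 50 epochs", {
  toy <- separable_toy(400, seed = 11)
  m <- build_model(model_config(16, 12, 0, 2, 16, 0, vocab_rows = 12L), seed = 4)
  fit <- train_blstm(m, toy$enc, toy$y, toy$enc, toy$y,
                     train_config(seed = 2), max_epochs = 50, patience = 50)
  expect_lt(min(fit$history$train_loss), 0.1)
  # the recorded best lags the raw minimum by at most the min-delta margin
  expect_lte(fit$best_val_loss, min(fit$history$val_loss) + 1e-4)
})

test_that("prediction is deterministic and batch-order invariant", {
  toy <- separable_toy(100, seed = 13)
  m <- build_model(model_config(8, 8, 0.15, 2, 8, 0.1, vocab_rows = 12L), seed = 3)
  fit <- train_blstm(m, toy$enc, toy$y, toy$enc, toy$y,
                     train_config(seed = 1), max_epochs = 3)
  p1 <- predict(fit, toy$enc)
  p2 <- predict(fit, toy$enc)
  expect_identical(p1, p2)
  perm <- withr::with_seed(5, sample(100))
  p3 <- predict(fit, encoded_subset(toy$enc, perm))
  expect_equal(p3, p1[perm])
  expect_error(predict(build_model(model_config(vocab_rows = 12L), seed = 1),
                       toy$enc),
               class = "cvdnotes_config_error")
})

test_that("training is reproducible given the same seeds", {
  toy <- separable_toy(120, seed = 17)
  run <- function() {
    m <- build_model(model_config(8, 8, 0.15, 2, 8, 0, vocab_rows = 12L), seed = 6)
    train_blstm(m, toy$enc, toy$y, toy$enc, toy$y, train_config(seed = 2),
                max_epochs = 4)
  }
  expect_identical(run()$history, run()$history)
})

test_that("cross-validation folds are patient-disjoint", {
  pid <- rep(sprintf("P%02d", 1:30), times = sample(1:5, 30, replace = TRUE))
  folds <- patient_folds(pid, k = 5, seed = 3)
  per_patient <- tapply(folds, pid, function(f) length(unique(f)))
  expect_true(all(per_patient == 1))
  expect_equal(sort(unique(folds)), 1:5)
  expect_error(patient_folds(c("A", "B"), k = 5), class = "cvdnotes_config_error")
})

test_that("random search is exhaustive at full budget and returns the CV minimiser", {
  toy <- separable_toy(240, seed = 19)
  pid <- rep(sprintf("P%02d", 1:40), each = 6)
  grid <- tidyr::expand_grid(embedding_dim = c(4L, 8L), lstm_dim = 4L,
                             lstm_dropout = 0, n_dense = 2L,
                             dense_max_dim = c(4L, 8L), dense_dropout = 0)
  tcfg <- train_config(n_search = 4, cv_folds = 3, cv_max_epochs = 3,
                       cv_patience = 3, seed = 8)
  sr <- random_search(toy$enc, toy$y, pid, tcfg, grid = grid)
  expect_equal(dplyr::n_distinct(sr$log$config_id), 4)   # n_search == grid size
  expect_equal(nrow(sr$log), 4 * 3)
  # the returned configuration attains the minimum mean CV loss (recomputed)
  recomputed <- tapply(sr$log$val_loss, sr$log$config_id, mean)
  best_id <- as.integer(names(which.min(recomputed)))
  best_row <- sr$log[sr$log$config_id == best_id, ][1, ]
  expect_equal(sr$best_config$embedding_dim, best_row$embedding_dim)
  expect_equal(sr$best_config$dense_max_dim, best_row$dense_max_dim)
  # over-budget searches are capped with a warning
  tcfg$n_search <- 10L
  expect_warning(random_search(toy$enc, toy$y, pid, tcfg, grid = grid),
                 "grid size")
})

test_that("multi-restart selection equals the minimum of the restart log", {
  toy <- separable_toy(150, seed = 23)
  cfg <- model_config(8, 8, 0, 2, 8, 0, vocab_rows = 12L)
  tcfg <- train_config(n_restarts = 3, max_epochs = 5, seed = 12)
  mr <- multi_restart(cfg, toy$enc, toy$y, toy$enc, toy$y, tcfg)
  expect_equal(nrow(mr$log), 3)
  expect_equal(mr$model$best_val_loss, min(mr$log$val_loss))
  one <- multi_restart(cfg, toy$enc, toy$y, toy$enc, toy$y,
                       train_config(n_restarts = 1, max_epochs = 3, seed = 12))
  expect_equal(nrow(one$log), 1)
})
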