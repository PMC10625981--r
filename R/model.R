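#' Architecture configuration for the bi-LSTM note classifier
#'
#' The network is a cascade of a token embedding, a bidirectional LSTM, and a
#' stack of dense ReLU layers each half the width of its predecessor,
#' converging into a single sigmoid output unit. `dense_dims` is derived from
#' `n_dense` and `dense_max_dim` by successive halving (floored, minimum 1).
#'
#' @param embedding_dim embedding dimension (tuning grid: 32, 64, 128, 256).
#' @param lstm_dim LSTM units per direction (grid: 16, 32, 64, 128); the
#'   effective recurrent width is twice this because the layer is
#'   bidirectional.
#' @param lstm_dropout non-recurrent LSTM dropout (grid: 0, 0.15, 0.3).
#' @param n_dense number of dense layers (grid: 2..6).
#' @param dense_max_dim width of the first dense layer (grid: 16, 32, 64,
#'   128).
#' @param dense_dropout dropout after each dense layer (grid: 0, 0.1).
#' @param vocab_rows number of embedding rows (max token index + 1); usually
#'   taken from an encoded dataset.
#' @param max_len maximum sequence length (informational).
#' @return A list of class `model_config`.
#' @export
model_config <- function(embedding_dim = 64, lstm_dim = 32, lstm_dropout = 0.15,
                         n_dense = 2, dense_max_dim = 32, dense_dropout = 0,
                         vocab_rows = NULL, max_len = NULL) {
  check_pos_int <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != round(x)) {
      abort(sprintf("`%s` must be a positive integer.", nm),
            class = "cvdnotes_config_error")
    }
  }
  check_pos_int(embedding_dim, "embedding_dim")
  check_pos_int(lstm_dim, "lstm_dim")
  check_pos_int(n_dense, "n_dense")
  check_pos_int(dense_max_dim, "dense_max_dim")
  for (dr in c(lstm_dropout, dense_dropout)) {
    if (!is.numeric(dr) || is.na(dr) || dr < 0 || dr >= 1) {
      abort("Dropout rates must lie in [0, 1).", class = "cvdnotes_config_error")
    }
  }
  dims <- integer(n_dense)
  w <- as.integer(dense_max_dim)
  for (k in seq_len(n_dense)) {
    dims[k] <- w
    w <- max(1L, w %/% 2L)
  }
  structure(list(embedding_dim = as.integer(embedding_dim),
                 lstm_dim = as.integer(lstm_dim),
                 lstm_dropout = lstm_dropout, n_dense = as.integer(n_dense),
                 dense_max_dim = as.integer(dense_max_dim),
                 dense_dropout = dense_dropout, dense_dims = dims,
                 vocab_rows = if (is.null(vocab_rows)) NULL else as.integer(vocab_rows),
                 max_len = if (is.null(max_len)) NULL else as.integer(max_len)),
            class = "model_config")
}

#' Hyperparameter tuning grid
#'
#' The full factorial grid searched during tuning: embedding dimension x LSTM
#' dimension x LSTM dropout x number of dense layers x first dense width x
#' dense dropout (1920 combinations).
#'
#' @return Tibble with one row per configuration.
#' @export
model_grid <- function() {
  tidyr::expand_grid(embedding_dim = c(32L, 64L, 128L, 256L),
                     lstm_dim = c(16L, 32L, 64L, 128L),
                     lstm_dropout = c(0, 0.15, 0.3),
                     n_dense = 2:6,
                     dense_max_dim = c(16L, 32L, 64L, 128L),
                     dense_dropout = c(0, 0.1))
}

#' Tuned architecture presets per look-back window
#'
#' The optimal configurations found by cross-validated random search for each
#' look-back window, shipped as presets: the infinite window uses
#' (embedding 64, LSTM 128, LSTM dropout 0.3, 5 dense layers from width 128,
#' no dense dropout); the 24- and 12-month windows share (64, 128, 0.15, 4
#' dense from 64, 0); the 6-month window uses (256, 128, 0.3, 2 dense from
#' 16, 0).
#'
#' @return Tibble keyed by `window` (Inf, 24, 12, 6).
#' @export
window_presets <- function() {
  tibble::tibble(
    window = c(Inf, 24, 12, 6),
    embedding_dim = c(64L, 64L, 64L, 256L),
    lstm_dim = 128L,
    lstm_dropout = c(0.3, 0.15, 0.15, 0.3),
    n_dense = c(5L, 4L, 4L, 2L),
    dense_max_dim = c(128L, 64L, 64L, 16L),
    dense_dropout = 0
  )
}

#' @rdname window_presets
#' @param window one of `Inf`, 24, 12, 6.
#' @param vocab_rows,max_len passed to [model_config()].
#' @export
preset_config <- function(window, vocab_rows = NULL, max_len = NULL) {
  p <- window_presets()
  row <- p[p$window == window, ]
  if (nrow(row) != 1) {
    abort("No preset for this window; use Inf, 24, 12 or 6.",
          class = "cvdnotes_config_error")
  }
  model_config(row$embedding_dim, row$lstm_dim, row$lstm_dropout, row$n_dense,
               row$dense_max_dim, row$dense_dropout, vocab_rows, max_len)
}

#' Training protocol configuration
#'
#' Desk-scale defaults keep the full protocol structure (Adam, binary
#' cross-entropy, time-based learning-rate decay `initial_lr / max_epochs`,
#' early stopping after `patience` epochs without a validation-loss
#' improvement of at least `min_delta`, best-validation weights restored) at
#' a budget that runs on a laptop CPU. `full_scale = TRUE` switches to the
#' full-scale protocol: learning rate 5e-5, 200 epochs, 100 restarts, 200
#' random-search draws. At desk scale the learning rate defaults to 1e-3
#' because the number of gradient steps is roughly 40x smaller; see the
#' methods vignette.
#'
#' @param initial_lr initial Adam learning rate.
#' @param max_epochs maximum training epochs.
#' @param decay per-iteration time-based decay rate; defaults to
#'   `initial_lr / max_epochs`.
#' @param patience early-stopping patience (epochs).
#' @param min_delta minimum validation-loss decrease that counts as an
#'   improvement.
#' @param n_restarts random restarts for final model selection.
#' @param cv_folds folds for hyperparameter cross-validation (patient-
#'   grouped).
#' @param n_search random-search draws from [model_grid()].
#' @param cv_max_epochs,cv_patience reduced screening budget used inside
#'   cross-validation folds during hyperparameter search.
#' @param batch_size minibatch size.
#' @param pos_weight positive-class loss weight (1 = unweighted; class
#'   balancing is off by default).
#' @param seed base seed for initialisation, shuffling and dropout.
#' @param full_scale use the full-scale protocol values.
#' @return A list of class `train_config`.
#' @export
train_config <- function(initial_lr = 1e-3, max_epochs = 60, decay = NULL,
                         patience = 20, min_delta = 1e-4, n_restarts = 5,
                         cv_folds = 5, n_search = 20, cv_max_epochs = 12,
                         cv_patience = 4, batch_size = 64, pos_weight = 1,
                         seed = 1L, full_scale = FALSE) {
  if (full_scale) {
    initial_lr <- 5e-5; max_epochs <- 200; n_restarts <- 100; n_search <- 200
    cv_max_epochs <- 200; cv_patience <- 20
  }
  if (is.null(decay)) decay <- initial_lr / max_epochs
  cfg <- list(initial_lr = initial_lr, max_epochs = as.integer(max_epochs),
              decay = decay, patience = as.integer(patience),
              min_delta = min_delta, n_restarts = as.integer(n_restarts),
              cv_folds = as.integer(cv_folds), n_search = as.integer(n_search),
              cv_max_epochs = as.integer(cv_max_epochs),
              cv_patience = as.integer(cv_patience),
              batch_size = as.integer(batch_size), pos_weight = pos_weight,
              seed = as.integer(seed))
  bad <- vapply(cfg, function(x) !is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0,
                logical(1))
  bad["seed"] <- FALSE  # any integer seed is fine
  if (any(bad)) {
    abort(paste0("Training config fields must be positive: ",
                 paste(names(cfg)[bad], collapse = ", ")),
          class = "cvdnotes_config_error")
  }
  structure(cfg, class = "train_config")
}

.cfg_for_cpp <- function(config) {
  list(vocab_rows = config$vocab_rows, embedding_dim = config$embedding_dim,
       lstm_dim = config$lstm_dim, lstm_dropout = config$lstm_dropout,
       dense_dropout = config$dense_dropout,
       dense_dims = as.integer(config$dense_dims))
}

#' Number of trainable parameters of a configuration
#'
#' Closed form: embedding rows x embedding dim, plus per direction the LSTM
#' gate kernels `4 d (e + d + 1)`, plus the dense cascade on the
#' concatenated `2 d` recurrent output.
#'
#' @param config a [model_config()] with `vocab_rows` set.
#' @return Integer parameter count.
#' @export
count_params <- function(config) {
  e <- config$embedding_dim; d <- config$lstm_dim
  n <- config$vocab_rows * e + 2 * (4 * d * (e + d + 1))
  prev <- 2 * d
  for (w in config$dense_dims) {
    n <- n + w * prev + w
    prev <- w
  }
  n + prev + 1
}

#' Build an (untrained) bi-LSTM classifier
#'
#' Initialises weights deterministically from `seed` (Glorot-uniform kernels,
#' forget-gate bias 1, embedding uniform in (-0.05, 0.05), padding row fixed
#' at zero).
#'
#' @param config a [model_config()] with `vocab_rows` set (or an encoded
#'   dataset via `enc` from which `vocab_rows`/`max_len` are filled in).
#' @param enc optional [encode_visits()] result supplying `vocab_rows`.
#' @param seed integer seed.
#' @return An object of class `blstm`.
#' @export
build_model <- function(config, enc = NULL, seed = 1L) {
  if (!inherits(config, "model_config")) {
    abort("`config` must be a model_config().", class = "cvdnotes_config_error")
  }
  if (!is.null(enc)) {
    config$vocab_rows <- enc$vocab_rows
    config$max_len <- enc$max_len
  }
  if (is.null(config$vocab_rows)) {
    abort("`vocab_rows` unknown: pass `enc` or set it in the config.",
          class = "cvdnotes_config_error")
  }
  weights <- cpp_blstm_init(.cfg_for_cpp(config), as.integer(seed))
  structure(list(config = config, weights = weights, fitted = FALSE,
                 seed = as.integer(seed), history = NULL, best_epoch = NA_integer_,
                 best_val_loss = NA_real_),
            class = "blstm")
}

.check_enc <- function(enc, y = NULL) {
  stopifnot(inherits(enc, "cvd_encoded"))
  if (!is.null(y)) {
    stopifnot(length(y) == nrow(enc$ids), all(y %in% c(0, 1)))
  }
}

#' Train a bi-LSTM classifier
#'
#' Minimises binary cross-entropy with Adam, stopping early after
#' `patience` epochs without validation improvement and restoring the
#' best-validation weights. Deterministic given the model seed and `tcfg`.
#'
#' @param model a [build_model()] result.
#' @param enc_train,y_train encoded training sequences and 0/1 labels.
#' @param enc_val,y_val encoded validation sequences and labels.
#' @param tcfg a [train_config()].
#' @param max_epochs,patience optional overrides of `tcfg` (used for the
#'   reduced screening budget inside cross-validation).
#' @return The fitted `blstm` with `history` (tibble of per-epoch losses),
#'   `best_epoch` and `best_val_loss`.
#' @export
train_blstm <- function(model, enc_train, y_train, enc_val, y_val, tcfg = train_config(),
                        max_epochs = NULL, patience = NULL) {
  stopifnot(inherits(model, "blstm"))
  .check_enc(enc_train, y_train); .check_enc(enc_val, y_val)
  if (nrow(enc_train$ids) == 0) {
    abort("Empty training set.", class = "cvdnotes_config_error")
  }
  fit_cfg <- list(initial_lr = tcfg$initial_lr, decay = tcfg$decay,
                  max_epochs = as.integer(max_epochs %||% tcfg$max_epochs),
                  patience = as.integer(patience %||% tcfg$patience),
                  min_delta = tcfg$min_delta, batch_size = tcfg$batch_size,
                  pos_weight = tcfg$pos_weight)
  res <- cpp_blstm_fit(model$weights, .cfg_for_cpp(model$config),
                       enc_train$ids, as.integer(enc_train$lengths),
                       as.numeric(y_train), enc_val$ids,
                       as.integer(enc_val$lengths), as.numeric(y_val),
                       fit_cfg, model$seed)
  model$weights <- res$weights
  model$history <- tibble::tibble(epoch = seq_along(res$train_loss),
                                  train_loss = res$train_loss,
                                  val_loss = res$val_loss)
  model$best_epoch <- res$best_epoch
  model$best_val_loss <- res$best_val_loss
  model$fitted <- TRUE
  model
}

#' Predict visit-level probabilities
#'
#' @param object a fitted `blstm`.
#' @param enc an encoded dataset.
#' @param ... unused.
#' @return Numeric vector of probabilities in (0, 1), one per row of
#'   `enc$ids`, invariant to row order.
#' @export
predict.blstm <- function(object, enc, ...) {
  if (!isTRUE(object$fitted)) {
    abort("Model is not fitted; call train_blstm() first.",
          class = "cvdnotes_config_error")
  }
  .check_enc(enc)
  as.numeric(cpp_blstm_predict(object$weights, .cfg_for_cpp(object$config),
                               enc$ids, as.integer(enc$lengths)))
}

#' @export
print.blstm <- function(x, ...) {
  cat(sprintf("<blstm> embedding %d | biLSTM %d (x2) | dense %s | %s params\n",
              x$config$embedding_dim, x$config$lstm_dim,
              paste(x$config$dense_dims, collapse = "-"),
              format(count_params(x$config), big.mark = ",")))
  if (isTRUE(x$fitted)) {
    cat(sprintf("  fitted: best epoch %d, val loss %.4f\n", x$best_epoch,
                x$best_val_loss))
  } else cat("  not fitted\n")
  invisible(x)
}

#' @export
tidy.blstm <- function(x, ...) {
  if (is.null(x$history)) return(tibble::tibble(epoch = integer(),
                                                train_loss = numeric(),
                                                val_loss = numeric()))
  x$history
}

#' @export
glance.blstm <- function(x, ...) {
  tibble::tibble(n_params = count_params(x$config),
                 n_epochs = if (is.null(x$history)) 0L else nrow(x$history),
                 best_epoch = x$best_epoch, best_val_loss = x$best_val_loss,
                 fitted = isTRUE(x$fitted))
}

#' Patient-grouped cross-validation folds
#'
#' @param patient_id character vector, one entry per visit.
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer fold id (1..k) per visit; all visits of one patient share
#'   a fold.
#' @export
patient_folds <- function(patient_id, k, seed = 1L) {
  patients <- sort(unique(as.character(patient_id)))
  if (length(patients) < k) {
    abort("Fewer patients than folds.", class = "cvdnotes_config_error")
  }
  shuffled <- withr::with_seed(seed, sample(patients))
  fold <- setNames(rep_len(seq_len(k), length(patients)), shuffled)
  unname(fold[as.character(patient_id)])
}

#' Random hyperparameter search with patient-grouped cross-validation
#'
#' Samples `n_search` distinct configurations uniformly without replacement
#' from the grid and scores each by the mean best validation binary
#' cross-entropy across `cv_folds` patient-disjoint folds of the training
#' split, training each fold under the reduced screening budget
#' (`cv_max_epochs`, `cv_patience`). Returns the configuration minimising the
#' mean fold loss together with the full search log.
#'
#' @param enc encoded training-split sequences.
#' @param y 0/1 labels.
#' @param patient_id patient identifier per sequence (defines the folds).
#' @param tcfg a [train_config()] (supplies `n_search`, `cv_folds`, seeds and
#'   budgets).
#' @param grid configuration grid (default [model_grid()]).
#' @return List of class `cvd_search`: `best_config` (a [model_config()]),
#'   `log` (tibble: one row per configuration x fold), `summary` (mean loss
#'   per configuration).
#' @export
random_search <- function(enc, y, patient_id, tcfg = train_config(),
                          grid = model_grid()) {
  .check_enc(enc, y)
  n_search <- tcfg$n_search
  if (n_search > nrow(grid)) {
    warn(sprintf("n_search = %d exceeds the grid size (%d); using the full grid.",
                 n_search, nrow(grid)))
    n_search <- nrow(grid)
  }
  picks <- withr::with_seed(tcfg$seed, sample.int(nrow(grid), n_search))
  folds <- patient_folds(patient_id, tcfg$cv_folds, seed = tcfg$seed + 1L)
  log <- vector("list", n_search)
  for (ci in seq_len(n_search)) {
    row <- grid[picks[ci], ]
    cfg <- model_config(row$embedding_dim, row$lstm_dim, row$lstm_dropout,
                        row$n_dense, row$dense_max_dim, row$dense_dropout,
                        vocab_rows = enc$vocab_rows, max_len = enc$max_len)
    fold_loss <- numeric(tcfg$cv_folds)
    for (f in seq_len(tcfg$cv_folds)) {
      tr <- folds != f
      model <- build_model(cfg, seed = tcfg$seed + 7919L * ci + f)
      fit <- train_blstm(model, encoded_subset(enc, tr), y[tr],
                         encoded_subset(enc, !tr), y[!tr], tcfg,
                         max_epochs = tcfg$cv_max_epochs,
                         patience = tcfg$cv_patience)
      fold_loss[f] <- fit$best_val_loss
    }
    log[[ci]] <- dplyr::bind_cols(config_id = ci, row,
                                  tibble::tibble(fold = seq_len(tcfg$cv_folds),
                                                 val_loss = fold_loss))
  }
  log <- dplyr::bind_rows(log)
  summary <- log |>
    dplyr::group_by(dplyr::across(c("config_id", "embedding_dim", "lstm_dim",
                                    "lstm_dropout", "n_dense", "dense_max_dim",
                                    "dense_dropout"))) |>
    dplyr::summarise(mean_val_loss = mean(.data$val_loss), .groups = "drop") |>
    dplyr::arrange(.data$mean_val_loss)
  best <- summary[1, ]
  best_config <- model_config(best$embedding_dim, best$lstm_dim,
                              best$lstm_dropout, best$n_dense,
                              best$dense_max_dim, best$dense_dropout,
                              vocab_rows = enc$vocab_rows, max_len = enc$max_len)
  structure(list(best_config = best_config, log = log, summary = summary),
            class = "cvd_search")
}

#' @export
tidy.cvd_search <- function(x, ...) x$log

#' @export
glance.cvd_search <- function(x, ...) {
  dplyr::slice_min(x$summary, .data$mean_val_loss, n = 1)
}

#' Multi-restart training with best-validation selection
#'
#' Re-trains the chosen architecture `n_restarts` times from different random
#' initialisations and keeps the restart with the lowest validation loss.
#'
#' @param config a [model_config()].
#' @param enc_train,y_train,enc_val,y_val encoded data and labels.
#' @param tcfg a [train_config()].
#' @return List of class `cvd_restarts`: `model` (the selected fitted
#'   `blstm`) and `log` (tibble restart / val_loss / best_epoch).
#' @export
multi_restart <- function(config, enc_train, y_train, enc_val, y_val,
                          tcfg = train_config()) {
  stopifnot(tcfg$n_restarts >= 1)
  fits <- vector("list", tcfg$n_restarts)
  for (r in seq_len(tcfg$n_restarts)) {
    model <- build_model(config, enc = enc_train, seed = tcfg$seed + 104729L + r)
    fits[[r]] <- train_blstm(model, enc_train, y_train, enc_val, y_val, tcfg)
  }
  log <- tibble::tibble(restart = seq_len(tcfg$n_restarts),
                        val_loss = vapply(fits, `[[`, numeric(1), "best_val_loss"),
                        best_epoch = vapply(fits, `[[`, integer(1), "best_epoch"))
  structure(list(model = fits[[which.min(log$val_loss)]], log = log),
            class = "cvd_restarts")
}

#' @export
tidy.cvd_restarts <- function(x, ...) x$log
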