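# Sequence-to-scalar recurrent surrogate: one-hot encoding, 64:16:20
# split with k-fold cross-validation over train+val, bidirectional GRU
# regressor trained with an L1 objective and lowest-validation-epoch
# weight selection.

#' One-hot encode a sequence
#'
#' @param seq Canonical amino-acid sequence.
#' @return L x 20 matrix over the fixed alphabet ACDEFGHIKLMNPQRSTVWY; one
#'   1 per row.
#' @export
one_hot_encode <- function(seq) {
  chars <- seq_chars(seq)
  m <- matrix(0L, length(chars), length(AA_ALPHABET),
              dimnames = list(NULL, AA_ALPHABET))
  m[cbind(seq_along(chars), match(chars, AA_ALPHABET))] <- 1L
  m
}

#' Decode a one-hot matrix back to a sequence
#'
#' @param mat L x 20 one-hot matrix from [one_hot_encode()].
#' @export
one_hot_decode <- function(mat) {
  paste(AA_ALPHABET[max.col(mat)], collapse = "")
}

#' Train/validation/test split with cross-validation folds
#'
#' Records are shuffled by a seeded generator, split by largest-remainder
#' counts into the stated proportions (default 64:16:20), and the combined
#' train+val portion is partitioned into `k` folds for cross-validation.
#'
#' @param n Number of records (or a vector whose length is used).
#' @param split Three percentages summing to 100 (train, val, test).
#' @param k Number of CV folds (default 5).
#' @param seed Integer seed.
#' @return List: `train`, `val`, `test` (index vectors), `folds` (list of k
#'   index vectors partitioning train+val).
#' @export
split_and_fold <- function(n, split = c(64, 16, 20), k = 5L, seed = 1L) {
  if (length(n) > 1) n <- length(n)
  if (sum(split) != 100) stop("split percentages must sum to 100")
  if (n < 5 * k) stop("need at least ", 5 * k, " records")
  counts <- largest_remainder_counts(split / 100, n)
  rng <- local_rng(seed)
  idx <- rng$sample(seq_len(n), n)
  train <- idx[seq_len(counts[1])]
  val <- idx[counts[1] + seq_len(counts[2])]
  test <- idx[counts[1] + counts[2] + seq_len(counts[3])]
  tv <- c(train, val)
  fold_sizes <- largest_remainder_counts(rep(1 / k, k), length(tv))
  folds <- split(tv, rep(seq_len(k), fold_sizes))
  list(train = train, val = val, test = test, folds = unname(folds))
}

#' Training configuration for the recurrent surrogate
#'
#' Defaults follow the training recipe: learning rate 0.001, 5-fold CV for
#' 500 epochs, final training for 750 epochs with weights taken from the
#' lowest-validation-loss epoch, 64:16:20 split, L1 loss. Hyperparameters
#' outside the search ranges (hidden layers 1-2, hidden dimension 10-55,
#' batch size 4-32) are accepted with a warning.
#'
#' @param learning_rate Adam learning rate.
#' @param cv_folds,cv_epochs Cross-validation folds and epochs.
#' @param final_epochs Epochs of the final fit.
#' @param split Train/val/test percentages.
#' @param hidden_layers,hidden_dim,batch_size Network hyperparameters.
#' @param seed Integer seed.
#' @return List of class `surrogate_config`.
#' @export
surrogate_config <- function(learning_rate = 0.001, cv_folds = 5L,
                             cv_epochs = 500L, final_epochs = 750L,
                             split = c(64, 16, 20), hidden_layers = 2L,
                             hidden_dim = 32L, batch_size = 16L, seed = 1L) {
  if (sum(split) != 100) stop("split must sum to 100")
  if (hidden_layers < 1 || hidden_layers > 2)
    warning("hidden_layers outside the searched range 1-2")
  if (hidden_dim < 10 || hidden_dim > 55)
    warning("hidden_dim outside the searched range 10-55")
  if (batch_size < 4 || batch_size > 32)
    warning("batch_size outside the searched range 4-32")
  structure(list(learning_rate = learning_rate, cv_folds = as.integer(cv_folds),
                 cv_epochs = as.integer(cv_epochs),
                 final_epochs = as.integer(final_epochs), split = split,
                 hidden_layers = as.integer(hidden_layers),
                 hidden_dim = as.integer(hidden_dim),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 loss = "L1"), class = "surrogate_config")
}

seq_to_types <- function(seq) match(seq_chars(seq), AA_ALPHABET) - 1L

#' Train the bidirectional recurrent regressor
#'
#' Trains a stacked bidirectional GRU with a linear head on the final
#' forward/backward states, minimizing L1 loss with Adam. The returned
#' weights are those of the epoch with the lowest validation loss; the
#' full train and validation loss curves are retained. Deterministic per
#' seed on one platform.
#'
#' @param dataset data.frame with columns `seq` and `label` (finite).
#' @param config `surrogate_config`.
#' @param property Name of the predicted property (metadata).
#' @param epochs Number of epochs (default `config$final_epochs`).
#' @param partitions Optional partitions from [split_and_fold()]; computed
#'   from the config seed otherwise. Training uses the train indices,
#'   epoch selection the val indices; test indices are stored for
#'   [evaluate_regressor()].
#' @return Object of class `brnn_model`.
#' @export
train_regressor <- function(dataset, config = surrogate_config(),
                            property = "re", epochs = NULL,
                            partitions = NULL) {
  if (nrow(dataset) < 50) stop("need at least 50 labeled examples")
  if (!all(is.finite(dataset$label))) stop("labels must be finite")
  if (is.null(epochs)) epochs <- config$final_epochs
  if (is.null(partitions))
    partitions <- split_and_fold(nrow(dataset), config$split,
                                 config$cv_folds, config$seed)
  types <- lapply(dataset$seq, seq_to_types)
  tr <- partitions$train; va <- partitions$val
  res <- cpp_gru_train(types[tr], dataset$label[tr], types[va],
                       dataset$label[va], config$hidden_layers,
                       config$hidden_dim, 20L, as.integer(epochs),
                       config$batch_size, config$learning_rate, config$seed)
  structure(list(
    weights = res$weights,
    architecture = list(type = "bidirectional GRU", layers = config$hidden_layers,
                        hidden_dim = config$hidden_dim, input_dim = 20L,
                        alphabet = paste(AA_ALPHABET, collapse = "")),
    property = property,
    train_loss = res$train_loss, val_loss = res$val_loss,
    best_epoch = res$best_epoch, best_val_loss = res$best_val_loss,
    config = config, partitions = partitions,
    train_range = range(nchar(dataset$seq))
  ), class = "brnn_model")
}

#' @export
print.brnn_model <- function(x, ...) {
  cat(sprintf("brnn_model for '%s': %d-layer bidirectional GRU, hidden %d (%d weights)\n",
              x$property, x$architecture$layers, x$architecture$hidden_dim,
              length(x$weights)))
  cat(sprintf("  best epoch %d / %d, validation L1 %.4f\n",
              x$best_epoch, length(x$val_loss), x$best_val_loss))
  invisible(x)
}

#' Predict scalars for a batch of sequences
#'
#' One scalar per sequence, order preserved; each sequence is evaluated
#' with its own length (no padding), so batched and single-sequence
#' predictions are identical. Sequences with non-canonical residues yield
#' `NA` with a warning and the batch continues. A warning is emitted for
#' lengths outside the training range.
#'
#' @param model `brnn_model`.
#' @param seqs Character vector of sequences.
#' @return Numeric vector.
#' @export
predict_batch <- function(model, seqs) {
  types <- vector("list", length(seqs))
  ok <- rep(TRUE, length(seqs))
  for (i in seq_along(seqs)) {
    t <- tryCatch(seq_to_types(seqs[[i]]), error = function(e) e)
    if (inherits(t, "error")) {
      warning("sequence ", i, " skipped: ", conditionMessage(t))
      ok[i] <- FALSE
    } else types[[i]] <- t
  }
  out <- rep(NA_real_, length(seqs))
  if (any(ok)) {
    lens <- lengths(types[ok])
    if (!is.null(model$train_range) &&
        (min(lens) < model$train_range[1] || max(lens) > model$train_range[2]))
      warning("predicting outside the trained length range [",
              model$train_range[1], ", ", model$train_range[2], "]")
    out[ok] <- cpp_gru_predict(model$weights, types[ok],
                               model$architecture$layers,
                               model$architecture$hidden_dim, 20L)
  }
  out
}

#' @export
predict.brnn_model <- function(object, newdata, ...) {
  predict_batch(object, newdata)
}

#' Evaluate a trained regressor on a test set
#'
#' @param model `brnn_model`.
#' @param dataset data.frame with `seq` and `label`.
#' @param indices Test indices (default: the partitions stored at training
#'   time).
#' @return List: `r2` (NA for a single-point test set), `rmse`,
#'   `residuals` (prediction - label).
#' @export
evaluate_regressor <- function(model, dataset, indices = NULL) {
  if (is.null(indices)) indices <- model$partitions$test
  if (length(indices) == 0) stop("empty test set")
  preds <- predict_batch(model, dataset$seq[indices])
  labels <- dataset$label[indices]
  resid <- preds - labels
  r2 <- if (length(indices) < 2 || stats::var(labels) == 0) NA_real_
        else 1 - sum(resid^2) / sum((labels - mean(labels))^2)
  list(r2 = r2, rmse = sqrt(mean(resid^2)), residuals = resid)
}

#' Cross-validate a hyperparameter configuration
#'
#' Runs k-fold cross-validation over the train+val portion: each fold in
#' turn is the validation set and the remaining folds the training set,
#' for `config$cv_epochs` epochs. Returns per-fold best validation losses.
#'
#' @inheritParams train_regressor
#' @return List: `fold_val_loss`, `mean_val_loss`.
#' @export
cross_validate <- function(dataset, config = surrogate_config(),
                           partitions = NULL) {
  if (is.null(partitions))
    partitions <- split_and_fold(nrow(dataset), config$split,
                                 config$cv_folds, config$seed)
  types <- lapply(dataset$seq, seq_to_types)
  losses <- vapply(seq_along(partitions$folds), function(f) {
    va <- partitions$folds[[f]]
    tr <- setdiff(unlist(partitions$folds), va)
    res <- cpp_gru_train(types[tr], dataset$label[tr], types[va],
                         dataset$label[va], config$hidden_layers,
                         config$hidden_dim, 20L, config$cv_epochs,
                         config$batch_size, config$learning_rate,
                         config$seed + f)
    res$best_val_loss
  }, numeric(1))
  list(fold_val_loss = losses, mean_val_loss = mean(losses))
}

#' Save / load a trained surrogate model
#'
#' The model directory holds a JSON metadata file (architecture, property,
#' config, loss curves) and the flat weight vector as plain text.
#'
#' @param model `brnn_model`.
#' @param dir Model directory.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- model[c("architecture", "property", "best_epoch", "best_val_loss",
                  "train_range")]
  meta$config <- unclass(model$config)
  meta$train_loss <- model$train_loss
  meta$val_loss <- model$val_loss
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(format(model$weights, digits = 17),
             file.path(dir, "weights.txt"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  w <- as.numeric(readLines(file.path(dir, "weights.txt")))
  structure(list(weights = w, architecture = as.list(meta$architecture),
                 property = meta$property, train_loss = meta$train_loss,
                 val_loss = meta$val_loss, best_epoch = meta$best_epoch,
                 best_val_loss = meta$best_val_loss,
                 config = do.call(surrogate_config,
                                  as.list(meta$config)[c("learning_rate",
                                    "cv_folds", "cv_epochs", "final_epochs",
                                    "hidden_layers",
                                    "hidden_dim", "batch_size", "seed")]),
                 partitions = NULL,
                 train_range = meta$train_range),
            class = "brnn_model")
}
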