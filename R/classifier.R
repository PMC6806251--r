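# Action classification network over pose-evolution maps.
#
# Architecture (fixed unless overridden): two blocks of two 3x3
# convolutions with block widths (128, 256); the first layer of each
# block has stride 2 and the second stride 1, all with "same" padding.
# Every convolution is followed by a ReLU, batch normalization and
# dropout. A global average pooling layer reduces the final feature map
# to a width-256 vector, and a 5-way fully connected layer with softmax
# produces class probabilities. Training minimizes softmax
# cross-entropy with Adam (base learning rate 0.01, batch size 70,
# dropout 0.3); the seed controls weight initialization, batch order
# and dropout masks. Heavy numerics run in compiled single-precision
# code on BLAS.

#' Classifier hyperparameter configuration
#'
#' @param C Time-encoding channels of the input maps (input has
#'   `14 * C` channels).
#' @param H,W Spatial size of the input maps.
#' @param widths Block widths (filters of block 1 and block 2).
#' @param n_classes Number of classes (5 actions).
#' @param dropout Dropout probability after every block layer.
#' @param lr Adam base learning rate.
#' @param batch_size Mini-batch size.
#' @param epochs Maximum training epochs.
#' @param patience Early stopping: stop after this many epochs without
#'   a new best validation weighted accuracy.
#' @param stop_acc Early stopping: stop once validation weighted
#'   accuracy reaches this value.
#' @param seed RNG seed for initialization, batch order and dropout.
#' @return An object of class `"model_config"`.
#' @export
model_config <- function(C = 3, H = 135, W = 240, widths = c(128, 256),
                         n_classes = 5, dropout = 0.3, lr = 0.01,
                         batch_size = 70, epochs = 20, patience = 2,
                         stop_acc = 0.99, seed = 1L) {
  stopifnot(length(widths) == 2, all(widths > 0), dropout >= 0,
            dropout < 1, lr > 0, batch_size > 0, epochs > 0)
  structure(list(C = as.integer(C), H = as.integer(H), W = as.integer(W),
                 in_channels = 14L * as.integer(C),
                 widths = as.integer(widths),
                 n_classes = as.integer(n_classes), dropout = dropout,
                 lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 patience = as.integer(patience), stop_acc = stop_acc,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Number of learnable parameters of the classifier
#'
#' Closed form: four convolutions (`3*3*Cin*Cout + Cout` each), batch
#' normalization scale and shift (`2 * Cout` per convolution) and the
#' fully connected layer (`widths[2] * n_classes + n_classes`).
#'
#' @param config A [model_config()].
#' @return Named list `conv`, `bn`, `fc`, `total`.
#' @export
n_parameters <- function(config) {
  cins <- c(config$in_channels, config$widths[1], config$widths[1],
            config$widths[2])
  couts <- c(config$widths[1], config$widths[1], config$widths[2],
             config$widths[2])
  conv <- sum(9 * cins * couts + couts)
  bn <- sum(2 * couts)
  fc <- config$widths[2] * config$n_classes + config$n_classes
  list(conv = conv, bn = bn, fc = fc, total = conv + bn + fc)
}

#' Build (initialize) the classification network
#'
#' Weights are randomly initialized (He-scaled Gaussians) under the
#' config seed; the same config yields bitwise-identical initial
#' weights.
#'
#' @param config A [model_config()].
#' @return An object of class `"pose_cnn"` with elements `config`,
#'   `params` and `n_params`.
#' @export
build_model <- function(config) {
  if (config$H < 4 || config$W < 4)
    stop("input smaller than the receptive-field minimum: H and W must ",
         "be >= 4")
  params <- .cnn_init(c(config$in_channels, config$H, config$W),
                      config$widths, config$n_classes, config$seed)
  structure(list(config = config, params = params,
                 n_params = n_parameters(config)$total,
                 trained = FALSE, history = NULL),
            class = "pose_cnn")
}

labels_to_int <- function(labels) {
  idx <- match(labels, action_labels())
  if (anyNA(idx))
    stop("unknown label(s): ",
         paste(unique(labels[is.na(idx)]), collapse = ", "))
  idx - 1L
}

check_feature_matrix <- function(X, config) {
  D <- config$in_channels * config$H * config$W
  if (nrow(X) != D)
    stop("feature matrix has ", nrow(X), " rows but the model expects ",
         D, " (= ", config$in_channels, " x ", config$H, " x ", config$W,
         ")")
  invisible(X)
}

#' Train the classifier
#'
#' Minimizes softmax cross-entropy with Adam. When validation data is
#' given, the model with the best validation weighted accuracy is kept
#' and training stops early once `stop_acc` is reached or `patience`
#' epochs pass without improvement. Optionally augments the training
#' maps with additive white noise (clipped to `[0, 1]`).
#'
#' @param model A [build_model()] object.
#' @param X_train Feature matrix `D x N` (columns = clips), e.g. from
#'   [featurize_clips()].
#' @param y_train Character labels (length N).
#' @param X_val,y_val Optional validation data (disjoint from training).
#' @param augment_sigma White-noise augmentation sigma (0 = none).
#' @param verbose Print per-epoch progress.
#' @return The trained model; `$history` holds per-epoch training loss
#'   and validation weighted accuracy, `$best_epoch` the selected epoch.
#' @export
train_classifier <- function(model, X_train, y_train, X_val = NULL,
                             y_val = NULL, augment_sigma = 0,
                             verbose = FALSE) {
  stopifnot(inherits(model, "pose_cnn"))
  cfg <- model$config
  check_feature_matrix(X_train, cfg)
  y <- labels_to_int(y_train)
  present <- sort(unique(y))
  if (length(present) < cfg$n_classes)
    stop("class(es) absent from training data: ",
         paste(setdiff(action_labels(), action_labels()[present + 1L]),
               collapse = ", "))
  if (augment_sigma > 0) {
    X_train <- with_local_seed(cfg$seed + 1L, {
      Xa <- X_train + matrix(rnorm(length(X_train), 0, augment_sigma),
                             nrow(X_train))
      Xa[Xa < 0] <- 0; Xa[Xa > 1] <- 1
      Xa
    })
  }
  if (is.null(X_val)) {
    X_val <- matrix(0, nrow(X_train), 0)
    yv <- integer(0)
  } else {
    check_feature_matrix(X_val, cfg)
    yv <- labels_to_int(y_val)
  }
  fit <- .cnn_train(X_train, y, X_val, yv, model$params,
                    c(cfg$in_channels, cfg$H, cfg$W), cfg$widths,
                    cfg$n_classes, cfg$lr, cfg$batch_size, cfg$dropout,
                    cfg$epochs, cfg$patience, cfg$stop_acc, cfg$seed,
                    verbose)
  model$params <- fit$params
  model$history <- data.frame(epoch = seq_along(fit$train_loss),
                              train_loss = fit$train_loss,
                              val_accuracy = fit$val_accuracy)
  model$best_epoch <- fit$best_epoch
  model$trained <- TRUE
  model
}

#' Predict class probabilities
#'
#' @param model A trained (or freshly built) `pose_cnn`.
#' @param X Feature matrix `D x N`.
#' @return `N x 5` matrix of class probabilities (rows sum to 1),
#'   columns named by [action_labels()].
#' @export
predict_classifier <- function(model, X) {
  stopifnot(inherits(model, "pose_cnn"))
  check_feature_matrix(X, model$config)
  probs <- .cnn_predict(model$params, X,
                        c(model$config$in_channels, model$config$H,
                          model$config$W),
                        model$config$widths, model$config$n_classes)
  colnames(probs) <- action_labels()
  probs
}

#' Predicted labels (argmax of class probabilities)
#' @param model A `pose_cnn`.
#' @param X Feature matrix `D x N`.
#' @return Character vector of predicted labels.
#' @export
predict_labels <- function(model, X) {
  probs <- predict_classifier(model, X)
  action_labels()[max.col(probs, ties.method = "first")]
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the config (including the seed) together with
#' the weights.
#'
#' @param model A `pose_cnn`.
#' @param path Checkpoint path.
#' @return `path` (save) or the restored model (load).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path, version = 3)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "pose_cnn"))
  model
}

#' @export
print.pose_cnn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<pose_cnn> input (%d, %d, %d), widths (%d, %d), %d classes, %s\n",
    cfg$in_channels, cfg$H, cfg$W, cfg$widths[1], cfg$widths[2],
    cfg$n_classes,
    if (x$trained) sprintf("trained (best epoch %d)", x$best_epoch)
    else "untrained"))
  cat(sprintf("  %d learnable parameters\n", x$n_params))
  invisible(x)
}
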