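#' Training configuration
#'
#' Defaults are the selected hyperparameters of the study protocol:
#' 500 epochs, batch size 16, ADAM with learning rate 0.0005, softmax
#' cross-entropy on one-hot 5-class targets.
#'
#' @param epochs number of passes over the training instances.
#' @param batch mini-batch size.
#' @param lr ADAM learning rate.
#' @param dropout dropout rate between the two fully-connected layers.
#' @param seed integer seed driving shuffles, dropout and initialization.
#' @export
train_config <- function(epochs = 500L, batch = 16L, lr = 5e-4,
                         dropout = 0.5, seed = 1L) {
  if (epochs < 1 || batch < 1) stop("epochs and batch must be >= 1")
  if (lr < 0) stop("lr must be >= 0")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(epochs = as.integer(epochs), batch = as.integer(batch),
                 lr = lr, dropout = dropout, seed = as.integer(seed)),
            class = "train_config")
}

#' Hyperparameter search grids
#'
#' The stated search lattice: epochs in {300, 400, 500}, batch size in
#' {16, 32, 64, 128}, learning rate in {0.0001, 0.0005, 0.001, 0.005}.
#' @export
hp_grids <- function() {
  list(epochs = c(300L, 400L, 500L), batch = c(16L, 32L, 64L, 128L),
       lr = c(1e-4, 5e-4, 1e-3, 5e-3))
}

#' Build the error-classification CNN
#'
#' Constructs the dual-channel network: a 3x3 stem convolution 2->16,
#' three conv/batch-norm/ReLU blocks (16->16, 16->32, 32->64) with 2x2 max
#' pools after the first two, global average pooling, a 64->128
#' fully-connected layer, dropout 0.5 and a 128->5 softmax head.
#' Convolutions are same-padded; pools use floor division, so a (2,21,66)
#' input follows (16,21,66) -> (16,10,33) -> (32,10,33) -> (32,5,16) ->
#' (64,5,16) -> 64 -> 128 -> 5.
#'
#' Initialization (reproducible from the seed): He-normal everywhere,
#' except the stem, where four filters start as calculated-minus-measured
#' contrast detectors at graded gains (1, 3, 10, 30 — spanning the 2%
#' dose-error ratio up to the ~30% edge perturbations of 1-degree
#' geometric errors) and two as per-channel pass-throughs, with the
#' random component scaled down.  The QA signal lives in the contrast
#' between the two channels, and from a purely random stem the network
#' frequently memorizes plan-specific structure instead of discovering
#' that contrast (observed as erratic fold generalization); seeding the
#' stem with the physically meaningful features removes that failure mode
#' while leaving every parameter free to train.
#'
#' @param seed integer seed for the initial parameters.
#' @param input_dim input dimensions `c(channels, rows, cols)`;
#'   channels must be 2.
#' @return object of class `cnn_model` (parameters plus dimensions).
#' @export
build_cnn <- function(seed = 1L, input_dim = c(2L, 21L, 66L)) {
  if (input_dim[1] != 2L) stop("the network takes 2 input channels")
  H <- as.integer(input_dim[2]); W <- as.integer(input_dim[3])
  if (H < 4L || W < 4L) stop("input too small for two 2x2 pools")
  he <- function(nin, nout)
    matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
  stem_init <- function(W) {
    W <- W * 0.05                    # keep symmetry-breaking noise small
    centre <- 5                      # centre tap of the 3x3 kernel
    gains <- c(1, 3, 10, 30)
    for (f in seq_along(gains)) {
      W[centre, f] <- gains[f]       # calculated channel
      W[9 + centre, f] <- -gains[f]  # minus measured channel
    }
    W[centre, 5] <- 1                # pass-throughs
    W[9 + centre, 6] <- 1
    W
  }
  params <- withr_seed(seed, list(
    Ws = stem_init(he(2 * 9, 16)), bs = rep(0, 16),
    W1 = he(16 * 9, 16),  b1 = rep(0, 16),
    g1 = rep(1, 16), be1 = rep(0, 16), rm1 = rep(0, 16), rv1 = rep(1, 16),
    W2 = he(16 * 9, 32),  b2 = rep(0, 32),
    g2 = rep(1, 32), be2 = rep(0, 32), rm2 = rep(0, 32), rv2 = rep(1, 32),
    W3 = he(32 * 9, 64),  b3 = rep(0, 64),
    g3 = rep(1, 64), be3 = rep(0, 64), rm3 = rep(0, 64), rv3 = rep(1, 64),
    Wf1 = he(64, 128),    bf1 = rep(0, 128),
    Wf2 = he(128, 5),     bf2 = rep(0, 5)))
  structure(list(params = params, H = H, W = W, seed = as.integer(seed),
                 trained = FALSE, loss = numeric()),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  np <- sum(vapply(x$params[!grepl("^r[mv]", names(x$params))], length, 0))
  cat(sprintf("<cnn_model> input (2,%d,%d), %d parameters, %s\n",
              x$H, x$W, np, if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Forward pass: class probabilities
#'
#' Inference mode (batch-norm running statistics, no dropout); each output
#' row is a softmax simplex over the five classes.
#'
#' @param model a [build_cnn()] model.
#' @param instances list of `model_instance`s, or a feature matrix from
#'   the internal layout.
#' @return numeric matrix, `n x 5`.
#' @export
cnn_forward <- function(model, instances) {
  stopifnot(inherits(model, "cnn_model"))
  X <- if (is.matrix(instances)) instances else instance_features(instances)
  .cnn_predict(model$params, X, model$H, model$W)
}

#' Activation-shape trace of a forward pass
#'
#' Runs one instance through the network and reports the dimensions of
#' every intermediate activation, for auditing the architecture.
#'
#' @inheritParams cnn_forward
#' @return named list of integer dimension vectors.
#' @export
cnn_shape_trace <- function(model, instances) {
  stopifnot(inherits(model, "cnn_model"))
  X <- if (is.matrix(instances)) instances else instance_features(instances)
  .cnn_trace(model$params, X[1, , drop = FALSE], model$H, model$W)
}

#' Train the CNN on one set of instances
#'
#' Mini-batch ADAM on softmax cross-entropy; epoch shuffles and dropout
#' masks are reproducible from `config$seed`.
#'
#' @param model a [build_cnn()] model.
#' @param instances training `model_instance`s (normalized, one-hot).
#' @param config a [train_config()].
#' @return the trained `cnn_model`, with per-epoch mean loss in `$loss`.
#' @export
train_fold <- function(model, instances, config = train_config()) {
  stopifnot(inherits(model, "cnn_model"), inherits(config, "train_config"))
  if (length(instances) == 0) stop("empty training set")
  X <- instance_features(instances)
  y <- instance_labels(instances)
  fit <- .cnn_train(model$params, X, as.integer(y), model$H, model$W,
                    config$epochs, config$batch, config$lr,
                    config$dropout, config$seed)
  model$params <- fit$params
  model$loss <- fit$loss
  model$trained <- TRUE
  model
}

#' Five-fold cross-validation ensemble
#'
#' Trains one model per fold on the other folds' instances, logs each
#' fold's validation accuracy, and returns the ensemble whose prediction
#' is the average of the five softmax outputs.
#'
#' @param instances augmented training `model_instance`s.
#' @param split a [make_split()] whose folds cover the instances' plans.
#' @param config a [train_config()]; fold `k` trains with seed
#'   `config$seed + k` (initialization and shuffling).
#' @return object of class `cnn_ensemble` with `models`, `val_acc`,
#'   `fold` assignment and the configuration.
#' @export
crossval_train <- function(instances, split, config = train_config()) {
  stopifnot(inherits(split, "split_plan"))
  fold <- fold_of(instances, split)
  if (any(is.na(fold)))
    stop("some instances belong to no training fold")
  n_folds <- length(split$folds)
  models <- vector("list", n_folds)
  val_acc <- numeric(n_folds)
  y <- instance_labels(instances)
  for (k in seq_len(n_folds)) {
    m <- build_cnn(seed = config$seed + k,
                   input_dim = c(2L, dim(instances[[1]]$channels)[2],
                                 dim(instances[[1]]$channels)[3]))
    cfg_k <- config; cfg_k$seed <- config$seed + k
    m <- train_fold(m, instances[fold != k], cfg_k)
    probs <- cnn_forward(m, instances[fold == k])
    val_acc[k] <- mean(max.col(probs, ties.method = "first") - 1L ==
                         y[fold == k])
    models[[k]] <- m
  }
  structure(list(models = models, val_acc = val_acc, fold = fold,
                 config = config),
            class = "cnn_ensemble")
}

#' @export
print.cnn_ensemble <- function(x, ...) {
  cat(sprintf("<cnn_ensemble> %d folds, validation accuracy %s\n",
              length(x$models),
              paste(sprintf("%.3f", x$val_acc), collapse = " ")))
  invisible(x)
}

#' Ensemble prediction
#'
#' Averages the five fold models' softmax outputs; the hard label is the
#' argmax, ties broken toward the lowest class index.
#'
#' @param object a `cnn_ensemble`.
#' @param instances list of `model_instance`s or a feature matrix.
#' @param ... unused.
#' @return list with `probs` (`n x 5`, rows sum to 1) and `class`
#'   (integer codes 0-4).
#' @export
predict.cnn_ensemble <- function(object, instances, ...) {
  probs <- Reduce(`+`, lapply(object$models, cnn_forward,
                              instances = instances)) /
    length(object$models)
  list(probs = probs, class = max.col(probs, ties.method = "first") - 1L)
}

#' Hyperparameter grid search by cross-validation accuracy
#'
#' Enumerates the grid (subsets of [hp_grids()]), runs five-fold
#' cross-validation for each combination and returns the configuration
#' with the highest mean validation accuracy.  Ties break toward fewest
#' epochs, then smallest batch, then smallest learning rate.  Model
#' selection deliberately uses cross-validation accuracy, never the test
#' set.
#'
#' @param instances augmented training instances.
#' @param split a [make_split()].
#' @param grids named list with `epochs`, `batch`, `lr` vectors.
#' @param seed seed passed into each [train_config()].
#' @return list with `best` (a [train_config()]) and `results` (one row
#'   per combination with its mean CV accuracy).
#' @export
grid_search <- function(instances, split, grids = hp_grids(), seed = 1L) {
  if (any(lengths(grids) == 0)) stop("empty hyperparameter grid")
  combos <- expand.grid(epochs = grids$epochs, batch = grids$batch,
                        lr = grids$lr)
  combos$cv_accuracy <- NA_real_
  for (i in seq_len(nrow(combos))) {
    cfg <- train_config(combos$epochs[i], combos$batch[i], combos$lr[i],
                        seed = seed)
    ens <- crossval_train(instances, split, cfg)
    combos$cv_accuracy[i] <- mean(ens$val_acc)
  }
  ord <- order(-combos$cv_accuracy, combos$epochs, combos$batch, combos$lr)
  best <- combos[ord[1], ]
  list(best = train_config(best$epochs, best$batch, best$lr, seed = seed),
       results = combos)
}
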