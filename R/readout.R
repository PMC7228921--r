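# Trained readout layers.
#
# Both readouts are trained by full-batch gradient descent on a one-vs-all
# logistic (sigmoid + cross-entropy) objective:
#  - a fully connected layer (e.g. 31 x 4) for whole-train pattern
#    recognition;
#  - a bilayer convolutional readout (one shared kernel + perceptron) for
#    streaming (27 x 1 kernel -> 5 x 5 perceptron) and synchronization
#    (6 x 2 kernel, stride 2 -> 20 x 3 perceptron) tasks.

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Training configuration for the readout layers
#'
#' @param learning_rate gradient-descent step size.
#' @param epochs number of full-batch epochs.
#' @param seed integer seed for weight initialization and data splits.
#' @param train_fraction fraction of samples used for training (default 0.8).
#' @param output output nonlinearity: `"sigmoid"` (one-vs-all, the default)
#'   or `"softmax"` (coupled multiclass).
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1, epochs = 4000, seed = 1,
                         train_fraction = 0.8,
                         output = c("sigmoid", "softmax")) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must be strictly between 0 and 1")
  if (learning_rate <= 0 || epochs < 1) stop("invalid optimizer settings")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 seed = as.integer(seed), train_fraction = train_fraction,
                 output = match.arg(output)),
            class = "train_config")
}

softmax <- function(Z) {
  E <- exp(Z - apply(Z, 1, max))
  E / rowSums(E)
}

#' Fully connected sigmoid readout model
#'
#' @param weights numeric matrix of shape (n_in + 1) x n_out; the first row
#'   is the bias.
#' @param class_names output class labels (length n_out).
#' @param output output nonlinearity, `"sigmoid"` or `"softmax"`.
#' @return an object of class `fc_model`.
#' @export
fc_model <- function(weights, class_names, output = "sigmoid") {
  weights <- as.matrix(weights)
  if (!all(is.finite(weights))) stop("weights must be finite")
  if (ncol(weights) != length(class_names)) stop("one class name per output")
  if (ncol(weights) < 2) stop("at least 2 output classes are required")
  structure(list(weights = weights, class_names = as.character(class_names),
                 output = output),
            class = "fc_model")
}

#' @export
print.fc_model <- function(x, ...) {
  cat(sprintf("<fc_model> %d x %d (+bias), classes: %s\n",
              nrow(x$weights) - 1L, ncol(x$weights),
              paste(x$class_names, collapse = ", ")))
  invisible(x)
}

#' Forward pass of the fully connected readout
#'
#' Per-output sigmoid of an affine transform: one-vs-all probabilities
#' (argmax of the outputs gives the decision; rows need not sum to 1).
#'
#' @param x numeric vector of length n_in, or a matrix with one sample per
#'   row.
#' @param model an `fc_model`.
#' @return a matrix of per-class probabilities (samples x classes).
#' @export
fc_forward <- function(x, model) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != nrow(model$weights) - 1L)
    stop("input dimension does not match the model")
  Z <- cbind(1, X) %*% model$weights
  P <- if (identical(model$output, "softmax")) softmax(Z) else sigmoid(Z)
  colnames(P) <- model$class_names
  P
}

# Seeded uniform init in [-0.1, 0.1]; small symmetric values suit sigmoid
# units.
init_weights <- function(nr, nc, seed) {
  with_seed(seed, matrix(stats::runif(nr * nc, -0.1, 0.1), nr, nc))
}

one_hot <- function(y, classes) {
  Y <- matrix(0, length(y), length(classes),
              dimnames = list(NULL, classes))
  Y[cbind(seq_along(y), match(as.character(y), classes))] <- 1
  Y
}

# Mean one-vs-all cross-entropy.
ce_loss <- function(P, Y) {
  eps <- 1e-12
  -mean(Y * log(P + eps) + (1 - Y) * log(1 - P + eps))
}

#' Train a fully connected logistic readout
#'
#' Full-batch gradient descent on the one-vs-all cross-entropy; training is
#' deterministic given the seed, and the loss is non-increasing at the
#' committed default learning rate.
#'
#' @param X sample matrix (samples x features), already scaled.
#' @param y class labels (character or factor), at least two classes present.
#' @param config a `train_config`.
#' @param classes optional explicit class ordering.
#' @return an `fc_model` with attribute `"loss"` (per-epoch training loss).
#' @export
train_logistic <- function(X, y, config = train_config(), classes = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (is.null(classes)) classes <- sort(unique(y))
  if (length(classes) < 2) stop("at least two classes must be present")
  Y <- one_hot(y, classes)
  Xa <- cbind(1, X)
  W <- init_weights(ncol(Xa), length(classes), config$seed)
  n <- nrow(X)
  softmax_out <- identical(config$output, "softmax")
  loss <- numeric(config$epochs)
  for (e in seq_len(config$epochs)) {
    Z <- Xa %*% W
    if (softmax_out) {
      P <- softmax(Z)
      loss[e] <- -mean(rowSums(Y * log(P + 1e-12)))
      G <- crossprod(Xa, P - Y) / n
    } else {
      P <- sigmoid(Z)
      loss[e] <- ce_loss(P, Y)
      G <- crossprod(Xa, P - Y) / (n * length(classes))
    }
    W <- W - config$learning_rate * G
  }
  m <- fc_model(W, classes, output = config$output)
  attr(m, "loss") <- loss
  m
}

#' Valid cross-correlation of a reservoir-state matrix with a shared kernel
#'
#' Slides one k x r kernel along the node axis (full height across the r
#' device rows, no padding) with the given stride, adds a bias and applies a
#' sigmoid, producing a feature map of length floor((n - k) / stride) + 1.
#'
#' @param states a `reservoir_states` or a numeric matrix (devices x nodes).
#' @param kernel numeric k x r matrix (node axis x device axis).
#' @param stride positive integer stride.
#' @param bias scalar bias added before the activation.
#' @param activation activation function (default sigmoid; use `identity`
#'   for the raw map).
#' @return numeric feature-map vector.
#' @export
conv_forward <- function(states, kernel, stride = 1, bias = 0,
                         activation = sigmoid) {
  X <- if (inherits(states, "reservoir_states")) states$values else
    rbind(states)
  kernel <- as.matrix(kernel)
  k <- nrow(kernel)
  if (ncol(kernel) != nrow(X))
    stop("kernel device-axis width must equal the number of device rows")
  n <- ncol(X)
  if (n < k) stop("kernel is longer than the input node axis")
  L <- floor((n - k) / stride) + 1L
  f <- vapply(seq_len(L), function(j) {
    idx <- (j - 1L) * stride + seq_len(k)
    sum(t(X[, idx, drop = FALSE]) * kernel) + bias
  }, numeric(1))
  activation(f)
}

#' Bilayer convolutional readout model
#'
#' @param kernel shared k x r convolution kernel.
#' @param bias convolution bias (scalar).
#' @param stride convolution stride.
#' @param fc an `fc_model` over the feature map.
#' @return an object of class `conv_readout`.
#' @export
conv_readout <- function(kernel, bias, stride, fc) {
  stopifnot(inherits(fc, "fc_model"))
  structure(list(kernel = as.matrix(kernel), bias = bias,
                 stride = as.integer(stride), fc = fc),
            class = "conv_readout")
}

#' @export
print.conv_readout <- function(x, ...) {
  cat(sprintf(
    "<conv_readout> kernel %d x %d (stride %d) -> %d x %d perceptron\n",
    nrow(x$kernel), ncol(x$kernel), x$stride,
    nrow(x$fc$weights) - 1L, ncol(x$fc$weights)))
  invisible(x)
}

# Unfold a list of (r x n) input matrices into the patch tensor used by the
# convolution: a list with one (n_samples x k*r) matrix per feature-map
# position.
unfold_patches <- function(inputs, k, stride, L) {
  lapply(seq_len(L), function(j) {
    idx <- (j - 1L) * stride + seq_len(k)
    t(vapply(inputs, function(X) as.numeric(t(X[, idx, drop = FALSE])),
             numeric(k * nrow(inputs[[1]]))))
  })
}

#' Train a bilayer convolutional readout
#'
#' End-to-end full-batch gradient descent (backpropagation through the single
#' shared-kernel convolution layer) on the one-vs-all cross-entropy;
#' deterministic given the seed.
#'
#' @param inputs list of numeric matrices (devices x nodes), one per sample,
#'   all of equal shape and already scaled.
#' @param y class labels.
#' @param kernel_size kernel length along the node axis (k).
#' @param stride convolution stride.
#' @param config a `train_config`.
#' @param classes optional explicit class ordering.
#' @param class_weights optional per-class loss weights (named or in class
#'   order); e.g. a reduced transition-class weight trades detection
#'   sensitivity against false alarms in the streaming task.
#' @return a `conv_readout` with attribute `"loss"`.
#' @export
train_conv_readout <- function(inputs, y, kernel_size, stride = 1,
                               config = train_config(), classes = NULL,
                               class_weights = NULL) {
  stopifnot(is.list(inputs), length(inputs) >= 2)
  inputs <- lapply(inputs, rbind)
  r <- nrow(inputs[[1]])
  n <- ncol(inputs[[1]])
  if (n < kernel_size) stop("kernel is longer than the input node axis")
  y <- as.character(y)
  if (is.null(classes)) classes <- sort(unique(y))
  if (length(classes) < 2) stop("at least two classes must be present")
  L <- floor((n - kernel_size) / stride) + 1L
  C <- length(classes)
  ns <- length(inputs)
  Y <- one_hot(y, classes)
  if (is.null(class_weights)) class_weights <- rep(1, C)
  if (!is.null(names(class_weights)))
    class_weights <- class_weights[classes]
  stopifnot(length(class_weights) == C, all(class_weights > 0))
  patches <- unfold_patches(inputs, kernel_size, stride, L)

  kv <- as.numeric(init_weights(kernel_size * r + 1L, 1L, config$seed))
  b1 <- kv[1L]
  kvec <- kv[-1L]
  W2 <- init_weights(L + 1L, C, config$seed + 1L)
  loss <- numeric(config$epochs)

  softmax_out <- identical(config$output, "softmax")
  for (e in seq_len(config$epochs)) {
    FM <- vapply(patches, function(P) sigmoid(P %*% kvec + b1),
                 numeric(ns))                   # ns x L feature map
    FMa <- cbind(1, FM)
    Z2 <- FMa %*% W2
    eps <- 1e-12
    if (softmax_out) {
      P2 <- softmax(Z2)
      loss[e] <- -mean(rowSums(sweep(Y * log(P2 + eps), 2, class_weights,
                                     "*")))
      dZ2 <- sweep(P2 - Y, 2, class_weights, "*") / ns
    } else {
      P2 <- sigmoid(Z2)
      loss[e] <- -mean(sweep(Y * log(P2 + eps) +
                               (1 - Y) * log(1 - P2 + eps),
                             2, class_weights, "*"))
      dZ2 <- sweep(P2 - Y, 2, class_weights, "*") / (ns * C)
    }
    dW2 <- crossprod(FMa, dZ2)
    dFM <- dZ2 %*% t(W2[-1L, , drop = FALSE])
    dZ1 <- dFM * FM * (1 - FM)
    dkvec <- numeric(length(kvec))
    for (j in seq_len(L)) dkvec <- dkvec + crossprod(patches[[j]],
                                                     dZ1[, j])
    db1 <- sum(dZ1)
    W2 <- W2 - config$learning_rate * dW2
    kvec <- kvec - config$learning_rate * dkvec
    b1 <- b1 - config$learning_rate * db1
  }
  m <- conv_readout(matrix(kvec, kernel_size, r), b1, stride,
                    fc_model(W2, classes, output = config$output))
  attr(m, "loss") <- loss
  m
}

#' Predict class probabilities
#'
#' @param object an `fc_model` or `conv_readout`.
#' @param x input: matrix of samples (rows) for `fc_model`; a single
#'   devices x nodes matrix, `reservoir_states`, or a list of them for
#'   `conv_readout`.
#' @param ... unused.
#' @return matrix of per-class probabilities.
#' @export
predict.fc_model <- function(object, x, ...) fc_forward(x, object)

#' @rdname predict.fc_model
#' @export
predict.conv_readout <- function(object, x, ...) {
  if (inherits(x, "reservoir_states")) x <- list(x$values)
  if (is.matrix(x)) x <- list(x)
  FM <- t(vapply(x, function(X)
    conv_forward(X, object$kernel, object$stride, object$bias),
    numeric(nrow(object$fc$weights) - 1L)))
  fc_forward(FM, object$fc)
}

# Argmax decision with deterministic tie-breaking (lowest class index wins).
decide <- function(P, classes) classes[max.col(P, ties.method = "first")]

#' Classify inputs with a trained readout
#'
#' @param model an `fc_model` or `conv_readout`.
#' @param x inputs as accepted by [predict.fc_model()].
#' @return character vector of predicted class labels.
#' @export
classify <- function(model, x) {
  P <- predict(model, x)
  cls <- if (inherits(model, "conv_readout")) model$fc$class_names else
    model$class_names
  decide(P, cls)
}

#' Evaluate a readout on labeled data
#'
#' @param model a trained `fc_model` or `conv_readout`.
#' @param x inputs as accepted by [predict.fc_model()].
#' @param y true class labels.
#' @return list with `accuracy` (overall fraction correct) and `confusion`
#'   (row-normalized confusion matrix: rows are true classes, entries are
#'   occurrence probabilities and each row sums to 1).
#' @export
evaluate <- function(model, x, y) {
  y <- as.character(y)
  if (!length(y)) stop("empty evaluation data")
  pred <- classify(model, x)
  cls <- if (inherits(model, "conv_readout")) model$fc$class_names else
    model$class_names
  cm <- table(factor(y, levels = cls), factor(pred, levels = cls))
  acc <- sum(diag(cm)) / sum(cm)
  cmn <- sweep(unclass(cm), 1, pmax(rowSums(cm), 1), "/")
  list(accuracy = acc, confusion = cmn, n = length(y))
}
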