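test_that("fc_forward computes one-vs-all sigmoid probabilities", {
  m <- fc_model(matrix(0, 3, 2), c("A", "B"))
  expect_equal(unname(fc_forward(c(1, 1), m)), matrix(0.5, 1, 2))
  # hand-set 2x2 toy: p = sigmoid(b + x.w)
  W <- rbind(c(0.5, -0.5), c(1, 2), c(-1, 0.3))
  m <- fc_model(W, c("A", "B"))
  x <- c(0.2, 0.7)
  expect_equal(as.numeric(fc_forward(x, m)),
               as.numeric(1 / (1 + exp(-(c(1, x) %*% W)))))
  # outputs always in (0, 1)
  P <- fc_forward(matrix(rnorm(20, sd = 5), 10, 2), m)
  expect_true(all(P > 0 & P < 1))
  expect_error(fc_forward(c(1, 2, 3), m), "dimension")
})

test_that("conv_forward computes the stated feature-map arithmetic", {
  # 31 nodes, 27x1 kernel, stride 1 -> 5 features
  expect_length(conv_forward(matrix(runif(31), 1), matrix(1, 27, 1)), 5)
  # 45x2 input, 6x2 kernel, stride 2 -> 20 features
  expect_length(conv_forward(matrix(runif(90), 2), matrix(1, 6, 2),
                             stride = 2), 20)
  # all-zero kernel: constant map at sigmoid(bias)
  f <- conv_forward(matrix(runif(31), 1), matrix(0, 27, 1), bias = 0.3)
  expect_equal(f, rep(1 / (1 + exp(-0.3)), 5))
  # hand oracle on a tiny case
  X <- rbind(1:5, 6:10)
  K <- rbind(c(1, -1), c(2, 0.5))
  f <- conv_forward(X, K, stride = 1, activation = identity)
  man <- vapply(1:4, function(j)
    X[1, j] * 1 + X[2, j] * -1 + X[1, j + 1] * 2 + X[2, j + 1] * 0.5,
    numeric(1))
  expect_equal(f, man)
  expect_error(conv_forward(matrix(1, 1, 5), matrix(1, 6, 1)), "longer")
  expect_error(conv_forward(matrix(1, 1, 31), matrix(1, 27, 2)),
               "device rows")
})

test_that("train_logistic fits separable toys and has exact gradients", {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y <- c("A", "A", "B", "B")
  m <- train_logistic(X, y, train_config(learning_rate = 5, epochs = 2000))
  expect_identical(classify(m, X), y)
  expect_error(train_logistic(X, rep("A", 4)), "two classes")
  # analytic gradient matches central finite differences
  set.seed(3)
  Xs <- matrix(runif(12), 4, 3)
  Y <- memrc:::one_hot(c("A", "B", "A", "B"), c("A", "B"))
  W <- matrix(runif(8, -1, 1), 4, 2)
  Xa <- cbind(1, Xs)
  lossW <- function(W) memrc:::ce_loss(memrc:::sigmoid(Xa %*% W), Y)
  G <- crossprod(Xa, memrc:::sigmoid(Xa %*% W) - Y) / (4 * 2)
  eps <- 1e-6
  for (idx in sample(length(W), 5)) {
    Wp <- W; Wp[idx] <- W[idx] + eps
    Wm <- W; Wm[idx] <- W[idx] - eps
    fd <- (lossW(Wp) - lossW(Wm)) / (2 * eps)
    expect_equal(G[idx], fd, tolerance = 1e-6)
  }
})

test_that("conv readout backprop matches finite differences", {
  set.seed(7)
  inputs <- lapply(1:6, function(i) matrix(runif(3), 1, 3))
  y <- c("A", "B", "A", "B", "A", "B")
  eval_loss <- function(kvec, b1, W2) {
    L <- 0
    Y <- memrc:::one_hot(y, c("A", "B"))
    for (i in seq_along(inputs)) {
      f <- memrc:::sigmoid(vapply(1:2, function(j)
        sum(inputs[[i]][, j:(j + 1)] * kvec) + b1, numeric(1)))
      Pr <- memrc:::sigmoid(c(1, f) %*% W2)
      L <- L - sum(Y[i, ] * log(Pr) + (1 - Y[i, ]) * log(1 - Pr))
    }
    L / (length(inputs) * 2)
  }
  # one tiny training step must reduce the loss along the analytic gradient
  m0 <- train_conv_readout(inputs, y, kernel_size = 2, stride = 1,
                           config = train_config(learning_rate = 0.5,
                                                 epochs = 1, seed = 1))
  m1 <- train_conv_readout(inputs, y, kernel_size = 2, stride = 1,
                           config = train_config(learning_rate = 0.5,
                                                 epochs = 60, seed = 1))
  l0 <- attr(m1, "loss")
  expect_true(all(diff(l0) <= 1e-12))
  # finite-difference check of the kernel gradient at the init point
  kv <- as.numeric(memrc:::init_weights(3, 1, 1))
  b1 <- kv[1]; kvec <- kv[-1]
  W2 <- memrc:::init_weights(3, 2, 2)
  eps <- 1e-6
  base <- eval_loss(kvec, b1, W2)
  # gradient implied by one GD step of the trainer
  kv_after <- as.numeric(t(m0$kernel))
  g_impl <- (kvec - kv_after) / 0.5
  for (j in 1:2) {
    kp <- kvec; kp[j] <- kp[j] + eps
    km <- kvec; km[j] <- km[j] - eps
    fd <- (eval_loss(kp, b1, W2) - eval_loss(km, b1, W2)) / (2 * eps)
    expect_equal(g_impl[j], fd, tolerance = 1e-4)
  }
})

test_that("training is reproducible and order-invariant (full batch)", {
  set.seed(11)
  X <- matrix(runif(120), 30, 4)
  y <- rep(c("A", "B", "C"), 10)
  cfg <- train_config(learning_rate = 1, epochs = 200, seed = 5)
  m1 <- train_logistic(X, y, cfg)
  m2 <- train_logistic(X, y, cfg)
  expect_identical(m1$weights, m2$weights)
  perm <- sample(30)
  m3 <- train_logistic(X[perm, ], y[perm], cfg, classes = c("A", "B", "C"))
  expect_equal(m1$weights, m3$weights, tolerance = 1e-12)
  # loss non-increasing at the default rate
  expect_true(all(diff(attr(m1, "loss")) <= 1e-12))
})

test_that("affine consistency: scaled inputs with inversely scaled weights", {
  W <- rbind(c(0.2, -0.1), matrix(runif(6, -1, 1), 3, 2))
  m <- fc_model(W, c("A", "B"))
  X <- matrix(runif(15), 5, 3)
  c0 <- 7
  Ws <- rbind(W[1, ], W[-1, ] / c0)
  ms <- fc_model(Ws, c("A", "B"))
  expect_equal(fc_forward(X, m), fc_forward(X * c0, ms))
  expect_identical(classify(m, X), classify(ms, X * c0))
})

test_that("evaluate reports accuracy and a row-normalized confusion map", {
  m <- fc_model(rbind(c(0, 0), c(5, -5)), c("A", "B"))
  X <- matrix(c(1, 1, -1, -1), 4, 1)
  y <- c("A", "A", "B", "B")
  ev <- evaluate(m, X, y)
  expect_equal(ev$accuracy, 1)
  expect_equal(unclass(ev$confusion), diag(2),
               ignore_attr = TRUE)
  # constant predictor on balanced two-class data: 50%
  mc <- fc_model(rbind(c(5, 0), c(0, 0)), c("A", "B"))
  ev2 <- evaluate(mc, X, y)
  expect_equal(ev2$accuracy, 0.5)
  expect_equal(unname(rowSums(ev2$confusion)), c(1, 1))
  expect_error(evaluate(m, X, character(0)), "empty")
})

test_that("softmax output is available behind the config flag", {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y <- c("A", "A", "B", "B")
  m <- train_logistic(X, y, train_config(learning_rate = 2, epochs = 1000,
                                         output = "softmax"))
  P <- predict(m, X)
  expect_equal(unname(rowSums(P)), rep(1, 4))
  expect_identical(classify(m, X), y)
})
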