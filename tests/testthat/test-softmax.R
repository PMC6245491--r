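test_that("zero weights give the uniform distribution; argmax ties break by
           class order", {
  model <- structure(list(weights = matrix(0, 3, 2,
                                           dimnames = list(c("a", "b", "c"),
                                                           NULL)),
                          biases = stats::setNames(numeric(3),
                                                   c("a", "b", "c")),
                          classes = c("a", "b", "c"),
                          control = softmax_control()),
                     class = "softmax_model")
  p <- softmax_predict_proba(model, c(1, 2))
  expect_equal(unname(p), rep(1 / 3, 3))
  expect_identical(softmax_predict(model, c(1, 2)), "a")
})

test_that("probabilities match the printed exponential-normalization formulas", {
  withr::with_seed(51, {
    for (r in 1:20) {
      k <- sample(2:6, 1); f <- sample(1:4, 1); n <- sample(1:10, 1)
      cls <- sprintf("c%d", seq_len(k))
      model <- structure(list(weights = matrix(rnorm(k * f), k, f,
                                               dimnames = list(cls, NULL)),
                              biases = stats::setNames(rnorm(k), cls),
                              classes = cls, control = softmax_control()),
                         class = "softmax_model")
      x <- matrix(rnorm(n * f), n, f)
      p <- softmax_predict_proba(model, x)
      for (i in seq_len(n)) {
        z <- as.numeric(model$weights %*% x[i, ] + model$biases)
        t_i <- exp(z)
        expect_equal(unname(p[i, ]), t_i / sum(t_i), tolerance = 1e-12)
      }
      expect_equal(unname(rowSums(p)), rep(1, n), tolerance = 1e-12)
    }
  })
})

test_that("softmax is shift-invariant in the logits", {
  cls <- c("a", "b", "c")
  w <- matrix(c(1, -2, 0.5, 3, 0, -1), 3, 2, dimnames = list(cls, NULL))
  b <- stats::setNames(c(0.3, -0.7, 1), cls)
  m1 <- structure(list(weights = w, biases = b, classes = cls,
                       control = softmax_control()), class = "softmax_model")
  m2 <- structure(list(weights = w, biases = b + 123.45, classes = cls,
                       control = softmax_control()), class = "softmax_model")
  x <- matrix(rnorm(10), 5, 2)
  expect_equal(softmax_predict_proba(m1, x), softmax_predict_proba(m2, x),
               tolerance = 1e-12)
})

test_that("with two classes the model reduces to the logistic sigmoid", {
  cls <- c("neg", "pos")
  w <- matrix(c(-0.8, 0.8), 2, 1, dimnames = list(cls, NULL))
  b <- stats::setNames(c(-0.2, 0.2), cls)
  m <- structure(list(weights = w, biases = b, classes = cls,
                      control = softmax_control()), class = "softmax_model")
  x <- seq(-3, 3, by = 0.5)
  p <- softmax_predict_proba(m, matrix(x, ncol = 1))
  margin <- (w[2] - w[1]) * x + (b[2] - b[1])
  expect_equal(unname(p[, "pos"]), plogis(margin), tolerance = 1e-12)
})

test_that("batch prediction equals per-row prediction", {
  withr::with_seed(52, {
    cls <- c("a", "b", "c", "d")
    m <- structure(list(weights = matrix(rnorm(12), 4, 3,
                                         dimnames = list(cls, NULL)),
                        biases = stats::setNames(rnorm(4), cls),
                        classes = cls, control = softmax_control()),
                   class = "softmax_model")
    x <- matrix(rnorm(30), 10, 3)
    batch <- softmax_predict(m, x)
    single <- vapply(seq_len(10), function(i) softmax_predict(m, x[i, ]), "")
    expect_identical(batch, single)
  })
})

test_that("a linearly separable two-class problem is learned perfectly", {
  x <- matrix(c(rep(0, 20), rep(2, 20)), ncol = 1)
  y <- rep(c("low", "high"), each = 20)
  m <- softmax_train(x, y)
  expect_identical(softmax_predict(m, x), y)
})

test_that("the analytic gradient matches finite differences", {
  withr::with_seed(53, {
    x <- matrix(rnorm(30), 10, 3)
    y <- c(rep("a", 4), rep("b", 3), rep("c", 3))
    cls <- c("a", "b", "c")
    w <- matrix(rnorm(9, sd = 0.5), 3, 3, dimnames = list(cls, NULL))
    b <- stats::setNames(rnorm(3, sd = 0.5), cls)
    for (l2 in c(0, 0.05)) {
      g <- chromaim:::.softmax_gradient(x, y, w, b, l2 = l2)
      h <- 1e-6
      for (i in 1:3) for (j in 1:3) {
        wp <- w; wp[i, j] <- w[i, j] + h
        wm <- w; wm[i, j] <- w[i, j] - h
        fd <- (softmax_loss(x, y, wp, b, l2 = l2) -
                 softmax_loss(x, y, wm, b, l2 = l2)) / (2 * h)
        expect_equal(unname(g$weights[i, j]), unname(fd), tolerance = 1e-6)
      }
      for (i in 1:3) {
        bp <- b; bp[i] <- b[i] + h
        bm <- b; bm[i] <- b[i] - h
        fd <- (softmax_loss(x, y, w, bp, l2 = l2) -
                 softmax_loss(x, y, w, bm, l2 = l2)) / (2 * h)
        expect_equal(g$biases[i], fd, tolerance = 1e-6,
                     ignore_attr = TRUE)
      }
    }
  })
})

test_that("the two-class fit agrees with an unpenalized logistic regression", {
  withr::with_seed(54, {
    n <- 80
    x <- rnorm(n)
    y01 <- rbinom(n, 1, plogis(0.5 + 1.5 * x))
    y <- ifelse(y01 == 1, "b", "a")
    ref <- glm(y01 ~ x, family = binomial)
    p_ref <- unname(predict(ref, type = "response"))
    m <- softmax_train(matrix(x, ncol = 1), y,
                       softmax_control(learning_rate = 0.5, epochs = 5000,
                                       l2 = 0))
    p_fit <- unname(softmax_predict_proba(m, matrix(x, ncol = 1))[, "b"])
    expect_equal(p_fit, p_ref, tolerance = 1e-3)
  })
})

test_that("training loss is non-increasing across epochs", {
  withr::with_seed(55, {
    x <- matrix(rnorm(60), 30, 2)
    y <- sample(c("a", "b", "c"), 30, replace = TRUE)
    while (length(unique(y)) < 3) y <- sample(c("a", "b", "c"), 30, TRUE)
    losses <- vapply(c(1, 5, 20, 80, 200, 500), function(ep) {
      softmax_train(x, y, softmax_control(epochs = ep))$final_loss
    }, numeric(1))
    expect_true(all(diff(losses) <= 1e-12))
  })
})

test_that("training validates its preconditions", {
  expect_error(softmax_train(matrix(1:4, ncol = 1), c("a", "a", "a", "a"),
                             classes = c("a", "b")),
               "class absent")
  expect_error(softmax_train(matrix(1, 1, 1), "a"), "at least two classes")
})

test_that("evaluation tallies the confusion matrix like a brute-force count", {
  withr::with_seed(56, {
    x <- matrix(rnorm(120), 60, 2)
    y <- sample(c("a", "b", "c"), 60, replace = TRUE)
    while (length(unique(y)) < 3) y <- sample(c("a", "b", "c"), 60, TRUE)
    m <- softmax_train(x, y, softmax_control(epochs = 100))
    ev <- softmax_evaluate(m, x, y)
    pred <- softmax_predict(m, x)
    for (ti in m$classes) {
      expect_identical(sum(ev$confusion[ti, ]), sum(y == ti))
      for (pj in m$classes) {
        expect_identical(unname(ev$confusion[ti, pj]),
                         sum(y == ti & pred == pj))
      }
    }
    expect_equal(ev$accuracy, 100 * mean(pred == y))
  })
})

test_that("a perfect predictor yields a diagonal confusion matrix and a
           constant predictor a single nonzero column", {
  cls <- c("a", "b")
  perfect <- structure(list(weights = matrix(c(-5, 5), 2, 1,
                                             dimnames = list(cls, NULL)),
                            biases = stats::setNames(c(0, 0), cls),
                            classes = cls, control = softmax_control()),
                       class = "softmax_model")
  x <- matrix(c(-1, -1, 1, 1), ncol = 1)
  y <- c("a", "a", "b", "b")
  ev <- softmax_evaluate(perfect, x, y)
  expect_equal(ev$accuracy, 100)
  expect_identical(unname(diag(ev$confusion)), c(2L, 2L))
  constant <- structure(list(weights = matrix(0, 2, 1,
                                              dimnames = list(cls, NULL)),
                             biases = stats::setNames(c(5, 0), cls),
                             classes = cls, control = softmax_control()),
                        class = "softmax_model")
  ev2 <- softmax_evaluate(constant, x, y)
  expect_equal(unname(colSums(ev2$confusion > 0)), c(2, 0))
})
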