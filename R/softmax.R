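#' Training hyperparameters for the softmax classifier
#'
#' Defaults are deliberately plain: full-batch gradient descent from zero
#' initialization with a small ridge penalty. Because initialization is
#' deterministic (zeros), \code{seed} only matters if stochastic options are
#' ever enabled; it is kept in the control object so every report can log it.
#'
#' @param learning_rate gradient-descent step size.
#' @param epochs number of full-batch iterations.
#' @param l2 ridge penalty on the weights (biases unpenalized).
#' @param seed integer recorded with the model.
#' @return list of class \code{softmax_control}.
#' @export
softmax_control <- function(learning_rate = 0.1, epochs = 500L, l2 = 1e-4,
                            seed = 1L) {
  stopifnot(learning_rate > 0, epochs >= 1, l2 >= 0)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 l2 = l2, seed = as.integer(seed)),
            class = "softmax_control")
}

.softmax_design <- function(x) {
  x <- if (is.null(dim(x))) matrix(as.numeric(x), ncol = 1L) else
    as.matrix(x)
  storage.mode(x) <- "double"
  x
}

# row-wise softmax with max subtraction (overflow-safe; identical to
# t_i = exp(z_i), a_i = t_i / sum(t_i) because softmax is shift-invariant)
.softmax_rows <- function(z) {
  mx <- z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  e <- exp(z - mx)
  e / rowSums(e)
}

.softmax_forward <- function(x, weights, biases) {
  z <- tcrossprod(x, weights)
  z <- z + rep(biases, each = nrow(z))
  .softmax_rows(z)
}

#' Multinomial cross-entropy loss of a softmax model
#'
#' Weighted mean negative log-likelihood plus \code{l2/2 * sum(weights^2)}.
#'
#' @param x feature matrix (N x F) or vector.
#' @param y labels (length N).
#' @param weights K x F weight matrix (rows ordered as \code{classes}).
#' @param biases length-K bias vector.
#' @param classes ordered class labels; default \code{rownames(weights)}.
#' @param l2 ridge penalty.
#' @param sample_weights optional nonnegative case weights.
#' @return numeric scalar.
#' @export
softmax_loss <- function(x, y, weights, biases, classes = rownames(weights),
                         l2 = 0, sample_weights = NULL) {
  x <- .softmax_design(x)
  ki <- match(as.character(y), classes)
  if (anyNA(ki)) stop("labels outside the class set")
  p <- .softmax_forward(x, weights, biases)
  w <- if (is.null(sample_weights)) rep(1, nrow(x)) else sample_weights
  nll <- -log(p[cbind(seq_len(nrow(x)), ki)])
  sum(w * nll) / sum(w) + l2 / 2 * sum(weights^2)
}

# analytic gradient of softmax_loss w.r.t. weights and biases
.softmax_gradient <- function(x, y, weights, biases,
                              classes = rownames(weights), l2 = 0,
                              sample_weights = NULL) {
  x <- .softmax_design(x)
  n <- nrow(x)
  ki <- match(as.character(y), classes)
  p <- .softmax_forward(x, weights, biases)
  yk <- matrix(0, n, length(classes))
  yk[cbind(seq_len(n), ki)] <- 1
  w <- if (is.null(sample_weights)) rep(1, n) else sample_weights
  e <- (p - yk) * w
  sw <- sum(w)
  list(weights = crossprod(e, x) / sw + l2 * weights,
       biases = colSums(e) / sw)
}

#' Train a K-class softmax (multinomial logistic) classifier
#'
#' Fits the model \eqn{z_i = \sum_j w_{ij} x_j + b_i}, \eqn{t_i = e^{z_i}},
#' \eqn{a_i = t_i / \sum_k t_k} by minimizing the multinomial cross-entropy
#' with an optional ridge penalty, using full-batch gradient descent from
#' zero initialization. Training is deterministic. Optional case weights
#' let identical (feature, label) rows be collapsed with multiplicities;
#' the weighted fit is mathematically identical to the expanded one.
#'
#' @param x feature matrix (N x F) or numeric vector (single feature).
#' @param y class labels (character or factor, length N).
#' @param control a [softmax_control()].
#' @param classes ordered class labels; defaults to factor levels or sorted
#'   unique labels. Every class must occur in \code{y}.
#' @param sample_weights optional nonnegative case weights (length N).
#' @return object of class \code{softmax_model}: list with \code{weights}
#'   (K x F), \code{biases} (K), \code{classes}, \code{control},
#'   \code{final_loss}.
#' @export
softmax_train <- function(x, y, control = softmax_control(), classes = NULL,
                          sample_weights = NULL) {
  x <- .softmax_design(x)
  ychr <- as.character(y)
  if (is.null(classes)) {
    classes <- if (is.factor(y)) levels(y) else sort(unique(ychr))
  }
  if (!all(classes %in% ychr)) {
    stop("class absent from training labels: ",
         paste(setdiff(classes, ychr), collapse = ", "))
  }
  if (!all(ychr %in% classes)) stop("labels outside the class set")
  k <- length(classes)
  if (k < 2) stop("need at least two classes")
  if (nrow(x) < k) stop("fewer training rows than classes")
  n <- nrow(x)
  yk <- matrix(0, n, k)
  yk[cbind(seq_len(n), match(ychr, classes))] <- 1
  w <- if (is.null(sample_weights)) rep(1, n) else as.numeric(sample_weights)
  fit <- softmax_gd_cpp(x, yk, w, control$learning_rate, control$epochs,
                        control$l2)
  weights <- fit$weights
  dimnames(weights) <- list(classes, colnames(x))
  biases <- stats::setNames(as.numeric(fit$biases), classes)
  structure(list(weights = weights, biases = biases, classes = classes,
                 control = control,
                 final_loss = softmax_loss(x, ychr, weights, biases,
                                           classes = classes,
                                           l2 = control$l2,
                                           sample_weights = sample_weights)),
            class = "softmax_model")
}

#' Class probabilities from a softmax model
#'
#' @param model a \code{softmax_model}.
#' @param x feature matrix (N x F) or a single length-F feature vector.
#' @return N x K probability matrix (rows sum to 1), or a named length-K
#'   vector for a single feature vector.
#' @export
softmax_predict_proba <- function(model, x) {
  single <- is.null(dim(x))
  if (single && length(x) != ncol(model$weights)) {
    stop("feature length does not match the model")
  }
  x <- .softmax_design(if (single) matrix(x, nrow = 1L) else x)
  if (ncol(x) != ncol(model$weights)) {
    stop("feature dimension does not match the model")
  }
  p <- .softmax_forward(x, model$weights, model$biases)
  colnames(p) <- model$classes
  if (single) p[1L, ] else p
}

#' Predicted class labels (argmax; ties broken by class order)
#'
#' @inheritParams softmax_predict_proba
#' @return character vector of predicted labels.
#' @export
softmax_predict <- function(model, x) {
  p <- softmax_predict_proba(model, x)
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  model$classes[max.col(p, ties.method = "first")]
}

#' Evaluate a softmax model on labelled data
#'
#' @param model a \code{softmax_model}.
#' @param x feature matrix of test samples.
#' @param y true labels.
#' @param metadata optional metadata data.frame; when supplied, per-continent
#'   accuracies are reported, crediting a test individual of continent j as
#'   correct iff the predicted label's continent equals j (labels may be
#'   population or continent codes).
#' @return list with \code{accuracy} (percent), \code{confusion} (true x
#'   predicted count matrix over the model's classes) and
#'   \code{per_continent} (named percent vector, or NULL).
#' @export
softmax_evaluate <- function(model, x, y, metadata = NULL) {
  pred <- softmax_predict(model, x)
  y <- as.character(y)
  confusion <- table(true = factor(y, levels = model$classes),
                     predicted = factor(pred, levels = model$classes))
  acc <- 100 * mean(pred == y)
  per_cont <- NULL
  if (!is.null(metadata)) {
    tc <- label_to_continent(y, metadata)
    pc <- label_to_continent(pred, metadata)
    lev <- intersect(continent_levels(metadata), unique(tc))
    per_cont <- vapply(lev, function(j) 100 * mean(pc[tc == j] == j),
                       numeric(1))
  }
  list(accuracy = acc, confusion = confusion, per_continent = per_cont)
}
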