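# Extreme learning machine: a single-hidden-layer feedforward network
# whose hidden weights/biases are fixed (random, or supplied by an
# optimizer) and whose output weights are the minimum-norm least-squares
# solution beta = pinv(H) T.

activation_fun <- function(name) {
  switch(name,
    sigmoid = function(z) 1 / (1 + exp(-z)),
    tanh = tanh,
    identity = identity,
    stopf("unknown activation '%s' (use sigmoid, tanh or identity)", name)
  )
}

#' Hidden-layer output matrix
#'
#' Computes `H[p, i] = g(X[p, ] %*% W[i, ] + b[i])` for hidden nodes
#' `i = 1..L` and samples `p = 1..N`.
#'
#' @param X N x d feature matrix.
#' @param W L x d input-weight matrix.
#' @param b length-L bias vector.
#' @param activation one of `"sigmoid"`, `"tanh"`, `"identity"`.
#' @return N x L matrix.
#' @export
elm_hidden_output <- function(X, W, b, activation = "sigmoid") {
  X <- as.matrix(X)
  W <- as.matrix(W)
  if (ncol(X) != ncol(W)) {
    stopf("feature dimension %d does not match input-weight dimension %d",
          ncol(X), ncol(W))
  }
  if (length(b) != nrow(W)) {
    stopf("bias length %d does not match hidden-node count %d",
          length(b), nrow(W))
  }
  g <- activation_fun(activation)
  g(sweep(X %*% t(W), 2L, b, `+`))
}

#' Train an extreme learning machine
#'
#' Hidden weights and biases are fixed (supplied, or drawn uniformly from
#' \[-1, 1\] under `seed`); the output weights are the minimum-norm
#' least-squares solution of `H beta = T`, obtained through the SVD-based
#' Moore-Penrose pseudoinverse.
#'
#' @param X N x d training features.
#' @param T_out length-N vector (or N x o matrix) of targets; for binary
#'   interaction prediction a 0/1 vector.
#' @param hidden_nodes number of hidden nodes L (ignored when `W` given).
#' @param W,b optional L x d input weights and length-L biases; when
#'   omitted both are drawn randomly.
#' @param activation hidden activation name.
#' @param seed seed for the random hidden layer (only used when `W` is
#'   missing).
#' @return object of class `elm` with fields `input_weights`, `biases`,
#'   `output_weights`, `activation`, `hidden_nodes`.
#' @examples
#' X <- matrix(rnorm(40), 20, 2)
#' y <- as.numeric(X[, 1] + X[, 2] > 0)
#' fit <- elm_train(X, y, hidden_nodes = 25, seed = 1)
#' head(elm_predict(fit, X))
#' @export
elm_train <- function(X, T_out, hidden_nodes = 100, W = NULL, b = NULL,
                      activation = "sigmoid", seed = NULL) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stopf("features must be finite")
  T_out <- as.matrix(T_out)
  if (nrow(T_out) != nrow(X)) stopf("targets must have one row per sample")
  if (!all(is.finite(T_out))) stopf("targets must be finite")
  d <- ncol(X)
  if (is.null(W)) {
    L <- as.integer(hidden_nodes)
    wb <- with_seed(seed, stats::runif(L * (d + 1L), -1, 1))
    W <- matrix(wb[seq_len(L * d)], nrow = L, byrow = TRUE)
    b <- wb[L * d + seq_len(L)]
  } else {
    W <- as.matrix(W)
    L <- nrow(W)
    if (is.null(b)) stopf("b must be supplied together with W")
  }
  H <- elm_hidden_output(X, W, b, activation)
  beta <- MASS::ginv(H) %*% T_out
  structure(
    list(input_weights = W, biases = as.numeric(b), output_weights = beta,
         activation = activation, hidden_nodes = L),
    class = "elm"
  )
}

#' Predict with a trained extreme learning machine
#'
#' @param model a trained `elm` object.
#' @param X feature matrix.
#' @param type `"score"` (default) returns the raw network output used
#'   for ranking; `"label"` thresholds scores at 0.5.
#' @return numeric vector (o = 1) or matrix of scores or 0/1 labels.
#' @export
elm_predict <- function(model, X, type = c("score", "label")) {
  type <- match.arg(type)
  if (!inherits(model, "elm") || is.null(model$output_weights)) {
    stopf("model is not a trained elm")
  }
  H <- elm_hidden_output(X, model$input_weights, model$biases,
                         model$activation)
  out <- H %*% model$output_weights
  if (type == "label") out <- (out >= 0.5) + 0
  if (ncol(out) == 1L) out <- drop(out)
  out
}

#' @export
print.elm <- function(x, ...) {
  cat(sprintf("elm: %d hidden nodes, %s activation, %d inputs -> %d outputs\n",
              x$hidden_nodes, x$activation, ncol(x$input_weights),
              ncol(x$output_weights)))
  invisible(x)
}

#' Serialize / restore an ELM as JSON
#'
#' @param model a trained `elm`.
#' @param path output (input) path.
#' @return `path` invisibly; `elm_from_json` returns the restored model.
#' @export
elm_to_json <- function(model, path) {
  jsonlite::write_json(
    list(input_weights = model$input_weights, biases = model$biases,
         output_weights = model$output_weights,
         activation = model$activation, hidden_nodes = model$hidden_nodes),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor"
  )
  invisible(path)
}

#' @rdname elm_to_json
#' @export
elm_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(input_weights = as.matrix(x$input_weights),
         biases = as.numeric(x$biases),
         output_weights = as.matrix(x$output_weights),
         activation = x$activation,
         hidden_nodes = as.integer(x$hidden_nodes)),
    class = "elm"
  )
}
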