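#' The protocell translation network
#'
#' Each protocell's primitive translation system is modelled as a fully
#' connected feed-forward multilayer perceptron with 3 input nodes (one per
#' codon base position), 6 hidden nodes and 11 output nodes (the chemical
#' space), logistic activation on hidden and output nodes, and a bias unit
#' into each of those two layers. It is trained by online gradient-descent
#' backpropagation on the per-sample error \eqn{\varepsilon(n) = \frac12
#' \sum_j e_j^2(n)}, \eqn{e_j = d_j - y_j}.
#'
#' @name translation_network
NULL

NET_INPUT <- 3L
NET_HIDDEN <- 6L
NET_OUTPUT <- 11L

#' Initialise a translation network
#'
#' All weights and biases are drawn i.i.d. from a zero-mean distribution with
#' standard deviation \code{sd} (default 0.1): uniform on
#' \eqn{[-sd\sqrt{3}, +sd\sqrt{3}]} by default (the unique zero-mean uniform
#' with that sd), or Gaussian. Draws consume the R session RNG, so
#' \code{set.seed()} makes initialisation reproducible.
#'
#' @param learning_rate Backpropagation learning rate \eqn{\eta}
#'   (default 0.1).
#' @param init \code{"uniform"} (default) or \code{"gaussian"}.
#' @param sd Standard deviation of the initial weight distribution.
#' @return An object of class \code{"perceptron_translator"}: a list with
#'   \code{w_ih} (3 x 6), \code{b_h} (6), \code{w_ho} (6 x 11), \code{b_o}
#'   (11) and \code{learning_rate}.
#' @export
init_network <- function(learning_rate = 0.1, init = c("uniform", "gaussian"),
                         sd = 0.1) {
  init <- match.arg(init)
  stopifnot(is.numeric(learning_rate), learning_rate >= 0, sd > 0)
  n <- NET_INPUT * NET_HIDDEN + NET_HIDDEN +
    NET_HIDDEN * NET_OUTPUT + NET_OUTPUT
  w <- if (init == "uniform") {
    half <- sd * sqrt(3)
    stats::runif(n, -half, half)
  } else {
    stats::rnorm(n, 0, sd)
  }
  net <- list(
    w_ih = matrix(w[1:18], NET_INPUT, NET_HIDDEN),
    b_h = w[19:24],
    w_ho = matrix(w[25:90], NET_HIDDEN, NET_OUTPUT),
    b_o = w[91:101],
    learning_rate = learning_rate
  )
  class(net) <- "perceptron_translator"
  net
}

#' @export
print.perceptron_translator <- function(x, ...) {
  cat("perceptron translator 3-6-11, eta =", x$learning_rate, "\n")
  invisible(x)
}

.check_net <- function(net) {
  if (!inherits(net, "perceptron_translator")) {
    stop("not a perceptron_translator")
  }
  invisible(net)
}

#' Forward pass
#'
#' Propagates codon encodings through the network. Hidden activation
#' \eqn{y_j = \sigma(\sum_i w_{ij} x_i + b_j)} with the logistic
#' \eqn{\sigma(v) = 1/(1+e^{-v})}; outputs likewise from hidden activations.
#' All outputs lie strictly in (0, 1).
#'
#' @param net A \code{perceptron_translator}.
#' @param x Numeric 3-vector or n x 3 matrix of inputs in \[0, 1\].
#' @return 11-vector (vector input) or n x 11 matrix.
#' @export
forward <- function(net, x) {
  .check_net(net)
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, 1, NET_INPUT) else as.matrix(x)
  if (ncol(X) != NET_INPUT) stop("input must have 3 components per codon")
  if (!all(is.finite(X))) stop("non-finite network input")
  Y <- net_forward_cpp(X, net$w_ih, net$b_h, net$w_ho, net$b_o)
  if (vec) Y[1, ] else Y
}

#' Train on signal-meaning pairs
#'
#' Performs \code{epochs} passes of online stochastic gradient descent on the
#' per-sample squared error. Within each pass the pairs are presented one at
#' a time in a freshly shuffled random order (consuming the R RNG) and all
#' weights and biases are updated after each presentation with rate
#' \code{net$learning_rate}.
#'
#' @param net A \code{perceptron_translator}.
#' @param inputs n x 3 matrix (or 3-vector) of codon encodings.
#' @param targets n x 11 matrix (or 11-vector) of target chemical-space
#'   points.
#' @param epochs Non-negative integer; 0 returns the network unchanged.
#' @param shuffle Reshuffle presentation order each epoch (default TRUE).
#' @return The updated \code{perceptron_translator}.
#' @export
train_on_pairs <- function(net, inputs, targets, epochs, shuffle = TRUE) {
  .check_net(net)
  X <- if (is.null(dim(inputs))) matrix(inputs, 1) else as.matrix(inputs)
  D <- if (is.null(dim(targets))) matrix(targets, 1) else as.matrix(targets)
  if (nrow(X) == 0) stop("no training pairs")
  if (nrow(X) != nrow(D) || ncol(X) != NET_INPUT || ncol(D) != NET_OUTPUT) {
    stop("training pair dimension mismatch: inputs ", nrow(X), "x", ncol(X),
         ", targets ", nrow(D), "x", ncol(D))
  }
  stopifnot(epochs >= 0, epochs == as.integer(epochs))
  if (epochs == 0) return(net)
  upd <- net_train_cpp(X, D, net$w_ih, net$b_h, net$w_ho, net$b_o,
                       as.integer(epochs), net$learning_rate, shuffle)
  net[c("w_ih", "b_h", "w_ho", "b_o")] <- upd[c("w_ih", "b_h", "w_ho", "b_o")]
  net
}

#' Network checkpoint serialisation
#'
#' Writes/reads the full network state as JSON at 17 significant digits,
#' which round-trips IEEE doubles exactly.
#'
#' @param net A \code{perceptron_translator}.
#' @param file Path.
#' @return \code{read_network} returns the restored
#'   \code{perceptron_translator}.
#' @export
write_network <- function(net, file) {
  .check_net(net)
  obj <- list(architecture = c(NET_INPUT, NET_HIDDEN, NET_OUTPUT),
              w_ih = net$w_ih, b_h = net$b_h,
              w_ho = net$w_ho, b_o = net$b_o,
              learning_rate = net$learning_rate)
  jsonlite::write_json(obj, file, digits = I(17), auto_unbox = TRUE)
  invisible(file)
}

#' @rdname write_network
#' @export
read_network <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  net <- list(w_ih = matrix(as.numeric(obj$w_ih), NET_INPUT, NET_HIDDEN),
              b_h = as.numeric(obj$b_h),
              w_ho = matrix(as.numeric(obj$w_ho), NET_HIDDEN, NET_OUTPUT),
              b_o = as.numeric(obj$b_o),
              learning_rate = as.numeric(obj$learning_rate))
  class(net) <- "perceptron_translator"
  net
}
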