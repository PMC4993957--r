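#' Initialize a single-hidden-layer feedforward network
#'
#' Builds the 9-11-1 (by default) regression network used as the yield
#' surrogate: tanh hidden units, a single linear output. Weights are drawn
#' uniformly from `[-1/sqrt(fan_in), +1/sqrt(fan_in)]` and biases start at
#' zero; the same seed always reproduces the same parameters. The output is
#' linear (unbounded) deliberately: a bounded output could never predict
#' above the training maximum, while surrogate-guided optimization must be
#' able to extrapolate.
#'
#' @param n_in Number of inputs (default 9, one per medium component).
#' @param n_hidden Number of hidden units (default 11).
#' @param seed Optional integer seed for the weight draw.
#' @return An object of class `bp_network`: list with `n_in`, `n_hidden`,
#'   `W1` (`n_hidden x n_in`), `b1`, `W2` (`1 x n_hidden`), `b2`, and the
#'   activation names.
#' @export
#' @examples
#' net <- init_network(9, 11, seed = 1)
#' dim(net$W1)
init_network <- function(n_in = 9L, n_hidden = 11L, seed = NULL) {
  if (n_in < 1L || n_hidden < 1L) stop("layer sizes must be positive")
  if (!is.null(seed)) set.seed(seed)
  r1 <- 1 / sqrt(n_in)
  r2 <- 1 / sqrt(n_hidden)
  structure(list(
    n_in = as.integer(n_in), n_hidden = as.integer(n_hidden), n_out = 1L,
    W1 = matrix(stats::runif(n_hidden * n_in, -r1, r1), n_hidden, n_in),
    b1 = rep(0, n_hidden),
    W2 = matrix(stats::runif(n_hidden, -r2, r2), 1, n_hidden),
    b2 = 0,
    hidden_activation = "tanh", output_activation = "linear"
  ), class = "bp_network")
}

#' @export
print.bp_network <- function(x, ...) {
  cat(sprintf("Feedforward surrogate %d-%d-%d (tanh hidden, linear output), %d parameters\n",
              x$n_in, x$n_hidden, x$n_out, length(.pack_params(x))))
  invisible(x)
}

.as_input_matrix <- function(net, x) {
  if (is.null(dim(x))) {
    if (length(x) != net$n_in) {
      stop("input length ", length(x), " does not match n_in = ", net$n_in)
    }
    x <- matrix(x, nrow = 1)
  } else if (ncol(x) != net$n_in) {
    stop("input has ", ncol(x), " columns; network expects ", net$n_in)
  }
  if (any(!is.finite(x))) stop("network inputs must be finite")
  x
}

#' Forward pass of the surrogate network
#'
#' Computes `W2 tanh(W1 x + b1) + b2` for one input vector or for each row
#' of an input matrix. The linear output is unbounded and may leave the
#' scaled unit interval.
#'
#' @param net A [init_network()] object.
#' @param x Numeric vector of length `n_in`, or an `n x n_in` matrix.
#' @return Numeric vector of predictions (length `n`).
#' @export
nn_forward <- function(net, x) {
  x <- .as_input_matrix(net, x)
  a <- tanh(x %*% t(net$W1) + rep(net$b1, each = nrow(x)))
  drop(a %*% t(net$W2)) + net$b2
}

#' Mean squared error of the surrogate on a labeled set
#'
#' @param net A network.
#' @param inputs `n x n_in` matrix of (scaled) inputs.
#' @param targets Length-`n` vector of (scaled) targets.
#' @return Scalar mean of squared residuals.
#' @export
nn_mse <- function(net, inputs, targets) {
  inputs <- .as_input_matrix(net, inputs)
  if (nrow(inputs) != length(targets)) stop("inputs and targets disagree in length")
  if (length(targets) == 0L) stop("empty training data")
  mean((nn_forward(net, inputs) - targets)^2)
}

# ---- parameter vector packing (column-major, order W1, b1, W2, b2) ----

.pack_params <- function(net) {
  c(as.vector(net$W1), net$b1, as.vector(net$W2), net$b2)
}

.unpack_params <- function(net, theta) {
  h <- net$n_hidden; p <- net$n_in
  i <- 0L
  net$W1 <- matrix(theta[i + seq_len(h * p)], h, p); i <- i + h * p
  net$b1 <- theta[i + seq_len(h)]; i <- i + h
  net$W2 <- matrix(theta[i + seq_len(h)], 1, h); i <- i + h
  net$b2 <- theta[i + 1L]
  net
}

# residuals r = yhat - t and Jacobian J[i, k] = d r_i / d theta_k,
# for the packing order above; everything vectorized over samples
.resid_jacobian <- function(net, x, targets) {
  n <- nrow(x); h <- net$n_hidden; p <- net$n_in
  z <- x %*% t(net$W1) + rep(net$b1, each = n)
  a <- tanh(z)
  yhat <- drop(a %*% t(net$W2)) + net$b2
  r <- yhat - targets
  s <- (1 - a^2) * rep(drop(net$W2), each = n)    # n x h, dyhat/dz
  J <- matrix(0, n, h * p + h + h + 1L)
  for (k in seq_len(p)) J[, (k - 1L) * h + seq_len(h)] <- s * x[, k]
  J[, h * p + seq_len(h)] <- s
  J[, h * p + h + seq_len(h)] <- a
  J[, h * p + 2L * h + 1L] <- 1
  list(r = r, J = J, mse = mean(r^2))
}

#' Gradient of the training MSE with respect to all parameters
#'
#' Analytic backpropagation gradient of `mean((f(x) - t)^2)` as a flat
#' vector in the canonical packing order (`W1` column-major, `b1`, `W2`,
#' `b2`). Exposed mainly so that the analytic derivative can be checked
#' against finite differences.
#'
#' @inheritParams nn_mse
#' @return Numeric vector, one entry per network parameter.
#' @export
nn_gradient <- function(net, inputs, targets) {
  inputs <- .as_input_matrix(net, inputs)
  rj <- .resid_jacobian(net, inputs, targets)
  drop(2 * crossprod(rj$J, rj$r) / length(rj$r))
}

#' Predict flavonoid yield for raw medium compositions
#'
#' End-to-end surrogate evaluation on the raw measurement scale: scales a
#' chromosome (nine component concentrations in canonical order) with the
#' training scaler, runs the network forward, and inverse-scales the output
#' back to micrograms per milliliter. Because the output unit is linear,
#' predictions may exceed the training maximum; such values are
#' extrapolations.
#'
#' @param net A trained network.
#' @param scaler The [fit_scaler()] object fitted on the training table.
#' @param chromosome Length-9 vector or `n x 9` matrix of concentrations.
#' @return Predicted yield(s) in ug/mL.
#' @export
predict_production <- function(net, scaler, chromosome) {
  xs <- scale_chromosomes(chromosome, scaler)
  inverse_scale(nn_forward(net, xs), .target_column, scaler)
}

#' Serialize a trained surrogate to JSON
#'
#' Writes the network shapes, flat parameter arrays, activation names and
#' (optionally) the fitted scaler to a plain JSON document. Parameters are
#' stored as 17-significant-digit decimal strings, which reproduce IEEE
#' doubles exactly, so that save/load round-trips are bit-exact.
#'
#' @param net A network.
#' @param path Output file path.
#' @param scaler Optional [fit_scaler()] object stored alongside.
#' @return `path`, invisibly.
#' @export
save_network <- function(net, path, scaler = NULL) {
  num <- function(x) sprintf("%.17g", x)
  doc <- list(
    n_in = net$n_in, n_hidden = net$n_hidden, n_out = net$n_out,
    hidden_activation = net$hidden_activation,
    output_activation = net$output_activation,
    W1 = num(as.vector(net$W1)), b1 = num(net$b1),
    W2 = num(as.vector(net$W2)), b2 = num(net$b2)
  )
  if (!is.null(scaler)) {
    doc$scaler <- list(columns = names(scaler$x_min),
                       x_min = num(unname(scaler$x_min)),
                       x_max = num(unname(scaler$x_max)),
                       range = num(scaler$range))
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load a surrogate saved by [save_network()]
#'
#' @param path Path to the JSON document.
#' @return A list with elements `net` (class `bp_network`) and `scaler`
#'   (class `minmax_scaler`, or `NULL` if none was stored).
#' @export
load_network <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- structure(list(
    n_in = as.integer(doc$n_in), n_hidden = as.integer(doc$n_hidden),
    n_out = as.integer(doc$n_out),
    W1 = matrix(as.numeric(doc$W1), doc$n_hidden, doc$n_in),
    b1 = as.numeric(doc$b1),
    W2 = matrix(as.numeric(doc$W2), 1, doc$n_hidden),
    b2 = as.numeric(doc$b2),
    hidden_activation = doc$hidden_activation,
    output_activation = doc$output_activation
  ), class = "bp_network")
  scaler <- NULL
  if (!is.null(doc$scaler)) {
    scaler <- structure(list(
      x_min = stats::setNames(as.numeric(doc$scaler$x_min), doc$scaler$columns),
      x_max = stats::setNames(as.numeric(doc$scaler$x_max), doc$scaler$columns),
      range = as.numeric(doc$scaler$range)
    ), class = "minmax_scaler")
    scaler$degenerate <- scaler$x_max == scaler$x_min
  }
  list(net = net, scaler = scaler)
}
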