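# Construct a network with given parameters (for closed-form checks).
make_net <- function(W1, b1, W2, b2) {
  W1 <- as.matrix(W1)
  structure(list(n_in = ncol(W1), n_hidden = nrow(W1), n_out = 1L,
                 W1 = W1, b1 = b1, W2 = matrix(W2, nrow = 1), b2 = b2,
                 hidden_activation = "tanh", output_activation = "linear"),
            class = "bp_network")
}

zero_net <- function(n_in = 9, n_hidden = 3, b2 = 0) {
  make_net(matrix(0, n_hidden, n_in), rep(0, n_hidden),
           rep(0, n_hidden), b2)
}

# Central finite-difference gradient of the training MSE.
fd_gradient <- function(net, x, y, eps = 1e-6) {
  theta <- fermga:::.pack_params(net)
  vapply(seq_along(theta), function(k) {
    tp <- theta; tp[k] <- tp[k] + eps
    tm <- theta; tm[k] <- tm[k] - eps
    (nn_mse(fermga:::.unpack_params(net, tp), x, y) -
       nn_mse(fermga:::.unpack_params(net, tm), x, y)) / (2 * eps)
  }, numeric(1))
}

# A tiny valid fermentation table (n rows, varying columns, positive TF).
tiny_dataset <- function(n = 4, seed = 99) {
  set.seed(seed)
  m <- matrix(runif(n * 9, 1, 10), n, 9,
              dimnames = list(NULL, medium_components()))
  d <- as.data.frame(m)
  d$total_flavonoids <- runif(n, 500, 1500)
  d
}

write_temp_csv <- function(lines) {
  p <- tempfile(fileext = ".csv")
  writeLines(lines, p)
  p
}
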