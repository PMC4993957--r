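test_that("initialization is seeded, shaped and range-bounded", {
  a <- init_network(9, 11, seed = 0)
  b <- init_network(9, 11, seed = 0)
  expect_identical(a, b)
  expect_equal(dim(a$W1), c(11, 9))
  expect_equal(dim(a$W2), c(1, 11))
  expect_true(all(abs(a$W1) <= 1 / sqrt(9)))
  expect_true(all(abs(a$W2) <= 1 / sqrt(11)))
  expect_true(all(a$b1 == 0) && a$b2 == 0)
  expect_error(init_network(0, 5), "positive")
})

test_that("forward pass matches closed forms", {
  expect_equal(nn_forward(zero_net(), runif(9)), 0)
  one <- make_net(matrix(1, 1, 1), 0, 1, 0)
  expect_equal(nn_forward(one, 0), 0)
  expect_lt(abs(nn_forward(one, 10) - 1), 1e-8)  # tanh saturation
  expect_equal(nn_forward(one, 0.3), tanh(0.3))
  expect_error(nn_forward(one, c(1, 2)), "does not match")
})

test_that("MSE matches hand arithmetic", {
  net <- make_net(matrix(1, 1, 1), 0, 2, 0.5)  # f(x) = 2 tanh(x) + 0.5
  x <- matrix(c(0, 1, -1), 3, 1)
  t <- c(0, 1, 0)
  hand <- (0.5^2 + (2 * tanh(1) + 0.5 - 1)^2 + (-2 * tanh(1) + 0.5)^2) / 3
  expect_equal(nn_mse(net, x, t), hand)
  expect_equal(nn_mse(net, x, nn_forward(net, x)), 0)
  zn <- zero_net(n_in = 2)
  expect_equal(nn_mse(zn, matrix(runif(10), 5, 2), rep(0.5, 5)), 0.25)
  expect_error(nn_mse(net, x[0, , drop = FALSE], numeric(0)), "empty")
})

test_that("analytic gradient agrees with central finite differences", {
  for (s in 1:5) {
    set.seed(s)
    net <- init_network(n_in = 3, n_hidden = 4, seed = s)
    net$b1 <- rnorm(4, sd = 0.3); net$b2 <- rnorm(1, sd = 0.3)
    x <- matrix(rnorm(18), 6, 3)
    y <- rnorm(6)
    g <- nn_gradient(net, x, y)
    fd <- fd_gradient(net, x, y)
    expect_lt(max(abs(g - fd)) / max(1e-8, max(abs(fd))), 1e-5)
  }
})

test_that("constant predictor maps through the scaler as expected", {
  sc <- fit_scaler(table1_fixture())
  net <- zero_net(n_in = 9, b2 = 0.25)
  expect_equal(unname(predict_production(net, sc, rep(21, 9))),
               inverse_scale(0.25, "total_flavonoids", sc))
})

test_that("exact fit on one record reproduces its measured yield", {
  d <- table1_fixture()
  sc <- fit_scaler(d)
  sets <- fermga:::.scaled_training_set(d, sc)
  row <- 20  # inputs [20,20,20,10,10,5,0.5,10,1.5], yield 1560
  fit <- train_network(init_network(9, 2, seed = 1),
                       sets$x[row, , drop = FALSE], sets$y[row],
                       train_config(target_mse = 1e-14, max_epochs = 300))
  expect_lt(fit$report$final_mse, 1e-12)
  pred <- predict_production(fit$net, sc,
                             as.numeric(d[row, medium_components()]))
  expect_equal(unname(pred), 1560, tolerance = 1e-4)
})

test_that("trained predictions are finite and may exceed the training maximum", {
  d <- table1_fixture()
  fit <- fit_surrogate(d, seed = 3)
  set.seed(1)
  chroms <- t(replicate(20, runif(9, 0, 40)))
  p <- predict_production(fit$network, fit$scaler, chroms)
  expect_true(all(is.finite(p)))
})

test_that("JSON serialization round-trips bit-exactly", {
  fit <- fit_surrogate(table1_fixture(), seed = 2,
                       control = train_config(max_epochs = 50))
  path <- tempfile(fileext = ".json")
  save_network(fit$network, path, scaler = fit$scaler)
  back <- load_network(path)
  expect_identical(back$net$W1, fit$network$W1)
  expect_identical(back$net$b1, fit$network$b1)
  expect_identical(back$net$W2, fit$network$W2)
  expect_identical(back$net$b2, fit$network$b2)
  expect_identical(unname(back$scaler$x_min), unname(fit$scaler$x_min))
  x <- runif(9, 0, 30)
  expect_identical(predict_production(back$net, back$scaler, x),
                   predict_production(fit$network, fit$scaler, x))
})
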