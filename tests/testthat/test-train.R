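test_that("LM drives an exactly-representable affine target below 1e-8", {
  x <- matrix(seq(0, 1, length.out = 5), 5, 1)
  y <- 2 * drop(x)
  fit <- train_network(init_network(1, 3, seed = 1), x, y,
                       train_config(target_mse = 1e-10, max_epochs = 500))
  expect_lt(fit$report$final_mse, 1e-8)
  # independent least-squares oracle: a line through these points is exact
  expect_equal(unname(sum(residuals(lm(y ~ drop(x)))^2)), 0, tolerance = 1e-20)
})

test_that("accepted-step MSE sequence is non-increasing for both trainers", {
  d <- table1_fixture()
  sc <- fit_scaler(d)
  sets <- fermga:::.scaled_training_set(d, sc)
  for (alg in c("levenberg_marquardt", "scaled_conjugate_gradient")) {
    fit <- train_network(init_network(9, 11, seed = 4), sets$x, sets$y,
                         train_config(algorithm = alg, target_mse = 1e-6,
                                      max_epochs = 150))
    h <- fit$report$mse_history
    expect_true(all(diff(h) <= 0))
    expect_equal(fit$report$final_mse, h[length(h)])
    expect_equal(fit$report$epochs_run, length(h) - 1L)
    expect_lt(fit$report$final_mse, h[1])
  }
})

test_that("zero-epoch training is a no-op", {
  net <- init_network(4, 3, seed = 7)
  x <- matrix(runif(20), 5, 4)
  y <- runif(5)
  fit <- train_network(net, x, y, train_config(max_epochs = 0))
  expect_identical(fit$net$W1, net$W1)
  expect_equal(fit$report$final_mse, nn_mse(net, x, y))
  expect_equal(fit$report$epochs_run, 0L)
  expect_length(fit$report$mse_history, 1)
})

test_that("training is deterministic given (data, config, seed)", {
  d <- table1_fixture()
  a <- fit_surrogate(d, seed = 11, control = train_config(max_epochs = 60))
  b <- fit_surrogate(d, seed = 11, control = train_config(max_epochs = 60))
  expect_identical(coef(a), coef(b))
  expect_identical(a$report, b$report)
})

test_that("the scaled training table is fit to the published error level", {
  # 122 parameters for 25 records: at least one early seed must reach the
  # 0.019 scaled-MSE regime quickly
  d <- table1_fixture()
  sets <- fermga:::.scaled_training_set(d, fit_scaler(d))
  mses <- vapply(1:3, function(s) {
    train_network(init_network(9, 11, seed = s), sets$x, sets$y,
                  train_config(target_mse = 0.019))$report$final_mse
  }, numeric(1))
  expect_lte(min(mses), 0.019)
})

test_that("SCG fits a small smooth problem", {
  set.seed(3)
  x <- matrix(runif(40), 20, 2)
  y <- 0.3 + 0.5 * x[, 1] - 0.4 * x[, 2]
  fit <- train_network(init_network(2, 4, seed = 3), x, y,
                       train_config(algorithm = "scaled_conjugate_gradient",
                                    target_mse = 1e-6, max_epochs = 2000))
  expect_lt(fit$report$final_mse, 1e-5)
})

test_that("hidden-size selection honours singletons, ties and recovery", {
  expect_equal(as.integer(select_hidden_size(matrix(runif(40), 20, 2),
                                             runif(20), candidates = 7,
                                             folds = 4, restarts = 1,
                                             config = train_config(max_epochs = 20))),
               7L)
  expect_error(select_hidden_size(matrix(runif(10), 5, 2), runif(5),
                                  candidates = integer(0)), "empty")
  # data generated noiselessly by a 1-hidden-unit network: a small
  # candidate should reach near-zero held-out error
  gen <- make_net(matrix(c(0.8, -0.5), 1, 2), 0.1, 1.2, 0.05)
  set.seed(21)
  x <- matrix(runif(80, -1, 1), 40, 2)
  y <- nn_forward(gen, x)
  sel <- select_hidden_size(x, y, candidates = 1:5, folds = 4, restarts = 2,
                            seed = 2,
                            config = train_config(target_mse = 1e-9,
                                                  max_epochs = 120))
  cv <- attr(sel, "cv_mse")
  expect_true(as.integer(sel) %in% 1:5)
  expect_lt(cv[[as.character(sel)]], 1e-4)
})

test_that("configuration validation rejects nonsense", {
  expect_error(train_config(target_mse = 0), "target_mse")
  expect_error(train_config(max_epochs = -1), "max_epochs")
  expect_error(train_config(lm_factor = 0.5), "damping")
})
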