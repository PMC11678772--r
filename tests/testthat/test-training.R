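test_that("mse_loss is the elementwise mean of squared differences", {
  expect_equal(mse_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(mse_loss(c(0, 0), c(1, 1)), 1)
  expect_equal(mse_loss(c(1, 2, 3), c(2, 2, 5)), 5 / 3)
  # brute-force loop oracle on random matrices
  withr::with_seed(8, {
    a <- matrix(rnorm(30), 5); b <- matrix(rnorm(30), 5)
    acc <- 0
    for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
      acc <- acc + (a[i, j] - b[i, j])^2
    expect_equal(mse_loss(a, b), acc / 30)
  })
  expect_error(mse_loss(1:3, 1:4), "shape mismatch")
})

test_that("a small MLP fits a linear map to near-zero loss", {
  # y = 2x is exactly representable; Adam should reach ~the optimum
  withr::with_seed(10, {
    x <- matrix(runif(400, -1, 1), 400)
    y <- 2 * x
  })
  net <- build_quant_mlp(input_len = 1L, seed = 3L, hidden = 8L,
                         n_outputs = 1L)
  fit <- train_model(net, list(x = x[1:300, , drop = FALSE],
                               y = y[1:300, , drop = FALSE]),
                     list(x = x[301:400, , drop = FALSE],
                          y = y[301:400, , drop = FALSE]),
                     train_config(max_epochs = 200L, patience = 200L,
                                  batch_size = 32L, learning_rate = 0.01,
                                  seed = 2L))
  expect_lt(min(fit$history$train_loss), 1e-4)
  expect_equal(fit$history$best_val_loss,
               min(fit$history$val_loss))
})

test_that("early stopping fires after exactly patience+1 epochs when frozen", {
  withr::with_seed(1, {
    x <- matrix(rnorm(40), 20); y <- matrix(rnorm(40), 20)
  })
  net <- build_quant_mlp(input_len = 2L, seed = 1L, hidden = 3L,
                         n_outputs = 2L)
  # learning rate 0 freezes the network: the first epoch sets the best,
  # then patience epochs pass without strict improvement
  fit <- train_model(net, list(x = x, y = y), list(x = x, y = y),
                     train_config(max_epochs = 300L, patience = 25L,
                                  learning_rate = 0, seed = 1L))
  expect_equal(fit$history$n_epochs, 26L)
  expect_equal(fit$history$stopped_reason, "early_stop")
  expect_equal(fit$history$best_epoch, 1L)
  expect_true(all(fit$history$val_loss == fit$history$val_loss[1]))
})

test_that("training restores the best-validation parameters", {
  # tiny train set, disjoint validation: val loss worsens as it overfits
  withr::with_seed(21, {
    xt <- matrix(rnorm(12), 6); yt <- matrix(rnorm(12), 6)
    xv <- matrix(rnorm(40), 20); yv <- matrix(rnorm(40), 20)
  })
  net <- build_quant_mlp(input_len = 2L, seed = 5L, hidden = 16L,
                         n_outputs = 2L)
  fit <- train_model(net, list(x = xt, y = yt), list(x = xv, y = yv),
                     train_config(max_epochs = 60L, patience = 60L,
                                  learning_rate = 0.05, seed = 3L))
  h <- fit$history
  expect_equal(h$best_val_loss, min(h$val_loss))
  expect_equal(h$best_epoch, which.min(h$val_loss))
  # re-evaluating the returned network reproduces the recorded best loss
  expect_equal(mse_loss(predict(fit$net, xv), yv), h$best_val_loss)
  expect_lte(h$n_epochs, 60L)
})

test_that("identical seeds give identical histories; datasets are checked", {
  withr::with_seed(2, {
    x <- matrix(rnorm(60), 30); y <- matrix(rnorm(30), 30)
  })
  run <- function() train_model(
    build_quant_mlp(input_len = 2L, seed = 9L, hidden = 4L, n_outputs = 1L),
    list(x = x, y = y), list(x = x, y = y),
    train_config(max_epochs = 5L, patience = 5L, seed = 4L))
  expect_identical(run()$history, run()$history)
  expect_identical(run()$net$params, run()$net$params)

  net <- build_quant_mlp(input_len = 2L, seed = 1L, hidden = 3L,
                         n_outputs = 1L)
  expect_error(train_model(net, list(x = x[0, , drop = FALSE],
                                     y = y[0, , drop = FALSE]),
                           list(x = x, y = y), train_config()),
               "empty dataset")
  expect_error(train_model(net, list(x = matrix(0, 4, 7), y = y[1:4, , drop = FALSE]),
                           list(x = x, y = y), train_config()),
               "dimension mismatch")
})

test_that("max-scaling normalization trains on a bounded scale and rescales back", {
  withr::with_seed(6, {
    x <- matrix(runif(200, 0, 50), 100)
    y <- 3 * x
  })
  net <- build_quant_mlp(input_len = 2L, seed = 2L, hidden = 8L,
                         n_outputs = 2L)
  fit <- train_model(net, list(x = x, y = y), list(x = x, y = y),
                     train_config(max_epochs = 30L, patience = 30L,
                                  seed = 1L, normalize = TRUE))
  expect_equal(fit$net$scale, max(abs(x), abs(y)))
  pred <- fieldlift:::predict_scaled(fit$net, x)
  expect_equal(dim(pred), dim(y))
})
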