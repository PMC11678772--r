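make_quant_fixture <- function() {
  # tiny trained MLPs + a tiny transformer converter on a 60-point axis
  lib <- toy_library(2)
  ax <- make_axis(60L, -0.32, 10.2, 400)
  aug <- augmentation_config(ref_linewidth_hz = 2, include_triplets = FALSE)
  corpus <- build_corpus(lib, aug,
                         corpus_config(30L, 30L, 48L, 12L, n_test = 4L,
                                       seed = 3L), ax)
  list(lib = lib, ax = ax, aug = aug, corpus = corpus)
}

test_that("per-spectrum MSE reports are consistent with mse_loss", {
  fx <- make_quant_fixture()
  # an untrained MLP serves as an arbitrary deterministic converter
  net <- build_quant_mlp(input_len = 60L, seed = 1L, hidden = 4L,
                         n_outputs = 60L)
  rep <- spectrum_mse_report(net, fx$corpus$test)
  expect_length(rep$per_spectrum, 4)
  expect_equal(rep$mean_mse, mean(rep$per_spectrum))
  pred <- predict(net, fx$corpus$test$lf)
  for (i in 1:4)
    expect_equal(rep$per_spectrum[[i]],
                 mse_loss(pred[i, ], fx$corpus$test$hf[i, ]))
  expect_error(spectrum_mse_report(net, list(lf = fx$corpus$test$lf[0, , drop = FALSE],
                                             hf = fx$corpus$test$hf[0, , drop = FALSE])),
               "empty test set")
})

test_that("quant_mape matches the brute-force definition and guards zeros", {
  expect_equal(quant_mape(c(5, 5), c(5, 5)), 0)
  expect_equal(quant_mape(4, 5), 20)
  expect_equal(quant_mape(c(4, 6), c(5, 5)), 20)
  withr::with_seed(3, {
    est <- runif(21, 1, 50); truth <- runif(21, 1, 50)
    acc <- 0
    for (k in seq_along(truth)) acc <- acc + abs(est[k] - truth[k]) / truth[k]
    expect_equal(quant_mape(est, truth), 100 * acc / 21)
  })
  expect_error(quant_mape(c(1, 2), c(1, 0)), "truth")
  expect_error(quant_mape(1:3, 1:2), "length mismatch")
})

test_that("convert_then_quantify composes converter and MLP, clamped at zero", {
  conv <- build_network(model_spec("transformer", 24L, 2L,
                                   scheme = chunk_scheme(4L, 6L),
                                   d_model = 8L, n_layers = 1L,
                                   n_heads = 2L, d_ff = 16L))
  mlp <- build_quant_mlp(input_len = 24L, seed = 4L, hidden = 5L,
                         n_outputs = 3L)
  x <- rnorm(24)
  got <- convert_then_quantify(x, conv, mlp)
  manual <- pmax(drop(predict(mlp, predict(conv, matrix(x, 1)))), 0)
  expect_equal(got, manual)
  expect_true(all(got >= 0))

  bad_mlp <- build_quant_mlp(input_len = 30L, seed = 1L, hidden = 5L,
                             n_outputs = 3L)
  expect_error(convert_then_quantify(x, conv, bad_mlp), "dimension mismatch")
  expect_error(convert_then_quantify(rnorm(10), conv, mlp),
               "dimension mismatch")
})

test_that("the comparison suite reports one row per architecture, deterministically", {
  fx <- make_quant_fixture()
  archs <- list(
    dae = model_spec("dae", 60L, 1L, widths = c(12L, 4L)),
    transformer = model_spec("transformer", 60L, 2L,
                             scheme = chunk_scheme(6L, 10L), d_model = 8L,
                             n_layers = 1L, n_heads = 2L, d_ff = 16L))
  cfg <- train_config(max_epochs = 2L, patience = 2L, batch_size = 16L,
                      seed = 9L)
  out1 <- withr::local_tempdir()
  suppressMessages({
    r1 <- run_comparison_suite(fx$corpus, archs, cfg, out_dir = out1)
    r2 <- run_comparison_suite(fx$corpus, archs, cfg)
  })
  expect_equal(nrow(r1$table), 2)
  expect_equal(r1$table$architecture, c("dae", "transformer"))
  expect_identical(r1$table, r2$table)          # seeded determinism
  expect_true(file.exists(file.path(out1, "conversion_mse.csv")))
  csv <- utils::read.csv(file.path(out1, "conversion_mse.csv"))
  expect_equal(csv$mean_mse, r1$table$mean_mse)
  # no report can beat the uniform-noise floor of its corpus
  expect_true(all(r1$table$mean_mse >= noise_floor(fx$corpus)))
})

test_that("quantification pipelines are scored per level and pipeline", {
  fx <- make_quant_fixture()
  gen <- prepare_generator(fx$lib, fx$aug, fx$ax)
  tests <- with_seed(5, build_fixed_concentration_tests(gen, c(5, 25)))
  suppressMessages(
    qr <- run_quant_comparison(fx$corpus, converter = NULL, tests,
                               train_config(max_epochs = 3L, patience = 3L,
                                            seed = 1L,
                                            task = "quantification"),
                               hidden = 8L))
  expect_s3_class(qr, "quant_report")
  expect_equal(sort(unique(qr$mape$level_mM)), c(5, 25))
  expect_setequal(unique(qr$mape$pipeline), c("lf_direct", "hf_direct"))
  expect_true(all(qr$mape$mape >= 0))
  # per-metabolite absolute percent errors average to the reported MAPE
  key <- "lf_direct_5mM"
  expect_equal(mean(qr$per_metabolite[[key]]),
               qr$mape$mape[qr$mape$pipeline == "lf_direct" &
                              qr$mape$level_mM == 5])
})
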