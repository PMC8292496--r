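test_that("architecture configuration is validated", {
  expect_error(network_config(output_units = 2), "exactly 1")
  expect_error(network_config(recurrent_layers = 0), "recurrent_layers")
  expect_error(network_config(head_units = 0), "positive")
  expect_error(network_config(validation_fraction = 1), "validation_fraction")
})

test_that("parameter layout matches the standard LSTM parameter count", {
  cfg <- network_config()
  shapes <- inrcast:::param_shapes(cfg)
  # first recurrent layer, input width 2, 32 units: 4((2+32)32 + 32) = 4480
  lstm1 <- prod(shapes$lstm_Wx1) + prod(shapes$lstm_Wh1) + prod(shapes$lstm_b1)
  expect_equal(lstm1, 4 * ((2 + 32) * 32 + 32))
  net <- build_network(cfg)
  expect_equal(length(net$par), inrcast:::n_params(cfg))
})

test_that("initialization is a pure function of the seed", {
  cfg <- network_config(seed = 7)
  expect_identical(build_network(cfg)$par, build_network(cfg)$par)
  expect_false(identical(build_network(network_config(seed = 8))$par,
                         build_network(cfg)$par))
})

test_that("forward pass equals a hand-unrolled step-by-step computation", {
  cfg <- network_config(seed = 21)
  net <- build_network(cfg)
  set.seed(99)
  for (i in 1:5) {
    static <- rnorm(5)
    series8 <- rnorm(8)
    oracle <- r_reference_forward(net$par, cfg, static, series8)
    got <- inrcast:::nn_forward_cpp(net$par, matrix(static, 1),
                                    matrix(series8, 1),
                                    inrcast:::cpp_cfg(cfg))
    expect_equal(as.numeric(got), oracle, tolerance = 1e-12)
  }
})

test_that("analytic gradients match finite differences", {
  cfg <- network_config(static_branch = 3, recurrent_layers = 2,
                        recurrent_units = 4, head_layers = 2, head_units = 5,
                        seed = 42)
  net <- build_network(cfg)
  ccfg <- inrcast:::cpp_cfg(cfg)
  set.seed(9)
  n <- 7
  Xs <- matrix(rnorm(n * 5), n)
  Xq <- matrix(rnorm(n * 8), n)
  y <- rnorm(n)
  res <- inrcast:::nn_loss_grad_cpp(net$par, Xs, Xq, y, ccfg)
  loss_at <- function(p) mean(abs(inrcast:::nn_forward_cpp(p, Xs, Xq, ccfg) - y))
  idx <- sample(length(net$par), 50)
  eps <- 1e-6
  fd <- vapply(idx, function(i) {
    up <- net$par; up[i] <- up[i] + eps
    dn <- net$par; dn[i] <- dn[i] - eps
    (loss_at(up) - loss_at(dn)) / (2 * eps)
  }, numeric(1))
  expect_equal(fd, res$grad[idx], tolerance = 1e-6)
})

test_that("a representable linear response is learned to low error", {
  w <- make_random_windows(500, seed = 31)
  w$target_inr <- 0.5 + 0.8 * w$inr4
  pred <- train_predictor(w, tiny_config(seed = 3, max_epochs = 200,
                                         early_stop_patience = 25))
  mae <- mean(abs(predict(pred, w) - w$target_inr))
  expect_lt(mae, 0.05)
})

test_that("with targets independent of inputs, predictions approach the target center", {
  w <- make_random_windows(600, seed = 32)
  set.seed(33)
  w$target_inr <- rnorm(600, mean = 2.5, sd = 0.3)  # symmetric: median = mean
  pred <- train_predictor(w, tiny_config(seed = 4, max_epochs = 60))
  p <- predict(pred, w)
  expect_equal(mean(p), 2.5, tolerance = 0.1)
  # MAE cannot beat the mean absolute deviation from the optimal constant
  mad0 <- mean(abs(w$target_inr - median(w$target_inr)))
  expect_equal(mean(abs(p - w$target_inr)), mad0, tolerance = 0.05)
})

test_that("training preconditions and diagnostics", {
  expect_error(train_predictor(make_random_windows(5, 1), tiny_config()),
               "at least 10")
  # an absurd learning rate overflows the weights within a step or two
  expect_error(train_predictor(make_random_windows(100, 1),
                               tiny_config(learning_rate = 1e150,
                                           max_epochs = 5)),
               "non-finite")
})

test_that("training is reproducible for a fixed seed", {
  w <- make_random_windows(120, seed = 34)
  cfg <- tiny_config(seed = 11, max_epochs = 4)
  a <- train_predictor(w, cfg)
  b <- train_predictor(w, cfg)
  expect_identical(a$par, b$par)
  expect_identical(a$history$val_loss, b$history$val_loss)
})

test_that("predictions reduce to the output bias when all weights are zero", {
  pred <- make_dummy_predictor(seed = 12)
  pred$par[] <- 0
  pred$par[length(pred$par)] <- 1.25  # output bias is the last parameter
  s <- pred$standardizer$stats$target_inr
  expected <- 1.25 * s["sd"] + s["mean"]
  p1 <- predict_day5(pred, c(1, 60, 70, 170, 1.82),
                     cbind(c(2, 2.1, 2.2, 2.3), c(3, 3, 3, 3)))
  p2 <- predict_day5(pred, c(0, 30, 50, 150, 1.44),
                     cbind(c(1, 1, 1, 1), c(8, 8, 8, 8)))
  expect_equal(p1, expected, ignore_attr = TRUE)
  expect_equal(p2, expected, ignore_attr = TRUE)
})

test_that("prediction is deterministic and invariant to sample order", {
  pred <- make_dummy_predictor(seed = 13)
  w <- make_random_windows(40, seed = 14)
  p <- predict(pred, w)
  expect_identical(p, predict(pred, w))
  perm <- sample(nrow(w))
  expect_identical(predict(pred, w[perm, ]), p[perm])
})

test_that("predict_day5 validates its input schema", {
  pred <- make_dummy_predictor(seed = 15)
  series <- cbind(c(2, 2, 2, 2), c(3, 3, 3, 3))
  expect_error(predict_day5(pred, c(1, 60, 70, 170), series), "5 values")
  expect_error(predict_day5(pred, c(1, 60, 70, 170, 1.8), series[1:3, ]),
               "4 x 2")
  bad <- series; bad[2, 2] <- 0
  expect_error(predict_day5(pred, c(1, 60, 70, 170, 1.8), bad), "> 0")
})

test_that("save/load round trip reproduces identical predictions", {
  w <- make_random_windows(120, seed = 36)
  pred <- train_predictor(w, tiny_config(seed = 16, max_epochs = 3))
  dir <- withr::local_tempdir()
  save_predictor(pred, dir)
  back <- load_predictor(dir)
  newdata <- make_random_windows(100, seed = 37)
  expect_identical(predict(back, newdata), predict(pred, newdata))

  # a tampered pairing is refused
  std2 <- fit_standardizer(make_random_windows(30, seed = 38))
  write_standardizer(std2, file.path(dir, "standardizer.json"))
  expect_error(load_predictor(dir), "checksum")
})
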