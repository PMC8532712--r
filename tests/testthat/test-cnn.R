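test_that("configurations are validated", {
  expect_error(classifier_config(1, 6, 100, 8), "n_classes")
  expect_error(classifier_config(3, 0, 100, 8), "dimensions")
  expect_error(classifier_config(3, 6, 6, 8), "dimensions")  # too short
  expect_error(classifier_config(3, 6, 100, 8, conv_filters = c(8, 0)),
               "positive")
  cfg <- classifier_config(3, 6, 100, 8)
  expect_equal(cfg$dropout, 0.55)
  expect_equal(cfg$task, "classification")
  expect_equal(velocity_config(100)$n_channels, 8)
})

test_that("forward pass produces a probability distribution", {
  cfg <- classifier_config(3, 2, 40, 4, conv_filters = c(4, 8), dense = 8)
  model <- build_classifier(cfg)
  set.seed(1)
  x <- array(rnorm(40 * 2 * 7), c(40, 2, 7))
  f <- matrix(rnorm(7 * 4), 7, 4)
  out <- equigait:::cnn_forward(model, x, f)$out
  expect_true(all(out >= 0))
  expect_equal(rowSums(out), rep(1, 7), tolerance = 1e-6)
})

test_that("training separates a separable two-class set and is deterministic", {
  acts <- c(halt = 30, working_trot = 30)
  ws <- gen_windows(acts, seed = 31)
  arr <- windows_to_arrays(ws)
  run <- function() {
    cfg <- small_cfg(2, arr$x, arr$features, seed = 31)
    train_classifier(build_classifier(cfg), arr$x, arr$features, arr$labels,
                     seed = 31)
  }
  fit1 <- run()
  expect_equal(fit1$accuracy, 1.0)
  fit2 <- run()
  expect_identical(fit1$model$params, fit2$model$params)
  expect_identical(fit1$accuracy, fit2$accuracy)
  # training inputs on the fitted model reproduce the training labels
  pred <- predict(fit1$model, arr$x, arr$features)
  expect_equal(mean(pred$label == arr$labels), 1.0)
  post <- attr(pred, "posterior")
  expect_equal(unname(rowSums(post)), rep(1, nrow(post)), tolerance = 1e-6)
})

test_that("label-shuffled training stays at chance level", {
  acts <- c(halt = 30, working_trot = 30)
  ws <- gen_windows(acts, seed = 32)
  arr <- windows_to_arrays(ws)
  set.seed(32)
  shuffled <- sample(arr$labels)
  cfg <- small_cfg(2, arr$x, arr$features, seed = 32, epochs = 25)
  fit <- train_classifier(build_classifier(cfg), arr$x, arr$features,
                          shuffled, seed = 32)
  expect_lt(abs(fit$accuracy - 0.5), 0.25)
})

test_that("degenerate training inputs are rejected with the class named", {
  acts <- c(halt = 10, working_trot = 10)
  ws <- gen_windows(acts, seed = 33)
  arr <- windows_to_arrays(ws)
  cfg <- small_cfg(2, arr$x, arr$features)
  labs <- arr$labels
  labs[labs == "halt"] <- "working_trot"
  labs[1] <- "halt"    # one lone window for halt
  expect_error(train_classifier(build_classifier(cfg), arr$x, arr$features,
                                labs),
               "halt")
  expect_error(train_classifier(build_classifier(cfg), arr$x, arr$features,
                                rep("halt", length(labs))),
               "2 classes")
})

test_that("saved models reload with bit-identical predictions", {
  acts <- c(halt = 12, working_canter = 12)
  ws <- gen_windows(acts, seed = 34)
  arr <- windows_to_arrays(ws)
  cfg <- small_cfg(2, arr$x, arr$features, seed = 34, epochs = 10)
  fit <- train_classifier(build_classifier(cfg), arr$x, arr$features,
                          arr$labels, seed = 34)
  dir <- file.path(tempdir(), "eg-model")
  save_cnn(fit$model, dir)
  model2 <- load_cnn(dir)
  p1 <- predict(fit$model, arr$x, arr$features)
  p2 <- predict(model2, arr$x, arr$features)
  expect_identical(attr(p1, "posterior"), attr(p2, "posterior"))
  unlink(dir, recursive = TRUE)
})

test_that("prediction validates shapes", {
  acts <- c(halt = 10, working_trot = 10)
  ws <- gen_windows(acts, seed = 35)
  arr <- windows_to_arrays(ws)
  cfg <- small_cfg(2, arr$x, arr$features, seed = 35, epochs = 5)
  fit <- train_classifier(build_classifier(cfg), arr$x, arr$features,
                          arr$labels, seed = 35)
  expect_error(predict(fit$model, arr$x[1:50, , , drop = FALSE],
                       arr$features),
               "does not match")
  expect_error(predict(fit$model, arr$x, arr$features[1:3, , drop = FALSE]),
               "mismatch")
  expect_error(predict(build_classifier(cfg), arr$x, arr$features),
               "not trained")
})

test_that("velocity regressor recovers velocity on noiseless windows", {
  labs <- paste0(c("collected_", "working_", "extended_"), "trot")
  ws <- gen_windows(stats::setNames(rep(40, 3), labs), seed = 36,
                    noise_sd = 0)
  inp <- velocity_inputs(ws)
  cfg <- velocity_config(dim(inp$x)[1], conv_filters = c(16, 32),
                         dense = 32, batch_size = 16, epochs = 150,
                         patience = 20, seed = 36)
  fit <- train_velocity_regressor(inp$x, inp$height, inp$velocity,
                                  config = cfg, seed = 36)
  expect_gte(fit$r2, 0.95)
  expect_error(train_velocity_models(ws[1:10]), "fewer than 20")
})

test_that("walk velocities are estimated within the reported error", {
  labs <- paste0(c("collected_", "working_", "extended_"), "walk")
  ws <- gen_windows(stats::setNames(rep(70, 3), labs), seed = 42)
  fit <- train_velocity_models(ws, seed = 42)$walk
  expect_lte(fit$rmse, 0.07)
})
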