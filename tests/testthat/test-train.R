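small_ds <- function() tiny_dataset(n_strides = 3, window_len = 50)

test_that("chronological splits leave no shared time steps across the boundary", {
  ds <- tiny_dataset(n_strides = 5)
  sp <- split_windows(ds, 0.7, "chronological")
  L <- ds$window_len
  last_train_step <- ds$end_index[max(sp$train)]
  first_test_start <- ds$end_index[min(sp$test)] - L + 1
  expect_gt(first_test_start, last_train_step)
  # the gap swallows exactly window_len - 1 windows
  expect_equal(min(sp$test) - max(sp$train), L)
  # random mode covers every window exactly once
  sp_r <- split_windows(ds, 0.7, "random", seed = 4)
  expect_setequal(c(sp_r$train, sp_r$test), seq_len(n_windows(ds)))
  expect_error(split_windows(ds, 0.999), "empty")
})

test_that("a zero learning rate leaves parameters untouched", {
  ds <- small_ds()
  cfg <- ptt_config(n_channels = 5, window_len = 50, patch_len = 10,
                    embed_dim = 8, n_heads = 2, n_layers = 1, dropout = 0)
  m <- ptt_model(cfg, seed = 2)
  fit <- train_model(m, ds, train_config(learning_rate = 0, epochs = 2,
                                         batch_size = 16, seed = 1))
  expect_identical(fit$params, m$params)
  expect_equal(nrow(fit$history), 2)
})

test_that("training is deterministic given the seed and reduces the loss", {
  ds <- small_ds()
  cfg <- ptt_config(n_channels = 5, window_len = 50, patch_len = 10,
                    embed_dim = 16, n_heads = 2, n_layers = 1, dropout = 0)
  tc <- train_config(batch_size = 16, learning_rate = 2e-3, epochs = 8,
                     seed = 5)
  fit1 <- train_model(ptt_model(cfg, seed = 3), ds, tc)
  fit2 <- train_model(ptt_model(cfg, seed = 3), ds, tc)
  expect_identical(fit1$history$train_loss, fit2$history$train_loss)
  expect_lt(tail(fit1$history$train_loss, 1), fit1$history$train_loss[1])
})

test_that("prediction output is tidy and decodes to valid phases", {
  ds <- small_ds()
  cfg <- ptt_config(n_channels = 5, window_len = 50, patch_len = 10,
                    embed_dim = 8, n_heads = 2, n_layers = 1, dropout = 0)
  m <- ptt_model(cfg, seed = 1)
  preds <- predict_phase(m, ds)
  expect_s3_class(preds, "tbl_df")
  expect_equal(nrow(preds), n_windows(ds))
  expect_true(all(preds$phase_pred >= 0 & preds$phase_pred < 100))
  # shape mismatch is caught early
  cfg_bad <- ptt_config(n_channels = 4, window_len = 50, patch_len = 10,
                        embed_dim = 8, n_heads = 2, n_layers = 0)
  expect_error(predict_phase(ptt_model(cfg_bad, 1), ds), "channels")
})

test_that("tidy and glance summarise fits", {
  ds <- small_ds()
  cfg <- ptt_config(n_channels = 5, window_len = 50, patch_len = 10,
                    embed_dim = 8, n_heads = 2, n_layers = 1, dropout = 0)
  m <- ptt_model(cfg, seed = 1)
  expect_error(tidy(m), "not been trained")
  fit <- train_model(m, ds, train_config(batch_size = 16,
                                         learning_rate = 1e-3,
                                         epochs = 2, seed = 1))
  expect_named(tidy(fit), c("epoch", "train_loss"))
  gl <- glance(fit)
  expect_equal(gl$model, "patch-transformer")
  expect_equal(gl$epochs, 2)
  expect_gt(gl$n_params, 0)
})
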