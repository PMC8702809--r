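# short training runs on a small window keep these fast; the full-length
# training sanity check lives with the acceptance suite

tiny_cfg <- function(...) {
  args <- utils::modifyList(list(batch_size = 8L, epochs = 2L, seed = 7L,
                                 val_fraction = 0), list(...))
  do.call(train_config, args)
}

tiny_patches <- function(n = 16L, w = 16L, seed = 13L) {
  set.seed(seed)
  inputs <- array(runif(w * w * n), c(w, w, n))
  labels <- array(0, c(w, w, n))
  for (i in seq_len(n)) {
    r0 <- sample.int(w - 4L, 1)
    labels[r0:(r0 + 3L), , i] <- 1
    inputs[r0:(r0 + 3L), , i] <- inputs[r0:(r0 + 3L), , i] * 0.2 # dark band
  }
  list(inputs = inputs, labels = labels)
}

test_that("training is deterministic given the seed and logs the beta schedule", {
  sp <- tiny_model_spec(window = 16L)
  p <- tiny_patches()
  f1 <- train_model(sp, p, tiny_cfg())
  f2 <- train_model(sp, p, tiny_cfg())
  expect_equal(f1$run_log$loss4[1], f2$run_log$loss4[1], tolerance = 1e-14)
  expect_equal(f1$run_log$total, f2$run_log$total, tolerance = 1e-14)
  expect_equal(f1$run_log$beta, 1 - (seq_len(2) - 1) / 2)

  cfg10 <- tiny_cfg(epochs = 5L)
  f3 <- train_model(sp, p, cfg10)
  expect_equal(f3$run_log$beta, 1 - (0:4) / 5)
  # logged components recompose into the logged total under the default mode
  expect_equal(f3$run_log$total,
               f3$run_log$beta * (f3$run_log$loss1 + f3$run_log$loss2 +
                                    f3$run_log$loss3) + f3$run_log$loss4,
               tolerance = 1e-10)
})

test_that("training refuses unlabeled patches", {
  sp <- tiny_model_spec(window = 16L)
  p <- tiny_patches()
  expect_error(train_model(sp, list(inputs = p$inputs), tiny_cfg()),
               class = "retseg_data_error")
})

test_that("checkpoint round trip reproduces predictions bit for bit", {
  sp <- tiny_model_spec(window = 16L)
  fit <- train_model(sp, tiny_patches(), tiny_cfg())
  img <- matrix(runif(40 * 52), 40, 52)
  before <- predict_image(fit$model, img, step = 8L)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(fit$model, path)
  after <- predict_image(load_checkpoint(path), img, step = 8L)
  expect_identical(before$prob, after$prob)
  expect_identical(before$seg, after$seg)
  unlink(path)
})

test_that("prediction matches input dimensions and respects threshold extremes", {
  m <- build_model(tiny_model_spec(window = 16L), seed = 2L)
  img <- matrix(runif(50 * 45), 50, 45)
  out <- predict_image(m, img, step = 8L)
  expect_identical(dim(out$prob), c(50L, 45L))
  expect_true(all(out$prob >= 0 & out$prob <= 1))
  expect_true(all(out$seg %in% c(0, 1)))
  expect_true(all(predict_image(m, img, threshold = 0, step = 8L)$seg == 1))
  expect_true(all(predict_image(m, img, threshold = 1.00001, step = 8L)$seg == 0))
})

test_that("prediction is invariant to the forward batch decomposition", {
  m <- build_model(tiny_model_spec(window = 16L), seed = 2L)
  img <- matrix(runif(48 * 48), 48, 48)
  a <- predict_image(m, img, step = 8L, batch_patches = 3L)
  b <- predict_image(m, img, step = 8L, batch_patches = 64L)
  expect_equal(a$prob, b$prob, tolerance = 1e-12)
})

test_that("dataset evaluation reports one row per image and consistent means", {
  dir <- file.path(tempdir(), "retseg_ds")
  on.exit(unlink(dir, recursive = TRUE))
  generate_dataset(synth_spec(height = 96L, width = 96L, n_roots = 3L, seed = 2L),
                   n_images = 2L, out_dir = dir)
  m <- build_model(tiny_model_spec(window = 16L), seed = 2L)
  rep <- evaluate_dataset(m, dir)
  expect_identical(nrow(rep$per_image), 2L)
  expect_equal(rep$means$accuracy, mean(rep$per_image$accuracy))
  expect_equal(rep$means$auc, mean(rep$per_image$auc))
  expect_true(all(rep$per_image$tp + rep$per_image$tn +
                    rep$per_image$fp + rep$per_image$fn > 0))
  # report writers round-trip
  jf <- tempfile(fileext = ".json")
  write_eval_report(rep, jf)
  parsed <- jsonlite::read_json(jf)
  expect_length(parsed$per_image, 2L)
  unlink(jf)
})

test_that("configuration loader merges defaults and rejects unknown keys", {
  cfg <- load_config(NULL)
  expect_equal(cfg$train$batch_size, 20L)
  expect_equal(cfg$train$epochs, 500L)
  expect_equal(cfg$train$learning_rate, 0.001)
  expect_equal(cfg$preprocess$gamma, 1.3)
  f <- tempfile(fileext = ".yaml")
  writeLines(c("train:", "  epochs: 3", "patch:", "  step: 8"), f)
  cfg2 <- load_config(f)
  expect_equal(cfg2$train$epochs, 3)
  expect_equal(cfg2$patch$step, 8)
  expect_equal(cfg2$train$batch_size, 20L)
  writeLines(c("train:", "  epohcs: 3"), f)
  expect_error(load_config(f), class = "retseg_config_error")
  unlink(f)
})
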