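test_that("split_dataset is stratified, exhaustive and deterministic", {
  docs <- data.frame(id = sprintf("d%03d", 1:100),
                     label = rep(0:4, each = 20),
                     stringsAsFactors = FALSE)
  sp <- split_dataset(docs, 1 / 5, seed = 10)
  expect_identical(nrow(sp$train), 80L)
  expect_identical(nrow(sp$val), 20L)
  expect_identical(sort(c(sp$train$id, sp$val$id)), sort(docs$id))
  expect_identical(as.integer(table(sp$val$label)), rep(4L, 5))

  sp2 <- split_dataset(docs, 1 / 5, seed = 10)
  expect_identical(sp, sp2)

  two <- data.frame(label = rep(0:1, each = 25))
  sp3 <- split_dataset(two, 1 / 5, seed = 11)
  expect_true(max(abs(table(sp3$val$label) - 5)) <= 1)
  expect_error(split_dataset(docs, 0), "between 0 and 1")
  expect_error(split_dataset(docs, 1.2), "between 0 and 1")
})

test_that("build_model adapts input channels and head size", {
  m <- build_model(in_channels = 12, n_classes = 5, base_width = 8, seed = 1)
  expect_identical(dim(m$params$conv1$w), c(12L, 7L, 7L, 8L))
  expect_identical(dim(m$params$fc$w), c(5L, as.integer(8 * 8)))
  x <- array(rnorm(12 * 25 * 25), c(12, 25, 25))
  p <- predict(m, x)
  expect_identical(dim(p$logits), c(5L, 1L))
  expect_error(build_model(0, 5), "in_channels")
  expect_error(build_model(4, 1), "n_classes")
})

test_that("the 1-D CNN accepts a length-625 embedded sequence", {
  m <- build_model(in_channels = 6, n_classes = 5, backbone = "cnn1d",
                   seed = 2)
  x <- array(rnorm(6 * 625), c(6, 1, 625))
  p <- predict(m, x)
  expect_identical(dim(p$logits), c(5L, 1L))
  expect_equal(sum(p$probabilities), 1, tolerance = 1e-6)
})

test_that("transfer surgery preserves interior weights bit-exactly", {
  donor <- synthetic_pretrained_backbone(base_width = 8, seed = 77,
                                         epochs = 0)
  m <- build_model(in_channels = 10, n_classes = 4, pretrained = TRUE,
                   base_width = 8, seed = 3, donor = donor)
  expect_identical(sort(m$replaced), c("conv1", "fc"))
  interior <- interior_param_names(m)
  expect_identical(param_fingerprint(m$params, interior),
                   param_fingerprint(donor$params, interior))
  # replaced layers differ from the donor and have the adapted shapes
  expect_identical(dim(m$params$conv1$w)[c(1, 4)], c(10L, 8L))
  expect_identical(nrow(m$params$fc$w), 4L)
  expect_false(identical(m$params$fc$w, donor$params$fc$w))
})

test_that("the mismatched ablation mode is flagged and evaluation-only", {
  donor <- synthetic_pretrained_backbone(base_width = 8, seed = 77,
                                         epochs = 0)
  expect_warning(
    m <- build_model(in_channels = 10, n_classes = 4, pretrained = TRUE,
                     fine_tune_io = FALSE, base_width = 8, seed = 3,
                     donor = donor),
    "mismatched")
  expect_true(m$mismatched)
  x <- array(rnorm(10 * 25 * 25), c(10, 25, 25))
  p <- predict(m, x)   # forwards on the first 3 channels
  expect_identical(dim(p$logits), c(4L, 1L))
  xb <- array(rnorm(10 * 25 * 25 * 4), c(10, 25, 25, 4))
  expect_error(train_classifier(m, xb, c(0, 1, 2, 3), train_config(epochs = 1)),
               "evaluation-only")
})

test_that("predictions are normalised, argmax-consistent and repeatable", {
  w <- tcam_test_world()
  x <- stack_grids(w$embedded[w$split$val$id[1:8]])
  p1 <- predict(w$model, x)
  expect_equal(colSums(p1$probabilities), rep(1, 8), tolerance = 1e-6)
  expect_identical(p1$predicted_class,
                   apply(p1$logits, 2, which.max) - 1L)
  p2 <- predict(w$model, x)
  expect_identical(p1$logits, p2$logits)
  expect_error(predict(w$model, array(0, c(3, 25, 25))), "channels")
})

test_that("one small SGD step on a fixed batch decreases the loss", {
  set.seed(20)
  m <- build_model(in_channels = 4, n_classes = 3, base_width = 4, seed = 21)
  x <- array(rnorm(4 * 25 * 25 * 16), c(4, 25, 25, 16))
  y <- sample(0:2, 16, replace = TRUE) + 1L
  fw1 <- textcam:::net_forward(m$net, m$params, m$state, x, TRUE, TRUE)
  ce1 <- textcam:::softmax_ce(fw1$logits, y)
  bw <- textcam:::net_backward(m$net, m$params, fw1$caches, fw1$values,
                               ce1$dlogits)
  st <- textcam:::sgd_step(m$params, bw$pgrads, list(), 1e-3, 0, 0)
  fw2 <- textcam:::net_forward(m$net, st$params, fw1$state, x, TRUE, TRUE)
  ce2 <- textcam:::softmax_ce(fw2$logits, y)
  expect_lt(ce2$loss, ce1$loss)
})

test_that("training history has one row per iteration and per epoch", {
  set.seed(30)
  x <- array(rnorm(3 * 25 * 25 * 50), c(3, 25, 25, 50))
  y <- rep(0:1, 25)
  m <- build_model(3, 2, base_width = 4, seed = 31)
  fit <- train_classifier(m, x, y,
                          train_config(epochs = 2, batch_size = 16, seed = 32),
                          verbose = FALSE)
  # 40 training rows (val_fraction 0.2) in batches of 16 -> 3 iterations
  expect_identical(nrow(fit$history$iteration), 2L * 3L)
  expect_identical(nrow(fit$history$epoch), 2L)
  expect_true(fit$best_epoch %in% 1:2)
})

test_that("training is bitwise deterministic under a fixed seed", {
  set.seed(33)
  x <- array(rnorm(3 * 25 * 25 * 40), c(3, 25, 25, 40))
  y <- rep(0:1, 20)
  run <- function() {
    m <- build_model(3, 2, base_width = 4, seed = 34)
    train_classifier(m, x, y,
                     train_config(epochs = 2, batch_size = 16, seed = 35),
                     verbose = FALSE)
  }
  f1 <- run(); f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("checkpoints round-trip through save/load", {
  w <- tcam_test_world()
  p <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(w$model, p)
  m2 <- load_checkpoint(p)
  x <- w$embedded[[w$split$val$id[1]]]
  expect_identical(predict(w$model, x)$logits, predict(m2, x)$logits)
})
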