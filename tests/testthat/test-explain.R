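test_that("Grad-CAM alpha and map match the finite-difference oracle", {
  toy <- tcam_toy_net(seed = 9)
  set.seed(4)
  x <- array(rnorm(2 * 6 * 6), c(2, 6, 6))
  cam <- compute_gradcam(toy$model, x, class_id = 0L,
                         config = cam_config(target_layer = "r1"))
  fw <- textcam:::net_forward(toy$model$net, toy$model$params,
                              toy$model$state, array(x, c(2, 6, 6, 1)),
                              FALSE, TRUE)
  A0 <- fw$values[["r1"]]
  eps <- 1e-5
  fd_grad <- array(0, dim(A0))
  for (i in seq_along(A0)) {
    Ap <- A0; Ap[i] <- Ap[i] + eps
    Am <- A0; Am[i] <- Am[i] - eps
    fd_grad[i] <- (toy$logit_from_r1(Ap) - toy$logit_from_r1(Am)) / (2 * eps)
  }
  alpha_fd <- rowMeans(matrix(fd_grad, nrow = 3))
  expect_equal(cam$alpha, alpha_fd, tolerance = 1e-4)
  raw_fd <- matrix(pmax(colSums(matrix(A0, nrow = 3) * alpha_fd), 0), 6, 6)
  expect_equal(cam$raw, raw_fd, tolerance = 1e-4)
})

test_that("CAM nonnegativity and min-max normalisation hold on random inputs", {
  toy <- tcam_toy_net(seed = 19)
  set.seed(5)
  for (i in 1:100) {
    x <- array(rnorm(2 * 6 * 6, sd = 2), c(2, 6, 6))
    cam <- compute_gradcam(toy$model, x, class_id = sample(0:1, 1),
                           config = cam_config(target_layer = "r1"))
    expect_true(all(cam$raw >= 0))
    expect_true(all(cam$grid_scores >= 0 & cam$grid_scores <= 1))
    if (any(cam$raw > 0)) {
      expect_equal(max(cam$grid_scores), 1)
      expect_equal(min(cam$grid_scores), 0)
    } else {
      expect_true(all(cam$grid_scores == 0))
    }
  }
})

test_that("a constant logit yields an all-zero CAM", {
  toy <- tcam_toy_net(seed = 29)
  toy$model$params$fc$w[1, ] <- 0   # class-0 logit no longer depends on activations
  set.seed(6)
  x <- array(rnorm(2 * 6 * 6), c(2, 6, 6))
  cam <- compute_gradcam(toy$model, x, class_id = 0L,
                         config = cam_config(target_layer = "r1"))
  expect_true(all(cam$raw == 0))
  expect_true(all(cam$grid_scores == 0))
})

test_that("negative channel weights are clamped by the ReLU", {
  # single-channel 1x1 conv net: logit = v * mean(A) with v < 0 and A > 0
  net <- textcam:::net_new(c(1L, 4L, 4L))
  net <- textcam:::net_add(net, "c1", "conv", "input", filters = 1L,
                           kernel = c(1L, 1L), stride = c(1L, 1L),
                           pad = c(0L, 0L))
  net <- textcam:::net_add(net, "r1", "relu", "c1")
  net <- textcam:::net_add(net, "gap", "gap", "r1")
  net <- textcam:::net_add(net, "fc", "linear", "gap", units = 2L)
  ini <- textcam:::net_init_params(net, seed = 1)
  ini$params$c1$w[] <- 1
  ini$params$fc$w[1, ] <- -2     # negative weight v
  ini$params$fc$w[2, ] <- 2
  model <- structure(list(net = net, params = ini$params, state = ini$state,
                          backbone = "toy", in_channels = 1L, n_classes = 2L,
                          mismatched = FALSE, input_slice = NULL,
                          replaced = character(0)), class = "tcam_model")
  x <- array(abs(rnorm(16)) + 0.1, c(1, 4, 4))
  cam_neg <- compute_gradcam(model, x, class_id = 0L,
                             config = cam_config(target_layer = "r1"))
  expect_true(all(cam_neg$raw == 0))
  expect_true(all(cam_neg$grid_scores == 0))
  # the positive-weight class sees the activation map rescaled to [0, 1]
  cam_pos <- compute_gradcam(model, x, class_id = 1L,
                             config = cam_config(target_layer = "r1"))
  A <- array(x, c(4, 4))
  expect_equal(cam_pos$grid_scores,
               (A - min(A)) / (max(A) - min(A)), tolerance = 1e-10)
})

test_that("attribute_tokens aligns scores cell-for-cell with the grid", {
  grid <- format_grid(sprintf("tok%d", 1:7), h = 3, w = 3)
  cam <- structure(list(raw = matrix(1, 3, 3),
                        grid_scores = matrix(1, 3, 3),
                        target_class = 0L, target_layer = "x",
                        alpha = 1, prediction = 0L, source_grid = NULL),
                   class = "class_activation_map")
  at <- attribute_tokens(cam, grid)
  expect_identical(nrow(at), 9L)
  expect_true(all(at$score == 1))
  expect_identical(at$token[1:7], sprintf("tok%d", 1:7))
  expect_identical(at$is_pad, c(rep(FALSE, 7), TRUE, TRUE))

  # single-hot map
  sh <- matrix(0, 3, 3); sh[2, 3] <- 1
  cam$grid_scores <- sh
  at2 <- attribute_tokens(cam, grid)
  expect_identical(which(at2$score == 1), 6L)   # row-major position (2,3)
  expect_true(all(at2$score[-6] == 0))

  # all-pad grid
  at3 <- attribute_tokens(cam, format_grid(character(0), 3, 3))
  expect_true(all(at3$is_pad))

  expect_error(attribute_tokens(cam, format_grid("a", 2, 2)), "disagree")
})

test_that("CAMs separate disjoint evidence regions by class", {
  w <- tcam_test_world()
  kwA <- w$spec$class_keywords[[1]]
  kwB <- w$spec$class_keywords[[2]]
  set.seed(50)
  # class-0 evidence in rows 1-5, class-1 evidence in rows 8-12
  toks <- c(sample(kwA, 125, replace = TRUE),
            sample(w$spec$noise_vocab, 50, replace = TRUE),
            sample(kwB, 125, replace = TRUE))
  eg <- embed_grid(format_grid(toks), w$embedding)
  top <- 1:5; bottom <- 8:12
  camA <- compute_gradcam(w$model, eg, class_id = 0L)
  camB <- compute_gradcam(w$model, eg, class_id = 1L)
  expect_gt(mean(camA$grid_scores[top, ]), mean(camA$grid_scores[bottom, ]))
  expect_gt(mean(camB$grid_scores[bottom, ]), mean(camB$grid_scores[top, ]))
})

test_that("re-randomising the head changes the CAMs (sanity check)", {
  w <- tcam_test_world()
  ids <- w$split$val$id[1:30]
  randomized <- w$model
  set.seed(60)
  randomized$params$fc$w[] <- rnorm(length(randomized$params$fc$w))
  rc <- vapply(ids, function(id) {
    c1 <- compute_gradcam(w$model, w$embedded[[id]])
    c2 <- compute_gradcam(randomized, w$embedded[[id]],
                          class_id = c1$target_class)
    suppressWarnings(cor(as.vector(c1$raw), as.vector(c2$raw),
                         method = "spearman"))
  }, numeric(1))
  expect_lt(mean(rc, na.rm = TRUE), 0.5)
})

test_that("heatmap rendering is monotone in score and writes files", {
  w <- tcam_test_world()
  cam <- compute_gradcam(w$model, w$embedded[[w$split$val$id[1]]])
  ras <- cam_raster(cam)
  o <- order(as.vector(cam$grid_scores))
  expect_true(all(diff(as.vector(ras)[o]) >= 0))   # monotone colormap
  expect_identical(dim(cam_raster(cam, scale = 4)), c(100L, 100L))

  pgm <- withr::local_tempfile(fileext = ".pgm")
  render_heatmap(cam, pgm, scale = 1)
  lines <- readLines(pgm)
  expect_identical(lines[1], "P2")
  expect_identical(lines[2], "25 25")
  vals <- scan(text = paste(lines[-(1:3)], collapse = " "), quiet = TRUE)
  expect_identical(length(vals), 625L)
  expect_identical(as.integer(vals), as.vector(t(ras)))

  # all-zero cam -> uniform dark raster
  zero <- cam
  zero$grid_scores <- matrix(0, 25, 25)
  expect_true(all(cam_raster(zero) == 0L))

  if (isTRUE(capabilities("png"))) {
    png_path <- withr::local_tempfile(fileext = ".png")
    render_heatmap(cam, png_path)
    expect_gt(file.info(png_path)$size, 0)
  }
})

test_that("HTML highlighting wraps exactly the over-threshold tokens", {
  grid <- format_grid(c("alpha", "beta", "gamma"), 2, 2)
  cam <- structure(list(raw = matrix(1, 2, 2),
                        grid_scores = matrix(c(1, 0.2, 0.8, 0), 2, 2,
                                             byrow = TRUE),
                        target_class = 0L, target_layer = "x", alpha = 1,
                        prediction = 0L, source_grid = NULL),
                   class = "class_activation_map")
  at <- attribute_tokens(cam, grid)
  n_spans <- function(html) lengths(regmatches(html, gregexpr("<span", html)))
  expect_identical(n_spans(render_highlight(at, threshold = 0)), 3L)
  expect_identical(n_spans(render_highlight(at, threshold = 1.5)), 0L)
  expect_identical(n_spans(render_highlight(at, threshold = 0.5)), 2L)
  html <- render_highlight(at, threshold = 0.5)
  expect_false(grepl("#", html, fixed = TRUE))   # pads omitted
  p <- withr::local_tempfile(fileext = ".html")
  render_highlight(at, 0.5, path = p)
  expect_true(file.exists(p))

  jp <- withr::local_tempfile(fileext = ".json")
  write_attribution_json(at, jp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_identical(nrow(back$cells), 4L)
  expect_equal(back$cells$score, at$score)
})
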