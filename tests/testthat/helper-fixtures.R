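# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# A small but non-trivial trained world: 5 classes x 40 docs, 8-dim
# embeddings, width-8 backbone, 3 epochs. Used by the explain/render tests
# that need a model whose CAMs carry real signal.
tcam_test_world <- function() {
  if (!is.null(.fixtures$world)) return(.fixtures$world)
  spec <- synthetic_spec(n_classes = 5, docs_per_class = 100,
                         keyword_rate = 0.3, doc_length = c(30L, 300L),
                         noise_vocab_size = 200L, seed = 301)
  corp <- generate_corpus(spec)
  toks <- tokenize_corpus(corp$documents$text)
  names(toks) <- corp$documents$id
  split <- split_dataset(corp$documents, 0.2, seed = 302)
  emb <- train_embedding(toks[split$train$id],
                         embed_config(vector_size = 8, window = 5,
                                      epochs = 2, seed = 303))
  grids <- lapply(toks, format_grid)
  names(grids) <- corp$documents$id
  egs <- lapply(grids, embed_grid, model = emb)
  model <- build_model(8, 5, base_width = 8, seed = 304)
  fit <- train_classifier(model, stack_grids(egs[split$train$id]),
                          split$train$label,
                          train_config(epochs = 6, batch_size = 32,
                                       seed = 305),
                          x_val = stack_grids(egs[split$val$id]),
                          y_val = split$val$label, verbose = FALSE)
  .fixtures$world <- list(spec = spec, corpus = corp, tokens = toks,
                          split = split, embedding = emb, grids = grids,
                          embedded = egs, model = fit$model,
                          history = fit$history)
  .fixtures$world
}

# A tiny hand-built convolutional net exposing the graph internals, for
# finite-difference oracles: conv(2->3) - relu - conv(3->4) - relu - gap -
# fc(2), on 2 x 6 x 6 inputs. Returns the model plus a closure that
# recomputes the class-0 logit from a perturbed stage-1 activation.
tcam_toy_net <- function(seed = 9) {
  net <- textcam:::net_new(c(2L, 6L, 6L))
  net <- textcam:::net_add(net, "c1", "conv", "input", filters = 3L,
                           kernel = c(3L, 3L), stride = c(1L, 1L),
                           pad = c(1L, 1L))
  net <- textcam:::net_add(net, "r1", "relu", "c1")
  net <- textcam:::net_add(net, "c2", "conv", "r1", filters = 4L,
                           kernel = c(3L, 3L), stride = c(1L, 1L),
                           pad = c(1L, 1L))
  net <- textcam:::net_add(net, "r2", "relu", "c2")
  net <- textcam:::net_add(net, "gap", "gap", "r2")
  net <- textcam:::net_add(net, "fc", "linear", "gap", units = 2L)
  attr(net, "stages") <- c(s1 = "r1")
  ini <- textcam:::net_init_params(net, seed = seed)
  model <- structure(list(net = net, params = ini$params, state = ini$state,
                          backbone = "toy", in_channels = 2L, n_classes = 2L,
                          mismatched = FALSE, input_slice = NULL,
                          replaced = character(0)),
                     class = "tcam_model")
  logit_from_r1 <- function(A, class0 = 1L) {
    c2 <- textcam:::cpp_conv2d_fwd(A, model$params$c2$w, 1L, 1L, 1L, 1L)
    r2 <- pmax(c2, 0)
    g <- matrix(rowMeans(matrix(r2, nrow = 4L)), 4L, 1L)
    (model$params$fc$w %*% g + model$params$fc$b)[class0, 1L]
  }
  list(model = model, logit_from_r1 = logit_from_r1)
}

# Brute-force (explicit per-class loops) weighted metrics, the independent
# oracle for weighted_metrics().
bruteforce_metrics <- function(cm) {
  C <- nrow(cm)
  n <- sum(cm)
  prec <- rec <- f1 <- sup <- numeric(C)
  for (i in seq_len(C)) {
    tp <- cm[i, i]
    fp <- 0; fn <- 0
    for (j in seq_len(C)) {
      if (j != i) {
        fp <- fp + cm[j, i]
        fn <- fn + cm[i, j]
      }
    }
    sup[i] <- tp + fn
    prec[i] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[i] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[i] <- if (prec[i] + rec[i] > 0) 2 * prec[i] * rec[i] / (prec[i] + rec[i]) else 0
  }
  wp <- wr <- wf <- 0
  for (i in seq_len(C)) {
    wp <- wp + sup[i] / n * prec[i]
    wr <- wr + sup[i] / n * rec[i]
    wf <- wf + sup[i] / n * f1[i]
  }
  acc <- 0
  for (i in seq_len(C)) acc <- acc + cm[i, i]
  list(precision = wp, recall = wr, f1 = wf, accuracy = acc / n)
}

random_tokens <- function(n, vocab_size = 50) {
  sprintf("t%d", sample.int(vocab_size, n, replace = TRUE))
}
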