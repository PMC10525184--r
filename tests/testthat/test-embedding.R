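make_corpus <- function(n_docs = 40, vocab = 30, len = 20, seed = 7) {
  set.seed(seed)
  lapply(seq_len(n_docs), function(i) random_tokens(len, vocab))
}

test_that("train_embedding honours the configuration contract", {
  corpus <- make_corpus()
  m <- train_embedding(corpus, embed_config(vector_size = 100, window = 5,
                                            epochs = 1, seed = 1))
  expect_s3_class(m, "embedding_model")
  expect_identical(ncol(m$vectors), 100L)
  expect_identical(m$dim, 100L)

  # min_count = 1 keeps every training token
  m2 <- train_embedding(list(c("a", "b")),
                        embed_config(vector_size = 4, epochs = 1, seed = 1))
  expect_true(all(c("a", "b") %in% names(m2$vocab)))

  expect_error(train_embedding(list(), embed_config()), "non-empty")
  expect_error(embed_config(vector_size = 0), ">= 1")
  expect_error(train_embedding(list(character(0))), "no trainable tokens")
})

test_that("embedding training is deterministic under a seed", {
  corpus <- make_corpus()
  cfg <- embed_config(vector_size = 16, window = 5, epochs = 2, seed = 99)
  m1 <- train_embedding(corpus, cfg)
  m2 <- train_embedding(corpus, cfg)
  expect_identical(m1$vectors, m2$vectors)
})

test_that("lookup maps pads and OOV tokens to the zero vector", {
  m <- train_embedding(make_corpus(), embed_config(vector_size = 8, window = 5,
                                                   epochs = 2, seed = 2))
  expect_identical(lookup(m, "#"), numeric(8))
  expect_identical(lookup(m, "zzz-never-seen"), numeric(8))
  tok <- names(m$vocab)[1]
  expect_gt(sum(abs(lookup(m, tok))), 0)
})

test_that("embed_grid places vectors channel-first, zeros at pads/OOV", {
  m <- train_embedding(make_corpus(vocab = 20),
                       embed_config(vector_size = 6, window = 5,
                                    epochs = 1, seed = 3))
  # all-pad grid embeds to all zeros
  eg0 <- embed_grid(format_grid(character(0), h = 4, w = 4), m)
  expect_identical(dim(eg0$values), c(6L, 4L, 4L))
  expect_true(all(eg0$values == 0))

  toks <- c(names(m$vocab)[1:5], "unseen-token", names(m$vocab)[6])
  g <- format_grid(toks, h = 3, w = 3)
  eg <- embed_grid(g, m)
  # values[m, j, k] equals element m of the token vector at (j, k)
  for (j in 1:3) for (k in 1:3)
    expect_equal(as.numeric(eg$values[, j, k]), lookup(m, g$tokens[j, k]))
  # zero columns exactly at pad + OOV cells
  zero_cell <- apply(eg$values, c(2, 3), function(v) all(v == 0))
  expect_identical(zero_cell, g$pad_mask | g$tokens == "unseen-token")
})

test_that("permuting two grid cells permutes exactly those columns", {
  m <- train_embedding(make_corpus(), embed_config(vector_size = 5, window = 5,
                                                   epochs = 1, seed = 4))
  toks <- names(m$vocab)[1:9]
  eg1 <- embed_grid(format_grid(toks, 3, 3), m)
  toks2 <- toks; toks2[c(2, 7)] <- toks2[c(7, 2)]
  eg2 <- embed_grid(format_grid(toks2, 3, 3), m)
  # row-major positions 2 and 7 are (1,2) and (3,1)
  expect_equal(eg2$values[, 1, 2], eg1$values[, 3, 1])
  expect_equal(eg2$values[, 3, 1], eg1$values[, 1, 2])
  same <- setdiff(1:9, c(2, 7))
  for (p in same) {
    j <- (p - 1) %/% 3 + 1; k <- (p - 1) %% 3 + 1
    expect_equal(eg2$values[, j, k], eg1$values[, j, k])
  }
})

test_that("nonzero cell vectors are exactly the in-vocabulary lookups (multiset)", {
  m <- train_embedding(make_corpus(vocab = 15),
                       embed_config(vector_size = 4, window = 5,
                                    epochs = 1, seed = 5))
  set.seed(6)
  toks <- c(sample(names(m$vocab), 12, replace = TRUE), "oov1", "oov2")
  g <- format_grid(toks, 4, 5)
  eg <- embed_grid(g, m)
  cells <- matrix(eg$values, nrow = 4)
  nz <- cells[, colSums(abs(cells)) > 0, drop = FALSE]
  expected <- vapply(toks[1:12], function(t) lookup(m, t), numeric(4))
  sig <- function(x) sort(as.vector(apply(unname(x), 2, paste, collapse = ",")))
  expect_identical(sig(nz), sig(expected))
})

test_that("word2vec text format round-trips", {
  m <- train_embedding(make_corpus(), embed_config(vector_size = 7, window = 5,
                                                   epochs = 1, seed = 8))
  p <- withr::local_tempfile(fileext = ".txt")
  save_embedding(m, p)
  hdr <- strsplit(readLines(p, n = 1), " ")[[1]]
  expect_identical(as.integer(hdr), c(nrow(m$vectors), 7L))
  m2 <- load_embedding(p)
  expect_equal(m2$vectors, m$vectors, tolerance = 1e-12)
  expect_identical(names(m2$vocab), names(m$vocab))
  expect_identical(lookup(m2, "#"), numeric(7))
})

test_that("embed_sequence pads/truncates to the fixed length", {
  m <- train_embedding(make_corpus(), embed_config(vector_size = 3, window = 5,
                                                   epochs = 1, seed = 9))
  s <- embed_sequence(names(m$vocab)[1:4], m, length_out = 10)
  expect_identical(dim(s), c(3L, 1L, 10L))
  expect_true(all(s[, 1, 5:10] == 0))
  s2 <- embed_sequence(rep(names(m$vocab)[1], 20), m, length_out = 10)
  expect_identical(dim(s2), c(3L, 1L, 10L))
})
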