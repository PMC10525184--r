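test_that("generate_corpus honours the spec exactly", {
  spec <- synthetic_spec(n_classes = 5, docs_per_class = 100, seed = 90)
  corp <- generate_corpus(spec)
  expect_identical(nrow(corp$documents), 500L)
  expect_identical(as.integer(table(corp$documents$label)), rep(100L, 5))
  lens <- lengths(strsplit(corp$documents$text, " "))
  expect_true(all(lens >= 30 & lens <= 600))
  # recorded positions index exactly the keyword tokens
  for (d in c(1L, 250L, 500L)) {
    toks <- strsplit(corp$documents$text[d], " ")[[1]]
    kws <- spec$class_keywords[[corp$documents$label[d] + 1]]
    expect_identical(which(toks %in% kws), corp$keyword_positions[[d]])
  }

  # determinism
  corp2 <- generate_corpus(spec)
  expect_identical(corp$documents, corp2$documents)
  expect_identical(corp$keyword_positions, corp2$keyword_positions)
})

test_that("keyword_rate = 1 plants keywords everywhere", {
  spec <- synthetic_spec(n_classes = 2, docs_per_class = 5, keyword_rate = 1,
                         doc_length = c(10, 20), seed = 91)
  corp <- generate_corpus(spec)
  for (d in seq_len(nrow(corp$documents))) {
    toks <- strsplit(corp$documents$text[d], " ")[[1]]
    kws <- spec$class_keywords[[corp$documents$label[d] + 1]]
    expect_true(all(toks %in% kws))
    expect_identical(corp$keyword_positions[[d]], seq_along(toks))
  }
})

test_that("generated text survives the tokenizer unchanged", {
  spec <- synthetic_spec(n_classes = 3, docs_per_class = 4, seed = 92,
                         doc_length = c(10, 50))
  corp <- generate_corpus(spec)
  for (d in 1:nrow(corp$documents))
    expect_identical(tokenize(corp$documents$text[d]),
                     strsplit(corp$documents$text[d], " ")[[1]])
})

test_that("invalid specs are rejected", {
  expect_error(synthetic_spec(n_classes = 1), "n_classes")
  expect_error(synthetic_spec(keyword_rate = 0), "keyword_rate")
  expect_error(synthetic_spec(keyword_rate = 1.2), "keyword_rate")
  expect_error(synthetic_spec(doc_length = c(100, 700)), "grid cell")
  expect_error(synthetic_spec(doc_length = c(50, 20)), "doc_length")
  expect_error(synthetic_spec(n_classes = 2,
                              class_keywords = list(c("x", "y"), c("y", "z"))),
               "disjoint")
})

make_attr <- function(scores, n_tokens, h = 5, w = 5) {
  grid <- format_grid(sprintf("t%d", seq_len(n_tokens)), h, w)
  sc <- matrix(0, h, w)
  sc[!grid$pad_mask] <- 0
  full <- rep(0, h * w)
  full[seq_len(n_tokens)] <- scores
  structure(data.frame(token = as.vector(t(grid$tokens)),
                       row = rep(seq_len(h), each = w),
                       col = rep(seq_len(w), h),
                       score = full,
                       is_pad = as.vector(t(grid$pad_mask)),
                       stringsAsFactors = FALSE),
            class = c("token_attribution", "data.frame"))
}

test_that("localisation score follows the strict-inequality convention", {
  # indicator scores on keywords -> 1
  a <- make_attr(c(1, 0, 0, 1, 0, 0, 0, 0, 0, 0), 10)
  expect_equal(as.numeric(keyword_localization_score(a, c(1L, 4L))), 1)
  # uniform scores tie -> 0
  u <- make_attr(rep(0.5, 10), 10)
  expect_equal(as.numeric(keyword_localization_score(u, c(1L, 4L))), 0)
  # documents with no keywords are excluded
  expect_error(suppressMessages(keyword_localization_score(u, integer(0))),
               "no scoreable")
  expect_message(
    s <- keyword_localization_score(list(a, u), list(c(1L, 4L), integer(0))),
    "excluded")
  expect_equal(as.numeric(s), 1)
  expect_identical(attr(s, "n_excluded"), 1L)
})

test_that("random scores localise at chance level (Monte Carlo)", {
  set.seed(93)
  attrs <- list(); truths <- list()
  for (i in 1:1000) {
    n <- 20
    attrs[[i]] <- make_attr(runif(n), n)
    truths[[i]] <- sort(sample.int(n, 6))
  }
  s <- keyword_localization_score(attrs, truths)
  expect_gt(as.numeric(s), 0.45)
  expect_lt(as.numeric(s), 0.55)
  expect_identical(attr(s, "n_scored"), 1000L)
})
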