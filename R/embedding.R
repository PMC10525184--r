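#' Word-embedding training configuration
#'
#' Skip-gram word2vec with hierarchical softmax. The defaults mirror the
#' reference configuration for clinical abstracts: 100-dimensional vectors
#' and a window of 100 tokens (wide enough that, for abstracts of a few
#' hundred tokens, every co-occurring pair in a document is in scope), with
#' `min_count = 1` so every training token enters the vocabulary. Training
#' epochs are not part of that configuration; the conventional default of 5
#' is used.
#'
#' @param vector_size Embedding dimension D (>= 1).
#' @param window Maximum half-window; the effective half-window at each
#'   position is drawn uniformly from `1..window` (standard word2vec
#'   shrinking).
#' @param min_count Minimum corpus frequency for a token to be kept (>= 1).
#' @param epochs Passes over the corpus.
#' @param alpha,min_alpha Initial and floor learning rate (linear decay).
#' @param seed Integer seed; when supplied, training is single-threaded and
#'   bit-reproducible.
#' @return An object of class `embed_config`.
#' @export
embed_config <- function(vector_size = 100L, window = 100L, min_count = 1L,
                         epochs = 5L, alpha = 0.025, min_alpha = 1e-4,
                         seed = NULL) {
  vector_size <- as.integer(vector_size)
  if (is.na(vector_size) || vector_size < 1L) stop("vector_size must be >= 1")
  if (as.integer(min_count) < 1L) stop("min_count must be >= 1")
  if (as.integer(window) < 1L) stop("window must be >= 1")
  if (as.integer(epochs) < 1L) stop("epochs must be >= 1")
  structure(list(vector_size = vector_size, algorithm = "skip-gram",
                 optimizer = "hierarchical-softmax",
                 window = as.integer(window), min_count = as.integer(min_count),
                 epochs = as.integer(epochs), alpha = alpha,
                 min_alpha = min_alpha, seed = seed),
            class = "embed_config")
}

#' Train a skip-gram word-embedding model
#'
#' Trains hierarchical-softmax skip-gram vectors on raw (ungridded) token
#' sequences — typically the training split only, so validation text never
#' leaks into the vocabulary. Tokens listed in `zero_tokens` (by default the
#' grid pad symbol `"#"`) are excluded from training and forced to the zero
#' vector at lookup time, as are all out-of-vocabulary tokens.
#'
#' @param corpus List of character token vectors (see [tokenize_corpus()]).
#' @param config An [embed_config()].
#' @param zero_tokens Tokens that must always embed to the zero vector.
#' @return An object of class `embedding_model`: `vectors` (|V| x D matrix
#'   with token rownames), `vocab` (named index), `dim`, `zero_tokens`.
#' @export
train_embedding <- function(corpus, config = embed_config(),
                            zero_tokens = "#") {
  stopifnot(inherits(config, "embed_config"))
  if (!is.list(corpus) || length(corpus) == 0L) stop("corpus must be a non-empty list of token vectors")
  corpus <- lapply(corpus, function(d) {
    d <- as.character(d)
    d[!(d %in% zero_tokens)]
  })
  all_tokens <- unlist(corpus, use.names = FALSE)
  if (length(all_tokens) == 0L) stop("corpus contains no trainable tokens")
  tab <- table(all_tokens)
  tab <- tab[tab >= config$min_count]
  if (length(tab) == 0L) stop("no token reaches min_count")
  # count-descending order (required by the Huffman build); lexicographic
  # tie-break keeps the ordering deterministic across platforms
  ord <- order(-as.integer(tab), names(tab))
  vocab_tokens <- names(tab)[ord]
  counts <- as.numeric(tab)[ord]
  vocab <- stats::setNames(seq_along(vocab_tokens), vocab_tokens)

  docs_ids <- lapply(corpus, function(d) {
    ids <- vocab[d]
    as.integer(ids[!is.na(ids)]) - 1L
  })
  docs_ids <- docs_ids[vapply(docs_ids, length, 1L) > 0L]
  if (length(docs_ids) == 0L) stop("no document survives vocabulary filtering")

  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
  syn0 <- cpp_sg_hs_train(docs_ids, counts, config$vector_size,
                          config$window, config$epochs,
                          config$alpha, config$min_alpha)
  vectors <- t(syn0)
  rownames(vectors) <- vocab_tokens
  structure(list(vectors = vectors, vocab = vocab,
                 dim = config$vector_size,
                 zero_tokens = as.character(zero_tokens),
                 config = config),
            class = "embedding_model")
}

#' Look up a token's vector
#'
#' In-vocabulary tokens return their trained vector; the pad symbol and any
#' out-of-vocabulary token return the all-zeros vector.
#'
#' @param model An [train_embedding()] model.
#' @param token A single token string.
#' @return Numeric vector of length `model$dim`.
#' @export
lookup <- function(model, token) {
  stopifnot(inherits(model, "embedding_model"), length(token) == 1L)
  if (token %in% model$zero_tokens) return(numeric(model$dim))
  i <- model$vocab[token]
  if (is.na(i)) numeric(model$dim) else as.numeric(model$vectors[i, ])
}

#' Embed a token grid as a channels-first array
#'
#' Cell-wise application of [lookup()]: element `m` of the vector of the
#' token at row `j`, column `k` becomes `values[m, j, k]`, so embedding
#' dimensions act as image channels. Pad and out-of-vocabulary cells carry
#' all-zero channel columns.
#'
#' @param grid A [format_grid()] result.
#' @param model An [train_embedding()] model.
#' @return An object of class `embedded_grid`: `values` (D x H x W array)
#'   and `grid` (the source `token_grid`).
#' @export
embed_grid <- function(grid, model) {
  stopifnot(inherits(grid, "token_grid"), inherits(model, "embedding_model"))
  vals <- embed_cells(as.vector(grid$tokens), model)     # D x (H*W), column-major cells
  values <- array(vals, dim = c(model$dim, grid$h, grid$w))
  structure(list(values = values, grid = grid), class = "embedded_grid")
}

# token vector -> D x n matrix of embeddings (zeros for pad/OOV)
embed_cells <- function(tokens, model) {
  idx <- model$vocab[tokens]
  idx[tokens %in% model$zero_tokens] <- NA_integer_
  out <- matrix(0, nrow = model$dim, ncol = length(tokens))
  hit <- !is.na(idx)
  if (any(hit)) out[, hit] <- t(model$vectors[idx[hit], , drop = FALSE])
  out
}

#' Embed a token sequence for the 1-D CNN baseline
#'
#' Pads (or truncates) the raw token sequence to a fixed length and embeds
#' each position, yielding a D x 1 x L array: the 1-D analogue of
#' [embed_grid()] that skips the 2-D formatting stage.
#'
#' @param tokens Character token vector.
#' @param model An [train_embedding()] model.
#' @param length_out Fixed sequence length (default 625).
#' @param pad_symbol Pad token (embeds to zero).
#' @return D x 1 x `length_out` numeric array.
#' @export
embed_sequence <- function(tokens, model, length_out = 625L, pad_symbol = "#") {
  tokens <- as.character(tokens)
  if (length(tokens) > length_out) tokens <- tokens[seq_len(length_out)]
  tokens <- c(tokens, rep(pad_symbol, length_out - length(tokens)))
  array(embed_cells(tokens, model), dim = c(model$dim, 1L, length_out))
}

#' Stack embedded grids into a batch array
#'
#' @param grids List of `embedded_grid` objects (or bare D x H x W arrays)
#'   sharing one shape.
#' @return D x H x W x N array.
#' @export
stack_grids <- function(grids) {
  arrs <- lapply(grids, function(g) if (inherits(g, "embedded_grid")) g$values else g)
  d <- dim(arrs[[1L]])
  stopifnot(length(d) == 3L)
  for (a in arrs) if (!identical(dim(a), d)) stop("all grids must share one shape")
  array(unlist(arrs, use.names = FALSE), dim = c(d, length(arrs)))
}

#' Save an embedding in word2vec text format
#'
#' Header line `"|V| D"`, then one line per token: the token followed by its
#' D vector elements, space-separated.
#'
#' @param model An `embedding_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_embedding <- function(model, path) {
  stopifnot(inherits(model, "embedding_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(model$vectors), model$dim), con)
  lines <- paste(rownames(model$vectors),
                 apply(model$vectors, 1L, function(v)
                   paste(formatC(v, format = "g", digits = 17), collapse = " ")))
  writeLines(lines, con)
  invisible(path)
}

#' Load a word2vec text-format embedding
#'
#' @param path File written by [save_embedding()] (or any tool emitting the
#'   same format).
#' @param zero_tokens Tokens forced to the zero vector at lookup.
#' @return An `embedding_model`.
#' @export
load_embedding <- function(path, zero_tokens = "#") {
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(trimws(lines[1L]), "[[:space:]]+")[[1L]])
  v <- hdr[1L]; d <- hdr[2L]
  if (length(lines) - 1L != v) stop("embedding file header disagrees with line count")
  parts <- strsplit(trimws(lines[-1L]), "[[:space:]]+")
  tokens <- vapply(parts, `[[`, "", 1L)
  vectors <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(d)))
  rownames(vectors) <- tokens
  structure(list(vectors = vectors,
                 vocab = stats::setNames(seq_along(tokens), tokens),
                 dim = d, zero_tokens = as.character(zero_tokens),
                 config = NULL),
            class = "embedding_model")
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf("<embedding_model |V| = %d, D = %d>\n", nrow(x$vectors), x$dim))
  invisible(x)
}
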