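#' Multinomial naive Bayes baseline over tf-idf features
#'
#' The traditional text-classification baseline: raw tokenized text (no
#' grid formatting, no padding, no embeddings) is turned into tf-idf
#' features — term counts scaled by the smoothed inverse document frequency
#' `idf(t) = log((1 + N) / (1 + df(t))) + 1`, then L2-normalised per
#' document — and classified with multinomial naive Bayes under Laplace
#' smoothing. The vocabulary is built on the training split; unseen test
#' tokens are ignored. Deterministic given a fixed input ordering.
#'
#' @param train,test `data.frame`s with `label` and `text` columns.
#' @param alpha Laplace smoothing for the class-conditional feature model.
#' @param rules [tokenizer_rules()] applied to both splits.
#' @return List with `report` (a [weighted_metrics()] result on `test`)
#'   and `preds` (0-based predicted class ids).
#' @export
baseline_nb <- function(train, test, alpha = 1.0,
                        rules = tokenizer_rules()) {
  if (nrow(train) == 0L || nrow(test) == 0L) stop("both splits must be non-empty")
  tr_toks <- tokenize_corpus(train$text, rules)
  te_toks <- tokenize_corpus(test$text, rules)
  vocab <- sort(unique(unlist(tr_toks, use.names = FALSE)))
  if (length(vocab) == 0L) stop("empty training vocabulary")

  dtm <- function(toks) {
    i <- integer(0); j <- integer(0); v <- integer(0)
    for (d in seq_along(toks)) {
      ids <- match(toks[[d]], vocab)
      ids <- ids[!is.na(ids)]
      if (!length(ids)) next
      tab <- table(ids)
      i <- c(i, rep.int(d, length(tab)))
      j <- c(j, as.integer(names(tab)))
      v <- c(v, as.integer(tab))
    }
    m <- matrix(0, nrow = length(toks), ncol = length(vocab))
    if (length(i)) m[cbind(i, j)] <- v
    m
  }
  x_tr <- dtm(tr_toks)
  n <- nrow(x_tr)
  df <- colSums(x_tr > 0)
  idf <- log((1 + n) / (1 + df)) + 1
  tfidf <- function(m) {
    m <- m * rep(idf, each = nrow(m))
    nrm <- sqrt(rowSums(m * m))
    nrm[nrm == 0] <- 1
    m / nrm
  }
  x_tr <- tfidf(x_tr)
  x_te <- tfidf(dtm(te_toks))

  y <- as.integer(train$label)
  classes <- sort(unique(y))
  feat <- t(vapply(classes,
                   function(cl) colSums(x_tr[y == cl, , drop = FALSE]),
                   numeric(ncol(x_tr))))
  log_prob <- log(feat + alpha) - log(rowSums(feat) + alpha * ncol(feat))
  log_prior <- log(vapply(classes, function(cl) mean(y == cl), 1))

  scores <- x_te %*% t(log_prob) + rep(log_prior, each = nrow(x_te))
  preds <- classes[max.col(scores, ties.method = "first")]
  cm <- confusion_matrix(preds, as.integer(test$label),
                         n_classes = max(classes, as.integer(test$label)) + 1L)
  list(report = weighted_metrics(cm), preds = preds)
}
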