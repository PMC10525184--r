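#' Tokenizer configuration
#'
#' Rules applied by [tokenize()]. The defaults implement conventional
#' bag-of-words preprocessing: case-fold, split on runs of whitespace, strip
#' leading/trailing punctuation from each token and drop anything that
#' becomes empty.
#'
#' @param lowercase Case-fold the text before splitting.
#' @param strip_punct Strip leading and trailing punctuation from each token.
#' @param split_regex Regular expression used to split the text into tokens.
#' @return An object of class `tokenizer_rules`.
#' @export
tokenizer_rules <- function(lowercase = TRUE, strip_punct = TRUE,
                            split_regex = "[[:space:]]+") {
  structure(list(lowercase = lowercase, strip_punct = strip_punct,
                 split_regex = split_regex),
            class = "tokenizer_rules")
}

#' Tokenize a document
#'
#' Deterministically converts one raw character string into an ordered token
#' sequence. Empty input yields an empty sequence.
#'
#' @param text A single character string (may be empty or `NA`).
#' @param rules A [tokenizer_rules()] object.
#' @return Character vector of tokens in document order.
#' @examples
#' tokenize("Follicular thyroid cancer.")
#' @export
tokenize <- function(text, rules = tokenizer_rules()) {
  stopifnot(inherits(rules, "tokenizer_rules"))
  if (length(text) != 1L) stop("tokenize() takes a single document; see lapply() for corpora")
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  if (rules$lowercase) text <- tolower(text)
  toks <- strsplit(trimws(text), rules$split_regex)[[1L]]
  if (rules$strip_punct)
    toks <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", toks)
  toks[nzchar(toks)]
}

#' Tokenize every document of a corpus
#'
#' @param texts Character vector of raw documents.
#' @param rules A [tokenizer_rules()] object.
#' @return List of token vectors, one per document.
#' @export
tokenize_corpus <- function(texts, rules = tokenizer_rules()) {
  lapply(as.character(texts), tokenize, rules = rules)
}
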