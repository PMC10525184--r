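#' Arrange a token sequence on a fixed 2-D grid
#'
#' Fills an `H x W` grid with tokens in row-major (reading) order: left to
#' right, top to bottom. Remaining cells hold the pad symbol and are flagged
#' in the pad mask. Sequences longer than `H * W` are truncated with a
#' warning, so the fixed-input contract of the downstream CNN always holds.
#' The pad symbol is injected here, after tokenization, and never passes
#' through the tokenizer.
#'
#' @param tokens Character vector of tokens (possibly empty).
#' @param h,w Grid height and width; defaults give the 25 x 25 = 625-slot
#'   layout sized to hold documents of up to 600 tokens.
#' @param pad_symbol Token written into unused cells (default `"#"`).
#' @return An object of class `token_grid` with elements `tokens` (H x W
#'   character matrix), `pad_mask` (H x W logical matrix, `TRUE` = pad),
#'   `h`, `w`, `pad_symbol` and `n_tokens` (number of non-pad cells).
#' @examples
#' g <- format_grid(c("a", "b", "c"), h = 2, w = 2)
#' g$tokens
#' @export
format_grid <- function(tokens, h = 25L, w = 25L, pad_symbol = "#") {
  h <- as.integer(h); w <- as.integer(w)
  if (is.na(h) || is.na(w) || h < 1L || w < 1L)
    stop("grid dimensions must be at least 1 x 1")
  stopifnot(is.character(pad_symbol), length(pad_symbol) == 1L, nzchar(pad_symbol))
  tokens <- as.character(tokens)
  ncell <- h * w
  if (length(tokens) > ncell) {
    warning(sprintf("document has %d tokens; truncating to the %d grid cells",
                    length(tokens), ncell))
    tokens <- tokens[seq_len(ncell)]
  }
  n <- length(tokens)
  cells <- c(tokens, rep(pad_symbol, ncell - n))
  structure(list(
    tokens = matrix(cells, nrow = h, ncol = w, byrow = TRUE),
    pad_mask = matrix(seq_len(ncell) > n, nrow = h, ncol = w, byrow = TRUE),
    h = h, w = w, pad_symbol = pad_symbol, n_tokens = n
  ), class = "token_grid")
}

#' Read a grid's cells back in row-major order
#'
#' @param grid A [format_grid()] result.
#' @param drop_pads Drop pad cells, leaving the original token sequence.
#' @return Character vector of cell contents.
#' @export
grid_tokens <- function(grid, drop_pads = TRUE) {
  stopifnot(inherits(grid, "token_grid"))
  toks <- as.vector(t(grid$tokens))
  if (drop_pads) toks[!as.vector(t(grid$pad_mask))] else toks
}

#' @export
print.token_grid <- function(x, ...) {
  cat(sprintf("<token_grid %d x %d, %d tokens, %d pads ('%s')>\n",
              x$h, x$w, x$n_tokens, x$h * x$w - x$n_tokens, x$pad_symbol))
  invisible(x)
}
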