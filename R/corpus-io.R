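#' Read a labeled corpus
#'
#' Reads a document corpus with one record per document. CSV/TSV files must
#' carry columns `id`, `label`, `text`; `label` is an integer class id in
#' `0..C-1` (may be missing for inference-only corpora). The `lines` format
#' reads one unlabeled document per line.
#'
#' @param path File to read.
#' @param format One of `"csv"`, `"tsv"`, `"lines"`; defaults to the file
#'   extension.
#' @return A `data.frame` with columns `id` (character), `label` (integer or
#'   `NA`) and `text` (character).
#' @export
read_corpus <- function(path, format = c("auto", "csv", "tsv", "lines")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "lines",
                     stop("cannot infer corpus format from extension '", ext, "'"))
  }
  if (format == "lines") {
    txt <- readLines(path, warn = FALSE)
    return(data.frame(id = sprintf("doc%05d", seq_along(txt)),
                      label = NA_integer_, text = txt,
                      stringsAsFactors = FALSE))
  }
  dt <- data.table::fread(path, sep = if (format == "csv") "," else "\t",
                          colClasses = list(character = "text"),
                          data.table = FALSE, showProgress = FALSE)
  need <- c("id", "label", "text")
  if (!all(need %in% names(dt)))
    stop("corpus file must have columns id, label, text")
  data.frame(id = as.character(dt$id),
             label = suppressWarnings(as.integer(dt$label)),
             text = as.character(dt$text),
             stringsAsFactors = FALSE)
}

#' Write a labeled corpus as CSV/TSV
#'
#' @param documents `data.frame` with columns `id`, `label`, `text`.
#' @param path Output file; `.tsv` extension selects tab separation.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(documents, path) {
  stopifnot(all(c("id", "label", "text") %in% names(documents)))
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  data.table::fwrite(documents[, c("id", "label", "text")], path, sep = sep)
  invisible(path)
}
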