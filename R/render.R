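#' Convert a class activation map to an 8-bit raster
#'
#' Maps scores in `[0, 1]` monotonically to intensities `0..255` (dark =
#' low attention, bright = high attention), optionally upscaled by an
#' integer factor. Exposed separately from [render_heatmap()] so the
#' score-to-intensity mapping is testable without decoding an image file.
#'
#' @param cam A [compute_gradcam()] result.
#' @param scale Integer cell-to-pixel upscale factor.
#' @return Integer matrix of intensities in `0..255`.
#' @export
cam_raster <- function(cam, scale = 1L) {
  stopifnot(inherits(cam, "class_activation_map"))
  scale <- as.integer(scale)
  m <- round(cam$grid_scores * 255)
  if (scale > 1L)
    m <- m[rep(seq_len(nrow(m)), each = scale),
           rep(seq_len(ncol(m)), each = scale), drop = FALSE]
  storage.mode(m) <- "integer"
  m
}

#' Render a class activation map as an image file
#'
#' Writes a grayscale heatmap whose pixel intensity is monotone in the
#' attention score (bright = high attention). PNG output is used when the
#' R build provides a png device; otherwise (or when `path` ends in
#' `.pgm`) a plain-text portable graymap is written.
#'
#' @param cam A [compute_gradcam()] result.
#' @param path Output file (`.png` or `.pgm`).
#' @param scale Integer cell-to-pixel upscale factor (default 16).
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(cam, path, scale = 16L) {
  ras <- cam_raster(cam, scale)
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm" || !isTRUE(capabilities("png"))) {
    if (ext != "pgm")
      warning("png device unavailable; writing portable graymap instead")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(ras), nrow(ras)), "255"), con)
    write(t(ras), con, ncolumns = ncol(ras))
    return(invisible(path))
  }
  grDevices::png(path, width = ncol(ras), height = nrow(ras))
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  graphics::image(t(ras)[, rev(seq_len(nrow(ras))), drop = FALSE],
                  col = grDevices::gray(0:255 / 255),
                  breaks = seq(-0.5, 255.5, by = 1),
                  axes = FALSE, useRaster = TRUE)
  invisible(path)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render highlighted document text as HTML
#'
#' Reconstructs the document in reading order (pads omitted) and wraps
#' every token whose attention score reaches the threshold in highlight
#' markup whose opacity is proportional to the score.
#'
#' @param attr A [attribute_tokens()] result.
#' @param threshold Minimum score for highlighting; a value in `[0, 1]`,
#'   or a string like `"q90"` for a quantile of the non-pad scores.
#' @param path Optional output file; when given, a standalone HTML document
#'   is written there.
#' @param title Heading shown in the document.
#' @return The HTML string, invisibly.
#' @export
render_highlight <- function(attr, threshold = 0.5, path = NULL,
                             title = "Token attribution") {
  stopifnot(inherits(attr, "token_attribution"))
  toks <- attr[!attr$is_pad, , drop = FALSE]
  if (is.character(threshold)) {
    q <- as.numeric(sub("^q", "", threshold)) / 100
    threshold <- if (nrow(toks)) stats::quantile(toks$score, q, names = FALSE) else 1
  }
  spans <- ifelse(
    toks$score >= threshold,
    sprintf('<span class="hl" style="background-color: rgba(255, 87, 34, %.3f)">%s</span>',
            pmin(pmax(toks$score, 0), 1), html_escape(toks$token)),
    html_escape(toks$token))
  body <- paste(spans, collapse = " ")
  html <- paste0(
    "<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\">",
    "<title>", html_escape(title), "</title>",
    "<style>body{font-family:sans-serif;max-width:60em;margin:2em auto;",
    "line-height:1.7}.hl{border-radius:3px;padding:0 2px}</style>",
    "</head><body><h3>", html_escape(title), "</h3><p>", body,
    "</p></body></html>\n")
  if (!is.null(path)) writeLines(html, path)
  invisible(html)
}

#' Write a token attribution as a JSON sidecar
#'
#' One record per grid cell: token, row, col, score, is_pad.
#'
#' @param attr A [attribute_tokens()] result.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_attribution_json <- function(attr, path) {
  stopifnot(inherits(attr, "token_attribution"))
  jsonlite::write_json(
    list(target_class = attr(attr, "target_class"),
         cells = as.data.frame(attr)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
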