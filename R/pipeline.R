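#' Default end-to-end run configuration
#'
#' A plain nested list mirroring the settings tables of the method: grid
#' geometry, embedding, model, training and Grad-CAM parameters, plus
#' output locations. Saved/loaded as JSON. Any subset of fields may be
#' overridden; missing fields take these defaults.
#'
#' @param corpus_path CSV/TSV corpus to load (`NULL` means: generate a
#'   synthetic corpus from `synth`).
#' @param out_dir Output directory for all artifacts.
#' @param seed Master seed for the run.
#' @return Nested configuration list.
#' @export
default_run_config <- function(corpus_path = NULL, out_dir = "textcam_run",
                               seed = 1L) {
  list(
    corpus_path = corpus_path,
    out_dir = out_dir,
    seed = as.integer(seed),
    grid = list(h = 25L, w = 25L, pad_symbol = "#"),
    synth = list(n_classes = 5L, docs_per_class = 100L,
                 keywords_per_class = 20L, keyword_rate = 0.3,
                 noise_vocab_size = 500L, doc_length = c(30L, 600L)),
    embed = list(vector_size = 100L, window = 100L, min_count = 1L,
                 epochs = 5L),
    model = list(backbone = "resnet18", pretrained = FALSE,
                 fine_tune_io = TRUE, base_width = 64L),
    train = list(learning_rate = 0.1, weight_decay = 5e-4,
                 batch_size = 128L, epochs = 25L, momentum = 0.9,
                 val_fraction = 0.2),
    cam = list(target_layer = NULL, upsample = "bilinear"),
    explain_ids = character(0)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a JSON run configuration
#'
#' @param path JSON file with any subset of the [default_run_config()]
#'   fields.
#' @return Complete configuration list.
#' @export
read_run_config <- function(path) {
  merge_config(default_run_config(),
               jsonlite::read_json(path, simplifyVector = TRUE))
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

run_stage <- function(stage, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
  stage_log(stage, "done in %.1fs", proc.time()[["elapsed"]] - t0)
  res
}

#' Run the full pipeline
#'
#' Executes preprocess -> embed -> train -> evaluate -> explain and writes
#' the artifacts to `config$out_dir`: the embedding in word2vec text
#' format (`embedding.txt`), the best-validation checkpoint
#' (`checkpoint.rds`), validation metrics (`metrics.json`, `metrics.csv`),
#' the per-iteration/per-epoch training log (`history.csv`), and, for each
#' requested document id, a heatmap, highlighted HTML and a JSON sidecar
#' under `cam/`.
#'
#' @param config A configuration list (see [default_run_config()]) or path
#'   to a JSON config file.
#' @return Invisibly, a list with the trained model, metrics report,
#'   history, corpus and artifact paths.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  config <- merge_config(default_run_config(), config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  corpus <- run_stage("corpus", {
    if (!is.null(config$corpus_path)) {
      docs <- read_corpus(config$corpus_path)
      truth <- NULL
      list(documents = docs, keyword_positions = truth)
    } else {
      sy <- config$synth
      generate_corpus(synthetic_spec(
        n_classes = sy$n_classes, docs_per_class = sy$docs_per_class,
        keywords_per_class = sy$keywords_per_class,
        keyword_rate = sy$keyword_rate,
        noise_vocab_size = sy$noise_vocab_size,
        doc_length = sy$doc_length, seed = config$seed,
        grid_cells = config$grid$h * config$grid$w))
    }
  })
  docs <- corpus$documents
  if (any(is.na(docs$label))) stop("pipeline requires a fully labeled corpus")

  split <- split_dataset(docs, config$train$val_fraction, seed = config$seed)
  stage_log("preprocess", "%d train / %d validation documents",
            nrow(split$train), nrow(split$val))

  toks <- run_stage("preprocess", {
    all <- tokenize_corpus(docs$text)
    names(all) <- docs$id
    all
  })
  grids <- lapply(toks, format_grid,
                  h = config$grid$h, w = config$grid$w,
                  pad_symbol = config$grid$pad_symbol)

  emb <- run_stage("embed", {
    e <- config$embed
    train_embedding(toks[split$train$id],
                    embed_config(vector_size = e$vector_size,
                                 window = e$window, min_count = e$min_count,
                                 epochs = e$epochs, seed = config$seed),
                    zero_tokens = config$grid$pad_symbol)
  })
  emb_path <- file.path(config$out_dir, "embedding.txt")
  save_embedding(emb, emb_path)

  embedded <- lapply(grids, embed_grid, model = emb)
  fit <- run_stage("train", {
    m <- config$model
    model <- build_model(in_channels = emb$dim,
                         n_classes = length(unique(docs$label)),
                         backbone = m$backbone, pretrained = m$pretrained,
                         fine_tune_io = m$fine_tune_io,
                         base_width = m$base_width,
                         grid_h = config$grid$h, grid_w = config$grid$w,
                         seed = config$seed)
    tr <- config$train
    train_classifier(model,
                     stack_grids(embedded[split$train$id]),
                     split$train$label,
                     train_config(learning_rate = tr$learning_rate,
                                  weight_decay = tr$weight_decay,
                                  batch_size = tr$batch_size,
                                  epochs = tr$epochs,
                                  momentum = tr$momentum,
                                  val_fraction = tr$val_fraction,
                                  seed = config$seed),
                     x_val = stack_grids(embedded[split$val$id]),
                     y_val = split$val$label,
                     verbose = TRUE)
  })
  ckpt_path <- file.path(config$out_dir, "checkpoint.rds")
  save_checkpoint(fit$model, ckpt_path)
  hist_path <- file.path(config$out_dir, "history.csv")
  data.table::fwrite(merge(fit$history$iteration, fit$history$epoch,
                           by = "epoch", suffixes = c("", "_epoch")),
                     hist_path)

  report <- run_stage("evaluate", {
    pr <- predict(fit$model, stack_grids(embedded[split$val$id]))
    weighted_metrics(confusion_matrix(pr$predicted_class, split$val$label,
                                      n_classes = fit$model$n_classes))
  })
  write_metrics(report,
                json_path = file.path(config$out_dir, "metrics.json"),
                csv_path = file.path(config$out_dir, "metrics.csv"))

  cam_paths <- run_stage("explain", {
    ids <- config$explain_ids
    if (length(ids) == 0L) list() else {
      cam_dir <- file.path(config$out_dir, "cam")
      dir.create(cam_dir, showWarnings = FALSE)
      img_ext <- if (isTRUE(capabilities("png"))) "png" else "pgm"
      out <- list()
      for (id in ids) {
        if (!id %in% docs$id) stop("explain id not in corpus: ", id)
        cam <- compute_gradcam(fit$model, embedded[[id]],
                               config = cam_config(
                                 target_layer = config$cam$target_layer,
                                 upsample = config$cam$upsample))
        at <- attribute_tokens(cam, grids[[id]])
        base <- file.path(cam_dir, paste0("doc_", id))
        render_heatmap(cam, paste0(base, ".", img_ext))
        render_highlight(at, threshold = "q80",
                         path = paste0(base, ".html"),
                         title = paste("Document", id))
        write_attribution_json(at, paste0(base, ".json"))
        out[[id]] <- paste0(base, c(paste0(".", img_ext), ".html", ".json"))
      }
      out
    }
  })

  invisible(list(model = fit$model, history = fit$history, report = report,
                 corpus = corpus, split = split, embedding = emb,
                 paths = list(embedding = emb_path, checkpoint = ckpt_path,
                              history = hist_path,
                              metrics_json = file.path(config$out_dir, "metrics.json"),
                              metrics_csv = file.path(config$out_dir, "metrics.csv"),
                              cam = cam_paths)))
}
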