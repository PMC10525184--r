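# ResNet-18 over small text-image grids, and the 1-D LeNet-style baseline.

# Append one basic residual block (two 3x3 conv-bn pairs plus identity or
# 1x1-conv shortcut). Returns the net; the block's output node is
# "<prefix>_out".
add_basic_block <- function(net, prefix, in_name, out_ch, stride) {
  in_ch <- net$shapes[[in_name]][1L]
  n <- function(s) paste0(prefix, "_", s)
  net <- net_add(net, n("conv1"), "conv", in_name,
                 filters = out_ch, kernel = c(3L, 3L),
                 stride = c(stride, stride), pad = c(1L, 1L))
  net <- net_add(net, n("bn1"), "bn", n("conv1"))
  net <- net_add(net, n("relu1"), "relu", n("bn1"))
  net <- net_add(net, n("conv2"), "conv", n("relu1"),
                 filters = out_ch, kernel = c(3L, 3L),
                 stride = c(1L, 1L), pad = c(1L, 1L))
  net <- net_add(net, n("bn2"), "bn", n("conv2"))
  shortcut <- in_name
  if (stride != 1L || in_ch != out_ch) {
    net <- net_add(net, n("down_conv"), "conv", in_name,
                   filters = out_ch, kernel = c(1L, 1L),
                   stride = c(stride, stride), pad = c(0L, 0L))
    net <- net_add(net, n("down_bn"), "bn", n("down_conv"))
    shortcut <- n("down_bn")
  }
  net <- net_add(net, n("add"), "add", c(n("bn2"), shortcut))
  net_add(net, n("out"), "relu", n("add"))
}

# ResNet-18 graph: 7x7/2 stem, 3x3/2 max pool, four stages of two basic
# blocks with channel widths base_width * (1, 2, 4, 8), global average
# pooling and a linear head. For 25x25 inputs the stage outputs have
# spatial sizes 7x7, 4x4, 2x2 and 1x1.
build_resnet18_net <- function(in_channels, n_classes, base_width = 64L,
                               in_h = 25L, in_w = 25L) {
  w <- as.integer(base_width)
  net <- net_new(c(in_channels, in_h, in_w))
  net <- net_add(net, "conv1", "conv", "input",
                 filters = w, kernel = c(7L, 7L),
                 stride = c(2L, 2L), pad = c(3L, 3L))
  net <- net_add(net, "bn1", "bn", "conv1")
  net <- net_add(net, "relu1", "relu", "bn1")
  net <- net_add(net, "pool1", "maxpool", "relu1",
                 kernel = c(3L, 3L), stride = c(2L, 2L), pad = c(1L, 1L))
  in_name <- "pool1"
  widths <- w * c(1L, 2L, 4L, 8L)
  for (s in 1:4) {
    for (b in 1:2) {
      prefix <- sprintf("l%db%d", s, b)
      stride <- if (s > 1L && b == 1L) 2L else 1L
      net <- add_basic_block(net, prefix, in_name, widths[s], stride)
      in_name <- paste0(prefix, "_out")
    }
  }
  net <- net_add(net, "gap", "gap", in_name)
  net <- net_add(net, "fc", "linear", "gap", units = as.integer(n_classes))
  attr(net, "stages") <- c(stem = "pool1", layer1 = "l1b2_out",
                           layer2 = "l2b2_out", layer3 = "l3b2_out",
                           layer4 = "l4b2_out")
  net
}

# LeNet translated to one dimension: the embedded token sequence enters as a
# (D x 1 x L) "image"; two conv(1x5)+maxpool(1x2) blocks with 6 then 16
# filters, then 120- and 84-unit dense layers. Layer sizes are configurable
# since the translation from the 2-D original is not canonical.
build_cnn1d_net <- function(in_channels, n_classes, seq_len = 625L,
                            conv_channels = c(6L, 16L),
                            fc_units = c(120L, 84L)) {
  net <- net_new(c(in_channels, 1L, seq_len))
  net <- net_add(net, "conv1", "conv", "input",
                 filters = conv_channels[1L], kernel = c(1L, 5L),
                 stride = c(1L, 1L), pad = c(0L, 0L))
  net <- net_add(net, "relu1", "relu", "conv1")
  net <- net_add(net, "pool1", "maxpool", "relu1",
                 kernel = c(1L, 2L), stride = c(1L, 2L), pad = c(0L, 0L))
  net <- net_add(net, "conv2", "conv", "pool1",
                 filters = conv_channels[2L], kernel = c(1L, 5L),
                 stride = c(1L, 1L), pad = c(0L, 0L))
  net <- net_add(net, "relu2", "relu", "conv2")
  net <- net_add(net, "pool2", "maxpool", "relu2",
                 kernel = c(1L, 2L), stride = c(1L, 2L), pad = c(0L, 0L))
  net <- net_add(net, "flat", "flatten", "pool2")
  net <- net_add(net, "fc1", "linear", "flat", units = fc_units[1L])
  net <- net_add(net, "fc1_relu", "relu", "fc1")
  net <- net_add(net, "fc2", "linear", "fc1_relu", units = fc_units[2L])
  net <- net_add(net, "fc2_relu", "relu", "fc2")
  net <- net_add(net, "fc", "linear", "fc2_relu", units = as.integer(n_classes))
  attr(net, "stages") <- c(conv1 = "pool1", conv2 = "pool2")
  net
}

.tcam_env <- new.env(parent = emptyenv())

#' Synthetic pretraining stand-in for publicly distributed backbone weights
#'
#' Transfer learning in this package reuses the interior weights of a donor
#' backbone. The original recipe initialises them from an ImageNet-trained
#' checkpoint; such weights cannot be bundled here, so this function builds a
#' SYNTHETIC donor instead: a 3-channel ResNet-18 trained on a generated
#' pretext corpus (keyword-planted token grids embedded in 3 dimensions,
#' mirroring the RGB channel count of natural-image pretraining). The donor
#' is deterministic under `seed` and cached per configuration for the
#' session.
#'
#' @param base_width Stem width of the backbone (64 for the standard
#'   ResNet-18; smaller values give proportionally narrower desk-scale
#'   models).
#' @param seed Integer seed controlling the pretext corpus, embedding and
#'   training.
#' @param epochs Pretraining epochs; `0` returns the freshly initialised
#'   donor (useful where only the surgery mechanics matter).
#' @param docs_per_class,n_classes Size and label count of the pretext
#'   corpus.
#' @param grid_h,grid_w Spatial size of the pretext grids.
#' @return A `tcam_model` with `in_channels = 3`.
#' @export
synthetic_pretrained_backbone <- function(base_width = 64L, seed = 42L,
                                          epochs = 2L, docs_per_class = 60L,
                                          n_classes = 10L,
                                          grid_h = 25L, grid_w = 25L) {
  key <- paste("resnet18", base_width, seed, epochs, docs_per_class,
               n_classes, grid_h, grid_w, sep = "|")
  if (!is.null(.tcam_env[[key]])) return(.tcam_env[[key]])
  donor <- build_model(in_channels = 3L, n_classes = n_classes,
                       backbone = "resnet18", pretrained = FALSE,
                       base_width = base_width, grid_h = grid_h,
                       grid_w = grid_w, seed = seed)
  if (epochs > 0L) {
    spec <- synthetic_spec(n_classes = n_classes,
                           docs_per_class = docs_per_class,
                           keywords_per_class = 10L, keyword_rate = 0.3,
                           noise_vocab_size = 300L,
                           doc_length = c(30L, min(600L, grid_h * grid_w)),
                           seed = seed + 1L)
    corp <- generate_corpus(spec)
    toks <- tokenize_corpus(corp$documents$text)
    emb <- train_embedding(toks, embed_config(vector_size = 3L, window = 5L,
                                              epochs = 2L, seed = seed + 2L))
    grids <- lapply(toks, function(tk)
      embed_grid(format_grid(tk, grid_h, grid_w), emb))
    x <- stack_grids(grids)
    y <- corp$documents$label
    donor <- train_classifier(donor, x, y,
                              train_config(epochs = epochs, seed = seed + 3L,
                                           batch_size = 64L,
                                           learning_rate = 0.05),
                              verbose = FALSE)$model
  }
  donor$synthetic_pretrained <- TRUE
  .tcam_env[[key]] <- donor
  donor
}

#' Build a classifier
#'
#' Constructs either the channel-adapted ResNet-18 over `H x W` embedded
#' grids or the LeNet-style 1-D CNN over length-`seq_len` embedded token
#' sequences.
#'
#' With `pretrained = TRUE` the backbone undergoes transfer surgery: all
#' interior weights are copied bit-exactly from a donor backbone (see
#' [synthetic_pretrained_backbone()]) and only the replaced input
#' convolution and output head are freshly He-initialised. The degenerate
#' combination `pretrained = TRUE, fine_tune_io = FALSE` with
#' `in_channels != 3` reproduces, for ablation purposes only, the
#' shape-mismatched mode in which 3-channel donor weights meet
#' multi-channel text input: the donor's input convolution is kept, the
#' forward pass uses only the first 3 input channels, the head is replaced
#' for shape alone, and the model is flagged `mismatched` (it is
#' evaluation-only; [train_classifier()] refuses it).
#'
#' @param in_channels Input channel count (= embedding dimension D).
#' @param n_classes Number of classes (>= 2).
#' @param backbone `"resnet18"` or `"cnn1d"`.
#' @param pretrained Start from donor interior weights.
#' @param fine_tune_io Replace the input convolution and output head.
#' @param base_width ResNet stem width (64 = standard ResNet-18).
#' @param grid_h,grid_w Grid size expected by the resnet backbone.
#' @param seq_len Sequence length expected by the cnn1d backbone.
#' @param seed Seed for the fresh weight initialisation.
#' @param donor Optional explicit donor `tcam_model`; defaults to the cached
#'   synthetic pretrained backbone.
#' @param pretrain_opts List of arguments forwarded to
#'   [synthetic_pretrained_backbone()] when `donor` is not given.
#' @return A `tcam_model`.
#' @export
build_model <- function(in_channels, n_classes,
                        backbone = c("resnet18", "cnn1d"),
                        pretrained = FALSE, fine_tune_io = TRUE,
                        base_width = 64L, grid_h = 25L, grid_w = 25L,
                        seq_len = 625L, seed = NULL, donor = NULL,
                        pretrain_opts = list()) {
  backbone <- match.arg(backbone)
  in_channels <- as.integer(in_channels)
  n_classes <- as.integer(n_classes)
  if (in_channels < 1L) stop("in_channels must be >= 1")
  if (n_classes < 2L) stop("n_classes must be >= 2")

  if (backbone == "cnn1d") {
    net <- build_cnn1d_net(in_channels, n_classes, seq_len = seq_len)
    ini <- net_init_params(net, seed = seed)
    return(structure(list(net = net, params = ini$params, state = ini$state,
                          backbone = backbone, in_channels = in_channels,
                          n_classes = n_classes, base_width = NA_integer_,
                          pretrained = FALSE, fine_tune_io = TRUE,
                          mismatched = FALSE, replaced = character(0),
                          input_slice = NULL),
                     class = "tcam_model"))
  }

  if (!pretrained) {
    net <- build_resnet18_net(in_channels, n_classes, base_width,
                              grid_h, grid_w)
    ini <- net_init_params(net, seed = seed)
    return(structure(list(net = net, params = ini$params, state = ini$state,
                          backbone = backbone, in_channels = in_channels,
                          n_classes = n_classes, base_width = as.integer(base_width),
                          pretrained = FALSE, fine_tune_io = fine_tune_io,
                          mismatched = FALSE, replaced = character(0),
                          input_slice = NULL),
                     class = "tcam_model"))
  }

  if (is.null(donor))
    donor <- do.call(synthetic_pretrained_backbone,
                     c(list(base_width = base_width), pretrain_opts))
  if (!identical(donor$backbone, "resnet18") ||
      !identical(donor$base_width, as.integer(base_width)))
    stop("donor backbone does not match the requested configuration")

  if (fine_tune_io) {
    net <- build_resnet18_net(in_channels, n_classes, base_width,
                              grid_h, grid_w)
    ini <- net_init_params(net, seed = seed)
    params <- donor$params
    state <- donor$state
    replaced <- c("conv1", "fc")
    for (nm in replaced) params[[nm]] <- ini$params[[nm]]
    structure(list(net = net, params = params, state = state,
                   backbone = backbone, in_channels = in_channels,
                   n_classes = n_classes, base_width = as.integer(base_width),
                   pretrained = TRUE, fine_tune_io = TRUE,
                   mismatched = FALSE, replaced = replaced,
                   input_slice = NULL),
              class = "tcam_model")
  } else {
    mismatched <- in_channels != donor$in_channels
    if (mismatched)
      warning(sprintf(paste0("pretrained = TRUE with fine_tune_io = FALSE and ",
                             "in_channels = %d: keeping the %d-channel donor input ",
                             "convolution; forward passes use only the first %d ",
                             "input channels (deliberately mismatched ablation mode)"),
                      in_channels, donor$in_channels, donor$in_channels))
    net <- build_resnet18_net(donor$in_channels, n_classes, base_width,
                              grid_h, grid_w)
    ini <- net_init_params(net, seed = seed)
    params <- donor$params
    params$fc <- ini$params$fc   # shape-forced head replacement, untrained
    structure(list(net = net, params = params, state = donor$state,
                   backbone = backbone, in_channels = in_channels,
                   n_classes = n_classes, base_width = as.integer(base_width),
                   pretrained = TRUE, fine_tune_io = FALSE,
                   mismatched = mismatched, replaced = "fc",
                   input_slice = if (mismatched) seq.int(1L, donor$in_channels) else NULL),
              class = "tcam_model")
  }
}

#' Names of parameter tensors untouched by transfer surgery
#'
#' @param model A `tcam_model`.
#' @return Character vector of node names whose parameters are interior
#'   (i.e. not in `model$replaced`).
#' @export
interior_param_names <- function(model) {
  setdiff(names(model$params), model$replaced)
}

#' Fingerprint a set of parameter tensors
#'
#' MD5 digest of the serialised parameters of the named nodes, in sorted
#' name order. Used to verify that transfer surgery preserves interior
#' pretrained weights bit-exactly.
#'
#' @param params A model's `params` list (node name -> tensors).
#' @param nodes Node names to include (default: all).
#' @return Character scalar (md5 hex digest).
#' @export
param_fingerprint <- function(params, nodes = names(params)) {
  nodes <- sort(nodes)
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(params[nodes], tf, compress = FALSE)
  unname(tools::md5sum(tf))
}

#' @export
print.tcam_model <- function(x, ...) {
  npar <- sum(vapply(unlist(x$params, recursive = FALSE), length, 1L))
  cat(sprintf("<tcam_model %s: %d -> %d classes, %s params%s%s>\n",
              x$backbone, x$in_channels, x$n_classes,
              format(npar, big.mark = ","),
              if (x$pretrained) ", pretrained" else "",
              if (x$mismatched) ", MISMATCHED (ablation mode)" else ""))
  invisible(x)
}
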