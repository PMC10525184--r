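#' Training configuration
#'
#' Defaults follow the reference recipe for the text-as-image classifier:
#' SGD with learning rate 0.1, weight decay 5e-4, batch size 128,
#' cross-entropy loss, 25 epochs, and one fifth of the training documents
#' held out as the validation set. Momentum (0.9) and the constant learning
#' rate are conventional choices where the recipe is silent.
#'
#' @param learning_rate SGD learning rate.
#' @param weight_decay L2 penalty coefficient.
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @param momentum SGD momentum.
#' @param val_fraction Fraction held out for validation when no explicit
#'   validation set is passed; must lie in (0, 1).
#' @param seed Integer seed; makes shuffling and initialisation-free runs
#'   bit-reproducible.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.1, weight_decay = 5e-4,
                         batch_size = 128L, epochs = 25L, momentum = 0.9,
                         val_fraction = 0.2, seed = NULL) {
  if (!(val_fraction > 0 && val_fraction < 1))
    stop("val_fraction must lie strictly between 0 and 1")
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), momentum = momentum,
                 val_fraction = val_fraction, seed = seed,
                 loss = "cross-entropy", optimizer = "sgd"),
            class = "train_config")
}

#' Stratified train/validation split
#'
#' Splits a labeled corpus into disjoint, exhaustive train and validation
#' sets, stratified by class (each class contributes `round(n_c *
#' val_fraction)` validation documents, at least 0 and at most `n_c - 1`),
#' deterministically under `seed`.
#'
#' @param documents `data.frame` with a `label` column (integer class ids).
#' @param val_fraction Validation fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with `train` and `val` data frames.
#' @export
split_dataset <- function(documents, val_fraction = 0.2, seed = NULL) {
  if (!(val_fraction > 0 && val_fraction < 1))
    stop("val_fraction must lie strictly between 0 and 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  lab <- documents$label
  if (any(is.na(lab))) stop("split_dataset() needs labels on every document")
  val_idx <- integer(0)
  for (cl in sort(unique(lab))) {
    rows <- which(lab == cl)
    n_val <- min(max(round(length(rows) * val_fraction), 0L), length(rows) - 1L)
    if (n_val > 0L) val_idx <- c(val_idx, sample(rows, n_val))
  }
  val_idx <- sort(val_idx)
  list(train = documents[setdiff(seq_len(nrow(documents)), val_idx), , drop = FALSE],
       val = documents[val_idx, , drop = FALSE])
}

model_forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  if (!is.null(model$input_slice))
    x <- x[model$input_slice, , , , drop = FALSE]
  net_forward(model$net, model$params, model$state, x,
              training = training, keep_cache = keep_cache)
}

sgd_step <- function(params, grads, velocity, lr, momentum, weight_decay) {
  for (nm in names(grads)) {
    for (pn in names(grads[[nm]])) {
      g <- grads[[nm]][[pn]] + weight_decay * params[[nm]][[pn]]
      v <- velocity[[nm]][[pn]]
      v <- if (is.null(v)) -lr * g else momentum * v - lr * g
      velocity[[nm]][[pn]] <- v
      params[[nm]][[pn]] <- params[[nm]][[pn]] + v
    }
  }
  list(params = params, velocity = velocity)
}

#' Train a classifier
#'
#' Mini-batch SGD with momentum and weight decay on softmax cross-entropy.
#' Records training loss/accuracy at every iteration and validation
#' loss/accuracy at every epoch, and retains the parameters of the epoch
#' with the best validation accuracy (the returned model carries that
#' checkpoint).
#'
#' @param model A [build_model()] classifier (not a mismatched ablation
#'   model).
#' @param x D x H x W x N array of embedded inputs (see [stack_grids()]).
#' @param y Integer class labels in `0..C-1`, length N.
#' @param config A [train_config()].
#' @param x_val,y_val Optional explicit validation inputs; when absent, a
#'   stratified `val_fraction` split of `(x, y)` is made internally.
#' @param verbose Print one line per epoch.
#' @return List with `model` (best-validation checkpoint), `history`
#'   (`$iteration` and `$epoch` data frames) and `best_epoch`.
#' @export
train_classifier <- function(model, x, y, config = train_config(),
                             x_val = NULL, y_val = NULL, verbose = TRUE) {
  stopifnot(inherits(model, "tcam_model"), inherits(config, "train_config"))
  if (model$mismatched)
    stop("the mismatched ablation mode is evaluation-only and cannot be trained")
  if (length(dim(x)) != 4L) stop("x must be a D x H x W x N array")
  y <- as.integer(y)
  n <- dim(x)[4L]
  if (n == 0L || length(y) != n) stop("x and y sizes disagree or are empty")
  if (any(is.na(y)) || any(y < 0L) || any(y >= model$n_classes))
    stop("labels must lie in 0..n_classes-1")
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))

  if (is.null(x_val)) {
    sp <- split_dataset(data.frame(label = y, row = seq_len(n)),
                        config$val_fraction)
    tr_rows <- sp$train$row
    va_rows <- sp$val$row
    x_val <- x[, , , va_rows, drop = FALSE]
    y_val <- y[va_rows]
    x <- x[, , , tr_rows, drop = FALSE]
    y <- y[tr_rows]
    n <- length(y)
  } else {
    y_val <- as.integer(y_val)
  }

  velocity <- list()
  it_hist <- list()
  ep_hist <- list()
  best <- list(acc = -Inf, params = model$params, state = model$state,
               epoch = 0L)
  iter <- 0L
  for (ep in seq_len(config$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    ep_losses <- numeric(0)
    for (s in starts) {
      idx <- perm[s:min(s + config$batch_size - 1L, n)]
      xb <- x[, , , idx, drop = FALSE]
      yb <- y[idx] + 1L
      fw <- model_forward(model, xb, training = TRUE, keep_cache = TRUE)
      model$state <- fw$state
      ce <- softmax_ce(fw$logits, yb)
      if (!is.finite(ce$loss))
        stop(sprintf("non-finite loss at epoch %d, iteration %d; try a lower learning rate",
                     ep, iter + 1L))
      bw <- net_backward(model$net, model$params, fw$caches, fw$values,
                         ce$dlogits)
      st <- sgd_step(model$params, bw$pgrads, velocity,
                     config$learning_rate, config$momentum,
                     config$weight_decay)
      model$params <- st$params
      velocity <- st$velocity
      iter <- iter + 1L
      acc <- mean(max.col(t(fw$logits)) == yb)
      it_hist[[iter]] <- data.frame(epoch = ep, iteration = iter,
                                    train_loss = ce$loss, train_acc = acc)
      ep_losses <- c(ep_losses, ce$loss)
    }
    vfw <- model_forward(model, x_val, training = FALSE)
    vce <- softmax_ce(vfw$logits, y_val + 1L)
    vacc <- mean(max.col(t(vfw$logits)) == y_val + 1L)
    ep_hist[[ep]] <- data.frame(epoch = ep, train_loss = mean(ep_losses),
                                val_loss = vce$loss, val_acc = vacc)
    if (vacc > best$acc)
      best <- list(acc = vacc, params = model$params, state = model$state,
                   epoch = ep)
    if (verbose)
      message(sprintf("epoch %d/%d  train loss %.4f  val acc %.3f%s",
                      ep, config$epochs, mean(ep_losses), vacc,
                      if (best$epoch == ep) "  *" else ""))
  }
  model$params <- best$params
  model$state <- best$state
  list(model = model,
       history = list(iteration = do.call(rbind, it_hist),
                      epoch = do.call(rbind, ep_hist)),
       best_epoch = best$epoch, best_val_acc = best$acc)
}

#' Predict classes for embedded inputs
#'
#' Runs the network in evaluation mode (batch-norm uses running statistics;
#' repeated calls on the same input are identical).
#'
#' @param object A `tcam_model`.
#' @param x An `embedded_grid`, a D x H x W array, or a D x H x W x N batch.
#' @param ... Unused.
#' @return An object of class `tcam_prediction`: `logits` (C x N),
#'   `probabilities` (C x N, columns sum to 1), `predicted_class` (length-N
#'   integer vector of 0-based class ids).
#' @export
predict.tcam_model <- function(object, x, ...) {
  if (inherits(x, "embedded_grid")) x <- x$values
  if (length(dim(x)) == 3L) x <- array(x, dim = c(dim(x), 1L))
  if (length(dim(x)) != 4L) stop("x must be D x H x W (x N)")
  expect_c <- if (is.null(object$input_slice)) object$in_channels else object$in_channels
  if (dim(x)[1L] != expect_c)
    stop(sprintf("input has %d channels; model expects %d", dim(x)[1L], expect_c))
  fw <- model_forward(object, x, training = FALSE)
  logits <- fw$logits
  sm <- softmax_ce(logits, rep(1L, ncol(logits)))  # labels irrelevant for probs
  structure(list(logits = logits, probabilities = sm$probs,
                 predicted_class = max.col(t(logits)) - 1L),
            class = "tcam_prediction")
}

#' @export
print.tcam_prediction <- function(x, ...) {
  cat(sprintf("<tcam_prediction: %d document(s), classes %s>\n",
              ncol(x$logits), paste(x$predicted_class, collapse = " ")))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the full model (graph, parameters, batch-norm
#' state and configuration flags).
#'
#' @param model A `tcam_model`.
#' @param path Checkpoint file (RDS).
#' @return `path` / the restored `tcam_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "tcam_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "tcam_model")) stop("not a tcam_model checkpoint")
  model
}
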