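#' Training configuration
#'
#' Defaults follow the reference training recipe: Adam with initial learning
#' rate 0.0005, categorical cross-entropy over annotated pixels, 200 epochs
#' of 600 iterations, and learning-rate decay by 0.5 after a validation-loss
#' plateau of 5 epochs. Batch size defaults to 4 for the u-net family and 16
#' for the dense-net family.
#'
#' @param epochs number of epochs.
#' @param iterations iterations (batches) per epoch.
#' @param batch_size patches per batch.
#' @param lr initial learning rate.
#' @param decay_factor multiplier applied on plateau.
#' @param patience epochs without strict validation-loss improvement that
#'   constitute a plateau.
#' @param n_val validation patches used for the per-epoch validation loss.
#' @return list of class `training_config`.
#' @export
training_config <- function(epochs = 200, iterations = 600, batch_size = 4,
                            lr = 5e-4, decay_factor = 0.5, patience = 5,
                            n_val = 32) {
  stopifnot(epochs >= 1, iterations >= 1, batch_size >= 1, lr > 0,
            decay_factor > 0, decay_factor <= 1, patience >= 1, n_val >= 1)
  structure(list(epochs = as.integer(epochs),
                 iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size), lr = lr,
                 decay_factor = decay_factor, patience = as.integer(patience),
                 n_val = as.integer(n_val)),
            class = "training_config")
}

#' Masked categorical cross-entropy
#'
#' Mean of `-log p(true class)` over annotated pixels only; pixels carrying
#' [unlabeled_value()] contribute nothing. Errors when the batch has no
#' annotated pixel (the caller should resample).
#'
#' @param probs H x W x K (or H x W x K x N) probability array.
#' @param labels H x W (or H x W x N) integer labels with
#'   [unlabeled_value()] for unannotated pixels.
#' @return scalar loss.
#' @export
masked_cross_entropy <- function(probs, labels) {
  d <- dim(probs)
  if (length(d) == 3) {
    dim(probs) <- c(d, 1L)
    d <- dim(probs)
  }
  if (is.matrix(labels)) dim(labels) <- c(dim(labels), 1L)
  stopifnot(all(dim(labels) == d[c(1, 2, 4)]))
  K <- d[3]
  P <- matrix(aperm(probs, c(1, 2, 4, 3)), ncol = K)
  lab <- as.vector(labels)
  ann <- lab != unlabeled_value()
  if (!any(ann)) stop("no annotated pixels in batch")
  p_true <- P[cbind(which(ann), lab[ann] + 1L)]
  -mean(log(pmax(p_true, 1e-12)))
}

#' Reduce-on-plateau learning-rate schedule
#'
#' A pure function of the validation-loss history: the rate is multiplied by
#' `factor` whenever the validation loss has gone `patience` consecutive
#' epochs without strict improvement over the best seen, after which the
#' plateau counter resets. Returns the learning rate in force after the last
#' recorded epoch.
#'
#' @param history data.frame with a `val_loss` column (one row per epoch),
#'   or a numeric vector of validation losses.
#' @param lr0 initial learning rate.
#' @param factor decay multiplier.
#' @param patience plateau length in epochs.
#' @return the current learning rate (scalar).
#' @export
plateau_scheduler <- function(history, lr0 = 5e-4, factor = 0.5,
                              patience = 5) {
  val <- if (is.data.frame(history)) history$val_loss else as.numeric(history)
  stopifnot(length(val) >= 1)
  lr_schedule(val, lr0, factor, patience)[length(val)]
}

# full learning-rate trajectory implied by a validation-loss sequence;
# element t is the rate in force after epoch t's validation pass
lr_schedule <- function(val, lr0, factor, patience) {
  lr <- lr0
  best <- Inf
  since <- 0L
  out <- numeric(length(val))
  for (t in seq_along(val)) {
    if (val[t] < best) {
      best <- val[t]
      since <- 0L
    } else {
      since <- since + 1L
      if (since >= patience) {
        lr <- lr * factor
        since <- 0L
      }
    }
    out[t] <- lr
  }
  out
}

adam_init <- function(params) {
  lapply(params, function(p) {
    if (is.null(p)) return(NULL)
    list(mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0)
  })
}

adam_step <- function(params, grads, state, lr, t, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(params)) {
    if (is.null(params[[i]]) || is.null(grads[[i]])) next
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * grads[[i]]$W
    s$vW <- beta2 * s$vW + (1 - beta2) * grads[[i]]$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * grads[[i]]$b
    s$vb <- beta2 * s$vb + (1 - beta2) * grads[[i]]$b^2
    params[[i]]$W <- params[[i]]$W - lr * (s$mW / bc1) /
      (sqrt(s$vW / bc2) + eps)
    params[[i]]$b <- params[[i]]$b - lr * (s$mb / bc1) /
      (sqrt(s$vb / bc2) + eps)
    state[[i]] <- s
  }
  list(params = params, state = state)
}

patches_to_batch <- function(patches) {
  h <- dim(patches[[1]]$pixels)[1]
  w <- dim(patches[[1]]$pixels)[2]
  n <- length(patches)
  x <- array(0, c(h, w, 3, n))
  y <- array(unlabeled_value(), c(h, w, n))
  for (i in seq_len(n)) {
    x[, , , i] <- normalize_pixels(patches[[i]]$pixels)
    y[, , i] <- patches[[i]]$labels
  }
  list(x = x, y = y)
}

# loss and logits gradient for one batch; gradient of the mean masked CE
# w.r.t. logits is (softmax - onehot) / n_annotated at annotated pixels
batch_loss_grad <- function(logits, labels) {
  d <- dim(logits)
  K <- d[3]
  P <- matrix(aperm(logits, c(1, 2, 4, 3)), ncol = K)
  P <- P - P[cbind(seq_len(nrow(P)), max.col(P, ties.method = "first"))]
  E <- exp(P)
  P <- E / rowSums(E)
  lab <- as.vector(labels)
  ann <- lab != unlabeled_value()
  n_ann <- sum(ann)
  if (n_ann == 0) stop("no annotated pixels in batch")
  idx <- cbind(which(ann), lab[ann] + 1L)
  loss <- -mean(log(pmax(P[idx], 1e-12)))
  G <- matrix(0, nrow(P), K)
  G[ann, ] <- P[ann, ] / n_ann
  G[idx] <- G[idx] - 1 / n_ann
  dlogits <- aperm(array(G, c(d[1], d[2], d[4], K)), c(1, 2, 4, 3))
  list(loss = loss, dlogits = dlogits, probs = P)
}

#' Train a segmentation network
#'
#' Runs `epochs x iterations` minibatches of sampled, augmented patches,
#' optimizing the masked categorical cross-entropy with Adam. After every
#' epoch the loss on a fixed validation patch set is computed, the plateau
#' schedule is applied, and the best-validation weights are checkpointed;
#' those weights are returned. Fully driven by R's RNG stream: seed the
#' session for exact reproducibility.
#'
#' @param model a `segnet` from [build_network()].
#' @param sampler function(n) returning n training patches (e.g. from
#'   [patch_sampler()] over training-partition cases only).
#' @param augment_fn function(patch) -> patch, e.g. [augmenter()]; `NULL`
#'   disables augmentation.
#' @param config a [training_config()].
#' @param val_sampler like `sampler` but over validation cases; when `NULL`,
#'   validation patches are drawn from `sampler`.
#' @param verbose print per-epoch progress.
#' @return list with `model` (best-validation weights) and `history`
#'   (data.frame: epoch, train_loss, val_loss, lr, val_macro_dice).
#' @export
train <- function(model, sampler, augment_fn = NULL,
                  config = training_config(), val_sampler = NULL,
                  verbose = FALSE) {
  vs <- if (is.null(val_sampler)) sampler else val_sampler
  val_batch <- patches_to_batch(vs(config$n_val))
  state <- adam_init(model$params)
  lr <- config$lr
  val_hist <- numeric(0)
  best_val <- Inf
  best_params <- model$params
  best_bn <- model$bn_stats
  history <- data.frame()
  t_global <- 0L
  for (epoch in seq_len(config$epochs)) {
    losses <- numeric(config$iterations)
    for (it in seq_len(config$iterations)) {
      patches <- sampler(config$batch_size)
      if (!is.null(augment_fn)) patches <- lapply(patches, augment_fn)
      batch <- patches_to_batch(patches)
      fwd <- forward_graph(model, batch$x)
      model$bn_stats <- fwd$bn_stats
      logits <- fwd$acts[[length(model$nodes)]]
      lg <- batch_loss_grad(logits, batch$y)
      if (!is.finite(lg$loss)) {
        stop("training diverged at epoch ", epoch, " iteration ", it,
             " (loss = ", lg$loss, ")")
      }
      grads <- backward_graph(model, fwd, lg$dlogits)
      t_global <- t_global + 1L
      upd <- adam_step(model$params, grads, state, lr, t_global)
      model$params <- upd$params
      state <- upd$state
      losses[it] <- lg$loss
    }
    vl <- validation_metrics(model, val_batch)
    val_hist <- c(val_hist, vl$loss)
    lr <- lr_schedule(val_hist, config$lr, config$decay_factor,
                      config$patience)[epoch]
    if (vl$loss < best_val) {
      best_val <- vl$loss
      best_params <- model$params
      best_bn <- model$bn_stats
    }
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = mean(losses), val_loss = vl$loss,
      lr = lr, val_macro_dice = vl$macro_dice))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2e  mDice %.3f",
                      epoch, mean(losses), vl$loss, lr, vl$macro_dice))
    }
  }
  model$params <- best_params
  model$bn_stats <- best_bn
  list(model = model, history = history)
}

validation_metrics <- function(model, val_batch) {
  logits <- net_logits(model, val_batch$x)
  probs <- softmax_probs(logits)
  loss <- masked_cross_entropy(probs, val_batch$y)
  K <- dim(probs)[3]
  P <- matrix(aperm(probs, c(1, 2, 4, 3)), ncol = K)
  pred <- max.col(P, ties.method = "first") - 1L
  lab <- as.vector(val_batch$y)
  ann <- lab != unlabeled_value()
  cm <- confusion_from_vectors(lab[ann], pred[ann], K)
  list(loss = loss, macro_dice = macro_dice(cm))
}
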