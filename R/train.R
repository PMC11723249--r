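#' Training and evaluation protocol
#'
#' Adam with decoupled weight decay, cosine-annealed learning rate over the
#' epoch budget (single cycle, no restarts, floor 0), batched forward /
#' backward through the autodiff tape, per-epoch validation, JSON-lines
#' history and best-validation checkpoint retention. Fully deterministic
#' under the configured seed.
#'
#' @name training
NULL

#' Training configuration
#'
#' Defaults are the study protocol: Adam, initial learning rate 1e-4,
#' batch size 16, 100 epochs, cosine annealing, weight decay 0.01.
#'
#' @param lr initial learning rate.
#' @param batch_size minibatch size.
#' @param epochs training epochs (one cosine cycle).
#' @param weight_decay decoupled weight-decay coefficient.
#' @param seed integer seed for shuffling (parameter init is governed by
#'   the model config seed).
#' @param augment reserved flag; no augmentation by default (images are
#'   resized only).
#' @export
train_config <- function(lr = 1e-4, batch_size = 16L, epochs = 100L,
                         weight_decay = 0.01, seed = 42L, augment = FALSE) {
  structure(list(optimizer = "adam", lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), schedule = "cosine",
                 weight_decay = weight_decay, seed = as.integer(seed),
                 augment = isTRUE(augment)),
            class = "train_config")
}

#' Cosine-annealed learning rate at a (0-based) epoch.
#' @keywords internal
cosine_lr <- function(epoch, epochs, lr0) {
  lr0 * 0.5 * (1 + cos(pi * epoch / epochs))
}

#' @keywords internal
adam_new <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) array(0, dim = dim(p$v) %||% length(p$v))),
       v = lapply(params, function(p) array(0, dim = dim(p$v) %||% length(p$v))))
}

#' One Adam step with decoupled weight decay; gradients read from `$g`.
#' @keywords internal
adam_step <- function(params, st, lr, weight_decay = 0, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$g
    if (is.null(g)) next
    st$m[[i]] <- beta1 * st$m[[i]] + (1 - beta1) * g
    st$v[[i]] <- beta2 * st$v[[i]] + (1 - beta2) * g * g
    upd <- (st$m[[i]] / bc1) / (sqrt(st$v[[i]] / bc2) + eps)
    p$v <- p$v - lr * (upd + weight_decay * p$v)
  }
  st
}

#' Load a batch of images as a normalised `(N, 3, H, W)` array.
#' @keywords internal
load_batch <- function(paths, size, norm_mean, norm_sd) {
  n <- length(paths)
  x <- array(0, dim = c(n, 3L, size, size))
  for (i in seq_len(n)) {
    img <- read_image(paths[i])
    if (dim(img)[1] != size || dim(img)[2] != size) img <- resize_rgb(img, size)
    for (ch in 1:3) {
      x[i, ch, , ] <- (img[, , ch] - norm_mean[ch]) / norm_sd[ch]
    }
  }
  x
}

#' @keywords internal
manifest_labels <- function(manifest) {
  cls <- attr(manifest, "class_names") %||% sort(unique(manifest$label))
  match(manifest$label, cls)
}

#' Train a model
#'
#' @param model a materialised [build_model()] result.
#' @param manifest dataset manifest with `split` assigned; the `train`
#'   split is optimised, the `val` split (if any) monitored per epoch.
#' @param cfg a [train_config()].
#' @param history_file optional path; per-epoch records are appended as
#'   JSON lines.
#' @param checkpoint optional path; the best-validation-accuracy model is
#'   saved there (the final model when no validation split exists).
#' @param verbose print per-epoch progress.
#' @return list with the trained `model`, `history` (data.frame with
#'   epoch, lr, train_loss, train_acc, val_acc) and `best_epoch`.
#' @export
train <- function(model, manifest, cfg = train_config(), history_file = NULL,
                  checkpoint = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "affnet_model"), inherits(cfg, "train_config"))
  tr <- manifest[!is.na(manifest$split) & manifest$split == "train", , drop = FALSE]
  va <- manifest[!is.na(manifest$split) & manifest$split == "val", , drop = FALSE]
  if (nrow(tr) == 0L) stop("manifest has an empty train split")
  labs <- manifest_labels(manifest)
  tr_lab <- labs[!is.na(manifest$split) & manifest$split == "train"]
  size <- model$config$input_size
  nm <- model$config$norm_mean; nsd <- model$config$norm_sd

  params <- ag_collect_params(model[c("stem", "stages", "downsamples", "head")])
  opt <- adam_new(params)
  set.seed(cfg$seed)
  hist <- list()
  best <- list(acc = -Inf, epoch = NA_integer_, params = NULL)

  for (ep in seq_len(cfg$epochs)) {
    lr <- cosine_lr(ep - 1L, cfg$epochs, cfg$lr)
    ord <- sample(nrow(tr))
    losses <- c()
    correct <- 0L
    for (b0 in seq(1L, nrow(tr), by = cfg$batch_size)) {
      idx <- ord[b0:min(b0 + cfg$batch_size - 1L, nrow(tr))]
      x <- load_batch(tr$path[idx], size, nm, nsd)
      y <- tr_lab[idx]
      ag_zero_grad(params)
      tp <- ag_tape_open()
      out <- model_forward(model, ag_tensor(x))
      loss <- t_softmax_xent(out$logits, y)
      ag_tape_close()
      lv <- val(loss)[1]
      if (!is.finite(lv)) {
        stop("training diverged (non-finite loss) at epoch ", ep,
             "; last lr = ", signif(lr, 3))
      }
      ag_backward(tp, loss)
      opt <- adam_step(params, opt, lr, cfg$weight_decay)
      losses <- c(losses, lv)
      correct <- correct + sum(max.col(val(out$logits)) == y)
    }
    rec <- list(epoch = ep, lr = lr, train_loss = mean(losses),
                train_acc = correct / nrow(tr), val_acc = NA_real_)
    if (nrow(va) > 0L) {
      ev <- evaluate(model, manifest, split = "val")
      rec$val_acc <- ev$accuracy
      if (ev$accuracy > best$acc) {
        best <- list(acc = ev$accuracy, epoch = ep,
                     params = lapply(params, val))
      }
    }
    hist[[ep]] <- rec
    if (!is.null(history_file)) {
      cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
          file = history_file, append = TRUE, sep = "")
    }
    if (verbose) {
      message(sprintf("epoch %3d  lr %.2e  loss %.4f  train %.3f  val %s",
                      ep, lr, rec$train_loss, rec$train_acc,
                      ifelse(is.na(rec$val_acc), "-", sprintf("%.3f", rec$val_acc))))
    }
  }
  if (!is.null(best$params)) {
    for (nmp in names(params)) params[[nmp]]$v <- best$params[[nmp]]
  }
  if (!is.null(checkpoint)) save_checkpoint(model, checkpoint)
  list(model = model,
       history = do.call(rbind, lapply(hist, as.data.frame)),
       best_epoch = if (is.na(best$epoch)) cfg$epochs else best$epoch)
}

#' Evaluate a model on one split
#'
#' @param model a materialised model.
#' @param manifest manifest with splits assigned.
#' @param split `"train"`, `"val"` or `"test"`.
#' @param batch_size forward batch size.
#' @param roc also compute one-vs-rest ROC points.
#' @return a [compute_metrics()] report, with `predictions`, `probs` and
#'   (optionally) `roc` attached.
#' @export
evaluate <- function(model, manifest, split = "test", batch_size = 16L,
                     roc = FALSE) {
  rows <- manifest[!is.na(manifest$split) & manifest$split == split, , drop = FALSE]
  if (nrow(rows) == 0L) stop("split '", split, "' is empty or missing")
  labs <- manifest_labels(manifest)[!is.na(manifest$split) & manifest$split == split]
  M <- length(attr(manifest, "class_names") %||% sort(unique(manifest$label)))
  size <- model$config$input_size
  probs <- matrix(0, nrow(rows), model$config$num_classes)
  for (b0 in seq(1L, nrow(rows), by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1L, nrow(rows))
    x <- load_batch(rows$path[idx], size, model$config$norm_mean,
                    model$config$norm_sd)
    lg <- model_forward(model, x)$logits
    e <- exp(lg - apply(lg, 1, max))
    probs[idx, ] <- e / rowSums(e)
  }
  preds <- max.col(probs)
  rep_ <- compute_metrics(preds, labs, max(M, model$config$num_classes))
  rep_$predictions <- preds
  rep_$labels <- labs
  rep_$probs <- probs
  if (roc) rep_$roc <- roc_points(probs, labs)
  rep_
}

#' Export pooled pre-head embeddings
#'
#' One row per image of the requested split: the pooled layer-normalised
#' features feeding the classifier (C4 columns), with label and path.
#' Suitable for external 2-D projection; [plot_embeddings()] draws a PCA
#' scatter.
#'
#' @param model a materialised model.
#' @param manifest manifest; @param split split name (NULL = all rows).
#' @param file optional CSV output path.
#' @return data.frame with `path`, `label` and `f1..fC` feature columns.
#' @export
extract_embeddings <- function(model, manifest, split = NULL, file = NULL,
                               batch_size = 16L) {
  rows <- if (is.null(split)) manifest else
    manifest[!is.na(manifest$split) & manifest$split == split, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no rows selected")
  size <- model$config$input_size
  feats <- NULL
  for (b0 in seq(1L, nrow(rows), by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1L, nrow(rows))
    x <- load_batch(rows$path[idx], size, model$config$norm_mean,
                    model$config$norm_sd)
    f <- model_forward(model, x)$features
    feats <- rbind(feats, f)
  }
  colnames(feats) <- paste0("f", seq_len(ncol(feats)))
  out <- cbind(data.frame(path = rows$path, label = rows$label,
                          stringsAsFactors = FALSE), as.data.frame(feats))
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}

#' PCA scatter of exported embeddings
#'
#' @param emb result of [extract_embeddings()].
#' @param file optional PNG path.
#' @export
plot_embeddings <- function(emb, file = NULL) {
  f <- as.matrix(emb[, grep("^f[0-9]+$", names(emb))])
  keep <- apply(f, 2, stats::sd) > 0
  p <- stats::prcomp(f[, keep, drop = FALSE], scale. = TRUE)
  cls <- factor(emb$label)
  if (!is.null(file)) grDevices::png(file, width = 700, height = 600)
  plot(p$x[, 1], p$x[, 2], col = as.integer(cls), pch = 19,
       xlab = "PC1", ylab = "PC2", main = "embedding projection")
  graphics::legend("topright", legend = levels(cls), col = seq_along(levels(cls)),
                   pch = 19)
  if (!is.null(file)) grDevices::dev.off()
  invisible(p)
}
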