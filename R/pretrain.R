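#' Pre-training configuration
#'
#' Defaults follow the reference training recipe: Adam with learning rate 1e-4 and L2
#' regularization 1e-4 (as optimizer weight decay), batch size 128, at most
#' 50 epochs, linear warmup over the first 8% of the scheduled updates
#' followed by cosine decay to zero, and early stopping with a patience of 5
#' epochs that only begins after epoch 20.
#'
#' @param lr Peak learning rate.
#' @param l2 Weight decay.
#' @param batch Batch size.
#' @param max_epochs Maximum epochs.
#' @param warmup_frac Fraction of total updates used for linear warmup.
#' @param patience Early-stopping patience in epochs.
#' @param patience_start Epoch after which early stopping may trigger.
#' @param seed Integer seed driving shuffling, dropout and negative draws.
#' @return A `vqcpc_pretrain_config`.
#' @export
pretrain_config <- function(lr = 1e-4, l2 = 1e-4, batch = 128L,
                            max_epochs = 50L, warmup_frac = 0.08,
                            patience = 5L, patience_start = 20L, seed = 1L) {
  stopifnot(warmup_frac > 0, warmup_frac < 1, patience_start < max_epochs)
  structure(list(lr = lr, l2 = l2, batch = as.integer(batch),
                 max_epochs = as.integer(max_epochs),
                 warmup_frac = warmup_frac, patience = as.integer(patience),
                 patience_start = as.integer(patience_start),
                 seed = as.integer(seed)),
            class = "vqcpc_pretrain_config")
}

#' Learning rate at a given update index
#'
#' Linear ramp from 0 to `cfg$lr` over the first `warmup_frac * total`
#' updates, then cosine decay `lr * 0.5 * (1 + cos(pi * progress))` reaching
#' zero at the final update. The schedule is laid out over
#' `max_epochs * batches_per_epoch` updates regardless of early stopping.
#'
#' @param update Update index (1-based; 0 allowed, giving 0).
#' @param total_updates Total scheduled updates.
#' @param cfg A [pretrain_config()].
#' @return The learning rate.
#' @export
lr_at <- function(update, total_updates, cfg = pretrain_config()) {
  w <- cfg$warmup_frac * total_updates
  ifelse(update <= w,
         cfg$lr * update / w,
         cfg$lr * 0.5 * (1 + cos(pi * (update - w) / (total_updates - w))))
}

# pure early-stopping rule: stop after epoch length(val_losses) when the
# best epoch is `patience` or more epochs back and we are past patience_start
should_stop <- function(val_losses, patience, patience_start) {
  e <- length(val_losses)
  if (e <= patience_start) return(FALSE)
  since_best <- e - which.min(val_losses)
  since_best >= patience
}

#' Self-supervised pre-training loop
#'
#' Trains the full VQ-CPC objective with Adam, the warmup+cosine schedule,
#' and early stopping on the validation total loss. The checkpoint with the
#' best validation loss is returned. Fully deterministic given `cfg$seed`.
#'
#' @param model A [vqcpc_model()].
#' @param train_windows,val_windows Disjoint lists of normalized windows.
#' @param cfg A [pretrain_config()].
#' @param verbose Print per-epoch losses.
#' @return List with `model` (best checkpoint), `history` (per-epoch
#'   data.frame of loss terms), and `best_epoch`.
#' @export
pretrain <- function(model, train_windows, val_windows,
                     cfg = pretrain_config(), verbose = FALSE) {
  if (!length(train_windows) || !length(val_windows)) {
    stop_vqcpc("empty train or validation split", "vqcpc_config_error")
  }
  Xtr <- windows_to_array(train_windows)
  Xval <- windows_to_array(val_windows)
  n <- dim(Xtr)[1]
  batches_per_epoch <- max(1L, n %/% cfg$batch)
  total_updates <- cfg$max_epochs * batches_per_epoch
  params <- model$params
  opt <- adam_init(params)
  history <- NULL
  best <- list(val = Inf, params = params, epoch = 0L)
  val_losses <- numeric(0)
  update <- 0L
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      ep <- c(cpc = 0, codebook = 0, commitment = 0, total = 0)
      for (bi in seq_len(batches_per_epoch)) {
        take <- ord[((bi - 1L) * cfg$batch + 1L):min(bi * cfg$batch, n)]
        model$params <- params
        fb <- model_forward_backward(model, Xtr[take, , , drop = FALSE],
                                     train = TRUE)
        update <- update + 1L
        st <- adam_step(params, fb$grads, opt,
                        lr = lr_at(update, total_updates, cfg),
                        weight_decay = cfg$l2)
        params <- st$params
        opt <- st$state
        ep <- ep + c(fb$breakdown$cpc, fb$breakdown$codebook,
                     fb$breakdown$commitment, fb$breakdown$total)
      }
      ep <- ep / batches_per_epoch
      model$params <- params
      vb <- total_loss(model, Xval, train = FALSE,
                       seed = derive_seed(cfg$seed, "val", epoch))
      val_losses <- c(val_losses, vb$total)
      history <- rbind(history,
                       data.frame(epoch = epoch, cpc = ep[["cpc"]],
                                  codebook = ep[["codebook"]],
                                  commitment = ep[["commitment"]],
                                  total = ep[["total"]],
                                  val_total = vb$total))
      if (vb$total < best$val) {
        best <- list(val = vb$total, params = params, epoch = epoch)
      }
      if (verbose) {
        message(sprintf("epoch %d: train %.4f, val %.4f", epoch,
                        ep[["total"]], vb$total))
      }
      if (should_stop(val_losses, cfg$patience, cfg$patience_start)) break
    }
  })
  model$params <- best$params
  list(model = model, history = history, best_epoch = best$epoch)
}
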