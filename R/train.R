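# Two-phase adversarial training.
#
# Phase 1 (discriminators frozen): supervised cross-entropy on augmented
# source images, Charbonnier entropy minimization on unlabeled target
# images, and the adversarial term pushing target probability maps to be
# scored as "source" by both discriminators; segmentation parameters are
# updated with SGD (momentum, weight decay, linear warmup + cosine decay).
# Phase 2 (segmenter frozen): both discriminators are updated with Adam
# (polynomial learning-rate decay) on detached probability maps.

#' Training configuration
#'
#' Defaults follow the published implementation: SGD with learning rate
#' 0.001, weight decay 5e-4, linear warmup then cosine decay for the
#' segmenter; Adam with learning rate 1e-4, betas (0.9, 0.99) and
#' polynomial decay for the discriminators.
#'
#' @param epochs training epochs.
#' @param batch_size images per batch.
#' @param seg_lr,seg_momentum,seg_weight_decay SGD settings for the
#'   segmentation network.
#' @param warmup_iters linear warmup length in iterations (published: 1000;
#'   scale it down together with the run length for desk-scale runs).
#' @param disc_lr,disc_betas Adam settings for the discriminators.
#' @param poly_power exponent of the discriminator's polynomial decay.
#' @param loss_weights a [loss_weights()] object.
#' @param aug_config an [augmentation_config()] object.
#' @param network a [network_config()] object.
#' @param j_shot number of labelled target images for few-shot supervised
#'   adaptation (0 = unsupervised).
#' @param seed master seed; all randomness in a fit flows from it.
#' @param eval_every checkpoint-evaluation period in epochs (0 disables
#'   checkpoint selection; the final parameters are then used).
#' @param checkpoint_metric `"source_val"` (default; target labels are
#'   nominally unavailable) or `"target_val"`.
#' @return object of class `training_config`.
#' @export
training_config <- function(epochs = 30, batch_size = 4, seg_lr = 0.001,
                            seg_momentum = 0.9, seg_weight_decay = 5e-4,
                            warmup_iters = 1000, disc_lr = 1e-4,
                            disc_betas = c(0.9, 0.99), poly_power = 0.9,
                            loss_weights = weedadapt::loss_weights(),
                            aug_config = augmentation_config(),
                            network = network_config("tiny"),
                            j_shot = 0, seed = 1L, eval_every = 0,
                            checkpoint_metric = c("source_val", "target_val")) {
  stopifnot(epochs >= 1, batch_size >= 1, seg_lr > 0, disc_lr > 0,
            j_shot >= 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seg_lr = seg_lr, seg_momentum = seg_momentum,
                 seg_weight_decay = seg_weight_decay,
                 warmup_iters = as.integer(warmup_iters), disc_lr = disc_lr,
                 disc_betas = disc_betas, poly_power = poly_power,
                 loss_weights = loss_weights, aug_config = aug_config,
                 network = network, j_shot = as.integer(j_shot),
                 seed = as.integer(seed), eval_every = as.integer(eval_every),
                 checkpoint_metric = match.arg(checkpoint_metric)),
            class = "training_config")
}

# ---- optimizers ------------------------------------------------------------

sgd_update <- function(net, lr, momentum, weight_decay) {
  if (is.null(net$opt)) net$opt <- lapply(net$params, function(p) { p[] <- 0; p })
  for (nm in names(net$params)) {
    g <- net$grads[[nm]] + weight_decay * net$params[[nm]]
    v <- momentum * net$opt[[nm]] + g
    net$opt[[nm]] <- v
    net$params[[nm]] <- net$params[[nm]] - lr * v
  }
  invisible(net)
}

adam_update <- function(net, lr, betas, eps = 1e-8) {
  if (is.null(net$opt)) {
    net$opt <- list(m = lapply(net$params, function(p) { p[] <- 0; p }),
                    v = lapply(net$params, function(p) { p[] <- 0; p }),
                    t = 0)
  }
  net$opt$t <- net$opt$t + 1
  b1 <- betas[1]; b2 <- betas[2]
  bc1 <- 1 - b1^net$opt$t
  bc2 <- 1 - b2^net$opt$t
  for (nm in names(net$params)) {
    g <- net$grads[[nm]]
    net$opt$m[[nm]] <- b1 * net$opt$m[[nm]] + (1 - b1) * g
    net$opt$v[[nm]] <- b2 * net$opt$v[[nm]] + (1 - b2) * g^2
    mhat <- net$opt$m[[nm]] / bc1
    vhat <- net$opt$v[[nm]] / bc2
    net$params[[nm]] <- net$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(net)
}

seg_lr_at <- function(iter, total, config) {
  wu <- min(config$warmup_iters, total)
  if (iter < wu) return(config$seg_lr * (iter + 1) / wu)
  if (total <= wu) return(config$seg_lr)
  config$seg_lr * 0.5 * (1 + cos(pi * (iter - wu) / (total - wu)))
}

disc_lr_at <- function(iter, total, config) {
  config$disc_lr * (1 - iter / total)^config$poly_power
}

# ---- batch plumbing --------------------------------------------------------

stack_images <- function(samples) {
  d <- dim(samples[[1]]$image)
  x <- array(0, dim = c(d[1], d[2], 3, length(samples)))
  for (i in seq_along(samples)) x[, , , i] <- samples[[i]]$image
  normalize_image(x)
}

stack_masks <- function(samples) {
  d <- dim(samples[[1]]$mask)
  m <- array(0L, dim = c(d[1], d[2], length(samples)))
  for (i in seq_along(samples)) m[, , i] <- samples[[i]]$mask
  m
}

#' One joint training iteration (both phases)
#'
#' Phase 1 updates the segmentation network on the composite
#' objective with the discriminators frozen; phase 2 updates both
#' discriminators on detached probability maps with the segmenter frozen.
#'
#' @param seg_net a `seg_network`.
#' @param discs list with `main` and `aux` discriminators.
#' @param src_batch list of labelled source `labeled_image` (already
#'   augmented per the current schedule).
#' @param tgt_batch list of unlabeled target `labeled_image`.
#' @param config a [training_config()].
#' @param lr_seg,lr_disc learning rates for this iteration.
#' @param few_batch optional list of labelled target samples (few-shot
#'   mode); requires `config$j_shot > 0`.
#' @param check_freeze when `TRUE`, attach an attribute `freeze` recording
#'   whether discriminator parameters were bit-unchanged across phase 1
#'   and segmentation parameters bit-unchanged across phase 2.
#' @return named list of component losses (`L_seg`, `L_ent`, `L_adv`,
#'   `L_seg_hat`, `total`, `L_d`, `L_d_aux`, `L_D`).
#' @export
train_step <- function(seg_net, discs, src_batch, tgt_batch, config,
                       lr_seg = config$seg_lr, lr_disc = config$disc_lr,
                       few_batch = NULL, check_freeze = FALSE) {
  if (check_freeze) {
    disc_snap <- list(discs$main$params, discs$aux$params)
  }
  lw <- config$loss_weights
  if (!is.null(few_batch) && config$j_shot == 0)
    stop("labelled target samples supplied in unsupervised mode (j_shot = 0)")
  tgt_roles <- vapply(tgt_batch, function(s) s$role %||% "target", "")
  if (is.null(few_batch) && config$j_shot == 0 &&
      any(vapply(tgt_batch, function(s) isFALSE(s$mask_hidden) &&
                 identical(s$role, "target"), TRUE)))
    stop("labelled target samples present in unsupervised training")
  x_s <- stack_images(src_batch)
  y_s <- stack_masks(src_batch)
  x_t <- stack_images(tgt_batch)

  # ---- phase 1: update segmenter, discriminators frozen ----
  zero_grads(seg_net)
  out_s <- seg_forward(seg_net, x_s)
  L_seg <- segmentation_loss(out_s$main_probs, y_s)
  dmain_s <- grad_segmentation_loss(out_s$main_probs, y_s)
  out_t <- seg_forward(seg_net, x_t)
  L_ent <- entropy_loss(entropy_map(out_t$main_probs), lw)
  dmain_t <- lw$lambda_ent * grad_entropy_objective(out_t$main_probs, lw)
  dm <- disc_forward(discs$main, out_t$main_probs)
  da <- disc_forward(discs$aux, out_t$aux_probs)
  L_adv_main <- adversarial_loss(dm$logits)
  L_adv_aux <- adversarial_loss(da$logits)
  L_adv <- L_adv_main + lw$lambda_aux * L_adv_aux
  daux_t <- NULL
  if (lw$lambda_adv > 0) {
    dmain_t <- dmain_t + lw$lambda_adv *
      disc_input_grad(discs$main, dm$cache, grad_adversarial_loss(dm$logits))
    daux_t <- lw$lambda_adv * lw$lambda_aux *
      disc_input_grad(discs$aux, da$cache, grad_adversarial_loss(da$logits))
  }
  L_seg_hat <- NA_real_
  out_f <- NULL
  if (!is.null(few_batch)) {
    x_f <- stack_images(few_batch)
    y_f <- stack_masks(few_batch)
    out_f <- seg_forward(seg_net, x_f)
    L_seg_hat <- segmentation_loss(out_f$main_probs, y_f)
    dmain_f <- lw$lambda_seg * grad_segmentation_loss(out_f$main_probs, y_f)
  }
  seg_backward(seg_net, out_s$cache, dmain = dmain_s)
  if (lw$lambda_ent > 0 || lw$lambda_adv > 0)
    seg_backward(seg_net, out_t$cache, dmain = dmain_t, daux = daux_t)
  if (!is.null(out_f))
    seg_backward(seg_net, out_f$cache, dmain = dmain_f)
  sgd_update(seg_net, lr_seg, config$seg_momentum, config$seg_weight_decay)
  if (check_freeze) {
    disc_frozen <- identical(disc_snap[[1]], discs$main$params) &&
      identical(disc_snap[[2]], discs$aux$params)
    seg_snap <- seg_net$params
  }

  # ---- phase 2: update discriminators, segmenter frozen ----
  # fresh forward passes on detached maps (values only; no path to seg params)
  zero_grads(discs$main)
  zero_grads(discs$aux)
  # source probability maps must reflect the updated segmenter? No: the
  # maps from phase 1 are reused as detached inputs, one forward saved.
  sm <- disc_forward(discs$main, out_s$main_probs)
  tm <- disc_forward(discs$main, out_t$main_probs)
  sa <- disc_forward(discs$aux, out_s$aux_probs)
  ta <- disc_forward(discs$aux, out_t$aux_probs)
  L_d <- discriminator_loss(sm$logits, tm$logits)
  L_d_aux <- discriminator_loss(sa$logits, ta$logits)
  gm <- grad_discriminator_loss(sm$logits, tm$logits)
  ga <- grad_discriminator_loss(sa$logits, ta$logits)
  disc_backward(discs$main, sm$cache, gm$d_src)
  disc_backward(discs$main, tm$cache, gm$d_tgt)
  disc_backward(discs$aux, sa$cache, ga$d_src * config$loss_weights$lambda_aux)
  disc_backward(discs$aux, ta$cache, ga$d_tgt * config$loss_weights$lambda_aux)
  adam_update(discs$main, lr_disc, config$disc_betas)
  adam_update(discs$aux, lr_disc, config$disc_betas)

  parts <- list(L_seg = L_seg, L_ent = L_ent, L_adv = L_adv)
  if (!is.null(out_f)) parts$L_seg_hat <- L_seg_hat
  total <- total_segmentation_objective(parts, lw, j_shot = config$j_shot)
  rec <- list(L_seg = L_seg, L_ent = L_ent, L_adv = L_adv, L_seg_hat = L_seg_hat,
              total = total, L_d = L_d, L_d_aux = L_d_aux,
              L_D = total_discriminator_loss(L_d, L_d_aux, lw))
  if (check_freeze)
    attr(rec, "freeze") <- list(disc_unchanged_phase1 = disc_frozen,
                                seg_unchanged_phase2 = identical(seg_snap,
                                                                 seg_net$params))
  rec
}

# Supervised-only step used by source-training-only (STO) fits: no target
# forward, no discriminator work.
supervised_step <- function(seg_net, src_batch, config, lr_seg) {
  x_s <- stack_images(src_batch)
  y_s <- stack_masks(src_batch)
  zero_grads(seg_net)
  out_s <- seg_forward(seg_net, x_s)
  L_seg <- segmentation_loss(out_s$main_probs, y_s)
  seg_backward(seg_net, out_s$cache,
               dmain = grad_segmentation_loss(out_s$main_probs, y_s))
  sgd_update(seg_net, lr_seg, config$seg_momentum, config$seg_weight_decay)
  list(L_seg = L_seg, L_ent = NA_real_, L_adv = NA_real_,
       L_seg_hat = NA_real_, total = L_seg, L_d = NA_real_,
       L_d_aux = NA_real_, L_D = NA_real_)
}

#' Split source and target datasets into train and test sets
#'
#' Source: 80% train-validation / 20% test. Targets: 70% train / 30% test.
#' Shuffles are seeded; train and test are disjoint by construction.
#'
#' @param source list of `labeled_image`.
#' @param targets one target dataset (list of `labeled_image`) or a list
#'   of several target datasets.
#' @param seed shuffle seed.
#' @return list with `source = list(train, test)` and `target(s)` split
#'   the same way.
#' @export
split_datasets <- function(source, targets, seed = 1L) {
  split_one <- function(ds, frac, label) {
    if (length(ds) < 5) warning("dataset '", label, "' has fewer than 5 images")
    n <- length(ds)
    idx <- sample.int(n)
    k <- max(1L, round(frac * n))
    if (k >= n) k <- n - 1L
    list(train = ds[idx[seq_len(k)]], test = ds[idx[(k + 1):n]])
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  res <- list(source = split_one(source, 0.8, "source"))
  multi <- length(targets) > 0 && !inherits(targets[[1]], "labeled_image")
  if (multi) {
    res$targets <- lapply(seq_along(targets), function(i)
      split_one(targets[[i]], 0.7, paste0("target", i)))
  } else {
    res$target <- split_one(targets, 0.7, "target")
  }
  res
}

#' Fit a domain-adaptive segmentation model
#'
#' The single fitting entry point. `mode = "uda"` runs the full two-phase
#' adversarial loop (supervised source loss, target entropy minimization,
#' adversarial alignment, discriminator updates); `mode = "sto"` trains the
#' segmenter on source labels only (the source-training-only baseline).
#' Source batches are augmented per the progressive schedule.
#'
#' @param source list of labelled source `labeled_image`.
#' @param target list of target `labeled_image` (required for `"uda"`).
#' @param config a [training_config()].
#' @param mode `"uda"` or `"sto"`.
#' @param validation optional labelled hold-out list used for checkpoint
#'   selection when `config$eval_every > 0`.
#' @param verbose print per-epoch loss summaries.
#' @return object of class `field_adapt` with the fitted `seg_net`,
#'   `discs`, the per-iteration loss `history` data.frame, and the
#'   configuration.
#' @export
field_adapt <- function(source, target = NULL, config = training_config(),
                        mode = c("uda", "sto"), validation = NULL,
                        verbose = FALSE) {
  mode <- match.arg(mode)
  if (length(source) == 0) stop("source dataset is empty")
  if (mode == "uda" && (is.null(target) || length(target) == 0))
    stop("uda mode requires a target dataset")
  set.seed(config$seed)
  seg_net <- build_segmentation_network(config$network)
  discs <- list(main = build_discriminator(config$network$num_classes,
                                           config$network$disc_channels),
                aux = build_discriminator(config$network$num_classes,
                                          config$network$disc_channels))
  obj <- list(seg_net = seg_net, discs = discs, config = config, mode = mode,
              classes = config$network$num_classes)
  class(obj) <- "field_adapt"
  run_training(obj, source, target, validation, few = NULL, verbose = verbose)
}

run_training <- function(obj, source, target, validation, few, verbose,
                         epochs = obj$config$epochs) {
  config <- obj$config
  seg_net <- obj$seg_net
  discs <- obj$discs
  mode <- obj$mode
  bs <- config$batch_size
  ipe <- max(1L, ceiling(length(source) / bs))
  total_iters <- epochs * ipe
  hist <- vector("list", total_iters)
  it <- 0L
  ti <- 0L
  best <- list(miou = -Inf, params = NULL)
  for (ep in seq_len(epochs)) {
    st <- schedule_probabilities(ep - 1, config$aug_config)
    ord <- sample.int(length(source))
    ep_losses <- c()
    for (b in seq_len(ipe)) {
      idx <- ord[((b - 1L) * bs + 1L):min(b * bs, length(source))]
      src_batch <- augment_batch(source[idx], st, config$aug_config)
      lr_s <- seg_lr_at(it, total_iters, config)
      lr_d <- disc_lr_at(it, total_iters, config)
      if (mode == "sto") {
        rec <- supervised_step(seg_net, src_batch, config, lr_s)
      } else {
        tidx <- (ti + seq_len(min(bs, length(target))) - 1L) %% length(target) + 1L
        ti <- ti + length(tidx)
        rec <- train_step(seg_net, discs, src_batch, target[tidx], config,
                          lr_seg = lr_s, lr_disc = lr_d, few_batch = few)
      }
      it <- it + 1L
      hist[[it]] <- c(iter = it, epoch = ep, lr_seg = lr_s, lr_disc = lr_d,
                      unlist(rec))
      ep_losses <- c(ep_losses, rec$total)
    }
    if (verbose)
      message(sprintf("epoch %d/%d  mean total loss %.4f", ep, epochs,
                      mean(ep_losses)))
    if (config$eval_every > 0 && !is.null(validation) &&
        (ep %% config$eval_every == 0 || ep == epochs)) {
      miou <- evaluate_dataset(seg_net, validation, config$network$num_classes)$mean_iou
      if (!is.na(miou) && miou > best$miou)
        best <- list(miou = miou, params = seg_net$params)
    }
  }
  if (!is.null(best$params)) seg_net$params <- best$params
  new_hist <- as.data.frame(do.call(rbind, hist[seq_len(it)]))
  obj$history <- if (is.null(obj$history)) new_hist else rbind(obj$history, new_hist)
  obj$val_miou <- if (is.finite(best$miou)) best$miou else NA_real_
  obj
}

#' Few-shot supervised fine-tuning on j labelled target images
#'
#' Continues training a fitted model with the few-shot composite
#' objective: the j labelled target images contribute a
#' `lambda_seg`-weighted cross-entropy each iteration, while the remaining
#' (unlabeled) target images keep contributing the entropy term. The j
#' samples are excluded from the unlabeled entropy pool.
#'
#' @param state a `field_adapt` fit.
#' @param target_samples list of labelled target `labeled_image`; the
#'   first `config$j_shot` (or `j`) are used.
#' @param config optional replacement [training_config()]; defaults to the
#'   fit's config.
#' @param j number of shots; defaults to `config$j_shot`.
#' @param epochs fine-tuning epochs; defaults to a quarter of the original.
#' @param unlabeled_pool optional unlabeled target images for the entropy
#'   term; defaults to `target_samples` minus the j selected.
#' @param source labelled source images to keep the supervised source term
#'   active (recommended; pass the training split used in the fit).
#' @param verbose print progress.
#' @return the updated `field_adapt` object.
#' @export
finetune_few_shot <- function(state, target_samples, config = state$config,
                              j = config$j_shot, epochs = NULL,
                              unlabeled_pool = NULL, source = NULL,
                              verbose = FALSE) {
  stopifnot(inherits(state, "field_adapt"))
  if (j < 1) stop("j must be >= 1; use field_adapt() for unsupervised adaptation")
  if (length(target_samples) < j) stop("need at least j labelled target samples")
  config$j_shot <- as.integer(j)
  few <- lapply(target_samples[seq_len(j)], function(s) {
    if (is.null(s$mask)) stop("few-shot samples must carry masks")
    s$mask_hidden <- FALSE
    s
  })
  pool <- unlabeled_pool %||% target_samples[-seq_len(j)]
  if (length(pool) == 0) pool <- few  # degenerate fully supervised limit
  if (is.null(source)) stop("supply the labelled source training split")
  epochs <- epochs %||% max(1L, config$epochs %/% 4L)
  state$config <- config
  state$mode <- "uda"
  run_training(state, source, pool, validation = NULL, few = few,
               verbose = verbose, epochs = epochs)
}

# ---- S3 methods ------------------------------------------------------------

#' @export
print.field_adapt <- function(x, ...) {
  cat("Domain-adaptive crop-weed segmentation fit\n")
  cat("  mode:", x$mode,
      if (x$config$j_shot > 0) sprintf("(%d-shot)", x$config$j_shot) else "", "\n")
  cat("  network:", x$config$network$size_preset, "preset,",
      format(n_params(x$seg_net), big.mark = ","), "segmenter parameters\n")
  cat("  trained iterations:", nrow(x$history), "\n")
  if (!is.null(x$val_miou) && !is.na(x$val_miou))
    cat("  best validation mIoU:", sprintf("%.4f", x$val_miou), "\n")
  invisible(x)
}

#' @export
summary.field_adapt <- function(object, ...) {
  h <- object$history
  last <- h[nrow(h), ]
  cat("Domain-adaptive segmentation fit (", object$mode, ")\n", sep = "")
  cat("  iterations:", nrow(h), " epochs:", max(h$epoch), "\n")
  cat("  final losses: L_seg =", signif(last$L_seg, 4))
  if (!is.na(last$L_ent)) cat(", L_ent =", signif(last$L_ent, 4))
  if (!is.na(last$L_adv)) cat(", L_adv =", signif(last$L_adv, 4))
  if (!is.na(last$L_D)) cat(", L_D =", signif(last$L_D, 4))
  cat("\n")
  invisible(object)
}

#' Predict segmentation masks from a fitted model
#'
#' @param object a `field_adapt` fit.
#' @param newdata a `labeled_image`, an image array, or a list of either.
#' @param type `"mask"` (argmax class indices), `"prob"` (probability
#'   maps) or `"entropy"` (normalized entropy maps).
#' @param ... unused.
#' @return a mask / probability map / entropy map, or a list of them.
#' @export
predict.field_adapt <- function(object, newdata, type = c("mask", "prob", "entropy"),
                                ...) {
  type <- match.arg(type)
  one <- function(im) {
    out <- predict_segmentation(object$seg_net, im, with_entropy = type == "entropy")
    switch(type, mask = out$pred_mask, prob = out$main_probs, entropy = out$entropy)
  }
  if (is.list(newdata) && !inherits(newdata, "labeled_image"))
    lapply(newdata, one) else one(newdata)
}

#' Plot training loss curves
#'
#' @param x a `field_adapt` fit.
#' @param ... passed to `matplot`.
#' @export
plot.field_adapt <- function(x, ...) {
  h <- x$history
  cols <- intersect(c("L_seg", "L_ent", "L_adv", "L_D"), names(h))
  keep <- cols[colSums(!is.na(h[cols])) > 0]
  graphics::matplot(h$iter, h[keep], type = "l", lty = 1,
                    xlab = "iteration", ylab = "loss", ...)
  graphics::legend("topright", legend = keep, col = seq_along(keep), lty = 1)
  invisible(x)
}
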