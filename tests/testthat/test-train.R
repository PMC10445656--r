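# Two-phase optimization: freeze isolation, loss bookkeeping, schedules,
# splits, determinism, and few-shot contracts.

digest_image <- function(s) paste(c(s$image[1:20], s$mask[1:20]), collapse = ",")

make_nets <- function(seed = 1) {
  set.seed(seed)
  cfg <- network_config("tiny")
  list(seg = build_segmentation_network(cfg),
       discs = list(main = build_discriminator(3, cfg$disc_channels),
                    aux = build_discriminator(3, cfg$disc_channels)))
}

test_that("train_step freezes each subnetwork in the other's phase", {
  nets <- make_nets(31)
  pair <- fixture_pair(n_source = 2, n_target = 2, size = 64)
  cfg <- tiny_train_config()
  disc_before_main <- nets$discs$main$params
  disc_before_aux <- nets$discs$aux$params
  seg_before <- nets$seg$params
  rec <- train_step(nets$seg, nets$discs, pair$source, pair$target, cfg)
  # segmentation parameters moved (phase 1 ran)
  expect_false(identical(seg_before, nets$seg$params))
  # discriminators moved only via phase 2's Adam update; verify phase-1
  # isolation by re-running phase 1 alone with zero adversarial weight and
  # a fresh net: discriminator params must be bit-identical afterwards
  nets2 <- make_nets(32)
  d_main <- nets2$discs$main$params
  d_aux <- nets2$discs$aux$params
  cfg0 <- tiny_train_config(loss_weights = loss_weights(lambda_adv = 0.4))
  # phase 1 only: call the exported step, then compare the recorded pre-phase-2
  # snapshot; train_step runs phase 2 too, so instead freeze-check via
  # disc_input_grad directly
  x <- weedadapt:::stack_images(pair$target)
  out <- weedadapt:::seg_forward(nets2$seg, x)
  dm <- weedadapt:::disc_forward(nets2$discs$main, out$main_probs)
  weedadapt:::zero_grads(nets2$discs$main)
  g0 <- nets2$discs$main$grads
  invisible(weedadapt:::disc_input_grad(nets2$discs$main, dm$cache,
                                        grad_adversarial_loss(dm$logits)))
  expect_identical(nets2$discs$main$params, d_main)
  expect_identical(nets2$discs$main$grads, g0)  # gradient buffers untouched too
  # the loss record reproduces the composite objective from its parts
  expect_equal(rec$total,
               total_segmentation_objective(list(L_seg = rec$L_seg,
                                                 L_ent = rec$L_ent,
                                                 L_adv = rec$L_adv),
                                            cfg$loss_weights),
               tolerance = 1e-12)
  expect_equal(rec$L_D,
               total_discriminator_loss(rec$L_d, rec$L_d_aux, cfg$loss_weights),
               tolerance = 1e-12)
})

test_that("phase 2 leaves segmentation parameters bit-identical", {
  nets <- make_nets(33)
  pair <- fixture_pair(n_source = 2, n_target = 2, size = 64)
  cfg <- tiny_train_config()
  # run a full step, then replay phase 2 in isolation on fresh maps
  x_s <- weedadapt:::stack_images(pair$source)
  x_t <- weedadapt:::stack_images(pair$target)
  out_s <- weedadapt:::seg_forward(nets$seg, x_s, keep_cache = FALSE)
  out_t <- weedadapt:::seg_forward(nets$seg, x_t, keep_cache = FALSE)
  seg_params <- nets$seg$params
  seg_grads <- nets$seg$grads
  for (d in nets$discs) weedadapt:::zero_grads(d)
  sm <- weedadapt:::disc_forward(nets$discs$main, out_s$main_probs)
  tm <- weedadapt:::disc_forward(nets$discs$main, out_t$main_probs)
  gm <- grad_discriminator_loss(sm$logits, tm$logits)
  weedadapt:::disc_backward(nets$discs$main, sm$cache, gm$d_src)
  weedadapt:::disc_backward(nets$discs$main, tm$cache, gm$d_tgt)
  weedadapt:::adam_update(nets$discs$main, 1e-4, c(0.9, 0.99))
  expect_identical(nets$seg$params, seg_params)
  expect_identical(nets$seg$grads, seg_grads)
})

test_that("train_step rejects labelled target samples in unsupervised mode", {
  nets <- make_nets(34)
  pair <- fixture_pair(n_source = 2, n_target = 2, size = 64)
  labelled <- lapply(pair$target, function(s) { s$mask_hidden <- FALSE; s })
  cfg <- tiny_train_config()
  expect_error(train_step(nets$seg, nets$discs, pair$source, labelled, cfg),
               "unsupervised")
  expect_error(train_step(nets$seg, nets$discs, pair$source, pair$target, cfg,
                          few_batch = labelled[1]), "j_shot = 0")
})

test_that("learning-rate schedules warm up, decay, and stay positive", {
  cfg <- training_config(epochs = 5, warmup_iters = 10, seg_lr = 0.001,
                         disc_lr = 1e-4)
  total <- 100
  lrs <- vapply(0:99, weedadapt:::seg_lr_at, 0, total = total, config = cfg)
  expect_lt(lrs[1], cfg$seg_lr)        # warm start below the base rate
  expect_true(all(diff(lrs[1:10]) > 0))  # rising through warmup
  expect_equal(max(lrs), cfg$seg_lr, tolerance = 1e-9)
  expect_true(all(diff(lrs[11:100]) < 0))  # cosine decay after warmup
  dlr <- vapply(0:99, weedadapt:::disc_lr_at, 0, total = total, config = cfg)
  expect_true(all(diff(dlr) < 0))
  expect_true(all(dlr >= 0))
  expect_equal(dlr[1], 1e-4)
})

test_that("dataset splits are disjoint with the stated ratios", {
  pair <- fixture_pair(n_source = 10, n_target = 10, size = 32)
  sp <- split_datasets(pair$source, pair$target, seed = 4)
  expect_length(sp$source$train, 8)
  expect_length(sp$source$test, 2)
  expect_length(sp$target$train, 7)
  expect_length(sp$target$test, 3)
  key <- function(s) digest_image(s)
  tr <- vapply(sp$source$train, key, "")
  te <- vapply(sp$source$test, key, "")
  expect_length(intersect(tr, te), 0)
  expect_warning(split_datasets(pair$source[1:3], pair$target, seed = 1),
                 "fewer than 5")
  # 100-image source splits 80/20
  big <- rep(pair$source, 10)
  spb <- split_datasets(big, pair$target, seed = 9)
  expect_length(spb$source$train, 80)
  expect_length(spb$source$test, 20)
})

test_that("equal seeds give identical loss histories; training reduces loss", {
  pair <- fixture_pair(n_source = 6, n_target = 4, size = 64)
  cfg <- training_config(epochs = 3, batch_size = 2, warmup_iters = 5, seed = 7)
  f1 <- field_adapt(pair$source, pair$target, cfg, mode = "uda")
  f2 <- field_adapt(pair$source, pair$target, cfg, mode = "uda")
  expect_equal(f1$history, f2$history, tolerance = 1e-12)
  # supervised loss decreases over a slightly longer STO run
  cfg2 <- training_config(epochs = 6, batch_size = 2, warmup_iters = 5, seed = 8)
  f3 <- field_adapt(pair$source, config = cfg2, mode = "sto")
  h <- f3$history$L_seg
  expect_lt(mean(tail(h, 3)), mean(head(h, 3)))
  # degenerate weights reduce the composite objective to the supervised term
  cfg3 <- training_config(epochs = 1, batch_size = 2, warmup_iters = 5, seed = 9,
                          loss_weights = loss_weights(lambda_ent = 0,
                                                      lambda_adv = 0))
  f4 <- field_adapt(pair$source, pair$target, cfg3, mode = "uda")
  expect_equal(f4$history$total, f4$history$L_seg, tolerance = 1e-12)
})

test_that("few-shot fine-tuning enforces its contracts", {
  pair <- fixture_pair(n_source = 4, n_target = 4, size = 64)
  cfg <- tiny_train_config(seed = 11)
  fit <- field_adapt(pair$source, pair$target, cfg, mode = "uda")
  labelled <- lapply(pair$target, function(s) { s$mask_hidden <- FALSE; s })
  expect_error(finetune_few_shot(fit, labelled, j = 0, source = pair$source),
               "j must be >= 1")
  n0 <- nrow(fit$history)
  ft <- finetune_few_shot(fit, labelled, j = 1, epochs = 1,
                          source = pair$source)
  expect_gt(nrow(ft$history), n0)
  # the few-shot term is present and lambda_seg-weighted in the record
  tail_rec <- ft$history[nrow(ft$history), ]
  expect_false(is.na(tail_rec$L_seg_hat))
  expect_equal(tail_rec$total,
               tail_rec$L_seg + 0.5 * tail_rec$L_ent + 0.4 * tail_rec$L_adv +
                 2 * tail_rec$L_seg_hat,
               tolerance = 1e-12)
  # masks are required on the j samples
  expect_error(finetune_few_shot(fit, list(list(image = pair$target[[1]]$image,
                                                mask = NULL)),
                                 j = 1, source = pair$source), "mask")
})

test_that("S3 surface: print, summary, predict and plot work", {
  pair <- fixture_pair(n_source = 4, n_target = 2, size = 64)
  fit <- field_adapt(pair$source, pair$target, tiny_train_config(seed = 3),
                     mode = "uda")
  expect_output(print(fit), "Domain-adaptive")
  expect_output(summary(fit), "iterations")
  m <- predict(fit, pair$target[[1]])
  expect_identical(dim(m), c(64L, 64L))
  p <- predict(fit, pair$target[[1]], type = "prob")
  expect_identical(dim(p)[3], 3L)
  e <- predict(fit, pair$target, type = "entropy")
  expect_length(e, 2)
  expect_true(all(e[[1]] >= 0 & e[[1]] <= 1))
  tf <- withr::local_tempfile(fileext = ".png")
  grDevices::png(tf)
  plot(fit)
  grDevices::dev.off()
  expect_true(file.exists(tf))
})
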