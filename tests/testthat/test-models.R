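# Network architecture contracts: shapes, normalization, presets, timing.

test_that("network_config presets carry the published and desk-scale widths", {
  paper <- network_config("paper")
  expect_identical(paper$stage_channels, c(192L, 384L, 768L, 1536L))
  expect_identical(paper$stage_depths, c(3L, 3L, 27L, 3L))
  expect_identical(paper$disc_channels, c(64L, 128L, 256L, 512L, 1L))
  tiny <- network_config("tiny")
  expect_true(all(tiny$stage_channels <= 32))
  expect_true(all(tiny$stage_depths <= 2))
  expect_error(network_config(num_classes = 1), "num_classes")
  expect_error(network_config(stage_channels = c(8, 16)), "4 positive")
})

test_that("tiny segmenter maps 128x128x3 to two normalized K-maps", {
  set.seed(1)
  net <- build_segmentation_network(network_config("tiny"))
  expect_lt(weedadapt:::n_params(net), 1e6)
  x <- array(rnorm(128 * 128 * 3 * 2), c(128, 128, 3, 2))
  out <- weedadapt:::seg_forward(net, x, keep_cache = FALSE)
  expect_identical(dim(out$main_probs), c(128L, 128L, 3L, 2L))
  expect_identical(dim(out$aux_probs), c(128L, 128L, 3L, 2L))
  sums <- rowSums(aperm(out$main_probs, c(1, 2, 4, 3)), dims = 3)
  expect_lt(max(abs(sums - 1)), 1e-5)
  sums_aux <- rowSums(aperm(out$aux_probs, c(1, 2, 4, 3)), dims = 3)
  expect_lt(max(abs(sums_aux - 1)), 1e-5)
  expect_error(weedadapt:::seg_forward(net, array(0, c(100, 100, 3, 1))),
               "divisible")
})

test_that("forward+backward of a 4-image tiny batch is fast enough for desks", {
  set.seed(2)
  net <- build_segmentation_network(network_config("tiny"))
  x <- array(rnorm(128 * 128 * 3 * 4), c(128, 128, 3, 4))
  t0 <- proc.time()
  out <- weedadapt:::seg_forward(net, x)
  weedadapt:::zero_grads(net)
  weedadapt:::seg_backward(net, out$cache, dmain = out$main_probs * 1e-3,
                           daux = out$aux_probs * 1e-3)
  elapsed <- (proc.time() - t0)[3]
  expect_lt(elapsed, 5)
})

test_that("gating reduces channels linearly with spatial dims unchanged", {
  set.seed(3)
  x <- array(rnorm(32 * 32 * 64), c(32, 32, 64, 1))
  g <- gate_skip_features(x, 16)
  expect_identical(dim(g), c(32L, 32L, 16L, 1L))
  expect_identical(dim(gate_skip_features(x, 64))[3], 64L)
  expect_error(gate_skip_features(x, 0), "positive")
  # linearity (before any nonlinearity): G(2 x1 + 3 x2) = 2 G(x1) + 3 G(x2)
  W <- array(rnorm(64 * 8), c(1, 1, 64, 8))
  b0 <- numeric(8)
  x1 <- array(rnorm(8 * 8 * 64), c(8, 8, 64, 1))
  x2 <- array(rnorm(8 * 8 * 64), c(8, 8, 64, 1))
  lhs <- gate_skip_features(2 * x1 + 3 * x2, 8, W = W, b = b0)
  rhs <- 2 * gate_skip_features(x1, 8, W = W, b = b0) +
    3 * gate_skip_features(x2, 8, W = W, b = b0)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("discriminator patch maps follow the stride-32 arithmetic", {
  set.seed(4)
  dn <- build_discriminator(3, c(8L, 16L, 32L, 32L, 1L))
  x <- array(abs(rnorm(128 * 128 * 3 * 2)), c(128, 128, 3, 2))
  out <- weedadapt:::disc_forward(dn, x, keep_cache = FALSE)
  expect_identical(dim(out$logits), c(4L, 4L, 1L, 2L))
  x64 <- array(rnorm(64 * 64 * 3), c(64, 64, 3, 1))
  expect_identical(dim(weedadapt:::disc_forward(dn, x64, FALSE)$logits),
                   c(2L, 2L, 1L, 1L))
  expect_error(weedadapt:::disc_forward(dn, array(0, c(16, 16, 3, 1))), ">= 32")
  # the two framework discriminators have independent parameters
  d2 <- build_discriminator(3, c(8L, 16L, 32L, 32L, 1L))
  expect_false(identical(dn$params, d2$params))
})

test_that("inference is deterministic and a zeroed head is maximally uncertain", {
  set.seed(5)
  net <- build_segmentation_network(network_config("tiny"))
  img <- generate_field_image(domain_spec(seed = 44), 64, 64)$image
  a <- predict_segmentation(net, img, with_entropy = TRUE)
  b <- predict_segmentation(net, img, with_entropy = TRUE)
  expect_identical(a, b)
  expect_identical(dim(a$pred_mask), c(64L, 64L))
  expect_true(all(a$pred_mask %in% 0:2))
  # uniform-initialized (zero) heads give per-pixel entropy ~ 1
  net$params[["head.conv.W"]][] <- 0
  net$params[["head.conv.b"]][] <- 0
  u <- predict_segmentation(net, img, with_entropy = TRUE)
  expect_gt(min(u$entropy), 0.999)
  # batch order preserved
  batch <- array(0L, c(64, 64, 3, 3))
  for (i in 1:3) batch[, , , i] <- generate_field_image(domain_spec(seed = 50 + i),
                                                        64, 64)$image
  ob <- predict_segmentation(net, batch)
  o1 <- predict_segmentation(net, batch[, , , 1])
  expect_equal(ob$main_probs[, , , 1], o1$main_probs[, , , 1], tolerance = 1e-12)
})

test_that("model summaries report preset, stages and parameter counts", {
  set.seed(7)
  net <- build_segmentation_network(network_config("tiny"))
  expect_output(model_summary(net), "tiny preset")
  expect_output(model_summary(net), "ASPP")
  dn <- build_discriminator(3, c(8L, 16L, 32L, 32L, 1L))
  expect_output(model_summary(dn), "8/16/32/32/1")
})

test_that("network gradients match finite differences on a micro input", {
  # end-to-end check through stem, stages, ASPP, DAM, heads and softmax
  set.seed(6)
  cfg <- network_config("tiny", stage_channels = c(4, 6, 6, 8),
                        stage_depths = c(1, 1, 1, 1), gating_channels = 4,
                        aspp_channels = 6, decoder_channels = 6)
  net <- build_segmentation_network(cfg)
  x <- array(rnorm(32 * 32 * 3), c(32, 32, 3, 1))
  labs <- matrix(sample(0:2, 32 * 32, replace = TRUE), 32, 32)
  loss_of <- function(net) {
    out <- weedadapt:::seg_forward(net, x, keep_cache = FALSE)
    segmentation_loss(out$main_probs, labs) +
      0.5 * entropy_loss(entropy_map(out$aux_probs), loss_weights())
  }
  out <- weedadapt:::seg_forward(net, x)
  weedadapt:::zero_grads(net)
  lw <- loss_weights()
  weedadapt:::seg_backward(net, out$cache,
    dmain = grad_segmentation_loss(out$main_probs, labs),
    daux = 0.5 * weedadapt:::grad_entropy_objective(out$aux_probs, lw))
  for (nm in c("stem.conv1.W", "stage3.block1.pw1.W", "down2.conv.W",
               "aspp.b2.W", "dam.ca1.W", "gate.conv.W", "fuse.conv.b",
               "head.conv.W", "aux.conv.W", "stem.ln1.g")) {
    g <- net$grads[[nm]]
    idx <- which(abs(g) == max(abs(g)))[1]
    eps <- 1e-5
    net$params[[nm]][idx] <- net$params[[nm]][idx] + eps
    lp <- loss_of(net)
    net$params[[nm]][idx] <- net$params[[nm]][idx] - 2 * eps
    lm <- loss_of(net)
    net$params[[nm]][idx] <- net$params[[nm]][idx] + eps
    fd <- (lp - lm) / (2 * eps)
    expect_equal(g[idx], fd, tolerance = 1e-3, info = nm)
  }
})
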