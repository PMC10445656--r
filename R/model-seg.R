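# Encoder-decoder segmentation network.
#
# Encoder: stem of two 7x7 stride-2 convolutions, then four stages of
# ConvNext blocks (depthwise 7x7 -> layer norm -> 1x1 expansion -> GELU ->
# 1x1 projection -> residual) with stride-2 downsampling between stages;
# total encoder stride 32.
# Decoder: ASPP (dilations 6/12/18 + image pooling) on the encoder output,
# bilinear upsampling to 1/8 resolution, concatenation with gated (1x1)
# stage-2 encoder features, refinement by a dense attention module
# (channel attention then spatial attention), a 3x3 fusion convolution and
# a 1x1 classifier head. An auxiliary 1x1 classifier head reads the
# encoder's stage-3 features. Both heads are bilinearly upsampled to input
# resolution and softmax-normalized.

#' Segmentation network configuration
#'
#' @param size_preset `"tiny"` (desk-scale: < 1e6 parameters) or `"paper"`
#'   (published widths: stage channels 192/384/768/1536, depths 3/3/27/3).
#' @param num_classes number of classes K (>= 2); default 3
#'   (background / crop / weed).
#' @param stage_channels,stage_depths optional overrides (4 positive
#'   integers each).
#' @param gating_channels channels r retained by the skip gating function.
#' @param aspp_channels,decoder_channels decoder widths.
#' @param disc_channels channel progression of the patch discriminators.
#' @return object of class `network_config`.
#' @export
network_config <- function(size_preset = c("tiny", "paper"), num_classes = 3,
                           stage_channels = NULL, stage_depths = NULL,
                           gating_channels = NULL, aspp_channels = NULL,
                           decoder_channels = NULL, disc_channels = NULL) {
  size_preset <- match.arg(size_preset)
  if (num_classes < 2) stop("num_classes must be >= 2")
  if (size_preset == "paper") {
    def <- list(stage_channels = c(192L, 384L, 768L, 1536L),
                stage_depths = c(3L, 3L, 27L, 3L), gating_channels = 48L,
                aspp_channels = 256L, decoder_channels = 256L,
                disc_channels = c(64L, 128L, 256L, 512L, 1L))
  } else {
    def <- list(stage_channels = c(8L, 16L, 24L, 32L),
                stage_depths = c(1L, 1L, 2L, 1L), gating_channels = 8L,
                aspp_channels = 24L, decoder_channels = 24L,
                disc_channels = c(8L, 16L, 32L, 32L, 1L))
  }
  cfg <- list(size_preset = size_preset, num_classes = as.integer(num_classes),
              stage_channels = as.integer(stage_channels %||% def$stage_channels),
              stage_depths = as.integer(stage_depths %||% def$stage_depths),
              gating_channels = as.integer(gating_channels %||% def$gating_channels),
              aspp_channels = as.integer(aspp_channels %||% def$aspp_channels),
              decoder_channels = as.integer(decoder_channels %||% def$decoder_channels),
              disc_channels = as.integer(disc_channels %||% def$disc_channels))
  if (length(cfg$stage_channels) != 4 || any(cfg$stage_channels <= 0))
    stop("stage_channels must be 4 positive integers")
  if (length(cfg$stage_depths) != 4 || any(cfg$stage_depths <= 0))
    stop("stage_depths must be 4 positive integers")
  if (cfg$gating_channels <= 0) stop("gating_channels must be positive")
  structure(cfg, class = "network_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

SEG_STRIDE <- 32L
ASPP_RATES <- c(6L, 12L, 18L)

#' Build the segmentation network
#'
#' Allocates and initializes all learnable parameters. Initialization draws
#' from the current R random stream, so seed beforehand for reproducible
#' weights.
#'
#' @param config a [network_config()].
#' @return an environment of class `seg_network` holding `params`, `grads`
#'   and `config`.
#' @export
build_segmentation_network <- function(config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  ch <- config$stage_channels
  K <- config$num_classes
  r <- config$gating_channels
  a <- config$aspp_channels
  dc <- config$decoder_channels
  net <- new_net(config)
  add_conv_param(net, "stem.conv1", 7, 7, 3, ch[1])
  add_ln_param(net, "stem.ln1", ch[1])
  add_conv_param(net, "stem.conv2", 7, 7, ch[1], ch[1])
  add_ln_param(net, "stem.ln2", ch[1])
  for (s in 1:4) {
    if (s > 1) {
      add_ln_param(net, sprintf("down%d.ln", s), ch[s - 1])
      add_conv_param(net, sprintf("down%d.conv", s), 2, 2, ch[s - 1], ch[s])
    }
    for (b in seq_len(config$stage_depths[s])) {
      pf <- sprintf("stage%d.block%d", s, b)
      add_dwconv_param(net, paste0(pf, ".dw"), 7, 7, ch[s])
      add_ln_param(net, paste0(pf, ".ln"), ch[s])
      add_conv_param(net, paste0(pf, ".pw1"), 1, 1, ch[s], 4 * ch[s])
      add_conv_param(net, paste0(pf, ".pw2"), 1, 1, 4 * ch[s], ch[s])
    }
  }
  add_conv_param(net, "aspp.b0", 1, 1, ch[4], a)
  for (i in seq_along(ASPP_RATES))
    add_conv_param(net, sprintf("aspp.b%d", i), 3, 3, ch[4], a)
  add_conv_param(net, "aspp.pool", 1, 1, ch[4], a)
  add_conv_param(net, "aspp.proj", 1, 1, 5 * a, dc)
  add_conv_param(net, "gate.conv", 1, 1, ch[2], r)
  zc <- dc + r
  ca_mid <- max(2L, zc %/% 4L)
  add_conv_param(net, "dam.ca1", 1, 1, zc, ca_mid)
  add_conv_param(net, "dam.ca2", 1, 1, ca_mid, zc)
  add_conv_param(net, "dam.sa", 7, 7, 2, 1)
  add_conv_param(net, "fuse.conv", 3, 3, zc, dc)
  add_conv_param(net, "head.conv", 1, 1, dc, K, gain = 1)
  add_conv_param(net, "aux.conv", 1, 1, ch[3], K, gain = 1)
  zero_grads(net)
  class(net) <- c("seg_network", "weedadapt_net")
  net
}

convnext_block_f <- function(net, pf, x, cache) {
  y <- dwconv_f(net, paste0(pf, ".dw"), x, cache, stride = 1L, pad = 3L)
  y <- ln_f(net, paste0(pf, ".ln"), y, cache)
  y <- conv_f(net, paste0(pf, ".pw1"), y, cache)
  y <- gelu_f(y, cache, paste0(pf, ".act"))
  y <- conv_f(net, paste0(pf, ".pw2"), y, cache)
  x + y
}

convnext_block_b <- function(net, pf, dy, cache) {
  d <- conv_b(net, paste0(pf, ".pw2"), dy, cache)
  d <- gelu_b(d, cache, paste0(pf, ".act"))
  d <- conv_b(net, paste0(pf, ".pw1"), d, cache)
  d <- ln_b(net, paste0(pf, ".ln"), d, cache)
  d <- dwconv_b(net, paste0(pf, ".dw"), d, cache)
  dy + d
}

cat_channels <- function(xs) {
  d1 <- dim(xs[[1]])
  cs <- vapply(xs, function(x) dim(x)[3], 0)
  out <- array(0, dim = c(d1[1], d1[2], sum(cs), d1[4]))
  at <- 0
  for (x in xs) {
    cx <- dim(x)[3]
    out[, , at + seq_len(cx), ] <- x
    at <- at + cx
  }
  out
}

split_channels <- function(x, sizes) {
  at <- 0
  lapply(sizes, function(s) {
    sl <- x[, , at + seq_len(s), , drop = FALSE]
    at <<- at + s
    sl
  })
}

# Forward pass. Returns main/aux probability maps plus a cache for backward.
seg_forward <- function(net, x, keep_cache = TRUE) {
  cfg <- net$config
  d <- dim(x)
  if (d[1] %% SEG_STRIDE != 0 || d[2] %% SEG_STRIDE != 0)
    stop("input spatial dims must be divisible by ", SEG_STRIDE)
  H <- d[1]; W <- d[2]
  cache <- new.env(parent = emptyenv())
  h <- conv_f(net, "stem.conv1", x, cache, stride = 2L, pad = 3L)
  h <- ln_f(net, "stem.ln1", h, cache)
  h <- gelu_f(h, cache, "stem.act1")
  h <- conv_f(net, "stem.conv2", h, cache, stride = 2L, pad = 3L)
  h <- ln_f(net, "stem.ln2", h, cache)
  h <- gelu_f(h, cache, "stem.act2")
  stage_out <- vector("list", 4)
  for (s in 1:4) {
    if (s > 1) {
      h <- ln_f(net, sprintf("down%d.ln", s), h, cache)
      h <- conv_f(net, sprintf("down%d.conv", s), h, cache, stride = 2L)
    }
    for (b in seq_len(cfg$stage_depths[s]))
      h <- convnext_block_f(net, sprintf("stage%d.block%d", s, b), h, cache)
    stage_out[[s]] <- h
  }
  s2 <- stage_out[[2]]; s3 <- stage_out[[3]]; s4 <- stage_out[[4]]
  # ASPP
  b0 <- relu_f(conv_f(net, "aspp.b0", s4, cache), cache, "aspp.act0")
  br <- list(b0)
  for (i in seq_along(ASPP_RATES)) {
    nm <- sprintf("aspp.b%d", i)
    br[[i + 1]] <- relu_f(conv_f(net, nm, s4, cache, pad = ASPP_RATES[i],
                                 dil = ASPP_RATES[i]),
                          cache, sprintf("aspp.act%d", i))
  }
  gp <- gap_f(s4, cache, "aspp.gap")
  gp <- relu_f(conv_f(net, "aspp.pool", gp, cache), cache, "aspp.actp")
  d4 <- dim(s4)
  br[[5]] <- broadcast_spatial(gp, d4[1], d4[2])
  cache$aspp_sizes <- vapply(br, function(x) dim(x)[3], 0)
  acat <- cat_channels(br)
  A <- relu_f(conv_f(net, "aspp.proj", acat, cache), cache, "aspp.actproj")
  # decoder at 1/8 resolution
  d2 <- dim(s2)
  up1 <- resize_bilinear(A, d2[1], d2[2])
  cache$A_dims <- dim(A)
  g <- conv_f(net, "gate.conv", s2, cache)  # linear gating, no nonlinearity
  z <- cat_channels(list(up1, g))
  cache$z_sizes <- c(dim(up1)[3], dim(g)[3])
  # DAM: channel attention
  q <- gap_f(z, cache, "dam.gap")
  q <- relu_f(conv_f(net, "dam.ca1", q, cache), cache, "dam.caact")
  q <- conv_f(net, "dam.ca2", q, cache)
  ac <- sigmoid(q)
  cache$dam_ac <- ac; cache$dam_q <- q; cache$dam_z <- z
  acb <- broadcast_spatial(ac, d2[1], d2[2])
  z1 <- z * acb
  # DAM: spatial attention over channel mean / max
  dz <- dim(z1)
  zm <- matrix(aperm(z1, c(1, 2, 4, 3)), ncol = dz[3])  # (H*W*B) x C
  amax <- max.col(zm, ties.method = "first")
  mx <- zm[cbind(seq_len(nrow(zm)), amax)]
  mn <- rowMeans(zm)
  sa_in <- aperm(array(c(mn, mx), dim = c(dz[1], dz[2], dz[4], 2)), c(1, 2, 4, 3))
  cache$dam_amax <- amax; cache$dam_z1 <- z1
  sl <- conv_f(net, "dam.sa", sa_in, cache, pad = 3L)
  as_ <- sigmoid(sl)
  cache$dam_as <- as_
  asb <- array(rep(as.vector(as_), times = dz[3]), dim = c(dz[1], dz[2], dz[4], dz[3]))
  asb <- aperm(asb, c(1, 2, 4, 3))
  z2 <- z1 * asb
  cache$dam_asb <- asb
  f <- relu_f(conv_f(net, "fuse.conv", z2, cache, pad = 1L), cache, "fuse.act")
  logits <- conv_f(net, "head.conv", f, cache)
  logits_up <- resize_bilinear(logits, H, W)
  main_probs <- softmax_channels(logits_up)
  aux_logits <- conv_f(net, "aux.conv", s3, cache)
  aux_up <- resize_bilinear(aux_logits, H, W)
  aux_probs <- softmax_channels(aux_up)
  cache$main_probs <- main_probs
  cache$aux_probs <- aux_probs
  cache$logits_dims <- dim(logits)
  cache$aux_logits_dims <- dim(aux_logits)
  cache$in_dims <- d
  list(main_probs = main_probs, aux_probs = aux_probs,
       cache = if (keep_cache) cache else NULL)
}

# Backward pass from gradients w.r.t. the two probability maps.
seg_backward <- function(net, cache, dmain = NULL, daux = NULL) {
  cfg <- net$config
  # auxiliary branch
  ds3_aux <- NULL
  if (!is.null(daux)) {
    dz <- softmax_channels_back(cache$aux_probs, daux)
    dz <- resize_bilinear_back(dz, cache$aux_logits_dims[1], cache$aux_logits_dims[2])
    ds3_aux <- conv_b(net, "aux.conv", dz, cache)
  }
  dh <- NULL
  if (!is.null(dmain)) {
    dz <- softmax_channels_back(cache$main_probs, dmain)
    dz <- resize_bilinear_back(dz, cache$logits_dims[1], cache$logits_dims[2])
    df <- conv_b(net, "head.conv", dz, cache)
    df <- relu_b(df, cache, "fuse.act")
    dz2 <- conv_b(net, "fuse.conv", df, cache)
    # spatial attention backward
    z1 <- cache$dam_z1; asb <- cache$dam_asb; as_ <- cache$dam_as
    dz1 <- dz2 * asb
    dims <- dim(z1)
    das_full <- dz2 * z1
    das <- rowSums(aperm(das_full, c(1, 2, 4, 3)), dims = 3)  # sum over C
    das <- array(das, dim = c(dims[1], dims[2], 1, dims[4]))
    dsl <- das * as_ * (1 - as_)
    dsa_in <- conv_b(net, "dam.sa", dsl, cache)
    # route mean/max channel gradients back into z1
    n <- dims[1] * dims[2] * dims[4]
    dmn <- as.vector(dsa_in[, , 1, , drop = FALSE])
    dmx <- as.vector(dsa_in[, , 2, , drop = FALSE])
    dz1m <- matrix(0, nrow = n, ncol = dims[3])
    dz1m <- dz1m + dmn / dims[3]
    dz1m[cbind(seq_len(n), cache$dam_amax)] <-
      dz1m[cbind(seq_len(n), cache$dam_amax)] + dmx
    dz1 <- dz1 + aperm(array(dz1m, dim = c(dims[1], dims[2], dims[4], dims[3])),
                       c(1, 2, 4, 3))
    # channel attention backward
    z <- cache$dam_z; ac <- cache$dam_ac
    acb <- broadcast_spatial(ac, dims[1], dims[2])
    dzc <- dz1 * acb
    dac <- broadcast_spatial_back(dz1 * z)
    dq <- dac * ac * (1 - ac)
    dq <- conv_b(net, "dam.ca2", dq, cache)
    dq <- relu_b(dq, cache, "dam.caact")
    dq <- conv_b(net, "dam.ca1", dq, cache)
    dzc <- dzc + gap_b(dq, cache, "dam.gap")
    # split concat into decoder / gate paths
    parts <- split_channels(dzc, cache$z_sizes)
    dup1 <- parts[[1]]; dg <- parts[[2]]
    ds2_gate <- conv_b(net, "gate.conv", dg, cache)
    dA <- resize_bilinear_back(dup1, cache$A_dims[1], cache$A_dims[2])
    dA <- relu_b(dA, cache, "aspp.actproj")
    dacat <- conv_b(net, "aspp.proj", dA, cache)
    brs <- split_channels(dacat, cache$aspp_sizes)
    ds4 <- NULL
    d0 <- relu_b(brs[[1]], cache, "aspp.act0")
    ds4 <- conv_b(net, "aspp.b0", d0, cache)
    for (i in seq_along(ASPP_RATES)) {
      di <- relu_b(brs[[i + 1]], cache, sprintf("aspp.act%d", i))
      ds4 <- ds4 + conv_b(net, sprintf("aspp.b%d", i), di, cache)
    }
    dgp <- broadcast_spatial_back(brs[[5]])
    dgp <- relu_b(dgp, cache, "aspp.actp")
    dgp <- conv_b(net, "aspp.pool", dgp, cache)
    ds4 <- ds4 + gap_b(dgp, cache, "aspp.gap")
    dh <- ds4
  }
  # walk encoder stages backwards, injecting skip/aux gradients
  for (s in 4:1) {
    if (s == 3 && !is.null(ds3_aux))
      dh <- if (is.null(dh)) ds3_aux else dh + ds3_aux
    if (s == 2 && !is.null(dmain))
      dh <- if (is.null(dh)) ds2_gate else dh + ds2_gate
    if (is.null(dh)) next
    for (b in rev(seq_len(cfg$stage_depths[s])))
      dh <- convnext_block_b(net, sprintf("stage%d.block%d", s, b), dh, cache)
    if (s > 1) {
      dh <- conv_b(net, sprintf("down%d.conv", s), dh, cache)
      dh <- ln_b(net, sprintf("down%d.ln", s), dh, cache)
    }
  }
  if (is.null(dh)) return(invisible(NULL))
  dh <- gelu_b(dh, cache, "stem.act2")
  dh <- ln_b(net, "stem.ln2", dh, cache)
  dh <- conv_b(net, "stem.conv2", dh, cache)
  dh <- gelu_b(dh, cache, "stem.act1")
  dh <- ln_b(net, "stem.ln1", dh, cache)
  dh <- conv_b(net, "stem.conv1", dh, cache)
  invisible(dh)
}

#' Apply the skip-connection gating function
#'
#' The gating function is a learnable 1x1 convolution reducing a feature
#' map to `r` channels (suppressing low-level information) before the skip
#' concatenation. This standalone version draws fresh weights from the
#' current random stream; inside the network the gate's parameters are
#' part of the model.
#'
#' @param features array `(H, W, C)` or `(H, W, C, B)` with `C >= r`.
#' @param r output channel count (> 0).
#' @param W,b optional explicit kernel `(1, 1, C, r)` and bias.
#' @return array with `r` channels and unchanged spatial dims.
#' @export
gate_skip_features <- function(features, r, W = NULL, b = NULL) {
  if (r <= 0) stop("r must be positive")
  features <- as_batch(features)
  C <- dim(features)[3]
  if (C < r) stop("features must have at least r channels")
  if (is.null(W)) W <- array(stats::rnorm(C * r, sd = sqrt(1 / C)), dim = c(1, 1, C, r))
  if (is.null(b)) b <- numeric(r)
  .cpp_conv2d_fwd(features, W, b, 1L, 0L, 1L)
}

# Normalize an 8-bit RGB image array (H,W,3) or batch to network input scale.
normalize_image <- function(x) {
  x <- as_batch(x)
  (x / 255 - 0.5) / 0.25
}

#' Run inference with the segmentation network
#'
#' @param network a `seg_network`.
#' @param image 8-bit RGB array `(H, W, 3)` or batch `(H, W, 3, B)`, or a
#'   `labeled_image`.
#' @param with_entropy also compute the normalized entropy map of the main
#'   head (as for target-domain inputs).
#' @return object of class `segmentation_output`: `main_probs`, `aux_probs`,
#'   `pred_mask` (argmax of the main head, values `0..K-1`) and optionally
#'   `entropy`.
#' @export
predict_segmentation <- function(network, image, with_entropy = FALSE) {
  if (inherits(image, "labeled_image")) image <- image$image
  x <- normalize_image(image)
  out <- seg_forward(network, x, keep_cache = FALSE)
  pm <- out$main_probs
  d <- dim(pm)
  K <- d[3]
  pmat <- matrix(aperm(pm, c(1, 2, 4, 3)), ncol = K)
  pred <- max.col(pmat, ties.method = "first") - 1L
  pred <- array(pred, dim = c(d[1], d[2], d[4]))
  res <- list(main_probs = pm, aux_probs = out$aux_probs,
              pred_mask = if (d[4] == 1L) pred[, , 1] else pred)
  if (with_entropy) res$entropy <- entropy_map(pm)
  structure(res, class = "segmentation_output")
}
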