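# Fully convolutional patch discriminator (PatchGAN): five 4x4 stride-2
# convolutions; the first four are followed by instance normalization and
# LeakyReLU(0.2); the last emits a 1-channel patch logit map. Total stride
# 32, so a 128x128 input yields a 4x4 logit map. It consumes K-channel
# softmax probability maps and scores each receptive-field patch as
# source (1) vs target (0).

DISC_STRIDE <- 32L

#' Build a patch discriminator
#'
#' @param num_classes input channel count K (the discriminator reads
#'   probability maps).
#' @param channels channel progression of the five layers; the published
#'   setting is `c(64, 128, 256, 512, 1)`.
#' @return environment of class `disc_network`.
#' @export
build_discriminator <- function(num_classes = 3,
                                channels = c(64L, 128L, 256L, 512L, 1L)) {
  stopifnot(length(channels) == 5, channels[5] == 1)
  net <- new_net(list(num_classes = as.integer(num_classes),
                      channels = as.integer(channels)))
  cin <- num_classes
  for (i in 1:5) {
    add_conv_param(net, sprintf("d%d", i), 4, 4, cin, channels[i],
                   gain = if (i == 5) 1 else 2)
    cin <- channels[i]
  }
  zero_grads(net)
  class(net) <- c("disc_network", "weedadapt_net")
  net
}

disc_forward <- function(net, x, keep_cache = TRUE) {
  d <- dim(x)
  if (d[1] < DISC_STRIDE || d[2] < DISC_STRIDE)
    stop("discriminator input spatial dims must be >= ", DISC_STRIDE)
  cache <- new.env(parent = emptyenv())
  h <- x
  for (i in 1:4) {
    h <- conv_f(net, sprintf("d%d", i), h, cache, stride = 2L, pad = 1L)
    h <- in_f(h, cache, sprintf("in%d", i))
    h <- lrelu_f(h, cache, sprintf("act%d", i))
  }
  logits <- conv_f(net, "d5", h, cache, stride = 2L, pad = 1L)
  list(logits = logits, cache = if (keep_cache) cache else NULL)
}

# Backward from d(loss)/d(logits); accumulates parameter gradients and
# returns the gradient w.r.t. the input probability map (needed for the
# adversarial update of the segmentation network).
disc_backward <- function(net, cache, dlogits) {
  dh <- conv_b(net, "d5", dlogits, cache)
  for (i in 4:1) {
    dh <- lrelu_b(dh, cache, sprintf("act%d", i))
    dh <- in_b(dh, cache, sprintf("in%d", i))
    dh <- conv_b(net, sprintf("d%d", i), dh, cache)
  }
  dh
}

# Gradient w.r.t. the input only, leaving the discriminator's own gradient
# accumulators untouched (used in phase 1, where discriminators are frozen).
disc_input_grad <- function(net, cache, dlogits) {
  saved <- net$grads
  dx <- disc_backward(net, cache, dlogits)
  net$grads <- saved
  dx
}
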