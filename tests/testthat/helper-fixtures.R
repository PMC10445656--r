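# Shared fixtures: tiny synthetic datasets and probability-map builders.

fixture_pair <- function(n_source = 6, n_target = 4, size = 64,
                         src_seed = 101L, tgt_seed = 20001L) {
  generate_domain_pair(domain_spec(seed = src_seed),
                       shifted_target_spec(seed = tgt_seed),
                       n_source, n_target, size, size)
}

# Probability map (H, W, K) with every pixel set to `p` (length K).
uniform_prob_map <- function(h, w, p) {
  K <- length(p)
  array(rep(p, each = h * w), dim = c(h, w, K))
}

# Random valid probability map via softmax of Gaussian logits.
random_prob_map <- function(h, w, K) {
  z <- array(rnorm(h * w * K), dim = c(h, w, K, 1))
  p <- weedadapt:::softmax_channels(z)
  array(p, dim = c(h, w, K))
}

# Central-difference gradient of scalar-valued f at x.
numeric_gradient <- function(f, x, eps = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

rel_err <- function(a, b) {
  max(abs(a - b)) / max(max(abs(a)), max(abs(b)), 1e-8)
}

tiny_train_config <- function(...) {
  training_config(epochs = 2, batch_size = 2, warmup_iters = 5,
                  network = network_config("tiny"), ...)
}
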