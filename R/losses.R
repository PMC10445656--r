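# Loss functions for the adversarial domain-adaptation objective.
# Probability maps are arrays (H, W, K) or (H, W, K, B); logit maps are
# (H, W, 1) or (H, W, 1, B). Every loss has an analytic gradient companion
# used by the training loop and checked against finite differences.

PROB_FLOOR <- 1e-7

as_batch <- function(x) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

#' Loss weights and penalty settings
#'
#' Container for the scalar weights of the composite training objective:
#' `lambda_aux` (auxiliary discriminator weight), `lambda_ent` (entropy
#' minimization weight), `lambda_adv` (adversarial weight), `lambda_seg`
#' (few-shot supervised target weight), the Charbonnier exponent `eta`
#' and constant `epsilon`. Defaults are the framework's published
#' hyperparameter table.
#'
#' @param lambda_aux,lambda_ent,lambda_adv,lambda_seg non-negative scalars.
#' @param eta Charbonnier exponent (penalizes high entropy more than low
#'   when `eta > 0.5`).
#' @param epsilon Charbonnier constant.
#' @param charbonnier if `FALSE`, the entropy penalty uses the squared
#'   (no square root) reading instead of the Charbonnier form.
#' @return an object of class `loss_weights`.
#' @export
loss_weights <- function(lambda_aux = 0.4, lambda_ent = 0.5, lambda_adv = 0.4,
                         lambda_seg = 2, eta = 2.0, epsilon = 1e-4,
                         charbonnier = TRUE) {
  vals <- c(lambda_aux, lambda_ent, lambda_adv, lambda_seg, eta, epsilon)
  if (any(vals < 0)) stop("loss weights must be non-negative")
  structure(list(lambda_aux = lambda_aux, lambda_ent = lambda_ent,
                 lambda_adv = lambda_adv, lambda_seg = lambda_seg,
                 eta = eta, epsilon = epsilon, charbonnier = charbonnier),
            class = "loss_weights")
}

#' Supervised segmentation loss (pixel-wise cross-entropy)
#'
#' Mean over pixels of the negative log-probability assigned to the true
#' class. Probabilities are floored at `1e-7` before the logarithm.
#'
#' @param probs probability map, array `(H, W, K)` or `(H, W, K, B)`.
#' @param labels integer mask `(H, W)` or `(H, W, B)` with values in `[0, K)`.
#' @return non-negative scalar.
#' @export
segmentation_loss <- function(probs, labels) {
  probs <- as_batch(probs)
  d <- dim(probs)
  K <- d[3]
  lab <- as.integer(labels)
  if (any(lab < 0L) || any(lab >= K))
    stop("labels must lie in [0, K)")
  pt <- prob_at_label(probs, lab)
  mean(-log(pmax(pt, PROB_FLOOR)))
}

# Extract per-pixel probability of the labelled class.
prob_at_label <- function(probs, lab) {
  d <- dim(probs)
  H <- d[1]; W <- d[2]; K <- d[3]; B <- d[4]
  pix <- seq_len(H * W * B) - 1L
  img <- pix %/% (H * W)
  within <- pix %% (H * W)
  idx <- within + H * W * (lab + K * img) + 1
  probs[idx]
}

#' @rdname segmentation_loss
#' @return `grad_segmentation_loss`: array like `probs` holding
#'   d(loss)/d(probs).
#' @export
grad_segmentation_loss <- function(probs, labels) {
  probs <- as_batch(probs)
  d <- dim(probs)
  H <- d[1]; W <- d[2]; K <- d[3]; B <- d[4]
  lab <- as.integer(labels)
  if (any(lab < 0L) || any(lab >= K)) stop("labels must lie in [0, K)")
  g <- array(0, dim = d)
  pix <- seq_len(H * W * B) - 1L
  img <- pix %/% (H * W)
  within <- pix %% (H * W)
  idx <- within + H * W * (lab + K * img) + 1
  pt <- probs[idx]
  n <- H * W * B
  g[idx] <- ifelse(pt >= PROB_FLOOR, -1 / (n * pt), 0)
  g
}

#' Normalized per-pixel entropy map
#'
#' Shannon entropy of each pixel's class distribution divided by `log(K)`,
#' so a uniform distribution maps to 1 and a one-hot distribution to 0.
#'
#' @param probs probability map `(H, W, K)` or `(H, W, K, B)`.
#' @return array `(H, W)` or `(H, W, B)` with values in `[0, 1]`.
#' @export
entropy_map <- function(probs) {
  probs <- as_batch(probs)
  d <- dim(probs)
  K <- d[3]
  if (K < 2) stop("entropy_map requires K >= 2 classes")
  pc <- pmax(probs, PROB_FLOOR)
  e <- -rowSums(aperm(probs * log(pc), c(1, 2, 4, 3)), dims = 3) / log(K)
  e <- pmin(pmax(e, 0), 1)
  if (d[4] == 1L) dim(e) <- d[1:2] else dim(e) <- d[c(1, 2, 4)]
  e
}

# d(entropy at each pixel)/d(probs); same shape as probs.
grad_entropy_map <- function(probs) {
  probs <- as_batch(probs)
  K <- dim(probs)[3]
  pc <- pmax(probs, PROB_FLOOR)
  g <- -(log(pc) + 1) / log(K)
  g * (probs >= PROB_FLOOR)
}

#' Robust entropy loss (Charbonnier penalty)
#'
#' `L_ent = (mean_i sqrt(e_i^2 + epsilon^2))^eta`. With `eta > 0.5` high
#' entropy pixels are penalized more strongly than low entropy ones, which
#' makes minimization effective even in already-confident regions. With
#' `charbonnier = FALSE` in `weights` the square root is dropped:
#' `(mean_i (e_i^2 + epsilon^2))^eta`.
#'
#' @param e entropy map (any-dimension numeric array with values in `[0,1]`).
#' @param weights a [loss_weights()] object (uses `eta`, `epsilon`,
#'   `charbonnier`).
#' @return non-negative scalar, strictly increasing in every entry of `e`.
#' @export
entropy_loss <- function(e, weights = loss_weights()) {
  if (weights$charbonnier) {
    mean(sqrt(e^2 + weights$epsilon^2))^weights$eta
  } else {
    mean(e^2 + weights$epsilon^2)^weights$eta
  }
}

#' @rdname entropy_loss
#' @return `grad_entropy_loss`: array like `e` with d(loss)/d(e).
#' @export
grad_entropy_loss <- function(e, weights = loss_weights()) {
  n <- length(e)
  if (weights$charbonnier) {
    rho <- sqrt(e^2 + weights$epsilon^2)
    s <- mean(rho)
    weights$eta * s^(weights$eta - 1) * (e / rho) / n
  } else {
    s <- mean(e^2 + weights$epsilon^2)
    weights$eta * s^(weights$eta - 1) * 2 * e / n
  }
}

# Numerically stable binary cross-entropy with logits against constant target.
bce_logits <- function(x, target) {
  mean(pmax(x, 0) - x * target + log1p(exp(-abs(x))))
}

grad_bce_logits <- function(x, target) {
  (sigmoid(x) - target) / length(x)
}

#' Discriminator loss (source vs target patches)
#'
#' Mean binary cross-entropy of source patch logits against the source
#' label 1 plus mean BCE of target patch logits against the target label 0.
#'
#' @param src_logits,tgt_logits 1-channel patch logit maps.
#' @return non-negative scalar.
#' @export
discriminator_loss <- function(src_logits, tgt_logits) {
  bce_logits(src_logits, 1) + bce_logits(tgt_logits, 0)
}

#' @rdname discriminator_loss
#' @return `grad_discriminator_loss`: list with `d_src` and `d_tgt`.
#' @export
grad_discriminator_loss <- function(src_logits, tgt_logits) {
  list(d_src = grad_bce_logits(src_logits, 1),
       d_tgt = grad_bce_logits(tgt_logits, 0))
}

#' Total discriminator objective
#'
#' Combines the decoder-level and auxiliary (encoder-level) discriminator
#' losses: `L_D = L_d + lambda_aux * L_d_aux`.
#'
#' @param L_d,L_d_aux non-negative scalars.
#' @param weights a [loss_weights()] object.
#' @return scalar.
#' @export
total_discriminator_loss <- function(L_d, L_d_aux, weights = loss_weights()) {
  if (L_d < 0 || L_d_aux < 0) stop("discriminator losses must be >= 0")
  L_d + weights$lambda_aux * L_d_aux
}

#' Adversarial loss for the segmentation network
#'
#' Mean BCE of the discriminator's target-domain patch logits against the
#' source label 1: minimizing it trains the segmenter to make target
#' predictions indistinguishable from source predictions.
#'
#' @param tgt_logits 1-channel patch logit map for target-domain inputs.
#' @return non-negative scalar.
#' @export
adversarial_loss <- function(tgt_logits) {
  bce_logits(tgt_logits, 1)
}

#' @rdname adversarial_loss
#' @export
grad_adversarial_loss <- function(tgt_logits) {
  grad_bce_logits(tgt_logits, 1)
}

#' Composite segmentation objective
#'
#' Unsupervised mode: `L_seg + lambda_ent * L_ent + lambda_adv * L_adv`.
#' Few-shot mode (`j_shot > 0` and `parts$L_seg_hat` supplied) adds
#' `lambda_seg * L_seg_hat`, the supervised cross-entropy on the j labelled
#' target images.
#'
#' @param parts list with elements `L_seg`, `L_ent`, `L_adv` and optionally
#'   `L_seg_hat`.
#' @param weights a [loss_weights()] object.
#' @param j_shot number of labelled target images (0 = unsupervised).
#' @return scalar total objective.
#' @export
total_segmentation_objective <- function(parts, weights = loss_weights(),
                                         j_shot = 0) {
  stopifnot(all(c("L_seg", "L_ent", "L_adv") %in% names(parts)))
  if (!is.null(parts$L_seg_hat) && j_shot == 0)
    stop("L_seg_hat supplied but j_shot is 0; few-shot term requires j >= 1")
  total <- parts$L_seg + weights$lambda_ent * parts$L_ent +
    weights$lambda_adv * parts$L_adv
  if (j_shot > 0 && !is.null(parts$L_seg_hat))
    total <- total + weights$lambda_seg * parts$L_seg_hat
  total
}

# Combined d(entropy_loss(entropy_map(probs)))/d(probs), used in training.
grad_entropy_objective <- function(probs, weights = loss_weights()) {
  probs <- as_batch(probs)
  e <- entropy_map(probs)
  de <- grad_entropy_loss(e, weights)
  ge <- grad_entropy_map(probs)
  d <- dim(probs)
  # broadcast de (H,W[,B]) over the K axis
  deb <- array(rep(as.vector(de), times = d[3]), dim = c(d[1], d[2], if (length(dim(e)) == 3) d[4] else 1, d[3]))
  deb <- aperm(deb, c(1, 2, 4, 3))
  ge * deb
}

# Validate a probability map's normalization (module-surface checker).
validate_probability_map <- function(probs, tol = 1e-5) {
  probs <- as_batch(probs)
  s <- rowSums(aperm(probs, c(1, 2, 4, 3)), dims = 3)
  if (any(abs(s - 1) > tol)) stop("probability map rows do not sum to 1")
  invisible(TRUE)
}
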