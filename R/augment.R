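# Augmentation categories and the progressive activation schedule.
#
# Three categories: geometric (G) transforms the image-mask pair, noise
# (D) distorts the image only, collage (C) tiles M image-mask pairs into
# one composite. Training starts with identity only, then category
# activation probabilities ramp up one category at a time (G, then D,
# then C), each over lambda_aug epochs, to ceilings alpha / beta / gamma.

#' Augmentation configuration
#'
#' @param alpha,beta,gamma ceiling probabilities in `[0, 1]` for the
#'   geometric, noise and collage categories (published setting: 0.3 each).
#' @param lambda_aug epochs per activation phase (>= 1; published: 20).
#' @param collage_grid integer `(rows, cols)`; the collage tiles
#'   `M = rows * cols` samples.
#' @param collage_border_px border width b_c in pixels between tiles (>= 0);
#'   border pixels carry class 0.
#' @param collage_size output `(width, height)` of a collage; `NULL` means
#'   "same as the input images".
#' @param vanilla if `TRUE`, all three probabilities are constant at their
#'   ceilings from epoch 0 (the constant-probability baseline used in the
#'   scheduling ablation).
#' @return object of class `augmentation_config`.
#' @export
augmentation_config <- function(alpha = 0.3, beta = 0.3, gamma = 0.3,
                                lambda_aug = 20, collage_grid = c(2L, 2L),
                                collage_border_px = 2L, collage_size = NULL,
                                vanilla = FALSE) {
  probs <- c(alpha, beta, gamma)
  if (any(probs < 0) || any(probs > 1))
    stop("alpha, beta and gamma must lie in [0, 1]")
  if (lambda_aug < 1) stop("lambda_aug must be >= 1")
  grid <- as.integer(collage_grid)
  if (length(grid) != 2 || any(grid < 1) || prod(grid) < 1)
    stop("collage_grid must be two positive integers")
  if (collage_border_px < 0) stop("collage_border_px must be >= 0")
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 lambda_aug = lambda_aug, collage_grid = grid,
                 collage_border_px = as.integer(collage_border_px),
                 collage_size = collage_size, vanilla = vanilla),
            class = "augmentation_config")
}

ramp <- function(epoch, onset, duration, ceiling) {
  if (epoch <= onset) return(0)
  if (epoch >= onset + duration) return(ceiling)
  ceiling * (epoch - onset) / duration
}

#' Scheduled augmentation probabilities at an epoch
#'
#' Staged piecewise-linear ramps: geometric ramps from 0 to `alpha` over
#' epochs `[lambda_aug, 2 lambda_aug]`, noise from 0 to `beta` over
#' `[2 lambda_aug, 3 lambda_aug]`, collage from 0 to `gamma` over
#' `[3 lambda_aug, 4 lambda_aug]`. Every probability is non-decreasing in
#' the epoch and 0 at epoch 0 (identity augmentation only). With
#' `config$vanilla` the ceilings apply from epoch 0.
#'
#' @param epoch training epoch (>= 0).
#' @param config an [augmentation_config()].
#' @return object of class `schedule_state` with fields `epoch`,
#'   `p_geometric`, `p_noise`, `p_collage`.
#' @export
schedule_probabilities <- function(epoch, config = augmentation_config()) {
  if (epoch < 0) stop("epoch must be >= 0")
  la <- config$lambda_aug
  if (config$vanilla) {
    st <- list(epoch = epoch, p_geometric = config$alpha,
               p_noise = config$beta, p_collage = config$gamma)
  } else {
    st <- list(epoch = epoch,
               p_geometric = ramp(epoch, la, la, config$alpha),
               p_noise = ramp(epoch, 2 * la, la, config$beta),
               p_collage = ramp(epoch, 3 * la, la, config$gamma))
  }
  structure(st, class = "schedule_state")
}

clip8 <- function(x) {
  x <- round(x)
  x[x < 0] <- 0
  x[x > 255] <- 255
  array(as.integer(x), dim = dim(x))
}

# Nearest-neighbor resize for integer masks.
resize_nearest_mask <- function(mask, h, w) {
  d <- dim(mask)
  ih <- pmin(pmax(floor((seq_len(h) - 0.5) * d[1] / h) + 1, 1), d[1])
  iw <- pmin(pmax(floor((seq_len(w) - 0.5) * d[2] / w) + 1, 1), d[2])
  mask[ih, iw, drop = FALSE]
}

resize_image_bilinear <- function(image, h, w) {
  d <- dim(image)
  x <- array(as.numeric(image), dim = c(d[1], d[2], d[3], 1))
  clip8(resize_bilinear(x, h, w)[, , , 1])
}

GEOMETRIC_TRANSFORMS <- c("hflip", "vflip", "rot90", "rot180", "rot270", "scale_crop")

rot90_arr <- function(x) {
  # counter-clockwise quarter turn of (H,W[,C])
  if (length(dim(x)) == 3) aperm(x, c(2, 1, 3))[rev(seq_len(dim(x)[2])), , , drop = FALSE]
  else t(x)[rev(seq_len(ncol(x))), , drop = FALSE]
}

#' Apply one geometric augmentation to an image-mask pair
#'
#' Draws one transform from horizontal flip, vertical flip, quarter-turn
#' rotations and scale-crop, and applies it identically to image and mask
#' (nearest-neighbor interpolation for the mask). Quarter turns are only
#' drawn for square images.
#'
#' @param image H x W x 3 integer array (0-255).
#' @param mask H x W integer mask.
#' @param transform optional fixed transform name ("hflip", "vflip",
#'   "rot90", "rot180", "rot270", "scale_crop"); default draws one at
#'   random.
#' @param scale scale factor for `"scale_crop"`; default drawn from
#'   U(1, 1.3). `scale = 1` is the identity.
#' @return list `(image, mask)`.
#' @export
apply_geometric <- function(image, mask, transform = NULL, scale = NULL) {
  stopifnot(all(dim(image)[1:2] == dim(mask)))
  square <- dim(image)[1] == dim(image)[2]
  pool <- if (square) GEOMETRIC_TRANSFORMS else setdiff(GEOMETRIC_TRANSFORMS, c("rot90", "rot270"))
  tr <- transform %||% sample(pool, 1)
  h <- dim(image)[1]; w <- dim(image)[2]
  switch(tr,
    hflip = list(image = image[, rev(seq_len(w)), , drop = FALSE],
                 mask = mask[, rev(seq_len(w)), drop = FALSE]),
    vflip = list(image = image[rev(seq_len(h)), , , drop = FALSE],
                 mask = mask[rev(seq_len(h)), , drop = FALSE]),
    rot90 = list(image = rot90_arr(image), mask = rot90_arr(mask)),
    rot180 = list(image = image[rev(seq_len(h)), rev(seq_len(w)), , drop = FALSE],
                  mask = mask[rev(seq_len(h)), rev(seq_len(w)), drop = FALSE]),
    rot270 = list(image = rot90_arr(rot90_arr(rot90_arr(image))),
                  mask = rot90_arr(rot90_arr(rot90_arr(mask)))),
    scale_crop = {
      s <- scale %||% stats::runif(1, 1, 1.3)
      if (s == 1) {
        list(image = image, mask = mask)
      } else {
        hh <- round(h * s); ww <- round(w * s)
        im2 <- resize_image_bilinear(image, hh, ww)
        mk2 <- resize_nearest_mask(mask, hh, ww)
        y0 <- sample.int(hh - h + 1, 1); x0 <- sample.int(ww - w + 1, 1)
        list(image = im2[y0:(y0 + h - 1), x0:(x0 + w - 1), , drop = FALSE],
             mask = mk2[y0:(y0 + h - 1), x0:(x0 + w - 1), drop = FALSE])
      }
    },
    stop("unknown geometric transform: ", tr))
}

NOISE_TRANSFORMS <- c("gaussian_noise", "gaussian_blur", "brightness_contrast",
                      "hue_jitter", "motion_blur")

#' Apply one noise (distortion) augmentation to an image
#'
#' Draws one transform from Gaussian noise, Gaussian blur,
#' brightness/contrast jitter, hue jitter and motion blur; the label mask
#' is untouched by contract. Output stays in the valid 8-bit range.
#'
#' @param image H x W x 3 integer array (0-255).
#' @param kind optional fixed transform name.
#' @param strength multiplier on the transform magnitude; 0 is the identity.
#' @return distorted image (integer, 0-255).
#' @export
apply_noise <- function(image, kind = NULL, strength = 1) {
  tr <- kind %||% sample(NOISE_TRANSFORMS, 1)
  if (strength == 0) return(image)
  x <- as.numeric(image)
  dim(x) <- dim(image)
  out <- switch(tr,
    gaussian_noise = x + stats::rnorm(length(x), 0, 10 * strength),
    gaussian_blur = blur_image(x / 255, 1.2 * strength) * 255,
    brightness_contrast = {
      b <- stats::runif(1, -30, 30) * strength
      ct <- 1 + stats::runif(1, -0.25, 0.25) * strength
      (x - 127.5) * ct + 127.5 + b
    },
    hue_jitter = {
      d <- dim(x)
      m <- rbind(as.vector(x[, , 1]), as.vector(x[, , 2]), as.vector(x[, , 3]))
      hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
      dh <- stats::runif(1, -25, 25) * strength / 360
      rgb <- hsv_to_rgb((hsv["h", ] + dh) * 360, hsv["s", ], hsv["v", ])
      array(c(rgb$r, rgb$g, rgb$b), dim = d) * 255
    },
    motion_blur = {
      len <- max(3L, as.integer(round(5 * strength)))
      if (len %% 2L == 0L) len <- len + 1L
      horiz <- stats::runif(1) < 0.5
      k <- rep(1 / len, len)
      d <- dim(x)
      xb <- array(x / 255, dim = c(d[1], d[2], 3, 1))
      W <- if (horiz) array(rep(k, each = 1, times = 3), dim = c(1, len, 3))
           else array(rep(k, times = 3), dim = c(len, 1, 3))
      pad_h <- if (horiz) 0L else (len - 1L) %/% 2L
      pad_w <- if (horiz) (len - 1L) %/% 2L else 0L
      # depthwise conv expects square padding; pad manually for the long axis
      num <- .cpp_dwconv2d_fwd(xb, W, numeric(3), 1L, max(pad_h, pad_w))
      den <- .cpp_dwconv2d_fwd(array(1, dim(xb)), W, numeric(3), 1L, max(pad_h, pad_w))
      y <- num / den
      # crop back to original size (padding was applied on both axes)
      dy <- dim(y)
      oh <- (dy[1] - d[1]) %/% 2; ow <- (dy[2] - d[2]) %/% 2
      y[oh + seq_len(d[1]), ow + seq_len(d[2]), , 1, drop = FALSE] * 255
    },
    stop("unknown noise transform: ", tr))
  dim(out) <- dim(image)
  clip8(out)
}

#' Tile image-mask pairs into a collage
#'
#' Draws `M = rows * cols` samples, resizes each to the implied cell size
#' and tiles them into a `w_c x h_c` composite with `b_c`-pixel borders
#' between cells; border pixels carry class 0 in the mask (and black in
#' the image).
#'
#' @param samples list of `labeled_image` or `list(image, mask)` pairs,
#'   length >= M.
#' @param config an [augmentation_config()].
#' @return list `(image, mask)` of the collage.
#' @export
make_collage <- function(samples, config = augmentation_config()) {
  grid <- config$collage_grid
  M <- prod(grid)
  if (length(samples) < M)
    stop("make_collage needs at least ", M, " samples")
  b <- config$collage_border_px
  sz <- config$collage_size %||% rev(dim(samples[[1]]$image)[1:2])  # (w, h)
  wc <- as.integer(sz[1]); hc <- as.integer(sz[2])
  rows <- grid[1]; cols <- grid[2]
  ch <- (hc - (rows - 1L) * b) %/% rows
  cw <- (wc - (cols - 1L) * b) %/% cols
  if (ch <= 0 || cw <= 0)
    stop("collage cell size is not positive after border subtraction")
  pick <- if (length(samples) == M) seq_len(M) else sample(length(samples), M)
  img <- array(0L, dim = c(hc, wc, 3))
  mask <- matrix(0L, hc, wc)
  idx <- 1
  for (r in seq_len(rows)) {
    for (cl in seq_len(cols)) {
      s <- samples[[pick[idx]]]
      idx <- idx + 1
      ci <- resize_image_bilinear(s$image, ch, cw)
      cm <- resize_nearest_mask(s$mask, ch, cw)
      y0 <- (r - 1L) * (ch + b) + 1L
      x0 <- (cl - 1L) * (cw + b) + 1L
      img[y0:(y0 + ch - 1L), x0:(x0 + cw - 1L), ] <- ci
      mask[y0:(y0 + ch - 1L), x0:(x0 + cw - 1L)] <- cm
    }
  }
  list(image = img, mask = mask)
}

#' Augment a batch of source-domain samples
#'
#' Each category is applied independently with its scheduled probability:
#' geometric and noise per sample; a triggered collage consumes the next
#' `M` samples of the batch and yields a single composite sample (the
#' batch may therefore shrink). Samples with no draw pass through
#' unchanged. Only source-domain samples may be augmented.
#'
#' @param batch list of `labeled_image` (all `role == "source"`).
#' @param state a `schedule_state` from [schedule_probabilities()].
#' @param config an [augmentation_config()].
#' @return list of augmented `labeled_image`; attributes `n_geometric`,
#'   `n_noise`, `n_collage` count category applications.
#' @export
augment_batch <- function(batch, state, config = augmentation_config()) {
  roles <- vapply(batch, function(s) s$role %||% "source", "")
  if (any(roles == "target"))
    stop("augment_batch received a target-domain sample; only source images are augmented")
  n_g <- 0L; n_n <- 0L; n_c <- 0L
  out <- lapply(batch, function(s) {
    if (stats::runif(1) < state$p_geometric) {
      r <- apply_geometric(s$image, s$mask)
      s$image <- r$image; s$mask <- r$mask
      n_g <<- n_g + 1L
    }
    if (stats::runif(1) < state$p_noise) {
      s$image <- apply_noise(s$image)
      n_n <<- n_n + 1L
    }
    s
  })
  M <- prod(config$collage_grid)
  if (state$p_collage > 0 && length(out) >= M) {
    res <- list()
    i <- 1
    while (i <= length(out)) {
      if (length(out) - i + 1 >= M && stats::runif(1) < state$p_collage) {
        grp <- out[i:(i + M - 1)]
        cg <- make_collage(grp, config)
        s <- grp[[1]]
        s$image <- cg$image; s$mask <- cg$mask
        res[[length(res) + 1]] <- s
        n_c <- n_c + 1L
        i <- i + M
      } else {
        res[[length(res) + 1]] <- out[[i]]
        i <- i + 1
      }
    }
    out <- res
  }
  attr(out, "n_geometric") <- n_g
  attr(out, "n_noise") <- n_n
  attr(out, "n_collage") <- n_c
  out
}
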