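# Synthetic domain-parameterized field imagery with pixel-perfect masks.
#
# A domain is a rendering recipe: soil color and texture, flat vs ridged
# seeding bed, illumination, acquisition blur (moving platform), crop row
# layout, weed density and a vegetation hue shift. Crops render as
# near-circular discs with low-frequency boundary perturbation placed on
# evenly spaced rows; weeds render as star-like blobs with high-frequency
# boundaries scattered uniformly, so shape as well as color separates the
# classes. Classes: 0 = background (soil), 1 = crop, 2 = weed.

#' Domain specification for the synthetic field generator
#'
#' @param soil_hue soil hue in degrees `[0, 360)`.
#' @param soil_brightness mean soil brightness fraction `[0, 1]`.
#' @param illumination_gain global multiplicative gain (> 0) applied to the
#'   rendered image (sunny vs overcast).
#' @param blur_sigma Gaussian blur sigma in pixels (>= 0); emulates a
#'   moving acquisition platform (0 = stationary).
#' @param crop_rows number of planted crop rows (>= 0).
#' @param crop_radius_px mean crop blob radius in pixels (> 0).
#' @param weed_density expected number of weed instances per image (>= 0,
#'   Poisson distributed).
#' @param ridge_amplitude `[0, 1]`; 0 renders a flat seeding bed, > 0
#'   renders periodic ridge/furrow brightness stripes parallel to the rows.
#' @param hue_shift_vegetation hue shift in degrees applied to all plants.
#' @param seed integer seed making generation deterministic.
#' @return object of class `domain_spec`.
#' @export
domain_spec <- function(soil_hue = 30, soil_brightness = 0.45,
                        illumination_gain = 1, blur_sigma = 0,
                        crop_rows = 3, crop_radius_px = 10,
                        weed_density = 3, ridge_amplitude = 0,
                        hue_shift_vegetation = 0, seed = 1L) {
  if (soil_hue < 0 || soil_hue >= 360) stop("soil_hue must be in [0, 360)")
  if (soil_brightness < 0 || soil_brightness > 1)
    stop("soil_brightness must be in [0, 1]")
  if (illumination_gain <= 0) stop("illumination_gain must be > 0")
  if (blur_sigma < 0) stop("blur_sigma must be >= 0")
  if (crop_rows < 0) stop("crop_rows must be >= 0")
  if (crop_radius_px <= 0) stop("crop_radius_px must be > 0")
  if (weed_density < 0) stop("weed_density must be >= 0")
  if (ridge_amplitude < 0 || ridge_amplitude > 1)
    stop("ridge_amplitude must be in [0, 1]")
  structure(list(soil_hue = soil_hue, soil_brightness = soil_brightness,
                 illumination_gain = illumination_gain, blur_sigma = blur_sigma,
                 crop_rows = as.integer(crop_rows),
                 crop_radius_px = crop_radius_px, weed_density = weed_density,
                 ridge_amplitude = ridge_amplitude,
                 hue_shift_vegetation = hue_shift_vegetation,
                 seed = as.integer(seed)),
            class = "domain_spec")
}

# Vectorized HSV -> RGB; h in degrees, s/v in [0,1]; arguments recycle to a
# common length. Returns list(r, g, b) of that length.
hsv_to_rgb <- function(h, s, v) {
  n <- max(length(h), length(s), length(v))
  h <- rep_len(as.vector(h), n)
  s <- rep_len(as.vector(s), n)
  v <- rep_len(as.vector(v), n)
  hh <- (h %% 360) / 60
  i <- floor(hh) %% 6
  f <- hh - floor(hh)
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  tt <- v * (1 - s * (1 - f))
  r <- v; g <- tt; b <- p                      # sector 0
  for (sec in 1:5) {
    m <- i == sec
    if (!any(m)) next
    if (sec == 1) { r[m] <- q[m]; g[m] <- v[m]; b[m] <- p[m] }
    if (sec == 2) { r[m] <- p[m]; g[m] <- v[m]; b[m] <- tt[m] }
    if (sec == 3) { r[m] <- p[m]; g[m] <- q[m]; b[m] <- v[m] }
    if (sec == 4) { r[m] <- tt[m]; g[m] <- p[m]; b[m] <- v[m] }
    if (sec == 5) { r[m] <- v[m]; g[m] <- p[m]; b[m] <- q[m] }
  }
  list(r = r, g = g, b = b)
}

# Multi-octave value noise in [0, 1], drawn from the current RNG stream.
value_noise <- function(h, w, octaves = 4, base = 4) {
  acc <- matrix(0, h, w)
  amp <- 1
  total <- 0
  for (o in seq_len(octaves)) {
    res <- base * 2^(o - 1)
    g <- array(stats::runif(res * res), dim = c(res, res, 1, 1))
    up <- resize_bilinear(g, h, w)[, , 1, 1]
    acc <- acc + amp * up
    total <- total + amp
    amp <- amp / 2
  }
  acc / total
}

# Rasterize one blob with angular radius perturbation into mask/value fields.
# Returns a logical matrix over the full image (TRUE = inside blob).
blob_pixels <- function(h, w, cy, cx, r0, radius_fn) {
  rmax <- r0 * 2
  y0 <- max(1, floor(cy - rmax)); y1 <- min(h, ceiling(cy + rmax))
  x0 <- max(1, floor(cx - rmax)); x1 <- min(w, ceiling(cx + rmax))
  if (y0 > y1 || x0 > x1) return(NULL)
  ys <- y0:y1; xs <- x0:x1
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  d <- sqrt(dy^2 + dx^2)
  th <- atan2(dy, dx)
  inside <- d <= radius_fn(th)
  list(ys = ys, xs = xs, inside = inside)
}

paint_blob <- function(img, mask, px, class_id, hue, sat, val_base, vnoise) {
  ys <- px$ys; xs <- px$xs
  sel <- which(px$inside, arr.ind = TRUE)
  if (nrow(sel) == 0) return(list(img = img, mask = mask))
  ry <- ys[sel[, 1]]; rx <- xs[sel[, 2]]
  v <- val_base * (0.75 + 0.5 * vnoise[cbind(ry, rx)])
  rgb <- hsv_to_rgb(hue, sat, pmin(v, 1))
  idx <- cbind(ry, rx)
  img[cbind(idx, 1)] <- rgb$r
  img[cbind(idx, 2)] <- rgb$g
  img[cbind(idx, 3)] <- rgb$b
  mask[idx] <- class_id
  list(img = img, mask = mask)
}

gaussian_kernel_1d <- function(sigma) {
  k <- 2L * as.integer(ceiling(2 * sigma)) + 1L
  x <- seq(-(k %/% 2), k %/% 2)
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

# Gaussian blur of an (H,W,3) image in [0,1]; edge-normalized.
blur_image <- function(img, sigma) {
  if (sigma <= 0) return(img)
  g <- gaussian_kernel_1d(sigma)
  k <- length(g)
  ker <- outer(g, g)
  d <- dim(img)
  x <- array(img, dim = c(d[1], d[2], 3, 1))
  W <- array(rep(ker, 3), dim = c(k, k, 3))
  pad <- (k - 1L) %/% 2L
  num <- .cpp_dwconv2d_fwd(x, W, numeric(3), 1L, pad)
  ones <- array(1, dim = c(d[1], d[2], 3, 1))
  den <- .cpp_dwconv2d_fwd(ones, W, numeric(3), 1L, pad)
  array(num / den, dim = d)
}

#' Generate one synthetic field image with its mask
#'
#' Deterministic in `(spec, height, width, seed)`: the same inputs produce
#' bit-identical output.
#'
#' @param spec a [domain_spec()].
#' @param height,width image dimensions in pixels (>= 32).
#' @param domain_id string tag stored on the sample.
#' @param seed RNG seed; defaults to `spec$seed`.
#' @return a `labeled_image`: list with `image` (H x W x 3 integer array,
#'   0-255), `mask` (H x W integer matrix, values 0/1/2), `domain_id`,
#'   `role` ("source"), `mask_hidden` (FALSE) and `n_weeds` (the drawn
#'   Poisson weed-instance count).
#' @export
generate_field_image <- function(spec, height = 128, width = 128,
                                 domain_id = "domain", seed = spec$seed) {
  stopifnot(inherits(spec, "domain_spec"))
  if (height < 32 || width < 32)
    stop("height and width must be >= 32 pixels")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  h <- as.integer(height); w <- as.integer(width)
  vn <- value_noise(h, w)
  vn2 <- value_noise(h, w, octaves = 2, base = 8)
  # soil background
  v <- spec$soil_brightness * (0.7 + 0.6 * vn)
  if (spec$ridge_amplitude > 0) {
    period <- h / max(spec$crop_rows, 4L)
    phase <- stats::runif(1, 0, 2 * pi)
    stripe <- sin(2 * pi * (seq_len(h) - 0.5) / period + phase)
    v <- v * (1 + spec$ridge_amplitude * 0.5 * stripe)
  }
  v <- pmin(pmax(v, 0), 1)
  sat <- 0.3 + 0.15 * vn2
  rgb <- hsv_to_rgb(spec$soil_hue, sat, v)
  img <- array(0, dim = c(h, w, 3))
  img[, , 1] <- rgb$r; img[, , 2] <- rgb$g; img[, , 3] <- rgb$b
  mask <- matrix(0L, h, w)
  veg_hue <- 120 + spec$hue_shift_vegetation
  # crops on evenly spaced rows with jitter
  if (spec$crop_rows > 0) {
    n_per_row <- max(1L, as.integer(floor(w / (4 * spec$crop_radius_px))))
    for (r in seq_len(spec$crop_rows)) {
      cy0 <- (r - 0.5) / spec$crop_rows * h
      for (j in seq_len(n_per_row)) {
        cx <- (j - 0.5) / n_per_row * w + stats::runif(1, -0.08, 0.08) * w
        cy <- cy0 + stats::runif(1, -0.06, 0.06) * h
        r0 <- spec$crop_radius_px * stats::runif(1, 0.8, 1.2)
        a1 <- stats::runif(1, 0.05, 0.18); p1 <- stats::runif(1, 0, 2 * pi)
        a2 <- stats::runif(1, 0.03, 0.12); p2 <- stats::runif(1, 0, 2 * pi)
        rf <- function(th) r0 * (1 + a1 * sin(2 * th + p1) + a2 * sin(3 * th + p2))
        px <- blob_pixels(h, w, cy, cx, r0, rf)
        if (is.null(px)) next
        hue <- veg_hue + stats::rnorm(1, 0, 4)
        res <- paint_blob(img, mask, px, 1L, hue, 0.6, 0.45, vn)
        img <- res$img; mask <- res$mask
      }
    }
  }
  # weeds scattered uniformly, star-like outline
  n_weeds <- stats::rpois(1, spec$weed_density)
  for (i in seq_len(n_weeds)) {
    cy <- stats::runif(1, 1, h); cx <- stats::runif(1, 1, w)
    r0 <- spec$crop_radius_px * stats::runif(1, 0.45, 0.8)
    k <- sample(5:9, 1)
    ph <- stats::runif(1, 0, 2 * pi)
    rf <- function(th) r0 * (0.45 + 0.65 * abs(sin(k * th / 2 + ph))^0.7)
    px <- blob_pixels(h, w, cy, cx, r0, rf)
    if (is.null(px)) next
    hue <- veg_hue - 20 + stats::rnorm(1, 0, 6)
    res <- paint_blob(img, mask, px, 2L, hue, 0.55, 0.4, vn)
    img <- res$img; mask <- res$mask
  }
  # illumination gain and acquisition blur affect the image only
  img <- pmin(pmax(img * spec$illumination_gain, 0), 1)
  img <- blur_image(img, spec$blur_sigma)
  img8 <- array(as.integer(round(img * 255)), dim = c(h, w, 3))
  structure(list(image = img8, mask = mask, domain_id = domain_id,
                 role = "source", mask_hidden = FALSE, n_weeds = n_weeds),
            class = "labeled_image")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a labeled source / unlabeled target domain pair
#'
#' Target masks are generated (evaluation and j-shot selection need them)
#' but flagged `mask_hidden = TRUE`: unsupervised training must not read
#' them, and [augment_batch()] / the training loop enforce the source-only
#' contract via the `role` tag.
#'
#' @param source,target [domain_spec()]s for the two domains.
#' @param n_source,n_target number of images (>= 1).
#' @param height,width image dimensions.
#' @return list with elements `source` and `target`, each a list of
#'   `labeled_image`.
#' @export
generate_domain_pair <- function(source, target, n_source, n_target,
                                 height = 128, width = 128) {
  stopifnot(inherits(source, "domain_spec"), inherits(target, "domain_spec"))
  if (n_source < 1 || n_target < 1) stop("n_source and n_target must be >= 1")
  if (source$seed == target$seed)
    warning("source and target specs share a seed; domains would be statistically identical")
  src <- lapply(seq_len(n_source), function(i)
    generate_field_image(source, height, width, domain_id = "source",
                         seed = source$seed + i - 1L))
  tgt <- lapply(seq_len(n_target), function(i) {
    im <- generate_field_image(target, height, width, domain_id = "target",
                               seed = target$seed + i - 1L)
    im$role <- "target"
    im$mask_hidden <- TRUE
    im
  })
  list(source = src, target = tgt)
}

# Circular mean hue (degrees) of the background (mask == 0) pixels.
mean_background_hue <- function(sample) {
  img <- sample$image
  bg <- sample$mask == 0
  m <- rbind(r = img[, , 1][bg], g = img[, , 2][bg], b = img[, , 3][bg])
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  ang <- hsv["h", ] * 2 * pi
  (atan2(mean(sin(ang)), mean(cos(ang))) * 180 / pi) %% 360
}
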