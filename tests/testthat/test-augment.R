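# Augmentation categories and the progressive schedule.

test_that("schedule starts at identity, ramps in order, and saturates", {
  cfg <- augmentation_config()  # alpha = beta = gamma = 0.3, lambda_aug = 20
  s0 <- schedule_probabilities(0, cfg)
  expect_equal(c(s0$p_geometric, s0$p_noise, s0$p_collage), c(0, 0, 0))
  s1000 <- schedule_probabilities(1000, cfg)
  expect_equal(c(s1000$p_geometric, s1000$p_noise, s1000$p_collage),
               c(0.3, 0.3, 0.3))
  # midpoint of the geometric ramp
  s30 <- schedule_probabilities(30, augmentation_config(alpha = 0.2))
  expect_equal(s30$p_geometric, 0.1)
  expect_equal(s30$p_noise, 0)
  expect_equal(s30$p_collage, 0)
  expect_error(schedule_probabilities(-1, cfg), ">= 0")
})

test_that("schedule is monotone, capped, and ordered G <= D <= C in onset", {
  cfg <- augmentation_config(alpha = 0.25, beta = 0.4, gamma = 0.15,
                             lambda_aug = 7)
  traj <- t(vapply(0:60, function(e) {
    s <- schedule_probabilities(e, cfg)
    c(s$p_geometric, s$p_noise, s$p_collage)
  }, numeric(3)))
  expect_true(all(diff(traj[, 1]) >= 0))
  expect_true(all(diff(traj[, 2]) >= 0))
  expect_true(all(diff(traj[, 3]) >= 0))
  expect_true(all(traj[, 1] <= 0.25 + 1e-12))
  expect_true(all(traj[, 2] <= 0.4 + 1e-12))
  expect_true(all(traj[, 3] <= 0.15 + 1e-12))
  onset <- apply(traj, 2, function(p) which(p > 0)[1])
  expect_true(onset[1] <= onset[2] && onset[2] <= onset[3])
  # vanilla mode: ceilings from epoch 0
  v <- schedule_probabilities(0, augmentation_config(vanilla = TRUE))
  expect_equal(c(v$p_geometric, v$p_noise, v$p_collage), c(0.3, 0.3, 0.3))
})

test_that("geometric transforms preserve registration and pixel counts", {
  s <- generate_field_image(domain_spec(seed = 31, weed_density = 4), 64, 64)
  counts <- table(factor(s$mask, levels = 0:2))
  for (tr in c("hflip", "vflip", "rot90", "rot180", "rot270")) {
    g <- apply_geometric(s$image, s$mask, transform = tr)
    expect_identical(dim(g$image)[1:2], dim(g$mask))
    expect_equal(table(factor(g$mask, levels = 0:2)), counts)
  }
  # involution and identity cases
  g <- apply_geometric(s$image, s$mask, transform = "hflip")
  g2 <- apply_geometric(g$image, g$mask, transform = "hflip")
  expect_identical(g2$image, s$image)
  expect_identical(g2$mask, s$mask)
  id <- apply_geometric(s$image, s$mask, transform = "scale_crop", scale = 1)
  expect_identical(id$image, s$image)
  set.seed(2)
  sc <- apply_geometric(s$image, s$mask, transform = "scale_crop")
  expect_identical(dim(sc$image), dim(s$image))
  expect_true(all(sc$mask %in% 0:2))
})

test_that("noise transforms touch only the image and stay in 8-bit range", {
  s <- generate_field_image(domain_spec(seed = 33), 48, 48)
  for (tr in weedadapt:::NOISE_TRANSFORMS) {
    set.seed(5)
    out <- apply_noise(s$image, kind = tr)
    expect_true(all(out >= 0L & out <= 255L), info = tr)
    expect_identical(dim(out), dim(s$image))
    expect_identical(apply_noise(s$image, kind = tr, strength = 0), s$image)
  }
  # Gaussian noise recovers its sigma on a constant image
  flat <- array(128L, c(64, 64, 3))
  set.seed(8)
  noisy <- apply_noise(flat, kind = "gaussian_noise")
  expect_equal(stats::sd(as.numeric(noisy) - 128), 10, tolerance = 0.5)
})

test_that("collage tiling geometry is exact", {
  pair <- fixture_pair(n_source = 4, n_target = 1, size = 64)
  # borderless 2x2 of 64x64 inputs -> 128x128 with quadrant-exact content
  cfg <- augmentation_config(collage_grid = c(2, 2), collage_border_px = 0,
                             collage_size = c(128, 128))
  cg <- make_collage(pair$source, cfg)
  expect_identical(dim(cg$image), c(128L, 128L, 3L))
  expect_identical(cg$image[1:64, 1:64, ], pair$source[[1]]$image)
  expect_identical(cg$image[1:64, 65:128, ], pair$source[[2]]$image)
  expect_identical(cg$image[65:128, 1:64, ], pair$source[[3]]$image)
  expect_identical(cg$mask[65:128, 65:128], pair$source[[4]]$mask)
  # border pixels carry class 0; count follows from grid arithmetic
  cfgb <- augmentation_config(collage_grid = c(2, 2), collage_border_px = 4,
                              collage_size = c(128, 128))
  all_fg <- lapply(pair$source, function(s) { s$mask[] <- 1L; s })
  cgb <- make_collage(all_fg, cfgb)
  expect_identical(sum(cgb$mask == 0L), 128L * 128L - 4L * 62L * 62L)
  # single-cell identity
  cfg1 <- augmentation_config(collage_grid = c(1, 1), collage_border_px = 0,
                              collage_size = c(64, 64))
  cg1 <- make_collage(pair$source[1], cfg1)
  expect_identical(cg1$image, pair$source[[1]]$image)
  expect_identical(cg1$mask, pair$source[[1]]$mask)
  expect_error(make_collage(pair$source,
                            augmentation_config(collage_grid = c(2, 2),
                                                collage_border_px = 70,
                                                collage_size = c(64, 64))),
               "not positive")
  expect_error(make_collage(pair$source[1:2], cfg), "at least 4")
})

test_that("augment_batch applies categories at the scheduled frequencies", {
  pair <- fixture_pair(n_source = 8, n_target = 1, size = 32)
  batch <- rep(pair$source, length.out = 1000)
  cfg <- augmentation_config()
  # identity state passes everything through untouched
  id <- augment_batch(batch[1:20], schedule_probabilities(0, cfg), cfg)
  expect_identical(lapply(id, `[[`, "image"), lapply(batch[1:20], `[[`, "image"))
  expect_identical(attr(id, "n_geometric") + attr(id, "n_noise") +
                     attr(id, "n_collage"), 0L)
  # certain application leaves no sample unaugmented
  st1 <- structure(list(epoch = 0, p_geometric = 1, p_noise = 1, p_collage = 1),
                   class = "schedule_state")
  set.seed(3)
  full <- augment_batch(batch[1:200], st1, cfg)
  expect_identical(attr(full, "n_geometric"), 200L)
  expect_identical(attr(full, "n_noise"), 200L)
  # binomial 99% interval at p = 0.3 over 1000 draws
  st <- structure(list(epoch = 0, p_geometric = 0.3, p_noise = 0.3,
                       p_collage = 0.3), class = "schedule_state")
  set.seed(17)
  out <- augment_batch(batch, st, cfg)
  ci <- stats::qbinom(c(0.005, 0.995), 1000, 0.3)
  expect_gte(attr(out, "n_geometric"), ci[1])
  expect_lte(attr(out, "n_geometric"), ci[2])
  # mask vocabulary and registration survive the full pipeline
  expect_true(all(vapply(out, function(s) all(s$mask %in% 0:2), TRUE)))
  expect_true(all(vapply(out, function(s)
    all(dim(s$image)[1:2] == dim(s$mask)), TRUE)))
})

test_that("augment_batch rejects target samples and is seed-reproducible", {
  pair <- fixture_pair(n_source = 4, n_target = 2, size = 32)
  st <- schedule_probabilities(1000, augmentation_config())
  expect_error(augment_batch(c(pair$source, pair$target), st), "target-domain")
  set.seed(9); a <- augment_batch(pair$source, st)
  set.seed(9); b <- augment_batch(pair$source, st)
  expect_identical(a, b)
})
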