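# Dataset persistence: RGB images and single-channel index masks as PNG,
# plus a JSON manifest per dataset listing file pairs, domain ids, class
# names and provenance. Checkpoints carry parameters and configuration.

CLASS_NAMES <- c("background", "crop", "weed")

#' Write a dataset of labelled images to disk
#'
#' Images become 8-bit RGB PNGs, masks single-channel PNGs holding raw
#' class indices (0, 1, 2); a `manifest.json` lists the pairs. Masks of
#' samples flagged `mask_hidden` are omitted from the manifest when
#' `respect_hidden = TRUE` (their mask files are still written next to the
#' images so evaluation tooling can find them).
#'
#' @param dataset list of `labeled_image`.
#' @param dir output directory (created if needed).
#' @param provenance free-text provenance string (e.g. a domain-spec dump).
#' @param respect_hidden omit hidden masks from the manifest.
#' @return path of the manifest, invisibly.
#' @export
write_dataset <- function(dataset, dir, provenance = "synthetic",
                          respect_hidden = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- vector("list", length(dataset))
  for (i in seq_along(dataset)) {
    s <- dataset[[i]]
    ip <- sprintf("img_%04d.png", i)
    mp <- sprintf("mask_%04d.png", i)
    png::writePNG(s$image / 255, file.path(dir, ip))
    png::writePNG(s$mask / 255, file.path(dir, mp))
    hide <- respect_hidden && isTRUE(s$mask_hidden)
    e <- list(image_path = ip, domain_id = s$domain_id %||% "domain",
              role = s$role %||% "source")
    if (!hide) e$mask_path <- mp
    entries[[i]] <- e
  }
  manifest <- list(entries = entries, class_names = CLASS_NAMES,
                   provenance = provenance)
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(mf)
}

read_png_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3 && dim(a)[3] == 4) a <- a[, , 1:3]
  array(as.integer(round(a * 255)), dim = dim(a))
}

read_png_mask <- function(path, K = 3) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  m <- matrix(as.integer(round(a * 255)), nrow = nrow(a))
  if (any(m >= K))
    stop("mask ", path, " contains class indices >= K = ", K)
  m
}

#' Load a dataset from a manifest
#'
#' @param manifest_path path to a `manifest.json` written by
#'   [write_dataset()].
#' @param K number of classes used to validate mask values.
#' @return list of `labeled_image`.
#' @export
load_dataset <- function(manifest_path, K = 3) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  man <- jsonlite::read_json(manifest_path)
  dir <- dirname(manifest_path)
  lapply(man$entries, function(e) {
    ip <- file.path(dir, e$image_path)
    if (!file.exists(ip)) stop("missing image file: ", ip)
    img <- read_png_image(ip)
    mask <- NULL
    if (length(e$mask_path) == 0) e$mask_path <- NULL
    if (!is.null(e$mask_path)) {
      mp <- file.path(dir, e$mask_path)
      if (!file.exists(mp)) stop("missing mask file: ", mp)
      mask <- read_png_mask(mp, K)
    } else if (identical(e$role, "source")) {
      stop("manifest entry ", e$image_path,
           ": mask_path may be null only for target-domain entries")
    }
    structure(list(image = img, mask = mask,
                   domain_id = e$domain_id %||% "domain",
                   role = e$role %||% "source",
                   mask_hidden = is.null(e$mask_path) ||
                     identical(e$role, "target")),
              class = "labeled_image")
  })
}

#' Save / load a model checkpoint
#'
#' Checkpoints embed the parameters, optimizer state and configuration of
#' the segmentation network and both discriminators.
#'
#' @param fit a `field_adapt` object (or a bare `seg_network`).
#' @param path file path.
#' @return `load_checkpoint` returns the restored object.
#' @export
save_checkpoint <- function(fit, path) {
  if (inherits(fit, "field_adapt")) {
    payload <- list(kind = "field_adapt",
                    seg = list(params = fit$seg_net$params, config = fit$seg_net$config),
                    disc_main = fit$discs$main$params,
                    disc_aux = fit$discs$aux$params,
                    config = fit$config, mode = fit$mode,
                    history = fit$history, val_miou = fit$val_miou)
  } else {
    payload <- list(kind = "seg_network",
                    seg = list(params = fit$params, config = fit$config))
  }
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  p <- readRDS(path)
  net <- build_segmentation_network(p$seg$config)
  net$params <- p$seg$params
  if (identical(p$kind, "seg_network")) return(net)
  discs <- list(main = build_discriminator(p$config$network$num_classes,
                                           p$config$network$disc_channels),
                aux = build_discriminator(p$config$network$num_classes,
                                          p$config$network$disc_channels))
  discs$main$params <- p$disc_main
  discs$aux$params <- p$disc_aux
  structure(list(seg_net = net, discs = discs, config = p$config,
                 mode = p$mode, history = p$history, val_miou = p$val_miou,
                 classes = p$config$network$num_classes),
            class = "field_adapt")
}

#' Print a model summary with per-stage shapes and parameter counts
#'
#' @param network a `seg_network` or `disc_network`.
#' @param input_size spatial input size used to report stage shapes.
#' @export
model_summary <- function(network, input_size = 128) {
  cfg <- network$config
  if (inherits(network, "seg_network")) {
    cat("Segmentation network (", cfg$size_preset, " preset)\n", sep = "")
    cat("  stem: 2x conv7x7/2 ->", input_size / 4, "x", input_size / 4,
        "x", cfg$stage_channels[1], "\n")
    sz <- input_size / 4
    for (s in 1:4) {
      if (s > 1) sz <- sz / 2
      cat(sprintf("  stage %d: %d ConvNext block(s), %dx%dx%d\n", s,
                  cfg$stage_depths[s], sz, sz, cfg$stage_channels[s]))
    }
    cat("  decoder: ASPP(", paste(ASPP_RATES, collapse = ","),
        ") + gated skip (r=", cfg$gating_channels, ") + DAM -> K=",
        cfg$num_classes, "\n", sep = "")
  } else {
    cat("Patch discriminator: 5x conv4x4/2, channels",
        paste(cfg$channels, collapse = "/"), "\n")
  }
  cat("  parameters:", format(n_params(network), big.mark = ","), "\n")
  invisible(network)
}
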