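# Desk-scale adaptation experiment: the package's standard protocol for
# comparing source-training-only (STO), unsupervised adaptation (UDA) and
# few-shot supervised adaptation on a synthetic domain pair with a strong
# soil-hue / illumination / bed-geometry / blur / density shift.

#' Desk-scale domain-adaptation experiment
#'
#' Generates a synthetic source domain (flat bed, low weed density,
#' neutral soil) and a strongly shifted target domain (ridged bed, shifted
#' hue, platform blur, denser weeds), splits them (source 80/20, target
#' 70/30), then trains and evaluates on the target test split:
#' 1. an STO control (supervised source training only),
#' 2. a UDA model (entropy minimization + adversarial alignment),
#' 3. optionally a j-shot fine-tuned model continuing from the UDA fit.
#'
#' @param seed master seed for generation, splits and training.
#' @param n_source,n_target images per domain.
#' @param size square image size in pixels (divisible by 32).
#' @param epochs training epochs (with `n_source = 40` and batch 4, 38
#'   epochs is roughly 300 iterations).
#' @param j_shot shots for the fine-tuning arm (0 skips it).
#' @param config base [training_config()]; epochs/seed are overridden.
#' @return list with `sto_miou`, `uda_miou`, optional `jshot_miou`
#'   (target-test mean IoU of each arm), `source_miou` (UDA model on the
#'   source test split) and `model`, the final fitted `field_adapt`
#'   object (the fine-tuned model when `j_shot > 0`, since fine-tuning
#'   continues training in place).
#' @export
desk_adaptation_experiment <- function(seed = 1, n_source = 40, n_target = 30,
                                       size = 128, epochs = 38, j_shot = 1,
                                       config = NULL) {
  if (is.null(config))
    config <- training_config(epochs = epochs, batch_size = 4, seg_lr = 0.005,
                              warmup_iters = 50, eval_every = 0)
  config$epochs <- as.integer(epochs)
  config$seed <- as.integer(seed)
  src_spec <- domain_spec(seed = seed * 1000L + 1L)
  tgt_spec <- shifted_target_spec(seed = seed * 1000L + 500L)
  pair <- generate_domain_pair(src_spec, tgt_spec, n_source, n_target,
                               size, size)
  sp <- split_datasets(pair$source, pair$target, seed = seed)
  K <- config$network$num_classes
  sto <- field_adapt(sp$source$train, config = config, mode = "sto")
  uda <- field_adapt(sp$source$train, sp$target$train, config = config,
                     mode = "uda")
  res <- list(
    sto_miou = evaluate_dataset(sto, sp$target$test, K)$mean_iou,
    uda_miou = evaluate_dataset(uda, sp$target$test, K)$mean_iou,
    source_miou = evaluate_dataset(uda, sp$source$test, K)$mean_iou)
  if (j_shot > 0) {
    tgt_lab <- lapply(sp$target$train, function(s) { s$mask_hidden <- FALSE; s })
    ft <- finetune_few_shot(uda, tgt_lab, j = j_shot,
                            epochs = max(2L, epochs %/% 4L),
                            source = sp$source$train)
    res$jshot_miou <- evaluate_dataset(ft, sp$target$test, K)$mean_iou
    res$model <- ft
  } else {
    res$model <- uda
  }
  res
}
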