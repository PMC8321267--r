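# End-to-end experiment orchestration: generate the two synthetic domains,
# train the translator, build the artificial macroscopic set, train the
# segmenter under both experiment arms (macro + dermo versus macro +
# translated dermo), and report FID/VR and segmentation metrics. Every
# stage draws from a named substream of one root seed, so a full run is a
# pure function of its configuration.

sym_copy <- function(dataset) {
  new_dataset(lapply(dataset, function(s) { s$image <- to_sym(s$image); s }))
}

unit_copy <- function(dataset) {
  new_dataset(lapply(dataset, function(s) {
    s$image <- clamp(to_unit(s$image), 0, 1)
    s
  }))
}

#' Pipeline configuration
#'
#' Defaults are smoke-scale (small images, few epochs) so a full two-arm
#' experiment runs on one CPU in minutes; every knob scales up to the
#' reference setting (512 px, hundreds of epochs) by configuration.
#'
#' @param seed root seed; all stage seeds are derived substreams.
#' @param n_images synthetic images per domain.
#' @param image_size image side in pixels (multiple of 16).
#' @param dermo_probs,macro_probs artifact probabilities per domain.
#' @param gan_epochs,gan_base_channels,gan_res_blocks translator settings.
#' @param seg_epochs,seg_alpha segmenter settings.
#' @param lambda_cyc cycle-consistency weight.
#' @param embedder_dim toy embedder dimension for FID.
#' @param write_images write all intermediate images as PNG with manifests.
#' @param verbose print stage progress.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_images = 8L, image_size = 32L,
                            dermo_probs = c(dark_corners = 1, gel = 0,
                                            ruler = 0),
                            macro_probs = c(glare = 1, depth_shading = 0.5),
                            gan_epochs = 3L, gan_base_channels = 8L,
                            gan_res_blocks = 2L, seg_epochs = 3L,
                            seg_alpha = 0.35, lambda_cyc = 10,
                            embedder_dim = 64L, write_images = TRUE,
                            verbose = FALSE) {
  stopifnot(image_size %% 16L == 0L, n_images >= 4)
  structure(list(seed = as.integer(seed), n_images = as.integer(n_images),
                 image_size = as.integer(image_size),
                 dermo_probs = dermo_probs, macro_probs = macro_probs,
                 gan_epochs = as.integer(gan_epochs),
                 gan_base_channels = as.integer(gan_base_channels),
                 gan_res_blocks = as.integer(gan_res_blocks),
                 seg_epochs = as.integer(seg_epochs), seg_alpha = seg_alpha,
                 lambda_cyc = lambda_cyc,
                 embedder_dim = as.integer(embedder_dim),
                 write_images = isTRUE(write_images),
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Assemble the two segmentation training arms
#'
#' Arm 1 merges the macroscopic set with the dermoscopic set as-is; arm 2
#' merges it with the dermoscopic set translated into the macroscopic
#' domain (the artificial macroscopic set). Counts are conserved and every
#' translated sample keeps its original ground-truth mask.
#'
#' @param set_m macroscopic `d2m_dataset` (images in `[0,1]`).
#' @param set_d dermoscopic `d2m_dataset` (images in `[0,1]`).
#' @param bundle a trained `translation_bundle`.
#' @return `list(m_plus_d, m_plus_martificial, martificial)`.
#' @export
assemble_training_sets <- function(set_m, set_d, bundle) {
  mart <- unit_copy(translate(bundle, sym_copy(set_d), "dermo2macro"))
  list(m_plus_d = new_dataset(c(unclass(set_m), unclass(set_d))),
       m_plus_martificial = new_dataset(c(unclass(set_m), unclass(mart))),
       martificial = mart)
}

stage_msg <- function(cfg, ...) if (cfg$verbose) message("[pipeline] ", ...)

eval_arm <- function(fit, test_set, threshold = 0.5) {
  pairs <- lapply(test_set, function(s)
    list(pred = predict_mask(fit, s$image, threshold), truth = s$mask))
  mets <- segmentation_metrics(pairs)
  rates <- normalized_error_rates(pairs)
  list(TJA = mets$TJA, JA = mets$JA, DI = mets$DI, AC = mets$AC,
       SE = mets$SE, SP = mets$SP,
       norm_fp = rates[["fp"]], norm_fn = rates[["fn"]],
       best_epoch = fit$best_epoch, best_val_dice = fit$best_val_dice)
}

#' Run the full two-arm experiment
#'
#' generate -> train translator -> translate the dermoscopic set ->
#' assemble both training arms -> train the segmenter per arm -> evaluate
#' FID/VR and the six segmentation metrics on the held-out macroscopic test
#' split. The report contains no timestamps, so a rerun with the same
#' configuration is byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory for the report, histories, manifests and
#'   (optionally) images.
#' @return the experiment report, invisibly (also written as
#'   `report.json` and `report.md`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage_msg(config, "generating synthetic domains")
  syn <- generate_dataset(synthetic_config(
    n_images = config$n_images, image_size = config$image_size,
    seed = derive_seed(config$seed, "synthetic"),
    dermo_probs = config$dermo_probs, macro_probs = config$macro_probs,
    split_fractions = c(train = 0.75, test = 0.25)))
  macro_train <- dataset_subset(syn$macro, "train")
  macro_test <- dataset_subset(syn$macro, "test")
  dermo_train <- dataset_subset(syn$dermo, "train")
  dermo_test <- dataset_subset(syn$dermo, "test")
  # id-level leak audit
  stopifnot(!any(vapply(macro_train, `[[`, "", "id") %in%
                   vapply(macro_test, `[[`, "", "id")))

  stage_msg(config, "training translator (", config$gan_epochs, " epochs)")
  gan_cfg <- cyclegan_config(
    gen_spec = generator_spec(config$image_size, config$gan_base_channels,
                              config$gan_res_blocks),
    disc_spec = discriminator_spec(config$image_size,
                                   config$gan_base_channels),
    lambda_cyc = config$lambda_cyc, max_epochs = config$gan_epochs,
    early_stop_window = config$gan_epochs + 1L,
    seed = derive_seed(config$seed, "translator"), verbose = config$verbose)
  bundle <- train_cyclegan(sym_copy(dermo_train), sym_copy(macro_train),
                           gan_cfg)

  stage_msg(config, "translating and assembling arms")
  arms <- assemble_training_sets(macro_train, dermo_train, bundle)
  trans_macro_test <- unit_copy(translate(bundle, sym_copy(dermo_test),
                                          "dermo2macro"))
  trans_dermo_test <- unit_copy(translate(bundle, sym_copy(macro_test),
                                          "macro2dermo"))

  emb <- make_toy_embedder(config$embedder_dim,
                           seed = derive_seed(config$seed, "embedder"))
  fid <- list(
    macro_dermo = fid_between(macro_test, dermo_test, emb),
    macro_transmacro = fid_between(macro_test, trans_macro_test, emb),
    dermo_transdermo = fid_between(dermo_test, trans_dermo_test, emb),
    setM_setD = fid_between(macro_train, dermo_train, emb),
    setM_setMartificial = fid_between(macro_train, arms$martificial, emb))
  fid$vr_transmacro <- variation_ratio(fid$macro_dermo,
                                       fid$macro_transmacro, digits = 2)
  fid$vr_transdermo <- variation_ratio(fid$macro_dermo,
                                       fid$dermo_transdermo, digits = 2)
  fid$vr_setMartificial <- variation_ratio(fid$setM_setD,
                                           fid$setM_setMartificial,
                                           digits = 2)

  seg_results <- list()
  for (arm in c("m_plus_d", "m_plus_martificial")) {
    stage_msg(config, "training segmenter arm ", arm)
    fit <- train_segmenter(arms[[arm]], seg_train_config(
      spec = seg_model_spec(config$seg_alpha, config$image_size),
      epochs = config$seg_epochs,
      seed = derive_seed(config$seed, paste0("seg-", arm)),
      verbose = config$verbose))
    seg_results[[arm]] <- eval_arm(fit, macro_test)
    utils::write.csv(fit$history,
                     file.path(out_dir, paste0("seg_history_", arm, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(bundle$history, file.path(out_dir, "gan_history.csv"),
                   row.names = FALSE)

  if (config$write_images) {
    write_dataset(syn$macro, file.path(out_dir, "macro"))
    write_dataset(syn$dermo, file.path(out_dir, "dermo"))
    write_dataset(arms$martificial, file.path(out_dir, "martificial"))
  }

  report <- list(
    config = unclass(config),
    n_train = c(macro = length(macro_train), dermo = length(dermo_train)),
    n_test = c(macro = length(macro_test), dermo = length(dermo_test)),
    fid = fid,
    segmentation = seg_results,
    gan_final_losses = as.list(bundle$history[nrow(bundle$history), ]))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(report_markdown(report), file.path(out_dir, "report.md"))
  invisible(report)
}

report_markdown <- function(report) {
  f <- report$fid
  s <- report$segmentation
  fmt <- function(x) sprintf("%.4f", x)
  c("# Experiment report",
    "",
    "## Frechet distance and Variation Ratio (toy embedder)",
    "",
    "| Domains | FID | VR |",
    "|---|---|---|",
    sprintf("| Macro/Dermo (reference) | %s | |", fmt(f$macro_dermo)),
    sprintf("| Macro/TransMacro | %s | %.2f |", fmt(f$macro_transmacro),
            f$vr_transmacro),
    sprintf("| Dermo/TransDermo | %s | %.2f |", fmt(f$dermo_transdermo),
            f$vr_transdermo),
    sprintf("| Set M/Set D (reference) | %s | |", fmt(f$setM_setD)),
    sprintf("| Set M/Set M_artificial | %s | %.2f |",
            fmt(f$setM_setMartificial), f$vr_setMartificial),
    "",
    "## Segmentation on the macroscopic test split",
    "",
    "| Training set | TJA | JA | DI | AC | SE | SP |",
    "|---|---|---|---|---|---|---|",
    vapply(names(s), function(nm)
      sprintf("| %s | %s | %s | %s | %s | %s | %s |", nm,
              fmt(s[[nm]]$TJA), fmt(s[[nm]]$JA), fmt(s[[nm]]$DI),
              fmt(s[[nm]]$AC), fmt(s[[nm]]$SE), fmt(s[[nm]]$SP)), ""))
}
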