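# Configuration loading/validation and the staged pipeline surface:
# generate -> features -> train -> evaluate, plus one-off grading and the
# robustness experiment. Every stage derives its seed deterministically from
# the global seed and writes its artifacts under the configured output
# directory.

default_run_config <- function() {
  list(
    paths = list(output_dir = "plumgrade-output"),
    synthetic = list(n_samples = 600L, ambiguity_rate = 0.2, image_size = 320L,
                     n_wavelengths = 512L, noise_sd = 0.01, score_margin = 0.04),
    split = list(ratios = c(0.64, 0.16, 0.20), stratified = TRUE),
    augment = list(target_fraction = 0.15),
    image = list(threshold = 0.15, out_dim = 4096L, base_width = 4L,
                 input_size = 224L),
    spectral = list(window = 5L, out_dim = 512L, width_factor = 1,
                    bands = list(c(900, 1350), c(1400, 1600))),
    fusion = list(hidden_widths = c(512L, 256L), dropout_rate = 0.3,
                  use_residual = TRUE, alpha = 0.65, learning_rate = 0.001,
                  weight_decay = 1e-4, batch_size = 32L, max_epochs = 100L,
                  patience = 10L, folds = 5L),
    robustness = list(fraction = 0.33),
    pretrain_epochs = 25L,
    seed = 1L,
    log_level = "info"
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste0(path, ".", key)
    if (!key %in% names(defaults))
      stop_plum("plum_config_error", "unknown configuration key '%s'", full)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop_plum("plum_config_error", "key '%s' must be a mapping", full)
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

validate_run_config <- function(cfg) {
  if (cfg$fusion$alpha < 0 || cfg$fusion$alpha > 1)
    stop_plum("plum_config_error", "fusion.alpha must lie in [0, 1]")
  if (abs(sum(cfg$split$ratios) - 1) > 1e-9)
    stop_plum("plum_config_error", "split.ratios must sum to 1")
  if (cfg$robustness$fraction < 0 || cfg$robustness$fraction >= 1)
    stop_plum("plum_config_error", "robustness.fraction must lie in [0, 1)")
  if (cfg$augment$target_fraction <= 0 || cfg$augment$target_fraction >= 1)
    stop_plum("plum_config_error", "augment.target_fraction must lie in (0, 1)")
  cfg
}

#' Load a run configuration
#'
#' Reads a YAML (or JSON) configuration file, fills defaults for missing
#' keys, rejects unknown keys, and validates ranges. An empty file yields
#' the full default configuration.
#'
#' @param path Path to the configuration file, or `NULL` for all defaults.
#' @return A validated `plum_run_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop_plum("plum_config_error", "configuration file '%s' not found", path)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- merge_config(cfg, user)
  }
  structure(validate_run_config(cfg), class = "plum_run_config")
}

#' Save a run configuration
#'
#' @param config A `plum_run_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  x <- config
  class(x) <- NULL
  yaml::write_yaml(x, path)
  invisible(path)
}

write_json_atomic <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

pipeline_log <- function(cfg, stage, t0, files) {
  if (identical(cfg$log_level, "info")) {
    hashes <- tools::md5sum(files[file.exists(files)])
    message(sprintf("[plumgrade] stage=%s seed=%d elapsed=%.1fs", stage,
                    cfg$seed, as.numeric(proc.time()[3] - t0)))
    for (f in names(hashes)) message(sprintf("[plumgrade]   %s %s", hashes[[f]], f))
  }
}

#' Read a dataset written by the generate stage
#'
#' @param dir Dataset directory (metadata.csv, images/, spectra/).
#' @return A `plum_dataset`.
#' @export
read_dataset <- function(dir) {
  md_path <- file.path(dir, "metadata.csv")
  if (!file.exists(md_path))
    stop_plum("plum_stage_error", "no dataset at '%s'; run the 'generate' stage first", dir)
  md <- utils::read.csv(md_path, stringsAsFactors = FALSE)
  samples <- lapply(seq_len(nrow(md)), function(i) {
    s <- list(sample_id = md$sample_id[i], ssc = md$ssc_brix[i],
              true_grade = md$grade[i], archetype = md$archetype[i])
    ip <- file.path(dir, "images", paste0(md$sample_id[i], ".png"))
    if (file.exists(ip)) {
      img <- png::readPNG(ip)
      s$image <- img[, , 1:3, drop = FALSE]
    }
    sp <- file.path(dir, "spectra", paste0(md$sample_id[i], ".csv"))
    if (file.exists(sp)) {
      tab <- utils::read.csv(sp)
      s$spectrum <- structure(list(wavelengths = tab$wavelength_nm,
                                   sample_intensity = tab$sample,
                                   dark_intensity = tab$dark,
                                   reference_intensity = tab$reference),
                              class = "plum_spectrum")
    }
    s
  })
  cfg_path <- file.path(dir, "config.json")
  cfg <- if (file.exists(cfg_path)) {
    raw <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
    do.call(synthetic_config, raw[setdiff(names(raw), character(0))])
  } else {
    synthetic_config(n_samples = nrow(md))
  }
  structure(list(samples = samples, metadata = md, config = cfg,
                 bounds = compute_bounds(md)),
            class = "plum_dataset")
}

require_stage <- function(path, needed, hint) {
  if (!file.exists(path))
    stop_plum("plum_stage_error", "missing %s; run '%s' first", needed, hint)
  path
}

#' Run a pipeline stage
#'
#' Orchestrates the grading pipeline on disk. Stages: `generate` (synthetic
#' dataset), `features` (both modalities, encoders pre-trained on the
#' training split), `train` (fusion + single-modal heads), `evaluate`
#' (clean-test reports), `grade` (one image/spectrum pair), `robustness`
#' (label-noise experiment). Each stage requires its predecessors'
#' artifacts and reports which command to run when they are missing.
#'
#' @param config A `plum_run_config` from [load_config()].
#' @param command One of `generate`, `features`, `train`, `evaluate`,
#'   `grade`, `robustness`.
#' @param image_path,spectrum_path Inputs for the `grade` command.
#' @return Invisible list of artifact paths written by the stage.
#' @export
run_pipeline <- function(config, command = c("generate", "features", "train",
                                             "evaluate", "grade", "robustness"),
                         image_path = NULL, spectrum_path = NULL) {
  command <- match.arg(command)
  out <- config$paths$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[3]
  data_dir <- file.path(out, "data")
  feat_dir <- file.path(out, "features")
  model_dir <- file.path(out, "models")
  written <- character(0)

  if (command == "generate") {
    scfg <- do.call(synthetic_config,
                    c(config$synthetic, list(seed = derive_seed(config$seed, 1L))))
    ds <- generate_dataset(scfg)
    write_dataset(ds, data_dir)
    split <- split_dataset(ds$metadata$grade,
                           split_spec(config$split$ratios, config$split$stratified,
                                      seed = derive_seed(config$seed, 3L)))
    write_json_atomic(lapply(split, function(ix) ds$metadata$sample_id[ix]),
                      file.path(data_dir, "splits.json"))
    write_json_atomic(unclass(ds$bounds), file.path(data_dir, "bounds.json"))
    written <- file.path(data_dir, c("metadata.csv", "splits.json", "bounds.json"))
  }

  if (command == "features") {
    ds <- read_dataset(data_dir)
    split_ids <- jsonlite::read_json(
      require_stage(file.path(data_dir, "splits.json"), "split manifest", "generate"),
      simplifyVector = TRUE)
    split <- lapply(split_ids, function(ids) match(ids, ds$metadata$sample_id))
    aug <- augment_minority(ds, split$train, config$augment$target_fraction,
                            seed = derive_seed(config$seed, 5L))
    ds <- aug$dataset
    split$train <- aug$train_ids
    feats <- plum_features(
      ds, split$train, split$val,
      image_enc = image_encoder(config$image$out_dim, config$image$base_width,
                                config$image$input_size,
                                seed = derive_seed(config$seed, 7L)),
      spectral_dim = config$spectral$out_dim,
      width_factor = config$spectral$width_factor,
      window = config$spectral$window,
      bands = band_selection(config$spectral$bands),
      epochs = config$pretrain_epochs, seed = config$seed)
    dir.create(feat_dir, showWarnings = FALSE)
    utils::write.csv(cbind(sample_id = ds$metadata$sample_id, feats$manual),
                     file.path(feat_dir, "manual.csv"), row.names = FALSE)
    saveRDS(list(image = feats$image, spectral = feats$spectral,
                 labels = ds$metadata$grade, split = split,
                 schema = "plumgrade-features-v1",
                 image_encoder = feats$image_encoder,
                 spectral_encoder = feats$spectral_encoder),
            file.path(feat_dir, "features.rds"))
    written <- file.path(feat_dir, c("manual.csv", "features.rds"))
  }

  if (command %in% c("train", "evaluate", "robustness")) {
    fs <- readRDS(require_stage(file.path(feat_dir, "features.rds"),
                                "feature store", "features"))
    model_feats <- list(fusion = concat_features(fs$image, fs$spectral),
                        image = fs$image, spectral = fs$spectral)
  }

  if (command == "train") {
    dir.create(model_dir, showWarnings = FALSE)
    bounds <- jsonlite::read_json(file.path(data_dir, "bounds.json"),
                                  simplifyVector = TRUE)
    for (tag in names(model_feats)) {
      X <- model_feats[[tag]]
      cfg <- do.call(fusion_config,
                     c(config$fusion,
                       list(image_dim = ncol(X), spectral_dim = 0L,
                            seed = derive_seed(config$seed, 13L))))
      fit <- train_model(build_fusion_head(cfg),
                         X[fs$split$train, , drop = FALSE],
                         fs$labels[fs$split$train],
                         X[fs$split$val, , drop = FALSE],
                         fs$labels[fs$split$val], cfg)
      saveRDS(fit$model, file.path(model_dir, paste0(tag, ".rds")))
      write_json_atomic(list(model = tag, classes = fit$model$classes,
                             bounds = bounds, config = unclass(cfg),
                             stop_epoch = attr(fit$history, "stop_epoch")),
                        file.path(model_dir, paste0(tag, "_sidecar.json")))
      utils::write.csv(fit$history, file.path(model_dir, paste0(tag, "_history.csv")),
                       row.names = FALSE)
      written <- c(written, file.path(model_dir, paste0(tag, ".rds")))
    }
  }

  if (command == "evaluate") {
    reports <- list()
    for (tag in names(model_feats)) {
      model <- readRDS(require_stage(file.path(model_dir, paste0(tag, ".rds")),
                                     sprintf("trained '%s' model", tag), "train"))
      pred <- predict_grade(model, model_feats[[tag]][fs$split$test, , drop = FALSE])
      rep <- evaluate_predictions(fs$labels[fs$split$test], pred$grade, tag)
      reports[[tag]] <- rep
      utils::write.csv(rep$confusion,
                       file.path(out, paste0("confusion_", tag, ".csv")))
    }
    cmp <- compare_models(reports)
    write_json_atomic(
      list(models = lapply(reports, function(r)
             list(accuracy = r$accuracy, macro_precision = r$macro_precision,
                  macro_recall = r$macro_recall, macro_f1 = r$macro_f1,
                  n = r$n)),
           comparison = cmp$table, best = as.list(cmp$best)),
      file.path(out, "eval_report.json"))
    written <- file.path(out, "eval_report.json")
  }

  if (command == "grade") {
    model <- readRDS(require_stage(file.path(model_dir, "fusion.rds"),
                                   "trained fusion model", "train"))
    fs <- readRDS(require_stage(file.path(feat_dir, "features.rds"),
                                "feature store", "features"))
    img <- png::readPNG(image_path)[, , 1:3, drop = FALSE]
    seg <- segment_plum(img, config$image$threshold)
    std <- standardize_image(seg$cropped, config$image$input_size)
    fi <- encode_image(std, fs$image_encoder)
    tab <- utils::read.csv(spectrum_path)
    triplet <- structure(list(wavelengths = tab$wavelength_nm,
                              sample_intensity = tab$sample,
                              dark_intensity = tab$dark,
                              reference_intensity = tab$reference),
                         class = "plum_spectrum")
    bv <- preprocess_spectrum(triplet, config$spectral$window,
                              band_selection(config$spectral$bands))$values
    fspec <- fc_forward(fs$spectral_encoder$fc,
                        spectral_conv_features(fs$spectral_encoder, bv))
    pred <- predict_grade(model, concat_features(fi, fspec))
    res <- list(grade = as.character(pred$grade),
                probabilities = as.list(stats::setNames(as.numeric(pred$probs),
                                                        colnames(pred$probs))))
    write_json_atomic(res, file.path(out, "grade.json"))
    written <- file.path(out, "grade.json")
  }

  if (command == "robustness") {
    res <- noise_experiment(model_feats, fs$labels, fs$split,
                            config$robustness$fraction,
                            do.call(fusion_config,
                                    c(config$fusion,
                                      list(seed = derive_seed(config$seed, 17L)))),
                            seed = derive_seed(config$seed, 19L))
    write_json_atomic(
      list(fraction = res$fraction,
           models = lapply(res$models, function(m) m[setdiff(names(m), "model")]),
           flipped_ids = res$flipped_ids),
      file.path(out, "robustness.json"))
    written <- file.path(out, "robustness.json")
  }

  pipeline_log(config, command, t0, written)
  invisible(written)
}
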