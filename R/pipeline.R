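# default run configuration (desk scale); every numeric constant used by any
# stage is a named field here
config_defaults <- function() {
  list(
    seed = 1L,
    scale = "desk",
    phantom = list(grid_shape = c(36L, 36L, 36L), spacing = c(1, 1, 1),
                   nodule_center = NULL, radii = c(3, 3, 3),
                   radial_bumpiness = 0.1, nodule_intensity = 40,
                   background_intensity = -800, noise_sigma = 10,
                   n_readers = 4L, reader_jitter = 0.2, n_vertices = 96L),
    preprocess = list(target_spacing = c(1, 1, 1), pad = 10L),
    sampling = list(per_slice_n = 200L, balance = 0.5),
    patches = list(size = 30L, fill = "replicate", fill_value = 0,
                   vh_normalize = "minmax"),
    network = list(stem_channels = 32L, rb1_widths = c(32L, 32L, 32L),
                   c4_channels = 128L, rb2_widths = c(128L, 128L, 128L),
                   fc_width = 256L, fusion_width = 256L, variant = "MV-SIR"),
    training = list(learning_rate = 2e-2, weight_decay = 0.05,
                    batch_size = 64L, epochs = 10L,
                    validation_fraction = 0.10, decay_mode = "lr"),
    inference = list(stride = 1L, threshold = "auto", chunk = 2048L),
    evaluation = list(reference = "gt"))
}

# full-scale protocol values injected by the "paper" scale preset
config_paper_preset <- function() {
  list(sampling = list(per_slice_n = 4000L),
       training = list(learning_rate = 1e-4, weight_decay = 0.01,
                       batch_size = 2000L, epochs = 100L))
}

merge_config <- function(base, user, path = "") {
  for (k in names(user)) {
    here <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(base))
      stop_config("unknown config key '%s'", here)
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      if (!is.list(user[[k]]))
        stop_config("config key '%s' must be a section", here)
      base[[k]] <- merge_config(base[[k]], user[[k]], here)
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Validate and complete a pipeline run configuration
#'
#' Fills defaults for all stages (the desk-scale preset), applies the scale
#' preset, and rejects unknown keys with the offending path. The `"paper"`
#' scale injects the full-scale protocol: 4000 centers per slice, batch size
#' 2000, 100 epochs, learning rate 1e-4. Explicit user values always win
#' over the preset.
#'
#' @param config A (possibly partial) nested configuration list, a path to a
#'   JSON file with one, or `NULL` for pure defaults.
#' @return A validated configuration list of class `mvsir_config` with every
#'   stage's effective parameters, plus a `hash` attribute tagging run
#'   artifacts.
#' @export
#' @examples
#' cfg <- mvsir_config()                       # desk defaults
#' cfg$sampling$per_slice_n                    # 200
#' mvsir_config(list(scale = "paper"))$sampling$per_slice_n   # 4000
mvsir_config <- function(config = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop_config("config must be a list or a JSON path")
  base <- config_defaults()
  scale <- if (!is.null(config$scale)) config$scale else base$scale
  if (!scale %in% c("desk", "paper"))
    stop_config("config key 'scale' must be \"desk\" or \"paper\"")
  if (scale == "paper") base <- merge_config(base, config_paper_preset())
  cfg <- merge_config(base, config)
  # constructors perform the numeric validation
  do.call(phantom_params, c(cfg$phantom, list(seed = cfg$seed)))
  do.call(sampling_plan, c(cfg$sampling, list(seed = cfg$seed)))
  do.call(net_config, c(cfg$network,
                        list(patch_size = as.integer(cfg$patches$size))))
  do.call(train_config, c(cfg$training, list(seed = cfg$seed)))
  if (!is_count(cfg$preprocess$pad) || cfg$preprocess$pad < 0)
    stop_config("config key 'preprocess.pad' must be >= 0")
  if (!is_count(cfg$inference$stride) || cfg$inference$stride < 1)
    stop_config("config key 'inference.stride' must be >= 1")
  thr <- cfg$inference$threshold
  if (!(identical(thr, "auto") || (is.numeric(thr) && thr > 0 && thr < 1)))
    stop_config("config key 'inference.threshold' must be \"auto\" or in (0, 1)")
  if (!cfg$evaluation$reference %in% c("gt", "consensus"))
    stop_config("config key 'evaluation.reference' must be \"gt\" or \"consensus\"")
  structure(cfg, hash = config_hash(cfg), class = c("mvsir_config", "list"))
}

stage_log <- function(verbose, stage, t0, ...) {
  if (verbose)
    message(sprintf("[%s] %s (%.1fs)", stage, sprintf(...),
                    as.numeric(proc.time()[3] - t0)))
}

# stages 1-5: phantom -> cube -> centers -> streams, shared across variants
prepare_case <- function(cfg, verbose = TRUE) {
  t0 <- proc.time()[3]
  params <- do.call(phantom_params,
                    c(cfg$phantom, list(seed = derive_seed(cfg$seed, "phantom"))))
  case <- generate_phantom(params)
  stage_log(verbose, "phantom", t0, "%d nodule voxels, %d contours",
            sum(case$gt_mask), length(case$annotations))

  t0 <- proc.time()[3]
  vol <- resample_isotropic(case$volume, cfg$preprocess$target_spacing)
  if (!identical(dim(vol$data), dim(case$volume$data)))
    stop_config("run_pipeline: phantom spacing must match target spacing (annotations are in native voxel coordinates)")
  consensus <- consensus_mask(case$annotations, dim(vol$data))
  cube <- extract_cube(vol, consensus, pad = cfg$preprocess$pad)
  stage_log(verbose, "prepare", t0, "cube %s, %d consensus voxels",
            paste(dim(cube$data), collapse = "x"), sum(cube$mask))

  t0 <- proc.time()[3]
  plan <- do.call(sampling_plan,
                  c(cfg$sampling, list(seed = derive_seed(cfg$seed, "sample"))))
  centers <- sample_balanced_centers(cube, plan)
  stage_log(verbose, "sample", t0, "%d centers on %d slices (%d positive)",
            nrow(centers), length(unique(centers$slice)), sum(centers$label))

  t0 <- proc.time()[3]
  streams <- build_patch_streams(cube, centers, size = cfg$patches$size,
                                 fill = cfg$patches$fill,
                                 fill_value = cfg$patches$fill_value,
                                 vh_normalize = cfg$patches$vh_normalize)
  stage_log(verbose, "patches", t0, "%d x 6 patches of %d x %d",
            length(streams$labels), streams$size, streams$size)

  ref <- if (cfg$evaluation$reference == "gt") {
    d <- dim(cube$data)
    case$gt_mask[cube$offset[1] + seq_len(d[1]) - 1L,
                 cube$offset[2] + seq_len(d[2]) - 1L,
                 cube$offset[3] + seq_len(d[3]) - 1L, drop = FALSE]
  } else cube$mask
  list(params = params, case = case, cube = cube, centers = centers,
       streams = streams, reference = ref)
}

# stages 6-9 for one variant
fit_and_evaluate <- function(prep, cfg, variant = NULL, verbose = TRUE) {
  if (is.null(variant)) variant <- cfg$network$variant
  net_args <- cfg$network
  net_args$variant <- variant
  net <- do.call(net_config, c(net_args,
                               list(patch_size = as.integer(cfg$patches$size))))
  tcfg <- do.call(train_config,
                  c(cfg$training, list(seed = derive_seed(cfg$seed, "train"))))
  t0 <- proc.time()[3]
  model <- mvsir(prep$streams, net, tcfg)
  last <- model$curve[nrow(model$curve), ]
  stage_log(verbose, "train", t0, "%s val acc %.3f", variant, last$val_acc)

  t0 <- proc.time()[3]
  pred <- predict_cube(model, prep$cube, stride = cfg$inference$stride,
                       chunk = cfg$inference$chunk,
                       vh_normalize = cfg$patches$vh_normalize,
                       fill = cfg$patches$fill,
                       fill_value = cfg$patches$fill_value)
  stage_log(verbose, "predict", t0, "%d voxels scored", sum(pred$evaluated))

  roc <- roc_optimal_threshold(pred, prep$reference)
  thr <- if (identical(cfg$inference$threshold, "auto")) {
    t <- roc$optimal_threshold
    if (!is.finite(t) || t <= 0 || t >= 1) 0.5 else t
  } else cfg$inference$threshold
  seg <- binarize(pred, thr,
                  provenance = list(variant = variant,
                                    config_hash = attr(cfg, "hash"),
                                    fingerprint = model$fingerprint))
  report <- evaluate_segmentation(seg$mask, prep$reference, prep$cube$spacing)
  report$auc <- roc$auc
  report$threshold <- thr
  report$model <- variant
  report <- report[, c("model", "dice", "ppv", "sen", "hsd", "asd", "auc",
                       "threshold")]
  if (verbose)
    message(sprintf("[evaluate] dice %.3f ppv %.3f sen %.3f hsd %.2f asd %.3f auc %.4f",
                    report$dice, report$ppv, report$sen, report$hsd,
                    report$asd, report$auc))
  list(model = model, pred = pred, roc = roc, seg = seg, report = report)
}

#' Run the full phantom-to-metrics pipeline
#'
#' Executes phantom generation, consensus fusion and cube cropping, balanced
#' center sampling, patch extraction, network training, per-voxel cube
#' prediction, ROC threshold selection, binarization and evaluation, with
#' per-stage logging. Reruns with the same configuration (including seed)
#' reproduce the sampled centers and patch archives exactly.
#'
#' @param config Anything accepted by [mvsir_config()].
#' @param out_dir Optional run directory; when given, all artifacts are
#'   written there (phantom files, cube, centers CSV, learning-curve CSV,
#'   model checkpoint, confidence/mask NIfTI, metrics report CSV, effective
#'   config JSON), each tagged with the config hash.
#' @param verbose Log stage progress (default TRUE).
#' @return List with `report` (one-row metrics data.frame: dice, ppv, sen,
#'   hsd, asd, auc, threshold), `model`, `roc`, `pred`, `seg`, `cube`,
#'   `case`, `centers`, `config` and (if written) `paths`.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL, verbose = TRUE) {
  cfg <- mvsir_config(config)
  prep <- prepare_case(cfg, verbose)
  fit <- fit_and_evaluate(prep, cfg, verbose = verbose)
  out <- list(report = fit$report, model = fit$model, roc = fit$roc,
              pred = fit$pred, seg = fit$seg, cube = prep$cube,
              case = prep$case, centers = prep$centers, config = cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_phantom(prep$case, file.path(out_dir, "phantom"))
    write_cube(prep$cube, file.path(out_dir, "cube"))
    write_centers(prep$centers, file.path(out_dir, "centers.csv"))
    write.csv(fit$model$curve, file.path(out_dir, "learning_curve.csv"),
              row.names = FALSE)
    save_mvsir(fit$model, file.path(out_dir, "model.rds"))
    reconstruct_export(fit$seg, fit$pred, prep$cube,
                       file.path(out_dir, "segmentation"))
    write.csv(data.frame(threshold = fit$roc$thresholds, fpr = fit$roc$fpr,
                         tpr = fit$roc$tpr),
              file.path(out_dir, "roc.csv"), row.names = FALSE)
    jsonlite::write_json(list(auc = fit$roc$auc,
                              optimal_threshold = fit$roc$optimal_threshold),
                         file.path(out_dir, "roc.json"),
                         auto_unbox = TRUE, digits = NA)
    write.csv(fit$report, file.path(out_dir, "report.csv"), row.names = FALSE)
    jsonlite::write_json(list(config = unclass(cfg), hash = attr(cfg, "hash")),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    out$paths <- out_dir
  }
  out
}

#' Compare network variants on identical synthetic data
#'
#' Trains and evaluates the MV-CNN, MV-I-CNN and MV-SIR variants on one
#' shared phantom, center sample and patch archive, and reports the
#' per-variant segmentation metrics side by side. No ordering among variants
#' is implied on synthetic data.
#'
#' @param config Anything accepted by [mvsir_config()].
#' @param variants Character vector of variants to sweep.
#' @param out_dir Optional directory for the comparison CSV.
#' @param verbose Log stage progress.
#' @return A `data.frame` with one row per variant: `model, dice, ppv, sen,
#'   hsd, asd, auc, threshold, n_params`.
#' @export
run_variant_sweep <- function(config = NULL,
                              variants = c("MV-CNN", "MV-I-CNN", "MV-SIR"),
                              out_dir = NULL, verbose = TRUE) {
  cfg <- mvsir_config(config)
  prep <- prepare_case(cfg, verbose)
  rows <- lapply(variants, function(v) {
    fit <- fit_and_evaluate(prep, cfg, variant = v, verbose = verbose)
    rep <- fit$report
    rep$n_params <- fit$model$fingerprint$n_params
    rep
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(out, file.path(out_dir, "variant_comparison.csv"),
              row.names = FALSE)
  }
  out
}
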