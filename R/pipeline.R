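#' Luminance of an RGB volume
#' @param volume an RGB [volume_grid()].
#' @return scalar [volume_grid()] (double) of Rec.601 luminance.
#' @export
volume_luminance <- function(volume) {
  stopifnot(inherits(volume, "volume_grid"), volume$rgb)
  v <- volume$voxels
  lum <- 0.299 * v[1, , , ] + 0.587 * v[2, , , ] + 0.114 * v[3, , , ]
  volume_grid(array(lum, dim(v)[-1]), volume$spacing, volume$origin,
              type = "double")
}

#' Binary mould mask of a reconstructed colour volume
#'
#' Thresholds the luminance: everything brighter than `threshold` (the
#' embedded block and its interior structures against the dark background)
#' is mould.
#'
#' @param volume an RGB [volume_grid()].
#' @param threshold luminance threshold (0..255).
#' @return scalar uint8 mask [volume_grid()].
#' @export
mould_mask_from_volume <- function(volume, threshold = 60) {
  lum <- volume_luminance(volume)
  mask <- (lum$voxels > threshold) * 1L
  volume_grid(array(as.integer(mask), dim(lum$voxels)), volume$spacing,
              volume$origin, type = "uint8")
}

pipeline_config_schema <- list(
  global = c("seed", "out_dir", "verbose"),
  phantom = c("preset", "size_px", "pixel_spacing", "n_slices",
              "nominal_removal", "sigma_removal", "sigma_gauge", "jitter",
              "seam_prob", "drift_amplitude", "corrupt"),
  align = c("metric", "chain_seed", "dsat", "subsample", "tx_range",
            "ty_range", "theta_range", "tx_step", "ty_step", "theta_step",
            "refine"),
  reconstruct = c("dz"),
  register = c("allow_scale"),
  validate = c("density", "mask_threshold"))

#' Read and validate a pipeline run configuration
#'
#' The config is a YAML file with one block per stage (`global`, `phantom`,
#' `align`, `reconstruct`, `register`, `validate`); unknown blocks or keys
#' are rejected before any stage runs.
#'
#' @param path YAML file path, or a list already in memory.
#' @return validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  bad_blocks <- setdiff(names(cfg), names(pipeline_config_schema))
  if (length(bad_blocks))
    stop(sprintf("unknown config block(s): %s",
                 paste(bad_blocks, collapse = ", ")), call. = FALSE)
  for (blk in names(cfg)) {
    bad <- setdiff(names(cfg[[blk]]), pipeline_config_schema[[blk]])
    if (length(bad))
      stop(sprintf("unknown key(s) in config block '%s': %s", blk,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  cfg
}

cfg_get <- function(cfg, block, key, default) {
  val <- cfg[[block]][[key]]
  if (is.null(val)) default else val
}

#' Run the full synthetic pipeline: phantom -> align -> reconstruct ->
#' register -> validate
#'
#' Generates the phantom, exports its fixture layout, aligns the raw stack
#' to the template outline, reconstructs the colour volume on the 150 um
#' virtual grid, registers the ground-truth label volume to the
#' reconstruction via mould bounding-box landmarks, and validates the
#' reconstructed mould against ground truth (Hausdorff + volumetric error).
#' Every file written is listed, with its MD5 checksum, in
#' `manifest.json`; the resolved configuration is archived as
#' `config_resolved.yaml`. Fully deterministic for a fixed config and seed.
#'
#' @param config path to a YAML config, or a config list
#'   (see [read_run_config()]).
#' @param out_dir output directory (overrides the config's).
#' @return invisibly, list with `status` (0 on success), `manifest`
#'   (data.frame of files + checksums), `report` (the validation result)
#'   and `alignment` (per-slice report).
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- read_run_config(config)
  out_dir <- out_dir %||% cfg_get(cfg, "global", "out_dir", "pipeline_out")
  seed <- cfg_get(cfg, "global", "seed", 42L)
  verbose <- isTRUE(cfg_get(cfg, "global", "verbose", FALSE))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))

  stage <- "phantom"
  result <- tryCatch({
    spec_args <- cfg$phantom
    spec_args$corrupt <- NULL
    spec_args$seed <- seed
    spec <- do.call(phantom_spec, spec_args)
    say("[phantom] generating %d slices (seed %d)", spec$n_slices, seed)
    ph <- generate_phantom(spec)
    if (isTRUE(cfg_get(cfg, "phantom", "corrupt", FALSE)))
      ph$stack <- corrupt_stack(ph$stack, spec)
    dz <- cfg_get(cfg, "reconstruct", "dz", 0.15)
    export_fixture(ph, file.path(out_dir, "phantom"), dz = dz)

    stage <- "align"
    grid <- search_grid(
      tx_range = cfg_get(cfg, "align", "tx_range", c(-50, 50)),
      ty_range = cfg_get(cfg, "align", "ty_range", c(-50, 50)),
      theta_range = cfg_get(cfg, "align", "theta_range", c(-15, 15)),
      tx_step = cfg_get(cfg, "align", "tx_step", 2),
      ty_step = cfg_get(cfg, "align", "ty_step", 2),
      theta_step = cfg_get(cfg, "align", "theta_step", 1))
    say("[align] %d slices", length(ph$stack))
    aligned <- align_stack(
      ph$stack, ph$template, grid = grid,
      metric = cfg_get(cfg, "align", "metric", "dtf"),
      chain_seed = isTRUE(cfg_get(cfg, "align", "chain_seed", TRUE)),
      dsat = cfg_get(cfg, "align", "dsat", 25),
      subsample = cfg_get(cfg, "align", "subsample", 1L),
      refine = isTRUE(cfg_get(cfg, "align", "refine", TRUE)),
      verbose = verbose)
    write_transform_table(aligned$transforms,
                          file.path(out_dir, "transforms.csv"))

    stage <- "reconstruct"
    say("[reconstruct] dz = %g mm", dz)
    volume <- reconstruct_volume(aligned, dz = dz)
    write_nrrd(volume, file.path(out_dir, "reconstruction.nrrd"))

    stage <- "register"
    mask_thr <- cfg_get(cfg, "validate", "mask_threshold", 60)
    recon_mask <- mould_mask_from_volume(volume, mask_thr)
    truth_labels <- phantom_label_volume(
      spec, dz = dz, n_slots = dim(recon_mask$voxels)[3])
    truth_mask <- volume_grid(
      array(as.integer(truth_labels$voxels >= 1L),
            dim(truth_labels$voxels)),
      truth_labels$spacing, truth_labels$origin, type = "uint8")
    lm <- mask_corner_landmarks(truth_mask, recon_mask)
    reg <- landmark_register(lm$fixed, lm$moving,
                             allow_scale = isTRUE(cfg_get(cfg, "register",
                                                          "allow_scale",
                                                          FALSE)))
    say("[register] FRE = %.4g mm", reg$fre)
    export_transform(reg$transform, file.path(out_dir, "registration.txt"))
    export_transform_itk(reg$transform,
                         file.path(out_dir, "registration.tfm"))

    stage <- "validate"
    density <- cfg_get(cfg, "validate", "density", 70)
    say("[validate] density %g points/mm^2", density)
    report <- compare_overmould(
      truth_mask, recon_mask, density = density, seed = seed,
      report_path = file.path(out_dir, "accuracy_assessment.txt"))

    list(aligned = aligned, report = report, reg = reg, cfg = cfg)
  }, error = function(e) e)
  if (inherits(result, "error"))
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(result)), call. = FALSE)

  resolved <- file.path(out_dir, "config_resolved.yaml")
  yaml::write_yaml(list(global = list(seed = seed),
                        phantom = cfg$phantom, align = cfg$align,
                        reconstruct = cfg$reconstruct,
                        register = cfg$register,
                        validate = cfg$validate), resolved)
  files <- sort(list.files(out_dir, recursive = TRUE, full.names = TRUE))
  files <- setdiff(files, file.path(out_dir, "manifest.json"))
  manifest <- data.frame(file = sub(paste0("^", out_dir, "/?"), "", files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(status = 0L, manifest = manifest,
                 report = result$report,
                 alignment = attr(result$aligned, "alignment_report"),
                 registration = result$reg))
}

# landmarks at the corners of the mask bounding boxes (physical mm); the
# two masks live on the same grid here, so this exercises the landmark
# stage with a near-identity ground truth
mask_corner_landmarks <- function(fixed_mask, moving_mask) {
  corners <- function(v) {
    idx <- which(v$voxels > 0, arr.ind = TRUE)
    lo <- (apply(idx, 2, min) - 1) * v$spacing + v$origin
    hi <- (apply(idx, 2, max) - 1) * v$spacing + v$origin
    as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                          z = c(lo[3], hi[3])))
  }
  list(fixed = corners(fixed_mask), moving = corners(moving_mask))
}
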