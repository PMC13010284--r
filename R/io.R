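#' Read a 3D volume from a NIfTI-1 file
#'
#' @param path NIfTI file (`.nii` / `.nii.gz`)
#' @return a volume ([as_volume()]) carrying the voxel size from the file
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("%s is %dD; a 3D volume was expected", path, length(d)))
  as_volume(array(as.numeric(img), dim = d),
            abs(RNifti::pixdim(img)[1:3]))
}

#' Write a volume to a NIfTI-1 file
#'
#' @param volume a volume ([as_volume()]) or bare 3D array
#' @param path output file path (`.nii` / `.nii.gz`)
#' @return the path, invisibly
#' @export
write_volume <- function(volume, path) {
  img <- RNifti::asNifti(bare(volume))
  RNifti::pixdim(img) <- voxel_size(volume)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a subject's volumes, masks and sidecar to a directory
#'
#' One NIfTI file per volume/mask plus `sidecar.json` with the subject id,
#' seed, gains, tumor geometry and sampling points.
#'
#' @param subject a `subject_volume_set`
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_subject <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fields <- c("t1w", "t2w", "t1gd", "pet_suv", "brain_mask",
              "cerebellum_mask", "enhancing_mask", "tumor_mask",
              "cell_density")
  for (f in intersect(fields, names(subject)))
    write_volume(subject[[f]], file.path(dir, paste0(f, ".nii.gz")))
  side <- list(subject_id = subject$subject_id,
               seed = subject$seed,
               gains = as.list(subject$gains),
               voxel_size_mm = subject$voxel_size_mm,
               tumor_center_mm = subject$tumor_center_mm,
               tumor_radii_mm = as.list(subject$tumor_radii_mm),
               sampling_points = subject$sampling_points)
  jsonlite::write_json(side, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a subject directory written by [write_subject()]
#'
#' @param dir subject directory
#' @return a `subject_volume_set`
#' @export
read_subject <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "sidecar.json"),
                              simplifyVector = TRUE)
  fields <- c("t1w", "t2w", "t1gd", "pet_suv", "brain_mask",
              "cerebellum_mask", "enhancing_mask", "tumor_mask",
              "cell_density")
  subject <- list(subject_id = side$subject_id)
  for (f in fields) {
    p <- file.path(dir, paste0(f, ".nii.gz"))
    if (file.exists(p)) subject[[f]] <- read_volume(p)
  }
  subject$sampling_points <- tibble::as_tibble(side$sampling_points)
  subject$gains <- unlist(side$gains)
  subject$voxel_size_mm <- side$voxel_size_mm
  subject$seed <- side$seed
  class(subject) <- "subject_volume_set"
  subject
}

#' Default end-to-end pipeline configuration
#'
#' Desk-scale defaults: a small synthetic cohort, 64-px pairs and the
#' desk GAN preset. Any part can be overridden via `...` (named nested
#' lists are merged) or by loading a YAML file with
#' [load_pipeline_config()].
#'
#' @param seed global seed (drives phantom cohort, split and GAN)
#' @param out_dir run directory for all stage outputs
#' @param ... overrides merged into the defaults
#' @return a `pipeline_config` nested list
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("gliomap_run_"),
                            ...) {
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    phantom = list(spec = phantom_spec(seed = as.integer(seed)),
                   n_subjects = 10L),
    dataset = list(n_train = 8L, slice_axis = 3L, min_brain_fraction = 0.05,
                   image_size = 64L, max_train_pairs = 200L,
                   n_val_pairs = 16L),
    gan = gan_preset("desk", seed = as.integer(seed)),
    evaluate = list(thresholds = seq(1.1, 2, 0.1))
  )
  over <- list(...)
  if (length(over)) cfg <- utils::modifyList(cfg, over)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys override [pipeline_config()] defaults
#' @param ... further overrides
#' @return a `pipeline_config`
#' @export
load_pipeline_config <- function(path, ...) {
  over <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, c(over[intersect(names(over),
                                                   c("seed", "out_dir"))],
                                    list(...)))
  utils::modifyList(cfg, over[setdiff(names(over), c("seed", "out_dir"))])
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full pipeline on a synthetic cohort
#'
#' phantom -> normalize -> zCE -> PET T/N -> dataset assembly (subject-level
#' split, mirroring of the training partition only) -> adversarial training
#' -> per-test-subject map generation -> evaluation. All stage outputs,
#' logs and the exact configuration are written under `config$out_dir`;
#' the run is a deterministic function of `config$seed`.
#'
#' @param config a [pipeline_config()]
#' @return a `pipeline_result`: list with `reports` (per test subject),
#'   `summary` (cohort tibble), `model`, `split`, `config`
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- config
  cfg_json$gan <- unclass(cfg_json$gan)
  cfg_json$phantom$spec <- unclass(cfg_json$phantom$spec)
  jsonlite::write_json(unclass(cfg_json), file.path(config$out_dir,
                                                    "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")

  cohort <- run_stage("phantom",
    generate_cohort(config$phantom$spec, config$phantom$n_subjects,
                    seed = config$seed))
  split <- run_stage("dataset",
    split_cohort(cohort, config$dataset$n_train, seed = config$seed))

  ids <- vapply(cohort, `[[`, character(1), "subject_id")
  processed <- lapply(cohort, function(s)
    run_stage("preprocess", preprocess_subject(s)))
  names(processed) <- ids

  ds <- config$dataset
  mk_pairs <- function(id) run_stage("dataset",
    build_pairs(processed[[id]], ds$slice_axis, ds$min_brain_fraction,
                ds$image_size))
  pooled <- do.call(c, lapply(split$train_subjects, mk_pairs))
  # cap the training set at max_train_pairs: a seeded uniform subsample of
  # slices, drawn before mirroring so each kept slice trains with its
  # mirrored copy
  if (!is.null(ds$max_train_pairs) &&
      2L * length(pooled) > ds$max_train_pairs) {
    set.seed(config$seed)
    pooled <- pooled[sort(sample(length(pooled), ds$max_train_pairs %/% 2L))]
  }
  train_pairs <- mirror_augment(pooled)
  test_pairs <- do.call(c, lapply(split$test_subjects, mk_pairs))
  # evenly spaced held-out slices give a representative validation monitor
  vidx <- unique(round(seq(1, length(test_pairs),
                           length.out = min(ds$n_val_pairs,
                                            length(test_pairs)))))
  val_pairs <- test_pairs[vidx]

  manifest <- tibble::tibble(
    subject_id = vapply(train_pairs, `[[`, character(1), "subject_id"),
    slice = vapply(train_pairs, `[[`, integer(1), "slice_index"),
    mirrored = vapply(train_pairs, `[[`, logical(1), "mirrored"),
    partition = "train")
  manifest <- rbind(manifest, tibble::tibble(
    subject_id = vapply(test_pairs, `[[`, character(1), "subject_id"),
    slice = vapply(test_pairs, `[[`, integer(1), "slice_index"),
    mirrored = vapply(test_pairs, `[[`, logical(1), "mirrored"),
    partition = "test"))
  write.csv(manifest, file.path(config$out_dir, "pair_manifest.csv"),
            row.names = FALSE)

  model <- run_stage("gan", gan_train(train_pairs, config$gan, val_pairs))
  write.csv(model$trace, file.path(config$out_dir, "training_trace.csv"),
            row.names = FALSE)

  reports <- lapply(split$test_subjects, function(id) {
    p <- processed[[id]]
    gm <- run_stage("gan", generate_gliomap(model, p, ds$slice_axis,
                                            ds$min_brain_fraction))
    run_stage("evaluate",
      evaluate_subject(gm, p$tn, p$brain_mask, p$enhancing_mask,
                       config$evaluate$thresholds))
  })
  names(reports) <- split$test_subjects

  summary <- do.call(rbind, lapply(reports, function(r) {
    i15 <- which.min(abs(r$dice_curve$threshold - 1.5))
    tibble::tibble(subject_id = r$subject_id,
                   residual_mean = r$residual$mean,
                   residual_sd = r$residual$sd,
                   signed_mean = r$residual$signed_mean,
                   psnr_db = r$quality$psnr_db, snr_db = r$quality$snr_db,
                   ssim = r$quality$ssim,
                   dice_1p5 = r$dice_curve$dice[i15],
                   expansion_gliomap_1p5 = r$expansion_curve$expansion_gliomap[i15],
                   expansion_truth_1p5 = r$expansion_curve$expansion_truth[i15])
  }))
  write.csv(summary, file.path(config$out_dir, "evaluation_summary.csv"),
            row.names = FALSE)

  out <- list(reports = reports, summary = summary, model = model,
              split = split, config = config)
  class(out) <- "pipeline_result"
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(paste0("<pipeline_result> %d train / %d test subjects; mean ",
                     "test residual %.3f T/N, mean Dice@1.5 %.3f\n"),
              length(x$split$train_subjects), length(x$split$test_subjects),
              mean(x$summary$residual_mean), mean(x$summary$dice_1p5)))
  invisible(x)
}
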