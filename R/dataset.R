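#' Run the full preprocessing chain on one subject
#'
#' Normalizes T1W, T2W and T1Gd with the mode-anchored 8-bit rule, builds
#' the zCE map from the normalized T1Gd/T1W pair, and converts PET SUV to
#' the encoded T/N target. The result holds everything the dataset and
#' evaluation stages need.
#'
#' @param subject a `subject_volume_set` (see [generate_subject()]) or any
#'   list with the same volume/mask fields
#' @return a `processed_subject` list: `t1w_norm`, `t2w_norm`, `t1gd_norm`,
#'   `zce`, `tn`, the masks, `subject_id`, `voxel_size_mm`
#' @export
preprocess_subject <- function(subject) {
  t1w <- normalize_mri(subject$t1w, subject$brain_mask, modality = "t1w")
  t2w <- normalize_mri(subject$t2w, subject$brain_mask, modality = "t2w")
  t1gd <- normalize_mri(subject$t1gd, subject$brain_mask, modality = "t1gd")
  fit <- fit_t1gd_on_t1w(t1gd, t1w, subject$brain_mask)
  zce <- zce_map(t1gd, t1w, fit)
  tn <- tn_normalize(subject$pet_suv, subject$cerebellum_mask)
  out <- list(subject_id = subject$subject_id,
              t1w_norm = t1w, t2w_norm = t2w, t1gd_norm = t1gd,
              zce = zce, tn = tn,
              brain_mask = subject$brain_mask,
              cerebellum_mask = subject$cerebellum_mask,
              enhancing_mask = subject$enhancing_mask,
              tumor_mask = subject$tumor_mask,
              cell_density = subject$cell_density,
              sampling_points = subject$sampling_points,
              voxel_size_mm = voxel_size(subject$t1w))
  class(out) <- "processed_subject"
  out
}

# round-half-up quantization to 8-bit integers
quantize_8bit <- function(x) pmin(floor(x + 0.5), 255)

# center-crop or zero-pad a matrix to size s x s
fit_square <- function(m, s) {
  out <- matrix(0, s, s)
  n <- dim(m)
  src <- dst <- list()
  for (d in 1:2) {
    if (n[d] >= s) {
      o <- floor((n[d] - s) / 2)
      src[[d]] <- (o + 1):(o + s); dst[[d]] <- 1:s
    } else {
      o <- floor((s - n[d]) / 2)
      src[[d]] <- 1:n[d]; dst[[d]] <- (o + 1):(o + n[d])
    }
  }
  out[dst[[1]], dst[[2]]] <- m[src[[1]], src[[2]]]
  out
}

#' Assemble per-slice RGB source / PET target training pairs
#'
#' One pair per slice (default: axial, the third axis) whose brain-mask
#' coverage is at least `min_brain_fraction`. The source packs the
#' normalized T1W, T2W and encoded zCE into the red, green and blue
#' channels; the target is the encoded T/N image. Continuous 0-255 values
#' are quantized to 8-bit integers (round half up) here and only here, and
#' slices are center-cropped / zero-padded to a square `image_size`.
#'
#' @param processed a `processed_subject` ([preprocess_subject()])
#' @param slice_axis axis to slice along (1, 2 or 3; default 3 = axial)
#' @param min_brain_fraction minimum fraction of in-slice voxels inside the
#'   brain mask for the slice to produce a pair (default 0.05)
#' @param image_size square output size in pixels, a power of two
#' @return list of `source_target_pair`: each has `subject_id`,
#'   `slice_index`, `source` (size x size x 3 integer array), `target`
#'   (size x size matrix), `mirrored = FALSE`
#' @export
build_pairs <- function(processed, slice_axis = 3L, min_brain_fraction = 0.05,
                        image_size = 64L) {
  slice_of <- function(vol, k) {
    switch(slice_axis,
           `1` = vol[k, , ], `2` = vol[, k, ], `3` = vol[, , k])
  }
  nk <- dim(processed$brain_mask)[slice_axis]
  pairs <- list()
  for (k in seq_len(nk)) {
    bm <- slice_of(bare(processed$brain_mask), k)
    if (mean(bm != 0) < min_brain_fraction) next
    chans <- lapply(list(processed$t1w_norm, processed$t2w_norm,
                         processed$zce$encoded),
                    function(v) quantize_8bit(fit_square(slice_of(bare(v), k),
                                                         image_size)))
    target <- quantize_8bit(fit_square(slice_of(bare(processed$tn$encoded), k),
                                       image_size))
    pair <- list(subject_id = processed$subject_id, slice_index = k,
                 source = array(c(chans[[1]], chans[[2]], chans[[3]]),
                                dim = c(image_size, image_size, 3)),
                 target = target, mirrored = FALSE,
                 brain_fraction = mean(bm != 0))
    class(pair) <- "source_target_pair"
    pairs[[length(pairs) + 1L]] <- pair
  }
  if (length(pairs) == 0L)
    warning(sprintf("no slice of %s reached min_brain_fraction = %g",
                    processed$subject_id, min_brain_fraction))
  pairs
}

#' Horizontal-mirroring augmentation
#'
#' Returns the input pairs followed by their left-right mirrored copies
#' (source and target flipped together, flagged `mirrored = TRUE`), exactly
#' doubling the pair count. Intended for the training partition only.
#'
#' @param pairs list of `source_target_pair`
#' @return list of length `2 * length(pairs)`
#' @export
mirror_augment <- function(pairs) {
  flipped <- lapply(pairs, function(p) {
    p$source <- p$source[rev(seq_len(dim(p$source)[1])), , , drop = FALSE]
    p$target <- p$target[rev(seq_len(nrow(p$target))), , drop = FALSE]
    p$mirrored <- TRUE
    p
  })
  c(pairs, flipped)
}

#' Subject-level train/test split
#'
#' Randomly assigns `n_train` subjects to the training partition and the
#' rest to the test partition. The split is by subject, never by slice, so
#' no subject contributes pairs to both sides.
#'
#' @param subjects list of subjects (or a character vector of subject ids)
#' @param n_train number of training subjects (< length of `subjects`)
#' @param seed integer seed making the split deterministic
#' @return a `dataset_split`: list with `train_subjects`, `test_subjects`
#'   (character), `seed`
#' @export
split_cohort <- function(subjects, n_train, seed = 1L) {
  ids <- if (is.character(subjects)) subjects
         else vapply(subjects, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids)) stop("subject ids must be unique")
  if (n_train >= length(ids))
    stop("n_train must be smaller than the cohort size")
  set.seed(as.integer(seed))
  train <- sort(sample(length(ids), n_train))
  out <- list(train_subjects = ids[train], test_subjects = ids[-train],
              seed = as.integer(seed))
  class(out) <- "dataset_split"
  out
}

#' Export pairs as side-by-side PNGs with a CSV manifest
#'
#' Writes each pair as an 8-bit `source|target` PNG (the aligned paired
#' layout) under `dir`, plus `manifest.csv` with subject, slice, mirrored
#' flag and file name.
#'
#' @param pairs list of `source_target_pair`
#' @param dir output directory (created if missing)
#' @return invisibly, the manifest tibble
#' @export
write_pairs <- function(pairs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    s <- dim(p$target)
    img <- array(0, dim = c(s[1], 2 * s[2], 3))
    img[, seq_len(s[2]), ] <- p$source / 255
    img[, s[2] + seq_len(s[2]), ] <- array(rep(p$target / 255, 3),
                                           dim = c(s, 3))
    file <- sprintf("%s_slice%03d%s.png", p$subject_id, p$slice_index,
                    if (p$mirrored) "_m" else "")
    png::writePNG(img, file.path(dir, file))
    tibble::tibble(subject_id = p$subject_id, slice = p$slice_index,
                   mirrored = p$mirrored, file = file)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
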