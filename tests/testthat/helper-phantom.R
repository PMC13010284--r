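# compact phantom spec so unit tests run in seconds
small_spec <- function(...,
                       tumor_geometry = list(center_mm = NULL,
                                             core_radius_mm = 10,
                                             rim_thickness_mm = 6,
                                             edema_thickness_mm = 8)) {
  phantom_spec(grid_shape = c(48, 48, 32), voxel_size_mm = c(3, 3, 3),
               tumor_geometry = tumor_geometry, ...)
}

# a low-noise small subject shared across tests (computed once)
quiet_subject <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      spec <- small_spec(noise_sd = c(t1w = 1, t2w = 1, t1gd = 1, pet = 0.02),
                         seed = 101L)
      memo <<- generate_subject(spec, 1)
    }
    memo
  }
})

# fake processed subject with hand-set constant volumes (for dataset tests)
constant_processed <- function(val_t1 = 10, val_t2 = 20, val_zce = 30,
                               val_tn = 76.5, dims = c(8, 8, 4)) {
  vol <- function(v) as_volume(array(v, dim = dims), c(2, 2, 2))
  list(subject_id = "sub-const",
       t1w_norm = vol(val_t1), t2w_norm = vol(val_t2),
       zce = list(encoded = vol(val_zce)),
       tn = list(encoded = vol(val_tn)),
       brain_mask = vol(1))
}
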