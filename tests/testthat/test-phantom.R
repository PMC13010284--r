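test_that("subject generation is deterministic under identical spec and seed", {
  spec <- small_spec(seed = 7L)
  a <- generate_subject(spec, 3)
  b <- generate_subject(spec, 3)
  expect_identical(a$t1w, b$t1w)
  expect_identical(a$pet_suv, b$pet_suv)
  expect_identical(a$sampling_points, b$sampling_points)
})

test_that("masks satisfy the anatomical subset relations on every subject", {
  cohort <- generate_cohort(small_spec(), 3, seed = 5)
  for (s in cohort) {
    expect_true(all(s$brain_mask[s$tumor_mask == 1] == 1))
    expect_true(all(s$tumor_mask[s$enhancing_mask == 1] == 1))
    expect_true(all(s$brain_mask[s$cerebellum_mask == 1] == 1))
    expect_true(all(s$cerebellum_mask[s$tumor_mask == 1] == 0))
    expect_true(all(s$cell_density[s$tumor_mask == 0] == 0))
    expect_identical(dim(s$t1w), dim(s$pet_suv))
  }
})

test_that("voxelized enhancing core matches the analytic sphere volume", {
  spec <- phantom_spec(grid_shape = c(64, 64, 64), voxel_size_mm = c(1, 1, 1),
                       tumor_geometry = list(center_mm = NULL,
                                             core_radius_mm = 8,
                                             rim_thickness_mm = 2,
                                             edema_thickness_mm = 2),
                       geometry_jitter = 0, n_sampling_points = 0)
  s <- generate_subject(spec, 1)
  analytic <- 4 / 3 * pi * 8^3
  voxelized <- sum(s$enhancing_mask) * prod(spec$voxel_size_mm)
  expect_lt(abs(voxelized - analytic) / analytic, 0.05)
})

test_that("zero noise and zero density give a flat PET baseline in the brain", {
  spec <- small_spec(noise_sd = c(t1w = 0, t2w = 0, t1gd = 0, pet = 0),
                     density_params = list(peak_density = 0,
                                           suv_per_cell = 8.7e-5,
                                           t2_density_gain = 40,
                                           enhancement_gain = 80))
  s <- generate_subject(spec, 1)
  expect_true(all(s$pet_suv[s$brain_mask == 1] == 1.5))
  expect_true(all(s$cell_density == 0))
})

test_that("PET uptake tracks the latent cell-density map inside the tumor", {
  s <- quiet_subject()
  idx <- s$tumor_mask == 1
  expect_gt(cor(s$cell_density[idx], s$pet_suv[idx]), 0.95)
})

test_that("sampling points lie in the brain with analytic densities", {
  s <- quiet_subject()
  pts <- s$sampling_points
  expect_equal(nrow(pts), 16L)
  vs <- s$voxel_size_mm
  ijk <- cbind(ceiling(pts$x / vs[1]), ceiling(pts$y / vs[2]),
               ceiling(pts$z / vs[3]))
  expect_true(all(s$brain_mask[ijk] == 1))
  expect_true(all(pts$true_density >= 0 &
                    pts$true_density <= 30000))
})

test_that("cohorts differ across subjects but are seed-deterministic", {
  spec <- small_spec()
  c1 <- generate_cohort(spec, 2, seed = 9)
  c2 <- generate_cohort(spec, 2, seed = 9)
  expect_identical(c1[[1]]$t1w, c2[[1]]$t1w)
  expect_false(identical(c1[[1]]$t1w, c1[[2]]$t1w))
  ids_a <- vapply(generate_cohort(spec, 3, seed = 1), `[[`, "", "subject_id")
  ids_b <- vapply(generate_cohort(spec, 3, seed = 2), `[[`, "", "subject_id")
  expect_length(intersect(ids_a, ids_b), 0)
})

test_that("subject gains empirically span the configured gain range", {
  spec <- small_spec(gain_range = c(0.5, 2))
  gains <- unlist(lapply(generate_cohort(spec, 50, seed = 3), `[[`, "gains"))
  expect_true(all(gains >= 0.5 & gains <= 2))
  expect_lt(min(gains), 0.65)
  expect_gt(max(gains), 1.8)
})

test_that("invalid specs are rejected", {
  expect_error(small_spec(gain_range = c(-1, 2)), "gain_range")
  expect_error(small_spec(tumor_geometry = list(center_mm = NULL,
                                                core_radius_mm = -1,
                                                rim_thickness_mm = 6,
                                                edema_thickness_mm = 8)),
               "positive")
  expect_error(small_spec(tumor_geometry = list(center_mm = c(0, 0, 0),
                                                core_radius_mm = 10,
                                                rim_thickness_mm = 6,
                                                edema_thickness_mm = 8)),
               "fit inside the brain")
})
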