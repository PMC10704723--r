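test_that("phantom pairs are deterministic and in range", {
  spec <- phantom_spec()
  a <- make_phantom_pair(spec, seed = 0)
  b <- make_phantom_pair(spec, seed = 0)
  expect_identical(a, b)
  expect_true(all(a$pair$mri >= 0 & a$pair$mri <= 1))
  expect_true(all(a$pair$ct >= 0 & a$pair$ct <= 1))
  c <- make_phantom_pair(spec, seed = 1)
  expect_false(identical(a$pair$ct, c$pair$ct))
})

test_that("masks depend only on the geometry stream", {
  spec <- phantom_spec()
  a <- make_phantom_pair(spec, seed = 0, geometry_seed = 5)
  b <- make_phantom_pair(spec, seed = 1, geometry_seed = 5)
  expect_identical(a$truth, b$truth)          # same geometry, masks stable
  expect_false(identical(a$pair$mri, b$pair$mri))  # noise differs
})

test_that("mask invariants hold", {
  for (seed in 0:3) {
    ph <- make_phantom_pair(phantom_spec(), seed = seed,
                            geometry_seed = seed + 10)
    t <- ph$truth
    expect_true(all(t$bone_mask <= t$head_mask))
    expect_true(all(t$tumor_mask <= t$head_mask))
    expect_equal(sum(t$tumor_mask * t$bone_mask), 0)
    expect_true(all(t$head_mask %in% c(0, 1)))
    expect_gt(sum(t$tumor_mask), 0)
  }
})

test_that("CT is bright on bone and has lower within-head dynamic range than MRI", {
  spec <- phantom_spec(noise_sigma_ct = 0, noise_sigma_mri = 0)
  ph <- make_phantom_pair(spec, seed = 0)
  bone <- ph$truth$bone_mask == 1
  soft <- ph$truth$head_mask == 1 & !bone
  expect_gt(mean(ph$pair$ct[bone]), mean(ph$pair$ct[soft]))
  head <- ph$truth$head_mask == 1
  expect_lt(diff(range(ph$pair$ct[head])), diff(range(ph$pair$mri[head])))
})

test_that("phantom dataset items are reproducible and pairwise distinct", {
  spec <- phantom_spec(image_size = 32)
  ds1 <- make_phantom_dataset(4, spec, seed = 7)
  ds2 <- make_phantom_dataset(4, spec, seed = 7)
  expect_identical(ds1, ds2)
  expect_length(make_phantom_dataset(1, spec, seed = 7), 1)
  big <- make_phantom_dataset(8, spec, seed = 0)
  for (i in 1:7) for (j in (i + 1):8)
    expect_false(identical(big[[i]]$pair$mri, big[[j]]$pair$mri))
  expect_error(make_phantom_dataset(0, spec, seed = 0), "n must be")
})

test_that("misalignment: identity, symmetry and round trip", {
  ph <- make_phantom_pair(phantom_spec(noise_sigma_ct = 0,
                                       noise_sigma_mri = 0), seed = 2)
  id <- apply_misalignment(ph$pair, rigid_transform2d(0, 0, 0))
  expect_equal(id$mri, ph$pair$mri)
  expect_identical(id$ct, ph$pair$ct)
  # rotating a radially symmetric disk changes nothing (up to interpolation)
  n <- 32
  disk <- (radius_map_test(n) <= 10) * 0.8
  pair <- slice_pair(disk, disk)
  rot <- apply_misalignment(pair, rigid_transform2d(90, 0, 0))
  expect_lt(mean(abs(rot$mri - disk)), 0.02)
  # transform then inverse recovers a smooth phantom
  t <- rigid_transform2d(11, 3.5, -2.25)
  fwd <- apply_misalignment(ph$pair, t)
  back <- apply_misalignment(fwd, invert_rigid(t))
  expect_lt(mean(abs(back$mri - ph$pair$mri)), 0.02)
})

test_that("bed artifact lies outside the head and only on the CT", {
  spec <- phantom_spec(include_bed = TRUE, noise_sigma_ct = 0,
                       noise_sigma_mri = 0)
  ph <- make_phantom_pair(spec, seed = 4)
  expect_gt(sum(ph$truth$bed_mask), 0)
  expect_equal(sum(ph$truth$bed_mask * ph$truth$head_mask), 0)
  outside_bright <- ph$pair$ct > 0.5 & ph$truth$head_mask == 0
  expect_gt(sum(outside_bright), 0)
  no_bed <- make_phantom_pair(phantom_spec(include_bed = FALSE,
                                           noise_sigma_ct = 0,
                                           noise_sigma_mri = 0), seed = 4)
  expect_identical(add_bed_artifact(no_bed$pair$ct,
                                    phantom_spec(include_bed = FALSE),
                                    no_bed$truth$head_mask),
                   no_bed$pair$ct)
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(image_size = 8), "image_size")
  expect_error(phantom_spec(skull_thickness_frac = 0.95,
                            skull_outer_radius_frac = 0.9), "skull")
  expect_error(phantom_spec(noise_sigma_ct = -0.1), "noise")
})
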