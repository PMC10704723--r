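test_that("min-max normalization follows the slice formula", {
  expect_equal(minmax_normalize(matrix(c(2, 4, 6), 1)), matrix(c(0, 0.5, 1), 1))
  x <- random_image(12, 12, 1)
  nx <- minmax_normalize(x)
  expect_equal(min(nx), 0)
  expect_equal(max(nx), 1)
  expect_equal(minmax_normalize(nx), nx)      # idempotent on non-constant input
  expect_warning(z <- minmax_normalize(matrix(3, 4, 4)), "constant")
  expect_equal(z, matrix(0, 4, 4))
  already <- matrix(seq(0, 1, length.out = 16), 4)
  expect_equal(minmax_normalize(already), already)
})

test_that("Otsu threshold equals the exhaustive between-class maximizer", {
  half <- matrix(c(rep(0, 32), rep(1, 32)), 8)
  thr <- otsu_threshold(half)
  expect_gt(thr, 0); expect_lt(thr, 1)
  set.seed(0)
  bimodal <- matrix(c(rnorm(32, 0.2, 0.05), rnorm(32, 0.8, 0.05)), 8)
  expect_equal(otsu_threshold(bimodal), otsu_oracle(bimodal))
  for (s in 1:25) {
    x <- random_image(8, 8, s)
    expect_equal(otsu_threshold(x), otsu_oracle(x))
  }
  x <- random_image(10, 10, 99)
  xp <- x[sample(nrow(x)), ]
  expect_equal(otsu_threshold(x), otsu_threshold(xp))  # histogram invariance
  expect_error(otsu_threshold(matrix(1, 4, 4)), "single-valued")
})

test_that("Otsu agrees with an established implementation", {
  for (s in 1:5) {
    x <- random_image(16, 16, s + 40)
    ours <- otsu_threshold(x, n_bins = 256)
    ref <- EBImage::otsu(EBImage::Image(x), range = range(x), levels = 256)
    # conventions differ by up to a couple of histogram bins
    expect_lt(abs(ours - ref), 3 / 256 * diff(range(x)))
  }
})

test_that("head mask recovers a disk, closes holes, keeps the largest blob", {
  n <- 48
  disk <- (radius_map_test(n) <= 15) * 0.9 + 0.02
  m <- head_mask(disk, closing_radius_px = 3)
  ref <- (radius_map_test(n) <= 15) * 1
  expect_lt(mean(abs(m - ref)), 0.02)         # within a ~1 px boundary band
  holed <- disk
  holed[23:25, 23:25] <- 0.02                 # 3-px interior hole
  m2 <- head_mask(holed, closing_radius_px = 2)
  expect_equal(sum(m2[23:25, 23:25]), 9)      # hole filled
  two <- matrix(0.02, n, n)
  two[5:24, 5:24] <- 0.9                      # large blob
  two[35:40, 35:40] <- 0.9                    # 4x smaller blob
  m3 <- head_mask(two, closing_radius_px = 1)
  expect_equal(sum(m3[35:40, 35:40]), 0)
  expect_gt(sum(m3[5:24, 5:24]), 300)
})

test_that("bed removal zeroes CT outside the MRI head mask", {
  spec <- phantom_spec(include_bed = TRUE)
  ph <- make_phantom_pair(spec, seed = 1)
  cleaned <- remove_bed(ph$pair$ct, ph$pair$mri)
  expect_true(all(cleaned[ph$truth$bed_mask == 1] == 0))
  expect_true(all(cleaned <= ph$pair$ct + 1e-12))   # masking monotonicity
  nobed <- make_phantom_pair(phantom_spec(), seed = 1)
  cleaned2 <- remove_bed(nobed$pair$ct, nobed$pair$mri)
  m <- head_mask(nobed$pair$mri)
  expect_equal(cleaned2, nobed$pair$ct * m)
})

test_that("NMI matches its definition, is symmetric, and detects identity", {
  a <- random_image(32, 32, 3)
  b <- random_image(32, 32, 4)
  expect_equal(nmi(a, a), 2, tolerance = 1e-12)
  expect_equal(nmi(a, b), nmi(b, a))
  expect_equal(nmi(a, b, 64), nmi_oracle(a, b, 64), tolerance = 1e-12)
  expect_error(nmi(a, random_image(16, 16, 5)), "shape")
})

test_that("NMI of independent noise approaches its floor", {
  a <- random_image(128, 128, 10)
  b <- random_image(128, 128, 11)
  v <- nmi(a, b, n_bins = 32)
  expect_gt(v, 1)
  expect_lt(v, 1.15)
})

test_that("registration recovers identity and improves NMI", {
  ph <- make_phantom_pair(phantom_spec(noise_sigma_ct = 0.01,
                                       noise_sigma_mri = 0.01), seed = 3)
  reg <- rigid_register(ph$pair$mri, ph$pair$mri,
                        rot_range_deg = 4, trans_range_px = 3)
  expect_lt(abs(reg$transform$rotation_deg), 0.5)
  expect_lt(abs(reg$transform$tx_px), 0.5)
  expect_lt(abs(reg$transform$ty_px), 0.5)
  # known misalignment, monomodal recovery
  tr <- rigid_transform2d(7, 4, -3)
  mis <- apply_misalignment(ph$pair, tr)
  reg2 <- rigid_register(mis$mri, ph$pair$mri,
                         rot_range_deg = 10, trans_range_px = 6)
  inv <- invert_rigid(tr)
  expect_lt(abs(reg2$transform$rotation_deg - inv$rotation_deg), 1)
  expect_lt(abs(reg2$transform$tx_px - inv$tx_px), 1)
  expect_lt(abs(reg2$transform$ty_px - inv$ty_px), 1)
  expect_gte(reg2$nmi, nmi(mis$mri, ph$pair$mri))  # optimizer contract
  expect_error(rigid_register(ph$pair$mri, ph$pair$mri, rot_step_deg = 0),
               "search range")
})

test_that("full preprocessing yields masked, normalized pairs", {
  ph <- make_phantom_pair(phantom_spec(include_bed = TRUE), seed = 6)
  out <- preprocess_pair(ph$pair)
  expect_true(all(out$ct >= 0 & out$ct <= 1))
  expect_true(all(out$mri >= 0 & out$mri <= 1))
  expect_true(all(out$ct[ph$truth$bed_mask == 1] == 0))
})
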