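test_that("entropy closed forms", {
  expect_equal(entropy(matrix(0.5, 8, 8)), 0)
  two <- matrix(c(rep(0.1, 32), rep(0.9, 32)), 8)
  expect_equal(entropy(two), 1)
  all_levels <- matrix((0:255) / 255, 16, 16)
  expect_equal(entropy(all_levels), 8)
})

test_that("standard deviation metric", {
  expect_equal(std_metric(matrix(2, 5, 5)), 0)
  half <- matrix(c(rep(0, 32), rep(1, 32)), 8)
  expect_equal(std_metric(half), 0.5)
  x <- random_image(9, 9, 1)
  expect_equal(std_metric(3 * x), 3 * std_metric(x), tolerance = 1e-12)
})

test_that("mean gradient closed forms", {
  expect_equal(mean_gradient(matrix(1, 6, 6)), 0)
  s <- 0.04
  ramp <- matrix(rep(s * (1:10), 10), 10, 10)     # slope s along rows
  expect_equal(mean_gradient(ramp), s / sqrt(2), tolerance = 1e-12)
  x <- random_image(7, 7, 2)
  expect_equal(mean_gradient(x + 0.3), mean_gradient(x), tolerance = 1e-12)
})

test_that("spatial frequency closed forms and permutation sensitivity", {
  expect_equal(spatial_frequency(matrix(0.2, 6, 6)), 0)
  checker <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  expect_equal(spatial_frequency(checker), sqrt(2), tolerance = 1e-12)
  x <- random_image(8, 8, 3)
  set.seed(1); xs <- matrix(sample(x), 8, 8)
  expect_false(isTRUE(all.equal(spatial_frequency(x), spatial_frequency(xs))))
  expect_equal(entropy(x), entropy(xs))           # but ENT is invariant
  expect_equal(std_metric(x), std_metric(xs))     # and so is STD
})

test_that("mutual information: identity doubles entropy, independence near 0", {
  x <- random_image(16, 16, 4)
  expect_equal(mutual_information(x, x, x, n_bins = 64),
               2 * local({
                 h <- tabulate(pmin(floor(x * 64) + 1, 64), 64)
                 p <- h[h > 0] / sum(h); -sum(p * log2(p))
               }), tolerance = 1e-12)
  a <- random_image(128, 128, 5); b <- random_image(128, 128, 6)
  f <- random_image(128, 128, 7)
  expect_lt(mutual_information(f, a, b, n_bins = 16) / 2, 0.15)
  # each term symmetric in its arguments
  expect_equal(medfusion:::mi_pair_bits(a, b, 32),
               medfusion:::mi_pair_bits(b, a, 32), tolerance = 1e-12)
})

test_that("NCC and PSNR closed forms", {
  x <- random_image(12, 12, 8)
  expect_equal(ncc(x, x, x), 1, tolerance = 1e-12)
  anti <- 2 * mean(x) - x
  expect_equal(ncc(anti, x, x), -1, tolerance = 1e-12)
  expect_identical(psnr(x, x, x), Inf)
  z <- matrix(0, 8, 8); h <- matrix(0.5, 8, 8)
  expect_equal(psnr(h, z, z), 6.0206, tolerance = 1e-3)
  noisier <- psnr(h + 0.1, z, z)
  expect_lt(noisier, psnr(h, z, z))               # monotone in MSE
})

test_that("edge preservation metric: perfect, destroyed, bounded", {
  ph <- tiny_phantom_pair(24, seed = 5)
  m <- ph$pair$mri; ct <- ph$pair$ct
  v_same <- q_xy_f(m, ct, m)
  # perfect preservation of the MRI edges still weighted by both sources;
  # fusing the sources themselves attains the metric maximum for identical
  # inputs:
  vmax <- q_xy_f(m, m, m)
  q <- qxy_params()
  qg1 <- q$gamma_g / (1 + exp(q$kappa_g * (1 - q$sigma_g)))
  qa1 <- q$gamma_a / (1 + exp(q$kappa_a * (1 - q$sigma_a)))
  expect_equal(vmax, qg1 * qa1, tolerance = 1e-6)
  expect_lt(q_xy_f(m, ct, matrix(0.5, 24, 24)), 0.05)
  for (s in 1:5) {
    f <- random_image(24, 24, s)
    v <- q_xy_f(m, ct, f)
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("fusion SSIM averages the two per-source indices", {
  ph <- tiny_phantom_pair(24, seed = 6)
  p <- ssim_params(window_size = 7)
  f <- random_image(24, 24, 9)
  expect_equal(ssim_fusion(f, ph$pair$mri, ph$pair$ct, p),
               (ssim_index(f, ph$pair$mri, p) + ssim_index(f, ph$pair$ct, p)) / 2)
  expect_equal(ssim_fusion(ph$pair$mri, ph$pair$mri, ph$pair$mri, p), 1,
               tolerance = 1e-12)
  expect_equal(ssim_fusion(f, ph$pair$ct, ph$pair$mri, p),
               ssim_fusion(f, ph$pair$mri, ph$pair$ct, p))
})

test_that("Dice examples and degeneracies", {
  a <- matrix(0, 6, 6); a[2:3, 2:3] <- 1
  expect_equal(dice(a, a), 1)
  b <- matrix(0, 6, 6); b[5:6, 5:6] <- 1
  expect_equal(dice(a, b), 0)
  c <- matrix(0, 6, 6); c[2:3, 3:4] <- 1       # shares 2 pixels with a
  expect_equal(dice(a, c), 0.5)
  expect_error(dice(matrix(0, 3, 3), matrix(0, 3, 3)), "empty")
})

test_that("Hausdorff examples, symmetry, spacing", {
  a <- matrix(0, 8, 8); a[2, 2] <- 1
  b <- matrix(0, 8, 8); b[2, 5] <- 1
  expect_equal(hausdorff(a, b), 3)
  expect_equal(hausdorff(b, a), hausdorff(a, b))
  expect_equal(hausdorff(a, b, pixel_spacing_mm = 0.5), 1.5)
  expect_equal(hausdorff(a, a), 0)
})

test_that("erosion degrades Dice and grows Hausdorff monotonically", {
  m <- (radius_map_test(32) <= 12) * 1
  prev_d <- 1; prev_h <- 0
  cur <- m
  for (i in 1:3) {
    cur <- EBImage::erode(cur, EBImage::makeBrush(3, "box"))
    cur <- matrix(as.numeric(cur), 32, 32)
    d <- dice(m, cur); h <- hausdorff(m, cur)
    expect_lte(d, prev_d); expect_gte(h, prev_h)
    prev_d <- d; prev_h <- h
  }
})

test_that("line profiles extract the stated row", {
  x <- random_image(10, 12, 12)
  pr <- line_profile(x, 4)
  expect_equal(pr$intensity, x[4, ])
  expect_equal(pr$col, 1:12)
  expect_error(line_profile(x, 11), "out of range")
})

test_that("evaluate reports all metrics and batches consistently", {
  ph <- make_phantom_pair(phantom_spec(image_size = 32), seed = 8)
  f <- random_image(32, 32, 10)
  p <- ssim_params(window_size = 7)
  rep <- evaluate(f, ph$pair, roi_pred = ph$truth$tumor_mask,
                  roi_ref = ph$truth$tumor_mask, p = p)
  expect_true(all(vapply(rep, is.finite, TRUE)))
  expect_equal(rep$dice, 1)
  expect_equal(rep$hausdorff_mm, 0)
  # a 1-slice batch has zero sd; batch means equal per-slice means
  eb <- evaluate_batch(list(f), list(ph$pair), p = p)
  expect_true(all(eb$summary$sd == 0))
  f2 <- random_image(32, 32, 11)
  eb2 <- evaluate_batch(list(f, f2), list(ph$pair, ph$pair), p = p)
  expect_equal(eb2$summary$mean[eb2$summary$metric == "ent"],
               mean(c(entropy(f), entropy(f2))))
  cmp <- compare_methods(eb2$per_slice, eb2$per_slice * 1.0)
  expect_true(all(cmp$p_value > 0.99 | is.nan(cmp$p_value)))
})
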