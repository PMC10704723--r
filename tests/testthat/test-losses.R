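test_that("gradient loss vanishes on identical and constant-offset images", {
  a <- random_image(8, 8, 1)
  expect_equal(gradient_loss(a, a), 0)
  expect_equal(gradient_loss(a + 0.25, a), 0, tolerance = 1e-12)
  expect_error(gradient_loss(a, random_image(4, 4, 2)), "shape")
})

test_that("gradient loss matches the per-pixel Sobel oracle", {
  for (s in 1:6) {
    f <- matrix(sample(0:5, 16, replace = TRUE), 4, 4)
    m <- matrix(sample(0:5, 16, replace = TRUE), 4, 4)
    expect_equal(gradient_loss(f, m), gradient_loss_oracle(f, m),
                 tolerance = 1e-12)
  }
})

test_that("SSIM index: identity, symmetry, constants, window guard", {
  a <- random_image(16, 16, 2)
  b <- random_image(16, 16, 3)
  expect_equal(ssim_index(a, a), 1, tolerance = 1e-12)
  expect_equal(ssim_index(a, b), ssim_index(b, a))
  p <- ssim_params()
  m1 <- 0.3; m2 <- 0.7
  expect_equal(ssim_index(matrix(m1, 12, 12), matrix(m2, 12, 12), p),
               (2 * m1 * m2 + p$C1) / (m1^2 + m2^2 + p$C1),
               tolerance = 1e-12)
  expect_error(ssim_index(random_image(8, 8, 1), random_image(8, 8, 2)),
               "window")
  # against the sliding-window oracle
  expect_equal(ssim_index(a, b), ssim_oracle(a, b), tolerance = 1e-12)
})

test_that("SSIM loss is 1 - index and exceeds 1 for anti-correlated texture", {
  a <- random_image(16, 16, 4)
  expect_equal(ssim_loss(a, a), 0, tolerance = 1e-12)
  b <- random_image(16, 16, 5)
  expect_equal(ssim_loss(a, b), 1 - ssim_index(a, b))
  tex <- 0.5 + 0.4 * sin(outer(1:16, 1:16, "+"))
  anti <- 1 - tex                              # sign-flipped structure
  expect_gt(ssim_loss(tex, anti), 1)
})

test_that("perceptual loss: zero at identity, nonnegative, reproducible", {
  phi <- feature_extractor(seed = 77)
  a <- random_image(16, 16, 6)
  b <- random_image(16, 16, 7)
  expect_equal(perceptual_loss(a, a, phi), 0)
  v <- perceptual_loss(a, b, phi)
  expect_gte(v, 0)
  phi2 <- feature_extractor(seed = 77)
  expect_identical(perceptual_loss(a, b, phi2), v)
  expect_error(feature_extractor(mode = "pretrained-perceptual"),
               "seeded-random-conv")
})

test_that("L1 term: direct arithmetic and bounds", {
  a <- random_image(8, 8, 8)
  expect_equal(l1_term(a, a, a), 0)
  z <- matrix(0, 8, 8); o <- matrix(1, 8, 8); h <- matrix(0.5, 8, 8)
  expect_equal(l1_term(h, z, o), 0.5)
  x <- random_image(8, 8, 9); y <- random_image(8, 8, 10)
  expect_lte(l1_term(a, x, y), 1)
})

test_that("content loss is linear in each weight and zero at identity", {
  phi <- feature_extractor(seed = 1)
  p <- ssim_params(window_size = 7)
  f <- random_image(16, 16, 11); m <- random_image(16, 16, 12)
  ct <- random_image(16, 16, 13)
  w0 <- loss_weights(lambda1_G = 0, lambda2_G = 0, lambda3_G = 0)
  expect_equal(as.numeric(content_loss(f, m, ct, w0, p, phi)), 0)
  expect_equal(as.numeric(content_loss(f, f, f, loss_weights(), p, phi)), 0,
               tolerance = 1e-12)
  w1 <- loss_weights(lambda1_G = 1, lambda2_G = 0.5, lambda3_G = 2)
  w2 <- loss_weights(lambda1_G = 2, lambda2_G = 0.5, lambda3_G = 2)
  c1 <- content_loss(f, m, ct, w1, p, phi)
  c2 <- content_loss(f, m, ct, w2, p, phi)
  br <- attr(c1, "breakdown")
  expect_equal(as.numeric(c2 - c1), br[["gradient"]], tolerance = 1e-12)
})

test_that("adversarial discriminator value: stub arithmetic and validation", {
  ph <- tiny_phantom_pair(16)
  fused <- ph$pair$mri
  stub <- function(x) 0.5
  v <- adversarial_d_value(stub, ph$pair, fused)
  expect_equal(as.numeric(v), 2 * log(0.5), tolerance = 1e-9)
  # perfect-discriminator limit: value approaches 0, the supremum
  perfect <- local({
    real <- medfusion:::pack2(ph$pair$mri, ph$pair$ct)
    function(x) if (isTRUE(all.equal(x, real))) 1 else 0
  })
  fused_other <- matrix(0.25, 16, 16)
  expect_gt(as.numeric(adversarial_d_value(perfect, ph$pair, fused_other)),
            -1e-6)
  expect_error(loss_weights(lambda1_D = 0.3, lambda2_D = 0.8), "equal 1")
  w_bad <- structure(list(lambda1_D = 0.3, lambda2_D = 0.8, lambda1_G = 1,
                          lambda2_G = 1, lambda3_G = 1),
                     class = "loss_weights")
  expect_error(adversarial_d_value(stub, ph$pair, fused, w_bad), "equal 1")
  # extreme stub scores stay finite through clamping
  for (s in c(0, 1)) {
    stub_extreme <- function(x) s
    expect_true(is.finite(adversarial_d_value(stub_extreme, ph$pair, fused)))
  }
})

test_that("generator objective: breakdown sums and stub value", {
  ph <- tiny_phantom_pair(16)
  phi <- feature_extractor(seed = 2)
  p <- ssim_params(window_size = 7)
  g <- build_generator(tiny_net_spec(), seed = 0)
  stub <- function(x) 0.5
  r <- generator_objective(stub, g, ph$pair, p = p, phi = phi)
  expect_equal(r$total, sum(r$breakdown), tolerance = 1e-6)
  # with fused == mri == ct only the adversarial constant survives
  same <- slice_pair(ph$pair$mri, ph$pair$mri)
  r2 <- generator_objective(stub, g, same, p = p, phi = phi,
                            fused = ph$pair$mri)
  expect_equal(r2$total, -log(0.5), tolerance = 1e-9)
  expect_equal(sum(r2$breakdown[-1]), 0, tolerance = 1e-12)
  # saturating form matches the literal fake term
  r3 <- generator_objective(stub, g, ph$pair, p = p, phi = phi,
                            adv_mode = "saturating", fused = ph$pair$mri)
  expect_equal(r3$breakdown[["adv_g"]], log(0.5), tolerance = 1e-9)
})

test_that("analytic loss gradients agree with finite differences", {
  set.seed(42)
  f <- random_image(12, 12, 20) * 0.8 + 0.1
  m <- random_image(12, 12, 21) * 0.8 + 0.1
  h <- 1e-6
  # SSIM gradient at 3 probe pixels
  p <- ssim_params(window_size = 7)
  gs <- medfusion:::ssim_index_grad(f, m, p)
  for (i in c(5, 40, 100)) {
    e <- matrix(0, 12, 12); e[i] <- h
    fd <- (ssim_index(f + e, m, p) - ssim_index(f - e, m, p)) / (2 * h)
    expect_equal(gs[i], fd, tolerance = 1e-5)
  }
  # Sobel gradient-loss gradient
  gg <- medfusion:::gradient_loss_grad(f, m)
  for (i in c(7, 66, 130)) {
    e <- matrix(0, 12, 12); e[i] <- h
    fd <- (gradient_loss(f + e, m) - gradient_loss(f - e, m)) / (2 * h)
    expect_equal(gg[i], fd, tolerance = 1e-4)
  }
  # perceptual gradient
  phi <- feature_extractor(seed = 5)
  gp <- medfusion:::perceptual_loss_grad(f, m, phi)
  for (i in c(11, 80)) {
    e <- matrix(0, 12, 12); e[i] <- h
    fd <- (perceptual_loss(f + e, m, phi) - perceptual_loss(f - e, m, phi)) / (2 * h)
    expect_equal(gp[i], fd, tolerance = 1e-5)
  }
})
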