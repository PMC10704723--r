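test_that("generator maps a pair to a same-size fused slice in [0, 1]", {
  spec <- small_net_spec()
  g <- build_generator(spec, seed = 0)
  ph <- make_phantom_pair(phantom_spec(), seed = 0)
  f <- generator_forward(g, ph$pair)
  expect_identical(dim(f), dim(ph$pair$mri))
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(is.finite(f)))
  expect_identical(f, generator_forward(g, ph$pair))   # inference determinism
  # default spec also honors the shape contract
  gd <- build_generator(network_spec(), seed = 1)
  fd <- generator_forward(gd, ph$pair)
  expect_identical(dim(fd), dim(ph$pair$mri))
  # indivisible sizes are rejected at forward time
  odd <- tiny_phantom_pair(24)$pair            # 24 not divisible by 2^2 * ...
  g5 <- build_generator(network_spec(n_down_blocks = 5, n_up_blocks = 4,
                                     base_channels = 4), seed = 0)
  expect_error(generator_forward(g5, odd), "divisible")
})

test_that("builds are deterministic in the seed", {
  spec <- tiny_net_spec()
  expect_identical(build_generator(spec, seed = 3), build_generator(spec, seed = 3))
  expect_identical(build_discriminator(spec, seed = 3),
                   build_discriminator(spec, seed = 3))
  expect_false(identical(build_generator(spec, seed = 3),
                         build_generator(spec, seed = 4)))
})

test_that("parameter count matches the closed-form architecture arithmetic", {
  spec <- network_spec(base_channels = 4, n_down_blocks = 2, n_up_blocks = 1,
                       disc_n_layers = 1, disc_base_channels = 4)
  g <- build_generator(spec, seed = 0)
  # independent count from the documented block structure:
  conv_p <- function(k, cin, cout) k * k * cin * cout + cout
  bn_p <- function(c) 2 * c
  expected <-
    conv_p(3, 2, 4) + bn_p(4) +                 # stem
    conv_p(3, 4, 4) + bn_p(4) +                 # down1 (stride 1, no proj)
    conv_p(3, 4, 8) + bn_p(8) + conv_p(1, 4, 8) +  # down2 strided + proj
    conv_p(3, 8, 4) +                           # up1 channel reduce
    2 * (conv_p(3, 4, 4) + bn_p(4)) +           # up1 residual units
    conv_p(3, 4, 1)                             # head
  expect_identical(medfusion:::nn_param_count(g$net), as.integer(expected))
})

test_that("discriminator patch map, averaging rule, and receptive field", {
  spec <- small_net_spec()
  d <- build_discriminator(spec, seed = 0)
  ph <- make_phantom_pair(phantom_spec(), seed = 0)
  out <- discriminator_forward(d, list(ph$pair$mri, ph$pair$ct))
  expect_lt(dim(out$patch_map)[1], 64)
  expect_lt(dim(out$patch_map)[2], 64)
  expect_true(all(out$patch_map > 0 & out$patch_map < 1))
  expect_gt(out$score, 0); expect_lt(out$score, 1)
  expect_equal(out$score, mean(out$patch_map))
  # receptive-field arithmetic: layer-by-layer accumulation oracle
  rf_oracle <- function(ks, ss) {
    rf <- 1; j <- 1
    for (i in seq_along(ks)) { rf <- rf + (ks[i] - 1) * j; j <- j * ss[i] }
    rf
  }
  expect_equal(disc_receptive_field(network_spec(disc_n_layers = 3)),
               rf_oracle(rep(4, 5), c(2, 2, 2, 1, 1)))
  expect_identical(network_spec(disc_n_layers = 3)$disc_patch_size_M, 70L)
  expect_identical(spec$disc_patch_size_M, 34L)
  expect_error(discriminator_forward(d, array(0, c(16, 16, 1, 3))), "2 channels")
})

test_that("default-spec discriminator shrinks a 64-px input patch map", {
  d <- build_discriminator(network_spec(), seed = 0)
  out <- discriminator_forward(d, array(0.5, c(64, 64, 2)))
  expect_true(all(dim(out$patch_map)[1:2] < 64))
  expect_identical(out$score, mean(out$patch_map))
  out2 <- discriminator_forward(d, array(0, c(64, 64, 2)))
  expect_identical(out2$score, discriminator_forward(d, array(0, c(64, 64, 2)))$score)
})

test_that("checkpoint serialization round trips bit-exactly", {
  spec <- tiny_net_spec()
  g <- build_generator(spec, seed = 1)
  d <- build_discriminator(spec, seed = 1)
  ck <- list(format_version = 1L, generator = g, discriminator = d)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(ck, path)
  ck2 <- load_checkpoint(path)
  expect_identical(ck2$generator, g)
  expect_identical(ck2$discriminator, d)
  ph <- tiny_phantom_pair(16)
  expect_identical(generator_forward(ck2$generator, ph$pair),
                   generator_forward(g, ph$pair))
  bad <- tempfile(fileext = ".rds"); saveRDS(list(a = 1), bad)
  expect_error(load_checkpoint(bad), "format")
})
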