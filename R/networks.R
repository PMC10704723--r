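# Generator (residual encoder/decoder) and PatchGAN discriminator.
#
# The generator maps a two-channel (MRI, CT) slice to a single fused slice
# through nine convolution blocks: five down-sampling residual blocks (the
# first at stride 1, the rest at stride 2) followed by four up-sampling
# blocks, each an upsampling layer plus two residual units. Every residual
# block is convolution -> batch normalization -> LeakyReLU(0.2) with a skip
# connection. The final 1-channel convolution is squashed by a sigmoid so
# fused intensities live in [0, 1] like the normalized sources.
#
# The discriminator is a PatchGAN over the 2-channel concatenation of a
# candidate fused slice with a source slice: strided 4x4 convolutions with
# batch norm (except the first layer) and LeakyReLU, then two stride-1
# layers and a sigmoid patch map whose mean is the final score. Each patch
# map element sees an M x M receptive field.

#' Network architecture hyperparameters
#'
#' @param base_channels width of the first generator block; doubled at each
#'   strided block, capped at 256.
#' @param n_down_blocks,n_up_blocks residual block counts for the encoder
#'   and decoder; `n_down_blocks - n_up_blocks` encoder blocks run at
#'   stride 1 so the output keeps the input size.
#' @param leaky_slope negative slope of the LeakyReLU activations.
#' @param disc_n_layers number of stride-2 discriminator layers; the patch
#'   receptive field `M` follows from this (2 layers: 34 px, 3: 70 px).
#' @param disc_base_channels width of the first discriminator layer.
#' @return an object of class `network_spec` with the derived
#'   `disc_patch_size_M` field.
#' @export
network_spec <- function(base_channels = 32, n_down_blocks = 5,
                         n_up_blocks = 4, leaky_slope = 0.2,
                         disc_n_layers = 3, disc_base_channels = 32) {
  if (n_down_blocks < n_up_blocks)
    stop_mf("n_down_blocks must be >= n_up_blocks")
  if (n_up_blocks < 1 || disc_n_layers < 1 || base_channels < 1)
    stop_mf("invalid network spec")
  s <- structure(list(base_channels = as.integer(base_channels),
                      n_down_blocks = as.integer(n_down_blocks),
                      n_up_blocks = as.integer(n_up_blocks),
                      leaky_slope = leaky_slope,
                      disc_n_layers = as.integer(disc_n_layers),
                      disc_base_channels = as.integer(disc_base_channels)),
                 class = "network_spec")
  s$disc_patch_size_M <- disc_receptive_field(s)
  s
}

#' Receptive field of one discriminator patch-map element
#'
#' Closed-form receptive-field arithmetic over the discriminator stack:
#' `disc_n_layers` 4x4 stride-2 layers followed by two 4x4 stride-1 layers.
#'
#' @param spec a [network_spec()].
#' @return patch size M in pixels.
#' @export
disc_receptive_field <- function(spec) {
  ks <- c(rep(4L, spec$disc_n_layers + 2L))
  ss <- c(rep(2L, spec$disc_n_layers), 1L, 1L)
  rf <- 1L; jump <- 1L
  for (i in seq_along(ks)) {
    rf <- rf + (ks[i] - 1L) * jump
    jump <- jump * ss[i]
  }
  rf
}

gen_channel_plan <- function(spec) {
  n_str <- spec$n_up_blocks                       # strided encoder blocks
  n_plain <- spec$n_down_blocks - n_str           # stride-1 encoder blocks
  ch <- spec$base_channels
  down <- integer(spec$n_down_blocks)
  cur <- ch
  for (i in seq_len(spec$n_down_blocks)) {
    strided <- i > n_plain
    if (strided) cur <- min(cur * 2L, 256L)
    down[i] <- cur
  }
  up <- integer(spec$n_up_blocks)
  cur2 <- cur
  for (i in seq_len(spec$n_up_blocks)) {
    cur2 <- max(cur2 %/% 2L, spec$base_channels %/% 2L, 4L)
    up[i] <- cur2
  }
  list(stem = ch, down = down, up = up, n_plain = n_plain)
}

# residual block: y = LReLU(BN(conv(x))) + proj(x)
res_block_ops <- function(prefix, input, cout, stride, slope, need_proj) {
  ops <- list(
    nn_op(paste0(prefix, "_conv"), "conv", input, k = 3L, cout = cout,
          stride = stride, pad = 1L),
    nn_op(paste0(prefix, "_bn"), "bn", paste0(prefix, "_conv")),
    nn_op(paste0(prefix, "_act"), "lrelu", paste0(prefix, "_bn"), slope = slope))
  skip_name <- input
  if (need_proj) {
    ops <- c(ops, list(nn_op(paste0(prefix, "_proj"), "conv", input, k = 1L,
                             cout = cout, stride = stride, pad = 0L)))
    skip_name <- paste0(prefix, "_proj")
  }
  c(ops, list(nn_op(paste0(prefix, "_out"), "add",
                    c(paste0(prefix, "_act"), skip_name))))
}

#' Build the fusion generator
#'
#' @param spec a [network_spec()].
#' @param seed integer seed for the (Kaiming-style) parameter
#'   initialization; two builds with the same seed are identical.
#' @return a generator state object (class `mf_generator`).
#' @export
build_generator <- function(spec = network_spec(), seed = 0) {
  stopifnot(inherits(spec, "network_spec"))
  plan <- gen_channel_plan(spec)
  sl <- spec$leaky_slope
  ops <- list(
    nn_op("stem_conv", "conv", ".input", k = 3L, cout = plan$stem,
          stride = 1L, pad = 1L),
    nn_op("stem_bn", "bn", "stem_conv"),
    nn_op("stem_act", "lrelu", "stem_bn", slope = sl))
  prev <- "stem_act"; prev_ch <- plan$stem
  for (i in seq_len(spec$n_down_blocks)) {
    stride <- if (i > plan$n_plain) 2L else 1L
    cout <- plan$down[i]
    need_proj <- (stride != 1L) || (cout != prev_ch)
    ops <- c(ops, res_block_ops(sprintf("down%d", i), prev, cout, stride, sl,
                                need_proj))
    prev <- sprintf("down%d_out", i); prev_ch <- cout
  }
  for (i in seq_len(spec$n_up_blocks)) {
    cout <- plan$up[i]
    ops <- c(ops, list(
      nn_op(sprintf("up%d_nn", i), "upsample2", prev),
      nn_op(sprintf("up%d_reduce", i), "conv", sprintf("up%d_nn", i),
            k = 3L, cout = cout, stride = 1L, pad = 1L)))
    prev <- sprintf("up%d_reduce", i)
    for (j in 1:2) {
      ops <- c(ops, res_block_ops(sprintf("up%d_res%d", i, j), prev, cout,
                                  1L, sl, need_proj = FALSE))
      prev <- sprintf("up%d_res%d_out", i, j)
    }
    prev_ch <- cout
  }
  ops <- c(ops, list(
    nn_op("head_conv", "conv", prev, k = 3L, cout = 1L, stride = 1L, pad = 1L),
    nn_op("head_sig", "sigmoid", "head_conv")))
  net <- nn_build(ops, in_channels = 2L, seed = derive_seed(seed, "gen"))
  structure(list(net = net, spec = spec, seed = seed, format_version = 1L),
            class = "mf_generator")
}

#' Build the PatchGAN discriminator
#'
#' Input is the 2-channel concatenation of two slices; output is a patch
#' map of probabilities whose arithmetic mean is the final score.
#'
#' @inheritParams build_generator
#' @return a discriminator state object (class `mf_discriminator`).
#' @export
build_discriminator <- function(spec = network_spec(), seed = 0) {
  stopifnot(inherits(spec, "network_spec"))
  sl <- spec$leaky_slope
  ch <- spec$disc_base_channels
  ops <- list(
    nn_op("d1_conv", "conv", ".input", k = 4L, cout = ch, stride = 2L, pad = 1L),
    nn_op("d1_act", "lrelu", "d1_conv", slope = sl))
  prev <- "d1_act"
  for (i in seq_len(spec$disc_n_layers - 1L)) {
    ch <- min(ch * 2L, 256L)
    nm <- sprintf("d%d", i + 1L)
    ops <- c(ops, list(
      nn_op(paste0(nm, "_conv"), "conv", prev, k = 4L, cout = ch,
            stride = 2L, pad = 1L),
      nn_op(paste0(nm, "_bn"), "bn", paste0(nm, "_conv")),
      nn_op(paste0(nm, "_act"), "lrelu", paste0(nm, "_bn"), slope = sl)))
    prev <- paste0(nm, "_act")
  }
  ch2 <- min(ch * 2L, 256L)
  ops <- c(ops, list(
    nn_op("dpen_conv", "conv", prev, k = 4L, cout = ch2, stride = 1L, pad = 1L),
    nn_op("dpen_bn", "bn", "dpen_conv"),
    nn_op("dpen_act", "lrelu", "dpen_bn", slope = sl),
    nn_op("dhead_conv", "conv", "dpen_act", k = 4L, cout = 1L, stride = 1L,
          pad = 1L),
    nn_op("dhead_sig", "sigmoid", "dhead_conv")))
  net <- nn_build(ops, in_channels = 2L, seed = derive_seed(seed, "disc"))
  structure(list(net = net, spec = spec, seed = seed, format_version = 1L),
            class = "mf_discriminator")
}

# pack two same-shape images into an [H, W, 1, 2] tensor (channels last)
pack2 <- function(a, b) {
  check_same_shape(a, b)
  array(c(a, b), c(nrow(a), ncol(a), 1L, 2L))
}

#' Run the generator on a slice pair
#'
#' Inference-mode forward (batch-norm running statistics frozen), so the
#' output is deterministic. Values lie in (0, 1) by the sigmoid head.
#'
#' @param g an `mf_generator` from [build_generator()].
#' @param pair a [slice_pair()] with values in \[0, 1\].
#' @return the fused slice as a matrix of the same shape.
#' @export
generator_forward <- function(g, pair) {
  stopifnot(inherits(g, "mf_generator"), inherits(pair, "slice_pair"))
  x <- pack2(pair$mri, pair$ct)
  check_gen_size(g, dim(x)[1:2])
  fw <- nn_forward(g$net, x, training = FALSE, keep_cache = FALSE)
  matrix(fw$y[, , 1, 1], nrow(pair$mri), ncol(pair$mri))
}

check_gen_size <- function(g, hw) {
  f <- 2^g$spec$n_up_blocks
  if (any(hw %% f != 0))
    stop_mf("image size %dx%d not divisible by 2^%d", hw[1], hw[2],
            g$spec$n_up_blocks)
  invisible(NULL)
}

#' Run the discriminator on a 2-channel input
#'
#' @param d an `mf_discriminator` from [build_discriminator()].
#' @param two_channel either an `[H, W, 2]`/`[H, W, 2, N]` array or a list
#'   of two same-shape matrices to concatenate.
#' @return list with `patch_map` (probabilities) and `score` (their mean).
#' @export
discriminator_forward <- function(d, two_channel) {
  stopifnot(inherits(d, "mf_discriminator"))
  x <- if (is.list(two_channel)) pack2(two_channel[[1]], two_channel[[2]])
       else two_channel
  if (length(dim(x)) == 3L) {
    # [H, W, 2] single image with channels last -> [H, W, 1, 2]
    dx <- dim(x); dim(x) <- c(dx[1], dx[2], 1L, dx[3])
  }
  if (dim(x)[4] != 2L) stop_mf("discriminator input must have exactly 2 channels")
  fw <- nn_forward(d$net, x, training = FALSE, keep_cache = FALSE)
  pm <- fw$y
  list(patch_map = pm, score = mean(pm))
}

# ---- checkpointing ------------------------------------------------------

#' Save a training checkpoint
#'
#' Stores both network states, their spec, the loss weights, optimizer and
#' RNG bookkeeping, and a format-version tag. Round trips are bit-exact.
#'
#' @param checkpoint a checkpoint list (as produced by [train()]).
#' @param path file path.
#' @export
save_checkpoint <- function(checkpoint, path) {
  checkpoint$format_version <- 1L
  saveRDS(checkpoint, path)
  invisible(path)
}

#' Load a training checkpoint
#'
#' @param path file path written by [save_checkpoint()].
#' @return the checkpoint list.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$format_version) || ck$format_version != 1L)
    stop_mf("unsupported checkpoint format")
  ck
}
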