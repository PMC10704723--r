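# Training objective: adversarial value, L1 term, and the three content
# losses (gradient, SSIM, perceptual). Every term carries a hand-derived
# gradient with respect to the fused image so the generator can be trained
# by exact backpropagation; the finite-difference tests pin these down.

#' Loss mixing weights
#'
#' `lambda1_D`/`lambda2_D` mix the two fake discriminator scores and must
#' sum to 1 (defaults 0.5/0.5). `lambda1_G`, `lambda2_G`, `lambda3_G`
#' weight the gradient, SSIM and perceptual content losses. The training
#' protocol does not pin the content weights; the defaults (1, 1, 30)
#' scale the single CT-side perceptual term to the combined magnitude of
#' the two MRI-side terms so that neither source dominates the fusion —
#' with equal weights the generator collapses onto the MRI. Fully exposed
#' in the configuration.
#'
#' @param lambda1_D,lambda2_D discriminator mixing weights (sum to 1).
#' @param lambda1_G,lambda2_G,lambda3_G content-loss weights (>= 0).
#' @return an object of class `loss_weights`.
#' @export
loss_weights <- function(lambda1_D = 0.5, lambda2_D = 0.5,
                         lambda1_G = 1, lambda2_G = 1, lambda3_G = 30) {
  w <- list(lambda1_D = lambda1_D, lambda2_D = lambda2_D,
            lambda1_G = lambda1_G, lambda2_G = lambda2_G,
            lambda3_G = lambda3_G)
  validate_loss_weights(w)
  structure(w, class = "loss_weights")
}

validate_loss_weights <- function(w) {
  if (any(unlist(w[c("lambda1_D", "lambda2_D", "lambda1_G", "lambda2_G",
                     "lambda3_G")]) < 0))
    stop_mf("loss weights must be >= 0")
  if (abs(w$lambda1_D + w$lambda2_D - 1) > 1e-9)
    stop_mf("lambda1_D + lambda2_D must equal 1 (got %g + %g)",
            w$lambda1_D, w$lambda2_D)
  invisible(w)
}

#' SSIM stabilization parameters
#'
#' The standard SSIM reference parameters for a unit dynamic range:
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` with `L = 1`, an 11x11 Gaussian
#' window with sigma 1.5.
#'
#' @param C1,C2 stabilizing constants (> 0).
#' @param window_size odd window side in pixels.
#' @param window_sigma Gaussian window sigma in pixels.
#' @return an object of class `ssim_params`.
#' @export
ssim_params <- function(C1 = 0.01^2, C2 = 0.03^2, window_size = 11,
                        window_sigma = 1.5) {
  if (C1 <= 0 || C2 <= 0) stop_mf("C1 and C2 must be > 0")
  structure(list(C1 = C1, C2 = C2, window_size = as.integer(window_size),
                 window_sigma = window_sigma), class = "ssim_params")
}

# normalized 1D Gaussian window; the 2D window is its outer product
gaussian_window <- function(size, sigma) {
  h <- (size - 1) / 2
  g <- dnorm(seq(-h, h), sd = sigma)
  g / sum(g)
}

# valid-mode window correlation with the separable window g %o% g
wcorr_valid <- function(x, g) {
  k <- length(g); H <- nrow(x); W <- ncol(x)
  Ho <- H - k + 1L; Wo <- W - k + 1L
  t1 <- matrix(0, Ho, W)
  for (a in seq_len(k)) t1 <- t1 + g[a] * x[a:(a + Ho - 1L), , drop = FALSE]
  out <- matrix(0, Ho, Wo)
  for (b in seq_len(k)) out <- out + g[b] * t1[, b:(b + Wo - 1L), drop = FALSE]
  out
}

# adjoint of wcorr_valid: scatter an [Ho, Wo] map back onto [H, W]
wcorr_valid_adjoint <- function(m, g, H, W) {
  k <- length(g); Ho <- nrow(m); Wo <- ncol(m)
  t1 <- matrix(0, Ho, W)
  for (b in seq_len(k))
    t1[, b:(b + Wo - 1L)] <- t1[, b:(b + Wo - 1L)] + g[b] * m
  out <- matrix(0, H, W)
  for (a in seq_len(k))
    out[a:(a + Ho - 1L), ] <- out[a:(a + Ho - 1L), ] + g[a] * t1
  out
}

# ---- SSIM ---------------------------------------------------------------

ssim_stats <- function(a, b, p) {
  w <- gaussian_window(p$window_size, p$window_sigma)
  mu_a <- wcorr_valid(a, w); mu_b <- wcorr_valid(b, w)
  va <- wcorr_valid(a * a, w) - mu_a^2
  vb <- wcorr_valid(b * b, w) - mu_b^2
  cab <- wcorr_valid(a * b, w) - mu_a * mu_b
  A1 <- 2 * mu_a * mu_b + p$C1; A2 <- 2 * cab + p$C2
  B1 <- mu_a^2 + mu_b^2 + p$C1; B2 <- va + vb + p$C2
  list(w = w, mu_a = mu_a, mu_b = mu_b, va = va, vb = vb, cab = cab,
       A1 = A1, A2 = A2, B1 = B1, B2 = B2, S = A1 * A2 / (B1 * B2))
}

#' Structural similarity index of two images
#'
#' Mean over all fully-interior sliding windows of the standard
#' luminance-contrast-structure product, with a Gaussian window. Equals 1
#' iff the images are identical; symmetric in its arguments.
#'
#' @param a,b numeric matrices of identical shape, values in \[0, 1\].
#' @param p an [ssim_params()].
#' @return scalar index in \[-1, 1\].
#' @export
ssim_index <- function(a, b, p = ssim_params()) {
  check_image(a, "a"); check_image(b, "b"); check_same_shape(a, b)
  if (p$window_size > min(dim(a)))
    stop_mf("SSIM window (%d) larger than image (%dx%d)",
            p$window_size, nrow(a), ncol(a))
  mean(ssim_stats(a, b, p)$S)
}

# gradient of ssim_index(a, b) w.r.t. a
ssim_index_grad <- function(a, b, p = ssim_params()) {
  st <- ssim_stats(a, b, p)
  Nv <- length(st$S)
  dS_dmu <- 2 * st$mu_b * st$A2 / (st$B1 * st$B2) - 2 * st$mu_a * st$S / st$B1
  dS_dva <- -st$S / st$B2
  dS_dcab <- 2 * st$A1 / (st$B1 * st$B2)
  H <- nrow(a); W <- ncol(a)
  P1 <- dS_dmu - 2 * st$mu_a * dS_dva - st$mu_b * dS_dcab
  (wcorr_valid_adjoint(P1, st$w, H, W) +
     2 * a * wcorr_valid_adjoint(dS_dva, st$w, H, W) +
     b * wcorr_valid_adjoint(dS_dcab, st$w, H, W)) / Nv
}

#' SSIM loss between fused and MRI slices
#'
#' `1 - ssim_index(fused, mri)`; zero iff the images are identical and can
#' exceed 1 for anti-correlated structure.
#'
#' @param fused,mri numeric matrices of identical shape.
#' @param p an [ssim_params()].
#' @return scalar loss in \[0, 2\].
#' @export
ssim_loss <- function(fused, mri, p = ssim_params()) {
  1 - ssim_index(fused, mri, p)
}

# ---- gradient (edge) loss ----------------------------------------------

sobel_kernels <- function() {
  kr <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # d/drow
  list(kr = kr, kc = t(kr))
}

pad_sym1 <- function(x) {
  H <- nrow(x); W <- ncol(x)
  x[c(1, seq_len(H), H), c(1, seq_len(W), W), drop = FALSE]
}

sobel_filter <- function(x, k) {
  xp <- pad_sym1(x)
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0, H, W)
  for (a in 1:3) for (b in 1:3) {
    if (k[a, b] == 0) next
    out <- out + k[a, b] * xp[a:(a + H - 1L), b:(b + W - 1L)]
  }
  out
}

# adjoint of sobel_filter (correlation with symmetric padding of 1 px)
sobel_filter_adjoint <- function(dy, k) {
  H <- nrow(dy); W <- ncol(dy)
  dxp <- matrix(0, H + 2L, W + 2L)
  for (a in 1:3) for (b in 1:3) {
    if (k[a, b] == 0) next
    dxp[a:(a + H - 1L), b:(b + W - 1L)] <-
      dxp[a:(a + H - 1L), b:(b + W - 1L)] + k[a, b] * dy
  }
  dx <- dxp[2:(H + 1L), 2:(W + 1L), drop = FALSE]
  dx[1, ] <- dx[1, ] + dxp[1, 2:(W + 1L)]
  dx[H, ] <- dx[H, ] + dxp[H + 2L, 2:(W + 1L)]
  dx[, 1] <- dx[, 1] + dxp[2:(H + 1L), 1]
  dx[, W] <- dx[, W] + dxp[2:(H + 1L), W + 2L]
  dx[1, 1] <- dx[1, 1] + dxp[1, 1]
  dx[1, W] <- dx[1, W] + dxp[1, W + 2L]
  dx[H, 1] <- dx[H, 1] + dxp[H + 2L, 1]
  dx[H, W] <- dx[H, W] + dxp[H + 2L, W + 2L]
  dx
}

#' Gradient (edge) loss between fused and MRI slices
#'
#' Mean absolute difference between the Sobel gradients of the two images,
#' averaged over pixels and the two gradient components. Transfers MRI
#' edge (soft-tissue) information to the fused image; invariant to adding
#' a constant to either image.
#'
#' @param fused,mri numeric matrices of identical shape.
#' @return nonnegative scalar.
#' @export
gradient_loss <- function(fused, mri) {
  check_same_shape(fused, mri, c("fused", "mri"))
  ks <- sobel_kernels()
  dr <- sobel_filter(fused, ks$kr) - sobel_filter(mri, ks$kr)
  dc <- sobel_filter(fused, ks$kc) - sobel_filter(mri, ks$kc)
  (mean(abs(dr)) + mean(abs(dc))) / 2
}

gradient_loss_grad <- function(fused, mri) {
  ks <- sobel_kernels()
  n <- length(fused)
  dr <- sobel_filter(fused, ks$kr) - sobel_filter(mri, ks$kr)
  dc <- sobel_filter(fused, ks$kc) - sobel_filter(mri, ks$kc)
  (sobel_filter_adjoint(sign(dr), ks$kr) +
     sobel_filter_adjoint(sign(dc), ks$kc)) / (2 * n)
}

# ---- perceptual loss ----------------------------------------------------

#' Frozen feature extractor for the perceptual loss
#'
#' Default mode `"seeded-random-conv"` builds a frozen, seeded 3-layer
#' convolutional stack (3 -> 16 -> 32 -> 32 channels, the first two layers
#' strided): random convolutional features are a standard, download-free
#' basis for perceptual distances and are bit-reproducible here. Mode
#' `"pretrained-perceptual"` loads a VGG16-style feature stack from
#' `weights_path` and errors with an instruction to use the fallback mode
#' when no weights file is given.
#'
#' @param mode `"seeded-random-conv"` or `"pretrained-perceptual"`.
#' @param layer_tag identifier of the feature level (kept with the object).
#' @param seed integer seed for the random-conv mode.
#' @param weights_path path to a serialized network for the pretrained mode.
#' @return an object of class `feature_extractor`; parameters are frozen.
#' @export
feature_extractor <- function(mode = c("seeded-random-conv",
                                       "pretrained-perceptual"),
                              layer_tag = "relu2_2", seed = 1234,
                              weights_path = NULL) {
  mode <- match.arg(mode)
  if (mode == "pretrained-perceptual") {
    if (is.null(weights_path) || !file.exists(weights_path))
      stop_mf(paste("pretrained perceptual weights not available;",
                    "pass weights_path or use mode = 'seeded-random-conv'"))
    net <- readRDS(weights_path)
  } else {
    ops <- list(
      nn_op("p1_conv", "conv", ".input", k = 3L, cout = 16L, stride = 2L, pad = 1L),
      nn_op("p1_act", "lrelu", "p1_conv", slope = 0.2),
      nn_op("p2_conv", "conv", "p1_act", k = 3L, cout = 32L, stride = 2L, pad = 1L),
      nn_op("p2_act", "lrelu", "p2_conv", slope = 0.2),
      nn_op("p3_conv", "conv", "p2_act", k = 3L, cout = 32L, stride = 1L, pad = 1L),
      nn_op("p3_act", "lrelu", "p3_conv", slope = 0.2))
    net <- nn_build(ops, in_channels = 3L, seed = derive_seed(seed, "phi"))
  }
  structure(list(net = net, mode = mode, layer_tag = layer_tag, seed = seed),
            class = "feature_extractor")
}

replicate3 <- function(img) {
  array(rep(img, 3), c(nrow(img), ncol(img), 1L, 3L))
}

#' Perceptual loss between fused and CT slices
#'
#' Both inputs are replicated to three channels, passed through the frozen
#' extractor, and compared by mean squared feature difference. Preserves
#' CT bone structure and texture.
#'
#' @param fused,ct numeric matrices of identical shape.
#' @param phi a [feature_extractor()].
#' @return nonnegative scalar.
#' @export
perceptual_loss <- function(fused, ct, phi = feature_extractor()) {
  check_same_shape(fused, ct, c("fused", "ct"))
  ff <- nn_forward(phi$net, replicate3(fused), training = FALSE,
                   keep_cache = FALSE)$y
  fc <- nn_forward(phi$net, replicate3(ct), training = FALSE,
                   keep_cache = FALSE)$y
  mean((ff - fc)^2)
}

perceptual_loss_grad <- function(fused, ct, phi) {
  fw <- nn_forward(phi$net, replicate3(fused), training = FALSE,
                   keep_cache = TRUE)
  fc <- nn_forward(phi$net, replicate3(ct), training = FALSE,
                   keep_cache = FALSE)$y
  dy <- 2 * (fw$y - fc) / length(fc)
  dx <- nn_backward(phi$net, fw, dy)$dx
  dx[, , 1, 1] + dx[, , 1, 2] + dx[, , 1, 3]
}

# ---- L1 term ------------------------------------------------------------

#' L1 term between the fused image and both sources
#'
#' Unweighted mean of the two per-source mean absolute differences:
#' `(E|F - mri| + E|F - ct|) / 2`. Bounded by 1 for \[0, 1\] inputs.
#'
#' @param fused,mri,ct numeric matrices of identical shape.
#' @return nonnegative scalar.
#' @export
l1_term <- function(fused, mri, ct) {
  check_same_shape(fused, mri, c("fused", "mri"))
  check_same_shape(fused, ct, c("fused", "ct"))
  (mean(abs(fused - mri)) + mean(abs(fused - ct))) / 2
}

l1_term_grad <- function(fused, mri, ct) {
  (sign(fused - mri) + sign(fused - ct)) / (2 * length(fused))
}

#' Combined content loss
#'
#' `lambda1_G * gradient + lambda2_G * SSIM + lambda3_G * perceptual`,
#' linear in each weight; zero when the fused image equals both sources.
#'
#' @param fused,mri,ct numeric matrices of identical shape.
#' @param w a [loss_weights()].
#' @param p an [ssim_params()].
#' @param phi a [feature_extractor()].
#' @return scalar loss; `attr(, "breakdown")` carries the three raw terms.
#' @export
content_loss <- function(fused, mri, ct, w = loss_weights(),
                         p = ssim_params(), phi = feature_extractor()) {
  g <- if (w$lambda1_G > 0) gradient_loss(fused, mri) else 0
  s <- if (w$lambda2_G > 0) ssim_loss(fused, mri, p) else 0
  pc <- if (w$lambda3_G > 0) perceptual_loss(fused, ct, phi) else 0
  out <- w$lambda1_G * g + w$lambda2_G * s + w$lambda3_G * pc
  attr(out, "breakdown") <- c(gradient = g, ssim = s, perceptual = pc)
  out
}

# ---- adversarial terms --------------------------------------------------

.mf_eps <- 1e-7
clamp_unit <- function(v) pmin(pmax(v, .mf_eps), 1)

# score of a discriminator (or stub function) on a 2-channel input
disc_score <- function(d, two_channel) {
  if (is.function(d)) {
    s <- d(two_channel)
    return(mean(s))
  }
  discriminator_forward(d, two_channel)$score
}

#' Adversarial discriminator value
#'
#' `log D([mri, ct]) + log(1 - lambda1_D D([F, mri]) - lambda2_D D([F, ct]))`
#' with `D` the averaged patch score and both log arguments clamped to
#' `[1e-7, 1]`. Discriminator training ascends this value; the supremum 0
#' is reached by a perfect discriminator.
#'
#' @param d an `mf_discriminator` or a stub function mapping a 2-channel
#'   array to a score.
#' @param pair a [slice_pair()].
#' @param fused fused slice matrix.
#' @param w a [loss_weights()]; `lambda1_D + lambda2_D` must equal 1.
#' @return scalar value (<= 0); `attr(, "scores")` carries the three raw
#'   discriminator scores.
#' @export
adversarial_d_value <- function(d, pair, fused, w = loss_weights()) {
  validate_loss_weights(w)
  s_real <- disc_score(d, pack2(pair$mri, pair$ct))
  s_f1 <- disc_score(d, pack2(fused, pair$mri))
  s_f2 <- disc_score(d, pack2(fused, pair$ct))
  v <- log(clamp_unit(s_real)) +
    log(clamp_unit(1 - w$lambda1_D * s_f1 - w$lambda2_D * s_f2))
  attr(v, "scores") <- c(real = s_real, fake_mri = s_f1, fake_ct = s_f2)
  v
}

#' Total generator objective with breakdown
#'
#' Adversarial term (non-saturating by default: minimize
#' `-log(lambda1_D D([F, mri]) + lambda2_D D([F, ct]))`; set
#' `adv_mode = "saturating"` for the literal fake term) plus the L1 term
#' and the content loss. The additive breakdown is returned for logging.
#'
#' @param d discriminator (or stub function).
#' @param g an `mf_generator`.
#' @param pair a normalized [slice_pair()].
#' @param w a [loss_weights()].
#' @param p an [ssim_params()].
#' @param phi a [feature_extractor()].
#' @param adv_mode `"non-saturating"` or `"saturating"`.
#' @param fused optional precomputed fused slice (skips the generator
#'   forward; used by stubs and tests).
#' @return list with `total`, `breakdown` (named numeric: adv_g, l1,
#'   gradient, ssim, perceptual) and `fused`.
#' @export
generator_objective <- function(d, g, pair, w = loss_weights(),
                                p = ssim_params(), phi = feature_extractor(),
                                adv_mode = c("non-saturating", "saturating"),
                                fused = NULL) {
  adv_mode <- match.arg(adv_mode)
  validate_loss_weights(w)
  if (is.null(fused)) fused <- generator_forward(g, pair)
  s1 <- disc_score(d, pack2(fused, pair$mri))
  s2 <- disc_score(d, pack2(fused, pair$ct))
  mix <- w$lambda1_D * s1 + w$lambda2_D * s2
  adv <- if (adv_mode == "non-saturating") -log(clamp_unit(mix))
         else log(clamp_unit(1 - mix))
  l1 <- l1_term(fused, pair$mri, pair$ct)
  cl <- content_loss(fused, pair$mri, pair$ct, w, p, phi)
  br <- attr(cl, "breakdown")
  total <- adv + l1 + as.numeric(cl)
  list(total = total,
       breakdown = c(adv_g = adv, l1 = l1,
                     gradient = w$lambda1_G * br[["gradient"]],
                     ssim = w$lambda2_G * br[["ssim"]],
                     perceptual = w$lambda3_G * br[["perceptual"]]),
       fused = fused)
}
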