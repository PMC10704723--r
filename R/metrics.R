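# Fusion-quality evaluation: the nine standard metrics (entropy, standard
# deviation, mean gradient, spatial frequency, mutual information,
# normalized cross-correlation, PSNR, the Xydeas-Petrovic edge-preservation
# index Q^XY/F, and SSIM) plus Dice and Hausdorff for ROI comparison.
# Intensity quantization for the histogram metrics bins [0, 1] uniformly
# with a right-closed last bin.

quantize01 <- function(x, n_levels) {
  pmin(floor(pmin(pmax(as.vector(x), 0), 1) * n_levels) + 1L, n_levels)
}

#' Shannon entropy of an image
#'
#' Base-2 entropy of the `n_levels`-bin intensity histogram over \[0, 1\].
#'
#' @param image numeric matrix with values in \[0, 1\].
#' @param n_levels histogram bins (default 256).
#' @return entropy in bits.
#' @export
entropy <- function(image, n_levels = 256) {
  check_image(image)
  shannon_from_counts(tabulate(quantize01(image, n_levels), nbins = n_levels))
}

#' Standard deviation of an image
#'
#' Population standard deviation over all pixels.
#'
#' @param image numeric matrix.
#' @return scalar in intensity units.
#' @export
std_metric <- function(image) {
  check_image(image)
  sqrt(mean((image - mean(image))^2))
}

#' Mean gradient of an image
#'
#' Mean over interior pixels of `sqrt((d_row^2 + d_col^2) / 2)` with
#' forward differences; a measure of overall edge strength.
#'
#' @param image numeric matrix, at least 2x2.
#' @return scalar in intensity per pixel.
#' @export
mean_gradient <- function(image) {
  check_image(image)
  H <- nrow(image); W <- ncol(image)
  if (H < 2 || W < 2) stop_mf("mean_gradient needs at least a 2x2 image")
  dr <- image[2:H, 1:(W - 1), drop = FALSE] - image[1:(H - 1), 1:(W - 1), drop = FALSE]
  dc <- image[1:(H - 1), 2:W, drop = FALSE] - image[1:(H - 1), 1:(W - 1), drop = FALSE]
  mean(sqrt((dr^2 + dc^2) / 2))
}

#' Spatial frequency of an image
#'
#' `sqrt(RF^2 + CF^2)` with RF/CF the root-mean-square of neighboring
#' pixel differences along rows and columns.
#'
#' @param image numeric matrix, at least 2x2.
#' @return scalar in intensity per pixel.
#' @export
spatial_frequency <- function(image) {
  check_image(image)
  H <- nrow(image); W <- ncol(image)
  if (H < 2 || W < 2) stop_mf("spatial_frequency needs at least a 2x2 image")
  rf2 <- mean((image[, 2:W, drop = FALSE] - image[, 1:(W - 1), drop = FALSE])^2)
  cf2 <- mean((image[2:H, , drop = FALSE] - image[1:(H - 1), , drop = FALSE])^2)
  sqrt(rf2 + cf2)
}

mi_pair_bits <- function(a, b, n_bins) {
  ia <- quantize01(a, n_bins); ib <- quantize01(b, n_bins)
  joint <- tabulate(ia + (ib - 1L) * n_bins, nbins = n_bins * n_bins)
  hj <- shannon_from_counts(joint)
  shannon_from_counts(tabulate(ia, nbins = n_bins)) +
    shannon_from_counts(tabulate(ib, nbins = n_bins)) - hj
}

#' Mutual information between the fused image and both sources
#'
#' `MI(F; MRI) + MI(F; CT)`, each computed from the joint
#' `n_bins x n_bins` histogram with base-2 logs.
#'
#' @param fused,mri,ct numeric matrices of identical shape, values in
#'   \[0, 1\].
#' @param n_bins histogram bins (default 256).
#' @return mutual information in bits.
#' @export
mutual_information <- function(fused, mri, ct, n_bins = 256) {
  check_same_shape(fused, mri, c("fused", "mri"))
  check_same_shape(fused, ct, c("fused", "ct"))
  mi_pair_bits(fused, mri, n_bins) + mi_pair_bits(fused, ct, n_bins)
}

#' Normalized cross-correlation with both sources
#'
#' Mean of the two zero-normalized (Pearson) correlations `corr(F, MRI)`
#' and `corr(F, CT)`; bounded in \[-1, 1\].
#'
#' @param fused,mri,ct numeric matrices of identical shape, non-constant.
#' @return dimensionless scalar.
#' @export
ncc <- function(fused, mri, ct) {
  check_same_shape(fused, mri, c("fused", "mri"))
  check_same_shape(fused, ct, c("fused", "ct"))
  (stats::cor(as.vector(fused), as.vector(mri)) +
     stats::cor(as.vector(fused), as.vector(ct))) / 2
}

#' Peak signal-to-noise ratio against both sources
#'
#' `10 log10(peak^2 / MSE)` with MSE the mean of `MSE(F, MRI)` and
#' `MSE(F, CT)`. A zero MSE yields `Inf`.
#'
#' @param fused,mri,ct numeric matrices of identical shape.
#' @param peak peak intensity (default 1 for normalized images).
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(fused, mri, ct, peak = 1.0) {
  check_same_shape(fused, mri, c("fused", "mri"))
  check_same_shape(fused, ct, c("fused", "ct"))
  mse <- (mean((fused - mri)^2) + mean((fused - ct)^2)) / 2
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

# ---- Q^XY/F edge preservation ------------------------------------------

#' Parameters of the edge-preservation metric
#'
#' Sigmoid constants of the Xydeas-Petrovic model for edge-strength and
#' orientation preservation, and the saliency exponent L.
#'
#' @param gamma_g,kappa_g,sigma_g strength sigmoid: amplitude, slope, shift.
#' @param gamma_a,kappa_a,sigma_a orientation sigmoid parameters.
#' @param L edge-saliency exponent for the weights.
#' @return a plain list.
#' @export
qxy_params <- function(gamma_g = 1, kappa_g = -10, sigma_g = 0.5,
                       gamma_a = 1, kappa_a = -20, sigma_a = 0.75, L = 1) {
  list(gamma_g = gamma_g, kappa_g = kappa_g, sigma_g = sigma_g,
       gamma_a = gamma_a, kappa_a = kappa_a, sigma_a = sigma_a, L = L)
}

sobel_strength_orient <- function(img) {
  ks <- sobel_kernels()
  gr <- sobel_filter(img, ks$kr)
  gc <- sobel_filter(img, ks$kc)
  list(g = sqrt(gr^2 + gc^2), a = atan2(gr, gc))
}

# per-source edge preservation map Q^{AF}
edge_preservation <- function(src, fus, q) {
  eps <- 1e-12
  # relative strength: the weaker over the stronger
  G <- ifelse(src$g > fus$g,
              fus$g / pmax(src$g, eps),
              src$g / pmax(fus$g, eps))
  G[src$g == 0 & fus$g == 0] <- 1
  da <- abs(src$a - fus$a)
  da <- pmin(da, 2 * pi - da)           # angular difference in [0, pi]
  da <- pmin(da, pi - da)               # undirected orientation in [0, pi/2]
  A <- 1 - da / (pi / 2)
  Qg <- q$gamma_g / (1 + exp(q$kappa_g * (G - q$sigma_g)))
  Qa <- q$gamma_a / (1 + exp(q$kappa_a * (A - q$sigma_a)))
  Qg * Qa
}

#' Xydeas-Petrovic edge-preservation metric Q^XY/F
#'
#' Measures how much of each source's Sobel edge strength and orientation
#' survives in the fused image, weighted by source edge saliency; 1 means
#' perfect preservation of all salient edges.
#'
#' @param mri,ct source images.
#' @param fused fused image, same shape.
#' @param q a [qxy_params()] list.
#' @return dimensionless scalar in \[0, 1\].
#' @export
q_xy_f <- function(mri, ct, fused, q = qxy_params()) {
  check_same_shape(fused, mri, c("fused", "mri"))
  check_same_shape(fused, ct, c("fused", "ct"))
  ex <- sobel_strength_orient(mri)
  ey <- sobel_strength_orient(ct)
  ef <- sobel_strength_orient(fused)
  qx <- edge_preservation(ex, ef, q)
  qy <- edge_preservation(ey, ef, q)
  wx <- ex$g^q$L; wy <- ey$g^q$L
  denom <- sum(wx + wy)
  if (denom == 0) return(0)
  sum(qx * wx + qy * wy) / denom
}

#' SSIM of the fused image against both sources
#'
#' Mean of `ssim_index(F, MRI)` and `ssim_index(F, CT)`.
#'
#' @param fused,mri,ct numeric matrices of identical shape.
#' @param p an [ssim_params()].
#' @return dimensionless scalar.
#' @export
ssim_fusion <- function(fused, mri, ct, p = ssim_params()) {
  (ssim_index(fused, mri, p) + ssim_index(fused, ct, p)) / 2
}

# ---- ROI metrics --------------------------------------------------------

#' Sorensen-Dice coefficient of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; 1 iff the masks are identical (both
#' nonempty), 0 for disjoint masks.
#'
#' @param mask_a,mask_b binary matrices of identical shape.
#' @return dimensionless scalar in \[0, 1\].
#' @export
dice <- function(mask_a, mask_b) {
  check_binary_mask(mask_a, "mask_a"); check_binary_mask(mask_b, "mask_b")
  check_same_shape(mask_a, mask_b, c("mask_a", "mask_b"))
  sa <- sum(mask_a != 0); sb <- sum(mask_b != 0)
  if (sa + sb == 0) stop_mf("both masks are empty")
  2 * sum(mask_a != 0 & mask_b != 0) / (sa + sb)
}

boundary_points <- function(mask) {
  m <- (mask != 0) * 1
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(0, H + 2, W + 2); pad[2:(H + 1), 2:(W + 1)] <- m
  inner <- pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
    pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  which(m == 1 & !inner, arr.ind = TRUE)
}

#' Hausdorff distance between two masks
#'
#' Maximum over both directions of the largest nearest-boundary-point
#' distance, scaled by the pixel spacing (isotropic).
#'
#' @param mask_a,mask_b nonempty binary matrices of identical shape.
#' @param pixel_spacing_mm mm per pixel (default 1).
#' @return distance in mm.
#' @export
hausdorff <- function(mask_a, mask_b, pixel_spacing_mm = 1) {
  check_binary_mask(mask_a, "mask_a"); check_binary_mask(mask_b, "mask_b")
  check_same_shape(mask_a, mask_b, c("mask_a", "mask_b"))
  if (sum(mask_a != 0) == 0 || sum(mask_b != 0) == 0)
    stop_mf("both masks must be nonempty")
  pa <- boundary_points(mask_a); pb <- boundary_points(mask_b)
  d2 <- outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2
  h <- sqrt(max(apply(d2, 1, min), apply(d2, 2, min)))
  h * pixel_spacing_mm
}

# ---- reports ------------------------------------------------------------

#' Evaluate a fused slice against its source pair
#'
#' Computes all nine fusion-quality metrics (ENT/STD/MG/SF on the fused
#' image, MI/NCC/PSNR/Q/SSIM against both sources) and, when ROI masks are
#' supplied, Dice and Hausdorff.
#'
#' @param fused fused slice matrix in \[0, 1\].
#' @param pair the source [slice_pair()].
#' @param roi_pred,roi_ref optional binary ROI masks to compare.
#' @param p an [ssim_params()].
#' @param q a [qxy_params()].
#' @param n_levels histogram bins for ENT and MI.
#' @return named list of metric values (class `metric_report`).
#' @export
evaluate <- function(fused, pair, roi_pred = NULL, roi_ref = NULL,
                     p = ssim_params(), q = qxy_params(), n_levels = 256) {
  stopifnot(inherits(pair, "slice_pair"))
  rep <- list(
    ent = entropy(fused, n_levels),
    std = std_metric(fused),
    mg = mean_gradient(fused),
    sf = spatial_frequency(fused),
    mi = mutual_information(fused, pair$mri, pair$ct, n_levels),
    ncc = ncc(fused, pair$mri, pair$ct),
    psnr = psnr(fused, pair$mri, pair$ct),
    q_xy_f = q_xy_f(pair$mri, pair$ct, fused, q),
    ssim = ssim_fusion(fused, pair$mri, pair$ct, p))
  if (!is.null(roi_pred) && !is.null(roi_ref)) {
    rep$dice <- dice(roi_pred, roi_ref)
    rep$hausdorff_mm <- hausdorff(roi_pred, roi_ref,
                                  pair$pixel_spacing_mm[1])
  }
  structure(rep, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  for (nm in names(x)) cat(sprintf("%-12s %8.4f\n", nm, x[[nm]]))
  invisible(x)
}

#' Evaluate a batch of fused slices
#'
#' @param fused_list list of fused slice matrices.
#' @param source_pairs list of matching [slice_pair()] objects.
#' @param ... passed to [evaluate()].
#' @return list with `per_slice` (data frame, one row per slice) and
#'   `summary` (mean and sd per metric).
#' @export
evaluate_batch <- function(fused_list, source_pairs, ...) {
  stopifnot(length(fused_list) == length(source_pairs))
  rows <- lapply(seq_along(source_pairs), function(i)
    as.data.frame(unclass(evaluate(fused_list[[i]], source_pairs[[i]], ...))))
  per_slice <- do.call(rbind, rows)
  summary <- data.frame(
    metric = names(per_slice),
    mean = vapply(per_slice, mean, 0),
    sd = vapply(per_slice, function(v) if (length(v) > 1) stats::sd(v) else 0, 0),
    row.names = NULL)
  list(per_slice = per_slice, summary = summary)
}

#' Extract an intensity profile along an image row
#'
#' Used to compare soft-tissue contrast of fusion results along a line
#' through a structure of interest (e.g. a tumor).
#'
#' @param image numeric matrix.
#' @param row row index of the horizontal line.
#' @param cols optional column range (defaults to the full width).
#' @return data frame with `col` and `intensity`.
#' @export
line_profile <- function(image, row, cols = seq_len(ncol(image))) {
  check_image(image)
  if (row < 1 || row > nrow(image)) stop_mf("row out of range")
  data.frame(col = cols, intensity = image[row, cols])
}

#' Paired significance test between two methods
#'
#' Two-sided paired Wilcoxon signed-rank test across slices, per metric.
#'
#' @param per_slice_a,per_slice_b per-slice metric data frames from
#'   [evaluate_batch()] for two fusion methods on the same slices.
#' @return data frame with metric and p-value.
#' @export
compare_methods <- function(per_slice_a, per_slice_b) {
  common <- intersect(names(per_slice_a), names(per_slice_b))
  data.frame(
    metric = common,
    p_value = vapply(common, function(m) {
      suppressWarnings(stats::wilcox.test(per_slice_a[[m]], per_slice_b[[m]],
                                          paired = TRUE)$p.value)
    }, 0),
    row.names = NULL)
}
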