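# Slice-pair container and the five dataset-preparation steps:
# rigid NMI co-registration, Otsu masking, bed removal, morphological mask
# cleanup, per-slice min-max normalization. Augmentation lives in augment.R.

#' An aligned (MRI, CT) slice pair
#'
#' The unit of training and fusion. Both channels are 2D intensity
#' matrices of identical shape, stored row-major with origin top-left.
#'
#' @param mri,ct numeric intensity matrices of identical shape.
#' @param pixel_spacing_mm length-2 numeric, (row, col) spacing in mm.
#' @return an object of class `slice_pair`.
#' @export
slice_pair <- function(mri, ct, pixel_spacing_mm = c(1, 1)) {
  check_image(mri, "mri"); check_image(ct, "ct")
  check_same_shape(mri, ct, c("mri", "ct"))
  structure(list(mri = mri, ct = ct,
                 pixel_spacing_mm = as.numeric(pixel_spacing_mm)),
            class = "slice_pair")
}

#' @export
print.slice_pair <- function(x, ...) {
  cat(sprintf("slice_pair: %dx%d, spacing (%.2f, %.2f) mm, mri [%.3f, %.3f], ct [%.3f, %.3f]\n",
              nrow(x$mri), ncol(x$mri), x$pixel_spacing_mm[1], x$pixel_spacing_mm[2],
              min(x$mri), max(x$mri), min(x$ct), max(x$ct)))
  invisible(x)
}

#' Per-slice min-max normalization to [0, 1]
#'
#' `(x - min) / (max - min)` computed over the given slice. A constant
#' slice (max == min) returns all zeros with a warning: black padding
#' slices occur in clinical volumes and must not abort a pipeline run.
#'
#' @param image numeric intensity matrix.
#' @return matrix of the same shape with values in \[0, 1\].
#' @export
minmax_normalize <- function(image) {
  check_image(image)
  lo <- min(image); hi <- max(image)
  if (hi == lo) {
    warning("constant image in minmax_normalize: returning all zeros")
    return(matrix(0, nrow(image), ncol(image)))
  }
  (image - lo) / (hi - lo)
}

#' Otsu threshold of an intensity image
#'
#' Maximizes the between-class variance over an `n_bins`-level histogram of
#' the image's own intensity range. The returned threshold is the bin-edge
#' intensity; pixels strictly above it are foreground.
#'
#' @param image numeric intensity matrix with at least two distinct values.
#' @param n_bins number of histogram levels (default 256).
#' @return scalar threshold on the intensity scale of `image`.
#' @export
otsu_threshold <- function(image, n_bins = 256) {
  check_image(image)
  lo <- min(image); hi <- max(image)
  if (hi == lo) stop_mf("Otsu threshold undefined for a single-valued image")
  # histogram over [lo, hi], right-closed last bin
  idx <- pmin(floor((as.vector(image) - lo) / (hi - lo) * n_bins) + 1L, n_bins)
  h <- tabulate(idx, nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)                     # class-0 probability at threshold k
  mu <- cumsum(p * seq_len(n_bins))      # class-0 first moment (bin index units)
  mu_t <- mu[n_bins]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- -Inf
  k <- which.max(sb2)                    # foreground = bins > k
  lo + k / n_bins * (hi - lo)
}

#' Extract the head mask of a slice
#'
#' Otsu-threshold foreground, binary closing with a disk structuring
#' element, retain the largest connected component, and fill enclosed
#' holes.
#'
#' @param image numeric intensity matrix.
#' @param closing_radius_px radius of the disk structuring element (default 3).
#' @return binary matrix (1 = head).
#' @export
head_mask <- function(image, closing_radius_px = 3) {
  check_image(image)
  thr <- otsu_threshold(image)
  fg <- (image > thr) * 1
  if (sum(fg) == 0) stop_mf("empty foreground after Otsu thresholding")
  brush <- EBImage::makeBrush(2L * as.integer(closing_radius_px) + 1L, "disc")
  closed <- EBImage::closing(fg, brush)
  lab <- EBImage::bwlabel(closed)
  tab <- tabulate(as.integer(lab[lab > 0]))
  keep <- (lab == which.max(tab)) * 1
  filled <- EBImage::fillHull(keep)
  matrix(as.numeric(filled > 0), nrow(image), ncol(image))
}

#' Remove the bed/tabletop from a CT slice
#'
#' The MRI never images the scanner table, so the MRI-derived head mask
#' identifies true head pixels; CT pixels outside that mask (bed, tabletop,
#' air) are set to zero, head pixels are unchanged.
#'
#' @param ct,mri co-registered intensity matrices of identical shape.
#' @param closing_radius_px passed to [head_mask()].
#' @return the masked CT image.
#' @export
remove_bed <- function(ct, mri, closing_radius_px = 3) {
  check_same_shape(ct, mri, c("ct", "mri"))
  m <- head_mask(mri, closing_radius_px)
  ct * m
}

#' Normalized mutual information of two images
#'
#' `NMI = (H(A) + H(B)) / H(A, B)` (Studholme's form) from the joint
#' `n_bins x n_bins` histogram, entropies in bits; each image is binned
#' over its own intensity range. Ranges over (1, 2], with 2 attained when
#' the images are related by a bijective intensity mapping.
#'
#' @param a,b numeric matrices of identical shape.
#' @param n_bins number of histogram bins per image (default 128).
#' @return scalar NMI value.
#' @export
nmi <- function(a, b, n_bins = 128) {
  check_image(a, "a"); check_image(b, "b")
  check_same_shape(a, b)
  ia <- quantize_bins(a, n_bins)
  ib <- quantize_bins(b, n_bins)
  joint <- tabulate(ia + (ib - 1L) * n_bins, nbins = n_bins * n_bins)
  pj <- joint[joint > 0] / length(ia)
  hj <- -sum(pj * log2(pj))
  ha <- shannon_from_counts(tabulate(ia, nbins = n_bins))
  hb <- shannon_from_counts(tabulate(ib, nbins = n_bins))
  (ha + hb) / hj
}

quantize_bins <- function(x, n_bins) {
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(rep(1L, length(x)))
  pmin(floor((as.vector(x) - lo) / (hi - lo) * n_bins) + 1L, n_bins)
}

shannon_from_counts <- function(h) {
  p <- h[h > 0] / sum(h)
  -sum(p * log2(p))
}

#' Rigid registration of a moving image onto a fixed image
#'
#' Maximizes `nmi(resample(moving, T), fixed)` over rigid transforms
#' (rotation about the image center plus translation). A coarse grid search
#' (integer-degree rotations, integer-pixel translations) is followed by
#' Nelder-Mead local refinement of the continuous parameters; fully
#' deterministic.
#'
#' @param moving,fixed numeric matrices of identical shape.
#' @param rot_range_deg,trans_range_px half-widths of the search ranges
#'   (defaults 15 degrees and 8 px).
#' @param rot_step_deg,trans_step_px coarse grid steps (defaults 1 and 1).
#' @param n_bins histogram bins for NMI (default 128).
#' @return list with `transform` (a [rigid_transform2d()]), `resampled`
#'   (the moving image under that transform) and `nmi` (achieved value).
#' @export
rigid_register <- function(moving, fixed,
                           rot_range_deg = 15, trans_range_px = 8,
                           rot_step_deg = 1, trans_step_px = 1,
                           n_bins = 128) {
  check_image(moving, "moving"); check_image(fixed, "fixed")
  check_same_shape(moving, fixed, c("moving", "fixed"))
  if (rot_range_deg < 0 || trans_range_px < 0 ||
      rot_step_deg <= 0 || trans_step_px <= 0)
    stop_mf("empty or invalid search range")
  rots <- seq(-rot_range_deg, rot_range_deg, by = rot_step_deg)
  trs <- seq(-trans_range_px, trans_range_px, by = trans_step_px)
  best <- list(val = -Inf, par = c(0, 0, 0))
  for (rd in rots) {
    rot_img <- if (rd == 0) moving else
      resample_rigid(moving, rigid_transform2d(rd, 0, 0))
    # integer translations of the rotated image by array shifting
    # (equivalent to resampling at integer offsets)
    for (tr in trs) for (tc in trs) {
      shifted <- shift_int(rot_img, tr, tc)
      v <- nmi(shifted, fixed, n_bins)
      if (v > best$val) best <- list(val = v, par = c(rd, tr, tc))
    }
  }
  # continuous refinement
  obj <- function(p) {
    t <- rigid_transform2d(p[1], p[2], p[3])
    -nmi(resample_rigid(moving, t), fixed, n_bins)
  }
  opt <- stats::optim(best$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 120, reltol = 1e-6))
  cand <- list(par = opt$par, val = -opt$value)
  if (cand$val < best$val) cand <- best   # refinement must not regress
  t <- rigid_transform2d(cand$par[1], cand$par[2], cand$par[3])
  res <- resample_rigid(moving, t)
  v0 <- nmi(moving, fixed, n_bins)
  if (nmi(res, fixed, n_bins) < v0) {     # optimizer contract: never worse
    t <- rigid_transform2d(0, 0, 0); res <- moving
  }
  list(transform = t, resampled = res, nmi = nmi(res, fixed, n_bins))
}

# integer shift with zero fill; shift (dr, dc) moves content down/right,
# matching resample_rigid with a pure translation of (dr, dc)
shift_int <- function(img, dr, dc) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  rs <- seq_len(H) - dr; cs <- seq_len(W) - dc
  rok <- rs >= 1 & rs <= H; cok <- cs >= 1 & cs <= W
  out[rok, cok] <- img[rs[rok], cs[cok]]
  out
}

#' Full preprocessing of a raw slice pair
#'
#' Pipeline order: optional rigid registration of the MRI onto the CT,
#' bed removal on the CT via the MRI head mask, head masking of both
#' channels, then per-slice min-max normalization.
#'
#' @param pair a [slice_pair()].
#' @param register if `TRUE`, rigidly register the MRI onto the CT first.
#' @param closing_radius_px disk radius for mask cleanup.
#' @param n_bins NMI histogram bins used during registration.
#' @return a normalized, masked `slice_pair`.
#' @export
preprocess_pair <- function(pair, register = FALSE, closing_radius_px = 3,
                            n_bins = 128) {
  stopifnot(inherits(pair, "slice_pair"))
  mri <- pair$mri; ct <- pair$ct
  if (register) {
    reg <- rigid_register(mri, ct, n_bins = n_bins)
    mri <- reg$resampled
  }
  m <- head_mask(mri, closing_radius_px)
  ct <- ct * m
  mri <- mri * m
  slice_pair(mri = minmax_normalize(mri), ct = minmax_normalize(ct),
             pixel_spacing_mm = pair$pixel_spacing_mm)
}
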