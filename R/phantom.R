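# Synthetic paired pseudo-CT / pseudo-MRI head phantoms.
#
# The generator emulates the essential contrast structure of clinical head
# slice pairs: the CT channel has a bright skull ring and low soft-tissue
# contrast (plus an optional table/bed artifact); the MRI channel has a dark
# skull, textured soft tissue with several distinct-intensity regions, and a
# bright tumor blob with a feathered rim. Both channels share the head
# geometry and carry independent Gaussian noise.

#' Specification of a synthetic head phantom
#'
#' @param image_size pixels per side (square image), at least 16.
#' @param skull_outer_radius_frac outer skull radius as a fraction of the
#'   image half-size.
#' @param skull_thickness_frac skull ring thickness as a fraction of the
#'   image half-size; must be smaller than `skull_outer_radius_frac`.
#' @param n_tissue_blobs number of distinct-intensity soft-tissue regions.
#' @param tumor_radius_frac tumor radius as a fraction of the half-size.
#' @param tumor_contrast additive intensity offset of the tumor over the
#'   surrounding soft tissue (dimensionless, normalized units).
#' @param noise_sigma_ct,noise_sigma_mri Gaussian noise standard deviation
#'   per channel, in normalized intensity units.
#' @param include_bed if `TRUE`, a bright table/bed arc is added to the CT
#'   channel below the head.
#' @param pixel_spacing_mm physical pixel spacing in mm.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 64,
                         skull_outer_radius_frac = 0.9,
                         skull_thickness_frac = 0.1,
                         n_tissue_blobs = 5,
                         tumor_radius_frac = 0.12,
                         tumor_contrast = 0.3,
                         noise_sigma_ct = 0.02,
                         noise_sigma_mri = 0.02,
                         include_bed = FALSE,
                         pixel_spacing_mm = 1.0) {
  s <- list(image_size = as.integer(image_size),
            skull_outer_radius_frac = skull_outer_radius_frac,
            skull_thickness_frac = skull_thickness_frac,
            n_tissue_blobs = as.integer(n_tissue_blobs),
            tumor_radius_frac = tumor_radius_frac,
            tumor_contrast = tumor_contrast,
            noise_sigma_ct = noise_sigma_ct,
            noise_sigma_mri = noise_sigma_mri,
            include_bed = isTRUE(include_bed),
            pixel_spacing_mm = pixel_spacing_mm)
  validate_phantom_spec(s)
  structure(s, class = "phantom_spec")
}

validate_phantom_spec <- function(s) {
  if (s$image_size < 16L) stop_mf("image_size must be >= 16")
  if (!(s$skull_thickness_frac > 0 &&
        s$skull_thickness_frac < s$skull_outer_radius_frac &&
        s$skull_outer_radius_frac <= 1))
    stop_mf("need 0 < skull_thickness_frac < skull_outer_radius_frac <= 1")
  if (s$noise_sigma_ct < 0 || s$noise_sigma_mri < 0)
    stop_mf("noise sigmas must be >= 0")
  if (s$n_tissue_blobs < 0) stop_mf("n_tissue_blobs must be >= 0")
  if (s$tumor_radius_frac < 0 || s$tumor_radius_frac >= s$skull_outer_radius_frac)
    stop_mf("tumor_radius_frac out of range")
  invisible(s)
}

# distance-from-center map (in pixels)
radius_map <- function(n) {
  cr <- (n + 1) / 2
  r <- seq_len(n) - cr
  sqrt(outer(r^2, r^2, "+"))
}

# small separable Gaussian blur (keeps the phantom generator free of heavy deps)
gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- max(3L, 2L * as.integer(ceiling(2 * sigma)) + 1L)
  h <- (k - 1L) %/% 2L
  w <- dnorm(seq(-h, h), sd = sigma); w <- w / sum(w)
  H <- nrow(img); W <- ncol(img)
  # replicate-pad then convolve rows, then columns
  padr <- img[c(rep(1, h), seq_len(H), rep(H, h)), , drop = FALSE]
  tmp <- matrix(0, H, W)
  for (i in seq_len(k)) tmp <- tmp + w[i] * padr[i:(i + H - 1), , drop = FALSE]
  padc <- tmp[, c(rep(1, h), seq_len(W), rep(W, h)), drop = FALSE]
  out <- matrix(0, H, W)
  for (i in seq_len(k)) out <- out + w[i] * padc[, i:(i + W - 1), drop = FALSE]
  out
}

#' Generate one paired pseudo-CT / pseudo-MRI phantom slice
#'
#' Deterministic given `(spec, seed, geometry_seed)`. Two independent RNG
#' streams are used: geometry (blob and tumor placement) is driven by
#' `geometry_seed`, per-channel noise by `seed`, so masks are stable across
#' noise realizations.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed for the noise stream.
#' @param geometry_seed integer seed for the geometry stream (defaults to
#'   `seed`).
#' @return a list with `pair` (a [slice_pair()]) and `truth` (a list with
#'   binary `head_mask`, `bone_mask`, `tumor_mask`, `bed_mask` and
#'   `applied_transform`).
#' @export
make_phantom_pair <- function(spec, seed, geometry_seed = seed) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  validate_phantom_spec(spec)
  n <- spec$image_size
  half <- n / 2
  rmap <- radius_map(n)
  r_out <- spec$skull_outer_radius_frac * half
  r_in <- r_out - spec$skull_thickness_frac * half
  head_mask <- (rmap <= r_out) * 1
  bone_mask <- (rmap <= r_out & rmap > r_in) * 1
  inner <- rmap <= r_in

  g <- with_seed(derive_seed(geometry_seed, "geom"), {
    # soft-tissue blobs: smoothed random ellipses with distinct mean offsets
    blob_field <- matrix(0, n, n)
    blob_means <- seq(-0.22, 0.22, length.out = max(1, spec$n_tissue_blobs))
    cr <- (n + 1) / 2
    for (b in seq_len(spec$n_tissue_blobs)) {
      ang <- runif(1, 0, 2 * pi)
      rad <- runif(1, 0.15, 0.6) * r_in
      bc <- c(cr + rad * cos(ang), cr + rad * sin(ang))
      ax <- runif(2, 0.12, 0.3) * r_in
      th <- runif(1, 0, pi)
      gr <- expand.grid(r = seq_len(n), c = seq_len(n))
      dr <- gr$r - bc[1]; dc <- gr$c - bc[2]
      u <- cos(th) * dr + sin(th) * dc
      v <- -sin(th) * dr + cos(th) * dc
      inside <- matrix((u / ax[1])^2 + (v / ax[2])^2 <= 1, n, n)
      blob_field[inside] <- blob_means[b]
    }
    blob_field <- gauss_blur(blob_field, sigma = n / 48)
    # tumor: circle with a Gaussian-feathered rim, inside the inner head,
    # away from center so it does not sit on blob boundaries by construction
    t_r <- spec$tumor_radius_frac * half
    ang <- runif(1, 0, 2 * pi)
    rad <- runif(1, 0.2, 0.55) * max(r_in - t_r - 2, 1)
    tc <- c(cr + rad * cos(ang), cr + rad * sin(ang))
    dmap <- sqrt(outer((seq_len(n) - tc[1])^2, (seq_len(n) - tc[2])^2, "+"))
    tumor_mask <- (dmap <= t_r & inner) * 1
    feather <- exp(-pmax(dmap - t_r, 0)^2 / (2 * (t_r / 3)^2))
    feather[dmap <= t_r] <- 1
    list(blob_field = blob_field, tumor_mask = tumor_mask, feather = feather)
  })

  # MRI channel: dark bone, textured soft tissue, bright feathered tumor
  mri <- matrix(0, n, n)
  mri[inner] <- 0.45 + g$blob_field[inner]
  tumor_core <- 0.55 + spec$tumor_contrast
  blend <- g$feather * inner
  mri <- mri + (tumor_core - mri) * blend
  mri[bone_mask == 1] <- 0.02
  # CT channel: bright bone, low-contrast soft tissue
  ct <- matrix(0, n, n)
  ct[inner] <- 0.30 + 0.05 * g$blob_field[inner]
  ct[bone_mask == 1] <- 0.97

  bed_mask <- matrix(0, n, n)
  if (spec$include_bed) {
    bed <- bed_artifact_mask(spec, head_mask)
    ct[bed == 1] <- 0.9
    bed_mask <- bed
  }

  noise <- with_seed(derive_seed(seed, "noise"), {
    list(ct = matrix(rnorm(n * n, 0, spec$noise_sigma_ct), n, n),
         mri = matrix(rnorm(n * n, 0, spec$noise_sigma_mri), n, n))
  })
  ct <- clip01(ct + noise$ct)
  mri <- clip01(mri + noise$mri)

  pair <- slice_pair(mri = mri, ct = ct,
                     pixel_spacing_mm = rep(spec$pixel_spacing_mm, 2))
  truth <- list(head_mask = head_mask, bone_mask = bone_mask,
                tumor_mask = g$tumor_mask, bed_mask = bed_mask,
                applied_transform = rigid_transform2d(0, 0, 0))
  list(pair = pair, truth = truth)
}

# Circular-arc bed slab below the head, clipped to stay disjoint from the
# (slightly dilated) head mask.
bed_artifact_mask <- function(spec, head_mask) {
  n <- spec$image_size
  cr <- (n + 1) / 2
  # arc of a large circle centered well above the image, passing near the
  # bottom edge: mimics the curved CT tabletop
  R <- 1.6 * n
  center_r <- n - 2 - R          # so the arc apex sits ~2 px above bottom
  gr <- expand.grid(r = seq_len(n), c = seq_len(n))
  d <- sqrt((gr$r - center_r)^2 + (gr$c - cr)^2)
  band <- matrix(d >= R & d <= R + max(2, round(0.04 * n)), n, n)
  dil <- EBImage::dilate(head_mask, EBImage::makeBrush(5, "disc"))
  band[dil > 0] <- FALSE
  band * 1
}

#' Generate a dataset of phantom pairs
#'
#' Item seeds are derived deterministically from the master seed; both
#' geometry and noise vary between items.
#'
#' @param n number of pairs (>= 1).
#' @param spec a [phantom_spec()].
#' @param seed master integer seed.
#' @return a list of `n` elements, each as returned by [make_phantom_pair()].
#' @export
make_phantom_dataset <- function(n, spec, seed) {
  if (n < 1) stop_mf("n must be >= 1")
  lapply(seq_len(n), function(i) {
    s <- derive_seed(seed, "item", i)
    make_phantom_pair(spec, seed = s, geometry_seed = derive_seed(s, "g"))
  })
}

#' Apply a known rigid misalignment to the MRI channel of a pair
#'
#' The MRI channel is resampled under the transform (rotation about the
#' image center, then translation, bilinear interpolation, zero fill); the
#' CT channel is left untouched. Used to create registration test cases
#' with a known ground-truth transform.
#'
#' @param pair a [slice_pair()].
#' @param transform a [rigid_transform2d()].
#' @return a new `slice_pair` with the transformed MRI channel.
#' @export
apply_misalignment <- function(pair, transform) {
  stopifnot(inherits(pair, "slice_pair"), inherits(transform, "rigid_transform2d"))
  slice_pair(mri = resample_rigid(pair$mri, transform),
             ct = pair$ct, pixel_spacing_mm = pair$pixel_spacing_mm)
}

#' Add a bed/tabletop artifact to a CT slice
#'
#' @param ct CT intensity matrix.
#' @param spec the [phantom_spec()] describing the geometry; if
#'   `spec$include_bed` is `FALSE` the image is returned unchanged.
#' @param head_mask binary head mask used to keep the bed disjoint from the
#'   head.
#' @return the CT image with a bright arc slab outside the head.
#' @export
add_bed_artifact <- function(ct, spec, head_mask) {
  if (!isTRUE(spec$include_bed)) return(ct)
  bed <- bed_artifact_mask(spec, head_mask)
  ct[bed == 1] <- 0.9
  ct
}
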