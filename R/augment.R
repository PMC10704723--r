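# Training-time data augmentation: horizontal/vertical flips, random
# rotation, random grid distortion; each applied independently with its own
# probability, and the SAME sampled transform applied to both channels so
# the pair stays pixel-aligned.

#' Augmentation configuration
#'
#' Defaults follow the training protocol: each augmentation fires
#' independently with probability 0.3, rotations are uniform within
#' +/- 20 degrees, grid distortion uses a 4x4 control grid with per-node
#' displacements uniform within +/- 2 px.
#'
#' @param p_hflip,p_vflip,p_rotate,p_grid_distort per-augmentation
#'   probabilities in \[0, 1\].
#' @param max_rotate_deg maximum absolute rotation in degrees.
#' @param grid_distort_cells control-grid nodes per side.
#' @param grid_distort_mag maximum absolute node displacement in px.
#' @return an object of class `augment_config`.
#' @export
augment_config <- function(p_hflip = 0.3, p_vflip = 0.3, p_rotate = 0.3,
                           p_grid_distort = 0.3, max_rotate_deg = 20,
                           grid_distort_cells = 4, grid_distort_mag = 2) {
  p <- c(p_hflip, p_vflip, p_rotate, p_grid_distort)
  if (any(p < 0 | p > 1)) stop_mf("augmentation probabilities must be in [0, 1]")
  if (max_rotate_deg < 0) stop_mf("max_rotate_deg must be >= 0")
  structure(list(p_hflip = p_hflip, p_vflip = p_vflip, p_rotate = p_rotate,
                 p_grid_distort = p_grid_distort,
                 max_rotate_deg = max_rotate_deg,
                 grid_distort_cells = as.integer(grid_distort_cells),
                 grid_distort_mag = grid_distort_mag),
            class = "augment_config")
}

# bilinear warp by a dense displacement field (out(p) = img(p + disp(p)))
warp_displacement <- function(img, disp_r, disp_c) {
  H <- nrow(img); W <- ncol(img)
  g <- expand.grid(r = seq_len(H), c = seq_len(W))
  matrix(bilinear_sample(img, g$r + as.vector(disp_r), g$c + as.vector(disp_c)),
         H, W)
}

# displacement field from a cells x cells control grid of node displacements,
# bilinearly interpolated to every pixel
grid_displacement_field <- function(H, W, node_dr, node_dc) {
  cells <- nrow(node_dr)
  # control nodes at the image corners and evenly between
  up <- function(nodes, n) {
    pos <- seq(1, cells, length.out = n)          # fractional node coords
    i0 <- pmin(floor(pos), cells - 1); f <- pos - i0
    list(i0 = i0, f = f)
  }
  r <- up(NULL, H); c <- up(NULL, W)
  interp <- function(nodes) {
    a <- nodes[r$i0, c$i0, drop = FALSE] * outer(1 - r$f, 1 - c$f) +
         nodes[r$i0 + 1, c$i0, drop = FALSE] * outer(r$f, 1 - c$f) +
         nodes[r$i0, c$i0 + 1, drop = FALSE] * outer(1 - r$f, c$f) +
         nodes[r$i0 + 1, c$i0 + 1, drop = FALSE] * outer(r$f, c$f)
    a
  }
  list(dr = interp(node_dr), dc = interp(node_dc))
}

#' Augment a slice pair
#'
#' Samples one transform per enabled augmentation and applies it
#' identically to both channels; deterministic given `seed`. Output values
#' are clipped to \[0, 1\].
#'
#' @param pair a [slice_pair()].
#' @param cfg an [augment_config()].
#' @param seed integer seed.
#' @return the augmented `slice_pair`.
#' @export
augment <- function(pair, cfg = augment_config(), seed = 0) {
  stopifnot(inherits(pair, "slice_pair"), inherits(cfg, "augment_config"))
  with_seed(derive_seed(seed, "augment"), {
    mri <- pair$mri; ct <- pair$ct
    if (stats::runif(1) < cfg$p_hflip) {
      mri <- mri[, rev(seq_len(ncol(mri))), drop = FALSE]
      ct <- ct[, rev(seq_len(ncol(ct))), drop = FALSE]
    }
    if (stats::runif(1) < cfg$p_vflip) {
      mri <- mri[rev(seq_len(nrow(mri))), , drop = FALSE]
      ct <- ct[rev(seq_len(nrow(ct))), , drop = FALSE]
    }
    if (stats::runif(1) < cfg$p_rotate) {
      ang <- stats::runif(1, -cfg$max_rotate_deg, cfg$max_rotate_deg)
      t <- rigid_transform2d(ang, 0, 0)
      mri <- resample_rigid(mri, t)
      ct <- resample_rigid(ct, t)
    }
    if (stats::runif(1) < cfg$p_grid_distort) {
      cells <- cfg$grid_distort_cells
      node_dr <- matrix(stats::runif(cells^2, -cfg$grid_distort_mag,
                                     cfg$grid_distort_mag), cells, cells)
      node_dc <- matrix(stats::runif(cells^2, -cfg$grid_distort_mag,
                                     cfg$grid_distort_mag), cells, cells)
      fld <- grid_displacement_field(nrow(mri), ncol(mri), node_dr, node_dc)
      mri <- warp_displacement(mri, fld$dr, fld$dc)
      ct <- warp_displacement(ct, fld$dr, fld$dc)
    }
    slice_pair(mri = clip01(mri), ct = clip01(ct),
               pixel_spacing_mm = pair$pixel_spacing_mm)
  })
}
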