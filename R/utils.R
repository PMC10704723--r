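#' @keywords internal
"_PACKAGE"

# ---- validation helpers -------------------------------------------------

stop_mf <- function(...) stop(sprintf(...), call. = FALSE)

check_image <- function(x, name = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    stop_mf("%s must be a numeric matrix", name)
  if (length(x) == 0L) stop_mf("%s is empty", name)
  if (any(!is.finite(x))) stop_mf("%s contains non-finite values", name)
  invisible(x)
}

check_same_shape <- function(a, b, names = c("a", "b")) {
  if (!identical(dim(a), dim(b)))
    stop_mf("%s and %s must have identical shape (got %s vs %s)",
            names[1], names[2],
            paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x"))
  invisible(NULL)
}

check_binary_mask <- function(m, name = "mask") {
  if (!is.matrix(m)) stop_mf("%s must be a matrix", name)
  v <- unique(as.vector(m))
  if (!all(v %in% c(0, 1, TRUE, FALSE)))
    stop_mf("%s must be binary (0/1)", name)
  invisible(m)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# ---- deterministic seed streams ----------------------------------------

# Derive a child seed from (seed, tag) so that independent RNG streams
# (geometry vs noise, per-step augmentation, per-item dataset seeds) never
# collide. Plain integer hash, kept below 2^31.
derive_seed <- function(seed, ...) {
  parts <- c(as.character(as.integer(seed)), vapply(list(...), as.character, ""))
  h <- 17
  for (p in parts) {
    for (cc in utf8ToInt(p)) h <- (h * 31 + cc) %% 2147483629
  }
  as.integer(h)
}

# Evaluate expr under a local RNG seeded with `seed`; global RNG untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# ---- rigid 2D transforms ------------------------------------------------

#' Create a rigid 2D transform
#'
#' Rotation is counter-clockwise about the image center, in degrees;
#' translations are in pixels, (row, col) order, applied after rotation.
#'
#' @param rotation_deg rotation angle in degrees (counter-clockwise).
#' @param tx_px,ty_px translation in pixels along rows and columns.
#' @return an object of class `rigid_transform2d`.
#' @export
rigid_transform2d <- function(rotation_deg = 0, tx_px = 0, ty_px = 0) {
  v <- c(rotation_deg, tx_px, ty_px)
  if (any(!is.finite(v))) stop_mf("rigid transform components must be finite")
  structure(list(rotation_deg = rotation_deg, tx_px = tx_px, ty_px = ty_px),
            class = "rigid_transform2d")
}

#' Invert a rigid 2D transform
#'
#' @param t a [rigid_transform2d()].
#' @return the inverse transform, also a `rigid_transform2d`.
#' @export
invert_rigid <- function(t) {
  th <- -t$rotation_deg * pi / 180
  # forward: p' = R p_c + c + t  =>  inverse: rot -theta, t' = -R^{-1} t
  ct <- cos(th); st <- sin(th)
  # R^{-1} = R(-theta); coordinates are (row, col)
  tx <- t$tx_px; ty <- t$ty_px
  rigid_transform2d(-t$rotation_deg,
                    -(ct * tx - st * ty),
                    -(st * tx + ct * ty))
}

#' @export
print.rigid_transform2d <- function(x, ...) {
  cat(sprintf("rigid 2D transform: %.3f deg, t = (%.3f, %.3f) px\n",
              x$rotation_deg, x$tx_px, x$ty_px))
  invisible(x)
}

# Sample image at fractional (row, col) positions with bilinear
# interpolation; positions outside the image yield `fill`.
bilinear_sample <- function(img, rows, cols, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  out <- numeric(length(rows)) + fill
  ok <- r0 >= 1 & c0 >= 1 & r0 + 1 <= H & c0 + 1 <= W
  # allow exact border hits
  edge <- !ok & rows >= 1 & rows <= H & cols >= 1 & cols <= W
  if (any(edge)) {
    re <- pmin(pmax(r0[edge], 1), H - 1); ce <- pmin(pmax(c0[edge], 1), W - 1)
    r0[edge] <- re; c0[edge] <- ce
    fr[edge] <- rows[edge] - re; fc[edge] <- cols[edge] - ce
    ok <- ok | edge
  }
  if (any(ok)) {
    r0k <- r0[ok]; c0k <- c0[ok]; frk <- fr[ok]; fck <- fc[ok]
    i00 <- r0k + (c0k - 1) * H
    v <- img[i00]       * (1 - frk) * (1 - fck) +
         img[i00 + 1]   * frk       * (1 - fck) +
         img[i00 + H]   * (1 - frk) * fck +
         img[i00 + H + 1] * frk     * fck
    out[ok] <- v
  }
  out
}

# Resample an image under a rigid transform: out(p) = img(T^{-1} p).
# Rotation counter-clockwise about the image center, then translation.
resample_rigid <- function(img, t, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  th <- t$rotation_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  g <- expand.grid(r = seq_len(H), c = seq_len(W))
  dr <- g$r - cr - t$tx_px
  dc <- g$c - cc - t$ty_px
  # inverse rotation of the centered, de-translated coordinates
  sr <- ct * dr + st * dc + cr
  sc <- -st * dr + ct * dc + cc
  matrix(bilinear_sample(img, sr, sc, fill = fill), H, W)
}
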