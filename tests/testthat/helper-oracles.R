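# Brute-force re-implementations of every metric, written as naive
# per-pixel loops, independent of the package's vectorized code paths.

bin_index <- function(v, n) min(floor(min(max(v, 0), 1) * n) + 1L, n)

ent_oracle <- function(x, n_levels = 256) {
  counts <- numeric(n_levels)
  for (v in as.vector(x)) {
    b <- bin_index(v, n_levels)
    counts[b] <- counts[b] + 1
  }
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

std_oracle <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / length(x))
}

mg_oracle <- function(x) {
  H <- nrow(x); W <- ncol(x)
  acc <- 0; cnt <- 0
  for (i in 1:(H - 1)) for (j in 1:(W - 1)) {
    dr <- x[i + 1, j] - x[i, j]
    dc <- x[i, j + 1] - x[i, j]
    acc <- acc + sqrt((dr^2 + dc^2) / 2)
    cnt <- cnt + 1
  }
  acc / cnt
}

sf_oracle <- function(x) {
  H <- nrow(x); W <- ncol(x)
  rf <- 0; cf <- 0
  for (i in 1:H) for (j in 2:W) rf <- rf + (x[i, j] - x[i, j - 1])^2
  for (i in 2:H) for (j in 1:W) cf <- cf + (x[i, j] - x[i - 1, j])^2
  sqrt(rf / (H * (W - 1)) + cf / ((H - 1) * W))
}

mi_oracle_pair <- function(a, b, n_bins) {
  joint <- matrix(0, n_bins, n_bins)
  va <- as.vector(a); vb <- as.vector(b)
  for (i in seq_along(va)) {
    joint[bin_index(va[i], n_bins), bin_index(vb[i], n_bins)] <-
      joint[bin_index(va[i], n_bins), bin_index(vb[i], n_bins)] + 1
  }
  p <- joint / sum(joint)
  pa <- rowSums(p); pb <- colSums(p)
  mi <- 0
  for (i in 1:n_bins) for (j in 1:n_bins) {
    if (p[i, j] > 0) mi <- mi + p[i, j] * log2(p[i, j] / (pa[i] * pb[j]))
  }
  mi
}

mi_oracle <- function(f, a, b, n_bins = 256) {
  mi_oracle_pair(f, a, n_bins) + mi_oracle_pair(f, b, n_bins)
}

ncc_oracle <- function(f, a, b) {
  pear <- function(u, v) {
    u <- as.vector(u) - mean(u); v <- as.vector(v) - mean(v)
    sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  }
  (pear(f, a) + pear(f, b)) / 2
}

psnr_oracle <- function(f, a, b, peak = 1) {
  mse <- (sum((f - a)^2) / length(f) + sum((f - b)^2) / length(f)) / 2
  if (mse == 0) Inf else 10 * log10(peak^2 / mse)
}

ssim_oracle <- function(a, b, C1 = 0.01^2, C2 = 0.03^2, win = 11,
                        sigma = 1.5) {
  h <- (win - 1) / 2
  g1 <- dnorm(seq(-h, h), sd = sigma)
  w <- outer(g1, g1); w <- w / sum(w)
  H <- nrow(a); W <- ncol(a)
  vals <- c()
  for (i in 1:(H - win + 1)) for (j in 1:(W - win + 1)) {
    wa <- a[i:(i + win - 1), j:(j + win - 1)]
    wb <- b[i:(i + win - 1), j:(j + win - 1)]
    mu_a <- sum(w * wa); mu_b <- sum(w * wb)
    va <- sum(w * wa^2) - mu_a^2
    vb <- sum(w * wb^2) - mu_b^2
    cab <- sum(w * wa * wb) - mu_a * mu_b
    vals <- c(vals, (2 * mu_a * mu_b + C1) * (2 * cab + C2) /
                ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2)))
  }
  mean(vals)
}

# naive Sobel with 1-px edge-replicated padding, matching the documented
# convention but computed pixel-by-pixel
sobel_oracle <- function(x) {
  H <- nrow(x); W <- ncol(x)
  kr <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  kc <- t(kr)
  at <- function(i, j) x[min(max(i, 1), H), min(max(j, 1), W)]
  gr <- matrix(0, H, W); gc <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    sr <- 0; sc <- 0
    for (a in -1:1) for (b in -1:1) {
      sr <- sr + kr[a + 2, b + 2] * at(i + a, j + b)
      sc <- sc + kc[a + 2, b + 2] * at(i + a, j + b)
    }
    gr[i, j] <- sr; gc[i, j] <- sc
  }
  list(gr = gr, gc = gc)
}

gradient_loss_oracle <- function(f, m) {
  sf <- sobel_oracle(f); sm <- sobel_oracle(m)
  (mean(abs(sf$gr - sm$gr)) + mean(abs(sf$gc - sm$gc))) / 2
}

qxyf_oracle <- function(mri, ct, fused, gamma_g = 1, kappa_g = -10,
                        sigma_g = 0.5, gamma_a = 1, kappa_a = -20,
                        sigma_a = 0.75, L = 1) {
  so <- function(img) {
    s <- sobel_oracle(img)
    list(g = sqrt(s$gr^2 + s$gc^2), a = atan2(s$gr, s$gc))
  }
  ex <- so(mri); ey <- so(ct); ef <- so(fused)
  pres <- function(src, fus) {
    H <- nrow(src$g); W <- ncol(src$g)
    out <- matrix(0, H, W)
    for (i in 1:H) for (j in 1:W) {
      gs <- src$g[i, j]; gf <- fus$g[i, j]
      G <- if (gs == 0 && gf == 0) 1
           else if (gs > gf) gf / max(gs, 1e-12)
           else gs / max(gf, 1e-12)
      da <- abs(src$a[i, j] - fus$a[i, j])
      da <- min(da, 2 * pi - da)
      da <- min(da, pi - da)
      A <- 1 - da / (pi / 2)
      Qg <- gamma_g / (1 + exp(kappa_g * (G - sigma_g)))
      Qa <- gamma_a / (1 + exp(kappa_a * (A - sigma_a)))
      out[i, j] <- Qg * Qa
    }
    out
  }
  qx <- pres(ex, ef); qy <- pres(ey, ef)
  wx <- ex$g^L; wy <- ey$g^L
  sum(qx * wx + qy * wy) / sum(wx + wy)
}

nmi_oracle <- function(a, b, n_bins = 128) {
  qz <- function(x) {
    lo <- min(x); hi <- max(x)
    sapply(as.vector(x), function(v)
      min(floor((v - lo) / (hi - lo) * n_bins) + 1L, n_bins))
  }
  ia <- qz(a); ib <- qz(b)
  joint <- matrix(0, n_bins, n_bins)
  for (i in seq_along(ia)) joint[ia[i], ib[i]] <- joint[ia[i], ib[i]] + 1
  p <- joint / sum(joint)
  hj <- -sum(p[p > 0] * log2(p[p > 0]))
  pa <- rowSums(p); pb <- colSums(p)
  ha <- -sum(pa[pa > 0] * log2(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log2(pb[pb > 0]))
  (ha + hb) / hj
}

# exhaustive Otsu: try every candidate split of the n-bin histogram and
# maximize between-class variance computed directly from class moments
otsu_oracle <- function(x, n_bins = 256) {
  lo <- min(x); hi <- max(x)
  idx <- sapply(as.vector(x), function(v)
    min(floor((v - lo) / (hi - lo) * n_bins) + 1L, n_bins))
  best_k <- NA; best_v <- -Inf
  for (k in 1:(n_bins - 1)) {
    c0 <- idx[idx <= k]; c1 <- idx[idx > k]
    if (length(c0) == 0 || length(c1) == 0) next
    w0 <- length(c0) / length(idx); w1 <- 1 - w0
    v <- w0 * w1 * (mean(c0) - mean(c1))^2
    if (v > best_v) { best_v <- v; best_k <- k }
  }
  lo + best_k / n_bins * (hi - lo)
}
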