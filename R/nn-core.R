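# Minimal convolutional-network engine.
#
# No deep-learning framework is available in this stack, and the network is
# the method's core, so the layers are implemented here directly. Tensors
# are dense 4D arrays [H, W, N, C] (column-major, channels last, so a
# per-channel reshape is copy-free). A k x k convolution is computed as k^2
# shifted BLAS GEMMs (one per kernel offset), which avoids materializing an
# im2col matrix; every layer carries a hand-derived backward pass.

# Geometry of a convolution: padded-matrix row indices. The padded input
# is held as a (Hp*Wp) x (N*Cin) matrix so each kernel-offset slice is one
# fast matrix row-subset; `base` indexes the window origins, `iidx` the
# unpadded interior.
conv_geom <- function(d, k, stride, pad) {
  H <- d[1]; W <- d[2]
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L; Wo <- (Wp - k) %/% stride + 1L
  base <- as.vector(outer(seq.int(1L, by = stride, length.out = Ho),
                          (seq.int(1L, by = stride, length.out = Wo) - 1L) * Hp,
                          "+"))
  iidx <- if (pad > 0L)
    as.vector(outer(pad + seq_len(H), (pad + seq_len(W) - 1L) * Hp, "+"))
  else NULL
  list(Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo, base = base, iidx = iidx)
}

# Forward convolution. x: [H, W, N, Cin], W: [k, k, Cin, Cout], b: length
# Cout. Zero padding `pad`, square stride. Returns y [Ho, Wo, N, Cout].
# Computed as k^2 shifted row-subsets + BLAS GEMMs.
conv_forward <- function(x, W, b, stride = 1L, pad = 0L, keep_cache = TRUE) {
  d <- dim(x); k <- dim(W)[1]; Cin <- dim(W)[3]; Cout <- dim(W)[4]
  stopifnot(d[4] == Cin)
  N <- d[3]
  g <- conv_geom(d, k, stride, pad)
  xm <- x; dim(xm) <- c(d[1] * d[2], N * Cin)
  if (pad > 0L) {
    xpm <- matrix(0, g$Hp * g$Wp, N * Cin)
    xpm[g$iidx, ] <- xm
  } else xpm <- xm
  nout <- g$Ho * g$Wo * N
  y <- matrix(0, nout, Cout)
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    xs <- xpm[g$base + (di - 1L) + (dj - 1L) * g$Hp, , drop = FALSE]
    dim(xs) <- c(nout, Cin)
    y <- y + xs %*% matrix(W[di, dj, , ], Cin, Cout)
  }
  y <- y + rep(b, each = nout)
  dim(y) <- c(g$Ho, g$Wo, N, Cout)
  cache <- if (keep_cache)
    list(xpm = xpm, g = g, k = k, stride = stride, pad = pad, in_dim = d)
  else NULL
  list(y = y, cache = cache)
}

# Backward convolution: dy [Ho, Wo, N, Cout] -> dx, dW, db.
conv_backward <- function(cache, W, dy) {
  k <- cache$k; Cin <- dim(W)[3]; Cout <- dim(W)[4]
  g <- cache$g; d <- cache$in_dim; N <- d[3]
  nout <- g$Ho * g$Wo * N
  dym <- dy; dim(dym) <- c(nout, Cout)
  db <- colSums(dym)
  dW <- array(0, dim(W))
  dxpm <- matrix(0, g$Hp * g$Wp, N * Cin)
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    idx <- g$base + (di - 1L) + (dj - 1L) * g$Hp
    xs <- cache$xpm[idx, , drop = FALSE]
    dim(xs) <- c(nout, Cin)
    dW[di, dj, , ] <- crossprod(xs, dym)
    dxs <- tcrossprod(dym, matrix(W[di, dj, , ], Cin, Cout))
    dim(dxs) <- c(g$Ho * g$Wo, N * Cin)
    dxpm[idx, ] <- dxpm[idx, ] + dxs
  }
  dxm <- if (cache$pad > 0L) dxpm[g$iidx, , drop = FALSE] else dxpm
  dim(dxm) <- d
  list(dx = dxm, dW = dW, db = db)
}

# ---- batch normalization ------------------------------------------------

bn_forward <- function(x, gamma, beta, running_mean, running_var,
                       training = TRUE, momentum = 0.1, eps = 1e-5) {
  d <- dim(x); C <- d[4]
  n <- d[1] * d[2] * d[3]
  xm <- x; dim(xm) <- c(n, C)
  if (training) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = n)
    var <- colMeans(xc^2)
    running_mean <- (1 - momentum) * running_mean + momentum * mu
    running_var <- (1 - momentum) * running_var + momentum * var
  } else {
    mu <- running_mean; var <- running_var
    xc <- xm - rep(mu, each = n)
  }
  ivar <- 1 / sqrt(var + eps)
  xhat <- xc * rep(ivar, each = n)
  ym <- xhat * rep(gamma, each = n) + rep(beta, each = n)
  dim(ym) <- d
  list(y = ym,
       cache = list(xhat = xhat, ivar = ivar, dims = d, training = training),
       running_mean = running_mean, running_var = running_var)
}

bn_backward <- function(cache, gamma, dy) {
  d <- cache$dims; C <- d[4]
  n <- d[1] * d[2] * d[3]
  dym <- dy; dim(dym) <- c(n, C)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- dym * rep(gamma, each = n)
  if (cache$training) {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * cache$xhat)
    dxm <- (dxhat * n - rep(s1, each = n) -
              cache$xhat * rep(s2, each = n)) * rep(cache$ivar / n, each = n)
  } else {
    dxm <- dxhat * rep(cache$ivar, each = n)
  }
  dim(dxm) <- d
  list(dx = dxm, dgamma = dgamma, dbeta = dbeta)
}

# ---- simple layers ------------------------------------------------------

lrelu_forward <- function(x, slope = 0.2) {
  neg <- x < 0
  list(y = x - (1 - slope) * (x * neg), cache = neg)
}
lrelu_backward <- function(cache, slope, dy) {
  dy - (1 - slope) * (dy * cache)
}

sigmoid_forward <- function(x) {
  y <- 1 / (1 + exp(-x))
  list(y = y, cache = y)
}
sigmoid_backward <- function(cache, dy) dy * cache * (1 - cache)

upsample2_forward <- function(x) {
  d <- dim(x)
  ri <- rep(seq_len(d[1]), each = 2)
  ci <- rep(seq_len(d[2]), each = 2)
  list(y = x[ri, ci, , , drop = FALSE], cache = d)
}
upsample2_backward <- function(cache, dy) {
  d <- cache
  od <- seq(1, 2 * d[1], by = 2); ev <- od + 1
  oc <- seq(1, 2 * d[2], by = 2); ec <- oc + 1
  dy[od, oc, , , drop = FALSE] + dy[ev, oc, , , drop = FALSE] +
    dy[od, ec, , , drop = FALSE] + dy[ev, ec, , , drop = FALSE]
}

# ---- op-graph networks --------------------------------------------------
#
# A network is a list of ops in topological order; each op names its input
# op(s). Parameters live in net$params[[op_name]]. This tiny tape is enough
# for residual encoder/decoder generators and strided PatchGAN
# discriminators, and makes the backward pass systematic.

nn_op <- function(name, type, input, ...) {
  c(list(name = name, type = type, input = input), list(...))
}

nn_init_conv <- function(k, cin, cout) {
  sdv <- sqrt(2 / (k * k * cin))
  list(W = array(stats::rnorm(k * k * cin * cout, 0, sdv), c(k, k, cin, cout)),
       b = numeric(cout))
}

nn_init_bn <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c),
       running_mean = numeric(c), running_var = rep(1, c))
}

# Build params for a graph given input channel count; returns net object.
nn_build <- function(ops, in_channels, seed) {
  params <- list()
  chan <- list(.input = in_channels)
  with_seed(derive_seed(seed, "init"), {
    for (op in ops) {
      cin <- chan[[op$input[1]]]
      if (op$type == "conv") {
        params[[op$name]] <- nn_init_conv(op$k, cin, op$cout)
        chan[[op$name]] <- op$cout
      } else if (op$type == "bn") {
        params[[op$name]] <- nn_init_bn(cin)
        chan[[op$name]] <- cin
      } else {
        chan[[op$name]] <- cin
      }
    }
  })
  structure(list(ops = ops, params = params, in_channels = in_channels),
            class = "mf_net")
}

# Forward pass. Returns output, per-op caches (for backward), and the net
# with updated BN running statistics (training mode only).
nn_forward <- function(net, x, training = FALSE, keep_cache = training) {
  vals <- list(.input = x)
  caches <- list()
  for (op in net$ops) {
    xin <- vals[[op$input[1]]]
    p <- net$params[[op$name]]
    out <- switch(op$type,
      conv = {
        r <- conv_forward(xin, p$W, p$b, op$stride, op$pad, keep_cache)
        caches[[op$name]] <- r$cache; r$y
      },
      bn = {
        r <- bn_forward(xin, p$gamma, p$beta, p$running_mean, p$running_var,
                        training = training)
        if (training) {
          net$params[[op$name]]$running_mean <- r$running_mean
          net$params[[op$name]]$running_var <- r$running_var
        }
        caches[[op$name]] <- r$cache; r$y
      },
      lrelu = { r <- lrelu_forward(xin, op$slope); caches[[op$name]] <- r$cache; r$y },
      sigmoid = { r <- sigmoid_forward(xin); caches[[op$name]] <- r$cache; r$y },
      upsample2 = { r <- upsample2_forward(xin); caches[[op$name]] <- r$cache; r$y },
      add = vals[[op$input[1]]] + vals[[op$input[2]]],
      stop_mf("unknown op type %s", op$type))
    vals[[op$name]] <- out
  }
  last <- net$ops[[length(net$ops)]]$name
  list(y = vals[[last]], caches = caches, vals = vals, net = net)
}

# Backward pass from dy at the output. Returns gradient list (same shapes
# as params) and gradient w.r.t. the network input.
nn_backward <- function(net, fw, dy) {
  grads <- list()
  dvals <- list()
  last <- net$ops[[length(net$ops)]]$name
  dvals[[last]] <- dy
  acc <- function(nm, g) {
    if (is.null(dvals[[nm]])) dvals[[nm]] <<- g else dvals[[nm]] <<- dvals[[nm]] + g
  }
  for (i in rev(seq_along(net$ops))) {
    op <- net$ops[[i]]
    d <- dvals[[op$name]]
    if (is.null(d)) next
    p <- net$params[[op$name]]
    switch(op$type,
      conv = {
        r <- conv_backward(fw$caches[[op$name]], p$W, d)
        grads[[op$name]] <- list(W = r$dW, b = r$db)
        acc(op$input[1], r$dx)
      },
      bn = {
        r <- bn_backward(fw$caches[[op$name]], p$gamma, d)
        grads[[op$name]] <- list(gamma = r$dgamma, beta = r$dbeta)
        acc(op$input[1], r$dx)
      },
      lrelu = acc(op$input[1], lrelu_backward(fw$caches[[op$name]], op$slope, d)),
      sigmoid = acc(op$input[1], sigmoid_backward(fw$caches[[op$name]], d)),
      upsample2 = acc(op$input[1], upsample2_backward(fw$caches[[op$name]], d)),
      add = { acc(op$input[1], d); acc(op$input[2], d) })
  }
  list(grads = grads, dx = dvals[[".input"]])
}

# ---- parameter utilities ------------------------------------------------

nn_param_vector <- function(net) {
  unlist(lapply(net$params, function(p)
    unlist(p[names(p) %in% c("W", "b", "gamma", "beta")], use.names = FALSE)),
    use.names = FALSE)
}

nn_param_count <- function(net) length(nn_param_vector(net))

# ---- Adam optimizer -----------------------------------------------------

adam_init <- function(net) {
  st <- list(t = 0L, m = list(), v = list())
  for (nm in names(net$params)) {
    for (field in intersect(names(net$params[[nm]]), c("W", "b", "gamma", "beta"))) {
      key <- paste(nm, field, sep = ".")
      z <- net$params[[nm]][[field]]; z[] <- 0
      st$m[[key]] <- z; st$v[[key]] <- z
    }
  }
  st
}

adam_step <- function(net, grads, state, lr = 2e-4, beta1 = 0.5,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    for (field in names(grads[[nm]])) {
      key <- paste(nm, field, sep = ".")
      g <- grads[[nm]][[field]]
      state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
      state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g^2
      mhat <- state$m[[key]] / bc1
      vhat <- state$v[[key]] / bc2
      net$params[[nm]][[field]] <- net$params[[nm]][[field]] -
        lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(net = net, state = state)
}
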