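# Alternating adversarial training with Adam, deterministic given the
# config seed, plus checkpoint/resume and inference-mode fusion.

#' Training configuration
#'
#' Defaults follow the published protocol: Adam with learning rate 2e-4,
#' batch size 8, 40 epochs; beta = (0.5, 0.999) is the common GAN setting.
#'
#' @param learning_rate Adam step size (> 0), shared by both networks.
#' @param batch_size slices per step (>= 1).
#' @param n_epochs passes over the dataset (>= 1).
#' @param n_steps optional explicit step count; overrides `n_epochs`.
#' @param seed master seed controlling initialization, shuffling and
#'   augmentation.
#' @param d_steps_per_g_step discriminator updates per generator update.
#' @param augment an [augment_config()], or `NULL` to disable.
#' @param checkpoint_every write a checkpoint every this many steps
#'   (`Inf` to disable intermediate checkpoints).
#' @param checkpoint_dir directory for intermediate checkpoints.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 2e-4, batch_size = 8, n_epochs = 40,
                         n_steps = NULL, seed = 0, d_steps_per_g_step = 1,
                         augment = NULL, checkpoint_every = Inf,
                         checkpoint_dir = tempdir()) {
  if (learning_rate <= 0) stop_mf("learning_rate must be > 0")
  if (batch_size < 1) stop_mf("batch_size must be >= 1")
  if (n_epochs < 1) stop_mf("n_epochs must be >= 1")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 n_epochs = as.integer(n_epochs),
                 n_steps = if (is.null(n_steps)) NULL else as.integer(n_steps),
                 seed = as.integer(seed),
                 d_steps_per_g_step = as.integer(d_steps_per_g_step),
                 augment = augment,
                 checkpoint_every = checkpoint_every,
                 checkpoint_dir = checkpoint_dir),
            class = "train_config")
}

# stack a list of slice_pairs into [H, W, N, 1] tensors (channels last)
stack_pairs <- function(pairs) {
  H <- nrow(pairs[[1]]$mri); W <- ncol(pairs[[1]]$mri); N <- length(pairs)
  xb <- array(0, c(H, W, N, 1L)); yb <- array(0, c(H, W, N, 1L))
  for (n in seq_len(N)) {
    xb[, , n, 1] <- pairs[[n]]$mri
    yb[, , n, 1] <- pairs[[n]]$ct
  }
  list(x = xb, y = yb)
}

# concatenate two [H,W,N,1] tensors along channels -> [H,W,N,2]
cat2 <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1], d[2], d[3], 2L))
  out[, , , 1] <- a[, , , 1]; out[, , , 2] <- b[, , , 1]
  out
}

per_image_scores <- function(pm) {
  d <- dim(pm)                       # [h, w, N, 1]
  m <- pm; dim(m) <- c(d[1] * d[2], d[3])
  colMeans(m)
}

# ---- discriminator step -------------------------------------------------

disc_step <- function(disc, xb, yb, fb, w, opt, lr) {
  N <- dim(xb)[3]
  branches <- list(real = cat2(xb, yb), f1 = cat2(fb, xb), f2 = cat2(fb, yb))
  fws <- list(); sc <- list()
  net <- disc$net
  for (nm in names(branches)) {
    fw <- nn_forward(net, branches[[nm]], training = TRUE, keep_cache = TRUE)
    net <- fw$net                       # BN running stats advance
    fws[[nm]] <- fw
    sc[[nm]] <- per_image_scores(fw$y)
  }
  mix <- w$lambda1_D * sc$f1 + w$lambda2_D * sc$f2
  arg_r <- clamp_unit(sc$real); arg_f <- clamp_unit(1 - mix)
  value <- mean(log(arg_r) + log(arg_f))
  # minimize -value
  dsr <- ifelse(sc$real > .mf_eps & sc$real < 1, -1 / (N * arg_r), 0)
  live <- (1 - mix) > .mf_eps & (1 - mix) < 1
  ds1 <- ifelse(live, w$lambda1_D / (N * arg_f), 0)
  ds2 <- ifelse(live, w$lambda2_D / (N * arg_f), 0)
  grads <- NULL
  for (nm in names(branches)) {
    ds <- switch(nm, real = dsr, f1 = ds1, f2 = ds2)
    pm <- fws[[nm]]$y
    npatch <- prod(dim(pm)[c(1, 2, 4)])
    dy <- pm; dy[] <- 0
    for (n in seq_len(N)) dy[, , n, ] <- ds[n] / npatch
    b <- nn_backward(net, fws[[nm]], dy)$grads
    grads <- if (is.null(grads)) b else add_grads(grads, b)
  }
  st <- adam_step(net, grads, opt, lr = lr)
  disc$net <- st$net
  list(disc = disc, opt = st$state, value = value)
}

add_grads <- function(a, b) {
  for (nm in names(b)) {
    if (is.null(a[[nm]])) a[[nm]] <- b[[nm]]
    else for (f in names(b[[nm]])) a[[nm]][[f]] <- a[[nm]][[f]] + b[[nm]][[f]]
  }
  a
}

# ---- generator step -----------------------------------------------------

# batched generator objective value + gradients w.r.t. generator params
gen_value_grads <- function(disc, gen, xb, yb, w, p, phi,
                            adv_mode = "non-saturating", training = TRUE) {
  N <- dim(xb)[3]; H <- dim(xb)[1]; W <- dim(xb)[2]
  gin <- cat2(xb, yb)
  gfw <- nn_forward(gen$net, gin, training = training, keep_cache = TRUE)
  gen$net <- gfw$net
  fb <- gfw$y                                   # [H, W, N, 1]
  # adversarial part through the frozen discriminator (eval mode)
  dfw1 <- nn_forward(disc$net, cat2(fb, xb), training = FALSE, keep_cache = TRUE)
  dfw2 <- nn_forward(disc$net, cat2(fb, yb), training = FALSE, keep_cache = TRUE)
  s1 <- per_image_scores(dfw1$y); s2 <- per_image_scores(dfw2$y)
  mix <- w$lambda1_D * s1 + w$lambda2_D * s2
  if (adv_mode == "non-saturating") {
    adv <- mean(-log(clamp_unit(mix)))
    live <- mix > .mf_eps & mix < 1
    dmix <- ifelse(live, -1 / (N * clamp_unit(mix)), 0)
  } else {
    adv <- mean(log(clamp_unit(1 - mix)))
    live <- (1 - mix) > .mf_eps & (1 - mix) < 1
    dmix <- ifelse(live, -1 / (N * clamp_unit(1 - mix)), 0)
  }
  dF <- fb; dF[] <- 0
  for (i in 1:2) {
    dfw <- if (i == 1) dfw1 else dfw2
    lam <- if (i == 1) w$lambda1_D else w$lambda2_D
    pm <- dfw$y; npatch <- prod(dim(pm)[c(1, 2, 4)])
    dy <- pm; dy[] <- 0
    for (n in seq_len(N)) dy[, , n, ] <- dmix[n] * lam / npatch
    dxi <- nn_backward(disc$net, dfw, dy)$dx    # [H, W, N, 2]
    dF[, , , 1] <- dF[, , , 1] + dxi[, , , 1]
  }
  # L1 term
  l1 <- (mean(abs(fb - xb)) + mean(abs(fb - yb))) / 2
  dF <- dF + (sign(fb - xb) + sign(fb - yb)) / (2 * H * W * N)
  # content terms per image
  gsum <- 0; ssum <- 0
  for (n in seq_len(N)) {
    f <- matrix(fb[, , n, 1], H, W)
    x <- matrix(xb[, , n, 1], H, W)
    if (w$lambda1_G > 0) {
      gsum <- gsum + gradient_loss(f, x)
      dF[, , n, 1] <- dF[, , n, 1] +
        w$lambda1_G * gradient_loss_grad(f, x) / N
    }
    if (w$lambda2_G > 0) {
      ssum <- ssum + ssim_loss(f, x)
      dF[, , n, 1] <- dF[, , n, 1] -
        w$lambda2_G * ssim_index_grad(f, x) / N
    }
  }
  gl <- gsum / N; sl <- ssum / N
  # perceptual term, batched
  pl <- 0
  if (w$lambda3_G > 0) {
    rf <- array(0, c(H, W, N, 3L)); rc <- rf
    for (c in 1:3) { rf[, , , c] <- fb[, , , 1]; rc[, , , c] <- yb[, , , 1] }
    pfw <- nn_forward(phi$net, rf, training = FALSE, keep_cache = TRUE)
    pfc <- nn_forward(phi$net, rc, training = FALSE, keep_cache = FALSE)$y
    pl <- mean((pfw$y - pfc)^2)
    dxp <- nn_backward(phi$net, pfw, 2 * (pfw$y - pfc) / length(pfc))$dx
    dF[, , , 1] <- dF[, , , 1] +
      w$lambda3_G * (dxp[, , , 1] + dxp[, , , 2] + dxp[, , , 3])
  }
  total <- adv + l1 + w$lambda1_G * gl + w$lambda2_G * sl + w$lambda3_G * pl
  gb <- nn_backward(gen$net, gfw, dF)
  list(total = total, grads = gb$grads, gen = gen, fused = fb,
       breakdown = c(adv_g = adv, l1 = l1, gradient = w$lambda1_G * gl,
                     ssim = w$lambda2_G * sl, perceptual = w$lambda3_G * pl))
}

#' Generator objective with analytic parameter gradients
#'
#' Exposes the exact backpropagated gradients of the total generator
#' objective with respect to every generator parameter, for one slice
#' pair. Used by the finite-difference validation tests; [train()] uses
#' the same code path.
#'
#' @inheritParams generator_objective
#' @param training forward the generator in training mode (batch-statistic
#'   batch norm), matching the in-training objective.
#' @return list with `total`, `breakdown` and `grads` (named like the
#'   generator's parameter list).
#' @export
generator_objective_grads <- function(d, g, pair, w = loss_weights(),
                                      p = ssim_params(),
                                      phi = feature_extractor(),
                                      adv_mode = "non-saturating",
                                      training = TRUE) {
  sb <- stack_pairs(list(pair))
  r <- gen_value_grads(d, g, sb$x, sb$y, w, p, phi, adv_mode = adv_mode,
                       training = training)
  list(total = r$total, breakdown = r$breakdown, grads = r$grads)
}

# ---- training loop ------------------------------------------------------

#' Train the fusion network
#'
#' Alternating updates: the discriminator ascends the adversarial value,
#' then the generator descends its total objective; Adam for both, same
#' learning rate. Deterministic given `cfg$seed` and the dataset order.
#'
#' @param dataset list of [slice_pair()] objects (or of lists holding a
#'   `$pair`), all the same shape, normalized to \[0, 1\].
#' @param net_spec a [network_spec()].
#' @param w a [loss_weights()].
#' @param cfg a [train_config()].
#' @param p an [ssim_params()].
#' @param phi a [feature_extractor()].
#' @param resume_from a checkpoint (list or path) to continue from.
#' @param verbose print a line every 25 steps.
#' @return list with `checkpoint` (final state) and `history` (one row per
#'   step: losses and the adversarial value).
#' @export
train <- function(dataset, net_spec = network_spec(), w = loss_weights(),
                  cfg = train_config(), p = ssim_params(),
                  phi = feature_extractor(), resume_from = NULL,
                  verbose = FALSE) {
  pairs <- lapply(dataset, function(e) if (inherits(e, "slice_pair")) e else e$pair)
  if (length(pairs) == 0) stop_mf("dataset is empty")
  H <- nrow(pairs[[1]]$mri)
  M <- disc_receptive_field(net_spec)
  if (M >= H)
    stop_mf("discriminator patch size M = %d must be smaller than the %d-px training images; reduce disc_n_layers", M, H)
  n <- length(pairs)
  steps_per_epoch <- max(1L, ceiling(n / cfg$batch_size))
  n_steps <- if (!is.null(cfg$n_steps)) cfg$n_steps
             else cfg$n_epochs * steps_per_epoch

  if (!is.null(resume_from)) {
    ck <- if (is.character(resume_from)) load_checkpoint(resume_from) else resume_from
    gen <- ck$generator; disc <- ck$discriminator
    opt_g <- ck$opt_g; opt_d <- ck$opt_d
    start_step <- ck$step + 1L
    history <- ck$history
    phi <- ck$phi
  } else {
    gen <- build_generator(net_spec, seed = cfg$seed)
    disc <- build_discriminator(net_spec, seed = cfg$seed)
    opt_g <- adam_init(gen$net); opt_d <- adam_init(disc$net)
    start_step <- 1L
    history <- NULL
  }

  hist_rows <- vector("list", max(0L, n_steps - start_step + 1L))
  hi <- 0L
  for (step in seq.int(start_step, length.out = max(0L, n_steps - start_step + 1L))) {
    epoch <- (step - 1L) %/% steps_per_epoch
    pos <- (step - 1L) %% steps_per_epoch
    perm <- with_seed(derive_seed(cfg$seed, "perm", epoch), sample.int(n))
    idx <- perm[(pos * cfg$batch_size + 1L):min((pos + 1L) * cfg$batch_size, n)]
    batch <- pairs[idx]
    if (!is.null(cfg$augment))
      batch <- lapply(seq_along(batch), function(i)
        augment(batch[[i]], cfg$augment, seed = derive_seed(cfg$seed, "aug", step, i)))
    sb <- stack_pairs(batch)

    # discriminator update(s) on the current generator's output
    gfw <- nn_forward(gen$net, cat2(sb$x, sb$y), training = FALSE,
                      keep_cache = FALSE)
    fb <- gfw$y
    adv_d <- NA_real_
    for (k in seq_len(cfg$d_steps_per_g_step)) {
      ds <- disc_step(disc, sb$x, sb$y, fb, w, opt_d, cfg$learning_rate)
      disc <- ds$disc; opt_d <- ds$opt; adv_d <- ds$value
    }
    # generator update
    gs <- gen_value_grads(disc, gen, sb$x, sb$y, w, p, phi)
    gen <- gs$gen
    if (!is.finite(gs$total) || !is.finite(adv_d)) {
      dump <- file.path(tempdir(), sprintf("medfusion_nan_step%d.rds", step))
      saveRDS(list(step = step, batch_idx = idx, breakdown = gs$breakdown,
                   adv_d = adv_d), dump)
      stop_mf("non-finite loss at step %d (diagnostic dump: %s)", step, dump)
    }
    st <- adam_step(gen$net, gs$grads, opt_g, lr = cfg$learning_rate)
    gen$net <- st$net; opt_g <- st$state

    hi <- hi + 1L
    hist_rows[[hi]] <- data.frame(step = step, adv_d = adv_d,
                                  t(gs$breakdown), total_g = gs$total)
    if (verbose && step %% 25 == 0)
      message(sprintf("step %d/%d total_g %.4f adv_d %.4f", step, n_steps,
                      gs$total, adv_d))
    if (is.finite(cfg$checkpoint_every) && step %% cfg$checkpoint_every == 0) {
      dir.create(cfg$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      ck <- make_checkpoint(gen, disc, net_spec, w, cfg, opt_g, opt_d, step,
                            rbind(history, do.call(rbind, hist_rows[seq_len(hi)])),
                            phi)
      save_checkpoint(ck, file.path(cfg$checkpoint_dir,
                                    sprintf("checkpoint_step%06d.rds", step)))
    }
  }
  history <- rbind(history, do.call(rbind, hist_rows[seq_len(hi)]))
  rownames(history) <- NULL
  ck <- make_checkpoint(gen, disc, net_spec, w, cfg, opt_g, opt_d, n_steps,
                        history, phi)
  list(checkpoint = ck, history = history)
}

make_checkpoint <- function(gen, disc, net_spec, w, cfg, opt_g, opt_d, step,
                            history, phi) {
  list(format_version = 1L, generator = gen, discriminator = disc,
       net_spec = net_spec, weights = w, cfg = cfg, opt_g = opt_g,
       opt_d = opt_d, step = step, history = history, phi = phi)
}

#' Fuse a slice pair with a trained checkpoint
#'
#' Deterministic inference-mode generator forward.
#'
#' @param checkpoint a checkpoint list or a path to one.
#' @param pair a normalized [slice_pair()].
#' @return the fused slice matrix, values in \[0, 1\].
#' @export
fuse <- function(checkpoint, pair) {
  ck <- if (is.character(checkpoint)) load_checkpoint(checkpoint) else checkpoint
  generator_forward(ck$generator, pair)
}

#' Patient-wise train/test split
#'
#' All slices of a patient fall entirely into one split, so there is no
#' patient overlap between training and testing.
#'
#' @param dataset list of slices (any type).
#' @param patient_ids vector of patient identifiers, one per slice.
#' @param fraction training fraction in (0, 1), default 0.8.
#' @param seed integer seed.
#' @return list with `train` and `test` index vectors into `dataset`.
#' @export
split_by_patient <- function(dataset, patient_ids, fraction = 0.8, seed = 0) {
  if (length(patient_ids) != length(dataset))
    stop_mf("patient_ids must match dataset length")
  if (fraction <= 0 || fraction >= 1) stop_mf("fraction must be in (0, 1)")
  pts <- unique(patient_ids)
  if (length(pts) < 2) stop_mf("need at least 2 patients to split")
  n_train <- min(max(round(fraction * length(pts)), 1L), length(pts) - 1L)
  train_pts <- with_seed(derive_seed(seed, "split"),
                         sample(pts, n_train))
  list(train = which(patient_ids %in% train_pts),
       test = which(!patient_ids %in% train_pts))
}
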