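# Shared fixtures: a desk-scale network spec and small phantom helpers.

small_net_spec <- function() {
  network_spec(base_channels = 8, n_down_blocks = 3, n_up_blocks = 2,
               disc_n_layers = 2, disc_base_channels = 8)
}

tiny_net_spec <- function() {
  network_spec(base_channels = 4, n_down_blocks = 2, n_up_blocks = 2,
               disc_n_layers = 1, disc_base_channels = 4)
}

tiny_phantom_pair <- function(size = 16, seed = 0) {
  make_phantom_pair(phantom_spec(image_size = size, n_tissue_blobs = 3),
                    seed = seed)
}

radius_map_test <- function(n) {
  cr <- (n + 1) / 2
  r <- seq_len(n) - cr
  sqrt(outer(r^2, r^2, "+"))
}

random_image <- function(H, W, seed) {
  set.seed(seed)
  matrix(runif(H * W), H, W)
}

# memoised desk-scale smoke training run shared by the acceptance tests
smoke_env <- new.env(parent = emptyenv())

smoke_conditions <- function() {
  list(n_pairs = 32, image_size = 64, batch_size = 8, lr = 2e-4,
       n_steps = 200, seed = 0, spec = small_net_spec())
}

get_smoke_run <- function() {
  if (is.null(smoke_env$run)) {
    cond <- smoke_conditions()
    ds <- make_phantom_dataset(cond$n_pairs, phantom_spec(), seed = cond$seed)
    pairs <- lapply(ds, `[[`, "pair")
    ckdir <- file.path(tempdir(), "medfusion-smoke")
    dir.create(ckdir, showWarnings = FALSE)
    cfg <- train_config(learning_rate = cond$lr, batch_size = cond$batch_size,
                        n_steps = cond$n_steps, seed = cond$seed,
                        checkpoint_every = 100, checkpoint_dir = ckdir)
    run <- train(pairs, net_spec = cond$spec, cfg = cfg)
    smoke_env$run <- list(run = run, pairs = pairs, cfg = cfg,
                          ckdir = ckdir, cond = cond)
  }
  smoke_env$run
}

ema_smooth <- function(v, alpha = 0.1) {
  s <- numeric(length(v)); s[1] <- v[1]
  for (i in 2:length(v)) s[i] <- alpha * v[i] + (1 - alpha) * s[i - 1]
  s
}
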