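#' beta-VAE configuration
#'
#' Hyperparameters of the variational autoencoder. The defaults are the
#' published operating point: 256 latent variables, five strided convolutional
#' layers in the encoder and five transposed-convolutional layers in the
#' decoder (total 12 layers counting the two dense heads), beta = 9, learning
#' rate 1e-4 and batch size 128.
#'
#' @param n_latent latent dimension (default 256).
#' @param channels channel widths of the five encoder convolutions (decoder
#'   mirrors them); default `c(32, 64, 128, 256, 256)`, i.e. doubling from 32.
#' @param beta KL weight (>= 0).
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param leaky_slope negative slope of the leaky-ReLU nonlinearity.
#' @param seed RNG seed governing initialization, shuffling and sampling.
#' @return a `vae_config` list.
#' @export
vae_config <- function(n_latent = 256L, channels = c(32L, 64L, 128L, 256L, 256L),
                       beta = 9, learning_rate = 1e-4, batch_size = 128L,
                       epochs = 20L, leaky_slope = 0.2, seed = 1L) {
  stopifnot(n_latent >= 1, beta >= 0, length(channels) == 5)
  structure(list(n_latent = as.integer(n_latent), channels = as.integer(channels),
                 encoder_conv_layers = 5L, decoder_deconv_layers = 5L,
                 total_layers = 12L, beta = beta, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 leaky_slope = leaky_slope, seed = as.integer(seed)),
            class = "vae_config")
}

#' Build a beta-VAE for grid frames
#'
#' Constructs the encoder (five stride-2, kernel-4 convolutions with leaky-ReLU
#' followed by dense heads for the posterior mean and log-variance) and the
#' mirrored decoder (dense layer, five stride-2 transposed convolutions, linear
#' output). The two hemispheres enter as input channels. The grid side must be
#' divisible by 2^5 = 32 so the five stride-2 stages reach a 1x1-compatible
#' spatial size.
#'
#' @param config a [vae_config()].
#' @param grid_shape c(H, W) of the input grids.
#' @param valid optional H x W x 2 validity mask; invalid cells are excluded
#'   from the reconstruction loss.
#' @return an object of class `vae_model`.
#' @export
build_vae <- function(config, grid_shape = c(32L, 32L), valid = NULL) {
  stopifnot(inherits(config, "vae_config"))
  H <- as.integer(grid_shape[1]); W <- as.integer(grid_shape[2])
  if (H %% 32L != 0L || W %% 32L != 0L)
    stop_dim(paste0("build_vae: grid %dx%d not divisible by 32; pad to %dx%d"),
             H, W, 32L * ceiling(H / 32), 32L * ceiling(W / 32))
  ch <- c(2L, config$channels)
  plans <- vector("list", 5L)
  h <- H; w <- W
  for (l in 1:5) {
    plans[[l]] <- make_conv_plan(h, w, ch[l])
    h <- plans[[l]]$H_out; w <- plans[[l]]$W_out
  }
  D_enc <- h * w * ch[6]
  L <- config$n_latent
  params <- with_seed(config$seed, {
    p <- list()
    for (l in 1:5) {
      fan_in <- plans[[l]]$kk
      p[[paste0("Wc", l)]] <- matrix(rnorm(fan_in * ch[l + 1], 0,
                                           sqrt(2 / fan_in)), fan_in, ch[l + 1])
      p[[paste0("bc", l)]] <- numeric(ch[l + 1])
    }
    p$W_mu <- matrix(rnorm(D_enc * L, 0, sqrt(1 / D_enc)), D_enc, L)
    p$b_mu <- numeric(L)
    p$W_lv <- matrix(rnorm(D_enc * L, 0, sqrt(1 / D_enc)), D_enc, L)
    p$b_lv <- numeric(L)
    p$W_dec <- matrix(rnorm(L * D_enc, 0, sqrt(1 / L)), L, D_enc)
    p$b_dec <- numeric(D_enc)
    for (l in 5:1) {
      fan_in <- plans[[l]]$kk
      # deconv l maps channels ch[l+1] (small side) -> ch[l] (big side);
      # with stride 2 each output cell receives (k/2)^2 taps of ch[l+1]
      # channels, so He-style init uses that effective fan-in
      eff_fan <- (plans[[l]]$k / 2)^2 * ch[l + 1]
      p[[paste0("Wd", l)]] <- matrix(rnorm(fan_in * ch[l + 1], 0,
                                           sqrt(2 / eff_fan)),
                                     fan_in, ch[l + 1])
      p[[paste0("bd", l)]] <- numeric(ch[l])
    }
    p
  })
  # deconv weight rows must address kk = k*k*C_big of the plan whose C_in is
  # ch[l]; plans[[l]]$kk == k^2 * ch[l] already, consistent.
  mask <- if (is.null(valid)) rep(TRUE, H * W * 2) else valid_to_batch(valid)
  structure(list(config = config, grid_shape = c(H, W), plans = plans,
                 channels = ch, D_enc = D_enc, params = params,
                 mask = as.numeric(mask)),
            class = "vae_model")
}

#' @exportS3Method base::print
print.vae_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<vae_model> grid %dx%dx2 -> %d latents  (beta=%g, %s parameters)\n",
              x$grid_shape[1], x$grid_shape[2], x$config$n_latent,
              x$config$beta, format(np, big.mark = ",")))
  invisible(x)
}

## encoder forward pass; returns mu, logvar and (optionally) the caches needed
## for backprop
vae_encode_forward <- function(model, X, keep_cache = FALSE) {
  a <- model$config$leaky_slope
  Z <- X
  caches <- if (keep_cache) vector("list", 5L) else NULL
  for (l in 1:5) {
    cf <- conv_forward(Z, model$plans[[l]], model$params[[paste0("Wc", l)]],
                       model$params[[paste0("bc", l)]])
    if (keep_cache) caches[[l]] <- list(Xc = cf$Xc, pre = cf$out, Z_in = NULL)
    Z <- lrelu(cf$out, a)
  }
  mu <- sweep(Z %*% model$params$W_mu, 2, model$params$b_mu, "+")
  lv <- sweep(Z %*% model$params$W_lv, 2, model$params$b_lv, "+")
  lv <- pmin(pmax(lv, -8), 4)  # keep sigma in a sane range (0.018 .. 7.4)
  list(mu = mu, logvar = lv, h_top = Z, caches = caches)
}

## decoder forward; z is n x L
vae_decode_forward <- function(model, z, keep_cache = FALSE) {
  a <- model$config$leaky_slope
  pre_d <- sweep(z %*% model$params$W_dec, 2, model$params$b_dec, "+")
  Zc <- lrelu(pre_d, a)
  caches <- if (keep_cache) vector("list", 5L) else NULL
  Z <- Zc
  for (l in 5:1) {
    df <- deconv_forward(Z, model$plans[[l]], model$params[[paste0("Wd", l)]],
                         model$params[[paste0("bd", l)]])
    if (keep_cache) caches[[l]] <- list(Zr = df$Zr, pre = df$out)
    Z <- if (l > 1) lrelu(df$out, a) else df$out  # final layer linear
  }
  list(xhat = Z, pre_dense = pre_d, h_dense = Zc, caches = caches)
}

#' beta-VAE loss for one frame
#'
#' `||x - x_rec||^2 + beta * sum_d 0.5 * (mu_d^2 + sigma_d^2 - ln sigma_d^2 - 1)`.
#' The KL term is zero iff mu = 0 and sigma = 1.
#'
#' @param x,x_rec numeric vectors/matrices of equal shape (original and
#'   reconstructed frame).
#' @param mu,sigma posterior mean and sd per latent (sigma > 0).
#' @param beta KL weight.
#' @return scalar loss (>= 0).
#' @export
vae_loss <- function(x, x_rec, mu, sigma, beta = 9) {
  if (!all(is.finite(x)) || !all(is.finite(x_rec)) || !all(is.finite(mu)) ||
      !all(is.finite(sigma)))
    stop("vae_loss: non-finite inputs", call. = FALSE)
  if (length(x) != length(x_rec))
    stop_dim("vae_loss: x and x_rec differ in length (%d vs %d)",
             length(x), length(x_rec))
  if (any(sigma <= 0)) stop("vae_loss: sigma must be positive", call. = FALSE)
  rec <- sum((x - x_rec)^2)
  kl <- 0.5 * sum(mu^2 + sigma^2 - log(sigma^2) - 1)
  rec + beta * kl
}

## full forward + backward for a minibatch; returns loss and gradients
vae_batch_grad <- function(model, X, eps_noise, beta) {
  n <- nrow(X)
  a <- model$config$leaky_slope
  mask <- model$mask
  enc <- vae_encode_forward(model, X, keep_cache = TRUE)
  mu <- enc$mu; lv <- enc$logvar
  sig <- exp(0.5 * lv)
  z <- mu + sig * eps_noise
  dec <- vae_decode_forward(model, z, keep_cache = TRUE)
  xhat <- dec$xhat
  diffm <- sweep(xhat - X, 2, mask, "*")
  rec <- sum(diffm^2) / n
  kl <- 0.5 * sum(mu^2 + sig^2 - lv - 1) / n
  loss <- rec + beta * kl

  g <- list()
  ## --- decoder backward ---
  dZ <- 2 * diffm / n                          # d loss / d xhat
  for (l in 1:5) {
    if (l > 1) dZ <- dZ * lrelu_grad(dec$caches[[l]]$pre, a)
    bk <- deconv_backward(dZ, dec$caches[[l]]$Zr, model$plans[[l]],
                          model$params[[paste0("Wd", l)]])
    g[[paste0("Wd", l)]] <- bk$dW
    g[[paste0("bd", l)]] <- bk$db
    dZ <- bk$dZ
  }
  dZc <- dZ * lrelu_grad(dec$pre_dense, a)
  g$W_dec <- crossprod(z, dZc)
  g$b_dec <- colSums(dZc)
  dz <- tcrossprod(dZc, model$params$W_dec)    # n x L
  ## --- KL gradients + reparameterization ---
  dmu <- beta * mu / n + dz
  dlv <- beta * 0.5 * (sig^2 - 1) / n + dz * eps_noise * sig * 0.5
  ## clamp grad through the logvar clamp
  dlv[lv <= -8 | lv >= 4] <- 0
  h_top <- enc$h_top
  g$W_mu <- crossprod(h_top, dmu); g$b_mu <- colSums(dmu)
  g$W_lv <- crossprod(h_top, dlv); g$b_lv <- colSums(dlv)
  dH <- tcrossprod(dmu, model$params$W_mu) + tcrossprod(dlv, model$params$W_lv)
  ## --- encoder backward ---
  for (l in 5:1) {
    dPre <- dH * lrelu_grad(enc$caches[[l]]$pre, a)
    bk <- conv_backward(dPre, enc$caches[[l]]$Xc, n, model$plans[[l]],
                        model$params[[paste0("Wc", l)]])
    g[[paste0("Wc", l)]] <- bk$dW
    g[[paste0("bc", l)]] <- bk$db
    dH <- bk$dZ
  }
  list(loss = loss, rec = rec, kl = kl, grads = g)
}

#' Train a beta-VAE
#'
#' Minimises the masked reconstruction error plus the beta-weighted KL
#' divergence with Adam, using reparameterized sampling of the latent during
#' training. Shuffling, sampling and initialization are all governed by the
#' config seed. With `epochs = 0` the parameters are returned unchanged.
#'
#' @param model a `vae_model` from [build_vae()].
#' @param frames training frames: a `grid_sequence` or an n x D batch matrix
#'   (see [to_grid()]).
#' @param epochs,batch_size,learning_rate optional overrides of the config.
#' @param kl_warmup_epochs KL warm-up: the KL weight ramps linearly from 0 to
#'   beta over this many epochs (default a quarter of the epochs), the
#'   standard guard against posterior collapse; the reported loss curve always
#'   uses the full beta objective.
#' @param clip_norm global gradient-norm clip (default 10; `Inf` disables).
#' @param verbose print per-epoch losses.
#' @return the trained `vae_model`, with a `loss_curve` data.frame
#'   (epoch, loss, recon, kl) attached, where `loss = recon + beta * kl`.
#' @export
train_vae <- function(model, frames, epochs = NULL, batch_size = NULL,
                      learning_rate = NULL, kl_warmup_epochs = NULL,
                      clip_norm = 3000, lr_schedule = c("constant", "onecycle"),
                      verbose = FALSE) {
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(inherits(model, "vae_model"))
  X <- if (inherits(frames, "grid_sequence")) grid_to_batch(frames) else frames
  if (nrow(X) == 0) stop("train_vae: empty dataset", call. = FALSE)
  if (ncol(X) != model$grid_shape[1] * model$grid_shape[2] * 2)
    stop_dim("train_vae: frames have %d cells, model expects %d",
             ncol(X), model$grid_shape[1] * model$grid_shape[2] * 2)
  cfg <- model$config
  epochs <- epochs %||% cfg$epochs
  bs <- batch_size %||% cfg$batch_size
  lr <- learning_rate %||% cfg$learning_rate
  if (epochs == 0) {
    model$loss_curve <- data.frame(epoch = integer(0), loss = numeric(0),
                                   recon = numeric(0), kl = numeric(0))
    return(model)
  }
  warmup <- kl_warmup_epochs %||% ceiling(epochs / 4)
  n <- nrow(X); L <- cfg$n_latent
  opt <- adam_init(model$params)
  curve <- matrix(0, epochs, 3)
  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(epochs)) {
      beta_ep <- cfg$beta * if (warmup > 0) min(1, ep / warmup) else 1
      lr_ep <- if (lr_schedule == "onecycle") {
        # ramp to 2.5x the base rate over the first 15% of epochs, then cosine
        # decay to 5% of it (limited-budget "one cycle" recipe)
        up <- max(1, round(0.15 * epochs))
        if (ep <= up) lr * (1 + 1.5 * ep / up)
        else {
          frac <- (ep - up) / max(1, epochs - up)
          peak <- 2.5 * lr
          0.05 * lr + (peak - 0.05 * lr) * 0.5 * (1 + cos(pi * frac))
        }
      } else lr
      ord <- sample.int(n)
      tot <- c(0, 0, 0); nb <- 0
      for (start in seq(1, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1, n)]
        xb <- X[idx, , drop = FALSE]
        eps <- matrix(rnorm(length(idx) * L), length(idx), L)
        bg <- vae_batch_grad(model, xb, eps, beta_ep)
        if (is.finite(clip_norm)) {
          gn <- sqrt(sum(vapply(bg$grads, function(g) sum(g^2), numeric(1))))
          if (gn > clip_norm)
            bg$grads <- lapply(bg$grads, function(g) g * (clip_norm / gn))
        }
        st <- adam_step(model$params, bg$grads, opt, lr_ep)
        model$params <- st$params; opt <- st$state
        tot <- tot + c(bg$rec + cfg$beta * bg$kl, bg$rec, bg$kl); nb <- nb + 1
      }
      curve[ep, ] <- tot / nb
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  recon %.4f  kl %.4f",
                        ep, curve[ep, 1], curve[ep, 2], curve[ep, 3]))
    }
  })
  model$loss_curve <- data.frame(epoch = seq_len(epochs), loss = curve[, 1],
                                 recon = curve[, 2], kl = curve[, 3])
  model
}

#' Encode grid frames to latent timeseries
#'
#' Deterministic inference: returns the posterior means `mu` (no sampling) and
#' sds `sigma` of each frame, as an `n_latent x T` latent timeseries.
#'
#' @param model a `vae_model`.
#' @param grids a `grid_sequence` or n x D batch matrix.
#' @param subject_id,session_id,age_weeks metadata carried on the result.
#' @param chunk frames encoded per forward pass (memory control).
#' @return an object of class `latent_ts` with fields `mu` (L x T), `sigma`
#'   (L x T) and the metadata.
#' @export
encode <- function(model, grids, subject_id = NA_character_,
                   session_id = NA_character_, age_weeks = NA_real_,
                   chunk = 512L) {
  stopifnot(inherits(model, "vae_model"))
  X <- if (inherits(grids, "grid_sequence")) grid_to_batch(grids) else grids
  if (ncol(X) != model$grid_shape[1] * model$grid_shape[2] * 2)
    stop_dim("encode: frames have %d cells, model expects %d",
             ncol(X), model$grid_shape[1] * model$grid_shape[2] * 2)
  n <- nrow(X); L <- model$config$n_latent
  mu <- matrix(0, n, L); lv <- matrix(0, n, L)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    enc <- vae_encode_forward(model, X[idx, , drop = FALSE])
    mu[idx, ] <- enc$mu; lv[idx, ] <- enc$logvar
  }
  latent_ts(mu = t(mu), sigma = t(exp(0.5 * lv)), subject_id = subject_id,
            session_id = session_id, age_weeks = age_weeks)
}

#' Latent timeseries container
#'
#' @param mu L x T matrix of posterior means.
#' @param sigma L x T matrix of posterior sds (> 0).
#' @param subject_id,session_id,age_weeks metadata.
#' @return an object of class `latent_ts`.
#' @export
latent_ts <- function(mu, sigma = NULL, subject_id = NA_character_,
                      session_id = NA_character_, age_weeks = NA_real_) {
  mu <- as.matrix(mu)
  if (!all(is.finite(mu))) stop("latent_ts: non-finite mu", call. = FALSE)
  if (!is.null(sigma)) {
    sigma <- as.matrix(sigma)
    if (any(sigma <= 0) || !all(is.finite(sigma)))
      stop("latent_ts: sigma must be positive and finite", call. = FALSE)
  }
  structure(list(mu = mu, sigma = sigma, subject_id = subject_id,
                 session_id = session_id, age_weeks = age_weeks),
            class = "latent_ts")
}

#' @exportS3Method base::print
print.latent_ts <- function(x, ...) {
  cat(sprintf("<latent_ts> %s/%s  L=%d  T=%d\n", x$subject_id, x$session_id,
              nrow(x$mu), ncol(x$mu)))
  invisible(x)
}

#' Decode latent vectors to grid frames
#'
#' Deterministic mapping from latent space back to two-channel grids.
#'
#' @param model a `vae_model`.
#' @param z an `n_latent` vector or `n_latent x n` matrix (one column per
#'   frame).
#' @param chunk frames decoded per forward pass.
#' @return a `grid_sequence` with n frames.
#' @export
decode <- function(model, z, chunk = 512L) {
  stopifnot(inherits(model, "vae_model"))
  if (is.null(dim(z))) z <- matrix(z, ncol = 1)
  if (nrow(z) != model$config$n_latent)
    stop_dim("decode: latent dimension %d, model expects %d",
             nrow(z), model$config$n_latent)
  zb <- t(z)
  n <- nrow(zb)
  out <- matrix(0, n, model$grid_shape[1] * model$grid_shape[2] * 2)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    out[idx, ] <- vae_decode_forward(model, zb[idx, , drop = FALSE])$xhat
  }
  batch_to_grid(out, model$grid_shape[1], model$grid_shape[2])
}

#' Save / load a VAE checkpoint
#'
#' The checkpoint stores weights, config, mask and loss curve; save, load and
#' [encode()] reproduce latent means bit-exactly.
#'
#' @param model a `vae_model`.
#' @param path file path.
#' @return `path` (save) or the restored `vae_model` (load).
#' @export
save_vae <- function(model, path) {
  stopifnot(inherits(model, "vae_model"))
  saveRDS(model[c("config", "grid_shape", "channels", "D_enc", "params",
                  "mask", "loss_curve")], path)
  invisible(path)
}

#' @rdname save_vae
#' @export
load_vae <- function(path) {
  obj <- readRDS(path)
  model <- build_vae(obj$config, obj$grid_shape)
  model$params <- obj$params
  model$mask <- obj$mask
  model$loss_curve <- obj$loss_curve
  model
}
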