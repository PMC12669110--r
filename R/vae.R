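# Self-supervised variational autoencoder for B-scans.
#
# The encoder maps a flattened scan to a diagonal-Gaussian posterior
# (mu, log sigma^2) of dimension `latent_dim`; the decoder maps a latent draw
# back to the image. Training minimizes L = L_MSE + beta * L_KL with the
# nonnegative Gaussian KL summed over latent dimensions and a linear KL
# annealing ramp for beta. Layers are fully connected (ReLU encoder,
# leaky-ReLU decoder, sigmoid output), trained by hand-derived
# backpropagation with Adam; inference uses the posterior mean, so all
# downstream features are deterministic.

#' VAE configuration
#'
#' @param latent_dim Latent dimension D.
#' @param arch `"conv"` (default): stride-2 3x3 convolutional encoder and
#'   nearest-neighbour-resize + conv decoder, the architecture whose latent
#'   directions stay spatially local; `"dense"`: fully connected layers.
#' @param conv_channels Output channels of the encoder conv layers (the
#'   decoder mirrors them); trimmed to `floor(log2(min(image dim)))` layers
#'   when the image is too small for the full stack.
#' @param hidden_dims Encoder hidden widths (decoder mirrors them); dense
#'   architecture only.
#' @param epochs Total training epochs.
#' @param beta_start,beta_max KL weight at epoch 0 and its plateau.
#' @param anneal_epochs Epochs over which beta ramps linearly to `beta_max`.
#' @param batch_size Minibatch size.
#' @param learning_rate,weight_decay Adam step size and L2 penalty.
#' @param leaky_slope Negative-side slope of the decoder activation.
#' @param split Train/validation/test proportions for [train_vae()].
#' @param seed Seed controlling initialization, the data split, shuffling and
#'   reparameterization noise.
#' @return A `vae_config` list.
#' @export
vae_config <- function(latent_dim = 128, arch = c("conv", "dense"),
                       conv_channels = c(16, 32, 64, 128, 128, 128),
                       hidden_dims = c(256, 128),
                       epochs = 100, beta_start = 0.001, beta_max = 0.01,
                       anneal_epochs = 20, batch_size = 64,
                       learning_rate = 1e-3, weight_decay = 0,
                       leaky_slope = 0.2, split = c(6, 2, 2) / 10,
                       seed = 1L) {
  arch <- match.arg(arch)
  if (beta_start <= 0 || beta_start > beta_max) {
    abort("need 0 < beta_start <= beta_max")
  }
  if (anneal_epochs > epochs) abort("anneal_epochs must be <= epochs")
  stopifnot(length(split) == 3, abs(sum(split) - 1) < 1e-8)
  structure(list(latent_dim = as.integer(latent_dim), arch = arch,
                 conv_channels = as.integer(conv_channels),
                 hidden_dims = as.integer(hidden_dims),
                 epochs = as.integer(epochs), beta_start = beta_start,
                 beta_max = beta_max, anneal_epochs = as.integer(anneal_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 leaky_slope = leaky_slope, split = split,
                 seed = as.integer(seed)),
            class = "vae_config")
}

#' KL annealing schedule
#'
#' Linear ramp from `beta_start` at epoch 0 to `beta_max` at
#' `anneal_epochs`, clamped thereafter; nondecreasing in `epoch`.
#'
#' @param epoch Epoch index (0-based), >= 0.
#' @param config A [vae_config()].
#' @return The KL weight beta.
#' @export
#' @examples
#' kl_anneal_weight(c(0, 10, 20, 80), vae_config())
kl_anneal_weight <- function(epoch, config = vae_config()) {
  stopifnot(all(epoch >= 0))
  # exact at the plateau so the clamp is not subject to rounding
  ifelse(epoch >= config$anneal_epochs, config$beta_max,
         config$beta_start + (config$beta_max - config$beta_start) *
           epoch / config$anneal_epochs)
}

#' Composite VAE loss
#'
#' `mse` is the squared reconstruction error per sample: the pixel-wise
#' squared difference summed over the image and averaged over the batch
#' (`1/N sum_i ||x_i - xhat_i||^2` with `N` the number of samples). Summing
#' rather than averaging over pixels keeps the reconstruction term on the
#' scale at which KL weights in the 0.001-0.01 range are meaningful; with a
#' per-pixel mean the KL term dominates by the pixel count and the posterior
#' collapses. `kl` is the Gaussian KL to the standard-normal prior, summed
#' over latent dimensions and averaged over the batch, in its nonnegative
#' form `sum_d 0.5 (sigma_d^2 + mu_d^2 - 1 - log sigma_d^2)`;
#' `total = mse + beta * kl`.
#'
#' @param x,xhat Original and reconstructed images (same shape; vectors,
#'   matrices, or n x P batches).
#' @param mean,logvar Posterior mean and log-variance (vectors for one image,
#'   n x D matrices for a batch).
#' @param beta KL weight.
#' @return A `loss_breakdown` tibble row: `total`, `mse`, `kl`, `beta`.
#' @export
#' @examples
#' vae_loss(0, 0, mean = c(1, 0), logvar = c(0, 0), beta = 0.01)
vae_loss <- function(x, xhat, mean, logvar, beta) {
  if (!identical(dim(x), dim(xhat)) || length(x) != length(xhat)) {
    abort("x and xhat must have the same shape")
  }
  if (is.null(dim(mean))) mean <- matrix(mean, nrow = 1)
  if (is.null(dim(logvar))) logvar <- matrix(logvar, nrow = 1)
  n <- nrow(mean)
  mse <- sum((as.numeric(x) - as.numeric(xhat))^2) / n
  kl_per <- 0.5 * rowSums(exp(logvar) + mean^2 - 1 - logvar)
  kl <- base::mean(kl_per)
  tibble::tibble(total = mse + beta * kl, mse = mse, kl = kl, beta = beta)
}

relu <- function(x) x * (x > 0)
lrelu <- function(x, a) x * (x > 0) + a * x * (x <= 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

he_init <- function(fan_in, fan_out) {
  matrix(rnorm(fan_in * fan_out, 0, sqrt(2 / fan_in)), fan_in, fan_out)
}

init_vae_params <- function(input_dim, config) {
  H <- config$hidden_dims
  D <- config$latent_dim
  enc_dims <- c(input_dim, H)
  dec_dims <- c(D, rev(H), input_dim)
  p <- list(We = list(), be = list(), Wd = list(), bd = list())
  for (l in seq_len(length(enc_dims) - 1)) {
    p$We[[l]] <- he_init(enc_dims[l], enc_dims[l + 1])
    p$be[[l]] <- numeric(enc_dims[l + 1])
  }
  last <- enc_dims[length(enc_dims)]
  p$Wm <- he_init(last, D) * 0.1
  p$bm <- numeric(D)
  p$Wv <- he_init(last, D) * 0.1
  p$bv <- numeric(D)
  for (l in seq_len(length(dec_dims) - 1)) {
    p$Wd[[l]] <- he_init(dec_dims[l], dec_dims[l + 1])
    p$bd[[l]] <- numeric(dec_dims[l + 1])
  }
  p
}

add_bias <- function(A, b) sweep(A, 2, b, `+`)

# --- convolutional architecture -------------------------------------------

# number of stride-2 layers the image supports, and the trimmed channel plan
conv_plan <- function(image_dim, config) {
  max_layers <- floor(log2(min(image_dim)))
  ch <- config$conv_channels[seq_len(min(length(config$conv_channels),
                                          max_layers))]
  L <- length(ch)
  if (any(image_dim %% (2^L) != 0)) {
    abort("image dimensions must be divisible by 2^n_conv_layers")
  }
  list(channels = ch, L = L,
       top = c(image_dim[1] / 2^L, image_dim[2] / 2^L))
}

conv_arch <- function(image_dim, config) {
  plan <- conv_plan(image_dim, config)
  list(H = as.integer(image_dim[1]), W = as.integer(image_dim[2]),
       D = config$latent_dim, enc_channels = as.integer(plan$channels),
       leaky = config$leaky_slope)
}

init_conv_params <- function(image_dim, config) {
  plan <- conv_plan(image_dim, config)
  ch <- plan$channels
  L <- plan$L
  D <- config$latent_dim
  conv_w <- function(cin, cout) {
    matrix(rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))), 9 * cin, cout)
  }
  enc <- purrr::map(seq_len(L), function(l) {
    cin <- if (l == 1) 1L else ch[l - 1]
    list(W = conv_w(cin, ch[l]), b = numeric(ch[l]))
  })
  f_top <- prod(plan$top) * ch[L]
  # decoder channel taper: mirror of the encoder, ending at a small width
  # before the 1-channel output conv
  cout_seq <- c(rev(ch)[-1], max(8L, ch[1] %/% 2))
  dec <- purrr::map(seq_len(L), function(l) {
    cin <- if (l == 1) ch[L] else cout_seq[l - 1]
    list(W = conv_w(cin, cout_seq[l]), b = numeric(cout_seq[l]))
  })
  list(enc = enc,
       Wm = he_init(f_top, D) * 0.1, bm = numeric(D),
       Wv = he_init(f_top, D) * 0.1, bv = numeric(D),
       U0 = he_init(D, f_top), c0 = numeric(f_top),
       dec = dec,
       out = list(W = conv_w(cout_seq[L], 1L), b = numeric(1)))
}

# add L2 decay to a gradient list matching the parameter structure
add_weight_decay <- function(g, p, wd) {
  if (wd <= 0) return(g)
  walk <- function(g, p) {
    if (is.list(g)) return(purrr::map2(g, p, walk))
    if (is.matrix(g)) g + wd * p else g  # decay weights, not biases
  }
  walk(g, p)
}

vae_forward <- function(p, X, config, eps = NULL) {
  nl <- length(p$We)
  H <- vector("list", nl)
  A <- X
  for (l in seq_len(nl)) {
    Z <- add_bias(A %*% p$We[[l]], p$be[[l]])
    A <- relu(Z)
    H[[l]] <- A
  }
  Mu <- add_bias(A %*% p$Wm, p$bm)
  Lv <- clamp(add_bias(A %*% p$Wv, p$bv), -10, 10)
  if (is.null(eps)) eps <- matrix(0, nrow(Mu), ncol(Mu))
  Zlat <- Mu + exp(Lv / 2) * eps

  a <- config$leaky_slope
  nd <- length(p$Wd)
  G <- vector("list", nd)
  Ag <- Zlat
  for (l in seq_len(nd - 1)) {
    Zd <- add_bias(Ag %*% p$Wd[[l]], p$bd[[l]])
    Ag <- lrelu(Zd, a)
    G[[l]] <- Ag
  }
  Po <- add_bias(Ag %*% p$Wd[[nd]], p$bd[[nd]])
  Xhat <- sigmoid(Po)
  list(H = H, Mu = Mu, Lv = Lv, eps = eps, Z = Zlat, G = G, Xhat = Xhat)
}

vae_backward <- function(p, X, fw, beta, config) {
  n <- nrow(X)
  a <- config$leaky_slope
  g <- list(We = list(), be = list(), Wd = list(), bd = list())

  dPo <- (2 / n) * (fw$Xhat - X) * fw$Xhat * (1 - fw$Xhat)
  nd <- length(p$Wd)
  Ag_prev <- if (nd > 1) fw$G[[nd - 1]] else fw$Z
  g$Wd[[nd]] <- crossprod(Ag_prev, dPo)
  g$bd[[nd]] <- colSums(dPo)
  dA <- dPo %*% t(p$Wd[[nd]])
  for (l in rev(seq_len(nd - 1))) {
    Gl <- fw$G[[l]]
    dZ <- dA * ifelse(Gl > 0, 1, a)
    Ag_prev <- if (l > 1) fw$G[[l - 1]] else fw$Z
    g$Wd[[l]] <- crossprod(Ag_prev, dZ)
    g$bd[[l]] <- colSums(dZ)
    dA <- dZ %*% t(p$Wd[[l]])
  }
  dZlat <- dA

  # clamp mask for logvar gradient
  lv_active <- fw$Lv > -10 & fw$Lv < 10
  dMu <- dZlat + beta * fw$Mu / n
  dLv <- (dZlat * fw$eps * 0.5 * exp(fw$Lv / 2) +
            beta * 0.5 * (exp(fw$Lv) - 1) / n) * lv_active

  nl <- length(p$We)
  Hlast <- fw$H[[nl]]
  g$Wm <- crossprod(Hlast, dMu)
  g$bm <- colSums(dMu)
  g$Wv <- crossprod(Hlast, dLv)
  g$bv <- colSums(dLv)
  dA <- dMu %*% t(p$Wm) + dLv %*% t(p$Wv)
  for (l in rev(seq_len(nl))) {
    Hl <- fw$H[[l]]
    dZ <- dA * (Hl > 0)
    A_prev <- if (l > 1) fw$H[[l - 1]] else X
    g$We[[l]] <- crossprod(A_prev, dZ)
    g$be[[l]] <- colSums(dZ)
    if (l > 1) dA <- dZ %*% t(p$We[[l]])
  }
  if (config$weight_decay > 0) {
    wd <- config$weight_decay
    for (l in seq_along(g$We)) g$We[[l]] <- g$We[[l]] + wd * p$We[[l]]
    for (l in seq_along(g$Wd)) g$Wd[[l]] <- g$Wd[[l]] + wd * p$Wd[[l]]
    g$Wm <- g$Wm + wd * p$Wm
    g$Wv <- g$Wv + wd * p$Wv
  }
  g
}

# Adam over the nested parameter list.
adam_init <- function(p) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(m = zero_like(p), v = zero_like(p), t = 0)
}

adam_step <- function(p, g, st, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- purrr::pmap(list(p, g, m, v), upd)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mh <- m / (1 - b1^st$t)
    vh <- v / (1 - b2^st$t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  out <- upd(p, g, st$m, st$v)
  list(p = out$p, state = list(m = out$m, v = out$v, t = st$t))
}

# Coerce images (n x H x W array, list of matrices, single matrix, or n x P
# matrix) to an n x P matrix plus the image dimensions.
images_to_matrix <- function(images, image_dim = NULL) {
  if (is.array(images) && length(dim(images)) == 3) {
    d <- dim(images)
    X <- matrix(images, d[1], d[2] * d[3])
    return(list(X = X, image_dim = d[2:3]))
  }
  if (is.list(images)) {
    image_dim <- dim(images[[1]])
    X <- t(vapply(images, as.numeric, numeric(prod(image_dim))))
    return(list(X = X, image_dim = image_dim))
  }
  if (is.matrix(images)) {
    if (!is.null(image_dim)) {
      if (all(dim(images) == image_dim)) {      # one H x W image
        return(list(X = matrix(as.numeric(images), 1), image_dim = image_dim))
      }
      if (ncol(images) == prod(image_dim)) {    # n x P batch
        return(list(X = images, image_dim = image_dim))
      }
      abort("matrix shape matches neither one image nor an n x P batch")
    }
    return(list(X = matrix(as.numeric(images), 1), image_dim = dim(images)))
  }
  abort("unsupported image container")
}

#' Initialize an untrained VAE
#'
#' Seeded parameter initialization without any fitting; useful for shape and
#' determinism contracts and as the starting point [train_vae()] uses.
#'
#' @param image_dim `c(height, width)` of the scans the model will consume.
#' @param config A [vae_config()].
#' @return An `oct_vae` with empty loss log.
#' @export
init_vae <- function(image_dim, config = vae_config()) {
  set.seed(config$seed)
  input_dim <- prod(image_dim)
  params <- if (config$arch == "conv") {
    init_conv_params(image_dim, config)
  } else {
    init_vae_params(input_dim, config)
  }
  structure(list(params = params, config = config,
                 image_dim = as.integer(image_dim), input_dim = input_dim,
                 split = list(train = integer(), val = integer(),
                              test = integer()),
                 loss_log = tibble::tibble()),
            class = "oct_vae")
}

#' Train a VAE on a set of B-scans
#'
#' Images are split into train/validation/test sets by seeded permutation
#' (default 6:2:2); training uses reparameterized sampling and the annealed KL
#' weight from [kl_anneal_weight()], and logs one `loss_breakdown` row per
#' epoch (training averages plus deterministic validation losses). Fully
#' deterministic under `config$seed`.
#'
#' @param images An n x H x W array or list of H x W matrices.
#' @param config A [vae_config()].
#' @param init_weights Optional parameter list from a previously trained model
#'   (warm start, e.g. initializing one eye's model from the other's).
#' @return An `oct_vae`: parameters, config, `image_dim`, split indices and
#'   `loss_log` tibble.
#' @export
train_vae <- function(images, config = vae_config(), init_weights = NULL) {
  im <- images_to_matrix(images)
  X <- im$X
  n <- nrow(X)
  if (n < 3) abort("need at least 3 images to split train/val/test")
  set.seed(config$seed)
  perm <- sample.int(n)
  n_tr <- max(1L, floor(config$split[1] * n))
  n_va <- max(1L, floor(config$split[2] * n))
  idx_tr <- perm[seq_len(n_tr)]
  idx_va <- perm[n_tr + seq_len(min(n_va, n - n_tr))]
  idx_te <- setdiff(perm, c(idx_tr, idx_va))
  if (length(idx_tr) == 0) abort("empty training set")

  conv <- config$arch == "conv"
  arch <- if (conv) conv_arch(im$image_dim, config)
  p <- if (!is.null(init_weights)) {
    init_weights
  } else if (conv) {
    init_conv_params(im$image_dim, config)
  } else {
    init_vae_params(ncol(X), config)
  }
  st <- adam_init(p)
  Xtr <- X[idx_tr, , drop = FALSE]
  Xva <- X[idx_va, , drop = FALSE]
  log <- vector("list", config$epochs)

  step_fn <- if (conv) {
    function(p, Xb, eps, beta) {
      out <- cvae_step_cpp(t(Xb), p, arch, t(eps), beta)
      list(mse = out$mse, kl = out$kl,
           grads = add_weight_decay(out$grads, p, config$weight_decay))
    }
  } else {
    function(p, Xb, eps, beta) {
      fw <- vae_forward(p, Xb, config, eps = eps)
      ls <- vae_loss(Xb, fw$Xhat, fw$Mu, fw$Lv, beta)
      list(mse = ls$mse, kl = ls$kl,
           grads = vae_backward(p, Xb, fw, beta, config))
    }
  }
  val_fn <- if (conv) {
    function(p, Xv, beta) {
      enc <- cvae_encode_cpp(t(Xv), p, arch)
      Xhat <- t(cvae_decode_cpp(enc$Mu, p, arch))
      vae_loss(Xv, Xhat, t(enc$Mu), t(enc$Lv), beta)
    }
  } else {
    function(p, Xv, beta) {
      fwv <- vae_forward(p, Xv, config)  # eps = 0: posterior mean
      vae_loss(Xv, fwv$Xhat, fwv$Mu, fwv$Lv, beta)
    }
  }

  for (ep in seq_len(config$epochs)) {
    beta <- kl_anneal_weight(ep - 1L, config)
    ord <- sample.int(nrow(Xtr))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    tr_tot <- tr_mse <- tr_kl <- 0
    for (b in batches) {
      Xb <- Xtr[b, , drop = FALSE]
      eps <- matrix(rnorm(length(b) * config$latent_dim),
                    length(b), config$latent_dim)
      ls <- step_fn(p, Xb, eps, beta)
      stp <- adam_step(p, ls$grads, st, config$learning_rate)
      p <- stp$p
      st <- stp$state
      wgt <- length(b) / nrow(Xtr)
      tr_tot <- tr_tot + (ls$mse + beta * ls$kl) * wgt
      tr_mse <- tr_mse + ls$mse * wgt
      tr_kl <- tr_kl + ls$kl * wgt
    }
    if (nrow(Xva)) {
      lv <- val_fn(p, Xva, beta)
    } else {
      lv <- tibble::tibble(total = NA_real_, mse = NA_real_, kl = NA_real_)
    }
    log[[ep]] <- tibble::tibble(epoch = ep, beta = beta, mse = tr_mse,
                                kl = tr_kl, total = tr_tot,
                                val_mse = lv$mse, val_kl = lv$kl,
                                val_total = lv$total)
  }
  structure(list(params = p, config = config, image_dim = im$image_dim,
                 input_dim = ncol(X),
                 split = list(train = idx_tr, val = idx_va, test = idx_te),
                 loss_log = dplyr::bind_rows(log)),
            class = "oct_vae")
}

#' @export
print.oct_vae <- function(x, ...) {
  cat(sprintf("<oct_vae> %dx%d px -> D=%d, %d epochs (final val total %.5f)\n",
              x$image_dim[1], x$image_dim[2], x$config$latent_dim,
              x$config$epochs,
              x$loss_log$val_total[nrow(x$loss_log)]))
  invisible(x)
}

check_input_dim <- function(model, X) {
  if (ncol(X) != model$input_dim) {
    abort(sprintf("input has %d pixels; model expects %d (%dx%d)", ncol(X),
                  model$input_dim, model$image_dim[1], model$image_dim[2]))
  }
}

#' Encode images to latent posteriors
#'
#' Deterministic: no sampling is involved, only the posterior parameters are
#' returned.
#'
#' @param model A trained `oct_vae`.
#' @param images A single H x W matrix, an n x H x W array, or a list of
#'   matrices.
#' @return For one image, a list with numeric vectors `mean` and `logvar`
#'   (length D); for a batch, n x D matrices.
#' @export
vae_encode <- function(model, images) {
  im <- images_to_matrix(images, image_dim = model$image_dim)
  check_input_dim(model, im$X)
  if (model$config$arch == "conv") {
    enc <- cvae_encode_cpp(t(im$X), model$params,
                           conv_arch(model$image_dim, model$config))
    Mu <- t(enc$Mu)
    Lv <- t(enc$Lv)
  } else {
    fw <- vae_forward(model$params, im$X, model$config)
    Mu <- fw$Mu
    Lv <- fw$Lv
  }
  if (nrow(im$X) == 1) {
    list(mean = as.numeric(Mu), logvar = as.numeric(Lv))
  } else {
    list(mean = Mu, logvar = Lv)
  }
}

#' Decode latent vectors to images
#'
#' @param model A trained `oct_vae`.
#' @param z A length-D vector or an n x D matrix.
#' @return An H x W image matrix (vector input) or an n x H x W array.
#' @export
vae_decode <- function(model, z) {
  single <- is.null(dim(z))
  if (single) z <- matrix(z, 1)
  if (ncol(z) != model$config$latent_dim) {
    abort(sprintf("z has length %d; latent dimension is %d", ncol(z),
                  model$config$latent_dim))
  }
  if (model$config$arch == "conv") {
    Xhat <- t(cvae_decode_cpp(t(z), model$params,
                              conv_arch(model$image_dim, model$config)))
  } else {
    p <- model$params
    a <- model$config$leaky_slope
    Ag <- z
    nd <- length(p$Wd)
    for (l in seq_len(nd - 1)) {
      Ag <- lrelu(add_bias(Ag %*% p$Wd[[l]], p$bd[[l]]), a)
    }
    Xhat <- sigmoid(add_bias(Ag %*% p$Wd[[nd]], p$bd[[nd]]))
  }
  h <- model$image_dim[1]
  w <- model$image_dim[2]
  if (single) matrix(Xhat, h, w) else array(Xhat, c(nrow(z), h, w))
}

#' Reconstruct images through the posterior mean
#'
#' `vae_reconstruct(m, x)` is `vae_decode(m, vae_encode(m, x)$mean)`.
#'
#' @inheritParams vae_encode
#' @return Same shape as the input image(s).
#' @export
vae_reconstruct <- function(model, images) {
  vae_decode(model, vae_encode(model, images)$mean)
}

#' Per-eye latent representation of a volume
#'
#' Aggregates the per-scan posterior means into one length-D vector per
#' volume. The default uses all B-scans (mean over scans); `"central"` uses
#' only the central slice; `"subset"` averages over `slices`.
#'
#' @param model A trained `oct_vae`.
#' @param volume An `oct_volume`.
#' @param mode Aggregation mode.
#' @param slices Scan indices for `mode = "subset"`.
#' @return Numeric vector of length D.
#' @export
extract_eye_latent <- function(model, volume,
                               mode = c("all", "central", "subset"),
                               slices = NULL) {
  mode <- match.arg(mode)
  n <- dim(volume$bscans)[1]
  idx <- switch(mode,
                all = seq_len(n),
                central = ceiling(n / 2),
                subset = {
                  if (is.null(slices)) abort("mode 'subset' needs `slices`")
                  stopifnot(all(slices >= 1), all(slices <= n))
                  slices
                })
  mu <- vae_encode(model, volume$bscans[idx, , , drop = FALSE])$mean
  if (is.null(dim(mu))) mu else colMeans(mu)
}

#' Latent feature table for one eye across a cohort
#'
#' @param model Trained `oct_vae` for that eye.
#' @param cohort An `oct_cohort`.
#' @param eye `"L"` or `"R"`.
#' @param subject_ids Restrict to these subjects (default: all with that eye).
#' @inheritParams extract_eye_latent
#' @return Tibble `subject_id` plus columns `zl000...` / `zr000...`.
#' @export
cohort_latents <- function(model, cohort, eye = c("L", "R"),
                           subject_ids = NULL, mode = "all", slices = NULL) {
  eye <- match.arg(eye)
  vols <- cohort$volumes[cohort$volumes$eye == eye, ]
  if (!is.null(subject_ids)) {
    vols <- vols[vols$subject_id %in% subject_ids, ]
  }
  prefix <- if (eye == "L") "zl" else "zr"
  D <- model$config$latent_dim
  Z <- t(vapply(vols$volume, function(v)
    extract_eye_latent(model, v, mode = mode, slices = slices), numeric(D)))
  colnames(Z) <- sprintf("%s%03d", prefix, seq_len(D) - 1)
  dplyr::bind_cols(tibble::tibble(subject_id = vols$subject_id),
                   tibble::as_tibble(Z))
}

#' @export
tidy.oct_vae <- function(x, ...) x$loss_log

#' @export
glance.oct_vae <- function(x, ...) {
  last <- x$loss_log[nrow(x$loss_log), ]
  tibble::tibble(epochs = x$config$epochs, latent_dim = x$config$latent_dim,
                 n_train = length(x$split$train), n_val = length(x$split$val),
                 n_test = length(x$split$test),
                 train_total = last$total, train_mse = last$mse,
                 train_kl = last$kl, val_total = last$val_total,
                 val_mse = last$val_mse)
}

#' @export
autoplot.oct_vae <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$loss_log[, c("epoch", "mse", "kl", "val_mse", "val_kl")],
    -"epoch", names_to = "component", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "loss (log scale)",
                  title = "VAE training curves")
}

#' Save / load a trained VAE
#'
#' The checkpoint is the serialized parameter list; a JSON sidecar
#' (`<path>.json`) records the configuration and a hash of the parameters.
#'
#' @param model An `oct_vae`.
#' @param path Checkpoint path.
#' @return `path` (write) or the model (read).
#' @export
write_vae <- function(model, path) {
  saveRDS(unclass(model), path)
  sidecar <- list(config = unclass(model$config),
                  image_dim = model$image_dim,
                  param_hash = object_hash(model$params))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_vae
#' @export
read_vae <- function(path) {
  m <- readRDS(path)
  m$config <- structure(m$config, class = "vae_config")
  structure(m, class = "oct_vae")
}
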