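test_that("the KL annealing ramp hits its endpoints and midpoint", {
  cfg <- vae_config()
  expect_equal(kl_anneal_weight(0, cfg), 0.001)
  expect_equal(kl_anneal_weight(20, cfg), 0.01)
  expect_equal(kl_anneal_weight(50, cfg), 0.01)
  expect_equal(kl_anneal_weight(10, cfg), 0.0055)
  # nondecreasing and clamped over the whole schedule
  trace <- kl_anneal_weight(0:120, cfg)
  expect_true(all(diff(trace) >= 0))
  expect_true(all(trace <= cfg$beta_max & trace >= cfg$beta_start))
})

test_that("the loss vanishes at perfect reconstruction under the prior", {
  l <- vae_loss(matrix(0.5, 4, 4), matrix(0.5, 4, 4),
                mean = numeric(2), logvar = numeric(2), beta = 0.01)
  expect_equal(l$total, 0)
  expect_equal(l$mse, 0)
  expect_equal(l$kl, 0)
})

test_that("kl matches the closed-form Gaussian divergence", {
  # mu = (1, 0), sigma^2 = (1, 1): KL = 1/2 mu^2 = 0.5
  for (beta in c(0.001, 0.01, 1)) {
    l <- vae_loss(1, 1, mean = c(1, 0), logvar = c(0, 0), beta = beta)
    expect_equal(l$kl, 0.5)
    expect_equal(l$total, 0.5 * beta)
  }
  # general case against the textbook formula
  set.seed(4)
  mu <- rnorm(5)
  lv <- rnorm(5, 0, 0.5)
  l <- vae_loss(0, 0, mu, lv, beta = 1)
  expect_equal(l$kl, sum(0.5 * (exp(lv) + mu^2 - 1 - lv)))
})

test_that("mse equals a brute-force per-pixel loop", {
  set.seed(11)
  x <- matrix(runif(64), 8, 8)
  xh <- matrix(runif(64), 8, 8)
  acc <- 0
  for (i in 1:8) for (j in 1:8) acc <- acc + (x[i, j] - xh[i, j])^2
  l <- vae_loss(x, xh, numeric(3), numeric(3), beta = 0.01)
  expect_equal(l$mse, acc)  # one sample: the summed per-pixel squared error
  # a two-sample batch averages the per-sample sums
  xb <- rbind(as.numeric(x), as.numeric(x))
  xhb <- rbind(as.numeric(xh), as.numeric(x))
  lb <- vae_loss(xb, xhb, matrix(0, 2, 3), matrix(0, 2, 3), beta = 0.01)
  expect_equal(lb$mse, acc / 2)
  expect_error(vae_loss(x, xh[1:4, ], numeric(3), numeric(3), 0.1), "shape")
})

test_that("kl is nonnegative with equality only at the prior", {
  set.seed(12)
  for (i in 1:25) {
    mu <- rnorm(4)
    lv <- rnorm(4)
    l <- vae_loss(0, 0, mu, lv, beta = 1)
    expect_gte(l$kl, 0)
    expect_equal(l$total, l$mse + 1 * l$kl)
    if (l$kl == 0) expect_true(all(mu == 0) && all(lv == 0))
  }
  expect_equal(vae_loss(0, 0, numeric(4), numeric(4), 1)$kl, 0)
})

test_that("convolutional step gradients match finite differences", {
  set.seed(1)
  cfg <- vae_config(latent_dim = 3, arch = "conv", conv_channels = c(2, 3),
                    epochs = 1, anneal_epochs = 1, seed = 1)
  m <- init_vae(c(8, 8), cfg)
  arch <- octcvd:::conv_arch(c(8, 8), cfg)
  p <- m$params
  X <- matrix(runif(2 * 64), 2, 64)
  eps <- matrix(rnorm(2 * 3), 2, 3)
  beta <- 0.005
  step <- octcvd:::cvae_step_cpp(t(X), p, arch, t(eps), beta)
  loss_of <- function(pp) {
    s <- octcvd:::cvae_step_cpp(t(X), pp, arch, t(eps), beta)
    s$mse + beta * s$kl
  }
  base <- loss_of(p)
  assign_in <- function(pl, path, val) {
    if (!length(path)) return(val)
    pl[[path[[1]]]] <- assign_in(pl[[path[[1]]]], path[-1], val)
    pl
  }
  get_in <- function(pl, path) { for (k in path) pl <- pl[[k]]; pl }
  paths <- list(list("enc", 1L, "W"), list("enc", 2L, "b"), list("Wm"),
                list("Wv"), list("U0"), list("c0"), list("dec", 1L, "W"),
                list("dec", 2L, "W"), list("out", "W"), list("out", "b"))
  for (path in paths) {
    g <- get_in(step$grads, path)
    target <- get_in(p, path)
    for (i in sample(length(target), min(2, length(target)))) {
      h <- 1e-6
      tmp <- target
      tmp[i] <- tmp[i] + h
      num <- (loss_of(assign_in(p, path, tmp)) - base) / h
      expect_equal(g[i], num, tolerance = 1e-4,
                   label = paste(unlist(path), collapse = "$"))
    }
  }
})

test_that("encode/decode respect shapes and are deterministic at inference", {
  m <- fresh_vae(c(32, 32), latent_dim = 16, hidden_dims = c(32, 16))
  img <- blob_image(32)
  z <- vae_encode(m, img)
  expect_length(z$mean, 16)
  expect_length(z$logvar, 16)
  expect_true(all(is.finite(c(z$mean, z$logvar))))
  d1 <- vae_decode(m, z$mean)
  d2 <- vae_decode(m, z$mean)
  expect_identical(d1, d2)
  expect_equal(dim(d1), c(32L, 32L))
  r1 <- vae_reconstruct(m, img)
  expect_identical(r1, d1)
  expect_error(vae_encode(m, blob_image(16)), "neither")
  expect_error(vae_decode(m, numeric(7)), "latent dimension")
})

test_that("training logs every epoch, follows the annealing trace, and is seeded", {
  sv <- cached_small_vae()
  m <- sv$model
  expect_equal(nrow(m$loss_log), m$config$epochs)
  expect_equal(m$loss_log$beta,
               kl_anneal_weight(seq_len(m$config$epochs) - 1, m$config))
  expect_true(all(m$loss_log$total >= 0))
  # per-epoch identity total = mse + beta * kl on the validation trace
  expect_equal(m$loss_log$val_total,
               m$loss_log$val_mse + m$loss_log$beta * m$loss_log$val_kl)
  # 6:2:2 split partitions the input
  n <- dim(sv$scans)[1]
  expect_equal(sort(c(m$split$train, m$split$val, m$split$test)), seq_len(n))
  expect_equal(length(m$split$train), floor(0.6 * n))
  # seeded determinism: retraining reproduces the final validation loss
  m2 <- train_vae(sv$scans, m$config)
  expect_identical(m2$loss_log$val_total, m$loss_log$val_total)
})

test_that("training improves reconstruction over an untrained model", {
  sv <- cached_small_vae()
  m <- sv$model
  m0 <- init_vae(c(32, 32), m$config)
  test_imgs <- sv$scans[m$split$test, , , drop = FALSE]
  mse_of <- function(model) {
    r <- vae_reconstruct(model, test_imgs)
    mean((test_imgs - r)^2)
  }
  expect_lt(mse_of(m), mse_of(m0))
})

test_that("warm-started training resumes from the given weights", {
  sv <- cached_small_vae()
  cfg2 <- sv$model$config
  cfg2$epochs <- 2L
  cfg2$anneal_epochs <- 1L
  warm <- train_vae(sv$scans, cfg2, init_weights = sv$model$params)
  cold <- train_vae(sv$scans, cfg2)
  expect_lt(warm$loss_log$val_mse[1], cold$loss_log$val_mse[1])
})

test_that("per-volume latents aggregate per-scan posterior means", {
  sv <- cached_small_vae()
  m <- sv$model
  vol <- sv$cohort$volumes$volume[[1]]
  # brute-force average over all per-slice codes
  n <- dim(vol$bscans)[1]
  per_slice <- sapply(seq_len(n), function(i)
    vae_encode(m, vol$bscans[i, , ])$mean)
  expect_equal(extract_eye_latent(m, vol), rowMeans(per_slice))
  # central-slice mode encodes scan ceiling(n/2)
  expect_equal(extract_eye_latent(m, vol, mode = "central"),
               per_slice[, ceiling(n / 2)])
  expect_equal(extract_eye_latent(m, vol, mode = "subset", slices = c(1, 3)),
               rowMeans(per_slice[, c(1, 3)]))
  # a volume of identical scans returns the single-scan code
  vol2 <- vol
  for (i in seq_len(n)) vol2$bscans[i, , ] <- vol$bscans[1, , ]
  expect_equal(extract_eye_latent(m, vol2), per_slice[, 1])
})

test_that("latent tables are named by eye and dimension", {
  sv <- cached_small_vae()
  lat <- cohort_latents(sv$model, sv$cohort, "L")
  expect_equal(names(lat)[2], "zl000")
  expect_equal(ncol(lat), 1 + sv$model$config$latent_dim)
  expect_equal(nrow(lat), sum(sv$cohort$volumes$eye == "L"))
  latR <- cohort_latents(sv$model, sv$cohort, "R",
                         subject_ids = sv$cohort$subjects$subject_id[1:3])
  expect_equal(nrow(latR), 3)
  expect_equal(names(latR)[2], "zr000")
})

test_that("checkpoints round-trip with a JSON sidecar", {
  sv <- cached_small_vae()
  path <- withr::local_tempfile(fileext = ".vae")
  write_vae(sv$model, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_vae(path)
  img <- sv$scans[1, , ]
  expect_identical(vae_reconstruct(back, img), vae_reconstruct(sv$model, img))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$config$latent_dim, sv$model$config$latent_dim)
})

test_that("tidy/glance/autoplot expose the training history", {
  sv <- cached_small_vae()
  td <- tidy(sv$model)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), sv$model$config$epochs)
  gl <- glance(sv$model)
  expect_equal(gl$latent_dim, sv$model$config$latent_dim)
  p <- autoplot(sv$model)
  expect_s3_class(p, "ggplot")
})
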