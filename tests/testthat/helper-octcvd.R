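# Shared fixture builders; everything is generated in code at test time.

tiny_phantom <- function(..., seed = 1L) {
  phantom_config(image_height = 32, image_width = 32, n_bscans = 2,
                 speckle_level = 0.1, seed = seed, ...)
}

# a noiseless flat-band scan configuration (no texture: exact constant bands)
flat_phantom <- function(...) {
  phantom_config(image_height = 32, image_width = 32, n_bscans = 1,
                 speckle_level = 0, undulation_amp = 0, choroid_texture = 0,
                 ...)
}

# smooth Gaussian blob, optionally shifted by (dr, dc) pixels
blob_image <- function(n = 32, dr = 0, dc = 0, sigma2 = 20) {
  outer(seq_len(n), seq_len(n), function(r, c)
    exp(-((r - n / 2 - dr)^2 + (c - n / 2 - dc)^2) / sigma2))
}

# an untrained VAE for shape/determinism contracts (no fitting needed)
fresh_vae <- function(image_dim = c(32, 32), ...) {
  init_vae(image_dim, vae_config(...))
}

# small trained VAE on clean phantoms, cached per test run
cached_small_vae <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- phantom_config(image_height = 32, image_width = 32, n_bscans = 4,
                            speckle_level = 0.05, seed = 404)
      coh <- generate_cohort(4, 12, cfg)
      X <- octcvd:::stack_scans(coh$volumes$volume[coh$volumes$eye == "L"])
      vc <- vae_config(latent_dim = 8, conv_channels = c(8, 16, 32),
                       epochs = 10, anneal_epochs = 5, batch_size = 32,
                       seed = 7)
      cache <<- list(model = train_vae(X, vc), cohort = coh, scans = X)
    }
    cache
  }
})

# synthetic records with controllable age/sex for matching tests
fake_records <- function(n_cases, n_controls, age_case = NULL,
                         age_control = NULL, sex = "M", seed = 1) {
  set.seed(seed)
  n <- n_cases + n_controls
  tibble::tibble(
    subject_id = sprintf("S%04d", seq_len(n)),
    cvd_label = c(rep("CVD+", n_cases), rep("CVD-", n_controls)),
    age = c(age_case %||% rnorm(n_cases, 60, 6),
            age_control %||% rnorm(n_controls, 60, 6)),
    sex = rep_len(sex, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a stand-in classifier whose predictions ride along as an attribute of the
# feature table; lets evaluation be tested against hand-chosen probabilities
registerS3method("predict", "prob_carrier",
                 function(object, newdata, ...) attr(newdata, "probs"),
                 envir = asNamespace("stats"))
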