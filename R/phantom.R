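# Synthetic OCT phantom generator.
#
# Phantoms are stacks of horizontal-band B-scans: 11 named retinal boundaries
# (ILM down to the lower choroidal boundary) delimit 10 tissue bands, each with
# its own reflectivity, undulated by a few low-frequency sinusoids and
# corrupted by multiplicative gamma speckle. A cardiovascular-disease signal is
# planted only in choroidal thickness (optionally with inner-layer thinning),
# giving downstream representation learning and explainability a known,
# recoverable target.

BOUNDARY_NAMES <- c("ILM", "RNFL", "GCL", "IPL", "INL", "OPL", "BMEIS",
                    "IB_OPR", "IB_RPE", "OB_RPE", "CHOROID_LOWER")

#' Default retinal layer specification
#'
#' One row per named boundary, ordered top to bottom. `mean_thickness` of a row
#' is the thickness (pixels) of the band ending at that boundary: the `ILM` row
#' is the vitreous gap between the image top and the inner limiting membrane
#' (its reflectivity is unused), and the `CHOROID_LOWER` row is the choroidal
#' band between the outer RPE boundary (`OB_RPE`) and the choroid/sclera
#' interface. Thicknesses are defined at a 128-pixel image height and scaled
#' linearly to `image_height`.
#'
#' @param image_height Image height in pixels the thicknesses are scaled to.
#' @return A tibble with columns `name`, `mean_thickness`, `thickness_sd`,
#'   `reflectivity`.
#' @export
#' @examples
#' layer_specs(64)
layer_specs <- function(image_height = 128) {
  stopifnot(image_height >= 16)
  # totals leave a bottom margin so the choroid-sclera interface stays inside
  # the frame even for thick (CVD+) choroids; a clipped lower boundary would
  # hide exactly the planted signal
  base <- tibble::tibble(
    name = BOUNDARY_NAMES,
    mean_thickness = c(14, 8, 10, 8, 8, 7, 12, 4, 4, 4, 24),
    thickness_sd   = c(2, 1.2, 1.5, 1.2, 1.2, 1, 1.8, 0.6, 0.6, 0.6, 3.5),
    # tissue bands sit mostly above the quality index's tau_hi so that noise
    # (speckle or additive) drains signal mass downward and degrades the QI,
    # as it does in real scans
    reflectivity   = c(0, 0.9, 0.6, 0.7, 0.55, 0.65, 0.45, 0.8, 0.85, 0.95, 0.6)
  )
  s <- image_height / 128
  base$mean_thickness <- base$mean_thickness * s
  base$thickness_sd <- base$thickness_sd * s
  base
}

validate_layers <- function(layers) {
  stopifnot(is.data.frame(layers))
  if (!identical(layers$name, BOUNDARY_NAMES)) {
    abort("`layers` must contain exactly the 11 named boundaries in order.")
  }
  if (any(layers$mean_thickness <= 0)) abort("layer thicknesses must be > 0")
  if (any(layers$reflectivity < 0 | layers$reflectivity > 1)) {
    abort("reflectivity must lie in [0, 1]")
  }
  invisible(layers)
}

#' Phantom generator configuration
#'
#' @param image_height,image_width B-scan size in pixels.
#' @param n_bscans Number of B-scans per macular volume (128 emulates the
#'   acquisition protocol of the device class modelled here).
#' @param speckle_level Multiplicative speckle strength; the gamma speckle
#'   field has unit mean and standard deviation `speckle_level` at scan
#'   quality 1. 0 disables noise.
#' @param choroid_effect Signed fractional change of mean choroidal thickness
#'   in CVD+ subjects relative to CVD− (the planted disease signal);
#'   `abs(choroid_effect) < 1`.
#' @param quality_mean_left,quality_mean_right Mean per-scan quality factors;
#'   speckle scales as `speckle_level / quality`, so the left eye is cleaner by
#'   default, mirroring acquisition-order quality differences in real cohorts.
#' @param quality_sd Between-scan standard deviation of the quality factor.
#' @param inter_eye_cor Correlation of the subject-level band-thickness latent
#'   between the two eyes (same anatomy, imaged twice).
#' @param undulation_amp Amplitude (pixels) of the smooth sinusoidal boundary
#'   undulation; 0 gives perfectly flat bands.
#' @param undulation_waves Maximum number of sinusoidal components (<= 3).
#' @param scan_jitter Per-scan thickness jitter, as a fraction of each band's
#'   `thickness_sd`.
#' @param rnfl_gcl_thinning If `TRUE`, additionally thins RNFL and GCL bands in
#'   CVD+ subjects by half the choroid effect (off by default so the planted
#'   signal is purely choroidal).
#' @param bg_reflectivity Background intensity above the ILM and below the
#'   choroid.
#' @param choroid_texture Amplitude of the depth-stratified reflectivity
#'   banding inside the choroid (the vascular sublayers of real choroid:
#'   choriocapillaris, Sattler and Haller zones). The banding is positioned
#'   at fixed fractional depths of the band, so thickness changes stretch
#'   it — giving optical flow trackable structure throughout the band, as in
#'   real scans. 0 disables it.
#' @param diabetes_rate,cardiomyopathy_rate Prevalence of the comorbidity flags
#'   used by the cohort exclusion rules.
#' @param event_window Event horizon (years) within which CVD+ offsets are
#'   drawn.
#' @param seed Integer seed used by [generate_cohort()].
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(image_height = 128, image_width = 128,
                           n_bscans = 128, speckle_level = 0.2,
                           choroid_effect = 0, quality_mean_left = 1,
                           quality_mean_right = 0.9, quality_sd = 0.12,
                           inter_eye_cor = 0.8, undulation_amp = 2,
                           undulation_waves = 3, scan_jitter = 0.25,
                           rnfl_gcl_thinning = FALSE, bg_reflectivity = 0.02,
                           choroid_texture = 0.25,
                           diabetes_rate = 0.05, cardiomyopathy_rate = 0.02,
                           event_window = 5, seed = 1L) {
  if (n_bscans < 1) abort("n_bscans must be >= 1")
  if (abs(choroid_effect) >= 1) abort("abs(choroid_effect) must be < 1")
  if (speckle_level < 0) abort("speckle_level must be >= 0")
  if (inter_eye_cor < -1 || inter_eye_cor > 1) abort("inter_eye_cor in [-1, 1]")
  structure(
    list(image_height = image_height, image_width = image_width,
         n_bscans = as.integer(n_bscans), speckle_level = speckle_level,
         choroid_effect = choroid_effect,
         quality_mean_left = quality_mean_left,
         quality_mean_right = quality_mean_right, quality_sd = quality_sd,
         inter_eye_cor = inter_eye_cor, undulation_amp = undulation_amp,
         undulation_waves = undulation_waves, scan_jitter = scan_jitter,
         rnfl_gcl_thinning = rnfl_gcl_thinning,
         bg_reflectivity = bg_reflectivity, choroid_texture = choroid_texture,
         diabetes_rate = diabetes_rate,
         cardiomyopathy_rate = cardiomyopathy_rate,
         event_window = event_window, seed = as.integer(seed)),
    class = "phantom_config"
  )
}

# Smooth integer-valued boundary undulation shared by all boundaries of a scan,
# a sum of <= `waves` low-frequency sinusoids with random phase. Draws from the
# current RNG stream.
sample_undulation <- function(width, amp, waves) {
  if (amp <= 0 || waves < 1) return(integer(width))
  x <- seq_len(width) / width
  s <- numeric(width)
  for (w in seq_len(waves)) {
    a <- amp * runif(1, 0.3, 1) / w
    f <- w * runif(1, 0.5, 1.5)
    s <- s + a * sin(2 * pi * (f * x + runif(1)))
  }
  as.integer(round(s))
}

#' Generate a single B-scan phantom
#'
#' Draws band thicknesses (unless supplied), stacks the bands top to bottom
#' with shared sinusoidal undulation, fills each band with its reflectivity and
#' applies multiplicative gamma speckle. Draws from the current RNG stream; set
#' a seed beforehand for reproducibility.
#'
#' @param layers Layer specification, see [layer_specs()].
#' @param config A [phantom_config()].
#' @param thickness Optional named integer vector of band thicknesses (pixels)
#'   overriding random sampling.
#' @param quality Per-scan quality factor; effective speckle is
#'   `speckle_level / quality`.
#' @return A `bscan` object: list with `image` (height x width matrix in
#'   `[0, 1]`), `boundaries` (11 x width integer matrix, row index of each
#'   named boundary per column), `thickness` (named integer vector) and
#'   `quality`.
#' @export
#' @examples
#' set.seed(1)
#' b <- generate_bscan(layer_specs(64), phantom_config(64, 64))
#' dim(b$image)
generate_bscan <- function(layers, config, thickness = NULL, quality = 1) {
  validate_layers(layers)
  h <- config$image_height
  w <- config$image_width
  if (is.null(thickness)) {
    thickness <- pmax(1L, as.integer(round(
      rnorm(nrow(layers), layers$mean_thickness, layers$thickness_sd))))
  }
  thickness <- as.integer(thickness)
  names(thickness) <- layers$name
  # the vitreous gap above the ILM absorbs sampling overflow (the retina sits
  # higher in the frame); a stack that cannot fit even then is a config error
  overflow <- sum(thickness) - h
  if (overflow > 0) thickness["ILM"] <- thickness["ILM"] - overflow
  if (thickness["ILM"] < 1L) {
    abort("layer thicknesses overflow image height; reduce thicknesses or enlarge the image")
  }
  b <- cumsum(thickness)
  s <- sample_undulation(w, config$undulation_amp, config$undulation_waves)
  s <- clamp(s, 1L - b[1], h - b[length(b)])
  boundaries <- outer(b, s, `+`)  # 11 x w
  rownames(boundaries) <- layers$name

  # band index per pixel: number of boundaries at or above each row
  count <- matrix(0L, h, w)
  rows <- matrix(seq_len(h), h, w)
  for (k in seq_len(nrow(boundaries))) {
    count <- count + (rows >= matrix(boundaries[k, ], h, w, byrow = TRUE))
  }
  lookup <- c(config$bg_reflectivity, layers$reflectivity[-1],
              config$bg_reflectivity)
  img <- matrix(lookup[count + 1L], h, w)

  # depth-stratified vascular banding inside the choroid: reflectivity
  # modulated sinusoidally in fractional band depth, so it stretches with
  # thickness
  if (config$choroid_texture > 0) {
    upper <- matrix(boundaries["OB_RPE", ], h, w, byrow = TRUE)
    lower <- matrix(boundaries["CHOROID_LOWER", ], h, w, byrow = TRUE)
    in_band <- rows >= upper & rows < lower
    frac <- (rows - upper) / pmax(lower - upper, 1L)
    mod <- 1 + config$choroid_texture * sin(2 * pi * 2 * frac)
    img[in_band] <- img[in_band] * mod[in_band]
  }

  lvl <- if (quality > 0) config$speckle_level / quality else config$speckle_level
  if (lvl > 0) {
    shape <- 1 / lvl^2
    img <- img * matrix(rgamma(h * w, shape = shape, rate = shape), h, w)
  }
  structure(list(image = clamp(img, 0, 1),
                 boundaries = boundaries,
                 thickness = thickness,
                 quality = quality),
            class = "bscan")
}

# Generate one eye's macular volume given per-eye mean band thicknesses.
generate_volume <- function(layers, config, eye_thickness, quality_mean,
                            subject_id = NA_character_, eye = NA_character_) {
  n <- config$n_bscans
  h <- config$image_height
  w <- config$image_width
  bscans <- array(0, c(n, h, w))
  boundaries <- array(0L, c(n, nrow(layers), w),
                      dimnames = list(NULL, layers$name, NULL))
  thickness <- matrix(0L, n, nrow(layers),
                      dimnames = list(NULL, layers$name))
  quality <- numeric(n)
  for (i in seq_len(n)) {
    th <- pmax(1L, as.integer(round(
      eye_thickness + rnorm(nrow(layers), 0,
                            config$scan_jitter * layers$thickness_sd))))
    q <- clamp(rnorm(1, quality_mean, config$quality_sd), 0.3, 2)
    sc <- generate_bscan(layers, config, thickness = th, quality = q)
    bscans[i, , ] <- sc$image
    boundaries[i, , ] <- sc$boundaries
    thickness[i, ] <- sc$thickness
    quality[i] <- q
  }
  structure(list(bscans = bscans, boundaries = boundaries,
                 thickness = thickness, quality = quality,
                 subject_id = subject_id, eye = eye),
            class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$bscans)
  cat(sprintf("<oct_volume> subject %s eye %s: %d B-scans of %dx%d px\n",
              x$subject_id, x$eye, d[1], d[2], d[3]))
  invisible(x)
}

# Calibration constants for synthetic clinical metadata, per CVD label
# (means/SDs and category frequencies of the modelled cohort).
table1_params <- function(label) {
  shared <- list(age = c(60.78, 6.47), p_female = 0.2974)
  eth_levels <- c("White", "Mixed", "Asian", "Black", "Chinese", "Other")
  if (label == "CVD+") {
    c(shared, list(
      bmi = c(28.31, 4.45), sbp = c(147.26, 19.57), dbp = c(84.75, 10.23),
      hba1c = c(36.52, 4.32),
      alcohol = c(never = 0.0359, previous = 0.0572, current = 0.9069, "NA" = 0),
      ethnicity = setNames(c(0.9018, 0.0426, 0.0393, 0.0033, 0.0016, 0.0115),
                           eth_levels)))
  } else {
    c(shared, list(
      bmi = c(27.43, 4.33), sbp = c(145.1, 18.75), dbp = c(83.22, 9.73),
      hba1c = c(36.59, 6.61),
      alcohol = c(never = 0.0392, previous = 0.0392, current = 0.9183,
                  "NA" = 0.0033),
      ethnicity = setNames(c(0.8922, 0.0425, 0.0441, 0.0082, 0.0049, 0.0082),
                           eth_levels)))
  }
}

sample_categorical <- function(n, probs) {
  names(probs)[1L + findInterval(runif(n), cumsum(probs / sum(probs)),
                                 left.open = TRUE)]
}

#' Generate one synthetic subject: metadata plus both-eye OCT volumes
#'
#' Metadata are drawn from per-label Gaussians/categoricals calibrated to the
#' modelled cohort; the age and sex marginals are identical across labels by
#' construction so matching is testable. Band thicknesses share a subject-level
#' latent between eyes (correlation `inter_eye_cor`); CVD+ subjects have mean
#' choroidal thickness scaled by `1 + choroid_effect`. Draws from the current
#' RNG stream.
#'
#' @inheritParams generate_bscan
#' @param cvd_label `"CVD+"` or `"CVD-"`.
#' @param subject_id Identifier stored in the record and volumes.
#' @param with_volumes If `FALSE`, draw only the metadata record (fast path
#'   for distribution checks); `left`/`right` are `NULL`.
#' @return List with `record` (one-row tibble), `left`, `right`
#'   (`oct_volume`s).
#' @export
generate_subject <- function(cvd_label = c("CVD-", "CVD+"), config,
                             layers = layer_specs(config$image_height),
                             subject_id = "S0001", with_volumes = TRUE) {
  cvd_label <- match.arg(cvd_label)
  p <- table1_params(cvd_label)

  record <- tibble::tibble(
    subject_id = subject_id,
    age = rnorm(1, p$age[1], p$age[2]),
    sex = ifelse(runif(1) < p$p_female, "F", "M"),
    ethnicity = sample_categorical(1, p$ethnicity),
    bmi = rnorm(1, p$bmi[1], p$bmi[2]),
    sbp = rnorm(1, p$sbp[1], p$sbp[2]),
    dbp = rnorm(1, p$dbp[1], p$dbp[2]),
    hba1c = rnorm(1, p$hba1c[1], p$hba1c[2]),
    alcohol = sample_categorical(1, p$alcohol),
    diabetes = runif(1) < config$diabetes_rate,
    cardiomyopathy = runif(1) < config$cardiomyopathy_rate,
    cvd_label = cvd_label,
    event_offset = if (cvd_label == "CVD+")
      config$event_window * runif(1) else NA_real_
  )

  mean_th <- layers$mean_thickness
  names(mean_th) <- layers$name
  if (cvd_label == "CVD+") {
    mean_th["CHOROID_LOWER"] <- mean_th["CHOROID_LOWER"] *
      (1 + config$choroid_effect)
    if (isTRUE(config$rnfl_gcl_thinning)) {
      mean_th[c("RNFL", "GCL")] <- mean_th[c("RNFL", "GCL")] *
        (1 - 0.5 * config$choroid_effect)
    }
  }
  if (!with_volumes) return(list(record = record, left = NULL, right = NULL))
  g <- rnorm(nrow(layers))
  rho <- config$inter_eye_cor
  eyes <- list()
  for (eye in c("L", "R")) {
    e <- rho * g + sqrt(1 - rho^2) * rnorm(nrow(layers))
    eye_th <- mean_th + layers$thickness_sd * e
    qm <- if (eye == "L") config$quality_mean_left else config$quality_mean_right
    eyes[[eye]] <- generate_volume(layers, config, eye_th, qm,
                                   subject_id = subject_id, eye = eye)
  }
  list(record = record, left = eyes$L, right = eyes$R)
}

#' Generate a full synthetic cohort
#'
#' Deterministic under `seed`: records, volumes and ground-truth boundary maps
#' are reproduced bit-identically for the same seed and configuration.
#'
#' @inheritParams generate_subject
#' @param n_cases,n_controls Numbers of CVD+ and CVD− subjects (each >= 1).
#' @param seed Integer seed; defaults to `config$seed`.
#' @return An `oct_cohort`: list with `subjects` (tibble of records),
#'   `volumes` (tibble `subject_id`, `eye`, `volume` list-column), `layers`,
#'   `config`, `seed`.
#' @export
#' @examples
#' coh <- generate_cohort(2, 3, phantom_config(32, 32, n_bscans = 2, seed = 7))
#' coh$subjects$cvd_label
generate_cohort <- function(n_cases, n_controls,
                            config = phantom_config(),
                            layers = layer_specs(config$image_height),
                            seed = config$seed, with_volumes = TRUE) {
  stopifnot(n_cases >= 1, n_controls >= 1)
  set.seed(seed)
  labels <- c(rep("CVD+", n_cases), rep("CVD-", n_controls))
  subjects <- vector("list", length(labels))
  volumes <- vector("list", 2 * length(labels))
  for (i in seq_along(labels)) {
    s <- generate_subject(labels[i], config, layers,
                          subject_id = sprintf("S%04d", i),
                          with_volumes = with_volumes)
    subjects[[i]] <- s$record
    if (with_volumes) {
      volumes[[2 * i - 1]] <- tibble::tibble(
        subject_id = s$record$subject_id, eye = "L", volume = list(s$left))
      volumes[[2 * i]] <- tibble::tibble(
        subject_id = s$record$subject_id, eye = "R", volume = list(s$right))
    }
  }
  structure(list(subjects = dplyr::bind_rows(subjects),
                 volumes = dplyr::bind_rows(volumes),
                 layers = layers, config = config, seed = as.integer(seed)),
            class = "oct_cohort")
}

#' @export
print.oct_cohort <- function(x, ...) {
  cat(sprintf("<oct_cohort> %d subjects (%d CVD+), %d volumes, %d B-scans each\n",
              nrow(x$subjects), sum(x$subjects$cvd_label == "CVD+"),
              nrow(x$volumes), x$config$n_bscans))
  invisible(x)
}

#' Logical mask of a layer band from a ground-truth boundary map
#'
#' @param boundaries 11 x width integer boundary map of one B-scan (as stored
#'   in `oct_volume$boundaries[i, , ]`).
#' @param image_height Height of the scan in pixels.
#' @param band Band name; the band spans from the previous boundary down to
#'   (excluding) the named one, e.g. `"CHOROID_LOWER"` selects the choroid
#'   (`OB_RPE` to `CHOROID_LOWER`).
#' @return `image_height` x width logical matrix.
#' @export
layer_band_mask <- function(boundaries, image_height, band = "CHOROID_LOWER") {
  k <- match(band, rownames(boundaries))
  if (is.na(k)) abort(sprintf("unknown band '%s'", band))
  if (k == 1L) abort("the ILM row is the vitreous gap, not a tissue band")
  w <- ncol(boundaries)
  rows <- matrix(seq_len(image_height), image_height, w)
  upper <- matrix(boundaries[k - 1L, ], image_height, w, byrow = TRUE)
  lower <- matrix(boundaries[k, ], image_height, w, byrow = TRUE)
  rows >= upper & rows < lower
}

#' Export cohort metadata as CSV
#'
#' @param cohort An `oct_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_metadata <- function(cohort, path) {
  write.csv(cohort$subjects, path, row.names = FALSE)
  invisible(path)
}

#' Persist / load a single-eye volume
#'
#' Volumes are stored as a plain serialized list (`bscans`, `boundaries`,
#' `thickness`, `quality`, `subject_id`, `eye`).
#'
#' @param volume An `oct_volume`.
#' @param path File path.
#' @return `path` (write) or the `oct_volume` (read).
#' @export
write_volume <- function(volume, path) {
  saveRDS(unclass(volume), path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  structure(readRDS(path), class = "oct_volume")
}
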