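# Global and local model explanations.
#
# Global: normalized Gini importance per feature and per data channel
# (left-eye latents, right-eye latents, metadata). Local: latent-traversal
# vector fields — perturb the most classifier-important latent dimension
# (z_max) by its population standard deviation (sigma_max), reconstruct, and
# localize the image change with Lucas-Kanade optical flow; an
# occlusion-sensitivity comparator cross-checks the highlighted regions.

#' Normalized feature importance of a fitted forest
#'
#' Mean Gini information gain per feature, normalized to sum to one, with
#' ranks (1 = most important).
#'
#' @param fit An `oct_rf`.
#' @return An `importance_table` tibble: `feature`, `importance`, `rank`.
#' @export
importance_table <- function(fit) {
  imp <- fit$model$variable.importance
  if (is.null(imp)) abort("model was fitted without importance")
  imp <- pmax(imp, 0)
  out <- tibble::tibble(feature = names(imp),
                        importance = unname(imp) / sum(imp))
  out <- dplyr::arrange(out, dplyr::desc(.data$importance), .data$feature)
  out$rank <- seq_len(nrow(out))
  class(out) <- c("importance_table", class(out))
  out
}

latent_channel <- function(feature) {
  dplyr::case_when(grepl("^zl[0-9]+$", feature) ~ "zl",
                   grepl("^zr[0-9]+$", feature) ~ "zr",
                   TRUE ~ "metadata")
}

#' Relative importance per data channel
#'
#' Aggregates feature importances into percentage shares of the left-eye
#' latent (`zl`), right-eye latent (`zr`) and `metadata` channels; shares sum
#' to 100.
#'
#' @param table An [importance_table()].
#' @param channel_map Optional named character vector `feature -> channel`
#'   overriding the prefix-based default; every feature must be mapped.
#' @return Tibble `channel`, `share_pct`.
#' @export
modality_importance <- function(table, channel_map = NULL) {
  if (is.null(channel_map)) {
    ch <- latent_channel(table$feature)
  } else {
    ch <- unname(channel_map[table$feature])
    if (anyNA(ch)) {
      abort(sprintf("unmapped feature(s): %s",
                    paste(table$feature[is.na(ch)], collapse = ", ")))
    }
  }
  dplyr::summarise(dplyr::group_by(tibble::tibble(channel = ch,
                                                  importance = table$importance),
                                   .data$channel),
                   share_pct = 100 * sum(.data$importance), .groups = "drop")
}

#' Most important latent dimension (z_max)
#'
#' The latent feature with the highest forest importance; ties are broken by
#' the lower latent index (left eye before right at equal index).
#'
#' @param table An [importance_table()].
#' @return List with `feature` (e.g. `"zl066"`), `eye` (`"L"`/`"R"`), `index`
#'   (0-based latent dimension) and `importance`.
#' @export
top_latent <- function(table) {
  lat <- table[latent_channel(table$feature) != "metadata", ]
  if (nrow(lat) == 0) abort("model contains no latent features")
  idx <- as.integer(sub("^z[lr]", "", lat$feature))
  eye <- ifelse(grepl("^zl", lat$feature), "L", "R")
  ord <- order(-lat$importance, idx, eye)
  pick <- ord[1]
  list(feature = lat$feature[pick], eye = eye[pick], index = idx[pick],
       importance = lat$importance[pick])
}

#' Population standard deviation of one latent dimension
#'
#' sigma_max: the SD of a latent feature's posterior means over the training
#' population, used as the traversal scale.
#'
#' @param latents Latent tibble (e.g. from [cohort_latents()]), restricted to
#'   the training subjects.
#' @param feature Latent column name, e.g. `"zl066"`.
#' @return Numeric scalar.
#' @export
latent_sd <- function(latents, feature) {
  if (!feature %in% names(latents)) abort(sprintf("no column '%s'", feature))
  sd(latents[[feature]])
}

#' Perturb one latent dimension and reconstruct
#'
#' Encodes the image, multiplies latent dimension `index` by `scale`
#' (sigma_max in the standard traversal; `mode = "additive"` instead adds
#' `scale`), leaves every other dimension unchanged, and decodes both the
#' original and the perturbed latent vector.
#'
#' @param model A trained `oct_vae`.
#' @param image H x W matrix.
#' @param index 0-based latent dimension to perturb.
#' @param scale Positive perturbation scalar.
#' @param mode `"multiplicative"` (default) or `"additive"`.
#' @return List `x_base`, `x_pert` (reconstructions), `z`, `z_pert`.
#' @export
perturb_and_reconstruct <- function(model, image, index, scale,
                                    mode = c("multiplicative", "additive")) {
  mode <- match.arg(mode)
  if (scale <= 0) abort("scale must be positive")
  D <- model$config$latent_dim
  if (index < 0 || index >= D) abort(sprintf("index must be in [0, %d)", D))
  z <- vae_encode(model, image)$mean
  z_pert <- z
  j <- index + 1L
  z_pert[j] <- if (mode == "multiplicative") z[j] * scale else z[j] + scale
  list(x_base = vae_decode(model, z), x_pert = vae_decode(model, z_pert),
       z = z, z_pert = z_pert)
}

# windowed box sums via an integral image (zero padding outside)
box_sum <- function(M, w) {
  r <- (w - 1) %/% 2
  h <- nrow(M)
  wd <- ncol(M)
  S <- matrix(0, h + 1, wd + 1)
  S[-1, -1] <- apply(apply(M, 2, cumsum), 1, cumsum) |> t()
  r1 <- pmax(seq_len(h) - r, 1)
  r2 <- pmin(seq_len(h) + r, h)
  c1 <- pmax(seq_len(wd) - r, 1)
  c2 <- pmin(seq_len(wd) + r, wd)
  S[r2 + 1, c2 + 1, drop = FALSE] - S[r1, c2 + 1, drop = FALSE] -
    S[r2 + 1, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
}

central_diff <- function(M, along = c("col", "row")) {
  along <- match.arg(along)
  h <- nrow(M)
  w <- ncol(M)
  if (along == "col") {
    (M[, c(2:w, w)] - M[, c(1, 1:(w - 1))]) / 2
  } else {
    (M[c(2:h, h), ] - M[c(1, 1:(h - 1)), ]) / 2
  }
}

#' Lucas-Kanade optical flow between two images
#'
#' Single-level dense flow: for every pixel, the optical-flow constraint
#' `Ix u + Iy v + It = 0` is solved in least squares over a square window,
#' with central-difference spatial gradients (averaged over the two frames)
#' and temporal difference `b - a`. Pixels whose 2 x 2 structure tensor has
#' minimum eigenvalue below `lambda_min` are masked invalid (flow set to 0
#' there). `u` is displacement along columns (rightward), `v` along rows
#' (downward), in pixels, estimating the motion from `a` to `b`.
#'
#' @param a,b Same-size single-channel image matrices.
#' @param window Odd window side length.
#' @param lambda_min Structure-tensor eigenvalue threshold.
#' @param levels Pyramid levels; 1 is single-level. With more levels the flow
#'   is first estimated on 2x-downsampled copies and refined by warping, so
#'   displacements well beyond one pixel remain trackable.
#' @return A `flow_field`: list of matrices `u`, `v`, `magnitude`, `valid`.
#' @export
#' @examples
#' f <- lucas_kanade(diag(8), diag(8))
#' all(f$u == 0)
lucas_kanade <- function(a, b, window = 5, lambda_min = 1e-4, levels = 1) {
  if (!all(dim(a) == dim(b))) abort("images must have the same shape")
  if (window > min(dim(a))) abort("window larger than the image")
  if (window %% 2 == 0) abort("window must be odd")
  if (levels > 1 && all(dim(a) %% 2 == 0) && min(dim(a)) >= 2 * window) {
    coarse <- lucas_kanade(downsample2(a), downsample2(b), window,
                           lambda_min, levels - 1)
    u0 <- 2 * upsample2_mat(coarse$u)
    v0 <- 2 * upsample2_mat(coarse$v)
    b_w <- warp_image(b, u0, v0)   # sample b forward: undoes the coarse motion
    fine <- lk_single(a, b_w, window, lambda_min)
    u <- u0 + fine$u
    v <- v0 + fine$v
    valid <- fine$valid
    u[!valid] <- 0
    v[!valid] <- 0
    return(structure(list(u = u, v = v, magnitude = sqrt(u^2 + v^2),
                          valid = valid),
                     class = "flow_field"))
  }
  lk_single(a, b, window, lambda_min)
}

lk_single <- function(a, b, window, lambda_min) {
  avg <- (a + b) / 2
  Ix <- central_diff(avg, "col")
  Iy <- central_diff(avg, "row")
  It <- b - a
  sxx <- box_sum(Ix * Ix, window)
  sxy <- box_sum(Ix * Iy, window)
  syy <- box_sum(Iy * Iy, window)
  sxt <- box_sum(Ix * It, window)
  syt <- box_sum(Iy * It, window)
  tr <- sxx + syy
  disc <- sqrt(pmax((sxx - syy)^2 + 4 * sxy^2, 0))
  eig_min <- (tr - disc) / 2
  valid <- eig_min >= lambda_min
  det <- sxx * syy - sxy^2
  det[!valid] <- 1  # avoid 0/0; overwritten below
  u <- (-sxt * syy + sxy * syt) / det
  v <- (sxy * sxt - sxx * syt) / det
  u[!valid] <- 0
  v[!valid] <- 0
  structure(list(u = u, v = v, magnitude = sqrt(u^2 + v^2), valid = valid),
            class = "flow_field")
}

# 2x box-filter downsample / nearest upsample for the flow pyramid
downsample2 <- function(m) {
  h <- nrow(m) %/% 2
  w <- ncol(m) %/% 2
  (m[2 * seq_len(h) - 1, 2 * seq_len(w) - 1] +
     m[2 * seq_len(h), 2 * seq_len(w) - 1] +
     m[2 * seq_len(h) - 1, 2 * seq_len(w)] +
     m[2 * seq_len(h), 2 * seq_len(w)]) / 4
}

upsample2_mat <- function(m) {
  m[rep(seq_len(nrow(m)), each = 2), rep(seq_len(ncol(m)), each = 2)]
}

# bilinear backward warp: out(r, c) = img(r + dv, c + du), clamped at edges
warp_image <- function(img, du, dv) {
  h <- nrow(img)
  w <- ncol(img)
  rows <- matrix(seq_len(h), h, w) + dv
  cols <- matrix(rep(seq_len(w), each = h), h, w) + du
  rows <- clamp(rows, 1, h)
  cols <- clamp(cols, 1, w)
  r0 <- pmin(floor(rows), h - 1)
  c0 <- pmin(floor(cols), w - 1)
  fr <- rows - r0
  fc <- cols - c0
  idx <- function(r, c) img[cbind(as.numeric(r), as.numeric(c))]
  out <- (1 - fr) * (1 - fc) * idx(r0, c0) + fr * (1 - fc) * idx(r0 + 1, c0) +
    (1 - fr) * fc * idx(r0, c0 + 1) + fr * fc * idx(r0 + 1, c0 + 1)
  matrix(out, h, w)
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("<flow_field> %dx%d px, %.1f%% valid, max |d| = %.3f px\n",
              nrow(x$u), ncol(x$u), 100 * mean(x$valid), max(x$magnitude)))
  invisible(x)
}

#' Latent-traversal vector-field explanation
#'
#' Composes [perturb_and_reconstruct()] and [lucas_kanade()]: the flow is
#' computed between the base and perturbed reconstructions (default) or, if
#' `compare = "original"`, between the original image and the perturbed
#' reconstruction (in which case reconstruction error contributes to the
#' field). The magnitude map is rendered over the original image by
#' [autoplot.vf_explanation()].
#'
#' @inheritParams perturb_and_reconstruct
#' @inheritParams lucas_kanade
#' @param compare Which image pair the flow is computed between.
#' @param levels Flow pyramid levels; the default 3 tracks the multi-pixel
#'   boundary displacements latent traversals produce.
#' @return A `vf_explanation`: list `image`, `x_base`, `x_pert`, `flow`,
#'   `perturbation`.
#' @export
vector_field_explanation <- function(model, image, index, scale,
                                     mode = "multiplicative",
                                     compare = c("reconstructions", "original"),
                                     window = 5, lambda_min = 1e-4,
                                     levels = 3) {
  compare <- match.arg(compare)
  pr <- perturb_and_reconstruct(model, image, index, scale, mode)
  from <- if (compare == "reconstructions") pr$x_base else image
  flow <- lucas_kanade(from, pr$x_pert, window, lambda_min, levels)
  structure(list(image = image, x_base = pr$x_base, x_pert = pr$x_pert,
                 flow = flow,
                 perturbation = list(index = index, scale = scale,
                                     mode = mode, compare = compare)),
            class = "vf_explanation")
}

#' Per-layer summary of a flow field
#'
#' Uses a ground-truth boundary map to average the displacement magnitude
#' inside each tissue band, and reports how strongly the top-decile magnitude
#' pixels concentrate in each band relative to the band's area fraction
#' (`enrichment` = top-decile fraction / area fraction).
#'
#' @param flow A `flow_field` (or `vf_explanation`).
#' @param boundaries 11 x width boundary map of the explained scan.
#' @param image_height Scan height in pixels.
#' @param decile Quantile defining "top" pixels (default top 10 percent).
#' @return Tibble `band`, `mean_magnitude`, `area_fraction`,
#'   `top_decile_fraction`, `enrichment`.
#' @export
flow_layer_summary <- function(flow, boundaries, image_height, decile = 0.9) {
  if (inherits(flow, "vf_explanation")) flow <- flow$flow
  mag <- flow$magnitude
  thr <- quantile(mag, decile)
  top <- mag >= thr
  bands <- rownames(boundaries)[-1]
  purrr::map_dfr(bands, function(bn) {
    mask <- layer_band_mask(boundaries, image_height, bn)
    tibble::tibble(
      band = bn,
      mean_magnitude = mean(mag[mask]),
      area_fraction = mean(mask),
      top_decile_fraction = if (any(top)) mean(mask[top]) else 0,
      enrichment = (if (any(top)) mean(mask[top]) else 0) / mean(mask))
  })
}

#' Pooled per-layer summary over several flow fields
#'
#' Mirrors the study procedure of estimating vector fields for every CVD+
#' test subject: magnitudes from all maps are pooled, the top decile is taken
#' over the pooled values, and band membership uses each map's own boundary
#' map.
#'
#' @param flows List of `flow_field`s (or `vf_explanation`s).
#' @param boundaries_list List of matching 11 x width boundary maps.
#' @param image_height Scan height in pixels.
#' @param decile Quantile defining "top" pixels.
#' @return Tibble as [flow_layer_summary()], pooled over maps.
#' @export
flow_layer_pooled_summary <- function(flows, boundaries_list, image_height,
                                      decile = 0.9) {
  stopifnot(length(flows) == length(boundaries_list), length(flows) >= 1)
  mags <- purrr::map(flows, function(f) {
    if (inherits(f, "vf_explanation")) f <- f$flow
    as.numeric(f$magnitude)
  })
  pooled <- unlist(mags)
  thr <- quantile(pooled, decile)
  bands <- rownames(boundaries_list[[1]])[-1]
  purrr::map_dfr(bands, function(bn) {
    in_band <- unlist(purrr::map(boundaries_list, function(b)
      as.numeric(layer_band_mask(b, image_height, bn))))
    top <- pooled >= thr
    tibble::tibble(
      band = bn,
      mean_magnitude = sum(pooled * in_band) / sum(in_band),
      area_fraction = mean(in_band),
      top_decile_fraction = if (any(top)) mean(in_band[top]) else 0,
      enrichment = (if (any(top)) mean(in_band[top]) else 0) / mean(in_band))
  })
}

#' Occlusion-sensitivity map
#'
#' Slides a mean-intensity patch over the image; at each location the occluded
#' image is re-encoded, the chosen eye's latent features in the classifier's
#' feature row are replaced by the new code, and the saliency is the drop in
#' predicted CVD+ probability. Overlapping patches are averaged; the map is
#' min-max normalized to `[0, 1]` (all-constant maps stay zero).
#'
#' @param image H x W matrix to explain.
#' @param model The eye's trained `oct_vae`.
#' @param fit The `oct_rf` classifier.
#' @param features_row One-row `feature_matrix` for this subject.
#' @param eye Which eye's latent block the image feeds (`"L"` or `"R"`).
#' @param patch Patch side length in pixels.
#' @param stride Patch stride; `stride = patch` tiles each pixel exactly once.
#' @param agg How the volume latent was aggregated (only used to build the
#'   replacement code: the single scan's code is used directly).
#' @return List with `saliency` (H x W in `[0, 1]`), `raw` (unnormalized
#'   probability drops) and `base_prob`.
#' @export
occlusion_explanation <- function(image, model, fit, features_row,
                                  eye = c("L", "R"), patch = 8,
                                  stride = patch, agg = "direct") {
  eye <- match.arg(eye)
  h <- nrow(image)
  w <- ncol(image)
  if (patch > h || patch > w) abort("patch larger than the image")
  prefix <- if (eye == "L") "zl" else "zr"
  zcols <- grep(sprintf("^%s[0-9]+$", prefix), fit$features, value = TRUE)
  if (length(zcols) == 0) {
    abort(sprintf("classifier uses no %s latent features", prefix))
  }
  zidx <- as.integer(sub(prefix, "", zcols)) + 1L

  prob_of <- function(img) {
    z <- vae_encode(model, img)$mean
    row <- features_row
    row[, zcols] <- as.list(z[zidx])
    predict(fit, row)
  }
  base_prob <- prob_of(image)
  fill <- mean(image)
  acc <- matrix(0, h, w)
  cnt <- matrix(0, h, w)
  for (r in seq(1, h - patch + 1, by = stride)) {
    for (c in seq(1, w - patch + 1, by = stride)) {
      occ <- image
      occ[r:(r + patch - 1), c:(c + patch - 1)] <- fill
      drop <- base_prob - prob_of(occ)
      acc[r:(r + patch - 1), c:(c + patch - 1)] <-
        acc[r:(r + patch - 1), c:(c + patch - 1)] + drop
      cnt[r:(r + patch - 1), c:(c + patch - 1)] <-
        cnt[r:(r + patch - 1), c:(c + patch - 1)] + 1
    }
  }
  raw <- ifelse(cnt > 0, acc / pmax(cnt, 1), 0)
  rng <- range(raw)
  saliency <- if (diff(rng) < .Machine$double.eps) {
    matrix(0, h, w)
  } else {
    (raw - rng[1]) / diff(rng)
  }
  list(saliency = saliency, raw = raw, base_prob = base_prob, counts = cnt)
}

#' Vector-field maps for representative B-scans of a volume
#'
#' Batch convenience over [vector_field_explanation()]: by default the first,
#' central and last scans of the volume.
#'
#' @inheritParams vector_field_explanation
#' @param volume An `oct_volume`.
#' @param scans Scan indices to explain.
#' @return Named list of `vf_explanation`s (names `scan_<i>`).
#' @export
vf_batch <- function(model, volume, index, scale, scans = NULL, ...) {
  n <- dim(volume$bscans)[1]
  if (is.null(scans)) scans <- unique(c(1L, ceiling(n / 2), n))
  stopifnot(all(scans >= 1), all(scans <= n))
  out <- purrr::map(scans, function(i)
    vector_field_explanation(model, volume$bscans[i, , ], index, scale, ...))
  names(out) <- paste0("scan_", scans)
  out
}

#' @export
autoplot.flow_field <- function(object, grid = 16, ...) {
  h <- nrow(object$u)
  w <- ncol(object$u)
  df <- expand.grid(row = seq_len(h), col = seq_len(w))
  df$magnitude <- as.numeric(object$magnitude)
  rs <- unique(round(seq(1, h, length.out = grid)))
  cs <- unique(round(seq(1, w, length.out = grid)))
  qv <- expand.grid(row = rs, col = cs)
  qv$u <- object$u[as.matrix(qv[, c("row", "col")])]
  qv$v <- object$v[as.matrix(qv[, c("row", "col")])]
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$magnitude)) +
    ggplot2::geom_segment(data = qv,
                          ggplot2::aes(xend = .data$col + 4 * .data$u,
                                       yend = .data$row + 4 * .data$v),
                          colour = "white", linewidth = 0.2,
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "pt"))) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "|d| (px)")
}

#' @export
autoplot.vf_explanation <- function(object, grid = 16, ...) {
  h <- nrow(object$image)
  w <- ncol(object$image)
  df <- expand.grid(row = seq_len(h), col = seq_len(w))
  df$intensity <- as.numeric(object$image)
  df$magnitude <- as.numeric(object$flow$magnitude)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::geom_raster(data = df[df$magnitude > quantile(df$magnitude, 0.9), ],
                         ggplot2::aes(alpha = .data$magnitude),
                         fill = "orange") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("latent traversal of dim %d (x%.2f)",
                                  object$perturbation$index,
                                  object$perturbation$scale))
}

#' @export
autoplot.importance_table <- function(object, top = 20, ...) {
  df <- head(object, top)
  ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$feature,
                                                  .data$importance),
                                   .data$importance)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "normalized Gini importance")
}
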