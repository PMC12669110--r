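make_importance <- function(features, importance) {
  out <- tibble::tibble(feature = features, importance = importance / sum(importance))
  out <- dplyr::arrange(out, dplyr::desc(importance), feature)
  out$rank <- seq_len(nrow(out))
  class(out) <- c("importance_table", class(out))
  out
}

test_that("importance tables are normalized with permutation ranks", {
  sv <- cached_small_vae()
  lat <- cohort_latents(sv$model, sv$cohort, "L")
  X <- assemble_features(lat, labels = sv$cohort$subjects[, c("subject_id", "cvd_label")],
                         mode = "LE")
  fit <- train_rf(X, grid = data.frame(num_trees = 100, mtry = 2,
                                       min_node_size = 5), seed = 1)
  tab <- importance_table(fit)
  expect_equal(sum(tab$importance), 1)
  expect_setequal(tab$rank, seq_len(nrow(tab)))
  expect_true(all(diff(tab$importance) <= 0))
  shares <- modality_importance(tab)
  expect_equal(sum(shares$share_pct), 100)
})

test_that("modality shares follow the uniform-importance arithmetic", {
  feats <- c(sprintf("zl%03d", 0:127), sprintf("zr%03d", 0:127),
             c("age", "sex", "ethnicity", "bmi", "sbp", "dbp", "hba1c",
               "alcohol"))
  tab <- make_importance(feats, rep(1, 264))
  shares <- modality_importance(tab)
  got <- setNames(shares$share_pct, shares$channel)
  expect_equal(unname(got["zl"]), 100 * 128 / 264, tolerance = 1e-10)
  expect_equal(unname(got["zr"]), 100 * 128 / 264, tolerance = 1e-10)
  expect_equal(unname(got["metadata"]), 100 * 8 / 264, tolerance = 1e-10)
  # degenerate concentration
  tab1 <- make_importance(c("zl005", "zr001", "bmi"), c(1, 0, 0))
  s1 <- modality_importance(tab1)
  expect_equal(s1$share_pct[s1$channel == "zl"], 100)
  # explicit map with a hole errors
  expect_error(modality_importance(tab1, channel_map = c(zl005 = "zl")),
               "unmapped")
})

test_that("z_max selection respects importance and documented tie-breaks", {
  expect_equal(top_latent(make_importance("zl004", 1))$index, 4)
  tab <- make_importance(c("zl003", "zl007", "bmi"), c(2, 2, 5))
  zm <- top_latent(tab)
  expect_equal(zm$index, 3)  # tie at 3 and 7: lowest index wins
  expect_equal(zm$feature, "zl003")
  expect_error(top_latent(make_importance(c("bmi", "age"), c(1, 2))),
               "no latent")
})

test_that("perturbation is local, identity at scale 1, with a brute-force sigma", {
  sv <- cached_small_vae()
  m <- sv$model
  img <- sv$scans[1, , ]
  pr <- perturb_and_reconstruct(m, img, index = 3, scale = 1)
  expect_identical(pr$x_base, pr$x_pert)
  pr2 <- perturb_and_reconstruct(m, img, index = 3, scale = 2.5)
  expect_equal(which(pr2$z_pert != pr2$z), 4)
  expect_equal(pr2$z_pert[4], pr2$z[4] * 2.5)
  pr3 <- perturb_and_reconstruct(m, img, index = 3, scale = 0.5,
                                 mode = "additive")
  expect_equal(pr3$z_pert[4], pr3$z[4] + 0.5)
  expect_error(perturb_and_reconstruct(m, img, index = 3, scale = 0), "positive")
  expect_error(perturb_and_reconstruct(m, img, index = 99, scale = 1), "index")
  # sigma_max: brute-force SD of that component over a latent table
  lat <- cohort_latents(m, sv$cohort, "L")
  manual <- sqrt(sum((lat$zl003 - mean(lat$zl003))^2) / (nrow(lat) - 1))
  expect_equal(latent_sd(lat, "zl003"), manual)
  expect_error(latent_sd(lat, "zl999"), "no column")
})

test_that("identical images give exactly zero flow", {
  img <- blob_image(32)
  fl <- lucas_kanade(img, img)
  expect_true(all(fl$u == 0))
  expect_true(all(fl$v == 0))
  expect_true(all(fl$magnitude == 0))
  expect_true(any(fl$valid))
})

test_that("a one-pixel translation is recovered within tolerance", {
  a <- blob_image(48)
  b <- blob_image(48, dc = 1)  # shifted right by one column
  fl <- lucas_kanade(a, b)
  expect_gt(median(fl$u[fl$valid]), 0.7)
  expect_lt(median(fl$u[fl$valid]), 1.3)
  expect_gt(median(fl$v[fl$valid]), -0.3)
  expect_lt(median(fl$v[fl$valid]), 0.3)
  # downward shift moves v
  d <- blob_image(48, dr = 1)
  fl2 <- lucas_kanade(a, d)
  expect_gt(median(fl2$v[fl2$valid]), 0.7)
  expect_lt(median(abs(fl2$u[fl2$valid])), 0.3)
})

test_that("flow is antisymmetric under frame exchange", {
  a <- blob_image(48)
  b <- blob_image(48, dc = 1)
  fab <- lucas_kanade(a, b)
  fba <- lucas_kanade(b, a)
  shared <- fab$valid & fba$valid
  expect_lt(median(abs(fab$u[shared] + fba$u[shared])), 0.2)
  expect_lt(median(abs(fab$v[shared] + fba$v[shared])), 0.2)
})

test_that("flow rejects bad windows and mismatched shapes", {
  img <- blob_image(16)
  expect_error(lucas_kanade(img, img[1:8, ]), "same shape")
  expect_error(lucas_kanade(img, img, window = 17), "window larger")
  expect_error(lucas_kanade(img, img, window = 4), "odd")
})

test_that("identity perturbation yields an all-zero magnitude map", {
  sv <- cached_small_vae()
  vf <- vector_field_explanation(sv$model, sv$scans[2, , ], index = 1,
                                 scale = 1)
  expect_true(all(vf$flow$magnitude == 0))
  p <- autoplot(vf)
  expect_s3_class(p, "ggplot")
})

test_that("batch explanation emits maps for the first, central and last scans", {
  sv <- cached_small_vae()
  vol <- sv$cohort$volumes$volume[[1]]
  maps <- vf_batch(sv$model, vol, index = 0, scale = 2)
  n <- dim(vol$bscans)[1]
  expect_equal(names(maps),
               paste0("scan_", unique(c(1, ceiling(n / 2), n))))
  expect_s3_class(maps[[1]], "vf_explanation")
})

test_that("layer summaries report magnitude, area and enrichment per band", {
  # constructed flow: all magnitude concentrated in the choroid band
  cfg <- flat_phantom()
  ly <- layer_specs(32)
  set.seed(3)
  b <- generate_bscan(ly, cfg)
  mask <- layer_band_mask(b$boundaries, 32, "CHOROID_LOWER")
  flow <- structure(list(u = matrix(0, 32, 32), v = mask * 1.0,
                         magnitude = mask * 1.0,
                         valid = matrix(TRUE, 32, 32)),
                    class = "flow_field")
  summ <- flow_layer_summary(flow, b$boundaries, 32)
  ch <- summ[summ$band == "CHOROID_LOWER", ]
  expect_equal(ch$area_fraction, mean(mask))
  expect_equal(ch$top_decile_fraction, 1)
  expect_equal(ch$enrichment, 1 / mean(mask))
  expect_true(all(summ$top_decile_fraction[summ$band != "CHOROID_LOWER"] == 0))
})

test_that("occlusion maps are zero for constant inputs and tile exactly", {
  sv <- cached_small_vae()
  lat <- cohort_latents(sv$model, sv$cohort, "L")
  lab <- sv$cohort$subjects[, c("subject_id", "cvd_label")]
  X <- assemble_features(lat, labels = lab, mode = "LE")
  fit <- train_rf(X, grid = data.frame(num_trees = 50, mtry = 2,
                                       min_node_size = 5), seed = 1)
  img <- matrix(0.5, 32, 32)
  # constant image: every occlusion replaces 0.5 by 0.5, so nothing changes
  occ <- occlusion_explanation(img, sv$model, fit, X[1, ], eye = "L",
                               patch = 8, stride = 8)
  expect_true(all(occ$saliency == 0))
  expect_true(all(occ$counts == 1))  # stride = patch tiles exactly once
  occ2 <- occlusion_explanation(sv$scans[1, , ], sv$model, fit, X[1, ],
                                eye = "L", patch = 8, stride = 4)
  expect_true(all(occ2$saliency >= 0 & occ2$saliency <= 1))
  expect_error(occlusion_explanation(img, sv$model, fit, X[1, ], eye = "R",
                                     patch = 8), "no zr")
  expect_error(occlusion_explanation(img, sv$model, fit, X[1, ], patch = 64),
               "patch larger")
})
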