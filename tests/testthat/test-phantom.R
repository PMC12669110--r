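test_that("noise-free flat-band scans are exact reflectivity bands", {
  cfg <- flat_phantom()
  ly <- layer_specs(32)
  set.seed(1)
  b <- generate_bscan(ly, cfg)
  # every row strictly inside a band is constant at that band's reflectivity
  for (k in 2:nrow(ly)) {
    top <- b$boundaries[k - 1, 1]
    bot <- b$boundaries[k, 1]
    if (bot > top) {
      expect_true(all(b$image[top:(bot - 1), ] == ly$reflectivity[k]),
                  label = sprintf("band below %s constant", ly$name[k - 1]))
    }
  }
  expect_true(all(b$image[seq_len(b$boundaries[1, 1] - 1), ] ==
                    cfg$bg_reflectivity))
})

test_that("scan generation is bit-identical under a fixed seed", {
  cfg <- tiny_phantom()
  ly <- layer_specs(32)
  set.seed(99); b1 <- generate_bscan(ly, cfg)
  set.seed(99); b2 <- generate_bscan(ly, cfg)
  expect_identical(b1, b2)
})

test_that("choroid band in the boundary map matches the sampled thickness", {
  cfg <- tiny_phantom()
  ly <- layer_specs(32)
  set.seed(7)
  for (i in 1:5) {
    b <- generate_bscan(ly, cfg)
    # brute force: count rows between the OB_RPE and CHOROID_LOWER boundaries
    # in every column
    counted <- vapply(seq_len(ncol(b$image)), function(c)
      sum(seq_len(nrow(b$image)) >= b$boundaries["OB_RPE", c] &
            seq_len(nrow(b$image)) < b$boundaries["CHOROID_LOWER", c]),
      numeric(1))
    expect_true(all(counted == b$thickness[["CHOROID_LOWER"]]))
  }
})

test_that("impossible layer stacks raise a configuration error", {
  cfg <- flat_phantom()
  ly <- layer_specs(32)
  ly$mean_thickness <- ly$mean_thickness * 10
  set.seed(1)
  expect_error(generate_bscan(ly, cfg), "overflow")
})

test_that("generated metadata is calibrated to the modelled cohort", {
  cfg <- tiny_phantom()
  set.seed(123)
  recs <- dplyr::bind_rows(lapply(1:500, function(i)
    generate_subject("CVD+", cfg, with_volumes = FALSE)$record))
  # means within 4 Monte-Carlo standard errors of the generator targets
  expect_lt(abs(mean(recs$bmi) - 28.31), 4 * 4.45 / sqrt(500))
  expect_lt(abs(mean(recs$sbp) - 147.26), 4 * 19.57 / sqrt(500))
  expect_lt(abs(mean(recs$dbp) - 84.75), 4 * 10.23 / sqrt(500))
  expect_lt(abs(mean(recs$hba1c) - 36.52), 4 * 4.32 / sqrt(500))
  expect_lt(abs(sd(recs$bmi) - 4.45), 0.6)
  set.seed(124)
  ctrl <- dplyr::bind_rows(lapply(1:500, function(i)
    generate_subject("CVD-", cfg, with_volumes = FALSE)$record))
  expect_lt(abs(mean(ctrl$bmi) - 27.43), 4 * 4.33 / sqrt(500))
  expect_lt(abs(mean(ctrl$sbp) - 145.1), 4 * 18.75 / sqrt(500))
  # age/sex marginals are shared across labels by construction
  expect_lt(abs(mean(recs$age) - mean(ctrl$age)), 4 * 6.47 * sqrt(2 / 500))
})

test_that("a null choroid effect leaves measured thickness indistinguishable", {
  cfg <- phantom_config(image_height = 32, image_width = 16, n_bscans = 1,
                        speckle_level = 0, choroid_effect = 0)
  set.seed(55)
  measure <- function(label, n) {
    vapply(seq_len(n), function(i) {
      s <- generate_subject(label, cfg)
      mean(s$left$thickness[, "CHOROID_LOWER"])
    }, numeric(1))
  }
  pos <- measure("CVD+", 200)
  neg <- measure("CVD-", 200)
  expect_gt(t.test(pos, neg)$p.value, 0.01)
})

test_that("measured choroidal thickness increases with the planted effect", {
  set.seed(66)
  means <- vapply(c(0, 0.25, 0.5), function(eff) {
    cfg <- phantom_config(image_height = 48, image_width = 16, n_bscans = 1,
                          speckle_level = 0, choroid_effect = eff)
    mean(vapply(seq_len(100), function(i) {
      s <- generate_subject("CVD+", cfg)
      mean(s$left$thickness[, "CHOROID_LOWER"])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("cohort bookkeeping, event offsets and determinism hold", {
  cfg <- tiny_phantom(seed = 31)
  coh <- generate_cohort(10, 30, cfg)
  expect_equal(nrow(coh$subjects), 40)
  expect_equal(nrow(coh$volumes), 80)
  expect_equal(sum(coh$subjects$cvd_label == "CVD+"), 10)
  offs <- coh$subjects$event_offset[coh$subjects$cvd_label == "CVD+"]
  expect_true(all(offs > 0 & offs <= 5))
  expect_true(all(is.na(coh$subjects$event_offset[
    coh$subjects$cvd_label == "CVD-"])))
  coh2 <- generate_cohort(10, 30, cfg)
  expect_identical(coh$subjects, coh2$subjects)
  expect_identical(coh$volumes$volume[[3]], coh2$volumes$volume[[3]])
})

test_that("cohort age mean matches the generator target at n = 500", {
  cfg <- tiny_phantom(seed = 77)
  coh <- generate_cohort(100, 400, cfg, with_volumes = FALSE)
  expect_lt(abs(mean(coh$subjects$age) - 60.78), 3 * 6.47 / sqrt(500))
})

test_that("layer band masks select the rows between boundaries", {
  cfg <- flat_phantom()
  ly <- layer_specs(32)
  set.seed(2)
  b <- generate_bscan(ly, cfg)
  m <- layer_band_mask(b$boundaries, 32, "CHOROID_LOWER")
  expect_equal(sum(m), b$thickness[["CHOROID_LOWER"]] * ncol(b$image))
  expect_error(layer_band_mask(b$boundaries, 32, "ILM"), "vitreous")
  expect_error(layer_band_mask(b$boundaries, 32, "NOPE"), "unknown")
})

test_that("volumes round-trip through the on-disk container", {
  cfg <- tiny_phantom(seed = 8)
  s <- generate_subject("CVD-", cfg, subject_id = "S0042")
  path <- withr::local_tempfile(fileext = ".oct")
  write_volume(s$left, path)
  back <- read_volume(path)
  expect_identical(back$bscans, s$left$bscans)
  expect_identical(back$boundaries, s$left$boundaries)
  expect_equal(back$subject_id, "S0042")
})
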