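# End-to-end orchestration: simulate -> quality filter -> cohort rules and
# matching -> per-eye VAE training -> seven-mode classification -> dual
# explainability, under a single run seed fanned out to per-stage seeds.

#' Pipeline configuration
#'
#' One object drives a full run. The single `seed` is fanned out to
#' per-stage seeds via [stage_seed()], so stages rerun in isolation reproduce
#' their outputs.
#'
#' @param seed Run seed.
#' @param n_cases,n_controls Synthetic cohort composition before exclusions.
#'   Controls should be ample enough to supply `match_ratio` matches per case.
#' @param phantom A [phantom_config()] (its `seed` is overridden by the
#'   simulate-stage seed).
#' @param vae A [vae_config()] (its `seed` is overridden per eye).
#' @param quality_fraction Lowest-QI fraction of volumes excluded.
#' @param match_ratio,match_caliper Controls per case and age caliper (years).
#' @param split Train/validation/test proportions at the subject level; the
#'   grid search cross-validates over train+validation while the test split
#'   stays untouched and hash-locked.
#' @param rfe_k Features kept by RFE; `rfe_k_re` overrides it for the
#'   right-eye-only mode.
#' @param rf_grid Hyperparameter grid for [train_rf()].
#' @param n_boot Bootstrap replicates per evaluation.
#' @param latent_mode Per-volume latent aggregation (see
#'   [extract_eye_latent()]).
#' @param vae_max_volumes Cap on the number of volumes per eye used for VAE
#'   training (seeded subsample; `Inf` uses all retained volumes). Latent
#'   extraction always covers every matched subject.
#' @param modes Feature modes to run (default: all seven).
#' @param explain_mode Mode whose best classifier is explained; `"best"`
#'   picks the highest test AUROC.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, n_cases = 20, n_controls = 100,
                            phantom = phantom_config(image_height = 64,
                                                     image_width = 64,
                                                     n_bscans = 16,
                                                     choroid_effect = 0.3),
                            vae = vae_config(latent_dim = 32,
                                             conv_channels = c(8, 16, 32,
                                                               64, 64, 64),
                                             epochs = 30),
                            quality_fraction = 0.2, match_ratio = 3,
                            match_caliper = 2, split = c(5, 2, 3) / 10,
                            rfe_k = 10, rfe_k_re = 5,
                            rf_grid = default_rf_grid(), n_boot = 200,
                            latent_mode = "all", vae_max_volumes = Inf,
                            modes = FEATURE_MODES, explain_mode = "best") {
  stopifnot(length(split) == 3, abs(sum(split) - 1) < 1e-8)
  structure(list(seed = as.integer(seed), n_cases = n_cases,
                 n_controls = n_controls, phantom = phantom, vae = vae,
                 quality_fraction = quality_fraction,
                 match_ratio = match_ratio, match_caliper = match_caliper,
                 split = split, rfe_k = rfe_k, rfe_k_re = rfe_k_re,
                 rf_grid = rf_grid, n_boot = n_boot,
                 latent_mode = latent_mode, vae_max_volumes = vae_max_volumes,
                 modes = modes, explain_mode = explain_mode),
            class = "pipeline_config")
}

# stack every B-scan of the given volumes into one n x H x W array
stack_scans <- function(volumes) {
  mats <- purrr::map(volumes, function(v) {
    d <- dim(v$bscans)
    matrix(v$bscans, d[1], d[2] * d[3])
  })
  X <- do.call(rbind, mats)
  d <- dim(volumes[[1]]$bscans)
  array(X, c(nrow(X), d[2], d[3]))
}

#' Run the full pipeline
#'
#' Executes simulate -> quality -> cohort -> VAE training (per eye) ->
#' classification over the configured feature modes -> explanation, and
#' returns the metrics table (one row per mode), the STROBE ledger, the run
#' manifest and the fitted models.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return An `oct_run` list: `metrics`, `ledger`, `matched`, `models`,
#'   `latents`, `splits`, `explain`, `manifest`, `cohort`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  seeds <- purrr::map_int(
    c("simulate", "quality", "match", "vae_L", "vae_R", "split",
      "classify", "evaluate", "explain"),
    ~ stage_seed(config$seed, .x))
  names(seeds) <- c("simulate", "quality", "match", "vae_L", "vae_R", "split",
                    "classify", "evaluate", "explain")

  ## simulate
  say("simulate: %d cases + %d controls", config$n_cases, config$n_controls)
  ph <- config$phantom
  ph$seed <- seeds[["simulate"]]
  cohort <- generate_cohort(config$n_cases, config$n_controls, ph)

  ## quality filter (volume level); subjects need both retained eyes
  say("quality: scoring %d volumes", nrow(cohort$volumes))
  scores <- score_cohort(cohort)
  filt <- filter_lowest_fraction(scores, config$quality_fraction)
  eyes_ok <- dplyr::count(filt$retained, .data$subject_id)
  keep_ids <- eyes_ok$subject_id[eyes_ok$n == 2]
  ledger <- ledger_add(new_strobe_ledger(), "quality_filter",
                       nrow(cohort$subjects),
                       nrow(cohort$subjects) - length(keep_ids),
                       sprintf("lowest %d%% QI volumes excluded; both eyes required",
                               round(100 * config$quality_fraction)))
  records <- cohort$subjects[cohort$subjects$subject_id %in% keep_ids, ]

  ## cohort rules
  ew <- apply_event_window(records, window = ph$event_window, ledger = ledger)
  ex <- apply_exclusions(ew$kept, ledger = ew$ledger)
  records <- ex$kept
  ledger <- ex$ledger
  validate_ledger(ledger)

  ## matching
  say("match: 1:%d within caliper %g y", config$match_ratio, config$match_caliper)
  matched <- propensity_match(records, ratio = config$match_ratio,
                              caliper = config$match_caliper,
                              seed = seeds[["match"]], on_unmatched = "drop")
  matched_ids <- c(matched$cases, matched$controls)
  ledger <- ledger_add(
    ledger, "propensity_match", nrow(records),
    nrow(records) - length(matched_ids),
    sprintf("1:%d age/sex propensity matching (%d unmatchable case(s) removed)",
            config$match_ratio, length(matched$unmatched)))
  records <- records[records$subject_id %in% matched_ids, ]

  ## VAE per eye, trained self-supervised on all quality-retained volumes
  models <- list()
  latents <- list()
  for (eye in c("L", "R")) {
    vols <- cohort$volumes[cohort$volumes$eye == eye &
                             paste(cohort$volumes$subject_id, eye) %in%
                               paste(filt$retained$subject_id, filt$retained$eye), ]
    if (is.finite(config$vae_max_volumes) &&
        nrow(vols) > config$vae_max_volumes) {
      set.seed(stage_seed(config$seed, paste0("vae_cap_", eye)))
      vols <- vols[sort(sample.int(nrow(vols), config$vae_max_volumes)), ]
    }
    say("vae_%s: %d volumes x %d scans", eye, nrow(vols), ph$n_bscans)
    vc <- config$vae
    vc$seed <- seeds[[paste0("vae_", eye)]]
    models[[eye]] <- train_vae(stack_scans(vols$volume), vc)
    latents[[eye]] <- cohort_latents(models[[eye]], cohort, eye,
                                     subject_ids = records$subject_id,
                                     mode = config$latent_mode)
  }

  ## subject-level 5:2:3 split, stratified by label; test hash-locked
  set.seed(seeds[["split"]])
  splits <- split(records$subject_id, records$cvd_label) |>
    purrr::map(function(ids) {
      ids <- ids[sample.int(length(ids))]
      n <- length(ids)
      n_tr <- round(config$split[1] * n)
      n_va <- round(config$split[2] * n)
      list(train = ids[seq_len(n_tr)],
           val = ids[n_tr + seq_len(min(n_va, n - n_tr))],
           test = ids[-seq_len(min(n_tr + n_va, n))])
    })
  split_ids <- list(train = unlist(purrr::map(splits, "train"), use.names = FALSE),
                    val = unlist(purrr::map(splits, "val"), use.names = FALSE),
                    test = unlist(purrr::map(splits, "test"), use.names = FALSE))
  test_hash <- cohort_split_hash(split_ids$test)

  ## classification over modes
  labels <- records[, c("subject_id", "cvd_label")]
  fits <- list()
  reports <- list()
  metrics <- vector("list", length(config$modes))
  for (mi in seq_along(config$modes)) {
    mode <- config$modes[mi]
    say("classify: %s", mode)
    X <- assemble_features(latents$L, latents$R, records, labels, mode)
    X_pool <- X[X$subject_id %in% c(split_ids$train, split_ids$val), ]
    X_test <- X[X$subject_id %in% split_ids$test, ]
    k <- if (mode == "RE") config$rfe_k_re else config$rfe_k
    k <- min(k, length(feature_columns(X)))
    mode_seed <- stage_seed(seeds[["classify"]], mode)
    sel <- rfe_select(X_pool, k = k, seed = mode_seed)
    fit <- train_rf(X_pool, grid = config$rf_grid, features = sel,
                    seed = mode_seed)
    fit$mode <- mode
    rep <- evaluate_classifier(fit, X_test, n_boot = config$n_boot,
                               seed = seeds[["evaluate"]],
                               expected_hash = test_hash)
    fits[[mode]] <- fit
    reports[[mode]] <- rep
    metrics[[mi]] <- dplyr::bind_cols(tibble::tibble(classifier = mode),
                                      glance(rep)[, 1:4],
                                      tidyr::pivot_wider(
                                        tibble::as_tibble(rep)[, c("metric", "conf_low", "conf_high")],
                                        names_from = "metric",
                                        values_from = c("conf_low", "conf_high")))
  }
  metrics <- dplyr::bind_rows(metrics)

  ## explanation of the chosen classifier
  exp_mode <- config$explain_mode
  if (identical(exp_mode, "best")) {
    img_modes <- metrics$classifier[metrics$classifier != "MTDT"]
    exp_mode <- img_modes[which.max(metrics$auroc[metrics$classifier != "MTDT"])]
  }
  say("explain: %s", exp_mode)
  imp <- importance_table(fits[[exp_mode]])
  modal <- modality_importance(imp)
  zmax <- top_latent(imp)
  eye_lat <- latents[[zmax$eye]]
  sigma_max <- latent_sd(eye_lat[eye_lat$subject_id %in% split_ids$train, ],
                         zmax$feature)
  # vector-field maps for the CVD+ test subjects' central B-scans (the same
  # per-patient procedure the analysis applies to the whole CVD+ test set),
  # pooled for the per-layer summary
  case_ids <- sort(intersect(split_ids$test,
                             records$subject_id[records$cvd_label == "CVD+"]))
  if (length(case_ids) == 0) case_ids <- sort(matched$cases)
  vfs <- list()
  bnds <- list()
  for (id in case_ids) {
    vol <- cohort$volumes$volume[cohort$volumes$subject_id == id &
                                   cohort$volumes$eye == zmax$eye][[1]]
    central <- ceiling(dim(vol$bscans)[1] / 2)
    vfs[[id]] <- vector_field_explanation(models[[zmax$eye]],
                                          vol$bscans[central, , ],
                                          index = zmax$index,
                                          scale = sigma_max)
    bnds[[id]] <- vol$boundaries[central, , ]
  }
  vf <- vfs[[1]]
  layer_sum <- flow_layer_pooled_summary(vfs, bnds, ph$image_height)

  manifest <- list(
    package_version = as.character(utils::packageVersion("octcvd")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config_hash = object_hash(unclass(config)),
    seed = config$seed, stage_seeds = as.list(seeds),
    stage_order = c("simulate", "quality", "cohort", "match", "vae", "classify",
                    "explain"),
    n_subjects_simulated = config$n_cases + config$n_controls,
    n_subjects_matched = length(matched_ids),
    test_set_hash = test_hash,
    metrics_hash = object_hash(metrics))

  structure(list(metrics = metrics, ledger = ledger, matched = matched,
                 models = models, fits = fits, reports = reports,
                 latents = latents, splits = split_ids,
                 explain = list(mode = exp_mode, importance = imp,
                                modality = modal, z_max = zmax,
                                sigma_max = sigma_max, vector_field = vf,
                                vector_fields = vfs,
                                layer_summary = layer_sum,
                                subjects = case_ids),
                 manifest = manifest, records = records, cohort = cohort),
            class = "oct_run")
}

#' @export
print.oct_run <- function(x, ...) {
  cat(sprintf("<oct_run> seed %d: %d matched subjects, %d classifiers\n",
              x$manifest$seed, x$manifest$n_subjects_matched,
              nrow(x$metrics)))
  print(x$metrics[, c("classifier", "accuracy", "sensitivity", "specificity",
                      "auroc")])
  cat(sprintf("explained: %s (z_max = %s, sigma_max = %.3f)\n",
              x$explain$mode, x$explain$z_max$feature, x$explain$sigma_max))
  invisible(x)
}

#' @export
autoplot.oct_run <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$metrics[, c("classifier", "accuracy", "sensitivity", "specificity",
                       "auroc")],
    -"classifier", names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$classifier, .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL, title = "classifier comparison") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Desk-scale study configuration
#'
#' The pipeline configuration used to reproduce the full analysis at desk
#' scale: 60 cases and 360 controls of 16-scan 64 x 64 volumes with a strong
#' planted choroidal effect (+35 percent CVD+ choroidal thickness), 32-epoch
#' per-eye VAE training with the 0.001 to 0.01 KL ramp over the first 20
#' epochs, 1:3 age/sex matching, all seven feature modes with RFE (top 10;
#' top 5 for the right-eye-only mode) and 1000-replicate bootstrap intervals.
#' Designed to finish in minutes on one CPU.
#'
#' @param seed Run seed.
#' @return A [pipeline_config()].
#' @export
study_config <- function(seed = 1L) {
  pipeline_config(
    seed = seed, n_cases = 60, n_controls = 360,
    phantom = phantom_config(image_height = 64, image_width = 64,
                             n_bscans = 16, speckle_level = 0.2,
                             choroid_effect = 0.35),
    vae = vae_config(latent_dim = 32, arch = "conv",
                     conv_channels = c(8, 16, 32, 64, 64, 64), epochs = 48,
                     anneal_epochs = 20, batch_size = 64),
    match_caliper = 3, rfe_k = 10, rfe_k_re = 5, n_boot = 1000,
    rf_grid = expand.grid(num_trees = 800, mtry = c(2, 4),
                          min_node_size = c(3, 8)),
    vae_max_volumes = 80)
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields override [pipeline_config()] defaults; `phantom:` and `vae:`
#' sub-maps override the respective sub-configurations.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  ph <- do.call(phantom_config, y$phantom %||% list())
  va <- do.call(vae_config, y$vae %||% list())
  top <- y[setdiff(names(y), c("phantom", "vae"))]
  do.call(pipeline_config, c(top, list(phantom = ph, vae = va)))
}

#' Write the metrics table and manifest of a run
#'
#' @param run An `oct_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(run$metrics, file.path(dir, "metrics.csv"), row.names = FALSE)
  write.csv(run$ledger, file.path(dir, "strobe_ledger.csv"), row.names = FALSE)
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(run$explain$layer_summary, file.path(dir, "layer_summary.csv"),
            row.names = FALSE)
  invisible(dir)
}
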