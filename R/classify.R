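# Multimodal random-forest classification over seven data-channel
# combinations: per-eye OCT latents (zl*, zr*), clinical metadata, and their
# combinations. Feature selection by recursive feature elimination on forest
# impurity importance; model selection by seeded five-fold cross-validated
# grid search on AUROC; evaluation at a fixed probability threshold with
# bootstrap confidence intervals.

FEATURE_MODES <- c("LE", "RE", "BE", "MTDT", "LE-MTDT", "RE-MTDT", "BE-MTDT")

#' Encode clinical metadata for the classifier
#'
#' The eight clinical variables (sex, age, ethnicity, BMI, SBP, DBP, HbA1c,
#' alcohol status) are encoded to one numeric column each: categoricals as
#' integer codes (with `NA` kept as its own level for alcohol), continuous
#' passed raw (forests are scale-free). Missing continuous values are set to 0
#' and flagged by an appended `<var>_missing` indicator (only when missingness
#' is present, so complete data stay at exactly 8 columns).
#'
#' @param metadata Subject tibble with the clinical columns.
#' @return Tibble `subject_id` plus numeric metadata columns.
#' @export
encode_metadata <- function(metadata) {
  alcohol_levels <- c("never", "previous", "current", "NA")
  eth_levels <- c("White", "Mixed", "Asian", "Black", "Chinese", "Other")
  alc <- ifelse(is.na(metadata$alcohol), "NA", metadata$alcohol)
  out <- tibble::tibble(
    subject_id = metadata$subject_id,
    sex = as.numeric(metadata$sex == "M"),
    age = metadata$age,
    ethnicity = as.numeric(factor(metadata$ethnicity, levels = eth_levels)),
    bmi = metadata$bmi,
    sbp = metadata$sbp,
    dbp = metadata$dbp,
    hba1c = metadata$hba1c,
    alcohol = as.numeric(factor(alc, levels = alcohol_levels)) - 1)
  for (v in c("age", "ethnicity", "bmi", "sbp", "dbp", "hba1c")) {
    miss <- is.na(out[[v]])
    if (any(miss)) {
      out[[v]][miss] <- 0
      out[[paste0(v, "_missing")]] <- as.numeric(miss)
    }
  }
  out
}

#' Assemble one of the seven feature-channel datasets
#'
#' Columns are concatenated in the order `[zl | zr | metadata]`, restricted to
#' the requested mode. Every subject present in `labels` must be present in
#' each requested channel; missing subjects raise an error naming them.
#'
#' @param latents_left,latents_right Tibbles `subject_id` + `zl*` / `zr*`
#'   columns (from [cohort_latents()]); may be `NULL` for modes not using that
#'   eye.
#' @param metadata Subject tibble (see [encode_metadata()]); may be `NULL` for
#'   image-only modes.
#' @param labels Tibble `subject_id`, `cvd_label`.
#' @param mode One of `r paste(FEATURE_MODES, collapse = ", ")`.
#' @return A `feature_matrix` tibble: `subject_id`, `cvd_label`, then feature
#'   columns; the mode is stored in `attr(, "mode")`.
#' @export
assemble_features <- function(latents_left = NULL, latents_right = NULL,
                              metadata = NULL, labels,
                              mode = FEATURE_MODES) {
  mode <- match.arg(mode)
  need_l <- mode %in% c("LE", "BE", "LE-MTDT", "BE-MTDT")
  need_r <- mode %in% c("RE", "BE", "RE-MTDT", "BE-MTDT")
  need_m <- grepl("MTDT", mode)
  out <- tibble::tibble(subject_id = labels$subject_id,
                        cvd_label = labels$cvd_label)
  join_channel <- function(out, tbl, what) {
    if (is.null(tbl)) abort(sprintf("mode needs the %s channel", what))
    missing <- setdiff(out$subject_id, tbl$subject_id)
    if (length(missing)) {
      abort(sprintf("subject(s) missing the %s channel: %s", what,
                    paste(sort(missing), collapse = ", ")))
    }
    dplyr::inner_join(out, tbl, by = "subject_id")
  }
  if (need_l) out <- join_channel(out, latents_left, "left-eye latent")
  if (need_r) out <- join_channel(out, latents_right, "right-eye latent")
  if (need_m) out <- join_channel(out, encode_metadata(metadata), "metadata")
  if (anyNA(out)) abort("feature matrix contains missing values after encoding")
  attr(out, "mode") <- mode
  class(out) <- c("feature_matrix", class(out))
  out
}

feature_columns <- function(X) setdiff(names(X), c("subject_id", "cvd_label"))

rf_fit_once <- function(X, cols, num_trees, mtry, min_node_size, seed,
                        importance = "none") {
  df <- as.data.frame(X[, cols, drop = FALSE])
  df$.label <- factor(X$cvd_label, levels = c("CVD-", "CVD+"))
  ranger::ranger(
    dependent.variable.name = ".label", data = df, probability = TRUE,
    num.trees = num_trees, mtry = min(mtry, length(cols)),
    min.node.size = min_node_size, importance = importance,
    seed = seed, num.threads = 1)
}

rf_prob <- function(fit, X, cols) {
  predict(fit, data = as.data.frame(X[, cols, drop = FALSE]),
          num.threads = 1)$predictions[, "CVD+"]
}

#' Area under the ROC curve by the rank statistic
#'
#' Equivalent to the probability that a random positive outranks a random
#' negative, with ties counting one half (midranks).
#'
#' @param probs Predicted CVD+ probabilities (or any scores).
#' @param labels Vector with positives labelled `"CVD+"` (or logical/0-1).
#' @return AUROC in `[0, 1]`.
#' @export
#' @examples
#' auroc(c(0.9, 0.4, 0.6, 0.1), c("CVD+", "CVD+", "CVD-", "CVD-"))
auroc <- function(probs, labels) {
  pos <- as_positive(labels)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(probs)  # midranks: ties contribute 1/2
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels > 0)
  labels == "CVD+"
}

#' Recursive feature elimination on forest importance
#'
#' Repeatedly fits a seeded random forest with impurity (Gini) importance and
#' drops the least important `drop_frac` of the remaining columns (at least
#' one, never past `k`) until `k` columns remain. Returned names are ordered
#' by final-model importance, most important first.
#'
#' @param X A `feature_matrix`.
#' @param k Number of features to keep.
#' @param drop_frac Fraction of columns dropped per round.
#' @param num_trees,min_node_size Forest size used during elimination.
#' @param seed Seed shared by all elimination fits.
#' @return Character vector of `k` selected column names.
#' @export
rfe_select <- function(X, k = 10, drop_frac = 0.1, num_trees = 300,
                       min_node_size = 5, seed = 1L) {
  cols <- feature_columns(X)
  if (k <= 0) abort("k must be positive")
  if (k > length(cols)) abort("k exceeds the number of feature columns")
  while (length(cols) > k) {
    fit <- rf_fit_once(X, cols, num_trees,
                       mtry = max(1, floor(sqrt(length(cols)))),
                       min_node_size = min_node_size, seed = seed,
                       importance = "impurity")
    imp <- fit$variable.importance[cols]
    n_drop <- min(max(1L, floor(drop_frac * length(cols))), length(cols) - k)
    cols <- names(sort(imp, decreasing = TRUE))[seq_len(length(cols) - n_drop)]
  }
  fit <- rf_fit_once(X, cols, num_trees,
                     mtry = max(1, floor(sqrt(length(cols)))),
                     min_node_size = min_node_size, seed = seed,
                     importance = "impurity")
  names(sort(fit$variable.importance[cols], decreasing = TRUE))
}

#' Train a random-forest classifier with cross-validated grid search
#'
#' Each grid point is scored by mean AUROC over seeded `cv_folds`-fold
#' cross-validation; the best point (ties: first in grid order) is refit on
#' the full training data with impurity importance.
#'
#' @param X A `feature_matrix` (training split).
#' @param grid Data frame of hyperparameters with columns among `num_trees`,
#'   `mtry`, `min_node_size`.
#' @param cv_folds Number of cross-validation folds.
#' @param features Optional subset of feature columns (e.g. from
#'   [rfe_select()]).
#' @param seed Seed for fold assignment and forest growth.
#' @return An `oct_rf`: fitted ranger model, chosen hyperparameters, CV
#'   results, feature names.
#' @export
train_rf <- function(X, grid = default_rf_grid(), cv_folds = 5,
                     features = NULL, seed = 1L) {
  cols <- features %||% feature_columns(X)
  y <- factor(X$cvd_label, levels = c("CVD-", "CVD+"))
  if (nlevels(droplevels(y)) < 2) abort("training data must contain both classes")
  grid <- as.data.frame(grid)
  for (nm in c("num_trees", "mtry", "min_node_size")) {
    if (is.null(grid[[nm]])) {
      grid[[nm]] <- switch(nm, num_trees = 500,
                           mtry = max(1, floor(sqrt(length(cols)))),
                           min_node_size = 5)
    }
  }
  set.seed(seed)
  folds <- sample(rep_len(seq_len(cv_folds), nrow(X)))
  cv <- purrr::map_dfr(seq_len(nrow(grid)), function(gi) {
    aucs <- purrr::map_dbl(seq_len(cv_folds), function(f) {
      tr <- X[folds != f, ]
      te <- X[folds == f, ]
      if (length(unique(tr$cvd_label)) < 2) return(NA_real_)
      fit <- rf_fit_once(tr, cols, grid$num_trees[gi], grid$mtry[gi],
                         grid$min_node_size[gi], seed = seed + f)
      auroc(rf_prob(fit, te, cols), te$cvd_label)
    })
    dplyr::bind_cols(grid[gi, , drop = FALSE],
                     tibble::tibble(cv_auroc = mean(aucs, na.rm = TRUE)))
  })
  best <- which.max(cv$cv_auroc)
  fit <- rf_fit_once(X, cols, grid$num_trees[best], grid$mtry[best],
                     grid$min_node_size[best], seed = seed,
                     importance = "impurity")
  structure(list(model = fit, features = cols,
                 best_params = grid[best, , drop = FALSE],
                 cv_results = cv, mode = attr(X, "mode"), seed = seed),
            class = "oct_rf")
}

#' Default random-forest hyperparameter grid
#' @return A data frame of grid points.
#' @export
default_rf_grid <- function() {
  expand.grid(num_trees = 500, mtry = c(2, 4), min_node_size = c(3, 8))
}

#' Predict CVD+ probabilities
#'
#' @param object An `oct_rf`.
#' @param newdata A `feature_matrix` containing the model's feature columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.oct_rf <- function(object, newdata, ...) {
  rf_prob(object$model, newdata, object$features)
}

#' @export
print.oct_rf <- function(x, ...) {
  cat(sprintf("<oct_rf> mode %s, %d features, CV AUROC %.3f\n",
              x$mode %||% "?", length(x$features), max(x$cv_results$cv_auroc)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a classifier on a held-out test set
#'
#' Threshold metrics (accuracy, sensitivity, specificity at probability
#' threshold `t`: predicted probability >= t is called CVD+), AUROC, confusion
#' counts, and seeded bootstrap 95 percent confidence intervals over test
#' subjects.
#'
#' @param fit An `oct_rf` (or any object with a `predict` method returning
#'   CVD+ probabilities).
#' @param X_test A `feature_matrix` disjoint from training data.
#' @param t Probability threshold.
#' @param n_boot Bootstrap replicates for the CIs.
#' @param seed Bootstrap seed.
#' @param expected_hash Optional test-set hash recorded at split time
#'   (see [cohort_split_hash()]); evaluation aborts on mismatch so the
#'   held-out set provably never changes between experiments.
#' @return An `eval_report`: tibble with one row per metric (`estimate`,
#'   `conf_low`, `conf_high`) plus confusion counts in attributes.
#' @export
evaluate_classifier <- function(fit, X_test, t = 0.5, n_boot = 1000,
                                seed = 1L, expected_hash = NULL) {
  if (!is.null(expected_hash)) {
    got <- cohort_split_hash(X_test$subject_id)
    if (!identical(got, expected_hash)) {
      abort("held-out test set changed: hash mismatch")
    }
  }
  probs <- predict(fit, X_test)
  labels <- X_test$cvd_label
  metrics_of <- function(probs, labels) {
    pos <- as_positive(labels)
    pred <- probs >= t
    tp <- sum(pred & pos); tn <- sum(!pred & !pos)
    fp <- sum(pred & !pos); fn <- sum(!pred & pos)
    c(accuracy = (tp + tn) / length(pos),
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      auroc = auroc(probs, labels),
      tp = tp, tn = tn, fp = fp, fn = fn)
  }
  est <- metrics_of(probs, labels)
  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, 4,
                 dimnames = list(NULL, c("accuracy", "sensitivity",
                                         "specificity", "auroc")))
  for (b in seq_len(n_boot)) {
    i <- sample.int(length(probs), replace = TRUE)
    boot[b, ] <- metrics_of(probs[i], labels[i])[1:4]
  }
  ci <- apply(boot, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  out <- tibble::tibble(
    metric = c("accuracy", "sensitivity", "specificity", "auroc"),
    estimate = unname(est[1:4]),
    conf_low = ci[1, ], conf_high = ci[2, ],
    boot_se = apply(boot, 2, sd, na.rm = TRUE))
  attr(out, "confusion") <- est[c("tp", "tn", "fp", "fn")]
  attr(out, "threshold") <- t
  attr(out, "n_test") <- length(probs)
  attr(out, "probs") <- probs
  class(out) <- c("eval_report", class(out))
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cf <- attr(x, "confusion")
  cat(sprintf("<eval_report> n = %d at t = %g (TP %d TN %d FP %d FN %d)\n",
              attr(x, "n_test"), attr(x, "threshold"),
              cf["tp"], cf["tn"], cf["fp"], cf["fn"]))
  print(tibble::as_tibble(x))
  invisible(x)
}

#' @export
tidy.eval_report <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.eval_report <- function(x, ...) {
  est <- setNames(x$estimate, x$metric)
  cf <- attr(x, "confusion")
  tibble::tibble(accuracy = est["accuracy"], sensitivity = est["sensitivity"],
                 specificity = est["specificity"], auroc = est["auroc"],
                 tp = cf["tp"], tn = cf["tn"], fp = cf["fp"], fn = cf["fn"],
                 n_test = attr(x, "n_test"))
}

#' @export
tidy.oct_rf <- function(x, ...) {
  imp <- x$model$variable.importance
  tibble::tibble(feature = names(imp), importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @export
glance.oct_rf <- function(x, ...) {
  dplyr::bind_cols(tibble::as_tibble(x$best_params),
                   tibble::tibble(cv_auroc = max(x$cv_results$cv_auroc),
                                  n_features = length(x$features)))
}

#' Hash of a held-out subject set
#'
#' Order-invariant identifier of a test split, recorded once at split time
#' and asserted by every later evaluation.
#'
#' @param subject_ids Character vector of subject ids.
#' @return Hex string.
#' @export
cohort_split_hash <- function(subject_ids) {
  fnv1a_hex(paste(sort(subject_ids), collapse = "|"))
}

#' Compare two classifiers on the same test subjects
#'
#' Default is McNemar's test on the discordant-correctness pairs: with `b`
#' subjects only classifier A gets right and `c` only B,
#' `chi2 = (b - c)^2 / (b + c)` on 1 degree of freedom (no continuity
#' correction; `correct = TRUE` switches it on). `method = "contingency"`
#' instead tests independence of the two classifiers' correctness in the
#' 2 x 2 table.
#'
#' @param pred_a,pred_b Predicted labels (or probabilities, thresholded at
#'   `t`) from the two classifiers on identical subjects.
#' @param labels True labels.
#' @param method `"mcnemar"` or `"contingency"`.
#' @param correct Continuity correction for McNemar.
#' @param t Threshold applied when predictions are probabilities.
#' @return Tibble `chi2`, `df`, `p_value`, `b`, `c`.
#' @export
#' @examples
#' compare_classifiers(c(1, 1, 0, 0), c(1, 0, 0, 1), c(1, 1, 0, 0))
compare_classifiers <- function(pred_a, pred_b, labels,
                                method = c("mcnemar", "contingency"),
                                correct = FALSE, t = 0.5) {
  method <- match.arg(method)
  if (length(pred_a) != length(pred_b) || length(pred_a) != length(labels)) {
    abort("prediction vectors and labels must have equal length")
  }
  to_call <- function(p) {
    if (is.numeric(p) && any(p %% 1 != 0)) p >= t else as_positive(p)
  }
  pos <- as_positive(labels)
  ok_a <- to_call(pred_a) == pos
  ok_b <- to_call(pred_b) == pos
  b <- sum(ok_a & !ok_b)
  cc <- sum(!ok_a & ok_b)
  if (method == "mcnemar") {
    if (b + cc == 0) {
      chi2 <- 0
    } else {
      d <- abs(b - cc) - if (correct) 1 else 0
      chi2 <- max(d, 0)^2 / (b + cc)
    }
  } else {
    tab <- table(factor(ok_a, c(FALSE, TRUE)), factor(ok_b, c(FALSE, TRUE)))
    chi2 <- suppressWarnings(stats::chisq.test(tab, correct = correct)$statistic)
    chi2 <- unname(chi2)
  }
  p <- if (chi2 == 0) 1 else pchisq(chi2, df = 1, lower.tail = FALSE)
  tibble::tibble(chi2 = chi2, df = 1L, p_value = p, b = b, c = cc)
}

#' ROC curve points
#'
#' @param probs Predicted probabilities.
#' @param labels True labels.
#' @return Tibble `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(probs, labels) {
  pos <- as_positive(labels)
  th <- c(Inf, sort(unique(probs), decreasing = TRUE))
  purrr::map_dfr(th, function(t) {
    pred <- probs >= t
    tibble::tibble(threshold = t,
                   fpr = sum(pred & !pos) / max(sum(!pos), 1),
                   tpr = sum(pred & pos) / max(sum(pos), 1))
  })
}

#' @export
autoplot.eval_report <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$metric, .data$estimate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$conf_low,
                                        ymax = .data$conf_high), width = 0.2) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(y = "estimate (95% bootstrap CI)", x = NULL)
}
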