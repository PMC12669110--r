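# Feature tables small enough to build by hand: latent tibbles with D
# columns and a label tibble.
fake_latents <- function(ids, D, prefix, seed = 1) {
  set.seed(seed)
  Z <- matrix(rnorm(length(ids) * D), length(ids), D)
  colnames(Z) <- sprintf("%s%03d", prefix, seq_len(D) - 1)
  dplyr::bind_cols(tibble::tibble(subject_id = ids), tibble::as_tibble(Z))
}

fake_metadata <- function(ids, seed = 2) {
  set.seed(seed)
  n <- length(ids)
  tibble::tibble(subject_id = ids,
                 age = rnorm(n, 60, 5), sex = sample(c("F", "M"), n, TRUE),
                 ethnicity = sample(c("White", "Mixed"), n, TRUE),
                 bmi = rnorm(n, 28, 4), sbp = rnorm(n, 146, 19),
                 dbp = rnorm(n, 84, 10), hba1c = rnorm(n, 36, 5),
                 alcohol = sample(c("never", "previous", "current"), n, TRUE))
}

fake_labels <- function(ids, n_pos = length(ids) %/% 2) {
  tibble::tibble(subject_id = ids,
                 cvd_label = c(rep("CVD+", n_pos),
                               rep("CVD-", length(ids) - n_pos)))
}

test_that("feature modes produce the documented column blocks", {
  ids <- sprintf("S%03d", 1:10)
  zl <- fake_latents(ids, 128, "zl", 1)
  zr <- fake_latents(ids, 128, "zr", 2)
  md <- fake_metadata(ids)
  lab <- fake_labels(ids)
  mt <- assemble_features(metadata = md, labels = lab, mode = "MTDT")
  expect_equal(length(feature_columns(mt)), 8)
  be <- assemble_features(zl, zr, md, lab, mode = "BE-MTDT")
  expect_equal(length(feature_columns(be)), 128 + 128 + 8)
  # column order [zl | zr | metadata]
  expect_equal(feature_columns(be)[1], "zl000")
  expect_equal(feature_columns(be)[129], "zr000")
  le <- assemble_features(zl, labels = lab, mode = "LE")
  expect_equal(le[, paste0("zl", sprintf("%03d", 0:127))],
               be[, paste0("zl", sprintf("%03d", 0:127))],
               ignore_attr = TRUE)
  expect_equal(attr(be, "mode"), "BE-MTDT")
})

test_that("missing channels and subjects are reported by name", {
  ids <- sprintf("S%03d", 1:6)
  zl <- fake_latents(ids[1:4], 4, "zl")
  lab <- fake_labels(ids)
  expect_error(assemble_features(zl, labels = lab, mode = "LE"), "S005")
  expect_error(assemble_features(labels = lab, mode = "LE"), "channel")
})

test_that("metadata encoding is numeric, 8 columns, with missingness flags", {
  md <- fake_metadata(sprintf("S%03d", 1:5))
  enc <- encode_metadata(md)
  expect_equal(ncol(enc), 9)  # subject_id + 8
  expect_true(all(vapply(enc[-1], is.numeric, logical(1))))
  md$alcohol[2] <- NA
  md$bmi[3] <- NA
  enc2 <- encode_metadata(md)
  expect_equal(enc2$alcohol[2], 3)  # NA as its own level
  expect_equal(enc2$bmi[3], 0)
  expect_equal(enc2$bmi_missing, c(0, 0, 1, 0, 0))
})

test_that("auroc equals the all-pairs statistic and the reference implementation", {
  probs <- c(0.9, 0.4, 0.6, 0.1)
  labels <- c("CVD+", "CVD+", "CVD-", "CVD-")
  # brute force over all positive-negative pairs
  brute <- function(p, l) {
    pos <- which(l == "CVD+"); neg <- which(l == "CVD-")
    s <- 0
    for (i in pos) for (j in neg)
      s <- s + (p[i] > p[j]) + 0.5 * (p[i] == p[j])
    s / (length(pos) * length(neg))
  }
  expect_equal(auroc(probs, labels), 0.75)
  expect_equal(auroc(probs, labels), brute(probs, labels))
  set.seed(20)
  for (i in 1:10) {
    p <- round(runif(30), 2)  # rounding forces ties
    l <- ifelse(rbinom(30, 1, 0.4) == 1, "CVD+", "CVD-")
    if (length(unique(l)) < 2) next
    expect_equal(auroc(p, l), brute(p, l))
    expect_equal(auroc(p, l),
                 as.numeric(pROC::auc(pROC::roc(l == "CVD+", p,
                                                quiet = TRUE,
                                                direction = "<"))))
  }
})

test_that("rfe keeps identity at k = n and recovers a planted feature", {
  ids <- sprintf("S%03d", 1:400)
  lab <- fake_labels(ids, 200)
  X <- fake_latents(ids, 20, "zl", seed = 30)
  X$cvd_label <- lab$cvd_label
  attr(X, "mode") <- "LE"
  class(X) <- c("feature_matrix", class(X))
  expect_setequal(rfe_select(X, k = 20, seed = 1), feature_columns(X))
  expect_error(rfe_select(X, k = 0), "positive")
  expect_error(rfe_select(X, k = 99), "exceeds")
  # plant signal in one column among 20 noise columns
  hits <- 0
  runs <- 40
  for (s in seq_len(runs)) {
    set.seed(1000 + s)
    Xp <- X
    Xp$zl007 <- rnorm(400, ifelse(lab$cvd_label == "CVD+", 1.5, 0))
    sel <- rfe_select(Xp, k = 5, num_trees = 150, seed = s)
    hits <- hits + ("zl007" %in% sel)
  }
  expect_gte(hits / runs, 0.95)
})

test_that("grid search picks the only point of a degenerate grid and separates blobs", {
  ids <- sprintf("S%03d", 1:120)
  lab <- fake_labels(ids, 60)
  set.seed(40)
  X <- tibble::tibble(subject_id = ids, cvd_label = lab$cvd_label,
                      f1 = rnorm(120, ifelse(lab$cvd_label == "CVD+", 2, -2)),
                      f2 = rnorm(120))
  class(X) <- c("feature_matrix", class(X))
  grid1 <- data.frame(num_trees = 100, mtry = 1, min_node_size = 5)
  fit <- train_rf(X, grid = grid1, seed = 2)
  expect_equal(fit$best_params$num_trees, 100)
  expect_equal(nrow(fit$cv_results), 1)
  expect_gt(max(fit$cv_results$cv_auroc), 0.95)
  # single-class input errors
  X1 <- X[X$cvd_label == "CVD+", ]
  expect_error(train_rf(X1, grid = grid1), "both classes")
})

test_that("threshold metrics match hand-counted confusion cells", {
  probs <- c(0.9, 0.4, 0.6, 0.1)
  labels <- c("CVD+", "CVD+", "CVD-", "CVD-")
  rep <- evaluate_classifier(
    structure(list(), class = "prob_carrier"),
    X_test = local({
      X <- tibble::tibble(subject_id = letters[1:4], cvd_label = labels)
      attr(X, "probs") <- probs
      X
    }), n_boot = 50, seed = 1)
  cf <- attr(rep, "confusion")
  expect_equal(unname(cf), c(1, 1, 1, 1))
  est <- setNames(rep$estimate, rep$metric)
  expect_equal(unname(est["accuracy"]), 0.5)
  expect_equal(unname(est["sensitivity"]), cf[["tp"]] / (cf[["tp"]] + cf[["fn"]]))
  expect_equal(unname(est["specificity"]), cf[["tn"]] / (cf[["tn"]] + cf[["fp"]]))
  expect_equal(unname(est["auroc"]), 0.75)
})

test_that("a perfect classifier scores 1 on every metric", {
  labels <- c(rep("CVD+", 5), rep("CVD-", 5))
  X <- tibble::tibble(subject_id = letters[1:10], cvd_label = labels)
  attr(X, "probs") <- ifelse(labels == "CVD+", 1, 0)
  rep <- evaluate_classifier(structure(list(), class = "prob_carrier"),
                             X, n_boot = 50, seed = 1)
  expect_equal(rep$estimate, rep(1, 4))
})

test_that("bootstrap CIs tighten with test-set size", {
  make_X <- function(n, seed) {
    set.seed(seed)
    labels <- rep(c("CVD+", "CVD-"), each = n / 2)
    p <- plogis(rnorm(n, ifelse(labels == "CVD+", 1, -1)))
    X <- tibble::tibble(subject_id = as.character(seq_len(n)),
                        cvd_label = labels)
    attr(X, "probs") <- p
    X
  }
  r100 <- evaluate_classifier(structure(list(), class = "prob_carrier"),
                              make_X(100, 1), n_boot = 300, seed = 2)
  r400 <- evaluate_classifier(structure(list(), class = "prob_carrier"),
                              make_X(400, 1), n_boot = 300, seed = 2)
  w <- function(r) (r$conf_high - r$conf_low)[r$metric == "auroc"]
  expect_lt(w(r400), w(r100))
})

test_that("evaluation enforces the recorded test-set hash", {
  labels <- c("CVD+", "CVD-")
  X <- tibble::tibble(subject_id = c("a", "b"), cvd_label = labels)
  attr(X, "probs") <- c(0.8, 0.2)
  h <- cohort_split_hash(c("b", "a"))
  expect_equal(h, cohort_split_hash(c("a", "b")))  # order-invariant
  r <- evaluate_classifier(structure(list(), class = "prob_carrier"), X,
                           n_boot = 10, seed = 1, expected_hash = h)
  expect_s3_class(r, "eval_report")
  expect_error(
    evaluate_classifier(structure(list(), class = "prob_carrier"), X,
                        n_boot = 10, seed = 1,
                        expected_hash = cohort_split_hash(c("a", "c"))),
    "hash mismatch")
})

test_that("classifier comparison matches McNemar closed forms", {
  labels <- rep(1, 12)
  a <- c(rep(1, 10), 0, 0)   # a right on 10, wrong on 2
  b <- rep(c(0, 1), times = c(10, 2))  # b wrong where a right and vice versa
  out <- compare_classifiers(a, a, labels)
  expect_equal(out$chi2, 0)
  expect_equal(out$p_value, 1)
  # discordant counts b=10, c=0 (no continuity correction): chi2 = 10
  out2 <- compare_classifiers(a, b, labels[1:12])
  expect_equal(out2$b + out2$c, 12)
  d <- compare_classifiers(c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
                           c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
                           rep(1, 10))
  expect_equal(d$chi2, 10)
  expect_equal(d$df, 1L)
  # cross-check against the reference implementation on random data
  set.seed(50)
  lab <- rbinom(60, 1, 0.5)
  pa <- rbinom(60, 1, 0.5)
  pb <- rbinom(60, 1, 0.5)
  ours <- compare_classifiers(pa, pb, lab)
  ref <- stats::mcnemar.test(table(factor(pa == lab, c(FALSE, TRUE)),
                                   factor(pb == lab, c(FALSE, TRUE))),
                             correct = FALSE)
  expect_equal(ours$chi2, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value)
  expect_error(compare_classifiers(pa, pb[1:10], lab), "equal length")
})

test_that("roc points trace from (0,0) to (1,1)", {
  pts <- roc_points(c(0.9, 0.4, 0.6, 0.1), c("CVD+", "CVD+", "CVD-", "CVD-"))
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1)
  expect_equal(pts$tpr[nrow(pts)], 1)
})
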