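# Scan quality indexing and lowest-fraction exclusion.
#
# The quality index (QI) combines two ingredients computed on the
# [0,1]-normalized intensity image: an intensity ratio taken from the image
# histogram (mean intensity above the saturation-free upper histogram mode
# relative to the overall mean) and a tissue signal ratio (highly reflective
# pixels per weakly reflective pixel). qi = intensity_ratio *
# tissue_signal_ratio; the thresholds are configuration, not anatomy.

#' Compute the quality index of a B-scan
#'
#' @param image Numeric matrix with values in `[0, 1]` (or a `bscan`).
#' @param tau_hi Reflectivity threshold above which a pixel counts as tissue
#'   signal.
#' @param tau_lo Threshold below which a pixel counts as background.
#' @param n_bins Number of histogram bins used to locate the upper mode.
#' @return A `quality_score`: list with `qi`, `intensity_ratio`,
#'   `tissue_signal_ratio` and a `degenerate` flag (constant images score 0).
#' @export
#' @examples
#' compute_qi(matrix(c(rep(0.9, 4), rep(0.1, 12)), 4, 4),
#'            tau_hi = 0.5, tau_lo = 0.5)
compute_qi <- function(image, tau_hi = 0.55, tau_lo = 0.30, n_bins = 64) {
  if (inherits(image, "bscan")) image <- image$image
  stopifnot(is.numeric(image))
  x <- as.numeric(image)
  if (any(x < 0 | x > 1)) abort("image values must lie in [0, 1]")
  if (diff(range(x)) < 1e-12) {
    return(structure(list(qi = 0, intensity_ratio = NA_real_,
                          tissue_signal_ratio = NA_real_, degenerate = TRUE),
                     class = "quality_score"))
  }
  # histogram upper mode, excluding the top (saturation) bin
  bin <- pmin(pmax(ceiling(x * n_bins), 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  padded <- c(-1, counts, -1)
  is_mode <- counts > 0 &
    counts >= padded[seq_len(n_bins)] & counts >= padded[seq_len(n_bins) + 2]
  modes <- which(is_mode)
  modes <- modes[modes < n_bins]
  upper_mode <- if (length(modes)) max(modes) else which.max(counts)
  mode_edge <- (upper_mode - 1) / n_bins
  intensity_ratio <- mean(x[x >= mode_edge]) / mean(x)

  n_hi <- sum(x > tau_hi)
  n_lo <- sum(x < tau_lo)
  tissue_signal_ratio <- if (n_lo == 0) as.numeric(n_hi) else n_hi / n_lo

  structure(list(qi = intensity_ratio * tissue_signal_ratio,
                 intensity_ratio = intensity_ratio,
                 tissue_signal_ratio = tissue_signal_ratio,
                 degenerate = FALSE),
            class = "quality_score")
}

#' @export
print.quality_score <- function(x, ...) {
  cat(sprintf("<quality_score> qi = %.4f (intensity %.3f, tissue %.3f)%s\n",
              x$qi, x$intensity_ratio, x$tissue_signal_ratio,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Score every B-scan of a volume
#'
#' The volume-level QI is the median of the per-scan indices.
#'
#' @param volume An `oct_volume`.
#' @inheritParams compute_qi
#' @return A tibble with `scan`, `qi`, `intensity_ratio`,
#'   `tissue_signal_ratio`, `degenerate`; the volume median is in
#'   `attr(, "volume_qi")`.
#' @export
score_volume <- function(volume, tau_hi = 0.55, tau_lo = 0.30, n_bins = 64) {
  n <- dim(volume$bscans)[1]
  scores <- purrr::map(seq_len(n), function(i)
    compute_qi(volume$bscans[i, , ], tau_hi, tau_lo, n_bins))
  out <- tibble::tibble(
    scan = seq_len(n),
    qi = purrr::map_dbl(scores, "qi"),
    intensity_ratio = purrr::map_dbl(scores, "intensity_ratio"),
    tissue_signal_ratio = purrr::map_dbl(scores, "tissue_signal_ratio"),
    degenerate = purrr::map_lgl(scores, "degenerate"))
  attr(out, "volume_qi") <- median(out$qi)
  out
}

#' Score every volume of a cohort
#'
#' @param cohort An `oct_cohort`.
#' @inheritParams compute_qi
#' @return Tibble `subject_id`, `eye`, `qi` (volume-level median QI).
#' @export
score_cohort <- function(cohort, tau_hi = 0.55, tau_lo = 0.30, n_bins = 64) {
  dplyr::mutate(
    cohort$volumes[, c("subject_id", "eye")],
    qi = purrr::map_dbl(cohort$volumes$volume, function(v)
      attr(score_volume(v, tau_hi, tau_lo, n_bins), "volume_qi")))
}

#' Exclude the lowest-quality fraction of scored images
#'
#' Drops the `floor(fraction * n)` rows with smallest `qi`, breaking ties by
#' stable input order; both returned sets preserve the input row order.
#'
#' @param scored A data frame with a `qi` column (e.g. from [score_cohort()]).
#' @param fraction Fraction to exclude, in `[0, 1)`.
#' @return List with tibbles `retained` and `excluded`.
#' @export
#' @examples
#' filter_lowest_fraction(tibble::tibble(id = 1:10, qi = 10:1), 0.2)
filter_lowest_fraction <- function(scored, fraction = 0.2) {
  stopifnot(is.data.frame(scored), "qi" %in% names(scored))
  if (nrow(scored) == 0) abort("cannot filter an empty set of scored images")
  if (fraction < 0 || fraction >= 1) abort("fraction must lie in [0, 1)")
  n <- nrow(scored)
  n_excl <- floor(fraction * n)
  ord <- order(scored$qi, seq_len(n))   # stable: ties keep input order
  excl_idx <- sort(head(ord, n_excl))
  list(retained = tibble::as_tibble(scored[setdiff(seq_len(n), excl_idx), ]),
       excluded = tibble::as_tibble(scored[excl_idx, ]))
}
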