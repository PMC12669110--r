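#' @useDynLib octcvd, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data abort warn
#' @importFrom stats rnorm runif rgamma predict median sd quantile glm binomial
#'   plogis pchisq rbinom setNames complete.cases
#' @importFrom utils head write.csv
#' @import tibble
NULL

#' Derive a reproducible stage seed from a run seed
#'
#' Fans a single run seed out to per-stage seeds via an FNV-1a style hash of
#' the stage name, so stages rerun independently still see the same stream.
#'
#' @param seed Integer run seed.
#' @param stage Character stage name.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' stage_seed(1, "simulate")
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 2166136261
  for (b in utf8ToInt(stage)) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer((h + as.numeric(seed) * 1000003) %% 2147483647)
}

# FNV-1a hash of a character scalar, returned as hex. Used for run manifests
# and the held-out test-set immutability check; stable across sessions.
fnv1a_hex <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 2166136261
  for (b in utf8ToInt(x)) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

# Deterministic hash of an arbitrary (small) R object.
object_hash <- function(x) fnv1a_hex(paste(deparse(x), collapse = "\n"))

# Clamp numeric values into [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
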