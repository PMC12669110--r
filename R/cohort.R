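# Cohort construction: event window, comorbidity exclusions with a
# STROBE-style ledger, and 1:3 age/sex propensity matching.

#' Five-year event-window flag
#'
#' An event qualifies when it occurred after imaging and within the window:
#' the interval is half-open, `0 < event_offset <= window`, so pre-imaging
#' events are excluded and an event exactly at the horizon still counts.
#'
#' @param event_offset Years from imaging to the first MI/stroke event (may be
#'   `NA` for event-free subjects, which returns `FALSE`).
#' @param window Event horizon in years.
#' @return Logical vector.
#' @export
#' @examples
#' event_in_window(c(4.9, -1, 5, 5.000001, NA))
event_in_window <- function(event_offset, window = 5) {
  !is.na(event_offset) & event_offset > 0 & event_offset <= window
}

new_strobe_ledger <- function() {
  tibble::tibble(step = character(), n_before = integer(),
                 n_excluded = integer(), n_after = integer(),
                 reason = character())
}

ledger_add <- function(ledger, step, n_before, n_excluded, reason) {
  dplyr::bind_rows(ledger, tibble::tibble(
    step = step, n_before = as.integer(n_before),
    n_excluded = as.integer(n_excluded),
    n_after = as.integer(n_before - n_excluded), reason = reason))
}

#' Validate a STROBE ledger
#'
#' Checks per-step conservation (`n_after = n_before - n_excluded`) and
#' chaining (`n_after` of each step equals `n_before` of the next).
#'
#' @param ledger A ledger tibble as returned by [apply_exclusions()].
#' @return `TRUE` invisibly, or an error.
#' @export
validate_ledger <- function(ledger) {
  if (nrow(ledger) == 0) return(invisible(TRUE))
  if (!all(ledger$n_after == ledger$n_before - ledger$n_excluded)) {
    abort("ledger conservation violated: n_after != n_before - n_excluded")
  }
  if (nrow(ledger) > 1 &&
      !all(ledger$n_after[-nrow(ledger)] == ledger$n_before[-1])) {
    abort("ledger steps do not chain")
  }
  invisible(TRUE)
}

#' Apply comorbidity exclusion criteria with a STROBE-style ledger
#'
#' Each configured boolean flag is applied as one ledger step, in declaration
#' order; kept records have every flag `FALSE`.
#'
#' @param records Subject tibble carrying logical columns named by `flags`.
#' @param flags Character vector of exclusion flag columns.
#' @param ledger An existing ledger to append to (so the event-window step and
#'   further filters can share one ledger).
#' @return List with `kept` (tibble) and `ledger`.
#' @export
#' @examples
#' rec <- tibble::tibble(id = 1:4, diabetes = c(TRUE, FALSE, FALSE, FALSE),
#'                       cardiomyopathy = FALSE)
#' apply_exclusions(rec)$ledger
apply_exclusions <- function(records,
                             flags = c("diabetes", "cardiomyopathy"),
                             ledger = new_strobe_ledger()) {
  stopifnot(is.data.frame(records))
  missing <- setdiff(flags, names(records))
  if (length(missing)) {
    abort(sprintf("unknown exclusion flag(s): %s",
                  paste(missing, collapse = ", ")))
  }
  kept <- tibble::as_tibble(records)
  for (f in flags) {
    drop <- isTRUE_vec(kept[[f]])
    ledger <- ledger_add(ledger, paste0("exclude_", f), nrow(kept), sum(drop),
                         sprintf("subjects with %s excluded", f))
    kept <- kept[!drop, ]
  }
  validate_ledger(ledger)
  list(kept = kept, ledger = ledger)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Restrict CVD+ subjects to events inside the follow-up window
#'
#' CVD− records (no event) are kept; CVD+ records are kept only when
#' [event_in_window()] holds. Recorded as one ledger step.
#'
#' @inheritParams apply_exclusions
#' @param window Event horizon in years.
#' @return List with `kept` and `ledger`.
#' @export
apply_event_window <- function(records, window = 5,
                               ledger = new_strobe_ledger()) {
  is_case <- records$cvd_label == "CVD+"
  drop <- is_case & !event_in_window(records$event_offset, window)
  ledger <- ledger_add(ledger, "event_window", nrow(records), sum(drop),
                       sprintf("CVD+ events outside (0, %g] years", window))
  validate_ledger(ledger)
  list(kept = tibble::as_tibble(records)[!drop, ], ledger = ledger)
}

#' 1:3 age/sex propensity-score matching
#'
#' Fits a logistic propensity model of case status on the covariates, then —
#' within exact sex strata and in seeded random case order — greedily matches
#' each case without replacement to the `ratio` nearest controls by propensity
#' score, subject to an absolute age caliper. Matching is all-or-nothing: if
#' any case cannot be given `ratio` controls, an error lists the unmatched
#' cases rather than returning a silently partial match.
#'
#' @param records Subject tibble with `subject_id`, `cvd_label`, `age`, `sex`.
#' @param ratio Controls per case.
#' @param covariates Covariates of the propensity model.
#' @param caliper Maximum absolute age difference (years) of a matched pair.
#' @param seed Seed for the case-order shuffle.
#' @param on_unmatched `"error"` (default) aborts listing the unmatched cases;
#'   `"drop"` instead removes them from the matched cohort and records their
#'   ids in the result (`$unmatched`), the way studies drop cases that cannot
#'   be balanced.
#' @return A `matched_cohort`: list with `cases`, `controls` (ids), `pairing`
#'   (tibble `case_id`, `control_id`, `stratum`, `ps_distance`), `unmatched`,
#'   and the fitted propensity scores.
#' @export
propensity_match <- function(records, ratio = 3,
                             covariates = c("age", "sex"), caliper = 2,
                             seed = 1L, on_unmatched = c("error", "drop")) {
  on_unmatched <- match.arg(on_unmatched)
  stopifnot(all(c("subject_id", "cvd_label", covariates) %in% names(records)))
  records <- tibble::as_tibble(records)
  is_case <- records$cvd_label == "CVD+"
  if (!any(is_case) || !any(!is_case)) abort("need both cases and controls")

  # constant covariates (e.g. single-sex cohorts) carry no information and
  # would break the model matrix
  active <- covariates[vapply(records[covariates],
                              function(x) length(unique(x)) > 1, logical(1))]
  if (length(active)) {
    fml <- stats::as.formula(paste("is_case ~", paste(active, collapse = "+")))
    fit <- glm(fml, data = cbind(records, is_case = is_case),
               family = binomial())
    ps <- as.numeric(predict(fit, type = "response"))
  } else {
    ps <- rep(mean(is_case), nrow(records))
  }

  cases <- which(is_case)
  set.seed(seed)
  cases <- cases[sample.int(length(cases))]
  used <- rep(FALSE, nrow(records))
  rows <- vector("list", length(cases))
  unmatched <- character()
  for (j in seq_along(cases)) {
    i <- cases[j]
    cand <- which(!is_case & !used &
                    records$sex == records$sex[i] &
                    abs(records$age - records$age[i]) <= caliper)
    if (length(cand) < ratio) {
      unmatched <- c(unmatched, records$subject_id[i])
      next
    }
    d <- abs(ps[cand] - ps[i])
    pick <- cand[order(d, cand)][seq_len(ratio)]
    used[pick] <- TRUE
    rows[[j]] <- tibble::tibble(
      case_id = records$subject_id[i],
      control_id = records$subject_id[pick],
      stratum = records$sex[i],
      ps_distance = abs(ps[pick] - ps[i]))
  }
  if (length(unmatched) && on_unmatched == "error") {
    abort(sprintf("insufficient controls within caliper for case(s): %s",
                  paste(sort(unmatched), collapse = ", ")))
  }
  pairing <- dplyr::bind_rows(rows)
  matched_cases <- setdiff(records$subject_id[sort(cases)], unmatched)
  structure(list(cases = matched_cases,
                 controls = pairing$control_id,
                 pairing = pairing,
                 unmatched = sort(unmatched),
                 propensity = tibble::tibble(
                   subject_id = records$subject_id, ps = ps)),
            class = "matched_cohort")
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf("<matched_cohort> %d cases : %d controls (ratio %.2f)\n",
              length(x$cases), length(x$controls),
              length(x$controls) / length(x$cases)))
  invisible(x)
}

#' Covariate balance of a matched cohort
#'
#' Standardized mean differences between matched cases and controls
#' (difference in means over the pooled standard deviation); values below 0.1
#' are conventionally called balanced.
#'
#' @param matched A `matched_cohort`.
#' @param records The subject tibble the match was built from.
#' @param vars Continuous covariates to check.
#' @return Tibble `variable`, `smd`.
#' @export
matching_balance <- function(matched, records, vars = "age") {
  ca <- records[records$subject_id %in% matched$cases, , drop = FALSE]
  co <- records[records$subject_id %in% matched$controls, , drop = FALSE]
  tibble::tibble(
    variable = vars,
    smd = purrr::map_dbl(vars, function(v) {
      s <- sqrt((stats::var(ca[[v]]) + stats::var(co[[v]])) / 2)
      (mean(ca[[v]]) - mean(co[[v]])) / s
    }))
}

#' Render a ledger as a small text STROBE diagram
#'
#' @param ledger A ledger tibble.
#' @return Character scalar (multi-line).
#' @export
format_strobe <- function(ledger) {
  if (nrow(ledger) == 0) return("(empty ledger)")
  lines <- sprintf("[n = %d]\n  |-- %s: excluded %d (%s)\n  v",
                   ledger$n_before, ledger$step, ledger$n_excluded,
                   ledger$reason)
  paste(c(lines, sprintf("[n = %d]", ledger$n_after[nrow(ledger)])),
        collapse = "\n")
}

#' Export the ledger / matched pairs as CSV
#'
#' @param x Ledger tibble or `matched_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ledger_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ledger_csv
#' @export
write_matched_csv <- function(x, path) {
  write.csv(x$pairing, path, row.names = FALSE)
  invisible(path)
}
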