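#' Construct a right-censored dataset from time/status vectors
#'
#' The universal fitting input: positive follow-up times in years since
#' enrollment and an event indicator (1 = death observed, 0 = censored).
#'
#' @param time Positive follow-up times (years).
#' @param status 0/1 event indicators.
#' @param cohort_label,lock_label Free-text metadata.
#' @param max_followup Maximum follow-up (lock time minus enrollment start),
#'   in years; \code{NA} when unknown (e.g., user-supplied data).
#' @return A \code{data.frame} of class \code{"surv_dataset"} with columns
#'   \code{id}, \code{time}, \code{status}.
#' @export
surv_dataset <- function(time, status, cohort_label = "cohort",
                         lock_label = "all", max_followup = NA_real_) {
  if (length(time) == 0L) stop("empty dataset: no subjects")
  if (any(!is.finite(time)) || any(time <= 0))
    stop_field("time", "must be positive and finite")
  if (!all(status %in% c(0, 1))) stop_field("status", "must be 0 or 1")
  structure(
    data.frame(id = seq_along(time), time = as.numeric(time),
               status = as.integer(status)),
    cohort_label = cohort_label, lock_label = lock_label,
    max_followup = max_followup,
    class = c("surv_dataset", "data.frame")
  )
}

#' Apply a database lock to a raw cohort
#'
#' Emulates an administrative data cut-off at calendar time \code{lock_time}:
#' subjects enrolled at or after the lock are excluded; for each retained
#' subject the observed time is
#' \code{min(death_time, ltfu_time, lock_time) - enroll_time}, with an event
#' only when death occurs strictly before both the lock and any loss to
#' follow-up. Subjects alive and on study at the lock are censored there.
#' A death exactly at the lock instant counts as censored (administrative
#' censoring wins ties; with continuous times this is a measure-zero case).
#'
#' @param cohort A \code{raw_cohort}.
#' @param lock_time Calendar lock time in decimal years.
#' @param label Lock label stored in the dataset metadata.
#' @return A \code{\link{surv_dataset}} with \code{max_followup} equal to
#'   \code{lock_time - enroll_start} of the cohort.
#' @examples
#' spec <- cohort_spec(50, 2002, 2007, seed = 7)
#' locked <- apply_lock(generate_cohort(spec), 2008)
#' censoring_summary(locked)
#' @export
apply_lock <- function(cohort, lock_time, label = sprintf("lock@%.2f", lock_time)) {
  stopifnot(is.data.frame(cohort))
  if (!is_number(lock_time)) stop_field("lock_time", "must be a finite number")
  spec <- attr(cohort, "spec")
  enroll_start <- if (!is.null(spec)) spec$enroll_start else min(cohort$enroll_time)
  if (lock_time <= enroll_start)
    stop("empty dataset: lock precedes the start of enrollment")
  keep <- cohort$enroll_time < lock_time
  if (!any(keep)) stop("empty dataset: no subjects enrolled before the lock")
  sub <- cohort[keep, , drop = FALSE]
  ltfu <- ifelse(is.na(sub$ltfu_time), Inf, sub$ltfu_time)
  obs_end <- pmin(sub$death_time, ltfu, lock_time)
  status <- as.integer(sub$death_time <= ltfu & sub$death_time < lock_time)
  ds <- surv_dataset(obs_end - sub$enroll_time, status,
                     cohort_label = if (!is.null(spec)) spec$label else "cohort",
                     lock_label = label,
                     max_followup = lock_time - enroll_start)
  ds$id <- sub$id
  ds
}

#' Build a grid of locked datasets of increasing maximum follow-up
#'
#' Locks are anchored at the start of enrollment: each entry of
#' \code{max_followups} gives a lock at \code{enroll_start + max_followup},
#' the maturity axis of the analysis. The metadata of each dataset records
#' the maximum follow-up and the minimum potential follow-up
#' (\code{lock_time - enroll_end}, reported as \code{NA} when the lock falls
#' inside the enrollment window).
#'
#' @param cohort A \code{raw_cohort} produced by \code{\link{generate_cohort}}.
#' @param max_followups Strictly increasing positive years, e.g.
#'   \code{c(3, 6, 8, 10, 13)}.
#' @return A named list of \code{\link{surv_dataset}} objects, one per lock.
#' @export
lock_grid <- function(cohort, max_followups = c(3, 6, 8, 10, 13)) {
  if (any(max_followups <= 0) || is.unsorted(max_followups, strictly = TRUE))
    stop_field("max_followups", "must be strictly increasing and positive")
  spec <- attr(cohort, "spec")
  enroll_start <- if (!is.null(spec)) spec$enroll_start else min(cohort$enroll_time)
  enroll_end <- if (!is.null(spec)) spec$enroll_end else max(cohort$enroll_time)
  out <- lapply(max_followups, function(mf) {
    ds <- apply_lock(cohort, enroll_start + mf, label = sprintf("<%gy", mf))
    mpf <- enroll_start + mf - enroll_end
    attr(ds, "min_potential_followup") <- if (mpf > 0) mpf else NA_real_
    ds
  })
  names(out) <- sprintf("<%gy", max_followups)
  out
}

#' Censoring summary of a locked dataset
#'
#' @param ds A \code{\link{surv_dataset}}.
#' @return A list with \code{pct_censored} (percent), \code{n_events} and
#'   \code{n_subjects}.
#' @export
censoring_summary <- function(ds) {
  if (!is.data.frame(ds) || nrow(ds) == 0L) stop("empty dataset")
  n <- nrow(ds)
  ev <- sum(ds$status == 1L)
  list(pct_censored = 100 * (n - ev) / n, n_events = ev, n_subjects = n)
}

#' Read or write survival datasets as delimited text
#'
#' The standard two-column survival layout: columns \code{id}, \code{time},
#' \code{status} (1 = event, 0 = censored).
#'
#' @param ds A \code{surv_dataset}.
#' @param path File path.
#' @param time_col,status_col Column names in the file to read.
#' @return \code{read_surv_data} returns a \code{\link{surv_dataset}}.
#' @export
write_surv_data <- function(ds, path) {
  utils::write.csv(as.data.frame(ds)[c("id", "time", "status")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_surv_data
#' @export
read_surv_data <- function(path, time_col = "time", status_col = "status") {
  df <- utils::read.csv(path)
  if (!all(c(time_col, status_col) %in% names(df)))
    stop("file must have columns '", time_col, "' and '", status_col, "'")
  surv_dataset(df[[time_col]], df[[status_col]],
               cohort_label = basename(path))
}
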