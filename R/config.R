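#' Archetype cohort specifications for the default maturity experiment
#'
#' Three archetypes mirroring the structure of the data sources the analysis
#' is designed around: a randomized trial cohort (about 170 subjects enrolled
#' over five calendar years, evaluation horizon 11 years), a registry cohort
#' (about 550 subjects over five years, horizon 14 years) and a short-window
#' registry cohort (about 640 subjects over two years, horizon 8 years). All
#' use the generalized-gamma truth with median overall survival of 3.5 years
#' and no loss to follow-up (all censoring administrative).
#'
#' @param survival_model True hazard preset (default the non-monotone
#'   generalized gamma).
#' @param seed Base seed stored on each spec.
#' @return Named list of lists, each with elements \code{spec} (a
#'   \code{\link{cohort_spec}}), \code{horizon} and \code{max_followups}.
#' @export
study_cohorts <- function(survival_model = mm_hazard_presets()$gengamma,
                          seed = 1L) {
  list(
    trial = list(
      spec = cohort_spec(168, 2002.72, 2007.54, survival_model,
                         label = "trial", seed = seed),
      horizon = 11, max_followups = c(3, 6, 8, 10)),
    registry = list(
      spec = cohort_spec(552, 2005.0, 2010.0, survival_model,
                         label = "registry", seed = seed),
      horizon = 14, max_followups = c(3, 6, 8, 10, 13)),
    registry_short = list(
      spec = cohort_spec(637, 2014.03, 2016.03, survival_model,
                         label = "registry_short", seed = seed),
      horizon = 8, max_followups = c(3, 6, 8))
  )
}

#' Read a cohort specification from a key:value text file
#'
#' Plain-text format, one \code{key: value} pair per line; \code{#} starts a
#' comment. Recognised keys: \code{n_subjects}, \code{enroll_start},
#' \code{enroll_end}, \code{ltfu_rate}, \code{label}, \code{seed},
#' \code{survival_model} (a preset name from
#' \code{\link{mm_hazard_presets}}).
#'
#' @param path File path.
#' @return A \code{\link{cohort_spec}}.
#' @export
read_cohort_spec <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*:\\s*(.+)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stop("malformed config line: ", lines[bad][1L])
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- trimws(vapply(kv, `[`, character(1), 3L))
  cfg <- stats::setNames(as.list(vals), keys)
  num <- function(k, default) if (!is.null(cfg[[k]])) as.numeric(cfg[[k]]) else default
  preset <- if (!is.null(cfg$survival_model)) {
    presets <- mm_hazard_presets()
    if (!cfg$survival_model %in% names(presets))
      stop_field("survival_model", paste("unknown preset; use one of",
                                         paste(names(presets), collapse = ", ")))
    presets[[cfg$survival_model]]
  } else mm_hazard_presets()$gengamma
  cohort_spec(
    n_subjects = num("n_subjects", stop_field("n_subjects", "missing")),
    enroll_start = num("enroll_start", stop_field("enroll_start", "missing")),
    enroll_end = num("enroll_end", stop_field("enroll_end", "missing")),
    survival_model = preset,
    ltfu_rate = num("ltfu_rate", 0),
    label = if (!is.null(cfg$label)) cfg$label else "cohort",
    seed = num("seed", 1)
  )
}
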