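#' The 16-model extrapolation roster
#'
#' The seven standard parametric families plus the nine Royston-Parmar spline
#' models (hazard, odds and normal scales crossed with 1-3 internal knots).
#' The roster order is fixed and documented because it is the final
#' tie-break in model selection.
#'
#' @return A data.frame with columns \code{model}, \code{class},
#'   \code{family} (or NA), \code{scale}, \code{n_internal_knots}.
#' @export
model_roster <- function() {
  std <- data.frame(model = survival_families(), class = "standard",
                    family = survival_families(), scale = NA_character_,
                    n_internal_knots = NA_integer_)
  grid <- expand.grid(n_internal_knots = 1:3,
                      scale = c("hazard", "odds", "normal"),
                      stringsAsFactors = FALSE)
  spl <- data.frame(model = sprintf("spline_%s_%dk", grid$scale, grid$n_internal_knots),
                    class = "spline", family = NA_character_,
                    scale = grid$scale, n_internal_knots = grid$n_internal_knots)
  rbind(std, spl)
}

#' Fit every roster model to one locked dataset
#'
#' Fit failures (e.g., infeasible knot placement under heavy ties) are
#' retained as flagged non-converged stubs so evaluation tables keep one row
#' per roster model.
#'
#' @param ds A \code{\link{surv_dataset}}.
#' @param roster A roster data.frame, by default \code{\link{model_roster}}.
#' @return Named list of fits (or failure stubs) in roster order.
#' @export
fit_roster <- function(ds, roster = model_roster()) {
  fits <- vector("list", nrow(roster))
  names(fits) <- roster$model
  for (i in seq_len(nrow(roster))) {
    fits[[i]] <- tryCatch({
      if (roster$class[i] == "standard") {
        fit_parametric(roster$family[i], ds)
      } else {
        fit_spline(ds, spline_spec(roster$scale[i], roster$n_internal_knots[i]))
      }
    }, error = function(e) {
      structure(list(model = roster$model[i], class_label = roster$class[i],
                     k = if (roster$class[i] == "standard")
                       family_spec(roster$family[i])$n_params
                     else roster$n_internal_knots[i] + 2L,
                     error = conditionMessage(e)),
                class = "failed_fit")
    })
  }
  fits
}

#' Select models by information criterion
#'
#' Per criterion, the converged model with the lowest value; exact ties are
#' broken by the smallest number of free parameters (parsimony), then by
#' roster order. Non-converged and failed fits are excluded from selection.
#'
#' @param fits List of fits as returned by \code{\link{fit_roster}}.
#' @param criteria Which criteria to apply.
#' @return Named list mapping criterion to the selected model id.
#' @examples
#' ds <- surv_dataset(rexp(80, 0.3), rep(1, 80))
#' fits <- list(exp = fit_parametric("exponential", ds),
#'              wei = fit_parametric("weibull", ds))
#' select_models(fits)
#' @export
select_models <- function(fits, criteria = c("AIC", "BIC")) {
  ok <- vapply(fits, function(f) inherits(f, "surv_model_fit") && f$converged,
               logical(1))
  if (!any(ok)) stop("no converged model to select from")
  usable <- fits[ok]
  ids <- vapply(usable, model_id, character(1))
  ks <- vapply(usable, n_free_params, numeric(1))
  out <- lapply(criteria, function(cr) {
    val <- vapply(usable, function(f) if (cr == "AIC") f$aic else f$bic, numeric(1))
    cand <- which(val == min(val))
    cand <- cand[ks[cand] == min(ks[cand])]
    unname(ids[cand[1L]]) # roster order as final tie-break
  })
  names(out) <- criteria
  out
}

#' Evaluate one lock against long-follow-up reference data
#'
#' The core accuracy measurement: every roster model is fitted to the locked
#' dataset; lifetime RMST (default horizon 35 years), RMST over the
#' evaluation horizon and conditional RMST (conditioning at the lock's
#' maximum follow-up, the point from which extrapolation is required) are
#' computed from each fitted model and compared to the Kaplan-Meier estimate
#' of the reference (long follow-up) dataset. Errors are signed: model minus
#' Kaplan-Meier. The Kaplan-Meier side of the conditional error uses the
#' reference curve for both the integral and \eqn{S(t_0)}.
#'
#' @param reference A \code{\link{surv_dataset}} whose follow-up covers
#'   \code{horizon}.
#' @param locked A lock of the same cohort (a \code{\link{surv_dataset}}).
#' @param horizon Evaluation horizon in years.
#' @param lifetime_horizon Lifetime horizon in years (default 35).
#' @param t0 Conditioning time; defaults to the locked dataset's maximum
#'   follow-up.
#' @param roster Model roster data.frame.
#' @return A data.frame with one row per roster model (an
#'   \code{EvaluationRecord}): cohort/lock labels, max_followup,
#'   pct_censored, n_events, model id/class/k, converged flag, loglik, aic,
#'   bic, lifetime_rmst, rmst, rmst_error, cond_rmst, cond_rmst_error,
#'   selected_by.
#' @export
evaluate_lock <- function(reference, locked, horizon,
                          lifetime_horizon = 35,
                          t0 = attr(locked, "max_followup"),
                          roster = model_roster()) {
  km_ref <- km_fit(reference)
  if (km_ref$last_obs < horizon && km_surv(km_ref, km_ref$last_obs) > 0)
    warning("reference follow-up ends before the horizon with survivors; ",
            "KM RMST uses the flat extension")
  km_h <- as.numeric(km_rmst(km_ref, horizon, extend = TRUE))
  do_cond <- is_number(t0) && t0 > 0 && t0 < horizon
  if (do_cond) {
    s0_ref <- km_surv(km_ref, t0)
    km_cond <- if (s0_ref > 0) km_conditional_rmst(km_ref, t0, horizon, extend = TRUE) else NA_real_
  } else {
    km_cond <- NA_real_
  }

  fits <- fit_roster(locked, roster)
  sel <- tryCatch(select_models(fits), error = function(e) list(AIC = NA, BIC = NA))
  cs <- censoring_summary(locked)

  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    base <- data.frame(
      cohort = attr(locked, "cohort_label") %||% "cohort",
      lock = attr(locked, "lock_label") %||% "lock",
      max_followup = attr(locked, "max_followup") %||% NA_real_,
      pct_censored = cs$pct_censored, n_events = cs$n_events,
      model = roster$model[i], class = roster$class[i])
    if (!inherits(f, "surv_model_fit")) {
      return(cbind(base, data.frame(
        n_free_params = f$k, converged = FALSE,
        loglik = NA_real_, aic = NA_real_, bic = NA_real_,
        lifetime_rmst = NA_real_, rmst = NA_real_, rmst_error = NA_real_,
        cond_rmst = NA_real_, cond_rmst_error = NA_real_,
        selected_by = "", note = f$error)))
    }
    life <- tryCatch(rmst(f, lifetime_horizon), error = function(e) NA_real_)
    r_h <- tryCatch(rmst(f, horizon), error = function(e) NA_real_)
    r_c <- if (do_cond) tryCatch(rmst(f, horizon, t0 = t0), error = function(e) NA_real_)
           else NA_real_
    picked <- c("AIC", "BIC")[vapply(sel, identical, logical(1), y = model_id(f))]
    cbind(base, data.frame(
      n_free_params = n_free_params(f), converged = f$converged,
      loglik = f$loglik, aic = f$aic, bic = f$bic,
      lifetime_rmst = life, rmst = r_h, rmst_error = r_h - km_h,
      cond_rmst = r_c, cond_rmst_error = r_c - km_cond,
      selected_by = paste(picked, collapse = "+"), note = ""))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "km_rmst") <- km_h
  attr(out, "km_cond_rmst") <- km_cond
  attr(out, "fits") <- fits
  class(out) <- c("evaluation_records", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Configure a full maturity experiment
#'
#' @param cohorts List of \code{\link{cohort_spec}} objects (each carries its
#'   own seed; \code{\link{run_experiment}} reseeds them from the experiment
#'   seed and replicate index).
#' @param max_followups Lock grid in years since enrollment start.
#' @param horizon Evaluation horizon in years (must be covered by the
#'   reference follow-up).
#' @param lifetime_horizon Lifetime RMST horizon (default 35 years).
#' @param ref_followup Maximum follow-up of the reference lock; defaults to
#'   \code{horizon} plus the longest enrollment window so that every subject
#'   has potential follow-up of at least \code{horizon}.
#' @param n_replicates Number of replicate cohorts per spec.
#' @param seed Experiment master seed.
#' @return An object of class \code{"experiment_config"}.
#' @export
experiment_config <- function(cohorts, max_followups = c(3, 6, 8, 10, 13),
                              horizon = 14, lifetime_horizon = 35,
                              ref_followup = NULL, n_replicates = 1L,
                              seed = 1L) {
  if (inherits(cohorts, "cohort_spec")) cohorts <- list(cohorts)
  stopifnot(all(vapply(cohorts, inherits, logical(1), "cohort_spec")))
  windows <- vapply(cohorts, function(cs) cs$enroll_end - cs$enroll_start, numeric(1))
  if (is.null(ref_followup)) ref_followup <- horizon + max(windows)
  if (ref_followup < horizon + max(windows))
    stop_field("ref_followup", "must cover the evaluation horizon for every subject")
  if (max(max_followups) > ref_followup)
    stop_field("max_followups", "locks cannot exceed the reference follow-up")
  structure(list(cohorts = cohorts, max_followups = max_followups,
                 horizon = horizon, lifetime_horizon = lifetime_horizon,
                 ref_followup = ref_followup,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run a full maturity experiment
#'
#' For each cohort spec and replicate: generate the cohort, build the
#' reference dataset (a lock at \code{ref_followup}), build the lock grid,
#' and evaluate every lock with \code{\link{evaluate_lock}}. Everything is
#' reproducible from the experiment seed: replicate r of cohort c uses seed
#' \code{seed + 10000 * c + r}.
#'
#' @param cfg An \code{\link{experiment_config}}.
#' @param out_dir Optional directory; when given, the record table, the
#'   summary tables, the run manifest and diagnostic figures are written
#'   there.
#' @return List with \code{records} (all EvaluationRecords), \code{summaries}
#'   (see \code{\link{summarize_records}}) and \code{config}.
#' @export
run_experiment <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  all_records <- list()
  for (ci in seq_along(cfg$cohorts)) {
    spec0 <- cfg$cohorts[[ci]]
    for (r in seq_len(cfg$n_replicates)) {
      spec <- spec0
      spec$seed <- cfg$seed + 10000L * ci + r
      spec$label <- if (cfg$n_replicates > 1L)
        sprintf("%s_rep%d", spec0$label, r) else spec0$label
      cohort <- generate_cohort(spec)
      reference <- apply_lock(cohort, spec$enroll_start + cfg$ref_followup,
                              label = "reference")
      locks <- lock_grid(cohort, cfg$max_followups)
      for (ds in locks) {
        rec <- evaluate_lock(reference, ds, horizon = cfg$horizon,
                             lifetime_horizon = cfg$lifetime_horizon)
        attr(rec, "fits") <- NULL
        rec$replicate <- r
        all_records[[length(all_records) + 1L]] <- as.data.frame(rec)
      }
    }
  }
  records <- do.call(rbind, all_records)
  summaries <- summarize_records(records)
  res <- list(records = records, summaries = summaries, config = cfg)
  if (!is.null(out_dir)) write_experiment(res, out_dir)
  res
}

#' Summarise RMST errors by maturity strata
#'
#' Median signed and median absolute RMST error (plain and conditional),
#' grouped the way the maturity analysis stratifies accuracy: by lock, by
#' 10-point censoring-percentage bins, by event-count bins, and by model
#' class (standard parametric vs spline).
#'
#' @param records EvaluationRecord data.frame from \code{\link{run_experiment}}
#'   or \code{\link{evaluate_lock}}.
#' @return Named list of summary data.frames: \code{by_lock},
#'   \code{by_censoring}, \code{by_events}, \code{by_class}.
#' @export
summarize_records <- function(records) {
  rec <- records[records$converged & is.finite(records$rmst_error), , drop = FALSE]
  if (nrow(rec) == 0L) stop("no converged records to summarise")
  grp_summary <- function(g) {
    g <- droplevels(factor(g)) # empty bins carry no rows
    agg <- function(v, f) unname(tapply(v, g, f))
    data.frame(group = levels(g),
               n_records = as.vector(table(g)),
               median_error = agg(rec$rmst_error, stats::median),
               median_abs_error = agg(abs(rec$rmst_error), stats::median),
               median_cond_error = agg(rec$cond_rmst_error,
                                       function(x) stats::median(x, na.rm = TRUE)),
               median_abs_cond_error = agg(abs(rec$cond_rmst_error),
                                           function(x) stats::median(x, na.rm = TRUE)))
  }
  cens_bin <- cut(rec$pct_censored, breaks = seq(0, 100, by = 10),
                  include.lowest = TRUE, right = FALSE)
  ev_bin <- cut(rec$n_events, breaks = c(0, 25, 50, 100, 200, 400, Inf),
                include.lowest = TRUE)
  list(
    by_lock = grp_summary(sprintf("%05.1fy|%s", rec$max_followup, rec$lock)),
    by_censoring = grp_summary(cens_bin),
    by_events = grp_summary(ev_bin),
    by_class = grp_summary(rec$class)
  )
}

write_experiment <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$records, file.path(out_dir, "records.csv"),
                   row.names = FALSE)
  for (nm in names(res$summaries)) {
    utils::write.csv(res$summaries[[nm]],
                     file.path(out_dir, sprintf("summary_%s.csv", nm)),
                     row.names = FALSE)
  }
  manifest <- c(
    sprintf("package: survmature %s", as.character(utils::packageVersion("survmature"))),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    sprintf("seed: %d", res$config$seed),
    sprintf("replicates: %d", res$config$n_replicates),
    sprintf("horizon: %g", res$config$horizon),
    sprintf("lifetime_horizon: %g", res$config$lifetime_horizon),
    sprintf("ref_followup: %g", res$config$ref_followup),
    sprintf("max_followups: %s", paste(res$config$max_followups, collapse = ",")),
    sprintf("cohorts: %s", paste(vapply(res$config$cohorts, function(cs)
      sprintf("%s(n=%d)", cs$label, cs$n_subjects), character(1)), collapse = ","))
  )
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  for (p in c("pct_censored", "n_events")) {
    gg <- plot_rmst_error(res$records, x = p)
    ggplot2::ggsave(file.path(out_dir, sprintf("rmst_error_by_%s.png", p)),
                    gg, width = 7, height = 5, dpi = 150)
    gg2 <- plot_rmst_error(res$records, x = p, conditional = TRUE)
    ggplot2::ggsave(file.path(out_dir, sprintf("cond_rmst_error_by_%s.png", p)),
                    gg2, width = 7, height = 5, dpi = 150)
  }
  invisible(out_dir)
}
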