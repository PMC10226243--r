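#' Scatter plot of RMST error against a maturity covariate
#'
#' The standard diagnostic of the maturity analysis: signed RMST error (or
#' conditional RMST error) for every fitted model, plotted against the
#' percentage censored or the absolute number of events at the lock, coloured
#' by model class.
#'
#' @param records EvaluationRecord data.frame.
#' @param x Covariate: \code{"pct_censored"} or \code{"n_events"}.
#' @param conditional Plot the conditional RMST error instead?
#' @return A ggplot object.
#' @export
plot_rmst_error <- function(records, x = c("pct_censored", "n_events"),
                            conditional = FALSE) {
  x <- match.arg(x)
  y <- if (conditional) "cond_rmst_error" else "rmst_error"
  rec <- records[records$converged & is.finite(records[[y]]), , drop = FALSE]
  ggplot2::ggplot(rec, ggplot2::aes(x = .data[[x]], y = .data[[y]],
                                    colour = .data$class)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = if (x == "pct_censored") "Censored (%)" else "Number of events",
      y = if (conditional) "Conditional RMST error (years)" else "RMST error (years)",
      colour = "Model class") +
    ggplot2::theme_bw()
}

#' Survival and smoothed-hazard diagnostic panels for one locked dataset
#'
#' Kaplan-Meier step curve with the fitted model survival curves overlaid
#' (left), and the kernel-smoothed hazard with fitted model hazards (right) -
#' the two visual-fit diagnostics used to judge extrapolations.
#'
#' @param ds Locked \code{\link{surv_dataset}}.
#' @param fits List of fitted models (e.g. from \code{\link{fit_roster}}).
#' @param horizon Time axis upper limit (defaults to twice the last
#'   observation).
#' @return A ggplot object (faceted survival/hazard panels).
#' @export
plot_fit_diagnostics <- function(ds, fits, horizon = NULL) {
  km <- km_fit(ds)
  if (is.null(horizon)) horizon <- 2 * km$last_obs
  grid <- seq(horizon / 400, horizon, length.out = 400L)
  fits <- Filter(function(f) inherits(f, "surv_model_fit") && f$converged, fits)
  model_df <- do.call(rbind, lapply(fits, function(f) {
    data.frame(model = model_id(f), class = model_class(f), time = grid,
               survival = surv_prob(f, grid), hazard = haz_rate(f, grid))
  }))
  long <- rbind(
    transform(model_df, panel = "Survival", value = model_df$survival),
    transform(model_df, panel = "Hazard", value = model_df$hazard)
  )
  km_df <- data.frame(time = c(0, rep(km$event_times, each = 2), km$last_obs),
                      value = c(1, 1, rep(km$surv, each = 2)),
                      panel = "Survival")
  hz <- smoothed_hazard(ds)
  hz_df <- data.frame(time = hz$grid, value = hz$hazard, panel = "Hazard")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$model, colour = .data$class),
                       alpha = 0.7) +
    ggplot2::geom_step(data = km_df, linewidth = 0.9) +
    ggplot2::geom_line(data = hz_df, linewidth = 0.9) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "Years since enrollment", y = NULL,
                  colour = "Model class") +
    ggplot2::theme_bw()
}
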