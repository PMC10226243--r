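#' Kaplan-Meier estimate of a locked dataset
#'
#' Product-limit estimator \eqn{S(t) = \prod_{t_i \le t} (1 - d_i/n_i)} over
#' distinct event times, with events processed before censorings at tied
#' times (the standard convention) and Greenwood standard errors. The
#' estimate is delegated to \code{\link[survival]{survfit}}.
#'
#' @param ds A \code{\link{surv_dataset}}.
#' @return An object of class \code{"km_curve"}: list with \code{event_times},
#'   \code{surv}, \code{n_risk}, \code{n_event}, \code{std_err} (Greenwood, on
#'   the survival scale), and \code{last_obs}, the largest observed time.
#' @examples
#' ds <- surv_dataset(c(1, 2, 3), c(1, 0, 1))
#' km_fit(ds)$surv
#' @export
km_fit <- function(ds) {
  if (!is.data.frame(ds) || nrow(ds) == 0L) stop("empty dataset")
  sf <- survival::survfit(survival::Surv(time, status) ~ 1,
                          data = as.data.frame(ds), conf.type = "log-log")
  ev <- sf$n.event > 0
  structure(
    list(event_times = sf$time[ev], surv = sf$surv[ev],
         n_risk = sf$n.risk[ev], n_event = sf$n.event[ev],
         std_err = (sf$std.err * sf$surv)[ev],
         last_obs = max(ds$time), n = nrow(ds)),
    class = "km_curve"
  )
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d subjects, %d event times, last observation %.3g\n",
              x$n, length(x$event_times), x$last_obs))
  invisible(x)
}

#' Survival probability of a Kaplan-Meier curve at arbitrary times
#'
#' Step-function lookup; 1 before the first event, flat after the last.
#' Values beyond \code{last_obs} are returned (flat) but are only meaningful
#' under the extend-flat convention of \code{\link{km_rmst}}.
#'
#' @param curve A \code{km_curve}.
#' @param t Times (years).
#' @return Survival probabilities.
#' @export
km_surv <- function(curve, t) {
  idx <- findInterval(t, curve$event_times)
  c(1, curve$surv)[idx + 1L]
}

#' Restricted mean survival time from a Kaplan-Meier curve
#'
#' Exact area under the step survival function on \code{[0, horizon]}. The
#' Kaplan-Meier curve is undefined beyond its largest observed time, so
#' horizons past \code{last_obs} are refused unless \code{extend = TRUE},
#' which carries the final survival value flat to the horizon and flags the
#' result with attribute \code{"extended"}.
#'
#' @param curve A \code{km_curve}.
#' @param horizon Positive horizon in years.
#' @param extend Carry the curve flat beyond its last observation?
#' @return RMST in years.
#' @export
km_rmst <- function(curve, horizon, extend = FALSE) {
  if (!is_number(horizon) || horizon <= 0) stop_field("horizon", "must be positive")
  if (horizon > curve$last_obs && !extend)
    stop("horizon ", horizon, " exceeds the last observed time ",
         signif(curve$last_obs, 6),
         "; the KM curve is undefined there (use extend = TRUE to carry it flat)")
  breaks <- c(0, curve$event_times, Inf)
  vals <- c(1, curve$surv)
  out <- step_auc(breaks, vals, 0, horizon)
  if (horizon > curve$last_obs) attr(out, "extended") <- TRUE
  out
}

#' Conditional restricted mean survival time from a Kaplan-Meier curve
#'
#' Expected additional survival on \code{[t0, horizon]} given survival to
#' \code{t0}: \eqn{\int_{t0}^{horizon} S(u)\,du \; / \; S(t0)}.
#'
#' @param curve A \code{km_curve}.
#' @param t0 Conditioning time, \code{0 < t0 < horizon}.
#' @param horizon Horizon in years.
#' @param extend Passed to the underlying area computation as in
#'   \code{\link{km_rmst}}.
#' @return Conditional RMST in years.
#' @export
km_conditional_rmst <- function(curve, t0, horizon, extend = FALSE) {
  if (!is_number(t0) || t0 <= 0 || t0 >= horizon)
    stop_field("t0", "must satisfy 0 < t0 < horizon")
  s0 <- km_surv(curve, t0)
  if (s0 <= 0) stop("conditional RMST undefined: S(t0) = 0")
  num <- as.numeric(km_rmst(curve, horizon, extend = extend)) -
    as.numeric(km_rmst(curve, t0, extend = extend))
  num / s0
}

#' Kernel-smoothed hazard estimate
#'
#' Smooths the Nelson-Aalen increments \eqn{d_i/n_i} with an Epanechnikov
#' kernel of fixed bandwidth, renormalising the kernel mass near \eqn{t = 0}
#' (boundary correction), on a 256-point grid from 0 to the last event time.
#' Intended as a visual diagnostic for judging fitted hazard shapes.
#'
#' @param ds A \code{\link{surv_dataset}} with at least 2 events.
#' @param bandwidth Bandwidth in years, or \code{"auto"} for
#'   (last event time - first event time) / 8.
#' @return An object of class \code{"hazard_curve"}: list with \code{grid},
#'   \code{hazard}, \code{bandwidth}.
#' @export
smoothed_hazard <- function(ds, bandwidth = "auto") {
  if (sum(ds$status == 1L) < 2L) stop("need at least 2 events to smooth a hazard")
  km <- km_fit(ds)
  tev <- km$event_times
  dn <- km$n_event / km$n_risk
  b <- if (identical(bandwidth, "auto")) (max(tev) - min(tev)) / 8 else bandwidth
  if (!is_number(b) || b <= 0) stop_field("bandwidth", "must be positive or 'auto'")
  grid <- seq(0, max(tev), length.out = 256L)
  epan <- function(u) ifelse(abs(u) <= 1, 0.75 * (1 - u^2), 0)
  haz <- vapply(grid, function(g) {
    w <- epan((g - tev) / b) / b
    sum(w * dn)
  }, numeric(1))
  # boundary renormalisation: divide by the kernel mass visible on [0, last]
  q <- vapply(grid, function(g) {
    lo <- max(-1, -g / b)
    # integral of epan on [lo, 1]
    0.75 * ((1 - 1^3 / 3) - (lo - lo^3 / 3))
  }, numeric(1))
  q[q < 1e-12] <- 1
  structure(list(grid = grid, hazard = haz / q, bandwidth = b),
            class = "hazard_curve")
}

#' Export a Kaplan-Meier curve as a plain-text table
#'
#' @param curve A \code{km_curve}.
#' @param path File path; columns \code{time}, \code{estimate}, \code{lower},
#'   \code{upper} (pointwise normal-approximation bounds from the Greenwood
#'   standard error, clipped to [0, 1]).
#' @return \code{path}, invisibly.
#' @export
write_km_curve <- function(curve, path) {
  lower <- pmax(curve$surv - 1.96 * curve$std_err, 0)
  upper <- pmin(curve$surv + 1.96 * curve$std_err, 1)
  utils::write.csv(data.frame(time = curve$event_times, estimate = curve$surv,
                              lower = lower, upper = upper),
                   path, row.names = FALSE)
  invisible(path)
}
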