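#' Restricted and conditional restricted mean survival time of a fitted model
#'
#' RMST is the area under the model survival curve: \eqn{\int_0^{horizon}
#' S(u)\,du}. With \code{t0 > 0} the conditional form is returned, the
#' restricted mean residual life \eqn{\int_{t0}^{horizon} S(u)\,du / S(t0)}.
#' Integration is adaptive quadrature at absolute tolerance 1e-8; for spline
#' models the integral over \code{[0, t0]} uses the log-time change of
#' variable \eqn{t = e^u}, avoiding the \eqn{t = 0} boundary where the
#' log-time spline is not defined.
#'
#' @param fit A \code{surv_model_fit} (parametric or spline).
#' @param horizon Upper limit in years.
#' @param t0 Conditioning time; 0 (default) gives the unconditional RMST.
#' @return RMST in years.
#' @examples
#' ds <- surv_dataset(rexp(100, 0.2), rep(1, 100))
#' fit <- fit_parametric("exponential", ds)
#' rmst(fit, 35)
#' @export
rmst <- function(fit, horizon, t0 = 0) {
  stopifnot(inherits(fit, "surv_model_fit"))
  if (!is_number(horizon) || !is_number(t0) || t0 < 0 || t0 >= horizon)
    stop_field("t0", "must satisfy 0 <= t0 < horizon")
  if (t0 == 0) return(.surv_auc(fit, 0, horizon))
  s0 <- surv_prob(fit, t0)
  if (!is.finite(s0) || s0 <= 0)
    stop("conditional RMST undefined: S(t0) underflows to 0")
  .surv_auc(fit, t0, horizon) / s0
}

# \int_lower^upper S(u) du by adaptive quadrature. Spline survival is defined
# only for t > 0, so integrals starting at 0 are computed in u = log t.
.surv_auc <- function(fit, lower, upper) {
  if (lower == 0 && inherits(fit, "spline_fit")) {
    f <- function(u) surv_prob(fit, pmax(exp(u), .Machine$double.xmin)) * exp(u)
    stats::integrate(f, -Inf, log(upper), abs.tol = 1e-8, rel.tol = 1e-10,
                     subdivisions = 500L)$value
  } else {
    stats::integrate(function(u) surv_prob(fit, pmax(u, .Machine$double.xmin)),
                     lower, upper, abs.tol = 1e-8, rel.tol = 1e-10,
                     subdivisions = 500L)$value
  }
}
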