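#' Right-censored log-likelihood of a parametric family
#'
#' \eqn{\ell = \sum_{\delta_i = 1} \log f(t_i) + \sum_{\delta_i = 0} \log
#' S(t_i)} under the pinned parameterizations of \code{\link{family_spec}}.
#' Parameter points outside the family's domain return \code{-Inf} rather
#' than raising an error, so optimizers can step through them.
#'
#' @param family Family name (see \code{\link{survival_families}}) or a
#'   \code{family_spec}.
#' @param params Natural-scale parameter vector.
#' @param ds A \code{\link{surv_dataset}}.
#' @return The log-likelihood (scalar; \code{-Inf} off-domain).
#' @examples
#' ds <- surv_dataset(1, 1)
#' surv_loglik("exponential", 1, ds) # log f(1) = -1
#' @export
surv_loglik <- function(family, params, ds) {
  name <- if (inherits(family, "family_spec")) family$name else family
  if (any(ds$time <= 0)) stop_field("time", "must be positive")
  if (!family_params_valid(name, params)) return(-Inf)
  ev <- ds$status == 1L
  ll <- sum(family_logdens(name, ds$time[ev], params)) +
    sum(family_logsurv(name, ds$time[!ev], params))
  if (!is.finite(ll)) -Inf else ll
}

# Deterministic multi-start points on the unconstrained scale: the
# moment-based start plus 4 fixed perturbations (seeded once, frozen).
.start_perturbations <- function(k) {
  mat <- with_seed(20230529L, matrix(stats::rnorm(4L * k, sd = 0.5), nrow = 4L))
  rbind(rep(0, k), mat)
}

# Moment-based natural-scale starting values per family.
.family_start <- function(name, ds) {
  tev <- ds$time[ds$status == 1L]
  rate0 <- max(sum(ds$status) / sum(ds$time), 1e-8) # events per person-year
  mlog <- mean(log(tev))
  slog <- stats::sd(log(tev))
  if (!is.finite(slog) || slog < 0.05) slog <- 0.5
  m <- mean(tev); s <- stats::sd(tev)
  if (!is.finite(s) || s <= 0) s <- m
  switch(name,
    exponential = rate0,
    weibull = c(min(max(1 / slog, 0.2), 10), exp(mlog)),
    gompertz = c(0, rate0),
    gamma = c(min(max((m / s)^2, 0.2), 50), min(max(m / s^2, 1e-6), 50)),
    loglogistic = c(exp(mlog), min(max(pi / (sqrt(3) * slog), 0.2), 10)),
    lognormal = c(mlog, slog),
    gengamma = c(mlog, slog, 0)
  )
}

#' Fit a parametric survival family by censored maximum likelihood
#'
#' Maximizes \code{\link{surv_loglik}} on the unconstrained scale (positive
#' parameters log-transformed) by Nelder-Mead followed by quasi-Newton (BFGS)
#' polishing, from 5 deterministic starts (a moment-based start plus frozen
#' perturbations). The best finite optimum is kept. Non-converged fits are
#' returned flagged, not dropped, so that downstream selection can exclude
#' them while evaluation tables still report them.
#'
#' @param family Family name or \code{family_spec}.
#' @param ds A \code{\link{surv_dataset}} with at least one event and more
#'   subjects than free parameters.
#' @return An object of classes \code{"parametric_fit"} and
#'   \code{"surv_model_fit"}: list with \code{family} (family_spec),
#'   \code{params} (natural scale, named), \code{coef_unconstrained},
#'   \code{loglik}, \code{aic}, \code{bic} (BIC uses n = subjects),
#'   \code{converged}, \code{n_used}, \code{n_events}, \code{vcov}
#'   (unconstrained scale, or NULL).
#' @examples
#' ds <- surv_dataset(rexp(50, 0.4), rep(1, 50))
#' fit <- fit_parametric("exponential", ds)
#' coef(fit); AIC(fit)
#' @export
fit_parametric <- function(family, ds) {
  fam <- if (inherits(family, "family_spec")) family else family_spec(family)
  n <- nrow(ds)
  n_ev <- sum(ds$status == 1L)
  if (n_ev < 1L) stop("fit refused: dataset has no events")
  if (n < fam$n_params + 1L)
    stop("fit refused: need at least ", fam$n_params + 1L, " subjects")
  theta0 <- fam$to_unconstrained(.family_start(fam$name, ds))
  negll <- function(theta) {
    ll <- surv_loglik(fam$name, fam$from_unconstrained(theta), ds)
    if (!is.finite(ll)) 1e10 else -ll
  }
  starts <- sweep(.start_perturbations(fam$n_params), 2L, theta0, `+`)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- .optimize_negll(starts[i, ], negll)
    if (is.null(best) || o$value < best$value) best <- o
  }
  loglik <- -best$value
  k <- fam$n_params
  vcov <- .safe_vcov(best$hessian)
  converged <- isTRUE(best$convergence == 0L) && is.finite(loglik) &&
    !is.null(vcov)
  params <- fam$from_unconstrained(best$par)
  names(params) <- fam$par_names
  structure(
    list(family = fam, params = params, coef_unconstrained = best$par,
         loglik = loglik, aic = -2 * loglik + 2 * k,
         bic = -2 * loglik + k * log(n),
         converged = converged, n_used = n, n_events = n_ev, vcov = vcov),
    class = c("parametric_fit", "surv_model_fit")
  )
}

.optimize_negll <- function(start, negll, gradll = NULL) {
  o1 <- if (length(start) == 1L) {
    # golden-section search in 1D, where a simplex is unreliable
    tryCatch({
      g <- stats::optimize(function(x) negll(x), interval = start + c(-8, 8),
                           tol = 1e-12)
      list(par = g$minimum, value = g$objective, convergence = 0L)
    }, error = function(e) NULL)
  } else {
    tryCatch(
      stats::optim(start, negll, method = "Nelder-Mead",
                   control = list(maxit = 1000L, reltol = 1e-12)),
      error = function(e) NULL
    )
  }
  if (is.null(o1)) o1 <- list(par = start, value = negll(start), convergence = 1L)
  o2 <- tryCatch(
    stats::optim(o1$par, negll, gr = gradll, method = "BFGS", hessian = TRUE,
                 control = list(maxit = 500L, reltol = 1e-14)),
    error = function(e) NULL
  )
  if (is.null(o2) || !is.finite(o2$value) || o2$value > o1$value) {
    h <- tryCatch(stats::optimHess(o1$par, negll), error = function(e) NULL)
    c(o1, list(hessian = h))
  } else o2
}

.safe_vcov <- function(hessian) {
  if (is.null(hessian) || any(!is.finite(hessian))) return(NULL)
  v <- tryCatch(solve(hessian), error = function(e) NULL)
  if (is.null(v) || any(!is.finite(v)) || any(diag(v) <= 0)) return(NULL)
  v
}

#' @export
logLik.surv_model_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$params),
            nobs = object$n_used, class = "logLik")
}

#' @export
coef.parametric_fit <- function(object, ...) object$params

#' @export
print.parametric_fit <- function(x, ...) {
  cat(sprintf("Parametric survival fit: %s (%s)\n", x$family$name,
              if (x$converged) "converged" else "NOT converged"))
  print(signif(x$params, 5))
  cat(sprintf("logLik %.3f  AIC %.2f  BIC %.2f  (n = %d, events = %d)\n",
              x$loglik, x$aic, x$bic, x$n_used, x$n_events))
  invisible(x)
}

#' Survival, hazard and density accessors for fitted models
#'
#' Generic accessors shared by parametric and spline fits.
#'
#' @param fit A fitted model (\code{parametric_fit} or \code{spline_fit}).
#' @param t Positive times (years).
#' @return Numeric vector of the same length as \code{t}.
#' @export
surv_prob <- function(fit, t) UseMethod("surv_prob")

#' @rdname surv_prob
#' @export
haz_rate <- function(fit, t) UseMethod("haz_rate")

#' @rdname surv_prob
#' @export
event_dens <- function(fit, t) UseMethod("event_dens")

#' @export
surv_prob.parametric_fit <- function(fit, t) {
  unname(exp(family_logsurv(fit$family$name, t, fit$params)))
}

#' @export
haz_rate.parametric_fit <- function(fit, t) {
  unname(family_hazard(fit$family$name, t, fit$params))
}

#' @export
event_dens.parametric_fit <- function(fit, t) {
  unname(exp(family_logdens(fit$family$name, t, fit$params)))
}

#' Serialize a fitted model to a flat record
#'
#' @param fit A \code{surv_model_fit}.
#' @return A one-row \code{data.frame}: model id, class, natural-scale
#'   parameters (collapsed \code{name=value;...}), loglik, aic, bic,
#'   converged, n.
#' @export
model_record <- function(fit) {
  pars <- paste(sprintf("%s=%.10g", names(model_params(fit)), model_params(fit)),
                collapse = ";")
  data.frame(model = model_id(fit), class = model_class(fit),
             n_free_params = n_free_params(fit), params = pars,
             loglik = fit$loglik, aic = fit$aic, bic = fit$bic,
             converged = fit$converged, n = fit$n_used)
}

model_params <- function(fit) {
  if (inherits(fit, "parametric_fit")) fit$params else fit$gamma
}

#' @rdname model_record
#' @export
model_id <- function(fit) UseMethod("model_id")

#' @export
model_id.parametric_fit <- function(fit) fit$family$name

#' @rdname model_record
#' @export
model_class <- function(fit) UseMethod("model_class")

#' @export
model_class.parametric_fit <- function(fit) "standard"

n_free_params <- function(fit) {
  if (inherits(fit, "parametric_fit")) fit$family$n_params
  else length(fit$gamma)
}
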