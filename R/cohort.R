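#' Specify a synthetic cohort
#'
#' A cohort specification holds everything needed to generate one staggered
#' enrollment cohort: the number of subjects, the calendar enrollment window
#' (decimal years), the true overall-survival model, an optional loss to
#' follow-up hazard, and a seed. The defaults emulate the structure of the
#' trial and registry cohorts the maturity analysis is designed around:
#' enrollment spread over several calendar years, cohort sizes of a few
#' hundred, and median overall survival of a few years.
#'
#' @param n_subjects Positive integer, cohort size.
#' @param enroll_start,enroll_end Calendar time in decimal years; enrollment is
#'   uniform on \code{[enroll_start, enroll_end]}.
#' @param survival_model A preset from \code{\link{mm_hazard_presets}} or a
#'   list with elements \code{family} (a family name) and \code{params}
#'   (natural-scale parameter vector).
#' @param ltfu_rate Nonnegative per-year hazard of loss to follow-up
#'   (exponential); 0 disables loss to follow-up so that all censoring is
#'   administrative.
#' @param label Cohort label carried through locks and evaluation records.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return An object of class \code{"cohort_spec"}.
#' @examples
#' spec <- cohort_spec(n_subjects = 200, enroll_start = 2002.72,
#'                     enroll_end = 2007.54, seed = 1)
#' cohort <- generate_cohort(spec)
#' head(cohort)
#' @export
cohort_spec <- function(n_subjects,
                        enroll_start,
                        enroll_end,
                        survival_model = mm_hazard_presets()$gengamma,
                        ltfu_rate = 0,
                        label = "cohort",
                        seed = 1L) {
  if (!is_number(n_subjects) || n_subjects < 1 || n_subjects != round(n_subjects))
    stop_field("n_subjects", "must be a positive integer")
  if (!is_number(enroll_start)) stop_field("enroll_start", "must be a finite number")
  if (!is_number(enroll_end)) stop_field("enroll_end", "must be a finite number")
  if (enroll_end <= enroll_start)
    stop_field("enroll_end", "must be greater than enroll_start")
  if (!is_number(ltfu_rate) || ltfu_rate < 0)
    stop_field("ltfu_rate", "must be a nonnegative number")
  if (!is_number(seed) || seed != round(seed))
    stop_field("seed", "must be an integer")
  if (!is.list(survival_model) || is.null(survival_model$family))
    stop_field("survival_model", "must be a hazard preset or list(family=, params=)")
  structure(
    list(n_subjects = as.integer(n_subjects),
         enroll_start = enroll_start, enroll_end = enroll_end,
         survival_model = survival_model, ltfu_rate = ltfu_rate,
         label = label, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a raw (pre-lock) cohort
#'
#' Draws, for each subject, a uniform calendar enrollment time on the
#' specified window, an overall-survival time from the true survival model,
#' and (when \code{ltfu_rate > 0}) an exponential loss-to-follow-up time.
#' Times are continuous years; every subject carries a death time (no cure
#' fraction). Draws are vectorised in a fixed order under a single seed, so
#' two calls with the same spec are identical.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @return A \code{data.frame} of class \code{"raw_cohort"} with columns
#'   \code{id}, \code{enroll_time}, \code{death_time}, \code{ltfu_time}
#'   (\code{NA} when no loss to follow-up), all in calendar decimal years.
#'   The spec travels along as attribute \code{"spec"}.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("'spec' must be a cohort_spec")
  n <- spec$n_subjects
  sm <- spec$survival_model
  out <- with_seed(spec$seed, {
    enroll <- stats::runif(n, spec$enroll_start, spec$enroll_end)
    ttd <- model_rsurv(sm, n)
    ltfu <- if (spec$ltfu_rate > 0) stats::rexp(n, spec$ltfu_rate) else rep(NA_real_, n)
    data.frame(id = seq_len(n),
               enroll_time = enroll,
               death_time = enroll + ttd,
               ltfu_time = enroll + ltfu)
  })
  structure(out, spec = spec, class = c("raw_cohort", "data.frame"))
}

# Draw n survival times (years since enrollment) from a true-model description.
model_rsurv <- function(sm, n) {
  if (identical(sm$family, "piecewise-exponential")) {
    rpiecewise_exp(n, sm$params$rates, sm$params$knots)
  } else {
    family_rsurv(sm$family, n, unlist(sm$params))
  }
}

# True survival function S(t) of a true-model description, vectorised in t.
model_true_surv <- function(sm) {
  if (identical(sm$family, "piecewise-exponential")) {
    rates <- sm$params$rates; knots <- sm$params$knots
    function(t) exp(-piecewise_cumhaz(t, rates, knots))
  } else {
    pars <- unlist(sm$params)
    function(t) unname(exp(family_logsurv(sm$family, t, pars)))
  }
}

# Piecewise-constant hazard: rates[i] on [knots[i-1], knots[i]), left-continuous
# at the knots (the hazard at a knot is the rate of the interval ending there).
piecewise_cumhaz <- function(t, rates, knots) {
  bounds <- c(0, knots, Inf)
  H <- numeric(length(t))
  for (i in seq_along(rates)) {
    H <- H + rates[i] * pmax(pmin(t, bounds[i + 1L]) - bounds[i], 0)
  }
  H
}

piecewise_hazard <- function(t, rates, knots) {
  idx <- findInterval(t, c(0, knots), left.open = TRUE) # left-continuous
  idx[idx < 1L] <- 1L
  rates[pmin(idx, length(rates))]
}

rpiecewise_exp <- function(n, rates, knots) {
  u <- stats::runif(n)
  target <- -log(u)
  bounds <- c(0, knots, Inf)
  Hk <- cumsum(rates[-length(rates)] * diff(c(0, knots))) # cum hazard at knots
  Hbounds <- c(0, Hk)
  idx <- findInterval(target, Hbounds) # interval whose hazard range holds target
  bounds[idx] + (target - Hbounds[idx]) / rates[idx]
}

#' Myeloma-like true hazard presets
#'
#' A catalogue of data-generating overall-survival models whose shapes mirror
#' long-term survival in newly diagnosed multiple myeloma: median overall
#' survival of a few years and a hazard that rises over the first years of
#' follow-up and then falls.
#'
#' \describe{
#'   \item{\code{gengamma}}{Generalized gamma (Prentice form) with a
#'     non-monotone hazard and median OS of 3.5 years; the default generator
#'     truth.}
#'   \item{\code{piecewise}}{Piecewise-exponential with a rising-then-falling
#'     hazard (turning point at 1.5 years, decline after 4 years), so that
#'     single-turning-point parametric families are misspecified. The hazard
#'     is left-continuous at its knots.}
#'   \item{\code{exponential}}{Constant hazard \eqn{\lambda = \log 2 / 3.5}
#'     (median 3.5 years), for closed-form testing.}
#' }
#'
#' Each preset carries \code{true_surv(t)} and \code{true_rmst(horizon)}; the
#' latter uses the closed form where one exists and adaptive quadrature
#' (absolute tolerance 1e-8) otherwise.
#'
#' @return Named list of presets, each a list with \code{family},
#'   \code{params}, \code{true_surv}, \code{true_rmst}.
#' @examples
#' p <- mm_hazard_presets()$exponential
#' p$true_rmst(35)
#' @export
mm_hazard_presets <- function() {
  # gengamma: sigma/Q fixed for a lognormal-like rise-and-fall hazard; mu is
  # solved so the median is exactly 3.5 years.
  sigma <- 0.9; Q <- -0.3
  k <- Q^-2
  w_med <- log(stats::qgamma(0.5, k) / k) / Q
  mu <- log(3.5) - sigma * w_med
  gg <- list(family = "gengamma", params = list(mu = mu, sigma = sigma, Q = Q))
  gg$true_surv <- model_true_surv(gg)
  gg$true_rmst <- local({
    S <- gg$true_surv
    function(horizon) stats::integrate(S, 0, horizon, abs.tol = 1e-8,
                                       rel.tol = 1e-10, subdivisions = 500L)$value
  })

  pw <- list(family = "piecewise-exponential",
             params = list(rates = c(0.12, 0.32, 0.10), knots = c(1.5, 4)))
  pw$true_surv <- model_true_surv(pw)
  pw$true_hazard <- function(t) piecewise_hazard(t, pw$params$rates, pw$params$knots)
  pw$true_rmst <- function(horizon) {
    rates <- pw$params$rates; knots <- pw$params$knots
    bounds <- c(0, knots, Inf)
    S0 <- exp(-piecewise_cumhaz(bounds[-length(bounds)], rates, knots))
    total <- 0
    for (i in seq_along(rates)) {
      lo <- bounds[i]; hi <- min(bounds[i + 1L], horizon)
      if (hi <= lo) break
      # segment integral of S0[i] * exp(-rates[i] (t - lo))
      total <- total + S0[i] * (1 - exp(-rates[i] * (hi - lo))) / rates[i]
    }
    total
  }

  ex <- list(family = "exponential", params = list(rate = log(2) / 3.5))
  ex$true_surv <- model_true_surv(ex)
  ex$true_rmst <- function(horizon) {
    lam <- ex$params$rate
    (1 - exp(-lam * horizon)) / lam
  }

  list(gengamma = gg, piecewise = pw, exponential = ex)
}

#' @export
print.raw_cohort <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("Raw cohort '%s': %d subjects, enrollment %.2f-%.2f\n",
              if (is.null(spec)) "?" else spec$label, nrow(x),
              min(x$enroll_time), max(x$enroll_time)))
  NextMethod()
}

#' Read or write a raw cohort as delimited text
#'
#' One row per subject, columns \code{id,enroll_time,death_time,ltfu_time};
#' absent loss to follow-up is written as \code{NA}.
#'
#' @param cohort A \code{raw_cohort}.
#' @param path File path.
#' @return \code{read_cohort} returns a \code{raw_cohort};
#'   \code{write_cohort} returns \code{path} invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort)[c("id", "enroll_time", "death_time",
                                           "ltfu_time")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path)
  need <- c("id", "enroll_time", "death_time", "ltfu_time")
  if (!all(need %in% names(df)))
    stop("cohort file must have columns ", paste(need, collapse = ", "))
  bad <- df$death_time <= df$enroll_time
  if (any(bad)) stop("death_time must exceed enroll_time for every subject")
  if (any(!is.na(df$ltfu_time) & df$ltfu_time <= df$enroll_time))
    stop("ltfu_time must exceed enroll_time where present")
  structure(df[need], class = c("raw_cohort", "data.frame"))
}
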