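#' Standard parametric survival families
#'
#' The seven families commonly recommended for survival extrapolation in
#' health-technology assessment (NICE DSU TSD 14): exponential, Weibull,
#' Gompertz, gamma, log-logistic, lognormal and generalized gamma.
#' Parameterizations are pinned so that results are unambiguous and can be
#' cross-validated against other survival software:
#'
#' \itemize{
#'   \item exponential: \eqn{S(t) = e^{-\lambda t}} (parameter \code{rate}).
#'   \item weibull: \eqn{S(t) = \exp\{-(t/\sigma)^\alpha\}}
#'     (\code{shape} \eqn{\alpha}, \code{scale} \eqn{\sigma}).
#'   \item gompertz: hazard \eqn{h(t) = b e^{a t}} (\code{shape} \eqn{a}
#'     real, \code{rate} \eqn{b > 0}); \eqn{a = 0} is the exponential.
#'   \item gamma: shape/rate density as in \code{\link[stats]{dgamma}}.
#'   \item loglogistic: \eqn{S(t) = 1/\{1 + (t/\alpha)^\beta\}}
#'     (\code{scale} \eqn{\alpha}, \code{shape} \eqn{\beta}).
#'   \item lognormal: \eqn{S(t) = 1 - \Phi\{(\log t - \mu)/\sigma\}}
#'     (\code{meanlog}, \code{sdlog}).
#'   \item gengamma: Prentice \eqn{(\mu, \sigma, Q)} form; \eqn{Q \to 0} is
#'     lognormal, \eqn{Q = 1} is Weibull with shape \eqn{1/\sigma} and scale
#'     \eqn{e^\mu}.
#' }
#'
#' @param name Family name, one of \code{survival_families()}.
#' @return \code{family_spec} returns an object of class \code{"family_spec"}
#'   with elements \code{name}, \code{par_names}, \code{n_params}, and the
#'   transform pair mapping natural-scale parameters to the unconstrained
#'   fitting scale.
#' @examples
#' family_spec("weibull")$par_names
#' @export
family_spec <- function(name) {
  name <- match.arg(name, survival_families())
  info <- .family_table[[name]]
  structure(
    list(name = name, par_names = info$par_names,
         n_params = length(info$par_names),
         to_unconstrained = info$to_u, from_unconstrained = info$from_u),
    class = "family_spec"
  )
}

#' @rdname family_spec
#' @export
survival_families <- function() {
  c("exponential", "weibull", "gompertz", "gamma",
    "loglogistic", "lognormal", "gengamma")
}

.log_all <- function(x) log(x)
.exp_all <- function(x) exp(x)

.family_table <- list(
  exponential = list(par_names = "rate", to_u = .log_all, from_u = .exp_all),
  weibull = list(par_names = c("shape", "scale"),
                 to_u = .log_all, from_u = .exp_all),
  gompertz = list(par_names = c("shape", "rate"),
                  to_u = function(x) c(x[1L], log(x[2L])),
                  from_u = function(x) c(x[1L], exp(x[2L]))),
  gamma = list(par_names = c("shape", "rate"),
               to_u = .log_all, from_u = .exp_all),
  loglogistic = list(par_names = c("scale", "shape"),
                     to_u = .log_all, from_u = .exp_all),
  lognormal = list(par_names = c("meanlog", "sdlog"),
                   to_u = function(x) c(x[1L], log(x[2L])),
                   from_u = function(x) c(x[1L], exp(x[2L]))),
  gengamma = list(par_names = c("mu", "sigma", "Q"),
                  to_u = function(x) c(x[1L], log(x[2L]), x[3L]),
                  from_u = function(x) c(x[1L], exp(x[2L]), x[3L]))
)

# Natural-scale domain check. Out-of-domain points are signalled by the caller
# returning -Inf log-likelihood, never an error, so optimizers can recover.
family_params_valid <- function(name, p) {
  if (any(!is.finite(p))) return(FALSE)
  switch(name,
    exponential = p[1L] > 0,
    weibull = p[1L] > 0 && p[2L] > 0,
    gompertz = p[2L] > 0,
    gamma = p[1L] > 0 && p[2L] > 0,
    loglogistic = p[1L] > 0 && p[2L] > 0,
    lognormal = p[2L] > 0,
    gengamma = p[2L] > 0
  )
}

# Q treated as exactly lognormal below this threshold: the (mu, sigma, Q)
# density is continuous through Q = 0 but the Q != 0 branch is 0/0 there.
.GG_Q_EPS <- 1e-6

# log density of the generalized gamma, Prentice (mu, sigma, Q) form
.dgengamma_log <- function(t, mu, sigma, Q) {
  if (abs(Q) < .GG_Q_EPS) return(stats::dlnorm(t, mu, sigma, log = TRUE))
  w <- (log(t) - mu) / sigma
  k <- Q^-2
  log(abs(Q)) - log(sigma * t) + k * log(k) - lgamma(k) + k * (Q * w - exp(Q * w))
}

# log survival of the generalized gamma
.pgengamma_logsurv <- function(t, mu, sigma, Q) {
  if (abs(Q) < .GG_Q_EPS) return(stats::plnorm(t, mu, sigma, lower.tail = FALSE, log.p = TRUE))
  w <- (log(t) - mu) / sigma
  k <- Q^-2
  y <- k * exp(Q * w)
  if (Q > 0) {
    stats::pgamma(y, k, lower.tail = FALSE, log.p = TRUE)
  } else {
    stats::pgamma(y, k, lower.tail = TRUE, log.p = TRUE)
  }
}

# Vectorised log f(t) and log S(t) for each family at natural-scale `p`.
# `t` must be positive. Invalid parameter points never reach here.
family_logdens <- function(name, t, p) {
  switch(name,
    exponential = stats::dexp(t, p[1L], log = TRUE),
    weibull = stats::dweibull(t, shape = p[1L], scale = p[2L], log = TRUE),
    gompertz = {
      a <- p[1L]; b <- p[2L]
      # log h - H; H = b(e^{at}-1)/a, continuous at a = 0
      H <- if (abs(a) < 1e-12) b * t else b * expm1(a * t) / a
      log(b) + a * t - H
    },
    gamma = stats::dgamma(t, shape = p[1L], rate = p[2L], log = TRUE),
    loglogistic = {
      al <- p[1L]; be <- p[2L]
      z <- (t / al)^be
      log(be) - log(al) + (be - 1) * (log(t) - log(al)) - 2 * log1p(z)
    },
    lognormal = stats::dlnorm(t, p[1L], p[2L], log = TRUE),
    gengamma = .dgengamma_log(t, p[1L], p[2L], p[3L])
  )
}

family_logsurv <- function(name, t, p) {
  switch(name,
    exponential = -p[1L] * t,
    weibull = -(t / p[2L])^p[1L],
    gompertz = {
      a <- p[1L]; b <- p[2L]
      if (abs(a) < 1e-12) -b * t else -b * expm1(a * t) / a
    },
    gamma = stats::pgamma(t, shape = p[1L], rate = p[2L],
                          lower.tail = FALSE, log.p = TRUE),
    loglogistic = -log1p((t / p[1L])^p[2L]),
    lognormal = stats::plnorm(t, p[1L], p[2L], lower.tail = FALSE, log.p = TRUE),
    gengamma = .pgengamma_logsurv(t, p[1L], p[2L], p[3L])
  )
}

family_hazard <- function(name, t, p) {
  exp(family_logdens(name, t, p) - family_logsurv(name, t, p))
}

# Random survival times, used by the synthetic-data generator and test oracles.
family_rsurv <- function(name, n, p) {
  switch(name,
    exponential = stats::rexp(n, p[1L]),
    weibull = stats::rweibull(n, shape = p[1L], scale = p[2L]),
    gompertz = {
      a <- p[1L]; b <- p[2L]
      u <- stats::runif(n)
      # invert S(t) = exp(-b(e^{at}-1)/a)
      if (abs(a) < 1e-12) -log(u) / b else log1p(-a * log(u) / b) / a
    },
    gamma = stats::rgamma(n, shape = p[1L], rate = p[2L]),
    loglogistic = {
      u <- stats::runif(n)
      p[1L] * (u / (1 - u))^(1 / p[2L])
    },
    lognormal = stats::rlnorm(n, p[1L], p[2L]),
    gengamma = {
      mu <- p[1L]; sigma <- p[2L]; Q <- p[3L]
      if (abs(Q) < .GG_Q_EPS) {
        stats::rlnorm(n, mu, sigma)
      } else {
        # if g ~ Gamma(Q^-2, 1) then exp(mu + sigma * log(Q^2 g)/Q) ~ GG
        g <- stats::rgamma(n, shape = Q^-2, rate = 1)
        exp(mu + sigma * log(Q^2 * g) / Q)
      }
    }
  )
}
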