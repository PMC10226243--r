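# Independent oracles and small fixtures shared across test files.
# Everything here is deliberately naive (loops, brute force) and never calls
# the package code paths it is used to check.

# Naive product-limit estimate by a double loop over distinct event times.
# Deaths precede censorings at tied times.
naive_km <- function(time, status) {
  tev <- sort(unique(time[status == 1]))
  surv <- numeric(length(tev))
  s <- 1
  for (i in seq_along(tev)) {
    n_risk <- 0
    d <- 0
    for (j in seq_along(time)) {
      if (time[j] > tev[i] || (time[j] == tev[i])) n_risk <- n_risk + 1
      if (time[j] == tev[i] && status[j] == 1) d <- d + 1
    }
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  list(event_times = tev, surv = surv)
}

# Naive step-function RMST: sum of rectangle areas segment by segment.
naive_step_rmst <- function(event_times, surv, horizon) {
  ts <- c(0, event_times[event_times <= horizon], horizon)
  vals <- c(1, surv[event_times <= horizon])
  total <- 0
  for (i in seq_along(vals)) total <- total + vals[i] * (ts[i + 1] - ts[i])
  total
}

# A hand-written 10-subject raw cohort used for exhaustive lock enumeration.
hand_cohort <- function() {
  df <- data.frame(
    id = 1:10,
    enroll_time = c(2000.0, 2000.5, 2001.0, 2001.5, 2002.0,
                    2002.5, 2003.0, 2003.5, 2004.0, 2004.5),
    death_time = c(2001.0, 2006.0, 2003.5, 2010.0, 2004.0,
                    2015.0, 2004.5, 2007.0, 2012.0, 2005.5),
    ltfu_time = c(NA, NA, 2002.0, NA, NA, 2008.0, NA, NA, NA, NA)
  )
  structure(df, class = c("raw_cohort", "data.frame"))
}

# Exhaustive per-subject enumeration of a lock, written independently of
# apply_lock (scalar loop, explicit case analysis).
enumerate_lock <- function(cohort, lock_time) {
  out <- data.frame(id = integer(), time = numeric(), status = integer())
  for (j in seq_len(nrow(cohort))) {
    e <- cohort$enroll_time[j]
    if (e >= lock_time) next
    d <- cohort$death_time[j]
    l <- if (is.na(cohort$ltfu_time[j])) Inf else cohort$ltfu_time[j]
    end <- min(d, l, lock_time)
    st <- if (d < lock_time && d <= l) 1L else 0L
    out <- rbind(out, data.frame(id = cohort$id[j], time = end - e, status = st))
  }
  out
}

# Minimal surv_model_fit stub with prescribed parameters, for exercising the
# quadrature and selection code paths at exact parameter values.
param_stub <- function(family, params, loglik = NA_real_, aic = NA_real_,
                       bic = NA_real_, n = NA_integer_, converged = TRUE) {
  fam <- family_spec(family)
  names(params) <- fam$par_names
  structure(list(family = fam, params = params, loglik = loglik, aic = aic,
                 bic = bic, converged = converged, n_used = n,
                 n_events = n, vcov = NULL),
            class = c("parametric_fit", "surv_model_fit"))
}

# Simulated right-censored dataset with administrative censoring at cens_time.
sim_ds <- function(n, family, params, cens_time = Inf, seed = 1) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  t_true <- withr_seed(survmature:::family_rsurv(family, n, params))
  obs <- pmin(t_true, cens_time)
  surv_dataset(obs, as.integer(t_true <= cens_time))
}
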