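make_sel_stub <- function(family, aic, bic, converged = TRUE) {
  param_stub(family, rep(1, family_spec(family)$n_params), loglik = 0,
             aic = aic, bic = bic, converged = converged)
}

test_that("model selection: lowest criterion, parsimony tie-break, convergence filter", {
  fits <- list(make_sel_stub("exponential", aic = 204, bic = 207),
               make_sel_stub("weibull", aic = 206, bic = 206))
  sel <- select_models(fits)
  expect_equal(sel$AIC, "exponential")
  expect_equal(sel$BIC, "weibull") # BIC may disagree with AIC on one roster

  # exact AIC tie: k = 1 exponential beats k = 3 gengamma
  tie <- list(make_sel_stub("gengamma", aic = 204, bic = 210),
              make_sel_stub("exponential", aic = 204, bic = 205))
  expect_equal(select_models(tie)$AIC, "exponential")

  # non-converged models are never selected
  fits2 <- list(make_sel_stub("exponential", aic = 100, bic = 100, converged = FALSE),
                make_sel_stub("weibull", aic = 300, bic = 300))
  expect_equal(select_models(fits2)$AIC, "weibull")
  expect_error(select_models(list(make_sel_stub("weibull", 1, 1, converged = FALSE))),
               "no converged")
})

test_that("an AIC/BIC disagreement arises from a parameter-count gap at n = 500", {
  # identical likelihoods except a small edge for the richer model:
  # AIC (penalty 2 per parameter) keeps the richer model, BIC (log 500 ~ 6.2)
  # prefers the sparser one.
  ll_rich <- -1000; ll_sparse <- -1002.5
  rich <- make_sel_stub("gengamma", aic = -2 * ll_rich + 2 * 3,
                        bic = -2 * ll_rich + 3 * log(500))
  sparse <- make_sel_stub("exponential", aic = -2 * ll_sparse + 2 * 1,
                          bic = -2 * ll_sparse + 1 * log(500))
  sel <- select_models(list(rich, sparse))
  expect_equal(sel$AIC, "gengamma")
  expect_equal(sel$BIC, "exponential")
})

test_that("evaluate_lock is self-consistent on complete exponential data", {
  set.seed(1234)
  lam <- log(2) / 3.5
  tt <- rexp(4000, lam)
  ds <- surv_dataset(tt, rep(1L, 4000))
  attr(ds, "max_followup") <- 3
  roster <- model_roster()[1, , drop = FALSE] # exponential only
  rec <- evaluate_lock(ds, ds, horizon = 8, roster = roster)
  # with no censoring the KM RMST is the empirical mean of min(T, h)
  x <- pmin(tt, 8)
  expect_equal(attr(rec, "km_rmst"), mean(x), tolerance = 1e-10)
  mc_se <- sd(x) / sqrt(length(x))
  expect_lt(abs(rec$rmst_error), 2 * mc_se)
})

test_that("a model whose survival matches the KM step curve has zero RMST error", {
  # the signed error is model area minus KM area over the same horizon, so a
  # model reproducing the step function exactly must score zero
  ds <- surv_dataset(c(2, 4, 9), c(1, 0, 0))
  km <- km_fit(ds)
  h <- 8
  model_area <- integrate(function(u) km_surv(km, u), 0, h,
                          subdivisions = 1000L, rel.tol = 1e-10)$value
  expect_equal(model_area - as.numeric(km_rmst(km, h)), 0, tolerance = 1e-6)
})

test_that("the true conditional RMST is recovered on a large exponential cohort", {
  lam <- log(2) / 3.5
  spec <- cohort_spec(1e5, 2000, 2005, mm_hazard_presets()$exponential,
                      seed = 314)
  coh <- generate_cohort(spec)
  ref <- apply_lock(coh, 2000 + 5 + 8) # every subject followed >= 8 years
  km <- km_fit(ref)
  truth <- (1 - exp(-lam * 5)) / lam # memoryless: horizon 8, t0 = 3
  expect_equal(km_conditional_rmst(km, 3, 8, extend = TRUE), truth,
               tolerance = 0.02)
  f <- fit_parametric("exponential", apply_lock(coh, 2008))
  expect_equal(rmst(f, 8, t0 = 3), truth, tolerance = 0.02)
})

test_that("evaluation records carry consistent errors and selections", {
  set.seed(60)
  spec <- cohort_spec(250, 2004, 2008, mm_hazard_presets()$piecewise, seed = 17)
  coh <- generate_cohort(spec)
  ref <- apply_lock(coh, 2004 + 18)
  locked <- lock_grid(coh, c(4))[[1]]
  rec <- evaluate_lock(ref, locked, horizon = 12)
  expect_equal(nrow(rec), 16)
  expect_setequal(rec$class, c("standard", "spline"))
  km_h <- attr(rec, "km_rmst")
  ok <- rec$converged
  expect_equal(rec$rmst_error[ok], rec$rmst[ok] - km_h, tolerance = 1e-12)
  expect_true(all(rec$rmst[ok] <= 12 + 1e-9))
  expect_true(all(rec$lifetime_rmst[ok] <= 35 + 1e-9))
  # exactly one AIC and one BIC selection among converged records
  expect_equal(sum(grepl("AIC", rec$selected_by)), 1)
  expect_equal(sum(grepl("BIC", rec$selected_by)), 1)

  # signed error equals int(S_model) - int(S_KM): the model side by smooth
  # quadrature, the KM side by the naive rectangle oracle
  km <- km_fit(ref)
  km_area <- naive_step_rmst(km$event_times, km$surv, 12)
  fits <- attr(rec, "fits")
  for (id in c("weibull", "gengamma", "spline_hazard_2k")) {
    f <- fits[[id]]
    skip_if(!f$converged)
    model_area <- integrate(function(u) surv_prob(f, pmax(u, 1e-12)), 0, 12,
                            subdivisions = 1000L, rel.tol = 1e-10)$value
    expect_equal(rec$rmst_error[rec$model == id], model_area - km_area,
                 tolerance = 1e-6)
  }
})

test_that("conditional/unconditional RMST identity holds for fitted models", {
  set.seed(61)
  preset <- mm_hazard_presets()$gengamma
  tt <- survmature:::family_rsurv("gengamma", 300, unlist(preset$params))
  ds <- surv_dataset(pmin(tt, 6), as.integer(tt <= 6))
  t0 <- 3; h <- 11
  for (f in list(fit_parametric("gompertz", ds),
                 fit_spline(ds, spline_spec("normal", 2)))) {
    lhs <- rmst(f, h, t0 = t0) * surv_prob(f, t0) + rmst(f, t0)
    expect_equal(lhs, rmst(f, h), tolerance = 1e-6)
  }
})

test_that("run_experiment bookkeeping, maturity trend, summaries and plots", {
  cfg <- experiment_config(
    cohort_spec(220, 2004, 2008, mm_hazard_presets()$piecewise, label = "pw"),
    max_followups = c(3, 8), horizon = 11, seed = 5)
  res <- run_experiment(cfg)
  expect_equal(nrow(res$records), 32) # 1 cohort x 2 locks x 16 models
  expect_equal(sort(unique(res$records$max_followup)), c(3, 8))
  expect_equal(table(res$records$class)[["spline"]], 18)

  by_lock <- res$summaries$by_lock
  expect_equal(nrow(by_lock), 2)
  # administrative censoring only: censoring decreases with longer follow-up
  pct <- tapply(res$records$pct_censored, res$records$max_followup, unique)
  expect_lt(pct[["8"]], pct[["3"]])

  p1 <- plot_rmst_error(res$records)
  p2 <- plot_rmst_error(res$records, x = "n_events", conditional = TRUE)
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")

  out <- withr::local_tempdir()
  write_out <- run_experiment(cfg, out_dir = out)
  expect_true(file.exists(file.path(out, "records.csv")))
  expect_true(file.exists(file.path(out, "manifest.txt")))
  expect_true(file.exists(file.path(out, "rmst_error_by_pct_censored.png")))
})

test_that("cohort specs are readable from key:value config files", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# myeloma-like registry cohort",
               "n_subjects: 300", "enroll_start: 2005.0",
               "enroll_end: 2010.0", "survival_model: piecewise",
               "ltfu_rate: 0.02", "label: registry", "seed: 11"), path)
  spec <- read_cohort_spec(path)
  expect_s3_class(spec, "cohort_spec")
  expect_equal(spec$n_subjects, 300L)
  expect_equal(spec$survival_model$family, "piecewise-exponential")
  expect_equal(spec$ltfu_rate, 0.02)
  expect_error(read_cohort_spec({
    p2 <- withr::local_tempfile(); writeLines("survival_model: nope\nn_subjects: 5\nenroll_start: 0\nenroll_end: 1", p2); p2
  }), "survival_model")
})
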