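test_that("natural cubic spline basis: tails, endpoint algebra, derivative", {
  knots <- c(-1, 0.2, 0.9, 2)
  below <- ncs_basis(c(-5, -1), knots)
  expect_true(all(below$basis == 0)) # linear (all plus-functions vanish)
  expect_true(all(below$deriv == 0))

  # lambda at an internal knot equal to a boundary
  kmin <- -1; kmax <- 2
  lam <- function(kj) (kmax - kj) / (kmax - kmin)
  expect_equal(lam(kmin), 1)
  expect_equal(lam(kmax), 0)

  set.seed(88)
  z <- runif(100, -3, 4)
  nb <- ncs_basis(z, knots)
  eps <- 1e-5
  fd <- (ncs_basis(z + eps, knots)$basis - ncs_basis(z - eps, knots)$basis) /
    (2 * eps)
  expect_equal(nb$deriv, fd, tolerance = 1e-6)
  expect_error(ncs_basis(NA_real_, knots), "finite")
})

test_that("basis is linear beyond the upper boundary knot", {
  knots <- c(0, 1, 3)
  z <- c(3.5, 4.5, 6.5)
  nb <- ncs_basis(z, knots)
  # constant slope beyond kmax for each basis function
  slopes <- diff(nb$basis[, 1]) / diff(z)
  expect_equal(slopes[1], slopes[2], tolerance = 1e-10)
})

test_that("knots are placed at centiles of log uncensored event times", {
  ds <- surv_dataset(c(1, exp(1), exp(2)), c(1, 1, 1))
  expect_equal(place_knots(ds, 1), c(0, 1, 2))

  set.seed(6)
  tt <- rlnorm(40, 1, 0.6)
  ds2 <- surv_dataset(c(tt, 5, 6), c(rep(1, 40), 0, 0))
  k3 <- place_knots(ds2, 3)
  expect_equal(k3[2:4], unname(quantile(log(tt), c(0.25, 0.5, 0.75))))
  expect_true(all(k3[2:4] > k3[1] & k3[2:4] < k3[5]))

  tied <- surv_dataset(rep(c(1, 2, 3), each = 5), rep(1, 15))
  expect_error(place_knots(tied, 3), class = "survmature_infeasible_spline")
})

test_that("knotless spline survival reduces to closed forms on each scale", {
  grid <- seq(0.05, 20, length.out = 200)
  knots <- c(log(0.5), log(8))
  base <- list(spec = spline_spec("hazard", 0), knots = knots, converged = TRUE)
  class(base) <- c("spline_fit", "surv_model_fit")

  unit <- base; unit$gamma <- c(0, 1)
  expect_equal(surv_prob(unit, grid), exp(-grid), tolerance = 1e-12)

  g0 <- -1.8; g1 <- 1.4
  wei <- base; wei$gamma <- c(g0, g1)
  expect_equal(surv_prob(wei, grid), exp(-exp(g0) * grid^g1), tolerance = 1e-12)
  expect_equal(haz_rate(wei, grid),
               exp(g0) * g1 * grid^(g1 - 1), tolerance = 1e-9)

  alpha <- 4; beta <- 1.5
  llog <- base; llog$spec <- spline_spec("odds", 0)
  llog$gamma <- c(-beta * log(alpha), beta)
  expect_equal(surv_prob(llog, grid), 1 / (1 + (grid / alpha)^beta),
               tolerance = 1e-12)

  lnrm <- base; lnrm$spec <- spline_spec("normal", 0)
  mu <- 1.1; sdl <- 0.7
  lnrm$gamma <- c(-mu / sdl, 1 / sdl)
  expect_equal(surv_prob(lnrm, grid), plnorm(grid, mu, sdl, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("hazard-scale fit with no internal knots equals the Weibull MLE", {
  set.seed(42)
  tt <- rweibull(500, 1.4, 3.5)
  ds <- surv_dataset(pmin(tt, 6), as.integer(tt <= 6))
  fw <- fit_parametric("weibull", ds)
  fs <- fit_spline(ds, spline_spec("hazard", 0))
  shape_s <- unname(fs$gamma[2])
  scale_s <- unname(exp(-fs$gamma[1] / fs$gamma[2]))
  expect_equal(shape_s, unname(fw$params["shape"]), tolerance = 1e-4)
  expect_equal(scale_s, unname(fw$params["scale"]), tolerance = 1e-4)
  expect_equal(fs$loglik, fw$loglik, tolerance = 1e-8)
})

test_that("spline fits match the reference implementation's likelihood", {
  skip_if_not_installed("flexsurv")
  set.seed(52)
  preset <- mm_hazard_presets()$gengamma
  tt <- survmature:::family_rsurv("gengamma", 400, unlist(preset$params))
  ds <- surv_dataset(pmin(tt, 9), as.integer(tt <= 9))
  for (sc in c("hazard", "odds", "normal")) {
    fs <- fit_spline(ds, spline_spec(sc, 2))
    fx <- flexsurv::flexsurvspline(
      survival::Surv(time, status) ~ 1, data = as.data.frame(ds), k = 2,
      scale = switch(sc, hazard = "hazard", odds = "odds", normal = "normal"))
    expect_equal(fs$knots, unname(fx$knots), tolerance = 1e-10)
    expect_equal(fs$loglik, fx$loglik, tolerance = 1e-4,
                 label = paste("loglik on scale", sc))
  }
})

test_that("spline nests Weibull and recovers a misspecified truth closely", {
  set.seed(9)
  tt <- rweibull(400, 1.2, 4)
  ds <- surv_dataset(pmin(tt, 7), as.integer(tt <= 7))
  fw <- fit_parametric("weibull", ds)
  fs <- fit_spline(ds, spline_spec("hazard", 1))
  expect_gte(fs$loglik, fw$loglik - 1e-6)

  preset <- mm_hazard_presets()$gengamma
  tg <- survmature:::family_rsurv("gengamma", 2000, unlist(preset$params))
  dsg <- surv_dataset(tg, rep(1L, 2000))
  fg <- fit_spline(dsg, spline_spec("hazard", 2))
  dec <- sapply(seq(0.1, 0.9, by = 0.1), function(p)
    uniroot(function(t) preset$true_surv(t) - (1 - p), c(1e-6, 200))$root)
  expect_true(all(abs(surv_prob(fg, dec) - seq(0.9, 0.1, by = -0.1)) <= 0.03))
})

test_that("fitted spline survival is non-increasing far into the tail", {
  set.seed(23)
  preset <- mm_hazard_presets()$piecewise
  tt <- survmature:::rpiecewise_exp(300, preset$params$rates, preset$params$knots)
  ds <- surv_dataset(pmin(tt, 8), as.integer(tt <= 8))
  for (sc in c("hazard", "odds", "normal")) {
    fs <- fit_spline(ds, spline_spec(sc, 2))
    upper <- 3 * exp(max(fs$knots))
    grid <- seq(upper / 512, upper, length.out = 512)
    S <- surv_prob(fs, grid)
    expect_true(all(diff(S) <= 1e-12), label = paste("monotone S on", sc))
    expect_lte(max(S), 1)
    expect_gte(min(S), 0)
  }
})

test_that("spline refits are bit-identical and bookkeeping matches k = m + 2", {
  set.seed(64)
  ds <- surv_dataset(rexp(120, 0.3), rbinom(120, 1, 0.8))
  f1 <- fit_spline(ds, spline_spec("odds", 2))
  f2 <- fit_spline(ds, spline_spec("odds", 2))
  expect_identical(f1$gamma, f2$gamma)
  expect_equal(f1$aic, -2 * f1$loglik + 2 * 4) # m = 2 -> k = 4
  expect_equal(f1$bic, -2 * f1$loglik + 4 * log(120))
})
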