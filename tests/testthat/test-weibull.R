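test_that("Weibull hazard is 0 up to the shift and a power law beyond", {
  wp <- weibull_params(0.02, 5, 17)
  expect_equal(weib_hazard(c(0, 10, 17), wp), c(0, 0, 0))
  # log-log linearity with slope r - 1
  t <- 17 + c(10, 20, 40, 80)
  sl <- diff(log(weib_hazard(t, wp))) / diff(log(t - 17))
  expect_equal(sl, rep(4, 3), tolerance = 1e-12)
  # r = 1: constant hazard lambda
  w1 <- weibull_params(0.01, 1, 5)
  expect_equal(weib_hazard(c(6, 50, 200), w1), rep(0.01, 3))
  expect_error(weibull_params(-1, 5, 17))
  expect_error(weibull_params(0.01, 0.5, 17))
})

test_that("cumulative hazard integrates the hazard", {
  wp <- weibull_params(0.016, 6, 17)
  expect_equal(weib_cum_hazard(17, wp), 0)
  expect_equal(weib_cum_hazard(17 + 100, weibull_params(0.01, 1, 17)), 1)
  for (t1 in c(30, 60, 95)) {
    num <- stats::integrate(weib_hazard, 17, t1, params = wp,
                            rel.tol = 1e-10)$value
    expect_equal(weib_cum_hazard(t1, wp), num, tolerance = 1e-8)
  }
})

test_that("mixture population hazard collapses, bounds and turns over", {
  wp <- weibull_params(0.016, 6, 17)
  t <- seq(20, 105, 0.5)
  # p = 1: population IS the susceptible pool
  expect_equal(population_hazard_fn(t, wp, p = 1), weib_hazard(t, wp))
  # p < 1: bounded above by the individual hazard; p -> 0 limit is the density
  h <- population_hazard_fn(t, wp, p = 0.003)
  expect_true(all(h <= weib_hazard(t, wp) + 1e-15))
  tiny <- population_hazard_fn(t, wp, p = 1e-8) / 1e-8
  expect_equal(tiny, weib_hazard(t, wp) * exp(-weib_cum_hazard(t, wp)),
               tolerance = 1e-6)
  # interior maximum then decline for a small pool
  h <- population_hazard_fn(t, wp, p = 0.003)
  imax <- which.max(h)
  expect_gt(imax, 1); expect_lt(imax, length(t))
  expect_lt(h[length(t)], h[imax])
  # r = 1 first-order: exponential decay p*lambda*exp(-lambda(t-A))
  w1 <- weibull_params(0.01, 1, 5)
  expect_equal(population_hazard_fn(50, w1, 0.01, "first_order"),
               0.01 * 0.01 * exp(-0.01 * 45), tolerance = 1e-12)
})

test_that("first-order and exact population hazards agree to order p", {
  wp <- weibull_params(0.016, 6, 17)
  t <- seq(25, 100, 1)
  for (p in c(1e-3, 1e-2)) {
    ex <- population_hazard_fn(t, wp, p)
    fo <- population_hazard_fn(t, wp, p, "first_order")
    expect_lt(max(abs(fo - ex) / pmax(ex, 1e-300)), 2 * p)
  }
})

test_that("mixture conserves the pool: lifetime cumulative incidence is p", {
  wp <- weibull_params(0.016, 6, 17)
  for (p in c(0.3, 0.003)) {
    Hpop <- stats::integrate(population_hazard_fn, 0, 2000, params = wp,
                             p = p, rel.tol = 1e-12)$value
    expect_equal(1 - exp(-Hpop), p, tolerance = 1e-6)
  }
})

test_that("stratified first-order predictions are exactly proportional", {
  wp <- weibull_params(0.016, 6, 17)
  pred <- predict_strata(wp, c(a = 0.003, b = 0.0012), t = seq(30, 100, 2.5))
  ha <- pred$h_pop_per_100k[pred$stratum == "a"]
  hb <- pred$h_pop_per_100k[pred$stratum == "b"]
  expect_equal(ha / hb, rep(0.003 / 0.0012, length(ha)), tolerance = 1e-12)
  expect_equal(pred$theta_per_100k[pred$stratum == "a"],
               pred$theta_per_100k[pred$stratum == "b"])
})

test_that("peak age: grid search agrees with the stationarity root", {
  # (r-1)/(t-A) = theta(t)  =>  t = A + ((r-1)/r)^(1/r)/lambda
  for (par in list(c(0.016, 6, 17), c(0.02, 4, 10), c(0.009, 3, 0))) {
    wp <- weibull_params(par[1], par[2], par[3])
    grid_pk <- peak_age(wp)$age
    root <- par[3] + ((par[2] - 1) / par[2])^(1 / par[2]) / par[1]
    expect_lt(abs(grid_pk - root), 0.1)
    # independent root-finding oracle on the stationarity condition
    uni <- stats::uniroot(function(t) (par[2] - 1) / (t - par[3]) -
                            weib_hazard(t, wp),
                          c(par[3] + 1, 109), tol = 1e-10)$root
    expect_lt(abs(grid_pk - uni), 0.1)
  }
  # r = 1: boundary, flagged
  pk <- peak_age(weibull_params(0.01, 1, 5))
  expect_true(pk$boundary)
  expect_equal(pk$age, 5)
})

test_that("correct bracketing keeps the peak age stable across pool sizes", {
  wp <- weibull_params(0.016, 6, 17)
  aud <- audit_peak_shift(wp, p_values = 10^seq(-4, -2, by = 0.25))
  expect_lt(diff(range(aud$peak_correct)), 2)
})

test_that("mis-bracketed variant pushes rarer cancers to younger peaks", {
  wp <- weibull_params(0.016, 6, 17)
  aud <- audit_peak_shift(wp, p_values = 10^seq(-4, -2, by = 0.25))
  # rows are ordered by increasing p: peak must increase strictly with p,
  # i.e. strictly decrease as p decreases
  expect_true(all(diff(aud$peak_misbracketed) > 0))
  # and at p = 1 the correct variant reduces to ln theta
  t <- seq(30, 90, 5)
  expect_equal(log_population_hazard(t, wp, p = 1),
               log(weib_hazard(t, wp)), tolerance = 1e-12)
})

test_that("noise-free Weibull fit recovers the generating parameters", {
  wp <- weibull_params(0.0155, 5, 20)
  g <- age_grid()
  theta <- weib_hazard(g$midpoints, wp)
  ind <- structure(list(theta = theta, se = 0.05 * theta, grid = g,
                        stratum = "synthetic", final_bin_flag = FALSE,
                        method = "synthetic", se_method = "synthetic"),
                   class = "individual_hazard")
  fit <- fit_weibull(ind, exclude_final_bin = FALSE)
  expect_lt(rel_dev(fit$params$lambda, 0.0155), 1e-4)
  expect_lt(rel_dev(fit$params$r, 5), 1e-4)
  expect_lt(rel_dev(fit$params$A, 20), 1e-3)
  expect_lt(fit$sse_w, 1e-10)
})

test_that("fit reports AICc from the weighted SSE and is deterministic", {
  ind <- invert_hazard(pc_hazards("men")$population)
  f1 <- fit_weibull(ind)
  f2 <- fit_weibull(ind)
  expect_identical(f1$params, f2$params)
  m <- f1$n_points; k <- 3
  expect_equal(f1$aicc,
               m * log(f1$sse_w / m) + 2 * k + 2 * k * (k + 1) / (m - k - 1))
  expect_equal(m, 13)  # final interval excluded
  expect_true(all(is.finite(f1$se)))
  expect_error(fit_weibull(ind, exclude_final_bin = FALSE), NA)
})

test_that("single-stratum fits describe a near-common individual hazard", {
  # the individual hazard is 'nearly the same' across strata: each stratum's
  # fitted curve tracks every other stratum's estimates to within a small
  # factor while theta itself spans almost three orders of magnitude, and
  # the fitted turnover ages all but coincide
  fits <- lapply(pc_strata, function(s)
    fit_weibull(invert_hazard(pc_hazards(s)$population)))
  names(fits) <- pc_strata
  for (s in pc_strata) {
    ind <- invert_hazard(pc_hazards(s)$population)
    i <- 1:13
    expect_gt(max(ind$theta[i]) / min(ind$theta[i]), 500)
    for (s2 in setdiff(pc_strata, s)) {
      pred <- weib_hazard(ind$grid$midpoints[i], fits[[s2]]$params)
      expect_lt(max(abs(log10(pred / ind$theta[i]))), 0.25)
    }
  }
  peaks <- vapply(fits, function(f) f$peak_age, 0)
  expect_lt(diff(range(peaks)), 3)
  rs <- vapply(fits, function(f) f$params$r, 0)
  expect_true(all(rs >= 2 & rs <= 7))
})
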