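test_that("cumulative hazard uses rectangle-rule Q and midpoint H", {
  # single nonzero interval: Q = dt*x, H at that midpoint = dt/2*x
  g <- age_grid(n_intervals = 3)
  x <- 2e-5
  pop <- population_hazard(c(x, 0, 0), c(1e-6, 0, 0), grid = g, per_100k = FALSE)
  ch <- cumulative_hazard(pop)
  expect_equal(ch$pool$Q, 5 * x)
  expect_equal(ch$H, c(2.5 * x, 5 * x, 5 * x))
  expect_equal(ch$pool$p_exact, 1 - exp(-5 * x))
})

test_that("brute-force quadrature oracle matches Q on the reference strata", {
  # independent oracle: plain arithmetic on the published per-100k column
  for (s in c("men", "women")) {
    lam_100k <- utils::read.csv(system.file("extdata",
      sprintf("pc_%s.csv", s), package = "poolhaz"))$pop_rate_per_100k
    oracle_Q <- 5 * sum(lam_100k) / 1e5
    Q <- cumulative_hazard(pc_hazards(s)$population)$pool$Q
    expect_equal(Q, oracle_Q, tolerance = 1e-12)
  }
  expect_equal(cumulative_hazard(pc_hazards("men")$population)$pool$Q,
               3.071e-3, tolerance = 3e-4)
  expect_equal(cumulative_hazard(pc_hazards("women")$population)$pool$Q,
               2.427e-3, tolerance = 3e-4)
})

test_that("H is increasing and the inversion denominator stays positive", {
  for (s in pc_strata) {
    pop <- pc_hazards(s)$population
    ch <- cumulative_hazard(pop)
    expect_true(all(diff(ch$H) > 0))
    D <- ch$pool$Q - ch$H
    expect_true(all(D > 0))
    expect_true(all(diff(D) < 0))
  }
})

test_that("constant population hazard inverts to the closed-form theta_1", {
  # lambda = c in all m bins: theta_1 = c / (c*dt*(m - 1/2)) = 1/(dt*(m-1/2))
  g <- age_grid()
  pop <- population_hazard(rep(3e-5, 14), rep(1e-6, 14), grid = g,
                           per_100k = FALSE)
  ind <- invert_hazard(pop)
  expect_equal(ind$theta[1], 1 / (5 * 13.5), tolerance = 1e-12)
  expect_equal(ind$theta[14], 2 / 5, tolerance = 1e-12)
})

test_that("final interval inverts to the forced constant 2/dt", {
  for (s in pc_strata) {
    ind <- invert_hazard(pc_hazards(s)$population)
    expect_equal(ind$theta[14] * 1e5, 4.00e4, tolerance = 1e-12)
    expect_true(as.data.frame(ind)$final_bin_flag[14])
  }
})

test_that("inversion reproduces the published individual hazard columns", {
  for (s in pc_strata) {
    ref <- pc_hazards(s)
    ind <- invert_hazard(ref$population)
    expect_lt(max(rel_dev(ind$theta[1:13], ref$individual$theta[1:13])), 0.01)
  }
})

test_that("individual hazard increases with age on every stratum", {
  for (s in pc_strata) {
    ind <- invert_hazard(pc_hazards(s)$population)
    expect_true(all(diff(ind$theta[1:13]) > 0))
  }
})

test_that("exact and first-order inversions agree to order Q", {
  for (s in pc_strata) {
    pop <- pc_hazards(s)$population
    Q <- cumulative_hazard(pop)$pool$Q
    fo <- invert_hazard(pop, method = "first_order")
    ex <- invert_hazard(pop, method = "exact")
    expect_lt(max(rel_dev(ex$theta[1:13], fo$theta[1:13])), 2 * Q)
  }
  # and on the toy hazard
  pop <- toy_population()
  Q <- cumulative_hazard(pop)$pool$Q
  expect_lt(Q, 0.01)
  fo <- invert_hazard(pop); ex <- invert_hazard(pop, method = "exact")
  expect_lt(max(rel_dev(ex$theta[1:13], fo$theta[1:13])), 2 * Q)
})

test_that("degenerate inputs are handled: all-zero rates, zero final rate", {
  g <- age_grid(n_intervals = 3)
  pop0 <- population_hazard(rep(0, 3), rep(0, 3), grid = g, per_100k = FALSE)
  expect_warning(ind0 <- invert_hazard(pop0), "zero")
  expect_equal(ind0$theta, rep(0, 3))
  popz <- population_hazard(c(1e-5, 1e-5, 0), c(1e-6, 1e-6, 0), grid = g,
                            per_100k = FALSE)
  expect_warning(indz <- invert_hazard(popz), "final")
  expect_true(is.na(indz$theta[3]))
  expect_false(anyNA(indz$theta[1:2]))
})

test_that("published-convention SEs match the printed error columns", {
  for (s in pc_strata) {
    ref <- pc_hazards(s)
    se <- propagate_se(ref$population)
    # full 14 intervals, final one included: the convention pins it too
    expect_lt(max(rel_dev(se, ref$individual$se)), 0.01)
  }
})

test_that("full-gradient SEs match a finite-difference delta-method oracle", {
  pop <- pc_hazards("men")$population
  se_an <- propagate_se(pop, se_method = "delta")
  # oracle: numeric gradient of the whole inversion pipeline
  theta_of <- function(lam) {
    dt <- 5
    Q <- dt * sum(lam)
    H <- dt * (cumsum(lam) - lam) + dt / 2 * lam
    lam / (Q - H)
  }
  lam <- pop$rate; se <- pop$se
  eps <- 1e-10
  Jn <- sapply(seq_along(lam), function(j) {
    lp <- lam; lp[j] <- lp[j] + eps
    lm_ <- lam; lm_[j] <- lm_[j] - eps
    (theta_of(lp) - theta_of(lm_)) / (2 * eps)
  })
  se_fd <- sqrt((Jn^2) %*% (se^2))[, 1]
  expect_equal(se_an[1:13], se_fd[1:13], tolerance = 1e-5)
  # frozen hand-derived spot values (per 100k)
  expect_equal(se_an[1] * 1e5, 2.39, tolerance = 0.01)
  expect_equal(se_an[13] * 1e5, 2.82e3, tolerance = 0.01)
})

test_that("zero rate errors propagate to zero hazard errors", {
  pop <- toy_population()
  pop$se[] <- 0
  expect_equal(propagate_se(pop), rep(0, 14))
  expect_equal(propagate_se(pop, se_method = "delta")[1:13], rep(0, 13))
})

test_that("pool comparison z-test behaves as a Gaussian two-sample test", {
  mk <- function(Q, se, s = "x") structure(
    list(Q = Q, se_Q = se, p_exact = 1 - exp(-Q), stratum = s),
    class = "pool_estimate")
  same <- compare_pools(mk(0.003, 1e-4), mk(0.003, 1e-4))
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
  hand <- compare_pools(mk(0.003, 1e-4), mk(0.0024, 1e-4))
  expect_equal(hand$z, 0.0006 / sqrt(2e-8), tolerance = 1e-12)
  expect_equal(hand$z, 4.24, tolerance = 0.01)
  expect_error(compare_pools(mk(0.003, 0), mk(0.002, 1e-4)), "positive")
})

test_that("pool sizes differ significantly between paired strata", {
  pool_of <- function(s) cumulative_hazard(pc_hazards(s)$population)$pool
  for (pair in list(c("men", "women"), c("blacks", "whites"),
                    c("eastern", "western"))) {
    cmpr <- compare_pools(pool_of(pair[1]), pool_of(pair[2]))
    expect_gt(cmpr$dQ, 0)   # first of each pair has the larger pool
    expect_lt(cmpr$p_value, 0.05)
  }
})
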