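#' Weighted Weibull fit to individual hazard estimates
#'
#' Fits the three-parameter Weibull hazard [weib_hazard()] to inverted
#' individual hazard estimates by weighted nonlinear least squares,
#' minimizing `SSE_w = sum_i w_i * (theta_hat_i - theta(tau_i))^2` with
#' inverse-variance weights `w_i = 1 / SE(theta_hat_i)^2` on the linear
#' hazard scale. One or several strata can be fitted jointly: passing a list
#' of `individual_hazard` objects pools their points under a single shared
#' parameter set (the working assumption that the individual hazard does not
#' differ across strata).
#'
#' The final age interval of each series is excluded by default: its
#' inverted value is a discretization constant, not data (see
#' [invert_hazard()]).
#'
#' Because the three-parameter Weibull least-squares surface is multi-modal,
#' the optimizer (Levenberg-Marquardt, `minpack.lm::nls.lm`, bounded
#' parameters) is restarted from a deterministic coarse lattice of starting
#' values: `A` in `{0, 10, 20, 30}` (capped below the youngest fitted age),
#' `r` in `2..8`, and for each pair the `lambda` that makes the model pass
#' through the observed point nearest 62.5 years. The best converged start
#' by `SSE_w` wins; no stochastic restarts are used, so the fit is fully
#' deterministic.
#'
#' Parameter standard errors come from the delta method at the optimum,
#' `cov = s2 * (J' J)^-1` with the weighted Jacobian `J` and
#' `s2 = SSE_w / (m - k)`. Goodness of fit is summarized by the
#' small-sample-corrected Akaike criterion
#' `AICc = m * log(SSE_w / m) + 2k + 2k(k + 1) / (m - k - 1)` (`k = 3`),
#' reported as `NA` when `m <= k + 1`.
#'
#' @param ind An `individual_hazard` (see [invert_hazard()]) or a list of
#'   them for a pooled fit.
#' @param exclude_final_bin Drop the final interval of each series
#'   (default `TRUE`).
#' @param start_A,start_r Lattices of starting values for the multi-start.
#' @return An object of class `weibull_fit`: `params` ([weibull_params()]),
#'   `se` (named vector of parameter SEs), `sse_w`, `n_points`, `n_params`,
#'   `aicc`, `peak_age` (years, first-order turnover), and the fitted
#'   points in `data`.
#' @examples
#' ind <- invert_hazard(pc_hazards("men")$population)
#' fit <- fit_weibull(ind)
#' fit$params
#' @export
fit_weibull <- function(ind, exclude_final_bin = TRUE,
                        start_A = c(0, 10, 20, 30), start_r = 2:8) {
  if (inherits(ind, "individual_hazard")) ind <- list(ind)
  stopifnot(length(ind) >= 1,
            all(vapply(ind, inherits, TRUE, "individual_hazard")))
  tt <- th <- se <- numeric(0)
  for (x in ind) {
    keep <- seq_len(x$grid$n_intervals)
    if (exclude_final_bin) keep <- keep[-length(keep)]
    tt <- c(tt, x$grid$midpoints[keep])
    th <- c(th, x$theta[keep])
    se <- c(se, x$se[keep])
  }
  ok <- is.finite(th) & is.finite(se) & se > 0
  tt <- tt[ok]; th <- th[ok]; se <- se[ok]
  m <- length(tt); k <- 3
  if (m < 5) stop("need at least 5 usable points with positive SEs, got ", m)
  w <- 1 / se^2
  sw <- sqrt(w)

  model <- function(par, t) {
    s <- pmax(t - par[3], 0)
    ifelse(s > 0, par[2] * par[1] * (par[1] * s)^(par[2] - 1), 0)
  }
  resid_fn <- function(par) sw * (th - model(par, tt))

  A_hi <- min(tt) - 0.5
  lower <- c(1e-10, 1, 0)
  upper <- c(10, 15, A_hi)
  anchor <- which.min(abs(tt - 62.5))

  best <- NULL
  for (A0 in start_A[start_A < A_hi - 1]) {
    for (r0 in start_r) {
      s0 <- tt[anchor] - A0
      la0 <- (th[anchor] / (r0 * s0^(r0 - 1)))^(1 / r0)
      o <- tryCatch(
        minpack.lm::nls.lm(par = c(la0, r0, A0), fn = resid_fn,
                           lower = lower, upper = upper,
                           control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(o)) next
      sse <- sum(o$fvec^2)
      if (is.null(best) || sse < best_sse) { best <- o; best_sse <- sse }
    }
  }
  if (is.null(best))
    stop("Weibull fit failed to converge from any lattice start")

  par <- best$par
  params <- weibull_params(par[1], par[2], par[3])
  sse_w <- best_sse

  # analytic weighted Jacobian at the optimum
  s <- pmax(tt - par[3], 0)
  pos <- s > 0
  f <- model(par, tt)
  J <- matrix(0, m, k)
  J[pos, 1] <- par[2]^2 * par[1]^(par[2] - 1) * s[pos]^(par[2] - 1)
  J[pos, 2] <- f[pos] * (1 / par[2] + log(par[1] * s[pos]))
  J[pos, 3] <- -par[2] * (par[2] - 1) * par[1]^par[2] * s[pos]^(par[2] - 2)
  Jw <- sw * J
  ses <- rep(NA_real_, k)
  if (m > k) {
    cv <- tryCatch(solve(crossprod(Jw)) * sse_w / (m - k),
                   error = function(e) NULL)
    if (!is.null(cv)) ses <- sqrt(pmax(diag(cv), 0))
  }
  names(ses) <- c("lambda", "r", "A")

  aicc <- if (m > k + 1)
    m * log(sse_w / m) + 2 * k + 2 * k * (k + 1) / (m - k - 1)
  else NA_real_

  structure(list(params = params, se = ses, sse_w = sse_w,
                 n_points = m, n_params = k, aicc = aicc,
                 peak_age = peak_age(params)$age,
                 data = data.frame(age = tt, theta = th, se = se)),
            class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat("<weibull_fit>\n")
  print(x$params)
  cat(sprintf("  SE: lambda %.3g, r %.3g, A %.3g\n",
              x$se["lambda"], x$se["r"], x$se["A"]))
  cat(sprintf("  %d points, SSE_w = %.4g, AICc = %.4g, turnover at %.1f y\n",
              x$n_points, x$sse_w, x$aicc, x$peak_age))
  invisible(x)
}

#' Predicted hazard curves from a fitted Weibull model
#'
#' @param object A `weibull_fit`.
#' @param t Ages (years) at which to predict; defaults to a 0.5-year grid
#'   over the fitted range.
#' @param p Optional susceptible fraction; when supplied, the first-order
#'   population hazard is returned alongside the individual hazard.
#' @param ... Unused.
#' @return A data frame with `age`, `theta` (individual hazard per year) and,
#'   when `p` is given, `h_pop` (first-order population hazard per year).
#' @export
predict.weibull_fit <- function(object, t = NULL, p = NULL, ...) {
  if (is.null(t))
    t <- seq(min(object$data$age), max(object$data$age), by = 0.5)
  out <- data.frame(age = t, theta = weib_hazard(t, object$params))
  if (!is.null(p))
    out$h_pop <- population_hazard_fn(t, object$params, p,
                                      method = "first_order")
  out
}

#' Stratified population-hazard predictions from a shared individual hazard
#'
#' Applies the first-order mixture prediction
#' `h_s(t) = Q_s * theta(t) * exp(-Theta(t))` to each stratum, using a
#' common individual hazard and each stratum's own pool estimate. Predicted
#' curves for any two strata are exactly proportional, with ratio equal to
#' the ratio of their pool sizes.
#'
#' @param params A [weibull_params()] object (shared across strata).
#' @param pools Named list of `pool_estimate` objects (see
#'   [cumulative_hazard()]), or a named numeric vector of pool fractions.
#' @param t Ages (years) at which to predict.
#' @return A data frame with columns `stratum`, `age`, `theta_per_100k`,
#'   `h_pop_per_100k`.
#' @export
predict_strata <- function(params, pools, t = seq(30, 100, by = 0.5)) {
  stopifnot(inherits(params, "weibull_params"))
  if (is.numeric(pools)) {
    p_vec <- pools
  } else {
    p_vec <- vapply(pools, function(x) x$Q, 0)
    if (is.null(names(p_vec)))
      names(p_vec) <- vapply(pools, function(x) x$stratum, "")
  }
  stopifnot(length(p_vec) >= 1, !is.null(names(p_vec)))
  th <- weib_hazard(t, params)
  S <- exp(-weib_cum_hazard(t, params))
  do.call(rbind, lapply(names(p_vec), function(nm) {
    data.frame(stratum = nm, age = t,
               theta_per_100k = th * 1e5,
               h_pop_per_100k = p_vec[[nm]] * th * S * 1e5)
  }))
}
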