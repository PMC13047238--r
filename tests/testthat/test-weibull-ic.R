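test_that("likelihood contributions reduce to closed forms at the edges", {
  m <- truth_model()
  # never positive, censored at the last screen (L = T*): the bracket is
  # P00(L, L) = 1, so the contribution is log P00(0, L)
  iv <- data.frame(id = "a", L = 24, R = NA_real_, tstar = 24, delta = 0)
  expect_equal(weibull_ic_loglik(m, iv), log(idm_transprob(m, 0, 24)["0", "0"]),
               tolerance = 1e-10)
  # never positive, death immediately after the last screen: the onset
  # integral vanishes and only the direct-death term survives
  iv2 <- data.frame(id = "a", L = 24, R = NA_real_, tstar = 24 + 1e-7,
                    delta = 1)
  lam02 <- idm_hazard(m, "02", iv2$tstar)
  expect_equal(weibull_ic_loglik(m, iv2),
               log(idm_transprob(m, 0, 24)["0", "0"] * lam02),
               tolerance = 1e-4)
  expect_error(weibull_ic_loglik(m, data.frame(id = "x", L = 10, R = 5,
                                               tstar = 20, delta = 0)),
               "interval ordering")
})

test_that("onset integral matches the constant-hazard closed form", {
  # with all shapes 1 the contribution for a positive-in-(L,R] subject is
  # P00(0,L) * P11(R', T*)-type closed form derived from the
  # constant-hazard competing-risks expression
  l01 <- 0.05; l02 <- 0.03; l12 <- 0.4
  m <- weibull_idm(shape = 1, rate = c(l01, l02, l12))
  L <- 4; R <- 9; tstar <- 15
  # closed form of P00(0,L) * int_L^R e^{-(l01+l02)(u-L)} l01
  #   e^{-l12 (tstar-u)} du with c = l01 + l02 - l12 (negative here)
  cc <- l01 + l02 - l12
  cf <- l01 * exp(-l12 * tstar) * (exp(-cc * L) - exp(-cc * R)) / cc
  iv <- data.frame(id = "a", L = L, R = R, tstar = tstar, delta = 0)
  expect_equal(weibull_ic_loglik(m, iv), log(cf), tolerance = 1e-8)
  # and the death version adds log lambda12(T*)
  iv2 <- iv; iv2$delta <- 1
  expect_equal(weibull_ic_loglik(m, iv2), log(cf) + log(l12),
               tolerance = 1e-8)
})

test_that("interval likelihood approaches the exact-data likelihood as tau -> 0", {
  m <- truth_model()
  # one diseased-then-dead subject with onset pinned ever more precisely
  t1 <- 7.31; tstar <- 20
  exact <- log(idm_transprob(m, 0, t1)["0", "0"]) +
    log(idm_hazard(m, "01", t1)) +
    log(idm_transprob(m, t1, tstar)["1", "1"]) +
    log(idm_hazard(m, "12", tstar))
  gap <- vapply(c(2, 0.5, 0.05, 0.005), function(tau) {
    iv <- data.frame(id = "a", L = t1 - tau / 2, R = t1 + tau / 2,
                     tstar = tstar, delta = 1)
    # width-normalised interval likelihood converges to the density
    weibull_ic_loglik(m, iv) - log(tau) - exact
  }, numeric(1))
  expect_true(all(abs(gap) == cummin(abs(gap))))
  expect_lt(abs(gap[4]), 1e-3)
})

test_that("fit recovers the generating parameters within 3 SE (scenario A)", {
  pd <- simulate_scenario("A", seed = 101)
  fit <- fit_weibull_ic(pd)
  expect_true(fit$converged)
  truth <- log(c(0.05, 0.05, 0.56, 0.5, 0.5, 0.5))
  est <- log(c(fit$rate, fit$shape))
  for (i in 1:6) {
    expect_lt(abs(est[i] - truth[i]), 3 * fit$se_log[i])
  }
})

test_that("with near-exact onset times the fit matches per-transition Weibull MLEs", {
  set.seed(202)
  lat <- draw_latent_paths(1500, truth_model())
  tstar <- pmin(lat$td, 120)
  delta <- as.integer(lat$td <= 120)
  ill <- lat$exit_state == 1L & lat$t1 <= tstar
  eps <- 1e-4   # vanishingly narrow onset intervals
  iv <- data.frame(id = sprintf("s%d", seq_along(tstar)),
                   L = ifelse(ill, pmax(lat$t1 - eps, 0), tstar),
                   R = ifelse(ill, lat$t1, NA_real_),
                   tstar = tstar, delta = delta)
  fit <- fit_weibull_ic(iv)

  # oracle: separate parametric survival fits per transition
  # 0 -> 1: time to onset, competing exit censored at min(td, 120)
  sr01 <- survival::survreg(
    survival::Surv(ifelse(ill, lat$t1, tstar), ill) ~ 1, dist = "weibull")
  k01 <- 1 / sr01$scale
  a01 <- exp(-sr01$coefficients[[1]] / sr01$scale)
  expect_equal(fit$shape[["01"]], k01, tolerance = 0.05)
  expect_equal(fit$rate[["01"]], a01, tolerance = 0.12)

  # 1 -> 2: death after onset, left-truncated at t1
  d12 <- data.frame(start = lat$t1[ill], stop = tstar[ill],
                    ev = delta[ill])
  ll12 <- function(p) {
    a <- exp(p[1]); k <- exp(p[2])
    -sum(d12$ev * log(a * k * d12$stop^(k - 1)) -
           a * (d12$stop^k - d12$start^k))
  }
  o12 <- optim(c(log(0.5), log(0.5)), ll12)
  expect_equal(fit$shape[["12"]], exp(o12$par[2]), tolerance = 0.05)
  expect_equal(fit$rate[["12"]], exp(o12$par[1]), tolerance = 0.12)
})

test_that("event-free data pushes the onset rate to its lower boundary", {
  # everyone censored alive at their last (negative) screen: the
  # likelihood is maximised by vanishing exit rates from state 0
  set.seed(303)
  tstar <- sample(seq(12, 120, by = 12), 120, replace = TRUE)
  iv <- data.frame(id = sprintf("s%d", 1:120), L = tstar, R = NA_real_,
                   tstar = tstar, delta = 0L)
  expect_warning(fit <- fit_weibull_ic(iv), "boundary")
  expect_true("a01" %in% fit$boundary)
  expect_lt(fit$rate[["01"]], 1e-5)
})

test_that("time-dependent hazard ratio behaves per its closed form", {
  m <- truth_model()
  expect_equal(weibull_hr(m, c(1, 10, 100)), rep(11.2, 3))
  up <- weibull_idm(shape = c(0.5, 0.5, 0.9), rate = c(0.05, 0.05, 0.2))
  hr <- weibull_hr(up, c(5, 20, 80))
  expect_true(all(diff(hr) > 0))
  expect_warning(weibull_hr(up, 0), "degenerate")
})
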