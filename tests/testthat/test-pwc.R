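const_rates <- function(q01, q02, q12, changepoints = c(6, 30, 60, 90)) {
  matrix(c(q01, q02, q12), 3, length(changepoints) + 1,
         dimnames = list(c("01", "02", "12"), NULL))
}

test_that("interval transition matrix matches its closed form and limits", {
  m <- pwc_idm(const_rates(0.05, 0.05, 0.56))
  P <- idm_transprob(m, 0, 1)
  expect_equal(P["0", "1"],
               0.05 / (0.1 - 0.56) * (exp(-0.56) - exp(-0.1)),
               tolerance = 1e-12)
  expect_equal(idm_transprob(m, 3, 3), diag(3), ignore_attr = TRUE)
  # removable singularity q01 + q02 = q12: limit and continuity
  m0 <- pwc_idm(const_rates(0.04, 0.06, 0.10))
  expect_equal(idm_transprob(m0, 0, 2)["0", "1"],
               0.04 * 2 * exp(-0.10 * 2), tolerance = 1e-10)
  meps <- pwc_idm(const_rates(0.04, 0.06, 0.10 + 1e-9))
  expect_equal(idm_transprob(meps, 0, 2)["0", "1"],
               idm_transprob(m0, 0, 2)["0", "1"], tolerance = 1e-7)
})

test_that("piecewise products agree with a generic matrix exponential", {
  skip_if_not_installed("Matrix")
  set.seed(77)
  for (rep in 1:5) {
    rates <- matrix(runif(15, 0.001, 0.6), 3, 5,
                    dimnames = list(c("01", "02", "12"), NULL))
    m <- pwc_idm(rates)
    s <- runif(1, 0, 40); t <- s + runif(1, 0, 60)
    # oracle: expm of each piece generator, multiplied across pieces
    bounds <- c(0, m$changepoints, Inf)
    P <- diag(3)
    for (j in 1:5) {
      d <- max(0, min(t, bounds[j + 1]) - max(s, bounds[j]))
      if (d > 0) {
        Q <- matrix(0, 3, 3)
        Q[1, 2] <- rates["01", j]; Q[1, 3] <- rates["02", j]
        Q[2, 3] <- rates["12", j]
        diag(Q) <- -rowSums(Q)
        P <- P %*% as.matrix(Matrix::expm(Q * d))
      }
    }
    got <- idm_transprob(m, s, t)
    expect_lt(max(abs(got - P)), 1e-10)
    expect_equal(unname(rowSums(got)), rep(1, 3), tolerance = 1e-10)
  }
})

test_that("hazard lookups use the left-limit piece", {
  rates <- matrix(1:15 / 100, 3, 5, dimnames = list(c("01", "02", "12"), NULL))
  m <- pwc_idm(rates)
  expect_equal(unname(idm_hazard(m, "01", c(2, 6, 6.1, 90, 91))),
               unname(rates["01", c(1, 1, 2, 4, 5)]))
  expect_equal(unname(death_hazard_ratio(m, 30)),
               unname(rates["12", 2] / rates["02", 2]))
  expect_equal(idm_cumhaz(m, "02", 10),
               unname(rates["02", 1] * 6 + rates["02", 2] * 4))
})

test_that("panel log-likelihood matches hand computation", {
  q01 <- 0.03; q02 <- 0.02; q12 <- 0.3
  m <- pwc_idm(const_rates(q01, q02, q12))
  # subject healthy at 0 and at t: single P00 factor
  visits <- data.frame(id = "a", time = c(0, 10), marker = c(0, 0))
  out <- data.frame(id = "a", tstar = 10, delta = 0)
  expect_equal(pwc_panel_loglik(m, idm_panel(visits, out)),
               -(q01 + q02) * 10, tolerance = 1e-12)
  # healthy at last screen v*, dies at T*: two-term sum over the
  # unknown terminal state
  out2 <- data.frame(id = "a", tstar = 13.7, delta = 1)
  p <- idm_transprob(m, 10, 13.7)
  expect_equal(pwc_panel_loglik(m, idm_panel(visits, out2)),
               -(q01 + q02) * 10 +
                 log(p["0", "0"] * q02 + p["0", "1"] * q12),
               tolerance = 1e-12)
  # observed ill at the last screen, then dies: only state 1 reachable
  visits3 <- data.frame(id = "a", time = c(0, 10), marker = c(0, 1))
  p3 <- idm_transprob(m, 10, 13.7)
  expect_equal(pwc_panel_loglik(m, idm_panel(visits3, out2)),
               log(idm_transprob(m, 0, 10)["0", "1"]) +
                 log(p3["1", "1"] * q12),
               tolerance = 1e-12)
})

test_that("Chapman-Kolmogorov factorisation leaves the likelihood invariant", {
  # inserting an intermediate time and summing over the latent state at it
  # reproduces the direct interval probability
  m <- pwc_idm(const_rates(0.04, 0.03, 0.2))
  P1 <- idm_transprob(m, 2, 17)
  P2 <- idm_transprob(m, 2, 9) %*% idm_transprob(m, 9, 17)
  expect_lt(max(abs(P1 - P2)), 1e-12)
})

test_that("single-piece fit recovers constant generating rates within 3 SE", {
  q <- c(0.02, 0.015, 0.25)
  m <- weibull_idm(shape = 1, rate = q)   # constant-hazard generator
  pd <- simulate_idm(1500, tau = 6, censoring = "admin", model = m, seed = 55)
  fit <- fit_pwc_idm(pd, changepoints = 60)  # 2 pieces, both truly constant
  expect_true(fit$converged)
  se <- sqrt(pmax(diag(fit$covariance), 0))  # log-rate scale
  for (j in 1:2) {
    expect_lt(abs(log(fit$rates["01", j]) - log(q[1])), 3 * se[j] + 1e-6)
    expect_lt(abs(log(fit$rates["02", j]) - log(q[2])), 3 * se[2 + j] + 1e-6)
    expect_lt(abs(log(fit$rates["12", j]) - log(q[3])), 3 * se[4 + j] + 1e-6)
  }
})

test_that("constrained fit recovers the generating hazard ratio", {
  # 12-monthly screens: the panel likelihood should stay close to the
  # generating HR of 11.2 while the interval-censoring-blind Cox estimate
  # is attenuated
  pd <- simulate_idm(1000, tau = 12, censoring = "uniform", seed = 57)
  fit <- fit_pwc_idm(pd, constrained = TRUE)
  expect_true(fit$converged)
  expect_lt(abs(fit$beta - log(11.2)), 3 * fit$se_beta + 0.2)
  # yearly screens attenuate the naive Cox coefficient
  cox <- fit_cox_idm(pd)
  expect_lt(cox$beta, log(11.2))
})
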