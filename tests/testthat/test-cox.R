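test_that("counting-process rows encode diagnosis and death correctly", {
  rows <- build_counting_process(tiny_panel())
  a <- rows[rows$id == "a", ]
  expect_equal(a$tstart, c(0, 6))
  expect_equal(a$tstop, c(6, 14))
  expect_equal(a$x, c(0L, 1L))
  expect_equal(a$event, c(0L, 1L))
  b <- rows[rows$id == "b", ]
  expect_equal(nrow(b), 1L)
  expect_equal(unlist(b[, c("tstart", "tstop", "x", "event")]),
               c(tstart = 0, tstop = 7.2, x = 0, event = 0))
})

test_that("diagnosis at end of follow-up obeys the chosen convention", {
  visits <- data.frame(id = "d", time = c(0, 6), marker = c(0, 1))
  outcomes <- data.frame(id = "d", tstar = 6, delta = 1)
  pd <- idm_panel(visits, outcomes)
  r1 <- build_counting_process(pd, diag_at_end = "diseased")
  expect_equal(r1$x[which.max(r1$tstop)], 1L)   # dies with marker set
  expect_true(all(r1$tstop - r1$tstart > 0))
  r2 <- build_counting_process(pd, diag_at_end = "disease-free")
  expect_equal(nrow(r2), 1L)
  expect_equal(r2$x, 0L)
})

test_that("partial-likelihood estimate matches a brute-force grid oracle", {
  # 3 subjects: A dies t=2 (never diseased); B diagnosed t=1, dies t=3;
  # C censored t=4 disease-free. Two death terms in the partial likelihood:
  #   t=2: risk set {A (x=0), B (x=1), C (x=0)}, case A
  #   t=3: risk set {B (x=1), C (x=0)}, case B
  visits <- data.frame(id = c("A", "B", "B", "C", "C"),
                       time = c(0, 0, 1, 0, 1),
                       marker = c(0, 0, 1, 0, 0))
  outcomes <- data.frame(id = c("A", "B", "C"), tstar = c(2, 3, 4),
                         delta = c(1, 1, 0))
  pd <- idm_panel(visits, outcomes)
  logpl <- function(b) {
    log(1 / (2 + exp(b))) + log(exp(b) / (1 + exp(b)))
  }
  grid <- seq(-3, 5, length.out = 8001)
  bracket <- grid[which.max(logpl(grid))] + c(-0.01, 0.01)
  beta_oracle <- optimize(logpl, bracket, maximum = TRUE, tol = 1e-10)$maximum
  fit <- fit_cox_idm(pd)
  expect_equal(fit$beta, beta_oracle, tolerance = 1e-6)
  # oracle score is (numerically) zero at the fitted value
  eps <- 1e-5
  expect_lt(abs((logpl(fit$beta + eps) - logpl(fit$beta - eps)) / (2 * eps)),
            1e-4)
})

test_that("marker permuted independently of death gives a null coefficient", {
  set.seed(21)
  pd <- simulate_idm(1500, tau = 3, censoring = "uniform", seed = 21)
  iv <- summarize_intervals(pd)
  # re-assign the observed diagnosis times to random subjects (keeping
  # each admissible: R <= tstar), breaking the marker-death link
  Rvals <- iv$R[!is.na(iv$R)]
  iv$R[] <- NA
  for (r in sample(Rvals)) {
    ok <- which(is.na(iv$R) & iv$tstar > r)
    if (length(ok)) iv$R[sample(ok, 1)] <- r
  }
  visits <- do.call(rbind, lapply(seq_len(nrow(iv)), function(i) {
    tm <- seq(0, floor(iv$tstar[i] / 3) * 3, by = 3)
    data.frame(id = iv$id[i], time = tm,
               marker = as.integer(!is.na(iv$R[i]) & tm >= iv$R[i]))
  }))
  fit <- fit_cox_idm(idm_panel(visits, iv[, c("id", "tstar", "delta")]))
  expect_lt(abs(fit$beta), 3 * fit$se_beta)
})

test_that("Aalen-Johansen product integral matches a hand-computed product", {
  # worked 5-subject set: diagnoses at t=1 (E) and t=2 (D); deaths at
  # t=3 (D) and t=4 (B); C and E censored later
  visits <- data.frame(
    id = c("A", "B", "C", "D", "D", "E", "E"),
    time = c(0, 0, 0, 0, 2, 0, 1),
    marker = c(0, 0, 0, 0, 1, 0, 1))
  outcomes <- data.frame(id = c("A", "B", "C", "D", "E"),
                         tstar = c(2.5, 4, 5, 3, 5),
                         delta = c(0, 1, 0, 1, 0))
  fit <- fit_cox_idm(idm_panel(visits, outcomes))
  j <- fit$jumps
  P <- diag(3)
  for (i in seq_len(nrow(j))) {
    if (j$time[i] > 4) break
    dA <- matrix(0, 3, 3)
    dA[1, 2] <- j$dL01[i]; dA[1, 3] <- j$dL02[i]
    dA[2, 3] <- min(exp(fit$beta) * j$dL02[i], 1)
    diag(dA) <- -rowSums(dA)
    P <- P %*% (diag(3) + dA)
  }
  expect_equal(unname(idm_transprob(fit, 0, 4)), unname(P), tolerance = 1e-10)
  expect_equal(idm_transprob(fit, 2, 2), diag(3), ignore_attr = TRUE)
})

test_that("with no diagnoses the fit degenerates to a survival model", {
  visits <- data.frame(id = rep(c("A", "B", "C", "D"), each = 2),
                       time = rep(c(0, 3), 4), marker = 0L)
  outcomes <- data.frame(id = c("A", "B", "C", "D"),
                         tstar = c(5, 6, 7, 8), delta = c(1, 1, 0, 1))
  fit <- fit_cox_idm(idm_panel(visits, outcomes))
  expect_equal(fit$beta, 0)
  for (t in c(4, 5.5, 7.5)) {
    P <- idm_transprob(fit, 0, t)
    expect_equal(P["0", "1"], 0)
    # single active transition: Aalen-Johansen reduces to the
    # product-limit (Kaplan-Meier) survivor estimate
    km <- survival::survfit(survival::Surv(tstar, delta) ~ 1, data = outcomes)
    expect_equal(P["0", "0"], summary(km, times = t)$surv, tolerance = 1e-10)
  }
})

test_that("risk-set ROC AUC handles the degenerate cases", {
  pd <- simulate_idm(200, tau = 6, censoring = "admin", seed = 31)
  fit <- fit_cox_idm(pd)
  # beta = 0 makes weights uniform: AUC identically one half
  fit0 <- fit
  fit0$beta <- 0
  rs0 <- riskset_auc_id(fit0, c(6, 12, 24, 48))
  expect_equal(rs0$auc, rep(0.5, 4), tolerance = 1e-12)
  # before the first death time the curve sits at one half
  expect_equal(riskset_auc_id(fit, 1e-4)$auc, 0.5)
  # the real fit discriminates above chance at later times
  rs <- riskset_auc_id(fit, c(12, 36, 60))
  expect_true(all(rs$auc >= 0.5))
})

test_that("risk-set and transition-probability incident AUC curves agree", {
  pd <- simulate_idm(1000, tau = 3, censoring = "uniform", seed = 33)
  fit <- fit_cox_idm(pd)
  grid <- seq(12, 96, by = 6)
  rs <- riskset_auc_id(fit, grid)$auc
  tp <- vapply(grid, function(t) auc_id(fit, t)$value, numeric(1))
  expect_lt(mean(abs(rs - tp)), 0.02)
})
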