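#' Counting-process rows for the Cox model with time-dependent marker
#'
#' Encodes the naive analysis that ignores interval censoring: the
#' diagnosis time is taken to be the first positive visit `R`, so a
#' diagnosed subject contributes a disease-free row `(0, R]` and a
#' diseased row `(R, T*]` carrying the death indicator; an undiagnosed
#' subject contributes a single `(0, T*]` row.
#'
#' When diagnosis coincides with the end of follow-up (`R == T*`, e.g. a
#' positive screen at the death/censoring visit) a zero-length diseased row
#' cannot be emitted. Under the default convention (`diag_at_end =
#' "diseased"`, matching the generating rule that the marker at `T*` equals
#' its value at the last visit) the switch is moved to just before `T*` so
#' the terminal row carries `x = 1`; under `"disease-free"` the diagnosis
#' is dropped and the subject stays `x = 0` throughout.
#'
#' @param panel an [idm_panel()].
#' @param diag_at_end convention for `R == T*`, see above.
#' @return data.frame with columns `id`, `tstart`, `tstop`, `x`, `event`
#'   (half-open risk intervals `(tstart, tstop]`).
#' @export
build_counting_process <- function(panel,
                                   diag_at_end = c("diseased", "disease-free")) {
  diag_at_end <- match.arg(diag_at_end)
  iv <- summarize_intervals(panel)
  diag <- !is.na(iv$R)
  if (diag_at_end == "disease-free") diag <- diag & iv$R < iv$tstar
  R <- iv$R
  # move a terminal-visit diagnosis epsilon before T* to keep (R, T*] valid
  tie <- diag & R >= iv$tstar
  R[tie] <- iv$tstar[tie] - 1e-6
  n0 <- sum(!diag); n1 <- sum(diag)
  one <- data.frame(id = iv$id[!diag], tstart = rep(0, n0),
                    tstop = iv$tstar[!diag], x = rep(0L, n0),
                    event = iv$delta[!diag])
  pre <- data.frame(id = iv$id[diag], tstart = rep(0, n1), tstop = R[diag],
                    x = rep(0L, n1), event = rep(0L, n1))
  post <- data.frame(id = iv$id[diag], tstart = R[diag],
                     tstop = iv$tstar[diag], x = rep(1L, n1),
                     event = iv$delta[diag])
  rows <- rbind(one, pre, post)
  rows <- rows[order(rows$id, rows$tstart), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Cox illness-death fit ignoring interval censoring
#'
#' Fits the proportional hazards model
#' \eqn{\lambda(t \mid X(t)) = \lambda_0(t)\exp\{\beta X(t)\}} with the
#' observed binary diagnosis marker as a time-dependent covariate (Breslow
#' tie handling), and assembles the corresponding illness-death model:
#' the baseline identifies \eqn{\lambda_{02}}, \eqn{\lambda_{12}(t) =
#' e^{\beta}\lambda_{02}(t)}, and the 0->1 cumulative hazard is a
#' Nelson-Aalen estimator treating the first positive visit as an exact
#' onset time. Transition probabilities are Aalen-Johansen product
#' integrals over the merged jump grid, so the resulting AUC curves are
#' step functions.
#'
#' @inheritParams build_counting_process
#' @return object of class `c("cox_idm", "fitted_idm")` with elements
#'   `beta`, `se_beta`, `jumps` (jump grid with increments `dL01`, `dL02`),
#'   `rows` (the counting-process data), `separated` (logical flag) and
#'   `coxph` (the underlying [survival::coxph()] fit).
#' @examples
#' pd <- simulate_idm(300, tau = 3, censoring = "uniform", seed = 1)
#' fit <- fit_cox_idm(pd)
#' exp(fit$beta)   # hazard ratio of death, diseased vs disease-free
#' @export
fit_cox_idm <- function(panel, diag_at_end = c("diseased", "disease-free")) {
  rows <- build_counting_process(panel, diag_at_end)
  if (sum(rows$event) == 0) stop("no deaths observed; cannot fit Cox model")
  if (all(rows$x == 0L)) {
    cfit <- NULL
    beta <- 0
    se <- NA_real_
    separated <- FALSE   # no marker variation: beta pinned at 0
  } else {
    # timefix would collapse the very early death times the k < 1 hazard
    # produces into zero-length intervals; keep exact times
    cfit <- survival::coxph(
      survival::Surv(tstart, tstop, event) ~ x,
      data = rows, ties = "breslow",
      control = survival::coxph.control(timefix = FALSE))
    beta <- unname(cfit$coefficients[1])
    se <- sqrt(unname(cfit$var[1, 1]))
    separated <- !is.finite(beta) || abs(beta) > 15
  }

  # Breslow baseline cumulative hazard (0->2): dL02(t) = d(t) / sum exp(b x)
  # over the risk set tstart < t <= tstop; risk-set sums via sorted-time
  # cumulative weights rather than a scan per death time
  dtimes <- sort(unique(rows$tstop[rows$event == 1L]))
  w <- exp(beta * rows$x)
  sum_before <- function(times, at) {   # sum of w over rows with times < at
    o <- order(times)
    cw <- c(0, cumsum(w[o]))
    cw[findInterval(at - 1e-9, times[o]) + 1L]
  }
  denom <- sum_before(rows$tstart, dtimes) - sum_before(rows$tstop, dtimes)
  nev <- as.numeric(table(factor(rows$tstop[rows$event == 1L],
                                 levels = dtimes)))
  dL02 <- nev / denom

  # Nelson-Aalen for 0->1 on observed diagnosis times (exit from state 0
  # at diagnosis or at end of follow-up, whichever is first)
  iv <- summarize_intervals(panel)
  t01 <- ifelse(is.na(iv$R), iv$tstar, iv$R)
  e01 <- !is.na(iv$R)
  otimes <- sort(unique(t01[e01]))
  srt <- sort(t01)
  nrisk01 <- length(srt) - findInterval(otimes - 1e-9, srt)
  dL01 <- as.numeric(table(factor(t01[e01], levels = otimes))) / nrisk01

  grid <- sort(unique(c(dtimes, otimes)))
  jumps <- data.frame(
    time = grid,
    dL01 = ifelse(grid %in% otimes, dL01[match(grid, otimes)], 0),
    dL02 = ifelse(grid %in% dtimes, dL02[match(grid, dtimes)], 0))

  structure(
    list(beta = beta, se_beta = se, jumps = jumps, rows = rows,
         separated = separated, coxph = cfit),
    class = c("cox_idm", "fitted_idm"))
}

#' @export
print.cox_idm <- function(x, ...) {
  cat("Cox illness-death fit (time-dependent diagnosis marker)\n")
  cat(sprintf("  beta = %.4f (se %.4f), HR = %.3f%s\n", x$beta, x$se_beta,
              exp(x$beta), if (x$separated) "  [separation flagged]" else ""))
  cat(sprintf("  %d jump times\n", nrow(x$jumps)))
  invisible(x)
}

#' @export
idm_jump_times.cox_idm <- function(object, ...) object$jumps$time

#' @export
death_hazard_ratio.cox_idm <- function(object, t, ...) {
  if (object$separated) stop("separated Cox fit: hazard ratio is not finite")
  rep(exp(object$beta), length(t))
}

#' @export
idm_cumhaz.cox_idm <- function(object, transition, t, ...) {
  check_transition(transition)
  j <- object$jumps
  inc <- switch(transition, "01" = j$dL01, "02" = j$dL02,
                "12" = exp(object$beta) * j$dL02)
  vapply(t, function(tt) sum(inc[j$time <= tt]), numeric(1))
}

#' @export
idm_hazard.cox_idm <- function(object, transition, t, ...) {
  stop("the Cox illness-death fit has no hazard density; ",
       "use idm_cumhaz() increments or death_hazard_ratio()")
}

#' @export
idm_transprob.cox_idm <- function(object, s, t, left = FALSE, ...) {
  check_interval(s, t)
  if (object$separated) stop("separated Cox fit: transition probabilities unavailable")
  j <- object$jumps
  keep <- if (left) j$time > s & j$time < t else j$time > s & j$time <= t
  p00 <- 1; p01 <- 0; p11 <- 1
  hr <- exp(object$beta)
  for (i in which(keep)) {
    d01 <- j$dL01[i]; d02 <- j$dL02[i]; d12 <- min(hr * j$dL02[i], 1)
    p01 <- p00 * d01 + p01 * (1 - d12)
    p00 <- p00 * (1 - d01 - d02)
    p11 <- p11 * (1 - d12)
  }
  idm_probmat(p00, p01, p11)
}

#' Risk-set (ROC-based) incident/dynamic AUC for the Cox fit
#'
#' The alternative incident/dynamic estimator assembled from the ROC curve
#' at each death time: incident sensitivity uses the Cox-model risk-set
#' weights \eqn{\pi_i(t) = \exp(\hat\beta x_i)/\sum_{j \in R(t)}
#' \exp(\hat\beta x_j)}, the dynamic control distribution of the binary
#' marker is empirical in the risk set, and the AUC uses the ties-aware
#' binary-marker formula. Between death times the curve is a step function
#' (last value carried forward); it equals 0.5 before the first death time
#' and wherever no disease has been observed in the risk set.
#'
#' @param fit a [fit_cox_idm()] object.
#' @param t_grid evaluation times (months).
#' @return data.frame with columns `time` and `auc`.
#' @export
riskset_auc_id <- function(fit, t_grid) {
  stopifnot(inherits(fit, "cox_idm"))
  if (fit$separated) stop("separated Cox fit: risk-set AUC unavailable")
  rows <- fit$rows
  dtimes <- sort(unique(rows$tstop[rows$event == 1L]))
  hr <- exp(fit$beta)
  auc_d <- vapply(dtimes, function(tt) {
    atrisk <- rows$tstart < tt & tt <= rows$tstop
    x <- rows$x[atrisk]
    w <- exp(fit$beta * x)
    sens <- sum(w * x) / sum(w)               # model-based case distribution
    q <- mean(x)                              # control distribution in risk set
    sens * (1 - q) + 0.5 * (sens * q + (1 - sens) * (1 - q))
  }, numeric(1))
  idx <- findInterval(t_grid, dtimes)
  data.frame(time = t_grid, auc = ifelse(idx == 0, 0.5, auc_d[pmax(idx, 1)]))
}
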