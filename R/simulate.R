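#' Scenario catalogue for the simulation study
#'
#' The 18 study conditions (A-R) crossing sample size (1000, 2000, 400),
#' death censoring (uniform on 5-10 years vs administrative at 10 years)
#' and visit spacing (3, 6, 12 months). All scenarios share the Weibull
#' generating model with common shape 0.5 and rates 0.05/0.05/0.56 per
#' month-scale transition, i.e. a death hazard ratio of 11.2 for diseased
#' vs disease-free subjects.
#'
#' @return data.frame with columns `scenario`, `n`, `censoring`
#'   (`"uniform"` or `"admin"`), `a` (lower censoring bound, months; `NA`
#'   for administrative), `y` (follow-up horizon, months), `tau` (visit
#'   spacing, months).
#' @export
scenario_catalogue <- function() {
  ns <- rep(c(1000L, 2000L, 400L), each = 6L)
  cens <- rep(rep(c("uniform", "admin"), each = 3L), times = 3L)
  data.frame(
    scenario = LETTERS[1:18],
    n = ns,
    censoring = cens,
    a = ifelse(cens == "uniform", 60, NA_real_),
    y = 120,
    tau = rep(c(3, 6, 12), times = 6L),
    stringsAsFactors = FALSE)
}

#' Draw latent illness-death paths from a common-shape Weibull model
#'
#' Inversion sampling of the progressive three-state process. With common
#' shape `k` across the three transitions, the first exit time from the
#' disease-free state is
#' \eqn{T_1 = (-\ln U_1 / (\alpha_{01}+\alpha_{02}))^{1/k}}, the exit goes
#' to disease with probability \eqn{\alpha_{01}/(\alpha_{01}+\alpha_{02})},
#' and for diseased subjects the death time is drawn conditionally on
#' having survived to \eqn{T_1}:
#' \eqn{T_D = (T_1^k - \ln U_2 / \alpha_{12})^{1/k}}.
#'
#' @param n number of paths.
#' @param model a [weibull_idm()]; the three shapes must be equal (the
#'   inversion formulas require a common shape).
#' @return data.frame with columns `t1` (first exit time from state 0,
#'   months), `exit_state` (1 = disease, 2 = death), `td` (death time,
#'   equal to `t1` for direct deaths), `u1`, `u2` (`u2` is `NA` for direct
#'   deaths). Uses the current RNG stream.
#' @export
draw_latent_paths <- function(n, model = weibull_idm()) {
  stopifnot(inherits(model, "weibull_idm"))
  k <- unname(model$shape)
  if (max(k) - min(k) > 0) {
    stop("inversion sampling requires a common shape across transitions")
  }
  k <- k[1]
  a01 <- model$rate[["01"]]; a02 <- model$rate[["02"]]
  a12 <- model$rate[["12"]]
  u1 <- runif(n)
  t1 <- (-log(u1) / (a01 + a02))^(1 / k)
  exit_state <- ifelse(runif(n) < a01 / (a01 + a02), 1L, 2L)
  u2 <- ifelse(exit_state == 1L, runif(n), NA_real_)
  td <- ifelse(exit_state == 1L, (t1^k - log(u2) / a12)^(1 / k), t1)
  data.frame(t1 = t1, exit_state = exit_state, td = td, u1 = u1, u2 = u2)
}

#' Censor latent death times
#'
#' Administrative censoring truncates follow-up at the horizon `y`
#' (`tstar = min(td, y)`); uniform censoring draws `C ~ Uniform(a, y)` per
#' subject and sets `tstar = min(td, C)`. `delta` indicates an observed
#' death.
#'
#' @param td latent death times (months).
#' @param censoring `"admin"` or `"uniform"`.
#' @param a,y censoring window bounds in months (`a` only for uniform).
#' @return data.frame with columns `tstar`, `delta`.
#' @export
apply_censoring <- function(td, censoring = c("admin", "uniform"),
                            a = 60, y = 120) {
  censoring <- match.arg(censoring)
  if (censoring == "admin") {
    cens <- rep(y, length(td))
  } else {
    if (!(a < y)) stop("uniform censoring needs a < y")
    cens <- runif(length(td), a, y)
  }
  data.frame(tstar = pmin(td, cens), delta = as.integer(td <= cens))
}

#' Interval-censor illness times on a regular visit grid
#'
#' Visits occur at `0, tau, 2*tau, ..., y`; follow-up for the marker stops
#' at the last visit `v* = max{grid t <= tstar}`. A true illness time
#' `t1 <= tstar` is observed at the first visit at or after onset,
#' `v = min{grid t >= t1}`; the marker is 0 at visits before `v` and 1
#' from `v` through `v*`. Illness with `v > v*` (onset after the last
#' visit but before death/censoring) is never observed.
#'
#' @param t1 true illness times (months); `NA` or `Inf` for subjects who
#'   never entered the disease state.
#' @param tstar,delta end of follow-up and death indicator.
#' @param tau visit spacing (months).
#' @param y follow-up horizon (months).
#' @param id subject identifiers (defaults to `s0001, ...`).
#' @return an [idm_panel()].
#' @export
discretize_marker <- function(t1, tstar, delta, tau, y = 120,
                              id = sprintf("s%05d", seq_along(tstar))) {
  n <- length(tstar)
  stopifnot(length(t1) == n, length(delta) == n)
  t1 <- ifelse(is.na(t1), Inf, t1)
  vstar <- pmin(floor(tstar / tau + 1e-12), y / tau) * tau
  # first visit at/after onset ("at" inclusive: onset on a visit day is seen)
  v <- ceiling(t1 / tau - 1e-12) * tau
  observed <- is.finite(t1) & t1 <= tstar & v <= vstar
  nv <- as.integer(round(vstar / tau)) + 1L
  times <- (sequence(nv) - 1) * tau
  ids <- rep(id, nv)
  vrep <- rep(ifelse(observed, v, Inf), nv)
  visits <- data.frame(id = ids, time = times,
                       marker = as.integer(times >= vrep),
                       stringsAsFactors = FALSE)
  idm_panel(visits, data.frame(id = id, tstar = tstar,
                               delta = as.integer(delta),
                               stringsAsFactors = FALSE))
}

#' Simulate an interval-censored illness-death dataset
#'
#' Full data-generating pipeline: latent Weibull paths, censoring of death
#' times, and interval censoring of illness on the regular visit grid.
#' Deterministic given `seed`.
#'
#' @param n number of subjects.
#' @param tau visit spacing (months).
#' @param censoring `"admin"` or `"uniform"`.
#' @param a,y censoring bounds / horizon in months.
#' @param model the generating [weibull_idm()] (common shape).
#' @param seed integer seed; `NULL` to use the current RNG state.
#' @return an [idm_panel()] with attribute `"latent"` holding the latent
#'   paths (for diagnostics and truth-known tests).
#' @examples
#' pd <- simulate_idm(200, tau = 3, censoring = "uniform", seed = 1)
#' pd
#' @export
simulate_idm <- function(n, tau, censoring = c("admin", "uniform"),
                         a = 60, y = 120, model = weibull_idm(),
                         seed = NULL) {
  censoring <- match.arg(censoring)
  if (!is.null(seed)) set.seed(as.integer(seed))
  paths <- draw_latent_paths(n, model)
  cens <- apply_censoring(paths$td, censoring, a = a, y = y)
  t1 <- ifelse(paths$exit_state == 1L, paths$t1, NA_real_)
  panel <- discretize_marker(t1, cens$tstar, cens$delta, tau = tau, y = y)
  attr(panel, "latent") <- paths
  panel
}

#' @rdname simulate_idm
#' @param scenario a scenario letter `"A"`..`"R"` (see
#'   [scenario_catalogue()]).
#' @export
simulate_scenario <- function(scenario, seed = NULL, model = weibull_idm()) {
  cat_ <- scenario_catalogue()
  row <- cat_[cat_$scenario == scenario, ]
  if (nrow(row) != 1L) stop("unknown scenario: ", scenario)
  simulate_idm(row$n, tau = row$tau, censoring = row$censoring,
               a = ifelse(is.na(row$a), 60, row$a), y = row$y,
               model = model, seed = seed)
}
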