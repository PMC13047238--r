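#' @keywords internal
"_PACKAGE"

#' @importFrom stats integrate optim optimHess sd rbinom runif setNames
#' @importFrom utils read.csv write.csv
NULL

# State space of the progressive illness-death process:
#   0 = disease-free, 1 = diseased, 2 = dead (absorbing).
# Allowed transitions: 0->1, 0->2, 1->2, indexed by the keys below.
IDM_TRANSITIONS <- c("01", "02", "12")

IDM_STATES <- c("0", "1", "2")

#' Generic contract for a fitted (or true) illness-death model
#'
#' Every model object in this package -- the true Weibull generating model,
#' the Cox fit, the piecewise-constant panel fit and the Weibull
#' interval-censored fit -- implements the same small interface: transition
#' hazards, cumulative hazards, the transition probability matrix
#' \eqn{P(s,t)} of the time-inhomogeneous Markov chain, the ratio
#' \eqn{\gamma(t) = \lambda_{12}(t)/\lambda_{02}(t)} of the two death
#' hazards, and (for step-function models) the grid of jump times used to
#' form left limits. The plug-in AUC estimators in [auc_id()] and
#' [auc_cd()] are written against this contract only.
#'
#' @param object a fitted illness-death model.
#' @param transition one of `"01"`, `"02"`, `"12"`.
#' @param t,s time in months, `s <= t`.
#' @param left logical; if `TRUE`, step-function models evaluate
#'   \eqn{P(s, t-)}, excluding any jump at exactly `t`. Smooth models
#'   ignore it.
#' @param ... passed to methods.
#'
#' @return `idm_hazard` and `idm_cumhaz` return non-negative numeric
#'   vectors; `idm_transprob` a 3x3 row-stochastic matrix with rows/columns
#'   named `"0","1","2"`; `death_hazard_ratio` a positive numeric vector;
#'   `idm_jump_times` a numeric vector (length 0 for smooth models).
#' @seealso [weibull_idm()], [fit_cox_idm()], [fit_pwc_idm()],
#'   [fit_weibull_ic()]
#' @name idm-contract
NULL

#' @rdname idm-contract
#' @export
idm_hazard <- function(object, transition, t, ...) UseMethod("idm_hazard")

#' @rdname idm-contract
#' @export
idm_cumhaz <- function(object, transition, t, ...) UseMethod("idm_cumhaz")

#' @rdname idm-contract
#' @export
idm_transprob <- function(object, s, t, left = FALSE, ...) {
  UseMethod("idm_transprob")
}

#' @rdname idm-contract
#' @export
death_hazard_ratio <- function(object, t, ...) UseMethod("death_hazard_ratio")

#' @rdname idm-contract
#' @export
idm_jump_times <- function(object, ...) UseMethod("idm_jump_times")

#' @export
idm_jump_times.default <- function(object, ...) numeric(0)

check_transition <- function(transition) {
  if (!is.character(transition) || length(transition) != 1L ||
      !transition %in% IDM_TRANSITIONS) {
    stop("`transition` must be one of ", paste(IDM_TRANSITIONS, collapse = ", "))
  }
  transition
}

check_interval <- function(s, t) {
  if (!is.numeric(s) || !is.numeric(t) || length(s) != 1L || length(t) != 1L ||
      is.na(s) || is.na(t)) {
    stop("`s` and `t` must be finite scalars")
  }
  if (s < 0) stop("`s` must be non-negative")
  if (s > t) stop("`s` must not exceed `t` (got s = ", s, ", t = ", t, ")")
  invisible(NULL)
}

# Assemble a named 3x3 transition probability matrix for the progressive
# chain from the survivor-type entries; the remaining mass goes to death.
idm_probmat <- function(p00, p01, p11) {
  p00 <- min(max(p00, 0), 1)
  p01 <- min(max(p01, 0), 1)
  p11 <- min(max(p11, 0), 1)
  P <- matrix(c(p00, p01, 1 - p00 - p01,
                0,   p11, 1 - p11,
                0,   0,   1),
              nrow = 3, byrow = TRUE,
              dimnames = list(IDM_STATES, IDM_STATES))
  P[P < 0] <- 0
  P
}
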