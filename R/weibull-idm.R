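#' Weibull illness-death model
#'
#' Constructs a Markov illness-death model with Weibull transition
#' intensities \eqn{\lambda_{hl}(t) = \alpha_{hl} k_{hl} t^{k_{hl}-1}}
#' for the three transitions 0->1 (disease onset), 0->2 (death without
#' disease) and 1->2 (death after disease). With the default simulation
#' parameters (common shape 0.5, rates 0.05/0.05/0.56 on the months time
#' scale) the hazard ratio of death for diseased vs disease-free subjects
#' is constant at \eqn{0.56/0.05 = 11.2}.
#'
#' Survivor-type transition probabilities are available in closed form,
#' \deqn{P_{00}(s,t) = \exp\{-[\Lambda_{01}(t)-\Lambda_{01}(s)]
#'   - [\Lambda_{02}(t)-\Lambda_{02}(s)]\},\quad
#'   P_{11}(s,t) = \exp\{-[\Lambda_{12}(t)-\Lambda_{12}(s)]\},}
#' while \eqn{P_{01}(s,t) = \int_s^t P_{00}(s,u)\lambda_{01}(u)
#' P_{11}(u,t)\,du} is computed by Gauss-Legendre quadrature after the
#' substitution \eqn{z = u^{k_{01}}}, which removes the integrable
#' singularity of the 0->1 hazard at zero when its shape is below one.
#'
#' @param shape named or unnamed numeric vector of three positive shapes
#'   (order `01`, `02`, `12`), or a single value recycled to all three.
#' @param rate numeric vector of three positive rates (same order).
#' @param quad_nodes number of Gauss-Legendre nodes for the
#'   \eqn{P_{01}} integral.
#' @return an object of class `c("weibull_idm", "fitted_idm")` honouring
#'   the [idm-contract].
#' @examples
#' truth <- weibull_idm()  # the default generating model
#' idm_hazard(truth, "12", 1)            # 0.28
#' idm_transprob(truth, 0, 12)["0", "0"] # about 0.707
#' @export
weibull_idm <- function(shape = c(0.5, 0.5, 0.5),
                        rate = c(0.05, 0.05, 0.56),
                        quad_nodes = 41L) {
  shape <- rep_len(as.numeric(shape), 3L)
  rate <- rep_len(as.numeric(rate), 3L)
  if (any(!is.finite(shape)) || any(shape <= 0)) {
    stop("all shape parameters must be strictly positive")
  }
  if (any(!is.finite(rate)) || any(rate <= 0)) {
    stop("all rate parameters must be strictly positive")
  }
  structure(
    list(shape = setNames(shape, IDM_TRANSITIONS),
         rate = setNames(rate, IDM_TRANSITIONS),
         quad_nodes = as.integer(quad_nodes)),
    class = c("weibull_idm", "fitted_idm"))
}

#' @export
print.weibull_idm <- function(x, ...) {
  cat("Weibull illness-death model (time in months)\n")
  print(rbind(shape = x$shape, rate = x$rate))
  gam <- x$rate[["12"]] * x$shape[["12"]] / (x$rate[["02"]] * x$shape[["02"]])
  if (x$shape[["12"]] == x$shape[["02"]]) {
    cat(sprintf("constant death hazard ratio gamma = %.4g\n", gam))
  }
  invisible(x)
}

#' @export
idm_hazard.weibull_idm <- function(object, transition, t, ...) {
  check_transition(transition)
  if (any(t < 0)) stop("`t` must be non-negative")
  a <- object$rate[[transition]]
  k <- object$shape[[transition]]
  # for shape < 1 the hazard diverges at t = 0: return Inf there
  ifelse(t == 0 & k < 1, Inf, a * k * t^(k - 1))
}

#' @export
idm_cumhaz.weibull_idm <- function(object, transition, t, ...) {
  check_transition(transition)
  if (any(t < 0)) stop("`t` must be non-negative")
  object$rate[[transition]] * t^object$shape[[transition]]
}

#' @export
death_hazard_ratio.weibull_idm <- function(object, t, ...) {
  idm_hazard(object, "12", t) / idm_hazard(object, "02", t)
}

# P01(s,t) with z = u^{k01}: du * lambda01(u) = a01 dz
weibull_p01 <- function(object, s, t) {
  a <- object$rate; k <- object$shape
  k01 <- k[["01"]]
  sk01 <- s^k01; sk02 <- s^k[["02"]]; tk12 <- t^k[["12"]]
  f <- function(z) {
    u <- z^(1 / k01)
    exp(-a[["01"]] * (z - sk01) -
          a[["02"]] * (u^k[["02"]] - sk02) -
          a[["12"]] * (tk12 - u^k[["12"]]))
  }
  a[["01"]] * gl_integrate(f, sk01, t^k01, n = object$quad_nodes)
}

#' @export
idm_transprob.weibull_idm <- function(object, s, t, left = FALSE, ...) {
  check_interval(s, t)
  p00 <- exp(-(idm_cumhaz(object, "01", t) - idm_cumhaz(object, "01", s)) -
               (idm_cumhaz(object, "02", t) - idm_cumhaz(object, "02", s)))
  p11 <- exp(-(idm_cumhaz(object, "12", t) - idm_cumhaz(object, "12", s)))
  p01 <- if (t > s) weibull_p01(object, s, t) else 0
  idm_probmat(p00, p01, p11)
}

#' True time-specific AUC under a Weibull illness-death model
#'
#' Exact incident/dynamic and cumulative/dynamic AUC of the binary disease
#' marker, computed from the model's transition probabilities and hazards.
#'
#' The incident/dynamic AUC at time `t` contrasts subjects dying exactly
#' at `t` (incident cases) with subjects surviving beyond `t` (dynamic
#' controls):
#' \deqn{AUC^{I/D}(t) = 0.5 + 0.5\,(p(t) - \pi_1(t)),}
#' with disease prevalence among survivors
#' \eqn{\pi_1(t) = P_{01}(0,t) / [P_{00}(0,t) + P_{01}(0,t)]} and
#' disease prevalence among the dying
#' \eqn{p(t) = P_{01}(0,t)\gamma(t) / [P_{00}(0,t) + P_{01}(0,t)\gamma(t)]},
#' where \eqn{\gamma(t) = \lambda_{12}(t)/\lambda_{02}(t)}. If
#' \eqn{\gamma \equiv 1} the AUC is exactly 0.5 at all times; \eqn{\gamma >
#' 1} pushes it above 0.5 and \eqn{\gamma < 1} below.
#'
#' The cumulative/dynamic AUC freezes the marker at time `s` and contrasts
#' deaths in `(s, t]` with survivors beyond `t`:
#' \deqn{AUC^{C/D}(s,t) = 0.5 + 0.5\,(p(s,t) - \pi_1(s,t)),}
#' \deqn{\pi_1(s,t) = \frac{P_{01}(0,s) P_{11}(s,t)}
#'   {P_{00}(0,t) + P_{01}(0,t)},\qquad
#'   p(s,t) = \frac{P_{01}(0,s) P_{12}(s,t)}
#'   {P_{00}(0,s) P_{02}(s,t) + P_{01}(0,s) P_{12}(s,t)}.}
#'
#' @param object a [weibull_idm()] model.
#' @param t evaluation time in months (`true_auc_id`) or window end
#'   (`true_auc_cd`); vectorised.
#' @param s marker evaluation time in months, `0 < s < t` (`true_auc_cd`).
#' @return numeric vector of AUC values in `[0, 1]`. `true_auc_id(0)` is
#'   0.5 by convention (no disease can have occurred yet).
#' @examples
#' truth <- weibull_idm()
#' round(true_auc_id(truth, 12), 2)       # 0.71
#' round(true_auc_cd(truth, 12, 72), 2)   # 0.59
#' @export
true_auc_id <- function(object, t) {
  stopifnot(inherits(object, "weibull_idm"))
  vapply(t, function(tt) {
    if (tt < 0) stop("`t` must be non-negative")
    if (tt == 0) return(0.5)
    P <- idm_transprob(object, 0, tt)
    p00 <- P["0", "0"]; p01 <- P["0", "1"]
    gam <- death_hazard_ratio(object, tt)
    pi1 <- p01 / (p00 + p01)
    p <- p01 * gam / (p00 + p01 * gam)
    0.5 + 0.5 * (p - pi1)
  }, numeric(1))
}

#' @rdname true_auc_id
#' @export
true_auc_cd <- function(object, s, t) {
  stopifnot(inherits(object, "weibull_idm"))
  n <- max(length(s), length(t))
  s <- rep_len(s, n); t <- rep_len(t, n)
  vapply(seq_len(n), function(i) {
    if (s[i] <= 0 || s[i] >= t[i]) stop("need 0 < s < t")
    P0s <- idm_transprob(object, 0, s[i])
    P0t <- idm_transprob(object, 0, t[i])
    Pst <- idm_transprob(object, s[i], t[i])
    pi1 <- P0s["0", "1"] * Pst["1", "1"] / (P0t["0", "0"] + P0t["0", "1"])
    den <- P0s["0", "0"] * Pst["0", "2"] + P0s["0", "1"] * Pst["1", "2"]
    p <- if (den > 0) P0s["0", "1"] * Pst["1", "2"] / den else 0
    0.5 + 0.5 * (p - pi1)
  }, numeric(1))
}
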