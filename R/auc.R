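#' Plug-in time-specific AUC for a fitted illness-death model
#'
#' Model-based estimators of the incident/dynamic and cumulative/dynamic
#' AUC of the binary disease marker, computed by plugging the fitted
#' transition probabilities and death-hazard ratio of any model honouring
#' the [idm-contract] into
#' \deqn{\widehat{AUC}(\cdot) = 0.5 + 0.5(\hat p - \hat\pi_1).}
#'
#' For the incident/dynamic AUC at `t`,
#' \eqn{\hat\pi_1 = \hat P_{01}/(\hat P_{00}+\hat P_{01})} and
#' \eqn{\hat p = \hat P_{01} r/(\hat P_{00}+\hat P_{01} r)} with
#' \eqn{r = \hat\lambda_{12}(t)/\hat\lambda_{02}(t)}; the ratio form
#' avoids 0/0 from step-hazard increments. Models with a jump grid (the
#' Cox fit) are evaluated at the left limit \eqn{t-} for both components:
#' the marker enters the risk set as a predictable process, so its value
#' at an event time is the value just before it. In particular the curve
#' equals 0.5 before the first observed diagnosis. Smooth models are
#' unaffected (left limit equals the value at `t`).
#'
#' For the cumulative/dynamic AUC the marker is frozen at `s` (measured
#' at the visit at `s`, so right-continuous there):
#' \eqn{\hat\pi_1(s,t) = \hat P_{01}(0,s)\hat P_{11}(s,t) /
#' [\hat P_{00}(0,t)+\hat P_{01}(0,t)]} and
#' \eqn{\hat p(s,t) = \hat P_{01}(0,s)\hat P_{12}(s,t) /
#' [\hat P_{00}(0,s)\hat P_{02}(s,t)+\hat P_{01}(0,s)\hat P_{12}(s,t)]}.
#'
#' @param model an object honouring the [idm-contract].
#' @param t evaluation time in months (scalar).
#' @param s marker time in months, `0 < s < t` (cumulative/dynamic only).
#' @return a list of class `auc_estimate` with elements `kind`, `t` (and
#'   `s`), `value`, `pi1_hat`, `p_hat`, and `flag` (`NA` or a string for
#'   degenerate cases: no survivors possible, or no information in the
#'   window, where the value defaults to 0.5).
#' @examples
#' truth <- weibull_idm()
#' auc_id(truth, 12)$value       # about 0.706
#' auc_cd(truth, 12, 72)$value   # about 0.594
#' @export
auc_id <- function(model, t) {
  stopifnot(length(t) == 1L, t > 0)
  P <- idm_transprob(model, 0, t, left = TRUE)
  p00 <- P["0", "0"]; p01 <- P["0", "1"]
  if (p00 + p01 <= 0) {
    return(structure(list(kind = "ID", t = t, value = NA_real_,
                          pi1_hat = NA_real_, p_hat = NA_real_,
                          flag = "no survivors possible"),
                     class = "auc_estimate"))
  }
  r <- death_hazard_ratio(model, t)
  pi1 <- p01 / (p00 + p01)
  p <- p01 * r / (p00 + p01 * r)
  structure(list(kind = "ID", t = t, value = 0.5 + 0.5 * (p - pi1),
                 pi1_hat = pi1, p_hat = p, flag = NA_character_),
            class = "auc_estimate")
}

#' @rdname auc_id
#' @export
auc_cd <- function(model, s, t) {
  stopifnot(length(s) == 1L, length(t) == 1L)
  if (!(s > 0 && s < t)) stop("need 0 < s < t")
  P0s <- idm_transprob(model, 0, s)
  P0t <- idm_transprob(model, 0, t)
  Pst <- idm_transprob(model, s, t)
  num_pi <- P0s["0", "1"] * Pst["1", "1"]
  den_pi <- P0t["0", "0"] + P0t["0", "1"]
  den_p <- P0s["0", "0"] * Pst["0", "2"] + P0s["0", "1"] * Pst["1", "2"]
  flag <- NA_character_
  if (den_pi <= 0 || den_p <= 0) {
    # no survivors, or no deaths possible in the window: zero information
    return(structure(list(kind = "CD", s = s, t = t, value = 0.5,
                          pi1_hat = 0, p_hat = 0,
                          flag = "zero information"),
                     class = "auc_estimate"))
  }
  pi1 <- num_pi / den_pi
  p <- P0s["0", "1"] * Pst["1", "2"] / den_p
  structure(list(kind = "CD", s = s, t = t, value = 0.5 + 0.5 * (p - pi1),
                 pi1_hat = pi1, p_hat = p, flag = flag),
            class = "auc_estimate")
}

#' @export
print.auc_estimate <- function(x, ...) {
  if (x$kind == "ID") {
    cat(sprintf("AUC^I/D(%g mo) = %.4f  (pi1 = %.4f, p = %.4f)\n",
                x$t, x$value, x$pi1_hat, x$p_hat))
  } else {
    cat(sprintf("AUC^C/D(%g, %g mo) = %.4f  (pi1 = %.4f, p = %.4f)\n",
                x$s, x$t, x$value, x$pi1_hat, x$p_hat))
  }
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' AUC curve over a time grid
#'
#' Evaluates [auc_id()] over `times`, or [auc_cd()] at
#' `(times, times + window)`; for the cumulative/dynamic kind the grid is
#' truncated so that `times + window` stays within `horizon`.
#'
#' @inheritParams auc_id
#' @param kind `"ID"` or `"CD"`.
#' @param times ascending evaluation grid, months (default monthly,
#'   1-120 for ID, 1-60 for CD).
#' @param window prediction window in months (CD only; default 60).
#' @param horizon largest admissible `t` (default 120 months).
#' @return data.frame with columns `s` (CD only), `t`, `pi1_hat`, `p_hat`,
#'   `auc`.
#' @export
auc_curve <- function(model, kind = c("ID", "CD"), times = NULL,
                      window = 60, horizon = 120) {
  kind <- match.arg(kind)
  if (is.null(times)) times <- seq(1, if (kind == "ID") horizon else horizon - window)
  if (kind == "CD") times <- times[times + window <= horizon]
  if (!length(times)) {
    return(data.frame(s = numeric(0), t = numeric(0), pi1_hat = numeric(0),
                      p_hat = numeric(0), auc = numeric(0)))
  }
  if (kind == "ID") {
    est <- lapply(times, function(tt) auc_id(model, tt))
    data.frame(t = times,
               pi1_hat = vapply(est, `[[`, numeric(1), "pi1_hat"),
               p_hat = vapply(est, `[[`, numeric(1), "p_hat"),
               auc = vapply(est, `[[`, numeric(1), "value"))
  } else {
    est <- lapply(times, function(ss) auc_cd(model, ss, ss + window))
    data.frame(s = times, t = times + window,
               pi1_hat = vapply(est, `[[`, numeric(1), "pi1_hat"),
               p_hat = vapply(est, `[[`, numeric(1), "p_hat"),
               auc = vapply(est, `[[`, numeric(1), "value"))
  }
}
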