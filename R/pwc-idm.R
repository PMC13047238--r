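#' Piecewise-constant illness-death model
#'
#' Transition intensities are constant on the pieces cut by the
#' changepoints `c_1 < ... < c_k` (piece `j` covers `(c_{j-1}, c_j]`).
#' Within a piece the process is time-homogeneous with a triangular
#' generator, so the interval transition matrix has the closed form
#' \deqn{P_{00} = e^{-(q_{01}+q_{02})d},\quad P_{11} = e^{-q_{12}d},\quad
#'  P_{01} = \frac{q_{01}}{q_{01}+q_{02}-q_{12}}
#'    \left(e^{-q_{12}d} - e^{-(q_{01}+q_{02})d}\right),}
#' with the limit \eqn{q_{01} d\, e^{-q_{12} d}} when
#' \eqn{q_{01}+q_{02} = q_{12}}; across pieces the matrices multiply in
#' order. The default changepoints are 6, 30, 60 and 90 months.
#'
#' @param rates 3 x (k+1) matrix of non-negative rates (per month), rows
#'   named `"01"`, `"02"`, `"12"`, one column per piece.
#' @param changepoints ascending changepoint times in months.
#' @return object of class `c("pwc_idm", "fitted_idm")`.
#' @examples
#' m <- pwc_idm(rates = matrix(c(0.05, 0.05, 0.56), 3, 5,
#'                             dimnames = list(c("01", "02", "12"), NULL)))
#' idm_transprob(m, 0, 12)
#' @export
pwc_idm <- function(rates, changepoints = c(6, 30, 60, 90)) {
  changepoints <- as.numeric(changepoints)
  if (is.unsorted(changepoints, strictly = TRUE) || any(changepoints <= 0)) {
    stop("`changepoints` must be strictly increasing and positive")
  }
  rates <- as.matrix(rates)
  if (nrow(rates) != 3L || ncol(rates) != length(changepoints) + 1L) {
    stop("`rates` must be 3 x (number of changepoints + 1)")
  }
  if (is.null(rownames(rates))) rownames(rates) <- IDM_TRANSITIONS
  if (!identical(rownames(rates), IDM_TRANSITIONS)) {
    stop("`rates` rows must be named 01, 02, 12")
  }
  if (any(rates < 0) || any(!is.finite(rates))) {
    stop("rates must be finite and non-negative")
  }
  structure(list(rates = rates, changepoints = changepoints),
            class = c("pwc_idm", "fitted_idm"))
}

#' @export
print.pwc_idm <- function(x, ...) {
  cat("Piecewise-constant illness-death model\n")
  cat("  changepoints (months):", paste(x$changepoints, collapse = ", "), "\n")
  print(round(x$rates, 5))
  invisible(x)
}

# index of the piece whose value is the left limit lambda(t-): the piece
# containing (t - eps), i.e. 1 + #{changepoints strictly below t}
pwc_piece_left <- function(t, changepoints) {
  1L + rowSums(outer(t, changepoints, ">"))
}

# Exposure matrix: E[i, j] = length of (s_i, t_i] inside piece j. The
# piece geometry does not depend on the rates, so repeated likelihood
# evaluations over the same observation times reuse it.
pwc_exposure <- function(s, t, changepoints) {
  bounds <- c(0, changepoints, Inf)
  np <- length(changepoints) + 1L
  E <- matrix(0, length(s), np)
  for (j in seq_len(np)) {
    E[, j] <- pmax(0, pmin(t, bounds[j + 1]) - pmax(s, bounds[j]))
  }
  E
}

# Survivor-type transition probabilities from a precomputed exposure
# matrix; pure matrix algebra in the rates.
pwc_probs_exposure <- function(rates, E) {
  np <- ncol(E)
  Q <- E %*% t(rates)                       # n x 3, columns 01/02/12
  p00 <- exp(-(Q[, 1] + Q[, 2]))
  p11 <- exp(-Q[, 3])
  # P01(s,t) = sum over pieces of a closed-form exponential integral:
  # within piece j the integrand is lambda01_j * exp(-A(u) - B(u)) with
  # A(u) = Lambda01+02(s,u) and B(u) = Lambda12(u,t), both linear in u
  p01 <- numeric(nrow(E))
  A <- numeric(nrow(E))                     # Lambda01+02(s, lo_j)
  for (j in seq_len(np)) {
    d <- E[, j]
    # B = Lambda12(lo_j, t): this piece plus all later ones
    B <- if (j < np) {
      drop(E[, j:np, drop = FALSE] %*% rates["12", j:np])
    } else {
      rates["12", np] * d
    }
    c0 <- rates["01", j] + rates["02", j] - rates["12", j]
    intg <- if (abs(c0) > 1e-12) -expm1(-c0 * d) / c0 else d
    p01 <- p01 + rates["01", j] * exp(-A - B) * intg
    A <- A + (rates["01", j] + rates["02", j]) * d
  }
  list(p00 = p00, p01 = p01, p11 = p11)
}

# Vectorised survivor-type transition probabilities over (s, t].
pwc_probs_vec <- function(object, s, t) {
  pwc_probs_exposure(object$rates, pwc_exposure(s, t, object$changepoints))
}

#' @export
idm_hazard.pwc_idm <- function(object, transition, t, ...) {
  check_transition(transition)
  if (any(t < 0)) stop("`t` must be non-negative")
  unname(object$rates[transition,
                      pwc_piece_left(pmax(t, 1e-12), object$changepoints)])
}

#' @export
idm_cumhaz.pwc_idm <- function(object, transition, t, ...) {
  check_transition(transition)
  bounds <- c(0, object$changepoints, Inf)
  r <- object$rates[transition, ]
  vapply(t, function(tt) {
    sum(r * pmax(0, pmin(tt, bounds[-1]) - bounds[-length(bounds)]))
  }, numeric(1))
}

#' @export
death_hazard_ratio.pwc_idm <- function(object, t, ...) {
  j <- pwc_piece_left(pmax(t, 1e-12), object$changepoints)
  unname(object$rates["12", j] / object$rates["02", j])
}

#' @export
idm_transprob.pwc_idm <- function(object, s, t, left = FALSE, ...) {
  check_interval(s, t)
  p <- pwc_probs_vec(object, s, t)
  idm_probmat(p$p00, p$p01, p$p11)
}

# ---- panel likelihood -------------------------------------------------

# Reduce a panel dataset to the sufficient statistics of the
# piecewise-constant likelihood: counts of consecutive-visit transitions
# per unique (from, to) time pair, plus per-subject terminal records.
# Visit grids are regular, so the number of distinct pairs is small; this
# is what makes repeated likelihood evaluation cheap.
pwc_prepare <- function(panel) {
  v <- panel$visits
  idx <- split(seq_len(nrow(v)), v$id)
  pair_s <- pair_t <- numeric(0); pair_type <- character(0)
  for (i in idx) {
    m <- length(i)
    if (m >= 2) {
      st <- v$marker[i]
      pair_s <- c(pair_s, v$time[i][-m])
      pair_t <- c(pair_t, v$time[i][-1])
      pair_type <- c(pair_type, paste0(st[-m], st[-1]))
    }
  }
  if (any(pair_type == "10")) stop("non-monotone marker in panel")
  key <- paste(pair_s, pair_t, pair_type)
  agg <- tapply(rep(1L, length(key)), key, sum)
  parts <- do.call(rbind, strsplit(names(agg), " "))
  pairs <- data.frame(s = as.numeric(parts[, 1]), t = as.numeric(parts[, 2]),
                      type = parts[, 3], n = as.integer(agg))

  last <- vapply(idx, function(i) i[length(i)], integer(1))
  term <- data.frame(id = v$id[last], vstar = v$time[last],
                     h = v$marker[last])
  term <- merge(term, panel$outcomes, by = "id", sort = FALSE)
  list(pairs = pairs, term = term)
}

#' Panel log-likelihood of the piecewise-constant illness-death model
#'
#' Per-subject contributions: a factor \eqn{P_{00}}, \eqn{P_{01}} or
#' \eqn{P_{11}} for each consecutive visit pair according to the observed
#' states; for a subject last seen in state `h` at the final visit
#' \eqn{v^*}, a terminal factor
#' \eqn{\sum_{l\in\{0,1\}} P_{hl}(v^*, T^*)\,\lambda_{l2}(T^*-)} for an
#' exact death at \eqn{T^*} (the state between the last screen and death
#' is unknown and is summed out), or
#' \eqn{\sum_{l\in\{0,1\}} P_{hl}(v^*, T^*)} for censoring alive.
#'
#' @param object a [pwc_idm()] model.
#' @param panel an [idm_panel()] (or the prepared statistics from it).
#' @return the log-likelihood; `-Inf` if any observed factor has
#'   probability zero.
#' @export
pwc_panel_loglik <- function(object, panel) {
  prep <- if (inherits(panel, "idm_panel")) pwc_prepare(panel) else panel
  geom <- pwc_geometry(prep, object$changepoints)
  pwc_loglik_geom(object$rates, prep, geom)
}

# Parameter-independent geometry of the likelihood: exposure matrices for
# the visit pairs and terminal windows, and the left-limit piece of each
# death/censoring time.
pwc_geometry <- function(prep, changepoints) {
  list(E_pairs = pwc_exposure(prep$pairs$s, prep$pairs$t, changepoints),
       E_term = pwc_exposure(prep$term$vstar, prep$term$tstar, changepoints),
       jl = pwc_piece_left(prep$term$tstar, changepoints),
       i00 = prep$pairs$type == "00", i01 = prep$pairs$type == "01")
}

pwc_loglik_geom <- function(rates, prep, geom) {
  pr <- pwc_probs_exposure(rates, geom$E_pairs)
  pv <- ifelse(geom$i00, pr$p00, ifelse(geom$i01, pr$p01, pr$p11))
  if (any(pv <= 0)) return(-Inf)
  ll <- sum(prep$pairs$n * log(pv))

  tm <- prep$term
  tp <- pwc_probs_exposure(rates, geom$E_term)
  q02 <- rates["02", geom$jl]; q12 <- rates["12", geom$jl]
  f <- ifelse(tm$h == 0,
              ifelse(tm$delta == 1, tp$p00 * q02 + tp$p01 * q12,
                     tp$p00 + tp$p01),
              ifelse(tm$delta == 1, tp$p11 * q12, tp$p11))
  if (any(f <= 0)) return(-Inf)
  ll + sum(log(f))
}

#' Maximum-likelihood fit of the piecewise-constant model to panel data
#'
#' Maximises the panel likelihood over the log-rates (quasi-Newton with
#' box constraints on the log scale, which enforces positivity). With
#' `constrained = TRUE` the death hazards are proportional,
#' \eqn{\lambda_{12,j} = \lambda_{02,j} e^{\beta}}, and the log hazard
#' ratio \eqn{\beta} is a free parameter reported with its standard error;
#' unconstrained fits leave the three transitions free, which is the
#' default used for AUC estimation.
#'
#' @param panel an [idm_panel()].
#' @param changepoints changepoint times in months.
#' @param constrained logical; proportional death hazards.
#' @param init optional named list with elements `rates` (3-vector of
#'   starting rates, recycled across pieces) and `beta`.
#' @return a [pwc_idm()] with extra elements `loglik`, `converged`,
#'   `covariance` (on the estimation scale), and for constrained fits
#'   `beta` and `se_beta`.
#' @examples
#' pd <- simulate_idm(300, tau = 6, censoring = "admin", seed = 2)
#' fit <- fit_pwc_idm(pd, constrained = TRUE)
#' exp(fit$beta)
#' @export
fit_pwc_idm <- function(panel, changepoints = c(6, 30, 60, 90),
                        constrained = FALSE, init = NULL) {
  prep <- pwc_prepare(panel)
  np <- length(changepoints) + 1L
  crude <- crude_rates(panel)
  pc <- crude_piece_rates(panel, changepoints)
  r0 <- if (!is.null(init$rates)) matrix(rep_len(init$rates, 3), 3, np) else pc
  beta0 <- if (!is.null(init$beta)) init$beta else
    log(max(crude["12"], 1e-6) / max(crude["02"], 1e-6))

  geom <- pwc_geometry(prep, changepoints)
  mk_rates <- function(par) {
    if (constrained) {
      l02 <- exp(par[np + 1:np])
      rbind("01" = exp(par[1:np]), "02" = l02,
            "12" = l02 * exp(par[2 * np + 1]))
    } else {
      rbind("01" = exp(par[1:np]), "02" = exp(par[np + 1:np]),
            "12" = exp(par[2 * np + 1:np]))
    }
  }
  negll <- function(par) {
    ll <- pwc_loglik_geom(mk_rates(par), prep, geom)
    if (!is.finite(ll)) 1e10 else -ll
  }
  par0 <- if (constrained) {
    c(log(pmax(r0[1, ], 1e-6)), log(pmax(r0[2, ], 1e-6)), beta0)
  } else {
    log(pmax(c(r0[1, ], r0[2, ], r0[3, ]), 1e-6))
  }
  lower <- c(rep(log(1e-8), length(par0) - constrained), if (constrained) -10)
  upper <- c(rep(log(5), length(par0) - constrained), if (constrained) 10)
  opt <- optim(par0, negll, method = "L-BFGS-B", lower = lower, upper = upper,
               control = list(maxit = 400, factr = 1e7))
  fit <- pwc_idm(mk_rates(opt$par), changepoints)
  pinned <- opt$par <= lower + 1e-6
  if (any(pinned)) {
    fit$boundary <- which(pinned)
    warning("rate(s) pinned at the lower bound (piece(s) with little ",
            "information): parameter index ",
            paste(which(pinned), collapse = ", "))
  }
  H <- tryCatch(optimHess(opt$par, negll), error = function(e) NULL)
  cov <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL) else NULL
  fit$loglik <- -opt$value
  fit$converged <- opt$convergence == 0
  fit$covariance <- cov
  fit$constrained <- constrained
  if (constrained) {
    fit$beta <- opt$par[2 * np + 1]
    fit$se_beta <- if (!is.null(cov)) sqrt(cov[2 * np + 1, 2 * np + 1]) else NA_real_
  }
  fit
}

# Per-piece crude occurrence/exposure rates (first positive visit taken as
# exact onset); good starting values cut the quasi-Newton iteration count
# substantially.
crude_piece_rates <- function(panel, changepoints) {
  iv <- summarize_intervals(panel)
  bounds <- c(0, changepoints, Inf)
  np <- length(changepoints) + 1L
  diag <- !is.na(iv$R)
  end0 <- ifelse(diag, iv$R, iv$tstar)      # exit time from state 0
  out <- matrix(0, 3, np, dimnames = list(IDM_TRANSITIONS, NULL))
  for (j in seq_len(np)) {
    lo <- bounds[j]; hi <- bounds[j + 1]
    e0 <- sum(pmax(0, pmin(end0, hi) - lo))
    e1 <- sum(pmax(0, pmin(iv$tstar[diag], hi) - pmax(iv$R[diag], lo)))
    inpc <- function(x) x > lo & x <= hi
    out["01", j] <- (sum(diag & inpc(iv$R)) + 0.5) / max(e0, 1)
    out["02", j] <- (sum(!diag & iv$delta == 1 & inpc(iv$tstar)) + 0.5) /
      max(e0, 1)
    out["12", j] <- (sum(diag & iv$delta == 1 & inpc(iv$tstar)) + 0.5) /
      max(e1, 1)
  }
  out
}

# Crude occurrence/exposure rates treating the first positive visit as an
# exact onset time; used to initialise the likelihood optimisers.
crude_rates <- function(panel) {
  iv <- summarize_intervals(panel)
  diag <- !is.na(iv$R)
  exp0 <- sum(ifelse(diag, iv$R, iv$tstar))
  exp1 <- sum(iv$tstar[diag] - iv$R[diag])
  c("01" = (sum(diag) + 0.5) / max(exp0, 1),
    "02" = (sum(iv$delta == 1 & !diag) + 0.5) / max(exp0, 1),
    "12" = (sum(iv$delta == 1 & diag) + 0.5) / max(exp1, 1))
}
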