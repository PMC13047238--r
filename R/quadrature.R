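# Gauss-Legendre nodes/weights on [-1, 1], cached per node count.
# The illness-time integrals are evaluated after the substitution
# z = u^{k01}, which absorbs the u^{k01 - 1} factor of the 0->1 Weibull
# hazard; for shape < 1 the raw integrand is singular at u = 0, while in
# z the integrand is smooth, so a fixed Gauss rule converges fast.
.gl_cache <- new.env(parent = emptyenv())

gl_rule <- function(n) {
  key <- as.character(n)
  rule <- .gl_cache[[key]]
  if (is.null(rule)) {
    rule <- pracma::gaussLegendre(n, -1, 1)
    .gl_cache[[key]] <- rule
  }
  rule
}

# Integrate f over (lo, hi) with an n-node Gauss-Legendre rule.
# f must accept a vector and return a vector.
gl_integrate <- function(f, lo, hi, n = 41L) {
  if (hi <= lo) return(0)
  rule <- gl_rule(n)
  half <- (hi - lo) / 2
  mid <- (hi + lo) / 2
  half * sum(rule$w * f(mid + half * rule$x))
}

# Vectorised version: lo, hi are N-vectors, f(u, idx) returns the integrand
# evaluated at matrix of nodes u (N x n) for subject rows idx. Returns the
# N-vector of integrals. Rows with hi <= lo get 0.
gl_integrate_rows <- function(f, lo, hi, n = 41L) {
  N <- length(lo)
  out <- numeric(N)
  act <- which(hi > lo)
  if (!length(act)) return(out)
  rule <- gl_rule(n)
  half <- (hi[act] - lo[act]) / 2
  mid <- (hi[act] + lo[act]) / 2
  nodes <- outer(mid, rep(1, n)) + outer(half, rule$x)   # |act| x n
  vals <- f(nodes, act)
  out[act] <- half * as.vector(vals %*% rule$w)
  out
}
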