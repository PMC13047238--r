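# Shared fixtures: all test data are generated in code.

truth_model <- function() weibull_idm()   # k = 0.5, rates 0.05/0.05/0.56

# a model with gamma(t) = 1 (equal death hazards with and without disease)
null_gamma_model <- function() {
  weibull_idm(shape = c(0.5, 0.5, 0.5), rate = c(0.05, 0.07, 0.07))
}

# tiny hand-checkable panel: one diagnosed death, one clean censoring,
# one immediate death
tiny_panel <- function() {
  visits <- data.frame(
    id = c(rep("a", 4), rep("b", 3), "c"),
    time = c(0, 3, 6, 9, 0, 3, 6, 0),
    marker = c(0, 0, 1, 1, 0, 0, 0, 0))
  outcomes <- data.frame(id = c("a", "b", "c"),
                         tstar = c(14, 7.2, 1.5),
                         delta = c(1, 0, 1))
  idm_panel(visits, outcomes)
}

# independent quadrature oracle for P01 of a Weibull illness-death model
p01_quad_oracle <- function(model, s, t) {
  a <- model$rate; k <- model$shape
  integrate(function(u) {
    exp(-a[["01"]] * (u^k[["01"]] - s^k[["01"]]) -
          a[["02"]] * (u^k[["02"]] - s^k[["02"]])) *
      a[["01"]] * k[["01"]] * u^(k[["01"]] - 1) *
      exp(-a[["12"]] * (t^k[["12"]] - u^k[["12"]]))
  }, s, t, rel.tol = 1e-11, abs.tol = 1e-12)$value
}
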