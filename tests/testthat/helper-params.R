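# Shared fixtures: parameter draws and random admissible states.

# Worked dosing example: strong immune kill so the eligibility window is
# wide enough to contain r = 0.065.
worked_params <- function() {
  mmc_params(p2 = 5.5e-6, p1 = 0.2)
}

# Random parameter set inside the feasible ranges (point estimates fixed).
random_params <- function() {
  rg <- mmc_param_ranges()
  mmc_params(r  = runif(1, rg$r[1], rg$r[2]),
             k  = runif(1, rg$k[1], rg$k[2]),
             p1 = runif(1, rg$p1[1], rg$p1[2]),
             p2 = runif(1, rg$p2[1], rg$p2[2]),
             p3 = runif(1, rg$p3[1], rg$p3[2]))
}

# Random admissible state on the scales the model visits.
random_state <- function(params = mmc_params()) {
  c(M = runif(1, 0, 2 * params$m / params$mu1 + 1),
    T = 10^runif(1, 0, log10(params$k)),
    E = 10^runif(1, 2, 5))
}

# Central finite-difference Jacobian of mmc_rhs (independent oracle).
fd_jacobian <- function(state, params, h_rel = 1e-6) {
  J <- matrix(0, 3, 3)
  for (j in 1:3) {
    h <- max(abs(state[j]), 1) * h_rel
    up <- state; up[j] <- up[j] + h
    dn <- state; dn[j] <- max(dn[j] - h, 0)
    J[, j] <- (mmc_rhs(up, params) - mmc_rhs(dn, params)) / (up[j] - dn[j])
  }
  dimnames(J) <- list(c("M", "T", "E"), c("M", "T", "E"))
  J
}

# Max-norm rhs residual relative to the state magnitude.
rel_residual <- function(state, params) {
  max(abs(mmc_rhs(state, params))) / max(abs(state), 1)
}
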