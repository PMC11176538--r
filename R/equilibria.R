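#' Immune tumor-kill intensity
#'
#' The net daily tumor-kill intensity of the immune system,
#' `I1 = p2 d0 / mu2`: potential daily kill (production times kill rate)
#' discounted by effector mortality.  The homeostasis equilibrium is
#' locally stable iff the tumor growth rate satisfies `r < I1`.
#'
#' @param params an [mmc_params()] object.
#' @return Intensity \[1/day\].
#' @export
immune_intensity <- function(params) {
  params$p2 * params$d0 / params$mu2
}

#' Chemotherapy tumor-kill intensity
#'
#' The net daily tumor-kill intensity of continuous MMC instillation,
#' `I2 = p1 (m/mu1) / (m/mu1 + a)`: the saturating kill rate evaluated at
#' the residual drug level `m/mu1`.  Bounded above by `p1` for any
#' instillation rate.  The tumor-free equilibrium under treatment is
#' locally stable iff `r < I1 + I2`.
#'
#' @param params an [mmc_params()] object.
#' @return Intensity \[1/day\].
#' @export
chemo_intensity <- function(params) {
  Mstar <- params$m / params$mu1
  params$p1 * Mstar / (Mstar + params$a)
}

new_equilibrium <- function(state, eigenvalues, label) {
  re <- Re(eigenvalues)
  # real parts within rounding of zero count as zero: marginal, not stable
  tol <- 1e-11 * max(1, abs(re))
  structure(list(state = state,
                 eigenvalues = eigenvalues,
                 stable = all(re < -tol),
                 marginal = any(abs(re) <= tol),
                 label = label),
            class = "mmc_equilibrium")
}

#' @export
print.mmc_equilibrium <- function(x, ...) {
  cat(sprintf("%s: M*=%.6g, T*=%.6g, E*=%.6g\n", x$label,
              x$state[["M"]], x$state[["T"]], x$state[["E"]]))
  cat("  eigenvalues:", paste(format(x$eigenvalues, digits = 6),
                              collapse = ", "), "\n")
  cat("  locally stable:", x$stable,
      if (x$marginal) "(marginal: zero real part)" else "", "\n")
  invisible(x)
}

#' Disease-free equilibria and their stability
#'
#' Returns the tumor-free steady state of the regime selected by the
#' instillation rate: without treatment (`m = 0`) the homeostasis
#' equilibrium `EB1 = (0, 0, d0/mu2)`; under treatment (`m > 0`) the
#' tumor-free equilibrium `EB2 = (m/mu1, 0, d0/mu2)`.  Eigenvalues are the
#' closed forms `(-mu1, r - I1, -mu2)` and `(-mu1, r - I1 - I2, -mu2)`
#' respectively, so local stability reduces to `r < I1` (homeostasis) or
#' `r < I1 + I2` (tumor-free under treatment).  A zero eigenvalue at the
#' bifurcation boundary reports `stable = FALSE` with `marginal = TRUE`.
#'
#' @param params an [mmc_params()] object.
#' @return List of `mmc_equilibrium` objects (length 1: the regime's
#'   disease-free point).
#' @export
disease_free_equilibria <- function(params) {
  validate_params(params)
  I1 <- immune_intensity(params)
  Ehom <- params$d0 / params$mu2
  if (params$m == 0) {
    eq <- new_equilibrium(c(M = 0, T = 0, E = Ehom),
                          c(-params$mu1, params$r - I1, -params$mu2),
                          "homeostasis_EB1")
  } else {
    I2 <- chemo_intensity(params)
    eq <- new_equilibrium(c(M = params$m / params$mu1, T = 0, E = Ehom),
                          c(-params$mu1, params$r - I1 - I2, -params$mu2),
                          "tumor_free_EB2")
  }
  list(eq)
}

#' Interior (cancer) equilibria by polynomial root-finding
#'
#' With the drug fixed at its equilibrium level `M* = m/mu1`, the effector
#' nullcline gives `E*(T) = (d0 + gamma c1 T) / (p3 T + mu2)` where
#' `c1 = p1 M*/(M* + a)`, and the tumor nullcline requires
#' `r (1 - T/k) = c1 + p2 E*(T)` for `T > 0`.  Clearing the denominator
#' yields a quadratic in `T`, so at most two interior equilibria exist;
#' real roots in `(0, k]` are returned with numerically computed Jacobian
#' eigenvalues.
#'
#' @param params an [mmc_params()] object.
#' @return List of `mmc_equilibrium` objects labelled `cancer_numeric`
#'   (possibly empty).
#' @export
find_cancer_equilibria <- function(params) {
  validate_params(params)
  p <- params
  Mstar <- p$m / p$mu1
  c1 <- p$p1 * Mstar / (Mstar + p$a)
  # r(1 - T/k)(p3 T + mu2) - c1 (p3 T + mu2) - p2 d0 - p2 gamma c1 T = 0
  A <- -p$r * p$p3 / p$k
  B <- p$r * p$p3 - p$r * p$mu2 / p$k - c1 * p$p3 - p$p2 * p$gamma * c1
  C <- p$r * p$mu2 - c1 * p$mu2 - p$p2 * p$d0
  roots <- polyroot(c(C, B, A))
  Tstars <- Re(roots[abs(Im(roots)) < 1e-8 * pmax(1, abs(roots))])
  Tstars <- sort(unique(Tstars[Tstars > 0 & Tstars <= p$k]))
  lapply(Tstars, function(Ts) {
    Es <- (p$d0 + p$gamma * c1 * Ts) / (p$p3 * Ts + p$mu2)
    st <- c(M = Mstar, T = Ts, E = Es)
    ev <- eigen(mmc_jacobian(st, p), only.values = TRUE)$values
    new_equilibrium(st, ev, "cancer_numeric")
  })
}

#' Full equilibrium and stability report
#'
#' Convenience wrapper combining the disease-free point of the current
#' regime with any interior cancer equilibria, plus the two kill
#' intensities and which stability criterion holds.
#'
#' @param params an [mmc_params()] object.
#' @return List with elements `equilibria` (list of `mmc_equilibrium`),
#'   `I1`, `I2`, and `criterion` (named logical: is `r` below the relevant
#'   stability bound).
#' @export
stability_report <- function(params) {
  eqs <- c(disease_free_equilibria(params), find_cancer_equilibria(params))
  I1 <- immune_intensity(params)
  I2 <- if (params$m > 0) chemo_intensity(params) else 0
  crit <- if (params$m == 0) c(r_below_I1 = params$r < I1)
          else c(r_below_I1_plus_I2 = params$r < I1 + I2)
  list(equilibria = eqs, I1 = I1, I2 = I2, criterion = crit)
}
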