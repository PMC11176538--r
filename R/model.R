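#' Logistic tumor growth term
#'
#' Growth flux `r T (1 - T/k)` of the tumor compartment.
#'
#' @param T tumor cell count (vectorized), `T >= 0`.
#' @param params an [mmc_params()] object.
#' @return Growth rate \[cells/day\].
#' @export
logistic_growth <- function(T, params) {
  if (any(!is.finite(T)) || any(T < 0)) stop("T must be finite and >= 0")
  params$r * T * (1 - T / params$k)
}

# shared precondition for state vectors
check_state <- function(state) {
  state <- unlist(state[c("M", "T", "E")])
  if (length(state) != 3 || any(is.na(state)))
    stop("state must supply named components M, T, E")
  if (any(!is.finite(state)))
    stop("state components must be finite")
  if (any(state < 0))
    stop("state components must be nonnegative")
  state
}

#' Right-hand side of the tumor-immune-chemotherapy system
#'
#' Evaluates the derivative of the three-compartment model: intravesical
#' drug amount `M` \[uM\] with first-order washout and a constant source,
#' tumor cells `T` with logistic growth, a saturating (Michaelis-Menten)
#' drug kill term and mass-action immune kill, and effector cells `E` with
#' constant production, drug-apoptosis-driven activation, tumor-contact
#' deactivation and natural death:
#' \deqn{dM/dt = -\mu_1 M + m}
#' \deqn{dT/dt = -T\,(p_1 M/(M+a) + p_2 E) + r T (1 - T/k)}
#' \deqn{dE/dt = d_0 + \gamma p_1 T M/(M+a) - E\,(p_3 T + \mu_2)}
#'
#' Tumor counts above the carrying capacity are mathematically admissible
#' but outside the model's biological range and trigger a warning.
#'
#' @param state named numeric vector (or list) with components `M`, `T`,
#'   `E`; all nonnegative.
#' @param params an [mmc_params()] object.
#' @return Named numeric vector `c(dM, dT, dE)` in \[uM/day, cells/day,
#'   cells/day\].
#' @examples
#' p <- mmc_params()
#' mmc_rhs(c(M = 0, T = 0, E = 0), p)  # only the source terms survive
#' @export
mmc_rhs <- function(state, params) {
  s <- check_state(state)
  if (s[["T"]] > params$k)
    warning("T exceeds the carrying capacity k; outside the biological range")
  rhs_raw(s, params)
}

# unchecked evaluator: shared by mmc_rhs and the pure-R solver path, where
# the adaptive stepper may probe slightly negative trial states
rhs_raw <- function(s, params) {
  M <- s[["M"]]; T <- s[["T"]]; E <- s[["E"]]
  sat <- params$p1 * M / (M + params$a)
  c(dM = -params$mu1 * M + params$m,
    dT = -T * (sat + params$p2 * E) + params$r * T * (1 - T / params$k),
    dE = params$d0 + params$gamma * sat * T - E * (params$p3 * T + params$mu2))
}

#' Jacobian of the model right-hand side
#'
#' Closed-form 3x3 Jacobian of [mmc_rhs()] with respect to `(M, T, E)`.
#' The drug equation is decoupled, so the first row is
#' `(-mu1, 0, 0)` for every state.
#'
#' @inheritParams mmc_rhs
#' @return 3x3 numeric matrix with rows/columns named `M`, `T`, `E`.
#' @export
mmc_jacobian <- function(state, params) {
  s <- check_state(state)
  M <- s[["M"]]; T <- s[["T"]]; E <- s[["E"]]
  p <- params
  # d/dM of M/(M+a) = a/(M+a)^2, written as 1/(M+a) - M/(M+a)^2
  dsat <- p$p1 / (M + p$a) - p$p1 * M / (M + p$a)^2
  sat <- p$p1 * M / (M + p$a)
  J <- rbind(
    c(-p$mu1, 0, 0),
    c(-dsat * T,
      p$r - 2 * p$r * T / p$k - p$p2 * E - sat,
      -p$p2 * T),
    c(p$gamma * dsat * T,
      -p$p3 * E + p$gamma * sat,
      -p$p3 * T - p$mu2))
  dimnames(J) <- list(c("M", "T", "E"), c("M", "T", "E"))
  J
}
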