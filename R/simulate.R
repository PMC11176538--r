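#' Simulation scenario
#'
#' Bundles the initial condition, treatment switch, horizon and cure
#' threshold of a single model run.
#'
#' @param T0 initial tumor cell count.
#' @param M0 initial intravesical drug amount \[uM\]; default 0 (post-TUR,
#'   drug cleared).
#' @param E0 initial effector count; default `NULL` means the homeostatic
#'   level `d0/mu2` of the parameter set used for the run.
#' @param treated logical; `FALSE` forces `m = 0` (no instillation).
#' @param horizon simulation length \[days\].
#' @param cure_threshold tumor count below which the final state counts as
#'   cure (strict `<`).
#' @return An object of class `mmc_scenario`.
#' @export
mmc_scenario <- function(T0, M0 = 0, E0 = NULL, treated = TRUE,
                         horizon = 400, cure_threshold = 1) {
  if (horizon <= 0) stop("horizon must be > 0")
  if (cure_threshold < 0) stop("cure_threshold must be >= 0")
  if (T0 < 0 || M0 < 0 || (!is.null(E0) && E0 < 0))
    stop("initial conditions must be nonnegative")
  structure(list(T0 = T0, M0 = M0, E0 = E0, treated = isTRUE(treated),
                 horizon = horizon, cure_threshold = cure_threshold),
            class = "mmc_scenario")
}

#' Integrate the model over a scenario
#'
#' Solves the tumor-immune-chemotherapy system with an adaptive
#' Dormand-Prince Runge-Kutta 5(4) scheme (deSolve method `"ode45"`).  The
#' right-hand side is evaluated in compiled code by default; the pure-R
#' [mmc_rhs()] is used when `compiled = FALSE` and the two agree to solver
#' tolerance.
#'
#' @param params an [mmc_params()] object.
#' @param scenario an [mmc_scenario()] object.
#' @param times output times \[days\]; default daily from 0 to the horizon
#'   (always includes the horizon).
#' @param method deSolve integration method.
#' @param rtol,atol relative/absolute solver tolerances; `atol` may be a
#'   length-3 vector for `(M, T, E)`.  The default is component-wise:
#'   tight for the drug (which lives on the 0.1-1 uM scale) and `1e-6`
#'   for the two cell counts.
#' @param hmax maximum internal step \[days\]; the cap keeps the dense
#'   (interpolated) output accurate between widely spaced internal steps.
#' @param maxsteps maximum internal steps between two output times.
#' @param compiled use the compiled right-hand side.
#' @param ... further arguments passed to [deSolve::ode()].
#' @return A data frame of class `mmc_trajectory` with columns
#'   `t`, `M`, `T`, `E`; the parameters, scenario and solver settings are
#'   attached as attributes `params`, `scenario`, `solver`.
#' @examples
#' p <- mmc_params()
#' tr <- integrate_model(p, mmc_scenario(T0 = 5.3e6, horizon = 50))
#' tail(tr)
#' @export
integrate_model <- function(params, scenario, times = NULL,
                            method = "ode45", rtol = 1e-8,
                            atol = c(1e-12, 1e-6, 1e-6),
                            hmax = 1, maxsteps = 5e5, compiled = TRUE,
                            ...) {
  validate_params(params)
  if (!inherits(scenario, "mmc_scenario")) stop("scenario must be an mmc_scenario")
  p <- unclass(params)
  if (!scenario$treated) p$m <- 0
  E0 <- if (is.null(scenario$E0)) p$d0 / p$mu2 else scenario$E0
  y0 <- c(M = scenario$M0, T = scenario$T0, E = E0)
  if (is.null(times)) {
    times <- seq(0, scenario$horizon, by = 1)
    if (times[length(times)] < scenario$horizon)
      times <- c(times, scenario$horizon)
  }
  out <- if (compiled) {
    deSolve::ode(y0, times, func = "mmc_derivs", parms = param_vector(p),
                 dllname = "mmcdose", initfunc = "mmc_initmod",
                 method = method, rtol = rtol, atol = atol, hmax = hmax,
                 maxsteps = maxsteps, ...)
  } else {
    rhs_fn <- function(t, y, pr) list(unname(rhs_raw(y, pr)))
    deSolve::ode(y0, times, rhs_fn, structure(p, class = "mmc_params"),
                 method = method, rtol = rtol, atol = atol, hmax = hmax,
                 maxsteps = maxsteps, ...)
  }
  if (nrow(out) < length(times)) {
    last <- out[nrow(out), ]
    stop(sprintf(paste0("solver failed at t = %.4g ",
                        "(state M=%.4g, T=%.4g, E=%.4g)"),
                 last[["time"]], last[["M"]], last[["T"]], last[["E"]]))
  }
  traj <- data.frame(t = out[, "time"], M = out[, "M"], T = out[, "T"],
                     E = out[, "E"])
  structure(traj,
            params = structure(p, class = "mmc_params"),
            scenario = scenario,
            solver = list(method = method, rtol = rtol, atol = atol,
                          compiled = compiled),
            class = c("mmc_trajectory", "data.frame"))
}

#' Closed-form drug trajectory
#'
#' The drug equation is linear and decoupled, so its solution is
#' `M(t) = m/mu1 + (M0 - m/mu1) exp(-mu1 t)`.  Used as an internal accuracy
#' check on the numerical solver.
#'
#' @param t time(s) \[days\].
#' @param M0 initial drug amount \[uM\].
#' @param params an [mmc_params()] object.
#' @return Drug amount(s) \[uM\].
#' @export
drug_closed_form <- function(t, M0, params) {
  Minf <- params$m / params$mu1
  Minf + (M0 - Minf) * exp(-params$mu1 * t)
}

#' Classify the treatment outcome of a trajectory
#'
#' Cure iff the tumor count at the final time is strictly below the
#' threshold; ties classify as persistence.
#'
#' @param traj an `mmc_trajectory` from [integrate_model()].
#' @param cure_threshold cells; default taken from the trajectory's
#'   scenario.
#' @return `"cure"` or `"persistence"`.
#' @export
classify_outcome <- function(traj, cure_threshold = NULL) {
  if (!inherits(traj, "mmc_trajectory")) stop("traj must be an mmc_trajectory")
  sc <- attr(traj, "scenario")
  if (is.null(cure_threshold)) cure_threshold <- sc$cure_threshold
  if (nrow(traj) < 2 || traj$t[nrow(traj)] < sc$horizon)
    stop("incomplete trajectory: final time precedes the scenario horizon")
  Tend <- traj$T[nrow(traj)]
  if (Tend < cure_threshold) "cure" else "persistence"
}

#' Initial-tumor-size basin boundary by bisection
#'
#' Locates the critical initial tumor count separating trajectories that
#' reach the tumor-free state from those that grow toward carrying
#' capacity, by bisecting `log10(T0)` between a curing and a persisting
#' bracket endpoint.  All settings other than `T0` are held fixed.  The
#' default classification horizon is long (2000 days) so that trajectories
#' inside the basin have time to decay below the cure threshold.
#'
#' @param params an [mmc_params()] object.
#' @param bracket length-2 numeric, `c(low, high)` initial tumor counts;
#'   the low end must cure and the high end persist.
#' @param scenario template [mmc_scenario()]; its `T0` is ignored.
#' @param rel_tol relative width at which bisection stops (default 1%,
#'   enough to resolve thresholds to 3 significant figures).
#' @param ... passed to [integrate_model()].
#' @return The threshold initial tumor count \[cells\], with attribute
#'   `bracket` giving the final bracketing interval.
#' @export
find_initial_size_threshold <- function(params, bracket,
                                        scenario = mmc_scenario(
                                          T0 = 1, horizon = 2000),
                                        rel_tol = 0.01, ...) {
  if (length(bracket) != 2 || any(bracket <= 0) || diff(bracket) <= 0)
    stop("bracket must be an increasing positive pair c(low, high)")
  outcome_at <- function(T0) {
    sc <- scenario
    sc$T0 <- T0
    classify_outcome(integrate_model(params, sc, ...))
  }
  lo <- bracket[1]; hi <- bracket[2]
  o_lo <- outcome_at(lo); o_hi <- outcome_at(hi)
  if (o_lo == o_hi)
    stop("no threshold in bracket: both endpoints classify as ", o_lo)
  if (o_lo != "cure")
    stop("no threshold in bracket: expected cure at the low endpoint")
  while ((hi - lo) / lo > rel_tol) {
    mid <- 10^((log10(lo) + log10(hi)) / 2)
    if (outcome_at(mid) == "cure") lo <- mid else hi <- mid
  }
  structure(sqrt(lo * hi), bracket = c(lo, hi))
}

#' Export a trajectory as CSV
#'
#' Writes the columns `t,M,T,E`.
#'
#' @param traj an `mmc_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj)[, c("t", "M", "T", "E")], path,
                   row.names = FALSE)
  invisible(path)
}
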