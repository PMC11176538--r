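#' Latin hypercube sample of parameter space
#'
#' Stratified uniform sample: each parameter's `n` values occupy `n`
#' distinct equal-probability strata of `[theta * low, theta * high]`
#' around its base value `theta` (default half to twice the base, the
#' standard range for rate-constant uncertainty in this model class).
#'
#' @param n number of samples; must be at least `d + 2` where `d` is the
#'   number of varied parameters (PRCC degrees of freedom).
#' @param base_params an [mmc_params()] object.
#' @param range_factor `c(low, high)` multiplicative range.
#' @param parameters names of parameters to vary (default all 11).
#' @param seed integer seed.
#' @return `n x d` numeric matrix with parameter names as columns.
#' @export
lhs_sample <- function(n, base_params = mmc_params(),
                       range_factor = c(0.5, 2),
                       parameters = .mmc_param_names, seed = NULL) {
  d <- length(parameters)
  if (n < d + 2)
    stop("n must be >= number of varied parameters + 2")
  bad <- setdiff(parameters, .mmc_param_names)
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  U <- lhs::randomLHS(n, d)
  X <- sapply(seq_len(d), function(j) {
    theta <- base_params[[parameters[j]]]
    lo <- theta * range_factor[1]
    lo + U[, j] * theta * (range_factor[2] - range_factor[1])
  })
  colnames(X) <- parameters
  X
}

#' Partial rank correlation coefficients with p-values
#'
#' For each input column, ranks all inputs and the output, removes the
#' linear effect of the other rank-transformed inputs from both the
#' column's ranks and the output's ranks by least squares, and correlates
#' the two residual vectors.  Significance is assessed with the
#' t-statistic `prcc * sqrt(df / (1 - prcc^2))` on
#' `df = n - 2 - (d - 1)` degrees of freedom.
#'
#' @param X `n x d` numeric matrix of inputs (no constant columns).
#' @param y numeric output vector of length `n`.
#' @param alpha significance level; default 0.01.
#' @return Data frame with columns `parameter`, `prcc`, `p_value`,
#'   `significant`, ordered as the columns of `X`.
#' @export
prcc <- function(X, y, alpha = 0.01) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(d))
  const <- apply(X, 2, function(col) diff(range(col)) == 0)
  if (any(const))
    stop("constant column(s): ", paste(colnames(X)[const], collapse = ", "))
  R <- apply(X, 2, rank)
  ry <- rank(y)
  df <- n - 2 - (d - 1)
  if (df < 1) stop("too few samples for ", d, " parameters")
  out <- lapply(seq_len(d), function(j) {
    Z <- cbind(1, R[, -j, drop = FALSE])
    qz <- qr(Z)
    if (qz$rank < ncol(Z)) {
      drop_idx <- qz$pivot[seq_len(ncol(Z))][-seq_len(qz$rank)] - 1
      stop("collinear rank-transformed column(s) among: ",
           paste(colnames(X)[-j][drop_idx], collapse = ", "))
    }
    ex <- qr.resid(qz, R[, j])
    ey <- qr.resid(qz, ry)
    rho <- stats::cor(ex, ey)
    tstat <- rho * sqrt(df / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df)
    data.frame(parameter = colnames(X)[j], prcc = rho, p_value = p)
  })
  res <- do.call(rbind, out)
  res$significant <- res$p_value < alpha
  res
}

#' Global sensitivity of tumor burden to the model parameters
#'
#' Latin hypercube sampling over all model parameters followed by PRCC of
#' the tumor cell count at `output_time` (default day 365, at which point
#' the cumulative continuous dose equals one standard instillation).  The
#' initial effector level is the homeostatic `d0/mu2` of each sampled
#' parameter set; the initial tumor burden defaults to the "medium" tumor
#' of 1e7 cells.
#'
#' @param base_params an [mmc_params()] object (must have `m > 0`; the
#'   analysis is performed under treatment).
#' @param n number of LHS samples; default 1000.
#' @param output_time day at which the tumor count is read; default 365.
#' @param seed integer seed.
#' @param range_factor `c(low, high)` multiplicative sampling range.
#' @param parameters parameter names to vary.
#' @param T0 initial tumor cell count.
#' @param alpha significance level for the PRCC p-values.
#' @param max_fail_frac maximum tolerated fraction of failed integrations.
#' @param ... passed to [integrate_model()].
#' @return The [prcc()] table, with attributes `n_used`, `n_failed` and
#'   `output_time`.
#' @export
run_sensitivity <- function(base_params = mmc_params(), n = 1000,
                            output_time = 365, seed = NULL,
                            range_factor = c(0.5, 2),
                            parameters = .mmc_param_names, T0 = 1e7,
                            alpha = 0.01, max_fail_frac = 0.05, ...) {
  X <- lhs_sample(n, base_params, range_factor, parameters, seed)
  yT <- apply(X, 1, function(row) {
    p <- unclass(base_params)
    p[parameters] <- as.list(row)
    p <- structure(p, class = "mmc_params")
    sc <- mmc_scenario(T0 = T0, horizon = output_time)
    tryCatch(
      utils::tail(integrate_model(p, sc, times = c(0, output_time), ...)$T, 1),
      error = function(e) NA_real_)
  })
  failed <- !is.finite(yT)
  if (mean(failed) > max_fail_frac)
    stop(sum(failed), " of ", n, " integrations failed (> ",
         100 * max_fail_frac, "%)")
  res <- prcc(X[!failed, , drop = FALSE], yT[!failed], alpha)
  attr(res, "n_used") <- sum(!failed)
  attr(res, "n_failed") <- sum(failed)
  attr(res, "output_time") <- output_time
  res
}

#' Full-factorial uncertainty sweep
#'
#' Simulates the model over every combination of the supplied parameter
#' grids (intended for the loosely constrained washout rate `mu1` and
#' half-saturation constant `a`) and reports the tumor count at the
#' scenario horizon.
#'
#' @param base_params an [mmc_params()] object.
#' @param grids named list of numeric grids, e.g.
#'   `list(mu1 = c(10, 21.05, 40), a = c(50, 100, 200))`.
#' @param scenario an [mmc_scenario()]; its horizon is the read-out time.
#' @param ... passed to [integrate_model()].
#' @return Data frame: one column per swept parameter plus `T_out`, one
#'   row per grid point (`prod(lengths(grids))` rows).
#' @export
uncertainty_sweep <- function(base_params = mmc_params(), grids,
                              scenario = mmc_scenario(T0 = 1e7,
                                                      horizon = 365),
                              ...) {
  bad <- setdiff(names(grids), .mmc_param_names)
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  g <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  g$T_out <- apply(g, 1, function(row) {
    p <- unclass(base_params)
    p[names(grids)] <- as.list(row[names(grids)])
    p <- structure(p, class = "mmc_params")
    utils::tail(integrate_model(p, scenario,
                                times = c(0, scenario$horizon), ...)$T, 1)
  })
  g
}
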