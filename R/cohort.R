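#' Sample a virtual-patient cohort
#'
#' Draws hypothetical patients by sampling each ranged parameter uniformly
#' within its feasible range; point-estimate parameters are held at the
#' base values.  The growth rate `r` is left unset (`NA`) — it is
#' determined per patient by the dose-determination algorithm in
#' [run_cohort()], which samples it inside the patient's eligibility
#' window so that `I1 < r` always holds.
#'
#' @param n number of patients, `>= 1`.
#' @param base_params an [mmc_params()] object supplying the fixed
#'   parameters.
#' @param ranges named list of `c(low, high)` sampling ranges (default the
#'   published feasible ranges, minus `r`).  `low == high` pins a
#'   parameter at that value; `low > high` is rejected.
#' @param seed integer seed; the cohort is fully reproducible from
#'   `(seed, n, ranges)`.
#' @return Data frame with column `id` and one column per model parameter
#'   (`r` is `NA`).
#' @export
sample_cohort <- function(n, base_params = mmc_params(),
                          ranges = mmc_param_ranges()[c("k", "p1", "p2",
                                                        "p3")],
                          seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  bad <- names(ranges)[vapply(ranges, function(x)
    length(x) != 2 || x[1] > x[2] || x[1] <= 0, logical(1))]
  if (length(bad))
    stop("invalid sampling range(s): ", paste(bad, collapse = ", "))
  unknown <- setdiff(names(ranges), setdiff(.mmc_param_names, "r"))
  if (length(unknown))
    stop("ranges given for unknown or unsupported parameter(s): ",
         paste(unknown, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  out <- data.frame(id = seq_len(n))
  for (nm in setdiff(.mmc_param_names, "r"))
    out[[nm]] <- if (nm %in% names(ranges))
      stats::runif(n, ranges[[nm]][1], ranges[[nm]][2])
    else rep(base_params[[nm]], n)
  out$r <- NA_real_
  out
}

#' Run the dose-determination algorithm over a cohort
#'
#' For each patient: compute the eligibility window of the growth rate,
#' draw one `r` uniformly inside the open window (so every patient
#' satisfies `I1 < r < ` upper edge), and apply [recommend_dose()].
#' Infeasible doses are carried as `non_responder` classifications, never
#' as errors.
#'
#' @param patients data frame from [sample_cohort()].
#' @param variant formula variant, see [dose_bound()].
#' @param seed integer seed for the per-patient `r` draws.
#' @param max_mg,min_mg,tau,volume_ml,mw passed to [recommend_dose()].
#' @return Data frame: `id`, the model parameters, `r_low`, `r_high`,
#'   `r_sampled`, `bound_rate` \[uM/day\], `bound_mg`, `usable_mg` and
#'   `classification`.
#' @export
run_cohort <- function(patients, variant = c("printed", "rederived"),
                       seed = NULL, max_mg = 40, min_mg = 1, tau = 365,
                       volume_ml = 50, mw = 334) {
  variant <- match.arg(variant)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(patients)
  u <- stats::runif(n)   # one draw per patient, in row order
  rows <- lapply(seq_len(n), function(i) {
    p <- as.list(patients[i, setdiff(.mmc_param_names, "r")])
    p$r <- 1  # placeholder; recommend_dose takes r explicitly
    p <- structure(p[.mmc_param_names], class = "mmc_params")
    w <- eligibility_window(p, variant)
    r_i <- w[["r_low"]] + u[i] * (w[["r_high"]] - w[["r_low"]])
    rec <- recommend_dose(p, r = r_i, variant = variant, max_mg = max_mg,
                          min_mg = min_mg, tau = tau,
                          volume_ml = volume_ml, mw = mw)
    data.frame(id = patients$id[i], r_low = w[["r_low"]],
               r_high = w[["r_high"]], r_sampled = r_i,
               bound_rate = rec$bound_rate, bound_mg = rec$bound_mg,
               usable_mg = rec$usable_mg,
               classification = rec$classification)
  })
  res <- do.call(rbind, rows)
  cbind(patients[setdiff(names(patients), "r")],
        res[setdiff(names(res), "id")])
}

#' Sample and run a cohort with one seed
#'
#' Convenience wrapper chaining [sample_cohort()] and [run_cohort()] under
#' a single seeded generator, mirroring the published 2,000-patient
#' virtual experiment.
#'
#' @inheritParams sample_cohort
#' @inheritParams run_cohort
#' @return The [run_cohort()] result table.
#' @export
cohort_experiment <- function(n, base_params = mmc_params(), seed = 1,
                              variant = c("printed", "rederived"), ...) {
  variant <- match.arg(variant)
  set.seed(seed)
  patients <- sample_cohort(n, base_params, seed = NULL)
  run_cohort(patients, variant = variant, seed = NULL, ...)
}
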