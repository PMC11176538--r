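#' Eligibility window for the tumor growth rate
#'
#' The dose-determination algorithm applies to patients whose tumor growth
#' rate lies strictly between the immune kill intensity and the maximum
#' combined kill intensity.  Two algebraic variants are provided:
#'
#' * `"printed"` (default): window `(I1, I1 + p1/mu1)`, the form the dose
#'   formula below is published with; its width is always `p1/mu1`.
#' * `"rederived"`: window `(I1, I1 + p1)`, obtained by letting the
#'   instillation rate grow without bound in the stability criterion
#'   `r < I1 + I2(m)` (the chemo intensity saturates at `p1`); width `p1`.
#'
#' @param params an [mmc_params()] object.
#' @param variant `"printed"` or `"rederived"`.
#' @return Numeric `c(r_low, r_high)` \[1/day\].
#' @export
eligibility_window <- function(params, variant = c("printed", "rederived")) {
  variant <- match.arg(variant)
  I1 <- immune_intensity(params)
  width <- switch(variant,
                  printed = params$p1 / params$mu1,
                  rederived = params$p1)
  c(r_low = I1, r_high = I1 + width)
}

#' Instillation-rate bound from the stability criterion
#'
#' Solves the tumor-free stability criterion for the instillation rate `m`
#' at a given patient growth rate `r`:
#' `bound = mu1 a (I1 - r) / (r - I1 - w)` with `w = p1/mu1` (printed
#' variant) or `w = p1` (rederived variant).  For `r` strictly inside the
#' eligibility window both numerator and denominator are negative, so the
#' bound is positive.  The printed variant is published as an upper bound
#' on `m`; the rederived variant is the exact boundary of the stability
#' criterion `r < I1 + I2(m)`, which is crossed from below as `m`
#' increases, so stability holds for `m` *above* the rederived value
#' (`I1 + I2(m*) = r` exactly at the bound).
#'
#' @param params an [mmc_params()] object (its own `r` is ignored).
#' @param r patient tumor growth rate \[1/day\].
#' @param variant `"printed"` or `"rederived"`.
#' @return Instillation-rate bound \[uM/day\].
#' @export
dose_bound <- function(params, r, variant = c("printed", "rederived")) {
  variant <- match.arg(variant)
  w <- eligibility_window(params, variant)
  if (r <= w[["r_low"]])
    stop("not eligible: r <= I1 (immune system alone already suffices ",
         "or tumor outgrows any dose window) [lower edge]")
  if (r >= w[["r_high"]])
    stop("not eligible: r >= I1 + window width (no finite dose satisfies ",
         "the stability criterion) [upper edge]")
  I1 <- w[["r_low"]]
  width <- w[["r_high"]] - I1
  params$mu1 * params$a * (I1 - r) / (r - I1 - width)
}

#' Personalized dose recommendation
#'
#' The dose-determination algorithm: check the eligibility window for the
#' patient's growth rate; if inside, compute the instillation-rate bound,
#' convert it to mg per course via the same tau/volume/molecular-weight
#' chain as [rate_to_course_mg()], and classify:
#'
#' * `non_responder` — `r` outside the window, or the computed dose is
#'   below `min_mg` (insignificantly small);
#' * `over_toxicity_capped` — the computed dose exceeds `max_mg`; the
#'   recommended maximum is reported as the usable dose (the recommended
#'   range then lies inside the curative range);
#' * `eligible` — the computed dose lies in `[min_mg, max_mg]`.
#'
#' @param params an [mmc_params()] object.
#' @param r patient tumor growth rate \[1/day\]; defaults to `params$r`.
#' @param variant formula variant, see [dose_bound()].
#' @param max_mg recommended maximum course dose \[mg\]; default 40 (the
#'   standard single-instillation protocol).
#' @param min_mg smallest clinically meaningful course dose \[mg\].
#' @param tau course length \[days\].
#' @param volume_ml carrier volume \[ml\].
#' @param mw molecular weight \[g/mol\].
#' @return An object of class `mmc_dose_recommendation`: list with
#'   `r_window`, `eligible`, `bound_rate` \[uM/day\], `bound_mg`,
#'   `usable_mg`, `capped`, `classification`, `variant`.
#' @examples
#' p <- mmc_params(p2 = 5.5e-6)
#' recommend_dose(p, r = 0.065)
#' @export
recommend_dose <- function(params, r = params$r,
                           variant = c("printed", "rederived"),
                           max_mg = 40, min_mg = 1, tau = 365,
                           volume_ml = 50, mw = 334) {
  variant <- match.arg(variant)
  validate_params(params)
  w <- eligibility_window(params, variant)
  res <- list(r_window = w, r = r, eligible = FALSE, bound_rate = NA_real_,
              bound_mg = NA_real_, usable_mg = NA_real_, capped = FALSE,
              classification = "non_responder", variant = variant)
  inside <- r > w[["r_low"]] && r < w[["r_high"]]
  if (inside) {
    bound_rate <- dose_bound(params, r, variant)
    bound_mg <- rate_to_course_mg(bound_rate, tau, volume_ml, mw)
    res$bound_rate <- bound_rate
    res$bound_mg <- bound_mg
    if (bound_mg > max_mg) {
      res$capped <- TRUE
      res$usable_mg <- max_mg
      res$eligible <- TRUE
      res$classification <- "over_toxicity_capped"
    } else if (bound_mg < min_mg) {
      res$classification <- "non_responder"
    } else {
      res$usable_mg <- bound_mg
      res$eligible <- TRUE
      res$classification <- "eligible"
    }
  }
  structure(res, class = "mmc_dose_recommendation")
}

#' @export
print.mmc_dose_recommendation <- function(x, ...) {
  cat(sprintf("Dose recommendation (%s variant)\n", x$variant))
  cat(sprintf("  r = %.6g; eligibility window (%.6g, %.6g) [1/day]\n",
              x$r, x$r_window[["r_low"]], x$r_window[["r_high"]]))
  cat(sprintf("  classification: %s\n", x$classification))
  if (is.finite(x$bound_rate))
    cat(sprintf("  bound: %.6g uM/day = %.6g mg/course%s\n", x$bound_rate,
                x$bound_mg,
                if (x$capped) sprintf(" (capped to %.6g mg)", x$usable_mg)
                else ""))
  invisible(x)
}
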