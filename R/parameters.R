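#' @useDynLib mmcdose
#' @importFrom stats setNames
NULL

# Canonical parameter order; must match src/mmc_model.c.
.mmc_param_names <- c("mu1", "m", "r", "k", "p1", "a", "p2", "d0",
                      "gamma", "mu2", "p3")

#' Model parameters for the MMC tumor-immune system
#'
#' Constructs the 11 rate constants of the three-compartment model of
#' non-muscle-invasive bladder cancer under continuous mitomycin-C (MMC)
#' instillation.  Defaults are the published point estimates; parameters
#' reported only as biologically feasible ranges default to the range
#' midpoint (see [mmc_param_ranges()]).
#'
#' @param mu1 MMC washout (decay) rate \[1/day\].
#' @param m MMC instillation rate \[uM/day\]; `m = 0` encodes no treatment.
#' @param r tumor proliferation rate \[1/day\].
#' @param k tumor carrying capacity \[cells\].
#' @param p1 tumor inhibition rate by MMC \[1/day\].
#' @param a half-saturation constant of the drug kill term \[uM\].
#' @param p2 tumor kill rate by effector cells \[1/(cells day)\].
#' @param d0 constant effector production rate \[cells/day\].
#' @param gamma effector activation rate by drug-induced tumor apoptosis
#'   (dimensionless multiplier of the drug kill flux, carried numerically as
#'   published).
#' @param mu2 effector death rate \[1/day\].
#' @param p3 effector deactivation rate by tumor contact \[1/(cells day)\].
#'
#' @return An object of class `mmc_params`: a named list of the 11 values.
#'   All parameters must be strictly positive except `m`, which may be zero.
#'
#' @examples
#' p <- mmc_params()            # published defaults
#' p2 <- mmc_params(r = 0.03)   # override a single rate
#' @export
mmc_params <- function(mu1 = 21.05, m = 6.561, r = 0.0275, k = 5.45e8,
                       p1 = 0.16, a = 100, p2 = 4.6e-6, d0 = 1.032e5,
                       gamma = 9.12, mu2 = 9.12, p3 = 1.345e-6) {
  p <- list(mu1 = mu1, m = m, r = r, k = k, p1 = p1, a = a, p2 = p2,
            d0 = d0, gamma = gamma, mu2 = mu2, p3 = p3)
  validate_params(p)
  structure(p, class = "mmc_params")
}

#' Published feasible ranges for the ranged parameters
#'
#' Five parameters are reported as biologically feasible ranges rather than
#' point estimates; these ranges drive cohort sampling and fixture
#' generation.
#'
#' @return Named list of length-2 numeric vectors `c(low, high)` for
#'   `r`, `k`, `p1`, `p2` and `p3`.
#' @export
mmc_param_ranges <- function() {
  list(r  = c(0.01, 0.045),
       k  = c(0.09e9, 1e9),
       p1 = c(0.12, 0.2),
       p2 = c(3.7e-6, 5.5e-6),
       p3 = c(1.1e-6, 1.59e-6))
}

#' Validate a parameter set
#'
#' Checks completeness, finiteness and positivity (strict for all parameters
#' except the instillation rate `m`, which may be zero).
#'
#' @param params a list or `mmc_params` object.
#' @return The validated parameter list, invisibly.
#' @export
validate_params <- function(params) {
  missing <- setdiff(.mmc_param_names, names(params))
  if (length(missing))
    stop("missing parameters: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(params), .mmc_param_names)
  if (length(extra))
    stop("unknown parameters: ", paste(extra, collapse = ", "))
  v <- unlist(params[.mmc_param_names])
  if (!all(is.finite(v)))
    stop("non-finite parameter value(s): ",
         paste(.mmc_param_names[!is.finite(v)], collapse = ", "))
  strict <- setdiff(.mmc_param_names, "m")
  bad <- strict[unlist(params[strict]) <= 0]
  if (length(bad))
    stop("parameters must be strictly positive: ",
         paste(bad, collapse = ", "))
  if (params$m < 0) stop("instillation rate m must be >= 0")
  invisible(params)
}

# Parameter list -> numeric vector in canonical order (for the compiled RHS).
param_vector <- function(params) {
  unlist(params[.mmc_param_names])
}

#' @export
print.mmc_params <- function(x, ...) {
  cat("MMC tumor-immune model parameters\n")
  units <- c(mu1 = "1/day", m = "uM/day", r = "1/day", k = "cells",
             p1 = "1/day", a = "uM", p2 = "1/(cells day)", d0 = "cells/day",
             gamma = "-", mu2 = "1/day", p3 = "1/(cells day)")
  for (nm in .mmc_param_names)
    cat(sprintf("  %-5s = %-12.6g [%s]\n", nm, x[[nm]], units[[nm]]))
  invisible(x)
}

#' Read a parameter set from YAML or JSON
#'
#' Missing parameters are filled with the package defaults; unknown keys are
#' rejected.
#'
#' @param path file path; format inferred from the extension
#'   (`.yaml`/`.yml` or `.json`).
#' @param base parameter set supplying defaults for keys absent from the
#'   file.
#' @return An `mmc_params` object.
#' @export
read_params <- function(path, base = mmc_params()) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                yaml = ,
                yml  = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("unsupported parameter file extension: .", ext))
  if (is.null(raw)) raw <- list()
  extra <- setdiff(names(raw), .mmc_param_names)
  if (length(extra))
    stop("unknown parameter key(s) in ", path, ": ",
         paste(extra, collapse = ", "))
  p <- unclass(base)
  p[names(raw)] <- lapply(raw, as.numeric)
  validate_params(p)
  structure(p, class = "mmc_params")
}

#' Write a parameter set to YAML or JSON
#'
#' @param params an `mmc_params` object (or compatible list).
#' @param path output path; format inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  validate_params(params)
  x <- lapply(unclass(params)[.mmc_param_names], as.numeric)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         yaml = ,
         yml  = yaml::write_yaml(x, path),
         json = jsonlite::write_json(x, path, auto_unbox = TRUE,
                                     digits = NA),
         stop("unsupported parameter file extension: .", ext))
  invisible(path)
}
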