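#' Load a run configuration
#'
#' Reads a YAML or JSON configuration holding model parameters (flat keys
#' or under a `parameters` block) and optional `scenario`, `cohort`,
#' `sensitivity`, `seed` and `outdir` blocks.  Missing parameters are
#' filled with the package defaults; unknown keys are rejected with a
#' message listing them.
#'
#' @param path configuration file.
#' @param base parameter set supplying defaults.
#' @return List with elements `params` (an `mmc_params`), `scenario`,
#'   `cohort`, `sensitivity` (lists or `NULL`), `seed`, `outdir`.
#' @export
load_config <- function(path, base = mmc_params()) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                yaml = ,
                yml  = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("unsupported config extension: .", ext))
  if (is.null(raw)) raw <- list()
  blocks <- c("parameters", "scenario", "cohort", "sensitivity", "seed",
              "outdir")
  known <- c(.mmc_param_names, blocks)
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  overrides <- raw[intersect(names(raw), .mmc_param_names)]
  if (!is.null(raw$parameters)) {
    bad <- setdiff(names(raw$parameters), .mmc_param_names)
    if (length(bad))
      stop("unknown parameter key(s): ", paste(bad, collapse = ", "))
    overrides <- utils::modifyList(raw$parameters, overrides)
  }
  p <- unclass(base)
  p[names(overrides)] <- lapply(overrides, as.numeric)
  validate_params(p)
  list(params = structure(p, class = "mmc_params"),
       scenario = raw$scenario, cohort = raw$cohort,
       sensitivity = raw$sensitivity,
       seed = if (is.null(raw$seed)) NULL else as.integer(raw$seed),
       outdir = raw$outdir)
}

#' Generate deterministic parameter-set fixtures
#'
#' Writes `n` parameter sets drawn uniformly within the feasible ranges,
#' one deliberately stable tumor-free configuration (growth rate below
#' `I1 + I2`), one deliberately unstable configuration (growth rate above
#' it, still inside the feasible `r` range), and a small cohort CSV.
#' Byte-identical output for a given seed.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param n number of random parameter sets.
#' @return Character vector of the files written, invisibly.
#' @export
generate_fixtures <- function(dir, seed = 1, n = 3) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  ranges <- mmc_param_ranges()
  files <- character(0)
  for (i in seq_len(n)) {
    p <- unclass(mmc_params())
    for (nm in names(ranges))
      p[[nm]] <- stats::runif(1, ranges[[nm]][1], ranges[[nm]][2])
    f <- file.path(dir, sprintf("params_%02d.yaml", i))
    write_params(structure(p, class = "mmc_params"), f)
    files <- c(files, f)
  }
  # stable: strong immune kill, slow tumor -> r < I1 + I2 by construction
  stable <- mmc_params(p2 = 5.5e-6, r = 0.01)
  stopifnot(stable$r < immune_intensity(stable) + chemo_intensity(stable))
  f <- file.path(dir, "params_stable_eb2.yaml")
  write_params(stable, f); files <- c(files, f)
  # unstable: weak immune kill, fast tumor -> r > I1 + I2, r still feasible
  unstable <- mmc_params(p2 = 3.7e-6, r = 0.045)
  stopifnot(unstable$r > immune_intensity(unstable) +
              chemo_intensity(unstable))
  f <- file.path(dir, "params_unstable_eb2.yaml")
  write_params(unstable, f); files <- c(files, f)
  cohort <- cohort_experiment(10, seed = seed)
  f <- file.path(dir, "cohort_small.csv")
  utils::write.csv(cohort, f, row.names = FALSE); files <- c(files, f)
  invisible(files)
}
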