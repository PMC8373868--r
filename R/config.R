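#' Load a run configuration
#'
#' Reads a key-value configuration file (YAML or JSON, chosen by file
#' extension) and merges it over the shipped defaults. Recognized top-level
#' keys: `params` (named overrides of [model_params()] fields),
#' `inflammation` (`mode`, `ihd`, `ild`, `start_state`), `n_patients`,
#' `master_seed`, `record_trajectories`, `output_dir`, and `morris`
#' (`r`, `levels`, `n_patients_per_eval`, `output`). Unknown keys anywhere
#' are rejected by name; every override is validated against the parameter
#' invariants. `load -> dump -> load` is the identity.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return an object of class `run_config`: list with `params`
#'   (`model_params`), `scheme` (`inflammation_scheme`), `n_patients`,
#'   `master_seed`, `record_trajectories`, `output_dir`, `morris`.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("n_patients: 10", f)
#' load_config(f)$n_patients
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format '.", ext, "' (use .yaml/.yml/.json)",
         call. = FALSE)
  )
  if (is.null(raw)) raw <- list()
  known <- c("params", "inflammation", "n_patients", "master_seed",
             "record_trajectories", "output_dir", "morris")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  pars <- do.call(model_params, as.list(raw$params))
  infl <- raw$inflammation
  if (!is.null(infl)) {
    iknown <- c("mode", "ihd", "ild", "start_state")
    iunknown <- setdiff(names(infl), iknown)
    if (length(iunknown)) {
      stop("unknown inflammation key(s): ", paste(iunknown, collapse = ", "),
           call. = FALSE)
    }
  }
  scheme <- inflammation_scheme(
    mode = infl$mode %||% "CYCLING",
    ihd = infl$ihd %||% pars$IHD,
    ild = infl$ild %||% pars$ILD,
    start_state = infl$start_state %||% "LOW"
  )
  mor <- raw$morris
  if (!is.null(mor)) {
    mknown <- c("r", "levels", "n_patients_per_eval", "output")
    munknown <- setdiff(names(mor), mknown)
    if (length(munknown)) {
      stop("unknown morris key(s): ", paste(munknown, collapse = ", "),
           call. = FALSE)
    }
  }
  cfg <- list(
    params = pars,
    scheme = scheme,
    n_patients = as.integer(raw$n_patients %||% 100L),
    master_seed = as.integer(raw$master_seed %||% 1L),
    record_trajectories = isTRUE(raw$record_trajectories),
    output_dir = raw$output_dir %||% ".",
    morris = list(
      r = as.integer(mor$r %||% 30L),
      levels = as.integer(mor$levels %||% 4L),
      n_patients_per_eval = as.integer(mor$n_patients_per_eval %||% 100L),
      output = mor$output %||% "rmst"
    )
  )
  if (cfg$n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dump a run configuration
#'
#' Serializes a `run_config` back to YAML or JSON such that re-loading it
#' reproduces the configuration exactly.
#'
#' @param cfg a `run_config`.
#' @param path destination `.yaml`/`.yml` or `.json` path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  raw <- list(
    params = unclass(cfg$params),
    inflammation = list(mode = cfg$scheme$mode, ihd = cfg$scheme$ihd,
                        ild = cfg$scheme$ild,
                        start_state = cfg$scheme$start_state),
    n_patients = cfg$n_patients,
    master_seed = cfg$master_seed,
    record_trajectories = cfg$record_trajectories,
    output_dir = cfg$output_dir,
    morris = cfg$morris
  )
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = , yml = yaml::write_yaml(raw, path),
    json = jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    stop("unsupported config format '.", ext, "'", call. = FALSE)
  )
  invisible(path)
}

#' Write simulation outputs to disk
#'
#' Serializes a result object to CSV in `dir`, plus a JSON run manifest
#' (effective parameters, scheme, master seed, package version) that
#' suffices to re-run the computation exactly. Cohorts write
#' `cohort.csv` (+ per-patient `trajectory_<id>.csv` if recorded), KM curves
#' write `km.csv`, Morris results write `sensitivity.csv`.
#'
#' @param result a `cohort_result`, `km_curve`, or `morris_result`.
#' @param dir output directory (created if missing).
#' @return character vector of files written, invisibly.
#' @export
write_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  wr <- function(df, name) {
    f <- file.path(dir, name)
    readr::write_csv(df, f)
    written <<- c(written, f)
  }
  if (inherits(result, "cohort_result")) {
    wr(result$patients, "cohort.csv")
    if (!is.null(result$trajectories)) {
      for (i in seq_along(result$trajectories)) {
        tr <- result$trajectories[[i]]
        if (!is.null(tr)) wr(tr, sprintf("trajectory_%04d.csv", i))
      }
    }
    manifest <- list(
      kind = "cohort",
      package_version = as.character(utils::packageVersion("invasim")),
      master_seed = result$master_seed,
      n_patients = nrow(result$patients),
      inflammation = list(mode = result$scheme$mode, ihd = result$scheme$ihd,
                          ild = result$scheme$ild,
                          start_state = result$scheme$start_state),
      params = unclass(result$params)
    )
    mf <- file.path(dir, "manifest.json")
    jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <- c(written, mf)
  } else if (inherits(result, "km_curve")) {
    wr(tidy.km_curve(result), "km.csv")
  } else if (inherits(result, "morris_result")) {
    out <- tidy.morris_result(result)
    out$r <- attr(result, "r") %||% NA_integer_
    out$n_patients_per_eval <- attr(result, "n_patients_per_eval") %||%
      NA_integer_
    wr(out, "sensitivity.csv")
  } else {
    stop("no writer for objects of class ",
         paste(class(result), collapse = "/"), call. = FALSE)
  }
  invisible(written)
}

#' Re-run a cohort from its manifest
#'
#' Reads a `manifest.json` written by [write_outputs()] and reproduces the
#' cohort simulation it records.
#'
#' @param path path to a manifest file.
#' @return a `cohort_result`.
#' @export
rerun_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(m$kind, "cohort")) {
    stop("manifest does not describe a cohort run", call. = FALSE)
  }
  pars <- do.call(model_params, as.list(m$params))
  scheme <- inflammation_scheme(m$inflammation$mode, m$inflammation$ihd,
                                m$inflammation$ild,
                                m$inflammation$start_state)
  simulate_cohort(pars, scheme, n_patients = m$n_patients,
                  master_seed = m$master_seed)
}

#' Named deterministic test fixtures
#'
#' Small hand-checkable scenarios regenerated from code:
#' \describe{
#'   \item{`km-worked-example`}{the five-subject survival dataset with times
#'     (2, 3, 3, 5, 7) and events (T, T, T, F, T); `S(3) = 0.4`, restricted
#'     mean on `[0, 7]` = 4.4.}
#'   \item{`mutation-off`}{a tiny cohort with `mut_increment = 0`: mutation
#'     is impossible, so every patient is censored.}
#'   \item{`forced-progression`}{a `tumor_state` seeded with 60% mutant
#'     cells: progression holds at cycle 0.}
#' }
#'
#' @param name fixture name.
#' @param seed integer seed (fixtures are byte-identical per name + seed).
#' @return the fixture object (`surv_data`, `cohort_result` or
#'   `tumor_state`).
#' @examples
#' generate_fixture("km-worked-example")
#' @export
generate_fixture <- function(name, seed = 1L) {
  fixtures <- c("km-worked-example", "mutation-off", "forced-progression")
  if (!name %in% fixtures) {
    stop("unknown fixture '", name, "'; available: ",
         paste(fixtures, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  switch(name,
    "km-worked-example" = surv_data(c(2, 3, 3, 5, 7),
                                    c(TRUE, TRUE, TRUE, FALSE, TRUE)),
    "mutation-off" = simulate_cohort(
      model_params(mut_increment = 0, warmup_cycles = 20L, max_cycles = 50L,
                   N_0 = 10L),
      inflammation_scheme(), n_patients = 5L, master_seed = seed),
    "forced-progression" = tumor_state(
      tumor_cells(10, delta_P = rep(c(TRUE, FALSE), c(6, 4))),
      immune = immune_state(N_NK = 50), scheme = inflammation_scheme())
  )
}
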