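#' Read and write pipeline artifacts as CSV
#'
#' All artifacts are plain UTF-8, dot-decimal, euro-sign-free CSV so they
#' are locale-safe and diff-able. Kaplan-Meier curves are written one
#' file per (arm, endpoint) with header `time_months,survival`; the life
#' table uses `age,annual_death_prob`; transition schedules use
#' `arm,cycle,p_sp,p_sd,p_pd`; cohort traces use
#' `cycle,stable,progressive,dead,disc_cost,disc_ly,disc_qaly`.
#'
#' @param curves Long KM-curve tibble (see [generate_km_curves()]).
#' @param dir Output directory (created if absent).
#' @return `write_km_curves()`: invisibly, the written file paths.
#' @name pipeline_io
#' @export
write_km_curves <- function(curves, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  combos <- dplyr::distinct(curves, .data$arm, .data$endpoint)
  paths <- purrr::pmap_chr(combos, function(arm, endpoint) {
    path <- file.path(dir, paste0("km_", arm, "_", endpoint, ".csv"))
    sub <- dplyr::filter(curves, .data$arm == !!arm,
                         .data$endpoint == !!endpoint)
    utils::write.csv(sub[, c("time_months", "survival")], path,
                     row.names = FALSE, quote = FALSE)
    path
  })
  invisible(paths)
}

#' @rdname pipeline_io
#' @param paths Files named `km_<arm>_<endpoint>.csv`.
#' @export
read_km_curves <- function(paths) {
  purrr::map_dfr(paths, function(path) {
    meta <- strsplit(sub("\\.csv$", "", basename(path)), "_")[[1]]
    if (length(meta) != 3 || meta[1] != "km") {
      stop("KM file names must follow km_<arm>_<endpoint>.csv: ",
           basename(path), call. = FALSE)
    }
    d <- utils::read.csv(path)
    stopifnot(all(c("time_months", "survival") %in% names(d)))
    tibble::tibble(arm = meta[2], endpoint = meta[3],
                   time_months = d$time_months, survival = d$survival)
  })
}

#' @rdname pipeline_io
#' @param life_table Life-table tibble.
#' @param path Output file.
#' @export
write_life_table <- function(life_table, path) {
  utils::write.csv(life_table[, c("age", "annual_death_prob")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_life_table <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("age", "annual_death_prob") %in% names(d)))
  if (is.unsorted(d$age, strictly = TRUE)) {
    stop("life-table ages must be strictly increasing", call. = FALSE)
  }
  if (any(d$annual_death_prob < 0 | d$annual_death_prob > 1)) {
    stop("annual_death_prob must lie in [0, 1]", call. = FALSE)
  }
  tibble::as_tibble(d)
}

#' @rdname pipeline_io
#' @param schedule A [build_schedule()] tibble.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(schedule[, c("arm", "cycle", "p_sp", "p_sd", "p_pd")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @param trace A [run_cohort()] trace.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(
    trace[, c("cycle", "stable", "progressive", "dead", "disc_cost",
              "disc_ly", "disc_qaly")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @param ranking A fit-ranking tibble (from [fit_trial_curves()] or
#'   [select_survival_model()]).
#' @export
write_fit_report <- function(ranking, path) {
  utils::write.csv(ranking, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run manifest for reproducibility
#'
#' Records the configuration hash, input files with checksums, seed and
#' package version; identical manifests imply identical numeric outputs.
#'
#' @param config A `mirvcea_config`.
#' @param input_paths Character vector of input file paths.
#' @param seed Integer seed used for the run.
#' @return A tibble with one row per manifest field.
#' @export
run_manifest <- function(config, input_paths = character(0), seed = NA) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp, version = 2)
  cfg_hash <- unname(tools::md5sum(tmp))
  files <- if (length(input_paths)) {
    paste0(basename(input_paths), ":", unname(tools::md5sum(input_paths)),
           collapse = ";")
  } else ""
  tibble::tibble(
    field = c("config_md5", "inputs", "seed", "package_version",
              "timestamp"),
    value = c(cfg_hash, files, as.character(seed),
              as.character(utils::packageVersion("mirvcea")),
              format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  )
}
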