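#' Load a scenario from a YAML file
#'
#' The file holds any subset of the scenario fields (nested as in the builder
#' defaults) plus a mandatory `geometry$type`; defaults fill the rest and
#' unknown keys are rejected with a named error.
#'
#' @param path YAML file path.
#' @return A validated scenario.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("no such scenario file: ", path)
  raw <- yaml::read_yaml(path)
  do.call(new_scenario, raw)
}

#' Save a scenario to YAML
#'
#' Round-trips with [load_scenario()]: `load_scenario(save_scenario(x, f))`
#' reproduces `x`.
#'
#' @param spec a scenario.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_scenario <- function(spec, path) {
  spec <- validate_scenario(spec)
  x <- unclass(spec)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

TRAJ_SCHEMA <- c("time_s", "cell_id", "x_um", "y_um", "heading_rad",
                 "occupancy", "occupancy_avg", "event")
TRAJ_VERSION <- "sggsim-trajectories v1"

#' Write a trajectory table to CSV
#'
#' Deterministic byte-wise output: a fixed schema-version comment line, then
#' the column header, then rows with floats at 6 significant digits.
#'
#' @param traj trajectory tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(traj, path) {
  if (!all(TRAJ_SCHEMA %in% names(traj)))
    stop("trajectory table is missing columns: ",
         paste(setdiff(TRAJ_SCHEMA, names(traj)), collapse = ", "))
  traj <- traj[TRAJ_SCHEMA]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste0("# ", TRAJ_VERSION),
               paste(TRAJ_SCHEMA, collapse = ",")), con)
  if (nrow(traj) > 0) {
    fmt <- function(v) if (is.numeric(v)) formatC(v, digits = 6, format = "g")
                       else as.character(v)
    cols <- lapply(traj, fmt)
    writeLines(do.call(paste, c(cols, sep = ",")), con)
  }
  invisible(path)
}

#' Read a trajectory table from CSV
#'
#' Rejects files whose schema-version line or column set does not match the
#' writer's (extra or missing columns are errors, not warnings).
#'
#' @param path file written by [write_trajectories()].
#' @return Trajectory tibble.
#' @export
read_trajectories <- function(path) {
  header <- readLines(path, n = 2)
  if (length(header) < 2 || header[1] != paste0("# ", TRAJ_VERSION))
    stop("not a ", TRAJ_VERSION, " file: ", path)
  cols <- strsplit(header[2], ",")[[1]]
  if (!identical(cols, TRAJ_SCHEMA))
    stop("trajectory schema mismatch: expected columns ",
         paste(TRAJ_SCHEMA, collapse = ","), " but found ",
         paste(cols, collapse = ","))
  df <- utils::read.csv(path, skip = 1, colClasses = c(
    time_s = "numeric", cell_id = "integer", x_um = "numeric",
    y_um = "numeric", heading_rad = "numeric", occupancy = "numeric",
    occupancy_avg = "numeric", event = "character"))
  tibble::as_tibble(df)
}

#' Export a field snapshot as a plain CSV matrix
#'
#' One row per lattice row, bottom row first; metadata (time, spacing, units)
#' goes in comment lines so the numeric block loads anywhere.
#'
#' @param conc concentration matrix (or an [attractant_field]).
#' @param path output file path.
#' @param time snapshot time, s.
#' @param dx grid spacing, um (taken from the field when one is given).
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(conc, path, time = NA, dx = NULL) {
  if (inherits(conc, "attractant_field")) {
    dx <- conc$dx
    conc <- conc$conc
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("# sggsim-field v1 units=nM",
               paste0("# time_s=", time, " dx_um=", dx)), con)
  utils::write.table(formatC(conc, digits = 6, format = "g"), con,
                     sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' A JSON record of a finished run: the fully resolved scenario (defaults
#' included), package version, seed, wall-clock times, and an inventory of
#' the output files with md5 checksums. Re-running the embedded scenario with
#' [run_scenario()] reproduces the trajectories bit-identically.
#'
#' @param result an `sgg_result`.
#' @param path manifest path (JSON).
#' @param files character vector of output files to inventory.
#' @param started,finished POSIXct wall times.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(result, path, files = character(),
                           started = Sys.time(), finished = Sys.time()) {
  inv <- lapply(files, function(f)
    list(file = f, md5 = unname(tools::md5sum(f)), bytes = file.size(f)))
  manifest <- list(
    package = "sggsim",
    version = as.character(utils::packageVersion("sggsim")),
    seed = result$spec$seed,
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(finished, "%Y-%m-%dT%H:%M:%S%z"),
    scenario = unclass(result$spec),
    outputs = inv
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read back the scenario embedded in a manifest
#'
#' @param path manifest JSON path.
#' @return The validated scenario recorded in the manifest.
#' @export
read_manifest_scenario <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(new_scenario, m$scenario)
}
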