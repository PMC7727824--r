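# File round-tripping: trajectory / direction-path CSV schemas and the JSON
# run configuration. CSVs are plain UTF-8 with '.' decimal separator and no
# thousands separators; numbers are written with 17 significant digits so a
# read-back reproduces the doubles exactly.

traj_cols <- c("t", "alpha", "beta", "alpha_rate", "beta_rate",
               "alpha_acc", "beta_acc")
path_cols <- c("t", "ux", "uy", "uz")

fmt_num <- function(x) sprintf("%.17g", x)

write_numeric_csv <- function(df, file) {
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(lapply(df, fmt_num), sep = ",")))
  writeLines(lines, file, useBytes = TRUE)
  invisible(file)
}

read_numeric_csv <- function(file, cols, what) {
  if (!file.exists(file)) stop(what, ": file not found: ", file)
  df <- tryCatch(
    read.csv(file, colClasses = "numeric", check.names = FALSE),
    error = function(e) stop(what, ": malformed CSV (", conditionMessage(e), ")"))
  if (!identical(names(df), cols))
    stop(what, ": bad header; expected columns ", paste(cols, collapse = ","),
         " but found ", paste(names(df), collapse = ","))
  for (cl in cols) {
    bad <- which(!is.finite(df[[cl]]))
    if (length(bad))
      stop(what, ": non-finite value in column '", cl, "' at row ", bad[1])
  }
  if (nrow(df) < 1L) stop(what, ": no data rows")
  df
}

#' Write / read a trajectory CSV
#'
#' Schema: header `t,alpha,beta,alpha_rate,beta_rate,alpha_acc,beta_acc`, SI
#' units (seconds, radians and derivatives). Writing is deterministic, so a
#' seeded planner run always produces byte-identical files.
#'
#' @param traj An [trajectory()] object.
#' @param file Path of the CSV file.
#' @return `write_trajectory_csv` returns `file` invisibly;
#'   `read_trajectory_csv` returns the [trajectory()] (the sampling interval
#'   is recovered from the time column).
#' @export
write_trajectory_csv <- function(traj, file) {
  if (!inherits(traj, "mgs_trajectory")) stop("write_trajectory_csv: bad 'traj'")
  write_numeric_csv(as.data.frame(traj)[traj_cols], file)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(file) {
  df <- read_numeric_csv(file, traj_cols, "read_trajectory_csv")
  dt <- if (nrow(df) > 1L) df$t[2] - df$t[1] else 1
  trajectory(df, dt = dt)
}

#' Write / read a direction-path CSV
#'
#' Schema: header `t,ux,uy,uz`; unit gravity-direction vectors in the sample
#' frame.
#'
#' @param path An [direction_path()] object.
#' @param file Path of the CSV file.
#' @return `write_direction_csv` returns `file` invisibly;
#'   `read_direction_csv` returns the [direction_path()].
#' @export
write_direction_csv <- function(path, file) {
  if (!inherits(path, "mgs_direction_path")) stop("write_direction_csv: bad 'path'")
  write_numeric_csv(as.data.frame(path)[path_cols], file)
}

#' @rdname write_direction_csv
#' @export
read_direction_csv <- function(file) {
  df <- read_numeric_csv(file, path_cols, "read_direction_csv")
  direction_path(df$t, as.matrix(df[, c("ux", "uy", "uz")]))
}

# ---- run configuration ------------------------------------------------------

run_config_keys <- c("mode", "duration", "dt", "limits_deg", "target_g",
                     "seed", "compensation", "samples", "metrics", "log_level")
limits_keys <- c("rate_max", "acc_max", "jerk_max")
metrics_keys <- c("decimate", "normalization", "n_rings", "calib_reps")

#' Run configuration
#'
#' A JSON-serializable bundle of planner settings, sample mounting positions
#' and metric options, as consumed by the command-line entry points. Angle
#' limits are given in degrees at this boundary and converted to radians
#' internally.
#'
#' @param mode `"zero"` or `"partial"`.
#' @param duration,dt Run duration and sampling interval, s.
#' @param limits_deg Named list `rate_max`, `acc_max`, `jerk_max` in deg/s,
#'   deg/s^2, deg/s^3.
#' @param target_g Target partial-gravity level (fraction of g).
#' @param seed Integer seed.
#' @param compensation Logical, greedy residual compensation.
#' @param samples List of lists with `offset` (m), `volume` (m^3),
#'   `density` (kg/m^3).
#' @param metrics Named list: `decimate` (`NULL` = auto, keeping ~1000
#'   points), `normalization`, `n_rings`, `calib_reps`.
#' @param log_level `"info"` or `"quiet"`.
#' @return An object of class `mgs_run_config`.
#' @export
run_config <- function(mode = "zero", duration = 600, dt = 0.01,
                       limits_deg = list(rate_max = 60, acc_max = 60,
                                         jerk_max = 120),
                       target_g = 0, seed = 1, compensation = TRUE,
                       samples = list(list(offset = c(0, 0.1, 0),
                                           volume = 1e-6, density = 1000)),
                       metrics = list(decimate = NULL, normalization = "fn",
                                      n_rings = 12, calib_reps = 0),
                       log_level = "info") {
  bad <- setdiff(names(limits_deg), limits_keys)
  if (length(bad)) stop("run_config: unknown limit keys: ", paste(bad, collapse = ", "))
  bad <- setdiff(names(metrics), metrics_keys)
  if (length(bad)) stop("run_config: unknown metric keys: ", paste(bad, collapse = ", "))
  # canonical types, so a JSON round trip reproduces the object exactly
  limits_deg <- lapply(limits_deg[limits_keys], as.numeric)
  samples <- lapply(samples, function(s) list(offset = as.numeric(s$offset),
                                              volume = as.numeric(s$volume),
                                              density = as.numeric(s$density)))
  metrics <- list(
    decimate = if (is.null(metrics$decimate)) NULL else as.integer(metrics$decimate),
    normalization = as.character(if (is.null(metrics$normalization)) "fn" else metrics$normalization),
    n_rings = as.integer(if (is.null(metrics$n_rings)) 12L else metrics$n_rings),
    calib_reps = as.integer(if (is.null(metrics$calib_reps)) 0L else metrics$calib_reps))
  cfg <- list(mode = as.character(mode), duration = as.numeric(duration),
              dt = as.numeric(dt),
              limits_deg = limits_deg, target_g = as.numeric(target_g),
              seed = if (is.null(seed)) NULL else as.integer(seed),
              compensation = isTRUE(compensation), samples = samples,
              metrics = metrics, log_level = as.character(log_level))
  # validate by constructing the planner config now
  planner_config_from_run(cfg)
  structure(cfg, class = "mgs_run_config")
}

planner_config_from_run <- function(cfg) {
  lim <- motion_limits(rate_max = cfg$limits_deg$rate_max * pi / 180,
                       acc_max = cfg$limits_deg$acc_max * pi / 180,
                       jerk_max = cfg$limits_deg$jerk_max * pi / 180)
  planner_config(duration = cfg$duration, dt = cfg$dt, limits = lim,
                 mode = cfg$mode, target_g = cfg$target_g, seed = cfg$seed,
                 compensation = cfg$compensation)
}

#' Write / read a run configuration JSON file
#'
#' Round-trips losslessly; unknown keys in the file are rejected with an
#' error.
#'
#' @param cfg An [run_config()] object.
#' @param file Path of the JSON file.
#' @return `write_run_config` returns `file` invisibly; `read_run_config`
#'   returns the [run_config()].
#' @export
write_run_config <- function(cfg, file) {
  if (!inherits(cfg, "mgs_run_config")) stop("write_run_config: bad 'cfg'")
  jsonlite::write_json(unclass(cfg), file, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(file)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(file) {
  raw <- jsonlite::fromJSON(file, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  bad <- setdiff(names(raw), run_config_keys)
  if (length(bad)) stop("read_run_config: unknown keys: ", paste(bad, collapse = ", "))
  do.call(run_config, raw)
}
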