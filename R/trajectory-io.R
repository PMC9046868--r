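# Trajectory persistence: an R-native container file for the full trajectory
# (bit-exact series + snapshots) plus a flat CSV sidecar of the time series
# with the fixed schema t_day,total_mass,dose_B,dose_H,treatment_on.

#' Write / read a trajectory
#'
#' `writeTrajectory()` stores the full trajectory (series bit-exactly,
#' snapshots, configuration and its provenance hash) in one container file,
#' and writes a flat CSV of the time series next to it (same path with a
#' `.csv` extension). `readTrajectory()` restores the trajectory and verifies
#' the container is complete.
#'
#' @param trajectory a [Trajectory-class].
#' @param path container file path (conventional extension `.traj`).
#' @param csv also write the CSV sidecar (default TRUE).
#' @return `writeTrajectory()`: the path, invisibly. `readTrajectory()`: the
#'   [Trajectory-class].
#' @export
writeTrajectory <- function(trajectory, path, csv = TRUE) {
  stopifnot(is(trajectory, "Trajectory"))
  payload <- list(format = "melanosim-trajectory", version = 1L,
                  trajectory = trajectory)
  saveRDS(payload, path)
  if (csv)
    write.csv(trajectorySeries(trajectory), csvSidecarPath(path),
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrajectory
#' @export
readTrajectory <- function(path) {
  if (!file.exists(path))
    stop("trajectory file not found: ", path, call. = FALSE)
  payload <- tryCatch(readRDS(path), error = function(e)
    stop("read failure: '", path, "' is not a readable trajectory container (",
         conditionMessage(e), ")", call. = FALSE))
  if (!is.list(payload) ||
      !identical(payload$format, "melanosim-trajectory") ||
      !is(payload$trajectory, "Trajectory"))
    stop("read failure: '", path, "' is corrupt or not a trajectory container",
         call. = FALSE)
  validObject(payload$trajectory)
  payload$trajectory
}

csvSidecarPath <- function(path) {
  sub("\\.[A-Za-z0-9]+$", "", path) |> paste0(".csv")
}
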