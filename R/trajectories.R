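#' Per-track centroid trajectories
#'
#' Splits a track table into one trajectory per track: the ordered centroid
#' positions of a cell through the frames in which it appears. Coordinates
#' follow the image convention `x` = column, `y` = row (0-based pixels).
#'
#' @param table a `track_table` from [chain_mappings()] or [track_cells()].
#' @return A named list (one element per track id) of data frames with
#'   columns `frame`, `x`, `y`, `size`.
#' @export
trajectories <- function(table) {
  if (nrow(table) == 0L) return(stats::setNames(list(), character()))
  df <- data.frame(track_id = table$track_id, frame = table$frame,
                   x = table$col, y = table$row, size = table$size)
  df <- df[order(df$track_id, df$frame), , drop = FALSE]
  out <- split(df[c("frame", "x", "y", "size")], df$track_id)
  lapply(out, function(d) { rownames(d) <- NULL; d })
}

#' Per-step displacement vectors of a trajectory
#'
#' One record per consecutive point pair: the displacement `(dx, dy)` and
#' its Euclidean length, i.e. the direction and distance traveled between
#' two consecutive frames.
#'
#' @param traj one trajectory from [trajectories()] (columns `frame`, `x`,
#'   `y`).
#' @return A data frame with columns `frame` (the arrival frame), `dx`,
#'   `dy`, `step_length`; zero rows for a single-point trajectory.
#' @export
displacements <- function(traj) {
  n <- nrow(traj)
  if (n < 2L) {
    return(data.frame(frame = integer(), dx = numeric(), dy = numeric(),
                      step_length = numeric()))
  }
  dx <- diff(traj$x)
  dy <- diff(traj$y)
  data.frame(frame = traj$frame[-1], dx = dx, dy = dy,
             step_length = sqrt(dx^2 + dy^2))
}

#' Travel rate of a trajectory
#'
#' Total path length (sum of per-step Euclidean displacements) divided by
#' elapsed time, in pixels per minute.
#'
#' @param traj one trajectory with at least 2 points.
#' @param frame_interval_min minutes between consecutive frames.
#' @return Travel rate in px/min.
#' @export
travel_rate <- function(traj, frame_interval_min = 15) {
  if (nrow(traj) < 2L) {
    mt_validation_error("travel rate is undefined for a trajectory with fewer than 2 points")
  }
  if (frame_interval_min <= 0) mt_validation_error("frame_interval_min must be > 0")
  path <- sum(displacements(traj)$step_length)
  elapsed <- (traj$frame[nrow(traj)] - traj$frame[1]) * frame_interval_min
  path / elapsed
}

#' Export trajectories, displacements and travel rates as CSV
#'
#' Writes `trajectories.csv` (frame, track_id, x, y, size),
#' `displacements.csv` (track_id, frame, dx, dy, step_length) and
#' `rates.csv` (track_id, n_points, path_length_px, elapsed_min,
#' rate_px_per_min; single-point tracks get `NA` rates). Numeric fields are
#' written at full precision so a re-read reproduces them exactly.
#'
#' @param table a `track_table`.
#' @param directory output directory (created if missing).
#' @param frame_interval_min minutes between consecutive frames.
#' @return Named character vector of the three paths, invisibly.
#' @export
export_trajectories <- function(table, directory, frame_interval_min = 15) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) {
    mt_io_error(sprintf("cannot create output directory '%s'", directory))
  }
  trajs <- trajectories(table)

  traj_df <- data.frame(frame = table$frame, track_id = table$track_id,
                        x = table$col, y = table$row, size = table$size)
  traj_df <- traj_df[order(traj_df$track_id, traj_df$frame), , drop = FALSE]

  disp_list <- lapply(names(trajs), function(id) {
    d <- displacements(trajs[[id]])
    if (nrow(d)) cbind(track_id = as.integer(id), d) else NULL
  })
  disp_df <- do.call(rbind, disp_list) %||%
    data.frame(track_id = integer(), frame = integer(), dx = numeric(),
               dy = numeric(), step_length = numeric())

  rate_df <- do.call(rbind, lapply(names(trajs), function(id) {
    tr <- trajs[[id]]
    multi <- nrow(tr) >= 2L
    data.frame(track_id = as.integer(id),
               n_points = nrow(tr),
               path_length_px = if (multi) sum(displacements(tr)$step_length) else NA_real_,
               elapsed_min = if (multi) (tr$frame[nrow(tr)] - tr$frame[1]) * frame_interval_min else NA_real_,
               rate_px_per_min = if (multi) travel_rate(tr, frame_interval_min) else NA_real_)
  })) %||% data.frame(track_id = integer(), n_points = integer(),
                      path_length_px = numeric(), elapsed_min = numeric(),
                      rate_px_per_min = numeric())

  paths <- c(trajectories = file.path(directory, "trajectories.csv"),
             displacements = file.path(directory, "displacements.csv"),
             rates = file.path(directory, "rates.csv"))
  utils::write.csv(traj_df, paths[["trajectories"]], row.names = FALSE)
  utils::write.csv(disp_df, paths[["displacements"]], row.names = FALSE)
  utils::write.csv(rate_df, paths[["rates"]], row.names = FALSE)
  invisible(paths)
}

#' Quiver plot of centroid trajectories
#'
#' Draws each per-step displacement as an arrow in image coordinates (the y
#' axis increases downward, matching pixel row order). A convenience view
#' of where cells traveled, not a publication figure.
#'
#' @param table a `track_table`.
#' @param file optional PNG path; when given the plot is written there.
#' @param ... passed to [graphics::arrows()].
#' @return Invisibly, the number of arrows drawn.
#' @export
plot_trajectories <- function(table, file = NULL, ...) {
  trajs <- trajectories(table)
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 600)
    on.exit(grDevices::dev.off())
  }
  xr <- range(table$col, na.rm = TRUE)
  yr <- range(table$row, na.rm = TRUE)
  graphics::plot(NA, xlim = xr, ylim = rev(yr), xlab = "x (px)", ylab = "y (px)",
                 main = "Cell centroid trajectories", asp = 1)
  n_arrows <- 0L
  for (tr in trajs) {
    if (nrow(tr) < 2L) next
    graphics::arrows(tr$x[-nrow(tr)], tr$y[-nrow(tr)], tr$x[-1], tr$y[-1],
                     length = 0.05, ...)
    n_arrows <- n_arrows + nrow(tr) - 1L
  }
  invisible(n_arrows)
}
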