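#' Construct a trajectory matrix
#'
#' A trajectory matrix holds one head-position time series per trial (rows)
#' on a common, uniformly spaced time grid aligned to interval onset
#' (time 0 = trial initiation). Positions are in pixels along the port axis.
#'
#' @param positions numeric matrix, trials x timepoints.
#' @param frame_rate frames per second of the time grid.
#' @param time0 time of the first column, seconds relative to interval onset.
#' @param alignment alignment label; only `"interval_onset"` is defined.
#' @return `positions` with class `trajectory_matrix` and attributes
#'   `time_axis`, `frame_rate` and `alignment`.
#' @export
trajectory_matrix <- function(positions, frame_rate, time0 = -0.5,
                              alignment = "interval_onset") {
  positions <- as.matrix(positions)
  if (!is.numeric(frame_rate) || frame_rate <= 0) {
    stop("frame_rate must be positive")
  }
  alignment <- match.arg(alignment, "interval_onset")
  structure(
    positions,
    time_axis = time0 + (seq_len(ncol(positions)) - 1) / frame_rate,
    frame_rate = frame_rate,
    alignment = alignment,
    class = c("trajectory_matrix", class(positions))
  )
}

#' @export
`[.trajectory_matrix` <- function(x, i, j, ..., drop = FALSE) {
  m <- unclass(x)
  out <- if (missing(i) && missing(j)) m
  else if (missing(j)) m[i, , drop = drop]
  else if (missing(i)) m[, j, drop = drop]
  else m[i, j, drop = drop]
  if (is.matrix(out)) {
    ta <- attr(x, "time_axis")
    attr(out, "time_axis") <- if (missing(j)) ta else ta[j]
    attr(out, "frame_rate") <- attr(x, "frame_rate")
    attr(out, "alignment") <- attr(x, "alignment")
    class(out) <- class(x)
  }
  out
}

#' Time axis of a trajectory matrix
#' @param trajs a `trajectory_matrix` (or any matrix with a `time_axis`
#'   attribute).
#' @return numeric vector of column times in seconds.
#' @export
traj_time_axis <- function(trajs) {
  ta <- attr(trajs, "time_axis")
  if (is.null(ta)) stop("input error: matrix has no time_axis attribute")
  ta
}

#' Extract a time window from a trajectory matrix
#'
#' Selects the columns whose times fall in the half-open window
#' `[window[1], window[2])` and, when the source frame rate differs from
#' `target_fps`, linearly resamples each row onto a uniform grid at
#' `target_fps` so that downstream analyses always see the same
#' dimensionality (a 1 s window at 120 frames/s is 120 columns).
#'
#' @param trajs a `trajectory_matrix`.
#' @param window length-2 numeric, seconds relative to interval onset;
#'   half-open `[t0, t1)`.
#' @param target_fps frame rate of the returned window; defaults to the
#'   source rate (no resampling).
#' @return plain numeric matrix with a `time_axis` attribute.
#' @export
traj_window <- function(trajs, window = c(-0.5, 0.5), target_fps = NULL) {
  ta <- traj_time_axis(trajs)
  fps <- attr(trajs, "frame_rate")
  if (window[2] <= window[1]) stop("input error: empty window")
  keep <- which(ta >= window[1] - 1e-9 & ta < window[2] - 1e-9)
  if (length(keep) == 0) stop("input error: window outside trajectory support")
  out <- unclass(trajs)[, keep, drop = FALSE]
  sub_ta <- ta[keep]
  if (!is.null(target_fps) && !isTRUE(all.equal(target_fps, fps))) {
    n_out <- round((window[2] - window[1]) * target_fps)
    grid <- window[1] + (seq_len(n_out) - 1) / target_fps
    out <- t(apply(out, 1, function(row) {
      approx(sub_ta, row, xout = grid, rule = 2)$y
    }))
    sub_ta <- grid
  }
  attr(out, "time_axis") <- sub_ta
  out
}

#' Write / read a trajectory matrix as CSV plus a JSON sidecar
#'
#' The dense numeric matrix is written without row or column names; the
#' sidecar records `frame_rate`, `alignment` and `time0` so the time axis
#' can be reconstructed.
#'
#' @param trajs a `trajectory_matrix`.
#' @param path path of the CSV file; the sidecar is written at
#'   `paste0(path, ".json")`.
#' @return `write_trajectory_matrix()` returns `path` invisibly;
#'   `read_trajectory_matrix()` returns a `trajectory_matrix`.
#' @export
write_trajectory_matrix <- function(trajs, path) {
  ta <- traj_time_axis(trajs)
  utils::write.table(unclass(trajs), path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(frame_rate = attr(trajs, "frame_rate"),
               alignment = attr(trajs, "alignment"),
               time0 = ta[1])
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trajectory_matrix
#' @param path path of the CSV written by `write_trajectory_matrix()`.
#' @export
read_trajectory_matrix <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  trajectory_matrix(m, frame_rate = meta$frame_rate, time0 = meta$time0,
                    alignment = meta$alignment)
}
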