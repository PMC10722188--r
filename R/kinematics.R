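#' Per-frame speed vectors
#'
#' Computes the stacked displacement vector V(t) = X(t) - X(t - dt) by
#' backward finite differences: row t of the result is the displacement from
#' frame t to frame t+1 of the pose, so a pose with F frames yields F-1 speed
#' rows. Units are coordinate units *per frame* (the form all template
#' matching and correlation math operates on); set `per_second = TRUE` to
#' divide by the frame interval 1/fps and obtain physical speeds.
#'
#' For the default 18-point skeleton the stacked vector has 36 components in
#' 2D and 54 in 3D.
#'
#' @param pose A gap-free [pose_sequence()] with at least 2 frames.
#' @param per_second Convert to units/second instead of units/frame.
#' @return A `speed_series`: a `frames x |N|` matrix of components plus
#'   metadata (`fps`, `dims`, `config`, `frame_index` mapping rows to
#'   original video frames, 0-based, row t covering displacement into frame
#'   `frame_index[t]`).
#' @export
compute_speed <- function(pose, per_second = FALSE) {
  if (n_frames(pose) < 2L)
    stop("need at least 2 frames to compute speed", call. = FALSE)
  m <- flatten_pose(pose)
  if (anyNA(m))
    stop("pose contains gaps; run fill_gaps() first", call. = FALSE)
  v <- diff(m)
  if (per_second) v <- v * pose$fps
  speed_series(v, pose$config, pose$fps, dims = pose_dims(pose),
               frame_index = seq_len(nrow(v)),
               units = paste0(pose$units, if (per_second) "/s" else "/frame"))
}

#' @rdname compute_speed
#' @param values `frames x |N|` numeric matrix of speed components.
#' @param config The skeleton the columns are laid out by.
#' @param fps Source frame rate.
#' @param dims 2 or 3.
#' @param frame_index 1-based original frame indices of the rows (row t is
#'   the displacement X(frame_index[t]+1) - X(frame_index[t]) in 0-based
#'   video frames); kept through culling so results map back to video time.
#' @param units Unit label.
#' @export
speed_series <- function(values, config, fps, dims,
                         frame_index = seq_len(nrow(values)),
                         units = "px/frame") {
  stopifnot(is.matrix(values), dims %in% c(2L, 3L))
  if (ncol(values) != n_points(config) * dims)
    stop("speed series must have n_points * dims = ",
         n_points(config) * dims, " components", call. = FALSE)
  if (length(frame_index) != nrow(values))
    stop("frame_index length must match row count", call. = FALSE)
  colnames(values) <- component_names(config, dims)
  structure(list(values = values, config = config, fps = fps,
                 dims = as.integer(dims), frame_index = as.integer(frame_index),
                 units = units),
            class = "speed_series")
}

#' @export
print.speed_series <- function(x, ...) {
  cat("<speed_series> ", nrow(x$values), " frames x ", ncol(x$values),
      " components (", x$dims, "D), ", x$fps, " fps [", x$units, "]\n",
      sep = "")
  invisible(x)
}

#' Interval between two video frames
#' @param fps Frame rate, > 0.
#' @return Seconds per frame, 1/fps (0.0333 s at 30 fps).
#' @export
frame_interval <- function(fps) {
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("fps must be a positive number", call. = FALSE)
  1 / fps
}

#' Culling plan: frame intervals to keep
#'
#' Cycle extraction assumes the animal is walking; intervals when it stopped
#' on the beam or hesitated before the goal box are removed ("culled") from
#' the speed series first. A plan lists the half-open `[start, end)` 0-based
#' intervals of the speed timeline to keep.
#'
#' @param keep Two-column matrix or list of `c(start, end)` pairs, 0-based,
#'   half-open, on the speed-series timeline.
#' @param n_total Length of the series the plan applies to.
#' @export
culling_plan <- function(keep, n_total) {
  if (is.list(keep)) keep <- do.call(rbind, keep)
  keep <- matrix(as.integer(keep), ncol = 2)
  if (nrow(keep) == 0L)
    stop("culling plan keeps no frames", call. = FALSE)
  keep <- keep[order(keep[, 1]), , drop = FALSE]
  if (any(keep[, 1] < 0) || any(keep[, 2] > n_total) || any(keep[, 1] >= keep[, 2]))
    stop("intervals must be non-empty, within [0, ", n_total, ")", call. = FALSE)
  if (nrow(keep) > 1L && any(keep[-1, 1] < keep[-nrow(keep), 2]))
    stop("intervals must be disjoint", call. = FALSE)
  structure(list(keep = keep, n_total = as.integer(n_total)),
            class = "culling_plan")
}

#' Apply a culling plan to a speed series
#'
#' Concatenates the kept intervals; the original frame indices of surviving
#' rows are retained in `frame_index` so per-cycle results can be mapped back
#' to video time.
#'
#' @param speed A [speed_series()].
#' @param plan A [culling_plan()].
#' @export
cull <- function(speed, plan) {
  stopifnot(inherits(plan, "culling_plan"))
  if (plan$n_total != nrow(speed$values))
    stop("plan was built for a series of length ", plan$n_total,
         ", not ", nrow(speed$values), call. = FALSE)
  rows <- unlist(apply(plan$keep, 1, function(iv) (iv[1] + 1L):iv[2],
                       simplify = FALSE))
  speed_series(speed$values[rows, , drop = FALSE], speed$config, speed$fps,
               speed$dims, frame_index = speed$frame_index[rows],
               units = speed$units)
}

#' Propose a culling plan from foot inactivity
#'
#' The manual culling the workflow normally relies on can be automated for
#' clean data: maximal runs of at least `min_len` frames in which the
#' root-mean-square of the foot-group components stays below `epsilon` are
#' treated as stops and removed.
#'
#' @param speed A [speed_series()].
#' @param epsilon RMS foot-speed threshold (same units as the series).
#' @param min_len Minimum stop duration, frames.
#' @param foot_group Name of the foot group in the skeleton config.
#' @return A [culling_plan()], or an error if nothing survives.
#' @export
auto_cull_plan <- function(speed, epsilon, min_len = 5L, foot_group = "feet") {
  if (epsilon < 0) stop("epsilon must be >= 0", call. = FALSE)
  grp <- component_groups(speed$config, speed$dims)
  fv <- speed$values[, grp == foot_group, drop = FALSE]
  rms <- sqrt(rowMeans(fv^2))
  still <- rms < epsilon
  r <- rle(still)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  drop <- r$values & r$lengths >= min_len
  keep <- list()
  cursor <- 1L
  for (k in seq_along(r$lengths)) {
    if (drop[k]) {
      if (starts[k] > cursor) keep[[length(keep) + 1L]] <- c(cursor - 1L, starts[k] - 1L)
      cursor <- ends[k] + 1L
    }
  }
  if (cursor <= length(still)) keep[[length(keep) + 1L]] <- c(cursor - 1L, length(still))
  if (length(keep) == 0L)
    stop("no walking frames left: entire series is below the speed threshold",
         call. = FALSE)
  culling_plan(keep, nrow(speed$values))
}
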