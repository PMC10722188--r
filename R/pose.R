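#' Time-indexed pose sequence
#'
#' A `pose_sequence` holds per-frame coordinates of every feature point, the
#' container for the stacked coordinate vector X(t). Coordinates are stored
#' as a `frames x n_points x dims` array. For 2D data the pixel convention is
#' used: origin top-left, y pointing down, 0-based frame indexing in all file
#' formats (converted to R's 1-based indexing in memory). Calibrated data are
#' in cm with the beam along +x.
#'
#' @param coords Numeric array `frames x n_points x dims`, or a
#'   `frames x (n_points*dims)` matrix laid out point-major (x1,y1[,z1],x2,...).
#' @param config A [feature_point_config()].
#' @param fps Frame rate of the source video (frames/second).
#' @param units `"px"` (raw tracking) or `"cm"` (calibrated).
#' @param dims 2 or 3; inferred from `coords` when it is a 3D array.
#' @return A `pose_sequence`.
#' @export
pose_sequence <- function(coords, config, fps, units = c("px", "cm"), dims = NULL) {
  units <- match.arg(units)
  if (fps <= 0) stop("fps must be positive", call. = FALSE)
  np <- n_points(config)
  if (is.matrix(coords)) {
    if (is.null(dims)) stop("`dims` required when coords given as a flat matrix",
                            call. = FALSE)
    if (ncol(coords) != np * dims)
      stop("flat coords have ", ncol(coords), " columns; expected ",
           np * dims, call. = FALSE)
    coords <- array(coords, dim = c(nrow(coords), dims, np))
    coords <- aperm(coords, c(1, 3, 2))
  }
  d <- dim(coords)
  if (length(d) != 3L || d[2] != np || !(d[3] %in% c(2L, 3L)))
    stop("coords must be frames x ", np, " x {2,3}", call. = FALSE)
  dimnames(coords) <- list(NULL, point_names(config),
                           c("x", "y", "z")[seq_len(d[3])])
  structure(list(coords = coords, config = config, fps = fps, units = units),
            class = "pose_sequence")
}

#' @rdname pose_sequence
#' @param x A `pose_sequence`.
#' @export
n_frames <- function(x) dim(x$coords)[1]

#' @rdname pose_sequence
#' @export
pose_dims <- function(x) dim(x$coords)[3]

#' Flatten a pose sequence to the stacked component matrix
#'
#' Returns a `frames x (n_points*dims)` matrix in the canonical component
#' order (x1, y1[, z1], x2, ...), columns named `point_axis`. This ordering is
#' identical everywhere in the package, so component n of a speed series
#' always refers to the same point and axis.
#'
#' @param pose A `pose_sequence`.
#' @export
flatten_pose <- function(pose) {
  d <- dim(pose$coords)
  m <- matrix(aperm(pose$coords, c(1, 3, 2)), nrow = d[1])
  colnames(m) <- component_names(pose$config, d[3])
  m
}

#' Rebuild a pose sequence from a flat component matrix
#' @param m Matrix `frames x (n_points*dims)` in canonical component order.
#' @inheritParams pose_sequence
#' @export
unflatten_pose <- function(m, config, fps, units = "px") {
  dims <- ncol(m) / n_points(config)
  if (dims != floor(dims) || !(dims %in% c(2, 3)))
    stop("column count ", ncol(m), " is not n_points * {2,3}", call. = FALSE)
  pose_sequence(m, config, fps, units, dims = as.integer(dims))
}

#' @export
print.pose_sequence <- function(x, ...) {
  cat("<pose_sequence> ", n_frames(x), " frames, ", dim(x$coords)[2],
      " points, ", pose_dims(x), "D, ", x$fps, " fps [", x$units, "]\n",
      sep = "")
  ng <- sum(is.na(x$coords))
  if (ng > 0) cat("  ", ng, " missing coordinate values (gaps)\n", sep = "")
  invisible(x)
}

#' Extract a single frame as an initial posture
#' @param pose A `pose_sequence`.
#' @param frame 1-based frame index.
#' @return `n_points x dims` matrix.
#' @export
pose_frame <- function(pose, frame = 1L) {
  stopifnot(frame >= 1, frame <= n_frames(pose))
  pose$coords[frame, , , drop = TRUE]
}

#' Linearly interpolate short tracking gaps
#'
#' Tracking gaps (frames where the reader flagged a point as missing or
#' low-confidence) are filled by per-coordinate linear interpolation, but
#' only when the gap is interior and no longer than `max_gap` frames. Longer
#' gaps, or gaps touching the first or last frame, are tracking failures the
#' user must curate; they raise an error naming the offending point.
#'
#' @param pose A `pose_sequence` possibly containing `NA` coordinates.
#' @param max_gap Longest run of consecutive missing frames to interpolate.
#' @return A gap-free `pose_sequence`.
#' @export
fill_gaps <- function(pose, max_gap = 5L) {
  co <- pose$coords
  nf <- dim(co)[1]
  for (p in seq_len(dim(co)[2])) {
    for (a in seq_len(dim(co)[3])) {
      v <- co[, p, a]
      na <- is.na(v)
      if (!any(na)) next
      r <- rle(na)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        if (starts[k] == 1L || ends[k] == nf)
          stop("gap at sequence boundary for point '",
               dimnames(co)[[2]][p], "' (frames ", starts[k] - 1L, "-",
               ends[k] - 1L, ")", call. = FALSE)
        if (r$lengths[k] > max_gap)
          stop("gap of ", r$lengths[k], " frames for point '",
               dimnames(co)[[2]][p], "' exceeds max_gap = ", max_gap,
               call. = FALSE)
      }
      co[, p, a] <- stats::approx(which(!na), v[!na], xout = seq_len(nf),
                                  method = "linear")$y
    }
  }
  pose$coords <- co
  pose
}
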