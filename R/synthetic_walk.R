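#' Net displacement of each component over one cycle
#'
#' Discrete integral of the SWC speed waveform over its period: the plain
#' per-component frame sum, consistent with the per-frame displacement units
#' of the speed series and with Forward-Euler integration.
#'
#' @param swc A [standard_walk_cycle()] or `normalized_swc`.
#' @return Named numeric vector, one sum per component.
#' @export
cycle_displacement <- function(swc) {
  colSums(swc$values)
}

#' Normalize an SWC for drift-free synthetic walking
#'
#' Because the SWC is an average over real, slightly inconsistent cycles,
#' replaying it does not return the posture to its starting shape after one
#' period: points drift apart. Normalization enforces the closure condition
#' that every point advances by the same constant vector `(V_x, 0, 0)` per
#' period, where `V_x` is the largest per-point net x-displacement in the
#' input (the beam direction is the only admissible net motion; lateral and
#' vertical drift are set to zero). Each component is shifted by a constant
#' — the smallest change meeting the constraint, and one that leaves
#' zero-speed stance phases intact, unlike a multiplicative rescale.
#'
#' @param swc A [standard_walk_cycle()].
#' @return A `normalized_swc`: the shifted waveform plus the net period
#'   displacement vector `V` (length `dims`, `(V_x, 0[, 0])`).
#' @export
normalize_swc <- function(swc) {
  vals <- swc$values
  tau <- nrow(vals)
  sums <- colSums(vals)
  ax <- component_axes(swc$config, swc$dims)
  vx <- max(sums[ax == "x"])
  if (vx <= 0)
    stop("no point has positive net x-displacement; walk direction undefined",
         call. = FALSE)
  target <- ifelse(ax == "x", vx, 0)
  vals <- sweep(vals, 2, (target - sums) / tau, "+")
  structure(list(values = vals, config = swc$config, fps = swc$fps,
                 dims = swc$dims,
                 V = c(vx, rep(0, swc$dims - 1L))),
            class = "normalized_swc")
}

#' @export
print.normalized_swc <- function(x, ...) {
  cat("<normalized_swc> tau = ", nrow(x$values), ", V = (",
      paste(signif(x$V, 4), collapse = ", "), ") per cycle\n", sep = "")
  invisible(x)
}

#' Generate a synthetic walk animation from a normalized SWC
#'
#' Tiles the normalized cycle periodically and integrates it with the
#' Forward Euler scheme: `X(0) = X0`, `X(t+1) = X(t) + V_swc(t mod tau)`.
#' After every full period each point has advanced exactly by the cycle's
#' net displacement `(V_x, 0, 0)`.
#'
#' A 2D SWC may be applied to a 3D initial posture: the missing lateral
#' component simply stays constant (the synthetic walk then has no lateral
#' movement), mirroring what side-view-only data can support.
#'
#' @param nswc A `normalized_swc` from [normalize_swc()].
#' @param x0 Initial posture: an `n_points x dims` matrix (e.g. from
#'   [pose_frame()]) or a single-frame [pose_sequence()].
#' @param n_frames Number of animation frames to generate (including the
#'   initial posture).
#' @return A [pose_sequence()] of the animation; frame 1 equals `x0`.
#' @export
generate_walk <- function(nswc, x0, n_frames) {
  if (inherits(x0, "pose_sequence")) x0 <- pose_frame(x0, 1L)
  x0 <- as.matrix(x0)
  np <- n_points(nswc$config)
  if (nrow(x0) != np)
    stop("x0 must have one row per feature point (", np, ")", call. = FALSE)
  x0_dims <- ncol(x0)
  if (x0_dims < nswc$dims)
    stop("initial posture has fewer dimensions than the SWC", call. = FALSE)
  stopifnot(n_frames >= 1)
  v <- nswc$values                       # tau x (np*dims), axis-fastest layout
  tau <- nrow(v)
  co <- array(0, dim = c(n_frames, np, x0_dims))
  co[1, , ] <- x0
  if (n_frames > 1L) {
    steps <- (seq_len(n_frames - 1L) - 1L) %% tau + 1L
    vcube <- aperm(array(t(v), dim = c(nswc$dims, np, tau)), c(3, 2, 1))
    for (t in seq_len(n_frames - 1L))
      co[t + 1L, , seq_len(nswc$dims)] <-
        co[t, , seq_len(nswc$dims)] + vcube[steps[t], , ]
    if (x0_dims > nswc$dims)
      for (a in (nswc$dims + 1L):x0_dims) co[-1L, , a] <- rep(x0[, a], each = n_frames - 1L)
  }
  pose_sequence(co, nswc$config, nswc$fps, units = "cm")
}
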