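#' Standard walk cycle container
#'
#' The standard walk cycle (SWC) is a single-cycle speed waveform over all
#' components — the animal's typical gait on the beam — together with the
#' cumulative weight of the cycles averaged into it. The weight is carried so
#' that further videos can be folded in as a running weighted average.
#'
#' @param values `tau x |N|` matrix of per-frame speed components.
#' @param config Skeleton configuration ([feature_point_config()]).
#' @param fps Source frame rate.
#' @param dims 2 or 3.
#' @param weight Cumulative weight (sum of the per-cycle correlation scores
#'   that produced the average); must be positive.
#' @export
standard_walk_cycle <- function(values, config, fps, dims, weight) {
  stopifnot(is.matrix(values), dims %in% c(2L, 3L))
  if (ncol(values) != n_points(config) * dims)
    stop("SWC must have n_points * dims components", call. = FALSE)
  if (!is.finite(weight) || weight <= 0)
    stop("SWC weight must be positive and finite", call. = FALSE)
  colnames(values) <- component_names(config, dims)
  structure(list(values = values, config = config, fps = fps,
                 dims = as.integer(dims), weight = weight),
            class = "standard_walk_cycle")
}

#' @export
print.standard_walk_cycle <- function(x, ...) {
  cat("<standard_walk_cycle> tau = ", nrow(x$values), " frames x ",
      ncol(x$values), " components (", x$dims, "D), weight = ",
      format(x$weight), "\n", sep = "")
  invisible(x)
}

#' Select the initial cycle template
#'
#' Copies an interval of the (culled) speed series as the initial template
#' SWC0 from which cycle segmentation starts. In the original workflow the
#' interval is picked by eye from the prominent foot-speed peaks;
#' [suggest_template()] automates that choice.
#'
#' @param speed A [speed_series()].
#' @param t_start,t_end Half-open `[t_start, t_end)` 0-based interval on the
#'   culled timeline; at least 4 frames.
#' @return A `cycle_template`.
#' @export
select_template <- function(speed, t_start, t_end) {
  nf <- nrow(speed$values)
  if (t_start < 0 || t_end > nf || t_end - t_start < 4L)
    stop("template interval must lie within [0, ", nf,
         ") and span at least 4 frames", call. = FALSE)
  structure(list(values = speed$values[(t_start + 1L):t_end, , drop = FALSE],
                 config = speed$config, dims = speed$dims, fps = speed$fps,
                 t_start = as.integer(t_start)),
            class = "cycle_template")
}

#' Suggest a template interval from gait periodicity
#'
#' Estimates the dominant stride period from the autocorrelation of the
#' summed squared foot-speed (x components), then centres a one-period
#' window on the highest-energy stretch. Requires at least ~3 cycles of
#' genuine periodicity; flat or structureless series are rejected.
#'
#' @param speed A culled [speed_series()].
#' @param min_period,max_period Period search range in frames.
#' @param min_acf Minimum autocorrelation a candidate period peak must reach.
#' @param foot_group Name of the foot group.
#' @return `c(t_start, t_end)`, 0-based half-open, suitable for
#'   [select_template()].
#' @export
suggest_template <- function(speed, min_period = 4L, max_period = NULL,
                             min_acf = 0.2, foot_group = "feet") {
  grp <- component_groups(speed$config, speed$dims)
  ax <- component_axes(speed$config, speed$dims)
  fx <- speed$values[, grp == foot_group & ax == "x", drop = FALSE]
  e <- rowSums(fx^2)
  n <- length(e)
  if (is.null(max_period)) max_period <- floor(n / 3)
  if (max_period < min_period + 2L)
    stop("series too short to hold 3 cycles", call. = FALSE)
  if (stats::sd(e) == 0)
    stop("no periodicity detected: foot-speed energy is constant", call. = FALSE)
  ac <- stats::acf(e, lag.max = max_period, plot = FALSE)$acf[-1]
  # local maxima of the autocorrelation within the admissible period range
  cand <- which(diff(sign(diff(ac))) == -2) + 1L
  cand <- cand[cand >= min_period & ac[cand] >= min_acf]
  if (length(cand) == 0L)
    stop("no periodicity detected: autocorrelation has no peak >= ", min_acf,
         call. = FALSE)
  period <- cand[which.max(ac[cand])]
  # highest-energy window of one period
  cs <- cumsum(c(0, e))
  wins <- cs[(period + 1L):(n + 1L)] - cs[1:(n - period + 1L)]
  t0 <- which.max(wins) - 1L
  c(t_start = t0, t_end = t0 + period)
}

# Rescale a tau0 x N waveform to tau rows by per-component linear
# interpolation on the normalized frame grid; identity when tau == tau0.
rescale_cycle <- function(values, tau) {
  tau0 <- nrow(values)
  if (tau == tau0) return(values)
  x0 <- seq(0, 1, length.out = tau0)
  x1 <- seq(0, 1, length.out = tau)
  apply(values, 2, function(v) stats::approx(x0, v, xout = x1)$y)
}

#' Segment a speed series into walk cycles by template matching
#'
#' Greedy left-to-right segmentation: starting at frame 0 of the culled
#' series, every integer period `tau` in `[ceil(tau0*r1), floor(tau0*r2)]`
#' is tried; the template is rescaled to length `tau` by linear
#' interpolation and scored against the data window by the non-centred
#' correlation sum over all components, normalized by the rescaled
#' template's self inner product. The best-scoring period (ties resolved to
#' the shortest) closes the cycle, the window advances by `tau`
#' (contiguity: `t[i+1] = t[i] + tau[i]`), and the search repeats until
#' fewer than the minimum period remain; the tail is discarded. An optional
#' exhaustive dynamic-programming mode maximizes the total score over all
#' contiguous segmentations instead, useful to validate the greedy result on
#' short series.
#'
#' The normalized score is ~1 for a template-like cycle, 0 for no movement,
#' >1 for the same movement at higher speed and negative for movement
#' opposite to the template — the semantics the downstream correlation
#' matrix and VoC rely on.
#'
#' @param speed A culled [speed_series()].
#' @param template A `cycle_template` (or a [standard_walk_cycle()] when
#'   refining).
#' @param ratio_bounds Period search range relative to the template length
#'   (default half to double).
#' @param method `"greedy"` (default) or `"dp"` (exhaustive over contiguous
#'   segmentations).
#' @return A `cycle_segmentation`: 0-based starts `t`, periods `tau`, scores
#'   `score`, the template length `tau0`, and the culled frame index map.
#' @export
segment_cycles <- function(speed, template, ratio_bounds = c(0.5, 2),
                           method = c("greedy", "dp")) {
  method <- match.arg(method)
  tvals <- template$values
  if (ncol(tvals) != ncol(speed$values))
    stop("template and speed series have different component counts",
         call. = FALSE)
  if (sum(tvals^2) == 0)
    stop("zero-norm template: no movement to match", call. = FALSE)
  tau0 <- nrow(tvals)
  tau_min <- max(2L, as.integer(ceiling(tau0 * ratio_bounds[1])))
  tau_max <- as.integer(floor(tau0 * ratio_bounds[2]))
  v <- speed$values
  nf <- nrow(v)
  if (nf < tau_min)
    stop("series shorter than the minimal period (", tau_min, " frames)",
         call. = FALSE)
  # precompute rescaled templates and their self inner products
  taus <- tau_min:tau_max
  scaled <- lapply(taus, function(tau) rescale_cycle(tvals, tau))
  selfip <- vapply(scaled, function(s) sum(s * s), numeric(1))

  # the match metric is the normalized cross-correlation (cosine), which is
  # scale-free in the period so the arg-max lands on the true period; the
  # recorded weight Cmax is the projection coefficient <s,V>/<s,s>, whose
  # scale carries the 0 / 1 / >1 / negative movement semantics
  score_at <- function(t0, k) {  # t0 0-based, k index into taus
    tau <- taus[k]
    if (t0 + tau > nf) return(c(NA_real_, NA_real_))
    seg <- v[(t0 + 1L):(t0 + tau), , drop = FALSE]
    num <- sum(scaled[[k]] * seg)
    segn <- sqrt(sum(seg * seg))
    cosv <- if (segn == 0) 0 else num / (sqrt(selfip[k]) * segn)
    c(cosv, num / selfip[k])
  }

  if (method == "greedy") {
    t <- 0L
    starts <- integer(0); periods <- integer(0); scores <- numeric(0)
    while (nf - t >= tau_min) {
      sc <- vapply(seq_along(taus), function(k) score_at(t, k), numeric(2))
      ok <- !is.na(sc[1, ])
      k <- which(ok)[which.max(sc[1, ok])]  # which.max: smallest tau on ties
      starts <- c(starts, t); periods <- c(periods, taus[k])
      scores <- c(scores, sc[2, k])
      t <- t + taus[k]
    }
  } else {
    # DP over cut positions: best[j] = max total score of a contiguous
    # segmentation of [0, j); tail frames < tau_min may remain uncovered.
    # The accumulated score is tau * cosine — per-frame match quality — so
    # the optimum is not biased toward many short or few long cycles.
    best <- rep(-Inf, nf + 1L); best[1] <- 0
    prev <- integer(nf + 1L)
    for (j in seq_len(nf)) {
      for (k in seq_along(taus)) {
        i <- j - taus[k]
        if (i < 0 || !is.finite(best[i + 1L])) next
        s <- best[i + 1L] + taus[k] * score_at(i, k)[1]
        if (s > best[j + 1L]) { best[j + 1L] <- s; prev[j + 1L] <- i }
      }
    }
    reachable <- which(is.finite(best)) - 1L
    endpos <- reachable[reachable > nf - tau_min]
    if (length(endpos) == 0L)
      stop("no contiguous segmentation found", call. = FALSE)
    end <- endpos[which.max(best[endpos + 1L])]
    starts <- integer(0); j <- end
    while (j > 0) { starts <- c(prev[j + 1L], starts); j <- prev[j + 1L] }
    periods <- diff(c(starts, end))
    scores <- vapply(seq_along(starts), function(i)
      score_at(starts[i], match(periods[i], taus))[2], numeric(1))
  }
  structure(list(t = starts, tau = periods, score = scores, tau0 = tau0,
                 frame_index = speed$frame_index),
            class = "cycle_segmentation")
}

#' @export
print.cycle_segmentation <- function(x, ...) {
  cat("<cycle_segmentation> ", length(x$t), " cycles, template tau0 = ",
      x$tau0, "\n", sep = "")
  print(data.frame(t = x$t, tau = x$tau, score = signif(x$score, 4)))
  invisible(x)
}

#' Compute the standard walk cycle from segmented cycles
#'
#' Each segmented cycle is rescaled to `target_len` frames (the template
#' length by default) by linear interpolation and the cycles are averaged
#' with their correlation scores as weights; the SWC's cumulative weight is
#' the sum of the scores. Cycles with non-positive score (movement opposite
#' to the template) would invert the average and are dropped with a warning.
#'
#' @param speed The culled [speed_series()] that was segmented.
#' @param seg A `cycle_segmentation` of that series.
#' @param target_len Output cycle length in frames; defaults to the
#'   template length `seg$tau0`.
#' @return A [standard_walk_cycle()].
#' @export
compute_swc <- function(speed, seg, target_len = seg$tau0) {
  keep <- which(seg$score > 0)
  if (length(keep) == 0L)
    stop("all cycle scores are non-positive; no cycles to average",
         call. = FALSE)
  if (length(keep) < length(seg$score))
    warning(length(seg$score) - length(keep),
            " cycle(s) with non-positive score dropped from the average")
  acc <- matrix(0, nrow = target_len, ncol = ncol(speed$values))
  wsum <- 0
  for (i in keep) {
    cyc <- speed$values[(seg$t[i] + 1L):(seg$t[i] + seg$tau[i]), , drop = FALSE]
    acc <- acc + seg$score[i] * rescale_cycle(cyc, target_len)
    wsum <- wsum + seg$score[i]
  }
  standard_walk_cycle(acc / wsum, speed$config, speed$fps, speed$dims,
                      weight = wsum)
}

#' Fold a new video into an existing standard walk cycle
#'
#' Progressive refinement: the stored SWC serves as the template to segment
#' the new speed series, and the result is the running weighted average of
#' the old SWC (weighted by its cumulative weight) and the newly found
#' cycles (weighted by their scores). Weights add, so refinement order does
#' not matter up to the usual floating-point tolerance.
#'
#' @param prev A [standard_walk_cycle()] (e.g. from [read_swc()]).
#' @param new_speed A culled [speed_series()] from the new video.
#' @param ratio_bounds Period search range, as in [segment_cycles()].
#' @return Updated [standard_walk_cycle()] and, as attribute
#'   `"segmentation"`, the new video's `cycle_segmentation`.
#' @export
refine_swc <- function(prev, new_speed, ratio_bounds = c(0.5, 2)) {
  stopifnot(inherits(prev, "standard_walk_cycle"))
  if (ncol(prev$values) != ncol(new_speed$values))
    stop("SWC and new speed series have different component counts",
         call. = FALSE)
  seg <- segment_cycles(new_speed, prev, ratio_bounds = ratio_bounds)
  if (!any(seg$score > 0)) {
    warning("new video contributes no positively-correlated cycles; SWC unchanged")
    attr(prev, "segmentation") <- seg
    return(prev)
  }
  new_swc <- compute_swc(new_speed, seg, target_len = nrow(prev$values))
  w <- prev$weight + new_swc$weight
  out <- standard_walk_cycle(
    (prev$weight * prev$values + new_swc$weight * new_swc$values) / w,
    prev$config, prev$fps, prev$dims, weight = w)
  attr(out, "segmentation") <- seg
  out
}
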