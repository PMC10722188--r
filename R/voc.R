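#' Per-cycle, per-component correlation against the SWC
#'
#' For every segmented cycle i and component n the entry is the non-centred
#' correlation of the cycle's speed with the SWC, normalized by the SWC
#' component's own autocorrelation:
#' `entry(i, n) = <V_n on cycle i (rescaled to tau), SWC_n> / <SWC_n, SWC_n>`.
#' The normalization fixes the semantics componentwise: 0 means no movement,
#' 1 an exact match with the SWC, values above 1 the same movement at higher
#' speed, and negative values movement opposite to the SWC. Components whose
#' SWC waveform is identically zero carry no reference; they score 0 and are
#' reported in the `"zero_norm"` attribute.
#'
#' @param speed The culled [speed_series()].
#' @param swc A [standard_walk_cycle()].
#' @param seg A `cycle_segmentation` of `speed` against this SWC.
#' @return A `correlation_matrix`: cycles x components, with the
#'   segmentation attached.
#' @export
correlation_matrix <- function(speed, swc, seg) {
  if (length(seg$t) == 0L)
    stop("empty segmentation", call. = FALSE)
  tau <- nrow(swc$values)
  selfip <- colSums(swc$values^2)
  zero <- selfip == 0
  m <- matrix(0, nrow = length(seg$t), ncol = ncol(swc$values),
              dimnames = list(NULL, colnames(swc$values)))
  for (i in seq_along(seg$t)) {
    cyc <- speed$values[(seg$t[i] + 1L):(seg$t[i] + seg$tau[i]), , drop = FALSE]
    cyc <- rescale_cycle(cyc, tau)
    num <- colSums(cyc * swc$values)
    m[i, !zero] <- num[!zero] / selfip[!zero]
  }
  structure(m, class = c("correlation_matrix", "matrix"),
            segmentation = seg, zero_norm = colnames(swc$values)[zero])
}

#' Variance of correlation (VoC) per body group and cycle
#'
#' For each body-part group (head, body, tail, feet) and each walk cycle,
#' the VoC is the population variance (second central moment, divisor =
#' group size) of that group's normalized correlation values. It is
#' non-negative, 0 when the group's components all deviate from the SWC the
#' same way (including perfectly normal walking and complete stillness),
#' and grows when parts of the group move inconsistently with the rest — the
#' signature of slips, jumps, stops and other anomalies.
#'
#' By default only the x and y speed components enter the variance even for
#' 3D data, so 2D- and 3D-derived VoC values are directly comparable; set
#' `axes = c("x","y","z")` to include the lateral/depth component.
#'
#' @param corr A [correlation_matrix()].
#' @param config The skeleton configuration.
#' @param axes Which coordinate axes to include (default x and y).
#' @return A `voc_series`: `groups x cycles` matrix of variances plus the
#'   segmentation, with helper [voc_timeseries()] for the stepwise-in-time
#'   expansion.
#' @export
voc <- function(corr, config, axes = c("x", "y")) {
  seg <- attr(corr, "segmentation")
  dims <- ncol(corr) / n_points(config)
  if (dims != floor(dims))
    stop("correlation matrix does not match the configuration", call. = FALSE)
  grp <- component_groups(config, dims)
  ax <- component_axes(config, dims)
  sel_ax <- ax %in% axes
  groups <- group_names(config)
  out <- matrix(NA_real_, nrow = length(groups), ncol = nrow(corr),
                dimnames = list(groups, NULL))
  for (g in groups) {
    sel <- grp == g & sel_ax
    if (sum(sel) < 2L)
      stop("group '", g, "' has fewer than 2 components on axes ",
           paste(axes, collapse = ","), call. = FALSE)
    sub <- corr[, sel, drop = FALSE]
    mu <- rowMeans(sub)
    out[g, ] <- rowMeans((sub - mu)^2)   # population variance
  }
  structure(list(values = out, segmentation = seg, axes = axes),
            class = "voc_series")
}

#' @export
print.voc_series <- function(x, ...) {
  cat("<voc_series> ", nrow(x$values), " groups x ", ncol(x$values),
      " cycles (axes ", paste(x$axes, collapse = ","), ")\n", sep = "")
  print(signif(x$values, 4))
  invisible(x)
}

#' Expand per-cycle VoC to a stepwise function of time
#'
#' Each cycle's VoC value is held constant over the cycle's frame span
#' `[t_i, t_i + tau_i)`, on the culled timeline; the original video frame of
#' each row is included for plotting against video time.
#'
#' @param v A `voc_series`.
#' @return Data frame with `frame` (culled timeline, 0-based),
#'   `video_frame` (original, 0-based), `cycle`, and one column per group.
#' @export
voc_timeseries <- function(v) {
  seg <- v$segmentation
  rows <- lapply(seq_along(seg$t), function(i) {
    fr <- seg$t[i] + seq_len(seg$tau[i]) - 1L
    df <- data.frame(frame = fr,
                     video_frame = seg$frame_index[fr + 1L] - 1L,
                     cycle = i - 1L)
    for (g in rownames(v$values)) df[[g]] <- v$values[g, i]
    df
  })
  do.call(rbind, rows)
}

#' Flag anomalous cycles from VoC peaks
#'
#' Cycles whose VoC exceeds `threshold` are flagged per group; consecutive
#' flagged cycles within a group are merged into one event. Labels
#' (slip/jump/stop/hesitation) are user annotations in the original
#' workflow, so flags carry the group, cycle span, peak VoC and frame span
#' only.
#'
#' @param v A `voc_series`.
#' @param threshold Non-negative VoC threshold.
#' @return Data frame of events: `group`, `cycle_start`, `cycle_end`
#'   (inclusive, 0-based), `frame_start`, `frame_end` (culled timeline),
#'   `peak_voc`.
#' @export
flag_events <- function(v, threshold) {
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  seg <- v$segmentation
  out <- list()
  for (g in rownames(v$values)) {
    hot <- v$values[g, ] > threshold
    if (!any(hot)) next
    r <- rle(hot)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      idx <- starts[k]:ends[k]
      out[[length(out) + 1L]] <- data.frame(
        group = g,
        cycle_start = starts[k] - 1L, cycle_end = ends[k] - 1L,
        frame_start = seg$t[starts[k]],
        frame_end = seg$t[ends[k]] + seg$tau[ends[k]] - 1L,
        peak_voc = max(v$values[g, idx]))
    }
  }
  if (length(out) == 0L)
    return(data.frame(group = character(0), cycle_start = integer(0),
                      cycle_end = integer(0), frame_start = integer(0),
                      frame_end = integer(0), peak_voc = numeric(0)))
  do.call(rbind, out)
}
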