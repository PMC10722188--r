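#' Specification of a synthetic beam-walking gait
#'
#' States the world the simulator generates: an 18-point mouse walking a
#' 60 cm beam at 30 fps with a stride period of about 20 frames, the feet
#' following a 2-3-3 support pattern (two stance feet, then three, then
#' three within each cycle). `support_pattern` lists, per sub-phase, the
#' feet that *swing* (defaults: diagonal pair FL+RR, then FR, then RL —
#' i.e. stance sets (FR,RL), (FL,RL,RR), (FL,FR,RR)); `mirror_lateral`
#' swaps left and right, reproducing the laterally mirrored pattern seen
#' between individual animals. Head, body and tail points advance smoothly
#' with small periodic oscillation. Tracking noise is Gaussian on
#' coordinates; anomalies (stop/jump/slip/phase_shift) can be injected per
#' cycle.
#'
#' @param period Stride period in frames (>= 8).
#' @param n_cycles Number of strides.
#' @param stride_cm Forward advance per stride (cm).
#' @param support_pattern List of character vectors: feet swinging in each
#'   sub-phase; every foot must swing exactly once per cycle.
#' @param phase_fractions Relative durations of the sub-phases (sums to 1).
#' @param amplitudes Named oscillation amplitudes (cm) for head/body/tail.
#' @param lift_cm Foot lift height during swing (cm).
#' @param noise_sd Gaussian tracking noise on coordinates (cm).
#' @param period_jitter Max per-cycle period deviation (frames, uniform).
#' @param anomalies List of anomaly descriptors, each
#'   `list(cycle =, type =, magnitude =, foot =)`; cycles are 1-based. See
#'   [inject_anomaly()].
#' @param mirror_lateral Swap left/right feet in the pattern.
#' @param fps Frame rate.
#' @param start_x Starting x of the hindquarters on the beam (cm).
#' @param seed RNG seed.
#' @export
gait_spec <- function(period = 20L, n_cycles = 10L, stride_cm = 5,
                      support_pattern = list(c("FL", "RR"), "FR", "RL"),
                      phase_fractions = c(0.3, 0.35, 0.35),
                      amplitudes = c(head = 0.25, body = 0.1, tail = 0.35),
                      lift_cm = 1, noise_sd = 0, period_jitter = 0L,
                      anomalies = list(), mirror_lateral = FALSE,
                      fps = 30, start_x = 3, seed = 1L) {
  if (period < 8L) stop("period must be at least 8 frames", call. = FALSE)
  if (any(unlist(amplitudes) < 0) || lift_cm < 0 || noise_sd < 0)
    stop("amplitudes and noise must be non-negative", call. = FALSE)
  if (mirror_lateral)   # swap only the side letter (second character)
    support_pattern <- lapply(support_pattern, function(s)
      paste0(substr(s, 1, 1), chartr("LR", "RL", substr(s, 2, 2))))
  feet <- unlist(support_pattern)
  if (any(duplicated(feet)))
    stop("invalid support pattern: foot in two simultaneous swing sets",
         call. = FALSE)
  if (!setequal(feet, c("FL", "FR", "RL", "RR")))
    stop("every foot must swing exactly once per cycle", call. = FALSE)
  if (length(anomalies) && any(vapply(anomalies, `[[`, numeric(1), "cycle") > n_cycles))
    stop("anomaly cycle index beyond n_cycles", call. = FALSE)
  structure(list(period = as.integer(period), n_cycles = as.integer(n_cycles),
                 stride_cm = stride_cm, support_pattern = support_pattern,
                 phase_fractions = phase_fractions / sum(phase_fractions),
                 amplitudes = amplitudes, lift_cm = lift_cm,
                 noise_sd = noise_sd, period_jitter = as.integer(period_jitter),
                 anomalies = anomalies, fps = fps, start_x = start_x,
                 seed = as.integer(seed)),
            class = "gait_spec")
}

# resting posture, cm; beam surface at y = 0, beam along x, z lateral
base_posture <- function(config, start_x = 3) {
  pts <- point_names(config)
  xyz <- rbind(
    left_ear_tip  = c(8.0, 3.6,  0.8),
    right_ear_tip = c(8.0, 3.6, -0.8),
    nose_tip      = c(9.5, 2.9,  0.0),
    body_1        = c(7.0, 3.2,  0.0),
    body_2        = c(5.0, 3.4,  0.0),
    body_3        = c(3.0, 3.3,  0.0),
    body_4        = c(1.0, 3.0,  0.0),
    tail_1        = c(0.0, 2.6,  0.1),
    tail_2        = c(-1.2, 2.3, 0.2),
    tail_3        = c(-2.4, 2.1, 0.3),
    tail_4        = c(-3.6, 2.0, 0.3),
    tail_5        = c(-4.8, 2.0, 0.2),
    tail_6        = c(-6.0, 2.1, 0.1),
    tail_7        = c(-7.2, 2.2, 0.0),
    foot_FL       = c(6.5, 0.0,  0.9),
    foot_FR       = c(6.5, 0.0, -0.9),
    foot_RL       = c(2.0, 0.0,  0.9),
    foot_RR       = c(2.0, 0.0, -0.9))
  if (!all(pts %in% rownames(xyz)))
    stop("base posture is defined for the default 18-point skeleton only",
         call. = FALSE)
  out <- xyz[pts, , drop = FALSE]
  out[, 1] <- out[, 1] + start_x
  out
}

# swing windows per foot as 0-based frame ranges within one period
swing_windows <- function(spec) {
  P <- spec$period
  bounds <- round(cumsum(c(0, spec$phase_fractions)) * P)
  bounds[length(bounds)] <- P
  wins <- list()
  for (ph in seq_along(spec$support_pattern))
    for (f in spec$support_pattern[[ph]])
      wins[[f]] <- c(bounds[ph], bounds[ph + 1])
  wins
}

# raised-cosine bump over w frames scaled to integrate to `total`
speed_bump <- function(w, total) {
  b <- (1 - cos(2 * pi * (seq_len(w) - 0.5) / w)) / 2
  b * total / sum(b)
}

# vertical speed of a foot lift: difference of a smooth height profile,
# zero net over the window
lift_speed <- function(w, lift) {
  h <- lift * (1 - cos(2 * pi * (0:w) / w)) / 2
  diff(h)
}

# one-period speed waveform, period x (18*3) components, canonical layout
base_cycle_waveform <- function(spec, config) {
  P <- spec$period
  np <- n_points(config)
  W <- matrix(0, P, np * 3)
  colnames(W) <- component_names(config, 3L)
  grp <- point_groups(config)
  pts <- point_names(config)
  vx_mean <- spec$stride_cm / P
  wins <- swing_windows(spec)
  tt <- seq_len(P) - 1L
  for (i in seq_len(np)) {
    cx <- 3L * (i - 1L)
    if (grp[i] == "feet") {
      f <- sub("foot_", "", pts[i])
      w0 <- wins[[f]][1]; w1 <- wins[[f]][2]
      idx <- (w0 + 1L):w1
      W[idx, cx + 1L] <- speed_bump(length(idx), spec$stride_cm)
      W[idx, cx + 2L] <- lift_speed(length(idx), spec$lift_cm)
    } else {
      a <- spec$amplitudes[[grp[i]]]
      # positional oscillation amplitude a => speed amplitude a * 2*pi/P;
      # phases staggered per point so the parts do not move in lockstep
      ph <- 2 * pi * (i %% 7) / 7
      W[, cx + 1L] <- vx_mean + a * 2 * pi / P * sin(2 * pi * tt / P + ph)
      W[, cx + 2L] <- 0.6 * a * 2 * pi / P * sin(2 * pi * tt / P + ph + pi / 3)
      W[, cx + 3L] <- 0.4 * a * 2 * pi / P * sin(2 * pi * tt / P + ph + 2 * pi / 3)
    }
  }
  W
}

#' Simulate a ground-truthed beam-walking gait
#'
#' Builds a one-period speed waveform from the spec (stance feet have zero
#' speed on the beam; swinging feet follow a smooth raised-cosine forward
#' bump with a vertical lift; head/body/tail drift forward with small
#' oscillations), tiles it over `n_cycles` strides (rescaling each cycle
#' when `period_jitter > 0`), integrates to 3D positions, injects the
#' requested anomalies, and finally adds Gaussian tracking noise. All
#' randomness is driven by `spec$seed`.
#'
#' @param spec A [gait_spec()].
#' @return List: `pose` (3D [pose_sequence()], cm) and `truth` — cycle
#'   starts `t` (0-based, speed timeline) and periods `tau`, the true
#'   one-period `waveform`, `swing` windows (0-based fractions of the
#'   period), the noise-free pose, base posture, and anomaly records.
#' @export
simulate_gait <- function(spec) {
  config <- default_mouse_config()
  x0 <- base_posture(config, spec$start_x)
  W <- base_cycle_waveform(spec, config)
  with_seed(spec$seed, {
    taus <- spec$period + (if (spec$period_jitter > 0)
      sample(-spec$period_jitter:spec$period_jitter, spec$n_cycles,
             replace = TRUE) else rep(0L, spec$n_cycles))
    V <- do.call(rbind, lapply(taus, function(tau) rescale_cycle(W, tau)))
    n_sp <- nrow(V)
    flat0 <- as.vector(t(cbind(x0)))   # point-major, axis-fastest
    pos <- rbind(flat0, matrix(flat0, n_sp, length(flat0), byrow = TRUE) +
                   apply(V, 2, cumsum))
    dimnames(pos) <- NULL
    pose <- unflatten_pose(pos, config, spec$fps, units = "cm")
    truth <- list(t = c(0L, cumsum(taus))[seq_len(spec$n_cycles)],
                  tau = taus, waveform = W,
                  swing = lapply(swing_windows(spec), function(w) w / spec$period),
                  posture = x0, anomalies = list(), spec = spec)
    for (an in spec$anomalies) {
      mod <- inject_anomaly(pose, truth, an)
      pose <- mod$pose; truth <- mod$truth
    }
    truth$pose_clean <- pose
    if (spec$noise_sd > 0)
      pose$coords <- pose$coords +
        array(stats::rnorm(length(pose$coords), 0, spec$noise_sd),
              dim = dim(pose$coords))
    list(pose = pose, truth = truth)
  })
}

#' Inject a gait anomaly into a simulated pose
#'
#' Supported types, all anchored to a 1-based cycle index from the ground
#' truth:
#' * `stop`: the animal freezes — `magnitude` frames repeating the
#'   cycle-start posture are inserted, lengthening the sequence.
#' * `slip`: the given `foot` (default RL) dips `magnitude` cm below the
#'   beam surface during its stance and recovers within the cycle.
#' * `jump`: both rear feet swing simultaneously in that cycle (sharing the
#'   earlier rear swing window) instead of alternating; net displacements
#'   are preserved, so later cycles are untouched.
#' * `phase_shift`: the `foot`'s within-cycle movement is circularly
#'   shifted by `magnitude` frames from that cycle onwards.
#'
#' @param pose A simulated 3D [pose_sequence()] (noise-free).
#' @param truth The matching ground-truth list from [simulate_gait()].
#' @param anomaly `list(cycle =, type =, magnitude =, foot =)`.
#' @return List with modified `pose` and updated `truth` (boundaries shift
#'   when frames are inserted; the anomaly is recorded in
#'   `truth$anomalies`).
#' @export
inject_anomaly <- function(pose, truth, anomaly) {
  type <- anomaly$type
  i <- anomaly$cycle
  mag <- anomaly$magnitude %||% 1
  if (is.null(type) || !(type %in% c("stop", "slip", "jump", "phase_shift")))
    stop("unknown anomaly type: ", type, call. = FALSE)
  if (is.null(i) || i < 1L || i > length(truth$t))
    stop("anomaly cycle out of range", call. = FALSE)
  if (mag == 0 && type != "jump") {
    truth$anomalies <- c(truth$anomalies, list(anomaly))
    return(list(pose = pose, truth = truth))
  }
  m <- flatten_pose(pose)
  t0 <- truth$t[i]; tau <- truth$tau[i]
  rows <- (t0 + 1L):(t0 + tau)          # speed rows of cycle i
  config <- pose$config
  pts <- point_names(config)

  foot_cols <- function(foot) {
    p <- match(paste0("foot_", foot), pts)
    3L * (p - 1L) + 1:3
  }
  win_of <- function(foot) {
    fr <- truth$swing[[foot]]
    w0 <- round(fr[1] * tau); w1 <- round(fr[2] * tau)
    (w0 + 1L):max(w1, w0 + 2L)
  }

  if (type == "stop") {
    k <- as.integer(mag)
    b <- t0 + 1L                         # posture at the cycle start
    m <- rbind(m[seq_len(b), , drop = FALSE],
               m[rep(b, k), , drop = FALSE],
               m[(b + 1L):nrow(m), , drop = FALSE])
    sel <- truth$t >= t0
    truth$t[sel] <- truth$t[sel] + k
    anomaly$at <- t0
  } else if (type == "slip") {
    # a slip disrupts the foot two ways: it dips below the beam surface
    # during what should be stance, and its footfall timing that cycle is
    # thrown off (the swing lands late), which is what the cycle-to-SWC
    # correlation actually sees
    foot <- anomaly$foot %||% "RL"
    cols <- foot_cols(foot)
    seg <- m[(t0 + 1L):(t0 + tau + 1L), cols, drop = FALSE]
    inc <- diff(seg)
    # disruption grows with slip severity: a deeper slip throws the
    # footfall further off schedule
    sh <- max(1L, round(tau * min(0.45, 0.15 * mag)))
    inc <- inc[((seq_len(tau) - 1L - sh) %% tau) + 1L, , drop = FALSE]
    m[(t0 + 2L):(t0 + tau + 1L), cols] <-
      rep(1, tau) %o% seg[1, ] + apply(inc, 2, cumsum)
    sw <- win_of(foot)
    stance <- setdiff(seq_len(tau - 1L), sw)   # keep the boundary frame intact
    # longest contiguous stance run carries the below-beam dip
    runs <- split(stance, cumsum(c(TRUE, diff(stance) != 1L)))
    run <- runs[[which.max(lengths(runs))]]
    w <- length(run)
    prof <- -mag * (1 - cos(2 * pi * (seq_len(w) - 0.5) / w)) / 2
    # position frames are speed rows + 1
    m[t0 + run + 1L, cols[2]] <- m[t0 + run + 1L, cols[2]] + prof
    anomaly$at <- t0
  } else if (type == "jump") {
    rear <- c("RL", "RR")
    wins <- lapply(rear, win_of)
    shared <- wins[[which.min(vapply(wins, min, numeric(1)))]]
    for (k in seq_along(rear)) {
      cols <- foot_cols(rear[k])
      seg <- m[(t0 + 1L):(t0 + tau + 1L), cols, drop = FALSE]
      inc <- diff(seg)
      net <- colSums(inc)
      inc[] <- 0
      inc[shared, 1] <- speed_bump(length(shared), net[1])
      inc[shared, 2] <- lift_speed(length(shared), truth$spec$lift_cm) +
        net[2] / length(shared)
      inc[shared, 3] <- net[3] / length(shared)
      m[(t0 + 2L):(t0 + tau + 1L), cols] <-
        rep(1, tau) %o% seg[1, ] + apply(inc, 2, cumsum)
    }
    anomaly$at <- t0
  } else if (type == "phase_shift") {
    foot <- anomaly$foot %||% "RL"
    cols <- foot_cols(foot)
    sh <- as.integer(mag)
    for (j in i:length(truth$t)) {
      tj <- truth$t[j]; tauj <- truth$tau[j]
      seg <- m[(tj + 1L):(tj + tauj + 1L), cols, drop = FALSE]
      inc <- diff(seg)
      inc <- inc[((seq_len(tauj) - 1L - sh) %% tauj) + 1L, , drop = FALSE]
      m[(tj + 2L):(tj + tauj + 1L), cols] <-
        rep(1, tauj) %o% seg[1, ] + apply(inc, 2, cumsum)
    }
    anomaly$at <- t0
  }
  truth$anomalies <- c(truth$anomalies, list(anomaly))
  list(pose = unflatten_pose(m, config, pose$fps, units = pose$units),
       truth = truth)
}

#' Stereo camera rig specification
#'
#' Two pinhole cameras pointed at the centre of the beam: the `"45"`
#' configuration places both near the start of the beam with optical axes at
#' 45 degrees to it (axes roughly perpendicular to each other — good
#' triangulation); the `"90"` configuration places them facing each other on
#' either side of the beam (opposed axes — no reliable triangulation, the
#' views are merged in 2D instead).
#'
#' @param configuration `"45"` or `"90"`.
#' @param focal_px Focal length in pixels.
#' @param image_size `c(width, height)` in pixels.
#' @param distance_cm Camera distance from the beam centre.
#' @param height_cm Camera height above the beam surface.
#' @export
stereo_rig <- function(configuration = c("45", "90"), focal_px = 1000,
                       image_size = c(1280, 720), distance_cm = 80,
                       height_cm = 6) {
  configuration <- match.arg(configuration)
  target <- c(30, 0, 0)
  if (configuration == "45") {
    off <- distance_cm / sqrt(2)
    CL <- c(30 - off, height_cm, off)
    CR <- c(30 - off, height_cm, -off)
  } else {
    CL <- c(30, height_cm, distance_cm)
    CR <- c(30, height_cm, -distance_cm)
  }
  structure(list(configuration = configuration, focal_px = focal_px,
                 image_size = image_size, centers = list(left = CL, right = CR),
                 target = target),
            class = "stereo_rig")
}

# 3x4 camera matrix looking from C at `target`, image y down
camera_matrix <- function(C, target, focal_px, image_size) {
  f <- target - C; f <- f / sqrt(sum(f^2))
  r <- cross3(f, c(0, 1, 0)); r <- r / sqrt(sum(r^2))
  d <- cross3(f, r)
  R <- rbind(r, d, f)
  K <- matrix(c(focal_px, 0, 0, 0, focal_px, 0,
                image_size[1] / 2, image_size[2] / 2, 1), 3, 3)
  K %*% cbind(R, -R %*% C)
}

project_points <- function(P, X) {
  h <- cbind(X, 1) %*% t(P)
  if (any(h[, 3] <= 0)) stop("point behind camera", call. = FALSE)
  h[, 1:2] / h[, 3]
}

# ground-truth 3D calibration segments; p1 -> p2 order fixes +x/+y/+z
calibration_lines_3d <- function() {
  list(
    beam = list(rbind(c(0, 0, 0), c(60, 0, 0)),
                rbind(c(0, -2.54, 0), c(60, -2.54, 0))),
    box_y = list(rbind(c(63, -5, 6), c(63, 10, 6)),
                 rbind(c(63, -5, -6), c(63, 10, -6))),
    box_z = list(rbind(c(63, 10, -6), c(63, 10, 6)),
                 rbind(c(63, -5, -6), c(63, -5, 6))))
}

#' Project a simulated 3D gait into a stereo pair
#'
#' Pinhole projection of every feature point and of the ground-truth
#' calibration segments into both cameras. Optional Gaussian pixel noise is
#' added to the tracked feature points; calibration lines are traced once on
#' static structure, so they get separate (default zero) noise.
#'
#' @param pose3d A 3D [pose_sequence()] in cm (beam frame).
#' @param rig A [stereo_rig()].
#' @param pixel_noise_sd Pixel noise on feature-point projections.
#' @param calib_noise_sd Pixel noise on calibration-line endpoints.
#' @param trace_order `"scene"` writes each segment's endpoints in their 3D
#'   order in both views (consistent tracing); `"image"` orders the beam
#'   endpoints left-to-right in each image, as a tracer working purely in
#'   image space would (opposed cameras then yield mirrored beam axes and
#'   [merge_90()] needs `mirror = "x"`).
#' @param seed RNG seed for the noise.
#' @return List: `poseL`, `poseR` (2D [pose_sequence()]s, px), `lines`
#'   (`calibration_lines`), `cameras` (true 3x4 matrices), `lines3d`.
#' @export
project_stereo <- function(pose3d, rig, pixel_noise_sd = 0,
                           calib_noise_sd = 0,
                           trace_order = c("scene", "image"), seed = 1L) {
  trace_order <- match.arg(trace_order)
  P <- list(left = camera_matrix(rig$centers$left, rig$target, rig$focal_px,
                                 rig$image_size),
            right = camera_matrix(rig$centers$right, rig$target, rig$focal_px,
                                  rig$image_size))
  lines3d <- calibration_lines_3d()
  nf <- n_frames(pose3d)
  np <- dim(pose3d$coords)[2]
  X <- matrix(aperm(pose3d$coords, c(2, 1, 3)), ncol = 3)  # (pt within frame) rows
  with_seed(seed, {
    out <- list()
    rows <- list()
    for (v in c("left", "right")) {
      x <- project_points(P[[v]], X)
      if (pixel_noise_sd > 0)
        x <- x + matrix(stats::rnorm(length(x), 0, pixel_noise_sd), ncol = 2)
      co <- array(NA_real_, dim = c(nf, np, 2))
      co[, , 1] <- matrix(x[, 1], nf, np, byrow = TRUE)
      co[, , 2] <- matrix(x[, 2], nf, np, byrow = TRUE)
      out[[v]] <- pose_sequence(co, pose3d$config, pose3d$fps, units = "px")
      for (lab in names(lines3d)) {
        for (s in 1:2) {
          e <- project_points(P[[v]], lines3d[[lab]][[s]])
          if (calib_noise_sd > 0)
            e <- e + matrix(stats::rnorm(4, 0, calib_noise_sd), ncol = 2)
          if (trace_order == "image" && lab == "beam" && e[1, 1] > e[2, 1])
            e <- e[2:1, , drop = FALSE]
          rows[[length(rows) + 1L]] <- data.frame(
            view = v, label = lab, line = s,
            x1 = e[1, 1], y1 = e[1, 2], x2 = e[2, 1], y2 = e[2, 2])
        }
      }
    }
    lines <- calibration_lines_from_df(do.call(rbind, rows))
    list(poseL = out$left, poseR = out$right, lines = lines,
         cameras = P, lines3d = lines3d)
  })
}

#' Drop the lateral component of a 3D pose
#'
#' Orthographic side view: keeps x (beam) and y (vertical), giving the 2D
#' layout the 90-degree pipeline produces.
#'
#' @param pose A 3D [pose_sequence()].
#' @export
pose_project_xy <- function(pose) {
  stopifnot(pose_dims(pose) == 3L)
  pose_sequence(pose$coords[, , 1:2, drop = FALSE], pose$config, pose$fps,
                units = pose$units)
}

#' Write a complete synthetic fixture to disk
#'
#' Emits everything a pipeline run needs: DeepLabCut-style tracking tables
#' for both views, the calibration-line file, a run-config JSON, and a
#' ground-truth sidecar JSON (cycle boundaries, anomalies, camera matrices).
#'
#' @param dir Output directory (created if needed).
#' @param sim Result of [simulate_gait()].
#' @param stereo Result of [project_stereo()] on `sim$pose`.
#' @param scale A [physical_scale()].
#' @return Named list of the file paths written.
#' @export
write_fixture <- function(dir, sim, stereo, scale = physical_scale()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    trackL = file.path(dir, "track_left.csv"),
    trackR = file.path(dir, "track_right.csv"),
    lines = file.path(dir, "calibration_lines.csv"),
    config = file.path(dir, "config.json"),
    truth = file.path(dir, "ground_truth.json"))
  write_tracking_table(stereo$poseL, paths$trackL)
  write_tracking_table(stereo$poseR, paths$trackR)
  write_calibration_lines(stereo$lines, paths$lines)
  cfg <- sim$truth$spec
  jsonlite::write_json(list(
    groups = sim$pose$config$groups, fps = cfg$fps,
    beam_length_cm = scale$beam_length_cm, incline_deg = scale$incline_deg,
    seed = cfg$seed), paths$config, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(
    cycle_start = sim$truth$t, cycle_period = sim$truth$tau,
    anomalies = sim$truth$anomalies,
    cameras = lapply(stereo$cameras, function(p) unclass(p)),
    waveform = sim$truth$waveform), paths$truth, auto_unbox = TRUE,
    digits = NA)
  paths
}
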