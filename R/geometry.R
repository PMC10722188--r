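#' @keywords internal
hom <- function(x) cbind(x, 1)

dehom <- function(X) X[, seq_len(ncol(X) - 1L), drop = FALSE] / X[, ncol(X)]

cross3 <- function(a, b) c(a[2]*b[3] - a[3]*b[2],
                           a[3]*b[1] - a[1]*b[3],
                           a[1]*b[2] - a[2]*b[1])

camera_centre <- function(P) svd(P, nu = 0, nv = 4)$v[, 4]

skew3 <- function(v) matrix(c(0, v[3], -v[2],
                              -v[3], 0, v[1],
                              v[2], -v[1], 0), 3, 3)

# Hartley normalization: translate centroid to origin, scale mean distance
# to sqrt(2); returns 3x3 transform for homogeneous points.
norm_transform <- function(x) {
  ctr <- colMeans(x)
  d <- sqrt(rowSums(sweep(x, 2, ctr)^2))
  s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
  matrix(c(s, 0, 0, 0, s, 0, -s * ctr[1], -s * ctr[2], 1), 3, 3)
}

# Linear 8-point fit (least squares over >= 8 normalized correspondences),
# rank-2 enforced. Returns NULL for degenerate configurations.
eight_point <- function(xL, xR) {
  TL <- norm_transform(xL); TR <- norm_transform(xR)
  hL <- hom(xL) %*% t(TL); hR <- hom(xR) %*% t(TR)
  A <- cbind(hR[, 1] * hL[, 1], hR[, 1] * hL[, 2], hR[, 1] * hL[, 3],
             hR[, 2] * hL[, 1], hR[, 2] * hL[, 2], hR[, 2] * hL[, 3],
             hR[, 3] * hL[, 1], hR[, 3] * hL[, 2], hR[, 3] * hL[, 3])
  sv <- svd(A, nu = 0, nv = 9)
  # F only determined up to scale when A has a 1D null space
  if (sv$d[8] < 1e-10 * sv$d[1]) return(NULL)
  F0 <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  s <- svd(F0)
  F0 <- s$u %*% diag(c(s$d[1:2], 0)) %*% t(s$v)
  Fd <- t(TR) %*% F0 %*% TL
  Fd / sqrt(sum(Fd^2))
}

#' Squared Sampson distances of correspondences under F
#' @param F 3x3 fundamental matrix.
#' @param xL,xR n x 2 matrices of corresponding image points (left, right).
#' @return Numeric vector of squared Sampson residuals.
#' @export
sampson_residual <- function(F, xL, xR) {
  hL <- hom(xL); hR <- hom(xR)
  FxL <- hL %*% t(F)          # rows: F %*% xL
  FtxR <- hR %*% F            # rows: t(F) %*% xR
  e <- rowSums(hR * FxL)      # xR' F xL
  e^2 / (FxL[, 1]^2 + FxL[, 2]^2 + FtxR[, 1]^2 + FtxR[, 2]^2)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Estimate the fundamental matrix by least median of squares
#'
#' Robust fit of the epipolar geometry from >= 8 point correspondences —
#' normally the 12 endpoints of the three traced calibration line pairs,
#' optionally augmented with tracked feature points. Random (or, when few
#' enough, exhaustive) minimal 8-point samples are fit with the normalized
#' 8-point algorithm; the sample minimizing the median squared Sampson
#' residual wins, and the fit is refined on the resulting inlier set.
#' Deterministic for a fixed seed.
#'
#' @param xL,xR n x 2 matrices of corresponding points (n >= 8).
#' @param n_samples Number of random minimal samples (exhaustive enumeration
#'   is used instead when it is cheaper).
#' @param seed RNG seed for sampling.
#' @return 3x3 rank-2 fundamental matrix, unit Frobenius norm, with
#'   attributes `residuals` (squared Sampson, all points) and `inliers`.
#' @export
estimate_fundamental <- function(xL, xR, n_samples = 500L, seed = 1L) {
  xL <- as.matrix(xL); xR <- as.matrix(xR)
  n <- nrow(xL)
  if (n < 8L || nrow(xR) != n)
    stop("need at least 8 correspondences in both views", call. = FALSE)
  samples <- if (n == 8L) {
    list(1:8)
  } else if (choose(n, 8) <= n_samples) {
    utils::combn(n, 8, simplify = FALSE)
  } else {
    with_seed(seed, replicate(n_samples, sample.int(n, 8L), simplify = FALSE))
  }
  best <- NULL; best_med <- Inf
  for (idx in samples) {
    Fi <- eight_point(xL[idx, , drop = FALSE], xR[idx, , drop = FALSE])
    if (is.null(Fi)) next
    med <- stats::median(sampson_residual(Fi, xL, xR))
    if (med < best_med) { best_med <- med; best <- Fi }
  }
  if (is.null(best))
    stop("degenerate configuration: no 8-point sample determines the ",
         "epipolar geometry", call. = FALSE)
  # robust scale and inlier refit
  res <- sampson_residual(best, xL, xR)
  sigma <- 1.4826 * (1 + 5 / (n - 8)) * sqrt(best_med)
  inl <- res <= max((2.5 * sigma)^2, 1e-12)
  if (sum(inl) >= 8L) {
    Fr <- eight_point(xL[inl, , drop = FALSE], xR[inl, , drop = FALSE])
    if (!is.null(Fr)) best <- Fr
  }
  res <- sampson_residual(best, xL, xR)
  structure(best, residuals = res, inliers = inl)
}

#' Fundamental matrix implied by a camera pair
#' @param P_L,P_R 3x4 camera matrices.
#' @return 3x3 rank-2 matrix, unit Frobenius norm.
#' @export
fundamental_from_cameras <- function(P_L, P_R) {
  C <- camera_centre(P_L)                   # left camera centre (null space)
  e2 <- as.vector(P_R %*% C)                # right epipole
  Pp <- svd(P_L)
  pinv <- Pp$v %*% diag(1 / Pp$d) %*% t(Pp$u)   # Moore-Penrose of P_L
  F <- skew3(e2) %*% P_R %*% pinv
  F / sqrt(sum(F^2))
}

#' Canonical camera pair from a fundamental matrix
#'
#' Fixes the left camera to the canonical `[I | 0]` and derives a compatible
#' right camera `[ [e']_x F | e' ]` from the right epipole, so that the
#' fundamental matrix recomputed from the pair equals the input up to scale.
#' The pair defines the scene in a projective frame; [metric_upgrade()]
#' straightens it.
#'
#' @param F 3x3 rank-2 fundamental matrix.
#' @return List with `P_L`, `P_R`.
#' @export
derive_camera_pair <- function(F) {
  s <- svd(F)
  if (s$d[3] > 1e-6 * s$d[1])
    stop("F has full rank; not a valid fundamental matrix", call. = FALSE)
  if (s$d[2] < 1e-10 * s$d[1])
    stop("degenerate F (rank < 2)", call. = FALSE)
  e2 <- s$u[, 3]                # left null vector of t(F): t(F) e2 = 0
  P_R <- cbind(skew3(e2) %*% F, e2)
  list(P_L = cbind(diag(3), 0), P_R = P_R)
}

#' Triangulate corresponding image points (DLT)
#'
#' Homogeneous linear triangulation of each correspondence; the reprojection
#' residual (mean over the two views, px) is attached per point. With
#' near-metric cameras the rays from the two camera centres are also
#' checked: when their median crossing angle is close to 0 or 180 degrees —
#' the opposed-camera 90-degree rig — intersections are unreliable and a
#' warning is raised.
#'
#' @param P_L,P_R 3x4 camera matrices.
#' @param xL,xR n x 2 image points.
#' @param check_rays Check ray crossing angles (only meaningful for metric
#'   cameras; disabled inside the projective stage of the pipeline).
#' @param min_ray_sin Warn when the median sine of the ray crossing angle is
#'   below this (default sin of ~5.7 degrees).
#' @param allow_infinite Return NA coordinates for points at infinity
#'   instead of raising an error (used when screening camera-pose
#'   candidates).
#' @return n x 3 matrix of 3D points with attribute `reprojection` (px).
#' @export
triangulate <- function(P_L, P_R, xL, xR, check_rays = TRUE,
                        min_ray_sin = 0.1, allow_infinite = FALSE) {
  xL <- matrix(xL, ncol = 2); xR <- matrix(xR, ncol = 2)
  n <- nrow(xL)
  X <- matrix(NA_real_, n, 4)
  for (i in seq_len(n)) {
    A <- rbind(xL[i, 1] * P_L[3, ] - P_L[1, ],
               xL[i, 2] * P_L[3, ] - P_L[2, ],
               xR[i, 1] * P_R[3, ] - P_R[1, ],
               xR[i, 2] * P_R[3, ] - P_R[2, ])
    if (!all(is.finite(A))) stop("non-finite image coordinates", call. = FALSE)
    X[i, ] <- svd(A, nu = 0, nv = 4)$v[, 4]
  }
  w <- X[, 4]
  bad <- abs(w) < 1e-12 * sqrt(rowSums(X^2))
  if (any(bad)) {
    if (!allow_infinite)
      stop("triangulated point at infinity (homogeneous w ~ 0)", call. = FALSE)
    w[bad] <- NA_real_
  }
  pts <- X[, 1:3, drop = FALSE] / w
  reproj <- function(P, x) {
    h <- cbind(pts, 1) %*% t(P)
    sqrt(rowSums((h[, 1:2] / h[, 3] - x)^2))
  }
  rp <- (reproj(P_L, xL) + reproj(P_R, xR)) / 2
  if (check_rays) {
    axL <- P_L[3, 1:3] / sqrt(sum(P_L[3, 1:3]^2))
    axR <- P_R[3, 1:3] / sqrt(sum(P_R[3, 1:3]^2))
    if (sqrt(sum(cross3(axL, axR)^2)) < 0.26)   # axes within ~15 deg of collinear
      warning("ill-conditioned triangulation: camera optical axes are ",
              "nearly collinear (opposed or coincident camera axes)")
    CL <- camera_centre(P_L); CR <- camera_centre(P_R)
    if (abs(CL[4]) > 1e-12 && abs(CR[4]) > 1e-12) {
      cL <- CL[1:3] / CL[4]; cR <- CR[1:3] / CR[4]
      rL <- pts - rep(1, n) %o% cL; rR <- pts - rep(1, n) %o% cR
      sins <- vapply(seq_len(n), function(i) {
        a <- rL[i, ]; b <- rR[i, ]
        na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
        if (na == 0 || nb == 0) return(1)
        sqrt(sum(cross3(a, b)^2)) / (na * nb)
      }, numeric(1))
      if (stats::median(sins) < min_ray_sin)
        warning("ill-conditioned triangulation: viewing rays are nearly ",
                "collinear (opposed or coincident camera axes)")
    }
  }
  structure(pts, reprojection = rp)
}

# Vanishing point of a traced parallel line pair in one image: intersection
# of the two homogeneous image lines.
vanishing_point <- function(pair) {
  l1 <- cross3(c(pair[1, 1, ], 1), c(pair[1, 2, ], 1))
  l2 <- cross3(c(pair[2, 1, ], 1), c(pair[2, 2, ], 1))
  v <- cross3(l1, l2)
  if (sqrt(sum(v^2)) < 1e-9 * sqrt(sum(l1^2)) * sqrt(sum(l2^2)))
    stop("degenerate calibration: coincident line pair (no vanishing point)",
         call. = FALSE)
  v
}

# Camera intrinsics from the vanishing points of three mutually orthogonal
# directions, assuming zero skew and square pixels: each orthogonal pair
# gives v_i' w v_j = 0 on the image of the absolute conic
# w = [w1 0 w2; 0 w1 w3; w2 w3 w4]; three pairs fix w up to scale and K
# follows from K K' = w^-1.
intrinsics_from_vps <- function(vps) {
  rows <- list()
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  for (p in pairs) {
    a <- vps[[p[1]]]; b <- vps[[p[2]]]
    rows[[length(rows) + 1L]] <-
      c(a[1] * b[1] + a[2] * b[2],
        a[1] * b[3] + a[3] * b[1],
        a[2] * b[3] + a[3] * b[2],
        a[3] * b[3])
  }
  A <- do.call(rbind, rows)
  w <- svd(A, nu = 0, nv = 4)$v[, 4]
  omega <- matrix(c(w[1], 0, w[2],
                    0, w[1], w[3],
                    w[2], w[3], w[4]), 3, 3)
  if (omega[1, 1] < 0) omega <- -omega
  S <- tryCatch(solve(omega), error = function(e) NULL)
  if (is.null(S))
    stop("degenerate calibration: absolute-conic system is singular",
         call. = FALSE)
  # factor S = K K' with K upper triangular (reverse Cholesky)
  J <- diag(3)[3:1, ]
  U <- tryCatch(chol(J %*% S %*% J), error = function(e) NULL)
  if (is.null(U))
    stop("degenerate calibration: intrinsics not positive definite ",
         "(vanishing points inconsistent with orthogonal directions)",
         call. = FALSE)
  K <- J %*% t(U) %*% J
  K / K[3, 3]
}

# Decompose an essential matrix and pick the (R, t) with both cameras
# looking at the scene (cheirality on reference image points).
pose_from_essential <- function(E, K_L, K_R, xL, xR) {
  s <- svd(E)
  W <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  cands <- list()
  for (Rc in list(s$u %*% W %*% t(s$v), s$u %*% t(W) %*% t(s$v))) {
    if (det(Rc) < 0) Rc <- -Rc
    for (tc in list(s$u[, 3], -s$u[, 3]))
      cands[[length(cands) + 1L]] <- list(R = Rc, t = tc)
  }
  P1 <- K_L %*% cbind(diag(3), 0)
  best <- NULL; best_front <- -1L
  for (cand in cands) {
    P2 <- K_R %*% cbind(cand$R, cand$t)
    X <- suppressWarnings(triangulate(P1, P2, xL, xR, check_rays = FALSE,
                                      allow_infinite = TRUE))
    d1 <- X[, 3]
    d2 <- (X %*% t(cand$R))[, 3] + cand$t[3]
    front <- sum(d1 > 0 & d2 > 0, na.rm = TRUE)
    if (front > best_front) { best_front <- front; best <- cand }
  }
  if (best_front <= 0)
    stop("essential-matrix decomposition found no pose with the scene in ",
         "front of both cameras", call. = FALSE)
  best
}

#' Metric upgrade from three pairs of parallel scene lines
#'
#' Replaces the projective camera pair with a metric one using only the
#' traced calibration lines: the beam edges, the outer goal-box edges and
#' the goal-box entrance edges are parallel pairs with mutually orthogonal
#' directions. Their vanishing points in each view determine the camera
#' intrinsics through the image of the absolute conic (zero skew, square
#' pixels assumed), the essential matrix then yields the relative camera
#' pose, and the reconstruction is rotated so the three directions align
#' with the axes — beam to x, box edges to y, entrance edges to z.
#' Direction signs follow the endpoint order in the calibration file, so
#' consistently traced files give a reproducible orientation.
#'
#' @param P_L,P_R Projective camera pair (from [derive_camera_pair()]); used
#'   for the epipolar geometry they encode.
#' @param lines A `calibration_lines` object ([read_calibration_lines()]).
#' @return List: upgraded metric `P_L`, `P_R`; `H` (4x4 homography mapping
#'   homogeneous points triangulated under the input pair to the upgraded
#'   frame, points map as `X %*% t(H)`); `lines3d` — per label, a
#'   `2 x 2 x 3` array of upgraded segment endpoints; `K_L`, `K_R`.
#' @export
metric_upgrade <- function(P_L, P_R, lines) {
  labs <- calibration_labels
  F <- fundamental_from_cameras(P_L, P_R)
  vps <- lapply(c(left = "left", right = "right"), function(v)
    lapply(lines[[v]][labs], vanishing_point))
  for (v in c("left", "right")) {
    vv <- vps[[v]]
    for (p in list(c(1, 2), c(1, 3), c(2, 3))) {
      a <- vv[[p[1]]] / sqrt(sum(vv[[p[1]]]^2))
      b <- vv[[p[2]]] / sqrt(sum(vv[[p[2]]]^2))
      if (sqrt(sum(cross3(a, b)^2)) < 1e-8)
        stop("degenerate calibration: two direction pairs share a ",
             "vanishing point in the ", v, " view", call. = FALSE)
    }
  }
  K_L <- intrinsics_from_vps(vps$left)
  K_R <- intrinsics_from_vps(vps$right)
  E <- t(K_R) %*% F %*% K_L
  # reference correspondences: the 12 traced endpoints
  ep <- function(v) do.call(rbind, lapply(lines[[v]][labs], function(a)
    rbind(a[1, 1, ], a[1, 2, ], a[2, 1, ], a[2, 2, ])))
  xL <- ep("left"); xR <- ep("right")
  pose <- pose_from_essential(E, K_L, K_R, xL, xR)
  P1 <- K_L %*% cbind(diag(3), 0)
  P2 <- K_R %*% cbind(pose$R, pose$t)
  seg <- suppressWarnings(triangulate(P1, P2, xL, xR, check_rays = FALSE))
  # direction of each pair (mean of its two line directions, oriented by
  # the traced endpoint order), then the closest rotation taking them to
  # the coordinate axes
  dirs <- matrix(0, 3, 3)
  for (k in seq_along(labs)) {
    r <- seg[(4 * k - 3):(4 * k), , drop = FALSE]
    d1 <- r[2, ] - r[1, ]; d2 <- r[4, ] - r[3, ]
    if (sum(d1 * d2) < 0) d2 <- -d2
    d <- d1 / sqrt(sum(d1^2)) + d2 / sqrt(sum(d2^2))
    dirs[, k] <- d / sqrt(sum(d^2))
  }
  sv <- svd(dirs)
  if (sv$d[3] < 1e-3 * sv$d[1])
    stop("degenerate calibration: line-pair directions are nearly ",
         "coplanar; metric upgrade underdetermined", call. = FALSE)
  Q <- sv$v %*% t(sv$u)                  # rotation with Q %*% dirs ~ I
  Hrot <- rbind(cbind(Q, 0), c(0, 0, 0, 1))
  P_Lm <- P1 %*% solve(Hrot); P_Rm <- P2 %*% solve(Hrot)
  segq <- seg %*% t(Q)
  lines3d <- list()
  for (k in seq_along(labs)) {
    q <- segq[(4 * k - 3):(4 * k), , drop = FALSE]
    a <- array(NA_real_, dim = c(2, 2, 3),
               dimnames = list(NULL, c("p1", "p2"), c("x", "y", "z")))
    a[1, 1, ] <- q[1, ]; a[1, 2, ] <- q[2, ]
    a[2, 1, ] <- q[3, ]; a[2, 2, ] <- q[4, ]
    lines3d[[labs[k]]] <- a
  }
  # homography from the input projective frame to the upgraded frame,
  # fitted on the reference endpoints (for the record; points triangulated
  # with the upgraded cameras need no further mapping)
  seg_proj <- suppressWarnings(triangulate(P_L, P_R, xL, xR,
                                           check_rays = FALSE))
  H <- fit_homography_3d(hom(seg_proj), hom(segq))
  list(H = H, P_L = P_Lm / sqrt(sum(P_Lm^2)), P_R = P_Rm / sqrt(sum(P_Rm^2)),
       lines3d = lines3d, K_L = K_L, K_R = K_R)
}

# Least-squares 4x4 homography X2 ~ H X1 from >= 5 homogeneous point pairs
# (DLT with per-pair scale elimination via cross products of coordinates).
fit_homography_3d <- function(X1, X2) {
  n <- nrow(X1)
  rows <- list()
  for (i in seq_len(n)) {
    x <- X1[i, ]; y <- X2[i, ]
    for (a in 1:3) for (b in (a + 1):4) {
      r <- numeric(16)
      r[(a - 1) * 4 + 1:4] <- y[b] * x
      r[(b - 1) * 4 + 1:4] <- -y[a] * x
      rows[[length(rows) + 1L]] <- r
    }
  }
  A <- do.call(rbind, rows)
  h <- svd(A, nu = 0, nv = 16)$v[, 16]
  matrix(h, 4, 4, byrow = TRUE)
}

#' Physical scale and inclination parameters
#' @param beam_length_cm Physical length of the traced beam section (cm).
#' @param incline_deg Beam inclination above horizontal, degrees, in [0, 90).
#' @export
physical_scale <- function(beam_length_cm = 60, incline_deg = 0) {
  if (beam_length_cm <= 0) stop("beam_length_cm must be positive", call. = FALSE)
  if (incline_deg < 0 || incline_deg >= 90)
    stop("incline_deg must be in [0, 90)", call. = FALSE)
  structure(list(beam_length_cm = beam_length_cm, incline_deg = incline_deg),
            class = "physical_scale")
}

#' Map a beam-aligned reconstruction to physical units
#'
#' The metric upgrade leaves two distortions: an unknown global scale, and a
#' shear introduced by forcing the (truly vertical) box edges perpendicular
#' to the (inclined) beam. With inclination angle theta the exact correction
#' in the beam-vertical plane is `x <- x + y*sin(theta)`, `y <- y*cos(theta)`
#' (identity at theta = 0). The uniform scale is then set so the
#' reconstructed beam segment has its measured physical length, and the
#' origin is moved to the beam segment's start.
#'
#' @param points3d n x 3 matrix of reconstructed points (beam along x).
#' @param scale A [physical_scale()].
#' @param beam_endpoints_3d `2 x 2 x 3` array of the reconstructed beam-edge
#'   segments (from `metric_upgrade()$lines3d$beam`).
#' @return n x 3 matrix in cm, with attribute `scale_factor`.
#' @export
apply_physical_scale <- function(points3d, scale, beam_endpoints_3d) {
  th <- scale$incline_deg * pi / 180
  shear <- function(p) {
    cbind(p[, 1] + p[, 2] * sin(th), p[, 2] * cos(th), p[, 3])
  }
  b <- beam_endpoints_3d
  a0 <- (b[1, 1, ] + b[2, 1, ]) / 2      # beam axis start (edge midpoint)
  a1 <- (b[1, 2, ] + b[2, 2, ]) / 2
  seg <- shear(rbind(a0, a1))
  L <- sqrt(sum((seg[2, ] - seg[1, ])^2))
  if (L < 1e-12) stop("zero-length reconstructed beam", call. = FALSE)
  s <- scale$beam_length_cm / L
  out <- (shear(as.matrix(points3d)) - rep(1, nrow(points3d)) %o% seg[1, ]) * s
  attr(out, "scale_factor") <- s
  out
}

#' Reconstruct 3D postures from a 45-degree stereo pair
#'
#' Full autocalibrated pipeline: fundamental matrix from the traced
#' calibration-line endpoints (least median of squares), canonical camera
#' pair, per-frame DLT triangulation of every feature point, metric upgrade
#' from the line pairs, and physical scaling — yielding per-frame 3D
#' coordinates in cm with the beam along +x, y up (against the incline) and
#' z lateral.
#'
#' @param poseL,poseR 2D [pose_sequence()]s from the left and right cameras,
#'   same skeleton.
#' @param lines `calibration_lines` traced in both views.
#' @param scale A [physical_scale()].
#' @param frame_offset Integer frame shift of the right video relative to
#'   the left (frame t of left matches frame t + offset of right).
#' @param seed Seed for the LMS sampling.
#' @return A 3D [pose_sequence()] (cm); attributes `model` (cameras, H, F,
#'   upgraded calibration lines) and `reprojection` (per frame x point, px).
#' @export
reconstruct_45 <- function(poseL, poseR, lines, scale, frame_offset = 0L,
                           seed = 1L) {
  if (!identical(point_names(poseL$config), point_names(poseR$config)))
    stop("left and right sequences use different skeletons", call. = FALSE)
  mL <- flatten_pose(poseL); mR <- flatten_pose(poseR)
  if (frame_offset > 0) {
    mR <- mR[-seq_len(frame_offset), , drop = FALSE]
  } else if (frame_offset < 0) {
    mL <- mL[-seq_len(-frame_offset), , drop = FALSE]
  }
  nf <- min(nrow(mL), nrow(mR))
  if (nrow(mL) != nrow(mR))
    stop("frame counts differ after applying frame_offset (",
         nrow(mL), " vs ", nrow(mR), ")", call. = FALSE)
  # correspondences: the 12 traced line endpoints
  ptsv <- function(v) do.call(rbind, lapply(lines[[v]], function(a)
    rbind(a[1, 1, ], a[1, 2, ], a[2, 1, ], a[2, 2, ])))
  F <- estimate_fundamental(ptsv("left"), ptsv("right"), seed = seed)
  cams <- derive_camera_pair(F)
  mu <- metric_upgrade(cams$P_L, cams$P_R, lines)

  np <- n_points(poseL$config)
  co <- array(NA_real_, dim = c(nf, np, 3))
  rp <- matrix(NA_real_, nf, np)
  warned <- FALSE
  for (t in seq_len(nf)) {
    xL <- matrix(mL[t, ], ncol = 2, byrow = TRUE)
    xR <- matrix(mR[t, ], ncol = 2, byrow = TRUE)
    X <- withCallingHandlers(
      triangulate(mu$P_L, mu$P_R, xL, xR, check_rays = (t == 1L)),
      warning = function(w) {
        warned <<- TRUE
        invokeRestart("muffleWarning")
      })
    co[t, , ] <- apply_physical_scale(X, scale, mu$lines3d$beam)
    rp[t, ] <- attr(X, "reprojection")
  }
  if (warned)
    warning("ill-conditioned triangulation: viewing rays are nearly ",
            "collinear (opposed or coincident camera axes)")
  out <- pose_sequence(co, poseL$config, poseL$fps, units = "cm")
  attr(out, "model") <- list(F = F, P_L = mu$P_L, P_R = mu$P_R, H = mu$H,
                             K_L = mu$K_L, K_R = mu$K_R, lines3d = mu$lines3d)
  attr(out, "reprojection") <- rp
  out
}

# 2D view alignment for the 90-degree pipeline: rotate/translate image
# points into beam coordinates (x along the traced beam, y up) and scale to
# cm using the traced beam length.
align_view_2d <- function(m, beam_pair, beam_length_cm) {
  a0 <- (beam_pair[1, 1, ] + beam_pair[2, 1, ]) / 2
  a1 <- (beam_pair[1, 2, ] + beam_pair[2, 2, ]) / 2
  d <- a1 - a0
  L <- sqrt(sum(d^2))
  d <- d / L
  n <- c(d[2], -d[1])          # image y points down; this makes +y up
  s <- beam_length_cm / L
  np2 <- ncol(m) / 2
  out <- m
  for (p in seq_len(np2)) {
    px <- m[, 2 * p - 1] - a0[1]
    py <- m[, 2 * p] - a0[2]
    out[, 2 * p - 1] <- (px * d[1] + py * d[2]) * s
    out[, 2 * p] <- (px * n[1] + py * n[2]) * s
  }
  out
}

#' Merge opposed 90-degree views by averaging
#'
#' Each view is rotated into beam coordinates (x along its traced beam
#' segment, y up) and scaled to cm; because the cameras face each other one
#' view is a mirror image, so its x axis is reflected about the beam
#' midpoint (`mirror = "x"`, the default) before the per-point, per-frame
#' arithmetic mean. If the views disagree in walking direction after
#' alignment — matched foot x-speed components anti-correlated, as happens
#' when the mirror flag is wrong for how the lines were traced — a warning
#' is raised.
#'
#' @param poseL,poseR 2D [pose_sequence()]s from the opposed cameras.
#' @param lines `calibration_lines` with the beam traced in both views.
#' @param scale A [physical_scale()] (only the beam length is used; the 2D
#'   views are assumed perpendicular to the beam so no shear applies).
#' @param frame_offset Frame shift of the right video relative to the left.
#' @param mirror `"x"` to reflect the right view's beam axis (opposed
#'   cameras, lines traced in image order), `"none"` when the lines were
#'   traced in consistent walking order in both views.
#' @return A 2D [pose_sequence()] in cm (x along beam, y up).
#' @export
merge_90 <- function(poseL, poseR, lines, scale, frame_offset = 0L,
                     mirror = c("x", "none")) {
  mirror <- match.arg(mirror)
  if (!identical(point_names(poseL$config), point_names(poseR$config)))
    stop("left and right sequences use different skeletons", call. = FALSE)
  if (pose_dims(poseL) != 2L || pose_dims(poseR) != 2L)
    stop("merge_90 expects 2D sequences", call. = FALSE)
  mL <- flatten_pose(poseL); mR <- flatten_pose(poseR)
  if (frame_offset > 0) mR <- mR[-seq_len(frame_offset), , drop = FALSE]
  if (frame_offset < 0) mL <- mL[-seq_len(-frame_offset), , drop = FALSE]
  if (nrow(mL) != nrow(mR))
    stop("frame counts differ after applying frame_offset (",
         nrow(mL), " vs ", nrow(mR), ")", call. = FALSE)
  L <- scale$beam_length_cm
  aL <- align_view_2d(mL, lines$left$beam, L)
  aR <- align_view_2d(mR, lines$right$beam, L)
  if (mirror == "x") {
    xcols <- seq(1, ncol(aR), by = 2)
    aR[, xcols] <- L - aR[, xcols]
  }
  # consistency check: matched foot x-speeds must co-vary across views
  grp <- component_groups(poseL$config, 2L)
  ax <- component_axes(poseL$config, 2L)
  sel <- which(grp == "feet" & ax == "x")
  if (nrow(aL) >= 3L) {
    cors <- vapply(sel, function(j) {
      vl <- diff(aL[, j]); vr <- diff(aR[, j])
      if (stats::sd(vl) == 0 || stats::sd(vr) == 0) return(NA_real_)
      stats::cor(vl, vr)
    }, numeric(1))
    if (all(is.finite(cors)) && mean(cors) < 0)
      warning("left/right foot components are anti-correlated across views; ",
              "check the mirror setting (views appear mirror-inconsistent)")
  }
  unflatten_pose((aL + aR) / 2, poseL$config, poseL$fps, units = "cm")
}
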