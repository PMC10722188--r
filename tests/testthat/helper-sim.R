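# shared fixtures built in code: small simulated gaits and stereo projections

sim_clean <- function(seed = 1L, n_cycles = 10L, ...) {
  simulate_gait(gait_spec(seed = seed, n_cycles = n_cycles, ...))
}

speed_of <- function(sim) compute_speed(sim$pose)

# align a reconstruction to ground truth by a single global translation and
# return the RMS error in cm
rms_vs_truth <- function(rec_pose, truth_pose) {
  A <- apply(rec_pose$coords, 3, c)
  B <- apply(truth_pose$coords, 3, c)
  off <- colMeans(A) - colMeans(B)
  sqrt(mean((sweep(A, 2, off) - B)^2))
}

tiny_pose <- function(frames = 10, dims = 2, fps = 30, fill = NULL) {
  cfg <- default_mouse_config()
  co <- array(seq_len(frames * 18 * dims) / 10, dim = c(frames, 18, dims))
  if (!is.null(fill)) co[] <- fill
  pose_sequence(co, cfg, fps)
}
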