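setup_voc <- function(seed = 1, anomalies = list(), noise_sd = 0) {
  sim <- simulate_gait(gait_spec(seed = seed, anomalies = anomalies,
                                 noise_sd = noise_sd))
  sp <- speed_of(sim)
  seg <- suppressWarnings(
    segment_cycles(sp, select_template(sp, 0, 20), method = "dp"))
  swc <- suppressWarnings(compute_swc(sp, seg))
  list(sim = sim, sp = sp, seg = seg, swc = swc)
}

test_that("correlation semantics: match 1, zero 0, negated -1, doubled 2", {
  s <- setup_voc()
  # build a series containing the SWC itself, then scaled variants
  v <- rbind(s$swc$values, 2 * s$swc$values, -s$swc$values, 0 * s$swc$values)
  sp <- speed_series(v, s$swc$config, 30, 3L)
  seg <- structure(list(t = c(0L, 20L, 40L, 60L), tau = rep(20L, 4),
                        score = rep(1, 4), tau0 = 20L,
                        frame_index = seq_len(nrow(v))),
                   class = "cycle_segmentation")
  cm <- correlation_matrix(sp, s$swc, seg)
  live <- colSums(s$swc$values^2) > 0
  expect_lt(max(abs(cm[1, live] - 1)), 1e-9)
  expect_lt(max(abs(cm[2, live] - 2)), 1e-9)
  expect_lt(max(abs(cm[3, live] + 1)), 1e-9)
  expect_true(all(cm[4, ] == 0))
  expect_true(all(cm[, !live] == 0))
  expect_setequal(attr(cm, "zero_norm"), colnames(s$swc$values)[!live])
  expect_error(correlation_matrix(sp, s$swc,
                                  structure(list(t = integer(0)),
                                            class = "cycle_segmentation")),
               "empty")
})

test_that("VoC is a population variance per group, non-negative, 0 at uniformity", {
  cfg <- default_mouse_config()
  seg <- structure(list(t = 0L, tau = 20L, score = 1, tau0 = 20L,
                        frame_index = 1:20), class = "cycle_segmentation")
  mk <- function(vals) structure(matrix(vals, nrow = 1, ncol = 36,
                                        dimnames = list(NULL, component_names(cfg, 2))),
                                 class = c("correlation_matrix", "matrix"),
                                 segmentation = seg)
  uni <- voc(mk(rep(0.7, 36)), cfg)
  expect_true(all(uni$values == 0))
  # feet group (8 xy components): half 0, half 2 -> population variance 1
  vals <- rep(0.5, 36)
  grp <- component_groups(cfg, 2)
  vals[grp == "feet"] <- rep(c(0, 2), 4)
  v <- voc(mk(vals), cfg)
  expect_equal(unname(v$values["feet", 1]), 1)
  expect_equal(unname(v$values["head", 1]), 0)

  # property: non-negative and scales quadratically, over random matrices
  set.seed(42)
  for (i in 1:200) {
    m <- mk(rnorm(36, sd = runif(1, 0.1, 3)))
    vv <- voc(m, cfg)
    expect_true(all(vv$values >= 0))
    c2 <- m; c2[] <- 3 * unclass(m)
    expect_equal(unname(voc(c2, cfg)$values), unname(9 * vv$values),
                 tolerance = 1e-9)
  }
})

test_that("VoC on normal simulated gait is ~0 and XY-only by default", {
  s <- setup_voc()
  cm <- correlation_matrix(s$sp, s$swc, s$seg)
  v <- voc(cm, s$swc$config)
  expect_lt(max(v$values), 1e-12)
  expect_identical(v$axes, c("x", "y"))
  v3 <- voc(cm, s$swc$config, axes = c("x", "y", "z"))
  expect_equal(dim(v3$values), dim(v$values))
  ts <- voc_timeseries(v)
  expect_equal(nrow(ts), sum(s$seg$tau))
  expect_true(all(diff(ts$frame) == 1))
})

test_that("an injected slip maximizes feet VoC at the right cycle; flags fire", {
  s <- setup_voc(seed = 5, noise_sd = 0.05,
                 anomalies = list(list(cycle = 6, type = "slip",
                                       magnitude = 1.5, foot = "RL")))
  cm <- correlation_matrix(s$sp, s$swc, s$seg)
  v <- voc(cm, s$swc$config)
  expect_equal(which.max(v$values["feet", ]), 6L)
  ev <- flag_events(v, threshold = max(v$values["feet", ]) / 2)
  feet_ev <- ev[ev$group == "feet", ]
  expect_gte(nrow(feet_ev), 1L)
  expect_true(any(feet_ev$cycle_start <= 5 & feet_ev$cycle_end >= 5))

  quiet <- setup_voc()
  vq <- voc(correlation_matrix(quiet$sp, quiet$swc, quiet$seg), quiet$swc$config)
  expect_equal(nrow(flag_events(vq, threshold = 0.1)), 0L)
  expect_error(flag_events(vq, threshold = -1), ">= 0")
})

test_that("a jump (both rear feet together) is flagged at its cycle", {
  s <- setup_voc(seed = 2,
                 anomalies = list(list(cycle = 4, type = "jump")))
  v <- voc(correlation_matrix(s$sp, s$swc, s$seg), s$swc$config)
  expect_equal(which.max(v$values["feet", ]), 4L)
})

test_that("feet VoC grows with per-foot perturbation magnitude", {
  # one foot's movement scaled by (1 + m) within a cycle: its correlation
  # moves to 1 + m while the other feet stay near 1, so the group variance
  # must grow with m, noise notwithstanding (20 seeds, 3 levels)
  cache <- lapply(1:20, function(s) setup_voc(seed = s, noise_sd = 0.05))
  means <- sapply(c(0.2, 0.5, 1.0), function(m) {
    mean(sapply(cache, function(st) {
      sp <- st$sp
      cols <- grepl("^foot_RL", colnames(sp$values))
      rows <- (st$seg$t[5] + 1L):(st$seg$t[5] + st$seg$tau[5])
      sp$values[rows, cols] <- (1 + m) * sp$values[rows, cols]
      v <- voc(correlation_matrix(sp, st$swc, st$seg), st$swc$config)
      v$values["feet", 5]
    }))
  })
  expect_true(all(diff(means) > 0))
})
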