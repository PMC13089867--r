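test_that("embed_geometry reproduces the target distances exactly", {
  g <- fixture_graph()
  target <- unclass(affordance_rdm(g))
  P <- embed_geometry(target, n_voxels = 30, scale = 1, seed = 1)
  D <- as.matrix(dist(P))^2
  expect_lt(max(abs(D - target)), 1e-9)
  # arbitrary scale
  P2 <- embed_geometry(target, 30, scale = 2.5, seed = 1)
  expect_lt(max(abs(as.matrix(dist(P2))^2 - 2.5 * target)), 1e-9)
  # scale zero collapses all conditions
  P0 <- embed_geometry(target, 30, scale = 0)
  expect_equal(max(abs(P0)), 0)
  # patterns are centred across conditions
  expect_lt(max(abs(colMeans(P))), 1e-12)
})

test_that("non-Euclidean mixtures are rejected", {
  g <- fixture_graph()
  bad <- unclass(affordance_rdm(g)) - 5 * unclass(magnitude_rdm(g))
  expect_error(embed_geometry(bad, 20), "not-euclidean-embeddable")
})

test_that("noiseless BOLD yields betas equal to the true patterns", {
  g <- fixture_graph()
  cfg <- scaled_fmri_config(signal_scale = 2)
  cfg$noise <- list(noise_sd = 0, ar_coef = 0, spatial_range = 0,
                    run_jitter_sd = 0)
  ds <- simulate_subject_fmri(g, cfg, seed = 31)
  fit <- fit_glm(ds$runs[[1]]$bold, ds$runs[[1]]$design)
  expect_lt(max(abs(fit$betas - ds$patterns)), 1e-6)
  # and the crossnobis RDM equals the generating geometry / P
  est <- estimate_neural_rdm(ds$runs, cfg$TR, cov_mode = "identity")
  target <- 2 * unclass(affordance_rdm(g)) / cfg$n_voxels
  expect_lt(max(abs(unclass(est$rdm) - target)), 1e-6)
})

test_that("simulation is seed-deterministic", {
  g <- fixture_graph()
  cfg <- scaled_fmri_config(signal_scale = 1)
  a <- simulate_subject_fmri(g, cfg, seed = 8)
  b <- simulate_subject_fmri(g, cfg, seed = 8)
  expect_identical(a$runs[[2]]$bold, b$runs[[2]]$bold)
  cfgg <- scaled_gaze_config()
  ev <- generate_run_sequence(g, "eyetracker", n_trials = 20, n_probe = 4,
                              isi_models = list(), stim_duration = 1, seed = 2)
  s1 <- simulate_subject_gaze(ev, cfgg, seed = 9)
  s2 <- simulate_subject_gaze(ev, cfgg, seed = 9)
  expect_identical(s1, s2)
  d1 <- simulate_subject(g, scaled_fmri_config(1), seed = 4, gaze = FALSE)
  d2 <- simulate_subject(g, scaled_fmri_config(1), seed = 4, gaze = FALSE)
  expect_identical(d1$fmri$runs[[1]]$bold, d2$fmri$runs[[1]]$bold)
})

test_that("gaze streams carry the planted lateralization and blinks", {
  g <- fixture_graph()
  ev <- generate_run_sequence(g, "eyetracker", n_trials = 20, n_probe = 4,
                              isi_models = list(), stim_duration = 1, seed = 5)
  cfg <- scaled_gaze_config(noise_sd_px = 0.5, blink_rate_hz = 0)
  st <- simulate_subject_gaze(ev, cfg, shift_px = 25, seed = 6)
  expect_false(any(st$blink))
  lat <- estimate_gaze_lateralization(list(list(events = ev, stream = st)))
  mid <- lat$diff$time_ms > 1100 & lat$diff$time_ms < 1600
  # state 2 shifted +25 px, state 3 -25 px: difference about 50 px
  expect_lt(abs(mean(lat$diff$diff[mid]) - 50), 5)
  out <- lat$diff$time_ms < 800 & lat$diff$time_ms > 0
  expect_lt(abs(mean(lat$diff$diff[out])), 5)
  # blinks appear at a positive rate and are flagged
  st2 <- simulate_subject_gaze(ev, scaled_gaze_config(blink_rate_hz = 0.5),
                               seed = 7)
  expect_gt(sum(st2$blink), 0)
})

test_that("behavior respects accuracy, truncation and state-dependent RTs", {
  g <- fixture_graph()
  cfg <- scaled_fmri_config()
  evs <- lapply(1:30, function(r) {
    generate_run_sequence(g, "fmri", n_trials = 20, n_probe = 4,
                          isi_models = list(), stim_duration = 1, run = r)
  })
  set.seed(41)
  beh <- simulate_behavior(evs, cfg, accuracy = 1)
  expect_true(all(beh$correct[!beh$missed]))
  expect_true(all(beh$rt[!beh$missed] <= 1.4))
  expect_true(all(is.na(beh$rt[beh$missed])))
  # RT RDM recovers the planted state means in expectation
  cfg$behavior$rt_mean <- c(0.5, 0.7, 0.7, 0.5)
  cfg$behavior$rt_sd <- 0.05
  beh2 <- simulate_behavior(evs, cfg, seed = 42)
  rt <- tapply(beh2$rt, beh2$state, mean, na.rm = TRUE)
  v <- rdm_vec(behavior_rdm(rt))
  expect_lt(max(abs(v - c(0.2, 0.2, 0, 0, 0.2, 0.2))), 0.06)
})

test_that("gaze streams round-trip through the TSV writer", {
  g <- fixture_graph()
  ev <- generate_run_sequence(g, "eyetracker", n_trials = 12, n_probe = 4,
                              isi_models = list(), stim_duration = 1, seed = 3)
  st <- simulate_subject_gaze(ev, scaled_gaze_config(), seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gaze_tsv(st, path)
  back <- read_gaze_tsv(path)
  expect_equal(as.data.frame(back), as.data.frame(st), tolerance = 1e-12)
})
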