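# shared fixtures: a standard graph and down-scaled generative configs used
# across simulation-heavy tests

fixture_graph <- function(n_modules = 2) build_graph(21, n_modules)

# small fMRI config: 4 runs of 20 trials (16 stimulus, 4 per condition),
# 24 voxels; signal_scale = 6 is the calibrated operating point giving a
# subject-level mean partial affordance correlation near 0.4 at this size
scaled_fmri_config <- function(signal_scale = 0, ...) {
  generative_config(n_runs = 4, n_trials = 20, n_probe = 4, n_voxels = 24,
                    isi_constraint = FALSE, stim_duration = 1,
                    signal_scale = signal_scale, ...)
}

# small eyetracking config: one run of 20 trials at 500 Hz
scaled_gaze_config <- function(...) {
  generative_config(n_runs_eye = 1, n_trials = 20, n_probe = 4,
                    isi_constraint = FALSE, stim_duration = 1,
                    gaze = list(sampling_rate_hz = 500, ...))
}

# one simulated subject's crossnobis RDM under the scaled fMRI config
simulate_scaled_rdm <- function(graph, cfg) {
  ds <- simulate_subject_fmri(graph, cfg)
  estimate_neural_rdm(ds$runs, cfg$TR)$rdm
}

# per-subject gaze lateralization timecourse under the scaled gaze config
simulate_scaled_diff <- function(graph, cfg, shift_px) {
  ev <- generate_run_sequence(graph, "eyetracker", n_trials = cfg$n_trials,
                              n_probe = cfg$n_probe, isi_models = list(),
                              stim_duration = cfg$stim_duration)
  st <- simulate_subject_gaze(ev, cfg, shift_px = shift_px)
  estimate_gaze_lateralization(list(list(events = ev, stream = st)))$diff
}
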