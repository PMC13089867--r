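#' Generative configuration for synthetic participants
#'
#' Bundles every parameter of the synthetic cohort generator. Defaults
#' mirror the study conditions: 8 scanner runs (4 during eyetracking) of 80
#' trials with 16 probes, a TR of 1 s, an entorhinal-sized ROI of 140
#' voxels, a purely affordance-weighted pattern geometry, a rightward gaze
#' shift for the positive-affording state inside the 899-1757 ms window at
#' 1000 Hz, and probe behaviour with state-dependent reaction times (states
#' 1/4 slower than 2/3) and 82.7% mean accuracy.
#'
#' @param n_subjects Cohort size (57 analysed scanner participants).
#' @param n_runs,n_runs_eye fMRI / eyetracker runs per subject.
#' @param n_trials,n_probe Trials and probe trials per run.
#' @param n_voxels ROI size.
#' @param TR Repetition time in seconds.
#' @param n_vols Volumes per run, or `NULL` to fit the generated schedule.
#' @param geometry_weights Named weights of the model RDMs mixed into the
#'   true pattern geometry (`affordance`, `linkdist`, `magnitude`).
#' @param signal_scale Squared pattern distance per unit model
#'   dissimilarity; 0 gives null data. The default is calibrated so the
#'   subject-level affordance correlation averages about 0.3 under the
#'   default noise settings.
#' @param noise List: `noise_sd` (BOLD noise sd), `ar_coef` (temporal AR(1)
#'   coefficient), `spatial_range` (voxel-distance constant of the
#'   exponential spatial correlation; 0 = diagonal noise), `run_jitter_sd`
#'   (sd of run-wise pattern perturbation controlling cross-run
#'   reliability).
#' @param gaze List: `shift_px` (mean lateralization per state, pixels),
#'   `shift_sd_px` (between-subject sd), `window_ms` (effect window within
#'   the epoch), `ramp_ms` (linear on/off ramp), `noise_sd_px`,
#'   `eye_jitter_px`, `blink_rate_hz`, `sampling_rate_hz`,
#'   `performance_coupling` (latent correlation between a subject's gaze
#'   shift and probe accuracy), `snr_coupling` (log-scale coupling between
#'   the latent and the subject's BOLD signal scale).
#' @param behavior List: `rt_mean` (length-4 per-state mean RT, seconds),
#'   `rt_sd`, `accuracy` (mean probe accuracy), `accuracy_sd`.
#' @param isi_constraint Apply the ISI/model decorrelation search when
#'   generating schedules (disable for large simulation sweeps).
#' @param stim_duration Stimulus presentation in seconds.
#' @return A list of class `generative_config`.
#' @export
generative_config <- function(
    n_subjects = 57, n_runs = 8, n_runs_eye = 4,
    n_trials = 80, n_probe = 16, n_voxels = 140,
    TR = 1, n_vols = NULL,
    geometry_weights = c(affordance = 1, linkdist = 0, magnitude = 0),
    signal_scale = 1.2,
    noise = list(),
    gaze = list(),
    behavior = list(),
    isi_constraint = TRUE,
    stim_duration = 1.5) {
  noise <- utils::modifyList(
    list(noise_sd = 1, ar_coef = 0.3, spatial_range = 2, run_jitter_sd = 0.05),
    noise)
  gaze <- utils::modifyList(
    list(shift_px = 20, shift_sd_px = 8, window_ms = c(899, 1757),
         ramp_ms = 100, noise_sd_px = 30, eye_jitter_px = 2,
         blink_rate_hz = 0.15, sampling_rate_hz = 1000,
         performance_coupling = 0.5, snr_coupling = 0.3),
    gaze)
  behavior <- utils::modifyList(
    list(rt_mean = c(0.75, 0.68, 0.68, 0.75), rt_sd = 0.15,
         accuracy = 0.827, accuracy_sd = 0.12),
    behavior)
  cfg <- structure(
    list(n_subjects = n_subjects, n_runs = n_runs, n_runs_eye = n_runs_eye,
         n_trials = n_trials, n_probe = n_probe, n_voxels = n_voxels,
         TR = TR, n_vols = n_vols, geometry_weights = geometry_weights,
         signal_scale = signal_scale, noise = noise, gaze = gaze,
         behavior = behavior, isi_constraint = isi_constraint,
         stim_duration = stim_duration),
    class = "generative_config")
  cfg
}

#' @export
print.generative_config <- function(x, ...) {
  cat(sprintf("<generative_config> %d subjects, %d fMRI + %d eye runs of %d trials (%d probes)\n",
              x$n_subjects, x$n_runs, x$n_runs_eye, x$n_trials, x$n_probe))
  cat(sprintf("  %d voxels, signal %.3g, noise sd %.3g (AR %.2f), gaze shift %.3g px in [%d, %d] ms\n",
              x$n_voxels, x$signal_scale, x$noise$noise_sd, x$noise$ar_coef,
              x$gaze$shift_px, x$gaze$window_ms[1], x$gaze$window_ms[2]))
  invisible(x)
}

# weighted mixture of model RDMs as a squared-distance target matrix
geometry_target <- function(graph, weights) {
  models <- list(affordance = affordance_rdm(graph),
                 linkdist = linkdist_rdm(graph),
                 magnitude = magnitude_rdm(graph))
  m <- matrix(0, 4, 4)
  for (nm in names(weights)) {
    if (weights[[nm]] != 0) m <- m + weights[[nm]] * unclass(models[[nm]])
  }
  m
}

#' Embed a target geometry as voxel patterns
#'
#' Solves the inverse problem of the RSA pipeline: returns four voxel
#' patterns whose pairwise squared Euclidean distances equal
#' `scale * target`. The target (a model RDM or weighted mixture) is
#' treated as a squared-distance matrix, double-centred and
#' eigendecomposed; patterns are the eigen-embedding rotated into voxel
#' space by a seeded random orthonormal basis, so the signal is spread
#' isotropically across voxels and the condition mean is zero.
#'
#' @param target 4x4 nonnegative symmetric matrix ([rdm()] or plain).
#' @param n_voxels Number of voxels (>= 3).
#' @param scale Nonnegative multiplier of the squared distances.
#' @param seed Optional integer seed (controls the rotation only).
#' @param tol Tolerance on negative eigenvalues before the target is
#'   declared non-embeddable.
#' @return 4 x `n_voxels` numeric matrix.
#' @export
embed_geometry <- function(target, n_voxels, scale = 1, seed = NULL,
                           tol = 1e-8) {
  D <- unclass(target) * scale
  stopifnot(nrow(D) == 4, ncol(D) == 4, n_voxels >= 3)
  J <- diag(4) - matrix(1 / 4, 4, 4)
  B <- -0.5 * J %*% D %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  lam <- e$values
  if (any(lam < -tol * max(abs(lam), 1))) {
    stop("not-euclidean-embeddable: mixture has a negative eigenvalue beyond tolerance",
         call. = FALSE)
  }
  # eigenvalues at numerical zero include the centring null space; treating
  # them as signal would leak the ones-direction into the patterns
  lam[lam < tol * max(abs(lam), 1)] <- 0
  r <- sum(lam > 0)
  if (r == 0) return(matrix(0, 4, n_voxels))
  Y <- e$vectors[, seq_len(r), drop = FALSE] %*%
    diag(sqrt(lam[seq_len(r)]), r)
  with_seed(seed, {
    Q <- qr.Q(qr(matrix(stats::rnorm(n_voxels * r), n_voxels, r)))
    Y %*% t(Q)
  })
}

# AR(1)-filtered, spatially correlated noise matrix (time x voxels) with
# unit-free marginal sd `noise_sd`
bold_noise <- function(n_t, n_vox, noise_sd, ar_coef, spatial_range) {
  E <- matrix(stats::rnorm(n_t * n_vox), n_t, n_vox)
  if (spatial_range > 0) {
    d <- abs(outer(seq_len(n_vox), seq_len(n_vox), `-`))
    L <- chol(exp(-d / spatial_range) + diag(1e-9, n_vox))
    E <- E %*% L
  }
  if (ar_coef != 0) {
    E <- apply(E, 2, function(col) stats::filter(col, ar_coef, method = "recursive"))
    E <- E * sqrt(1 - ar_coef^2)
  }
  E * noise_sd
}

#' Simulate the fMRI branch of one subject
#'
#' Per run: a counterbalanced trial schedule, a stick-function design
#' convolved with the HRF, condition patterns equal to the subject's true
#' geometry embedding plus independent run-wise jitter, a probe nuisance
#' response, and AR(1) noise with exponential spatial covariance. With
#' `signal_scale = 0` the data are pure noise and every downstream estimate
#' is null-distributed.
#'
#' @param graph A [build_graph()] object.
#' @param config A [generative_config()].
#' @param seed Optional integer seed.
#' @param signal_scale Override of `config$signal_scale` (used for
#'   subject-level SNR variation).
#' @return List: `runs` (each with `events`, `bold`, `design`),
#'   `patterns` (true 4 x voxel matrix), `signal_scale`.
#' @export
simulate_subject_fmri <- function(graph, config, seed = NULL,
                                  signal_scale = config$signal_scale) {
  with_seed(seed, {
    target <- geometry_target(graph, config$geometry_weights)
    patterns <- embed_geometry(target, config$n_voxels, signal_scale)
    isi_models <- if (config$isi_constraint) NULL else list()
    runs <- lapply(seq_len(config$n_runs), function(r) {
      events <- generate_run_sequence(
        graph, "fmri", n_trials = config$n_trials, n_probe = config$n_probe,
        run = r, isi_models = isi_models,
        stim_duration = config$stim_duration)
      n_vols <- config$n_vols %||%
        ceiling((max(events$onset + events$duration) + 16) / config$TR)
      des <- build_design_matrix(events, config$TR, n_vols)
      run_patterns <- patterns +
        matrix(stats::rnorm(length(patterns), sd = config$noise$run_jitter_sd),
               nrow(patterns), ncol(patterns))
      probe_pattern <- stats::rnorm(config$n_voxels, sd = 0.5)
      signal <- des$X[, des$condition_cols] %*% run_patterns
      if ("probe" %in% colnames(des$X)) {
        signal <- signal + des$X[, "probe", drop = FALSE] %*% rbind(probe_pattern)
      }
      noise <- bold_noise(n_vols, config$n_voxels, config$noise$noise_sd,
                          config$noise$ar_coef, config$noise$spatial_range)
      list(events = events, design = des,
           bold = 100 + signal + noise)
    })
    list(runs = runs, patterns = patterns, signal_scale = signal_scale)
  })
}

#' Simulate a binocular gaze stream for one run
#'
#' A 1000 Hz (configurable) stream spanning the run: slow AR(1) fixation
#' noise around screen centre, plus a horizontal shift of `+shift` for
#' state-2 and `-shift` for state-3 stimulus trials inside the configured
#' latency window, ramped linearly over `ramp_ms` at the window edges.
#' Left/right eye channels are the common signal plus small independent
#' jitter; blinks are Poisson events flagged (not deleted) with tracker
#' dropout values.
#'
#' @param events Trial tibble for the run ([generate_run_sequence()]).
#' @param config A [generative_config()].
#' @param shift_px Subject's lateralization magnitude in pixels (default:
#'   the config mean).
#' @param seed Optional integer seed.
#' @return Tibble of class `gaze_stream`: `time_ms`, `xl`, `yl`, `xr`,
#'   `yr`, `blink`.
#' @export
simulate_subject_gaze <- function(events, config, shift_px = config$gaze$shift_px,
                                  seed = NULL) {
  gz <- config$gaze
  with_seed(seed, {
    rate <- gz$sampling_rate_hz
    dur_ms <- ceiling((max(events$onset + events$duration) + 4) * 1000)
    t_ms <- seq(0, dur_ms, by = 1000 / rate)
    n <- length(t_ms)
    slow <- function() {
      e <- stats::filter(stats::rnorm(n), 0.995, method = "recursive")
      as.numeric(e) * sqrt(1 - 0.995^2) * gz$noise_sd_px
    }
    x <- slow()
    y <- slow()
    stim <- events[events$type == "stimulus" & events$state %in% c(2L, 3L), ]
    if (nrow(stim)) {
      for (k in seq_len(nrow(stim))) {
        on_ms <- stim$onset[k] * 1000
        w <- gz$window_ms
        idx <- which(t_ms >= on_ms + w[1] & t_ms <= on_ms + w[2])
        if (!length(idx)) next
        tt <- t_ms[idx] - (on_ms + w[1])
        len <- w[2] - w[1]
        ramp <- pmin(1, pmin(tt, len - tt) / gz$ramp_ms)
        ramp[ramp < 0] <- 0
        sgn <- if (stim$state[k] == 2L) 1 else -1
        x[idx] <- x[idx] + sgn * shift_px * ramp
      }
    }
    blink <- rep(FALSE, n)
    n_blinks <- stats::rpois(1, gz$blink_rate_hz * dur_ms / 1000)
    if (n_blinks > 0) {
      starts <- stats::runif(n_blinks, 0, dur_ms)
      lens <- stats::runif(n_blinks, 100, 300)
      for (b in seq_len(n_blinks)) {
        blink[t_ms >= starts[b] & t_ms <= starts[b] + lens[b]] <- TRUE
      }
    }
    xl <- x + stats::rnorm(n, sd = gz$eye_jitter_px)
    xr <- x + stats::rnorm(n, sd = gz$eye_jitter_px)
    yl <- y + stats::rnorm(n, sd = gz$eye_jitter_px)
    yr <- y + stats::rnorm(n, sd = gz$eye_jitter_px)
    xl[blink] <- 0; xr[blink] <- 0; yl[blink] <- 0; yr[blink] <- 0
    out <- tibble::tibble(time_ms = t_ms, xl = xl, yl = yl, xr = xr, yr = yr,
                          blink = blink)
    class(out) <- c("gaze_stream", class(out))
    out
  })
}

#' Simulate probe-trial behaviour
#'
#' Per probe trial: a Bernoulli correct/incorrect response at the subject's
#' accuracy, and a reaction time drawn from the preceding state's mean plus
#' Gaussian noise. Draws beyond the response window are flagged as missed
#' (no RT); recorded RTs therefore never exceed the window.
#'
#' @param events Trial tibble (one run) or list of run tibbles.
#' @param config A [generative_config()].
#' @param accuracy Subject accuracy (default: config mean).
#' @param seed Optional integer seed.
#' @return Tibble: `run`, `trial`, `state` (preceding stimulus state),
#'   `truth` (probe showed the true pair), `correct`, `rt`, `missed`.
#' @export
simulate_behavior <- function(events, config, accuracy = config$behavior$accuracy,
                              seed = NULL) {
  if (!is.data.frame(events)) {
    runs <- events
  } else {
    runs <- list(events)
  }
  beh <- config$behavior
  with_seed(seed, {
    dplyr::bind_rows(lapply(runs, function(ev) {
      pi <- which(ev$is_probe)
      if (!length(pi)) return(NULL)
      prev_state <- ev$state[pi - 1L]
      rt_raw <- stats::rnorm(length(pi), beh$rt_mean[prev_state], beh$rt_sd)
      rt_raw <- pmax(rt_raw, 0.15)
      missed <- rt_raw > ev$response_window[pi]
      tibble::tibble(
        run = ev$run[pi], trial = ev$trial[pi], state = prev_state,
        truth = ev$probe_correct[pi],
        correct = ifelse(missed, NA,
                         stats::runif(length(pi)) < accuracy),
        rt = ifelse(missed, NA_real_, rt_raw),
        missed = missed)
    }))
  })
}

#' Simulate a complete synthetic participant
#'
#' Draws the subject's latent trait `u` (coupling gaze, accuracy and BOLD
#' SNR), then generates the fMRI branch, the eyetracking branch (separate
#' runs at the eyetracker response window and ISI) and probe behaviour for
#' both sessions. All ground-truth generative parameters are retained in
#' `$truth` so recovery tests compare estimates to truth.
#'
#' @param graph A [build_graph()] object.
#' @param config A [generative_config()].
#' @param subject Subject id.
#' @param seed Optional integer seed.
#' @param fmri,gaze Logical switches for the two branches.
#' @return List of class `subject_dataset`.
#' @export
simulate_subject <- function(graph, config, subject = 1L, seed = NULL,
                             fmri = TRUE, gaze = TRUE) {
  with_seed(seed, {
    u <- stats::rnorm(1)
    gz <- config$gaze
    beh <- config$behavior
    shift <- gz$shift_px + gz$shift_sd_px * u
    rho <- gz$performance_coupling
    accuracy <- min(0.99, max(0.5,
      beh$accuracy + beh$accuracy_sd * (rho * u + sqrt(1 - rho^2) * stats::rnorm(1))))
    subj_scale <- config$signal_scale * exp(gz$snr_coupling * u)

    fmri_data <- NULL
    if (fmri) {
      fmri_data <- simulate_subject_fmri(graph, config, signal_scale = subj_scale)
      fmri_data$behavior <- simulate_behavior(
        lapply(fmri_data$runs, `[[`, "events"), config, accuracy = accuracy)
    }
    gaze_data <- NULL
    if (gaze) {
      eye_runs <- lapply(seq_len(config$n_runs_eye), function(r) {
        ev <- generate_run_sequence(
          graph, "eyetracker", n_trials = config$n_trials,
          n_probe = config$n_probe, run = r,
          isi_models = if (config$isi_constraint) NULL else list(),
          stim_duration = config$stim_duration)
        list(events = ev,
             stream = simulate_subject_gaze(ev, config, shift_px = shift))
      })
      gaze_data <- list(
        runs = eye_runs,
        behavior = simulate_behavior(lapply(eye_runs, `[[`, "events"),
                                     config, accuracy = accuracy))
    }
    structure(
      list(subject = subject, fmri = fmri_data, gaze = gaze_data,
           truth = list(u = u, gaze_shift = shift, accuracy = accuracy,
                        signal_scale = subj_scale,
                        geometry_weights = config$geometry_weights,
                        patterns = if (fmri) fmri_data$patterns else NULL)),
      class = "subject_dataset")
  })
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat(sprintf("<subject_dataset> subject %s: %s%s\n", x$subject,
              if (!is.null(x$fmri)) sprintf("%d BOLD runs", length(x$fmri$runs)) else "no fMRI",
              if (!is.null(x$gaze)) sprintf(", %d gaze runs", length(x$gaze$runs)) else ""))
  cat(sprintf("  truth: gaze shift %.1f px, accuracy %.2f, signal scale %.3g\n",
              x$truth$gaze_shift, x$truth$accuracy, x$truth$signal_scale))
  invisible(x)
}

#' Write a gaze stream as TSV
#'
#' Columns `time_ms`, `xl`, `yl`, `xr`, `yr`, `blink`.
#'
#' @param stream A gaze stream tibble.
#' @param path File path.
#' @export
write_gaze_tsv <- function(stream, path) {
  readr::write_tsv(tibble::as_tibble(unclass(stream))[, c("time_ms", "xl", "yl", "xr", "yr", "blink")],
                   path, progress = FALSE)
  invisible(path)
}

#' @rdname write_gaze_tsv
#' @export
read_gaze_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  class(out) <- c("gaze_stream", class(out))
  out
}
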