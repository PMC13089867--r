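#' Estimate a subject's neural RDM from simulated (or loaded) runs
#'
#' Runs the first-level GLM on every run, estimates the run-wise (or
#' pooled) shrinkage noise covariance from the residuals, and computes the
#' crossnobis RDM from the per-run condition betas.
#'
#' @param runs List of runs, each a list with `events` and `bold` (and
#'   optionally a precomputed `design`).
#' @param TR Repetition time in seconds.
#' @param cov_mode `"per-run"` (default, one covariance per run),
#'   `"pooled"` (residuals pooled across runs) or `"identity"`.
#' @param gamma Shrinkage weight passed to [shrinkage_covariance()].
#' @return List: `rdm` (crossnobis [rdm()]), `betas` (run x condition x
#'   voxel array).
#' @export
estimate_neural_rdm <- function(runs, TR, cov_mode = c("per-run", "pooled", "identity"),
                                gamma = "auto") {
  cov_mode <- match.arg(cov_mode)
  n_runs <- length(runs)
  fits <- lapply(runs, function(run) {
    des <- run$design %||%
      build_design_matrix(run$events, TR, nrow(run$bold))
    fit_glm(run$bold, des)
  })
  P <- ncol(fits[[1]]$betas)
  betas <- array(0, dim = c(n_runs, 4, P))
  for (r in seq_len(n_runs)) betas[r, , ] <- fits[[r]]$betas
  cov <- switch(cov_mode,
    `per-run` = lapply(fits, function(f) shrinkage_covariance(f$residuals, gamma)),
    pooled = shrinkage_covariance(do.call(rbind, lapply(fits, `[[`, "residuals")), gamma),
    identity = NULL)
  list(rdm = crossnobis_rdm(betas, cov), betas = betas)
}

#' Per-subject gaze lateralization timecourse
#'
#' Preprocesses each run's stream (blink scrubbing, cyclopean reduction),
#' epochs all runs on the common grid, takes condition median timecourses
#' and returns the state-2 minus state-3 horizontal difference.
#'
#' @param gaze_runs List of runs, each a list with `events` and `stream`.
#' @param window_ms Epoch window.
#' @param blink_buffer_ms Scrub buffer.
#' @return List: `diff` (tibble `time_ms`, `diff`), `timecourses`
#'   (condition tibble), `epochs`.
#' @export
estimate_gaze_lateralization <- function(gaze_runs, window_ms = c(-500, 2500),
                                         blink_buffer_ms = 100) {
  cleans <- lapply(gaze_runs, function(r) preprocess_gaze(r$stream, blink_buffer_ms))
  evs <- lapply(gaze_runs, `[[`, "events")
  epochs <- epoch_gaze(cleans, evs, window_ms = window_ms, states = c(2L, 3L))
  tc <- condition_timecourses(epochs)
  list(diff = lateralization_timecourse(tc), timecourses = tc, epochs = epochs)
}

#' Pipeline configuration
#'
#' @param generative A [generative_config()].
#' @param seed Integer seed; every stochastic stage derives its stream from
#'   it. Required for a valid configuration.
#' @param base_offset Smallest state-1 number; per-subject offsets rotate
#'   through `base_offset + 0..4` to counterbalance number-state mappings.
#' @param covariates Character subset of `c("linkdist", "magnitude")`
#'   partialled out of the affordance test.
#' @param alpha Nominal alpha.
#' @param n_comparisons Bonferroni divisor for the RSA test (2 hemispheres
#'   in the original design).
#' @param n_perm Cluster-test permutations.
#' @param cov_mode Noise covariance mode for [estimate_neural_rdm()].
#' @param stages Named logical vector enabling the `fmri` and `gaze`
#'   branches.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(generative = generative_config(), seed = NULL,
                            base_offset = 21, covariates = c("linkdist", "magnitude"),
                            alpha = 0.05, n_comparisons = 2, n_perm = 10000,
                            cov_mode = "per-run",
                            stages = c(fmri = TRUE, gaze = TRUE)) {
  structure(
    list(generative = generative, seed = seed, base_offset = base_offset,
         covariates = covariates, alpha = alpha,
         n_comparisons = n_comparisons, n_perm = n_perm, cov_mode = cov_mode,
         stages = stages),
    class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Schema and cross-field checks; returns diagnostics rather than erroring
#' so a config can be inspected before a long run.
#'
#' @param config A [pipeline_config()].
#' @return Character vector of diagnostics; empty when the config is valid.
#' @export
validate_config <- function(config) {
  d <- character(0)
  g <- config$generative
  if (is.null(config$seed)) d <- c(d, "seed is missing: every stochastic stage needs an explicit seed")
  if (!is.null(config$seed) && (config$seed != round(config$seed))) {
    d <- c(d, "seed must be an integer")
  }
  if (g$n_probe > g$n_trials) d <- c(d, "n_probe exceeds n_trials")
  if ((g$n_trials - g$n_probe) %% 4 != 0) d <- c(d, "(n_trials - n_probe) must be a multiple of 4")
  if (g$gaze$window_ms[1] < -500 || g$gaze$window_ms[2] > 2500) {
    d <- c(d, "gaze effect window lies outside the -500..2500 ms epoch")
  }
  if (!all(is.finite(g$geometry_weights))) d <- c(d, "geometry weights must be finite")
  if (g$behavior$accuracy < 0 || g$behavior$accuracy > 1) d <- c(d, "accuracy must be in [0, 1]")
  if (g$signal_scale < 0) d <- c(d, "signal_scale must be nonnegative")
  if (config$base_offset <= 20) d <- c(d, "base_offset must be greater than 20")
  d
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Simulates a cohort under the generative config and runs both analysis
#' branches in dependency order, streaming subjects so raw BOLD and gaze
#' never accumulate in memory. The report contains the three headline
#' syntheses: (1) the group affordance RSA effect with link-distance and
#' magnitude covariates, (2) the gaze lateralization cluster plus its
#' correlation with probe performance, and (3) the brain-gaze link between
#' normalized state-2/3 neural distances and gaze shifts. Ground-truth
#' recovery diagnostics are included alongside.
#'
#' @param config A [pipeline_config()]; must validate cleanly.
#' @return Object of class `pipeline_report`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  diags <- validate_config(config)
  if (length(diags)) stop("invalid config: ", paste(diags, collapse = "; "), call. = FALSE)
  g <- config$generative
  do_fmri <- isTRUE(config$stages[["fmri"]])
  do_gaze <- isTRUE(config$stages[["gaze"]])

  graphs <- lapply(seq_len(g$n_subjects), function(i) {
    build_graph(config$base_offset + (i - 1L) %% 5L, 8)
  })
  rdms <- vector("list", g$n_subjects)
  diffs <- NULL
  subj_rows <- vector("list", g$n_subjects)
  for (i in seq_len(g$n_subjects)) {
    ds <- simulate_subject(graphs[[i]], g, subject = i,
                           seed = child_seed(config$seed, "subject", i),
                           fmri = do_fmri, gaze = do_gaze)
    row <- list(subject = i, truth_shift = ds$truth$gaze_shift,
                truth_accuracy = ds$truth$accuracy,
                truth_signal_scale = ds$truth$signal_scale)
    if (do_fmri) {
      est <- estimate_neural_rdm(ds$fmri$runs, g$TR, cov_mode = config$cov_mode)
      rdms[[i]] <- est$rdm
      row$mean_rdm <- mean_rdm_positivity(est$rdm)$mean
      beh <- ds$fmri$behavior
      row$fmri_accuracy <- mean(beh$correct, na.rm = TRUE)
      rt <- tapply(beh$rt, beh$state, mean, na.rm = TRUE)
      row$rt_rdm <- if (length(rt) == 4 && !anyNA(rt)) list(behavior_rdm(rt)) else list(NULL)
    }
    if (do_gaze) {
      lat <- estimate_gaze_lateralization(ds$gaze$runs)
      if (is.null(diffs)) {
        diffs <- matrix(NA_real_, g$n_subjects, nrow(lat$diff))
        diff_grid <- lat$diff$time_ms
      }
      diffs[i, ] <- lat$diff$diff
      row$gaze_accuracy <- mean(ds$gaze$behavior$correct, na.rm = TRUE)
    }
    subj_rows[[i]] <- row
  }
  subjects <- dplyr::bind_rows(lapply(subj_rows, function(r) {
    tibble::as_tibble(r[setdiff(names(r), "rt_rdm")])
  }))

  rsa <- NULL
  ceilings <- NULL
  if (do_fmri) {
    graph0 <- graphs[[1]]
    covs <- list(linkdist = linkdist_rdm(graph0),
                 magnitude = magnitude_rdm(graph0))[config$covariates]
    rsa <- rsa_test(rdms, affordance_rdm(graph0), covariates = covs,
                    alpha = config$alpha, n_comparisons = config$n_comparisons)
    subjects$r_affordance <- rsa$subjects$r
    subjects$partial_r_affordance <- rsa$subjects$partial_r
    ceilings <- noise_ceilings(rdms)
  }

  cluster <- NULL
  perf <- NULL
  link <- NULL
  if (do_gaze) {
    cluster <- cluster_permutation_test(diffs, time_ms = diff_grid,
                                        n_perm = config$n_perm,
                                        alpha = config$alpha,
                                        seed = child_seed(config$seed, "cluster"))
    sig <- cluster$clusters[cluster$clusters$p < config$alpha, ]
    if (nrow(sig)) {
      win <- unlist(sig[which.max(sig$mass), c("start_ms", "end_ms")])
      shifts <- apply(diffs, 1, cluster_median_shift, time_ms = diff_grid,
                      window = win)
      subjects$gaze_shift <- shifts
      perf <- performance_correlation(shifts, subjects$gaze_accuracy)
      if (do_fmri) link <- brain_gaze_link(rdms, shifts)
    }
  }

  recovery <- list()
  if (do_fmri) {
    group_vec <- rowMeans(vapply(rdms, rdm_vec, numeric(6)))
    target_vec <- rdm_vec(rdm(geometry_target(graphs[[1]], g$geometry_weights)))
    recovery$group_rdm_vs_truth <-
      if (stats::sd(target_vec) > 0) spearman_tc(group_vec, target_vec) else NA_real_
  }
  if (do_gaze && !is.null(subjects$gaze_shift)) {
    recovery$shift_vs_truth <-
      stats::cor(subjects$gaze_shift, subjects$truth_shift)
  }

  structure(
    list(subjects = subjects, rdms = if (do_fmri) rdms else NULL,
         rsa = rsa, noise_ceilings = ceilings, cluster = cluster,
         performance = perf, brain_gaze = link, recovery = recovery,
         config = config,
         provenance = list(seed = config$seed,
                           config_hash = rlang::hash(config),
                           package_version = as.character(utils::packageVersion("affordrsa")))),
    class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d subjects (seed %s, config %s)\n",
              nrow(x$subjects), x$provenance$seed, x$provenance$config_hash))
  if (!is.null(x$rsa)) {
    cat(sprintf("  affordance RSA: mean partial r = %.3f, t(%d) = %.2f, p = %.4g\n",
                x$rsa$group$mean_r, x$rsa$group$df, x$rsa$group$t, x$rsa$group$p))
    cat(sprintf("  noise ceiling: [%.3f, %.3f]\n",
                x$noise_ceilings$lower, x$noise_ceilings$upper))
  }
  if (!is.null(x$cluster)) {
    sig <- x$cluster$clusters[x$cluster$clusters$p < x$cluster$alpha, ]
    if (nrow(sig)) {
      k <- which.max(sig$mass)
      cat(sprintf("  gaze cluster: %g..%g ms, p = %.4g\n",
                  sig$start_ms[k], sig$end_ms[k], sig$p[k]))
    } else cat("  gaze cluster: none significant\n")
  }
  if (!is.null(x$performance)) {
    cat(sprintf("  shift~performance: r = %.3f, p = %.4g\n",
                x$performance$r, x$performance$p))
  }
  if (!is.null(x$brain_gaze)) {
    cat(sprintf("  brain~gaze link (states 2-3): r = %.3f, p = %.4g\n",
                x$brain_gaze$r, x$brain_gaze$p))
  }
  invisible(x)
}

#' @export
tidy.pipeline_report <- function(x, ...) x$subjects

#' @export
glance.pipeline_report <- function(x, ...) {
  sig <- if (!is.null(x$cluster)) {
    x$cluster$clusters[x$cluster$clusters$p < x$cluster$alpha, ]
  } else NULL
  tibble::tibble(
    n_subjects = nrow(x$subjects),
    rsa_mean_partial_r = if (!is.null(x$rsa)) x$rsa$group$mean_r else NA_real_,
    rsa_t = if (!is.null(x$rsa)) x$rsa$group$t else NA_real_,
    rsa_p = if (!is.null(x$rsa)) x$rsa$group$p else NA_real_,
    cluster_start_ms = if (!is.null(sig) && nrow(sig)) sig$start_ms[which.max(sig$mass)] else NA_real_,
    cluster_end_ms = if (!is.null(sig) && nrow(sig)) sig$end_ms[which.max(sig$mass)] else NA_real_,
    cluster_p = if (!is.null(sig) && nrow(sig)) min(sig$p) else NA_real_,
    performance_r = if (!is.null(x$performance)) x$performance$r else NA_real_,
    brain_gaze_r = if (!is.null(x$brain_gaze)) x$brain_gaze$r else NA_real_)
}
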