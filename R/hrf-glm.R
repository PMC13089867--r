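#' Canonical double-gamma hemodynamic response function
#'
#' The standard difference-of-gammas impulse response: a response gamma
#' peaking near 5 s minus a scaled undershoot gamma. Parameters follow the
#' common convention (response shape 6, undershoot shape 16, rate 1,
#' undershoot ratio 1/6).
#'
#' @param t Time in seconds (vectorized); values before 0 return 0.
#' @param peak_shape,undershoot_shape,rate,undershoot_ratio HRF parameters.
#' @return Numeric vector of HRF values (unnormalized; peak about 0.11).
#' @export
hrf <- function(t, peak_shape = 6, undershoot_shape = 16, rate = 1,
                undershoot_ratio = 1 / 6) {
  out <- stats::dgamma(t, shape = peak_shape, rate = rate) -
    undershoot_ratio * stats::dgamma(t, shape = undershoot_shape, rate = rate)
  out[t < 0] <- 0
  out
}

#' Build a first-level design matrix from an events table
#'
#' Condition regressors are stick (zero-duration) functions at stimulus
#' onsets, one regressor per state, convolved with the canonical HRF and
#' sampled on the TR grid; because sticks are delta functions the
#' convolution is computed exactly as a sum of shifted HRFs. Probe events
#' get their own nuisance regressor, and an intercept is always included.
#' Optional cosine drift regressors model slow trends.
#'
#' @param events Trial tibble (from [generate_run_sequence()] or
#'   [read_events_tsv()]) with `onset`, `type`, `state` columns.
#' @param TR Repetition time in seconds.
#' @param n_vols Number of volumes.
#' @param n_cosine Number of cosine drift regressors (0 = none).
#' @param extra Optional numeric matrix of additional nuisance regressors
#'   (e.g. motion), `n_vols` rows.
#' @return A list of class `design_matrix`: `X` (`n_vols` x regressors,
#'   labeled columns), `condition_cols` (names of the 4 state regressors),
#'   `frame_times`.
#' @export
build_design_matrix <- function(events, TR, n_vols, n_cosine = 0, extra = NULL) {
  stopifnot(all(events$onset < n_vols * TR))
  ft <- (seq_len(n_vols) - 1) * TR
  cond_cols <- paste0("state", 1:4)
  X <- matrix(0, n_vols, 0)
  for (s in 1:4) {
    onsets <- events$onset[events$type == "stimulus" & events$state == s]
    col <- rowSums(vapply(onsets, function(o) hrf(ft - o), numeric(n_vols)))
    if (length(onsets) == 0) col <- rep(0, n_vols)
    X <- cbind(X, col)
  }
  probe_onsets <- events$onset[events$type == "probe"]
  probe_col <- if (length(probe_onsets)) {
    rowSums(vapply(probe_onsets, function(o) hrf(ft - o), numeric(n_vols)))
  } else NULL
  colnames(X) <- cond_cols
  if (!is.null(probe_col)) X <- cbind(X, probe = probe_col)
  if (n_cosine > 0) {
    dr <- vapply(seq_len(n_cosine), function(k) {
      cos(pi * k * (ft + TR / 2) / (n_vols * TR))
    }, numeric(n_vols))
    colnames(dr) <- paste0("cosine", seq_len(n_cosine))
    X <- cbind(X, dr)
  }
  if (!is.null(extra)) {
    extra <- as.matrix(extra)
    stopifnot(nrow(extra) == n_vols)
    if (is.null(colnames(extra))) colnames(extra) <- paste0("nuis", seq_len(ncol(extra)))
    X <- cbind(X, extra)
  }
  X <- cbind(X, intercept = 1)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[-qrX$pivot[seq_len(qrX$rank)]]
    stop("design-singular: rank-deficient design; offending columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(X = X, condition_cols = cond_cols, frame_times = ft),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d volumes x %d regressors (%s)\n",
              nrow(x$X), ncol(x$X), paste(colnames(x$X), collapse = ", ")))
  invisible(x)
}

#' Fit a first-level GLM by ordinary least squares
#'
#' Per-voxel OLS of the BOLD timeseries on the design; residuals feed the
#' noise-covariance estimate used for crossnobis whitening.
#'
#' @param bold Numeric matrix, time x voxels.
#' @param design A [build_design_matrix()] object (or a plain full-rank
#'   matrix).
#' @return A list of class `glm_fit`: `betas` (condition x voxel, the 4
#'   state regressors), `all_betas` (every regressor), `residuals` (time x
#'   voxel), `dof` (timepoints minus design rank), `design`.
#' @export
fit_glm <- function(bold, design) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  bold <- as.matrix(bold)
  if (nrow(bold) != nrow(X)) stop("time dimension mismatch", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design-singular", call. = FALSE)
  coefs <- qr.coef(qrX, bold)
  fitted <- X %*% coefs
  res <- bold - fitted
  cond_cols <- if (inherits(design, "design_matrix")) design$condition_cols
               else intersect(paste0("state", 1:4), colnames(X))
  structure(
    list(betas = coefs[cond_cols, , drop = FALSE],
         all_betas = coefs,
         residuals = res,
         dof = nrow(X) - qrX$rank,
         design = X),
    class = "glm_fit"
  )
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> %d conditions x %d voxels; dof %d\n",
              nrow(x$betas), ncol(x$betas), x$dof))
  invisible(x)
}
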