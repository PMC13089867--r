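#' Preprocess a binocular gaze stream
#'
#' Flags every sample within `blink_buffer_ms` of a blink (boundary
#' inclusive) as missing and reduces the two eyes to a single cyclopean
#' position, the per-sample mean of left and right.
#'
#' @param stream Gaze tibble with `time_ms`, `xl`, `yl`, `xr`, `yr`,
#'   `blink` columns.
#' @param blink_buffer_ms Buffer around blinks in milliseconds (default
#'   100).
#' @return Tibble `time_ms`, `x`, `y`, `valid`; `x`/`y` are `NA` where
#'   scrubbed.
#' @export
preprocess_gaze <- function(stream, blink_buffer_ms = 100) {
  t <- stream$time_ms
  bad <- stream$blink
  if (any(bad)) {
    r <- rle(bad)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    mask <- rep(FALSE, length(t))
    for (k in which(r$values)) {
      lo <- t[starts[k]] - blink_buffer_ms
      hi <- t[ends[k]] + blink_buffer_ms
      mask[t >= lo & t <= hi] <- TRUE
    }
  } else {
    mask <- rep(FALSE, length(t))
  }
  if (all(mask)) stop("no-valid-samples: entire stream scrubbed", call. = FALSE)
  x <- (stream$xl + stream$xr) / 2
  y <- (stream$yl + stream$yr) / 2
  x[mask] <- NA_real_
  y[mask] <- NA_real_
  tibble::tibble(time_ms = t, x = x, y = y, valid = !mask)
}

#' Segment cleaned gaze into stimulus-locked epochs
#'
#' Cuts the cleaned stream into per-trial epochs on a fixed grid spanning
#' `window_ms` around each stimulus onset, at the stream's native sampling
#' step. Alignment is exact: a sample recorded k ms after onset lands at
#' epoch time k.
#'
#' @param clean Output of [preprocess_gaze()] (or a list of run outputs,
#'   paired with a list of event tables).
#' @param events Trial tibble(s) with `onset` (seconds), `type`, `state`.
#' @param window_ms Epoch window, default `c(-500, 2500)`.
#' @param states States to keep (default all four).
#' @return Object of class `gaze_epochs`: matrices `x`, `y`
#'   (trials x time, `NA` where scrubbed or out of record), integer
#'   `condition`, numeric `time_ms` grid.
#' @export
epoch_gaze <- function(clean, events, window_ms = c(-500, 2500), states = 1:4) {
  if (!is.data.frame(clean)) {
    parts <- purrr::map2(clean, events, epoch_gaze, window_ms = window_ms,
                         states = states)
    out <- list(
      x = do.call(rbind, lapply(parts, `[[`, "x")),
      y = do.call(rbind, lapply(parts, `[[`, "y")),
      condition = unlist(lapply(parts, `[[`, "condition")),
      time_ms = parts[[1]]$time_ms)
    class(out) <- "gaze_epochs"
    return(out)
  }
  t <- clean$time_ms
  dt <- stats::median(diff(t))
  n_t <- floor((window_ms[2] - window_ms[1]) / dt) + 1L
  grid <- window_ms[1] + (seq_len(n_t) - 1L) * dt
  stim <- events[events$type == "stimulus" & events$state %in% states, ]
  X <- matrix(NA_real_, nrow(stim), n_t)
  Y <- matrix(NA_real_, nrow(stim), n_t)
  for (k in seq_len(nrow(stim))) {
    on_ms <- stim$onset[k] * 1000
    i0 <- round((on_ms + window_ms[1] - t[1]) / dt) + 1L
    idx <- i0 + seq_len(n_t) - 1L
    ok <- idx >= 1L & idx <= length(t)
    X[k, ok] <- clean$x[idx[ok]]
    Y[k, ok] <- clean$y[idx[ok]]
  }
  structure(list(x = X, y = Y, condition = stim$state, time_ms = grid),
            class = "gaze_epochs")
}

#' @export
print.gaze_epochs <- function(x, ...) {
  cat(sprintf("<gaze_epochs> %d trials x %d timepoints (%g..%g ms), conditions: %s\n",
              nrow(x$x), ncol(x$x), min(x$time_ms), max(x$time_ms),
              paste(sort(unique(x$condition)), collapse = " ")))
  invisible(x)
}

#' @export
tidy.gaze_epochs <- function(x, ...) {
  n_trial <- nrow(x$x)
  tibble::tibble(
    trial = rep(seq_len(n_trial), each = length(x$time_ms)),
    condition = rep(x$condition, each = length(x$time_ms)),
    time_ms = rep(x$time_ms, n_trial),
    x = as.vector(t(x$x)),
    y = as.vector(t(x$y)))
}

# vectorized column medians with NA removal: one global order() call
# (column-major, NAs last within column), then pick the middle order
# statistics per column
col_medians_na <- function(X) {
  n <- nrow(X)
  m <- ncol(X)
  if (n == 1) return(as.numeric(X))
  v <- as.vector(X)
  ord <- order(rep(seq_len(m), each = n), v, na.last = TRUE)
  sorted <- matrix(v[ord], n, m)
  k <- colSums(!is.na(X))
  out <- rep(NA_real_, m)
  nz <- k > 0
  lo <- floor((k[nz] + 1) / 2)
  hi <- ceiling((k[nz] + 1) / 2)
  cols <- which(nz)
  out[nz] <- (sorted[cbind(lo, cols)] + sorted[cbind(hi, cols)]) / 2
  out
}

# truncated, renormalized Gaussian smoothing with NA pass-through
gauss_smooth <- function(v, sigma_ms, max_window_ms, dt) {
  half <- floor((max_window_ms / 2) / dt)
  if (half < 1) return(v)
  off <- (-half):half
  k <- exp(-(off * dt)^2 / (2 * sigma_ms^2))
  ok <- !is.na(v)
  vf <- ifelse(ok, v, 0)
  num <- rep(0, length(v))
  den <- rep(0, length(v))
  n <- length(v)
  for (j in seq_along(off)) {
    sh <- off[j]
    src <- seq_len(n) + sh
    valid <- src >= 1 & src <= n
    num[valid] <- num[valid] + k[j] * vf[src[valid]]
    den[valid] <- den[valid] + k[j] * ok[src[valid]]
  }
  out <- ifelse(den > 0, num / den, NA_real_)
  out[!ok] <- NA_real_
  out
}

#' Per-condition median gaze timecourses
#'
#' For each condition and timepoint, the median position across that
#' condition's trials (scrubbed samples excluded per timepoint, no
#' interpolation), lightly smoothed with a truncated Gaussian kernel
#' (sd 4.25 ms, support capped at 20 ms, renormalized).
#'
#' @param epochs A [epoch_gaze()] object.
#' @param sigma_ms Kernel standard deviation in ms.
#' @param max_window_ms Total kernel support cap in ms.
#' @return Tibble: `condition`, `time_ms`, `x`, `y`.
#' @export
condition_timecourses <- function(epochs, sigma_ms = 4.25, max_window_ms = 20) {
  dt <- stats::median(diff(epochs$time_ms))
  conds <- sort(unique(epochs$condition))
  dplyr::bind_rows(lapply(conds, function(cc) {
    sel <- epochs$condition == cc
    mx <- col_medians_na(epochs$x[sel, , drop = FALSE])
    my <- col_medians_na(epochs$y[sel, , drop = FALSE])
    tibble::tibble(condition = cc, time_ms = epochs$time_ms,
                   x = gauss_smooth(mx, sigma_ms, max_window_ms, dt),
                   y = gauss_smooth(my, sigma_ms, max_window_ms, dt))
  }))
}

#' Gaze lateralization timecourse
#'
#' Difference of the horizontal condition timecourses, positive-affording
#' minus negative-affording (state 2 minus state 3 by default): positive
#' values mean a rightward skew for states affording positive actions.
#'
#' @param tc Either the tibble from [condition_timecourses()] or a numeric
#'   x-timecourse for the positive condition.
#' @param tc_neg Numeric x-timecourse of the negative condition when `tc`
#'   is a vector; ignored otherwise.
#' @param pos,neg Condition labels used when `tc` is a tibble.
#' @return Tibble `time_ms`, `diff` (or a plain vector when vectors were
#'   supplied).
#' @export
lateralization_timecourse <- function(tc, tc_neg = NULL, pos = 2, neg = 3) {
  if (is.data.frame(tc)) {
    a <- tc[tc$condition == pos, ]
    b <- tc[tc$condition == neg, ]
    stopifnot(nrow(a) == nrow(b), all(a$time_ms == b$time_ms))
    return(tibble::tibble(time_ms = a$time_ms, diff = a$x - b$x))
  }
  if (length(tc) != length(tc_neg)) stop("grid mismatch", call. = FALSE)
  tc - tc_neg
}

# contiguous supra-threshold clusters of a t timecourse (one-tailed,
# positive); returns start/end indices and summed-t mass
find_clusters <- function(tvals, threshold) {
  supra <- !is.na(tvals) & tvals > threshold
  if (!any(supra)) {
    return(data.frame(start = integer(0), end = integer(0), mass = numeric(0)))
  }
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(
    start = starts[keep], end = ends[keep],
    mass = vapply(keep, function(k) sum(tvals[starts[k]:ends[k]]), numeric(1)))
}

#' Cluster-based sign-flip permutation test of a lateralization timecourse
#'
#' One-sample t statistics across subjects at every timepoint; contiguous
#' supra-threshold runs form clusters scored by summed t; the familywise
#' null is the distribution of the maximum cluster mass under random
#' per-subject sign flips. The test is one-tailed (positive shift
#' predicted). Cluster p-values use the +1-corrected estimator
#' `(1 + #(null >= observed)) / (1 + n_perm)` and are therefore never
#' exactly zero.
#'
#' @param subject_diffs Numeric matrix, subjects x time (per-subject
#'   lateralization timecourses on a common grid).
#' @param time_ms Time grid (defaults to column indices).
#' @param n_perm Number of sign-flip permutations (default 10000).
#' @param cluster_threshold Cluster-forming t threshold; default is the
#'   one-tailed p = 0.05 critical value at n - 1 degrees of freedom.
#' @param alpha Significance level recorded on clusters.
#' @param seed Optional integer seed.
#' @return Object of class `cluster_result`: tibble `clusters` (`start_ms`,
#'   `end_ms`, `mass`, `p`), `tvals`, `time_ms`, `threshold`, `n_perm`,
#'   `alpha`.
#' @export
cluster_permutation_test <- function(subject_diffs, time_ms = NULL,
                                     n_perm = 10000, cluster_threshold = NULL,
                                     alpha = 0.05, seed = NULL) {
  X <- as.matrix(subject_diffs)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 subjects", call. = FALSE)
  if (n_perm < 1) stop("n_perm must be at least 1", call. = FALSE)
  if (is.null(time_ms)) time_ms <- seq_len(ncol(X)) - 1
  keep <- colSums(is.na(X)) == 0
  thr <- cluster_threshold %||% stats::qt(1 - 0.05, df = n - 1)
  t_of <- function(m, css) {
    v <- (css - n * m^2) / (n - 1)
    v[v < 1e-24] <- 1e-24
    m / sqrt(v / n)
  }
  css <- colSums(X[, keep, drop = FALSE]^2)
  m_obs <- colMeans(X[, keep, drop = FALSE])
  t_obs_k <- t_of(m_obs, css)
  tvals <- rep(NA_real_, ncol(X))
  tvals[keep] <- t_obs_k
  cl <- find_clusters(tvals, thr)
  with_seed(seed, {
    S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    M <- (S %*% X[, keep, drop = FALSE]) / n
    null_max <- vapply(seq_len(n_perm), function(p) {
      tv <- t_of(M[p, ], css)
      cls <- find_clusters(tv, thr)
      if (nrow(cls)) max(cls$mass) else 0
    }, numeric(1))
    kept_idx <- which(keep)
    clusters <- tibble::tibble(
      start_ms = time_ms[kept_idx[cl$start]],
      end_ms = time_ms[kept_idx[cl$end]],
      mass = cl$mass,
      p = vapply(cl$mass, function(m) (1 + sum(null_max >= m)) / (1 + n_perm),
                 numeric(1)))
    clusters <- clusters[order(clusters$start_ms), ]
    structure(
      list(clusters = clusters, tvals = tvals, time_ms = time_ms,
           threshold = thr, n_perm = n_perm, alpha = alpha, n_subjects = n),
      class = "cluster_result")
  })
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d subjects, %d permutations, threshold t > %.2f\n",
              x$n_subjects, x$n_perm, x$threshold))
  if (nrow(x$clusters) == 0) {
    cat("  no supra-threshold clusters\n")
  } else {
    for (k in seq_len(nrow(x$clusters))) {
      cat(sprintf("  cluster %g..%g ms, mass %.1f, p = %.4g%s\n",
                  x$clusters$start_ms[k], x$clusters$end_ms[k],
                  x$clusters$mass[k], x$clusters$p[k],
                  if (x$clusters$p[k] < x$alpha) " *" else ""))
    }
  }
  invisible(x)
}

#' @export
tidy.cluster_result <- function(x, ...) x$clusters

#' @export
glance.cluster_result <- function(x, ...) {
  sig <- x$clusters[x$clusters$p < x$alpha, ]
  tibble::tibble(
    n_subjects = x$n_subjects, n_perm = x$n_perm, threshold = x$threshold,
    n_clusters = nrow(x$clusters), n_significant = nrow(sig),
    min_p = if (nrow(x$clusters)) min(x$clusters$p) else NA_real_)
}

#' Per-subject cluster-window effect size
#'
#' Median of a subject's lateralization timecourse over the significant
#' cluster window; the per-subject summary used for the performance and
#' brain linking correlations.
#'
#' @param diff Numeric lateralization timecourse (or tibble with `time_ms`,
#'   `diff`).
#' @param time_ms Time grid when `diff` is a vector.
#' @param window Length-2 window in ms (inclusive).
#' @return Median shift (same units as the timecourse).
#' @export
cluster_median_shift <- function(diff, time_ms = NULL, window) {
  if (is.data.frame(diff)) {
    time_ms <- diff$time_ms
    diff <- diff$diff
  }
  sel <- time_ms >= window[1] & time_ms <= window[2]
  if (!any(sel)) stop("empty window", call. = FALSE)
  stats::median(diff[sel], na.rm = TRUE)
}

#' Trial-median gaze lateralization in a fixed window
#'
#' The coarse-estimate path (e.g. gaze decoded from the MR signal at low
#' sampling rates): per trial, the median horizontal position within a 1-s
#' window centred on the cluster; per subject, the median across trials of
#' each condition; across subjects, a one-sided paired t test predicting
#' condition `pos` further right than `neg`.
#'
#' @param trial_gaze Tibble with columns `subject`, `condition`, `trial`,
#'   `time_ms`, `x`; any sampling rate.
#' @param window Length-2 window in ms.
#' @param pos,neg Conditions compared (defaults 2 and 3).
#' @return List: `per_subject` tibble (`subject`, `x_pos`, `x_neg`,
#'   `shift`), `t`, `p`, `df`.
#' @export
window_median_lateralization <- function(trial_gaze, window, pos = 2, neg = 3) {
  tg <- trial_gaze[trial_gaze$condition %in% c(pos, neg) &
                     trial_gaze$time_ms >= window[1] &
                     trial_gaze$time_ms <= window[2], ]
  if (!all(c(pos, neg) %in% tg$condition)) {
    stop("missing condition", call. = FALSE)
  }
  per_trial <- dplyr::summarise(
    dplyr::group_by(tg, .data$subject, .data$condition, .data$trial),
    x = stats::median(.data$x, na.rm = TRUE), .groups = "drop")
  per_cond <- dplyr::summarise(
    dplyr::group_by(per_trial, .data$subject, .data$condition),
    x = stats::median(.data$x, na.rm = TRUE), .groups = "drop")
  wide <- tidyr::pivot_wider(per_cond, names_from = "condition",
                             values_from = "x", names_prefix = "c")
  per_subject <- tibble::tibble(
    subject = wide$subject,
    x_pos = wide[[paste0("c", pos)]],
    x_neg = wide[[paste0("c", neg)]])
  per_subject$shift <- per_subject$x_pos - per_subject$x_neg
  n <- nrow(per_subject)
  if (n >= 2 && stats::sd(per_subject$shift) > 0) {
    tt <- stats::t.test(per_subject$shift, alternative = "greater")
    tval <- unname(tt$statistic)
    p <- tt$p.value
    df <- unname(tt$parameter)
  } else {
    tval <- 0; p <- 0.5; df <- n - 1
  }
  list(per_subject = per_subject, t = tval, p = p, df = df)
}

#' Link neural state separation to gaze lateralization
#'
#' Each subject's neural RDM is normalized (vector form divided by its root
#' mean square, so overall pattern scale cancels; `"z"` mean-centres and
#' unit-scales instead), the entry for the given state pair extracted, and
#' Pearson-correlated with the per-subject gaze shifts (two-sided).
#'
#' @param subject_rdms List of subject [rdm()] objects.
#' @param gaze_shifts Numeric vector of per-subject gaze shifts, same order.
#' @param pair State pair, default `c(2, 3)`.
#' @param normalize `"rms"` (default) or `"z"`.
#' @return List: `r`, `p`, `n`, `distances` (normalized per-subject pair
#'   entries).
#' @export
brain_gaze_link <- function(subject_rdms, gaze_shifts, pair = c(2, 3),
                            normalize = c("rms", "z")) {
  normalize <- match.arg(normalize)
  stopifnot(length(subject_rdms) == length(gaze_shifts),
            length(subject_rdms) >= 3)
  pairs <- canonical_pairs()
  k <- which(pairs[, "i"] == min(pair) & pairs[, "j"] == max(pair))
  d <- vapply(subject_rdms, function(x) {
    v <- rdm_vec(x)
    v <- switch(normalize,
                rms = v / sqrt(mean(v^2)),
                z = (v - mean(v)) / stats::sd(v))
    v[k]
  }, numeric(1))
  if (stats::sd(d) == 0 || stats::sd(gaze_shifts) == 0) {
    stop("zero-variance input", call. = FALSE)
  }
  ct <- stats::cor.test(d, gaze_shifts)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(d), distances = d)
}

#' Correlate gaze lateralization strength with probe performance
#'
#' @param shifts Per-subject cluster-window median shifts.
#' @param probe_accuracy Per-subject probe accuracy (any affine scaling).
#' @return List: `r`, `p`, `n` (Pearson, two-sided).
#' @export
performance_correlation <- function(shifts, probe_accuracy) {
  stopifnot(length(shifts) == length(probe_accuracy), length(shifts) >= 3)
  if (stats::sd(shifts) == 0 || stats::sd(probe_accuracy) == 0) {
    stop("constant input", call. = FALSE)
  }
  ct <- stats::cor.test(shifts, probe_accuracy)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(shifts))
}
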