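#' Shrinkage estimate of the voxel noise covariance
#'
#' Diagonal-target shrinkage of the sample covariance of GLM residuals:
#' `Sigma = (1 - gamma) * S + gamma * diag(S)`. With `gamma = "auto"` the
#' weight is the analytic optimum of Schafer-Strimmer type (ratio of the
#' summed sampling variances of the off-diagonal entries to their summed
#' squares), clamped to `[0, 1]`. A small ridge is added if any voxel has
#' (near-)zero variance so the result is always positive-definite.
#'
#' @param residuals Numeric matrix, time x voxels.
#' @param gamma Shrinkage weight in `[0, 1]`, or `"auto"`.
#' @return A list of class `noise_cov`: `sigma` (voxel x voxel), `gamma`,
#'   `dof` (rows of `residuals` minus 1).
#' @export
shrinkage_covariance <- function(residuals, gamma = "auto") {
  X <- as.matrix(residuals)
  n <- nrow(X)
  if (n < 2) stop("need more than one timepoint", call. = FALSE)
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / (n - 1)
  v <- diag(S)
  if (any(v <= 1e-12 * max(v, 1e-12))) {
    warning("degenerate-voxel: near-zero residual variance; ridge added")
    ridge <- 1e-8 * max(v, 1e-8)
    diag(S) <- v + ridge
    v <- diag(S)
  }
  if (identical(gamma, "auto")) {
    # sampling variance of each entry s_ij from the per-timepoint products
    # w_t = x_ti x_tj: var(s_ij) = n/(n-1)^3 * sum_t (w_t - wbar)^2, expanded
    # so it vectorizes as crossprods
    wbar <- S * (n - 1) / n
    sumsq <- crossprod(Xc^2) - 2 * wbar * crossprod(Xc) + n * wbar^2
    varS <- n / (n - 1)^3 * sumsq
    off <- upper.tri(S)
    num <- sum(varS[off])
    den <- sum(S[off]^2)
    gamma <- if (den <= 0) 1 else min(1, max(0, num / den))
  }
  stopifnot(is.numeric(gamma), gamma >= 0, gamma <= 1)
  sigma <- (1 - gamma) * S
  diag(sigma) <- v
  structure(list(sigma = sigma, gamma = gamma, dof = n - 1),
            class = "noise_cov")
}

#' @export
print.noise_cov <- function(x, ...) {
  cat(sprintf("<noise_cov> %d voxels, gamma = %.3f, dof = %d\n",
              nrow(x$sigma), x$gamma, x$dof))
  invisible(x)
}

# whiten a condition x voxel beta matrix: B %*% U^{-1} with Sigma = U'U
whiten_betas <- function(B, cov) {
  U <- chol(cov$sigma)
  t(backsolve(U, t(B), transpose = TRUE))
}

#' Cross-validated Mahalanobis (crossnobis) RDM
#'
#' Unbiased multivariate distances between condition patterns: for each
#' unordered pair of runs (m, n) the condition-difference patterns are
#' whitened by the noise covariance and their inner product taken, then
#' averaged over run pairs and divided by the voxel count P so estimates
#' are comparable across ROI sizes,
#' `d(i,j) = mean_{m<n} (b_i^m - b_j^m)' Sigma^-1 (b_i^n - b_j^n) / P`.
#' Because the two factors come from independent runs the estimate has zero
#' mean in the absence of signal and may legitimately be negative.
#'
#' @param betas 3-D array, run x condition x voxel (4 conditions).
#' @param cov A [shrinkage_covariance()] object (pooled across runs), a list
#'   of one per run, or `NULL` for identity (cross-validated squared
#'   Euclidean distance / P).
#' @return An [rdm()] of type `"crossnobis"` with `meta` recording
#'   `n_runs`, `n_voxels` and `normalization = "per-voxel"`.
#' @export
crossnobis_rdm <- function(betas, cov = NULL) {
  stopifnot(length(dim(betas)) == 3)
  n_runs <- dim(betas)[1]
  n_cond <- dim(betas)[2]
  P <- dim(betas)[3]
  if (n_runs < 2) stop("no-crossvalidation-possible: need at least 2 runs", call. = FALSE)
  stopifnot(n_cond == 4)
  wb <- vector("list", n_runs)
  for (m in seq_len(n_runs)) {
    B <- matrix(betas[m, , ], n_cond, P)
    wb[[m]] <- if (is.null(cov)) {
      B
    } else if (inherits(cov, "noise_cov")) {
      whiten_betas(B, cov)
    } else {
      whiten_betas(B, cov[[m]])
    }
  }
  pairs <- canonical_pairs()
  d <- numeric(6)
  n_pairs <- 0L
  acc <- numeric(6)
  for (m in seq_len(n_runs - 1)) {
    for (n2 in (m + 1):n_runs) {
      n_pairs <- n_pairs + 1L
      for (k in seq_len(6)) {
        i <- pairs[k, "i"]; j <- pairs[k, "j"]
        acc[k] <- acc[k] +
          sum((wb[[m]][i, ] - wb[[m]][j, ]) * (wb[[n2]][i, ] - wb[[n2]][j, ]))
      }
    }
  }
  d <- acc / n_pairs / P
  rdm(d, type = "crossnobis",
      meta = list(n_runs = n_runs, n_voxels = P, normalization = "per-voxel"))
}

#' Mean positivity of a cross-validated RDM
#'
#' Cross-validated distances are unbiased, so a positive mean across the six
#' state pairs indicates that the matrix is driven by condition responses
#' that are consistent across runs rather than by noise. Used to define the
#' consistent-pattern subject subset in robustness checks.
#'
#' @param x An [rdm()].
#' @return List with `mean` (mean of the canonical 6-vector) and `positive`.
#' @export
mean_rdm_positivity <- function(x) {
  m <- mean(rdm_vec(x))
  list(mean = m, positive = m > 0)
}

#' Permutation-based reliability voxel selection
#'
#' Splits runs into two halves (odd/even by default), computes each voxel's
#' condition-response profile (mean beta per condition) in each half, and
#' scores reliability as the Pearson correlation of the two profiles. A
#' null distribution per voxel is built by shuffling condition labels
#' independently within each run; voxels whose reliability exceeds the
#' `1 - alpha` null quantile are retained.
#'
#' @param betas 3-D array, run x condition x voxel.
#' @param n_perm Number of label permutations (must be >= 1).
#' @param alpha Selection level (default 0.05).
#' @param split `"odd_even"` or `"random"`.
#' @param seed Optional integer seed.
#' @return Logical voxel mask with attribute `reliability` (observed per-
#'   voxel correlations).
#' @export
reliability_voxel_mask <- function(betas, n_perm = 1000, alpha = 0.05,
                                   split = c("odd_even", "random"),
                                   seed = NULL) {
  split <- match.arg(split)
  stopifnot(length(dim(betas)) == 3)
  n_runs <- dim(betas)[1]
  n_cond <- dim(betas)[2]
  if (n_runs < 2) stop("need at least 2 runs", call. = FALSE)
  if (n_cond < 2) stop("undefined-reliability: need at least 2 conditions", call. = FALSE)
  if (n_perm < 1) stop("n_perm must be at least 1", call. = FALSE)
  with_seed(seed, {
    idx <- seq_len(n_runs)
    half1 <- if (split == "odd_even") idx[idx %% 2 == 1] else sort(sample(idx, floor(n_runs / 2)))
    half2 <- setdiff(idx, half1)
    rel_of <- function(b) {
      p1 <- apply(b[half1, , , drop = FALSE], c(2, 3), mean)
      p2 <- apply(b[half2, , , drop = FALSE], c(2, 3), mean)
      p1 <- sweep(p1, 2, colMeans(p1))
      p2 <- sweep(p2, 2, colMeans(p2))
      num <- colSums(p1 * p2)
      den <- sqrt(colSums(p1^2) * colSums(p2^2))
      ifelse(den > 0, num / den, 0)
    }
    obs <- rel_of(betas)
    exceed <- matrix(0, n_perm, dim(betas)[3])
    bp <- betas
    for (p in seq_len(n_perm)) {
      for (r in seq_len(n_runs)) bp[r, , ] <- betas[r, sample.int(n_cond), ]
      exceed[p, ] <- rel_of(bp)
    }
    thr <- apply(exceed, 2, stats::quantile, probs = 1 - alpha, names = FALSE)
    mask <- obs > thr
    attr(mask, "reliability") <- obs
    mask
  })
}

#' Noise ceilings for model-RDM correlations
#'
#' Bounds on the best group-level model correlation achievable given
#' between-subject variability. The upper ceiling is the mean over subjects
#' of the tie-corrected Spearman correlation between each subject's RDM and
#' the group-mean RDM including that subject; the lower ceiling uses the
#' leave-one-out group mean.
#'
#' @param subject_rdms List of at least 3 [rdm()] objects.
#' @return List with `lower` and `upper`.
#' @export
noise_ceilings <- function(subject_rdms) {
  stopifnot(length(subject_rdms) >= 3)
  V <- vapply(subject_rdms, rdm_vec, numeric(6))
  if (any(apply(V, 2, stats::sd) == 0)) {
    stop("undefined-correlation: constant subject RDM", call. = FALSE)
  }
  n <- ncol(V)
  gm <- rowMeans(V)
  upper <- mean(vapply(seq_len(n), function(s) spearman_tc(V[, s], gm), numeric(1)))
  lower <- mean(vapply(seq_len(n), function(s) {
    loo <- rowMeans(V[, -s, drop = FALSE])
    spearman_tc(V[, s], loo)
  }, numeric(1)))
  list(lower = lower, upper = upper)
}
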