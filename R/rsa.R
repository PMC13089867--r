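#' Tie-corrected Spearman rank correlation
#'
#' Pearson correlation of midranks: tied values receive the average of the
#' ranks they occupy. On tie-free inputs this equals the classical Spearman
#' formula `1 - 6 * sum(d^2) / (n (n^2 - 1))`.
#'
#' @param x,y Numeric vectors of equal length (>= 3), neither constant.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_tc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined-correlation: constant input", call. = FALSE)
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  stats::cor(rx, ry)
}

#' Partial tie-corrected Spearman correlation
#'
#' Removes the rank-level influence of one or more covariate vectors from
#' the correlation between `x` and `y` using the classical recursion
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`, applied
#' covariate by covariate on tie-corrected Spearman correlations. The
#' result is order-invariant; this is asserted at run time (an order effect
#' beyond round-off indicates degenerate covariates).
#'
#' @param x,y Numeric vectors (typically canonical 6-vectors of RDMs).
#' @param covariates List of covariate vectors (may be empty).
#' @param tol Tolerance for the order-invariance assertion.
#' @return Partial correlation in `[-1, 1]`.
#' @export
partial_spearman <- function(x, y, covariates = list(), tol = 1e-8) {
  if (!length(covariates)) return(spearman_tc(x, y))
  vars <- c(list(x = x, y = y), covariates)
  k <- length(vars)
  R <- matrix(1, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    R[i, j] <- R[j, i] <- spearman_tc(vars[[i]], vars[[j]])
  }
  val <- partial_recursion(R, 1, 2, seq_len(k)[-(1:2)])
  if (length(covariates) > 1) {
    alt <- partial_recursion(R, 1, 2, rev(seq_len(k)[-(1:2)]))
    if (abs(val - alt) > tol) {
      stop("degenerate-covariate: partial correlation depends on covariate order",
           call. = FALSE)
    }
  }
  val
}

# recursive partialling of covariates in the given order, on a correlation
# matrix R
partial_recursion <- function(R, i, j, zs) {
  if (!length(zs)) return(R[i, j])
  z <- zs[1]
  rest <- zs[-1]
  rxy <- partial_recursion(R, i, j, rest)
  rxz <- partial_recursion(R, i, z, rest)
  ryz <- partial_recursion(R, j, z, rest)
  den <- sqrt((1 - rxz^2) * (1 - ryz^2))
  if (!is.finite(den) || den < 1e-12) {
    stop("degenerate-covariate: covariate collinear with x or y in rank space",
         call. = FALSE)
  }
  (rxy - rxz * ryz) / den
}

#' Group-level test of model correlations
#'
#' Per-subject correlations are Fisher z-transformed (atanh) to approximate
#' normality and tested against zero with a one-sample t test.
#'
#' @param subject_r Numeric vector of per-subject correlations, all
#'   strictly inside (-1, 1), length >= 3.
#' @param side `"greater"` (one-sided, the directional default) or
#'   `"two-sided"`.
#' @return List with `t`, `p`, `df`, `mean_r` and `mean_z`.
#' @export
group_model_test <- function(subject_r, side = c("greater", "two-sided")) {
  side <- match.arg(side)
  stopifnot(length(subject_r) >= 3)
  if (any(abs(subject_r) >= 1)) stop("infinite-z: |r| = 1", call. = FALSE)
  z <- atanh(subject_r)
  n <- length(z)
  se <- stats::sd(z) / sqrt(n)
  tval <- if (se == 0) 0 else mean(z) / se
  df <- n - 1
  p <- if (side == "greater") stats::pt(tval, df, lower.tail = FALSE)
       else 2 * stats::pt(-abs(tval), df)
  list(t = tval, p = p, df = df, mean_r = mean(subject_r), mean_z = mean(z))
}

#' Bonferroni-corrected alpha level
#'
#' @param alpha Nominal level in (0, 1).
#' @param m Number of comparisons (>= 1).
#' @return `alpha / m` (e.g. 0.05/6 = 0.0083 for six pairwise state
#'   comparisons; 0.05/2 = 0.025 for two hemispheres).
#' @export
bonferroni_alpha <- function(alpha, m) {
  if (length(m) != 1 || is.na(m) || m < 1) stop("invalid m", call. = FALSE)
  stopifnot(alpha > 0, alpha < 1)
  alpha / m
}

#' Subject-wise RSA of neural against model RDMs
#'
#' For each subject's neural RDM, computes the tie-corrected Spearman
#' correlation with the target model and the partial correlation removing
#' the named covariate models, then runs the Fisher-z group test.
#'
#' @param neural_rdms List of subject [rdm()] objects (or 6-vectors).
#' @param model Target model [rdm()].
#' @param covariates Named list of covariate model [rdm()]s (may be empty).
#' @param side Test side for [group_model_test()].
#' @param alpha Nominal alpha before correction.
#' @param n_comparisons Bonferroni divisor applied to `alpha`.
#' @return Object of class `rsa_result`: tibble `subjects` (subject, r,
#'   partial_r, z), list `group` (t, p, df, ...), `corrected_alpha`,
#'   `model`, `covariate_names`, `side`.
#' @export
rsa_test <- function(neural_rdms, model, covariates = list(),
                     side = "greater", alpha = 0.05, n_comparisons = 1) {
  mv <- if (inherits(model, "rdm")) rdm_vec(model) else as.numeric(model)
  cov_v <- lapply(covariates, function(m) if (inherits(m, "rdm")) rdm_vec(m) else as.numeric(m))
  rows <- purrr::imap(neural_rdms, function(nr, s) {
    nv <- if (inherits(nr, "rdm")) rdm_vec(nr) else as.numeric(nr)
    r <- spearman_tc(nv, mv)
    pr <- partial_spearman(nv, mv, cov_v)
    tibble::tibble(subject = if (is.character(s)) s else as.character(s),
                   r = r, partial_r = pr, z = atanh(pr))
  })
  subjects <- dplyr::bind_rows(rows)
  subjects$subject <- as.character(seq_len(nrow(subjects)))
  grp <- group_model_test(subjects$partial_r, side = side)
  structure(
    list(subjects = subjects, group = grp,
         corrected_alpha = bonferroni_alpha(alpha, n_comparisons),
         model = attr(model, "type") %||% "model",
         covariate_names = names(covariates) %||% character(0),
         side = side),
    class = "rsa_result"
  )
}

#' @export
print.rsa_result <- function(x, ...) {
  cat(sprintf("<rsa_result> model '%s'%s; n = %d\n", x$model,
              if (length(x$covariate_names)) paste0(" | ", paste(x$covariate_names, collapse = ", ")) else "",
              nrow(x$subjects)))
  cat(sprintf("  mean r = %.3f, t(%d) = %.2f, p = %.4g (%s, alpha = %.4g)\n",
              x$group$mean_r, x$group$df, x$group$t, x$group$p, x$side,
              x$corrected_alpha))
  invisible(x)
}

#' @export
tidy.rsa_result <- function(x, ...) x$subjects

#' @importFrom generics glance
#' @export
generics::glance

#' @export
glance.rsa_result <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    covariates = paste(x$covariate_names, collapse = "+"),
    n = nrow(x$subjects),
    mean_r = x$group$mean_r,
    statistic = x$group$t,
    df = x$group$df,
    p.value = x$group$p,
    corrected_alpha = x$corrected_alpha,
    significant = x$group$p < x$corrected_alpha
  )
}
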