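# independent brute-force crossnobis: explicit double loop over run pairs
# and conditions, direct solve() of the covariance
oracle_crossnobis <- function(betas, sigma = NULL) {
  n_runs <- dim(betas)[1]
  P <- dim(betas)[3]
  if (is.null(sigma)) sigma <- diag(P)
  si <- solve(sigma)
  m <- matrix(0, 4, 4)
  np <- 0
  for (a in 1:(n_runs - 1)) for (b in (a + 1):n_runs) {
    np <- np + 1
    for (i in 1:4) for (j in 1:4) {
      d1 <- betas[a, i, ] - betas[a, j, ]
      d2 <- betas[b, i, ] - betas[b, j, ]
      m[i, j] <- m[i, j] + as.numeric(t(d1) %*% si %*% d2)
    }
  }
  m / np / P
}

fixed_cov <- function(sigma) {
  structure(list(sigma = sigma, gamma = 0, dof = Inf), class = "noise_cov")
}

test_that("crossnobis matches the brute-force double-loop oracle", {
  set.seed(51)
  betas <- array(rnorm(2 * 4 * 3), dim = c(2, 4, 3))
  A <- matrix(rnorm(9), 3, 3)
  sigma <- crossprod(A) + diag(3)
  est <- crossnobis_rdm(betas, fixed_cov(sigma))
  expect_lt(max(abs(unclass(est) - oracle_crossnobis(betas, sigma))), 1e-12)
  # identity covariance equals cross-validated squared Euclidean / P
  est_id <- crossnobis_rdm(betas)
  expect_lt(max(abs(unclass(est_id) - oracle_crossnobis(betas))), 1e-12)
  # more runs
  betas5 <- array(rnorm(5 * 4 * 6), dim = c(5, 4, 6))
  expect_lt(max(abs(unclass(crossnobis_rdm(betas5)) -
                      oracle_crossnobis(betas5))), 1e-12)
})

test_that("identical betas across runs give squared Euclidean distance over P", {
  set.seed(52)
  B <- matrix(rnorm(4 * 6), 4, 6)
  betas <- array(0, dim = c(3, 4, 6))
  for (r in 1:3) betas[r, , ] <- B
  est <- crossnobis_rdm(betas)
  expect_equal(unclass(est)[1, 2], sum((B[1, ] - B[2, ])^2) / 6)
  expect_equal(unclass(est), unname(as.matrix(dist(B))^2 / 6),
               ignore_attr = TRUE)
})

test_that("crossnobis is invariant to voxel permutation and needs two runs", {
  set.seed(53)
  betas <- array(rnorm(3 * 4 * 8), dim = c(3, 4, 8))
  A <- matrix(rnorm(64), 8, 8)
  sigma <- crossprod(A) + diag(8)
  perm <- sample(8)
  est1 <- crossnobis_rdm(betas, fixed_cov(sigma))
  est2 <- crossnobis_rdm(betas[, , perm, drop = FALSE],
                         fixed_cov(sigma[perm, perm]))
  expect_equal(unclass(est1), unclass(est2), tolerance = 1e-12)
  expect_error(crossnobis_rdm(betas[1, , , drop = FALSE]),
               "no-crossvalidation-possible")
})

test_that("shrinkage covariance interpolates to the diagonal and stays PD", {
  set.seed(54)
  R <- matrix(rnorm(60 * 8), 60, 8) %*% matrix(rnorm(64), 8, 8)
  full <- shrinkage_covariance(R, gamma = 1)
  expect_equal(full$sigma, diag(diag(stats::cov(R))), tolerance = 1e-12)
  none <- shrinkage_covariance(R, gamma = 0)
  expect_equal(none$sigma, stats::cov(R), tolerance = 1e-12)
  auto <- shrinkage_covariance(R)
  expect_true(auto$gamma >= 0 && auto$gamma <= 1)
  expect_silent(chol(auto$sigma))
  # iid residuals at large T converge to the identity
  big <- shrinkage_covariance(matrix(rnorm(20000 * 6), 20000, 6))
  expect_lt(max(abs(big$sigma - diag(6))), 0.05)
  # zero-variance voxel triggers the ridge warning
  Rz <- cbind(R, 0)
  expect_warning(shrinkage_covariance(Rz), "degenerate-voxel")
})

test_that("mean RDM positivity summarizes cross-validated consistency", {
  zero <- rdm(matrix(0, 4, 4))
  expect_equal(mean_rdm_positivity(zero), list(mean = 0, positive = FALSE))
  g <- fixture_graph()
  a <- affordance_rdm(g)
  expect_true(mean_rdm_positivity(a)$positive)
  neg <- rdm(-rdm_vec(a))
  expect_equal(mean_rdm_positivity(neg)$mean, -mean_rdm_positivity(a)$mean)
})

test_that("reliability selection keeps tuned voxels and rejects noise at alpha", {
  set.seed(55)
  n_runs <- 6
  tuning <- matrix(rnorm(4 * 10, sd = 3), 4, 10) # 10 tuned voxels
  betas <- array(rnorm(n_runs * 4 * 50), dim = c(n_runs, 4, 50))
  for (r in 1:n_runs) betas[r, , 1:10] <- betas[r, , 1:10] + tuning
  mask <- reliability_voxel_mask(betas, n_perm = 200, alpha = 0.05, seed = 1)
  # tuned voxels overwhelmingly retained (the coarse 4-condition label null
  # can spare the occasional symmetric tuning profile)
  expect_gte(sum(mask[1:10]), 8)
  expect_lt(mean(mask[11:50]), 0.2)
  # pure-noise retention near the nominal alpha
  null_betas <- array(rnorm(6 * 4 * 400), dim = c(6, 4, 400))
  m0 <- reliability_voxel_mask(null_betas, n_perm = 200, alpha = 0.05,
                               seed = 2)
  expect_gt(mean(m0), 0.005)
  expect_lt(mean(m0), 0.12)
  expect_error(reliability_voxel_mask(betas, n_perm = 0), "n_perm")
})

test_that("noise ceilings bracket subject consistency", {
  g <- fixture_graph()
  same <- replicate(5, affordance_rdm(g), simplify = FALSE)
  nc <- noise_ceilings(same)
  expect_equal(nc$lower, 1)
  expect_equal(nc$upper, 1)
  # lower never exceeds upper across random cohorts
  set.seed(56)
  for (i in 1:25) {
    rdms <- lapply(1:6, function(s) rdm(runif(6)))
    nci <- noise_ceilings(rdms)
    expect_lte(nci$lower, nci$upper + 1e-12)
  }
  const <- replicate(3, rdm(rep(1, 6)), simplify = FALSE)
  expect_error(noise_ceilings(const), "undefined-correlation")
})
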