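# independent oracle: partial rank correlation as the Pearson correlation of
# residuals from regressing midranks of x and y on midranks of the
# covariates
oracle_partial <- function(x, y, covs) {
  Z <- do.call(cbind, lapply(covs, rank))
  rx <- stats::resid(stats::lm(rank(x) ~ Z))
  ry <- stats::resid(stats::lm(rank(y) ~ Z))
  stats::cor(rx, ry)
}

test_that("tie-corrected Spearman equals Pearson of midranks", {
  set.seed(61)
  x <- rnorm(6)
  expect_equal(spearman_tc(x, x), 1)
  # tie-free inputs reduce to the classical formula
  for (i in 1:20) {
    a <- sample(10)
    b <- sample(10)
    d <- rank(a) - rank(b)
    classical <- 1 - 6 * sum(d^2) / (10 * 99)
    expect_equal(spearman_tc(a, b), classical)
  }
  # the affordance and link-distance vectors are exactly uncorrelated under
  # midranks
  expect_equal(spearman_tc(c(1, 1, 0, 2, 1, 1), c(2, 1, 1, 1, 1, 2)), 0)
  # agreement with the built-in tie-corrected estimator
  a <- c(1, 1, 2, 3, 3, 4)
  b <- c(2, 1, 1, 5, 4, 4)
  expect_equal(spearman_tc(a, b), cor(a, b, method = "spearman"))
  expect_error(spearman_tc(rep(1, 6), x), "undefined-correlation")
})

test_that("spearman_tc is invariant under strictly monotone transforms", {
  set.seed(62)
  for (i in 1:10) {
    x <- rnorm(8)
    y <- rnorm(8)
    r <- spearman_tc(x, y)
    expect_equal(spearman_tc(exp(x), y), r)
    expect_equal(spearman_tc(x, 3 * atan(y) - 2), r)
  }
})

test_that("recursive partial correlation matches the residual oracle", {
  set.seed(63)
  x <- rnorm(6); y <- rnorm(6); z <- rnorm(6); w <- rnorm(6)
  expect_equal(partial_spearman(x, y), spearman_tc(x, y))
  expect_equal(partial_spearman(x, y, list(z)), oracle_partial(x, y, list(z)),
               tolerance = 1e-10)
  expect_equal(partial_spearman(x, y, list(z, w)),
               oracle_partial(x, y, list(z, w)), tolerance = 1e-10)
  # covariate equal to x is degenerate
  expect_error(partial_spearman(x, y, list(x)), "degenerate-covariate")
})

test_that("an uncorrelated covariate leaves the correlation unchanged", {
  # construct a covariate with zero rank correlation to both inputs
  x <- c(1, 1, 0, 2, 1, 1) # affordance vector
  z <- c(2, 1, 1, 1, 1, 2) # link-distance vector: uncorrelated with x
  set.seed(64)
  for (i in 1:20) {
    y <- rnorm(6)
    if (abs(spearman_tc(y, z)) < 1e-12) {
      expect_equal(partial_spearman(x, y, list(z)), spearman_tc(x, y))
    }
  }
  # generic algebraic check: plug r_xz = r_yz = 0 into the recursion
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.4
  expect_equal(affordrsa:::partial_recursion(R, 1, 2, 3), 0.4)
})

test_that("the Fisher-z group test behaves under null and direction", {
  null <- group_model_test(rep(0, 10))
  expect_equal(null$t, 0)
  expect_equal(null$p, 0.5)
  expect_equal(null$df, 9)
  set.seed(65)
  r <- tanh(rnorm(20, 0.4, 0.3))
  one <- group_model_test(r, side = "greater")
  two <- group_model_test(r, side = "two-sided")
  expect_equal(two$p, 2 * min(one$p, 1 - one$p))
  # matches t.test on the z scores
  tt <- t.test(atanh(r), alternative = "greater")
  expect_equal(one$t, unname(tt$statistic))
  expect_equal(one$p, tt$p.value)
  expect_error(group_model_test(c(0.2, 1, 0.3)), "infinite-z")
  expect_error(group_model_test(c(0.2, 0.3)))
})

test_that("group test power matches the noncentral-t prediction", {
  set.seed(66)
  n <- 57
  mu <- 0.15; sdz <- 0.45
  rate <- mean(vapply(1:400, function(i) {
    r <- tanh(rnorm(n, mu, sdz))
    group_model_test(r)$p < 0.05
  }, logical(1)))
  ncp <- mu / (sdz / sqrt(n))
  predicted <- 1 - pt(qt(0.95, n - 1), n - 1, ncp = ncp)
  expect_lt(abs(rate - predicted), 0.08)
})

test_that("Bonferroni correction divides alpha by the comparison count", {
  expect_equal(round(bonferroni_alpha(0.05, 6), 4), 0.0083)
  expect_equal(bonferroni_alpha(0.05, 2), 0.025)
  expect_equal(bonferroni_alpha(0.01, 1), 0.01)
  expect_error(bonferroni_alpha(0.05, 0), "invalid")
})

test_that("rsa_test assembles subject and group results tidily", {
  g <- fixture_graph()
  set.seed(67)
  rdms <- lapply(1:12, function(i) {
    rdm(rdm_vec(affordance_rdm(g)) + rnorm(6, sd = 0.5))
  })
  res <- rsa_test(rdms, affordance_rdm(g),
                  covariates = list(linkdist = linkdist_rdm(g),
                                    magnitude = magnitude_rdm(g)),
                  n_comparisons = 2)
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(nrow(tidy(res)), 12)
  expect_true(all(abs(res$subjects$r) <= 1))
  gl <- glance(res)
  expect_equal(gl$corrected_alpha, 0.025)
  expect_identical(gl$significant, gl$p.value < 0.025)
  expect_equal(res$covariate_names, c("linkdist", "magnitude"))
})
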