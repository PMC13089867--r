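make_stream <- function(n_ms = 5000, xl = 10, xr = 20, blink_at = NULL) {
  t <- 0:n_ms
  blink <- rep(FALSE, length(t))
  if (!is.null(blink_at)) blink[t >= blink_at[1] & t <= blink_at[2]] <- TRUE
  tibble::tibble(time_ms = t, xl = xl, yl = 0, xr = xr, yr = 0, blink = blink)
}

test_that("blink scrubbing masks exactly blink plus 100 ms and averages eyes", {
  st <- make_stream(blink_at = c(1000, 1200))
  cl <- preprocess_gaze(st)
  expect_true(all(is.na(cl$x[cl$time_ms >= 900 & cl$time_ms <= 1300])))
  expect_true(all(!is.na(cl$x[cl$time_ms < 900 | cl$time_ms > 1300])))
  expect_equal(unique(cl$x[!is.na(cl$x)]), 15) # cyclopean mean of 10 and 20
  # blink-free stream equals the binocular mean everywhere
  cl2 <- preprocess_gaze(make_stream())
  expect_true(all(cl2$valid))
  expect_equal(unique(cl2$x), 15)
  allblink <- make_stream(n_ms = 300)
  allblink$blink <- TRUE
  expect_error(preprocess_gaze(allblink), "no-valid-samples")
})

test_that("epoching is alignment-exact at the native sampling step", {
  st <- make_stream(n_ms = 8000)
  st$xl <- st$time_ms
  st$xr <- st$time_ms
  cl <- preprocess_gaze(st)
  ev <- tibble::tibble(type = "stimulus", state = 2L, onset = 3.0)
  ep <- epoch_gaze(cl, ev)
  expect_equal(ncol(ep$x), 3001)
  expect_equal(ep$time_ms, -500:2500)
  # a sample recorded at onset + k ms lands at epoch time k
  expect_equal(ep$x[1, ep$time_ms == 0], 3000)
  expect_equal(ep$x[1, ep$time_ms == 750], 3750)
  expect_equal(ep$x[1, ep$time_ms == -500], 2500)
})

test_that("condition medians are robust and smoothing preserves constants", {
  time_ms <- 0:400
  n_t <- length(time_ms)
  # 15 constant trials plus one wild outlier: median unchanged
  x <- rbind(matrix(5, 15, n_t), matrix(500, 1, n_t))
  ep <- structure(list(x = x, y = x * 0, condition = rep(2L, 16),
                       time_ms = time_ms), class = "gaze_epochs")
  tc <- condition_timecourses(ep)
  expect_equal(tc$x, rep(5, n_t))
  expect_equal(tc$y, rep(0, n_t))
})

test_that("impulse response of the smoother is the truncated normalized kernel", {
  n_t <- 101
  x <- matrix(0, 1, n_t)
  x[1, 51] <- 1
  ep <- structure(list(x = x, y = x, condition = 2L, time_ms = 0:100),
                  class = "gaze_epochs")
  tc <- condition_timecourses(ep, sigma_ms = 4.25, max_window_ms = 20)
  off <- (-10):10
  k <- exp(-off^2 / (2 * 4.25^2))
  k <- k / sum(k)
  expect_equal(tc$x[41:61], k, tolerance = 1e-12)
  expect_equal(sum(tc$x), 1, tolerance = 1e-12)
  expect_true(all(tc$x[c(1:40, 62:101)] == 0))
})

test_that("lateralization is the x difference, positive for rightward skew", {
  tc <- tibble::tibble(condition = rep(c(2, 3), each = 4),
                       time_ms = rep(0:3, 2),
                       x = c(5, 6, 7, 8, 1, 2, 3, 4), y = 0)
  d <- lateralization_timecourse(tc)
  expect_equal(d$diff, rep(4, 4))
  expect_equal(lateralization_timecourse(c(1, 2), c(1, 2)), c(0, 0))
  expect_equal(lateralization_timecourse(c(1, 2), c(3, 5)),
               -lateralization_timecourse(c(3, 5), c(1, 2)))
  expect_error(lateralization_timecourse(c(1, 2), c(1, 2, 3)), "grid mismatch")
})

test_that("cluster test finds planted windows and returns valid p-values", {
  set.seed(71)
  n_sub <- 12
  time_ms <- seq(-500, 2500, by = 10)
  bump <- as.numeric(time_ms >= 900 & time_ms <= 1750)
  X <- matrix(rnorm(n_sub * length(time_ms), sd = 1), n_sub) +
    matrix(bump * 1.5, n_sub, length(time_ms), byrow = TRUE)
  res <- cluster_permutation_test(X, time_ms, n_perm = 999, seed = 5)
  sig <- res$clusters[res$clusters$p < 0.05, ]
  expect_gte(nrow(sig), 1)
  main <- sig[which.max(sig$mass), ]
  expect_lt(main$start_ms, 1100)
  expect_gt(main$end_ms, 1500)
  expect_gte(min(res$clusters$p), 1 / 1000)
  # constant-zero data produce no clusters
  res0 <- cluster_permutation_test(matrix(0, 5, 50), n_perm = 10, seed = 1)
  expect_equal(nrow(res0$clusters), 0)
  expect_error(cluster_permutation_test(X[1:2, ], time_ms), "3 subjects")
})

test_that("cluster median shift summarizes the window robustly", {
  time_ms <- 0:999
  d <- rep(3, 1000)
  expect_equal(cluster_median_shift(d, time_ms, c(100, 300)), 3)
  # robust to under half corrupted timepoints
  d2 <- d
  d2[101:190] <- 1000
  expect_equal(cluster_median_shift(d2, time_ms, c(100, 300)), 3)
  expect_error(cluster_median_shift(d, time_ms, c(2000, 3000)), "empty window")
})

test_that("window median lateralization works at any sampling rate", {
  set.seed(72)
  # coarse 10 Hz per-trial estimates, planted +8 px shift
  mk <- function(n_sub, shift) {
    dplyr::bind_rows(lapply(seq_len(n_sub), function(s) {
      dplyr::bind_rows(lapply(1:10, function(tr) {
        cond <- if (tr %% 2) 2 else 3
        tibble::tibble(subject = s, condition = cond, trial = tr,
                       time_ms = seq(850, 1800, by = 100),
                       x = rnorm(10, ifelse(cond == 2, shift / 2, -shift / 2), 2))
      }))
    }))
  }
  res <- window_median_lateralization(mk(10, 8), window = c(900, 1750))
  expect_equal(nrow(res$per_subject), 10)
  expect_lt(res$p, 0.05)
  expect_gt(mean(res$per_subject$shift), 4)
  # single trial per condition: medians equal those trials' medians
  one <- tibble::tibble(subject = 1, condition = c(2, 3), trial = c(1, 2),
                        time_ms = 1000, x = c(7, -3))
  res1 <- window_median_lateralization(one, window = c(900, 1100))
  expect_equal(res1$per_subject$x_pos, 7)
  expect_equal(res1$per_subject$x_neg, -3)
  expect_error(window_median_lateralization(one[1, ], window = c(900, 1100)),
               "missing condition")
})

test_that("brain-gaze linking is scale-invariant and tracks construction", {
  g <- fixture_graph()
  set.seed(73)
  base <- lapply(1:12, function(i) rdm(abs(rnorm(6)) + 0.1))
  shifts <- vapply(base, function(x) rdm_vec(x)[4], numeric(1)) # entry (2,3)
  res <- brain_gaze_link(base, shifts)
  expect_gt(res$r, 0.5)
  # scaling any subject's whole RDM leaves its normalized entry unchanged
  scaled <- base
  scaled[[3]] <- rdm(7.3 * rdm_vec(base[[3]]))
  res2 <- brain_gaze_link(scaled, shifts)
  expect_equal(res$distances, res2$distances, tolerance = 1e-12)
  expect_equal(res$r, res2$r, tolerance = 1e-12)
  # gaze shifts exactly proportional to normalized distances give r = 1
  res3 <- brain_gaze_link(base, res$distances * 3 + 1)
  expect_equal(res3$r, 1, tolerance = 1e-12)
})

test_that("performance correlation is affine-invariant", {
  set.seed(74)
  shifts <- rnorm(20)
  acc <- 0.7 + 0.1 * shifts
  res <- performance_correlation(shifts, acc)
  expect_equal(res$r, 1, tolerance = 1e-12)
  res_pct <- performance_correlation(shifts, 100 * acc)
  expect_equal(res$r, res_pct$r)
  expect_equal(res$p, res_pct$p)
  noisy <- performance_correlation(shifts, acc + rnorm(20, sd = 0.05))
  expect_true(abs(noisy$r) <= 1)
  expect_error(performance_correlation(shifts, rep(0.5, 20)), "constant input")
})
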