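test_that("track-length model reproduces the printed endpoints and rate", {
  # Z = 0 gives the maximum; Z = 1 gives floor(45 e^{-4.5} + 15) = 15
  expect_equal(pemtrack:::length_from_z(0), 60L)
  expect_equal(pemtrack:::length_from_z(1), 15L)
  # independent arithmetic at interior points, r = 45/10 = 4.5
  for (z in c(0.1, 0.37, 0.8)) {
    expect_equal(pemtrack:::length_from_z(z),
                 as.integer(floor(45 * exp(-4.5 * z) + 15)))
  }
  set.seed(2)
  n <- sample_track_length(10000)
  expect_equal(min(n), 15L)
  expect_lte(max(n), 60L)
  expect_equal(mean(n), 25, tolerance = 0.1)  # <N> = 25 up to flooring
})

test_that("a noiseless zero-diffusivity track stays at the origin", {
  tr <- simulate_track(D = 0, sigma = 0, n_steps = 10, acq = h_acq())
  expect_equal(tr$pos, matrix(0, 11, 2), ignore_attr = TRUE)
  expect_equal(n_steps(tr), 10L)
})

test_that("simulated displacement moments match the analytic covariance", {
  acq <- h_acq()
  D <- 0.1; sigma <- 0.05
  set.seed(19)
  n_tracks <- 2500; len <- 40
  pool <- replicate(n_tracks, {
    tr <- simulate_track(D, sigma, len, acq)
    diff(tr$pos)
  }, simplify = FALSE)
  d1 <- unlist(lapply(pool, function(m) m))        # both dims pooled
  lag <- unlist(lapply(pool, function(m) m[-len, ] * m[-1, ]))
  n <- length(d1)
  v_hat <- mean(d1^2)
  v_se <- sd(d1^2) / sqrt(n)
  expect_lt(abs(v_hat - 0.0092667), 3 * v_se)
  c_hat <- mean(lag)
  c_se <- sd(lag) / sqrt(length(lag))
  expect_lt(abs(c_hat - (-0.0014333)), 3 * c_se)
  # lag-2 covariance vanishes
  lag2 <- unlist(lapply(pool, function(m) m[1:(len - 2), ] * m[3:len, ]))
  expect_lt(abs(mean(lag2)), 3 * sd(lag2) / sqrt(length(lag2)))
})

test_that("mixture simulation honours counts, labels, and seeding", {
  acq <- h_acq()
  s1 <- simulate_tracks(D = c(0.02, 0.5), sigma = 0.05, pi = c(0.5, 0.5),
                        M = 10, acq = acq, seed = 1)
  expect_equal(as.vector(table(s1$truth$state)), c(5, 5))
  s2 <- simulate_tracks(D = c(0.01, 0.3), sigma = 0.05, pi = c(0.02, 0.98),
                        M = 100, acq = acq, seed = 1)
  expect_equal(as.vector(table(s2$truth$state)), c(2, 98))
  # labels partition all tracks exactly once
  expect_setequal(s2$truth$id, vapply(s2$tracks$tracks, `[[`, "", "id"))
  expect_equal(nrow(s2$truth), 100L)
  # same seed, same tracks
  s3 <- simulate_tracks(D = c(0.02, 0.5), sigma = 0.05, pi = c(0.5, 0.5),
                        M = 10, acq = acq, seed = 1)
  expect_identical(lapply(s1$tracks$tracks, `[[`, "pos"),
                   lapply(s3$tracks$tracks, `[[`, "pos"))
  expect_error(simulate_tracks(D = c(0.1, 0.2), sigma = 0.05,
                               pi = c(0.005, 0.995), M = 10, acq = acq),
               "too small")
})

test_that("state-switching tracks follow the per-frame Markov chain", {
  acq <- h_acq()
  set.seed(33)
  # identity transition matrix: never leaves the initial state
  r <- simulate_switching_track(D = c(0.01, 0.5), sigma = 0.05,
                                P = diag(2), n_steps = 50, acq = acq,
                                init_state = 2)
  expect_true(all(r$states == 2))
  expect_equal(n_steps(r$trajectory), 50L)
  # symmetric switching at p = 0.5: geometric dwell with mean 2 frames
  r2 <- simulate_switching_track(D = c(0.01, 0.5), sigma = 0.05,
                                 P = matrix(0.5, 2, 2), n_steps = 10000,
                                 acq = acq, n_micro = 2)
  dwell <- rle(r2$states)$lengths
  expect_equal(mean(dwell), 2, tolerance = 0.1)
  # identical states: displacement statistics match a plain track
  set.seed(34)
  r3 <- simulate_switching_track(D = c(0.2, 0.2), sigma = 0.05,
                                 P = matrix(0.5, 2, 2), n_steps = 3000,
                                 acq = acq, n_micro = 8)
  set.seed(34)
  est <- cve(r3$trajectory, acq)
  expect_equal(est$D, 0.2, tolerance = 0.15)
})
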