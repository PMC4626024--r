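test_that("E-step posteriors follow Bayes' rule per dimension", {
  acq <- h_acq()
  sim <- h_two_state(M = 15)
  st2 <- diffusive_states(c(0.02, 0.5), c(0.05, 0.05), c(0.4, 0.6), acq,
                          sort_by_D = FALSE)
  es <- e_step(sim$tracks, st2)
  # manual per-dimension Bayes from the single-track likelihoods
  manual <- sapply(1:2, function(d) {
    lw <- t(sapply(sim$tracks$tracks, function(tr) {
      dx <- displacements(tr, d)
      c(log(0.4) + loglik_displacements(dx, 0.02, 0.05, acq),
        log(0.6) + loglik_displacements(dx, 0.5, 0.05, acq))
    }))
    exp(lw - apply(lw, 1, max)) / rowSums(exp(lw - apply(lw, 1, max)))
  }, simplify = "array")
  expect_equal(es$gamma, (manual[, , 1] + manual[, , 2]) / 2,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(unname(rowSums(es$gamma)), rep(1, 15), tolerance = 1e-9)
  # complete log-likelihood sums the two per-dimension mixture lls
  ll_manual <- sum(sapply(1:2, function(d) {
    sum(sapply(sim$tracks$tracks, function(tr) {
      dx <- displacements(tr, d)
      l <- c(log(0.4) + loglik_displacements(dx, 0.02, 0.05, acq),
             log(0.6) + loglik_displacements(dx, 0.5, 0.05, acq))
      m <- max(l); m + log(sum(exp(l - m)))
    }))
  }))
  expect_equal(es$loglik, ll_manual, tolerance = 1e-8)
})

test_that("degenerate E-step cases behave as required", {
  sim <- h_two_state(M = 10)
  acq <- h_acq()
  # K = 1: all posteriors 1
  es1 <- e_step(sim$tracks, diffusive_states(0.1, 0.05, 1, acq))
  expect_equal(es1$gamma, matrix(1, 10, 1), ignore_attr = TRUE)
  # identical states: every row equals the fractions
  st <- diffusive_states(c(0.1, 0.1), c(0.05, 0.05), c(0.3, 0.7), acq,
                         sort_by_D = FALSE)
  es2 <- e_step(sim$tracks, st)
  expect_equal(es2$gamma, matrix(c(0.3, 0.7), 10, 2, byrow = TRUE),
               ignore_attr = TRUE)
})

test_that("M-step with unit weights equals the population CVE mean", {
  acq <- h_acq()
  sim <- h_two_state(M = 25)
  g <- matrix(1, 25, 1)
  st <- m_step(sim$tracks, g)
  cv <- cve(sim$tracks)
  expect_equal(st$D, mean(cv$D), tolerance = 1e-12)
  expect_equal(st$sigma^2, mean(cv$sigma2), tolerance = 1e-10)
  expect_equal(st$pi, 1)
})

test_that("M-step with hard labels gives group CVE means and exact fractions", {
  sim <- h_two_state(M = 30)
  cv <- cve(sim$tracks)
  lab <- as.integer(cv$D > median(cv$D)) + 1L
  g <- outer(lab, 1:2, "==") * 1
  st <- m_step(sim$tracks, g)
  for (k in 1:2) {
    expect_equal(sort(st$D)[k] , sort(tapply(cv$D, lab, mean))[[k]],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_equal(sum(st$pi), 1)
  expect_equal(sort(st$pi), sort(as.vector(table(lab)) / 30))
  # random soft weights still normalize exactly
  set.seed(2)
  gr <- matrix(runif(90), 30, 3)
  gr <- gr / rowSums(gr)
  expect_equal(sum(m_step(sim$tracks, gr)$pi), 1)
})

test_that("run_em honours max_iter = 0 and the K = 1 fixed point", {
  acq <- h_acq()
  sim <- h_two_state(M = 40)
  init <- diffusive_states(0.123, 0.04, 1, acq)
  r0 <- run_em(sim$tracks, init, max_iter = 0)
  expect_equal(r0$states$D, 0.123)
  expect_length(r0$loglik_trace, 1L)
  expect_equal(r0$n_iter, 0L)
  # K = 1 has no gamma dependence: one M-step reaches the fixed point,
  # which equals the closed-form population CVE
  r1 <- run_em(sim$tracks, init)
  cv <- cve(sim$tracks)
  expect_equal(r1$states$D, mean(cv$D), tolerance = 1e-12)
  expect_equal(r1$states$sigma^2, mean(cv$sigma2), tolerance = 1e-10)
  expect_lte(r1$n_iter, 3L)
  expect_true(r1$converged)
})

test_that("the EM likelihood rises to a plateau with decaying fixed-point relaxation", {
  # The covariance-based update is a moment fixed point, not an exact
  # M-step: the trace may overshoot slightly and relax back down. The
  # guaranteed behaviour is a large net rise, a final value within a hair
  # of the trace maximum, and geometrically decaying late decrements.
  sim <- h_two_state(M = 150, seed = 9)
  set.seed(21)
  for (K in c(2L, 3L)) {
    init <- random_init(sim$tracks, K)
    fit <- run_em(sim$tracks, init, max_iter = 400)
    tr <- fit$loglik_trace
    expect_gt(tr[length(tr)], tr[1])                       # net improvement
    # the net rise dwarfs any post-overshoot relaxation
    if (max(tr) > tr[length(tr)]) {
      expect_gt(tr[length(tr)] - tr[1], 10 * (max(tr) - tr[length(tr)]))
    }
    d <- diff(tr)
    neg <- d[d < 0]
    if (length(neg) >= 2) {
      # relaxation decrements shrink towards convergence
      expect_lt(abs(neg[length(neg)]), abs(neg[1]))
    }
    expect_equal(unname(rowSums(fit$gamma)), rep(1, 150), tolerance = 1e-9)
    expect_equal(sum(fit$states$pi), 1, tolerance = 1e-12)
  }
})

test_that("permuting the initial states permutes the converged solution", {
  acq <- h_acq()
  sim <- h_two_state(M = 80, seed = 13)
  init <- diffusive_states(c(0.01, 0.3), c(0.05, 0.05), c(0.6, 0.4), acq,
                           sort_by_D = FALSE)
  perm <- diffusive_states(c(0.3, 0.01), c(0.05, 0.05), c(0.4, 0.6), acq,
                           sort_by_D = FALSE)
  f1 <- run_em(sim$tracks, init, sort_states = FALSE)
  f2 <- run_em(sim$tracks, perm, sort_states = FALSE)
  expect_equal(f1$states$D, rev(f2$states$D), tolerance = 1e-9)
  expect_equal(f1$states$pi, rev(f2$states$pi), tolerance = 1e-9)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-9)
  # with sorting both give identical reported states
  f1s <- run_em(sim$tracks, init)
  f2s <- run_em(sim$tracks, perm)
  expect_equal(f1s$states$D, f2s$states$D, tolerance = 1e-9)
})

test_that("two-state parameters are recovered from a simulated population", {
  sim <- h_two_state(M = 400, seed = 31)
  truth <- diffusive_states(c(0.02, 0.5), 0.05, c(0.5, 0.5), h_acq())
  set.seed(32)
  fit <- run_em(sim$tracks, random_init(sim$tracks, 2))
  expect_equal(fit$states$D, truth$D, tolerance = 0.15)
  expect_equal(fit$states$pi, truth$pi, tolerance = 0.1)
  expect_equal(fit$states$sigma, truth$sigma, tolerance = 0.2)
})
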