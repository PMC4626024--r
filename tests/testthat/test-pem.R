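test_that("random initialization follows the quantile-midpoint rule", {
  sim <- h_two_state(M = 60, seed = 3)
  cvD <- cve(sim$tracks)$D
  cvs2 <- cve(sim$tracks)$sigma2
  for (K in c(1L, 2L, 4L)) {
    set.seed(99)
    init <- random_init(sim$tracks, K)
    # independent re-derivation of the rule
    set.seed(99)
    u <- runif(K)
    pi0 <- u / sum(u)
    lev <- cumsum(pi0) - pi0 / 2
    expect_equal(init$pi, pi0)
    expect_equal(init$D,
                 as.numeric(quantile(cvD, lev, type = 1, names = FALSE)))
    expect_equal(init$sigma, rep(sqrt(mean(cvs2)), K))
  }
  # K = 1: midpoint of the single region is the empirical median
  set.seed(1)
  i1 <- random_init(sim$tracks, 1)
  expect_equal(i1$D, as.numeric(quantile(cvD, 0.5, type = 1)))
  expect_equal(i1$pi, 1)
})

test_that("degenerate CVE distribution pins every initial diffusivity", {
  acq <- h_acq()
  # identical tracks -> all per-track CVE D equal -> any quantile equals it
  tr <- h_track(rep(c(0.1, -0.05), 10))
  ts <- track_set(rep(list(tr), 5), acq)
  set.seed(4)
  init <- random_init(ts, 3)
  expect_equal(init$D, rep(cve(tr, acq)$D, 3))
})

test_that("bootstrap resampling has the textbook exclusion rate and is reproducible", {
  sim <- h_two_state(M = 1000, seed = 6)
  set.seed(10)
  excl <- replicate(200, {
    idx <- vapply(bootstrap_resample(sim$tracks)$tracks, `[[`, "", "id")
    1 - length(unique(idx)) / 1000
  })
  expect_equal(mean(excl), (1 - 1 / 1000)^1000, tolerance = 0.01)
  # fixed seed -> identical resample
  set.seed(5); a <- bootstrap_resample(sim$tracks)
  set.seed(5); b <- bootstrap_resample(sim$tracks)
  expect_identical(vapply(a$tracks, `[[`, "", "id"),
                   vapply(b$tracks, `[[`, "", "id"))
  # M = 1: the only possible resample is the original track
  one <- sim$tracks[1]
  expect_identical(bootstrap_resample(one)$tracks[[1]]$id,
                   one$tracks[[1]]$id)
})

test_that("without perturbations pem_fit is best-of-restarts plain EM", {
  sim <- h_two_state(M = 100, seed = 8)
  set.seed(17)
  fit <- pem_fit(sim$tracks, K = 2, n_restarts = 3, n_perturb = 0)
  expect_identical(fit$restart_loglik, fit$plain_loglik)
  expect_equal(fit$loglik, max(fit$plain_loglik))
  expect_equal(fit$n_perturb_accepted, 0L)
})

test_that("perturbation never loses likelihood relative to plain EM", {
  for (s in c(23, 24, 25)) {
    sim <- h_two_state(M = 100, seed = s)
    set.seed(s + 100)
    fit <- pem_fit(sim$tracks, K = 3, n_restarts = 2, n_perturb = 3)
    expect_gte(fit$loglik, max(fit$plain_loglik, na.rm = TRUE))
  }
})

test_that("BIC scoring and model-size selection follow the stated rule", {
  expect_equal(bic_score(-1000, 3, 500), -1000 - 3 * log(500))
  expect_equal(bic_score(-1000, 3, 500), -1018.6438, tolerance = 1e-7)
  # penalty is monotone in K: equal likelihoods select the smaller model
  b <- bic_score(c(-50, -50), c(2, 3), 100)
  expect_equal(which.max(b), 1L)
  # parameter-counting variant
  expect_equal(bic_score(0, 2, 100, penalty = "parameters"),
               -2.5 * log(100))
})

test_that("a sweep on one-state data selects K = 1 and is seed-reproducible", {
  sim <- simulate_tracks(D = 0.2, sigma = 0.05, pi = 1, M = 120,
                         acq = h_acq(), seed = 12)
  f1 <- pem(sim$tracks, K = 1:3, n_restarts = 2, n_perturb = 2, seed = 7)
  expect_equal(f1$selected_K, 1L)
  expect_equal(nrow(f1$table), 3L)
  expect_true(all(diff(f1$table$K) > 0))
  f2 <- pem(sim$tracks, K = 1:3, n_restarts = 2, n_perturb = 2, seed = 7)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$table, f2$table)
})

test_that("pem methods expose the fitted model coherently", {
  sim <- h_two_state(M = 100, seed = 14)
  fit <- pem(sim$tracks, K = 1:3, n_restarts = 2, n_perturb = 2, seed = 15)
  expect_s3_class(fit, "pem")
  co <- coef(fit)
  expect_named(co, c("state", "D", "sigma", "pi"))
  expect_equal(sum(co$pi), 1, tolerance = 1e-12)
  expect_true(all(diff(co$D) > 0))  # reported sorted by D
  ll <- logLik(fit)
  expect_equal(attr(ll, "df"), 3 * fit$selected_K - 1)
  expect_equal(as.numeric(ll), fit$selected$loglik)
  pr <- predict(fit)
  expect_equal(nrow(pr), 100L)
  expect_true(all(pr$confidence >= 1 / fit$selected_K - 1e-12))
  gp <- predict(fit, type = "posterior")
  expect_equal(unname(rowSums(gp)), rep(1, 100), tolerance = 1e-9)
  # predicting on new data reuses the selected states
  newsim <- h_two_state(M = 20, seed = 16)
  prn <- predict(fit, newdata = newsim$tracks)
  expect_equal(nrow(prn), 20L)
  s <- summary(fit)
  expect_s3_class(s, "summary.pem")
  expect_output(print(s), "Model sweep")
  sims <- simulate(fit, nsim = 1, seed = 2, M = 30)
  expect_length(sims[[1]]$tracks$tracks, 30L)
})
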