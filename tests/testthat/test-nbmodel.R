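test_that("nb_loglik matches closed forms and the stats:: pmf oracle", {
  expect_equal(nb_loglik(0, mu = 1, phi = 0), -1)
  expect_equal(nb_loglik(0, mu = 1, phi = 1), log(1 / 2))
  cases <- list(
    list(y = c(2, 5, 1), mu = 2.5, phi = 0.3),
    list(y = c(0, 0, 4, 9), mu = 3.1, phi = 1.2),
    list(y = 0:10, mu = 7, phi = 0.05))
  for (cs in cases)
    expect_equal(nb_loglik(cs$y, cs$mu, cs$phi),
                 oracle_nb_ll(cs$y, cs$mu, cs$phi), tolerance = 1e-10)
  expect_error(nb_loglik(c(1, 2), mu = 0, phi = 1), "positive")
  expect_error(nb_loglik(c(1.5, 2), mu = 1, phi = 1), "integer")
})

test_that("nb_loglik is continuous in phi at the Poisson boundary", {
  for (y in list(c(0, 3, 7), c(1000, 990, 1010), c(12, 0, 0, 55))) {
    mu <- mean(y) + 0.5
    expect_lt(abs(nb_loglik(y, mu, 1e-8) - sum(dpois(y, mu, log = TRUE))),
              1e-4)
  }
})

test_that("nb_mle recovers the joint MLE found by grid search", {
  f <- nb_mle(c(3, 9, 1, 12))
  o <- oracle_nb_mle(c(3, 9, 1, 12))
  expect_equal(f$mu_hat, o$mu, tolerance = 1e-3)
  expect_equal(f$phi_hat, o$phi, tolerance = 1e-3)
  expect_equal(f$loglik, o$loglik, tolerance = 1e-6)

  set.seed(9)
  for (i in 1:4) {
    y <- rnbinom(6, mu = 8, size = 3)
    if (all(y == 0)) next
    f <- nb_mle(y)
    o <- oracle_nb_mle(y)
    expect_equal(f$phi_hat, o$phi, tolerance = 1e-3)
    expect_equal(f$mu_hat, mean(y), tolerance = 1e-8)  # profile property
  }
})

test_that("nb_mle boundary and contract cases", {
  f <- nb_mle(c(7, 7, 7, 7))
  expect_equal(f$mu_hat, 7)
  expect_equal(f$phi_hat, 0)
  expect_true(f$boundary)
  expect_error(nb_mle(c(0, 0, 0)), "all-zero")
  expect_error(nb_mle(5), "at least 2")
})

test_that("the two-group LRT is zero for identical groups, non-negative, and matches the grid oracle", {
  r0 <- lrt_statistic(c(4, 6, 5, 5), c(4, 6, 5, 5))
  expect_equal(r0$lr, 0)
  expect_equal(r0$p_chi2, 1)

  set.seed(4)
  for (i in 1:5) {
    y1 <- rnbinom(4, mu = 20, size = 2)
    y2 <- rnbinom(4, mu = 20, size = 2)
    if (all(y1 == 0) || all(y2 == 0)) next
    r <- lrt_statistic(y1, y2)
    expect_gte(r$lr, 0)
    expect_equal(r$p_chi2, exp(-r$lr / 2), tolerance = 1e-12)
  }

  y1 <- c(5, 6, 5, 4); y2 <- c(1, 25, 2, 30)
  r <- lrt_statistic(y1, y2)
  o1 <- oracle_nb_mle(y1); o2 <- oracle_nb_mle(y2)
  op <- oracle_nb_mle(c(y1, y2))
  expect_equal(r$lr, 2 * (o1$loglik + o2$loglik - op$loglik),
               tolerance = 1e-2)
})

test_that("a fit failure yields an NA gene-level result with a reason, not an error", {
  r <- lrt_statistic(c(0, 0, 0, 0), c(3, 4, 5, 6))
  expect_true(is.na(r$lr))
  expect_match(r$reason, "group1")
})

test_that("the plug-in statistic maximizes over means only and reduces to the LRT at unshrunken dispersions", {
  y1 <- c(4, 9, 2, 7); y2 <- c(11, 3, 8, 8)
  expect_equal(lrt_statistic_eb(y1, y1, 0.1, 0.1, 0.1), 0)

  # at fixed phi the maximizing mean is the sample mean: check against a
  # 1-D golden-section (optimize) oracle over mu
  for (phi in c(0, 0.05, 0.7)) {
    opt <- optimize(function(mu) oracle_nb_ll(y1, mu, phi),
                    c(0.1, 50), maximum = TRUE, tol = 1e-10)
    expect_equal(nb_loglik(y1, mean(y1), phi), opt$objective,
                 tolerance = 1e-8)
  }

  f1 <- nb_mle(y1); f2 <- nb_mle(y2); fp <- nb_mle(c(y1, y2))
  lr_eq1 <- 2 * (f1$loglik + f2$loglik - fp$loglik)
  expect_equal(lrt_statistic_eb(y1, y2, fp$phi_hat, f1$phi_hat, f2$phi_hat),
               lr_eq1, tolerance = 1e-8)
  expect_error(lrt_statistic_eb(y1, y2, -0.1, 0.1, 0.1), "non-negative")
})

test_that("dispersion estimation error shrinks as replication grows", {
  set.seed(21)
  phi_true <- 0.2; mu_true <- 60
  mae <- sapply(c(4, 20, 100), function(n) {
    err <- replicate(500, {
      y <- rnbinom(n, mu = mu_true, size = 1 / phi_true)
      if (all(y == 0)) return(NA_real_)
      abs(nb_mle(y)$phi_hat - phi_true)
    })
    mean(err, na.rm = TRUE)
  })
  expect_true(all(diff(mae) < 0))
})

test_that("the mean-only baseline detects mean shifts but not dispersion shifts", {
  set.seed(31)
  G <- 150
  y1 <- matrix(rnbinom(G * 4, mu = 100, size = 20), G, 4)
  y2_mean <- matrix(rnbinom(G * 4, mu = 300, size = 20), G, 4)
  y2_disp <- matrix(rnbinom(G * 4, mu = 100, size = 1 / 0.5), G, 4)
  m_shift <- meanonly_test(cbind(y1, y2_mean), rep(1:2, each = 4))
  d_shift <- meanonly_test(cbind(y1, y2_disp), rep(1:2, each = 4))
  expect_gt(mean(m_shift$p < 0.05, na.rm = TRUE), 0.9)
  expect_lt(mean(d_shift$p < 0.05, na.rm = TRUE), 0.3)
})
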