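test_that("the synthetic parameter pool matches its stated generator", {
  pool <- build_parameter_pool("synthetic", n_pool = 1e5, seed = 7)
  expect_equal(mean(pool$phi), 0.15, tolerance = 0.01)
  expect_true(all(pool$mu >= 1))
  expect_equal(mean(log10(pool$mu) > 2), 0.5, tolerance = 0.02)
  pool2 <- build_parameter_pool("synthetic", n_pool = 1e5, seed = 7)
  expect_identical(pool, pool2)
})

test_that("an empirical pool passes through and is validated", {
  tab <- data.frame(gene_id = c("a", "b"), mu = c(10, 200), phi = c(0, 0.2))
  pool <- build_parameter_pool(tab)
  expect_equal(pool$mu, c(10, 200))
  expect_equal(attr(pool, "provenance"), "empirical-file")
  expect_error(build_parameter_pool(data.frame(gene_id = "a", mu = -1, phi = 0.1)),
               "mu")
})

test_that("study compositions and scenario effect sizes match the design", {
  pool <- build_parameter_pool("synthetic", seed = 2)
  s1 <- simulate_study(1, n_genes = 1000, n_per_group = 4, pool, seed = 3)
  expect_equal(as.vector(table(s1$truth$scenario)), c(800, 200))
  s4 <- simulate_study(4, n_genes = 5000, n_per_group = 4, pool, seed = 3)
  expect_equal(as.vector(table(s4$truth$scenario)), c(3950, 350, 350, 350))
  expect_error(simulate_study(7, pool = pool), "study")

  big1 <- simulate_study(1, n_genes = 20000, n_per_group = 4, pool, seed = 5)
  de <- big1$truth$is_de
  # dispersion shift averages X_phi * E[Beta(2,2)] = 0.4 * 0.5
  expect_equal(mean(big1$phi2[de, 1] - big1$truth$phi1[de]), 0.2,
               tolerance = 0.01)
  expect_true(all(big1$phi2[!de, ] == big1$truth$phi1[!de]))

  big2 <- simulate_study(2, n_genes = 20000, n_per_group = 4, pool, seed = 5)
  de2 <- big2$truth$is_de
  expect_equal(mean(big2$truth$k[de2]), 2.5, tolerance = 0.05)
  # exactly the last k replicates are modified
  for (g in which(de2)[1:25]) {
    shifted <- big2$phi2[g, ] != big2$truth$phi1[g]
    k <- big2$truth$k[g]
    expect_identical(which(shifted), seq_len(4)[(4 - k + 1):4])
  }

  big3 <- simulate_study(3, n_genes = 20000, n_per_group = 4, pool, seed = 5)
  de3 <- big3$truth$is_de
  sigma1 <- sqrt(big3$truth$mu1 + big3$truth$phi1 * big3$truth$mu1^2)
  # standardized mean shift averages X_mu * E[Beta(2,4)] = 2 / 3
  expect_equal(mean((big3$mu2[de3, 1] - big3$truth$mu1[de3]) / sigma1[de3]),
               2 / 3, tolerance = 0.02)
  expect_equal(mean(big3$phi2[de3, 1] - big3$truth$phi1[de3]), 0.15,
               tolerance = 0.01)
})

test_that("simulated EE genes satisfy identity of law across groups", {
  pool <- build_parameter_pool("synthetic", seed = 8)
  sim <- simulate_study(1, n_genes = 400, n_per_group = 50, pool, seed = 9)
  m <- sim$counts$counts[!sim$truth$is_de, ]
  fp <- DESyn:::fit_context(m)
  f1 <- DESyn:::fit_context(m[, 1:50])
  f2 <- DESyn:::fit_context(m[, 51:100])
  lr <- pmax(0, 2 * (f1$loglik + f2$loglik - fp$loglik))
  p <- exp(-lr / 2)
  expect_lt(abs(mean(p < 0.05, na.rm = TRUE) - 0.05), 0.035)
})

test_that("evaluation metrics match brute-force threshold enumeration", {
  # perfect and anti-perfect separations
  de <- c(rep(TRUE, 5), rep(FALSE, 5))
  expect_equal(evaluate(c(rep(0, 5), rep(1, 5)), de)$auc, 1)
  expect_equal(evaluate(c(rep(1, 5), rep(0, 5)), de)$auc, 0)

  set.seed(55)
  for (i in 1:10) {
    sc <- round(runif(10), 1)  # force ties
    truth <- runif(10) < 0.4
    if (!any(truth) || all(truth)) next
    ev <- evaluate(sc, truth, fdr_grid = c(0.3, 0.6))
    expect_equal(ev$auc, oracle_auc(sc, truth))
    for (r in seq_len(nrow(ev$by_level))) {
      lv <- ev$by_level$level[r]
      expect_equal(ev$by_level$tp[r], sum(sc <= lv & truth))
      decl <- sum(sc <= lv)
      expect_equal(ev$by_level$actual_fdr[r],
                   if (decl > 0) sum(sc <= lv & !truth) / decl else 0)
    }
  }
  expect_error(evaluate(1:3, c(TRUE, FALSE)), "length")
})

test_that("study replication summarizes trivial callers correctly and is deterministic", {
  pool <- build_parameter_pool("synthetic", seed = 13)
  silent <- function(cm, seed) rep(1, nrow(cm$counts))
  r <- run_study_replicates(1, 4, 2, pool, silent, base_seed = 20,
                            n_genes = 100)
  expect_equal(r$per_rep$tp, c(0, 0))
  expect_equal(r$per_rep$n_declared, c(0, 0))
  expect_equal(r$per_rep$actual_fdr, c(0, 0))  # no-call convention

  oracle_caller <- function(cm, seed) {
    sim <- simulate_study(1, 100, 4, pool, seed = seed)
    ifelse(sim$truth$is_de, 0, 1)
  }
  ro <- run_study_replicates(1, 4, 2, pool, oracle_caller, base_seed = 20,
                             n_genes = 100)
  expect_equal(ro$per_rep$tpr, c(1, 1))
  expect_equal(ro$per_rep$actual_fdr, c(0, 0))
  expect_equal(ro$per_rep$auc, c(1, 1))

  r2 <- run_study_replicates(1, 4, 2, pool, silent, base_seed = 20,
                             n_genes = 100)
  expect_identical(r$per_rep, r2$per_rep)
})
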